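# Independent oracles and small fixtures shared across tests.

# matrix exponential independent of the package's eigen path
expm_oracle <- function(Q, t) as.matrix(Matrix::expm(Q * t))

# Brute-force log-likelihood: exhaustive sum over all internal-node state
# assignments (feasible for <= 4 tips and small spaces).  Mirrors the
# root-treatment conventions but shares no code with the pruning path.
oracle_loglik <- function(tree, counts, params, space,
                          root = c("weighted_by_partials", "flat")) {
  root <- match.arg(root)
  Q <- rate_matrix(params, space)
  K <- nrow(Q)
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  P_edge <- lapply(seq_len(nrow(tree$edge)),
                   function(e) expm_oracle(Q, tree$edge.length[e]))
  tip_state <- match(counts[tree$tip.label], space$counts)

  # conditional probability of tip data given each root state
  internal_ids <- n_tip + seq_len(n_node)  # root is n_tip + 1
  free_ids <- setdiff(internal_ids, n_tip + 1L)
  L_root <- numeric(K)
  grid <- if (length(free_ids) > 0) {
    as.matrix(expand.grid(rep(list(seq_len(K)), length(free_ids))))
  } else {
    matrix(0, 1, 0)
  }
  for (s in seq_len(K)) {
    total <- 0
    for (g in seq_len(nrow(grid))) {
      state <- integer(n_tip + n_node)
      state[seq_len(n_tip)] <- tip_state
      state[n_tip + 1L] <- s
      if (length(free_ids) > 0) state[free_ids] <- grid[g, ]
      pr <- 1
      for (e in seq_len(nrow(tree$edge))) {
        pr <- pr * P_edge[[e]][state[tree$edge[e, 1]], state[tree$edge[e, 2]]]
      }
      total <- total + pr
    }
    L_root[s] <- total
  }
  if (root == "flat") {
    log(mean(L_root))
  } else {
    log(sum(L_root^2) / sum(L_root))
  }
}

# stationary distribution of a generator via eigen of t(Q)
stationary_oracle <- function(Q) {
  eg <- eigen(t(Q))
  i <- which.min(abs(eg$values))
  v <- Re(eg$vectors[, i])
  v / sum(v)
}

# brute-force all-windows HPD scan (independent of hpd_interval's vectorized scan)
hpd_oracle <- function(x, mass) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  best <- c(x[1], x[n])
  best_w <- Inf
  for (i in seq_len(n - m + 1)) {
    w <- x[i + m - 1] - x[i]
    if (w < best_w - 1e-15) {
      best_w <- w
      best <- c(x[i], x[i + m - 1])
    }
  }
  best
}

# small record tables built in code
make_records <- function(species, haploid_count, genus = NA, order = NA,
                         sex_system = NA) {
  data.frame(species = species, genus = genus, order = order,
             family = NA_character_, haploid_count = haploid_count,
             sex_system = sex_system, source = NA_character_,
             stringsAsFactors = FALSE)
}

# the tree shapes used for exhaustive pruning checks
small_trees <- function() {
  list(
    two_tip = ape::read.tree(text = "(A:1.3,B:0.7);"),
    three_tip = ape::read.tree(text = "((A:0.6,B:1.1):0.8,C:1.9);"),
    four_balanced = ape::read.tree(text = "((A:0.5,B:1.2):0.9,(C:0.4,D:1.6):0.3);"),
    four_pectinate = ape::read.tree(text = "(((A:0.4,B:0.9):0.7,C:1.1):0.5,D:2.2);")
  )
}
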