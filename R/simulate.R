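#' Simulate a birth-death tree conditioned on the number of extant tips
#'
#' Constant-rate birth-death simulation started from the root split (two
#' lineages), run until the `n_tips`-th extant lineage appears and stopped
#' just before the next event, so every pendant edge has positive length;
#' pure-birth trees are ultrametric with root depth distributed as a sum
#' of exponential waits (mean `(1/birth_rate) * sum(1/(2:n_tips))`).
#' Histories that go extinct before reaching `n_tips` are rejected and
#' re-simulated; extinct side branches are pruned from accepted histories.
#'
#' @param n_tips Number of extant tips (>= 2).
#' @param birth_rate Speciation rate per lineage per My (> 0).
#' @param death_rate Extinction rate per lineage per My; must be >= 0 and
#'   strictly less than `birth_rate`.
#' @param seed Integer seed for reproducibility; `NULL` leaves the RNG
#'   state alone.
#' @param tree_depth_target If non-`NULL`, branch lengths are rescaled so
#'   the maximum root-to-tip depth equals this value (My).
#' @param max_attempts Rejection cap before giving up.
#' @return An `ape` `phylo` tree with tips `t1..tn` and branch lengths in
#'   My.
#' @export
simulate_tree <- function(n_tips, birth_rate = 0.1, death_rate = 0,
                          seed = NULL, tree_depth_target = NULL,
                          max_attempts = 1000) {
  if (n_tips < 2) stop("n_tips must be >= 2", call. = FALSE)
  if (birth_rate <= 0) stop("birth_rate must be > 0", call. = FALSE)
  if (death_rate < 0 || death_rate >= birth_rate)
    stop("death_rate must satisfy 0 <= death_rate < birth_rate", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  for (attempt in seq_len(max_attempts)) {
    tr <- sim_bd_once(n_tips, birth_rate, death_rate)
    if (!is.null(tr)) {
      if (!is.null(tree_depth_target)) {
        depth <- max(ape::node.depth.edgelength(tr))
        tr$edge.length <- tr$edge.length * (tree_depth_target / depth)
      }
      return(tr)
    }
  }
  stop("no surviving history in ", max_attempts, " attempts", call. = FALSE)
}

# one birth-death history; NULL if extinct before reaching n_tips.
# nodes are kept as a parent/children/start-time table and serialized to
# newick, then extinct tips are pruned with ape.
sim_bd_once <- function(n_tips, b, d) {
  n_nodes <- 1L
  parent <- c(NA_integer_)
  t_start <- c(0)
  t_end <- c(NA_real_)
  children <- list(integer(0))
  status <- c("internal")  # internal | alive | extinct
  grow <- function() {
    n_nodes <<- n_nodes + 1L
    parent[n_nodes] <<- NA_integer_
    t_start[n_nodes] <<- NA_real_
    t_end[n_nodes] <<- NA_real_
    children[[n_nodes]] <<- integer(0)
    status[n_nodes] <<- "alive"
    n_nodes
  }
  # root split at time 0
  alive <- integer(0)
  for (k in 1:2) {
    id <- grow()
    parent[id] <- 1L
    t_start[id] <- 0
    alive <- c(alive, id)
  }
  now <- 0
  while (length(alive) < n_tips) {
    na <- length(alive)
    if (na == 0) return(NULL)
    now <- now + rexp(1, na * (b + d))
    who <- alive[sample.int(na, 1)]
    if (runif(1) < b / (b + d)) {
      status[who] <- "internal"
      t_end[who] <- now
      alive <- setdiff(alive, who)
      for (k in 1:2) {
        id <- grow()
        parent[id] <- who
        t_start[id] <- now
        alive <- c(alive, id)
      }
    } else {
      status[who] <- "extinct"
      t_end[who] <- now
      alive <- setdiff(alive, who)
    }
  }
  # cut the tree just before the next event so pendant edges have
  # positive length (the n-tip interval's full exponential wait)
  now <- now + rexp(1, length(alive) * (b + d))
  t_end[alive] <- now

  tip_no <- 0L
  ext_no <- 0L
  label <- character(n_nodes)
  for (i in seq_len(n_nodes)) {
    if (status[i] == "alive") {
      tip_no <- tip_no + 1L
      label[i] <- paste0("t", tip_no)
    } else if (status[i] == "extinct") {
      ext_no <- ext_no + 1L
      label[i] <- paste0("ext", ext_no)
    }
  }
  as_newick <- function(i) {
    len <- if (is.na(parent[i])) 0 else t_end[i] - t_start[i]
    if (status[i] == "internal") {
      kids <- paste(vapply(children[[i]], as_newick, ""), collapse = ",")
      sprintf("(%s):%.10g", kids, len)
    } else {
      sprintf("%s:%.10g", label[i], len)
    }
  }
  for (i in seq_len(n_nodes))
    if (!is.na(parent[i]))
      children[[parent[i]]] <- c(children[[parent[i]]], i)
  tr <- ape::read.tree(text = paste0(as_newick(1L), ";"))
  if (ext_no > 0) {
    tr <- ape::keep.tip(tr, paste0("t", seq_len(tip_no)))
  }
  tr
}

# Gillespie simulation of the count process along one branch.
# Returns the end count and a data.frame of events (time measured from
# the branch start).
simulate_branch <- function(count, t_total, params, space, scale = 1) {
  ev <- list()
  t <- 0
  n <- count
  repeat {
    d <- if (n > space$min_count) params$delta * scale else 0
    g <- if (n < space$max_count) params$gamma * scale else 0
    p_allowed <- if (space$boundary_policy == "truncate_to_max") {
      n < space$max_count
    } else {
      2L * n <= space$max_count
    }
    p <- if (p_allowed) params$rho * scale else 0
    total <- d + g + p
    if (total <= 0) break
    t <- t + rexp(1, total)
    if (t > t_total) break
    type <- sample(c("fusion", "fission", "polyploidy"), 1, prob = c(d, g, p))
    n_new <- switch(type,
                    fusion = n - 1L,
                    fission = n + 1L,
                    polyploidy = min(2L * n, space$max_count))
    ev[[length(ev) + 1L]] <- data.frame(time = t, event = type,
                                        count_before = n, count_after = n_new)
    n <- n_new
  }
  events <- if (length(ev) == 0) {
    data.frame(time = numeric(0), event = character(0),
               count_before = integer(0), count_after = integer(0))
  } else {
    do.call(rbind, ev)
  }
  list(count = n, events = events)
}

#' Simulate chromosome counts along a phylogeny
#'
#' Forward Gillespie simulation of the fusion/fission/polyploidy chain
#' down the tree from a root count: on a lineage at count n the total
#' event rate is `delta` (if n is above the smallest state) plus `gamma`
#' (if below the largest) plus `rho` (where doubling is allowed under the
#' space's boundary policy), and the event type is drawn proportionally.
#' The generative process is exactly the chain whose generator
#' [rate_matrix()] builds, so simulated data can be used for
#' parameter-recovery experiments against the inference machinery.
#'
#' @param tree An `ape` `phylo` tree, branch lengths in My.
#' @param params A [rate_params()] object (true rates).
#' @param root_count Haploid count at the root; must lie in `space`.
#' @param space A [build_state_space()] object (boundaries of the
#'   simulation).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.  Branches
#'   are simulated in cladewise edge order from one stream, so identical
#'   tree + seed gives identical output.
#' @param edge_rate_scale Optional numeric vector, one multiplier per edge
#'   (in `tree$edge` order), scaling all three rates on that edge; used to
#'   plant fast-evolving subclades.
#' @return List with `tip_counts` (named integer vector) and `events`
#'   (data.frame: `edge`, `node`, `time` from branch start, `event`,
#'   `count_before`, `count_after`).
#' @export
simulate_counts <- function(tree, params, root_count, space, seed = NULL,
                            edge_rate_scale = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(params, "rate_params"),
            inherits(space, "chrom_space"))
  if (!root_count %in% space$counts)
    stop("root_count outside the state space", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  if (is.null(edge_rate_scale)) edge_rate_scale <- rep(1, nrow(tree$edge))
  stopifnot(length(edge_rate_scale) == nrow(tree$edge))

  state <- rep(NA_integer_, n_tip + tree$Nnode)
  state[n_tip + 1L] <- as.integer(root_count)
  logs <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    pa <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    res <- simulate_branch(state[pa], tree$edge.length[e], params, space,
                           scale = edge_rate_scale[e])
    state[ch] <- res$count
    if (nrow(res$events) > 0) {
      res$events$edge <- e
      res$events$node <- ch
      logs[[e]] <- res$events[, c("edge", "node", "time", "event",
                                  "count_before", "count_after")]
    }
  }
  events <- do.call(rbind, logs[!vapply(logs, is.null, TRUE)])
  if (is.null(events))
    events <- data.frame(edge = integer(0), node = integer(0),
                         time = numeric(0), event = character(0),
                         count_before = integer(0), count_after = integer(0))
  rownames(events) <- NULL
  list(tip_counts = setNames(state[seq_len(n_tip)], tree$tip.label),
       events = events)
}

#' Simulate a genus-structured sex-chromosome system table
#'
#' Generates genera that each contain both an ancestral-system and a
#' derived-system subset of species.  In a planted share of genera --
#' exactly `round(fusion_fraction * n_genera)` of them -- the derived
#' subset's mean autosome count is one less than the ancestral subset's
#' (the signature of an autosome fusing to the ancestral sex chromosome);
#' in the remaining genera the derived mean is equal to or above the
#' ancestral mean.
#'
#' @param n_genera Number of genera.
#' @param species_per_genus Species per genus (>= 2; split between the two
#'   systems).
#' @param fusion_fraction Fraction of genera with the fusion signature, in
#'   \[0, 1\].
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param ancestral,derived System labels (defaults `"XO"`, `"XY"`).
#' @return A `data.frame` with columns `genus`, `species`, `sex_system`,
#'   `autosome_count`; attribute `n_fused` records the planted count.
#' @export
simulate_sexsystem_table <- function(n_genera, species_per_genus = 4,
                                     fusion_fraction = 0.5, seed = NULL,
                                     ancestral = "XO", derived = "XY") {
  if (species_per_genus < 2) stop("species_per_genus must be >= 2", call. = FALSE)
  if (fusion_fraction < 0 || fusion_fraction > 1)
    stop("fusion_fraction must be in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_fused <- round(fusion_fraction * n_genera)
  fused <- seq_len(n_genera) %in% sample.int(n_genera, n_fused)
  n_anc <- ceiling(species_per_genus / 2)
  n_der <- species_per_genus - n_anc
  rows <- lapply(seq_len(n_genera), function(g) {
    a <- sample(8:15, 1)
    der_a <- if (fused[g]) a - 1L else a + sample(0:1, 1)
    data.frame(genus = sprintf("genus_%03d", g),
               species = sprintf("genus_%03d sp%02d", g, seq_len(species_per_genus)),
               sex_system = c(rep(ancestral, n_anc), rep(derived, n_der)),
               autosome_count = c(rep(a, n_anc), rep(der_a, n_der)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_fused") <- n_fused
  out
}
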