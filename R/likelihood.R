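#' Likelihood evaluation settings
#'
#' @param root_treatment How tip partial likelihoods are combined with a
#'   root-state distribution: `"weighted_by_partials"` (default; weights
#'   proportional to the root partials themselves, the convention of
#'   likelihood-based comparative frameworks), `"flat"` (uniform over
#'   states), or `"fixed"` (root conditioned on a known count,
#'   `root_state`; used in simulation studies where the generating root
#'   count is known, making the inferential model identical to the
#'   generative one).
#' @param root_state Haploid count the root is conditioned on; required
#'   when `root_treatment = "fixed"`, ignored otherwise.
#' @return A list of class `"likelihood_settings"`.
#' @export
likelihood_settings <- function(root_treatment = c("weighted_by_partials", "flat", "fixed"),
                                root_state = NULL) {
  root_treatment <- match.arg(root_treatment)
  if (root_treatment == "fixed" && is.null(root_state))
    stop("root_treatment = \"fixed\" requires root_state", call. = FALSE)
  structure(list(root_treatment = root_treatment,
                 root_state = root_state,
                 log_scaling = TRUE,
                 matrix_exponential_method = "eigen (Pade fallback)"),
            class = "likelihood_settings")
}

#' Transition probability matrix of the chromosome chain
#'
#' Computes `expm(Q t)` for the generator built from `params` and `space`.
#' Uses an eigendecomposition when the eigenbasis is well conditioned and
#' a Pade matrix exponential otherwise; tiny negative entries from
#' round-off are clamped to zero and rows renormalized (relative error
#' well below 1e-10).
#'
#' @param params A [rate_params()] object.
#' @param space A [build_state_space()] object.
#' @param t Elapsed time in millions of years (>= 0).
#' @return A stochastic matrix with rows and columns labelled by count.
#' @export
transition_matrix <- function(params, space, t) {
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  Q <- rate_matrix(params, space)
  K <- nrow(Q)
  P <- NULL
  eg <- eigen(Q)
  Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
  if (!is.null(Vi)) {
    recon <- Re(eg$vectors %*% (eg$values * Vi))
    qn <- max(sqrt(sum(Q^2)), 1e-12)
    if (sqrt(sum((recon - Q)^2)) / qn <= 1e-9)
      P <- Re(eg$vectors %*% (exp(eg$values * t) * Vi))
  }
  if (is.null(P)) P <- as.matrix(Matrix::expm(Q * t))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}

# closure evaluating the pruning log-likelihood for varying rates on a
# fixed matched dataset; tree bookkeeping done once, reused across the
# thousands of MCMC evaluations
make_loglik <- function(matched, space, settings = likelihood_settings()) {
  tree <- ape::reorder.phylo(matched$tree, "postorder")
  counts <- matched$counts[tree$tip.label]
  outside <- names(counts)[!counts %in% space$counts]
  if (length(outside) > 0)
    stop("tip count(s) outside the state space for tip(s): ",
         paste(outside, collapse = ", "), call. = FALSE)
  K <- space$n_states
  n_tip <- length(tree$tip.label)
  tip_partials <- matrix(0, K, n_tip)
  tip_partials[cbind(state_index(space, counts), seq_len(n_tip))] <- 1
  edge <- tree$edge
  storage.mode(edge) <- "integer"
  root_type <- switch(settings$root_treatment,
                      weighted_by_partials = 0L, flat = 1L, fixed = 2L)
  root_state <- 0L
  if (root_type == 2L)
    root_state <- state_index(space, settings$root_state) - 1L
  function(params) {
    Q <- rate_matrix(params, space)
    prune_loglik_cpp(Q, c(params$delta, params$gamma, params$rho),
                     edge, tree$edge.length, n_tip, tree$Nnode,
                     tip_partials, root_type, root_state)
  }
}

#' Pruning log-likelihood of tip chromosome counts
#'
#' Post-order (pruning) computation of the probability of the observed tip
#' counts under the fusion/fission/polyploidy chain: tip partials are
#' indicator vectors at the observed count, each branch propagates
#' partials through `expm(Q t)`, and the root partials are combined with
#' the root distribution chosen in `settings`.  Partials are renormalized
#' per edge with accumulated log scalers, so long trees do not underflow.
#' Polytomies are handled natively.
#'
#' @param matched A [matched_data()] object.
#' @param params A [rate_params()] object.
#' @param space A [build_state_space()] object; default is the matched
#'   data's observed range padded by 50%.
#' @param settings A [likelihood_settings()] object.
#' @return The log-likelihood (scalar; `-Inf` when the data have
#'   probability zero, e.g. all rates zero with unequal tip counts).
#' @export
log_likelihood <- function(matched, params, space = NULL,
                           settings = likelihood_settings()) {
  stopifnot(inherits(matched, "matched_karyotypes"),
            inherits(params, "rate_params"))
  if (is.null(space))
    space <- build_state_space(matched$min_count, matched$max_count)
  make_loglik(matched, space, settings)(params)
}
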