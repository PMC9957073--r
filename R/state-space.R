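#' Rate parameters of the chromosome-number Markov model
#'
#' Bundles the three per-lineage rates, in events per lineage per million
#' years: `delta` (fusion, n to n - 1), `gamma` (fission, n to n + 1) and
#' `rho` (whole-genome duplication, n to 2n).  In the simple two-parameter
#' model `rho` is pinned at zero.
#'
#' @param delta Fusion rate (>= 0), per lineage per My.
#' @param gamma Fission rate (>= 0), per lineage per My.
#' @param rho Whole-genome duplication rate (>= 0), per lineage per My.
#'   Defaults to 0, the two-parameter model.
#' @return An object of class `"rate_params"`: a named list with elements
#'   `delta`, `gamma`, `rho`.
#' @examples
#' rate_params(0.036, 0.064)
#' @export
rate_params <- function(delta, gamma, rho = 0) {
  for (v in list(delta = delta, gamma = gamma, rho = rho)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("rates must be single non-missing numbers", call. = FALSE)
  }
  if (delta < 0 || gamma < 0 || rho < 0)
    stop("rates must be non-negative", call. = FALSE)
  structure(list(delta = delta, gamma = gamma, rho = rho),
            class = "rate_params")
}

#' @exportS3Method base::print
print.rate_params <- function(x, ...) {
  cat(sprintf("chromosome rates [/lineage/My]: delta (fusion) = %g, gamma (fission) = %g, rho (polyploidy) = %g\n",
              x$delta, x$gamma, x$rho))
  invisible(x)
}

#' Construct the chromosome-count state space
#'
#' The Markov chain lives on a contiguous range of haploid counts.  The
#' bounds are the observed range padded outwards by `padding_fraction` on
#' each side (floored at 1), wide enough that boundary effects on the
#' likelihood of interior states are negligible while keeping the
#' generator small enough for dense matrix exponentials.
#'
#' @param observed_min,observed_max Smallest and largest haploid count in
#'   the data (integers >= 1).
#' @param padding_fraction Fraction by which the observed range is padded
#'   on each side; default 0.5.  `min_count = max(1,
#'   floor(observed_min * (1 - padding_fraction)))`, `max_count =
#'   ceil(observed_max * (1 + padding_fraction))`.
#' @param boundary_policy How a doubling that would exceed `max_count` is
#'   treated: `"truncate_to_max"` (default; the excess mass lands on the
#'   largest state) or `"forbid"` (no doubling from states with
#'   2n > max_count).
#' @return An object of class `"chrom_space"`: list with `min_count`,
#'   `max_count`, `counts` (the count of each matrix row), `n_states`,
#'   `boundary_policy`.
#' @examples
#' build_state_space(9, 49)  # counts 4..74
#' @export
build_state_space <- function(observed_min, observed_max,
                              padding_fraction = 0.5,
                              boundary_policy = c("truncate_to_max", "forbid")) {
  boundary_policy <- match.arg(boundary_policy)
  if (observed_min < 1) stop("observed_min must be >= 1", call. = FALSE)
  if (observed_max < observed_min)
    stop("observed_max must be >= observed_min", call. = FALSE)
  if (padding_fraction < 0) stop("padding_fraction must be >= 0", call. = FALSE)
  mn <- max(1L, as.integer(floor(observed_min * (1 - padding_fraction))))
  mx <- as.integer(ceiling(observed_max * (1 + padding_fraction)))
  structure(list(min_count = mn, max_count = mx, counts = mn:mx,
                 n_states = mx - mn + 1L, boundary_policy = boundary_policy),
            class = "chrom_space")
}

#' @exportS3Method base::print
print.chrom_space <- function(x, ...) {
  cat(sprintf("chromosome-count state space: %d..%d (%d states), polyploidy boundary: %s\n",
              x$min_count, x$max_count, x$n_states, x$boundary_policy))
  invisible(x)
}

state_index <- function(space, count) {
  i <- match(count, space$counts)
  if (anyNA(i)) stop("count outside state space", call. = FALSE)
  i
}

#' Infinitesimal generator of the chromosome-number chain
#'
#' For a state with haploid count n: rate `delta` to n - 1 (unless n is
#' the smallest state), rate `gamma` to n + 1 (unless n is the largest),
#' and rate `rho` to 2n.  When 2n exceeds the largest state the doubling
#' either truncates there (`truncate_to_max`, added to any existing entry)
#' or is dropped (`forbid`).  The diagonal is minus the row sum of the
#' off-diagonal entries, so every row sums to zero.
#'
#' @param params A [rate_params()] object.
#' @param space A [build_state_space()] object.
#' @return A dense `n_states x n_states` matrix with counts as dimnames.
#' @examples
#' rate_matrix(rate_params(0.1, 0.2), build_state_space(1, 3, padding_fraction = 0))
#' @export
rate_matrix <- function(params, space) {
  stopifnot(inherits(params, "rate_params"), inherits(space, "chrom_space"))
  if (params$delta < 0 || params$gamma < 0 || params$rho < 0)
    stop("rates must be non-negative", call. = FALSE)
  K <- space$n_states
  counts <- space$counts
  Q <- matrix(0, K, K, dimnames = list(counts, counts))
  for (i in seq_len(K)) {
    n <- counts[i]
    if (n > space$min_count) Q[i, i - 1L] <- Q[i, i - 1L] + params$delta
    if (n < space$max_count) Q[i, i + 1L] <- Q[i, i + 1L] + params$gamma
    if (params$rho > 0) {
      if (2L * n <= space$max_count) {
        j <- state_index(space, 2L * n)
        Q[i, j] <- Q[i, j] + params$rho
      } else if (space$boundary_policy == "truncate_to_max" && n < space$max_count) {
        Q[i, K] <- Q[i, K] + params$rho
      }
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}
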