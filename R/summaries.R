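#' Normalized fusion/fission rates ratio
#'
#' `delta / (delta + gamma)`: 0.5 means fusions and fissions balanced,
#' values above 0.5 a fusion bias.  Because a uniform error in tree depth
#' rescales both rates by the same factor, the ratio is invariant to tree
#' depth and comparable across clades.  Undefined (returned as `NA`) when
#' both rates are zero.
#'
#' @param delta,gamma Fusion and fission rates (vectors recycled together;
#'   must be non-negative).
#' @return Numeric vector of ratios in \[0, 1\], `NA` where delta + gamma = 0.
#' @examples
#' normalized_ratio(0.036, 0.064)  # 0.36
#' @export
normalized_ratio <- function(delta, gamma) {
  if (any(delta < 0, na.rm = TRUE) || any(gamma < 0, na.rm = TRUE))
    stop("rates must be non-negative", call. = FALSE)
  s <- delta + gamma
  ifelse(s > 0, delta / s, NA_real_)
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval over the sorted samples containing
#' `ceiling(mass * n)` of them; ties between equally short windows are
#' broken toward the lowest start, for determinism.
#'
#' @param samples Numeric vector of at least 10 posterior draws.
#' @param mass Probability mass, in (0, 1); default 0.95.
#' @return Named numeric vector `c(low, high)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  samples <- samples[!is.na(samples)]
  n <- length(samples)
  if (n < 10) stop("need at least 10 samples for an HPD interval", call. = FALSE)
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)", call. = FALSE)
  x <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) return(c(low = x[1], high = x[n]))
  starts <- seq_len(n - m + 1)
  widths <- x[starts + m - 1] - x[starts]
  i <- which.min(widths)  # which.min takes the first (lowest-start) tie
  c(low = x[i], high = x[i + m - 1])
}

#' Summarize pooled posterior samples
#'
#' Means and HPD intervals for each rate and for the normalized rates
#' ratio.  The ratio is summarized from the per-sample ratios (the mean of
#' ratios), not the ratio of mean rates; the two differ whenever rates and
#' their sum are correlated across draws.
#'
#' @param samples A `data.frame` of posterior draws as returned by
#'   [run_mcmc()] / [run_multitree()] (columns `delta`, `gamma`, `rho`,
#'   and optionally `ratio`, recomputed if absent).
#' @param mass HPD mass (default 0.95).
#' @param model Label stored with the summary (`"2param"`/`"3param"`;
#'   inferred from whether any `rho` draw is nonzero when `NULL`).
#' @return An object of class `"posterior_summary"`: a `data.frame` with
#'   columns `parameter`, `mean`, `hpd_low`, `hpd_high`; attributes
#'   `n_samples`, `mass`, `model`.
#' @export
summarize_posterior <- function(samples, mass = 0.95, model = NULL) {
  if (nrow(samples) == 0) stop("empty sample list", call. = FALSE)
  if (!all(c("delta", "gamma", "rho") %in% names(samples)))
    stop("samples must have columns delta, gamma, rho", call. = FALSE)
  if (!"ratio" %in% names(samples))
    samples$ratio <- normalized_ratio(samples$delta, samples$gamma)
  if (is.null(model)) model <- if (any(samples$rho > 0)) "3param" else "2param"
  row1 <- function(nm) {
    x <- samples[[nm]]
    xx <- x[!is.na(x)]
    if (length(xx) == 0) return(data.frame(parameter = nm, mean = NA_real_,
                                           hpd_low = NA_real_, hpd_high = NA_real_))
    h <- if (length(xx) >= 10) hpd_interval(xx, mass) else c(low = NA_real_, high = NA_real_)
    data.frame(parameter = nm, mean = mean(xx),
               hpd_low = unname(h["low"]), hpd_high = unname(h["high"]))
  }
  out <- do.call(rbind, lapply(c("delta", "gamma", "rho", "ratio"), row1))
  rownames(out) <- out$parameter
  attr(out, "n_samples") <- nrow(samples)
  attr(out, "mass") <- mass
  attr(out, "model") <- model
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' @exportS3Method base::print
print.posterior_summary <- function(x, ...) {
  cat(sprintf("posterior summary (%s model, %d samples, %.0f%% HPD):\n",
              attr(x, "model"), attr(x, "n_samples"), 100 * attr(x, "mass")))
  for (i in seq_len(nrow(x))) {
    dp <- if (x$parameter[i] == "ratio") 2 else 3
    cat(sprintf("  %-6s mean %.*f  (HPD %.*f-%.*f)\n", x$parameter[i],
                dp, x$mean[i], dp, x$hpd_low[i], dp, x$hpd_high[i]))
  }
  invisible(x)
}

#' Combine per-clade posterior summaries into one rate table
#'
#' @param summaries Named list of [summarize_posterior()] objects (names =
#'   clade labels).
#' @return A `data.frame` with one row per clade and columns
#'   `<parameter>_mean`, `<parameter>_low`, `<parameter>_high`.
#' @export
rate_table <- function(summaries) {
  stopifnot(length(summaries) > 0, !is.null(names(summaries)))
  rows <- lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    vals <- c(clade = nm)
    for (i in seq_len(nrow(s))) {
      p <- s$parameter[i]
      vals[paste0(p, "_mean")] <- s$mean[i]
      vals[paste0(p, "_low")] <- s$hpd_low[i]
      vals[paste0(p, "_high")] <- s$hpd_high[i]
    }
    as.data.frame(as.list(vals), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  for (j in seq(2, ncol(out))) out[[j]] <- as.numeric(out[[j]])
  out
}

#' Dot-and-interval plot of per-clade posterior rates
#'
#' One row per clade: posterior mean (point) and HPD interval (segment)
#' for the chosen parameter, on a log axis for rates and a linear \[0, 1\]
#' axis for the ratio.
#'
#' @param summaries Named list of [summarize_posterior()] objects.
#' @param parameter One of `"delta"`, `"gamma"`, `"rho"`, `"ratio"`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted table.
#' @export
plot_rate_intervals <- function(summaries, parameter = "delta", ...) {
  tab <- rate_table(summaries)
  m <- tab[[paste0(parameter, "_mean")]]
  lo <- tab[[paste0(parameter, "_low")]]
  hi <- tab[[paste0(parameter, "_high")]]
  n <- nrow(tab)
  logx <- parameter != "ratio" && all(c(m, lo) > 0, na.rm = TRUE)
  xlim <- if (parameter == "ratio") c(0, 1) else range(c(lo, hi, m), na.rm = TRUE)
  graphics::plot(m, seq_len(n), xlim = xlim, ylim = c(0.5, n + 0.5),
                 log = if (logx) "x" else "", yaxt = "n", pch = 19,
                 xlab = parameter, ylab = "", ...)
  graphics::axis(2, at = seq_len(n), labels = tab$clade, las = 1)
  graphics::segments(lo, seq_len(n), hi, seq_len(n))
  invisible(tab)
}
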