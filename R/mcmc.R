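#' MCMC run settings
#'
#' Defaults reproduce the fitting protocol used throughout the package's
#' analyses: 1000-generation chains with the first 700 discarded as
#' burn-in, an Exp(rate = 2) prior on each free rate (mean 0.5/My, chosen
#' to discourage unrealistically high rates; set `prior_rate = 0.5` for
#' the mean-2 reading), starting values drawn uniformly on \[0, 1\], and --
#' when a posterior sample of trees is available -- 3 retained draws from
#' each of 100 trees, pooling to 300.
#'
#' @param n_generations Chain length (default 1000).
#' @param burnin Generations discarded (default 700); must be smaller than
#'   `n_generations`.
#' @param prior_rate Rate of the exponential prior on each free parameter
#'   (default 2).
#' @param init_lower,init_upper Bounds of the uniform initialization
#'   (default 0 and 1).
#' @param sampler `"slice"` (default; univariate slice sampling with unit
#'   initial bracket) or `"metropolis"` (random-walk on log rates).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param samples_per_tree Draws retained per tree in multi-tree pooling
#'   (default 3), taken evenly spaced over the post-burn-in window.
#' @param n_trees Number of trees drawn from a posterior tree set
#'   (default 100).
#' @return A list of class `"mcmc_settings"`.
#' @export
mcmc_settings <- function(n_generations = 1000, burnin = 700, prior_rate = 2,
                          init_lower = 0, init_upper = 1,
                          sampler = c("slice", "metropolis"),
                          seed = NULL, samples_per_tree = 3, n_trees = 100) {
  sampler <- match.arg(sampler)
  if (prior_rate <= 0) stop("prior_rate must be > 0", call. = FALSE)
  if (n_generations > 0 && burnin >= n_generations)
    stop("burnin must be smaller than n_generations", call. = FALSE)
  if (init_upper <= init_lower) stop("init_upper must exceed init_lower", call. = FALSE)
  structure(list(n_generations = as.integer(n_generations),
                 burnin = as.integer(burnin), prior_rate = prior_rate,
                 init_lower = init_lower, init_upper = init_upper,
                 sampler = sampler, seed = seed,
                 samples_per_tree = as.integer(samples_per_tree),
                 n_trees = as.integer(n_trees)),
            class = "mcmc_settings")
}

#' Log prior density of the rate parameters
#'
#' Independent Exp(`prior_rate`) priors on each free rate; `rho` is
#' excluded under the two-parameter model.  `-Inf` for any negative rate.
#'
#' @param params A [rate_params()] object (or named list with `delta`,
#'   `gamma`, `rho`).
#' @param settings An [mcmc_settings()] object (only `prior_rate` is used).
#' @param model `"2param"` (rho pinned at 0) or `"3param"`.
#' @return Log prior density (scalar).
#' @export
log_prior <- function(params, settings = mcmc_settings(),
                      model = c("2param", "3param")) {
  model <- match.arg(model)
  r <- settings$prior_rate
  free <- c(params$delta, params$gamma)
  if (model == "3param") free <- c(free, params$rho)
  if (any(free < 0)) return(-Inf)
  sum(log(r) - r * free)
}

# univariate slice sampler (stepping-out + shrinkage), lower-bounded domain
slice_update <- function(logf, x0, fx0, w = 1, lower = 0, max_steps = 50) {
  z <- fx0 - rexp(1)
  u <- runif(1)
  L <- x0 - w * u
  R <- L + w
  j <- floor(runif(1) * max_steps)
  k <- max_steps - 1 - j
  while (j > 0 && L > lower && logf(L) > z) {
    L <- L - w
    j <- j - 1
  }
  if (L < lower) L <- lower
  while (k > 0 && logf(R) > z) {
    R <- R + w
    k <- k - 1
  }
  repeat {
    x1 <- runif(1, L, R)
    fx1 <- logf(x1)
    if (fx1 >= z) return(list(x = x1, fx = fx1))
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# random-walk Metropolis on the log scale (Jacobian-corrected)
metropolis_update <- function(logf, x0, fx0, sd = 0.4) {
  if (x0 <= 0) x0 <- 1e-8
  x1 <- exp(log(x0) + rnorm(1, 0, sd))
  fx1 <- logf(x1)
  if (log(runif(1)) < (fx1 + log(x1)) - (fx0 + log(x0)))
    list(x = x1, fx = fx1)
  else list(x = x0, fx = fx0)
}

# simple split-chain diagnostic (two-half R-hat) on post-burn-in draws
split_rhat <- function(x) {
  n <- length(x)
  if (n < 20) return(NA_real_)
  h <- floor(n / 2)
  a <- x[seq_len(h)]
  b <- x[seq.int(n - h + 1, n)]
  W <- (var(a) + var(b)) / 2
  if (!is.finite(W) || W <= 0) return(1)
  B <- h * (mean(a) - mean(b))^2 / 2
  sqrt(((h - 1) / h * W + B / h) / W)
}

#' Bayesian MCMC over the chromosome-rate parameters
#'
#' Samples the posterior (exponential prior times pruning likelihood) of
#' the fusion and fission rates -- and the polyploidy rate under the
#' three-parameter model -- by per-parameter slice sampling (or random-walk
#' Metropolis).  Under `"2param"` rho is pinned at exactly 0 in every
#' sample.  A split-chain diagnostic is computed on the post-burn-in draws
#' and a warning is issued if it exceeds 1.1 (short default chains can
#' trip this; lengthen the chain rather than trusting the summary).
#'
#' @param matched A [matched_data()] object.
#' @param model `"2param"` (default) or `"3param"`.
#' @param settings An [mcmc_settings()] object.
#' @param space State space; default built from the matched data's range
#'   with 50% padding.
#' @param lik_settings A [likelihood_settings()] object.
#' @param tree_id Identifier stored with each sample (default 1).
#' @param loglik_fn Optional replacement log-likelihood, a function of a
#'   [rate_params()] object (used e.g. for prior-recovery checks with a
#'   constant likelihood).
#' @return A `data.frame` of post-burn-in samples with columns `tree_id`,
#'   `generation`, `delta`, `gamma`, `rho`, `ratio` (per-sample
#'   delta/(delta+gamma)), `log_posterior`.
#' @export
run_mcmc <- function(matched, model = c("2param", "3param"),
                     settings = mcmc_settings(), space = NULL,
                     lik_settings = likelihood_settings(), tree_id = 1L,
                     loglik_fn = NULL) {
  model <- match.arg(model)
  empty <- data.frame(tree_id = integer(0), generation = integer(0),
                      delta = numeric(0), gamma = numeric(0),
                      rho = numeric(0), ratio = numeric(0),
                      log_posterior = numeric(0))
  if (settings$n_generations == 0) return(empty)
  if (is.null(loglik_fn)) {
    stopifnot(inherits(matched, "matched_karyotypes"))
    if (is.null(space))
      space <- build_state_space(matched$min_count, matched$max_count)
    loglik_fn <- make_loglik(matched, space, lik_settings)
  }
  free <- if (model == "3param") c("delta", "gamma", "rho") else c("delta", "gamma")
  if (!is.null(settings$seed)) set.seed(settings$seed)

  par <- c(delta = 0, gamma = 0, rho = 0)
  logpost <- function(p) {
    lp <- log_prior(as.list(p), settings, model)
    if (!is.finite(lp)) return(-Inf)
    ll <- loglik_fn(rate_params(p[["delta"]], p[["gamma"]], p[["rho"]]))
    lp + ll
  }
  fx <- -Inf
  for (attempt in seq_len(100)) {
    par[free] <- runif(length(free), settings$init_lower, settings$init_upper)
    fx <- logpost(par)
    if (is.finite(fx)) break
  }
  if (!is.finite(fx))
    stop("could not find a finite initial posterior in 100 draws", call. = FALSE)

  n <- settings$n_generations
  out <- matrix(NA_real_, n, 4,
                dimnames = list(NULL, c("delta", "gamma", "rho", "log_posterior")))
  for (gen in seq_len(n)) {
    for (nm in free) {
      f1 <- function(v) {
        p <- par
        p[nm] <- v
        logpost(p)
      }
      upd <- if (settings$sampler == "slice") {
        slice_update(f1, par[[nm]], fx)
      } else {
        metropolis_update(f1, par[[nm]], fx)
      }
      par[nm] <- upd$x
      fx <- upd$fx
    }
    out[gen, ] <- c(par[["delta"]], par[["gamma"]], par[["rho"]], fx)
  }

  keep <- seq.int(settings$burnin + 1L, n)
  for (nm in free) {
    rh <- split_rhat(out[keep, nm])
    if (is.finite(rh) && rh > 1.1) {
      warning(sprintf("split-chain diagnostic for %s is %.2f (> 1.1); chain may not have converged -- consider more generations",
                      nm, rh), call. = FALSE)
      break
    }
  }
  data.frame(tree_id = tree_id, generation = keep,
             delta = out[keep, "delta"], gamma = out[keep, "gamma"],
             rho = out[keep, "rho"],
             ratio = normalized_ratio(out[keep, "delta"], out[keep, "gamma"]),
             log_posterior = out[keep, "log_posterior"])
}

#' Fit the model across a posterior sample of trees and pool draws
#'
#' With a single tree, all post-burn-in draws are retained (300 under the
#' default 1000/700 protocol).  With a tree set, `n_trees` trees are drawn
#' without replacement (with replacement, with a message, if fewer are
#' available), the chain is run on each with a per-tree seed derived as
#' master seed + tree index, and `samples_per_tree` evenly spaced
#' post-burn-in draws are retained per tree (generations 800, 900, 1000
#' under defaults), pooling to `n_trees * samples_per_tree` draws.
#'
#' @param trees A `phylo` or `multiPhylo` object.
#' @param records Karyotype `data.frame` (see [read_karyotypes()]).
#' @param model `"2param"` or `"3param"`.
#' @param settings An [mcmc_settings()] object.
#' @param granularity Tip-matching granularity, see [match_tree()].
#' @param lik_settings A [likelihood_settings()] object.
#' @return Pooled post-burn-in samples, one `data.frame` as in
#'   [run_mcmc()]; `tree_id` identifies the source tree.
#' @export
run_multitree <- function(trees, records, model = c("2param", "3param"),
                          settings = mcmc_settings(),
                          granularity = "species",
                          lik_settings = likelihood_settings()) {
  model <- match.arg(model)
  if (inherits(trees, "phylo")) trees <- list(trees)
  n_avail <- length(trees)
  if (n_avail < 1) stop("need at least one tree", call. = FALSE)

  if (n_avail == 1) {
    matched <- match_tree(trees[[1]], records, granularity)
    return(run_mcmc(matched, model, settings, lik_settings = lik_settings,
                    tree_id = 1L))
  }

  if (!is.null(settings$seed)) set.seed(settings$seed)
  idx <- if (n_avail >= settings$n_trees) {
    sample.int(n_avail, settings$n_trees)
  } else {
    message(sprintf("only %d trees available for n_trees = %d; sampling with replacement",
                    n_avail, settings$n_trees))
    sample.int(n_avail, settings$n_trees, replace = TRUE)
  }

  matched_list <- lapply(unique(idx), function(i) match_tree(trees[[i]], records, granularity))
  names(matched_list) <- as.character(unique(idx))
  rng <- range(unlist(lapply(matched_list, function(m) c(m$min_count, m$max_count))))
  space <- build_state_space(rng[1], rng[2])

  post_gens <- settings$burnin +
    round(seq_len(settings$samples_per_tree) *
            (settings$n_generations - settings$burnin) / settings$samples_per_tree)
  pooled <- lapply(idx, function(i) {
    si <- settings
    si$seed <- if (is.null(settings$seed)) NULL else settings$seed + i
    draws <- run_mcmc(matched_list[[as.character(i)]], model, si, space = space,
                      lik_settings = lik_settings, tree_id = i)
    draws[draws$generation %in% post_gens, , drop = FALSE]
  })
  out <- do.call(rbind, pooled)
  rownames(out) <- NULL
  out
}
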