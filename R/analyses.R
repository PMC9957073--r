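#' Genus with the most variable chromosome counts
#'
#' Among genera with at least `min_species` records, returns the one with
#' the largest sample variance of haploid count; ties break alphabetically.
#' Used to pick the clade whose removal is most likely to move rate
#' estimates.
#'
#' @param records Karyotype `data.frame`.
#' @param min_species Minimum number of records a genus must have.
#' @return The genus name (character scalar).
#' @export
pick_high_variance_genus <- function(records, min_species = 10) {
  ok <- !is.na(records$genus) & nzchar(records$genus)
  by_genus <- split(records$haploid_count[ok], records$genus[ok])
  by_genus <- by_genus[vapply(by_genus, length, 1L) >= min_species]
  if (length(by_genus) == 0)
    stop("no genus has at least ", min_species, " records", call. = FALSE)
  v <- vapply(by_genus, var, 1.0)
  # deterministic: max variance, alphabetical tie-break
  vmax <- max(v)
  sort(names(v)[v == vmax])[1]
}

#' Sensitivity of rate estimates to removal of one genus
#'
#' Refits the model with every tip of the named genus pruned from the
#' matched dataset (state space rebuilt from the reduced data) and reports
#' the percent change of each posterior-mean parameter,
#' `100 * (reduced - full) / full`.  Both fits share the same MCMC
#' settings and seed.
#'
#' @param matched A [matched_data()] object (the full dataset).
#' @param records Karyotype `data.frame` supplying the species-to-genus
#'   map.
#' @param genus Genus whose tips are removed.
#' @param model `"2param"` (default, the configuration used for
#'   clade-removal checks) or `"3param"`.
#' @param settings An [mcmc_settings()] object.
#' @param mass HPD mass for the reported summaries.
#' @return An object of class `"sensitivity_result"`: list with
#'   `removed_clade`, `n_removed`, `rates_full`, `rates_reduced`
#'   (posterior summaries) and `percent_change` (named vector over the
#'   free parameters and the ratio).
#' @export
sensitivity_removal <- function(matched, records, genus,
                                model = c("2param", "3param"),
                                settings = mcmc_settings(), mass = 0.95) {
  model <- match.arg(model)
  stopifnot(inherits(matched, "matched_karyotypes"))
  gen_species <- normalize_name(records$species[!is.na(records$genus) &
                                                  records$genus == genus])
  drop <- matched$tree$tip.label[normalize_name(matched$tree$tip.label) %in% gen_species]
  if (length(drop) == 0)
    stop(sprintf("genus '%s' has no tips in the matched tree", genus), call. = FALSE)
  keep <- setdiff(matched$tree$tip.label, drop)
  if (length(keep) < 2)
    stop("removal would leave fewer than 2 tips", call. = FALSE)
  reduced <- matched_data(ape::keep.tip(matched$tree, keep),
                          matched$counts[keep])

  full_draws <- run_mcmc(matched, model, settings)
  reduced_draws <- run_mcmc(reduced, model, settings)
  s_full <- summarize_posterior(full_draws, mass, model)
  s_red <- summarize_posterior(reduced_draws, mass, model)

  pars <- if (model == "3param") c("delta", "gamma", "rho", "ratio") else c("delta", "gamma", "ratio")
  pc <- setNames(100 * (s_red[pars, "mean"] - s_full[pars, "mean"]) /
                   s_full[pars, "mean"], pars)
  structure(list(removed_clade = genus, n_removed = length(drop),
                 rates_full = s_full, rates_reduced = s_red,
                 percent_change = pc),
            class = "sensitivity_result")
}

#' @exportS3Method base::print
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("sensitivity: removed %d tip(s) of genus %s\n",
              x$n_removed, x$removed_clade))
  for (nm in names(x$percent_change))
    cat(sprintf("  %-6s %+0.1f%%\n", nm, x$percent_change[nm]))
  invisible(x)
}

#' Fusion signal in sex-chromosome system transitions
#'
#' Transitions from an ancestral to a derived sex-chromosome system (XO to
#' XY, or XY to NeoXY) are typically driven by an autosome fusing with an
#' ancestral sex chromosome, which removes one autosome pair.  Within each
#' genus containing species of both systems, this statistic compares the
#' mean autosome count of the two subsets and reports the fraction of
#' genera where the derived system's mean is strictly lower.
#'
#' Autosome counts are taken from an `autosome_count` column when present;
#' otherwise they are derived as `haploid_count - offset` with a per-system
#' offset (default 1 for each of XO, XY, NeoXY: the haploid set of the
#' homogametic sex carries one sex chromosome).  Only the within-genus
#' difference matters, so any constant per-system offset convention gives
#' the same statistic.
#'
#' @param records `data.frame` with columns `genus`, `sex_system`, and
#'   `autosome_count` or `haploid_count`.
#' @param ancestral,derived Sex-system labels to compare (defaults `"XO"`
#'   and `"XY"`).
#' @param sex_offset Named numeric vector of per-system haploid-to-autosome
#'   offsets; systems absent from it are excluded.
#' @return An object of class `"sexsystem_comparison"`: list with
#'   `ancestral_system`, `derived_system`, `n_genera_with_both`,
#'   `n_genera_derived_fewer`, `fraction`.
#' @export
fusion_signal <- function(records, ancestral = "XO", derived = "XY",
                          sex_offset = c(XO = 1, XY = 1, NeoXY = 1)) {
  if (!"sex_system" %in% names(records))
    stop("records lack a sex_system column", call. = FALSE)
  if ("autosome_count" %in% names(records)) {
    auto <- records$autosome_count
  } else if ("haploid_count" %in% names(records)) {
    auto <- records$haploid_count - sex_offset[records$sex_system]
  } else {
    stop("records need an autosome_count or haploid_count column", call. = FALSE)
  }
  ok <- records$sex_system %in% c(ancestral, derived) & !is.na(auto) &
    !is.na(records$genus) & nzchar(records$genus)
  df <- data.frame(genus = records$genus[ok], system = records$sex_system[ok],
                   auto = as.numeric(auto[ok]))
  mean_anc <- tapply(df$auto[df$system == ancestral], df$genus[df$system == ancestral], mean)
  mean_der <- tapply(df$auto[df$system == derived], df$genus[df$system == derived], mean)
  both <- intersect(names(mean_anc), names(mean_der))
  if (length(both) == 0)
    stop(sprintf("no genus has both %s and %s species", ancestral, derived),
         call. = FALSE)
  fewer <- sum(mean_der[both] < mean_anc[both])
  structure(list(ancestral_system = ancestral, derived_system = derived,
                 n_genera_with_both = length(both),
                 n_genera_derived_fewer = as.integer(fewer),
                 fraction = fewer / length(both)),
            class = "sexsystem_comparison")
}

#' @exportS3Method base::print
print.sexsystem_comparison <- function(x, ...) {
  cat(sprintf("%s -> %s fusion signal: %d of %d genera (%.0f%%) with lower mean autosome count in %s\n",
              x$ancestral_system, x$derived_system, x$n_genera_derived_fewer,
              x$n_genera_with_both, 100 * x$fraction, x$derived_system))
  invisible(x)
}
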