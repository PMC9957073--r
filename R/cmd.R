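## File-in / file-out wrappers tying the pipeline together.  These back
## the inst/cli/karyorate.R command-line dispatcher; R users normally call
## the underlying functions directly.

read_trees_file <- function(path) {
  if (grepl("\\.nex(us)?$", path, ignore.case = TRUE))
    ape::read.nexus(path)
  else
    ape::read.tree(path)
}

write_run_config <- function(config, out_dir) {
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
}

#' Simulate a tree + karyotype dataset and write it to disk
#'
#' Writes `tree.nwk`, `karyotypes.csv` (species, genus, order,
#' haploid_count, sex_system), `events.csv` and `config.json` into
#' `out_dir`.
#'
#' @param out_dir Output directory (created if absent).
#' @param n_tips,birth_rate,death_rate,tree_depth_target Tree simulation
#'   parameters, see [simulate_tree()].
#' @param delta,gamma,rho True rates, see [rate_params()].
#' @param root_count Haploid count at the root.
#' @param space State space for the simulation; default `1 ..
#'   4 * root_count`.
#' @param seed Master seed (tree uses `seed`, counts `seed + 1`).
#' @return Invisibly, the simulated dataset (list with `tree`,
#'   `tip_counts`, `events`).
#' @export
cmd_simulate <- function(out_dir, n_tips = 100, birth_rate = 0.1,
                         death_rate = 0, tree_depth_target = NULL,
                         delta = 0.2, gamma = 0.2, rho = 0,
                         root_count = 12, space = NULL, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(space)) space <- build_state_space(1, 4 * root_count, padding_fraction = 0)
  params <- rate_params(delta, gamma, rho)
  tree <- simulate_tree(n_tips, birth_rate, death_rate, seed = seed,
                        tree_depth_target = tree_depth_target)
  sim <- simulate_counts(tree, params, root_count, space, seed = seed + 1)
  ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
  write.csv(data.frame(species = names(sim$tip_counts),
                       genus = sub(" .*", "", names(sim$tip_counts)),
                       order = "Simulata",
                       haploid_count = as.integer(sim$tip_counts),
                       sex_system = NA_character_),
            file.path(out_dir, "karyotypes.csv"), row.names = FALSE)
  write.csv(sim$events, file.path(out_dir, "events.csv"), row.names = FALSE)
  write_run_config(list(command = "simulate", n_tips = n_tips,
                        birth_rate = birth_rate, death_rate = death_rate,
                        tree_depth_target = tree_depth_target,
                        delta = delta, gamma = gamma, rho = rho,
                        root_count = root_count,
                        space = unclass(space)[c("min_count", "max_count", "boundary_policy")],
                        seed = seed), out_dir)
  invisible(list(tree = tree, tip_counts = sim$tip_counts, events = sim$events))
}

#' Fit the chromosome model to a tree (or tree set) and karyotype table
#'
#' Runs match, state-space construction, (multi-tree) MCMC and
#' summarization; writes `posterior.csv`, `summary.json` and `config.json`
#' to `out_dir`.
#'
#' @param tree_file Newick or nexus tree file (may hold several trees).
#' @param karyotype_file Karyotype CSV, see [read_karyotypes()].
#' @param out_dir Output directory.
#' @param model `"2param"` or `"3param"`.
#' @param settings An [mcmc_settings()] object.
#' @param granularity Tip matching granularity, see [match_tree()].
#' @param root_treatment Root handling, see [likelihood_settings()].
#' @return Invisibly, list with `samples` and `summary`.
#' @export
cmd_fit <- function(tree_file, karyotype_file, out_dir,
                    model = "2param", settings = mcmc_settings(),
                    granularity = "species",
                    root_treatment = "weighted_by_partials") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trees <- read_trees_file(tree_file)
  records <- read_karyotypes(karyotype_file)
  samples <- run_multitree(trees, records, model, settings, granularity,
                           likelihood_settings(root_treatment))
  summ <- summarize_posterior(samples, model = model)
  write.csv(samples, file.path(out_dir, "posterior.csv"), row.names = FALSE)
  jsonlite::write_json(list(model = model,
                            n_samples = attr(summ, "n_samples"),
                            mass = attr(summ, "mass"),
                            parameters = as.data.frame(summ)),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_run_config(list(command = "fit", tree_file = tree_file,
                        karyotype_file = karyotype_file, model = model,
                        granularity = granularity,
                        root_treatment = root_treatment,
                        settings = unclass(settings)), out_dir)
  invisible(list(samples = samples, summary = summ))
}

#' Clade-removal sensitivity analysis from files
#'
#' @param tree_file,karyotype_file,out_dir,model,settings,granularity As
#'   in [cmd_fit()].
#' @param genus Genus to remove; when `NULL` it is chosen automatically as
#'   the highest-variance genus with at least `min_species` records.
#' @param min_species Threshold for the automatic choice.
#' @return Invisibly, the [sensitivity_removal()] result.
#' @export
cmd_sensitivity <- function(tree_file, karyotype_file, out_dir,
                            genus = NULL, min_species = 10,
                            model = "2param", settings = mcmc_settings(),
                            granularity = "species") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trees <- read_trees_file(tree_file)
  if (inherits(trees, "multiPhylo")) trees <- trees[[1]]
  records <- read_karyotypes(karyotype_file)
  if (is.null(genus)) genus <- pick_high_variance_genus(records, min_species)
  matched <- match_tree(trees, records, granularity)
  res <- sensitivity_removal(matched, records, genus, model, settings)
  write.csv(data.frame(parameter = names(res$percent_change),
                       full_mean = res$rates_full[names(res$percent_change), "mean"],
                       reduced_mean = res$rates_reduced[names(res$percent_change), "mean"],
                       percent_change = res$percent_change),
            file.path(out_dir, "sensitivity.csv"), row.names = FALSE)
  write_run_config(list(command = "sensitivity", tree_file = tree_file,
                        karyotype_file = karyotype_file, genus = genus,
                        n_removed = res$n_removed, model = model,
                        settings = unclass(settings)), out_dir)
  invisible(res)
}

#' Sex-chromosome fusion-signal statistic from a file
#'
#' @param karyotype_file CSV with `genus`, `sex_system` and
#'   `autosome_count` or `haploid_count` columns.
#' @param out_dir Output directory.
#' @param ancestral,derived System labels, see [fusion_signal()].
#' @return Invisibly, the [fusion_signal()] result.
#' @export
cmd_sexsystem <- function(karyotype_file, out_dir,
                          ancestral = "XO", derived = "XY") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read.csv(karyotype_file, stringsAsFactors = FALSE)
  if (!"sex_system" %in% names(records))
    stop("karyotype table lacks the required sex_system column", call. = FALSE)
  res <- fusion_signal(records, ancestral, derived)
  write.csv(data.frame(ancestral_system = res$ancestral_system,
                       derived_system = res$derived_system,
                       n_genera_with_both = res$n_genera_with_both,
                       n_genera_derived_fewer = res$n_genera_derived_fewer,
                       fraction = res$fraction),
            file.path(out_dir, "sexsystem.csv"), row.names = FALSE)
  write_run_config(list(command = "sexsystem", karyotype_file = karyotype_file,
                        ancestral = ancestral, derived = derived), out_dir)
  invisible(res)
}

#' Haploid-count histogram from a file
#'
#' @param karyotype_file Karyotype CSV.
#' @param out_file Output CSV path.
#' @param by_order,pool_at See [count_histogram()].
#' @return Invisibly, the histogram table.
#' @export
cmd_histogram <- function(karyotype_file, out_file, by_order = TRUE,
                          pool_at = 100) {
  records <- read_karyotypes(karyotype_file)
  tab <- count_histogram(records, by_order, pool_at)
  dir.create(dirname(out_file), showWarnings = FALSE, recursive = TRUE)
  write.csv(tab, out_file, row.names = FALSE)
  invisible(tab)
}
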