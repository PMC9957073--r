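## Matching karyotype records to phylogeny tips.

# conservative name normalization: underscores <-> spaces, case fold,
# collapse repeated whitespace.  No fuzzy matching, so every match is
# auditable.
normalize_name <- function(x) {
  x <- tolower(gsub("_", " ", x))
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# median rounded half up, for within-species (or within-genus) count
# conflicts
median_count <- function(x) as.integer(floor(median(x) + 0.5))

#' Bundle a tree with per-tip haploid counts
#'
#' Low-level constructor used by [match_tree()] and by simulation-based
#' analyses where counts come straight from the generator rather than a
#' record table.
#'
#' @param tree An `ape` `phylo` tree, branch lengths in millions of years.
#' @param counts Named integer vector of haploid counts; names must be
#'   exactly the tip labels of `tree`.
#' @return An object of class `"matched_karyotypes"`: list with `tree`,
#'   `counts` (ordered as `tree$tip.label`), `min_count`, `max_count`.
#' @export
matched_data <- function(tree, counts) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(names(counts)) || !setequal(names(counts), tree$tip.label))
    stop("counts must be named by the tree's tip labels", call. = FALSE)
  if (any(is.na(counts)) || any(counts < 1))
    stop("all haploid counts must be >= 1", call. = FALSE)
  counts <- counts[tree$tip.label]
  structure(list(tree = tree, counts = counts,
                 min_count = min(counts), max_count = max(counts)),
            class = "matched_karyotypes")
}

#' @exportS3Method base::print
print.matched_karyotypes <- function(x, ...) {
  cat(sprintf("matched dataset: %d tips, haploid counts %d..%d\n",
              length(x$counts), x$min_count, x$max_count))
  invisible(x)
}

#' Match a phylogeny to karyotype records
#'
#' Prunes the tree to the tips that have a karyotype record (exact string
#' match after underscore/whitespace/case normalization) and attaches one
#' haploid count per retained tip.  When several records share a key the
#' median count (rounded half up) is used and a message is emitted.  With
#' `granularity = "genus"` both tip labels and records are keyed by genus
#' (one count per genus by median), for trees whose tips are genera.
#'
#' @param tree An `ape` `phylo` tree.
#' @param records Karyotype `data.frame` (see [read_karyotypes()]).
#' @param granularity Match at `"species"` (default) or `"genus"` level.
#' @return A [matched_data()] object.
#' @export
match_tree <- function(tree, records, granularity = c("species", "genus")) {
  granularity <- match.arg(granularity)
  stopifnot(inherits(tree, "phylo"))
  key <- if (granularity == "species") records$species else records$genus
  if (granularity == "genus" && all(is.na(key)))
    stop("genus-level matching requested but records carry no genus column values",
         call. = FALSE)
  ok <- !is.na(key) & nzchar(key) & !is.na(records$haploid_count)
  key <- normalize_name(key[ok])
  cnt <- records$haploid_count[ok]
  tip_key <- normalize_name(tree$tip.label)

  shared <- intersect(unique(key), unique(tip_key))
  keep <- tree$tip.label[tip_key %in% shared]
  if (length(keep) < 2)
    stop(sprintf("only %d tip(s) shared between tree and records; need >= 2 to fit the model",
                 length(keep)), call. = FALSE)
  pruned <- ape::keep.tip(tree, keep)

  by_key <- split(cnt, key)
  n_multi <- sum(vapply(by_key[shared], length, 1L) > 1)
  if (n_multi > 0)
    message(sprintf("%d matched %s key(s) had multiple records; using median count (rounded half up)",
                    n_multi, granularity))
  resolved <- vapply(by_key, median_count, 1L)
  counts <- resolved[normalize_name(pruned$tip.label)]
  names(counts) <- pruned$tip.label
  matched_data(pruned, counts)
}

#' Write a matched dataset as paired newick + CSV
#'
#' @param matched A [matched_data()] object.
#' @param prefix Output path prefix; writes `<prefix>.nwk` and
#'   `<prefix>.csv`.
#' @return Invisibly, the two paths written.
#' @export
write_matched <- function(matched, prefix) {
  stopifnot(inherits(matched, "matched_karyotypes"))
  tree_path <- paste0(prefix, ".nwk")
  csv_path <- paste0(prefix, ".csv")
  ape::write.tree(matched$tree, tree_path)
  write.csv(data.frame(species = names(matched$counts),
                       haploid_count = as.integer(matched$counts)),
            csv_path, row.names = FALSE)
  invisible(c(tree = tree_path, counts = csv_path))
}
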