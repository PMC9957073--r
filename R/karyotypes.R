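#' Read a karyotype table
#'
#' Reads a CSV of one record per species carrying taxonomy, the haploid
#' chromosome count of the homogametic sex, and an optional sex-chromosome
#' system label.  Columns `species` and `haploid_count` are required;
#' `order`, `family`, `genus`, `sex_system` and `source` are carried along
#' when present and filled with `NA` otherwise.  Rows with a missing or
#' non-positive count are dropped with a warning; the number dropped is
#' attached as attribute `"n_dropped"`.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` of records with attribute `n_dropped`.
#' @export
read_karyotypes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("species", "haploid_count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("karyotype table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("order", "family", "genus", "sex_system", "source"))
    if (!col %in% names(df)) df[[col]] <- NA_character_
  df$haploid_count <- suppressWarnings(as.numeric(df$haploid_count))
  bad <- is.na(df$haploid_count) | df$haploid_count < 1 |
    is.na(df$species) | !nzchar(df$species)
  n_dropped <- sum(bad)
  if (n_dropped > 0) {
    warning(sprintf("dropped %d record(s) with missing or non-positive haploid_count or empty species name",
                    n_dropped), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  attr(df, "n_dropped") <- n_dropped
  df
}

#' Orders with enough karyotype records for model fitting
#'
#' @param records Karyotype `data.frame` (see [read_karyotypes()]).
#' @param min_records Minimum number of records an order must have;
#'   default 150, the cut used for order-level comparative fits.
#' @return Sorted character vector of order names.
#' @export
filter_orders <- function(records, min_records = 150) {
  if (min_records < 1) stop("min_records must be >= 1", call. = FALSE)
  if (nrow(records) == 0) return(character(0))
  tab <- table(records$order[!is.na(records$order)])
  sort(names(tab)[tab >= min_records])
}

#' Tabulate haploid counts, optionally per order
#'
#' @param records Karyotype `data.frame`.
#' @param by_order Tabulate within orders (default) or pooled.
#' @param pool_at If non-`NULL`, counts `>= pool_at` are pooled into a
#'   single open-ended bin labelled e.g. `"100+"`; the count column is then
#'   character.
#' @return A `data.frame` with columns `order` (if `by_order`),
#'   `haploid_count`, `n_records`.
#' @export
count_histogram <- function(records, by_order = TRUE, pool_at = NULL) {
  empty <- if (by_order) {
    data.frame(order = character(0), haploid_count = numeric(0),
               n_records = integer(0))
  } else {
    data.frame(haploid_count = numeric(0), n_records = integer(0))
  }
  if (nrow(records) == 0) return(empty)
  cnt <- records$haploid_count
  if (!is.null(pool_at)) {
    cnt <- ifelse(cnt >= pool_at, paste0(pool_at, "+"), as.character(cnt))
  }
  if (by_order) {
    tab <- aggregate(list(n_records = rep(1L, nrow(records))),
                     by = list(order = records$order, haploid_count = cnt),
                     FUN = sum)
    tab <- tab[order(tab$order, suppressWarnings(as.numeric(tab$haploid_count))), ]
  } else {
    tab <- aggregate(list(n_records = rep(1L, nrow(records))),
                     by = list(haploid_count = cnt), FUN = sum)
    tab <- tab[order(suppressWarnings(as.numeric(tab$haploid_count))), ]
  }
  rownames(tab) <- NULL
  tab
}

#' Sample variance of haploid counts within an order
#'
#' Uses the n - 1 denominator.
#'
#' @param records Karyotype `data.frame`.
#' @param order Order name.
#' @return The sample variance (numeric scalar).
#' @export
count_variance <- function(records, order) {
  x <- records$haploid_count[!is.na(records$order) & records$order == order]
  if (length(x) < 2)
    stop(sprintf("need at least 2 records in order '%s' (have %d)", order, length(x)),
         call. = FALSE)
  var(x)
}
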