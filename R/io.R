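# CSV readers/writers for decay tables and fit results.
#
# Decay tables: one gene per row; first column the gene id, remaining
# columns the relative levels, with the time points encoded in the header
# (e.g. "t0,t5,...,t60" or plain "0,5,...,60"). The grid is taken from the
# header, not assumed, so decay datasets on other grids load unchanged.

parse_time_header <- function(nm) {
  tm <- suppressWarnings(as.numeric(gsub("[^0-9.eE+-]", "", nm)))
  if (anyNA(tm)) stop("cannot parse time points from column names: ",
                      paste(nm[is.na(tm)], collapse = ", "))
  tm
}

#' Read decay tables from CSV
#'
#' @param path CSV file: header `gene_id,t0,t5,...` (any `t<min>` or bare
#'   numeric column labels), one gene per row.
#' @param strict if `TRUE`, any invalid row aborts; otherwise invalid rows
#'   are reported with their line numbers and skipped.
#' @return list of [decay_table()] objects.
#' @export
read_decay_tables <- function(path, strict = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("need a gene id column and >= 3 time points")
  times <- parse_time_header(names(df)[-1])
  if (is.unsorted(times, strictly = TRUE) || times[1] != 0)
    stop("header time points must be strictly increasing and start at 0")
  tables <- list()
  for (i in seq_len(nrow(df))) {
    tb <- tryCatch(
      decay_table(df[[1]][i], times, as.numeric(df[i, -1])),
      error = function(e) e)
    if (inherits(tb, "error")) {
      msg <- paste0("row ", i + 1L, " (gene ", df[[1]][i], "): ",
                    conditionMessage(tb))
      if (strict) stop(msg) else warning(msg, "; row skipped")
    } else tables[[tb$gene_id]] <- tb
  }
  tables
}

#' Write decay tables to CSV
#'
#' Inverse of [read_decay_tables()]; all tables must share one time grid.
#'
#' @param tables list of [decay_table()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_decay_tables <- function(tables, path) {
  stopifnot(length(tables) >= 1L)
  times <- tables[[1]]$times
  for (tb in tables)
    if (!identical(tb$times, times))
      stop("all tables must share the same time grid to be written together")
  mat <- t(vapply(tables, `[[`, numeric(length(times)), "levels"))
  df <- data.frame(gene_id = vapply(tables, `[[`, character(1), "gene_id"),
                   mat, check.names = FALSE)
  names(df) <- c("gene_id", paste0("t", times))
  write_csv_full_precision(df, path)
  invisible(path)
}

# full-precision, locale-independent numeric formatting so that
# write -> read -> write is byte-identical
write_csv_full_precision <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    s <- formatC(x, digits = 17, format = "g")
    s[is.na(x)] <- "NA"
    trimws(s)
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write fit results to CSV
#'
#' Column order follows the reference results-table schema: gene id,
#' category (0 = exponential, 1 = slow-fast, 2 = fast-slow), transition rate
#' omega, first and second degradation rate (1/min), RSS, mean lifetime and
#' half-life (min), then the input relative levels at their time points.
#' Rates are written at full precision and round-trip losslessly through
#' [read_fit_results()].
#'
#' @param results a `"batch_fit"` object or list of `"fit_result"`s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fit_results <- function(results, path) {
  if (inherits(results, "batch_fit")) results <- results$results
  stopifnot(length(results) >= 1L)
  times <- results[[1]]$times
  for (r in results)
    if (!identical(r$times, times))
      stop("all results must share the same time grid")
  df <- data.frame(
    gene_id = vapply(results, `[[`, character(1), "gene_id"),
    category = vapply(results, `[[`, integer(1), "category"),
    omega = vapply(results, `[[`, numeric(1), "omega"),
    delta1 = vapply(results, `[[`, numeric(1), "delta1"),
    delta2 = vapply(results, `[[`, numeric(1), "delta2"),
    rss = vapply(results, `[[`, numeric(1), "rss"),
    mean_lifetime = vapply(results, `[[`, numeric(1), "mean_lifetime"),
    half_life = vapply(results, `[[`, numeric(1), "half_life"),
    t(vapply(results, `[[`, numeric(length(times)), "levels")),
    check.names = FALSE)
  names(df)[-(1:8)] <- paste0("t", times)
  write_csv_full_precision(df, path)
  invisible(path)
}

#' Read fit results written by [write_fit_results()]
#'
#' @param path CSV path.
#' @return data frame with one row per gene.
#' @export
read_fit_results <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("gene_id", "category", "omega", "delta1", "delta2", "rss",
            "mean_lifetime", "half_life")
  if (!all(need %in% names(df)))
    stop("not a fit-results file; missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$category <- as.integer(df$category)
  df
}
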