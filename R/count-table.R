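## Population haplogroup count tables: read, validate, pool, convert to
## observed populations.  Canonical format is tab-separated text with a
## header row and columns population, group, n, carriers (UTF-8, '.'
## decimal separator).

validate_count_table <- function(df, where = "count table") {
  required <- c("population", "group", "n", "carriers")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s) %s", where,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in c("n", "carriers")) {
    bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric `%s` in row(s) %s", where, col,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    df[[col]] <- as.integer(as.numeric(df[[col]]))
  }
  bad <- which(df$n < 1)
  if (length(bad)) {
    stop(sprintf("%s: n < 1 in row(s) %s", where,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  bad <- which(df$carriers < 0 | df$carriers > df$n)
  if (length(bad)) {
    stop(sprintf("%s: carriers outside [0, n] in row(s) %s", where,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  dup <- df$population[duplicated(df$population)]
  if (length(dup)) {
    stop(sprintf("%s: duplicated population label(s) %s", where,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  df$freq <- df$carriers / df$n
  class(df) <- c("count_table", "data.frame")
  df
}

#' Build a count table from vectors
#'
#' @param population,group character vectors of labels.
#' @param n,carriers integer vectors of sample sizes and carrier counts.
#' @return A validated `count_table` (a data frame with a `freq` column).
#' @export
count_table <- function(population, group, n, carriers) {
  validate_count_table(
    data.frame(population = population, group = group, n = n,
               carriers = carriers),
    "count_table()"
  )
}

#' Read a population haplogroup count table
#'
#' Expects a header row and columns `population`, `group`, `n`,
#' `carriers`.  Malformed rows are reported with their row numbers.
#'
#' @param path file path.
#' @param sep field separator; tab by default, use `","` for CSV input.
#' @return A validated `count_table`.
#' @export
read_counts <- function(path, sep = "\t") {
  if (!file.exists(path)) {
    stop(sprintf("count table not found: %s", path), call. = FALSE)
  }
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, quote = "",
                      comment.char = ""),
    error = function(e) {
      stop(sprintf("cannot parse %s: %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  if (nrow(df) == 0) {
    stop(sprintf("%s: no data rows", path), call. = FALSE)
  }
  validate_count_table(df, path)
}

#' Write a count table as tab-separated text
#'
#' Canonical formatting: header, tab separators, no quoting, no row names;
#' the derived `freq` column is not written.  `write_counts(read_counts(p))`
#' round-trips byte-for-byte for canonically formatted input.
#'
#' @param table a `count_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  out <- table[c("population", "group", "n", "carriers")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pool count-table rows by group
#'
#' Sums sample sizes and carrier counts within each level of `by`; the
#' pooled frequency is pooled carriers over pooled n, and therefore always
#' lies within the range of member frequencies.
#'
#' @param table a `count_table`.
#' @param by grouping column name (default `"group"`).
#' @return A `count_table` with one row per group (the `population` column
#'   carries the group label).
#' @export
pool_counts <- function(table, by = "group") {
  stopifnot(inherits(table, "count_table"))
  if (!by %in% names(table)) {
    stop(sprintf("grouping column `%s` not present", by), call. = FALSE)
  }
  n <- tapply(table$n, table[[by]], sum)
  carriers <- tapply(table$carriers, table[[by]], sum)
  validate_count_table(
    data.frame(population = names(n), group = names(n),
               n = as.integer(n), carriers = as.integer(carriers)),
    "pool_counts()"
  )
}

#' Convert a pooled count table to observed populations
#'
#' Builds one [observed_population()] per row (applying the zero adjustment
#' and tolerance), named by the `population` column.
#'
#' @param table a `count_table`, one row per analysis population.
#' @param tolerance_variant passed to [observed_population()].
#' @return A named list of `observed_population` objects.
#' @export
as_observed <- function(table, tolerance_variant = c("halved", "classic")) {
  stopifnot(inherits(table, "count_table"))
  tolerance_variant <- match.arg(tolerance_variant)
  out <- lapply(seq_len(nrow(table)), function(i) {
    observed_population(table$population[i], table$n[i], table$carriers[i],
                        tolerance_variant)
  })
  names(out) <- table$population
  out
}
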