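#' Specimen tables
#'
#' A specimen table is the package's central data container: one row per fossil
#' or extant specimen, holding identifiers (`specimen_id`, `dataset`, `group`,
#' `sample_order`, `age_years`), the two armour scores (`pelvic_score` in
#' \[0, 3\] and `dorsal_spine_count` in 0--3), and one column per registry
#' trait.  Ages are years since the series' first sample.  Missing values are
#' `NA`.
#'
#' @param records data frame with the metadata columns and one column per
#'   registry trait.
#' @param registry a [trait_registry()]; defaults to [default_registry()].
#' @param provenance free-text note carried along with the table.
#' @param strict if `TRUE` (raw measurements), count traits must be
#'   non-negative integers and continuous traits non-negative; set to `FALSE`
#'   for tables of size-corrected values, which may legitimately be negative.
#' @return An object of class `specimen_table` (a data frame carrying the
#'   registry and provenance as attributes).
#' @export
specimen_table <- function(records, registry = default_registry(),
                           provenance = "", strict = TRUE) {
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(meta_columns(), registry$code), names(records))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  records <- records[, c(meta_columns(), registry$code)]
  records$specimen_id <- as.character(records$specimen_id)
  records$group <- as.character(records$group)
  records$sample_order <- as.integer(records$sample_order)
  records$age_years <- as.numeric(records$age_years)
  records$pelvic_score <- as.numeric(records$pelvic_score)
  records$dorsal_spine_count <- as.numeric(records$dorsal_spine_count)
  if (anyDuplicated(records$specimen_id))
    stop("duplicate specimen_id: ",
         paste(unique(records$specimen_id[duplicated(records$specimen_id)]),
               collapse = ", "))
  if (!all(records$dataset %in% c("fossil", "extant")))
    stop("dataset must be 'fossil' or 'extant'")

  for (code in registry$code) {
    v <- records[[code]]
    if (is.character(v) || is.factor(v)) {
      parsed <- suppressWarnings(as.numeric(as.character(v)))
      bad <- !is.na(as.character(v)) & is.na(parsed)
      if (any(bad))
        stop("unparseable value for trait ", code, ": ",
             paste(utils::head(as.character(v)[bad], 3L), collapse = ", "))
      v <- parsed
    }
    v <- as.numeric(v)
    kind <- registry$kind[registry$code == code]
    if (strict) {
      if (kind == "count" && any(!is.na(v) & (v < 0 | v != round(v))))
        stop("count trait non-integer or negative: ", code)
      if (kind == "continuous" && any(!is.na(v) & v < 0))
        stop("negative length for trait ", code)
    }
    records[[code]] <- v
  }
  ps <- records$pelvic_score
  if (any(!is.na(ps) & (ps < 0 | ps > 3)))
    stop("pelvic_score must lie in [0, 3]")
  dsc <- records$dorsal_spine_count
  if (any(!is.na(dsc) & !dsc %in% 0:3))
    stop("dorsal_spine_count outside admissible range 0-3")

  ## within a fossil series, age must increase with sample order
  fos <- records[records$dataset == "fossil" & !is.na(records$sample_order), ]
  if (nrow(fos)) {
    ord <- unique(fos[, c("group", "sample_order", "age_years")])
    ord <- ord[order(ord$sample_order), ]
    if (nrow(ord) > 1L && any(diff(ord$age_years) <= 0, na.rm = TRUE))
      stop("age_years must strictly increase with sample_order")
  }

  structure(records,
            registry = registry,
            provenance = provenance,
            class = c("specimen_table", "data.frame"))
}

meta_columns <- function() {
  c("specimen_id", "dataset", "group", "sample_order", "age_years",
    "pelvic_score", "dorsal_spine_count")
}

#' @export
print.specimen_table <- function(x, ...) {
  reg <- table_registry(x)
  cat("Specimen table:", nrow(x), "specimens,",
      length(unique(x$group)), "groups,", nrow(reg), "traits\n")
  prov <- attr(x, "provenance")
  if (nzchar(prov)) cat("Provenance:", prov, "\n")
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' @export
`[.specimen_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c(meta_columns()) %in% names(out))) {
    attr(out, "registry") <- attr(x, "registry")
    attr(out, "provenance") <- attr(x, "provenance")
    class(out) <- c("specimen_table", "data.frame")
  }
  out
}

table_registry <- function(table) {
  reg <- attr(table, "registry")
  if (is.null(reg)) default_registry() else reg
}

## rows belonging to one group, as a plain data.frame
group_rows <- function(table, group) {
  rows <- as.data.frame(table)[table$group == group, , drop = FALSE]
  if (!nrow(rows)) stop("group not present in table: ", group)
  rows
}

#' Read a specimen table from CSV
#'
#' Reads the package's CSV dialect (header row; empty fields and `"NA"` both
#' read as missing) and validates it against the registry.  Unparseable trait
#' values raise an error rather than being dropped; input row order is
#' preserved.
#'
#' @param path CSV file path.
#' @inheritParams specimen_table
#' @return A [specimen_table()].
#' @export
read_specimen_table <- function(path, registry = default_registry(),
                                strict = TRUE) {
  raw <- utils::read.csv(path, na.strings = c("", "NA"),
                         stringsAsFactors = FALSE, check.names = FALSE)
  specimen_table(raw, registry = registry,
                 provenance = paste("read from", basename(path)),
                 strict = strict)
}

#' Write a specimen table to CSV
#'
#' Missing values are written as `"NA"`.  Continuous trait values are emitted
#' by the synthetic generator rounded to 6 decimals, so write/read round-trips
#' reproduce the in-memory table exactly.
#'
#' @param table a [specimen_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_specimen_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, na = "NA", row.names = FALSE)
  invisible(path)
}
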