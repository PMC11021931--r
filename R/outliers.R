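#' Screen pooled trait distributions for outliers
#'
#' Flags trait values lying more than `threshold_sd` standard deviations from
#' the pooled mean of their dataset category: fossil specimens are pooled
#' across temporal samples and extant specimens across lakes, so the screen
#' targets measurement/data-entry errors rather than within-sample extremes.
#' The mean and s.d. are computed with the candidate point included, and the
#' screen is single-pass (it is never iterated on the masked table).
#'
#' @param table a [specimen_table()].
#' @param threshold_sd flag threshold in pooled standard deviations
#'   (default 3.5).
#' @return An object of class `outlier_report`: a list with the flagged cells
#'   (`specimen_id`, trait `code`, `value`, `z`), the threshold, and the
#'   pooling used.
#' @export
detect_outliers <- function(table, threshold_sd = 3.5) {
  stopifnot(inherits(table, "specimen_table"), threshold_sd > 0)
  registry <- table_registry(table)
  df <- as.data.frame(table)
  flagged <- list()
  for (ds in unique(df$dataset)) {
    sub <- df[df$dataset == ds, , drop = FALSE]
    for (code in registry$code) {
      v <- sub[[code]]
      ok <- !is.na(v)
      if (!any(ok))
        stop("trait entirely missing: ", code, " (", ds, ")")
      if (sum(ok) < 3L)
        stop("need >= 3 non-missing values to screen trait ", code)
      s <- stats::sd(v[ok])
      if (s == 0) {
        warning("trait ", code, " is constant in the ", ds,
                " pool; no outliers flagged")
        next
      }
      z <- (v - mean(v[ok])) / s
      hit <- ok & abs(z) > threshold_sd
      if (any(hit))
        flagged[[length(flagged) + 1L]] <- data.frame(
          specimen_id = sub$specimen_id[hit],
          code = code,
          value = v[hit],
          z = z[hit],
          stringsAsFactors = FALSE)
    }
  }
  flagged <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(specimen_id = character(), code = character(),
               value = numeric(), z = numeric(), stringsAsFactors = FALSE)
  pooling <- paste0(sort(unique(df$dataset)), "-pooled", collapse = "; ")
  structure(list(flagged = flagged, threshold_sd = threshold_sd,
                 pooling = pooling),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("Outlier report (", x$pooling, ", |z| > ", x$threshold_sd, "): ",
      nrow(x$flagged), " flagged cells\n", sep = "")
  if (nrow(x$flagged)) print.data.frame(x$flagged, ...)
  invisible(x)
}

#' Mask flagged outlier cells
#'
#' Sets every flagged cell in the report to missing and leaves all other cells
#' untouched.  Masking is idempotent for a fixed report, and the operation
#' does not re-run detection on the masked table.
#'
#' @param table the [specimen_table()] the report was computed from.
#' @param report an [detect_outliers()] report.
#' @return The masked [specimen_table()].
#' @export
apply_outlier_mask <- function(table, report) {
  stopifnot(inherits(table, "specimen_table"),
            inherits(report, "outlier_report"))
  fl <- report$flagged
  if (!nrow(fl)) return(table)
  unknown <- setdiff(fl$specimen_id, table$specimen_id)
  if (length(unknown))
    stop("report refers to specimens absent from the table: ",
         paste(unknown, collapse = ", "))
  n_masked <- 0L
  for (i in seq_len(nrow(fl))) {
    row <- match(fl$specimen_id[i], table$specimen_id)
    if (!is.na(table[[fl$code[i]]][row])) n_masked <- n_masked + 1L
    table[[fl$code[i]]][row] <- NA_real_
  }
  message(n_masked, " outlier cell(s) masked")
  table
}
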