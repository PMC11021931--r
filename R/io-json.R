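#' Serialize analysis results to JSON
#'
#' All result objects in the package (divergence fits, outlier reports, armour
#' tables, trajectories, manifests, ...) are plain lists/data frames behind
#' their classes, and serialize losslessly: numbers are written at full
#' precision, and `NaN`/`NA` fields are written as JSON `null` (the documented
#' convention).  Re-reading with [read_results()] yields an equal structure.
#'
#' @param results any result object (or list of them).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  jsonlite::write_json(strip_result(results), path,
                       auto_unbox = TRUE, digits = I(17),
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

## Recursively convert classed result objects to plain lists; drop calls and
## environments, which are not data.
strip_result <- function(x) {
  if (is.function(x) || is.environment(x) || is.call(x) || is.name(x))
    return(NULL)
  if (is.data.frame(x)) {
    x <- as.data.frame(x)
    rownames(x) <- NULL
    return(x)
  }
  if (is.list(x)) {
    x <- unclass(x)
    attributes(x) <- list(names = names(x))
    out <- lapply(x, strip_result)
    return(out[!vapply(out, is.null, logical(1L))])
  }
  if (is.matrix(x)) return(unname(x))
  x
}
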