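#' Trait registry
#'
#' A trait registry records, for every analyzed trait, its short code, whether
#' it is a meristic count or a continuous length (mm), and whether it should be
#' allometrically size-corrected.  Exactly one trait is designated the size
#' covariate (standard length, `stl`, in mm); only continuous traits other than
#' the size covariate may be size-corrected.
#'
#' @param entries data frame with columns `code`, `kind` (`"count"` or
#'   `"continuous"`), `size_correct` (logical), `size_covariate` (logical) and
#'   `label`.
#' @return An object of class `trait_registry` (a validated data frame).
#' @seealso [default_registry()]
#' @export
trait_registry <- function(entries) {
  stopifnot(is.data.frame(entries))
  needed <- c("code", "kind", "size_correct", "size_covariate", "label")
  missing_cols <- setdiff(needed, names(entries))
  if (length(missing_cols))
    stop("registry is missing columns: ", paste(missing_cols, collapse = ", "))
  entries$code <- as.character(entries$code)
  if (anyDuplicated(entries$code))
    stop("trait codes must be unique")
  if (!all(entries$kind %in% c("count", "continuous")))
    stop("trait kind must be 'count' or 'continuous'")
  if (sum(entries$size_covariate) != 1L)
    stop("exactly one trait must be the size covariate")
  if (entries$kind[entries$size_covariate] != "continuous")
    stop("the size covariate must be a continuous trait")
  if (any(entries$size_correct & entries$kind == "count"))
    stop("count traits cannot be size-corrected")
  if (any(entries$size_correct & entries$size_covariate))
    stop("the size covariate itself cannot be size-corrected")
  structure(entries, class = c("trait_registry", "data.frame"))
}

#' Default 16-trait registry
#'
#' The default registry holds the 16 traits analyzed in the fossil series and
#' the extant species-pair lakes: nine size-corrected continuous lengths (codes
#' carrying the `.sc` suffix), six meristic counts, and standard length `stl`
#' (the size covariate, itself analyzed but never corrected).  Anatomical
#' labels are best-effort readings of the published trait codes.
#'
#' @return A [trait_registry()] with 16 rows.
#' @examples
#' reg <- default_registry()
#' table(reg$kind)
#' @export
default_registry <- function() {
  entries <- data.frame(
    code = c("mds", "mcv", "mpt", "maf", "mdf", "mav",
             "lps.sc", "tpg.sc", "ds1.sc", "ds2.sc", "ds3.sc",
             "lpt.sc", "ect.sc", "pmx.sc", "cle.sc", "stl"),
    kind = c(rep("count", 6L), rep("continuous", 10L)),
    size_correct = c(rep(FALSE, 6L), rep(TRUE, 9L), FALSE),
    size_covariate = c(rep(FALSE, 15L), TRUE),
    label = c(
      "number of dorsal spines",
      "number of caudal vertebrae",
      "number of pterygiophores anterior to the third-spine pterygiophore",
      "number of anal-fin rays",
      "number of dorsal-fin rays",
      "number of abdominal vertebrae",
      "pelvic spine length, size-corrected (mm; best-effort label)",
      "third-spine pterygiophore length, size-corrected (mm; best-effort label)",
      "first dorsal spine length, size-corrected (mm)",
      "second dorsal spine length, size-corrected (mm)",
      "third dorsal spine length, size-corrected (mm)",
      "pelvic girdle length, size-corrected (mm; best-effort label)",
      "ectocoracoid length, size-corrected (mm)",
      "premaxilla ascending branch length, size-corrected (mm)",
      "cleithrum length, size-corrected (mm)",
      "standard length (mm; size covariate)"),
    stringsAsFactors = FALSE)
  trait_registry(entries)
}

#' @export
print.trait_registry <- function(x, ...) {
  cat("Trait registry:", nrow(x), "traits (",
      sum(x$kind == "count"), "counts,",
      sum(x$size_correct), "size-corrected lengths,",
      "size covariate:", x$code[x$size_covariate], ")\n")
  print.data.frame(x, ...)
  invisible(x)
}

## codes of traits entering multivariate statistics, in registry order
registry_codes <- function(registry) registry$code

size_covariate_code <- function(registry) registry$code[registry$size_covariate]
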