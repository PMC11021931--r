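#' Fit the allometric size-correction model
#'
#' For every registry trait flagged `size_correct`, fits a mixed-model
#' regression of the trait on standard length with a common (fixed) slope and
#' group-level random intercepts (`trait ~ stl + (1 | group)` via
#' [lme4::lmer()]).  The fossil and extant datasets have different histories
#' and ecologies, so they must be corrected separately: the table passed in
#' may contain only one dataset category.  Records missing either the trait
#' or standard length are excluded from that trait's fit.
#'
#' If a mixed fit fails or is singular, the model falls back to ordinary
#' least squares with fixed group intercepts (identical common-slope point
#' estimates in balanced cases); if standard length shows no within-group
#' variation at all, the common slope is unidentifiable and is set to 0 with
#' a warning (correction becomes the identity).
#'
#' @param table a [specimen_table()] holding a single dataset category.
#' @param grouping column used as the grouping unit (default `"group"`:
#'   temporal sample for fossils, lake x ecotype for extant specimens).
#' @return An object of class `size_correction` with the per-trait common
#'   slopes `b` (mm per mm of standard length), per-group intercepts, the
#'   grand mean standard length `stl_bar` (mm), and per-trait fit metadata.
#' @export
fit_size_correction <- function(table, grouping = "group") {
  stopifnot(inherits(table, "specimen_table"))
  registry <- table_registry(table)
  df <- as.data.frame(table)
  if (length(unique(df$dataset)) > 1L)
    stop("fit fossil and extant datasets separately")
  groups <- as.character(df[[grouping]])
  if (length(unique(groups)) < 2L)
    stop("size correction requires >= 2 groups (grouping required)")
  stl_code <- size_covariate_code(registry)
  stl <- df[[stl_code]]
  if (all(is.na(stl))) stop("standard length entirely missing")
  if (stats::sd(stl, na.rm = TRUE) == 0)
    stop("singular fit: all ", stl_code, " values equal")
  stl_bar <- mean(stl, na.rm = TRUE)

  traits <- registry$code[registry$size_correct]
  slopes <- stats::setNames(numeric(length(traits)), traits)
  intercepts <- stats::setNames(vector("list", length(traits)), traits)
  method <- stats::setNames(character(length(traits)), traits)
  n_used <- stats::setNames(integer(length(traits)), traits)

  for (code in traits) {
    y <- df[[code]]
    use <- !is.na(y) & !is.na(stl)
    n_used[code] <- sum(use)
    if (sum(use) < 3L)
      stop("too few complete records to fit size correction for ", code)
    dat <- data.frame(y = y[use], stl = stl[use],
                      g = factor(groups[use]))
    within_var <- stats::ave(dat$stl, dat$g,
                             FUN = function(v) stats::var(v))
    if (all(is.na(within_var) | within_var < 1e-12)) {
      warning("no within-group variation in ", stl_code,
              "; allometric slope for ", code,
              " is unidentifiable, using slope 0")
      slopes[code] <- 0
      gm <- tapply(dat$y, dat$g, mean)
      intercepts[[code]] <- gm
      method[code] <- "zero-slope"
      next
    }
    fit <- tryCatch({
      m <- suppressMessages(lme4::lmer(y ~ stl + (1 | g), data = dat,
                                       control = lme4::lmerControl(
                                         check.conv.singular =
                                           lme4::.makeCC(action = "ignore",
                                                         tol = 1e-4))))
      if (lme4::isSingular(m, tol = 1e-4)) NULL else m
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      b <- unname(lme4::fixef(fit)["stl"])
      re <- lme4::ranef(fit)$g
      a <- unname(lme4::fixef(fit)["(Intercept)"]) + re[["(Intercept)"]]
      names(a) <- rownames(re)
      method[code] <- "lmer"
    } else {
      ## OLS fallback with fixed group intercepts
      ols <- stats::lm(y ~ stl + g, data = dat,
                       contrasts = list(g = "contr.treatment"))
      cf <- stats::coef(ols)
      b <- unname(cf["stl"])
      levs <- levels(dat$g)
      a <- stats::setNames(rep(cf["(Intercept)"], length(levs)), levs)
      extra <- cf[grep("^g", names(cf))]
      extra[is.na(extra)] <- 0
      a[sub("^g", "", names(extra))] <-
        a[sub("^g", "", names(extra))] + extra
      method[code] <- "ols"
      message("mixed fit unavailable for ", code,
              "; fell back to fixed-intercept OLS")
    }
    slopes[code] <- b
    intercepts[[code]] <- a
  }

  structure(list(slopes = slopes, intercepts = intercepts,
                 stl_bar = stl_bar, grouping = grouping,
                 dataset = unique(df$dataset), traits = traits,
                 method = method, n_used = n_used),
            class = "size_correction")
}

#' @export
print.size_correction <- function(x, ...) {
  cat("Allometric size correction (", x$dataset, " data, grouping: ",
      x$grouping, ")\n", sep = "")
  cat("Grand mean standard length:", format(x$stl_bar), "mm\n")
  print(data.frame(trait = x$traits,
                   slope = unname(x$slopes),
                   n = unname(x$n_used),
                   method = unname(x$method)), ...)
  invisible(x)
}

#' @export
coef.size_correction <- function(object, ...) object$slopes

#' Fitted values under the size-correction model
#'
#' @param object a [fit_size_correction()] model.
#' @param table a [specimen_table()] with the same grouping levels.
#' @param ... unused.
#' @return Matrix of fitted trait values (rows = specimens, columns = the
#'   corrected traits); `NA` where standard length or a group intercept is
#'   unavailable.
#' @export
predict.size_correction <- function(object, table, ...) {
  registry <- table_registry(table)
  df <- as.data.frame(table)
  stl <- df[[size_covariate_code(registry)]]
  g <- as.character(df[[object$grouping]])
  out <- sapply(object$traits, function(code) {
    a <- object$intercepts[[code]][g]
    unname(a + object$slopes[[code]] * stl)
  })
  matrix(out, nrow = nrow(df), dimnames = list(df$specimen_id, object$traits))
}

#' @export
residuals.size_correction <- function(object, table, ...) {
  df <- as.data.frame(table)
  obs <- as.matrix(df[, object$traits, drop = FALSE])
  obs - predict(object, table)
}

#' Apply allometric size correction
#'
#' Replaces every covered trait value by `observed - b * (stl - stl_bar)`,
#' i.e. the value expected had the specimen been of grand-mean standard
#' length.  Corrected values stay in mm; count traits (fixed during early
#' development) and standard length itself pass through unchanged.  Records
#' missing standard length get a missing corrected value.
#'
#' @param table a [specimen_table()] of the same dataset category the model
#'   was fitted on.
#' @param model a [fit_size_correction()] model.
#' @return The corrected [specimen_table()] (validated non-strictly, since
#'   corrected lengths may be negative).
#' @export
size_correct <- function(table, model) {
  stopifnot(inherits(table, "specimen_table"),
            inherits(model, "size_correction"))
  registry <- table_registry(table)
  df <- as.data.frame(table)
  if (!identical(sort(unique(df$dataset)), sort(model$dataset)))
    stop("model was fitted on the ", model$dataset, " dataset")
  stl <- df[[size_covariate_code(registry)]]
  for (code in model$traits) {
    corrected <- df[[code]] - model$slopes[[code]] * (stl - model$stl_bar)
    corrected[is.na(stl)] <- NA_real_
    df[[code]] <- corrected
  }
  specimen_table(df, registry,
                 provenance = paste0(attr(table, "provenance"),
                                     " [size-corrected]"),
                 strict = FALSE)
}
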