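#' Wilcoxon rank-sum U statistic between two temporal samples
#'
#' `U` counts the cross-sample pairs in which the later specimen has the
#' larger value (plus half a count per tie), so that traits undergoing
#' reduction give effect sizes near 0.  The two-sided p-value uses the
#' normal approximation with tie-corrected variance and continuity
#' correction; for small samples without ties (`n1 + n2 <= 20`) the exact
#' distribution is used automatically.  Computation is delegated to
#' [stats::wilcox.test()].
#'
#' @param first,last numeric trait values from the earlier and later sample;
#'   missing values are dropped.
#' @param exact force (`TRUE`)/suppress (`FALSE`) the exact small-sample
#'   p-value; `NULL` (default) selects automatically.
#' @return list with `U` and two-sided `p`.
#' @export
wilcoxon_u <- function(first, last, exact = NULL) {
  first <- first[!is.na(first)]
  last <- last[!is.na(last)]
  if (!length(first) || !length(last))
    stop("each side needs at least one non-missing value")
  n1 <- length(first)
  n2 <- length(last)
  ties <- anyDuplicated(c(first, last)) > 0L
  if (is.null(exact)) exact <- (n1 + n2 <= 20L) && !ties
  if (length(unique(c(first, last))) == 1L) {
    ## completely tied data: no evidence either way
    return(list(U = n1 * n2 / 2, p = 1))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(last, first, exact = exact, correct = TRUE))
  p <- wt$p.value
  if (is.na(p)) p <- 1
  list(U = unname(wt$statistic), p = min(p, 1))
}

#' Common-language effect size
#'
#' `U` divided by the product of the sample sizes: the proportion of
#' cross-sample pairs in which the individual from the later sample has the
#' larger trait value.  Values near 0 or 1 reveal consistent differences;
#' values near 0 indicate that later individuals are smaller.
#'
#' @param U rank-sum statistic, in `[0, n_first * n_last]`.
#' @param n_first,n_last sample sizes (each >= 1).
#' @return Proportion in `[0, 1]`.
#' @examples
#' cles(318.5, 43, 55)  # 0.135: later specimens smaller for ~87% of pairs
#' @export
cles <- function(U, n_first, n_last) {
  stopifnot(n_first >= 1L, n_last >= 1L)
  if (U < 0 || U > n_first * n_last)
    stop("U out of range [0, n_first * n_last]")
  U / (n_first * n_last)
}

#' Trait-by-trait divergence table
#'
#' Runs the rank-sum comparison for every registry trait between two groups
#' (typically the first and last temporal samples of a size-corrected table),
#' reporting `U`, the two-sided p, the common-language effect size, the
#' median and mean differences (last minus first, trait units), the pooled
#' within-group variance, and a significance call at the Bonferroni family
#' level `alpha_total / n_traits`.  Traits with fewer than two values in a
#' group are flagged untestable rather than dropped.
#'
#' @param table a [specimen_table()] (size-corrected for `.sc` traits).
#' @param group_first,group_last group labels to contrast.
#' @param alpha_total family-wise error rate before correction
#'   (default 0.05).
#' @param traits trait codes to test (default: all registry traits).
#' @return data frame of class `trait_divergence` with attributes
#'   `alpha_family` and `n_significant`; also carries per-trait means and
#'   95% t-intervals for each group.
#' @export
trait_divergence_table <- function(table, group_first, group_last,
                                   alpha_total = 0.05, traits = NULL) {
  stopifnot(inherits(table, "specimen_table"))
  registry <- table_registry(table)
  if (is.null(traits)) traits <- registry$code
  first_rows <- group_rows(table, group_first)
  last_rows <- group_rows(table, group_last)
  alpha_family <- alpha_total / length(traits)

  t_int <- function(v) {
    v <- v[!is.na(v)]
    m <- mean(v)
    if (length(v) < 2L || stats::sd(v) == 0)
      return(c(mean = m, lo = m, hi = m))
    half <- stats::qt(0.975, length(v) - 1L) * stats::sd(v) / sqrt(length(v))
    c(mean = m, lo = m - half, hi = m + half)
  }

  rows <- lapply(traits, function(code) {
    x <- first_rows[[code]]
    y <- last_rows[[code]]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) {
      return(data.frame(trait = code, n_first = length(x),
                        n_last = length(y), U = NA_real_, p = NA_real_,
                        effect_size = NA_real_, median_diff = NA_real_,
                        mean_diff = NA_real_, pooled_variance = NA_real_,
                        significant = NA, untestable = TRUE,
                        mean_first = NA_real_, lo_first = NA_real_,
                        hi_first = NA_real_, mean_last = NA_real_,
                        lo_last = NA_real_, hi_last = NA_real_,
                        stringsAsFactors = FALSE))
    }
    w <- wilcoxon_u(x, y)
    pooled_var <- ((length(x) - 1L) * stats::var(x) +
                   (length(y) - 1L) * stats::var(y)) /
      (length(x) + length(y) - 2L)
    ci1 <- t_int(x)
    ci2 <- t_int(y)
    data.frame(trait = code, n_first = length(x), n_last = length(y),
               U = w$U, p = w$p,
               effect_size = cles(w$U, length(x), length(y)),
               median_diff = stats::median(y) - stats::median(x),
               mean_diff = mean(y) - mean(x),
               pooled_variance = pooled_var,
               significant = w$p < alpha_family,
               untestable = FALSE,
               mean_first = ci1[["mean"]], lo_first = ci1[["lo"]],
               hi_first = ci1[["hi"]], mean_last = ci2[["mean"]],
               lo_last = ci2[["lo"]], hi_last = ci2[["hi"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out,
            alpha_family = alpha_family,
            n_significant = sum(out$significant, na.rm = TRUE),
            groups = c(group_first, group_last),
            class = c("trait_divergence", "data.frame"))
}

#' @export
print.trait_divergence <- function(x, digits = 3L, ...) {
  gr <- attr(x, "groups")
  cat("Trait divergence, ", gr[1L], " vs ", gr[2L], ": ",
      attr(x, "n_significant"), "/", nrow(x),
      " traits significant at family alpha = ",
      format(attr(x, "alpha_family")), "\n", sep = "")
  cols <- c("trait", "median_diff", "mean_diff", "pooled_variance",
            "n_first", "n_last", "U", "p", "effect_size", "significant")
  print.data.frame(as.data.frame(x)[, cols], digits = digits,
                   row.names = FALSE, ...)
  invisible(x)
}
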