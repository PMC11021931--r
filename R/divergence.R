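#' Per-group trait mean vector
#'
#' Trait-wise means over the non-missing values of one group; missingness is
#' handled per trait, never by deleting whole specimens.
#'
#' @param table a [specimen_table()].
#' @param group group label.
#' @param traits trait codes (default: all registry traits).
#' @return Named numeric vector of means, with per-trait sample sizes in
#'   attribute `n`.
#' @export
mean_vector <- function(table, group, traits = NULL) {
  registry <- table_registry(table)
  if (is.null(traits)) traits <- registry$code
  rows <- group_rows(table, group)
  n <- vapply(traits, function(code) sum(!is.na(rows[[code]])), integer(1L))
  empty <- traits[n == 0L]
  if (length(empty))
    stop("trait ", paste(empty, collapse = ", "),
         " entirely missing in group ", group)
  m <- vapply(traits, function(code) mean(rows[[code]], na.rm = TRUE),
              numeric(1L))
  structure(m, n = n)
}

#' Multivariate Euclidean divergence between two mean vectors
#'
#' The divergence statistic `d`: the Euclidean distance between two groups'
#' trait-mean vectors, in mm-scale mixed units (size-corrected lengths in mm,
#' counts and standard length on their raw scales; no standardization to
#' unit variance).
#'
#' @param v1,v2 equal-length numeric vectors without missing entries.
#' @return Non-negative number.
#' @examples
#' euclidean_d(c(0, 0), c(3, 4))  # 5
#' @export
euclidean_d <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("vectors must have equal length")
  if (anyNA(v1) || anyNA(v2)) stop("mean vectors contain missing entries")
  sqrt(sum((v1 - v2)^2))
}

## trait-value matrix for one group (rows = specimens)
group_matrix <- function(table, group, traits) {
  rows <- group_rows(table, group)
  as.matrix(rows[, traits, drop = FALSE])
}

#' Bootstrap distribution of the divergence d
#'
#' Resamples specimens with replacement independently within each group
#' (keeping the group sizes), recomputes the two mean vectors and `d`, and
#' repeats `B` times.  Replicates in which a trait ends up entirely missing
#' in either group are redrawn (keeping `B` fixed), and the number of
#' redraws is reported.
#'
#' @param table a [specimen_table()].
#' @param group_first,group_last groups to contrast (each >= 2 specimens).
#' @param traits trait codes (default: all registry traits).
#' @param B number of bootstrap replicates (default 99).
#' @param seed integer seed for reproducible resampling.
#' @return list with `values` (length `B`), `mean`, `sd` and `redraws`.
#' @export
bootstrap_d <- function(table, group_first, group_last, traits = NULL,
                        B = 99L, seed = NULL) {
  registry <- table_registry(table)
  if (is.null(traits)) traits <- registry$code
  X1 <- group_matrix(table, group_first, traits)
  X2 <- group_matrix(table, group_last, traits)
  if (nrow(X1) < 2L || nrow(X2) < 2L)
    stop("both groups need >= 2 specimens")
  set_seed_if(seed)
  values <- numeric(B)
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      m1 <- colMeans(X1[sample_int(nrow(X1), nrow(X1), replace = TRUE), ,
                        drop = FALSE], na.rm = TRUE)
      m2 <- colMeans(X2[sample_int(nrow(X2), nrow(X2), replace = TRUE), ,
                        drop = FALSE], na.rm = TRUE)
      if (!anyNA(m1) && !any(is.nan(m1)) && !anyNA(m2) && !any(is.nan(m2)))
        break
      redraws <- redraws + 1L
      if (redraws > 1000L * B)
        stop("bootstrap cannot find replicates with all traits observed")
    }
    values[b] <- euclidean_d(m1, m2)
  }
  if (redraws) message(redraws, " bootstrap replicate(s) redrawn")
  list(values = values, mean = mean(values), sd = stats::sd(values),
       redraws = redraws)
}

#' Permutation test of the divergence d
#'
#' Shuffles sample identity (first versus last) across the pooled specimens
#' `P` times, preserving group sizes, and recomputes `d` each time.  The
#' p-value uses the add-one rule `(1 + #{d_perm >= d_obs}) / (P + 1)`, so the
#' minimum attainable p at `P = 99` is 0.01.
#'
#' @inheritParams bootstrap_d
#' @param P number of permutations (default 99).
#' @return list with `p`, the observed `d_obs` and the permuted `values`.
#' @export
permutation_d <- function(table, group_first, group_last, traits = NULL,
                          P = 99L, seed = NULL) {
  registry <- table_registry(table)
  if (is.null(traits)) traits <- registry$code
  X1 <- group_matrix(table, group_first, traits)
  X2 <- group_matrix(table, group_last, traits)
  if (nrow(X1) < 2L || nrow(X2) < 2L)
    stop("both groups need >= 2 specimens")
  pool <- rbind(X1, X2)
  n1 <- nrow(X1)
  d_obs <- euclidean_d(colMeans(X1, na.rm = TRUE),
                       colMeans(X2, na.rm = TRUE))
  set_seed_if(seed)
  values <- numeric(P)
  for (i in seq_len(P)) {
    idx <- sample_int(nrow(pool), n1)
    m1 <- colMeans(pool[idx, , drop = FALSE], na.rm = TRUE)
    m2 <- colMeans(pool[-idx, , drop = FALSE], na.rm = TRUE)
    if (anyNA(m1) || anyNA(m2) || any(is.nan(c(m1, m2)))) {
      values[i] <- NA_real_
    } else {
      values[i] <- euclidean_d(m1, m2)
    }
  }
  if (anyNA(values)) {
    message(sum(is.na(values)), " permutation(s) with an all-missing trait ",
            "dropped from the null")
    values <- values[!is.na(values)]
  }
  p <- (1 + sum(values >= d_obs)) / (length(values) + 1)
  list(p = p, d_obs = d_obs, values = values)
}

#' Fit the divergence analysis between two samples
#'
#' The package's central fit: contrasts two groups of a (size-corrected)
#' specimen table, computing the trait-by-trait rank-sum table, the
#' multivariate Euclidean divergence `d` between the group mean vectors, its
#' bootstrap distribution (`B` replicates of specimens within groups) and a
#' permutation test of sample identity (`P` shuffles).  Bootstrap and
#' permutation draws use substreams derived from `seed`, so a fixed seed
#' reproduces the fit exactly.
#'
#' @inheritParams bootstrap_d
#' @param drop_traits trait codes to exclude (e.g. `"stl"` to probe the
#'   influence of body size on `d`).
#' @param P permutations (default 99).
#' @param alpha_total family-wise error rate for the univariate table.
#' @return An object of class `divergence` with components `d`, `boot`,
#'   `perm`, `traits` (codes used), `trait_table`, `mean_first`,
#'   `mean_last`, `groups` and `n`.
#' @seealso [compare_divergence()], [divergence_trajectory()]
#' @export
divergence <- function(table, group_first, group_last, traits = NULL,
                       drop_traits = NULL, B = 99L, P = 99L,
                       alpha_total = 0.05, seed = NULL) {
  registry <- table_registry(table)
  if (is.null(traits)) traits <- registry$code
  traits <- setdiff(traits, drop_traits)
  if (!length(traits)) stop("no traits left to analyze")
  m1 <- mean_vector(table, group_first, traits)
  m2 <- mean_vector(table, group_last, traits)
  d <- euclidean_d(m1, m2)
  boot <- bootstrap_d(table, group_first, group_last, traits, B = B,
                      seed = derive_seed(seed, 1L))
  perm <- permutation_d(table, group_first, group_last, traits, P = P,
                        seed = derive_seed(seed, 2L))
  tt <- trait_divergence_table(table, group_first, group_last,
                               alpha_total = alpha_total, traits = traits)
  structure(list(d = d,
                 boot = boot,
                 perm = list(p = perm$p, values = perm$values),
                 traits = traits,
                 trait_table = tt,
                 mean_first = m1, mean_last = m2,
                 groups = c(first = group_first, last = group_last),
                 n = c(first = nrow(group_rows(table, group_first)),
                       last = nrow(group_rows(table, group_last))),
                 alpha_family = attr(tt, "alpha_family"),
                 B = B, P = P, seed = seed),
            class = "divergence")
}

#' @export
print.divergence <- function(x, ...) {
  cat("Multivariate divergence between ", x$groups[["first"]], " and ",
      x$groups[["last"]], " (", length(x$traits), " traits)\n", sep = "")
  cat("  d = ", format(x$d, digits = 4L),
      "  (bootstrap mean ", format(x$boot$mean, digits = 4L),
      ", s.d. ", format(x$boot$sd, digits = 3L),
      ", B = ", length(x$boot$values), ")\n", sep = "")
  cat("  permutation p = ", format(x$perm$p, digits = 3L),
      " (P = ", length(x$perm$values), ")\n", sep = "")
  cat("  ", attr(x$trait_table, "n_significant"), "/",
      nrow(x$trait_table),
      " traits significant at family alpha = ",
      format(x$alpha_family), "\n", sep = "")
  invisible(x)
}

#' @export
summary.divergence <- function(object, ...) {
  structure(list(fit = object), class = "summary.divergence")
}

#' @export
print.summary.divergence <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$fit$trait_table)
  invisible(x)
}

#' @export
coef.divergence <- function(object, ...) {
  structure(object$mean_last - object$mean_first, d = object$d)
}

#' Diagnostic plot for a divergence fit
#'
#' Left: bootstrap distribution of `d` with the point estimate; right: the
#' permutation null with the observed `d`.
#'
#' @param x a [divergence()] fit.
#' @param ... passed to [graphics::hist()].
#' @export
plot.divergence <- function(x, ...) {
  op <- graphics::par(mfrow = c(1L, 2L))
  on.exit(graphics::par(op))
  graphics::hist(x$boot$values, main = "bootstrap d", xlab = "d",
                 col = "grey85", border = "grey40", ...)
  graphics::abline(v = x$d, col = "red", lwd = 2L)
  xlim <- range(c(x$perm$values, x$d))
  graphics::hist(x$perm$values, main = "permutation null", xlab = "d",
                 xlim = xlim, col = "grey85", border = "grey40", ...)
  graphics::abline(v = x$d, col = "red", lwd = 2L)
  invisible(x)
}

#' Welch comparison of two bootstrap d distributions
#'
#' Two-sided Welch two-sample t-test (unequal variances,
#' Welch-Satterthwaite degrees of freedom) between the bootstrap
#' distributions of two divergences -- e.g. the fossil first-vs-last `d`
#' against a benthic-limnetic species pair.  Computation is delegated to
#' [stats::t.test()].
#'
#' @param x,y [divergence()] fits or numeric bootstrap value vectors
#'   (each >= 2 values).
#' @return list with `t`, `df`, `p` and the mean of each side.
#' @export
compare_divergence <- function(x, y) {
  bx <- if (inherits(x, "divergence")) x$boot$values else as.numeric(x)
  by <- if (inherits(y, "divergence")) y$boot$values else as.numeric(y)
  if (length(bx) < 2L || length(by) < 2L)
    stop("each distribution needs >= 2 values")
  ht <- stats::t.test(bx, by, var.equal = FALSE, paired = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_x = mean(bx), mean_y = mean(by))
}
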