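#' Divergence trajectory through a temporal series
#'
#' Computes `d` iteratively between the series' first sample and every
#' subsequent sample, with a bootstrap mean and s.d. for each, yielding the
#' accrual curve of multivariate divergence through time.  Ages are years
#' since the first sample; generations assume two years per generation.
#' Specimens belonging to an earlier resident lineage can be excluded from
#' the first (replacement-horizon) sample via `exclude_ids`.
#'
#' @param table a [specimen_table()] with fossil groups carrying
#'   `sample_order` and `age_years`.
#' @param ordered_groups group labels in temporal order (default: fossil
#'   groups sorted by `sample_order`).
#' @param traits trait codes (default: all registry traits).
#' @param drop_traits trait codes to exclude.
#' @param B bootstrap replicates per entry (default 99).
#' @param seed integer seed; each entry uses a derived substream.
#' @param exclude_ids specimen ids removed before analysis.
#' @param references optional named list of reference divergences (e.g.
#'   species pairs), attached for overlap queries and plotting.
#' @return An object of class `divergence_trajectory`: a data frame with one
#'   row per subsequent sample (`group`, `age_years`, `generations`, `d`,
#'   `boot_mean`, `boot_sd`), carrying the references as an attribute.
#' @export
divergence_trajectory <- function(table, ordered_groups = NULL,
                                  traits = NULL, drop_traits = NULL,
                                  B = 99L, seed = NULL,
                                  exclude_ids = NULL,
                                  references = NULL) {
  stopifnot(inherits(table, "specimen_table"))
  if (length(exclude_ids))
    table <- table[!table$specimen_id %in% exclude_ids, ]
  registry <- table_registry(table)
  if (is.null(traits)) traits <- registry$code
  traits <- setdiff(traits, drop_traits)
  df <- as.data.frame(table)
  if (is.null(ordered_groups)) {
    ord <- unique(df[!is.na(df$sample_order), c("group", "sample_order")])
    ord <- ord[order(ord$sample_order), ]
    ordered_groups <- ord$group
  }
  if (length(ordered_groups) < 2L)
    stop("need >= 2 ordered groups")
  ages <- vapply(ordered_groups, function(g)
    df$age_years[match(g, df$group)], numeric(1L))
  if (any(diff(ages) <= 0))
    stop("group ages must be strictly increasing")

  first <- ordered_groups[1L]
  entries <- lapply(seq_along(ordered_groups)[-1L], function(k) {
    g <- ordered_groups[k]
    d <- euclidean_d(mean_vector(table, first, traits),
                     mean_vector(table, g, traits))
    boot <- bootstrap_d(table, first, g, traits, B = B,
                        seed = derive_seed(seed, k))
    data.frame(group = g, age_years = ages[k],
               generations = ages[k] / 2,
               d = d, boot_mean = boot$mean, boot_sd = boot$sd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, entries)
  structure(out,
            first_group = first,
            traits = traits,
            references = references,
            class = c("divergence_trajectory", "data.frame"))
}

#' @export
print.divergence_trajectory <- function(x, digits = 4L, ...) {
  cat("Divergence trajectory from ", attr(x, "first_group"), " (",
      nrow(x), " entries, ", length(attr(x, "traits")), " traits)\n",
      sep = "")
  print.data.frame(as.data.frame(x), digits = digits, row.names = FALSE,
                   ...)
  invisible(x)
}

#' @export
plot.divergence_trajectory <- function(x, ...) {
  ylim <- range(c(x$boot_mean - x$boot_sd, x$boot_mean + x$boot_sd, x$d))
  refs <- attr(x, "references")
  if (!is.null(refs)) {
    rm_ <- vapply(refs, function(r) reference_summary(r)["mean"], numeric(1L))
    ylim <- range(c(ylim, rm_))
  }
  graphics::plot(x$age_years, x$d, type = "b", pch = 16L,
                 xlab = "age (years since first sample)", ylab = "d",
                 ylim = ylim, ...)
  graphics::segments(x$age_years, x$boot_mean - x$boot_sd,
                     x$age_years, x$boot_mean + x$boot_sd, col = "grey50")
  if (!is.null(refs)) {
    for (i in seq_along(refs)) {
      s <- reference_summary(refs[[i]])
      graphics::abline(h = s["mean"], col = "red", lty = 2L)
      graphics::mtext(names(refs)[i], side = 4L, at = s["mean"],
                      col = "red", cex = 0.7, las = 2L)
    }
  }
  invisible(x)
}

## mean/sd/range summary of a reference divergence in any accepted form
reference_summary <- function(reference) {
  if (inherits(reference, "divergence")) {
    vals <- reference$boot$values
    return(c(mean = reference$boot$mean, sd = reference$boot$sd,
             lo = min(vals), hi = max(vals)))
  }
  if (is.list(reference)) {
    m <- reference$boot_mean
    if (is.null(m)) m <- reference$mean
    s <- reference$boot_sd
    if (is.null(s)) s <- reference$sd
    if (is.null(m) || is.null(s))
      stop("reference must carry a bootstrap mean and sd")
    vals <- reference$values
    lo <- if (is.null(vals)) m - s else min(vals)
    hi <- if (is.null(vals)) m + s else max(vals)
    return(c(mean = m, sd = s, lo = lo, hi = hi))
  }
  if (is.numeric(reference) && length(reference) >= 2L)
    return(c(mean = mean(reference), sd = stats::sd(reference),
             lo = min(reference), hi = max(reference)))
  stop("unrecognized reference divergence")
}

#' First overlap of the fossil trajectory with a reference divergence
#'
#' Finds the earliest sample at which the fossil bootstrap interval
#' `[boot_mean - boot_sd, boot_mean + boot_sd]` reaches the same interval of
#' a reference divergence (criterion `"sd-interval"`, the default, matching
#' the mean +- s.d. presentation of the trajectories): the fossil interval
#' either intersects the reference interval or has already passed beyond it.
#' A rapidly diverging series can step across a narrow reference interval
#' between two consecutive samples, and the first sample at or beyond the
#' reference is then the minimum time at which reference-level divergence
#' had been attained.  The alternative criterion `"range"` asks instead when
#' the fossil point estimate first reaches the lower edge of the reference's
#' bootstrap range.  The age is returned in years since the first sample and
#' in generations (2 years per generation); a trajectory that never reaches
#' the reference returns `NA`.
#'
#' @param traj a [divergence_trajectory()].
#' @param reference a [divergence()] fit, a list with `boot_mean`/`boot_sd`
#'   (optionally `values`), or a numeric vector of bootstrap values.
#' @param criterion `"sd-interval"` or `"range"`.
#' @return list with `age_years`, `generations` and `group` (all `NA` if no
#'   overlap).
#' @export
first_overlap_time <- function(traj, reference,
                               criterion = c("sd-interval", "range")) {
  stopifnot(inherits(traj, "divergence_trajectory"))
  criterion <- match.arg(criterion)
  s <- reference_summary(reference)
  hit <- switch(criterion,
    "sd-interval" =
      traj$boot_mean + traj$boot_sd >= s[["mean"]] - s[["sd"]],
    "range" = traj$d >= s[["lo"]])
  if (!any(hit))
    return(list(age_years = NA_real_, generations = NA_real_,
                group = NA_character_, criterion = criterion))
  k <- which(hit)[1L]
  list(age_years = traj$age_years[k],
       generations = traj$generations[k],
       group = traj$group[k],
       criterion = criterion)
}
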