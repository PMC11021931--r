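#' Correlated trait evolution through a temporal series
#'
#' For each trait, forms the vector of temporal sample means (one entry per
#' ordered group), then computes the pairwise Pearson correlations among
#' those vectors for all traits.  Strongly positive off-diagonal
#' correlations indicate that traits reduce together through time.
#'
#' @param table a [specimen_table()].
#' @param ordered_groups group labels in temporal order (default: fossil
#'   groups sorted by `sample_order`); at least 3 required.
#' @param traits trait codes (default: all registry traits).
#' @return An object of class `trait_correlations`: the correlation matrix
#'   `r` plus the off-diagonal `mean`, `sd` and `median`.
#' @export
trait_mean_correlations <- function(table, ordered_groups = NULL,
                                    traits = NULL) {
  stopifnot(inherits(table, "specimen_table"))
  registry <- table_registry(table)
  if (is.null(traits)) traits <- registry$code
  df <- as.data.frame(table)
  if (is.null(ordered_groups)) {
    ord <- unique(df[!is.na(df$sample_order), c("group", "sample_order")])
    ord <- ord[order(ord$sample_order), ]
    ordered_groups <- ord$group
  }
  if (length(ordered_groups) < 3L)
    stop("need >= 3 ordered groups")
  M <- t(vapply(ordered_groups, function(g)
    mean_vector(table, g, traits), numeric(length(traits))))
  colnames(M) <- traits
  r <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))
  diag(r) <- 1
  off <- r[upper.tri(r)]
  structure(list(r = r,
                 mean = mean(off, na.rm = TRUE),
                 sd = stats::sd(off, na.rm = TRUE),
                 median = stats::median(off, na.rm = TRUE),
                 n_pairs = length(off),
                 groups = ordered_groups),
            class = "trait_correlations")
}

#' @export
print.trait_correlations <- function(x, ...) {
  cat("Pairwise Pearson correlations among trait-mean time vectors (",
      nrow(x$r), " traits, ", x$n_pairs, " pairs)\n", sep = "")
  cat("  off-diagonal mean ", format(x$mean, digits = 3L),
      ", s.d. ", format(x$sd, digits = 3L),
      ", median ", format(x$median, digits = 3L), "\n", sep = "")
  invisible(x)
}

#' @export
plot.trait_correlations <- function(x, ...) {
  k <- nrow(x$r)
  pal <- grDevices::hcl.colors(21L, "Blue-Red 3", rev = TRUE)
  graphics::image(seq_len(k), seq_len(k), t(x$r[k:1, ]), zlim = c(-1, 1),
                  col = pal, axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1L, at = seq_len(k), labels = colnames(x$r), las = 2L,
                 cex.axis = 0.7)
  graphics::axis(2L, at = seq_len(k), labels = rev(rownames(x$r)), las = 2L,
                 cex.axis = 0.7)
  invisible(x)
}
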