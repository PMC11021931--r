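#' Dichotomize armour phenotypes into a 2x2 table
#'
#' A specimen has a *full pelvis* when its pelvic score equals exactly 3
#' (scores such as 2.6 count as reduced) and is *high-spined* when it carries
#' exactly three dorsal spines.  Records missing either armour score are
#' excluded and counted in a message.
#'
#' @param table a [specimen_table()].
#' @return An object of class `armour_table`: counts `a` (full pelvis, 3
#'   spines), `b` (full pelvis, <3 spines), `c` (reduced pelvis, 3 spines),
#'   `d` (reduced pelvis, <3 spines), the total `n`, and the dichotomy rule.
#' @export
dichotomize_armour <- function(table) {
  stopifnot(inherits(table, "specimen_table"))
  if (!nrow(table)) stop("empty table")
  ps <- table$pelvic_score
  sp <- table$dorsal_spine_count
  keep <- !is.na(ps) & !is.na(sp)
  n_dropped <- sum(!keep)
  if (n_dropped)
    message(n_dropped, " specimen(s) with missing armour values excluded")
  if (!any(keep)) stop("no specimens with complete armour scores")
  full <- ps[keep] == 3
  three <- sp[keep] == 3
  structure(list(a = sum(full & three),
                 b = sum(full & !three),
                 c = sum(!full & three),
                 d = sum(!full & !three),
                 n = sum(keep),
                 rule = "full pelvis: pelvic_score == 3; high spines: dorsal_spine_count == 3"),
            class = "armour_table")
}

#' Construct an armour contingency table from counts
#'
#' @param a,b,c,d cell counts: rows are full/reduced pelvis, columns are
#'   three/fewer-than-three dorsal spines.
#' @return An `armour_table`.
#' @export
armour_table <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (sum(counts) < 1L) stop("table must hold at least one specimen")
  structure(list(a = a, b = b, c = c, d = d, n = sum(counts),
                 rule = "full pelvis: pelvic_score == 3; high spines: dorsal_spine_count == 3"),
            class = "armour_table")
}

#' @export
print.armour_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2L, byrow = TRUE,
              dimnames = list(pelvis = c("full", "reduced"),
                              spines = c("three", "fewer")))
  cat("Armour contingency table (n = ", x$n, ")\n", sep = "")
  print(m)
  invisible(x)
}

#' Fisher exact test of pelvis-spine association
#'
#' Exact two-sided p-value for a 2x2 armour table, defined by summing the
#' hypergeometric probabilities (at the observed margins) of all tables at
#' most as probable as the observed one -- the convention implemented by
#' [stats::fisher.test()].  If a margin is zero the association is
#' undefined and p = 1 is returned by convention, with a warning.
#'
#' @param t an [armour_table()] (or [dichotomize_armour()] result).
#' @return list with `p_two_sided`, the sample odds ratio `odds_ratio`
#'   (`a*d / (b*c)`, `Inf` when only concordant cells are filled), and the
#'   conditional-MLE odds ratio `odds_ratio_cmle`.
#' @export
fisher_exact_2x2 <- function(t) {
  stopifnot(inherits(t, "armour_table"))
  m <- matrix(c(t$a, t$b, t$c, t$d), 2L, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("a table margin is zero; association undefined, p = 1")
    ad <- t$a * t$d
    bc <- t$b * t$c
    or <- if (bc == 0 && ad == 0) NaN else if (bc == 0) Inf else ad / bc
    return(list(p_two_sided = 1, odds_ratio = or, odds_ratio_cmle = NA_real_))
  }
  ft <- stats::fisher.test(m)
  ad <- t$a * t$d
  bc <- t$b * t$c
  or <- if (bc == 0 && ad == 0) NaN else if (bc == 0) Inf else ad / bc
  list(p_two_sided = unname(ft$p.value),
       odds_ratio = or,
       odds_ratio_cmle = unname(ft$estimate))
}

#' Frequencies of mixed armour phenotypes
#'
#' Proportions, among all specimens with complete armour scores, of the two
#' discordant phenotypes: full pelvis with reduced dorsal spines, and three
#' dorsal spines with a reduced pelvis.  Low frequencies of both indicate
#' that the armour traits travel together, as expected under reproductive
#' isolation between high- and low-armoured forms.
#'
#' @param table a [specimen_table()].
#' @return list with `prop_full_pelvis_reduced_spines`,
#'   `prop_three_spines_reduced_pelvis` and the number of scored specimens
#'   `n`.
#' @export
mixed_armour_frequencies <- function(table) {
  ct <- dichotomize_armour(table)
  list(prop_full_pelvis_reduced_spines = ct$b / ct$n,
       prop_three_spines_reduced_pelvis = ct$c / ct$n,
       n = ct$n)
}
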