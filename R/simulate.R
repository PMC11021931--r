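#' Trait trajectory defaults for the fossil series generator
#'
#' One row per generated quantity: the 16 registry traits plus the pelvic
#' score.  `shape` is `"plateau"` (exponential approach,
#' `mean(t) = end + (start - end) * exp(-(t - lag)+ / tau)`, monotone
#' non-increasing after the lag) or `"linear"` (straight interpolation between
#' the endpoints).  Armour traits are plateau-shaped -- they reduce first and
#' fastest before levelling off -- with the pelvic traits lagging by 3000
#' years; body size and the other non-armour traits reduce slowly and near
#' linearly.  End minus start equals the published first-to-last mean
#' difference for each trait, and `sd` is the square root of the published
#' pooled within-sample variance, so the generator's study conditions match
#' the fossil series the package is designed for.  Counts are generated by
#' rounding a latent Gaussian and clamping to `[lo, hi]`.
#'
#' @return data frame with columns `code`, `shape`, `start`, `end`, `sd`,
#'   `lag`, `tau`, `lo`, `hi`.
#' @export
default_fossil_trajectories <- function() {
  tr <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
code          shape    start   end     sd    lag   tau   lo  hi
stl           linear   55.0    40.55   3.08  0     NA    0   Inf
mds           plateau  3.0     1.04    0.57  0     2500  0   3
mcv           linear   16.0    14.99   0.75  0     NA    0   Inf
mpt           linear   5.0     4.23    0.75  0     NA    0   Inf
maf           linear   8.0     7.69    0.81  0     NA    0   Inf
mdf           linear   11.0    10.86   0.84  0     NA    0   Inf
mav           linear   12.0    11.98   0.54  0     NA    0   Inf
lps.sc        plateau  9.0     2.19    0.71  3000  2500  0   Inf
tpg.sc        plateau  12.0    4.15    1.16  0     2500  0   Inf
ds1.sc        plateau  6.5     1.62    0.78  0     2500  0   Inf
ds2.sc        plateau  8.0     2.07    1.02  0     2500  0   Inf
ds3.sc        plateau  3.5     2.03    0.61  0     2500  0   Inf
lpt.sc        plateau  4.0     2.91    0.62  3000  2500  0   Inf
ect.sc        linear   5.0     3.45    0.91  0     NA    0   Inf
pmx.sc        linear   2.8     2.42    0.57  0     NA    0   Inf
cle.sc        linear   12.0    11.17   0.88  0     NA    0   Inf
pelvic_score  plateau  3.0     0.5     0.40  3000  2500  0   3
")
  tr
}

## default allometric slopes (mm trait per mm standard length) for the
## size-corrected continuous traits
default_allometry <- function() {
  c("lps.sc" = 0.12, "tpg.sc" = 0.15, "ds1.sc" = 0.10, "ds2.sc" = 0.12,
    "ds3.sc" = 0.06, "lpt.sc" = 0.08, "ect.sc" = 0.10, "pmx.sc" = 0.05,
    "cle.sc" = 0.20)
}

trajectory_mean <- function(t, span, shape, start, end, lag, tau) {
  if (shape == "linear") {
    start + (end - start) * (t / span)
  } else {
    end + (start - end) * exp(-pmax(t - lag, 0) / tau)
  }
}

#' Parameters for the fossil time-series generator
#'
#' Defaults reproduce the analyzed series' design: 18 temporal samples evenly
#' spanning 16 363 years (roughly 1000-year spacing), 12--67 specimens per
#' sample, armour trajectories that plateau, near-linear non-armour
#' trajectories, allometric dependence of continuous traits on standard
#' length, exchangeably correlated among-specimen noise, and sparse random
#' missingness.
#'
#' @param n_samples number of temporal samples.
#' @param span_years total span in years (first sample at age 0).
#' @param n_range inclusive range for the per-sample specimen counts.
#' @param trajectories per-trait trajectory table; see
#'   [default_fossil_trajectories()].
#' @param allometry named vector of slopes on standard length for the
#'   size-corrected continuous traits (use 0 or an empty vector for none).
#' @param noise_correlation exchangeable among-trait correlation of the
#'   per-specimen deviations, in `[0, 1)`.
#' @param miss_rate per-cell probability that a trait value is missing.
#' @return A parameter list of class `fossil_series_params`.
#' @export
fossil_series_params <- function(n_samples = 18L,
                                 span_years = 16363,
                                 n_range = c(12L, 67L),
                                 trajectories = default_fossil_trajectories(),
                                 allometry = default_allometry(),
                                 noise_correlation = 0.35,
                                 miss_rate = 0.05) {
  stopifnot(n_samples >= 2L, span_years > 0,
            length(n_range) == 2L, n_range[1] >= 2L, n_range[1] <= n_range[2],
            noise_correlation >= 0, noise_correlation < 1,
            miss_rate >= 0, miss_rate < 1)
  plateau <- trajectories$shape == "plateau"
  if (any(plateau & trajectories$end > trajectories$start))
    stop("inadmissible trajectory: end_mean > start_mean for monotone-",
         "decreasing trait ",
         paste(trajectories$code[plateau &
                                 trajectories$end > trajectories$start],
               collapse = ", "))
  if (any(plateau & (is.na(trajectories$tau) | trajectories$tau <= 0)))
    stop("plateau trajectories need a positive tau")
  if (any(trajectories$lag < 0)) stop("lag_years must be >= 0")
  structure(list(n_samples = as.integer(n_samples),
                 span_years = span_years,
                 n_range = as.integer(n_range),
                 trajectories = trajectories,
                 allometry = allometry,
                 noise_correlation = noise_correlation,
                 miss_rate = miss_rate),
            class = "fossil_series_params")
}

#' Simulate a fossil time series with known truth
#'
#' Generates a [specimen_table()] following `params`, together with a
#' `synthetic_truth` record holding the realized per-sample true trait means
#' (the clamped latent means), the true allometric slopes, and the true
#' multivariate divergence `d` between the first and last true mean vectors.
#' Continuous traits include the configured allometric component of standard
#' length, centred on the design's global mean standard length, so that the
#' size-corrected pipeline recovers the latent trajectories.
#'
#' @param params a [fossil_series_params()] list.
#' @param seed integer seed; fixed seeds give identical tables.
#' @return list with elements `table` and `truth`.
#' @export
simulate_fossil_series <- function(params = fossil_series_params(),
                                   seed = NULL) {
  stopifnot(inherits(params, "fossil_series_params"))
  set_seed_if(seed)
  registry <- default_registry()
  tr <- params$trajectories
  rownames(tr) <- tr$code
  codes <- registry$code
  if (!all(codes %in% tr$code))
    stop("trajectory table must cover every registry trait")
  span <- params$span_years
  ## ages to the nearest 0.001 year so the CSV dialect round-trips exactly
  ages <- round(seq(0, span, length.out = params$n_samples), 3L)

  ## latent per-sample means for every generated quantity
  gen_codes <- tr$code
  latent <- sapply(gen_codes, function(code) {
    r <- tr[code, ]
    m <- trajectory_mean(ages, span, r$shape, r$start, r$end, r$lag, r$tau)
    pmin(pmax(m, r$lo), r$hi)
  })
  rownames(latent) <- sprintf("K%02d", seq_len(params$n_samples))

  stl_center <- mean(latent[, "stl"])
  rho <- params$noise_correlation
  allo <- params$allometry

  rows <- vector("list", params$n_samples)
  for (k in seq_len(params$n_samples)) {
    n_k <- sample_int(params$n_range[2] - params$n_range[1] + 1L, 1L) +
      params$n_range[1] - 1L
    shared <- stats::rnorm(n_k)                     # among-trait correlation
    z <- sapply(gen_codes, function(code)
      sqrt(rho) * shared + sqrt(1 - rho) * stats::rnorm(n_k))
    z <- matrix(z, nrow = n_k,
                dimnames = list(NULL, gen_codes))
    ## size deviations stay independent of the trait noise, so the only
    ## trait-size covariance within a sample is the allometric slope itself
    z[, "stl"] <- stats::rnorm(n_k)

    r_stl <- tr["stl", ]
    stl <- latent[k, "stl"] + r_stl$sd * z[, "stl"]
    stl <- round(pmax(stl, 1), 6L)

    vals <- matrix(NA_real_, n_k, length(codes),
                   dimnames = list(NULL, codes))
    for (code in codes) {
      r <- tr[code, ]
      v <- latent[k, code] + r$sd * z[, code]
      if (code == "stl") {
        v <- stl
      } else if (registry$kind[registry$code == code] == "continuous") {
        slope <- if (code %in% names(allo)) allo[[code]] else 0
        v <- v + slope * (stl - stl_center)
        v <- round(pmin(pmax(v, r$lo), r$hi), 6L)
      } else {
        v <- pmin(pmax(round(v), r$lo), r$hi)
      }
      vals[, code] <- v
    }

    r_ps <- tr["pelvic_score", ]
    ps <- latent[k, "pelvic_score"] + r_ps$sd * z[, "pelvic_score"]
    ps <- round(pmin(pmax(ps, 0), 3), 2L)

    rows[[k]] <- data.frame(
      specimen_id = sprintf("K%02d_%03d", k, seq_len(n_k)),
      dataset = "fossil",
      group = sprintf("K%02d", k),
      sample_order = k,
      age_years = ages[k],
      pelvic_score = ps,
      dorsal_spine_count = vals[, "mds"],
      vals,
      check.names = FALSE,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)

  if (params$miss_rate > 0) {
    for (code in codes) {
      drop <- stats::runif(nrow(records)) < params$miss_rate
      records[[code]][drop] <- NA_real_
    }
  }

  table <- specimen_table(records, registry,
                          provenance = "synthetic fossil series")
  truth <- structure(list(
    kind = "fossil_series",
    groups = rownames(latent),
    ages = ages,
    true_means = latent[, codes, drop = FALSE],
    true_pelvic_score = latent[, "pelvic_score"],
    true_slopes = allo,
    stl_center = stl_center,
    true_d = euclidean_d(latent[1L, codes], latent[params$n_samples, codes]),
    params = params),
    class = "synthetic_truth")
  list(table = table, truth = truth)
}

#' Parameters for the species-pair lakes generator
#'
#' Defaults mirror the extant yardstick data: five lakes, each with a benthic
#' and a limnetic ecotype, 22--69 specimens per lake-ecotype combination, and
#' per-lake ecotype contrasts scaled so that the realized multivariate `d`
#' values span the published range (about 8--27).  The contrast template is a
#' unit vector dominated by body size, with smaller armour/feeding components.
#'
#' @param lakes lake names.
#' @param lake_d per-lake target true multivariate divergence between ecotype
#'   mean vectors (the benthic-limnetic contrast norm).
#' @param offset_scale scalar multiplier on `lake_d`; 0 gives a true null.
#' @param n_range inclusive range of per-group specimen counts.
#' @param base_means named per-trait grand means around which ecotypes split.
#' @param sds named per-trait within-group standard deviations.
#' @param allometry,noise_correlation,miss_rate as in
#'   [fossil_series_params()].
#' @return A parameter list of class `pair_lakes_params`.
#' @export
pair_lakes_params <- function(lakes = c("little_quarry", "enos", "paxton",
                                        "priest", "emily"),
                              lake_d = c(26.9, 18.6, 16.1, 12.1, 7.8),
                              offset_scale = 1,
                              n_range = c(22L, 69L),
                              base_means = NULL,
                              sds = NULL,
                              allometry = default_allometry(),
                              noise_correlation = 0.35,
                              miss_rate = 0.05) {
  stopifnot(length(lakes) == length(lake_d), offset_scale >= 0,
            length(n_range) == 2L, n_range[1] >= 2L, n_range[1] <= n_range[2])
  if (is.null(base_means))
    base_means <- c(stl = 48, mds = 2.8, mcv = 15, mpt = 5, maf = 8,
                    mdf = 11, mav = 12, "lps.sc" = 7, "tpg.sc" = 9,
                    "ds1.sc" = 5, "ds2.sc" = 6, "ds3.sc" = 3,
                    "lpt.sc" = 3.5, "ect.sc" = 4.5, "pmx.sc" = 2.6,
                    "cle.sc" = 11)
  if (is.null(sds)) {
    tr <- default_fossil_trajectories()
    sds <- stats::setNames(tr$sd, tr$code)[names(base_means)]
  }
  template <- c(stl = 12, "lps.sc" = 2, "tpg.sc" = 3, "ds1.sc" = 1.5,
                "ds2.sc" = 1.8, "ds3.sc" = 0.8, "lpt.sc" = 1, "ect.sc" = 1,
                "pmx.sc" = 0.5, "cle.sc" = 2, mds = 0.3, mcv = 1, mpt = 0.5,
                maf = 1, mdf = 0.5, mav = 0.5)
  template <- template / sqrt(sum(template^2))
  structure(list(lakes = lakes,
                 lake_d = stats::setNames(lake_d * offset_scale, lakes),
                 n_range = as.integer(n_range),
                 base_means = base_means,
                 sds = sds,
                 template = template,
                 allometry = allometry,
                 noise_correlation = noise_correlation,
                 miss_rate = miss_rate),
            class = "pair_lakes_params")
}

#' Simulate benthic-limnetic species-pair lakes with known truth
#'
#' Generates `length(params$lakes) * 2` groups labelled `lake.benthic` /
#' `lake.limnetic`.  Within each lake the two ecotype mean vectors sit at
#' `base +- (d_l / 2) * template`, so the true multivariate divergence between
#' ecotype means is `d_l` (up to clamping of count traits at their admissible
#' range, which the truth record reflects).
#'
#' @param params a [pair_lakes_params()] list.
#' @param seed integer seed.
#' @return list with elements `table` and `truth`.
#' @export
simulate_species_pairs <- function(params = pair_lakes_params(),
                                   seed = NULL) {
  stopifnot(inherits(params, "pair_lakes_params"))
  set_seed_if(seed)
  registry <- default_registry()
  codes <- registry$code
  base <- params$base_means[codes]
  u <- params$template[codes]
  sds <- params$sds[codes]
  rho <- params$noise_correlation
  allo <- params$allometry

  clamp_lo <- ifelse(codes == "mds", 0, 0)
  clamp_hi <- ifelse(codes == "mds", 3, Inf)
  names(clamp_lo) <- names(clamp_hi) <- codes

  groups <- as.vector(t(outer(params$lakes, c("benthic", "limnetic"),
                              paste, sep = ".")))
  true_means <- matrix(NA_real_, length(groups), length(codes),
                       dimnames = list(groups, codes))
  for (lake in params$lakes) {
    delta <- params$lake_d[[lake]]
    bent <- pmin(pmax(base + (delta / 2) * u, clamp_lo), clamp_hi)
    limn <- pmin(pmax(base - (delta / 2) * u, clamp_lo), clamp_hi)
    true_means[paste(lake, "benthic", sep = "."), ] <- bent
    true_means[paste(lake, "limnetic", sep = "."), ] <- limn
  }
  stl_center <- mean(true_means[, "stl"])

  rows <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    n_g <- sample_int(params$n_range[2] - params$n_range[1] + 1L, 1L) +
      params$n_range[1] - 1L
    shared <- stats::rnorm(n_g)
    z <- sapply(codes, function(code)
      sqrt(rho) * shared + sqrt(1 - rho) * stats::rnorm(n_g))
    z <- matrix(z, nrow = n_g, dimnames = list(NULL, codes))
    z[, "stl"] <- stats::rnorm(n_g)

    stl <- true_means[g, "stl"] + sds[["stl"]] * z[, "stl"]
    stl <- round(pmax(stl, 1), 6L)

    vals <- matrix(NA_real_, n_g, length(codes),
                   dimnames = list(NULL, codes))
    for (code in codes) {
      v <- true_means[g, code] + sds[[code]] * z[, code]
      if (code == "stl") {
        v <- stl
      } else if (registry$kind[registry$code == code] == "continuous") {
        slope <- if (code %in% names(allo)) allo[[code]] else 0
        v <- v + slope * (stl - stl_center)
        v <- round(pmin(pmax(v, clamp_lo[[code]]), clamp_hi[[code]]), 6L)
      } else {
        v <- pmin(pmax(round(v), clamp_lo[[code]]), clamp_hi[[code]])
      }
      vals[, code] <- v
    }

    rows[[gi]] <- data.frame(
      specimen_id = sprintf("%s_%03d", g, seq_len(n_g)),
      dataset = "extant",
      group = g,
      sample_order = NA_integer_,
      age_years = NA_real_,
      pelvic_score = pmin(pmax(round(3 + 0.2 * z[, "mds"], 2L), 0), 3),
      dorsal_spine_count = vals[, "mds"],
      vals,
      check.names = FALSE,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)

  if (params$miss_rate > 0) {
    for (code in codes) {
      drop <- stats::runif(nrow(records)) < params$miss_rate
      records[[code]][drop] <- NA_real_
    }
  }

  table <- specimen_table(records, registry,
                          provenance = "synthetic species-pair lakes")
  true_d <- vapply(params$lakes, function(lake)
    euclidean_d(true_means[paste(lake, "benthic", sep = "."), ],
                true_means[paste(lake, "limnetic", sep = "."), ]),
    numeric(1L))
  truth <- structure(list(
    kind = "species_pairs",
    groups = groups,
    true_means = true_means,
    true_slopes = allo,
    stl_center = stl_center,
    true_d = true_d,
    params = params),
    class = "synthetic_truth")
  list(table = table, truth = truth)
}

#' Parameters for mixed high/low armour samples
#'
#' Emulates a temporal sample in which high-armoured immigrants (full pelvis,
#' three dorsal spines) co-occur with the resident low-armoured population.
#' `hybridization_rate` is the probability that a specimen's pelvis and spine
#' states are drawn independently of one another rather than jointly: 0 gives
#' perfect association between the two armour traits, 1 gives independence,
#' as expected if the traits were free to recombine in a panmictic population.
#'
#' @param n_low,n_high numbers of low- and high-armoured specimens
#'   (`n_low + n_high >= 4`).
#' @param hybridization_rate probability in `[0, 1]`.
#' @return A parameter list of class `armour_scenario_params`.
#' @export
armour_scenario_params <- function(n_low, n_high, hybridization_rate = 0) {
  stopifnot(n_low >= 0, n_high >= 0,
            hybridization_rate >= 0, hybridization_rate <= 1)
  if (n_low + n_high < 4L)
    stop("n_low + n_high must be >= 4")
  structure(list(n_low = as.integer(n_low), n_high = as.integer(n_high),
                 hybridization_rate = hybridization_rate),
            class = "armour_scenario_params")
}

#' Simulate a mixed-armour sample
#'
#' Specimens carry only the two armour scores (all measurement traits are
#' missing).  High-armoured specimens have pelvic score 3 and three dorsal
#' spines; low-armoured specimens have pelvic scores at or below 1 and fewer
#' than three spines.  With probability `hybridization_rate` a specimen's
#' spine state is redrawn from the sample-wide marginal distribution,
#' decoupling it from the pelvis.
#'
#' @param params an [armour_scenario_params()] list.
#' @param seed integer seed.
#' @return A [specimen_table()].
#' @export
simulate_armour_sample <- function(params, seed = NULL) {
  stopifnot(inherits(params, "armour_scenario_params"))
  set_seed_if(seed)
  registry <- default_registry()
  n <- params$n_low + params$n_high
  high <- c(rep(TRUE, params$n_high), rep(FALSE, params$n_low))

  pelvic <- ifelse(high, 3,
                   sample(c(0, 0.5, 1), n, replace = TRUE,
                          prob = c(0.5, 0.3, 0.2)))
  low_spines <- function(m)
    sample(0:2, m, replace = TRUE, prob = c(0.55, 0.35, 0.10))
  spines <- ifelse(high, 3L, NA_integer_)
  spines[!high] <- low_spines(sum(!high))

  ## hybridization: decouple the spine state from the pelvis
  mix <- stats::runif(n) < params$hybridization_rate
  if (any(mix)) {
    p_high <- params$n_high / n
    redraw_high <- stats::runif(sum(mix)) < p_high
    new_spines <- integer(sum(mix))
    new_spines[redraw_high] <- 3L
    new_spines[!redraw_high] <- low_spines(sum(!redraw_high))
    spines[mix] <- new_spines
  }

  traits <- matrix(NA_real_, n, nrow(registry),
                   dimnames = list(NULL, registry$code))
  records <- data.frame(
    specimen_id = sprintf("A_%03d", seq_len(n)),
    dataset = "fossil",
    group = "mixed_sample",
    sample_order = 1L,
    age_years = 0,
    pelvic_score = pelvic,
    dorsal_spine_count = spines,
    traits,
    check.names = FALSE,
    stringsAsFactors = FALSE)
  specimen_table(records, registry,
                 provenance = "synthetic mixed-armour sample")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic truth record (", x$kind, ")\n", sep = "")
  if (x$kind == "fossil_series")
    cat("  true first-to-last d:", format(x$true_d), "\n")
  else
    cat("  true per-lake d:",
        paste(names(x$true_d), format(x$true_d), sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}
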