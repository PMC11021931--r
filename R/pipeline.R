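#' Configure the full divergence pipeline
#'
#' Bundles every setting of the end-to-end analysis in one place.  The
#' defaults are the study's stated settings: outlier threshold 3.5 pooled
#' s.d., 99 bootstrap replicates, 99 permutations, family-wise alpha 0.05
#' split over the traits, and the sd-interval overlap criterion.  Inputs are
#' either CSV paths (`fossil_csv`, `pairs_csv`, `armour_csv`) or simulation
#' parameter lists used to generate them.
#'
#' @param seed master seed; every stage draws from a derived substream.
#' @param threshold_sd outlier screen threshold.
#' @param B,P bootstrap replicates and permutations.
#' @param alpha_total family-wise error rate before Bonferroni splitting.
#' @param overlap_criterion `"sd-interval"` or `"range"`.
#' @param drop_traits trait codes excluded from multivariate statistics.
#' @param out_dir optional directory for artifacts (masked tables, model,
#'   reports, manifest); `NULL` keeps everything in memory.
#' @param fossil_csv,pairs_csv,armour_csv optional input CSV paths.
#' @param fossil_params,pairs_params,armour_params simulation parameters
#'   used when the corresponding CSV is absent.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            threshold_sd = 3.5,
                            B = 99L, P = 99L,
                            alpha_total = 0.05,
                            overlap_criterion = "sd-interval",
                            drop_traits = NULL,
                            out_dir = NULL,
                            fossil_csv = NULL,
                            pairs_csv = NULL,
                            armour_csv = NULL,
                            fossil_params = fossil_series_params(),
                            pairs_params = pair_lakes_params(),
                            armour_params = armour_scenario_params(63L, 7L)) {
  stopifnot(threshold_sd > 0, B >= 2L, P >= 2L,
            alpha_total > 0, alpha_total < 1)
  structure(list(seed = as.integer(seed), threshold_sd = threshold_sd,
                 B = as.integer(B), P = as.integer(P),
                 alpha_total = alpha_total,
                 overlap_criterion = overlap_criterion,
                 drop_traits = drop_traits, out_dir = out_dir,
                 fossil_csv = fossil_csv, pairs_csv = pairs_csv,
                 armour_csv = armour_csv,
                 fossil_params = fossil_params,
                 pairs_params = pairs_params,
                 armour_params = armour_params),
            class = "pipeline_config")
}

#' Run the full divergence pipeline
#'
#' Orchestrates simulate/load, outlier masking, size correction, the armour
#' association screen, the first-versus-last divergence fit, per-lake
#' species-pair divergences, Welch comparisons, the divergence trajectory
#' with overlap timing against the least-diverged pair and the grand-mean
#' pair reference, and the correlated-trait-evolution summary.  Reruns with
#' the same configuration are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `divergence_pipeline` with all stage results and
#'   a `manifest` of seeds and per-stage record counts; artifacts are also
#'   written under `config$out_dir` when set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## --- inputs -----------------------------------------------------------
  fossil_truth <- pairs_truth <- NULL
  fossil <- stage("simulate/load fossil", {
    if (!is.null(config$fossil_csv)) {
      read_specimen_table(config$fossil_csv)
    } else {
      sim <- simulate_fossil_series(config$fossil_params,
                                    seed = derive_seed(config$seed, 11L))
      fossil_truth <- sim$truth
      sim$table
    }
  })
  pairs <- stage("simulate/load pairs", {
    if (!is.null(config$pairs_csv)) {
      read_specimen_table(config$pairs_csv)
    } else {
      sim <- simulate_species_pairs(config$pairs_params,
                                    seed = derive_seed(config$seed, 12L))
      pairs_truth <- sim$truth
      sim$table
    }
  })
  armour <- stage("simulate/load armour", {
    if (!is.null(config$armour_csv)) {
      read_specimen_table(config$armour_csv)
    } else {
      simulate_armour_sample(config$armour_params,
                             seed = derive_seed(config$seed, 13L))
    }
  })

  ## --- preprocess -------------------------------------------------------
  prep <- function(table) {
    rep_ <- detect_outliers(table, config$threshold_sd)
    masked <- apply_outlier_mask(table, rep_)
    model <- fit_size_correction(masked)
    list(report = rep_, model = model,
         corrected = size_correct(masked, model))
  }
  fossil_prep <- stage("preprocess fossil", prep(fossil))
  pairs_prep <- stage("preprocess pairs", prep(pairs))

  ## --- armour association ----------------------------------------------
  assoc <- stage("armour association", {
    ct <- dichotomize_armour(armour)
    c(list(table = ct), fisher_exact_2x2(ct),
      mixed = mixed_armour_frequencies(armour))
  })

  ## --- divergence -------------------------------------------------------
  fdf <- as.data.frame(fossil_prep$corrected)
  ord <- unique(fdf[!is.na(fdf$sample_order), c("group", "sample_order")])
  ord <- ord[order(ord$sample_order), ]
  fossil_groups <- ord$group
  fossil_div <- stage("fossil divergence", {
    divergence(fossil_prep$corrected,
               fossil_groups[1L], fossil_groups[length(fossil_groups)],
               drop_traits = config$drop_traits,
               B = config$B, P = config$P,
               alpha_total = config$alpha_total,
               seed = derive_seed(config$seed, 21L))
  })

  lakes <- unique(sub("\\.(benthic|limnetic)$", "", pairs$group))
  pair_divs <- stage("species-pair divergence", {
    out <- lapply(seq_along(lakes), function(i) {
      divergence(pairs_prep$corrected,
                 paste0(lakes[i], ".benthic"),
                 paste0(lakes[i], ".limnetic"),
                 drop_traits = config$drop_traits,
                 B = config$B, P = config$P,
                 alpha_total = config$alpha_total,
                 seed = derive_seed(config$seed, 30L + i))
    })
    names(out) <- lakes
    out
  })
  comparisons <- stage("Welch comparisons", {
    lapply(pair_divs, function(p) compare_divergence(fossil_div, p))
  })

  ## --- timing -----------------------------------------------------------
  pair_means <- vapply(pair_divs, function(p) p$boot$mean, numeric(1L))
  least <- names(which.min(pair_means))
  grand_ref <- list(boot_mean = mean(pair_means),
                    boot_sd = stats::sd(pair_means) / sqrt(length(pair_means)))
  traj <- stage("divergence trajectory", {
    divergence_trajectory(fossil_prep$corrected, fossil_groups,
                          drop_traits = config$drop_traits,
                          B = config$B,
                          seed = derive_seed(config$seed, 41L),
                          references = c(pair_divs,
                                         list(grand_mean = grand_ref)))
  })
  timing <- stage("overlap timing", list(
    least_diverged_pair = least,
    first_overlap_least = first_overlap_time(traj, pair_divs[[least]],
                                             config$overlap_criterion),
    first_overlap_grand_mean = first_overlap_time(traj, grand_ref,
                                                  config$overlap_criterion)))

  ## --- correlated trait evolution --------------------------------------
  correlations <- stage("trait correlations", {
    trait_mean_correlations(fossil_prep$corrected, fossil_groups)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("paleodiv")),
    seed = config$seed,
    settings = list(threshold_sd = config$threshold_sd, B = config$B,
                    P = config$P, alpha_total = config$alpha_total,
                    alpha_family = fossil_div$alpha_family,
                    overlap_criterion = config$overlap_criterion,
                    drop_traits = config$drop_traits,
                    n_traits_used = length(fossil_div$traits)),
    counts = list(
      fossil_specimens = nrow(fossil),
      pair_specimens = nrow(pairs),
      armour_specimens = nrow(armour),
      fossil_cells_masked = nrow(fossil_prep$report$flagged),
      pair_cells_masked = nrow(pairs_prep$report$flagged),
      bootstrap_redraws = fossil_div$boot$redraws,
      n_significant_traits = attr(fossil_div$trait_table, "n_significant")))

  result <- structure(list(
    manifest = manifest,
    fossil_table = fossil, pairs_table = pairs, armour_table = armour,
    fossil_truth = fossil_truth, pairs_truth = pairs_truth,
    fossil_prep = fossil_prep, pairs_prep = pairs_prep,
    armour_association = assoc,
    fossil_divergence = fossil_div,
    pair_divergences = pair_divs,
    comparisons = comparisons,
    trajectory = traj,
    timing = timing,
    correlations = correlations),
    class = "divergence_pipeline")

  if (!is.null(config$out_dir)) write_pipeline_artifacts(result, config)
  result
}

write_pipeline_artifacts <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$out_dir, ...)
  write_specimen_table(result$fossil_prep$corrected, p("fossil_corrected.csv"))
  write_specimen_table(result$pairs_prep$corrected, p("pairs_corrected.csv"))
  utils::write.csv(result$fossil_prep$report$flagged, p("fossil_outliers.csv"),
                   row.names = FALSE)
  write_results(result$fossil_prep$model, p("fossil_size_model.json"))
  utils::write.csv(as.data.frame(result$fossil_divergence$trait_table),
                   p("trait_divergence.csv"), row.names = FALSE)
  write_results(result$armour_association, p("armour_association.json"))
  write_results(result$fossil_divergence, p("fossil_divergence.json"))
  write_results(result$pair_divergences, p("pair_divergences.json"))
  write_results(as.data.frame(result$trajectory), p("trajectory.json"))
  write_results(result$timing, p("timing.json"))
  write_results(result$correlations, p("trait_correlations.json"))
  write_results(result$manifest, p("manifest.json"))
  invisible(config$out_dir)
}

#' @export
print.divergence_pipeline <- function(x, ...) {
  cat("Divergence pipeline run (seed ", x$manifest$seed, ")\n", sep = "")
  print(x$fossil_divergence)
  pm <- vapply(x$pair_divergences, function(p) p$boot$mean, numeric(1L))
  cat("Species-pair bootstrap mean d:\n")
  print(round(pm, 2L))
  ov <- x$timing$first_overlap_least
  cat("First overlap with least-diverged pair (",
      x$timing$least_diverged_pair, "): ",
      format(ov$age_years), " years (", format(ov$generations),
      " generations)\n", sep = "")
  cat("Mean trait-mean correlation:",
      format(x$correlations$mean, digits = 3L), "\n")
  invisible(x)
}
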