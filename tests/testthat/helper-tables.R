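# Build a small specimen table from a data frame holding `group` plus any
# subset of trait/armour columns; everything else is filled with valid
# constants so validation passes.
build_table <- function(df, dataset = "fossil") {
  reg <- default_registry()
  groups <- unique(df$group)
  out <- df
  out$specimen_id <- sprintf("S%03d", seq_len(nrow(df)))
  out$dataset <- dataset
  if (dataset == "fossil") {
    out$sample_order <- match(df$group, groups)
    out$age_years <- (out$sample_order - 1L) * 1000
  } else {
    out$sample_order <- NA_integer_
    out$age_years <- NA_real_
  }
  if (!"pelvic_score" %in% names(out)) out$pelvic_score <- NA_real_
  if (!"dorsal_spine_count" %in% names(out))
    out$dorsal_spine_count <- NA_integer_
  for (code in setdiff(reg$code, names(out))) out[[code]] <- 1
  specimen_table(out, reg)
}

# armour-only table from per-specimen pelvic scores and spine counts
armour_specimens <- function(pelvic, spines) {
  build_table(data.frame(group = "mixed", pelvic_score = pelvic,
                         dorsal_spine_count = spines))
}

# published first-vs-last rank statistics for the 16-trait fossil series
# (trait code, U, first/last sample sizes, printed effect size)
reference_rank_stats <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
trait    U       n_first n_last cles_printed
mds      2.5     42      55     0.00
lps.sc   0.0     42      49     0.00
tpg.sc   3.0     41      49     0.00
ds1.sc   0.0     31      50     0.00
ds3.sc   0.0     35      54     0.00
ds2.sc   28.0    40      53     0.01
lpt.sc   46.0    41      47     0.02
ect.sc   92.0    32      46     0.06
stl      318.5   43      55     0.13
mcv      321.0   42      55     0.14
mpt      346.0   39      48     0.18
pmx.sc   339.0   37      41     0.22
cle.sc   92.0    13      31     0.23
maf      840.5   43      52     0.38
mdf      1052.5  43      53     0.46
mav      612.0   31      40     0.49
")
}

# a noise-free generator configuration: linear trajectories with integer
# count endpoints, no allometry, no missingness
noise_free_params <- function() {
  tr <- default_fossil_trajectories()
  tr$shape <- "linear"
  tr$sd <- 0
  tr$lag <- 0
  is_count <- tr$code %in% c("mds", "mcv", "mpt", "maf", "mdf", "mav")
  tr$start[is_count] <- round(tr$start[is_count])
  tr$end[is_count] <- round(tr$end[is_count])
  fossil_series_params(trajectories = tr, allometry = numeric(0),
                       noise_correlation = 0, miss_rate = 0)
}
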