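# End-to-end experiment pipelines on synthetic cohorts.
#
# Each pipeline is a pure function of (config, seed): the same config and
# seed reproduce byte-identical tables. Analysis never touches the
# generating (truth) parameters; truth is joined only into the `recovery`
# section of the result.

# Per-window PLV of a trial restricted to a segment [seg0, seg1) seconds,
# using phases computed over the full trial (so filter transients at trial
# edges do not contaminate interior segments).
segment_plv <- function(ph_brain, ph_env, fs_hz, seg0, seg1,
                        window_s, overlap_s) {
  starts <- window_starts(seg1 - seg0, window_s, overlap_s) + seg0
  wn <- round(window_s * fs_hz)
  vapply(starts, function(s0) {
    i0 <- round(s0 * fs_hz) + 1L
    plv(ph_brain$values[i0:(i0 + wn - 1L)], ph_env$values[i0:(i0 + wn - 1L)])
  }, numeric(1))
}

# Stimulation-window and baseline-window PLV for both auditory channels of
# one recording, pooling window PLVs across trials. The first `transient_s`
# seconds after stimulation onset are discarded (oscillator settling);
# baseline windows keep 0.5 s clear of the trial edge (filter transients)
# and of the stimulation onset (acausal ring of the zero-phase filter).
recording_plv_metrics <- function(rec, band, window_s, overlap_s,
                                  transient_s = 1, edge_s = 0.5) {
  fs <- rec$fs_hz
  nb_s <- rec$baseline_s
  total_s <- dim(rec$data)[3] / fs
  ph_env <- narrowband_phase(rec$envelope_rec, fs, band[1], band[2])
  out <- list()
  for (ch in c("audL", "audR")) {
    stim_w <- c(); base_w <- c()
    for (j in seq_len(dim(rec$data)[1])) {
      ph_b <- narrowband_phase(rec$data[j, ch, ], fs, band[1], band[2])
      stim_w <- c(stim_w, segment_plv(ph_b, ph_env, fs, nb_s + transient_s,
                                      total_s, window_s, overlap_s))
      if (nb_s > 0)
        base_w <- c(base_w, segment_plv(ph_b, ph_env, fs, edge_s,
                                        nb_s - edge_s, window_s, overlap_s))
    }
    out[[ch]] <- list(stim = mean(stim_w),
                      base = if (nb_s > 0) mean(base_w) else NA_real_)
  }
  out
}

# Mean within-trial Morlet wPLI between two channels of a recording.
recording_wpli <- function(rec, ch_x, ch_y, f0_hz = 4.5, n_cycles = 9,
                           mode = c("per_trial", "pooled")) {
  mode <- match.arg(mode)
  vals <- c(); pooledY <- c()
  for (j in seq_len(dim(rec$data)[1])) {
    zx <- morlet_coefficients(rec$data[j, ch_x, ], rec$fs_hz, f0_hz, n_cycles)
    zy <- morlet_coefficients(rec$data[j, ch_y, ], rec$fs_hz, f0_hz, n_cycles)
    if (mode == "per_trial") {
      vals <- c(vals, as.numeric(wpli_square_time(zx, zy)))
    } else {
      keep <- !(zx$edge | zy$edge)
      X <- zx$coeffs[keep] * Conj(zy$coeffs[keep])
      m <- Mod(X)
      pooledY <- c(pooledY, ifelse(m > 0, Im(X) / m, 0))
    }
  }
  if (mode == "per_trial") mean(vals) else as.numeric(debiased_square(pooledY))
}

default_config <- function(config, defaults) {
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$seed)) stop("config$seed is mandatory")
  cfg
}

write_pipeline_outputs <- function(result, out_dir, prefix) {
  if (is.null(out_dir)) return(invisible(result))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$table, file.path(out_dir, paste0(prefix, "_metrics.csv")),
            row.names = FALSE)
  jsonlite::write_json(
    list(config = result$config, stats = result$stats),
    file.path(out_dir, paste0(prefix, "_summary.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}

#' Rate-tuning experiment on a synthetic cohort
#'
#' Replays the rate-tuning design: each subject hears syllable trains at
#' several rates with a silent pre-stimulus baseline; per rate and
#' hemisphere the percent change of the windowed PLV (band = rate +- 0.5 Hz,
#' 2 s windows, 1 s overlap) from baseline is computed, plus the asymmetry
#' index from the stimulation-window PLVs. Cohort statistics: 2-SD outlier
#' exclusion per metric within rate, Kruskal-Wallis across rates per
#' hemisphere, Wilcoxon signed-rank of the asymmetry against zero per rate
#' with BH-FDR across rates.
#'
#' @param config list; recognized entries (with defaults):
#'   `seed` (mandatory), `n_subjects` (17), `rates_hz`
#'   (`c(2.5, 3.5, 4.5, 5.5, 6.5)`), `n_trials` (8), `fs_hz` (200),
#'   `stim_s` (6), `baseline_s` (3), `window_s` (2), `overlap_s` (1),
#'   `transient_s` (1), `out_dir` (NULL), plus any
#'   [sample_subject_params()] argument under `cohort` (a list).
#' @return list with `table` (per subject x rate metrics), `stats`
#'   (Kruskal-Wallis per hemisphere and on the asymmetry; per-rate Wilcoxon
#'   raw and FDR-adjusted p; which rates are FDR-significant with positive
#'   asymmetry), `recovery` (metrics joined with truth), `config`.
#' @export
run_rate_tuning <- function(config = list()) {
  cfg <- default_config(config, list(
    n_subjects = 17, rates_hz = c(2.5, 3.5, 4.5, 5.5, 6.5), n_trials = 12,
    fs_hz = 200, stim_s = 6, baseline_s = 3, window_s = 2, overlap_s = 1,
    transient_s = 1, out_dir = NULL, cohort = list()))
  params <- do.call(sample_subject_params,
                    c(list(n_subjects = cfg$n_subjects, seed = cfg$seed),
                      cfg$cohort))
  rows <- list()
  for (r_i in seq_along(cfg$rates_hz)) {
    rate <- cfg$rates_hz[r_i]
    spec <- stimulus_spec(rate, cfg$stim_s, cfg$fs_hz,
                          seed = derive_seed(cfg$seed, 1000 + r_i))
    band <- c(rate - 0.5, rate + 0.5)
    for (k in seq_along(params)) {
      rec <- simulate_subject(params[[k]], spec, cfg$n_trials,
                              baseline_s = cfg$baseline_s)
      m <- recording_plv_metrics(rec, band, cfg$window_s, cfg$overlap_s,
                                 cfg$transient_s)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = k, rate_hz = rate,
        plv_left = m$audL$stim, plv_right = m$audR$stim,
        plv_base_left = m$audL$base, plv_base_right = m$audR$base,
        pc_left = percent_change(m$audL$stim, m$audL$base),
        pc_right = percent_change(m$audR$stim, m$audR$base),
        asymmetry = asymmetry_index(m$audR$stim, m$audL$stim)$value)
    }
  }
  tab <- do.call(rbind, rows)

  excl <- function(metric) {
    keep <- rep(TRUE, nrow(tab))
    for (rate in cfg$rates_hz) {
      i <- tab$rate_hz == rate
      keep[i] <- exclude_outliers(tab[[metric]][i])$keep
    }
    keep
  }
  by_rate <- function(metric, keep)
    lapply(cfg$rates_hz, function(r) tab[[metric]][tab$rate_hz == r & keep])
  keep_l <- excl("pc_left"); keep_r <- excl("pc_right"); keep_a <- excl("asymmetry")
  kw_left <- rank_tests(by_rate("pc_left", keep_l), "kruskal_wallis")
  kw_right <- rank_tests(by_rate("pc_right", keep_r), "kruskal_wallis")
  kw_asym <- rank_tests(by_rate("asymmetry", keep_a), "kruskal_wallis")
  asym_groups <- by_rate("asymmetry", keep_a)
  p_asym <- vapply(asym_groups, function(a)
    rank_tests(a, "wilcoxon_signed_rank")$p_value, numeric(1))
  fdr <- fdr_bh(p_asym)
  sig_pos <- fdr$reject &
    vapply(asym_groups, function(a) median(a) > 0, logical(1))
  stats <- list(
    kw_left = kw_left, kw_right = kw_right, kw_asymmetry = kw_asym,
    asym_p_raw = p_asym, asym_p_fdr = fdr$p_adj,
    rates_hz = cfg$rates_hz, sig_positive_rates = cfg$rates_hz[sig_pos],
    n_excluded = c(pc_left = sum(!keep_l), pc_right = sum(!keep_r),
                   asymmetry = sum(!keep_a)))
  result <- list(table = tab, stats = stats,
                 recovery = merge(tab, attr(params, "truth"),
                                  by = "subject_id"),
                 config = cfg[setdiff(names(cfg), "out_dir")])
  write_pipeline_outputs(result, cfg$out_dir, "rate_tuning")
}

#' Connectivity-asymmetry experiment on a synthetic cohort
#'
#' Each subject hears a 4.5 syll/s stream; per subject the windowed PLV
#' (3.5--5.5 Hz, 1 s windows, 0.5 s overlap) gives the asymmetry index, and
#' the within-trial Morlet wPLI (4.5 Hz, 9 cycles) between the left
#' auditory and frontal channels gives the fronto-auditory connectivity.
#' The cohort-level result is the Spearman correlation between wPLI and
#' asymmetry after 2-SD exclusion. The `recovery` section joins the truth
#' table and adds a median split of the cohort by true top-down gain with a
#' Mann-Whitney comparison of the asymmetry between halves.
#'
#' @param config list; recognized entries (with defaults): `seed`
#'   (mandatory), `n_subjects` (37), `rate_hz` (4.5), `n_trials` (6),
#'   `trial_s` (10), `fs_hz` (200), `band_hz` (`c(3.5, 5.5)`), `window_s`
#'   (1), `overlap_s` (0.5), `wavelet_f0_hz` (4.5), `wavelet_cycles` (9),
#'   `wpli_mode` (`"per_trial"`), `transient_s` (1), `out_dir` (NULL),
#'   `cohort` (list passed to [sample_subject_params()], default
#'   `rho = 0.8`).
#' @return list with `table`, `stats` (Spearman rho/p, exclusion counts),
#'   `recovery`, `config`.
#' @export
run_connectivity_cohort <- function(config = list()) {
  cfg <- default_config(config, list(
    n_subjects = 37, rate_hz = 4.5, n_trials = 8, trial_s = 10, fs_hz = 200,
    band_hz = c(3.5, 5.5), window_s = 1, overlap_s = 0.5,
    wavelet_f0_hz = 4.5, wavelet_cycles = 9, wpli_mode = "per_trial",
    transient_s = 1, out_dir = NULL,
    cohort = list(rho = 0.8, g_range = c(0.3, 1.5))))
  params <- do.call(sample_subject_params,
                    c(list(n_subjects = cfg$n_subjects, seed = cfg$seed),
                      cfg$cohort))
  spec <- stimulus_spec(cfg$rate_hz, cfg$trial_s, cfg$fs_hz,
                        seed = derive_seed(cfg$seed, 2000))
  rows <- list()
  for (k in seq_along(params)) {
    rec <- simulate_subject(params[[k]], spec, cfg$n_trials)
    m <- recording_plv_metrics(rec, cfg$band_hz, cfg$window_s,
                               cfg$overlap_s, cfg$transient_s)
    rows[[k]] <- data.frame(
      subject_id = k,
      plv_left = m$audL$stim, plv_right = m$audR$stim,
      asymmetry = asymmetry_index(m$audR$stim, m$audL$stim)$value,
      wpli_frontal = recording_wpli(rec, "audL", "frontal",
                                    cfg$wavelet_f0_hz, cfg$wavelet_cycles,
                                    cfg$wpli_mode))
  }
  tab <- do.call(rbind, rows)
  keep <- exclude_outliers(tab$asymmetry)$keep &
    exclude_outliers(tab$wpli_frontal)$keep
  sc <- spearman_cor(tab$wpli_frontal[keep], tab$asymmetry[keep])
  lr <- rank_tests(list(tab$plv_right[keep], tab$plv_left[keep]),
                   "wilcoxon_signed_rank")
  truth <- attr(params, "truth")
  hi <- truth$g_td > median(truth$g_td)
  mw <- rank_tests(list(tab$asymmetry[hi], tab$asymmetry[!hi]),
                   "mann_whitney")
  stats <- list(spearman_rho = sc$rho, spearman_p = sc$p_value,
                n_used = sc$n, n_excluded = sum(!keep),
                plv_right_vs_left = lr)
  result <- list(
    table = tab, stats = stats,
    recovery = list(
      truth = merge(tab, truth, by = "subject_id"),
      split_by_g_td = list(
        mean_asym_high_g = mean(tab$asymmetry[hi]),
        mean_asym_low_g = mean(tab$asymmetry[!hi]),
        mann_whitney = mw)),
    config = cfg[setdiff(names(cfg), "out_dir")])
  write_pipeline_outputs(result, cfg$out_dir, "connectivity")
}

#' Condition-contrast experiment on a synthetic cohort
#'
#' Two conditions per subject differ only in the top-down gain: the
#' semantic-analog condition multiplies each subject's `g_td` by
#' `semantic_boost`. Per subject and condition, trial-wise coherence at
#' `f0_hz` between each auditory channel and the stimulus envelope (with
#' Fisher z), the asymmetry index from the coherence values, and the
#' trial-wise debiased wPLI between left auditory and frontal channels.
#' Trial counts are matched between conditions by seeded random
#' subselection when they differ. Tests: paired Wilcoxon on the asymmetry
#' between conditions; per-condition paired Wilcoxon of left vs right
#' Fisher z; per-condition Spearman between dwPLI and asymmetry.
#'
#' @param config list; recognized entries (with defaults): `seed`
#'   (mandatory), `n_subjects` (19), `rate_hz` (4), `n_trials`
#'   (`c(non_semantic = 12, semantic = 12)`), `trial_s` (10), `fs_hz` (200),
#'   `f0_hz` (4), `semantic_boost` (3), `transient_s` (1), `out_dir`
#'   (NULL), `cohort` (list passed to [sample_subject_params()]; default
#'   `g_range = c(0.1, 0.5)`).
#' @return list with `table`, `stats`, `recovery`, `config`.
#' @export
run_condition_contrast <- function(config = list()) {
  cfg <- default_config(config, list(
    n_subjects = 19, rate_hz = 4, n_trials = c(non_semantic = 12, semantic = 12),
    trial_s = 10, fs_hz = 200, f0_hz = 4, semantic_boost = 3,
    transient_s = 1, out_dir = NULL, cohort = list(g_range = c(0.1, 0.5))))
  params <- do.call(sample_subject_params,
                    c(list(n_subjects = cfg$n_subjects, seed = cfg$seed),
                      cfg$cohort))
  spec <- stimulus_spec(cfg$rate_hz, cfg$trial_s, cfg$fs_hz,
                        seed = derive_seed(cfg$seed, 3000))
  n_match <- min(cfg$n_trials)
  fs <- cfg$fs_hz
  seg <- (round(cfg$transient_s * fs) + 1L):round(cfg$trial_s * fs)
  rows <- list()
  for (k in seq_along(params)) {
    sp <- params[[k]]
    for (cond in c("non_semantic", "semantic")) {
      sp_c <- sp
      if (cond == "semantic") {
        sp_c$g_td <- sp$g_td * cfg$semantic_boost
        sp_c$seed <- derive_seed(sp$seed, 777L)
      }
      rec <- simulate_subject(sp_c, spec, cfg$n_trials[[cond]],
                              condition = cond)
      sel <- seq_len(cfg$n_trials[[cond]])
      if (cfg$n_trials[[cond]] > n_match)
        sel <- sort(with_seed(derive_seed(cfg$seed, 5000 + 2 * k +
                                            (cond == "semantic")),
                              sample(sel, n_match)))
      env_seg <- rec$envelope_rec[seg]
      env_tr <- matrix(rep(env_seg, length(sel)), nrow = length(sel),
                       byrow = TRUE)
      coh <- lapply(c(audL = "audL", audR = "audR"), function(ch)
        coherence_at_freq(rec$data[sel, ch, seg, drop = TRUE], env_tr,
                          fs, cfg$f0_hz))
      zx <- trial_coefficients(rec$data[sel, "audL", seg, drop = TRUE],
                               fs, cfg$f0_hz)
      zy <- trial_coefficients(rec$data[sel, "frontal", seg, drop = TRUE],
                               fs, cfg$f0_hz)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = k, condition = cond, n_trials_used = length(sel),
        coh_left = coh$audL$value, coh_right = coh$audR$value,
        z_left = coh$audL$fisher_z, z_right = coh$audR$fisher_z,
        asymmetry = asymmetry_index(coh$audR$value, coh$audL$value)$value,
        dwpli_frontal = as.numeric(dwpli_trials(zx, zy)))
    }
  }
  tab <- do.call(rbind, rows)
  sem <- tab[tab$condition == "semantic", ]
  non <- tab[tab$condition == "non_semantic", ]
  d_asym <- sem$asymmetry - non$asymmetry
  keep_d <- exclude_outliers(d_asym)$keep
  paired <- rank_tests(d_asym[keep_d], "wilcoxon_signed_rank")
  lr_test <- function(sub) {
    dz <- sub$z_left - sub$z_right
    keep <- exclude_outliers(dz)$keep
    rank_tests(dz[keep], "wilcoxon_signed_rank")
  }
  sp_cond <- function(sub) {
    keep <- exclude_outliers(sub$dwpli_frontal)$keep &
      exclude_outliers(sub$asymmetry)$keep
    tryCatch(spearman_cor(sub$dwpli_frontal[keep], sub$asymmetry[keep]),
             error = function(e) list(rho = NA_real_, p_value = NA_real_,
                                      n = sum(keep)))
  }
  stats <- list(
    paired_asym_p = paired$p_value, n_pairs_used = paired$n,
    mean_asym_semantic = mean(sem$asymmetry[keep_d]),
    mean_asym_non_semantic = mean(non$asymmetry[keep_d]),
    left_vs_right = list(semantic = lr_test(sem), non_semantic = lr_test(non)),
    spearman_dwpli = list(semantic = sp_cond(sem), non_semantic = sp_cond(non)))
  result <- list(table = tab, stats = stats,
                 recovery = merge(tab, attr(params, "truth"),
                                  by = "subject_id"),
                 config = cfg[setdiff(names(cfg), "out_dir")])
  write_pipeline_outputs(result, cfg$out_dir, "condition_contrast")
}
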