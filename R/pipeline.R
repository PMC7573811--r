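#' Build a pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()]: study arms
#' (a control light:dark arm and dim-light-at-night arms of increasing
#' exposure), per-arm rhythm-degradation and waking-delay settings, group
#' sizes, generator settings and analysis settings. All values can be
#' overridden by arguments or supplied as a YAML file to [read_config()].
#'
#' Arm defaults emulate the canonical exposure ladder: exposure indices
#' 1-4 code 0, 1, 7 and 30 days of exposure for the delay regression; the
#' three-month arm has no usable waking peak and is excluded from it
#' (`exposure_index = NA`). Programmed waking delays span 2-8 h and
#' disruption rises with exposure.
#'
#' @param seed Master seed; every per-animal seed derives from it.
#' @param n_activity Activity traces per arm (default 3).
#' @param n_eeg EEG/EMG recordings per arm (default 1).
#' @param activity_days Days per activity trace (default 15).
#' @param eeg_days Days per recording (default 2: baseline + deprivation
#'   day).
#' @param arms Optional arm table overriding the default five-arm design.
#' @return A config list (class `noxlux_config`).
#' @export
default_config <- function(seed = 1L, n_activity = 3, n_eeg = 1,
                           activity_days = 15, eeg_days = 2, arms = NULL) {
  arms <- arms %||% tibble(
    arm = c("control_LD", "DLAN_1d", "DLAN_1w", "DLAN_1m", "DLAN_3m"),
    night_lux = c(0, 5, 5, 5, 5),
    disruption = c(0, 0.1, 0.3, 0.5, 0.8),
    phase_delay_h = c(0, 2, 5, 8, 0),
    exposure_index = c(1, 2, 3, 4, NA)
  )
  structure(
    list(
      seed = as.integer(seed),
      arms = arms,
      n_activity = n_activity,
      n_eeg = n_eeg,
      activity = list(days = activity_days, bin_seconds = 60, mean_rate = 50,
                      circadian_amplitude = 0.9, fractal_beta = 1),
      eeg = list(days = eeg_days, sd_start_zt_h = 0, sd_duration_h = 6),
      dfa_fit_range_h = c(3, 8),
      periodogram_grid_h = c(20, 28, 0.05),
      swa_band = "swa",
      bin_hours = 2
    ),
    class = "noxlux_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file may set any subset of the [default_config()] fields
#' (unknown fields are rejected); `seed` is mandatory in the file.
#'
#' @param path YAML file.
#' @return A config list (class `noxlux_config`).
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) abort("`seed` is mandatory in the config file.")
  base <- default_config(seed = y$seed)
  known <- names(base)
  extra <- setdiff(names(y), known)
  if (length(extra)) {
    abort(paste("Unknown config fields:", paste(extra, collapse = ", ")))
  }
  for (nm in setdiff(names(y), "arms")) {
    if (is.list(y[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modifyList(base[[nm]], y[[nm]])
    } else {
      base[[nm]] <- y[[nm]]
    }
  }
  if (!is.null(y$arms)) base$arms <- dplyr::bind_rows(y$arms)
  structure(base, class = "noxlux_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage `%s` failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full simulation-and-analysis pipeline
#'
#' For every arm: simulate rest-activity traces and run the periodogram and
#' DFA; simulate baseline + sleep-deprivation EEG/EMG recordings, compute
#' 4-s epoch spectra, flag artifacts, score vigilance states, and build
#' state-percentage and slow-wave-activity timecourses with the
#' recovery-versus-baseline rebound. Then assemble the statistics report:
#' one-way ANOVAs for DFA alpha and rhythm strength across arms,
#' Bonferroni-corrected t-tests of each arm against control, and the
#' waking-peak delay regression on the exposure index. Fully reproducible
#' from config + seed.
#'
#' @param config A config list from [default_config()] or [read_config()].
#' @param out_dir Optional directory: writes TSV tables and a JSON stats
#'   report.
#' @return A report bundle (list of tibbles): `activity`, `timecourses`,
#'   `swa`, `rebound`, `scoring`, `stats`, `config`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  stopifnot(inherits(config, "noxlux_config"))
  set.seed(config$seed)
  seeds <- matrix(sample.int(.Machine$integer.max %/% 2,
                             nrow(config$arms) * (config$n_activity +
                                                    config$n_eeg)),
                  nrow = nrow(config$arms))
  pg_grid <- seq(config$periodogram_grid_h[1], config$periodogram_grid_h[2],
                 by = config$periodogram_grid_h[3])
  acts <- list(); tcs <- list(); tc_raw <- list()
  swas <- list(); rebs <- list(); scs <- list()
  for (a in seq_len(nrow(config$arms))) {
    arm <- config$arms[a, ]
    schedule <- light_schedule(night_lux = arm$night_lux)
    # --- actigraphy arm ---
    acts[[a]] <- pipeline_stage(paste0("actigraphy:", arm$arm), {
      purrr::map_dfr(seq_len(config$n_activity), function(i) {
        p <- activity_params(
          days = config$activity$days,
          bin_seconds = config$activity$bin_seconds,
          mean_rate = config$activity$mean_rate,
          circadian_amplitude = config$activity$circadian_amplitude,
          fractal_beta = config$activity$fractal_beta,
          phase_delay_h = arm$phase_delay_h,
          disruption = arm$disruption,
          seed = seeds[a, i]
        )
        tr <- simulate_activity(p, schedule)
        pg <- periodogram(tr, pg_grid)
        dd <- dfa(tr, config$dfa_fit_range_h)
        tibble(arm = arm$arm, animal = i, alpha = dd$alpha,
               fit_r2 = dd$fit_r2, peak_period_h = pg$peak_period_h,
               strength = pg$strength, significant = pg$peak_significant)
      })
    })
    # --- sleep arm ---
    for (i in seq_len(config$n_eeg)) {
      key <- paste0(arm$arm, ":", i)
      res <- pipeline_stage(paste0("sleep:", key), {
        p <- eeg_gen_params(days = config$eeg$days,
                            phase_delay_h = arm$phase_delay_h,
                            seed = seeds[a, config$n_activity + i])
        sdp <- if (config$eeg$days >= 2) {
          sd_protocol(config$eeg$sd_start_zt_h, config$eeg$sd_duration_h)
        }
        sim <- simulate_recording(p, schedule, sd = sdp)
        sp <- epoch_and_fft(sim$recording)
        sp <- detect_artifacts(sp, sim$recording)
        hyp <- score_epochs(sp)
        tc <- state_percent_timecourse(hyp, config$bin_hours)
        swa <- swa_timecourse(sp, hyp, config$swa_band, config$bin_hours)
        reb <- if (config$eeg$days >= 2) {
          compare_recovery_to_baseline(tc, tc, baseline_day = 1,
                                       recovery_day = 2)
        }
        list(tc = tc, swa = swa, reb = reb,
             agree = scoring_agreement(hyp, sim$hypnogram))
      })
      tc_raw[[key]] <- res$tc
      tcs[[key]] <- dplyr::mutate(res$tc, arm = arm$arm, animal = i)
      swas[[key]] <- dplyr::mutate(res$swa, arm = arm$arm, animal = i)
      if (!is.null(res$reb)) {
        rebs[[key]] <- dplyr::mutate(res$reb, arm = arm$arm, animal = i)
      }
      scs[[key]] <- tibble(arm = arm$arm, animal = i, agreement = res$agree)
    }
  }
  activity <- dplyr::bind_rows(acts)
  timecourses <- dplyr::bind_rows(tcs)
  # --- statistics report ---
  stats_out <- pipeline_stage("stats_report", {
    res <- list(
      alpha_anova = anova_table(activity, "alpha", "arm"),
      strength_anova = anova_table(activity, "strength", "arm"),
      alpha_vs_control = bonferroni_ttests(
        activity, "alpha", "arm",
        plan = purrr::map(setdiff(config$arms$arm, config$arms$arm[1]),
                          ~c(config$arms$arm[1], .x))),
      arm_means = activity |>
        dplyr::group_by(.data$arm) |>
        dplyr::summarise(mean_alpha = mean(.data$alpha),
                         mean_strength = mean(.data$strength),
                         .groups = "drop")
    )
    idx_arms <- config$arms[!is.na(config$arms$exposure_index), ]
    if (nrow(idx_arms) >= 3 && length(tc_raw) > 0 && config$bin_hours == 2) {
      peaks <- purrr::map_dfr(seq_len(nrow(idx_arms)), function(j) {
        keys <- grep(paste0("^", idx_arms$arm[j], ":"), names(tc_raw),
                     value = TRUE)
        pk <- purrr::map_dbl(keys, function(k) {
          waking_peak(tc_raw[[k]], day = 1)$peak_zt_h
        })
        tibble(arm = idx_arms$arm[j], exposure_index = idx_arms$exposure_index[j],
               peak_zt_h = mean(pk))
      })
      res$peak_regression <- glance(
        fit_delay_regression(peaks$exposure_index, peaks$peak_zt_h))
      res$peaks <- peaks
    }
    res
  })
  bundle <- list(activity = activity, timecourses = timecourses,
                 swa = dplyr::bind_rows(swas), rebound = dplyr::bind_rows(rebs),
                 scoring = dplyr::bind_rows(scs), stats = stats_out,
                 config = config)
  if (!is.null(out_dir)) write_report(bundle, out_dir)
  bundle
}

write_report <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("activity", "timecourses", "swa", "rebound", "scoring")) {
    if (nrow(bundle[[nm]] %||% tibble()) > 0) {
      readr::write_tsv(bundle[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
    }
  }
  jsonlite::write_json(
    purrr::map(bundle$stats, function(x) if (is.data.frame(x)) x else x),
    file.path(out_dir, "stats_report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(out_dir)
}
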