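# Orchestration of the full study design: Pre / Post 1 / Post 2 sessions
# for treatment and control groups, imaging and behavior arms, and the
# bootstrap comparison tables.

#' Configuration of a simulated dosing study
#'
#' Defaults mirror the reference design: a treatment group of 6 imaging
#' experiments whose response gain is biphasic across conditions (1, 1.4,
#' 0.8) and whose shared trial noise steps from 0.10 to 0.25 in the late
#' session, against a control group of 3 experiments with constant gain and
#' noise structure; plus 5 treatment-like and 5 control-like behavior
#' videos. Gains and correlation steps are calibration choices for the
#' synthetic reference study, not measured values.
#'
#' @param n_experiments Named vector: imaging experiments per group.
#' @param n_neurons Neurons per experiment.
#' @param conditions Session labels, in order.
#' @param gain Named list of per-condition response gains per group.
#' @param rho Named list of per-condition shared-noise correlations per
#'   group.
#' @param trial_noise_sd,tuning_width_oct,base_amplitude Generator
#'   parameters shared by both groups (see [synth_neural_config()]).
#' @param protocol Tone protocol parameters, passed to
#'   [make_tone_protocol()].
#' @param include_behavior Run the behavior arm.
#' @param n_mice Behavior videos per group.
#' @param behavior Behavior-arm parameters: video `duration_s`, `fps`,
#'   frame `shape`, hypoactivity `switch_time_s`, speeds, and analysis
#'   `windows_min`.
#' @param n_boot Bootstrap replicates for every comparison.
#' @return A `study_config` list.
#' @export
study_config <- function(n_experiments = c(treatment = 6, control = 3),
                         n_neurons = 100,
                         conditions = c("Pre", "Post1", "Post2"),
                         gain = list(treatment = c(1, 1.4, 0.8),
                                     control = c(1, 1, 1)),
                         rho = list(treatment = c(0.10, 0.10, 0.25),
                                    control = c(0.10, 0.10, 0.10)),
                         trial_noise_sd = 0.2,
                         tuning_width_oct = 1,
                         base_amplitude = 0.3,
                         protocol = list(),
                         include_behavior = TRUE,
                         n_mice = c(treatment = 5, control = 5),
                         behavior = list(duration_s = 2400, fps = 30,
                                         shape = c(64, 64),
                                         switch_time_s = 600,
                                         speed_pre = 20, speed_post = 3,
                                         windows_min = list(c(0, 10),
                                                            c(10, 60))),
                         n_boot = 10000) {
  cfg <- as.list(environment())
  for (g in names(cfg$gain)) {
    if (length(cfg$gain[[g]]) != length(conditions) ||
        length(cfg$rho[[g]]) != length(conditions))
      stop("`gain` and `rho` need one entry per condition for group ", g)
  }
  structure(cfg, class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Top-level YAML keys map one-to-one onto [study_config()] arguments;
#' omitted keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown study config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(raw$behavior$windows_min))
    raw$behavior$windows_min <- lapply(raw$behavior$windows_min, unlist)
  for (k in c("n_experiments", "n_mice"))
    if (!is.null(raw[[k]])) raw[[k]] <- unlist(raw[[k]])
  do.call(study_config, raw)
}

# One imaging session: simulate, extract, QC, dF/F, sigma-normalize.
# Returns per-neuron mean amplitudes, per-neuron off-BF percentages, and
# the experiment-mean noise correlation.
run_imaging_session <- function(config, protocol, condition) {
  exper <- simulate_experiment(config, protocol, condition)
  traces <- neuropil_correct(exper$traces, coeff = config$neuropil_coeff)
  keep <- qc_filter_cells(traces)
  tensor <- compute_dff(traces, protocol, neurons = keep)
  tensor <- sigma_normalize(tensor)
  amp <- response_amplitude(tensor)
  ftc <- tuning_curve(amp, tensor$trial_frequencies,
                      protocol$frequencies_khz)
  nc <- noise_correlations(amp, tensor$trial_frequencies)
  list(
    mean_amplitude = rowMeans(amp),
    off_bf_pct = suppressWarnings(off_bf_ratio(ftc)),
    noise_corr_mean = nc$experiment_mean,
    n_neurons = nrow(amp)
  )
}

run_imaging_arm <- function(cfg, protocol, seeds) {
  out <- list()
  s <- 0L
  for (grp in names(cfg$n_experiments)) {
    for (e in seq_len(cfg$n_experiments[[grp]])) {
      s <- s + 1L
      for (ci in seq_along(cfg$conditions)) {
        ncfg <- synth_neural_config(
          n_neurons = cfg$n_neurons,
          tuning_width_oct = cfg$tuning_width_oct,
          base_amplitude = cfg$base_amplitude,
          condition_gain = stats::setNames(cfg$gain[[grp]], cfg$conditions),
          shared_noise_rho = cfg$rho[[grp]][ci],
          trial_noise_sd = cfg$trial_noise_sd,
          seed = seeds[s]
        )
        res <- run_imaging_session(ncfg, protocol, cfg$conditions[ci])
        res$group <- grp; res$experiment <- e
        res$condition <- cfg$conditions[ci]
        out[[length(out) + 1L]] <- res
      }
    }
  }
  out
}

run_behavior_arm <- function(cfg, seeds) {
  b <- cfg$behavior
  out <- list()
  s <- 0L
  for (grp in names(cfg$n_mice)) {
    treatmentlike <- grp == names(cfg$n_mice)[1]
    for (m in seq_len(cfg$n_mice[[grp]])) {
      s <- s + 1L
      vid <- simulate_behavior_video(
        duration_s = b$duration_s, fps = b$fps, shape = b$shape,
        profile = if (treatmentlike)
          behavior_profile_hypoactive(b$switch_time_s, b$speed_pre,
                                      b$speed_post)
        else behavior_profile_control(b$speed_pre),
        htr_profile = if (treatmentlike) htr_rate_decaying()
        else htr_rate_constant(),
        seed = seeds[s]
      )
      trace <- movement_trace(vid)
      out[[length(out) + 1L]] <- list(
        group = grp, mouse = m,
        windows = suppressWarnings(window_means(trace, b$windows_min)),
        trace = trace,
        htr_times_s = vid$htr_times_s,
        duration_s = b$duration_s
      )
    }
  }
  out
}

pull <- function(sessions, field, group, condition = NULL) {
  vals <- lapply(sessions, function(x) {
    if (x$group != group) return(NULL)
    if (!is.null(condition) && x$condition != condition) return(NULL)
    x[[field]]
  })
  unlist(vals)
}

#' Run the full simulated study
#'
#' Executes the imaging arm (trace extraction, neuropil correction, QC,
#' dF/F, sigma normalization, 1-s amplitudes, tuning and noise
#' correlations, per experiment and condition) and optionally the behavior
#' arm (movement traces, window means, head-twitch template correlation),
#' then runs the pooled bootstrap comparisons:
#'
#' * response amplitudes between conditions, pooling neurons across a
#'   group's experiments;
#' * off-BF percentages between conditions, pooled the same way;
#' * noise correlations between conditions, one mean per experiment;
#' * behavior window means within and between groups, and template
#'   correlations between groups.
#'
#' Every stochastic stage receives a child seed derived from `seed`, so a
#' given `(config, seed)` pair reproduces the report exactly.
#'
#' @param config A [study_config()].
#' @param seed Top-level integer seed.
#' @return A `comparison_report`: `summary` data frame (one row per
#'   comparison: group, measure, conditions, sample sizes, means with SEM,
#'   `delta_mu`, `p_value`, `sig_level`), the full `tests` list of
#'   [bootstrap_mean_test()] results, per-session descriptives, and the
#'   config and seed.
#' @export
run_study <- function(config = study_config(), seed = 1) {
  cfg <- config
  n_img <- sum(cfg$n_experiments)
  n_beh <- if (cfg$include_behavior) sum(cfg$n_mice) else 0L
  seeds <- derive_seeds(seed, n_img + n_beh + 2L)
  protocol <- do.call(make_tone_protocol,
                      c(cfg$protocol, list(seed = seeds[n_img + n_beh + 1L])))
  boot_seed <- seeds[n_img + n_beh + 2L]

  sessions <- run_imaging_arm(cfg, protocol, seeds[seq_len(n_img)])
  behavior <- if (cfg$include_behavior)
    run_behavior_arm(cfg, seeds[n_img + seq_len(n_beh)]) else NULL

  tests <- list()
  rows <- list()
  bseq <- 0L
  add_test <- function(group, measure, label_a, label_b, A, B) {
    bseq <<- bseq + 1L
    bt <- bootstrap_mean_test(A, B, n_boot = cfg$n_boot,
                              seed = (boot_seed + bseq) %%
                                (.Machine$integer.max - 1L))
    key <- paste(group, measure, label_a, "vs", label_b, sep = "_")
    tests[[key]] <<- bt
    rows[[key]] <<- data.frame(
      group = group, measure = measure, a = label_a, b = label_b,
      n_a = bt$n_a, n_b = bt$n_b, mean_a = bt$mean_a, sem_a = bt$sem_a,
      mean_b = bt$mean_b, sem_b = bt$sem_b, delta_mu = bt$delta_mu,
      p_value = bt$p_value, sig_level = bt$sig_level
    )
  }

  cond_pairs <- utils::combn(cfg$conditions, 2, simplify = FALSE)
  for (grp in names(cfg$n_experiments)) {
    for (pr in cond_pairs) {
      add_test(grp, "amplitude", pr[1], pr[2],
               pull(sessions, "mean_amplitude", grp, pr[1]),
               pull(sessions, "mean_amplitude", grp, pr[2]))
      add_test(grp, "off_bf_pct", pr[1], pr[2],
               pull(sessions, "off_bf_pct", grp, pr[1]),
               pull(sessions, "off_bf_pct", grp, pr[2]))
      add_test(grp, "noise_corr", pr[1], pr[2],
               pull(sessions, "noise_corr_mean", grp, pr[1]),
               pull(sessions, "noise_corr_mean", grp, pr[2]))
    }
  }

  if (cfg$include_behavior) {
    grps <- names(cfg$n_mice)
    wm <- lapply(behavior, function(x) x$windows)
    grp_of <- vapply(behavior, function(x) x$group, character(1))
    early <- vapply(wm, `[[`, numeric(1), 1L)
    late <- vapply(wm, `[[`, numeric(1), 2L)
    for (grp in grps)
      add_test(grp, "movement", names(wm[[1]])[1], names(wm[[1]])[2],
               early[grp_of == grp], late[grp_of == grp])
    add_test("between", "movement_late", grps[1], grps[2],
             late[grp_of == grps[1]], late[grp_of == grps[2]])

    # Template built from the treatment-like group's generated head-twitch
    # events (the characteristic decaying time-course); every mouse's
    # movement trace is correlated against it.
    tmpl <- htr_template(
      unlist(lapply(behavior[grp_of == grps[1]], `[[`, "htr_times_s")),
      duration_s = cfg$behavior$duration_s, condition = grps[1])
    tc <- vapply(behavior, function(x)
      template_correlation(x$trace, tmpl), numeric(1))
    add_test("between", "template_corr", grps[1], grps[2],
             tc[grp_of == grps[1]], tc[grp_of == grps[2]])
    for (i in seq_along(behavior)) behavior[[i]]$template_corr <- tc[i]
  }

  # session-level descriptives (drop the heavy traces)
  sess_df <- do.call(rbind, lapply(sessions, function(x)
    data.frame(group = x$group, experiment = x$experiment,
               condition = x$condition, n_neurons = x$n_neurons,
               mean_amplitude = mean(x$mean_amplitude),
               mean_off_bf_pct = mean(x$off_bf_pct, na.rm = TRUE),
               noise_corr_mean = x$noise_corr_mean)))
  beh_df <- if (cfg$include_behavior)
    do.call(rbind, lapply(behavior, function(x)
      data.frame(group = x$group, mouse = x$mouse,
                 early = x$windows[[1]], late = x$windows[[2]],
                 n_htr = length(x$htr_times_s),
                 template_corr = x$template_corr))) else NULL

  structure(
    list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         tests = tests, sessions = sess_df, behavior = beh_df,
         config = cfg, seed = seed),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Study comparison report (seed", x$seed, ")\n\n")
  df <- x$summary
  df$p_value <- signif(df$p_value, 3)
  for (col in c("mean_a", "sem_a", "mean_b", "sem_b", "delta_mu"))
    df[[col]] <- signif(df[[col]], 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a comparison report to disk
#'
#' `summary.csv`, `sessions.csv` (and `behavior.csv` when present) plus a
#' `report.json` manifest carrying the configuration, seed and every test.
#'
#' @param report A [run_study()] result.
#' @param dir Output directory (created if missing).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$sessions, file.path(dir, "sessions.csv"),
                   row.names = FALSE)
  if (!is.null(report$behavior))
    utils::write.csv(report$behavior, file.path(dir, "behavior.csv"),
                     row.names = FALSE)
  tests <- lapply(report$tests, function(bt)
    bt[c("delta_mu", "p_value", "sig_level", "n_a", "n_b", "n_draw",
         "n_boot", "seed")])
  write_manifest_json(
    list(seed = report$seed,
         config = report$config[setdiff(names(report$config), "protocol")],
         tests = tests),
    file.path(dir, "report.json"))
  invisible(dir)
}
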