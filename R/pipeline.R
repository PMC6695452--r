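#' Default configuration for a full pipeline run
#'
#' The default sizes mirror the design of the experiments being emulated:
#' 70 neurons recorded with the saccade task (41 value-type, 29
#' salience-type), 19 neurons with the uncertain task, 86 exploration
#' sessions of 100 trials per cost condition, and 40+40 completed-trial
#' slots per saccade/uncertain session. Effect sizes (cost modulation of
#' neural responses, condition-specific learning rates, RT differences)
#' are on by default; `effects_on = FALSE` zeroes all of them, which
#' turns every contrast in the report into a null.
#'
#' @param subject response-window subject tag ("P" or "S").
#' @param effects_on master switch for all modelled effects.
#' @param n_neurons,n_uncertain_neurons,n_exploration_sessions cohort sizes.
#' @param n_rt_sessions saccade-task sessions simulated with gaze traces
#'   for the reaction-time contrasts.
#' @param true_rl_params generating [rl_params()] for exploration
#'   behaviour (default alpha 0.3 vs 0.2, beta 0.2, i.e. a 1.5x learning
#'   rate ratio).
#' @param cost_modulation HC/LC multipliers for neural responses, see
#'   [default_cost_modulation()].
#' @param prop_value proportion of value-type neurons (41/70 by default).
#' @param n_boot bootstrap replicates for the pooled learning-curve CI.
#' @param kernel_sigma_ms spike-density kernel SD (ms).
#' @return a `run_config` list.
#' @export
default_run_config <- function(subject = "P", effects_on = TRUE,
                               n_neurons = 70L, n_uncertain_neurons = 19L,
                               n_exploration_sessions = 86L,
                               n_rt_sessions = 20L,
                               true_rl_params = NULL,
                               cost_modulation = NULL,
                               prop_value = 41 / 70,
                               n_boot = 200L,
                               kernel_sigma_ms = 30) {
  if (is.null(true_rl_params)) {
    true_rl_params <- if (effects_on) rl_params(0.3, 0.2, 0.2, 0.2)
                      else rl_params(0.25, 0.25, 0.2, 0.2)
  }
  if (is.null(cost_modulation)) {
    cost_modulation <- if (effects_on) default_cost_modulation()
                       else list(cost_cue = 1, reward_pos_cue = 1,
                                 reward_neg_cue = 1, delivery = 1)
  }
  rt_model <- if (effects_on) default_rt_model("saccade") else {
    m <- default_rt_model("saccade")
    m$mean_ms[m$event == "cost_cue"] <- 235
    m$mean_ms[m$event == "reward_cue" & m$reward_condition == "R+"] <- 187
    m$mean_ms[m$event == "reward_cue" & m$reward_condition == "R-"] <- 232
    m
  }
  structure(list(
    subject = subject, effects_on = effects_on,
    n_neurons = as.integer(n_neurons),
    n_uncertain_neurons = as.integer(n_uncertain_neurons),
    n_exploration_sessions = as.integer(n_exploration_sessions),
    n_rt_sessions = as.integer(n_rt_sessions),
    true_rl_params = true_rl_params,
    cost_modulation = cost_modulation,
    rt_model = rt_model,
    prop_value = prop_value,
    baseline_rate = 5, waveform_duration_us = 350,
    n_boot = as.integer(n_boot),
    kernel_sigma_ms = kernel_sigma_ms,
    windows = response_windows(subject)
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' Schema and invariant checks; never mutates its input.
#'
#' @param config a `run_config` (or plain list with the same fields).
#' @return character vector of error messages; empty when the
#'   configuration is valid.
#' @export
validate_config <- function(config) {
  errs <- character()
  add <- function(msg) errs <<- c(errs, msg)
  num_field <- function(name, lower = -Inf, strict = FALSE) {
    x <- config[[name]]
    if (is.null(x) || !is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      add(sprintf("`%s` must be a single finite number", name))
      return(invisible(FALSE))
    }
    if ((strict && x <= lower) || (!strict && x < lower)) {
      add(sprintf("`%s` = %g is out of range", name, x))
    }
    invisible(TRUE)
  }
  for (f in c("n_neurons", "n_uncertain_neurons", "n_exploration_sessions",
              "n_rt_sessions", "n_boot")) num_field(f, lower = 0)
  num_field("kernel_sigma_ms", lower = 0, strict = TRUE)
  num_field("baseline_rate", lower = 0)
  num_field("waveform_duration_us", lower = 0, strict = TRUE)
  if (!is.null(config$prop_value) &&
      (config$prop_value < 0 || config$prop_value > 1)) {
    add("`prop_value` must be in [0, 1]")
  }
  if (!inherits(config$true_rl_params, "rl_params")) {
    add("`true_rl_params` must be an rl_params object")
  }
  cm <- config$cost_modulation
  if (is.null(cm) || !all(c("cost_cue", "reward_pos_cue", "reward_neg_cue",
                            "delivery") %in% names(cm))) {
    add("`cost_modulation` must name cost_cue, reward_pos_cue, reward_neg_cue, delivery")
  } else if (any(unlist(cm) < 0)) {
    add("`cost_modulation` factors must be >= 0")
  }
  if (is.null(config$windows)) {
    add("`windows` is missing")
  } else {
    for (w in names(config$windows)) {
      win <- config$windows[[w]]
      if (length(win) != 2L || !is.numeric(win)) {
        add(sprintf("window `%s` must be c(start, end)", w))
      } else if (win[1] >= win[2]) {
        add(sprintf("window `%s` has start >= end", w))
      }
    }
  }
  errs
}

run_stage <- function(name, verbose, expr) {
  if (verbose) message("stage ", name, " ...")
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  if (verbose) {
    message(sprintf("stage %s done (%.1f s)", name,
                    proc.time()[["elapsed"]] - t0))
  }
  out
}

lr_summary <- function(lr) {
  list(mean = lr$mean, n = lr$n, n_excluded = lr$n_excluded,
       t = lr$t, df = lr$df, p_t = lr$p_t, p_wilcoxon = lr$p_wilcoxon)
}

pop_summary <- function(values) {
  s <- population_auroc_summary(values)
  list(median = s$median, p_value = s$p_value, n = s$n)
}

#' Run the full simulation-and-analysis pipeline
#'
#' Executes four stages and assembles a report of every headline contrast:
#' \enumerate{
#'   \item Reaction times (saccade task): per-session mean RTs to the cost
#'     cues (HC vs LC) and reward cues (R+ and R-, HC vs LC), with paired
#'     t and signed-rank tests across sessions.
#'   \item Saccade-task neurons: per-neuron identification,
#'     value/salience classification, and auROC contrasts of the
#'     baseline-normalized window responses (cost cue, R+ cue, R- cue),
#'     with population medians and signed-rank tests against 0.5.
#'   \item Uncertain-task neurons: cost-cue and reward-delivery auROC
#'     contrasts.
#'   \item Exploration behaviour: per-session learning-curve and RL-model
#'     fits, session-wise log ratios of the HC vs LC parameters, a pooled
#'     curve fit per condition with bootstrap CIs.
#' }
#' The run is a pure function of `(config, seed)`.
#'
#' @param config a `run_config`, see [default_run_config()].
#' @param seed master seed; every stage derives its own substreams.
#' @param out_dir optional directory; when given, per-stage CSV tables and
#'   the JSON report are written there.
#' @param verbose print stage progress.
#' @return a `dopacost_report` list.
#' @export
run_pipeline <- function(config = default_run_config(), seed = 1L,
                         out_dir = NULL, verbose = FALSE) {
  errs <- validate_config(config)
  stop_if(length(errs) > 0,
          "invalid config:\n", paste("-", errs, collapse = "\n"))
  windows <- config$windows
  sac_spec <- task_spec("saccade")
  report <- list(seed = as.integer(seed),
                 effects_on = config$effects_on)

  ## -- stage 1: reaction times ------------------------------------------
  report$rt <- run_stage("reaction_times", verbose, {
    per_session <- list()
    for (s in seq_len(config$n_rt_sessions)) {
      ev <- generate_session_events(sac_spec, seed = derive_seed(seed, 1000 + 2 * s))
      tr <- generate_gaze_trace(ev, rt_model = config$rt_model,
                                seed = derive_seed(seed, 1001 + 2 * s))
      rts <- rbind(compute_reaction_times(ev, tr, "cost_cue"),
                   suppressWarnings(compute_reaction_times(ev, tr, "reward_cue")))
      agg <- function(event, cc, rc = NULL) {
        rows <- rts$event == event & rts$cost_condition == cc
        if (!is.null(rc)) rows <- rows & rts$reward_condition == rc
        mean(rts$rt_ms[rows])
      }
      per_session[[s]] <- data.frame(
        session = s,
        cost_hc = agg("cost_cue", "HC"), cost_lc = agg("cost_cue", "LC"),
        rpos_hc = agg("reward_cue", "HC", "R+"),
        rpos_lc = agg("reward_cue", "LC", "R+"),
        rneg_hc = agg("reward_cue", "HC", "R-"),
        rneg_lc = agg("reward_cue", "LC", "R-"))
    }
    ses <- do.call(rbind, per_session)
    contrast <- function(hc, lc) {
      tt <- t_test_summary(hc, lc)
      wt <- wilcoxon_signed_rank(hc, lc)
      list(mean_hc = mean(hc), mean_lc = mean(lc),
           mean_diff = mean(hc - lc), t = tt$t, df = tt$df,
           p_t = tt$p_value, p_wilcoxon = wt$p_value, n = length(hc))
    }
    list(cost_cue = contrast(ses$cost_hc, ses$cost_lc),
         reward_pos_cue = contrast(ses$rpos_hc, ses$rpos_lc),
         reward_neg_cue = contrast(ses$rneg_hc, ses$rneg_lc),
         per_session = ses)
  })

  ## -- stage 2: saccade-task neurons ------------------------------------
  neuron_cohort <- function(n, task_kind, offset) {
    spec <- task_spec(task_kind)
    n_value <- round(config$prop_value * n)
    lapply(seq_len(n), function(i) {
      ev <- generate_session_events(spec, seed = derive_seed(seed, offset + 2 * i))
      subtype <- if (i <= n_value) "value" else "salience"
      prof <- neuron_profile(sprintf("%s_%03d", task_kind, i),
                             subtype = subtype,
                             baseline_rate = config$baseline_rate,
                             waveform_duration_us = config$waveform_duration_us,
                             cost_modulation = config$cost_modulation,
                             task_kind = task_kind)
      rec <- generate_spike_trains(prof, ev,
                                   seed = derive_seed(seed, offset + 2 * i + 1))
      list(events = ev, neuron = rec, true_subtype = subtype)
    })
  }

  analyze_neuron <- function(unit, task_kind) {
    ev <- unit$events; nr <- unit$neuron
    id <- identify_dopamine_neuron(nr, ev, windows = windows)
    cls <- classify_neuron_subtype(nr, ev, window = windows$airpuff)
    split_auroc <- function(event, window, filter = NULL) {
      resp <- event_response(nr, ev, event, window)
      if (!is.null(filter)) resp <- filter(resp)
      hc <- resp$response[resp$cost_condition == "HC"]
      lc <- resp$response[resp$cost_condition == "LC"]
      auroc_condition_contrast(hc, lc)$auroc
    }
    out <- list(neuron_id = nr$neuron_id,
                accept = isTRUE(id$accept),
                tonic_rate_hz = id$tonic_rate_hz,
                waveform_us = nr$waveform_duration_us,
                subtype = cls$subtype, true_subtype = unit$true_subtype)
    if (task_kind == "saccade") {
      out$auroc_cost_cue <- split_auroc("cost_cue", windows$cost_cue)
      out$auroc_rpos_cue <- split_auroc("reward_cue", windows$reward_cue,
        function(r) r[r$reward_condition == "R+", ])
      out$auroc_rneg_cue <- split_auroc("reward_cue", windows$reward_cue,
        function(r) r[r$reward_condition == "R-", ])
    } else {
      out$auroc_cost_cue <- split_auroc("cost_cue", windows$cost_cue)
      out$auroc_delivery <- split_auroc("delivery", windows$delivery,
        function(r) r[r$rewarded == 1, ])
    }
    out
  }

  report$saccade_neurons <- run_stage("saccade_neurons", verbose, {
    units <- neuron_cohort(config$n_neurons, "saccade", 2000L)
    metrics <- do.call(rbind, lapply(units, function(u)
      as.data.frame(analyze_neuron(u, "saccade"), stringsAsFactors = FALSE)))
    acc <- metrics[metrics$accept, , drop = FALSE]
    list(n_simulated = nrow(metrics), n_accepted = nrow(acc),
         n_value = sum(acc$subtype == "value"),
         n_salience = sum(acc$subtype == "salience"),
         subtype_accuracy = mean(metrics$subtype == metrics$true_subtype),
         auroc = list(cost_cue = pop_summary(acc$auroc_cost_cue),
                      reward_pos_cue = pop_summary(acc$auroc_rpos_cue),
                      reward_neg_cue = pop_summary(acc$auroc_rneg_cue)),
         metrics = metrics)
  })

  ## -- stage 3: uncertain-task neurons ----------------------------------
  report$uncertain_neurons <- run_stage("uncertain_neurons", verbose, {
    units <- neuron_cohort(config$n_uncertain_neurons, "uncertain", 3000L)
    metrics <- do.call(rbind, lapply(units, function(u)
      as.data.frame(analyze_neuron(u, "uncertain"), stringsAsFactors = FALSE)))
    acc <- metrics[metrics$accept, , drop = FALSE]
    list(n_simulated = nrow(metrics), n_accepted = nrow(acc),
         auroc = list(cost_cue = pop_summary(acc$auroc_cost_cue),
                      delivery = pop_summary(acc$auroc_delivery)),
         metrics = metrics)
  })

  ## -- stage 4: exploration behaviour -----------------------------------
  report$exploration <- run_stage("exploration", verbose, {
    spec <- task_spec("exploration")
    sessions <- lapply(seq_len(config$n_exploration_sessions), function(i) {
      generate_exploration_choices(config$true_rl_params, spec,
                                   seed = derive_seed(seed, 4000 + i))
    })
    names(sessions) <- sprintf("s%03d", seq_along(sessions))
    by_cond <- function(ses, cc) ses$correct[ses$cost_condition == cc]
    curve_fits <- do.call(rbind, lapply(seq_along(sessions), function(i) {
      row <- list(session_id = names(sessions)[i])
      for (cc in c("HC", "LC")) {
        f <- fit_learning_curve(by_cond(sessions[[i]], cc))
        row[[paste0("a_", tolower(cc))]] <- f$a
        row[[paste0("b_", tolower(cc))]] <- f$b
        row[[paste0("boundary_", tolower(cc))]] <- f$boundary
      }
      as.data.frame(row, stringsAsFactors = FALSE)
    }))
    rl <- fit_rl(sessions)
    pooled <- lapply(c(HC = "HC", LC = "LC"), function(cc) {
      per_ses <- lapply(sessions, by_cond, cc)
      fit <- fit_learning_curve_pooled(per_ses)
      ci <- if (config$n_boot >= 100) {
        bootstrap_curve_ci(per_ses, n_boot = config$n_boot,
                           seed = derive_seed(seed, 5000))
      } else NULL
      list(a = fit$a, b = fit$b,
           ci_a = if (!is.null(ci)) ci$ci_a, ci_b = if (!is.null(ci)) ci$ci_b)
    })
    list(
      curve = list(log_ratio_a = lr_summary(log_ratio_stat(curve_fits$a_hc,
                                                           curve_fits$a_lc)),
                   log_ratio_b = lr_summary(log_ratio_stat(curve_fits$b_hc,
                                                           curve_fits$b_lc))),
      rl = list(log_ratio_alpha = lr_summary(log_ratio_stat(rl$fits$alpha_hc,
                                                            rl$fits$alpha_lc)),
                log_ratio_beta = lr_summary(log_ratio_stat(rl$fits$beta_hc,
                                                           rl$fits$beta_lc))),
      pooled = pooled,
      smoothed = lapply(c(HC = "HC", LC = "LC"), function(cc)
        smoothed_learning_process(lapply(sessions, by_cond, cc))),
      curve_fits = curve_fits, rl_fits = rl$fits)
  })

  class(report) <- "dopacost_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Pooled learning-curve fit over a list of sessions
#'
#' Convenience wrapper: pools per-trial success counts across sessions and
#' fits one curve.
#' @param sessions list of 0/1 per-trial vectors.
#' @param ... passed to [fit_learning_curve()].
#' @return a `learning_curve_fit`.
#' @export
fit_learning_curve_pooled <- function(sessions, ...) {
  p <- pool_sessions(sessions)
  fit_learning_curve(p$k, p$trial, p$n, ...)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  slim <- report
  slim$rt$per_session <- NULL
  slim$saccade_neurons$metrics <- NULL
  slim$uncertain_neurons$metrics <- NULL
  slim$exploration$curve_fits <- NULL
  slim$exploration$rl_fits <- NULL
  jsonlite::write_json(unclass(slim), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  write.csv(report$saccade_neurons$metrics,
            file.path(out_dir, "neuron_metrics.csv"), row.names = FALSE)
  write.csv(report$uncertain_neurons$metrics,
            file.path(out_dir, "neuron_metrics_uncertain.csv"),
            row.names = FALSE)
  write.csv(report$exploration$curve_fits,
            file.path(out_dir, "curve_fits.csv"), row.names = FALSE)
  write.csv(report$exploration$rl_fits,
            file.path(out_dir, "rl_fits.csv"), row.names = FALSE)
  write.csv(report$rt$per_session,
            file.path(out_dir, "rt_session_means.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.dopacost_report <- function(x, ...) {
  fmt_p <- function(p) if (is.na(p)) "NA" else sprintf("%.3g", p)
  cat("== dopacost pipeline report (seed", x$seed, ") ==\n")
  cat(sprintf("effects %s\n", if (x$effects_on) "ON" else "OFF"))
  rt <- x$rt
  cat(sprintf("RT cost cue     : HC %.0f ms vs LC %.0f ms (p_t = %s)\n",
              rt$cost_cue$mean_hc, rt$cost_cue$mean_lc, fmt_p(rt$cost_cue$p_t)))
  cat(sprintf("RT R+ cue       : HC %.0f ms vs LC %.0f ms (p_t = %s)\n",
              rt$reward_pos_cue$mean_hc, rt$reward_pos_cue$mean_lc,
              fmt_p(rt$reward_pos_cue$p_t)))
  sn <- x$saccade_neurons
  cat(sprintf("saccade neurons : %d/%d accepted (%d value, %d salience)\n",
              sn$n_accepted, sn$n_simulated, sn$n_value, sn$n_salience))
  for (k in names(sn$auroc)) {
    cat(sprintf("  auROC %-14s median %.3f (p = %s, n = %d)\n", k,
                sn$auroc[[k]]$median, fmt_p(sn$auroc[[k]]$p_value),
                sn$auroc[[k]]$n))
  }
  un <- x$uncertain_neurons
  for (k in names(un$auroc)) {
    cat(sprintf("  auROC %-14s median %.3f (p = %s, n = %d) [uncertain task]\n",
                k, un$auroc[[k]]$median, fmt_p(un$auroc[[k]]$p_value),
                un$auroc[[k]]$n))
  }
  ex <- x$exploration
  cat(sprintf("learning curves : mean log(a_HC/a_LC) = %.3f (p_t = %s, n = %d)\n",
              ex$curve$log_ratio_a$mean, fmt_p(ex$curve$log_ratio_a$p_t),
              ex$curve$log_ratio_a$n))
  cat(sprintf("RL model        : mean log(alpha_HC/alpha_LC) = %.3f (p_t = %s, n = %d)\n",
              ex$rl$log_ratio_alpha$mean, fmt_p(ex$rl$log_ratio_alpha$p_t),
              ex$rl$log_ratio_alpha$n))
  cat(sprintf("                  mean log(beta_HC/beta_LC) = %.3f (p_t = %s)\n",
              ex$rl$log_ratio_beta$mean, fmt_p(ex$rl$log_ratio_beta$p_t)))
  invisible(x)
}
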