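schedule_from_trials <- function(trials, delivery_rule = "bernoulli",
                                 p_rich = 0.6, p_lean = 0.2) {
  out <- data.frame(trial = trials$trial, block = trials$block,
                    stimulus = trials$stimulus,
                    mouth = if ("mouth" %in% names(trials)) trials$mouth
                            else ifelse(trials$stimulus == "rich", "short", "long"),
                    reward_scheduled = trials$reward_scheduled,
                    stringsAsFactors = FALSE)
  attr(out, "delivery_rule") <- delivery_rule
  attr(out, "p_rich") <- p_rich
  attr(out, "p_lean") <- p_lean
  class(out) <- c("prt_schedule", "data.frame")
  out
}

# session statistics used by the posterior predictive check; observed and
# simulated data go through this one code path
ppc_session_stats <- function(subject, n_bias_bins = 8, n_rt_bins = 4,
                              fast_q = 0.1, slow_q = 0.9, log_base = 10) {
  sp <- rt_speed_contrast(subject, fast_q, slow_q)
  tr <- subject$trials
  n <- max(tr$trial)
  bin_of <- function(nb) pmin(ceiling(tr$trial / (n / nb)), nb)
  bb <- bin_of(n_bias_bins)
  bias_bins <- vapply(seq_len(n_bias_bins), function(b) {
    cnt <- sdt_counts(tr[bb == b, , drop = FALSE])
    response_bias(cnt[1], cnt[2], cnt[3], cnt[4], log_base)
  }, 0)
  disc_bins <- vapply(seq_len(n_bias_bins), function(b) {
    cnt <- sdt_counts(tr[bb == b, , drop = FALSE])
    discriminability(cnt[1], cnt[2], cnt[3], cnt[4], log_base)
  }, 0)
  rb <- bin_of(n_rt_bins)
  v <- tr[tr$valid & tr$response != "none" & !is.na(tr$rt), , drop = FALSE]
  vrb <- rb[tr$valid & tr$response != "none" & !is.na(tr$rt)]
  rt_cell <- function(b, stim, corr) {
    x <- v$rt[vrb == b & v$stimulus == stim & v$correct == corr]
    if (length(x)) mean(x) else NA_real_
  }
  rt_bins <- expand.grid(bin = seq_len(n_rt_bins), stimulus = c("rich", "lean"),
                         correct = c(TRUE, FALSE), stringsAsFactors = FALSE)
  rt_bins$mean_rt <- mapply(rt_cell, rt_bins$bin, rt_bins$stimulus,
                            rt_bins$correct)
  list(acc_fast_rich = sp$table$accuracy[sp$table$stimulus == "rich" &
                                           sp$table$speed == "fast"],
       acc_fast_lean = sp$table$accuracy[sp$table$stimulus == "lean" &
                                           sp$table$speed == "fast"],
       acc_slow_rich = sp$table$accuracy[sp$table$stimulus == "rich" &
                                           sp$table$speed == "slow"],
       acc_slow_lean = sp$table$accuracy[sp$table$stimulus == "lean" &
                                           sp$table$speed == "slow"],
       fast_contrast = sp$fast_contrast, slow_contrast = sp$slow_contrast,
       bias_bins = bias_bins, disc_bins = disc_bins, rt_bins = rt_bins)
}

#' Posterior predictive check
#'
#' For each subject, draws parameter sets from that subject's posterior,
#' simulates `n_datasets` replicate sessions of `n_trials` trials on the
#' subject's own schedule, and compares the simulated behavior to the
#' observed behavior on the task's signature statistics: accuracy by stimulus
#' type and RT speed (fast/slow quantile classes), response bias and
#' discriminability trajectories over `n_bias_bins` equal trial bins, and
#' mean RTs for correct and error responses by stimulus over `n_rt_bins`
#' bins. Observed and simulated statistics are computed by the same code
#' path.
#'
#' @param fit An `addm_fit`.
#' @param data The observed subjects (defaults to the data the model was
#'   fitted to); must match the fit's subjects.
#' @param n_datasets Simulated datasets per subject (default 20).
#' @param n_trials Trials per simulated dataset (default 200; capped at the
#'   subject's schedule length).
#' @param seed Integer seed; with a fixed seed the report is deterministic.
#' @param reward_mode `"replay"` re-uses each subject's recorded scheduled
#'   rewards; `"redraw"` draws fresh Bernoulli reward flags.
#' @param n_bias_bins,n_rt_bins,fast_q,slow_q Statistic settings.
#' @param dt Diffusion integration step for the simulations.
#' @return An object of class `ppc_report` with per-subject and group-mean
#'   observed and simulated statistics and their discrepancies.
#' @export
posterior_predictive <- function(fit, data = NULL, n_datasets = 20,
                                 n_trials = 200, seed = 1,
                                 reward_mode = c("replay", "redraw"),
                                 n_bias_bins = 8, n_rt_bins = 4,
                                 fast_q = 0.1, slow_q = 0.9, dt = 1e-4) {
  reward_mode <- match.arg(reward_mode)
  subjects <- if (is.null(data)) fit$subjects else as_subject_list(data)
  ids <- vapply(subjects, `[[`, "", "subject_id")
  if (!identical(sort(ids), sort(fit$subject_ids)))
    stop("subjects in data do not match the fitted subjects")
  nat <- natural_theta_draws(fit)
  nd <- dim(nat)[1]

  obs_stats <- list()
  sim_stats <- list()
  for (s in seq_along(subjects)) {
    sub <- subjects[[s]]
    fidx <- match(sub$subject_id, fit$subject_ids)
    nt <- min(n_trials, nrow(sub$trials))
    tr <- sub$trials[seq_len(nt), , drop = FALSE]
    obs_sub <- sub
    obs_sub$trials <- tr
    obs_stats[[s]] <- ppc_session_stats(obs_sub, n_bias_bins, n_rt_bins,
                                        fast_q, slow_q)
    draw_idx <- with_local_seed(derive_seed(seed, s, salt = 71L),
                                sample.int(nd, n_datasets, replace = n_datasets > nd))
    mode_s <- if (!"reward_scheduled" %in% names(tr)) "redraw" else reward_mode
    reps <- lapply(seq_len(n_datasets), function(k) {
      trs <- tr
      if (mode_s == "redraw") {
        p <- ifelse(trs$stimulus == "rich", 0.6, 0.2)
        trs$reward_scheduled <- with_local_seed(
          derive_seed(seed, s * 1000 + k, salt = 73L),
          rbinom(nrow(trs), 1, p) == 1)
      }
      sched <- schedule_from_trials(trs)
      p <- nat[draw_idx[k], fidx, ]
      sim <- simulate_subject(p, sched, seed = derive_seed(seed, s * 1000 + k,
                                                           salt = 79L),
                              subject_id = sub$subject_id, dt = dt)
      ppc_session_stats(sim, n_bias_bins, n_rt_bins, fast_q, slow_q)
    })
    # average scalar statistics and bin trajectories over replicate datasets
    avg_num <- function(get) mean(vapply(reps, get, 0), na.rm = TRUE)
    avg_vec <- function(name) rowMeans(sapply(reps, `[[`, name), na.rm = TRUE)
    rtb <- reps[[1]]$rt_bins
    rtb$mean_rt <- rowMeans(sapply(reps, function(r) r$rt_bins$mean_rt),
                            na.rm = TRUE)
    sim_stats[[s]] <- list(acc_fast_rich = avg_num(function(r) r$acc_fast_rich),
                           acc_fast_lean = avg_num(function(r) r$acc_fast_lean),
                           acc_slow_rich = avg_num(function(r) r$acc_slow_rich),
                           acc_slow_lean = avg_num(function(r) r$acc_slow_lean),
                           fast_contrast = avg_num(function(r) r$fast_contrast),
                           slow_contrast = avg_num(function(r) r$slow_contrast),
                           bias_bins = avg_vec("bias_bins"),
                           disc_bins = avg_vec("disc_bins"),
                           rt_bins = rtb)
  }

  scalar_names <- c("acc_fast_rich", "acc_fast_lean", "acc_slow_rich",
                    "acc_slow_lean", "fast_contrast", "slow_contrast")
  mean_over <- function(stats, nm)
    mean(vapply(stats, function(x) x[[nm]], 0), na.rm = TRUE)
  bins_over <- function(stats, nm)
    colMeans(do.call(rbind, lapply(stats, `[[`, nm)), na.rm = TRUE)
  summary_tab <- data.frame(
    statistic = scalar_names,
    observed = vapply(scalar_names, function(nm) mean_over(obs_stats, nm), 0),
    simulated = vapply(scalar_names, function(nm) mean_over(sim_stats, nm), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  summary_tab$discrepancy <- summary_tab$observed - summary_tab$simulated

  structure(list(
    summary = summary_tab,
    bias_bins = list(observed = bins_over(obs_stats, "bias_bins"),
                     simulated = bins_over(sim_stats, "bias_bins")),
    disc_bins = list(observed = bins_over(obs_stats, "disc_bins"),
                     simulated = bins_over(sim_stats, "disc_bins")),
    per_subject = list(observed = obs_stats, simulated = sim_stats),
    subject_ids = ids, n_datasets = n_datasets, n_trials = n_trials,
    reward_mode = reward_mode, seed = seed),
    class = "ppc_report")
}

#' @export
print.ppc_report <- function(x, ...) {
  cat("Posterior predictive check:", length(x$subject_ids), "subjects x",
      x$n_datasets, "datasets x", x$n_trials, "trials\n")
  print(format(x$summary, digits = 3), row.names = FALSE)
  cat("response bias over bins (observed):",
      paste(sprintf("%.3f", x$bias_bins$observed), collapse = " "), "\n")
  cat("response bias over bins (simulated):",
      paste(sprintf("%.3f", x$bias_bins$simulated), collapse = " "), "\n")
  invisible(x)
}

#' Truth-versus-estimate recovery metrics
#'
#' Per-parameter Pearson correlation, mean bias and RMSE between generating
#' ("truth") parameter values and recovered estimates, matched by subject id.
#'
#' @param truths Data frame with `subject_id` and natural-scale parameter
#'   columns.
#' @param estimates Data frame as returned by
#'   [extract_subject_estimates()] (long format), or a wide data frame with
#'   the same parameter columns as `truths`.
#' @return A data frame with columns `param`, `r`, `bias`, `rmse`.
#' @export
recovery_metrics <- function(truths, estimates) {
  if (all(c("param", "mean") %in% names(estimates))) {
    wide <- stats::reshape(estimates[, c("subject_id", "param", "mean")],
                           idvar = "subject_id", timevar = "param",
                           direction = "wide")
    names(wide) <- sub("^mean\\.", "", names(wide))
    estimates <- wide
  }
  m <- merge(truths, estimates, by = "subject_id",
             suffixes = c("_true", "_est"))
  if (nrow(m) != nrow(truths)) stop("subject ids do not align")
  do.call(rbind, lapply(param_names, function(p) {
    tr <- m[[paste0(p, "_true")]]
    es <- m[[paste0(p, "_est")]]
    data.frame(param = p,
               r = if (sd(tr) < 1e-12 || sd(es) < 1e-12) NA_real_ else cor(tr, es),
               bias = mean(es - tr),
               rmse = sqrt(mean((es - tr)^2)),
               stringsAsFactors = FALSE)
  }))
}

#' Parameter recovery study
#'
#' The model's own estimation validation: sample generating parameters from a
#' group distribution (or take a supplied truth table), simulate one session
#' per synthetic subject, refit the model, and correlate generating with
#' recovered (posterior-mean) parameters.
#'
#' @param n_subjects Number of synthetic subjects (ignored when `truths` is
#'   supplied); 20 or more is recommended.
#' @param dist Group distribution the truths are sampled from.
#' @param truths Optional data frame of generating parameters (`subject_id`
#'   plus natural-scale parameter columns).
#' @param schedule_args Passed to [generate_schedule()].
#' @param variant,mcmc,priors,hierarchical Passed to [fit_hierarchical()]
#'   (`hierarchical = FALSE` refits each subject independently).
#' @param seed Integer seed.
#' @param deadline,dt Simulation settings.
#' @return An object of class `recovery_report`: metrics table, scatter data,
#'   the fit's maximum R-hat and convergence flag.
#' @export
parameter_recovery <- function(n_subjects = 30,
                               dist = default_group_distribution(),
                               truths = NULL, schedule_args = list(),
                               variant = "full", mcmc = mcmc_config("fast"),
                               priors = default_priors(), hierarchical = TRUE,
                               seed = 1, deadline = 2, dt = 1e-4) {
  if (is.null(truths)) {
    pars <- sample_group_params(n_subjects, dist,
                                seed = derive_seed(seed, 1L, salt = 91L))
    truths <- cbind(data.frame(subject_id = sprintf("s%03d", seq_len(n_subjects)),
                               stringsAsFactors = FALSE),
                    pars[, param_names])
  }
  n <- nrow(truths)
  subjects <- lapply(seq_len(n), function(i) {
    sched <- do.call(generate_schedule,
                     c(list(seed = derive_seed(seed, i, salt = 93L)),
                       schedule_args))
    p <- as.numeric(truths[i, param_names])
    names(p) <- param_names
    simulate_subject(p, sched, seed = derive_seed(seed, i, salt = 97L),
                     subject_id = truths$subject_id[i], deadline = deadline,
                     dt = dt)
  })
  fit <- suppressWarnings(
    fit_hierarchical(subjects, variant = variant, mcmc = mcmc, priors = priors,
                     hierarchical = hierarchical, seed = derive_seed(seed, 2L,
                                                                     salt = 99L)))
  est <- extract_subject_estimates(fit)
  metrics <- recovery_metrics(truths, est)
  wide <- stats::reshape(est[, c("subject_id", "param", "mean")],
                         idvar = "subject_id", timevar = "param",
                         direction = "wide")
  names(wide) <- sub("^mean\\.", "", names(wide))
  scatter <- merge(truths, wide, by = "subject_id",
                   suffixes = c("_true", "_est"))
  structure(list(metrics = metrics, scatter = scatter,
                 max_rhat = fit$convergence$max_rhat,
                 converged = fit$convergence$converged,
                 n_subjects = n, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery on", x$n_subjects, "synthetic subjects",
      sprintf("(max R-hat %.3f%s)\n", x$max_rhat,
              if (x$converged) "" else ", NOT converged"))
  print(format(x$metrics, digits = 3), row.names = FALSE)
  invisible(x)
}
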