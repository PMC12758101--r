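#' Default group-level parameter distribution
#'
#' Group-level distribution of subject parameters on the unconstrained (link)
#' scale: normal with the given location and scale per parameter, mapped back
#' through a logit link for `alpha`, log links for `a` and `t`, and identity
#' links for `b_v`, `b_z` and `v_intercept`.
#'
#' The default locations and scales are calibration choices: cohorts drawn
#' from them produce PRT behavior on the scale typically reported for the
#' task (accuracy around 0.8, mean RT around 0.53 s, a small positive
#' response bias around 0.05-0.10 log units that grows over trials).
#'
#' @return A data frame of class `group_distribution` with columns `param`,
#'   `link`, `location`, `scale`.
#' @export
default_group_distribution <- function() {
  out <- data.frame(
    param = param_names,
    link = c("logit", "identity", "identity", "identity", "log", "log"),
    location = c(qlogis(0.25), 0.35, 0.45, 1.60, log(0.95), log(0.35)),
    scale = c(0.75, 0.35, 0.65, 0.45, 0.20, 0.15),
    stringsAsFactors = FALSE)
  class(out) <- c("group_distribution", "data.frame")
  out
}

check_group_distribution <- function(dist) {
  stopifnot(is.data.frame(dist),
            all(c("param", "link", "location", "scale") %in% names(dist)),
            setequal(dist$param, param_names))
  if (any(dist$scale <= 0)) stop("group distribution scales must be positive")
  dist[match(param_names, dist$param), , drop = FALSE]
}

#' Sample subject parameters from a group distribution
#'
#' @param n Number of subjects.
#' @param dist A `group_distribution` (defaults to
#'   [default_group_distribution()]).
#' @param seed Optional seed.
#' @return A data frame with one row per subject: the six natural-scale
#'   parameters plus their unconstrained values (`u_` columns).
#' @export
sample_group_params <- function(n, dist = default_group_distribution(),
                                seed = NULL) {
  dist <- check_group_distribution(dist)
  with_local_seed(seed, {
    u <- sapply(seq_len(6), function(j) rnorm(n, dist$location[j], dist$scale[j]))
    u <- matrix(u, nrow = n)
    nat <- t(apply(u, 1, addm_transform))
    out <- as.data.frame(nat)
    names(out) <- param_names
    uu <- as.data.frame(u)
    names(uu) <- paste0("u_", param_names)
    cbind(out, uu)
  })
}

#' Sample a first passage of the diffusion process
#'
#' Forward counterpart of the WFPT likelihood: simulates the accumulator by
#' Euler-Maruyama with step `dt`, augmented with a Brownian-bridge check for
#' within-step boundary crossings, which removes the leading discretization
#' bias of the plain scheme.
#'
#' @param n Number of draws.
#' @param v,a,z,t DDM parameters.
#' @param seed Integer seed.
#' @param dt Integration step in seconds (default 1e-4).
#' @param deadline Censoring time in seconds; passages later than this are
#'   recorded as non-responses (`boundary = 0`, `rt = NA`).
#' @return A data frame with columns `rt` (seconds, includes `t`) and
#'   `boundary` (+1 upper, -1 lower, 0 censored).
#' @export
sample_first_passage <- function(n, v, a, z = 0.5, t = 0, seed = 1,
                                 dt = 1e-4, deadline = Inf) {
  dl <- if (is.finite(deadline)) deadline else t + 60
  res <- wfpt_sample_cpp(as.integer(n), v, a, z, t, dt, dl, as.numeric(seed))
  data.frame(rt = res$rt, boundary = res$boundary)
}

#' Simulate one subject's PRT session under the Action-DDM
#'
#' Iterates the schedule trial by trial: computes the latents from the current
#' response values, samples a response and RT from the diffusion, scores
#' correctness, applies the schedule's reward-delivery rule (Bernoulli flags
#' or the queued rule with re-queued missed rewards), and updates the chosen
#' response's value by the delta rule. First passages later than the response
#' deadline are recorded as non-responses that deliver no feedback.
#'
#' @param params Model parameters.
#' @param schedule A `prt_schedule` (see [generate_schedule()]).
#' @param seed Integer seed.
#' @param subject_id Identifier for the resulting subject.
#' @param deadline Response deadline in seconds (default 2).
#' @param dt Diffusion integration step.
#' @param sign_whole Drift sign convention flag (see [trial_latents()]).
#' @param group,symptom_score,age Optional covariates attached to the subject.
#' @return A `subject_data` object; the simulated latent trajectory is
#'   attached as element `latents`.
#' @export
simulate_subject <- function(params, schedule, seed = 1, subject_id = "sim",
                             deadline = 2, dt = 1e-4, sign_whole = FALSE,
                             group = NA_character_, symptom_score = NA_real_,
                             age = NA_real_) {
  p <- as_params_vector(params)
  stim <- ifelse(schedule$stimulus == "rich", 1L, -1L)
  queued <- identical(attr(schedule, "delivery_rule"), "queued")
  res <- simulate_subject_cpp(stim, as.integer(schedule$reward_scheduled),
                              as.integer(queued), as.numeric(p),
                              as.integer(sign_whole), dt, deadline,
                              as.numeric(seed), as.integer(schedule$block))
  response <- ifelse(res$resp == 1L, "rich",
                     ifelse(res$resp == -1L, "lean", "none"))
  tr <- data.frame(trial = schedule$trial, block = schedule$block,
                   stimulus = schedule$stimulus, mouth = schedule$mouth,
                   response = response, rt = res$rt, reward = res$reward,
                   reward_scheduled = schedule$reward_scheduled,
                   stringsAsFactors = FALSE)
  sub <- subject_data(subject_id, tr, group = group,
                      symptom_score = symptom_score, age = age)
  sub$latents <- res$latents
  sub$params <- p
  sub
}

#' Simulate a synthetic cohort
#'
#' Draws subject-level parameters from group distributions (optionally with
#' group-specific effects injected on the unconstrained scale, in units of
#' the group SD), simulates each subject's session on a fresh schedule, and
#' returns both the data and the generating ("truth") parameter table for
#' recovery studies. One master seed drives everything; per-subject seeds are
#' derived deterministically, so the same configuration reproduces the same
#' cohort.
#'
#' @param n_subjects Number of subjects (total, split across `groups` if
#'   given).
#' @param dist Group distribution of parameters.
#' @param groups Optional named integer vector of per-group sizes, e.g.
#'   `c(NC = 25, UNI = 25)`; overrides `n_subjects`.
#' @param effects Optional named list mapping a group name to named shifts of
#'   the distribution location, in group-SD units on the unconstrained scale,
#'   e.g. `list(UNI = c(b_z = -0.5))`.
#' @param schedule_args Arguments passed to [generate_schedule()] (a fresh
#'   schedule seed is derived per subject).
#' @param seed Master seed.
#' @param deadline,dt,sign_whole Passed to [simulate_subject()].
#' @return A list of class `addm_cohort` with elements `subjects` (list of
#'   `subject_data`), `truth` (data frame of generating parameters) and the
#'   generating configuration.
#' @export
simulate_cohort <- function(n_subjects = 20, dist = default_group_distribution(),
                            groups = NULL, effects = NULL,
                            schedule_args = list(), seed = 1,
                            deadline = 2, dt = 1e-4, sign_whole = FALSE) {
  dist <- check_group_distribution(dist)
  if (is.null(groups)) groups <- c(all = n_subjects)
  if (any(groups < 2))
    warning("fewer than 2 subjects in a group; group analyses will be degenerate")
  subjects <- list()
  truth <- list()
  idx <- 0L
  for (g in names(groups)) {
    gdist <- dist
    shift <- if (!is.null(effects) && g %in% names(effects)) effects[[g]] else NULL
    if (!is.null(shift)) {
      for (nm in names(shift)) {
        j <- match(nm, gdist$param)
        if (is.na(j)) stop("unknown parameter in effects: ", nm)
        gdist$location[j] <- gdist$location[j] + shift[[nm]] * gdist$scale[j]
      }
    }
    pars <- sample_group_params(groups[[g]], gdist,
                                seed = derive_seed(seed, idx + 1L, salt = 11L))
    for (i in seq_len(groups[[g]])) {
      idx <- idx + 1L
      id <- sprintf("s%03d", idx)
      sched <- do.call(generate_schedule,
                       c(list(seed = derive_seed(seed, idx, salt = 23L)),
                         schedule_args))
      p <- as.numeric(pars[i, param_names])
      names(p) <- param_names
      sub <- simulate_subject(p, sched, seed = derive_seed(seed, idx, salt = 37L),
                              subject_id = id, deadline = deadline, dt = dt,
                              sign_whole = sign_whole, group = g)
      subjects[[idx]] <- sub
      truth[[idx]] <- cbind(data.frame(subject_id = id, group = g,
                                       stringsAsFactors = FALSE),
                            pars[i, , drop = FALSE])
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  structure(list(subjects = subjects, truth = truth, dist = dist,
                 groups = groups, effects = effects, seed = seed),
            class = "addm_cohort")
}

#' @export
print.addm_cohort <- function(x, ...) {
  cat("Synthetic PRT cohort:", length(x$subjects), "subjects in",
      length(x$groups), "group(s); seed", x$seed, "\n")
  invisible(x)
}
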