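param_names <- c("alpha", "b_v", "b_z", "v_intercept", "a", "t")

#' Action-DDM subject-level parameters
#'
#' The six parameters of the response-outcome reinforcement-learning drift
#' diffusion model: `alpha` (delta-rule learning rate, in \[0, 1\]), `b_v`
#' (weight of the action-value difference on drift rate), `b_z` (weight of
#' action values on the starting point, through a softmax), `v_intercept`
#' (baseline drift rate, the subject's stimulus processing efficiency), `a`
#' (boundary separation, > 0) and `t` (non-decision time in seconds, >= 0).
#'
#' @param alpha,b_v,b_z,v_intercept,a,t Parameter values.
#' @return A named numeric vector of class `actionddm_params`.
#' @export
actionddm_params <- function(alpha, b_v, b_z, v_intercept, a, t) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (a <= 0) stop("threshold a must be positive")
  if (t < 0) stop("non-decision time t must be non-negative")
  structure(c(alpha = alpha, b_v = b_v, b_z = b_z,
              v_intercept = v_intercept, a = a, t = t),
            class = "actionddm_params")
}

as_params_vector <- function(params) {
  if (inherits(params, "actionddm_params")) return(unclass(params))
  if (is.numeric(params) && length(params) == 6) {
    if (!is.null(names(params)) && all(param_names %in% names(params)))
      return(params[param_names])
    return(stats::setNames(params, param_names))
  }
  stop("params must be an actionddm_params object or a named length-6 vector")
}

# unconstrained (sampling/link) scale <-> natural scale
# alpha: logit; a, t: log; b_v, b_z, v_intercept: identity
addm_transform <- function(u) {
  c(alpha = plogis(u[[1]]), b_v = u[[2]], b_z = u[[3]],
    v_intercept = u[[4]], a = exp(u[[5]]), t = exp(u[[6]]))
}

addm_untransform <- function(p) {
  p <- as_params_vector(p)
  c(alpha = qlogis(p[[1]]), b_v = p[[2]], b_z = p[[3]],
    v_intercept = p[[4]], a = log(p[[5]]), t = log(p[[6]]))
}

#' Delta-rule value update
#'
#' Updates the expected value of the *chosen* response after feedback:
#' `q + alpha * (r - q)`. The unchosen response's value is unchanged. With
#' rewards coded 0/1 and `q` starting in \[0, 1\], values remain in \[0, 1\].
#'
#' @param q Current expected value (vectorized).
#' @param r Reward, 0 or 1.
#' @param alpha Learning rate in \[0, 1\].
#' @return Updated expected value.
#' @export
q_update <- function(q, r, alpha) {
  stopifnot(all(alpha >= 0 & alpha <= 1), all(r %in% c(0, 1)))
  q + alpha * (r - q)
}

#' Trial-wise latent decision quantities
#'
#' Computes the pre-choice latents of the Action-DDM from the current response
#' values: the value difference `delta_q = q_rich - q_lean`, the starting
#' point `z_t = exp(b_z * q_rich) / (exp(b_z * q_rich) + exp(b_z * q_lean))`
#' (evaluated as the numerically stable logistic of `b_z * delta_q`), and the
#' signed drift rate toward the upper (rich) boundary.
#'
#' By default the drift is `s * v_intercept + b_v * delta_q` with `s = +1` for
#' a rich stimulus and `s = -1` for a lean stimulus, so that a growing value
#' difference speeds rich-stimulus decisions and slows lean-stimulus ones.
#' With `sign_whole = TRUE` the whole sum is signed by the stimulus instead:
#' `s * (v_intercept + b_v * delta_q)`.
#'
#' @param q_rich,q_lean Current expected values of the two responses.
#' @param params Model parameters (`actionddm_params` or named vector).
#' @param stimulus `"rich"` or `"lean"`.
#' @param sign_whole Sign convention flag (see Details).
#' @return A list with `q_rich`, `q_lean`, `delta_q`, `v_t`, `z_t`.
#' @export
trial_latents <- function(q_rich, q_lean, params, stimulus = c("rich", "lean"),
                          sign_whole = FALSE) {
  stimulus <- match.arg(stimulus)
  p <- as_params_vector(params)
  dq <- q_rich - q_lean
  z <- plogis(p[["b_z"]] * dq)
  s <- if (stimulus == "rich") 1 else -1
  v <- if (sign_whole) s * (p[["v_intercept"]] + p[["b_v"]] * dq)
       else s * p[["v_intercept"]] + p[["b_v"]] * dq
  list(q_rich = q_rich, q_lean = q_lean, delta_q = dq, v_t = v, z_t = z)
}

#' Wiener first-passage-time log density
#'
#' Log joint density of responding at a given boundary at time `rt` under a
#' diffusion with drift `v`, boundary separation `a`, relative starting point
#' `z` (fraction of `a` measured from the lower boundary) and non-decision
#' time `t`. Evaluated by automatic switching between small-time and
#' large-time series expansions of the standardized density, accurate to well
#' below 1e-6 in density over `rt - t` in \[0.01, 5\], `a` in \[0.5, 3\],
#' `|v| <= 5`.
#'
#' Observations with `rt <= t` are impossible under the model and return
#' `-Inf`; a numerical failure inside the series (which the switching rule is
#' designed to prevent) would surface as `NaN`, keeping the two cases
#' distinguishable.
#'
#' @param rt Response time(s) in seconds.
#' @param boundary `"upper"`/`"lower"`, or `+1`/`-1`.
#' @param v,a,z,t DDM parameters (recycled against `rt`).
#' @return Log density value(s).
#' @export
wfpt_logpdf <- function(rt, boundary, v, a, z = 0.5, t = 0) {
  n <- max(length(rt), length(boundary), length(v), length(a),
           length(z), length(t))
  b <- if (is.character(boundary))
    ifelse(boundary == "upper", 1L, -1L) else as.integer(sign(boundary))
  if (any(b == 0L)) stop("boundary must be 'upper'/'lower' or +1/-1")
  wfpt_logpdf_cpp(rep_len(as.numeric(rt), n), rep_len(b, n),
                  rep_len(as.numeric(v), n), rep_len(as.numeric(a), n),
                  rep_len(as.numeric(z), n), rep_len(as.numeric(t), n))
}

#' Probability of absorption at the upper boundary
#'
#' Closed-form probability that a diffusion with drift `v`, separation `a` and
#' relative start `z` is absorbed at the upper boundary.
#'
#' @param v,a,z DDM parameters.
#' @return Probability in \[0, 1\].
#' @export
ddm_prob_upper <- function(v, a, z = 0.5) {
  mapply(ddm_prob_upper_cpp, v, a, z)
}

#' Model variants of the Action-DDM
#'
#' Returns the specification of one member of the model lattice used for
#' model comparison. Each lesioned variant is a restriction or
#' reparameterization of the full model:
#' \describe{
#'   \item{full}{all six parameters free}
#'   \item{no_value_drift}{`b_v = 0`: action values do not influence drift}
#'   \item{no_value_start}{`b_z = 0`: action values do not influence the
#'     starting point}
#'   \item{unweighted_drift}{`b_v = 1`: value difference enters the drift
#'     unweighted}
#'   \item{unweighted_start}{`b_z = 1`: value difference enters the starting
#'     point unweighted}
#'   \item{shared_B}{one shared weight `B` controls both influences
#'     (`b_v = b_z = B`)}
#' }
#'
#' @param name Variant name.
#' @return A list with `name`, logical vector `active` (free parameters),
#'   numeric vector `fixed` (values used for restricted parameters),
#'   `shared_b` flag and a human-readable description.
#' @export
make_variant <- function(name) {
  variants <- list(
    full = list(fix = c(), shared = FALSE,
                desc = "full Action-DDM"),
    no_value_drift = list(fix = c(b_v = 0), shared = FALSE,
                          desc = "action values do not influence drift rate"),
    no_value_start = list(fix = c(b_z = 0), shared = FALSE,
                          desc = "action values do not influence starting point"),
    unweighted_drift = list(fix = c(b_v = 1), shared = FALSE,
                            desc = "value influence on drift not weighted by B_v"),
    unweighted_start = list(fix = c(b_z = 1), shared = FALSE,
                            desc = "value influence on starting point not weighted by B_z"),
    shared_B = list(fix = c(), shared = TRUE,
                    desc = "one shared B weights both value influences"))
  if (!name %in% names(variants))
    stop("unknown variant '", name, "'; valid variants: ",
         paste(names(variants), collapse = ", "))
  v <- variants[[name]]
  active <- stats::setNames(rep(TRUE, 6), param_names)
  fixed <- stats::setNames(rep(NA_real_, 6), param_names)
  for (nm in names(v$fix)) {
    active[nm] <- FALSE
    fixed[nm] <- v$fix[[nm]]
  }
  if (v$shared) active["b_z"] <- FALSE  # tied to b_v, not separately sampled
  list(name = name, active = active, fixed = fixed,
       shared_b = v$shared, description = v$desc)
}

#' Restrict a parameter set to a model variant
#'
#' Applies a variant's restrictions to a full parameter set (useful for
#' checking nesting relations between variants).
#'
#' @param params Full parameters.
#' @param variant A variant name or the result of [make_variant()].
#' @return An `actionddm_params` object satisfying the restriction.
#' @export
apply_variant <- function(params, variant) {
  if (is.character(variant)) variant <- make_variant(variant)
  p <- as_params_vector(params)
  fixed <- variant$fixed
  p[!is.na(fixed)] <- fixed[!is.na(fixed)]
  if (variant$shared_b) p[["b_z"]] <- p[["b_v"]]
  do.call(actionddm_params, as.list(p))
}

subject_to_cpp <- function(subject, update_q_invalid = TRUE) {
  tr <- subject$trials
  resp <- ifelse(tr$response == "rich", 1L,
                 ifelse(tr$response == "lean", -1L, 0L))
  stim <- ifelse(tr$stimulus == "rich", 1L, -1L)
  valid <- (if ("valid" %in% names(tr)) tr$valid else TRUE) &
    resp != 0L & !is.na(tr$rt)
  updq <- if (update_q_invalid) resp != 0L else valid
  rt <- tr$rt
  rt[is.na(rt)] <- -1
  list(stim = as.integer(stim), resp = as.integer(resp),
       reward = as.integer(tr$reward), valid = as.integer(valid),
       updq = as.integer(updq), rt = as.numeric(rt))
}

#' Sequential Action-DDM log likelihood for one subject
#'
#' Walks the session chronologically: before each choice the trial latents
#' (`delta_q`, `v_t`, `z_t`) are computed from the current response values;
#' valid trials contribute the WFPT log density of the observed response and
#' RT (upper boundary = rich response); after each trial with feedback the
#' chosen response's value is updated by the delta rule. QC-invalid trials
#' contribute nothing to the likelihood but, by default, still update values
#' when the subject responded and saw feedback.
#'
#' @param subject A `subject_data` object (trials in chronological order).
#' @param params Model parameters.
#' @param variant Optional variant restriction applied to `params`.
#' @param sign_whole Drift sign convention flag (see [trial_latents()]).
#' @param update_q_invalid Should feedback on QC-invalid response trials still
#'   update values? Default `TRUE`.
#' @param return_latents Also return the trial-wise latent trajectory.
#' @return The log likelihood, or (with `return_latents = TRUE`) a list with
#'   `loglik` and a `latents` matrix (`q_rich`, `q_lean`, `delta_q`, `v_t`,
#'   `z_t` per trial).
#' @export
subject_loglik <- function(subject, params, variant = NULL,
                           sign_whole = FALSE, update_q_invalid = TRUE,
                           return_latents = FALSE) {
  stopifnot(inherits(subject, "subject_data"))
  if (is.unsorted(subject$trials$trial, strictly = TRUE))
    stop("trials must be in chronological order")
  p <- as_params_vector(params)
  if (!is.null(variant)) p <- as_params_vector(apply_variant(p, variant))
  d <- subject_to_cpp(subject, update_q_invalid)
  res <- subject_loglik_cpp(d, as.numeric(p), as.integer(sign_whole),
                            return_latents)
  if (return_latents) res else res$loglik
}
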