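#' Generate a Probabilistic Reward Task schedule
#'
#' Builds the trial schedule for one PRT session: two 100-trial blocks in which
#' the two stimuli ("rich" and "lean") appear equally often in randomized
#' order, but correct identifications of the rich stimulus are scheduled for
#' reward three times as often as correct identifications of the lean stimulus.
#'
#' Two delivery mechanisms are supported. Under `"bernoulli"`, each trial is
#' independently flagged for reward with probability `p_rich` (rich trials) or
#' `p_lean` (lean trials); the 3:1 asymmetry holds in expectation. Under
#' `"queued"`, each block carries exactly `p_rich * 50` rich and `p_lean * 50`
#' lean scheduled rewards (30 and 10 at the defaults); a scheduled reward that
#' is not collected (incorrect response) is re-queued to the next correct
#' response of the same stimulus type within the block, so realized per-block
#' reward counts are exact whenever enough correct responses occur.
#'
#' @param seed Integer seed; the same seed always yields the same schedule.
#' @param counterbalance Which physical mouth length is assigned to the rich
#'   condition: `"short_rich"` or `"long_rich"`.
#' @param delivery_rule `"bernoulli"` (default) or `"queued"`.
#' @param p_rich,p_lean Scheduled-reward probabilities for correct rich and
#'   lean identifications. The task design requires `p_rich = 3 * p_lean`.
#' @param n_blocks,trials_per_block Session dimensions (defaults 2 and 100).
#' @return A data frame of class `prt_schedule` with columns `trial`, `block`,
#'   `stimulus`, `mouth`, `reward_scheduled`, and the delivery rule stored as
#'   an attribute.
#' @export
generate_schedule <- function(seed = 1L,
                              counterbalance = c("short_rich", "long_rich"),
                              delivery_rule = c("bernoulli", "queued"),
                              p_rich = 0.60, p_lean = 0.20,
                              n_blocks = 2L, trials_per_block = 100L) {
  counterbalance <- match.arg(counterbalance)
  delivery_rule <- match.arg(delivery_rule)
  if (!(p_rich > 0 && p_rich < 1 && p_lean > 0 && p_lean < 1))
    stop("reward probabilities must lie in (0, 1)")
  if (abs(p_rich - 3 * p_lean) > 1e-12)
    stop("task design requires p_rich = 3 * p_lean (got ",
         p_rich, " and ", p_lean, ")")
  if (trials_per_block %% 2L != 0L)
    stop("trials_per_block must be even (equal rich/lean counts)")

  half <- trials_per_block / 2L
  with_local_seed(seed, {
    blocks <- lapply(seq_len(n_blocks), function(b) {
      stim <- sample(rep(c("rich", "lean"), each = half))
      if (delivery_rule == "bernoulli") {
        rs <- ifelse(stim == "rich",
                     rbinom(trials_per_block, 1L, p_rich),
                     rbinom(trials_per_block, 1L, p_lean)) == 1L
      } else {
        n_rich_rw <- round(half * p_rich)
        n_lean_rw <- round(half * p_lean)
        rs <- logical(trials_per_block)
        rs[sample(which(stim == "rich"), n_rich_rw)] <- TRUE
        rs[sample(which(stim == "lean"), n_lean_rw)] <- TRUE
      }
      data.frame(block = b, stimulus = stim, reward_scheduled = rs,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, blocks)
    out$trial <- seq_len(nrow(out))
    rich_mouth <- if (counterbalance == "short_rich") "short" else "long"
    out$mouth <- ifelse(out$stimulus == "rich", rich_mouth,
                        setdiff(c("short", "long"), rich_mouth))
    out <- out[, c("trial", "block", "stimulus", "mouth", "reward_scheduled")]
    attr(out, "delivery_rule") <- delivery_rule
    attr(out, "p_rich") <- p_rich
    attr(out, "p_lean") <- p_lean
    attr(out, "counterbalance") <- counterbalance
    class(out) <- c("prt_schedule", "data.frame")
    out
  })
}

#' Construct a subject's PRT session
#'
#' Bundles a trial table with optional covariates (diagnostic group, anhedonia
#' symptom score, age). Trials must be uniquely indexed and chronologically
#' ordered.
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param trials Data frame with at least `trial`, `block`, `stimulus`,
#'   `response`, `rt`, `reward`. RTs are in seconds; `response` is one of
#'   `"rich"`, `"lean"`, `"none"`; `rt` must be `NA` exactly when the response
#'   is `"none"`.
#' @param group,symptom_score,age Optional covariates.
#' @return An object of class `subject_data`.
#' @export
subject_data <- function(subject_id, trials, group = NA_character_,
                         symptom_score = NA_real_, age = NA_real_) {
  required <- c("trial", "block", "stimulus", "response", "rt", "reward")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols))
    stop("trials is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(trials) == 0L) stop("empty trial list")
  if (anyDuplicated(trials$trial)) stop("duplicate trial index")
  if (is.unsorted(trials$trial, strictly = TRUE))
    stop("trials must be sorted by trial index")
  none <- trials$response == "none"
  if (any(none != is.na(trials$rt)))
    stop("rt must be missing exactly when response is 'none'")
  if (!("correct" %in% names(trials)))
    trials$correct <- ifelse(none, NA, trials$response == trials$stimulus)
  if (!("valid" %in% names(trials))) trials$valid <- !none
  structure(list(subject_id = as.character(subject_id), trials = trials,
                 group = group, symptom_score = symptom_score, age = age,
                 qc = NULL),
            class = "subject_data")
}

#' @export
print.subject_data <- function(x, ...) {
  cat("PRT subject", x$subject_id, "-", nrow(x$trials), "trials,",
      sum(x$trials$valid), "valid\n")
  if (!is.na(x$group)) cat("  group:", x$group, "\n")
  if (!is.null(x$qc))
    cat("  QC: invalid fraction", round(x$qc$invalid_frac, 3),
        if (x$qc$exclude) "(flagged for exclusion)" else "", "\n")
  invisible(x)
}

#' Apply quality control to a subject's trials
#'
#' Flags trials as invalid when the response is missing or the RT falls
#' outside `[rt_min, rt_max]`; invalid trials are excluded from the likelihood
#' but retained in the table. The subject is flagged for exclusion when the
#' invalid fraction exceeds `max_invalid_frac`. The operation is idempotent:
#' validity is always recomputed from the raw response and RT columns.
#'
#' @param subject A `subject_data` object.
#' @param rt_min,rt_max Valid RT window in seconds (defaults 0.150 and 2.0).
#' @param max_invalid_frac Exclusion threshold on the invalid-trial fraction.
#' @return The subject with an updated `valid` column and a `qc` report
#'   (counts per exclusion reason, invalid fraction, exclusion flag).
#' @export
apply_quality_control <- function(subject, rt_min = 0.150, rt_max = 2.0,
                                  max_invalid_frac = 0.20) {
  stopifnot(inherits(subject, "subject_data"))
  tr <- subject$trials
  if (nrow(tr) == 0L) stop("empty trial list")
  missing_resp <- tr$response == "none" | is.na(tr$rt)
  too_fast <- !missing_resp & tr$rt < rt_min
  too_slow <- !missing_resp & tr$rt > rt_max
  invalid <- missing_resp | too_fast | too_slow
  subject$trials$valid <- !invalid
  frac <- mean(invalid)
  subject$qc <- list(n_trials = nrow(tr),
                     n_missing_response = sum(missing_resp),
                     n_rt_too_fast = sum(too_fast),
                     n_rt_too_slow = sum(too_slow),
                     n_invalid = sum(invalid),
                     invalid_frac = frac,
                     rt_min = rt_min, rt_max = rt_max,
                     max_invalid_frac = max_invalid_frac,
                     exclude = frac > max_invalid_frac)
  subject
}

trial_table_cols <- c("subject", "block", "trial", "stimulus", "response",
                      "rt_ms", "reward")

#' Read PRT trial tables
#'
#' Reads a delimited trial table (CSV) with header columns `subject`, `block`,
#' `trial`, `stimulus`, `response`, `rt_ms`, `reward` (plus optional `mouth`,
#' `reward_scheduled`, `group`, `symptom_score`, `age`). RTs are stored in
#' milliseconds on disk and converted to seconds in memory.
#'
#' @param path File path.
#' @return A list of `subject_data` objects, one per subject, in order of
#'   first appearance.
#' @export
read_trials <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trial_table_cols, names(raw))
  if (length(missing_cols))
    stop("parse error: missing column: ", paste(missing_cols, collapse = ", "))
  bad_rt <- !is.na(raw$rt_ms) & (raw$rt_ms <= 0 | raw$rt_ms > 1e5)
  if (any(bad_rt))
    stop("parse error: rt_ms out of representable range on row(s) ",
         paste(head(which(bad_rt), 5), collapse = ", "))
  ids <- unique(raw$subject)
  lapply(ids, function(id) {
    rows <- raw[raw$subject == id, , drop = FALSE]
    if (is.unsorted(rows$trial, strictly = TRUE))
      stop("parse error: non-monotone trial index for subject ", id)
    tr <- data.frame(trial = rows$trial, block = rows$block,
                     stimulus = rows$stimulus, response = rows$response,
                     rt = rows$rt_ms / 1000, reward = rows$reward,
                     stringsAsFactors = FALSE)
    if ("mouth" %in% names(rows)) tr$mouth <- rows$mouth
    if ("reward_scheduled" %in% names(rows))
      tr$reward_scheduled <- as.logical(rows$reward_scheduled)
    grab <- function(col, default) if (col %in% names(rows)) rows[[col]][1] else default
    subject_data(id, tr,
                 group = as.character(grab("group", NA_character_)),
                 symptom_score = as.numeric(grab("symptom_score", NA_real_)),
                 age = as.numeric(grab("age", NA_real_)))
  })
}

#' Write PRT trial tables
#'
#' Inverse of [read_trials()]: writes a list of subjects (or a single subject)
#' to CSV with RTs in milliseconds. Writing and re-reading reproduces the
#' records exactly up to double-precision formatting.
#'
#' @param subjects A `subject_data` object or list of them.
#' @param path Output file path.
#' @export
write_trials <- function(subjects, path) {
  if (inherits(subjects, "subject_data")) subjects <- list(subjects)
  rows <- lapply(subjects, function(s) {
    tr <- s$trials
    out <- data.frame(subject = s$subject_id, block = tr$block,
                      trial = tr$trial, stimulus = tr$stimulus,
                      response = tr$response, rt_ms = tr$rt * 1000,
                      reward = tr$reward, stringsAsFactors = FALSE)
    if ("mouth" %in% names(tr)) out$mouth <- tr$mouth
    if ("reward_scheduled" %in% names(tr))
      out$reward_scheduled <- tr$reward_scheduled
    out$group <- s$group
    out$symptom_score <- s$symptom_score
    out$age <- s$age
    out
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
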