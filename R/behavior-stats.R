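#' Response bias
#'
#' Signal-detection response bias toward the rich response, in log units:
#' `0.5 * log10( ((rich_correct + 0.5) * (lean_incorrect + 0.5)) /
#' ((rich_incorrect + 0.5) * (lean_correct + 0.5)) )`. The 0.5 correction
#' keeps the measure defined for empty cells. Base-10 logs are the default
#' (matching the magnitude range conventionally reported for the task); set
#' `log_base = exp(1)` for natural logs.
#'
#' @param rich_correct,rich_incorrect,lean_correct,lean_incorrect Trial
#'   counts.
#' @param log_base Logarithm base (default 10).
#' @return Response bias in log units.
#' @export
response_bias <- function(rich_correct, rich_incorrect, lean_correct,
                          lean_incorrect, log_base = 10) {
  stopifnot(all(c(rich_correct, rich_incorrect, lean_correct,
                  lean_incorrect) >= 0))
  0.5 * log(((rich_correct + 0.5) * (lean_incorrect + 0.5)) /
              ((rich_incorrect + 0.5) * (lean_correct + 0.5)), base = log_base)
}

#' Discriminability
#'
#' Signal-detection discriminability (accuracy independent of bias), in log
#' units: `0.5 * log10( ((rich_correct + 0.5) * (lean_correct + 0.5)) /
#' ((rich_incorrect + 0.5) * (lean_incorrect + 0.5)) )`.
#'
#' @inheritParams response_bias
#' @return Discriminability in log units.
#' @export
discriminability <- function(rich_correct, rich_incorrect, lean_correct,
                             lean_incorrect, log_base = 10) {
  stopifnot(all(c(rich_correct, rich_incorrect, lean_correct,
                  lean_incorrect) >= 0))
  0.5 * log(((rich_correct + 0.5) * (lean_correct + 0.5)) /
              ((rich_incorrect + 0.5) * (lean_incorrect + 0.5)), base = log_base)
}

sdt_counts <- function(trials) {
  v <- trials[trials$valid & trials$response != "none", , drop = FALSE]
  c(rich_correct = sum(v$stimulus == "rich" & v$correct),
    rich_incorrect = sum(v$stimulus == "rich" & !v$correct),
    lean_correct = sum(v$stimulus == "lean" & v$correct),
    lean_incorrect = sum(v$stimulus == "lean" & !v$correct))
}

summary_row <- function(trials, log_base = 10) {
  cnt <- sdt_counts(trials)
  v <- trials[trials$valid & trials$response != "none", , drop = FALSE]
  mrt <- function(cond) {
    x <- v$rt[cond]
    if (length(x)) mean(x) else NA_real_
  }
  data.frame(
    response_bias = response_bias(cnt[1], cnt[2], cnt[3], cnt[4], log_base),
    discriminability = discriminability(cnt[1], cnt[2], cnt[3], cnt[4], log_base),
    rich_acc = if (cnt[1] + cnt[2] > 0) cnt[[1]] / (cnt[[1]] + cnt[[2]]) else NA_real_,
    lean_acc = if (cnt[3] + cnt[4] > 0) cnt[[3]] / (cnt[[3]] + cnt[[4]]) else NA_real_,
    rich_rt = mrt(v$stimulus == "rich"),
    lean_rt = mrt(v$stimulus == "lean"),
    rich_correct_rt = mrt(v$stimulus == "rich" & v$correct),
    lean_correct_rt = mrt(v$stimulus == "lean" & v$correct),
    rich_error_rt = mrt(v$stimulus == "rich" & !v$correct),
    lean_error_rt = mrt(v$stimulus == "lean" & !v$correct))
}

#' Behavioral summary of a PRT session
#'
#' Per-block and session-level performance statistics: response bias,
#' discriminability, accuracy and mean RTs (overall and split by
#' correct/error) for each stimulus type, plus the change in response bias
#' from block 1 to block 2.
#'
#' The session-level row can pool counts across blocks (`average =
#' "pooled"`, the default) or average the block-level statistics (`average =
#' "mean_of_blocks"`); both conventions appear in the literature.
#'
#' @param subject A `subject_data` object.
#' @param log_base Logarithm base for the signal-detection measures.
#' @param average `"pooled"` or `"mean_of_blocks"`.
#' @return A data frame of class `behavioral_summary` with one row per block
#'   plus an `"average"` row; the block-2 minus block-1 bias change is stored
#'   in the `bias_change` attribute (and column on the average row).
#' @export
behavioral_summary <- function(subject, log_base = 10,
                               average = c("pooled", "mean_of_blocks")) {
  stopifnot(inherits(subject, "subject_data"))
  average <- match.arg(average)
  tr <- subject$trials
  blocks <- sort(unique(tr$block))
  rows <- lapply(blocks, function(b)
    summary_row(tr[tr$block == b, , drop = FALSE], log_base))
  avg <- if (average == "pooled") summary_row(tr, log_base)
         else as.data.frame(t(colMeans(do.call(rbind, rows))))
  out <- rbind(do.call(rbind, rows), avg)
  out <- cbind(data.frame(block = c(as.character(blocks), "average"),
                          stringsAsFactors = FALSE), out)
  bias_change <- if (length(blocks) == 2)
    rows[[2]]$response_bias - rows[[1]]$response_bias else NA_real_
  out$bias_change <- c(rep(NA_real_, length(blocks)), bias_change)
  attr(out, "bias_change") <- bias_change
  rownames(out) <- NULL
  class(out) <- c("behavioral_summary", "data.frame")
  out
}

#' Accuracy by stimulus type and RT speed
#'
#' Classifies each subject's fast and slow trials by quantiles of their own
#' valid-RT distribution (defaults: fast below the 0.1 quantile, slow above
#' the 0.9 quantile) and returns rich/lean accuracy within each speed class,
#' together with the bias-by-speed signature: the rich minus lean accuracy
#' difference among fast trials versus among slow trials. A strong
#' starting-point bias predicts a larger rich advantage on fast than on slow
#' trials.
#'
#' @param subject A `subject_data` object.
#' @param fast_q,slow_q RT quantiles bounding the fast and slow classes.
#' @param min_cell Cells with fewer trials than this are flagged unreliable.
#' @return A list with the accuracy table (`stimulus` x `speed`), the fast
#'   and slow contrasts, their difference (`contrast_diff`), and an
#'   `unreliable` flag.
#' @export
rt_speed_contrast <- function(subject, fast_q = 0.1, slow_q = 0.9,
                              min_cell = 5) {
  stopifnot(inherits(subject, "subject_data"))
  v <- subject$trials
  v <- v[v$valid & v$response != "none" & !is.na(v$rt), , drop = FALSE]
  if (!nrow(v)) stop("no valid trials")
  qf <- quantile(v$rt, fast_q, names = FALSE)
  qs <- quantile(v$rt, slow_q, names = FALSE)
  cell <- function(stim, fast) {
    sel <- v$stimulus == stim & (if (fast) v$rt <= qf else v$rt >= qs)
    n <- sum(sel)
    data.frame(stimulus = stim, speed = if (fast) "fast" else "slow",
               n = n, accuracy = if (n) mean(v$correct[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  }
  tab <- rbind(cell("rich", TRUE), cell("lean", TRUE),
               cell("rich", FALSE), cell("lean", FALSE))
  acc <- function(stim, speed) tab$accuracy[tab$stimulus == stim & tab$speed == speed]
  fast_contrast <- acc("rich", "fast") - acc("lean", "fast")
  slow_contrast <- acc("rich", "slow") - acc("lean", "slow")
  list(table = tab,
       fast_contrast = fast_contrast,
       slow_contrast = slow_contrast,
       contrast_diff = fast_contrast - slow_contrast,
       unreliable = any(tab$n < min_cell))
}

#' Split-half reliability
#'
#' Across-block agreement of a per-subject measure: the Pearson correlation
#' of block-1 and block-2 values, its Spearman-Brown step-up
#' `r_sb = 2 r / (1 + r)`, and the intraclass correlation (two-way random
#' effects, absolute agreement, single measurement).
#'
#' @param block1_values,block2_values Paired per-subject values.
#' @return A list of class `reliability_report` with `r`, `r_sb`, `icc`,
#'   `n`, and a `degenerate` flag set when either half has zero variance.
#' @export
split_half_reliability <- function(block1_values, block2_values) {
  ok <- complete.cases(block1_values, block2_values)
  x <- block1_values[ok]; y <- block2_values[ok]
  n <- length(x)
  if (n < 3) stop("at least 3 paired values are required")
  if (sd(x) < 1e-12 || sd(y) < 1e-12)
    return(structure(list(r = NA_real_, r_sb = NA_real_, icc = NA_real_,
                          n = n, degenerate = TRUE),
                     class = "reliability_report"))
  r <- cor(x, y)
  r_sb <- 2 * r / (1 + r)
  # ICC(2,1): two-way random, absolute agreement, single measure
  k <- 2
  grand <- mean(c(x, y))
  row_means <- (x + y) / 2
  col_means <- c(mean(x), mean(y))
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((c(x, y) - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  structure(list(r = r, r_sb = r_sb, icc = icc, n = n, degenerate = FALSE),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  if (x$degenerate) cat("Split-half reliability: degenerate (zero variance)\n")
  else cat(sprintf(
    "Split-half reliability (n = %d): r = %.3f, Spearman-Brown = %.3f, ICC = %.3f\n",
    x$n, x$r, x$r_sb, x$icc))
  invisible(x)
}

#' Two-group comparison of a measure
#'
#' Welch two-sample t-test with Cohen's d (pooled-SD standardizer), for
#' comparing a per-subject measure between any two grouping labels.
#'
#' @param values Per-subject values.
#' @param group Grouping labels (exactly two levels after dropping NAs).
#' @return A list with `t`, `df`, `p`, `cohens_d`, group means and ns, and a
#'   `degenerate` flag when a group has (near) zero variance.
#' @export
group_compare <- function(values, group) {
  ok <- complete.cases(values, group)
  values <- values[ok]; group <- as.character(group[ok])
  lv <- unique(group)
  if (length(lv) != 2) stop("exactly two groups are required")
  x <- values[group == lv[1]]; y <- values[group == lv[2]]
  if (length(x) < 2 || length(y) < 2) stop("at least 2 values per group")
  degenerate <- sd(x) < 1e-12 && sd(y) < 1e-12
  if (degenerate) {
    tt <- list(statistic = c(t = 0), parameter = c(df = NA_real_), p.value = 1)
    d <- 0
  } else {
    tt <- t.test(x, y, var.equal = FALSE)
    sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                 (length(x) + length(y) - 2))
    d <- (mean(x) - mean(y)) / sp
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohens_d = d,
       means = stats::setNames(c(mean(x), mean(y)), lv),
       n = stats::setNames(c(length(x), length(y)), lv),
       degenerate = degenerate)
}

#' Dimensional symptom correlation
#'
#' Pearson correlation (two-sided test) between a per-subject measure and a
#' symptom score, e.g. an anhedonia scale sum.
#'
#' @param values Per-subject values.
#' @param scores Per-subject symptom scores.
#' @return A list with `r`, `p`, `n`, and a `degenerate` flag.
#' @export
symptom_correlation <- function(values, scores) {
  ok <- complete.cases(values, scores)
  x <- values[ok]; y <- scores[ok]
  if (length(x) < 3) stop("at least 3 complete pairs are required")
  if (sd(x) < 1e-12 || sd(y) < 1e-12)
    return(list(r = NA_real_, p = NA_real_, n = length(x), degenerate = TRUE))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       degenerate = FALSE)
}

#' Median split by age
#'
#' Divides subjects into younger and older subgroups at the median age; ties
#' at the median are assigned to the younger group.
#'
#' @param age Numeric ages.
#' @return A factor with levels `"younger"`, `"older"`.
#' @export
median_age_split <- function(age) {
  m <- median(age, na.rm = TRUE)
  factor(ifelse(age <= m, "younger", "older"), levels = c("younger", "older"))
}
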