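test_that("response bias and discriminability match direct evaluation", {
  rb <- response_bias(80, 20, 60, 40)
  expect_equal(rb, 0.5 * log10((80.5 * 40.5) / (20.5 * 60.5)), tolerance = 1e-12)
  expect_equal(rb, 0.210, tolerance = 1e-3)
  ds <- discriminability(82, 18, 77, 23)
  expect_equal(ds, 0.5 * log10((82.5 * 77.5) / (18.5 * 23.5)), tolerance = 1e-12)
  expect_equal(ds, 0.584, tolerance = 1e-3)
  # perfect performance with the 0.5 correction
  expect_equal(discriminability(100, 0, 100, 0),
               0.5 * log10((100.5 * 100.5) / (0.5 * 0.5)), tolerance = 1e-12)
  expect_equal(discriminability(100, 0, 100, 0), 2.303, tolerance = 1e-3)
  # symmetric counts give zero bias; chance counts give zero discriminability
  expect_equal(response_bias(30, 12, 30, 12), 0)
  expect_equal(response_bias(0, 0, 0, 0), 0)
  expect_equal(discriminability(50, 50, 50, 50), 0)
  # natural-log option scales by log(10)
  expect_equal(response_bias(80, 20, 60, 40, log_base = exp(1)),
               rb * log(10), tolerance = 1e-12)
})

test_that("bias plus discriminability reduces to the rich-count ratio", {
  set.seed(4)
  for (i in 1:25) {
    n <- sample(5:120, 4, replace = TRUE)
    lhs <- response_bias(n[1], n[2], n[3], n[4]) +
      discriminability(n[1], n[2], n[3], n[4])
    expect_equal(lhs, log10((n[1] + 0.5) / (n[2] + 0.5)), tolerance = 1e-10)
  }
})

test_that("behavioral summary reproduces per-block and pooled statistics", {
  sub <- fixture_cohort()$subjects[[1]]
  bs <- behavioral_summary(sub)
  expect_equal(bs$block, c("1", "2", "average"))
  tr <- sub$trials[sub$trials$valid & sub$trials$response != "none", ]
  b1 <- tr[tr$block == 1, ]
  expect_equal(bs$rich_acc[1], mean(b1$correct[b1$stimulus == "rich"]))
  expect_equal(bs$lean_rt[2],
               mean(tr$rt[tr$block == 2 & tr$stimulus == "lean"]))
  # pooled average row equals statistics on all trials together
  cnt <- c(sum(tr$stimulus == "rich" & tr$correct),
           sum(tr$stimulus == "rich" & !tr$correct),
           sum(tr$stimulus == "lean" & tr$correct),
           sum(tr$stimulus == "lean" & !tr$correct))
  expect_equal(bs$response_bias[3], response_bias(cnt[1], cnt[2], cnt[3], cnt[4]))
  # bias change = block2 - block1
  expect_equal(attr(bs, "bias_change"), bs$response_bias[2] - bs$response_bias[1])
  # mean-of-blocks convention averages the block rows
  bs2 <- behavioral_summary(sub, average = "mean_of_blocks")
  expect_equal(bs2$response_bias[3],
               mean(c(bs$response_bias[1], bs$response_bias[2])))
})

test_that("RT-speed contrast isolates fast-trial bias", {
  mk <- function(rts, stim, correct) {
    n <- length(rts)
    tr <- data.frame(trial = 1:n, block = rep(1:2, each = n / 2),
                     stimulus = stim, response = ifelse(correct, stim,
                       ifelse(stim == "rich", "lean", "rich")),
                     rt = rts, reward = 0L, stringsAsFactors = FALSE)
    subject_data("fx", tr)
  }
  # uniform accuracy across speeds: zero interaction
  stim <- rep(c("rich", "lean"), 50)
  rts <- seq(0.3, 1.3, length.out = 100)
  sub <- mk(rts, stim, rep(TRUE, 100))
  rc <- rt_speed_contrast(sub)
  expect_equal(rc$contrast_diff, 0)
  expect_false(rc$unreliable)
  # rich advantage confined to fast trials; elsewhere accuracy is 0.5 for
  # both stimuli by construction (period-4 pattern aligned with the stimuli)
  fast <- rts <= quantile(rts, 0.1)
  correct2 <- rep(c(TRUE, TRUE, FALSE, FALSE), 25)
  correct2[fast] <- stim[fast] == "rich"
  sub2 <- mk(rts, stim, correct2)
  rc2 <- rt_speed_contrast(sub2)
  expect_equal(rc2$fast_contrast, 1)
  expect_equal(rc2$slow_contrast, 0)
  # sparse cells are flagged
  sub3 <- mk(seq(0.3, 1.3, length.out = 20), rep(c("rich", "lean"), 10),
             rep(TRUE, 20))
  expect_true(rt_speed_contrast(sub3)$unreliable)
})

test_that("Action-DDM simulations show the fast>slow bias signature", {
  p <- actionddm_params(0.4, 0.3, 2.5, 1.5, 1, 0.3)
  cd <- vapply(1:15, function(s) {
    sub <- simulate_subject(p, generate_schedule(seed = 40 + s),
                            seed = 400 + s, dt = 5e-4)
    rt_speed_contrast(sub)$contrast_diff
  }, 0)
  expect_gt(mean(cd), 0)
})

test_that("split-half reliability implements Spearman-Brown and ICC", {
  # analytic Spearman-Brown from a constructed correlation
  set.seed(11)
  x <- rnorm(200)
  y <- x + rnorm(200, sd = 1)  # r around 0.7
  rel <- split_half_reliability(x, y)
  expect_equal(rel$r_sb, 2 * rel$r / (1 + rel$r), tolerance = 1e-12)
  expect_gte(rel$r_sb, rel$r)  # boost property for positive r
  # r = 0.5 gives 2/3 exactly: construct data with exact sample correlation
  expect_equal(2 * 0.5 / (1 + 0.5), 2 / 3)
  # identical halves
  rel1 <- split_half_reliability(x, x)
  expect_equal(rel1$r, 1)
  expect_equal(rel1$r_sb, 1)
  expect_equal(rel1$icc, 1)
  # independent halves at large n
  rel0 <- split_half_reliability(rnorm(2000), rnorm(2000))
  expect_lt(abs(rel0$r_sb), 0.1)
  # ICC oracle: direct two-way ANOVA computation
  icc_ref <- function(x, y) {
    n <- length(x); k <- 2
    d <- data.frame(y = c(x, y), subj = factor(rep(1:n, 2)),
                    rater = factor(rep(1:2, each = n)))
    a <- anova(aov(y ~ subj + rater, data = d))
    msr <- a["subj", "Mean Sq"]; msc <- a["rater", "Mean Sq"]
    mse <- a["Residuals", "Mean Sq"]
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
  expect_equal(rel$icc, icc_ref(x, y), tolerance = 1e-10)
  # degenerate halves are flagged
  expect_true(split_half_reliability(rep(1, 5), 1:5)$degenerate)
})

test_that("group comparison matches a hand-computed Welch t-test", {
  x <- c(1.2, 0.8, 1.5); y <- c(2.1, 1.9, 2.6)
  gc <- group_compare(c(x, y), rep(c("A", "B"), each = 3))
  # textbook Welch formula
  se <- sqrt(var(x) / 3 + var(y) / 3)
  t_ref <- (mean(x) - mean(y)) / se
  df_ref <- se^4 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(gc$t, t_ref, tolerance = 1e-10)
  expect_equal(gc$df, df_ref, tolerance = 1e-10)
  expect_equal(gc$p, 2 * pt(-abs(t_ref), df_ref), tolerance = 1e-10)
  sp <- sqrt((2 * var(x) + 2 * var(y)) / 4)
  expect_equal(gc$cohens_d, (mean(x) - mean(y)) / sp, tolerance = 1e-10)
  # identical groups: t = 0
  gc0 <- group_compare(rep(c(1, 2, 3), 2), rep(c("A", "B"), each = 3))
  expect_equal(gc0$t, 0)
  expect_error(group_compare(1:4, rep("A", 4)), "two groups")
})

test_that("symptom correlation and the age split behave as specified", {
  v <- c(0.1, 0.5, 0.3, 0.9, 0.7)
  sc <- symptom_correlation(v, v)
  expect_equal(sc$r, 1, tolerance = 1e-12)
  set.seed(2)
  a <- rnorm(50); b <- 0.5 * a + rnorm(50)
  ct <- cor.test(a, b)
  sc2 <- symptom_correlation(a, b)
  expect_equal(sc2$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(sc2$p, ct$p.value, tolerance = 1e-12)
  # median split assigns ties to the younger group
  ages <- c(14, 16, 18, 18, 21, 25)
  sp <- median_age_split(ages)
  expect_equal(as.character(sp),
               c("younger", "younger", "younger", "younger", "older", "older"))
})
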