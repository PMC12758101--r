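test_that("zero learning rate freezes the starting point at 0.5", {
  p <- actionddm_params(0, 0.8, 1.5, 1.5, 1, 0.3)
  sub <- simulate_subject(p, generate_schedule(seed = 2), seed = 2)
  expect_true(all(sub$latents[, "z_t"] == 0.5))
  expect_true(all(sub$latents[, "delta_q"] == 0))
})

test_that("without value-to-decision coupling rich and lean accuracy match", {
  p <- actionddm_params(0.3, 0, 0, 1.5, 1, 0.3)
  accs <- vapply(1:40, function(s) {
    sub <- simulate_subject(p, generate_schedule(seed = s), seed = s + 500,
                            dt = 5e-4)
    tr <- sub$trials[sub$trials$response != "none", ]
    c(mean(tr$correct[tr$stimulus == "rich"]),
      mean(tr$correct[tr$stimulus == "lean"]))
  }, numeric(2))
  # equal in expectation; 40 x 100 trials per cell gives MC error ~ 0.006
  expect_lt(abs(mean(accs[1, ]) - mean(accs[2, ])), 0.02)
})

test_that("a strong starting-point weight biases late-trial behavior rich-ward", {
  # the weight must dominate the stimulus drift for rich choices to prevail
  # even on lean trials
  p <- actionddm_params(0.4, 0.3, 6, 1.0, 1, 0.3)
  late_z <- numeric(30)
  rich_choice <- matrix(NA_real_, 30, 2)
  for (s in 1:30) {
    sub <- simulate_subject(p, generate_schedule(seed = s), seed = s + 900,
                            dt = 5e-4)
    late <- sub$trials$trial > 100
    late_z[s] <- mean(sub$latents[late, "z_t"])
    tr <- sub$trials[late & sub$trials$response != "none", ]
    rich_choice[s, ] <- c(mean(tr$response[tr$stimulus == "rich"] == "rich"),
                          mean(tr$response[tr$stimulus == "lean"] == "rich"))
  }
  expect_true(all(late_z > 0.5))
  # rich responses dominate on both stimulus types in the aggregate
  expect_gt(mean(rich_choice[, 1]), 0.5)
  expect_gt(mean(rich_choice[, 2]), 0.5)
})

test_that("simulated sessions respect the response deadline", {
  # long non-decision time forces censoring
  p <- actionddm_params(0.3, 0, 0, 0.3, 2.5, 1.2)
  sub <- simulate_subject(p, generate_schedule(seed = 4), seed = 4, dt = 5e-4)
  tr <- sub$trials
  expect_true(any(tr$response == "none"))
  expect_true(all(is.na(tr$rt[tr$response == "none"])))
  expect_true(all(tr$rt[tr$response != "none"] <= 2))
  expect_true(all(tr$reward[tr$response == "none"] == 0))
})

test_that("queued delivery re-queues missed rewards within a block", {
  sch <- generate_schedule(seed = 9, delivery_rule = "queued")
  # near-perfect responder collects nearly all scheduled rewards
  p <- actionddm_params(0.2, 0, 0, 6, 1.5, 0.2)
  sub <- simulate_subject(p, sch, seed = 9)
  tr <- sub$trials
  acc <- mean(tr$correct[tr$response != "none"])
  expect_gt(acc, 0.97)
  for (b in 1:2) {
    blk <- tr[tr$block == b, ]
    sched_b <- sum(sch$reward_scheduled[sch$block == b])
    # with high accuracy, re-queuing delivers (almost) every scheduled reward,
    # including those initially missed on error trials
    expect_gte(sum(blk$reward), sched_b - 3)
    expect_lte(sum(blk$reward), sched_b)
  }
  # rewards only follow correct responses
  expect_true(all(tr$correct[tr$reward == 1]))
})

test_that("cohort simulation is reproducible and honors group structure", {
  c1 <- simulate_cohort(4, seed = 77, dt = 1e-3)
  c2 <- simulate_cohort(4, seed = 77, dt = 1e-3)
  expect_identical(c1$truth, c2$truth)
  expect_identical(lapply(c1$subjects, `[[`, "trials"),
                   lapply(c2$subjects, `[[`, "trials"))
  # parameters respect their domains after the link transforms
  expect_true(all(c1$truth$alpha > 0 & c1$truth$alpha < 1))
  expect_true(all(c1$truth$a > 0) && all(c1$truth$t > 0))
  expect_warning(simulate_cohort(2, groups = c(A = 1, B = 1),
                                 schedule_args = list(trials_per_block = 10),
                                 dt = 1e-3),
                 "fewer than 2")
})

test_that("injected group effects shift sampled parameters with high power", {
  # Delta b_z = -0.5 group SDs at n = 50 per group: the sampled group
  # difference carries the injected sign in nearly all replicate cohorts
  hits <- 0
  dist <- default_group_distribution()
  for (r in 1:100) {
    pa <- sample_group_params(50, dist, seed = 3000 + r)
    db <- dist
    db$location[db$param == "b_z"] <- db$location[db$param == "b_z"] -
      0.5 * db$scale[db$param == "b_z"]
    pb <- sample_group_params(50, db, seed = 6000 + r)
    if (mean(pb$b_z) < mean(pa$b_z)) hits <- hits + 1
  }
  expect_gte(hits, 90)
  # the same shift reaches the truth table through simulate_cohort
  coh <- simulate_cohort(groups = c(NC = 25, UNI = 25),
                         effects = list(UNI = c(b_z = -2)),
                         schedule_args = list(trials_per_block = 10),
                         seed = 5, dt = 1e-3)
  expect_lt(mean(coh$truth$b_z[coh$truth$group == "UNI"]),
            mean(coh$truth$b_z[coh$truth$group == "NC"]))
})

test_that("null cohorts produce calibrated group tests on true parameters", {
  dist <- default_group_distribution()
  rej <- 0
  for (r in 1:200) {
    x <- sample_group_params(30, dist, seed = 9000 + r)$b_z
    y <- sample_group_params(30, dist, seed = 12000 + r)$b_z
    gc <- group_compare(c(x, y), rep(c("A", "B"), each = 30))
    if (gc$p < 0.05) rej <- rej + 1
  }
  # nominal 5% type-I rate; binomial 99% band for 200 draws
  expect_gte(rej, 1)
  expect_lte(rej, 20)
})

test_that("simulated data are on average most likely under the generating parameters", {
  p <- actionddm_params(0.3, 0.5, 0.9, 1.6, 1, 0.33)
  subs <- lapply(1:10, function(s)
    simulate_subject(p, generate_schedule(seed = 15 + s), seed = 150 + s))
  avg_ll <- function(pp) mean(vapply(subs, subject_loglik, 0, params = pp))
  ll0 <- avg_ll(p)
  dist <- default_group_distribution()
  for (j in seq_len(6)) {
    for (dir in c(-1, 1)) {
      u <- actionddm:::addm_untransform(p)
      u[j] <- u[j] + dir * dist$scale[j] * 1.5
      pp <- actionddm:::addm_transform(u)
      expect_lt(avg_ll(pp), ll0,
                label = sprintf("average loglik, %s perturbed (%+d)",
                                actionddm:::param_names[j], dir))
    }
  }
})
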