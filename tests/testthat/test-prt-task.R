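test_that("generated schedules satisfy the task design", {
  sch <- generate_schedule(seed = 1)
  expect_equal(nrow(sch), 200)
  expect_equal(as.vector(table(sch$block)), c(100, 100))
  # equal stimulus frequency within each block
  for (b in 1:2) {
    blk <- sch[sch$block == b, ]
    expect_equal(sum(blk$stimulus == "rich"), 50)
    expect_equal(sum(blk$stimulus == "lean"), 50)
  }
  expect_equal(sum(sch$stimulus == "rich"), 100)
  # reproducibility
  expect_identical(generate_schedule(seed = 5), generate_schedule(seed = 5))
  expect_false(identical(generate_schedule(seed = 5)$stimulus,
                         generate_schedule(seed = 6)$stimulus))
  # mouth counterbalancing
  expect_true(all(sch$mouth[sch$stimulus == "rich"] == "short"))
  sch2 <- generate_schedule(seed = 1, counterbalance = "long_rich")
  expect_true(all(sch2$mouth[sch2$stimulus == "rich"] == "long"))
})

test_that("queued delivery schedules exact 30:10 per-block reward counts", {
  sch <- generate_schedule(seed = 7, delivery_rule = "queued")
  for (b in 1:2) {
    blk <- sch[sch$block == b, ]
    expect_equal(sum(blk$reward_scheduled), 40)
    expect_equal(sum(blk$reward_scheduled & blk$stimulus == "rich"), 30)
    expect_equal(sum(blk$reward_scheduled & blk$stimulus == "lean"), 10)
  }
})

test_that("bernoulli scheduled rewards approach the 3:1 asymmetry in expectation", {
  counts <- vapply(1:150, function(s) {
    sch <- generate_schedule(seed = s)
    c(sum(sch$reward_scheduled & sch$stimulus == "rich"),
      sum(sch$reward_scheduled & sch$stimulus == "lean"))
  }, numeric(2))
  ratio <- mean(counts[1, ]) / mean(counts[2, ])
  expect_gt(ratio, 2.8)
  expect_lt(ratio, 3.2)
})

test_that("schedule generation rejects designs violating the task", {
  expect_error(generate_schedule(seed = 1, p_rich = 0.6, p_lean = 0.3),
               "3 \\* p_lean")
  expect_error(generate_schedule(seed = 1, p_rich = 1.5, p_lean = 0.5),
               "\\(0, 1\\)")
})

test_that("quality control flags trials and subjects and is idempotent", {
  sub <- simulate_subject(actionddm_params(0.3, 0.4, 0.5, 1.5, 1, 0.35),
                          generate_schedule(seed = 3), seed = 3)
  # all valid: identity
  qc <- apply_quality_control(sub)
  if (qc$qc$n_invalid == 0) expect_identical(qc$trials, sub$trials)
  # one too-fast trial
  sub2 <- sub
  sub2$trials$rt[5] <- 0.05
  qc2 <- apply_quality_control(sub2)
  expect_false(qc2$trials$valid[5])
  expect_equal(qc2$qc$n_rt_too_fast, qc$qc$n_rt_too_fast + 1)
  # exclusion threshold: 50 of 200 invalid -> 0.25 > 0.20
  sub3 <- sub
  sub3$trials$rt[1:50] <- 0.01
  qc3 <- apply_quality_control(sub3)
  expect_equal(qc3$qc$n_invalid, 50 + sum(sub$trials$response == "none"))
  expect_true(qc3$qc$exclude)
  # idempotence
  expect_identical(apply_quality_control(qc3)$trials, qc3$trials)
  expect_identical(apply_quality_control(qc3)$qc, qc3$qc)
  # empty trials
  sub4 <- sub
  sub4$trials <- sub$trials[0, ]
  expect_error(apply_quality_control(sub4), "empty")
})

test_that("trial tables round-trip through CSV with ms-to-s conversion", {
  coh <- fixture_cohort()
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_trials(coh$subjects[1:3], f)
  back <- read_trials(f)
  expect_length(back, 3)
  f2 <- tempfile(fileext = ".csv")
  on.exit(unlink(f2), add = TRUE)
  write_trials(back, f2)
  expect_identical(read_trials(f2), back)
  expect_equal(back[[1]]$trials$rt, coh$subjects[[1]]$trials$rt)
  # unit conversion: ms on disk, seconds in memory
  raw <- read.csv(f)
  i <- which(!is.na(raw$rt_ms))[1]
  expect_equal(back[[1]]$trials$rt[i], raw$rt_ms[i] / 1000)
  raw$rt_ms[i] <- 529
  write.csv(raw, f2, row.names = FALSE)
  expect_equal(read_trials(f2)[[1]]$trials$rt[i], 0.529)
})

test_that("malformed trial tables produce labeled parse errors", {
  coh <- fixture_cohort()
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_trials(coh$subjects[[1]], f)
  raw <- read.csv(f)
  write.csv(raw[, setdiff(names(raw), "rt_ms")], f, row.names = FALSE)
  expect_error(read_trials(f), "missing column: rt_ms")
  # non-monotone trial index
  raw2 <- raw
  raw2$trial[2:1] <- raw2$trial[1:2]
  write.csv(raw2, f, row.names = FALSE)
  expect_error(read_trials(f), "non-monotone")
  # out-of-range rt
  raw3 <- raw
  raw3$rt_ms[1] <- -4
  write.csv(raw3, f, row.names = FALSE)
  expect_error(read_trials(f), "out of representable range")
})
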