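test_that("delta-rule update matches direct evaluation and its identities", {
  expect_equal(q_update(0.2, 1, 0.5), 0.6, tolerance = 1e-12)
  # zero learning rate: value frozen
  expect_equal(q_update(c(0, 0.3, 1), 1, 0), c(0, 0.3, 1))
  expect_equal(q_update(c(0, 0.3, 1), 0, 0), c(0, 0.3, 1))
  # zero prediction error: value frozen for any alpha
  for (al in c(0.1, 0.5, 1)) {
    expect_equal(q_update(1, 1, al), 1)
    expect_equal(q_update(0, 0, al), 0)
  }
  # values stay in [0, 1] under 0/1 rewards
  set.seed(1)
  q <- 0.5
  for (i in 1:500) {
    q <- q_update(q, rbinom(1, 1, 0.5), runif(1))
    expect_true(q >= 0 && q <= 1)
  }
})

test_that("trial latents implement the value-difference mappings", {
  p <- actionddm_params(0.3, 0.5, 2, 1.5, 1.2, 0.3)
  # equal values: unbiased start, zero value difference
  l0 <- trial_latents(0.4, 0.4, p, "rich")
  expect_equal(l0$z_t, 0.5)
  expect_equal(l0$delta_q, 0)
  expect_equal(l0$v_t, 1.5)
  # softmax starting point: logistic(b_z * delta_q)
  l1 <- trial_latents(0.6, 0.2, p, "rich")
  expect_equal(l1$z_t, plogis(2 * 0.4), tolerance = 1e-12)
  expect_equal(l1$z_t, 0.6900, tolerance = 1e-4)
  expect_equal(l1$z_t,
               exp(2 * 0.6) / (exp(2 * 0.6) + exp(2 * 0.2)), tolerance = 1e-12)
  # signed drift: s * v_intercept + b_v * delta_q
  expect_equal(l1$v_t, 1.5 + 0.5 * 0.4, tolerance = 1e-12)
  expect_equal(trial_latents(0.6, 0.2, p, "lean")$v_t, -1.5 + 0.5 * 0.4)
  # whole-sum sign convention
  expect_equal(trial_latents(0.6, 0.2, p, "lean", sign_whole = TRUE)$v_t,
               -(1.5 + 0.5 * 0.4))
  # extreme weights do not overflow
  pbig <- actionddm_params(0.3, 0.5, 800, 1.5, 1.2, 0.3)
  expect_equal(trial_latents(1, 0, pbig, "rich")$z_t, 1)
  expect_equal(trial_latents(0, 1, pbig, "rich")$z_t, 0)
})

test_that("starting point is strictly increasing in b_z when delta_q > 0", {
  bz <- seq(-2, 4, by = 0.5)
  z <- vapply(bz, function(b)
    trial_latents(0.7, 0.3, actionddm_params(0.3, 0.5, b, 1.5, 1.2, 0.3),
                  "rich")$z_t, 0)
  expect_true(all(diff(z) > 0))
  # and decreasing when delta_q < 0
  z2 <- vapply(bz, function(b)
    trial_latents(0.2, 0.5, actionddm_params(0.3, 0.5, b, 1.5, 1.2, 0.3),
                  "rich")$z_t, 0)
  expect_true(all(diff(z2) < 0))
})

test_that("sequential likelihood matches a naive trial-by-trial loop", {
  sub <- fixture_cohort()$subjects[[2]]
  p <- actionddm_params(0.35, 0.6, 0.9, 1.4, 1.05, 0.3)
  expect_equal(subject_loglik(sub, p), ref_subject_loglik(sub, p),
               tolerance = 1e-8)
  # with invalid trials excluded from the likelihood but still updating Q
  sub2 <- apply_quality_control(sub, rt_min = 0.4)
  expect_equal(subject_loglik(sub2, p), ref_subject_loglik(sub2, p),
               tolerance = 1e-8)
})

test_that("lesioned likelihood reduces to a plain DDM", {
  sub <- fixture_cohort()$subjects[[1]]
  p0 <- actionddm_params(0, 0, 0, 1.5, 1.1, 0.3)
  tr <- sub$trials
  ok <- tr$valid & tr$response != "none"
  v <- ifelse(tr$stimulus == "rich", 1.5, -1.5)
  b <- ifelse(tr$response == "rich", 1L, -1L)
  plain <- sum(wfpt_logpdf(tr$rt[ok], b[ok], v[ok], 1.1, 0.5, 0.3))
  expect_equal(subject_loglik(sub, p0), plain, tolerance = 1e-10)
  # alpha > 0 but no value influence on the decision: still a plain DDM
  p1 <- actionddm_params(0.4, 0, 0, 1.5, 1.1, 0.3)
  expect_equal(subject_loglik(sub, p1), plain, tolerance = 1e-10)
})

test_that("one-trial sessions start from the unbiased initial state", {
  sub <- fixture_cohort()$subjects[[1]]
  sub$trials <- sub$trials[sub$trials$response != "none", ][1, , drop = FALSE]
  p <- actionddm_params(0.3, 0.7, 1.2, 1.5, 1.1, 0.3)
  tr <- sub$trials
  v <- if (tr$stimulus == "rich") 1.5 else -1.5
  b <- if (tr$response == "rich") "upper" else "lower"
  expect_equal(subject_loglik(sub, p), wfpt_logpdf(tr$rt, b, v, 1.1, 0.5, 0.3))
  lat <- subject_loglik(sub, p, return_latents = TRUE)$latents
  expect_equal(unname(lat[1, ]), c(0, 0, 0, v, 0.5))
})

test_that("variant restrictions nest inside the full model", {
  sub <- fixture_cohort()$subjects[[3]]
  full <- actionddm_params(0.3, 0, 0.8, 1.5, 1.1, 0.3)
  expect_equal(subject_loglik(sub, full),
               subject_loglik(sub, actionddm_params(0.3, 0.7, 0.8, 1.5, 1.1, 0.3),
                              variant = "no_value_drift"))
  # shared_B with B = 0 is the plain DDM
  shared0 <- apply_variant(actionddm_params(0.3, 0, 0.9, 1.5, 1.1, 0.3),
                           "shared_B")
  expect_equal(shared0[["b_z"]], 0)
  expect_equal(subject_loglik(sub, shared0),
               subject_loglik(sub, actionddm_params(0.3, 0, 0, 1.5, 1.1, 0.3)))
  # unweighted_drift is full with b_v = 1
  expect_equal(subject_loglik(sub, actionddm_params(0.3, 0.2, 0.8, 1.5, 1.1, 0.3),
                              variant = "unweighted_drift"),
               subject_loglik(sub, actionddm_params(0.3, 1, 0.8, 1.5, 1.1, 0.3)))
  expect_error(make_variant("nope"), "full, no_value_drift")
})

test_that("likelihood rejects non-chronological sessions", {
  sub <- fixture_cohort()$subjects[[1]]
  sub$trials <- sub$trials[c(2, 1, 3:nrow(sub$trials)), ]
  expect_error(subject_loglik(sub, actionddm_params(0.3, 0.5, 0.5, 1.5, 1, 0.3)),
               "chronological")
})

test_that("parameter constructors enforce domains", {
  expect_error(actionddm_params(1.2, 0, 0, 1, 1, 0.3), "alpha")
  expect_error(actionddm_params(0.3, 0, 0, 1, -1, 0.3), "positive")
  expect_error(actionddm_params(0.3, 0, 0, 1, 1, -0.1), "non-negative")
})
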