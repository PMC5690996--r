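test_that("imaging schedules match the protocol definitions", {
  expect_identical(imaging_schedule("enal", 30),
                   c(1L, 2L, 3L, 8L, 13L, 18L, 23L, 28L))
  expect_identical(imaging_schedule("enal", 28),
                   c(1L, 2L, 3L, 8L, 13L, 18L, 23L, 28L))
  expect_identical(imaging_schedule("enal_pp", 30),
                   imaging_schedule("enal", 30))
  expect_identical(imaging_schedule("nal", 30), 1:3)
  expect_identical(imaging_schedule("online", 30), 1:30)
  expect_identical(imaging_schedule("none", 30), integer(0))
  # short courses truncate the schedule, never extend past the course
  expect_identical(imaging_schedule("enal", 7), 1:3)
  expect_identical(imaging_schedule("nal", 2), 1:2)
  # non-default schedule parameters
  pol <- correction_policy("enal", nal_length = 4, followup_start = 10,
                           followup_interval = 7)
  expect_identical(imaging_schedule(pol, 30), c(1:4, 10L, 17L, 24L))
})

test_that("workload counts CBCTs and the reduction vs daily imaging", {
  w <- workload("enal_pp", 30)
  expect_identical(w$n_cbct, 8L)
  expect_equal(w$reduction_vs_online, 100 * 22 / 30)
  expect_gte(w$reduction_vs_online, 70)
  expect_equal(workload("online", 30)$reduction_vs_online, 0)
  expect_equal(workload("nal", 30)$reduction_vs_online, 90)
  # eNAL and eNAL++ always image the same fractions
  for (n in c(4, 10, 28, 30, 41))
    expect_identical(workload("enal", n), workload("enal_pp", n))
})

test_that("invalid policy parameters are rejected at construction", {
  expect_error(correction_policy("nal", nal_length = 0), "nal_length")
  expect_error(correction_policy("enal", followup_start = 3), "followup_start")
  expect_error(correction_policy("enal", followup_interval = 0),
               "followup_interval")
  expect_error(correction_policy("enal", couch_limit_deg = -1), "couch_limit")
  expect_error(correction_policy("sal"), "arg")
})

test_that("nal_correction is the negated mean of the initial measurements", {
  expect_equal(nal_correction(c(1, 2, 3)), -2)
  expect_equal(nal_correction(c(0, 0, 0)), 0)
  expect_equal(nal_correction(c(-1.7, 1.4, 0.3)), 0)
  m <- mat6(3, function(f) c(f, 0, 0, 0.5 * f, 0, -f))
  expect_equal(unname(nal_correction(m)), c(-2, 0, 0, -1, 0, 2))
  expect_error(nal_correction(c(1, 2), nal_length = 3), "too short")
})

test_that("enal_fit matches an independent least-squares oracle", {
  # exact line: interpolating fit recovers intercept and slope
  f <- c(1, 2, 3, 8)
  fit <- enal_fit(f, 0.5 + 0.1 * f)
  expect_equal(fit$S_k, 0.5)
  expect_equal(fit$a_k, 0.1)
  expect_identical(fit$f_k, 8)
  # degenerate single point: slope forced to zero
  fit1 <- enal_fit(1, 0.7)
  expect_equal(fit1$S_k, 0.7)
  expect_equal(fit1$a_k, 0)
  # random instances against lm() as the independent solver
  set.seed(202)
  for (i in 1:20) {
    n <- sample(2:10, 1)
    fr <- sort(sample(1:40, n))
    y <- rnorm(n)
    fit <- enal_fit(fr, y)
    ora <- unname(coef(lm(y ~ fr)))
    expect_equal(fit$S_k, ora[1], tolerance = 1e-10)
    expect_equal(fit$a_k, ora[2], tolerance = 1e-10)
  }
  # matrix input fits each axis independently
  y2 <- cbind(a = 1 + 0.2 * f, b = c(1, 0, 1, 0))
  fit2 <- enal_fit(f, y2)
  expect_equal(unname(fit2$S_k[1]), 1)
  ora2 <- unname(coef(lm(y2[, 2] ~ f)))
  expect_equal(unname(fit2$S_k[2]), ora2[1], tolerance = 1e-10)
  expect_equal(unname(fit2$a_k[2]), ora2[2], tolerance = 1e-10)
  expect_error(enal_fit(numeric(0), numeric(0)), "no measurements")
  expect_error(enal_fit(c(1, 1), c(0, 0)), "strictly increasing")
})

test_that("enal_correction evaluates the fit at the latest fraction", {
  fit <- structure(list(S_k = 0.5, a_k = 0.1, f_k = 8, n_points = 4),
                   class = "enal_fit")
  expect_equal(enal_correction(fit), -1.3)
  fit$a_k <- 0
  expect_equal(enal_correction(fit), -0.5) # reduces to running-mean NAL form
})

test_that("constant noiseless errors are corrected exactly", {
  vals <- c(1.2, -0.7, 0.4, 0.8, -0.5, 0.3)
  crs <- constant_course("P1", 30, vals)
  r_nal <- apply_policy(crs, "nal")
  expect_equal(r_nal$residuals[1:3, ], mat6(3, vals))   # uncorrected start
  expect_equal(max(abs(r_nal$residuals[4:30, ])), 0)
  r_enal <- apply_policy(crs, "enal")
  expect_equal(max(abs(r_enal$residuals[4:30, ])), 0)
  r_pp <- apply_policy(crs, "enal_pp")
  expect_equal(max(abs(r_pp$residuals)), 0)             # all fractions zero
  r_none <- apply_policy(crs, "none")
  expect_equal(r_none$residuals, crs$errors)
  expect_identical(r_none$n_cbct, 0L)
  r_online <- apply_policy(crs, "online")               # noise disabled
  expect_equal(max(abs(r_online$residuals)), 0)
  expect_identical(r_online$n_cbct, 30L)
})

test_that("a pure linear trend leaves the expected eNAL residuals", {
  a <- 0.05
  crs <- trend_course("P1", 30, 0, a)
  res <- apply_policy(crs, "enal")$residuals
  # fractions 1..3 are uncorrected
  expect_equal(res[1:3, "pitch"], a * (1:3))
  # fractions 4..8 carry the initial mean-based correction: mean(f=1..3) = 2
  expect_equal(res[4:8, "pitch"], a * ((4:8) - 2), tolerance = 1e-10)
  # after each follow-up f_k the exact fit gives residual a * (f - f_k)
  for (fk in c(8, 13, 18, 23)) {
    f_next <- (fk + 1):(fk + 5)
    expect_equal(res[f_next, "pitch"], a * (f_next - fk), tolerance = 1e-10)
  }
  # eNAL++ shares the off-line stream and zeroes the imaged fractions
  rpp <- apply_policy(crs, "enal_pp")
  sched <- imaging_schedule("enal_pp", 30)
  expect_equal(max(abs(rpp$residuals[sched, ])), 0)
  expect_equal(rpp$residuals[-sched, ], res[-sched, ], tolerance = 1e-12)
})

test_that("eNAL++ flags 8 online and 22 off-line fractions over 30", {
  crs <- constant_course("P1", 30, c(0, 0, 0, 1, 1, 1))
  r <- apply_policy(crs, "enal_pp")
  expect_identical(sum(r$online_corrected), 8L)
  expect_identical(sum(!r$online_corrected), 22L)
  expect_identical(r$n_cbct, 8L)
  expect_identical(which(r$imaged), which(r$online_corrected))
})

test_that("rotational corrections are clipped to the couch limit", {
  # systematic pitch of 5 degrees: the commanded correction would be -5
  crs <- constant_course("P1", 30, c(10, 0, 0, 5, -4, 2))
  for (pol in c("nal", "enal", "enal_pp")) {
    r <- apply_policy(crs, pol)
    rot <- r$corrections[, c("pitch", "roll", "yaw")]
    expect_lte(max(abs(rot)), 3)
    # translations are not clipped
    expect_equal(min(r$corrections[4:30, "tx"]), -10)
  }
  # residual reflects the saturated correction
  r <- apply_policy(crs, "nal")
  expect_equal(unname(r$residuals[10, "pitch"]), 2)   # 5 - 3
  expect_equal(unname(r$residuals[10, "roll"]), -1)   # -4 + 3
  # clipping can be disabled
  pol <- correction_policy("nal", clip_enabled = FALSE)
  expect_equal(unname(apply_policy(crs, pol)$residuals[10, "pitch"]), 0)
  # custom limit honoured
  pol2 <- correction_policy("nal", couch_limit_deg = 1)
  expect_equal(unname(apply_policy(crs, pol2)$residuals[10, "pitch"]), 4)
})

test_that("online-residual noise is seeded and bit-reproducible", {
  crs <- constant_course("P1", 30, c(0, 0, 0, 1, 1, 1))
  r1 <- apply_policy(crs, "online", online_sd = 0.2, seed = 42)
  r2 <- apply_policy(crs, "online", online_sd = 0.2, seed = 42)
  expect_identical(r1$residuals, r2$residuals)
  r3 <- apply_policy(crs, "online", online_sd = 0.2, seed = 43)
  expect_false(identical(r1$residuals, r3$residuals))
  # noise is zero-mean-ish and only on online fractions of eNAL++
  rpp <- apply_policy(crs, "enal_pp", online_sd = 0.2, seed = 42)
  expect_false(any(rpp$residuals[rpp$online_corrected, "pitch"] == 1))
  # per-axis named SDs are honoured; zero SD means exact zeros on that axis
  sd6 <- c(tx = 0, ty = 0, tz = 0, pitch = 0.2, roll = 0, yaw = 0)
  r4 <- apply_policy(crs, "online", online_sd = sd6, seed = 1)
  expect_equal(max(abs(r4$residuals[, c("tx", "ty", "tz", "roll", "yaw")])), 0)
  expect_gt(stats::sd(r4$residuals[, "pitch"]), 0)
  expect_error(apply_policy(crs, "online", online_sd = -0.1), "non-negative")
})

test_that("courses shorter than the initial block are rejected", {
  crs <- constant_course("P1", 2, c(0, 0, 0, 1, 0, 0))
  for (pol in c("nal", "enal", "enal_pp"))
    expect_error(apply_policy(crs, pol), "at least 3")
  expect_silent(apply_policy(crs, "none"))
})
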