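test_that("trial generation is seeded and its variability switches off", {
  cfg <- synthetic_gait_config(n_trials = 5, seed = 99)
  g1 <- generate_trials(cfg)
  g2 <- generate_trials(cfg)
  expect_identical(g1$curves$knee_angle$trials, g2$curves$knee_angle$trials)
  # zero variability: all trials identical
  g0 <- generate_trials(synthetic_gait_config(
    n_trials = 4, seed = 3, amplitude_sd = 0, timing_jitter_sd = 0,
    emg_noise_sd = 0))
  tr <- g0$curves$grf_v$trials
  expect_true(all(abs(sweep(tr, 2, tr[1, ])) < 1e-12))
})

test_that("curves are periodic and carry their generating truth", {
  g <- generate_trials(synthetic_gait_config(n_trials = 6, seed = 12))
  for (cs in g$curves)
    expect_true(all(abs(cs$trials[, 1] - cs$trials[, 101]) < 1e-12))
  expect_equal(dim(g$truth$amplitudes), c(6, 12))
  expect_length(g$truth$timing_deltas, 6)
  # smooth at the wrap point: the one-sided second difference is small
  k <- g$curves$knee_angle$trials[1, ]
  d1 <- k[2] - k[1]; d2 <- k[101] - k[100]
  expect_lt(abs(d1 - d2), 0.5)  # degrees per sample across the wrap
})

test_that("trial peak distribution is centered on the template peak", {
  knee_peak <- 65
  g <- generate_trials(synthetic_gait_config(
    n_trials = 200, seed = 42, amplitude_sd = 0.05, timing_jitter_sd = 0))
  peaks <- apply(g$curves$knee_angle$trials, 1, max)
  se <- sd(peaks) / sqrt(length(peaks))
  expect_lt(abs(mean(peaks) - knee_peak), 3 * se + 0.05)
})

test_that("mean difference outside an injected window is negligible", {
  nrep <- 40
  diffs <- matrix(0, nrep, 101)
  for (k in seq_len(nrep)) {
    A <- generate_trials(synthetic_gait_config(n_trials = 3, seed = k))
    B <- generate_trials(synthetic_gait_config(
      n_trials = 3, seed = 10000 + k,
      effect = list(variable = "knee_angle", window = c(30, 50),
                    offset = 10)))
    diffs[k, ] <- colMeans(B$curves$knee_angle$trials) -
      colMeans(A$curves$knee_angle$trials)
  }
  outside <- c(1:25, 60:101)
  md <- colMeans(diffs)[outside]
  se <- apply(diffs, 2, sd)[outside] / sqrt(nrep)
  expect_true(all(abs(md) <= 3 * se + 1e-9))
  inside <- 38:44
  expect_true(all(colMeans(diffs)[inside] > 5))
})

test_that("stiff-knee injection saturates smoothly and idempotently", {
  g <- generate_trials(synthetic_gait_config(n_trials = 4, seed = 1))
  ka <- g$curves$knee_angle
  sk <- inject_skg_effect(ka, 20)
  expect_lte(max(sk$trials), 21)  # 1 degree smoothing margin
  # a limit above the peak is a no-op
  expect_identical(inject_skg_effect(ka, 150), ka)
  # idempotent
  expect_identical(inject_skg_effect(sk, 20), sk)
  expect_error(inject_skg_effect(ka, -5), "limit_deg")
  # contralateral coupling: early-stance knee moment bump
  lst <- list(knee_angle = ka, knee_moment_cl = g$curves$knee_moment)
  out <- inject_skg_effect(lst, 20)
  expect_gt(mean(out$knee_moment_cl$trials[, 10:20]) -
              mean(g$curves$knee_moment$trials[, 10:20]), 0.05)
})

test_that("estimation datasets are exactly achievable with known truth", {
  am <- build_amputee_model(68.5, 1.78)
  ds <- generate_estimation_dataset(am, list(iliopsoas_il = 1.5), seed = 3)
  expect_equal(ds$truth$multipliers$iliopsoas_il, 1.5)
  expect_true(all(vapply(ds$truth$activation, function(a)
    all(a > 0 & a < 1), TRUE)))
  # round trip: recomputing the moment from the stored truth reproduces it
  mom <- 0
  for (nm in names(ds$truth$f_tilde)) {
    mus <- am$muscles[[nm]]
    geo <- muscle_geometry(am, nm, ds$q, ds$qdot)
    mult <- ds$truth$multipliers[[nm]]
    mom <- mom + geo$moment_arms[, "hip_il"] * ds$truth$f_tilde[[nm]] *
      mus$params$f_max_iso * mult
  }
  expect_lt(max(abs(mom - ds$moment)), 1e-9)
  # the moment contribution is linear in the strength multiplier
  expect_warning(
    ds2 <- generate_estimation_dataset(am, list(iliopsoas_il = 3), seed = 3),
    "bounds")
  c1 <- ds$truth$f_tilde$iliopsoas_il * 1.5
  c2 <- ds2$truth$f_tilde$iliopsoas_il * 3
  expect_equal(c2 / c1, rep(2, 101), tolerance = 1e-9)
})
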