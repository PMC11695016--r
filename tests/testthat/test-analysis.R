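make_sets <- function(n = 5, seed = 1, offset = 0, window = NULL) {
  gen <- generate_trials(synthetic_gait_config(
    n_trials = n, seed = seed,
    effect = if (is.null(window)) NULL else
      list(variable = "knee_angle", window = window, offset = offset)))
  gen$curves$knee_angle
}

test_that("SPM paired test is null on identical sets and errors on mismatch", {
  A <- make_sets(5, seed = 11)
  r <- spm_paired_nonparametric(A, A)
  expect_true(all(r$t_curve == 0))
  expect_equal(nrow(r$clusters), 0)
  expect_false(r$reject)
  B <- make_sets(4, seed = 2)
  expect_error(spm_paired_nonparametric(A, B), "equal trial counts")
  # 2^n * alpha < 1: the permutation test cannot reject
  expect_warning(
    spm_paired_nonparametric(make_sets(3, 1), make_sets(3, 2), alpha = 0.05),
    "cannot reject")
})

test_that("SPM matches the exhaustive sign-flip oracle at n = 3", {
  set.seed(5)
  A <- matrix(rnorm(3 * 101), 3, 101)
  B <- matrix(rnorm(3 * 101), 3, 101)
  orc <- oracle_spm_exhaustive(A, B, alpha = 0.25)
  r <- suppressWarnings(
    spm_paired_nonparametric(gait_curve_set(A), gait_curve_set(B),
                             alpha = 0.25))
  expect_equal(r$t_crit, orc$t_crit, tolerance = 1e-12)
  expect_equal(r$t_curve, orc$t_obs, tolerance = 1e-12)
  expect_equal(r$n_perm, 8)
})

test_that("SPM thresholds are invariant under relabeling and detect effects", {
  A <- make_sets(7, seed = 3)
  B <- make_sets(7, seed = 4)
  r1 <- spm_paired_nonparametric(A, B)
  r2 <- spm_paired_nonparametric(B, A)
  expect_equal(r1$t_crit, r2$t_crit, tolerance = 1e-12)
  expect_equal(r1$t_curve, -r2$t_curve, tolerance = 1e-12)
  # power: a strong offset over 40-60% of the cycle is detected there
  Beff <- make_sets(7, seed = 4, offset = 15, window = c(40, 60))
  r3 <- spm_paired_nonparametric(A, Beff)
  expect_true(r3$reject)
  expect_true(any(r3$clusters[, "start"] <= 60 & r3$clusters[, "end"] >= 40))
})

test_that("power: a 3-sigma offset over 20% of the cycle is detected reliably", {
  hits <- 0
  reps <- 30
  for (k in seq_len(reps)) {
    A <- make_sets(7, seed = 100 + k)
    # pointwise between-trial SD of the knee curve is ~5% of amplitude;
    # inject three times that over 20% of the cycle
    sd_pt <- mean(apply(A$trials, 2, sd))
    B <- make_sets(7, seed = 500 + k, offset = 3 * sd_pt, window = c(40, 60))
    r <- spm_paired_nonparametric(A, B)
    ok <- r$reject &&
      any(r$clusters[, "start"] <= 60 & r$clusters[, "end"] >= 40)
    hits <- hits + ok
  }
  expect_gte(hits / reps, 0.9)
})

test_that("DTW score is a banded alignment distance", {
  x <- gait_templates(seq(0, 1, length.out = 101))$knee_angle
  expect_identical(dtw_score(x, x)$score, 0)
  y <- x + 3 * sin(seq(0, 2 * pi, length.out = 101))
  expect_equal(dtw_score(x, y)$score, dtw_score(y, x)$score)
  # nonincreasing in the band width
  s <- vapply(c(0.02, 0.05, 0.2, 1), function(w) dtw_score(x, y, w)$score, 0)
  expect_true(all(diff(s) <= 1e-12))
  # a monotone re-timing within the band is fully absorbed: equal to the
  # unbanded oracle, which recovers zero cost
  y2 <- x
  y2[30:40] <- x[c(30, 30:39)]  # duplicate one sample, shift by one
  expect_equal(dtw_score(x, y2, 0.05)$score, oracle_dtw_unbanded(x, y2))
  expect_error(dtw_score(x, y[-1]), "equal lengths")
})

test_that("DTW normalization maps the comparison set into [-1, 1]", {
  cur <- list(a = c(-80, 40, 10), b = c(20, -5, 60))
  nrm <- normalize_curves_for_dtw(cur)
  expect_equal(nrm$a[2], 0.5)
  expect_true(all(abs(unlist(nrm)) <= 1))
  # idempotent once the shared constant is 1
  nrm2 <- normalize_curves_for_dtw(nrm)
  expect_equal(unlist(nrm2), unlist(nrm))
  expect_warning(normalize_curves_for_dtw(list(a = c(0, 0))), "all-zero")
})

test_that("DTW matrices propagate NaN for missing muscles and group by max", {
  s <- seq(0, 1, length.out = 101)
  act <- list(vasti = cyc_gauss(s, 0.1, 0.05), soleus = cyc_gauss(s, 0.4, 0.1))
  m <- dtw_matrix(act, act)
  expect_true(all(m$score == 0))
  act_il <- act; act_il$vasti <- NULL  # absent on the prosthetic side
  m2 <- dtw_matrix(act_il, act)
  expect_true(is.nan(m2$score[m2$muscle == "vasti"]))
  expect_false(is.nan(m2$score[m2$muscle == "soleus"]))
  # grouped curve is the pointwise max and dominates each component
  bf <- group_curves_max(0.8 * cyc_gauss(s, 0.9, 0.05),
                         0.5 * cyc_gauss(s, 0.2, 0.1))
  expect_true(all(bf >= 0.8 * cyc_gauss(s, 0.9, 0.05) - 1e-15))
  expect_true(all(bf >= 0.5 * cyc_gauss(s, 0.2, 0.1) - 1e-15))
  expect_error(dtw_matrix(list(), list()), "empty")
})

test_that("gait cycles are segmented at GRF threshold crossings", {
  # synthetic vertical GRF with a crossing constructed at t = 0.237 s
  t <- seq(0, 3.3, by = 0.001)
  cyc <- 1.1
  grf <- 700 * pmax(sin(2 * pi * (t - 0.2) / cyc), 0)^2
  grf[grf < 1e-6] <- 0
  sig <- list(knee = 30 + 20 * sin(2 * pi * t / cyc), grf_v = grf)
  out <- normalize_gait_cycle(t, sig, grf = "grf_v", threshold = 20)
  ev <- attr(out, "events")
  # the first upward crossing of 20 N: sin^2 term reaches 20/700 at
  # t = 0.2 + asin(sqrt(20/700)) * cyc / (2 pi)
  t_cross <- 0.2 + asin(sqrt(20 / 700)) * cyc / (2 * pi)
  expect_lt(abs(ev[1] - t_cross), 0.002)
  expect_equal(ncol(out$knee$trials), 101)
  expect_equal(diff(ev)[1], cyc, tolerance = 0.01)
  # a constant channel stays constant after resampling
  sig$const <- rep(5, length(t))
  out2 <- normalize_gait_cycle(t, sig, grf = "grf_v")
  expect_true(all(abs(out2$const$trials - 5) < 1e-9))
  expect_error(normalize_gait_cycle(t, sig, grf = rep(0, length(t))),
               "vertical GRF")
})

test_that("peak metrics refine the discrete maximum", {
  # triangular bump peaking exactly at 70%
  tri <- pmax(0, 1 - abs(0:100 - 70) / 10)
  pm <- peak_metrics(tri, c(50, 100))
  expect_equal(pm$peak, 1)
  expect_equal(pm$timing_pct, 70)
  # constant curve: documented tie-break toward the window start
  pm2 <- peak_metrics(rep(3, 101), c(20, 80))
  expect_equal(pm2$peak, 3)
  expect_equal(pm2$timing_pct, 20)
  # smooth curve: refined peak within 0.5% of a dense-grid argmax oracle
  f <- function(x) sin(2 * pi * x / 100) + 0.3 * cos(6 * pi * x / 100)
  dense <- seq(0, 100, by = 0.001)
  truth <- dense[which.max(f(dense))]
  pm3 <- peak_metrics(f(0:100), c(0, 100))
  expect_lt(abs(pm3$timing_pct - truth), 0.5)
  expect_error(peak_metrics(f(0:100), c(80, 20)), "window")
})
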