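# Simulator contracts: determinism, substream structure, censoring
# bookkeeping, and agreement with the analytic first-passage law.

test_that("identical seed and configuration give bit-identical samples", {
  p <- phys_cleft()
  w <- wall_params()
  cfg <- quick_cfg(n = 500)
  s1 <- simulate_fpt(p, w, cfg)
  s2 <- simulate_fpt(p, w, cfg)
  expect_identical(s1$times, s2$times)
  expect_identical(s1$n_censored, s2$n_censored)
  expect_false(identical(simulate_fpt(p, w, quick_cfg(n = 500, seed = 43))$times,
                         s1$times))
})

test_that("per-run substreams make results independent of batch size", {
  p <- phys_cleft()
  w <- wall_params()
  small <- simulate_fpt(p, w, quick_cfg(n = 100))
  big <- simulate_fpt(p, w, quick_cfg(n = 400))
  expect_identical(small$times, big$times[1:100])
})

test_that("sample bookkeeping: times within (0, t_max], counts add up", {
  p <- phys_cleft()
  w <- wall_params()
  cfg <- quick_cfg(n = 1000)
  s <- simulate_fpt(p, w, cfg)
  expect_identical(length(s$times) + s$n_censored, cfg$n_runs)
  expect_true(all(s$times >= cfg$dt & s$times <= cfg$t_max))
  # step-end times lie on the dt grid when interpolation is off
  expect_equal(s$times / cfg$dt, round(s$times / cfg$dt), tolerance = 1e-9)
  expect_error(simulate_fpt(p, w, sim_config(x_start = 3e-8)), "x_start")
})

test_that("censoring at t_max is counted, excluded, and warned about", {
  # slow cleft + short horizon forces censoring
  p <- cleft_params(D = to_si(0.03, "um2/ms"))
  w <- wall_params(variant = "off")
  cfg <- sim_config(dt = 1e-8, n_runs = 300L, t_max = 5e-6, seed = 42)
  expect_warning(s <- simulate_fpt(p, w, cfg), "censored")
  expect_gt(s$n_censored, 0)
  expect_identical(length(s$times) + s$n_censored, 300L)
  expect_true(all(s$times <= cfg$t_max))
})

test_that("interpolated crossing times are earlier than step-end times", {
  p <- phys_cleft()
  w <- wall_params()
  s_end <- simulate_fpt(p, w, quick_cfg(n = 300))
  s_int <- simulate_fpt(p, w, quick_cfg(n = 300, interpolate_crossing = TRUE))
  expect_identical(length(s_int$times), length(s_end$times))
  expect_true(all(s_int$times <= s_end$times))
  expect_true(all(s_int$times > s_end$times - 1.0000001 * to_si(10, "ns")))
})

test_that("wall-free empirical mean matches the quadrature mean of the analytic law", {
  p <- phys_cleft()
  woff <- wall_params(variant = "off")
  cfg <- quick_cfg(n = 5000, dt_ns = 1, interpolate_crossing = TRUE)
  s <- simulate_fpt(p, woff, cfg)
  m_quad <- integrate(function(t) t * fpt_density(t, analytic_fpt_from_params(p)),
                      0, 0.05, rel.tol = 1e-10)$value
  se <- sd(s$times) / sqrt(length(s$times))
  # 4 MC standard errors plus a 4% allowance for the sqrt(dt) crossing bias
  expect_lt(abs(mean(s$times) - m_quad), 4 * se + 0.04 * m_quad)
})

test_that("faster diffusion shortens the passage (stochastic monotonicity in D)", {
  woff <- wall_params(variant = "off")
  cfg <- quick_cfg(n = 2000)
  slow <- simulate_fpt(phys_cleft(), woff, cfg)
  fast <- simulate_fpt(cleft_params(D = 100 * 3.3e-10), woff, cfg)
  expect_lt(mean(fast$times), mean(slow$times))
})

test_that("rescaling D by 1/k and dt by k reproduces trajectories exactly", {
  # with T, d, V fixed the process at D/k is the D-process with time
  # dilated by k; with dt scaled alongside, the discrete update is
  # identical term by term, so passage times must scale bit-exactly.
  w <- wall_params()
  p1 <- phys_cleft()
  p2 <- cleft_params(D = p1$D / 4)
  s1 <- simulate_fpt(p1, w, quick_cfg(n = 500, dt_ns = 10))
  s2 <- simulate_fpt(p2, w, quick_cfg(n = 500, dt_ns = 40))
  expect_identical(s2$times, 4 * s1$times)
})

test_that("paired simulation: shared-noise hook, exchangeability, and sign of asymmetry", {
  p <- phys_cleft()
  w <- wall_params()
  cfg <- quick_cfg(n = 1000)
  # identical clefts driven by identical noise arrive simultaneously
  pr0 <- simulate_paired(p, p, w, w, cfg, .shared_noise = TRUE)
  expect_identical(unique(pr0$delta_times), 0)
  # independent noise: symmetric null, mean compatible with zero
  pr <- simulate_paired(p, p, w, w, cfg)
  expect_identical(length(pr$delta_times) + pr$n_pairs_censored, cfg$n_runs)
  expect_lt(abs(pr$summary$mean), 3 * pr$summary$se_mean +
              .Machine$double.eps)
  # slower cleft 1 (smaller D) implies mean(t1 - t2) > 0, and vice versa
  p_slow <- cleft_params(D = to_si(0.033, "um2/ms"))
  pr_sl <- simulate_paired(p_slow, p, w, w, cfg)
  expect_gt(pr_sl$summary$mean, 0)
  pr_fa <- simulate_paired(p, p_slow, w, w, cfg)
  expect_lt(pr_fa$summary$mean, 0)
  # exchangeability: swapping the clefts mirrors the difference distribution
  ks <- suppressWarnings(
    stats::ks.test(pr_sl$delta_times, -pr_fa$delta_times))
  expect_gt(ks$p.value, 1e-4)
})

test_that("the anti-return wall confines the walk to the cleft side", {
  p <- phys_cleft()
  cfg <- quick_cfg(n = 2000, dt_ns = 1)
  occ_wall <- simulate_fpt(p, wall_params(), cfg)$below_frac
  occ_free <- simulate_fpt(p, wall_params(variant = "off"), cfg)$below_frac
  # the wall suppresses time spent behind the membrane by orders of
  # magnitude relative to the free walk
  expect_gt(occ_free, 0.1)
  expect_lt(occ_wall / occ_free, 0.02)
  expect_lt(occ_wall, 5e-3)
})

test_that("coupled dt-refinement estimator converges once the wall is resolved", {
  p <- phys_cleft()
  w <- wall_params()
  r <- dt_convergence(p, w, quick_cfg(n = 20000, dt_ns = 5))
  expect_lt(r$rel_change, 0.02)
  expect_identical(r$n_used, 20000L)
  # the estimator itself is deterministic under the seed
  r2 <- dt_convergence(p, w, quick_cfg(n = 20000, dt_ns = 5))
  expect_identical(r$mean_coarse, r2$mean_coarse)
})
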