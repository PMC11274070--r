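test_that("summary statistics: symmetric toy sample, degenerate inputs", {
  s <- summarize_delta(c(-1, 0, 1) * 1e-6)
  expect_identical(s$mean, 0)
  expect_identical(s$skewness, 0)
  expect_equal(s$sd, 1e-6, tolerance = 1e-12)
  expect_error(summarize_delta(c(1, 2)), "at least 3")
  expect_error(summarize_delta(rep(1e-6, 10)), "zero variance")
  expect_error(summarize_delta(c(1, 2, NaN)), "finite")
})

test_that("skewness of a symmetric heavy-tailed null stays within its moment-based band", {
  # difference of i.i.d. inverse-Gaussian draws: symmetric but heavy-tailed;
  # the asymptotic SE must cover the observed g1 where sqrt(6/n) would not
  a <- analytic_fpt_from_params(cleft_params())
  t1 <- sample_analytic_fpt(a, 20000, seed = 42)$times
  t2 <- sample_analytic_fpt(a, 20000, seed = 4242)$times
  s <- summarize_delta(t1 - t2)
  expect_lt(abs(s$skewness), 3 * s$se_skewness)
  expect_gt(s$se_skewness, sqrt(6 / 20000))
})

test_that("histograms bin deterministically and conserve counts", {
  h <- build_histogram(c(-1e-6, 1e-6), n_bins = 2, range = c(-2e-6, 2e-6))
  expect_identical(h$counts, c(1L, 1L))
  expect_identical(h$n_out_of_range, 0L)

  set.seed(42)
  x <- rnorm(5000, sd = 1e-6)
  h2 <- build_histogram(x, n_bins = 101)
  expect_identical(sum(h2$counts), 5000L)           # default range covers all
  expect_identical(sum(h2$counts) + h2$n_out_of_range, h2$n_total)
  expect_true(all(diff(h2$bin_edges) > 0))
  # central bin of an odd binning straddles zero
  ctr <- (length(h2$counts) + 1) / 2
  expect_lt(h2$bin_edges[ctr], 0)
  expect_gt(h2$bin_edges[ctr + 1], 0)
  # explicit range: out-of-range values are counted, not dropped
  h3 <- build_histogram(x, n_bins = 10, range = c(-1e-6, 1e-6))
  expect_identical(sum(h3$counts) + h3$n_out_of_range, 5000L)
  expect_gt(h3$n_out_of_range, 0L)
  # fixed bin width tiles symmetrically about zero
  h4 <- build_histogram(x, bin_width = 5e-7)
  expect_identical(sum(h4$counts), 5000L)
  expect_equal(h4$bin_edges, -rev(h4$bin_edges), tolerance = 1e-12)

  expect_error(build_histogram(numeric(0)), "non-empty")
  expect_error(build_histogram(x, bin_width = -1), "positive")
})

test_that("KS statistic: exact-quantile construction and censoring guard", {
  a <- analytic_fpt_from_params(cleft_params())
  n <- 200L
  # sample placed at the exact CDF quantiles (i - 1/2)/n gives KS = 1/(2n)
  qs <- vapply((seq_len(n) - 0.5) / n, function(pr) {
    uniroot(function(t) fpt_cdf(t, a) - pr, c(1e-10, 1), tol = 1e-16)$root
  }, numeric(1))
  s <- list(times = qs, n_censored = 0L, n_runs = n)
  class(s) <- "fpt_sample"
  expect_equal(ks_validation(s, a)$statistic, 1 / (2 * n), tolerance = 1e-6)

  s_cens <- list(times = qs, n_censored = 3L, n_runs = n + 3L)
  class(s_cens) <- "fpt_sample"
  expect_error(ks_validation(s_cens, a), "t_max")
})

test_that("symmetric diffusion sweep has the documented columns and exact analytic scaling", {
  base <- phys_cleft()
  w <- wall_params()
  cfg <- quick_cfg(n = 2000)
  Ds <- to_si(c(0.132, 0.33, 1.32), "um2/ms")
  sw <- suppressWarnings(suppressMessages(
    sweep_symmetric_D(base, w, cfg, D_values = Ds)))
  expect_identical(names(sw),
                   c("D1", "D2", "V1", "V2", "delta_std_sim",
                     "delta_mean_sim", "delta_skewness",
                     "delta_std_analytic", "delta_std_full", "n_outlier",
                     "n_censored"))
  expect_identical(sw$D1, sw$D2)
  expect_true(all(sw$delta_std_sim >= 0))
  # analytic column reproduces delta ~ 1/D exactly
  expect_equal(sw$delta_std_analytic * sw$D1 /
                 (sw$delta_std_analytic[1] * sw$D1[1]),
               rep(1, 3), tolerance = 1e-12)
  # simulated width shrinks with D and sits below the wall-free benchmark
  expect_true(all(diff(sw$delta_std_sim[order(sw$D1)]) < 0))
  expect_true(all(sw$delta_std_sim < sw$delta_std_analytic))
  # bit-identical rerun
  sw2 <- suppressWarnings(suppressMessages(
    sweep_symmetric_D(base, w, cfg, D_values = Ds)))
  expect_identical(sw, sw2)
})

test_that("asymmetric sweep keeps cleft 2 fixed and its benchmark generalizes", {
  base <- phys_cleft()
  w <- wall_params()
  cfg <- quick_cfg(n = 2000)
  sw <- suppressWarnings(suppressMessages(sweep_asymmetric_D(
    base, w, cfg, D1_values = to_si(c(0.132, 0.33), "um2/ms"))))
  expect_identical(unique(sw$D2), to_si(0.33, "um2/ms"))
  # for the symmetric row the pair benchmark reduces to the closed form
  i_sym <- which(sw$D1 == sw$D2)
  expect_equal(sw$delta_std_analytic[i_sym], delta_std(base),
               tolerance = 1e-12)
  # independent-member benchmark: sqrt(Var1 + Var2)
  i <- which(sw$D1 != sw$D2)
  p1 <- cleft_params(D = sw$D1[i])
  expect_equal(sw$delta_std_analytic[i],
               sqrt(2 * p1$D * p1$d / p1$v_drift^3 +
                    2 * base$D * base$d / base$v_drift^3),
               tolerance = 1e-12)
})

test_that("voltage sweep row at V1 = V2 reproduces the baseline paired run", {
  base <- phys_cleft()
  w <- wall_params()
  cfg <- quick_cfg(n = 2000)
  sw <- suppressWarnings(suppressMessages(
    sweep_voltage(base, w, cfg, V1_values = to_si(-4, "mV"))))
  pr <- simulate_paired(base, base, w, w, cfg)
  expect_identical(sw$delta_std_full, pr$summary$sd)
  core <- summarize_core(pr$delta_times)
  expect_identical(sw$delta_std_sim, core$sd)
  expect_identical(sw$delta_mean_sim, core$mean)
  expect_error(sweep_voltage(base, w, cfg, V1_values = 1e-3))
})

test_that("run_experiment builds the default +/- 5 delta histogram around zero", {
  base <- phys_cleft()
  cfg <- quick_cfg(n = 2000)
  ex <- run_experiment(base, base, wall_params(), cfg = cfg)
  expect_s3_class(ex$histogram, "fpt_histogram")
  expect_identical(length(ex$histogram$counts), 101L)
  expect_equal(max(ex$histogram$bin_edges), 5 * delta_std(base),
               tolerance = 1e-12)
  expect_equal(ex$delta_std_analytic, delta_std(base), tolerance = 1e-12)
})

test_that("CSV and JSON round-trips preserve the paired sample", {
  base <- phys_cleft()
  w <- wall_params()
  cfg <- quick_cfg(n = 50)
  pr <- simulate_paired(base, base, w, w, cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_paired_csv(pr, csv)
  df <- read.csv(csv)
  expect_identical(nrow(df), 50L)
  expect_identical(names(df), c("run_id", "t1_s", "t2_s", "delta_s",
                                "censored"))
  ok <- !df$censored
  expect_equal(df$delta_s[ok], pr$t1[ok] - pr$t2[ok], tolerance = 1e-12)

  js <- withr::local_tempfile(fileext = ".json")
  write_run_sidecar(pr, base, base, w, w, cfg, js)
  side <- jsonlite::read_json(js)
  expect_equal(side$cleft1$D, base$D)
  expect_equal(side$sim$seed, cfg$seed)
  expect_equal(side$summary$sd, pr$summary$sd, tolerance = 1e-12)

  curves <- analytic_curves(analytic_fpt_from_params(base), n = 50)
  expect_true(all(diff(curves$cdf) >= 0))
  expect_true(all(curves$density_per_s >= 0))
})
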