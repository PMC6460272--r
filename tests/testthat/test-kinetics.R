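test_that("OD to transmittance follows Beer-Lambert and validates input", {
  expect_identical(od_to_transmittance(0), 1)
  expect_equal(od_to_transmittance(1.2), 0.0631, tolerance = 0.0005 / 0.0631)
  expect_equal(od_to_transmittance(2), 0.01)
  expect_error(od_to_transmittance(-0.1), class = "uvkin_validation_error")
  expect_error(od_to_transmittance("a"), class = "uvkin_validation_error")
})

test_that("irradiance config reconciles OD and explicit transmittance", {
  cfg <- irradiance_config()
  expect_equal(cfg$transmittance, 10^-1.2)
  # consistent pair accepted, explicit transmittance wins
  cfg2 <- irradiance_config(od600 = 1.2, transmittance = 10^-1.2)
  expect_identical(cfg2$transmittance, 10^-1.2)
  expect_error(irradiance_config(od600 = 1.2, transmittance = 0.5),
               class = "uvkin_validation_error")
  expect_error(irradiance_config(intensity_wm2 = 0),
               class = "uvkin_validation_error")
  expect_error(irradiance_config(od600 = NULL, transmittance = NULL),
               class = "uvkin_validation_error")
})

test_that("total fluence is the product T*b*H0*t, linear in t", {
  cfg <- irradiance_config(transmittance = 0.063, od600 = NULL,
                           bandwidth_nm = 10, intensity_wm2 = 70)
  expect_identical(total_fluence(cfg, 0), 0)
  expect_equal(total_fluence(cfg, 1), 44.1)
  unit <- irradiance_config(transmittance = 1, od600 = NULL,
                            bandwidth_nm = 1, intensity_wm2 = 1)
  expect_equal(total_fluence(unit, 5), 5)
  expect_error(total_fluence(cfg, -1), class = "uvkin_validation_error")
  # additivity over randomized time pairs
  set.seed(1)
  for (i in 1:25) {
    ab <- runif(2, 0, 120)
    expect_equal(total_fluence(cfg, sum(ab)),
                 sum(total_fluence(cfg, ab)), tolerance = 1e-12)
  }
})

test_that("predicted survival decays exponentially from n0", {
  expect_equal(predict_survival(2e7, 0.035, 0), 2e7)
  expect_equal(predict_survival(2e7, 0.035, log(2) / 0.035), 1e7,
               tolerance = 1 / 1e7)  # one half-life, 19.804 min
  expect_equal(predict_survival(1, 1, 1), exp(-1))
  # strictly decreasing in t and in k; k -> 0+ limit is n0
  t <- seq(0, 60, by = 5)
  expect_true(all(diff(predict_survival(100, 0.05, t)) < 0))
  ks <- c(0.01, 0.05, 0.2, 1)
  at30 <- vapply(ks, function(k) predict_survival(100, k, 30), numeric(1))
  expect_true(all(diff(at30) < 0))
  expect_equal(predict_survival(100, 1e-12, 30), 100, tolerance = 1e-9)
  expect_error(predict_survival(2e7, 0.035, 1, mode = "fluence"),
               class = "uvkin_validation_error")  # config required
})

test_that("half-life satisfies half_life(k) * k = ln 2 across scales", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(round(half_life(0.035), 2), 19.80)
  expect_equal(round(half_life(0.035) / 60, 2), 0.33)
  expect_equal(half_life(2 * log(2)), 0.5)
  for (k in 10^seq(-3, 3))
    expect_equal(half_life(k) * k, log(2), tolerance = 1e-12)
  expect_error(half_life(0), class = "uvkin_validation_error")
  expect_error(half_life(-1), class = "uvkin_validation_error")
})

test_that("noiseless model-generated series are recovered exactly", {
  # integer-count fixture: halving every 15 min
  s <- halving_series()
  fit <- fit_survival(s)
  expect_equal(fit$k, log(2) / 15, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$half_life_min, 15, tolerance = 1e-9)
  expect_identical(fit$n_points_used, 5L)
  expect_false(fit$non_decaying)

  # property sweep: k over three orders, random grids scaled to 1/k so that
  # a large n0 keeps integer rounding negligible
  set.seed(7)
  for (k in c(0.001, 0.01, 0.035, 0.3, 1)) {
    tau <- 1 / k
    times <- sort(sample(1:8, sample(3:6, 1))) * tau / 2
    times <- c(0, times)
    n0 <- 1e12
    counts <- round(n0 * exp(-k * times))
    fit <- fit_survival(survival_series(times, counts, n0 = n0,
                                        max_count = Inf))
    expect_equal(fit$k, k, tolerance = 1e-10)
    expect_equal(fit$r2, 1, tolerance = 1e-8)
  }
})

test_that("flat and zero-count series follow the documented contracts", {
  flat <- survival_series(c(0, 15, 30), rep(500, 3))
  fit <- fit_survival(flat)
  expect_equal(fit$slope, 0)
  expect_true(fit$non_decaying)
  expect_true(is.na(fit$k))
  expect_equal(fit$r2, 1)  # flat series reproduced exactly

  withzero <- survival_series(c(0, 15, 30, 45, 60), c(200, 100, 50, 0, 0),
                              n0 = 200)
  fit <- fit_survival(withzero)
  expect_identical(fit$excluded_zero_times, c(45, 60))
  expect_identical(fit$n_points_used, 3L)
  expect_equal(fit$k, log(2) / 15, tolerance = 1e-9)

  toofew <- survival_series(c(0, 15, 30), c(200, 0, 0), n0 = 200)
  expect_error(fit_survival(toofew), class = "uvkin_numeric_error")
})

test_that("time and fluence modes express the same decay", {
  cfg <- default_cfg()
  ff <- cfg$transmittance * cfg$bandwidth_nm * cfg$intensity_wm2
  set.seed(11)
  for (i in 1:10) {
    k <- runif(1, 0.01, 0.1)
    times <- c(0, 15, 30, 45, 60)
    counts <- rpois(5, 300 * exp(-k * times))
    counts[1] <- max(counts[1], 1)
    s <- survival_series(times, counts, n0 = 300)
    ft <- fit_survival(s, mode = "time")
    fh <- fit_survival(s, config = cfg, mode = "fluence")
    if (!ft$non_decaying) {
      expect_equal(ft$k, fh$k * ff, tolerance = 1e-9)
      expect_equal(ft$r2, fh$r2, tolerance = 1e-12)
      expect_equal(ft$half_life_min, fh$half_life_min, tolerance = 1e-9)
    }
  }
})

test_that("Poisson-noised series yield k inside the Monte-Carlo envelope", {
  k <- 0.035; n0 <- 2e7; dil <- 1e-5
  env <- oracle_k_envelope(k, n0, dil, c(0, 15, 30, 45, 60))
  sims <- simulate_survival_series(
    sim_spec(k_true = k, n0_range = c(n0, n0), dilution = dil,
             replicates = 1, seed = 123))
  fit <- fit_survival(sims[[1]])
  expect_gt(fit$k, env[1])
  expect_lt(fit$k, env[2])
})

test_that("time to threshold inverts the decay law", {
  expect_equal(time_to_threshold(1, exp(1), 1), 1)
  expect_equal(round(time_to_threshold(0.035, 2e7, 1e7), 2), 19.80)
  expect_equal(time_to_threshold(0.035, 2e7, 2), log(1e7) / 0.035,
               tolerance = 1e-12)
  expect_error(time_to_threshold(0.035, 100, 100),
               class = "uvkin_validation_error")
  expect_error(time_to_threshold(0.035, 100, 0),
               class = "uvkin_validation_error")
  # randomized round trip, both modes
  cfg <- default_cfg()
  set.seed(5)
  for (i in 1:20) {
    k <- runif(1, 0.001, 0.5); n0 <- runif(1, 1e3, 1e8)
    nt <- n0 * runif(1, 1e-6, 0.99)
    tt <- time_to_threshold(k, n0, nt)
    expect_equal(predict_survival(n0, k, tt), nt, tolerance = 1e-9)
    tf <- time_to_threshold(k, n0, nt, mode = "fluence", config = cfg)
    expect_equal(predict_survival(n0, k, tf, mode = "fluence", config = cfg),
                 nt, tolerance = 1e-9)
  }
})
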