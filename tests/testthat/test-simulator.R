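test_that("a single forced nucleus reproduces the analytic single-domain curve", {
  cfg <- sim_config(rate_params(kn = 0, kg_fast = 1e-3, r = 1), dt = 0.5,
                    t_max = 1200)
  fs <- forced_scenario(cfg, tibble::tibble(t = 0, x = 0.5, fast_side = "left"))
  an <- coverage_slow_realization(1e-3, 1, 0.5, fs$trajectory$t_s)$phi
  expect_equal(fs$trajectory$phi, an, tolerance = 1e-12)
  # asymmetric case against the same closed form
  cfg2 <- sim_config(rate_params(kn = 0, kg_fast = 1e-3, r = 0.25), dt = 0.5,
                     t_max = 4000)
  fs2 <- forced_scenario(cfg2, tibble::tibble(t = 0, x = 0.3, fast_side = "left"))
  an2 <- coverage_slow_realization(1e-3, 0.25, 0.3, fs2$trajectory$t_s)$phi
  expect_equal(fs2$trajectory$phi, an2, tolerance = 1e-12)
})

test_that("one-sided growth (r = 0) plateaus below saturation", {
  cfg <- sim_config(rate_params(kn = 0, kg_fast = 1e-3, r = 0), dt = 0.5,
                    t_max = 5000)
  fs <- forced_scenario(cfg, tibble::tibble(t = 0, x = 0.5, fast_side = "left"))
  expect_equal(max(fs$trajectory$phi), 0.5, tolerance = 1e-9)
})

test_that("merging domains are logged as exactly one domain-domain collision", {
  cfg <- sim_config(rate_params(kn = 0, kg_fast = 1e-3, r = 1), dt = 0.5,
                    t_max = 2000)
  fs <- forced_scenario(cfg, tibble::tibble(t = c(0, 0), x = c(0.3, 0.6),
                                            fast_side = c("left", "right")))
  dd <- fs$collisions[fs$collisions$type == 0, ]
  expect_equal(nrow(dd), 1L)
  # collision time by interpolation: the 0.3 gap closes at 2e-3 per second
  expect_equal(dd$t, 0.3 / 2e-3, tolerance = 0.5)
  ends <- fs$collisions[fs$collisions$type != 0, ]
  expect_equal(sort(ends$type), c(1L, 2L))
  expect_error(
    forced_scenario(cfg, tibble::tibble(t = c(0, 10), x = c(0.5, 0.505),
                                        fast_side = c("left", "left"))),
    "covered")
})

test_that("nucleation-only limit accumulates domains at the expected rate", {
  set.seed(5)
  cfg <- sim_config(rate_params(kn = 0.05, kg_fast = 0, r = 1), dt = 0.5,
                    t_max = 2000)
  counts <- replicate(40, nrow(simulate_once(cfg)$nucleations))
  # point nuclei never cover anything, so nucleation stays at full rate:
  # count ~ Poisson(kn * t_max)
  lam <- 0.05 * 2000
  expect_lt(abs(mean(counts) - lam) / lam, 0.1)
  expect_true(all(simulate_once(cfg)$trajectory$phi == 0))
})

test_that("replaying a stochastic run's event log reproduces it bitwise", {
  set.seed(17)
  cfg <- sim_config(rate_params(kn = 1e-3, kg_fast = 5e-4, r = 0.1), dt = 0.5,
                    t_max = 8000)
  once <- simulate_once(cfg)
  expect_gt(nrow(once$nucleations), 0)
  replay <- forced_scenario(cfg, once$nucleations)
  expect_identical(replay$trajectory$phi, once$trajectory$phi)
})

test_that("ensemble summary is reproducible, monotone, bounded, and exact for M = 2 clones", {
  rp <- rate_params(kn = 1e-3, kg_fast = 5e-4, r = 0.5)
  cfg <- sim_config(rp, dt = 0.5, t_max = 4000, M = 50,
                    time_origin = "first_nucleation")
  set.seed(3); a <- simulate_ensemble(cfg)
  set.seed(3); b <- simulate_ensemble(cfg)
  expect_identical(a$summary, b$summary)
  expect_true(all(diff(a$summary$phi_mean) >= -1e-12))
  expect_true(all(a$summary$phi_mean >= 0 & a$summary$phi_mean <= 1))
  expect_equal(a$summary$se, a$summary$phi_sd / sqrt(50))
  # two replicates on identical random numbers have zero spread
  cfg1 <- sim_config(rp, dt = 0.5, t_max = 2000)
  set.seed(9); p1 <- simulate_once(cfg1)$trajectory$phi
  set.seed(9); p2 <- simulate_once(cfg1)$trajectory$phi
  expect_identical(p1, p2)
  expect_equal(stats::sd(c(p1[100], p2[100])), 0)
})

test_that("slow-nucleation ensembles track the single-domain mean and deviate as r shrinks", {
  devs <- vapply(c(1, 0.5, 0.2), function(r) {
    set.seed(23)
    cfg <- sim_config(rate_params(kn = 1e-4, kg = 1e-3, r = r), dt = 0.5,
                      t_max = 2.4 / (r / (1 + r) * 1e-3),
                      time_origin = "first_nucleation", M = 1000)
    se <- simulate_ensemble(cfg)
    an <- coverage_slow_mean(1e-3 / (1 + r), r, se$summary$t_s)
    max(abs(se$summary$phi_mean - an))
  }, numeric(1))
  expect_lt(devs[1], 0.03)           # symmetric case: close agreement
  expect_gt(devs[3], devs[1])        # growing discrepancy as r decreases
  expect_gt(devs[2], devs[1] / 2)    # ordering is monotone within noise
})

test_that("kinetics depend on kg/kn only, up to the growth time scale", {
  set.seed(31)
  cfg_a <- sim_config(rate_params(kn = 1e-3, kg_fast = 5e-4, r = 1), dt = 0.5,
                      t_max = 4000, time_origin = "first_nucleation", M = 1500)
  a <- simulate_ensemble(cfg_a)
  set.seed(77)
  cfg_b <- sim_config(rate_params(kn = 1e-2, kg_fast = 5e-3, r = 1), dt = 0.05,
                      t_max = 400, time_origin = "first_nucleation", M = 1500)
  b <- simulate_ensemble(cfg_b)
  # times rescaled by tau_g = 1/kg: curves coincide within MC error
  expect_equal(length(a$summary$phi_mean), length(b$summary$phi_mean))
  expect_lt(max(abs(a$summary$phi_mean - b$summary$phi_mean)), 0.03)
})

test_that("halving the time step leaves the ensemble mean unchanged within 1%", {
  run <- function(dt) {
    set.seed(13)
    cfg <- sim_config(rate_params(kn = 1e-4, kg = 1e-3, r = 1), dt = dt,
                      t_max = 4000, time_origin = "first_nucleation", M = 8000)
    simulate_ensemble(cfg)$summary
  }
  coarse <- run(0.5)
  fine <- run(0.25)
  on_coarse <- fine$phi_mean[seq(1, nrow(fine), by = 2)]
  expect_lt(max(abs(coarse$phi_mean - on_coarse)), 0.01)
})

test_that("the standard error of the ensemble mean scales as 1/sqrt(M)", {
  rp <- rate_params(kn = 1e-3, kg_fast = 5e-4, r = 1)
  sds <- vapply(c(100, 1000, 10000), function(M) {
    set.seed(29)
    cfg <- sim_config(rp, dt = 0.5, t_max = 1500,
                      time_origin = "first_nucleation", M = M)
    s <- simulate_ensemble(cfg)$summary
    mid <- which.min(abs(s$phi_mean - 0.5))
    c(s$phi_sd[mid], s$se[mid])
  }, numeric(2))
  # the per-run spread is M-independent; the SE shrinks as 1/sqrt(M)
  expect_lt(max(sds[1, ]) / min(sds[1, ]), 1.25)
  expect_equal(sds[2, 1] / sds[2, 3], sqrt(100), tolerance = 0.25)
})

test_that("the many-nuclei sigmoid is approached as kg/kn decreases", {
  # finite-molecule lag vs the infinite-substrate closed form shrinks
  # roughly like sqrt(kg/kn)
  devs <- vapply(c(0.1, 0.03, 0.01), function(ratio) {
    set.seed(42)
    kn <- 1e-2 / sqrt(ratio / 0.1)
    rp <- rate_params(kn = kn, kg = ratio * kn, r = 1)
    cfg <- sim_config(rp, dt = 0.5, t_max = 6 / sqrt(rp$kn * rp$kg),
                      time_origin = "protein_addition", M = 2000)
    s <- simulate_ensemble(cfg)
    max(abs(s$summary$phi_mean - coverage_fast(rp, s$summary$t_s)))
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[3], 0.015)
})

test_that("the single-domain mean is approached as kg/kn grows", {
  devs <- vapply(c(3, 10, 30), function(ratio) {
    set.seed(24)
    rp <- rate_params(kn = 1e-3 / ratio, kg_fast = 5e-4, r = 1)
    cfg <- sim_config(rp, dt = 0.5, t_max = 4800,
                      time_origin = "first_nucleation", M = 1000)
    s <- simulate_ensemble(cfg)
    max(abs(s$summary$phi_mean - coverage_slow_mean(5e-4, 1, s$summary$t_s)))
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[3], 0.02)
})
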