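test_that("free-DNA exposure integrals reduce to known areas", {
  geom <- filament_geometry(12)
  flat <- coverage_curve(seq(0, 1000, 10), rep(12, 101), geom)
  bn <- compute_bn(list(flat), list(c(400, 900)))
  expect_equal(bn$B_N, c(12 * 400, 12 * 900))
  expect_equal(bn$N, c(1, 2))
  expect_error(compute_bn(list(flat), list(-5), t0 = 0), "before")
})

test_that("B_1 on a forced trace matches the closed-form piecewise integral", {
  # single domain nucleated at t = 100 with symmetric fronts: L_free falls
  # linearly at 2 v L0 until an end is reached
  geom <- filament_geometry(10)
  cfg <- sim_config(rate_params(kn = 0, kg_fast = 1e-3, r = 1), dt = 0.5,
                    t_max = 420)
  fs <- forced_scenario(cfg, tibble::tibble(t = 100, x = 0.5, fast_side = "left"))
  curve <- coverage_curve(fs$trajectory$t_s,
                          10 * (1 + fs$trajectory$phi / 2), geom)
  t_N <- 400
  bn <- compute_bn(list(curve), list(t_N))
  # L_free = 10 for t < 100, then 10 (1 - 2e-3 (t - 100))
  closed <- 10 * 100 + 10 * 300 - 10 * 2e-3 * 300^2 / 2
  expect_equal(bn$B_N, closed, tolerance = 1e-8)
  # and against an independent trapezoid oracle
  skip_if_not_installed("pracma")
  inside <- curve$t_s <= t_N
  expect_equal(bn$B_N, pracma::trapz(curve$t_s[inside], curve$Lfree_um[inside]),
               tolerance = 1e-6)
})

test_that("the B_N regression inverts exact linear data", {
  rec <- tibble::tibble(experiment = rep(1:3, each = 3),
                        N = rep(1:3, 3),
                        B_N = rep(1:3, 3) / 2.5e-4)
  fit <- fit_nucleation_density(rec)
  expect_equal(fit$n_hat, 2.5e-4, tolerance = 1e-10)
  expect_error(fit_nucleation_density(tibble::tibble(N = 1, B_N = 5)), "two or more")
})

test_that("the B_N method is calibrated on Poisson-generated nucleations", {
  # time-rescaling oracle: with intensity n * L_free(t), the transformed
  # times n * B(t_N) are a unit-rate Poisson process, so B_N = S_N / n with
  # S_N a sum of Exp(1) variables -- generated independently of compute_bn
  set.seed(19)
  n_true <- 5e-4   # per um per s; deep inside the observation window
  t <- seq(0, 9000, 2)
  Lfree <- 12 * exp(-t / 2500)  # a smooth decaying free length
  B <- cumsum(c(0, diff(t) * (head(Lfree, -1) + tail(Lfree, -1)) / 2))
  curve <- tibble::tibble(t_s = t, Lfree_um = Lfree)
  curves <- list(); times <- list()
  for (e in 1:200) {
    tn <- stats::approx(B, t, xout = cumsum(rexp(3)) / n_true)$y
    curves[[e]] <- curve
    times[[e]] <- tn[!is.na(tn)]
  }
  fit <- fit_nucleation_density(compute_bn(curves, times))
  # the pooled B_bar_N vs N slope is an unbiased estimate of 1/n
  expect_lt(abs(fit$slope - 1 / n_true), 3 * fit$slope_se)
  expect_lt(abs(fit$n_hat - n_true) / n_true, 0.05)
})

test_that("chi-square objective matches its definition", {
  em <- tibble::tibble(t_s = seq(0, 90, 10), phi_mean = seq(0.1, 1, 0.1),
                       se = 0.02)
  model <- tibble::tibble(t_s = em$t_s, phi_mean = em$phi_mean, se = 0.02)
  expect_equal(chi2_objective(em, model), 0)
  # offset by exactly one combined SE at each of T points -> chi2 = T
  comb <- sqrt(em$se^2 + model$se^2)
  model2 <- dplyr::mutate(model, phi_mean = phi_mean + comb)
  expect_equal(chi2_objective(em, model2), nrow(em), tolerance = 1e-10)
  # zero-variance points are floored, not infinite
  em0 <- dplyr::mutate(em, se = 0)
  model0 <- dplyr::mutate(model, se = 0, phi_mean = phi_mean + 1e-7)
  expect_true(is.finite(chi2_objective(em0, model0)))
})

test_that("chi-square at the generating parameters has the expected scale", {
  set.seed(47)
  truth <- rate_params(kn = 1.05e-3, kg_fast = 5.27e-4, r = 0.10)
  cfg <- sim_config(truth, dt = 0.5, t_max = 20000)
  curves <- list()
  while (length(curves) < 5) {
    s <- simulate_once(cfg)
    if (max(s$trajectory$phi) >= 0.999) curves[[length(curves) + 1]] <- s$trajectory
  }
  em <- align_and_average(curves, dt_out = 10, align_phi = 0)
  n_out <- ceiling(max(em$t_s) / 0.5)
  res <- recakinetics:::sim_ensemble_cpp(truth$kn, truth$kg_fast, truth$r,
                                         0.5, n_out, 4000L, 1L, 0, n_out + 2000L,
                                         n_out)
  model <- tibble::tibble(t_s = seq(0, by = 0.5, length.out = n_out + 1),
                          phi_mean = res$phi_mean,
                          se = res$phi_sd / sqrt(4000))
  chi2 <- chi2_objective(em, model)
  T_pts <- nrow(em)
  # correlated residuals widen the spread well beyond the iid 3*sqrt(2T)
  # band; the scale must still be of order T
  expect_gt(chi2, T_pts / 10)
  expect_lt(chi2, T_pts * 10)
})

test_that("a degenerate single-point scan returns that point, fully derived", {
  set.seed(3)
  truth <- rate_params(kn = 1.05e-3, kg_fast = 5.27e-4, r = 0.10)
  cfg <- sim_config(truth, dt = 0.5, t_max = 20000)
  curves <- list()
  while (length(curves) < 3) {
    s <- simulate_once(cfg)
    if (max(s$trajectory$phi) >= 0.999) curves[[length(curves) + 1]] <- s$trajectory
  }
  sp <- scan_spec(kn = 1.05e-3, kg_fast = 5.27e-4, r = 0.10,
                  M_schedule = c(200, 400), align_phi = 0)
  expect_warning(fit <- grid_scan_fit(curves, sp, n_sites = 11800),
                 "boundary")
  expect_equal(fit$r_hat, 0.10)
  expect_equal(fit$M_final, 400)
  # derived quantities satisfy the algebraic identities exactly
  expect_equal(fit$kg_hat, fit$kg_fast_hat * (1 + fit$r_hat))
  expect_equal(fit$n_hat, fit$kn_hat / 11800)
  expect_equal(fit$v_hat, fit$kg_hat * 11800)
  expect_equal(fit$dE_asym, -log(fit$r_hat))
  expect_equal(fit$ratio_fast_slow, 10)
  td <- tidy(fit)
  expect_true(all(c("kn", "kg_fast", "r", "dE_coop") %in% td$term))
  gl <- glance(fit)
  expect_true(gl$on_boundary)
})
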