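test_that("a noiseless bilinear trace yields its break to within one sample", {
  t <- seq(0, 200, by = 1)
  y <- 10 + 0.002 * pmin(t, 100) + 0.0005 * pmax(t - 100, 0)
  curve <- tibble::tibble(t_s = t, L_um = y)
  fit <- fit_piecewise_linear(curve, init_breaks = 80)
  expect_lt(abs(fit$t_breaks - 100), 1)
  expect_equal(fit$slopes[1:2], c(0.002, 0.0005), tolerance = 1e-6)
  expect_true(fit$significant)
})

test_that("a pure linear trace forced into two segments is flagged degenerate", {
  set.seed(2)
  t <- seq(0, 500, by = 1)
  curve <- tibble::tibble(t_s = t, L_um = 10 + 1e-3 * t + rnorm(length(t), 0, 1e-4))
  fit <- fit_piecewise_linear(curve, init_breaks = 250)
  expect_lt(abs(fit$slopes[1] - fit$slopes[2]), 0.05 * 1e-3)
  expect_false(fit$significant)
})

test_that("the two-domain trace decomposes exactly and rejects the unphysical scenario", {
  truth <- two_domain_truth()
  curve <- two_domain_curve(truth)
  init <- truth$breaks + c(30, -40, 25, -60, 80)
  fit <- fit_piecewise_linear(curve, init_breaks = init)
  expect_equal(fit$Q, 5)
  expect_equal(fit$n_domains, 2)
  expect_equal(fit$t_breaks, truth$breaks, tolerance = 1e-3)

  scen <- enumerate_scenarios(fit)
  expect_gte(length(scen), 2)
  sols <- lapply(scen, solve_scenario, fit = fit, geom = truth$geom)
  feas <- vapply(sols, function(s) isTRUE(s$feasible), logical(1))
  expect_true(any(feas))

  # the generating kinetics is among the feasible solutions, exactly
  L0 <- truth$geom$L_initial
  target_vf <- truth$nuc$v_left * L0   # fast sides are both "left"
  target_vs <- truth$nuc$v_right * L0
  hit <- FALSE
  for (s in sols[feas]) {
    d <- s$domains
    if (isTRUE(all.equal(d$v_fast_um_s, target_vf, tolerance = 1e-6)) &&
        isTRUE(all.equal(d$v_slow_um_s, target_vs, tolerance = 1e-6)) &&
        isTRUE(all.equal(sort(d$x_frac), sort(truth$nuc$x), tolerance = 1e-4))) {
      hit <- TRUE
    }
  }
  expect_true(hit)

  # the assignment in which the second domain's fast front reaches the end
  # before the domains meet solves to a negative velocity
  neg <- vapply(sols, function(s) {
    identical(s$feasible, FALSE) && grepl("negative", s$reason)
  }, logical(1))
  expect_true(any(neg))

  # sum rule: on every inter-break segment twice the fitted slope equals the
  # sum of the active front velocities
  best <- sols[feas][[which.max(vapply(sols[feas], function(s)
    sum(s$domains$v_fast_um_s), numeric(1)))]]
  fr <- best$fronts
  for (j in seq_len(fit$Q - 1)) {
    nuc_breaks <- which(diff(fit$slopes) > 0)
    active <- fr$v_um_s[nuc_breaks[fr$domain] <= j & fr$close_break > j]
    expect_equal(sum(active), 2 * fit$slopes[j + 1], tolerance = 1e-6,
                 info = sprintf("segment %d", j))
  }
})

test_that("single-domain traces give two mirror scenarios with one velocity set", {
  geom <- filament_geometry(12)
  n_sites <- geom$n_sites
  vf <- 10 / n_sites; vs <- 1 / n_sites  # 10 and 1 sites/s as fractions/s
  cfg <- sim_config(rate_params(kn = 0, kg_fast = vf, r = vs / vf), dt = 0.5,
                    t_max = ceiling(0.7 / vs) + 400)
  fs <- forced_scenario(cfg, tibble::tibble(t = 100, x = 0.3, fast_side = "left"))
  curve <- tibble::tibble(t_s = fs$trajectory$t_s,
                          L_um = 12 * (1 + fs$trajectory$phi / 2))
  t2 <- 100 + 0.3 / vf
  t3 <- 100 + 0.7 / vs
  fit <- fit_piecewise_linear(curve, init_breaks = c(80, t2 * 1.1, t3 * 0.97))
  scen <- enumerate_scenarios(fit)
  expect_length(scen, 2)
  sols <- lapply(scen, solve_scenario, fit = fit, geom = geom)
  vsets <- unique(lapply(sols, function(s)
    round(sort(c(s$domains$v_fast_sites_s, s$domains$v_slow_sites_s)), 4)))
  expect_length(vsets, 1)
  expect_equal(vsets[[1]], c(1, 10), tolerance = 1e-4)
})

test_that("degenerate slope patterns return an empty, flagged scenario list", {
  fake <- list(Q = 2, slopes = c(0, 1e-3, 5e-4),
               t_breaks = c(10, 50), n_domains = 0.5)
  class(fake) <- "breakpoint_fit"
  out <- enumerate_scenarios(fake)
  expect_length(out, 0)
  expect_match(attr(out, "reason"), "incomplete")
  fake2 <- list(Q = 1, slopes = c(1e-3, 5e-4), t_breaks = 10)
  class(fake2) <- "breakpoint_fit"
  out2 <- enumerate_scenarios(fake2)
  expect_length(out2, 0)
})

test_that("reconstruction round-trips solved kinetics and handles edge cases", {
  truth <- two_domain_truth()
  curve <- two_domain_curve(truth)
  dec <- decompose_curve(curve, init_breaks = truth$breaks + c(30, -40, 25, -60, 80),
                         geom = truth$geom)
  top <- dec$ranking[dec$ranking$feasible, ]
  expect_true(nrow(top) >= 1)
  best <- dec$solutions[[top$scenario[1]]]
  rec <- reconstruct_length(best, truth$geom, dt = 0.5, t_end = max(curve$t_s))
  L_hat <- stats::approx(rec$t_s, rec$L_um, xout = curve$t_s)$y
  expect_lt(max(abs(L_hat - curve$L_um)), 1e-4)

  empty <- reconstruct_length(tibble::tibble(), truth$geom, t_end = 100)
  expect_true(all(empty$L_um == truth$geom$L_initial))
  # saturating kinetics end at 1.5 L(0)
  expect_equal(max(rec$L_um), 1.5 * truth$geom$L_initial, tolerance = 1e-6)
})

test_that("break counting matches domain counting on complete traces", {
  # N_t = (Q - 1) / 2 across seeded stochastic runs
  set.seed(101)
  cfg <- sim_config(rate_params(kn = 1.05e-3, kg_fast = 5.27e-4, r = 0.1),
                    dt = 0.5, t_max = 30000)
  for (i in 1:20) {
    once <- simulate_once(cfg)
    if (max(once$trajectory$phi) < 1) next
    n_dom <- nrow(once$nucleations)
    n_dd <- sum(once$collisions$type == 0)
    n_end <- sum(once$collisions$type != 0)
    # Q = nucleations + collisions (each domain-domain merge and each end
    # absorption is one break)
    Q <- n_dom + n_dd + n_end
    expect_equal(n_dd, n_dom - 1)
    expect_equal(n_end, 2)
    expect_equal((Q - 1) / 2, n_dom)
  }
})

test_that("noisy breakpoint recovery stays within a few effective samples", {
  # reduced-size preview of the acceptance check: 15 replicates
  truth <- two_domain_truth()
  set.seed(7)
  ok <- 0L
  for (i in 1:15) {
    curve <- two_domain_curve(truth, noise_sd = 0.05, sample_dt = 0.1)
    fit <- fit_piecewise_linear(curve,
                                init_breaks = truth$breaks + c(60, -80, 50, -90, 120),
                                smooth_n = 50)
    if (all(abs(fit$t_breaks - truth$breaks) <= 3 * 5)) ok <- ok + 1L
  }
  expect_gte(ok, 13L)
})
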