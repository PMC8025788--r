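# Shared fixtures: all generated in code, sized for fast tests.

# Two-domain ground truth with the canonical few-nuclei trace structure:
# nucleation, end collision, nucleation, domain-domain collision, end
# collision (Q = 5). v2s < v1s so the "second scenario" assignment (the
# second domain's fast front reaching the end before the domains meet)
# solves to a negative velocity and must be rejected.
two_domain_truth <- function(L0 = 12) {
  list(
    geom = filament_geometry(L0),
    nuc = tibble::tibble(
      t = c(200, 1800),
      x = c(0.24, 0.75),
      fast_side = c("left", "left"),
      v_left = c(3e-4, 2.4e-4),   # fraction of substrate per second
      v_right = c(1.2e-4, 6e-5)
    ),
    # derived event times (exact): fast front of domain 1 reaches the left
    # end at 1000 s; the 0.318 gap open at the second nucleation closes at
    # 3.6e-4 per second (fronts meet at 2683.33 s); slow front of domain 2
    # reaches the right end at 5966.67 s
    breaks = c(200, 1000, 1800, 1800 + 0.318 / 3.6e-4, 1800 + 0.25 / 6e-5)
  )
}

two_domain_curve <- function(truth = two_domain_truth(), dt = 0.5,
                             t_max = 6600, noise_sd = 0, sample_dt = dt,
                             rng = NULL) {
  eng_dt <- min(dt, sample_dt)
  cfg <- sim_config(rate_params(kn = 0, kg_fast = 3e-4, r = 0.5),
                    dt = eng_dt, t_max = t_max)
  fs <- forced_scenario(cfg, truth$nuc)
  tr <- fs$trajectory
  if (sample_dt > eng_dt) {
    keep <- seq(1, nrow(tr), by = round(sample_dt / eng_dt))
    tr <- tr[keep, ]
  }
  L <- truth$geom$L_initial * (1 + tr$phi / 2)
  if (noise_sd > 0) L <- L + rnorm(length(L), 0, noise_sd)
  curve <- tibble::tibble(t_s = tr$t_s, L_um = L)
  attr(curve, "L_initial") <- truth$geom$L_initial
  curve
}

# uniform grids for property-style loops
grid_zrel <- seq(0.01, 0.98, by = 0.018)
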