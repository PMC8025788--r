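#' Nucleation-and-growth rate parameters
#'
#' Holds the macroscopic rate constants of RecA assembly on one dsDNA
#' molecule and, when the site count is known, their microscopic per-site
#' counterparts:
#' * `kn` — nucleation rate per molecule, 1/s; `kn = n * n_sites`;
#' * `kg_fast` — growth rate of the fast front of a domain, 1/s;
#' * `r` — slow/fast front asymmetry ratio in `[0, 1]`;
#' * `kg` — whole-domain growth rate, `kg = kg_fast * (1 + r)`; `kg = v / n_sites`;
#' * `n` — nucleation rate density, 1/(site s);
#' * `v` — domain growth velocity, RecA monomers/s (sites/s).
#'
#' Exactly one of `kn`/`n` and one of `kg`/`kg_fast`/`v` must be given;
#' the rest are derived.
#'
#' @param kn Nucleation rate per molecule, 1/s.
#' @param kg Whole-domain growth rate, 1/s.
#' @param kg_fast Fast-front growth rate, 1/s.
#' @param r Slow/fast asymmetry ratio in `[0, 1]` (default 1, symmetric).
#' @param n Nucleation rate density, 1/(site s).
#' @param v Domain growth velocity, sites/s.
#' @param n_sites Number of binding sites L0/a (needed to link macroscopic
#'   and microscopic values).
#' @return An object of class `rate_params`.
#' @examples
#' rate_params(kn = 1.05e-3, kg_fast = 5.27e-4, r = 0.10, n_sites = 10700)
#' @export
rate_params <- function(kn = NULL, kg = NULL, kg_fast = NULL, r = 1,
                        n = NULL, v = NULL, n_sites = NULL) {
  if (!is.numeric(r) || length(r) != 1L || r < 0 || r > 1) {
    abort("`r` must be a single number in [0, 1].")
  }
  if (!is.null(kn) && !is.null(n)) {
    if (is.null(n_sites)) abort("`n_sites` needed to check `kn` against `n`.")
    if (abs(kn - n * n_sites) > 1e-9 * max(kn, n * n_sites)) {
      abort("inconsistent simultaneous specification of `kn` and `n`.")
    }
  }
  n_growth <- sum(!is.null(kg), !is.null(kg_fast), !is.null(v))
  if (n_growth > 1L) {
    vals <- list(kg = kg, kg_fast = if (!is.null(kg_fast)) kg_fast * (1 + r),
                 v = if (!is.null(v) && !is.null(n_sites)) v / n_sites)
    vals <- vals[!vapply(vals, is.null, logical(1))]
    if (diff(range(unlist(vals))) > 1e-9 * max(unlist(vals))) {
      abort("inconsistent simultaneous specification of growth rates.")
    }
  }
  if (is.null(kn)) {
    if (is.null(n)) abort("supply `kn` or `n`.")
    if (is.null(n_sites)) abort("`n_sites` needed to derive `kn` from `n`.")
    kn <- n * n_sites
  }
  if (is.null(kg)) {
    if (!is.null(kg_fast)) {
      kg <- kg_fast * (1 + r)
    } else if (!is.null(v)) {
      if (is.null(n_sites)) abort("`n_sites` needed to derive `kg` from `v`.")
      kg <- v / n_sites
    } else {
      abort("supply one of `kg`, `kg_fast`, `v`.")
    }
  }
  if (kn < 0 || kg < 0) abort("rates must be non-negative.")
  out <- list(
    kn = kn,
    kg = kg,
    kg_fast = kg / (1 + r),
    r = r,
    n_sites = n_sites,
    n = if (!is.null(n_sites)) kn / n_sites else NA_real_,
    v = if (!is.null(n_sites)) kg * n_sites else NA_real_
  )
  structure(out, class = "rate_params")
}

#' @rdname rate_params
#' @param x Object to print.
#' @param ... Unused.
#' @export
print.rate_params <- function(x, ...) {
  cat("Nucleation-and-growth rates\n")
  cat(sprintf("  kn      = %.4g 1/s\n", x$kn))
  cat(sprintf("  kg      = %.4g 1/s   (kg_fast = %.4g, r = %.3g)\n",
              x$kg, x$kg_fast, x$r))
  if (!is.null(x$n_sites)) {
    cat(sprintf("  n_sites = %d;  n = %.4g 1/(site s);  v = %.4g sites/s\n",
                as.integer(x$n_sites), x$n, x$v))
  }
  invisible(x)
}

#' Convert between macroscopic and microscopic rate constants
#'
#' Thin wrapper over [rate_params()] emphasising the conversions
#' `kn = n * L0/a` and `kg = a v / L0`: give whichever of the molecular
#' (`kn`, `kg`) or per-site (`n`, `v`) values you have, plus the site count,
#' and receive the complete set.
#'
#' @inheritParams rate_params
#' @return A `rate_params` object with all fields filled.
#' @examples
#' convert_rates(n = 9.8e-8, kg = 5.8e-4, r = 0.10, n_sites = 10700)
#' @export
convert_rates <- function(kn = NULL, kg = NULL, kg_fast = NULL, r = 1,
                          n = NULL, v = NULL, n_sites = NULL) {
  if (is.null(n_sites)) abort("`n_sites` is required for rate conversion.")
  rate_params(kn = kn, kg = kg, kg_fast = kg_fast, r = r, n = n, v = v,
              n_sites = n_sites)
}

#' Mean-field kinetics of domain count and coverage
#'
#' Integrates the mean-field nucleation-and-growth system valid when many
#' domains are present:
#' \deqn{dN/dt = k_n (1-\phi) - k_g N^2/(1-\phi), \quad d\phi/dt = k_g N}
#' The first term creates nuclei on the undecorated part; the second removes
#' domains as their fronts collide. Optionally an extra `kn (1-phi)` term is
#' added to the coverage equation to account for the sites occupied by the
#' nuclei themselves (negligible unless nucleation is extremely fast).
#'
#' @param params A [rate_params()] object.
#' @param t_grid Increasing time grid starting at 0, s.
#' @param include_nucleation_coverage Add the `kn (1-phi)` term to
#'   `dphi/dt`? Default `FALSE` (matches the closed-form sigmoid).
#' @param rtol Relative tolerance of the integrator (default 1e-8).
#' @return A tibble with columns `t_s`, `N`, `phi`.
#' @examples
#' ode_mean_field(rate_params(kn = 1e-2, kg = 1e-3), seq(0, 1000, 5))
#' @export
ode_mean_field <- function(params, t_grid, include_nucleation_coverage = FALSE,
                           rtol = 1e-8) {
  if (t_grid[1] != 0 || any(diff(t_grid) <= 0)) {
    abort("`t_grid` must increase from 0.")
  }
  kn <- params$kn
  kg <- params$kg
  cap <- 1 - 1e-12 # keep the collision term finite at domain exhaustion
  deriv <- function(t, y, parms) {
    N <- y[1]
    phi <- min(y[2], cap)
    free <- 1 - phi
    dN <- kn * free - kg * N^2 / free
    dphi <- kg * N + if (include_nucleation_coverage) kn * free else 0
    list(c(dN, dphi))
  }
  sol <- deSolve::ode(
    y = c(N = 0, phi = 0), times = t_grid, func = deriv, parms = NULL,
    method = "lsoda", rtol = rtol, atol = 1e-12
  )
  tibble::tibble(
    t_s = sol[, "time"],
    N = sol[, "N"],
    phi = pmin(sol[, "phi"], 1)
  )
}

#' Coverage in the fast-nucleation (many-nuclei) limit
#'
#' Closed-form sigmoid for the mean coverage when nucleation is much faster
#' than growth: `phi(t) = 1 - exp(-1/2 kn kg_fast (1+r) t^2)`, which is
#' `1 - exp(-1/2 kn kg t^2)` in terms of the whole-domain rate
#' `kg = kg_fast (1+r)`. Depends on the rates only through the product
#' `kn * kg`, so nucleation and growth cannot be separated in this regime.
#'
#' @param params A [rate_params()] object.
#' @param t Time, s. Vectorised.
#' @return Coverage fraction phi(t).
#' @export
coverage_fast <- function(params, t) {
  if (any(t < 0)) abort("`t` must be non-negative.")
  1 - exp(-0.5 * params$kn * params$kg_fast * (1 + params$r) * t^2)
}

#' One realization of single-domain coverage with asymmetric fronts
#'
#' In the slow-nucleation limit a single domain nucleates at fractional
#' position `x` (time 0) and its fronts advance at `kg_fast` toward one end
#' and `r * kg_fast` toward the other (rates in substrate fractions per
#' second). The coverage rate is
#' \deqn{\dot\phi = (r+1) k_g' - k_g'\,\theta(t k_g' - x) - r k_g'\,\theta(r t k_g' - (1-x))}
#' (each step function switches a front off as it reaches its end); phi
#' follows by exact piecewise integration:
#' `phi(t) = min(kg_fast t, x) + min(r kg_fast t, 1 - x)`.
#'
#' @param kg_fast Fast-front rate, 1/s.
#' @param r Asymmetry ratio in `[0, 1]`.
#' @param x Nucleation position as a fraction of the molecule in `[0, 1]`
#'   (the fast front runs toward the near coordinate origin side, covering
#'   length `x`).
#' @param t Time since nucleation, s. Vectorised.
#' @return A tibble with columns `t_s`, `phi_dot`, `phi`.
#' @export
coverage_slow_realization <- function(kg_fast, r, x, t) {
  if (x < 0 || x > 1) abort("`x` must lie in [0, 1].")
  fast_done <- t * kg_fast >= x
  slow_done <- r * t * kg_fast >= (1 - x)
  phi_dot <- (r + 1) * kg_fast - kg_fast * fast_done - r * kg_fast * slow_done
  phi <- pmin(kg_fast * t, x) + pmin(r * kg_fast * t, 1 - x)
  tibble::tibble(t_s = t, phi_dot = phi_dot, phi = phi)
}

#' Ensemble-mean coverage in the slow-nucleation limit
#'
#' Average of [coverage_slow_realization()] over a uniform nucleation
#' position, giving the three-branch piecewise form (breakpoints at
#' `1/kg_fast` and `1/(r kg_fast)`):
#' \deqn{\bar\phi(t) = \begin{cases}
#'   k_g'(1+r)t - \tfrac12 k_g'^2 t^2 (1+r^2) & t < 1/k_g' \\
#'   k_g' r t - \tfrac12 k_g'^2 r^2 t^2 + \tfrac12 & 1/k_g' < t < 1/(r k_g') \\
#'   1 & t > 1/(r k_g')\end{cases}}
#' Continuous at both branch boundaries. Time is measured from the (single)
#' nucleation event. Valid strictly for one domain; additional nucleations
#' make the true mean deviate increasingly as `r` decreases.
#'
#' @param kg_fast Fast-front rate, 1/s.
#' @param r Asymmetry ratio in `(0, 1]` (`r = 0` makes the second breakpoint
#'   diverge and is rejected).
#' @param t Time since nucleation, s. Vectorised.
#' @return Mean coverage fraction.
#' @export
coverage_slow_mean <- function(kg_fast, r, t) {
  if (r <= 0 || r > 1) {
    abort("`r` must lie in (0, 1]; at r = 0 the slow front never finishes and the mean has no finite saturation time.")
  }
  if (any(t < 0)) abort("`t` must be non-negative.")
  u <- kg_fast * t
  out <- ifelse(
    u < 1,
    kg_fast * (1 + r) * t - 0.5 * kg_fast^2 * t^2 * (1 + r^2),
    ifelse(
      u < 1 / r,
      kg_fast * r * t - 0.5 * kg_fast^2 * r^2 * t^2 + 0.5,
      1
    )
  )
  pmin(out, 1)
}

#' Cooperativity activation-energy difference
#'
#' Arrhenius analysis of the fitted rate constants. With
#' `kn ~ (L0/a) exp(-En/kBT)` and `kg_fast ~ (a/L0) exp(-Egf/kBT)`, the
#' difference between the nucleation and fast-front-growth barriers is
#' \deqn{\Delta E_{coop} = E_n - E_g^f = k_B T \ln\!\big(\tfrac{k_g}{(1+r) k_n}\,(L_0/a)^2\big)}
#' in units of kBT. Large positive values mean nucleation is much harder
#' than elongation, i.e. strongly cooperative assembly.
#'
#' @param params A [rate_params()] object with `n_sites` set.
#' @return Energy difference in kBT units.
#' @examples
#' energy_coop(rate_params(kn = 1.05e-3, kg = 5.8e-4, r = 0.10, n_sites = 10700))
#' @export
energy_coop <- function(params) {
  if (is.null(params$n_sites)) abort("`n_sites` must be set in `params`.")
  if (params$kn <= 0 || params$kg <= 0) abort("rates must be positive.")
  log(params$kg / ((1 + params$r) * params$kn) * params$n_sites^2)
}

#' Front-asymmetry activation-energy difference
#'
#' The slow and fast fronts of a domain differ in their binding barrier by
#' `Delta E_asym = Egs - Egf = -kBT ln(r)`, in kBT units. Symmetric growth
#' (`r = 1`) gives zero; `r = 0.1` gives about 2.3 kBT.
#'
#' @param r Slow/fast front velocity ratio in `(0, 1]`. Vectorised.
#' @return Energy difference in kBT units.
#' @export
energy_asym <- function(r) {
  if (any(r <= 0)) abort("`r` must be positive.")
  -log(r)
}
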