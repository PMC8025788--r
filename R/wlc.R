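#' Worm-like-chain parameters for naked and RecA-coated dsDNA
#'
#' Bundles the two persistence lengths and the temperature that enter the
#' mixed-stiffness worm-like-chain (WLC) description of a partially decorated
#' filament. RecA coating stiffens dsDNA dramatically: the persistence length
#' grows from roughly 50 nm (naked) to roughly 1200 nm (fully coated).
#'
#' @param A0 Persistence length of naked dsDNA, nm.
#' @param AR Persistence length of the RecA-dsDNA filament, nm. Must exceed
#'   `A0`.
#' @param temperature Absolute temperature, K. Default 310.15 K (37 C, the
#'   usual assay temperature).
#' @return An object of class `wlc_params`: a list with fields `A0`, `AR`,
#'   `temperature` and the derived thermal energy `kBT` in pN nm.
#' @examples
#' p <- wlc_params()
#' p$kBT # about 4.28 pN nm at 37 C
#' @export
wlc_params <- function(A0 = 50, AR = 1200, temperature = 310.15) {
  if (!is.numeric(A0) || length(A0) != 1L || A0 <= 0) {
    abort("`A0` must be a single positive number (nm).")
  }
  if (!is.numeric(AR) || length(AR) != 1L || AR <= A0) {
    abort("`AR` must be a single number larger than `A0` (nm).")
  }
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0) {
    abort("`temperature` must be a single positive number (K).")
  }
  structure(
    list(A0 = A0, AR = AR, temperature = temperature, kBT = .kB * temperature),
    class = "wlc_params"
  )
}

#' Geometry of one dsDNA construct
#'
#' Describes a single tethered dsDNA molecule: its naked contour length, the
#' RecA binding-site size (one monomer occupies 3 bp) and the factor by which
#' binding extends the occupied contour (about 1.5). The number of binding
#' sites `n_sites = L0/a` links macroscopic rate constants to their
#' per-site microscopic counterparts.
#'
#' @param L_initial Naked contour length L(0), micrometers.
#' @param site_length_bp Binding-site size in base pairs (default 3).
#' @param extension_factor Decorated/naked contour-length ratio (default 1.5).
#' @param bp_nm Rise per base pair of naked dsDNA, nm (default 0.34).
#' @return An object of class `filament_geometry` with fields `L_initial`,
#'   `site_length_bp`, `extension_factor`, `site_length_um`, `n_sites`.
#' @examples
#' filament_geometry(12.04)$n_sites # about 11800 sites
#' @export
filament_geometry <- function(L_initial, site_length_bp = 3,
                              extension_factor = 1.5, bp_nm = 0.34) {
  if (!is.numeric(L_initial) || length(L_initial) != 1L || L_initial <= 0) {
    abort("`L_initial` must be a single positive number (um).")
  }
  if (extension_factor <= 1) {
    abort("`extension_factor` must exceed 1.")
  }
  site_um <- site_length_bp * bp_nm * 1e-3
  structure(
    list(
      L_initial = L_initial,
      site_length_bp = site_length_bp,
      extension_factor = extension_factor,
      site_length_um = site_um,
      n_sites = round(L_initial / site_um)
    ),
    class = "filament_geometry"
  )
}

#' Worm-like-chain force at a relative extension
#'
#' Interpolation formula for the force needed to hold a WLC polymer at
#' end-to-end distance z: F = (kBT/A) * (z/L + 1/(4 (1 - z/L)^2) - 1/4).
#' Strictly increasing in `z_rel`, zero at zero extension, and divergent as
#' the extension approaches the contour length.
#'
#' @param z_rel Relative extension z/L, in `[0, 1)`. Vectorised.
#' @param params A [wlc_params()] object (supplies kBT).
#' @param A Persistence length to use, nm. Defaults to `params$A0`.
#' @return Force in pN, same length as `z_rel`.
#' @examples
#' wlc_force(0.84) # near 0.8 pN for naked dsDNA at 37 C
#' @export
wlc_force <- function(z_rel, params = wlc_params(), A = params$A0) {
  if (any(z_rel < 0 | z_rel >= 1)) {
    abort("`z_rel` must lie in [0, 1): z >= L is outside WLC validity (overstretching).")
  }
  params$kBT / A * (z_rel + 1 / (4 * (1 - z_rel)^2) - 1 / 4)
}

#' Worm-like-chain extension at a given force
#'
#' Numerical inverse of [wlc_force()]: the unique end-to-end distance z in
#' `[0, L)` at which the chain pulls back with force `F`. Solved by bracketed
#' root finding (relative tolerance 1e-10).
#'
#' @param F Force, pN. Vectorised. Must be positive.
#' @param A Persistence length, nm.
#' @param L Contour length (any unit; the result is in the same unit).
#' @param params A [wlc_params()] object.
#' @return End-to-end distance in the unit of `L`.
#' @export
wlc_extension <- function(F, A, L = 1, params = wlc_params()) {
  if (any(F <= 0)) {
    abort("`F` must be positive.")
  }
  vapply(F, function(f) {
    root <- stats::uniroot(
      function(zr) wlc_force(zr, params = params, A = A) - f,
      lower = 0, upper = 1 - 1e-14, tol = 1e-12, maxiter = 1000L
    )
    root$root * L
  }, numeric(1))
}

# large-force WLC fractional end-shortening: 1 - z/L ~ sqrt(kBT / (4 F A))
wlc_c_factor <- function(F, A, params) {
  sqrt(params$kBT / (4 * F * A))
}

#' Coverage fraction from total contour length
#'
#' RecA binding extends each occupied stretch of contour by 1.5x, so a naked
#' length `L_initial` saturates at `1.5 * L_initial` when fully covered. The
#' decorated fraction of the naked contour is `phi = 2 (L/L_initial - 1)`,
#' and the undecorated naked length is `L_free = 3 L_initial - 2 L`.
#' Values of `L` slightly outside the physical band (measurement noise) are
#' clipped, with a once-per-session warning.
#'
#' @param L Total contour length, um. Vectorised.
#' @param L_initial Naked contour length L(0), um.
#' @param clip Clip `phi` to `[0, 1]` and `L_free` to non-negative values
#'   (default). Disable when the noise distribution around the physical
#'   bounds must stay symmetric, e.g. for chi-square fitting of ensemble
#'   means near saturation.
#' @return A tibble with columns `L_um`, `phi`, `Lfree_um`.
#' @examples
#' coverage_from_length(c(12, 15, 18), 12)
#' @export
coverage_from_length <- function(L, L_initial, clip = TRUE) {
  phi_raw <- 2 * (L / L_initial - 1)
  if (!clip) {
    return(tibble::tibble(L_um = L, phi = phi_raw,
                          Lfree_um = 3 * L_initial - 2 * L))
  }
  if (any(phi_raw < -1e-9 | phi_raw > 1 + 1e-9)) warn_clip_once()
  phi <- pmin(pmax(phi_raw, 0), 1)
  tibble::tibble(
    L_um = L,
    phi = phi,
    Lfree_um = pmax(3 * L_initial - 2 * L, 0)
  )
}

#' Contour-length and coverage kinetics from a force-clamp trace
#'
#' Converts a force-clamp trace (time, force, trap-anchor distance) into the
#' contour length of the growing RecA-dsDNA complex and the coverage
#' fraction. In the large-force regime each segment of the mixed filament
#' contributes `z_seg = L_seg (1 - C_seg)` with
#' `C_seg = sqrt(kBT / (4 F A_seg))`, which gives the decorated contour
#' length
#' \deqn{L_R = \frac{z - L(0)(1 - C_0)}{1/3 + (2/3) C_0 - C_R}}
#' and the total length `L(t) = L(0) + L_R/3` (each decorated contour unit
#' replaces 2/3 of its naked length). The end-to-end distance z is taken
#' equal to the measured trap-anchor distance `y_um` up to an optional
#' constant offset; bead-radius and trap-height corrections largely cancel
#' and are below typical experimental accuracy.
#'
#' @param trace A data frame with columns `t_s`, `F_pN`, `y_um` (see
#'   [read_trace()]).
#' @param geom A [filament_geometry()] for this construct.
#' @param params A [wlc_params()].
#' @param z_offset_um Constant offset added to `y_um` to form z (default 0).
#' @param clip Clip the coverage fraction to `[0, 1]` (default; see
#'   [coverage_from_length()]).
#' @return A coverage curve: tibble with columns `t_s`, `L_um`, `phi`,
#'   `Lfree_um`, carrying `L_initial`, `geom` and `params` as attributes
#'   (class `coverage_curve`).
#' @export
decorated_length_from_trace <- function(trace, geom, params = wlc_params(),
                                        z_offset_um = 0, clip = TRUE) {
  check_trace(trace)
  z <- trace$y_um + z_offset_um
  F <- trace$F_pN
  C0 <- wlc_c_factor(F, params$A0, params)
  CR <- wlc_c_factor(F, params$AR, params)
  denom <- 1 / 3 + (2 / 3) * C0 - CR
  if (any(denom <= 0)) {
    abort("non-positive denominator in the mixed-filament length relation: requires AR > A0 and forces well above kBT/A0.")
  }
  LR <- (z - geom$L_initial * (1 - C0)) / denom
  L <- geom$L_initial + LR / 3
  cov <- coverage_from_length(L, geom$L_initial, clip = clip)
  new_coverage_curve(
    tibble::tibble(t_s = trace$t_s, L_um = cov$L_um, phi = cov$phi,
                   Lfree_um = cov$Lfree_um),
    geom = geom, params = params
  )
}

#' Forward model: trap-anchor distance for a partially decorated filament
#'
#' Composes the end-to-end distance of a mixed filament with decorated
#' contour length `LR` on a construct of naked length `L(0)`, at clamp force
#' `F`: the naked remainder `L0 - (2/3) LR` and the decorated part each
#' extend according to their own full WLC inverse at the common force. Used
#' to generate synthetic traces and as the round-trip oracle for
#' [decorated_length_from_trace()].
#'
#' @param LR Decorated contour length, um. Vectorised.
#' @param F Clamp force, pN (scalar or same length as `LR`).
#' @param geom A [filament_geometry()].
#' @param params A [wlc_params()].
#' @param large_force Logical; if `TRUE` use the large-force expansion
#'   `z = L (1 - sqrt(kBT/(4 F A)))` per segment (the relation the inversion
#'   assumes) rather than the exact WLC inverse.
#' @return End-to-end distance z in um.
#' @export
filament_extension <- function(LR, F, geom, params = wlc_params(),
                               large_force = TRUE) {
  L0_naked <- geom$L_initial - (2 / 3) * LR
  if (any(L0_naked < -1e-9)) {
    abort("`LR` exceeds the fully decorated contour 1.5 L(0).")
  }
  L0_naked <- pmax(L0_naked, 0)
  if (large_force) {
    C0 <- wlc_c_factor(F, params$A0, params)
    CR <- wlc_c_factor(F, params$AR, params)
    L0_naked * (1 - C0) + LR * (1 - CR)
  } else {
    Fv <- rep_len(F, length(LR))
    z0 <- vapply(seq_along(LR), function(i) {
      if (L0_naked[i] == 0) 0 else wlc_extension(Fv[i], params$A0, L0_naked[i], params)
    }, numeric(1))
    zR <- vapply(seq_along(LR), function(i) {
      if (LR[i] == 0) 0 else wlc_extension(Fv[i], params$AR, LR[i], params)
    }, numeric(1))
    z0 + zR
  }
}

new_coverage_curve <- function(df, geom, params = NULL) {
  structure(
    df,
    class = c("coverage_curve", class(tibble::tibble())),
    L_initial = geom$L_initial,
    geom = geom,
    wlc = params
  )
}

#' Assemble a coverage curve from time and length vectors
#'
#' @param t_s Time, s (strictly increasing).
#' @param L_um Total contour length, um.
#' @param geom A [filament_geometry()].
#' @return A `coverage_curve` tibble (`t_s`, `L_um`, `phi`, `Lfree_um`).
#' @export
coverage_curve <- function(t_s, L_um, geom) {
  if (length(t_s) != length(L_um)) abort("`t_s` and `L_um` must have equal length.")
  if (any(diff(t_s) <= 0)) abort("`t_s` must be strictly increasing.")
  cov <- coverage_from_length(L_um, geom$L_initial)
  new_coverage_curve(
    tibble::tibble(t_s = t_s, L_um = cov$L_um, phi = cov$phi, Lfree_um = cov$Lfree_um),
    geom = geom
  )
}

check_trace <- function(trace) {
  need <- c("t_s", "F_pN", "y_um")
  if (!all(need %in% names(trace))) {
    abort(paste0("trace must have columns ", paste(need, collapse = ", "), "."))
  }
  if (any(diff(trace$t_s) <= 0)) abort("`t_s` must be strictly increasing.")
  invisible(trace)
}
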