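# Derivation of model inputs and observed endpoints from raw measurements.

#' Apparent permeability coefficient from a transwell assay
#'
#' \deqn{P_{app} = \frac{dC_r/dt \cdot V_r}{A \cdot C_0}} in cm/s, where
#' `dcr_dt` is the receiver-chamber accumulation rate (concentration/s),
#' `v_r` the receiver volume (mL, i.e. cm^3), `area` the monolayer area
#' (cm^2) and `c0` the initial donor concentration (same concentration
#' unit as `dcr_dt`).  Typical assay geometry: 0.075 mL apical /
#' 0.25 mL basolateral receiver volume, 0.0804 cm^2 monolayer.
#'
#' @param dcr_dt Receiver accumulation rate, concentration per second,
#'   nonnegative.
#' @param v_r Receiver chamber volume, mL, positive.
#' @param area Monolayer surface area, cm^2, positive.
#' @param c0 Initial donor concentration, positive.
#' @return Permeability in cm/s, vectorized.
#' @examples
#' papp(0.001, v_r = 0.25, area = 0.0804, c0 = 1)
#' @export
papp <- function(dcr_dt, v_r, area, c0) {
  if (any(dcr_dt < 0)) stop("receiver accumulation rate cannot be negative")
  if (any(v_r <= 0)) stop("receiver volume must be positive")
  if (any(area <= 0)) stop("monolayer area must be positive")
  if (any(c0 <= 0)) stop("donor concentration must be positive")
  dcr_dt * v_r / (area * c0)
}

#' Efflux ratio from directional permeabilities
#'
#' `P_app(B to A) / P_app(A to B)` in a transporter-overexpressing
#' monolayer; values above 1 indicate net active efflux.
#'
#' @param papp_b2a,papp_a2b Directional apparent permeabilities, cm/s;
#'   the A-to-B permeability must be positive (a compound with no
#'   measurable A-to-B flux has no defined efflux ratio).
#' @return Dimensionless ratio, vectorized.
#' @export
efflux_ratio <- function(papp_b2a, papp_a2b) {
  if (any(papp_a2b <= 0))
    stop("A-to-B permeability must be positive; efflux ratio unmeasurable")
  if (any(papp_b2a < 0)) stop("B-to-A permeability cannot be negative")
  papp_b2a / papp_a2b
}

#' Undiluted unbound fraction from a diluted-homogenate measurement
#'
#' Equilibrium dialysis of brain tissue is run on diluted homogenate; the
#' unbound fraction measured there (`fu_prime`) is corrected back to
#' undiluted tissue by
#' \deqn{f_u = \frac{1}{D\,(1/f_u' - 1) + 1}}
#' where `D` is the dilution factor (5 for the standard 20% w/v
#' homogenate).
#'
#' @param fu_prime Unbound fraction measured in the diluted homogenate,
#'   in (0, 1].
#' @param dilution Dilution factor `D >= 1`; default 5 (20% w/v).
#' @return Unbound fraction in undiluted tissue, in (0, 1], vectorized.
#' @examples
#' fu_from_homogenate(0.2)          # 20% w/v homogenate, D = 5
#' fu_from_homogenate(0.2, dilution = 1)  # no dilution: unchanged
#' @export
fu_from_homogenate <- function(fu_prime, dilution = 5) {
  if (any(fu_prime <= 0) || any(fu_prime > 1))
    stop("fu_prime must lie in (0, 1]")
  if (any(dilution < 1)) stop("dilution factor must be >= 1")
  1 / (dilution * (1 / fu_prime - 1) + 1)
}

#' Unbound fraction in CSF from the plasma unbound fraction
#'
#' CSF protein content is a small, species-specific fraction of plasma
#' protein (albumin ratio `Q_alb`), so the CSF unbound fraction is
#' estimated as
#' \deqn{f_{u,CSF} = \frac{1}{1 + Q_{alb}\,(1/f_{u,plasma} - 1)}}
#' which is always at least `fu_plasma` (CSF binds less than plasma).
#'
#' @param fu_plasma Plasma unbound fraction in (0, 1].
#' @param physiology A [species_physiology()] object or species name.
#' @return CSF unbound fraction in (0, 1], vectorized over `fu_plasma`.
#' @examples
#' fu_csf(0.01, "rat")
#' @export
fu_csf <- function(fu_plasma, physiology) {
  physiology <- as_physiology(physiology)
  if (any(fu_plasma <= 0) || any(fu_plasma > 1))
    stop("fu_plasma must lie in (0, 1]")
  1 / (1 + physiology$q_alb * (1 / fu_plasma - 1))
}

#' Observed Kp,uu from in vivo concentrations or total-ratio literature data
#'
#' Computes the observed unbound partition coefficients
#' \deqn{K_{p,uu,brain} = \frac{f_{u,brain} C_{brain}}
#'                             {f_{u,plasma} C_{plasma}}, \qquad
#'       K_{p,uu,CSF} = \frac{f_{u,CSF} C_{CSF}}
#'                           {f_{u,plasma} C_{plasma}}}
#' from matched steady-state concentrations.  `fu_csf` is derived from
#' `fu_plasma` via the albumin-ratio relation when not supplied.  The
#' literature pathway — total concentration ratios `kp_brain` / `kp_csf`
#' multiplied by the unbound-fraction ratio — uses the same formulas with
#' `kp_* = C_*/C_plasma`.  A missing concentration leaves that endpoint
#' `NA` (absent, not zero).
#'
#' @param c_plasma,c_brain,c_csf Steady-state concentrations in one
#'   common unit; `c_brain`/`c_csf` may be `NA`.
#' @param fu_plasma,fu_brain Unbound fractions in (0, 1].
#' @param fu_csf_val Optional measured CSF unbound fraction; derived from
#'   `fu_plasma` when `NULL`.
#' @param kp_brain,kp_csf Optional total-concentration ratios
#'   (tissue/plasma) for the literature pathway; used when the
#'   concentrations are not given.
#' @param physiology A [species_physiology()] object or species name
#'   (needed to derive `fu_csf`).
#' @return Named numeric: `kpuu_brain`, `kpuu_csf` (either may be `NA`).
#' @examples
#' observed_kpuu(c_plasma = 1, c_brain = 10, c_csf = NA,
#'               fu_plasma = 0.1, fu_brain = 0.01, physiology = "rat")
#' @export
observed_kpuu <- function(c_plasma = NA, c_brain = NA, c_csf = NA,
                          fu_plasma, fu_brain = NA, fu_csf_val = NULL,
                          kp_brain = NA, kp_csf = NA, physiology) {
  physiology <- as_physiology(physiology)
  if (fu_plasma <= 0 || fu_plasma > 1) stop("fu_plasma must lie in (0, 1]")
  if (is.na(kp_brain) && !is.na(c_brain)) {
    if (is.na(c_plasma) || c_plasma <= 0)
      stop("c_plasma must be positive when tissue concentrations are used")
    kp_brain <- c_brain / c_plasma
  }
  if (is.na(kp_csf) && !is.na(c_csf)) {
    if (is.na(c_plasma) || c_plasma <= 0)
      stop("c_plasma must be positive when tissue concentrations are used")
    kp_csf <- c_csf / c_plasma
  }
  kb <- NA_real_
  if (!is.na(kp_brain)) {
    if (is.na(fu_brain)) stop("fu_brain required for the brain endpoint")
    if (fu_brain <= 0 || fu_brain > 1) stop("fu_brain must lie in (0, 1]")
    kb <- fu_brain * kp_brain / fu_plasma
  }
  kc <- NA_real_
  if (!is.na(kp_csf)) {
    fc <- if (is.null(fu_csf_val)) fu_csf(fu_plasma, physiology) else fu_csf_val
    kc <- fc * kp_csf / fu_plasma
  }
  c(kpuu_brain = kb, kpuu_csf = kc)
}
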