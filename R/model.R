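# Steady-state three-compartment CNS disposition model.
#
# Unbound drug in plasma (fixed at 1), brain ECF, and CSF exchange through
# permeability-surface area clearances:
#   PS1  bidirectional passive clearance across the BBB
#   PS2  brain <-> CSF exchange (ependymal layer), PS1 / sigma
#   PS3  bidirectional passive clearance across the BCSFB, PS1 / gamma
#   PS4  MDR1/BCRP active efflux at the BBB, f(ERs) * PS1
# plus CL_bulkflow, the CSF bulk flow sink from CSF to plasma.
# At steady state the two unknown concentrations are the Kp,uu ratios.

#' Passive BBB permeability-surface area clearance (PS1)
#'
#' Estimates the bidirectional passive clearance across the blood-brain
#' barrier from lipophilicity and molecular size,
#' \deqn{PS_1 = \frac{3600}{1000}\, X \cdot
#'   10^{\,0.182\,(\log D - 0.5 \log_{10} MW) - 1.86}}{
#'   PS1 = (3600/1000) * X * 10^(0.182*(logD - 0.5*log10(MW)) - 1.86)}
#' in L/h/kg body weight, where \eqn{X} is brain weight in g per kg body
#' weight.  The permeability term \eqn{\log_{10}(D/\sqrt{MW})} follows the
#' empirical passive-permeability correlation for small molecules; the
#' 3600/1000 factor converts mL/s/g brain to L/h/kg body weight.
#'
#' @param logd Distribution coefficient log D at pH 7.4 (dimensionless).
#' @param mw Molecular weight, g/mol; must be positive.
#' @param physiology A [species_physiology()] object (or species name).
#' @return PS1 in L/h/kg. Vectorized over `logd` and `mw`.
#' @examples
#' compute_ps1(0, 400, species_physiology("rat"))
#' @export
compute_ps1 <- function(logd, mw, physiology) {
  physiology <- as_physiology(physiology)
  if (any(!is.finite(mw)) || any(mw <= 0))
    stop("molecular weight must be positive and finite")
  (3600 / 1000) * physiology$x_brain *
    10^(0.182 * (logd - 0.5 * log10(mw)) - 1.86)
}

as_physiology <- function(x) {
  if (inherits(x, "species_physiology")) return(x)
  if (is.character(x) && length(x) == 1L) return(species_physiology(x))
  stop("expected a species_physiology object or a species name")
}

as_scaling <- function(x) {
  if (inherits(x, "scaling_params")) return(x)
  stop("expected a scaling_params object (see scaling_params(), raf_params())")
}

#' In vivo efflux activity from in vitro efflux ratios
#'
#' Converts in vitro MDR1 and BCRP efflux ratios to the dimensionless in
#' vivo active-efflux term of the model:
#' \deqn{f(ERs) = \alpha (ER_{MDR1} - 1) + \beta (ER_{BCRP} - 1)}
#' Each `(ER - 1)` term is floored at 0: the active term represents efflux
#' only, so efflux ratios below unity (assay noise, weak uptake) contribute
#' no negative clearance.
#'
#' @param er_mdr1,er_bcrp Positive in vitro efflux ratios from MDCK-MDR1
#'   and MDCK-BCRP monolayers.
#' @param params A [scaling_params()] object supplying `alpha` and `beta`.
#' @return Nonnegative efflux activity, vectorized.
#' @examples
#' f_ers(10, 3, raf_params("rat"))
#' @export
f_ers <- function(er_mdr1, er_bcrp, params) {
  params <- as_scaling(params)
  if (any(er_mdr1 <= 0) || any(er_bcrp <= 0))
    stop("efflux ratios must be positive")
  params$alpha * (pmax(er_mdr1, 1) - 1) + params$beta * (pmax(er_bcrp, 1) - 1)
}

# Shared closed-form pieces of the steady-state solution.  Written so that
# sigma = Inf or gamma = Inf collapse to their analytic limits (1/Inf = 0;
# the gamma = Inf case divides through by gamma first).
.kpuu_terms <- function(ps1, fers, gamma, sigma, k) {
  n <- max(length(ps1), length(fers), length(gamma), length(sigma), length(k))
  ps1 <- rep_len(ps1, n); fers <- rep_len(fers, n)
  gamma <- rep_len(gamma, n); sigma <- rep_len(sigma, n); k <- rep_len(k, n)
  inf_g <- is.infinite(gamma)
  num_b <- num_c <- den <- numeric(n)
  fin <- !inf_g
  if (any(fin)) {
    g <- gamma[fin]; s <- sigma[fin]; p <- ps1[fin]; f <- fers[fin]; kk <- k[fin]
    nb <- 1 + g * kk / p + 1 / s + g / s
    nc <- 1 + f + 1 / s + g / s
    dd <- nb + f * (1 + g / s + g * kk / p) + g * kk / (s * p)
    num_b[fin] <- nb; num_c[fin] <- nc; den[fin] <- dd
  }
  if (any(inf_g)) {
    # divide numerators and denominator by gamma -> finite limit
    s <- sigma[inf_g]; p <- ps1[inf_g]; f <- fers[inf_g]; kk <- k[inf_g]
    nb <- kk / p + 1 / s
    nc <- 1 / s
    dd <- nb + f * (1 / s + kk / p) + kk / (s * p)
    num_b[inf_g] <- nb; num_c[inf_g] <- nc; den[inf_g] <- dd
  }
  list(num_brain = num_b, num_csf = num_c, den = den)
}

#' Predicted unbound brain-to-plasma ratio
#'
#' Closed-form steady-state solution for
#' \eqn{K_{p,uu,brain}} of the three-compartment model:
#' \deqn{K_{p,uu,brain} =
#'   \frac{1 + \gamma k/PS_1 + 1/\sigma + \gamma/\sigma}
#'        {1 + \gamma k/PS_1 + 1/\sigma + \gamma/\sigma
#'         + f(ERs)\left(1 + \gamma/\sigma + \gamma k/PS_1\right)
#'         + \gamma k/(\sigma PS_1)}}
#' with \eqn{k = CL_{bulkflow}}.  The result lies in (0, 1] whenever
#' \eqn{f(ERs) \ge 0}.  `sigma = Inf` and `gamma = Inf` are evaluated as
#' analytic limits.
#'
#' @param ps1 Passive BBB clearance, L/h/kg (see [compute_ps1()]).
#' @param fers In vivo efflux activity (see [f_ers()]).
#' @param params A [scaling_params()] object supplying `gamma`, `sigma`.
#' @param physiology A [species_physiology()] object supplying
#'   `cl_bulkflow`.
#' @return Dimensionless ratio in (0, 1], vectorized.
#' @seealso [predict_kpuu_csf()], [steady_state_kpuu()] for the
#'   independent linear-system solution.
#' @export
predict_kpuu_brain <- function(ps1, fers, params, physiology) {
  params <- as_scaling(params); physiology <- as_physiology(physiology)
  check_model_inputs(ps1, fers)
  t <- .kpuu_terms(ps1, fers, params$gamma, params$sigma,
                   physiology$cl_bulkflow)
  t$num_brain / t$den
}

#' Predicted unbound CSF-to-plasma ratio
#'
#' Closed-form steady-state solution for \eqn{K_{p,uu,CSF}}; shares its
#' denominator with [predict_kpuu_brain()], with numerator
#' \eqn{1 + f(ERs) + 1/\sigma + \gamma/\sigma}.  CSF exceeds brain exactly
#' when \eqn{f(ERs) > \gamma\, CL_{bulkflow} / PS_1}, which is why the
#' CSF/brain gap widens for strong efflux substrates.
#'
#' @inheritParams predict_kpuu_brain
#' @return Dimensionless ratio in (0, 1], vectorized.
#' @export
predict_kpuu_csf <- function(ps1, fers, params, physiology) {
  params <- as_scaling(params); physiology <- as_physiology(physiology)
  check_model_inputs(ps1, fers)
  t <- .kpuu_terms(ps1, fers, params$gamma, params$sigma,
                   physiology$cl_bulkflow)
  t$num_csf / t$den
}

check_model_inputs <- function(ps1, fers) {
  if (any(ps1 <= 0)) stop("ps1 must be positive")
  if (any(fers < 0)) stop("efflux activity f(ERs) must be nonnegative")
  invisible(TRUE)
}

#' Approximate CSF-to-brain ratio of the partition coefficients
#'
#' When \eqn{1/\sigma} is negligible the ratio
#' \eqn{K_{p,uu,CSF}/K_{p,uu,brain}} simplifies to
#' \deqn{\frac{1 + f(ERs)/(1+\gamma/\sigma)}
#'            {1 + \gamma k /(PS_1 (1+\gamma/\sigma))}}
#' This is the approximation used to reason about when CSF concentration
#' is a faithful surrogate for unbound brain concentration.
#'
#' @inheritParams predict_kpuu_brain
#' @return Dimensionless ratio, vectorized.
#' @export
kpuu_ratio_approx <- function(ps1, fers, params, physiology) {
  params <- as_scaling(params); physiology <- as_physiology(physiology)
  check_model_inputs(ps1, fers)
  gs <- params$gamma / params$sigma
  k <- physiology$cl_bulkflow
  (1 + fers / (1 + gs)) / (1 + params$gamma * k / (ps1 * (1 + gs)))
}

#' Steady-state solution by direct mass balance
#'
#' Solves the three-compartment steady state as a 2x2 linear system
#' instead of using the closed forms, with unbound plasma concentration
#' fixed at 1 so the solutions are the partition coefficients directly:
#' \deqn{PS_1 + PS_2 C_{CSF} = (PS_1 + PS_4 + PS_2)\, C_{brain}}
#' \deqn{PS_3 + PS_2 C_{brain} = (PS_2 + PS_3 + CL_{bulkflow})\, C_{CSF}}
#' Implemented independently of [predict_kpuu_brain()] /
#' [predict_kpuu_csf()]; the two routes agree to ~1e-15 relative and the
#' agreement is enforced by the test suite.
#'
#' @param ps1,ps2,ps3,ps4 PS products, L/h/kg; `ps1 > 0`, others
#'   nonnegative.
#' @param cl_bulkflow CSF bulk flow clearance, L/h/kg, nonnegative.
#' @return Named numeric: `kpuu_brain`, `kpuu_csf`.
#' @examples
#' steady_state_kpuu(0.2, 0.2 / 1054, 0.2 / 1910, 0, 0.000528)
#' @export
steady_state_kpuu <- function(ps1, ps2, ps3, ps4, cl_bulkflow) {
  stopifnot(length(ps1) == 1L, ps1 > 0, ps2 >= 0, ps3 >= 0, ps4 >= 0,
            cl_bulkflow >= 0)
  A <- rbind(c(ps1 + ps4 + ps2, -ps2),
             c(-ps2, ps2 + ps3 + cl_bulkflow))
  if (abs(det(A)) < .Machine$double.xmin)
    stop("degenerate steady state: all exit clearances from CSF are zero")
  x <- solve(A, c(ps1, ps3))
  c(kpuu_brain = x[1], kpuu_csf = x[2])
}

#' Predict Kp,uu for a table of compounds
#'
#' Runs the full prediction pipeline for each row of a compound table:
#' PS1 from `logD` and `MW`, efflux activity from `ER_MDR1`/`ER_BCRP`,
#' then the closed-form brain and CSF partition coefficients.
#'
#' @param compounds Data frame with columns `logD`, `MW`, `ER_MDR1`,
#'   `ER_BCRP` and optionally `compound_id` (see [read_compound_table()]
#'   for the full file format).
#' @param params A [scaling_params()] object.
#' @param physiology A [species_physiology()] object or species name;
#'   defaults to the species of `params`.
#' @return A data frame with one row per compound: `compound_id`,
#'   `species`, `mode`, `ps1`, `f_ers`, `kpuu_brain`, `kpuu_csf`.
#' @examples
#' d <- data.frame(compound_id = "drugA", logD = 2, MW = 350,
#'                 ER_MDR1 = 12, ER_BCRP = 1.1)
#' predict_kpuu(d, raf_params("rat"))
#' @export
predict_kpuu <- function(compounds, params, physiology = NULL) {
  params <- as_scaling(params)
  if (is.null(physiology)) physiology <- params$species
  physiology <- as_physiology(physiology)
  need <- c("logD", "MW", "ER_MDR1", "ER_BCRP")
  miss <- setdiff(need, names(compounds))
  if (length(miss))
    stop("compound table lacks column(s): ", paste(miss, collapse = ", "))
  ps1 <- compute_ps1(compounds$logD, compounds$MW, physiology)
  fe <- f_ers(compounds$ER_MDR1, compounds$ER_BCRP, params)
  data.frame(
    compound_id = if (!is.null(compounds$compound_id)) compounds$compound_id
                  else paste0("cpd", seq_len(nrow(compounds))),
    species = physiology$species,
    mode = params$mode,
    ps1 = ps1,
    f_ers = fe,
    kpuu_brain = predict_kpuu_brain(ps1, fe, params, physiology),
    kpuu_csf = predict_kpuu_csf(ps1, fe, params, physiology),
    stringsAsFactors = FALSE
  )
}
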