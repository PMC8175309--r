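# Synthetic compound-set generator.
#
# Emulates the statistical structure of a CNS discovery compound set:
# physicochemical properties and in vitro efflux ratios spanning drug
# space, with observed Kp,uu values generated from the steady-state model
# under chosen scaling parameters plus multiplicative log-normal noise.

#' Generate a synthetic compound table
#'
#' Draws `n` compounds with logD uniform, and molecular weight and
#' MDR1/BCRP efflux ratios log-uniform, within the given ranges;
#' computes their true model Kp,uu,brain and Kp,uu,CSF under `params`;
#' and produces observed values by multiplying with independent
#' log-normal noise whose log10-scale SD is
#' \eqn{\log_{10}(\mathrm{AAFE}) \sqrt{\pi/2}}, so that the expected
#' absolute log10 fold error — hence the expected AAFE — matches
#' `noise_aafe` (for half-normal \eqn{|X|} with \eqn{X \sim N(0, s^2)},
#' \eqn{E|X| = s\sqrt{2/\pi}}).  With `noise_aafe = 1` the observed
#' values equal the model predictions exactly.
#'
#' Binding and concentration columns are filled consistently: unbound
#' fractions are drawn log-uniformly, the diluted-homogenate value is
#' back-computed from the brain unbound fraction at the given dilution,
#' and tissue concentrations are back-computed from the observed Kp,uu
#' so that [observed_kpuu()] recovers the tabulated observed values.
#'
#' @param n Number of compounds.
#' @param species Species whose physiology and default parameters apply.
#' @param params A [scaling_params()] object; defaults to
#'   [raf_params()] for `species`.
#' @param noise_aafe Target AAFE of the observation noise (`>= 1`);
#'   default 2, the accuracy level typical of cross-species Kp,uu
#'   prediction.
#' @param seed Integer seed; the dataset is a deterministic function of
#'   the spec, and the caller's RNG state is untouched.
#' @param logd_range,mw_range,er_mdr1_range,er_bcrp_range Sampling
#'   ranges (logD uniform; the rest log-uniform).  Defaults span
#'   marketed CNS/non-CNS drug space: logD -2..5, MW 150..700 g/mol,
#'   efflux ratios 0.3..50.
#' @param fraction_mdr1,fraction_bcrp Optional proportions of compounds
#'   forced above the MDR1 (6.0) and BCRP (2.5) substrate cutoffs; when
#'   `NULL` (default) efflux ratios are drawn log-uniformly over the
#'   whole range.
#' @param fu_plasma_range,fu_brain_range Log-uniform ranges for the
#'   unbound fractions.
#' @param dilution Brain homogenate dilution factor (default 5).
#' @return A compound table (data frame) in the standard column layout:
#'   `compound_id`, `species`, `logD`, `MW`, `ER_MDR1`, `ER_BCRP`,
#'   `fu_plasma`, `fu_brain_prime`, `dilution`, `C_plasma`, `C_brain`,
#'   `C_CSF`, `Kpuu_brain_obs`, `Kpuu_csf_obs`, `provenance`, plus the
#'   noise-free truths `Kpuu_brain_true`, `Kpuu_csf_true`.
#' @examples
#' d <- simulate_compounds(5, seed = 1)
#' d[, c("compound_id", "ER_MDR1", "Kpuu_brain_obs")]
#' @export
simulate_compounds <- function(n, species = c("rat", "monkey", "human"),
                               params = NULL, noise_aafe = 2, seed = 1,
                               logd_range = c(-2, 5),
                               mw_range = c(150, 700),
                               er_mdr1_range = c(0.3, 50),
                               er_bcrp_range = c(0.3, 50),
                               fraction_mdr1 = NULL, fraction_bcrp = NULL,
                               fu_plasma_range = c(0.005, 1),
                               fu_brain_range = c(0.001, 1),
                               dilution = 5) {
  species <- match.arg(species)
  if (n < 1) stop("n must be at least 1")
  if (noise_aafe < 1) stop("noise_aafe must be >= 1")
  for (rg in list(logd_range, mw_range, er_mdr1_range, er_bcrp_range,
                  fu_plasma_range, fu_brain_range))
    if (rg[1] > rg[2]) stop("inverted range bounds")
  if (is.null(params)) params <- raf_params(species)
  params <- as_scaling(params)
  physiology <- species_physiology(species)

  with_local_seed(seed, {
    logd <- stats::runif(n, logd_range[1], logd_range[2])
    mw <- rlogunif(n, mw_range)
    er_m <- draw_er(n, er_mdr1_range, fraction_mdr1, cutoff = 6.0)
    er_b <- draw_er(n, er_bcrp_range, fraction_bcrp, cutoff = 2.5)
    fu_p <- rlogunif(n, fu_plasma_range)
    fu_b <- rlogunif(n, fu_brain_range)

    ps1 <- compute_ps1(logd, mw, physiology)
    fe <- f_ers(er_m, er_b, params)
    kb <- predict_kpuu_brain(ps1, fe, params, physiology)
    kc <- predict_kpuu_csf(ps1, fe, params, physiology)

    s <- log10(noise_aafe) * sqrt(pi / 2)
    kb_obs <- kb * 10^stats::rnorm(n, 0, s)
    kc_obs <- kc * 10^stats::rnorm(n, 0, s)

    # invert the dilution correction so fu_from_homogenate round-trips
    fu_bp <- 1 / ((1 / fu_b - 1) / dilution + 1)
    c_plasma <- rep(1, n)
    fu_c <- fu_csf(fu_p, physiology)
    data.frame(
      compound_id = sprintf("SYN-%03d", seq_len(n)),
      species = species,
      logD = logd, MW = mw, ER_MDR1 = er_m, ER_BCRP = er_b,
      fu_plasma = fu_p, fu_brain_prime = fu_bp, dilution = dilution,
      C_plasma = c_plasma,
      C_brain = kb_obs * fu_p * c_plasma / fu_b,
      C_CSF = kc_obs * fu_p * c_plasma / fu_c,
      Kpuu_brain_obs = kb_obs, Kpuu_csf_obs = kc_obs,
      provenance = "synthetic",
      Kpuu_brain_true = kb, Kpuu_csf_true = kc,
      stringsAsFactors = FALSE)
  })
}

rlogunif <- function(n, range) 10^stats::runif(n, log10(range[1]),
                                               log10(range[2]))

# Efflux-ratio draw, optionally stratified so a set proportion lies at or
# above the substrate cutoff.
draw_er <- function(n, range, fraction, cutoff) {
  if (is.null(fraction)) return(rlogunif(n, range))
  if (fraction < 0 || fraction > 1) stop("substrate fraction not in [0, 1]")
  if (cutoff <= range[1] || cutoff >= range[2])
    stop("substrate cutoff outside the efflux-ratio range")
  hi <- stats::runif(n) < fraction
  out <- numeric(n)
  out[hi] <- rlogunif(sum(hi), c(cutoff, range[2]))
  out[!hi] <- rlogunif(sum(!hi), c(range[1], cutoff))
  out
}

#' Transporter substrate class from in vitro efflux ratios
#'
#' Classifies a compound by the standard substrate cutoffs: MDR1
#' substrate if its MDCK-MDR1 efflux ratio is at least 6.0, BCRP
#' substrate if its MDCK-BCRP efflux ratio is at least 2.5, `dual` if
#' both, `non-substrate` otherwise.  Boundary values count as
#' substrates (inclusive cutoffs).
#'
#' @param er_mdr1,er_bcrp Positive in vitro efflux ratios.
#' @return Character vector in
#'   `{"MDR1", "BCRP", "dual", "non-substrate"}`.
#' @examples
#' substrate_class(c(10, 1, 8, 1), c(1, 3, 4, 1))
#' @export
substrate_class <- function(er_mdr1, er_bcrp) {
  if (any(er_mdr1 <= 0) || any(er_bcrp <= 0))
    stop("efflux ratios must be positive")
  m <- er_mdr1 >= 6.0
  b <- er_bcrp >= 2.5
  out <- rep("non-substrate", length(m))
  out[m & !b] <- "MDR1"
  out[!m & b] <- "BCRP"
  out[m & b] <- "dual"
  out
}
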