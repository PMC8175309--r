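# Species physiology registry and scaling-parameter sets.

.SPECIES <- c("rat", "monkey", "human")

# Fixed physiological constants per species:
#   x_brain      g brain / kg body weight
#   cl_bulkflow  CSF bulk flow clearance, L/h/kg body weight
#   q_alb        CSF:plasma albumin concentration ratio
#   body_weight_ref  reference body weight, kg (documentation only)
.PHYSIOLOGY <- list(
  rat    = list(species = "rat",    x_brain = 7.2, cl_bulkflow = 0.000528,
                q_alb = 0.003, body_weight_ref = 0.25),
  monkey = list(species = "monkey", x_brain = 18,  cl_bulkflow = 0.000492,
                q_alb = 0.002, body_weight_ref = 5),
  human  = list(species = "human",  x_brain = 20,  cl_bulkflow = 0.000300,
                q_alb = 0.005, body_weight_ref = 70)
)

#' Species physiology constants
#'
#' Fixed physiological constants used by the CNS steady-state disposition
#' model: brain weight per kg body weight (`x_brain`, g/kg), CSF bulk flow
#' clearance (`cl_bulkflow`, L/h/kg), and the CSF-to-plasma albumin
#' concentration ratio (`q_alb`, dimensionless) used to derive the unbound
#' fraction in CSF from the plasma unbound fraction.
#'
#' These are physiological values, not fitted quantities; the registry is
#' read-only and covers rats, cynomolgus monkeys, and humans.
#'
#' @param species One of `"rat"`, `"monkey"`, `"human"`.
#' @return An object of class `species_physiology`: a list with elements
#'   `species`, `x_brain`, `cl_bulkflow`, `q_alb`, `body_weight_ref`.
#' @examples
#' species_physiology("rat")$cl_bulkflow
#' @export
species_physiology <- function(species = c("rat", "monkey", "human")) {
  species <- match.arg(species)
  structure(.PHYSIOLOGY[[species]], class = "species_physiology")
}

#' @export
print.species_physiology <- function(x, ...) {
  cat(sprintf("Species physiology: %s (reference body weight %g kg)\n",
              x$species, x$body_weight_ref))
  cat(sprintf("  brain weight      %g g/kg body weight\n", x$x_brain))
  cat(sprintf("  CSF bulk flow     %g L/h/kg\n", x$cl_bulkflow))
  cat(sprintf("  Q_alb (CSF:plasma albumin) %g\n", x$q_alb))
  invisible(x)
}

#' Construct a scaling-parameter set
#'
#' Bundles the four species-specific scaling factors of the model:
#' `alpha` and `beta` scale the in vitro MDR1 and BCRP efflux ratios to in
#' vivo efflux activity (relative activity factors when fitted, relative
#' expression factors when proteomics-derived), while `gamma` and `sigma`
#' are the ratios of passive blood-brain barrier permeability to the
#' blood-CSF-barrier and ependymal-layer permeabilities, respectively.
#'
#' @param alpha,beta Nonnegative efflux scalers for MDR1 and BCRP.
#' @param gamma,sigma Positive structural permeability ratios. `Inf` is
#'   accepted and handled as an analytic limit by the prediction functions.
#' @param species Species the set applies to.
#' @param mode `"RAF"` (fitted relative activity factors) or `"REF"`
#'   (relative expression factors).
#' @param se Optional named numeric of standard errors
#'   (`alpha`, `beta`, `gamma`, `sigma`).
#' @return An object of class `scaling_params`.
#' @seealso [raf_params()], [ref_params()] for the built-in fitted sets.
#' @examples
#' scaling_params(0.4, 1.4, 1900, 1000, species = "rat")
#' @export
scaling_params <- function(alpha, beta, gamma, sigma,
                           species = c("rat", "monkey", "human"),
                           mode = c("RAF", "REF"), se = NULL) {
  species <- match.arg(species)
  mode <- match.arg(mode)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0,
            is.numeric(beta), length(beta) == 1L, beta >= 0,
            is.numeric(gamma), length(gamma) == 1L, gamma > 0,
            is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  if (!is.null(se)) {
    se <- se[c("alpha", "beta", "gamma", "sigma")]
    names(se) <- c("alpha", "beta", "gamma", "sigma")
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma, sigma = sigma,
                 species = species, mode = mode, se = se),
            class = "scaling_params")
}

#' @export
print.scaling_params <- function(x, ...) {
  cat(sprintf("%s scaling parameters (%s):\n", x$mode, x$species))
  est <- c(alpha = x$alpha, beta = x$beta, gamma = x$gamma, sigma = x$sigma)
  if (!is.null(x$se)) {
    cv <- 100 * x$se / est
    for (p in names(est))
      cat(sprintf("  %-6s %10.4g ± %.4g (%%CV %.0f)\n",
                  p, est[[p]], x$se[[p]], cv[[p]]))
  } else {
    for (p in names(est)) cat(sprintf("  %-6s %10.4g\n", p, est[[p]]))
  }
  invisible(x)
}

#' @export
coef.scaling_params <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta,
    gamma = object$gamma, sigma = object$sigma)
}

# RAF sets fitted simultaneously to observed log Kpuu,brain and Kpuu,CSF
# per species; SEs are the reported asymptotic standard errors.
.RAF <- list(
  rat    = list(est = c(alpha = 0.395, beta = 1.368, gamma = 1910, sigma = 1054),
                se  = c(alpha = 0.149, beta = 0.697, gamma = 1018, sigma = 1172)),
  monkey = list(est = c(alpha = 0.126, beta = 0.638, gamma = 1853, sigma = 530),
                se  = c(alpha = 0.075, beta = 0.398, gamma = 2515, sigma = 945)),
  human  = list(est = c(alpha = 0.096, beta = 2.054, gamma = 1468, sigma = 967),
                se  = c(alpha = 0.150, beta = 3.341, gamma = 1774, sigma = 1676))
)

# Internally calibrated REF values for alpha/beta; gamma and sigma are the
# structural ratios shared with the RAF fit for the same species.
.REF <- list(
  rat    = c(alpha = 0.240, beta = 0.437),
  monkey = c(alpha = 0.059, beta = 1.248),
  human  = c(alpha = 0.077, beta = 0.716)
)

#' Built-in fitted RAF parameter sets
#'
#' Relative-activity-factor scaling parameters estimated by simultaneous
#' log-space fitting to observed unbound brain and CSF partition
#' coefficients in each species, with their standard errors.
#'
#' @param species One of `"rat"`, `"monkey"`, `"human"`.
#' @return A [scaling_params()] object with `mode = "RAF"`.
#' @examples
#' coef(raf_params("rat"))
#' @export
raf_params <- function(species = c("rat", "monkey", "human")) {
  species <- match.arg(species)
  p <- .RAF[[species]]
  scaling_params(p$est[["alpha"]], p$est[["beta"]],
                 p$est[["gamma"]], p$est[["sigma"]],
                 species = species, mode = "RAF", se = p$se)
}

#' Built-in calibrated REF parameter sets
#'
#' Relative-expression-factor values for the MDR1 (`alpha`) and BCRP
#' (`beta`) scalers, derived from brain-microvessel transporter proteomics
#' and calibrated onto the internal efflux-ratio scale by cross-laboratory
#' regression of shared scaler compounds.  The structural ratios `gamma`
#' and `sigma` are shared with the RAF fit for the same species.
#'
#' @inheritParams raf_params
#' @return A [scaling_params()] object with `mode = "REF"`.
#' @export
ref_params <- function(species = c("rat", "monkey", "human")) {
  species <- match.arg(species)
  ab <- .REF[[species]]
  gs <- .RAF[[species]]$est
  scaling_params(ab[["alpha"]], ab[["beta"]], gs[["gamma"]], gs[["sigma"]],
                 species = species, mode = "REF")
}

#' Read or write scaling parameters as JSON
#'
#' Serializes a [scaling_params()] object to a small JSON document
#' (fields: `alpha`, `beta`, `gamma`, `sigma`, `species`, `mode`,
#' optional `se`) and reads it back.
#'
#' @param x A `scaling_params` object.
#' @param path File path.
#' @return `write_scaling_params()` returns `path` invisibly;
#'   `read_scaling_params()` returns a `scaling_params` object.
#' @export
write_scaling_params <- function(x, path) {
  stopifnot(inherits(x, "scaling_params"))
  out <- list(alpha = x$alpha, beta = x$beta, gamma = x$gamma,
              sigma = x$sigma, species = x$species, mode = x$mode)
  if (!is.null(x$se)) out$se <- as.list(x$se)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scaling_params
#' @export
read_scaling_params <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  se <- if (!is.null(j$se)) unlist(j$se) else NULL
  scaling_params(j$alpha, j$beta, j$gamma, j$sigma,
                 species = j$species, mode = j$mode, se = se)
}
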