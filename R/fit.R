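# Simultaneous log-space estimation of the species scaling factors.

#' Fit the CNS disposition model scaling factors to observed Kp,uu data
#'
#' Estimates the four species-specific scaling factors — the relative
#' activity factors `alpha` (MDR1) and `beta` (BCRP) and the structural
#' permeability ratios `gamma` (BBB:BCSFB) and `sigma` (BBB:ependymal
#' layer) — by minimizing the pooled sum of squared log10 residuals
#' \deqn{\sum_i [\log_{10} \hat K_{p,uu,brain,i} - \log_{10} K_{p,uu,brain,i}]^2
#'     + \sum_j [\log_{10} \hat K_{p,uu,CSF,j} - \log_{10} K_{p,uu,CSF,j}]^2}
#' over a single-species compound table, both endpoints fitted
#' simultaneously with equal weight.  A compound missing one endpoint
#' contributes only its available residual.
#'
#' Optimization runs in log10 parameter space (the parameters are
#' positive and span orders of magnitude) with bounded L-BFGS-B from
#' `n_starts` multistart points drawn log-uniformly within the bounds
#' under a fixed seed; the best local optimum is returned.  Standard
#' errors come from the Gauss-Newton curvature of the objective at the
#' optimum (numeric Jacobian of the log10 predictions with respect to
#' the raw parameters), with %CV = 100 SE / estimate.
#'
#' @param data Compound table (one species) with columns `logD`, `MW`,
#'   `ER_MDR1`, `ER_BCRP` and observed endpoints `Kpuu_brain_obs` and/or
#'   `Kpuu_csf_obs` (`NA` for a missing endpoint).
#' @param species Species fitted; taken from a `species` column if
#'   present and unique.
#' @param bounds Named list of length-2 numeric ranges for `alpha`,
#'   `beta` (default `[1e-6, 100]`) and `gamma`, `sigma` (default
#'   `[1, 1e6]`).  The lower `alpha`/`beta` bound 1e-6 is the practical
#'   zero of the log-scale search.
#' @param n_starts Number of multistart points (default 32).
#' @param seed Integer seed controlling the multistart draws.
#' @param maxit Maximum L-BFGS-B iterations per start.
#' @return An object of class `kpuu_fit` with components `coefficients`,
#'   `se`, `cv`, `vcov`, `objective`, `n_brain`, `n_csf`, `converged`,
#'   `multistart_best_of`, `seed`, `params` (a [scaling_params()]
#'   object), `data`, `fitted`, and `call`.  Supports `print()`,
#'   `summary()`, `coef()`, `vcov()`, `predict()`, `fitted()`,
#'   `residuals()`, `plot()`, and `simulate()`.
#' @examples
#' set.seed(1)
#' d <- simulate_compounds(40, species = "rat", noise_aafe = 1.5, seed = 7)
#' fit <- fit_kpuu(d, n_starts = 8)
#' coef(fit)
#' @export
fit_kpuu <- function(data, species = NULL,
                     bounds = list(alpha = c(1e-6, 100),
                                   beta  = c(1e-6, 100),
                                   gamma = c(1, 1e6),
                                   sigma = c(1, 1e6)),
                     n_starts = 32, seed = 1, maxit = 500) {
  cl <- match.call()
  if (is.null(species)) {
    sp <- unique(as.character(data$species))
    if (length(sp) != 1L)
      stop("supply `species` or a single-species `species` column")
    species <- sp
  }
  physiology <- species_physiology(species)

  need <- c("logD", "MW", "ER_MDR1", "ER_BCRP")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("compound table lacks column(s): ", paste(miss, collapse = ", "))
  obs_b <- if ("Kpuu_brain_obs" %in% names(data)) data$Kpuu_brain_obs
           else rep(NA_real_, nrow(data))
  obs_c <- if ("Kpuu_csf_obs" %in% names(data)) data$Kpuu_csf_obs
           else rep(NA_real_, nrow(data))
  if (any(obs_b <= 0, na.rm = TRUE) || any(obs_c <= 0, na.rm = TRUE))
    stop("observed Kp,uu values must be positive")
  has_b <- !is.na(obs_b); has_c <- !is.na(obs_c)
  n_b <- sum(has_b); n_c <- sum(has_c)
  if (n_b + n_c < 4L)
    stop("identifiability: need at least 4 observed endpoints to fit ",
         "4 parameters (have ", n_b + n_c, ")")
  act_m <- pmax(data$ER_MDR1, 1) - 1
  act_b <- pmax(data$ER_BCRP, 1) - 1
  if (all(act_m == 0) && all(act_b == 0))
    stop("identifiability: all efflux ratios are <= 1, so f(ERs) is ",
         "identically zero and alpha/beta are unidentifiable")
  if (all(act_m == 0))
    warning("all MDR1 efflux ratios <= 1: alpha is unidentifiable")
  if (all(act_b == 0))
    warning("all BCRP efflux ratios <= 1: beta is unidentifiable")

  ps1 <- compute_ps1(data$logD, data$MW, physiology)
  k <- physiology$cl_bulkflow
  lobs <- c(log10(obs_b[has_b]), log10(obs_c[has_c]))

  resid_fun <- function(p) {  # p = raw (alpha, beta, gamma, sigma)
    fe <- p[1] * act_m + p[2] * act_b
    t <- .kpuu_terms(ps1, fe, p[3], p[4], k)
    c(log10(t$num_brain[has_b] / t$den[has_b]),
      log10(t$num_csf[has_c] / t$den[has_c])) - lobs
  }
  obj <- function(theta) sum(resid_fun(10^theta)^2)

  bl <- log10(rbind(alpha = bounds$alpha, beta = bounds$beta,
                    gamma = bounds$gamma, sigma = bounds$sigma))
  starts <- multistart_points(bl, n_starts, seed)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = bl[, 1], upper = bl[, 2],
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("optimization failed from every multistart point")

  est <- 10^best$par
  names(est) <- c("alpha", "beta", "gamma", "sigma")

  # Gauss-Newton curvature SEs on the raw parameter scale
  se <- rep(NA_real_, 4); names(se) <- names(est)
  V <- matrix(NA_real_, 4, 4, dimnames = list(names(est), names(est)))
  n_res <- n_b + n_c
  if (n_res > 4L) {
    J <- num_jacobian(resid_fun, est)
    s2 <- best$value / (n_res - 4L)
    JtJ <- crossprod(J)
    Vt <- tryCatch(s2 * solve(JtJ), error = function(e) NULL)
    if (!is.null(Vt)) {
      V[] <- Vt
      se <- sqrt(pmax(diag(Vt), 0))
      names(se) <- names(est)
    }
  }

  params <- scaling_params(est[["alpha"]], est[["beta"]],
                           est[["gamma"]], est[["sigma"]],
                           species = species, mode = "RAF",
                           se = if (!all(is.na(se))) se else NULL)
  fitted_tab <- predict_kpuu(data, params, physiology)
  structure(list(
    coefficients = est, se = se, cv = 100 * se / est, vcov = V,
    objective = best$value, n_brain = n_b, n_csf = n_c,
    converged = best$convergence == 0, multistart_best_of = nrow(starts),
    seed = seed, species = species, mode = "RAF", params = params,
    data = data, fitted = fitted_tab,
    residuals = stats::setNames(resid_fun(est),
      c(paste0("brain.", which(has_b)), paste0("csf.", which(has_c)))),
    call = cl), class = "kpuu_fit")
}

# Log-uniform multistart grid: the midpoint of the log-bounds box plus
# n - 1 seeded random draws.  The caller's RNG state is untouched.
multistart_points <- function(log_bounds, n, seed) {
  mid <- rowMeans(log_bounds)
  if (n <= 1L) return(matrix(mid, nrow = 1))
  draws <- with_local_seed(seed, {
    matrix(stats::runif(4 * (n - 1L),
                        min = rep(log_bounds[, 1], n - 1L),
                        max = rep(log_bounds[, 2], n - 1L)),
           ncol = 4, byrow = TRUE)
  })
  rbind(mid, draws)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

# Central-difference Jacobian of a vector-valued function.
num_jacobian <- function(f, x, rel_h = 1e-5) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- max(rel_h * abs(x[j]), 1e-10)
    xp <- x; xm <- x
    xp[j] <- x[j] + h; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' @export
print.kpuu_fit <- function(x, digits = 4, ...) {
  cat(sprintf("CNS Kp,uu scaling-factor fit (%s, %s)\n", x$species, x$mode))
  cat(sprintf("  %d brain + %d CSF observations; SS(log10 residuals) = %.4g\n",
              x$n_brain, x$n_csf, x$objective))
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se, `%CV` = x$cv)
  print(signif(tab, digits))
  if (!x$converged) cat("  (optimizer did not report convergence)\n")
  invisible(x)
}

#' @export
coef.kpuu_fit <- function(object, ...) object$coefficients

#' @export
vcov.kpuu_fit <- function(object, ...) object$vcov

#' @export
fitted.kpuu_fit <- function(object, ...) object$fitted

#' Residuals of a Kp,uu scaling-factor fit
#'
#' Log10 prediction residuals (`log10(pred) - log10(obs)`), i.e. the
#' signed log fold errors the objective minimizes.
#'
#' @param object A `kpuu_fit` object.
#' @param endpoint `"both"` (stacked, named `brain.<row>` / `csf.<row>`),
#'   `"brain"`, or `"csf"`.
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
residuals.kpuu_fit <- function(object, endpoint = c("both", "brain", "csf"),
                               ...) {
  endpoint <- match.arg(endpoint)
  r <- object$residuals
  if (endpoint == "both") return(r)
  r[startsWith(names(r), endpoint)]
}

#' Predict from a fitted Kp,uu model
#'
#' @param object A `kpuu_fit` object.
#' @param newdata Optional compound table (`logD`, `MW`, `ER_MDR1`,
#'   `ER_BCRP`); defaults to the fitting data.
#' @param ... Unused.
#' @return A prediction table as from [predict_kpuu()].
#' @export
predict.kpuu_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  predict_kpuu(newdata, object$params)
}

#' Summary of a Kp,uu scaling-factor fit
#'
#' Parameter estimates with SE and %CV, plus the prediction-accuracy
#' statistics (AFE, AAFE, RMSE, 3-fold bins) for each observed endpoint.
#'
#' @param object A `kpuu_fit` object.
#' @param ... Unused.
#' @return A `summary.kpuu_fit` list with elements `parameters`
#'   (matrix) and `performance` (data frame, one row per endpoint).
#' @export
summary.kpuu_fit <- function(object, ...) {
  perf <- list()
  d <- object$data; f <- object$fitted
  if (object$n_brain > 0) {
    i <- !is.na(d$Kpuu_brain_obs)
    perf$brain <- evaluate_predictions(f$kpuu_brain[i], d$Kpuu_brain_obs[i],
                                       endpoint = "brain",
                                       species = object$species,
                                       mode = object$mode)
  }
  if (object$n_csf > 0) {
    i <- !is.na(d$Kpuu_csf_obs)
    perf$csf <- evaluate_predictions(f$kpuu_csf[i], d$Kpuu_csf_obs[i],
                                     endpoint = "csf",
                                     species = object$species,
                                     mode = object$mode)
  }
  structure(list(
    species = object$species, mode = object$mode,
    parameters = cbind(Estimate = object$coefficients,
                       `Std. Error` = object$se, `%CV` = object$cv),
    performance = do.call(rbind, perf),
    objective = object$objective, converged = object$converged,
    multistart_best_of = object$multistart_best_of, seed = object$seed),
    class = "summary.kpuu_fit")
}

#' @export
print.summary.kpuu_fit <- function(x, digits = 4, ...) {
  cat(sprintf("CNS Kp,uu scaling-factor fit (%s, %s)\n\n", x$species, x$mode))
  cat("Fitted parameters:\n")
  print(signif(x$parameters, digits))
  cat(sprintf("\nSS(log10 residuals) = %.4g; best of %d starts (seed %d)%s\n",
              x$objective, x$multistart_best_of, x$seed,
              if (x$converged) "" else "; NOT converged"))
  if (!is.null(x$performance)) {
    cat("\nPredictive performance:\n")
    print(x$performance, row.names = FALSE, digits = digits)
  }
  invisible(x)
}

#' Observed-versus-predicted plot for a fitted Kp,uu model
#'
#' Log-log scatter of observed against predicted partition coefficients
#' for the fitted endpoints, with the unity line (solid) and the 3-fold
#' band (dashed) conventionally used to judge CNS penetration
#' predictions.
#'
#' @param x A `kpuu_fit` object.
#' @param ... Passed to [plot_kpuu_correlation()].
#' @return Invisibly, `x`.
#' @export
plot.kpuu_fit <- function(x, ...) {
  d <- x$data; f <- x$fitted
  obs <- c(if (x$n_brain) d$Kpuu_brain_obs, if (x$n_csf) d$Kpuu_csf_obs)
  pred <- c(if (x$n_brain) f$kpuu_brain, if (x$n_csf) f$kpuu_csf)
  grp <- c(if (x$n_brain) rep("brain", nrow(d)),
           if (x$n_csf) rep("CSF", nrow(d)))
  keep <- !is.na(obs)
  plot_kpuu_correlation(obs[keep], pred[keep], group = grp[keep],
                        main = sprintf("%s (%s)", x$species, x$mode), ...)
  invisible(x)
}

#' Simulate compound datasets from a fitted model
#'
#' Draws synthetic compound tables whose observed Kp,uu values are
#' generated from the fitted scaling parameters with multiplicative
#' log-normal noise, mirroring the structure of the fitting data.
#'
#' @param object A `kpuu_fit` object.
#' @param nsim Number of datasets.
#' @param seed Integer seed (default: the fit's seed).
#' @param n Compounds per dataset (default: rows of the fitting data).
#' @param noise_aafe Target AAFE of the observation noise (default 2).
#' @param ... Passed to [simulate_compounds()].
#' @return A list of `nsim` compound tables.
#' @export
simulate.kpuu_fit <- function(object, nsim = 1, seed = NULL,
                              n = nrow(object$data), noise_aafe = 2, ...) {
  if (is.null(seed)) seed <- object$seed
  lapply(seq_len(nsim), function(i)
    simulate_compounds(n, species = object$species, params = object$params,
                       noise_aafe = noise_aafe, seed = seed + i - 1L, ...))
}
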