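# Prediction-accuracy statistics: fold errors, RMSE, 3-fold bins, and
# paired comparisons between prediction modes.

check_pairs <- function(pred, obs, positive = TRUE) {
  if (length(pred) == 0L || length(obs) == 0L)
    stop("empty prediction/observation vectors")
  if (length(pred) != length(obs))
    stop("pred and obs must have equal length")
  if (positive && (any(pred <= 0) || any(obs <= 0)))
    stop("fold-error statistics require positive values")
  invisible(TRUE)
}

#' Average fold error (AFE)
#'
#' Geometric mean of the prediction/observation ratios,
#' \eqn{10^{\mathrm{mean}(\log_{10}(pred/obs))}}: an accuracy index whose
#' log-symmetric deviations cancel (an AFE of 1 means no systematic
#' bias; above 1, over-prediction on average).
#'
#' @param pred,obs Positive numeric vectors of equal length.
#' @return Dimensionless scalar.
#' @examples
#' afe(c(2, 0.5), c(1, 1))   # 1: bias cancels
#' @export
afe <- function(pred, obs) {
  check_pairs(pred, obs)
  10^mean(log10(pred / obs))
}

#' Absolute average fold error (AAFE)
#'
#' \eqn{10^{\mathrm{mean}(|\log_{10}(pred/obs)|)}}: the typical fold
#' discrepancy regardless of direction, always at least 1 and at least
#' `max(afe, 1/afe)`.
#'
#' @inheritParams afe
#' @return Dimensionless scalar `>= 1`.
#' @examples
#' aafe(c(2, 0.5), c(1, 1))  # 2: both pairs are 2-fold off
#' @export
aafe <- function(pred, obs) {
  check_pairs(pred, obs)
  10^mean(abs(log10(pred / obs)))
}

#' Root mean squared error on the linear scale
#'
#' \eqn{\sqrt{\mathrm{mean}((pred - obs)^2)}} in the units of the inputs
#' (Kp,uu here): a precision index dominated by the well-penetrant
#' compounds, complementing the fold-error accuracy indices.
#'
#' @param pred,obs Numeric vectors of equal length.
#' @return Nonnegative scalar in the input units.
#' @export
rmse <- function(pred, obs) {
  check_pairs(pred, obs, positive = FALSE)
  sqrt(mean((pred - obs)^2))
}

#' Three-fold classification of prediction ratios
#'
#' Classifies each prediction/observation pair by its ratio: above
#' 3-fold, within 3-fold of unity, or below 1/3.  Boundary ratios of
#' exactly 3 or 1/3 count as within (`inclusive = TRUE`, the default);
#' set `inclusive = FALSE` for strict inequalities.
#'
#' @inheritParams afe
#' @param inclusive Whether the band boundaries belong to "within".
#' @param fold Band half-width on the ratio scale (default 3).
#' @return Named numeric `c(above, within, below)` of percentages
#'   rounded to integers (Table-style display); the unrounded
#'   percentages are kept in attribute `"raw"`.
#' @examples
#' threefold_bins(c(10, 1, 0.1), c(1, 1, 1))
#' @export
threefold_bins <- function(pred, obs, inclusive = TRUE, fold = 3) {
  check_pairs(pred, obs)
  r <- pred / obs
  if (inclusive) {
    above <- r > fold; below <- r < 1 / fold
  } else {
    above <- r >= fold; below <- r <= 1 / fold
  }
  raw <- 100 * c(above = mean(above),
                 within = mean(!above & !below),
                 below = mean(below))
  structure(round(raw), raw = raw)
}

#' One-row evaluation summary for an endpoint
#'
#' Bundles the accuracy and precision statistics for one species x
#' endpoint x parameter mode into a report row mirroring the standard
#' predictive-performance table layout.
#'
#' @inheritParams afe
#' @param endpoint,species,mode Labels carried into the row.
#' @param inclusive Passed to [threefold_bins()].
#' @return One-row data frame: `species`, `endpoint`, `mode`, `n`,
#'   `pct_above`, `pct_within`, `pct_below`, `afe`, `aafe`, `rmse`.
#' @export
evaluate_predictions <- function(pred, obs, endpoint = NA, species = NA,
                                 mode = NA, inclusive = TRUE) {
  keep <- !is.na(pred) & !is.na(obs)
  pred <- pred[keep]; obs <- obs[keep]
  check_pairs(pred, obs)
  bins <- threefold_bins(pred, obs, inclusive = inclusive)
  data.frame(species = species, endpoint = endpoint, mode = mode,
             n = length(pred),
             pct_above = bins[["above"]], pct_within = bins[["within"]],
             pct_below = bins[["below"]],
             afe = afe(pred, obs), aafe = aafe(pred, obs),
             rmse = rmse(pred, obs), stringsAsFactors = FALSE)
}

#' Paired comparison of two prediction modes
#'
#' Tests whether two sets of predictions (e.g. RAF-based versus
#' REF-based) differ in bias, accuracy, or precision against common
#' observations, via paired two-sided t-tests on three per-compound
#' error measures: the log10 fold error (bias), its absolute value
#' (accuracy), and the squared linear residual (precision).
#'
#' When the paired differences are all exactly zero the t statistic is
#' undefined and the row is reported as no difference (`t = NA`,
#' `p = 1`); a constant nonzero difference (zero variance, nonzero
#' mean) is reported as `t = +/-Inf`, `p = 0`.
#'
#' @param pred_a,pred_b Positive prediction vectors (e.g. RAF and REF).
#' @param obs Positive observations, same length; `n >= 3`.
#' @param labels Length-2 character labels for the two modes.
#' @return Data frame with one row per measure: `measure`, `mean_a`,
#'   `mean_b`, `t`, `df`, `p`.
#' @examples
#' obs <- c(0.1, 0.3, 0.8, 0.05)
#' compare_raf_ref(obs * 1.2, obs * 2.5, obs)
#' @export
compare_raf_ref <- function(pred_a, pred_b, obs, labels = c("RAF", "REF")) {
  check_pairs(pred_a, obs); check_pairs(pred_b, obs)
  if (length(obs) < 3L) stop("paired comparison needs n >= 3")
  measures <- list(
    fold_error = function(p) log10(p / obs),
    abs_fold_error = function(p) abs(log10(p / obs)),
    squared_residual = function(p) (p - obs)^2)
  rows <- lapply(names(measures), function(m) {
    ea <- measures[[m]](pred_a); eb <- measures[[m]](pred_b)
    d <- ea - eb
    if (stats::sd(d) == 0) {
      df <- length(d) - 1L
      if (all(d == 0)) { t <- NA_real_; p <- 1 }
      else { t <- sign(mean(d)) * Inf; p <- 0 }
    } else {
      tt <- stats::t.test(ea, eb, paired = TRUE)
      t <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
    }
    data.frame(measure = m, mean_a = mean(ea), mean_b = mean(eb),
               t = t, df = df, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- paste0("mean_", tolower(labels))
  out
}
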