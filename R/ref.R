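# REF calibration across laboratories and RAF/REF comparison.

#' Calibrate reported REF values onto the internal efflux-ratio scale
#'
#' Relative expression factors (REF) reported in the literature apply on
#' the efflux-ratio scale of the laboratory that measured them.  To use
#' them with internally measured efflux ratios, the in vitro efflux
#' ratios of shared scaler compounds (conventionally prazosin, quinidine,
#' metoprolol, and pitavastatin) measured in both laboratories are
#' regressed against each other per cell line, and the reported REF is
#' corrected by the regression slope.
#'
#' The regression is a zero-intercept simple linear regression (a pure
#' rescaling) of internal on literature efflux ratio; with
#' `internal = slope * literature`, the calibrated REF is
#' `reported / slope` (`direction = "divide"`, the default) so that the
#' product `REF * (ER - 1)` is preserved on the internal scale, or
#' `reported * slope` if the opposite convention is wanted.
#'
#' @param scalers Data frame with columns `compound_id`, `cell_line`
#'   (`"MDCK_MDR1"` or `"MDCK_BCRP"`), `er_internal`, `er_literature`;
#'   at least two scaler compounds per cell line.
#' @param ref_reported Data frame with columns `species`, `alpha`,
#'   `beta`: the reported REF values to calibrate.
#' @param direction `"divide"` (default) or `"multiply"`.
#' @return An object of class `ref_calibration`: list with `slopes`
#'   (named numeric, `mdr1` and `bcrp`), `scaler_compounds`,
#'   `ref_reported`, `ref_calibrated`, `direction`.
#' @examples
#' sc <- data.frame(
#'   compound_id = rep(c("prazosin", "quinidine", "metoprolol",
#'                       "pitavastatin"), 2),
#'   cell_line = rep(c("MDCK_MDR1", "MDCK_BCRP"), each = 4),
#'   er_literature = c(2, 30, 1, 1.5, 10, 1, 1, 6),
#'   er_internal   = c(2, 30, 1, 1.5, 10, 1, 1, 6))
#' ref <- data.frame(species = "rat", alpha = 0.24, beta = 0.437)
#' calibrate_ref(sc, ref)$slopes   # identity calibration
#' @export
calibrate_ref <- function(scalers, ref_reported,
                          direction = c("divide", "multiply")) {
  direction <- match.arg(direction)
  need <- c("compound_id", "cell_line", "er_internal", "er_literature")
  miss <- setdiff(need, names(scalers))
  if (length(miss))
    stop("scaler table lacks column(s): ", paste(miss, collapse = ", "))
  slope_for <- function(line) {
    d <- scalers[scalers$cell_line == line, ]
    if (nrow(d) < 2L)
      stop("need >= 2 shared scaler compounds for ", line)
    if (stats::var(d$er_literature) == 0 && length(unique(d$er_literature)) == 1L
        && nrow(d) < 2L || all(d$er_literature == 0))
      stop("degenerate regression: literature efflux ratios have no spread")
    if (sum(d$er_literature^2) == 0)
      stop("degenerate regression: literature efflux ratios are all zero")
    co <- stats::coef(stats::lm(er_internal ~ 0 + er_literature, data = d))
    s <- unname(co[["er_literature"]])
    if (!is.finite(s) || s <= 0)
      stop("degenerate regression: non-positive slope for ", line)
    s
  }
  slopes <- c(mdr1 = slope_for("MDCK_MDR1"), bcrp = slope_for("MDCK_BCRP"))
  adj <- function(v, s) if (direction == "divide") v / s else v * s
  cal <- ref_reported
  cal$alpha <- adj(ref_reported$alpha, slopes[["mdr1"]])
  cal$beta <- adj(ref_reported$beta, slopes[["bcrp"]])
  structure(list(slopes = slopes,
                 scaler_compounds = unique(scalers$compound_id),
                 ref_reported = ref_reported, ref_calibrated = cal,
                 direction = direction),
            class = "ref_calibration")
}

#' @export
print.ref_calibration <- function(x, ...) {
  cat("REF cross-laboratory calibration\n")
  cat(sprintf("  scalers: %s\n", paste(x$scaler_compounds, collapse = ", ")))
  cat(sprintf("  slopes (internal ~ 0 + literature): MDR1 %.3g, BCRP %.3g\n",
              x$slopes[["mdr1"]], x$slopes[["bcrp"]]))
  cat(sprintf("  calibrated REF (reported %sd by slope):\n",
              if (x$direction == "divide") "divide" else "multiplie"))
  print(x$ref_calibrated, row.names = FALSE)
  invisible(x)
}

#' RAF-to-REF ratios for the efflux scalers
#'
#' Element-wise quotient of the fitted relative activity factors by the
#' corresponding relative expression factors for one species.  A ratio
#' near 1 means the fitted in vivo activity tracks the measured
#' transporter protein level.
#'
#' @param raf A [scaling_params()] object with `mode = "RAF"`.
#' @param ref A [scaling_params()] object with `mode = "REF"`, same
#'   species.
#' @return Named numeric `c(alpha = ..., beta = ...)` with attribute
#'   `"display"` holding the two-significant-figure values used in
#'   reports.
#' @examples
#' raf_to_ref_ratio(raf_params("rat"), ref_params("rat"))
#' @export
raf_to_ref_ratio <- function(raf, ref) {
  raf <- as_scaling(raf); ref <- as_scaling(ref)
  if (raf$species != ref$species)
    stop("RAF and REF parameter sets are for different species")
  if (raf$mode != "RAF" || ref$mode != "REF")
    stop("expected a RAF set and a REF set, in that order")
  if (ref$alpha == 0 || ref$beta == 0)
    stop("REF values must be nonzero")
  r <- c(alpha = raf$alpha / ref$alpha, beta = raf$beta / ref$beta)
  attr(r, "display") <- signif(r, 2)
  r
}
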