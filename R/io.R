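# Compound-table file I/O and correlation plotting.

.COMPOUND_COLS <- c("compound_id", "species", "logD", "MW", "ER_MDR1",
                    "ER_BCRP", "fu_plasma", "fu_brain_prime", "dilution",
                    "C_plasma", "C_brain", "C_CSF", "Kpuu_brain_obs",
                    "Kpuu_csf_obs", "provenance")

#' Read or write a compound table
#'
#' The on-disk compound table is comma-separated UTF-8 text with a
#' header and `.` as the decimal mark.  Recognized columns:
#' `compound_id`, `species`, `logD`, `MW`, `ER_MDR1`, `ER_BCRP`,
#' `fu_plasma`, `fu_brain_prime`, `dilution`, `C_plasma`, `C_brain`,
#' `C_CSF`, `Kpuu_brain_obs`, `Kpuu_csf_obs`, `provenance`.  Only the
#' columns a given workflow needs are required (prediction needs `logD`,
#' `MW`, `ER_MDR1`, `ER_BCRP`; fitting additionally needs at least one
#' observed endpoint).  Unknown columns are kept; missing values are
#' empty fields or `NA`.
#'
#' @param path File path.
#' @param x Data frame to write.
#' @return `read_compound_table()` returns a data frame;
#'   `write_compound_table()` returns `path` invisibly.
#' @export
read_compound_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(d)) stop("empty compound table: ", path)
  num <- setdiff(.COMPOUND_COLS, c("compound_id", "species", "provenance"))
  for (col in intersect(num, names(d))) {
    v <- d[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(vn))
      if (length(bad))
        stop(sprintf("non-numeric value in column '%s', row(s) %s",
                     col, paste(bad, collapse = ", ")))
      v <- vn
    }
    d[[col]] <- v
  }
  d
}

#' @rdname read_compound_table
#' @export
write_compound_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Observed-versus-predicted Kp,uu correlation plot
#'
#' Log-log scatter of predicted against observed partition coefficients
#' with the unity line (solid) and the 3-fold acceptance band (dashed),
#' the conventional display for CNS penetration predictions.  Also
#' computes the least-squares slope of log10(pred) on log10(obs) as a
#' convenience (returned invisibly, shown in the legend).
#'
#' @param obs,pred Positive vectors of equal length.
#' @param group Optional factor for point colour (e.g. endpoint or
#'   substrate class).
#' @param fold Band half-width (default 3).
#' @param main Plot title.
#' @param xlab,ylab Axis labels.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the regression slope of log10 pred on log10 obs.
#' @export
plot_kpuu_correlation <- function(obs, pred, group = NULL, fold = 3,
                                  main = "Observed vs predicted Kp,uu",
                                  xlab = "Observed Kp,uu",
                                  ylab = "Predicted Kp,uu", ...) {
  check_pairs(pred, obs)
  lim <- range(c(obs, pred, obs * fold, obs / fold))
  col <- if (is.null(group)) "black"
         else grDevices::hcl.colors(nlevels(factor(group)),
                                    "Dark 3")[as.integer(factor(group))]
  graphics::plot(obs, pred, log = "xy", xlim = lim, ylim = lim,
                 pch = 19, col = col, main = main,
                 xlab = xlab, ylab = ylab, ...)
  graphics::abline(0, 1, untf = FALSE)  # on the log axes: unity
  xx <- 10^seq(log10(lim[1]), log10(lim[2]), length.out = 2)
  graphics::lines(xx, xx * fold, lty = 2)
  graphics::lines(xx, xx / fold, lty = 2)
  slope <- unname(stats::coef(stats::lm(log10(pred) ~ log10(obs)))[2])
  if (!is.null(group))
    graphics::legend("topleft", legend = levels(factor(group)),
                     col = grDevices::hcl.colors(nlevels(factor(group)),
                                                 "Dark 3"),
                     pch = 19, bty = "n")
  graphics::mtext(sprintf("log-log slope %.2f", slope), side = 3,
                  adj = 1, cex = 0.8)
  invisible(slope)
}
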