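# Scaling-factor estimation, REF cross-laboratory calibration, and the
# RAF/REF comparison.

test_that("noiseless generate-then-refit recovers the generating parameters", {
  truth <- par_custom(0.4, 1.4, 1900, 1000)
  d <- simulate_compounds(40, "rat", params = truth, noise_aafe = 1,
                          seed = 3)
  fit <- fit_kpuu(d, n_starts = 8, seed = 1)
  est <- coef(fit)
  expect_lt(abs(est[["alpha"]] / 0.4 - 1), 0.01)
  expect_lt(abs(est[["beta"]] / 1.4 - 1), 0.01)
  expect_lt(abs(est[["gamma"]] / 1900 - 1), 0.10)
  expect_lt(abs(est[["sigma"]] / 1000 - 1), 0.10)
  expect_true(fit$converged)
  expect_lt(fit$objective, 1e-8)
})

test_that("fit refuses unidentifiable datasets", {
  d <- simulate_compounds(20, "rat", noise_aafe = 1, seed = 2)
  d$ER_MDR1 <- 1; d$ER_BCRP <- 1
  expect_error(fit_kpuu(d, n_starts = 2), "unidentifiable")
  d2 <- simulate_compounds(20, "rat", noise_aafe = 1, seed = 2)[1:2, ]
  d2$Kpuu_csf_obs <- NA
  expect_error(fit_kpuu(d2, n_starts = 2), "identifiability")
})

test_that("row order does not affect the fit and duplication shrinks SEs", {
  d <- simulate_compounds(30, "rat", noise_aafe = 1.6, seed = 9)
  f1 <- fit_kpuu(d, n_starts = 8, seed = 1)
  f2 <- fit_kpuu(d[rev(seq_len(nrow(d))), ], n_starts = 8, seed = 1)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  expect_equal(f1$objective, f2$objective, tolerance = 1e-8)
  # duplicating every record: same estimates, SEs down by ~sqrt(2)
  fd <- fit_kpuu(rbind(d, d), n_starts = 8, seed = 1)
  expect_equal(coef(fd), coef(f1), tolerance = 1e-4)
  ratio <- fd$se / f1$se
  expect_true(all(abs(ratio - 1 / sqrt(2)) < 0.1))
})

test_that("records missing one endpoint contribute only that residual", {
  d <- simulate_compounds(30, "rat", noise_aafe = 1.4, seed = 12)
  d$Kpuu_csf_obs[1:10] <- NA
  fit <- fit_kpuu(d, n_starts = 8, seed = 1)
  expect_equal(fit$n_brain, 30)
  expect_equal(fit$n_csf, 20)
  expect_length(residuals(fit), 50)
  expect_length(residuals(fit, "csf"), 20)
  # objective equals the sum of squared reported residuals
  expect_equal(sum(residuals(fit)^2), fit$objective, tolerance = 1e-8)
})

test_that("fit methods are mutually consistent", {
  d <- simulate_compounds(25, "monkey", noise_aafe = 1.5, seed = 4)
  fit <- fit_kpuu(d, n_starts = 8, seed = 1)
  expect_s3_class(fit, "kpuu_fit")
  expect_identical(predict(fit), fitted(fit))
  nd <- toy_compounds()
  pr <- predict(fit, nd)
  expect_equal(pr$kpuu_brain,
               predict_kpuu(nd, fit$params)$kpuu_brain)
  s <- summary(fit)
  expect_s3_class(s, "summary.kpuu_fit")
  expect_equal(sort(unique(s$performance$endpoint)), c("brain", "csf"))
  expect_true(all(s$performance$n == 25))
  expect_output(print(fit), "scaling-factor fit")
  expect_output(print(s), "Predictive performance")
  # residuals really are log10(pred) - log10(obs)
  rb <- residuals(fit, "brain")
  expect_equal(unname(rb),
               log10(fitted(fit)$kpuu_brain) - log10(d$Kpuu_brain_obs))
})

test_that("REF calibration conventions: identity, pure rescaling, errors", {
  sc <- data.frame(
    compound_id = rep(c("prazosin", "quinidine", "metoprolol",
                        "pitavastatin"), 2),
    cell_line = rep(c("MDCK_MDR1", "MDCK_BCRP"), each = 4),
    er_literature = c(2.1, 28, 1.05, 1.4, 9, 1.1, 1.0, 5.5),
    er_internal   = c(2.1, 28, 1.05, 1.4, 9, 1.1, 1.0, 5.5))
  ref <- data.frame(species = c("rat", "human"),
                    alpha = c(0.24, 0.077), beta = c(0.437, 0.716))
  cal <- calibrate_ref(sc, ref)
  expect_equal(unname(cal$slopes), c(1, 1))
  expect_equal(cal$ref_calibrated, cal$ref_reported)
  # internal ERs exactly twice the literature values
  sc2 <- sc; sc2$er_internal <- 2 * sc2$er_literature
  cal2 <- calibrate_ref(sc2, ref)
  expect_equal(unname(cal2$slopes), c(2, 2))
  expect_equal(cal2$ref_calibrated$alpha, ref$alpha / 2)
  expect_equal(cal2$ref_calibrated$beta, ref$beta / 2)
  cal3 <- calibrate_ref(sc2, ref, direction = "multiply")
  expect_equal(cal3$ref_calibrated$alpha, ref$alpha * 2)
  # degenerate regression
  sc4 <- sc; sc4$er_literature <- 0
  expect_error(calibrate_ref(sc4, ref), "degenerate")
  expect_error(calibrate_ref(sc[c(1, 5), ], ref), ">= 2")
})

test_that("RAF-to-REF ratios match the built-in parameter sets", {
  r <- raf_to_ref_ratio(raf_params("rat"), ref_params("rat"))
  expect_equal(as.vector(r), c(0.395 / 0.240, 1.368 / 0.437))
  expect_equal(unname(attr(r, "display")), c(1.6, 3.1))
  same <- raf_to_ref_ratio(par_custom(0.2, 0.5, 1000, 1000),
                           par_custom(0.2, 0.5, 1000, 1000, mode = "REF"))
  expect_equal(as.vector(same), c(1, 1))
  expect_error(raf_to_ref_ratio(ref_params("rat"), raf_params("rat")),
               "RAF set and a REF set")
  expect_error(raf_to_ref_ratio(raf_params("rat"), ref_params("human")),
               "different species")
})
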