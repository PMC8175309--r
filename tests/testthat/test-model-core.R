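# Closed-form steady-state model: PS1, efflux activity, Kp,uu predictions,
# limiting forms, and agreement with the independent mass-balance solve.

test_that("PS1 matches the hand-evaluated formula and scales with physiology", {
  # (3600/1000) * 7.2 * 10^(0.182*(0 - 0.5*log10(400)) - 1.86); inner
  # exponent -2.0968
  expect_equal(compute_ps1(0, 400, species_physiology("rat")),
               0.2074, tolerance = 1e-4)
  # linear in brain-weight scalar: human/rat = 20/7.2 exactly
  expect_equal(compute_ps1(1.3, 300, species_physiology("human")) /
                 compute_ps1(1.3, 300, species_physiology("rat")),
               20 / 7.2)
  # monotone: increasing in logD, decreasing in MW
  expect_gt(compute_ps1(2, 400, "rat"), compute_ps1(1, 400, "rat"))
  expect_gt(compute_ps1(1, 100, "rat"), compute_ps1(1, 10000, "rat"))
  expect_error(compute_ps1(1, -5, "rat"), "positive")
  expect_error(compute_ps1(1, 0, "rat"), "positive")
})

test_that("efflux activity floors sub-unity ratios and matches arithmetic", {
  p <- par_rat()  # alpha 0.395, beta 1.368
  expect_equal(f_ers(1, 1, p), 0)
  expect_equal(f_ers(10, 3, par_custom(0, 0)), 0)
  expect_equal(f_ers(10, 3, p), 0.395 * 9 + 1.368 * 2)  # 6.291
  # ER below 1 contributes nothing, not a negative clearance
  expect_equal(f_ers(0.3, 0.5, p), 0)
  expect_equal(f_ers(0.3, 3, p), f_ers(1, 3, p))
  expect_error(f_ers(0, 1, p), "positive")
  expect_error(f_ers(2, -1, p), "positive")
})

test_that("brain prediction recovers the no-efflux and large-sigma limits", {
  phys <- species_physiology("rat")
  big_sigma <- par_custom(0.395, 1.368, gamma = 1910, sigma = 1e9)
  # no efflux, ependymal exchange negligible -> complete equilibration
  expect_equal(predict_kpuu_brain(0.2, 0, big_sigma, phys), 1,
               tolerance = 1e-6)
  # 1/(1 + f): the brain-only simplification
  expect_equal(predict_kpuu_brain(0.2, 6.291, big_sigma, phys),
               1 / 7.291, tolerance = 1e-6)
  # sigma = Inf is the exact analytic limit
  inf_sigma <- par_custom(0.395, 1.368, gamma = 1910, sigma = Inf)
  expect_equal(predict_kpuu_brain(0.2, 6.291, inf_sigma, phys), 1 / 7.291)
  # gamma = Inf limit is finite and in (0, 1]
  inf_gamma <- par_custom(0.4, 1.4, gamma = Inf, sigma = 1000)
  kb <- predict_kpuu_brain(0.2, 2, inf_gamma, phys)
  expect_true(is.finite(kb) && kb > 0 && kb <= 1)
})

test_that("CSF prediction limits and CSF-over-brain crossover condition", {
  p <- par_custom(0.4, 1.4, gamma = 1900, sigma = 1000)
  # no efflux and no bulk-flow sink -> full equilibration with plasma
  expect_equal(predict_kpuu_csf(0.2, 0, p, phys_with_k(0)), 1)
  phys <- species_physiology("rat")
  thr <- p$gamma * phys$cl_bulkflow / 0.2  # f at which CSF = brain
  for (f in c(0.2, 1.5, 8) * thr) {
    kb <- predict_kpuu_brain(0.2, f, p, phys)
    kc <- predict_kpuu_csf(0.2, f, p, phys)
    if (f > thr) expect_gt(kc, kb) else expect_lt(kc, kb)
  }
  kb <- predict_kpuu_brain(0.2, thr, p, phys)
  kc <- predict_kpuu_csf(0.2, thr, p, phys)
  expect_equal(kc, kb, tolerance = 1e-12)
})

test_that("closed forms agree with the mass-balance solve over random draws", {
  set.seed(42)
  ks <- c(0.000528, 0.000492, 0.0003)
  worst <- 0
  for (i in 1:1000) {
    ps1 <- 10^runif(1, -4, 1)
    gamma <- 10^runif(1, 1, 5); sigma <- 10^runif(1, 1, 5)
    f <- runif(1, 0, 100); k <- sample(ks, 1)
    p <- par_custom(1, 1, gamma, sigma)
    closed <- c(predict_kpuu_brain(ps1, f, p, phys_with_k(k)),
                predict_kpuu_csf(ps1, f, p, phys_with_k(k)))
    oracle <- steady_state_kpuu(ps1, ps1 / sigma, ps1 / gamma, f * ps1, k)
    worst <- max(worst, abs(closed - oracle) / oracle)
  }
  expect_lt(worst, 1e-10)
})

test_that("predictions are bounded by 1 and decrease with efflux", {
  set.seed(7)
  phys <- species_physiology("monkey")
  for (i in 1:50) {
    p <- par_custom(runif(1, 0, 2), runif(1, 0, 3),
                    10^runif(1, 1, 5), 10^runif(1, 1, 5))
    ps1 <- 10^runif(1, -3, 0)
    ers <- sort(10^runif(4, 0, 1.7))
    kb <- predict_kpuu_brain(ps1, f_ers(ers, 1, p), p, phys)
    kc <- predict_kpuu_csf(ps1, f_ers(ers, 1, p), p, phys)
    expect_true(all(kb > 0 & kb <= 1))
    expect_true(all(kc > 0 & kc <= 1))
    if (p$alpha > 0) {
      expect_true(all(diff(kb) < 0))
      expect_true(all(diff(kc) < 0))
    }
  }
})

test_that("the CSF/brain ratio approximation tracks the exact ratio", {
  phys <- species_physiology("rat")
  # trivial case: no efflux, no bulk flow
  expect_equal(kpuu_ratio_approx(0.2, 0, par_custom(), phys_with_k(0)), 1)
  # negligible 1/sigma: approximation agrees to 1e-6
  p <- par_custom(0.4, 1.4, gamma = 1910, sigma = 1e9)
  for (f in c(0, 0.5, 3)) {
    exact <- predict_kpuu_csf(0.05, f, p, phys) /
      predict_kpuu_brain(0.05, f, p, phys)
    expect_equal(kpuu_ratio_approx(0.05, f, p, phys), exact,
                 tolerance = 1e-6)
  }
  # fitted rat gamma/sigma: within 1% over the practical sweep
  p <- par_rat()
  grid <- expand.grid(f = seq(0, 10, length.out = 11),
                      ps1 = 10^seq(-3, 0, length.out = 7))
  exact <- predict_kpuu_csf(grid$ps1, grid$f, p, phys) /
    predict_kpuu_brain(grid$ps1, grid$f, p, phys)
  approx <- kpuu_ratio_approx(grid$ps1, grid$f, p, phys)
  expect_lt(max(abs(approx / exact - 1)), 0.01)
})

test_that("mass-balance solve handles degenerate and isolated cases", {
  # pure passive equilibrium: everything at plasma concentration
  expect_equal(steady_state_kpuu(0.2, 0.001, 0.001, 0, 0),
               c(kpuu_brain = 1, kpuu_csf = 1))
  # isolated brain: ECF balance reduces to 1/(1 + f)
  f <- 4
  out <- steady_state_kpuu(0.2, 0, 0, f * 0.2, 0.0005)
  expect_equal(unname(out["kpuu_brain"]), 1 / (1 + f))
  # CSF with no exit clearance at all -> singular system
  expect_error(steady_state_kpuu(0.2, 0, 0, 0, 0), "degenerate")
})

test_that("table-level prediction wires PS1, f(ERs), and both endpoints", {
  pred <- predict_kpuu(toy_compounds(), par_rat())
  expect_equal(nrow(pred), 3)
  expect_true(all(pred$kpuu_brain > 0 & pred$kpuu_brain <= 1))
  expect_true(all(pred$kpuu_csf > 0 & pred$kpuu_csf <= 1))
  # the free compound (both ERs <= 1) penetrates essentially fully
  expect_gt(pred$kpuu_brain[1], 0.9)
  expect_lt(pred$kpuu_brain[2], pred$kpuu_brain[1])
  expect_error(predict_kpuu(toy_compounds()[, -2], par_rat()), "lacks")
})
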