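test_that("competition matrices place coefficients per structure", {
  p <- suppressWarnings(
    model_params(theta = 0.9, phi = 0.9, psi = 0.9,
                 omega = 0.5, mu = 0.5, nu = 0.5))
  C <- competition_matrix(p)
  expect_equal(unname(C["00", ]), c(1, 0.9, 0.9, 0.9))
  expect_equal(unname(C["10", ]), c(0.9, 0.5, 1, 0.5))
  expect_true(isSymmetric(C))

  # near-zero interclonal competition: matrix approaches the identity
  eps <- 1e-9
  p0 <- model_params(theta = eps, phi = eps, psi = eps,
                     omega = eps, mu = eps, nu = eps)
  expect_equal(competition_matrix(p0), diag(4), tolerance = 1e-6,
               ignore_attr = TRUE)

  # two-niche asymmetric structure
  p3 <- model_params(structure = "III", theta = 0.3, phi = 0.7)
  C3 <- competition_matrix(p3)
  expect_identical(C3["01", "10"], 0.3)
  expect_identical(C3["11", "00"], 0.7)
  expect_identical(C3["01", "00"], 1)
  expect_identical(C3["10", "11"], 1)
  expect_false(isSymmetric(C3))
})

test_that("structure II equals structure I with producer pairs at 1", {
  pII <- model_params(structure = "II")
  pI <- model_params(structure = "I", omega = 1, mu = 1, nu = 1)
  expect_identical(competition_matrix(pII), competition_matrix(pI))
})

test_that("competition matrix invariants hold for random draws", {
  set.seed(11)
  for (s in c("I", "II", "III")) {
    for (i in 1:10) {
      C <- competition_matrix(sample_params(s))
      expect_equal(unname(diag(C)), rep(1, 4))
      expect_true(all(C <= 1 & C > 0))
      if (s != "III") expect_true(isSymmetric(C))
    }
  }
})

test_that("carrying capacity is k plus the focal benefit times R", {
  p <- model_params(k = 1e5, beta0 = 1, beta1 = 1.2)
  expect_equal(carrying_capacity("00", 0, p), 1e5)
  expect_equal(carrying_capacity("11", 0, p), 1e5)
  expect_equal(carrying_capacity("10", 1e5, p), 2.2e5)
  expect_equal(carrying_capacity("00", 1e5, p), 2.0e5)
  expect_equal(carrying_capacity("01", 1e5, p), 2.0e5)  # x = 0 clone
  expect_error(carrying_capacity("00", -1, p), "nonnegative")
})

test_that("dispersal rate is alpha N over the focal carrying capacity", {
  p <- model_params(k = 1e5, beta0 = 1, beta1 = 1.2, alpha = 1e-6)
  expect_equal(dispersal_rate("00", N = 1e5, R = 0, p), 1e-6)
  expect_equal(dispersal_rate("10", N = 2.2e5, R = 1e5, p), 1e-6)
  p0 <- model_params(alpha = 0)
  expect_identical(dispersal_rate("11", N = 1e7, R = 1e6, p0), 0)
})

test_that("rhs matches an independent term-by-term transcription", {
  p <- model_params()
  # empty tumor: pure resource decay
  d <- tumor_rhs(tumor_state(rep(0, 4), R = 5), p)
  expect_equal(unname(d$dn), rep(0, 4))
  expect_equal(d$dR, -0.005)
  # single-clone logistic fixed point with no intravasation
  p0 <- model_params(alpha = 0)
  d0 <- tumor_rhs(tumor_state(c(p0$k, 0, 0, 0), R = 0), p0)
  expect_equal(d0$dn[["00"]], 0)
  # reference parameters, founding state
  dref <- tumor_rhs(tumor_state(c(1e3, 0, 0, 0), R = 0), p)
  oref <- oracle_rhs(1e3, 0, 0, 0, 0, p)
  expect_equal(unname(dref$dn), oref$dn, tolerance = 1e-12)
  expect_equal(dref$dR, oref$dR)
  # random states, all structures
  set.seed(21)
  for (s in c("I", "II", "III")) {
    for (i in 1:20) {
      ps <- sample_params(s)
      n <- stats::runif(4, 0, 2 * ps$k)
      R <- stats::runif(1, 0, 10 * ps$k)
      got <- tumor_rhs(tumor_state(n, R), ps)
      want <- oracle_rhs(n[1], n[2], n[3], n[4], R, ps)
      expect_equal(unname(got$dn), want$dn, tolerance = 1e-12)
      expect_equal(got$dR, want$dR, tolerance = 1e-12)
    }
  }
  expect_error(tumor_rhs(list(n = c(-1, 0, 0, 0), R = 0), p),
               "nonnegative")
})

test_that("per-capita growth has a finite limit as a clone vanishes", {
  set.seed(31)
  p <- sample_params("I")
  n <- c(0.5 * p$k, 1e-30, 0.3 * p$k, 1e-30)
  d <- tumor_rhs(tumor_state(n, R = p$k), p)
  percap <- unname(d$dn) / n
  expect_true(all(is.finite(percap)))
  # and it equals the boundary invasion rate of the absent clone
  eq <- coexistence_equilibrium(p$k, p)
  expect_false(is.null(eq))  # feasible at this draw
  n2 <- eq$n_star + c(0, 1e-25, 0, 1e-25)
  d2 <- tumor_rhs(tumor_state(n2, R = p$k), p)
  expect_equal(d2$dn[["01"]] / n2[[2]],
               invasion_growth_rate("01", eq, p), tolerance = 1e-8)
})

test_that("trajectories stay nonnegative for random parameter draws", {
  set.seed(41)
  for (i in 1:5) {
    ps <- sample_params(sample(c("I", "II", "III"), 1))
    ini <- tumor_state(stats::runif(4, 0, ps$k), R = stats::runif(1, 0, ps$k))
    tr <- integrate_tumor(ps, ini, horizon = 300,
                          extinction_threshold = 0)
    expect_true(min(tr$states) >= -1e-6)
  }
})

test_that("parameter validation enforces bounds and warns on costs", {
  expect_error(model_params(k = -1), "'k'")
  expect_error(model_params(theta = 1.5), "'theta'")
  expect_error(model_params(theta = 0), "'theta'")
  expect_error(model_params(omega = 0), "'omega'")
  expect_silent(model_params(omega = 1))
  expect_warning(model_params(r01 = 0.08), "cost ordering")
  expect_warning(model_params(r11 = 0.06), "cost ordering")
  expect_error(competition_matrix(list(structure = "IV")),
               "unknown competition structure")
})

test_that("clone bookkeeping uses the canonical order", {
  ct <- cell_types()
  expect_identical(ct$label, c("00", "01", "10", "11"))
  expect_identical(ct$x, c(0, 0, 1, 1))
  expect_identical(ct$y, c(0, 1, 0, 1))
  s <- tumor_state(c(`10` = 3, `00` = 1, `11` = 4, `01` = 2), R = 0)
  expect_equal(unname(s$n), c(1, 2, 3, 4))  # reordered by label
  expect_error(tumor_state(c(1, 2, 3), R = 0), "length 4")
})
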