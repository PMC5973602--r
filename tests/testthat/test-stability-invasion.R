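test_that("fast Jacobian matches central differences and known forms", {
  p <- model_params()
  # at the origin: decoupled exponential growth, diag(r - m(0, R))
  J0 <- jacobian_fast(tumor_state(rep(0, 4), R = 100), p)
  expect_equal(J0, diag(c(p$r00, p$r01, p$r10, p$r11)),
               ignore_attr = TRUE)
  # single-clone equilibrium, alpha = 0: logistic restoring force -r
  p0 <- model_params(alpha = 0)
  eq <- single_type_equilibrium("10", 1e4, p0)
  Jeq <- jacobian_fast(tumor_state(eq$n_star, 1e4), p0)
  expect_equal(Jeq["10", "10"], -p0$r10, tolerance = 1e-12)
  # random states against the finite-difference oracle
  set.seed(51)
  for (s in c("I", "II", "III")) {
    for (i in 1:10) {
      ps <- sample_params(s)
      n <- stats::runif(4, 0, 2 * ps$k)
      R <- stats::runif(1, 0, 5 * ps$k)
      J <- jacobian_fast(tumor_state(n, R), ps)
      expect_equal(unname(J), fd_jacobian(n, R, ps),
                   tolerance = 1e-6)
    }
  }
})

test_that("invasion growth rate is the boundary eigenvalue", {
  p <- model_params(alpha = 0)
  eq <- single_type_equilibrium("00", 0, p)
  # cheater-only residents are open to local producers whenever theta < 1
  expect_equal(invasion_growth_rate("10", eq, p), p$r10 * (1 - p$theta),
               tolerance = 1e-10)
  # and it equals the corresponding diagonal Jacobian entry
  J <- jacobian_fast(tumor_state(eq$n_star, 0), p)
  expect_equal(J["10", "10"], invasion_growth_rate("10", eq, p),
               tolerance = 1e-10)
  # an invader with vanishing growth rate cannot do better than -m
  pr <- suppressWarnings(model_params(r11 = 1e-12))
  eqr <- single_type_equilibrium("00", 0, pr)
  lam <- invasion_growth_rate("11", eqr, pr)
  expect_equal(lam, -dispersal_rate("11", sum(eqr$n_star), 0, pr),
               tolerance = 1e-6)
  # secondary producers enter producer-only tumors iff omega < beta0/beta1
  pw <- model_params(alpha = 0, omega = 0.7, beta0 = 1, beta1 = 1.2)
  eqp <- single_type_equilibrium("10", 1e9, pw)
  expect_gt(invasion_growth_rate("01", eqp, pw), 0)
  expect_true(as.logical(analytic_invasion_exact("01", eqp, pw)))
  expect_error(invasion_growth_rate("10", eqp, pw), "already part")
})

test_that("producer-only stability pivots on theta vs beta0/beta1", {
  p_stable <- model_params(alpha = 0, theta = 0.9, beta0 = 1, beta1 = 1.2)
  eq <- single_type_equilibrium("10", 1e9 * p_stable$k, p_stable)
  rep_s <- is_stable(eq, p_stable)
  expect_true(rep_s$stable)
  expect_lt(rep_s$external_rates[["00"]], 0)
  p_open <- model_params(alpha = 0, theta = 0.5, beta0 = 1, beta1 = 1.2)
  eq2 <- single_type_equilibrium("10", 1e9 * p_open$k, p_open)
  rep_u <- is_stable(eq2, p_open)
  expect_false(rep_u$stable)
  expect_gt(rep_u$external_rates[["00"]], 0)
  # cheater-only communities are never stable (theta < 1)
  for (s in c("I", "II", "III")) {
    ps <- model_params(structure = s, alpha = 1e-9)
    expect_false(is_stable(single_type_equilibrium("00", 10, ps),
                           ps)$stable)
  }
})

test_that("exact invasion inequality reduces to the printed forms", {
  # cheater-only resident, alpha = 0: phi * n00 < k + beta0 R
  p <- model_params(alpha = 0, phi = 0.8)
  eq <- single_type_equilibrium("00", 0, p)
  v <- analytic_invasion_exact("01", eq, p)
  expect_true(as.logical(v))
  expect_equal(attr(v, "margin"),
               abs(p$k - p$phi * eq_n(eq, "00")) / p$k, tolerance = 1e-12)
  # structure III producer-only resident, alpha = 0: n10* = k + beta1 R
  # exactly, so global producers sit on the closed side of n10 < K1
  p3 <- model_params(structure = "III", alpha = 0)
  eq3 <- single_type_equilibrium("10", 1e6, p3)
  expect_false(as.logical(analytic_invasion_exact("11", eq3, p3)))
  # not-applicable combinations signal NA
  expect_true(is.na(analytic_invasion_exact("10", eq, p)))
  eq01 <- single_type_equilibrium("01", 0, p)
  expect_true(is.na(analytic_invasion_exact("11", eq01, p)))
})

test_that("sign of the eigenvalue matches the exact inequality", {
  set.seed(61)
  n_checked <- 0
  for (i in 1:30) {
    s <- sample(c("I", "II", "III"), 1)
    p <- sample_params(s, coexistence_feasible = TRUE)
    R <- sample(c(0, p$k, 1e3 * p$k), 1)
    for (res in list("00", "10", c("00", "10"))) {
      eq <- if (length(res) == 2) coexistence_equilibrium(R, p)
            else single_type_equilibrium(res, R, p)
      if (is.null(eq)) next
      for (inv in c("01", "11")) {
        lam <- invasion_growth_rate(inv, eq, p)
        ex <- analytic_invasion_exact(inv, eq, p)
        if (attr(ex, "margin") < 1e-3) next  # knife edge: sign untestable
        r_inv <- if (inv == "01") p$r01 else p$r11
        expect_identical(lam > 1e-10 * r_inv, as.logical(ex))
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gt(n_checked, 100)
})

test_that("limit-form grid reproduces the summary-table verdicts", {
  p <- model_params(theta = 0.9, beta0 = 1, beta1 = 1.2)
  v <- analytic_condition_limit("I", "producer_only", "stability", p)
  expect_true(as.logical(v))
  expect_equal(attr(v, "margin"), 0.9 - 1 / 1.2, tolerance = 1e-12)
  # global producers never invade producer-only tumors under II and III
  expect_false(as.logical(
    analytic_condition_limit("II", "producer_only", "invade_11", p)))
  expect_false(as.logical(
    analytic_condition_limit("III", "producer_only", "invade_11", p)))
  # structure III coexistence: r01 > r00 never holds with a growth cost
  expect_false(as.logical(
    analytic_condition_limit("III", "coexistence", "invade_01", p)))
  # cheater-only: never stable, open to producers below coefficient 1
  expect_false(as.logical(
    analytic_condition_limit("II", "cheater_only", "stability", p)))
  expect_true(as.logical(
    analytic_condition_limit("I", "cheater_only", "invade_11", p)))
  # coexistence stability is the intractable cell
  expect_true(is.na(
    analytic_condition_limit("I", "coexistence", "stability", p)))
  g <- table3_grid(p, structures = c("I", "II", "III"))
  expect_equal(nrow(g), 27)
  expect_true(g$verdict[g$structure == "I" &
                          g$resident == "producer_only" &
                          g$question == "stability"])
})

test_that("structure III: invasion by 01 and stability are exclusive", {
  set.seed(71)
  for (i in 1:30) {
    p <- sample_params("III")
    if (abs(p$theta - p$beta0 / p$beta1) < 1e-6) next
    stab <- as.logical(
      analytic_condition_limit("III", "producer_only", "stability", p))
    inv <- as.logical(
      analytic_condition_limit("III", "producer_only", "invade_01", p))
    expect_identical(stab, !inv)
    expect_identical(stab, p$theta > p$beta0 / p$beta1)
  }
})

test_that("window of specificity: stable yet invadable by 01", {
  set.seed(81)
  for (i in 1:10) {
    p <- sample_params("I")
    p$beta0 <- 1
    p$theta <- stats::runif(1, 0.6, 0.95)
    p$omega <- stats::runif(1, 0.1, p$theta - 0.1)
    ratio <- stats::runif(1, p$omega + 0.02, p$theta - 0.02)
    p$beta1 <- p$beta0 / ratio
    p$alpha <- 0
    eq <- single_type_equilibrium("10", 1e6 * p$k, p)
    expect_true(is_stable(eq, p)$stable)
    expect_gt(invasion_growth_rate("01", eq, p), 0)
  }
})

test_that("consistency report cross-checks the three verdict routes", {
  expect_equal(nrow(consistency_report(0)), 0)
  rep1 <- consistency_report(10, seed = 5, regime = "limit")
  expect_true(all(c("structure", "resident", "question", "numeric",
                    "limit", "boundary", "agree_limit") %in% names(rep1)))
  keep <- rep1[!rep1$boundary & !is.na(rep1$agree_limit), ]
  expect_gt(nrow(keep), 100)
  expect_gt(mean(keep$agree_limit), 0.98)
  rep2 <- consistency_report(5, seed = 6, regime = "exact")
  keep2 <- rep2[!rep2$boundary & !is.na(rep2$agree_exact), ]
  expect_true(all(keep2$agree_exact))
  s <- summarize_consistency(rep1)
  expect_true(all(s$n >= 1))
  expect_true(all(s$frac_agree_exact[s$question != "stability"] == 1,
                  na.rm = TRUE))
})
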