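# Randomized cross-validation of the analytic invasion/stability conditions
# against the numeric invasion eigenvalues.

#' Draw a random admissible parameter set
#'
#' Samples a parameter set respecting every [model_params()] invariant,
#' including the producer growth-rate cost ordering. Ranges bracket the
#' default registry values: `r00` in (0.04, 0.1)/day with multiplicative
#' costs, `beta0`, `beta1` in (0.5, 2), competition coefficients over
#' (0.05, 0.95) (the `omega`, `mu`, `nu` group up to 1), `alpha` log-uniform
#' around `1e-6`. With `coexistence_feasible = TRUE`, the cross-competition
#' coefficients between cheaters and local producers (`theta` under
#' structures I/II; `theta` and `phi` under structure III) are restricted
#' below 95% of the carrying-capacity ratios so that the
#' cheater/local-producer coexistence equilibrium exists at large `R`.
#'
#' Uses R's global RNG stream; seed it with [set.seed()] for
#' reproducibility.
#'
#' @param structure Competition structure of the drawn set.
#' @param coexistence_feasible Restrict `theta` as above.
#' @return A `tumor_model_params` object.
#' @export
sample_params <- function(structure = "I", coexistence_feasible = FALSE) {
  r00 <- stats::runif(1, 0.04, 0.10)
  r10 <- r00 * stats::runif(1, 0.50, 0.95)
  r01 <- r00 * stats::runif(1, 0.50, 0.95)
  r11 <- min(r10, r01) * stats::runif(1, 0.30, 0.95)
  beta0 <- stats::runif(1, 0.5, 2)
  beta1 <- stats::runif(1, 0.5, 2)
  # coexistence of cheaters and local producers at large R requires the
  # cross-competition coefficients to sit below the carrying-capacity
  # ratios: theta < beta0/beta1 and (structure III) phi < beta1/beta0;
  # under structures I and II both cross terms equal theta
  th_max <- 0.95
  ph_max <- 0.95
  if (coexistence_feasible) {
    th_max <- if (structure == "III") 0.95 * min(beta0 / beta1, 1)
              else 0.95 * min(beta0 / beta1, beta1 / beta0, 1)
    if (structure == "III") ph_max <- 0.95 * min(beta1 / beta0, 1)
  }
  model_params(r00 = r00, r01 = r01, r10 = r10, r11 = r11,
               k = 1e5, beta0 = beta0, beta1 = beta1,
               alpha = 10^stats::runif(1, -6.5, -5.5),
               g = stats::runif(1, 0.002, 0.006),
               l = stats::runif(1, 5e-4, 2e-3),
               structure = structure,
               theta = stats::runif(1, 0.05, th_max),
               phi = stats::runif(1, 0.05, ph_max),
               psi = stats::runif(1, 0.05, 0.95),
               omega = stats::runif(1, 0.05, 1),
               mu = stats::runif(1, 0.05, 1),
               nu = stats::runif(1, 0.05, 1))
}

# resident community -> (resident set, frozen R) in a given regime
.community_setup <- function(resident, k, regime, R_ratio) {
  set <- switch(resident, cheater_only = "00", producer_only = "10",
                coexistence = c("00", "10"))
  R <- if (resident == "cheater_only") 0 else R_ratio * k
  list(set = set, R = R)
}

# strict floating guard for sign decisions on per-capita rates: cells that
# are marginal at order alpha evaluate to an exact 0 up to rounding noise
.SIGN_NOISE <- 1e-10

#' Analytic-versus-numeric consistency report
#'
#' Samples random parameter sets and, for every (structure, resident
#' community, question) case, compares the numeric verdict (sign of the
#' invasion eigenvalue, or [is_stable()]) with the exact analytic
#' inequality ([analytic_invasion_exact()]) and — in the limit regime —
#' with the closed-form grid ([analytic_condition_limit()]).
#'
#' In the `"limit"` regime, `alpha` is set to 0 and residents are placed at
#' `R = R_ratio * k` (producer-containing) or `R = 0` (cheater-only), the
#' regime in which the closed forms hold. In the `"exact"` regime `alpha`
#' is kept as drawn and each case is evaluated over `R_values`
#' (default `c(0, 1, 1e3, 1e6) * k`) for the invasion questions only.
#'
#' Draws whose analytic margin (distance from the condition boundary,
#' suitably nondimensionalized) falls below `margin` are flagged
#' `boundary = TRUE` and are meant to be excluded from agreement
#' statistics: a sign test is meaningless at the knife edge. Coexistence
#' draws use a feasibility-restricted `theta` (see [sample_params()]);
#' infeasible coexistence cases are dropped.
#'
#' @param n_draws Number of parameter draws per structure.
#' @param seed Optional integer seed for the draw stream.
#' @param regime `"limit"` or `"exact"` (see above).
#' @param structures Competition structures to cover.
#' @param margin Boundary-exclusion margin (dimensionless), default `1e-3`.
#' @param R_ratio `R/k` used for producer-containing residents in the limit
#'   regime.
#' @param R_values Frozen resource levels for the exact regime (absolute
#'   units; default `c(0, 1, 1e3, 1e6) * k`).
#' @return A data frame with one row per evaluated case: `structure`,
#'   `draw`, `resident`, `question`, `R`, `lambda` (invasion eigenvalue,
#'   `NA` for stability rows), verdicts `numeric`, `exact`, `limit`, their
#'   margins, `boundary`, and agreement flags `agree_exact`,
#'   `agree_limit`. Summarize with [summarize_consistency()].
#' @examples
#' rep1 <- consistency_report(5, seed = 1, regime = "limit",
#'                            structures = "I")
#' summarize_consistency(rep1)
#' @export
consistency_report <- function(n_draws, seed = NULL,
                               regime = c("limit", "exact"),
                               structures = c("I", "II", "III"),
                               margin = 1e-3, R_ratio = 1e6,
                               R_values = NULL) {
  regime <- match.arg(regime)
  if (!is.null(seed)) set.seed(seed)
  if (n_draws < 1L) return(.empty_consistency())
  rows <- vector("list", 0L)
  for (s in structures) {
    for (d in seq_len(n_draws)) {
      p_free <- sample_params(s)
      p_coex <- sample_params(s, coexistence_feasible = TRUE)
      for (resident in .RESIDENT_COMMUNITIES) {
        p <- if (resident == "coexistence") p_coex else p_free
        if (regime == "limit") p$alpha <- 0
        Rs <- if (regime == "limit")
          .community_setup(resident, p$k, regime, R_ratio)$R
        else (if (is.null(R_values)) c(0, 1, 1e3, 1e6) * p$k else R_values)
        for (R in Rs) {
          eq <- .resident_equilibrium(resident, R, p)
          if (is.null(eq)) next
          qs <- if (regime == "limit") .QUESTIONS
                else c("invade_01", "invade_11")
          for (q in qs) {
            rows[[length(rows) + 1L]] <-
              .consistency_row(s, d, resident, q, R, eq, p, regime, margin)
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

.empty_consistency <- function() {
  data.frame(structure = character(0), draw = integer(0),
             resident = character(0), question = character(0),
             R = numeric(0), lambda = numeric(0),
             numeric = logical(0), exact = logical(0),
             exact_margin = numeric(0), limit = logical(0),
             limit_margin = numeric(0), boundary = logical(0),
             agree_exact = logical(0), agree_limit = logical(0),
             stringsAsFactors = FALSE)
}

.resident_equilibrium <- function(resident, R, p) {
  switch(resident,
         cheater_only = single_type_equilibrium("00", R, p),
         producer_only = single_type_equilibrium("10", R, p),
         coexistence = coexistence_equilibrium(R, p))
}

.consistency_row <- function(s, d, resident, q, R, eq, p, regime, margin) {
  lambda <- NA_real_
  exact <- NA
  exact_margin <- NA_real_
  if (q == "stability") {
    num <- is_stable(eq, p)$stable
  } else {
    inv <- if (q == "invade_01") "01" else "11"
    lambda <- invasion_growth_rate(inv, eq, p)
    r_inv <- .r_vec(p)[.type_index(inv)]
    num <- lambda > .SIGN_NOISE * r_inv
    ex <- analytic_invasion_exact(inv, eq, p)
    exact <- as.logical(ex)
    exact_margin <- attr(ex, "margin")
  }
  lim <- if (regime == "limit")
    analytic_condition_limit(s, resident, q, p) else NA
  limit_margin <- if (isTRUE(is.na(lim))) NA_real_ else attr(lim, "margin")
  # the boundary flag excludes knife-edge draws from the statistic the
  # regime is validating: the limit-form margin in the limit regime, the
  # exact-inequality margin in the exact regime. Cells decided at order
  # alpha have exact_margin 0 by construction (their limit verdict is a
  # parameter condition, checked through limit_margin instead).
  boundary <- if (regime == "limit")
    !is.na(limit_margin) && limit_margin < margin
  else !is.na(exact_margin) && exact_margin < margin
  # an exact margin at floating-point zero carries no sign information
  agree_exact <- if (is.na(exact) || exact_margin < 1e-12) NA
                 else num == exact
  data.frame(structure = s, draw = d, resident = resident, question = q,
             R = R, lambda = lambda, numeric = num,
             exact = exact, exact_margin = exact_margin,
             limit = as.logical(lim), limit_margin = limit_margin,
             boundary = boundary,
             agree_exact = agree_exact,
             agree_limit = if (isTRUE(is.na(lim))) NA
                           else num == as.logical(lim),
             stringsAsFactors = FALSE)
}

#' Summarize a consistency report
#'
#' Agreement fractions per (structure, resident, question) cell over
#' non-boundary draws.
#'
#' @param report Output of [consistency_report()].
#' @return A data frame with per-cell counts and agreement fractions
#'   (`frac_agree_exact`, `frac_agree_limit`; `NA` when not applicable).
#' @export
summarize_consistency <- function(report) {
  keep <- report[!report$boundary, , drop = FALSE]
  if (nrow(keep) == 0L) {
    return(data.frame(structure = character(0), resident = character(0),
                      question = character(0), n = integer(0),
                      frac_agree_exact = numeric(0),
                      frac_agree_limit = numeric(0)))
  }
  key <- interaction(keep$structure, keep$resident, keep$question,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(keep, key), function(g) {
    data.frame(structure = g$structure[1L], resident = g$resident[1L],
               question = g$question[1L], n = nrow(g),
               frac_agree_exact = mean(g$agree_exact, na.rm = TRUE),
               frac_agree_limit = mean(g$agree_limit, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
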