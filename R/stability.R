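# Linearization of the frozen-R cell subsystem and invasion analysis.

# analytic Jacobian of the cell derivatives at frozen R:
#   J[i,j] = d(dn_i/dt)/dn_j
#          = delta_ij * [r_i (1 - (Cn)_i/K_i) - alpha N / D_i]
#            + n_i * [-r_i C[i,j]/K_i - alpha/D_i]
.jacobian_cells <- function(n, R, p) {
  C <- competition_matrix(p)
  K <- .K_vec(R, p)
  D <- .D_vec(R, p)
  r <- .r_vec(p)
  N <- sum(n)
  percap <- r * (1 - as.vector(C %*% n) / K) - p$alpha * N / D
  J <- -(r * n / K) * C - matrix(p$alpha * n / D, 4L, 4L)
  diag(J) <- diag(J) + percap
  dimnames(J) <- list(.TYPES, .TYPES)
  J
}

#' Jacobian of the fast (cell) subsystem
#'
#' Analytic linearization of the four clone equations at frozen resource
#' level, validated against central finite differences in the test suite.
#' At the origin it reduces to `diag(r_i - m_i(0, R))`; at a single-clone
#' equilibrium with `alpha = 0` the focal diagonal entry is `-r` (the
#' logistic restoring force).
#'
#' @param state A [tumor_state()].
#' @param params A [model_params()] object.
#' @return A 4x4 matrix with clone labels as dimnames.
#' @export
jacobian_fast <- function(state, params) {
  .jacobian_cells(state$n, state$R, params)
}

#' Per-capita growth rate of a rare invader
#'
#' The invasion eigenvalue of a boundary equilibrium: the per-capita growth
#' rate of clone `invader` introduced at vanishing abundance into a
#' resident community at its quasi-equilibrium,
#' \deqn{\lambda = r_{inv} (1 - (C n^*)_{inv} / K_{inv}(R)) - m_{inv},}
#' which equals the corresponding diagonal entry of [jacobian_fast()] at
#' the boundary equilibrium. The invader establishes (deterministically)
#' when `lambda > 0`.
#'
#' @param invader Clone to introduce (label, role or index); must be absent
#'   from the resident set.
#' @param resident_eq A `quasi_equilibrium` (see [find_quasi_equilibria()]).
#' @param params A [model_params()] object.
#' @return Per-capita growth rate in 1/day.
#' @examples
#' p <- model_params()
#' eq <- single_type_equilibrium("00", R = 0, p)
#' invasion_growth_rate("10", eq, p)  # r10 * (1 - theta), up to alpha terms
#' @export
invasion_growth_rate <- function(invader, resident_eq, params) {
  i <- .type_index(invader)
  stopifnot(length(i) == 1L)
  if (.TYPES[i] %in% resident_eq$resident_set)
    stop("invader ", .TYPES[i], " is already part of the resident set")
  n <- resident_eq$n_star
  R <- resident_eq$R
  C <- competition_matrix(params)
  K <- .K_vec(R, params)[i]
  D <- .D_vec(R, params)[i]
  r <- .r_vec(params)[i]
  r * (1 - sum(C[i, ] * n) / K) - params$alpha * sum(n) / D
}

#' Stability of a quasi-equilibrium
#'
#' A quasi-equilibrium is reported stable when (a) all eigenvalues of the
#' fast Jacobian restricted to the resident clones have negative real part
#' (internal attractivity) and (b) every absent clone among the cheater
#' `"00"` and the local producer `"10"` has a negative invasion growth rate
#' (external stability against the tumor's founding composition).
#' Coexistence stability is decided numerically only; the symbolic
#' conditions are intractable.
#'
#' @inheritParams invasion_growth_rate
#' @return A list of class `stability_report`: `stable` (logical),
#'   `eigenvalues` (complex, resident block), `external_rates` (named
#'   invasion growth rates of absent `"00"`/`"10"`).
#' @export
is_stable <- function(resident_eq, params) {
  idx <- .type_index(resident_eq$resident_set)
  J <- .jacobian_cells(resident_eq$n_star, resident_eq$R, params)
  ev <- eigen(J[idx, idx, drop = FALSE], only.values = TRUE)$values
  absent <- setdiff(c("00", "10"), resident_eq$resident_set)
  ext <- vapply(absent, invasion_growth_rate, numeric(1L),
                resident_eq = resident_eq, params = params)
  structure(list(stable = all(Re(ev) < 0) && all(ext < 0),
                 eigenvalues = ev,
                 external_rates = ext),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("quasi-equilibrium is", if (x$stable) "STABLE" else "UNSTABLE", "\n")
  cat("  resident-block eigenvalues:",
      paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  if (length(x$external_rates))
    cat("  invasion rates of absent founding clones:",
        paste(names(x$external_rates),
              signif(x$external_rates, 4), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Exact invasion inequality for any absent invader:
#   lambda > 0  <=>  sum_j n_j (C[inv,j] + (alpha/r_inv) K_inv/D_inv) < K_inv
# With the focal dispersal denominator K_inv/D_inv = 1, this is the
# "(coefficient + alpha/r)" form of the printed conditions. Returns the
# verdict with a relative margin (distance of LHS from K_inv).
.invasion_inequality <- function(invader, resident_eq, params) {
  i <- .type_index(invader)
  n <- resident_eq$n_star
  R <- resident_eq$R
  C <- competition_matrix(params)
  K <- .K_vec(R, params)[i]
  D <- .D_vec(R, params)[i]
  r <- .r_vec(params)[i]
  lhs <- sum(n * (C[i, ] + (params$alpha / r) * K / D))
  list(satisfied = lhs < K, margin = abs(K - lhs) / K)
}

#' Exact analytic invasion condition
#'
#' Evaluates, at a resident quasi-equilibrium composed of cheaters and/or
#' local producers, the exact inequality deciding whether a rare
#' pre-metastatic niche constructor can invade:
#' `n00 (c0 + alpha/r_inv) + n10 (c1 + alpha/r_inv) < K_inv(R)`, where
#' `c0`, `c1` are the competition coefficients the invader experiences from
#' the residents under the parameter set's competition structure. The
#' inequality is algebraically equivalent to
#' `invasion_growth_rate(...) > 0`.
#'
#' @param invader `"01"` (secondary producer) or `"11"` (global producer).
#' @inheritParams invasion_growth_rate
#' @return `TRUE`/`FALSE`, with attribute `margin` (relative distance from
#'   the condition boundary); `NA` when the resident set is not a subset of
#'   `{"00", "10"}` or the invader is not a pre-metastatic niche
#'   constructor (not-applicable).
#' @examples
#' p <- model_params()
#' eq <- single_type_equilibrium("10", R = 1e9, p)
#' analytic_invasion_exact("01", eq, p)   # omega vs beta0/beta1
#' @export
analytic_invasion_exact <- function(invader, resident_eq, params) {
  i <- .type_index(invader)
  if (!(.TYPES[i] %in% c("01", "11")) ||
      !all(resident_eq$resident_set %in% c("00", "10")))
    return(NA)
  res <- .invasion_inequality(i, resident_eq, params)
  structure(res$satisfied, margin = res$margin)
}
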