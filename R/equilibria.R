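# Fast-subsystem (cell dynamics) equilibria at frozen resource level R.
#
# Any fixed point of the cell subsystem with all resident clones strictly
# positive satisfies, for each resident i,
#   r_i (1 - (C n)_i / K_i) = alpha N / D_i,
# which is linear in n:  sum_j (r_i C[i,j] + alpha K_i / D_i) n_j = r_i K_i.
# Closed forms for 1- and 2-clone resident sets come straight from this
# system; a hand-written multi-start Newton on the nonlinear right-hand side
# provides the independent numeric route for larger sets and cross-checks.

.new_quasi_eq <- function(resident, n_star, R, params, method) {
  names(n_star) <- .TYPES
  res <- .rhs_cells(n_star, R, params)
  scale <- max(.r_vec(params) * .K_vec(R, params))
  structure(list(resident_set = .TYPES[sort(unique(resident))],
                 n_star = n_star, R = R,
                 residual = max(abs(res)),
                 residual_scale = scale,
                 method = method),
            class = "quasi_equilibrium")
}

#' @export
print.quasi_equilibrium <- function(x, ...) {
  cat(sprintf("quasi-equilibrium (%s) at frozen R = %g\n", x$method, x$R))
  cat("  residents:", paste(x$resident_set, collapse = ", "), "\n")
  print(signif(x$n_star, 8))
  cat(sprintf("  max |rhs| residual: %.3g (scale %.3g)\n",
              x$residual, x$residual_scale))
  invisible(x)
}

# linear fixed-point system restricted to a support; NULL if infeasible
.linear_fixed_point <- function(idx, R, params, feas_tol = 1e-12) {
  C <- competition_matrix(params)
  K <- .K_vec(R, params)
  D <- .D_vec(R, params)
  r <- .r_vec(params)
  a <- params$alpha
  A <- r[idx] * C[idx, idx, drop = FALSE] + a * K[idx] / D[idx]
  b <- r[idx] * K[idx]
  if (rcond(A) < 1e-12)
    stop("degenerate competition geometry: the fixed-point system for ",
         "residents {", paste(.TYPES[idx], collapse = ", "),
         "} at R = ", R, " is singular")
  ns <- solve(A, b)
  if (any(ns <= feas_tol * max(K))) return(NULL)
  n <- numeric(4L)
  n[idx] <- ns
  n
}

#' Single-clone quasi-equilibrium
#'
#' Fixed point of the frozen-R cell dynamics when only one clone is
#' present. Growth balances intravasation at
#' `n* = K(R) * r / (r + alpha)` (focal dispersal denominator), which
#' reduces to the carrying capacity `K(R)` when `alpha = 0`.
#'
#' @param ct The resident clone (label, role or index).
#' @param R Frozen resource level.
#' @param params A [model_params()] object.
#' @return A `quasi_equilibrium` object.
#' @examples
#' single_type_equilibrium("00", R = 0, model_params())
#' @export
single_type_equilibrium <- function(ct, R, params) {
  idx <- .type_index(ct)
  stopifnot(length(idx) == 1L, R >= 0)
  K <- .K_vec(R, params)[idx]
  D <- .D_vec(R, params)[idx]
  r <- .r_vec(params)[idx]
  n <- numeric(4L)
  n[idx] <- r * K / (r + params$alpha * K / D)
  .new_quasi_eq(idx, n, R, params, "closed_form")
}

#' Cheater/local-producer coexistence quasi-equilibrium
#'
#' Solves the two-clone fixed point for residents `{"00", "10"}` at frozen
#' `R`, treating the intravasation term exactly:
#' `r00 (1 - (n00 + c01 n10)/K0) = m00` and
#' `r10 (1 - (c10 n00 + n10)/K1) = m10`, where `c01 = C["00","10"]` and
#' `c10 = C["10","00"]`. With `alpha = 0` this is the classic pair of
#' Lotka-Volterra isoclines `n00 + c01 n10 = K0`, `c10 n00 + n10 = K1`.
#'
#' @inheritParams single_type_equilibrium
#' @param feas_tol Relative positivity threshold: components below
#'   `feas_tol * max(K)` are treated as infeasible.
#' @return A `quasi_equilibrium`, or `NULL` when no feasible (componentwise
#'   positive) coexistence exists at this `R`.
#' @examples
#' coexistence_equilibrium(R = 0, model_params(theta = 0.5, phi = 0.5))
#' @export
coexistence_equilibrium <- function(R, params, feas_tol = 1e-12) {
  stopifnot(R >= 0)
  n <- .linear_fixed_point(c(1L, 3L), R, params, feas_tol)
  if (is.null(n)) return(NULL)
  .new_quasi_eq(c(1L, 3L), n, R, params, "closed_form")
}

#' Quasi-equilibria of the frozen-R cell subsystem
#'
#' Finds the fixed point(s) of the fast cell dynamics restricted to a
#' resident set, with every resident strictly positive and all other clones
#' exactly zero. One- and two-clone sets use the closed forms
#' ([single_type_equilibrium()], [coexistence_equilibrium()]); larger sets
#' (or `method = "root_find"`) use a multi-start Newton iteration on the
#' restricted right-hand side with the analytic Jacobian
#' ([jacobian_fast()]), starting from the vertices and centroid of the box
#' `[0, max K]^s`. Duplicate roots are merged at `1e-6` relative tolerance
#' and every returned equilibrium is verified to satisfy
#' `max |rhs| <= 1e-8 * max(r * K)`.
#'
#' @param R Frozen resource level.
#' @param params A [model_params()] object.
#' @param resident_set Character vector of resident clone labels (or roles,
#'   or indices), e.g. `c("00", "10")`.
#' @param method `"auto"` (closed form when available), `"closed_form"` or
#'   `"root_find"`.
#' @param residual_tol Relative residual bound for accepting a fixed point.
#' @return A list of `quasi_equilibrium` objects (possibly empty when no
#'   feasible equilibrium exists on that support).
#' @examples
#' find_quasi_equilibria(R = 0, model_params(), resident_set = "00")
#' @export
find_quasi_equilibria <- function(R, params, resident_set,
                                  method = c("auto", "closed_form",
                                             "root_find"),
                                  residual_tol = 1e-8) {
  method <- match.arg(method)
  idx <- sort(unique(.type_index(resident_set)))
  if (length(idx) == 0L) stop("resident_set must be nonempty")
  use_closed <- method == "closed_form" ||
    (method == "auto" && length(idx) <= 2L)
  eqs <- if (use_closed) {
    n <- if (length(idx) == 1L) {
      eq <- single_type_equilibrium(idx, R, params)
      eq$n_star
    } else {
      .linear_fixed_point(idx, R, params)
    }
    if (is.null(n)) list() else list(.new_quasi_eq(idx, n, R, params,
                                                   "closed_form"))
  } else {
    .newton_fixed_points(idx, R, params)
  }
  ok <- vapply(eqs, function(e)
    e$residual <= residual_tol * e$residual_scale, logical(1L))
  if (length(eqs) > 0L && !all(ok))
    stop("fixed-point search did not meet the residual bound for residents {",
         paste(.TYPES[idx], collapse = ", "), "} at R = ", R,
         "; worst residual ", signif(max(vapply(eqs, `[[`, 0, "residual")), 3))
  eqs
}

# Multi-start damped Newton on the restricted cell subsystem.
.newton_fixed_points <- function(idx, R, params, max_iter = 200L) {
  Kmax <- max(.K_vec(R, params))
  s <- length(idx)
  # vertices (low/high per coordinate) plus centroid of [0, Kmax]^s;
  # the zero corner is nudged off the boundary so Newton can move
  grid <- as.matrix(expand.grid(rep(list(c(0.02, 1)), s))) * Kmax
  starts <- rbind(grid, rep(0.5 * Kmax, s))
  f_restricted <- function(ns) {
    n <- numeric(4L); n[idx] <- ns
    .rhs_cells(n, R, params)[idx]
  }
  j_restricted <- function(ns) {
    n <- numeric(4L); n[idx] <- ns
    .jacobian_cells(n, R, params)[idx, idx, drop = FALSE]
  }
  roots <- list()
  n_converged <- 0L
  diag_msgs <- character(0)
  for (si in seq_len(nrow(starts))) {
    ns <- starts[si, ]
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      fv <- f_restricted(ns)
      if (max(abs(fv)) <= 1e-12 * max(.r_vec(params)) * Kmax) {
        converged <- TRUE
        break
      }
      J <- j_restricted(ns)
      if (!all(is.finite(J)) || rcond(J) < 1e-14) break
      step <- solve(J, -fv)
      lam <- 1
      repeat {  # backtrack to stay in the positive orthant, damped
        cand <- ns + lam * step
        if (all(cand > 0)) break
        lam <- lam / 2
        if (lam < 1e-8) break
      }
      ns <- pmax(ns + lam * step, 1e-12 * Kmax)
    }
    if (converged) {
      n_converged <- n_converged + 1L
      # roots that collapse onto the boundary of the support are fixed
      # points of a smaller resident set, not interior equilibria
      if (all(ns > 1e-9 * Kmax)) {
        dup <- any(vapply(roots, function(r)
          max(abs(r - ns)) <= 1e-6 * max(abs(ns), 1), logical(1L)))
        if (!dup) roots <- c(roots, list(ns))
      }
    } else {
      diag_msgs <- c(diag_msgs, sprintf("start %d did not converge", si))
    }
  }
  if (n_converged == 0L)
    stop("Newton fixed-point search failed for residents {",
         paste(.TYPES[idx], collapse = ", "), "} at R = ", R, ": ",
         paste(diag_msgs, collapse = "; "))
  lapply(roots, function(ns) {
    n <- numeric(4L); n[idx] <- ns
    .new_quasi_eq(idx, n, R, params, "root_find")
  })
}

#' Resource flow on the quasi-equilibrium manifold
#'
#' The slow dynamics of the resource once the fast cell subsystem has
#' settled at its quasi-equilibrium for the given resident set:
#' `dR/dt = g * (n10*(R) + n11*(R)) - l * R`.
#'
#' @inheritParams find_quasi_equilibria
#' @return `dR/dt` in resource units per day.
#' @examples
#' slow_resource_flow(R = 100, model_params(), resident_set = "10")
#' @export
slow_resource_flow <- function(R, params, resident_set) {
  eqs <- find_quasi_equilibria(R, params, resident_set)
  if (length(eqs) == 0L)
    stop("no feasible quasi-equilibrium for resident set {",
         paste(.TYPES[sort(.type_index(resident_set))], collapse = ", "),
         "} at R = ", R)
  n <- eqs[[1L]]$n_star
  params$g * (n[["10"]] + n[["11"]]) - params$l * R
}

#' Closed-form resource trajectory at frozen producer abundance
#'
#' Exact solution of `dR/dt = g * P - l * R` with constant producer total
#' `P`: `R(t) = g P / l + (R0 - g P / l) exp(-l t)`, with the `l = 0`
#' limit `R(t) = R0 + g P t`. Used as an integration-accuracy oracle.
#'
#' @param t Time(s) in days (vectorized).
#' @param R0 Initial resource level.
#' @param P Constant total abundance of local plus global producers.
#' @param params A [model_params()] object (uses `g` and `l`).
#' @return Resource level(s) at `t`.
#' @examples
#' resource_closed_form(1000, R0 = 1, P = 0, model_params())
#' @export
resource_closed_form <- function(t, R0, P, params) {
  if (params$l == 0) return(R0 + params$g * P * t)
  Rinf <- params$g * P / params$l
  Rinf + (R0 - Rinf) * exp(-params$l * t)
}

#' Serialize quasi-equilibrium reports
#'
#' @param x A `quasi_equilibrium`; `write_equilibrium_report()` also
#'   accepts a list of them.
#' @param ... Unused.
#' @return A data frame with one row per equilibrium: resident set, `R`,
#'   the four abundances, residual and method.
#' @export
as.data.frame.quasi_equilibrium <- function(x, ...) {
  data.frame(resident_set = paste(x$resident_set, collapse = "+"),
             R = x$R,
             n00 = x$n_star[[1L]], n01 = x$n_star[[2L]],
             n10 = x$n_star[[3L]], n11 = x$n_star[[4L]],
             residual = x$residual, method = x$method,
             stringsAsFactors = FALSE)
}

#' @rdname as.data.frame.quasi_equilibrium
#' @param eqs A `quasi_equilibrium` or list of them.
#' @param file Path of the CSV file to write.
#' @export
write_equilibrium_report <- function(eqs, file) {
  if (inherits(eqs, "quasi_equilibrium")) eqs <- list(eqs)
  df <- do.call(rbind, lapply(eqs, as.data.frame))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
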