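#' Interclonal competition matrix
#'
#' Builds the 4x4 competition matrix `C` for the parameter set's competition
#' structure, with the orientation convention `C[i, j]` = competitive effect
#' of clone `j` on clone `i`. Intraclonal competition has magnitude 1
#' (diagonal), interclonal entries are at most 1.
#'
#' * Structure I (general symmetric): row `"00"` is `(1, phi, theta, psi)`,
#'   row `"01"` is `(phi, 1, omega, nu)`, row `"10"` is
#'   `(theta, omega, 1, mu)`, row `"11"` is `(psi, nu, mu, 1)`.
#' * Structure II: as structure I with `omega = nu = mu = 1` — all
#'   producer-producer pairs compete at the intraclonal magnitude.
#' * Structure III (two niches, asymmetric): clones in the same niche
#'   (non-constructors `{"00","01"}` vs constructors `{"10","11"}` of the
#'   local resource) compete at 1; non-constructors experience competition
#'   `theta` from constructors, constructors experience `phi` from
#'   non-constructors.
#'
#' @param params A [model_params()] object.
#' @return A 4x4 numeric matrix with clone labels as dimnames.
#' @examples
#' competition_matrix(model_params(structure = "III", theta = 0.3, phi = 0.7))
#' @export
competition_matrix <- function(params) {
  if (!(params$structure %in% c("I", "II", "III")))
    stop("unknown competition structure: ", params$structure)
  if (params$structure %in% c("I", "II")) {
    om <- if (params$structure == "II") 1 else params$omega
    nu <- if (params$structure == "II") 1 else params$nu
    mu <- if (params$structure == "II") 1 else params$mu
    C <- rbind(c(1,            params$phi, params$theta, params$psi),
               c(params$phi,   1,          om,           nu),
               c(params$theta, om,         1,            mu),
               c(params$psi,   nu,         mu,           1))
  } else {
    C <- matrix(1, 4L, 4L)
    nonprod <- c(1L, 2L)   # x = 0: do not produce R
    prod <- c(3L, 4L)      # x = 1: produce R
    C[nonprod, prod] <- params$theta
    C[prod, nonprod] <- params$phi
  }
  dimnames(C) <- list(.TYPES, .TYPES)
  C
}

#' Resource-dependent carrying capacity
#'
#' The carrying capacity of a clone is its intrinsic value `k` plus the
#' benefit it draws from the constructed resource: `k + beta0 * R` for
#' clones that do not construct the local niche (`x = 0`: cheaters and
#' secondary producers) and `k + beta1 * R` for constructors (`x = 1`:
#' local and global producers).
#'
#' @param ct Clone, as label (`"10"`), role (`"local producer"`) or index;
#'   may be vectorized.
#' @param R Resource level (nonnegative scalar).
#' @param params A [model_params()] object.
#' @return Carrying capacity in cells (strictly positive).
#' @examples
#' carrying_capacity("10", R = 1e5, model_params())  # k + beta1 * R
#' @export
carrying_capacity <- function(ct, R, params) {
  if (R < 0) stop("resource level R must be nonnegative")
  .K_vec(R, params)[.type_index(ct)]
}

#' Density-dependent intravasation (dispersal) rate
#'
#' Per-capita rate at which cells of the focal clone leave the primary
#' tumor for the bloodstream: `m(N, R) = alpha * N / (k + beta_x * R)`,
#' where the denominator is the focal clone's carrying capacity (or the
#' shared `beta0` form when `dispersal_beta = "shared"`). Crowding relative
#' to the carrying capacity drives dispersal; `alpha` is several orders of
#' magnitude smaller than any other rate.
#'
#' @param ct Clone (label, role or index; vectorized).
#' @param N Total number of tumor cells.
#' @inheritParams carrying_capacity
#' @return Dispersal rate in 1/day (nonnegative).
#' @examples
#' dispersal_rate("00", N = 1e5, R = 0, model_params())  # alpha * N / k
#' @export
dispersal_rate <- function(ct, N, R, params) {
  if (N < 0) stop("total cell count N must be nonnegative")
  if (R < 0) stop("resource level R must be nonnegative")
  params$alpha * N / .D_vec(R, params)[.type_index(ct)]
}

#' Tumor state
#'
#' One snapshot of the system: the four clone abundances (cells, continuous)
#' in canonical order, the resource level and the time in days.
#'
#' @param n Length-4 nonnegative vector of clone abundances, canonical order
#'   `c("00", "01", "10", "11")`; a named vector is reordered by name.
#' @param R Resource level (nonnegative).
#' @param t Time in days.
#' @return An object of class `tumor_state`.
#' @examples
#' tumor_state(n = c(1000, 0, 10, 0), R = 1)
#' @export
tumor_state <- function(n, R, t = 0) {
  if (length(n) != 4L) stop("n must have length 4 (one entry per clone)")
  if (!is.null(names(n))) {
    if (!setequal(names(n), .TYPES))
      stop("names of n must be ", paste(.TYPES, collapse = ", "))
    n <- n[.TYPES]
  }
  n <- as.numeric(n)
  if (any(!is.finite(n)) || any(n < 0))
    stop("clone abundances must be finite and nonnegative")
  if (!is.finite(R) || R < 0) stop("resource level R must be nonnegative")
  names(n) <- .TYPES
  structure(list(n = n, R = R, t = t), class = "tumor_state")
}

#' @export
print.tumor_state <- function(x, ...) {
  cat(sprintf("tumor state at t = %g days:\n", x$t))
  print(c(x$n, R = x$R, N = sum(x$n)))
  invisible(x)
}

#' Right-hand side of the governing equations
#'
#' Time derivatives of the four clone abundances and the resource. Each
#' clone follows Lotka-Volterra competition with a resource-dependent
#' carrying capacity and loses cells to intravasation:
#' \deqn{dn_i/dt = r_i n_i (1 - (C n)_i / K_i(R)) - m_i(N, R) n_i,}
#' with `C` from [competition_matrix()], `K_i` from [carrying_capacity()]
#' and `m_i` from [dispersal_rate()]. The resource is produced by local and
#' global producers and decays independently:
#' `dR/dt = g (n10 + n11) - l R`. A clone at zero abundance has derivative
#' exactly zero.
#'
#' @param state A [tumor_state()] (or a list with elements `n` and `R`).
#' @param params A [model_params()] object.
#' @return A list with elements `dn` (length-4 named vector, cells/day) and
#'   `dR` (resource units/day).
#' @examples
#' tumor_rhs(tumor_state(c(1e3, 0, 0, 0), R = 0), model_params())
#' @export
tumor_rhs <- function(state, params) {
  n <- state$n
  R <- state$R
  if (any(n < 0)) stop("clone abundances must be nonnegative")
  if (R < 0) stop("resource level R must be nonnegative")
  d <- .rhs_cells(n, R, params)
  list(dn = stats::setNames(d, .TYPES),
       dR = unname(params$g * (n[3L] + n[4L]) - params$l * R))
}

# cell derivatives only (unnamed, unchecked) -- hot path for the solver
.rhs_cells <- function(n, R, p) {
  C <- competition_matrix(p)
  K <- .K_vec(R, p)
  D <- .D_vec(R, p)
  r <- .r_vec(p)
  N <- sum(n)
  r * n * (1 - as.vector(C %*% n) / K) - (p$alpha * N / D) * n
}
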