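#' Model parameters
#'
#' Collects every rate and coefficient defining one instance of the
#' four-clone niche-construction model. The defaults are the registry set
#' `"fig3_defaults"` (see [param_registry()]): growth rates in units of
#' 1/day (one cell cycle is about one day), the intrinsic carrying capacity
#' `k` in cells, resource-benefit slopes `beta0` (cheaters and secondary
#' producers) and `beta1` (local and global producers) in cells per resource
#' unit, the intravasation constant `alpha` (1/day at `N = k`, `R = 0`),
#' resource production `g` (resource units per producer cell per day) and
#' decay `l` (1/day).
#'
#' Interclonal competition coefficients are dimensionless and bounded by the
#' intraclonal magnitude of 1: `theta`, `phi`, `psi` must lie strictly in
#' (0, 1), while `omega`, `mu`, `nu` may equal 1. Which coefficients are
#' used depends on `structure` (see [competition_matrix()]).
#'
#' Producers are assumed to pay a growth-rate cost, i.e. `r00 > r10`,
#' `r00 > r01` and `r11 < min(r10, r01)`. Violations raise a warning, not an
#' error, so that scenarios in which therapy depresses the cheater growth
#' rate below `r01` remain explorable.
#'
#' @param r00,r01,r10,r11 Per-capita growth rates (1/day) of cheaters,
#'   secondary producers, local producers and global producers.
#' @param k Intrinsic carrying capacity (cells), shared by all clones.
#' @param beta0,beta1 Resource benefit for non-constructors (`x = 0`) and
#'   constructors (`x = 1`) of the local niche; the carrying capacity of a
#'   clone is `k + beta_x * R`. The ratio `beta1/beta0` is the niche
#'   construction specificity.
#' @param alpha Intravasation constant of the dispersal rate
#'   `m = alpha * N / (k + beta_x * R)`.
#' @param g,l Resource production rate per local/global producer cell and
#'   independent resource decay rate.
#' @param structure Competition structure, one of `"I"`, `"II"`, `"III"`.
#' @param theta,phi,psi,omega,mu,nu Interclonal competition coefficients.
#' @param dispersal_beta Which benefit coefficient enters the dispersal
#'   denominator: `"focal"` (default) uses the focal clone's own carrying
#'   capacity, `"shared"` uses the cheater coefficient `beta0` for every
#'   clone (a sensitivity variant).
#' @return An object of class `tumor_model_params` (a validated named list).
#' @seealso [param_registry()], [competition_matrix()], [tumor_rhs()]
#' @examples
#' p <- model_params()             # the default registry values
#' p_iii <- model_params(structure = "III", theta = 0.3, phi = 0.7)
#' @export
model_params <- function(r00 = 0.07, r01 = 0.045, r10 = 0.05, r11 = 0.02,
                         k = 1e5, beta0 = 1, beta1 = 1.2, alpha = 1e-6,
                         g = 0.004, l = 0.001,
                         structure = c("I", "II", "III"),
                         theta = 0.9, phi = 0.9, psi = 0.9,
                         omega = 0.9, mu = 1, nu = 0.9,
                         dispersal_beta = c("focal", "shared")) {
  structure <- match.arg(structure)
  dispersal_beta <- match.arg(dispersal_beta)
  p <- list(r00 = r00, r01 = r01, r10 = r10, r11 = r11,
            k = k, beta0 = beta0, beta1 = beta1, alpha = alpha,
            g = g, l = l, structure = structure,
            theta = theta, phi = phi, psi = psi,
            omega = omega, mu = mu, nu = nu,
            dispersal_beta = dispersal_beta)
  class(p) <- "tumor_model_params"
  validate_model_params(p)
}

#' Validate a parameter set
#'
#' Checks positivity of rates and `k`, nonnegativity of `beta0`, `beta1`,
#' `alpha`, the (0, 1) / (0, 1] bounds on the interclonal competition
#' coefficients, and warns when the producer growth-rate cost ordering
#' `r00 > r10`, `r00 > r01`, `r11 < min(r10, r01)` is violated.
#'
#' @param p A `tumor_model_params` object or a plain named list with the
#'   same fields.
#' @return The validated object, invisibly classed as `tumor_model_params`.
#' @export
validate_model_params <- function(p) {
  for (f in .PARAM_FIELDS) {
    v <- p[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number")
  }
  for (f in c("r00", "r01", "r10", "r11", "k", "g", "l"))
    if (p[[f]] <= 0) stop("parameter '", f, "' must be strictly positive")
  for (f in c("beta0", "beta1", "alpha"))
    if (p[[f]] < 0) stop("parameter '", f, "' must be nonnegative")
  for (f in c("theta", "phi", "psi"))
    if (p[[f]] <= 0 || p[[f]] >= 1)
      stop("parameter '", f, "' must lie strictly in (0, 1)")
  for (f in c("omega", "mu", "nu"))
    if (p[[f]] <= 0 || p[[f]] > 1)
      stop("parameter '", f, "' must lie in (0, 1]")
  if (!(p$structure %in% c("I", "II", "III")))
    stop("unknown competition structure: ", p$structure)
  if (is.null(p$dispersal_beta)) p$dispersal_beta <- "focal"
  if (!(p$dispersal_beta %in% c("focal", "shared")))
    stop("dispersal_beta must be \"focal\" or \"shared\"")
  if (!(p$r00 > p$r10 && p$r00 > p$r01 && p$r11 < min(p$r10, p$r01)))
    warning("growth-rate cost ordering violated: expected r00 > r10, ",
            "r00 > r01 and r11 < min(r10, r01); producers are assumed ",
            "to pay a niche-construction cost", call. = FALSE)
  class(p) <- "tumor_model_params"
  p
}

#' @export
print.tumor_model_params <- function(x, ...) {
  cat("Tumor niche-construction model parameters",
      sprintf("(competition structure %s)\n", x$structure))
  cat(sprintf("  growth rates (1/day): r00=%g r01=%g r10=%g r11=%g\n",
              x$r00, x$r01, x$r10, x$r11))
  cat(sprintf("  carrying capacity: k=%g, benefits beta0=%g beta1=%g",
              x$k, x$beta0, x$beta1),
      sprintf("(specificity beta1/beta0=%.3g)\n", x$beta1 / x$beta0))
  cat(sprintf("  resource: g=%g l=%g; intravasation alpha=%g (%s beta)\n",
              x$g, x$l, x$alpha, x$dispersal_beta))
  cat(sprintf("  competition: theta=%g phi=%g psi=%g omega=%g mu=%g nu=%g\n",
              x$theta, x$phi, x$psi, x$omega, x$mu, x$nu))
  invisible(x)
}

#' Named parameter registry
#'
#' Built-in parameter sets. `"fig3_defaults"` is the reference simulation
#' set: `r00 = 0.07`, `r10 = 0.05`, `r01 = 0.045`, `r11 = 0.02`, `k = 1e5`,
#' `beta0 = 1`, `beta1 = 1.2`, `theta = phi = 0.9`, `g = 0.004`,
#' `l = 0.001`, `alpha = 1e-6`, competition structure I. The coefficients
#' not fixed by that set are an assumption of this package: `psi = omega =
#' nu = 0.9` and `mu = 1`; `mu = 1` makes the producer-only community
#' marginally closed to global producers, so that established producer-only
#' tumors resist all pre-metastatic niche constructors (see the methods
#' vignette for the rationale).
#'
#' @param name Registry entry name; currently `"fig3_defaults"`.
#' @return A `tumor_model_params` object.
#' @examples
#' param_registry("fig3_defaults")$theta
#' @export
param_registry <- function(name = "fig3_defaults") {
  switch(name,
         fig3_defaults = model_params(),
         stop("unknown parameter registry entry: ", name))
}

.r_vec <- function(p) c(p$r00, p$r01, p$r10, p$r11)

# carrying capacities of the four clones at resource level R
.K_vec <- function(R, p) {
  beta <- ifelse(.TYPE_X == 1, p$beta1, p$beta0)
  unname(p$k + beta * R)
}

# dispersal denominators (carrying capacity entering m) per clone
.D_vec <- function(R, p) {
  if (identical(p$dispersal_beta, "shared")) rep(p$k + p$beta0 * R, 4L)
  else .K_vec(R, p)
}
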