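# Forward integration of the full (stiff-ish) system. Carrying capacities
# span 1e5-1e7 cells while alpha ~ 1e-6/day, so the default solver is the
# stiff-capable lsoda.

# closure for deSolve with structure-dependent constants hoisted out
.desolve_func <- function(p) {
  C <- competition_matrix(p)
  r <- .r_vec(p)
  bK <- ifelse(.TYPE_X == 1, p$beta1, p$beta0)
  bD <- if (identical(p$dispersal_beta, "shared")) rep(p$beta0, 4L) else bK
  k <- p$k; a <- p$alpha; g <- p$g; l <- p$l
  function(t, y, parms) {
    n <- pmax(y[1:4], 0)
    R <- max(y[5L], 0)
    K <- k + bK * R
    dn <- r * n * (1 - as.vector(C %*% n) / K) -
      (a * sum(n) / (k + bD * R)) * n
    list(c(dn, g * (n[3L] + n[4L]) - l * R))
  }
}

#' Integrate the full tumor/resource dynamics
#'
#' Solves the five governing equations forward in time with a stiff-capable
#' solver (deSolve's `lsoda` by default) at tight tolerances, clips tiny
#' negative undershoots to zero, and applies a pseudo-extinction rule:
#' a clone is set to exactly zero once its abundance falls below
#' `extinction_threshold` (default 1 cell) *while* its per-capita growth is
#' negative. Without this rule a competitively excluded clone only decays
#' asymptotically and never goes extinct in finite time. Extinctions are
#' recorded in the trajectory's event log.
#'
#' @param params A [model_params()] object.
#' @param initial A [tumor_state()] giving `n` and `R` at time 0.
#' @param horizon Length of the run in days (> 0).
#' @param sample_dt Output sampling interval in days (default 1).
#' @param rtol,atol Relative and absolute solver tolerances (defaults
#'   `1e-8` and `1e-6` cells).
#' @param extinction_threshold Pseudo-extinction threshold in cells; set to
#'   0 to disable.
#' @param method deSolve integration method (default `"lsoda"`).
#' @return A `tumor_trajectory`: list with `times`, a `states` matrix
#'   (columns `n00`, `n01`, `n10`, `n11`, `R`) and an `events` data frame
#'   (`time`, `label`).
#' @examples
#' tr <- integrate_tumor(model_params(alpha = 0),
#'                       tumor_state(c(1e3, 0, 0, 0), R = 0), horizon = 500)
#' utils::tail(as.data.frame(tr), 1)  # n00 has settled at k
#' @export
integrate_tumor <- function(params, initial, horizon, sample_dt = 1,
                            rtol = 1e-8, atol = 1e-6,
                            extinction_threshold = 1, method = "lsoda") {
  if (horizon <= 0) stop("horizon must be positive")
  func <- .desolve_func(params)
  times <- seq(0, horizon, by = sample_dt)
  if (times[length(times)] < horizon) times <- c(times, horizon)
  m <- length(times)
  st <- matrix(NA_real_, m, 5L,
               dimnames = list(NULL, c(.TYPES, "R")))
  y <- c(initial$n, initial$R)
  ev_time <- numeric(0)
  ev_label <- character(0)
  i <- 1L
  st[1L, ] <- y
  while (i < m) {
    # zero clones already under the threshold and declining
    z <- .extinct_now(y, params, extinction_threshold)
    if (any(z)) {
      y[z] <- 0
      st[i, ] <- y
      ev_time <- c(ev_time, rep(times[i], sum(z)))
      ev_label <- c(ev_label, paste0("extinction:", .TYPES[z]))
    }
    tseq <- times[i:m]
    sol <- deSolve::ode(y = y, times = tseq, func = func, parms = NULL,
                        method = method, rtol = rtol, atol = atol)
    if (nrow(sol) < length(tseq) || any(!is.finite(sol)))
      stop("ODE solver failed at t = ", sol[nrow(sol), 1L],
           "; last good state: ",
           paste(signif(sol[nrow(sol), -1L], 6), collapse = ", "))
    chunk <- sol[, -1L, drop = FALSE]
    chunk[, 1:4] <- pmax(chunk[, 1:4], 0)
    stop_j <- .first_extinction_row(chunk, y, params, extinction_threshold)
    j <- if (is.na(stop_j)) nrow(chunk) else stop_j
    st[i:(i + j - 1L), ] <- chunk[1:j, ]
    y <- chunk[j, ]
    i <- i + j - 1L
    if (is.na(stop_j) && i < m) break  # defensive; loop invariant keeps i = m
  }
  .new_trajectory(times, st,
                  data.frame(time = ev_time, label = ev_label,
                             stringsAsFactors = FALSE),
                  params)
}

# clones below threshold with negative per-capita growth, among live ones
.extinct_now <- function(y, params, thr) {
  if (thr <= 0) return(rep(FALSE, 4L))
  n <- y[1:4]
  dn <- .rhs_cells(pmax(n, 0), max(y[5L], 0), params)
  n > 0 & n < thr & dn < 0
}

# first row (>= 2) of an integrated chunk where a live clone should be
# zeroed; NA when no extinction occurs in the chunk
.first_extinction_row <- function(chunk, y0, params, thr) {
  if (thr <= 0) return(NA_integer_)
  alive <- y0[1:4] > 0
  if (!any(alive)) return(NA_integer_)
  below <- sweep(chunk[, 1:4, drop = FALSE] < thr, 2L, alive, `&`)
  cand <- which(rowSums(below) > 0)
  cand <- cand[cand > 1L]
  for (j in cand) {
    dn <- .rhs_cells(chunk[j, 1:4], chunk[j, 5L], params)
    if (any(below[j, ] & dn < 0)) return(j)
  }
  NA_integer_
}

.new_trajectory <- function(times, states, events, params) {
  structure(list(times = times, states = states, events = events,
                 params = params),
            class = "tumor_trajectory")
}

#' @export
print.tumor_trajectory <- function(x, ...) {
  m <- length(x$times)
  cat(sprintf("tumor trajectory: %d samples over %g days\n",
              m, x$times[m] - x$times[1L]))
  last <- x$states[m, ]
  cat(sprintf("  final state: N = %.6g, R = %.6g (%s)\n",
              sum(last[1:4]), last[5L],
              paste(.TYPES, signif(last[1:4], 4), sep = "=",
                    collapse = ", ")))
  if (nrow(x$events))
    cat("  events:", paste(sprintf("%s@%g", x$events$label, x$events$time),
                           collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.tumor_trajectory <- function(x, ...) {
  df <- data.frame(t = x$times, x$states)
  names(df) <- c("t", paste0("n", .TYPES), "R")
  df$N <- rowSums(x$states[, 1:4, drop = FALSE])
  df
}

#' Write a trajectory (and its event log) to CSV
#'
#' @param traj A `tumor_trajectory`.
#' @param file Output CSV path (columns `t`, `n00`, `n01`, `n10`, `n11`,
#'   `R`, `N`).
#' @param events_file Optional path for the event log CSV.
#' @export
write_trajectory <- function(traj, file, events_file = NULL) {
  utils::write.csv(as.data.frame(traj), file, row.names = FALSE)
  if (!is.null(events_file))
    utils::write.csv(traj$events, events_file, row.names = FALSE)
  invisible(traj)
}

#' Detect equilibration of the fast (cell) subsystem
#'
#' Returns the earliest sampled time after which the relative change per
#' day of every clone abundance stays below `tol` for the remainder of the
#' trajectory (the resource may keep drifting — that is the point of the
#' fast/slow separation), requiring at least `window` days of trajectory
#' after the detected time. Relative change uses a one-cell floor so that
#' extinct clones do not produce 0/0.
#'
#' @param traj A `tumor_trajectory`.
#' @param window Minimum number of days the quiescence must span.
#' @param tol Relative change per day below which a population counts as
#'   settled.
#' @return Detection time in days, or `NA` if the populations never
#'   settle.
#' @export
detect_fast_equilibration <- function(traj, window = 50, tol = 1e-4) {
  times <- traj$times
  m <- length(times)
  if (m < 2L) return(times[1L])
  n <- traj$states[, 1:4, drop = FALSE]
  dt <- diff(times)
  rel <- abs(n[-1L, , drop = FALSE] - n[-m, , drop = FALSE]) /
    (dt * pmax(n[-m, , drop = FALSE], 1))
  ok <- rowSums(rel < tol) == 4L
  # earliest i such that every step from i on is quiet
  suffix_ok <- rev(cumprod(rev(ok))) > 0
  idx <- which(suffix_ok & (times[m] - times[-m]) >= window)
  if (length(idx) == 0L) return(NA_real_)
  times[idx[1L]]
}
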