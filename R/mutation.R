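# Stochastic mutation arrivals layered on the deterministic dynamics.
# Between daily mutation draws the tumor evolves deterministically; each
# phenotype-changing mutation moves one (or a Poisson-drawn number of)
# cell(s) from the source clone into the target clone, seeding a rare
# lineage whose fate is then decided by the invasion conditions.

#' Mutation process parameters
#'
#' Daily phenotype-changing mutation process. Each cell mutates at
#' `rate` per day; conditional on a mutation, each one-step phenotype
#' transition (`00 -> 01`, `00 -> 10`, `10 -> 11`, `10 -> 00`) occurs with
#' probability `p_major` and each two-step transition (`00 -> 11`,
#' `01 -> 10`) with probability `p_double`; the residual probability mass
#' is phenotypically silent and is not tracked. Probabilities are read
#' per transition.
#'
#' @param rate Mutation probability per cell per day (default `2e-7`).
#' @param p_major Conditional probability of each one-step transition
#'   (default 1/500).
#' @param p_double Conditional probability of each two-step transition
#'   (default 1/1000).
#' @return An object of class `mutation_params`.
#' @examples
#' transition_table(mutation_params())
#' @export
mutation_params <- function(rate = 2e-7, p_major = 1 / 500,
                            p_double = 1 / 1000) {
  if (!is.numeric(rate) || rate < 0 || rate > 1)
    stop("mutation rate must lie in [0, 1]")
  if (p_major < 0 || p_double < 0)
    stop("transition probabilities must be nonnegative")
  tt <- data.frame(
    source = c("00", "00", "10", "10", "00", "01"),
    target = c("01", "10", "11", "00", "11", "10"),
    prob   = c(rep(p_major, 4L), rep(p_double, 2L)),
    class  = c(rep("one_step", 4L), rep("two_step", 2L)),
    stringsAsFactors = FALSE)
  per_source <- tapply(tt$prob, tt$source, sum)
  if (any(per_source > 1))
    stop("conditional transition probabilities from a source exceed 1")
  structure(list(rate = rate, p_major = p_major, p_double = p_double,
                 transitions = tt),
            class = "mutation_params")
}

#' @rdname mutation_params
#' @param mp A `mutation_params` object.
#' @export
transition_table <- function(mp) mp$transitions

#' Draw phenotype-changing mutation events
#'
#' For each allowed transition, the number of mutating cells over an
#' interval `dt` is Poisson with mean
#' `n_source * rate * dt * p(transition)`. Uses R's global RNG stream.
#'
#' @param state A [tumor_state()].
#' @param dt Interval length in days (> 0).
#' @param mp A [mutation_params()] object.
#' @return A data frame of events (possibly zero rows) with columns `t`,
#'   `source`, `target`, `count`.
#' @examples
#' set.seed(1)
#' mutation_kernel(tumor_state(c(1e7, 0, 0, 0), R = 0), dt = 1,
#'                 mutation_params())
#' @export
mutation_kernel <- function(state, dt = 1, mp) {
  if (dt <= 0) stop("dt must be positive")
  tt <- mp$transitions
  means <- state$n[tt$source] * mp$rate * dt * tt$prob
  counts <- stats::rpois(nrow(tt), means)
  keep <- counts > 0L
  data.frame(t = rep(state$t, sum(keep)),
             source = tt$source[keep], target = tt$target[keep],
             count = counts[keep], stringsAsFactors = FALSE)
}

#' Score the fate of a seeded lineage
#'
#' Deterministic scoring rule for a mutant lineage seeded at low abundance:
#' the lineage is `"established"` once its abundance reaches
#' `max(establish_factor * seeded_cells, establish_frac * N)` while not
#' declining, `"failed"` once it hits zero (the pseudo-extinction rule of
#' [integrate_tumor()] zeroes clones that fall below one cell while
#' declining), and `"pending"` otherwise. A pending verdict at the end of
#' the run is resolved by the sign of the lineage's current per-capita
#' growth rate when `final_percap` is supplied.
#'
#' @param pop Lineage abundance at successive (daily) samples, starting at
#'   the seeding time.
#' @param N Total tumor size at the same samples.
#' @param seeded_cells Cells initially seeded (default 1).
#' @param establish_factor,establish_frac Establishment thresholds (see
#'   above); defaults 100-fold growth or 0.1% of the tumor.
#' @param final_percap Optional growth-rate advantage (1/day) of the
#'   lineage at the last sample — its per-capita growth minus the tumor's
#'   mean per-capita growth — used to resolve a pending verdict. The
#'   relative form matters in growing tumors: a lineage whose absolute
#'   abundance creeps up more slowly than the tumor expands is being
#'   diluted, not established.
#' @return A list with `status` (`"established"`, `"failed"` or
#'   `"pending"`) and `index` (sample index at which the verdict fired,
#'   `NA` while pending).
#' @export
invasion_success <- function(pop, N, seeded_cells = 1,
                             establish_factor = 100,
                             establish_frac = 1e-3,
                             final_percap = NULL) {
  thr <- pmax(establish_factor * seeded_cells, establish_frac * N)
  growing <- c(TRUE, diff(pop) >= 0)
  est <- which(pop >= thr & growing)
  dead <- which(pop <= 0)
  if (length(est) && (!length(dead) || est[1L] < dead[1L]))
    return(list(status = "established", index = est[1L]))
  if (length(dead))
    return(list(status = "failed", index = dead[1L]))
  if (!is.null(final_percap))
    return(list(status = if (final_percap >= 0) "established" else "failed",
                index = length(pop)))
  list(status = "pending", index = NA_integer_)
}

# Resident community among the founding clones {00, 10} at one state row.
# A clone is a *resident* when it makes up a substantial share of the tumor
# (>= resident_frac of N, and past the lineage-establishment scale): a
# transitional minority — a freshly seeded mutant lineage, or a clone being
# competitively excluded — is an invader or a remnant, not a resident, in
# keeping with the fast/slow picture where the resident community is the
# quasi-equilibrium the tumor currently tracks.
.community_label <- function(n, establish_factor = 100,
                             resident_frac = 0.1) {
  N <- sum(n)
  has00 <- n[1L] > 0 && n[1L] >= resident_frac * N
  has10 <- n[3L] >= max(establish_factor, resident_frac * N)
  if (has00 && has10) "coexistence"
  else if (has10) "producer_only"
  else if (has00) "cheater_only"
  else "none"
}

#' Hybrid deterministic/stochastic single-tumor simulation
#'
#' Alternates deterministic integration of the governing equations with
#' daily Poisson mutation draws ([mutation_kernel()]): each day's draw uses
#' the populations at the start of that day and the mutating cells are
#' moved from source to target clone at the day boundary. Every arrival of
#' a mutant transition is recorded together with the resident community
#' (among cheaters and local producers) at the arrival time, and scored
#' with [invasion_success()] on the subsequent lineage trajectory.
#' Demographic noise is neglected except for the seeded lineages — at
#' tumor sizes of `1e5`-`1e7` cells the deterministic approximation is
#' the regime of interest.
#'
#' Integration proceeds internally in multi-day chunks with daily dense
#' output; because each day's mutation draw depends only on that day's
#' starting state and events are applied at day boundaries, the scheme is
#' equivalent to strict daily alternation.
#'
#' @param params A [model_params()] object.
#' @param mp A [mutation_params()] object.
#' @param horizon Run length in whole days.
#' @param seed Optional integer seed (sets the global RNG).
#' @param initial Initial [tumor_state()]; default is the founding tumor
#'   `n00 = 1000` cells, `R = 1`.
#' @param chunk_days Days integrated per solver call (equivalence to daily
#'   stepping does not depend on this).
#' @param extinction_threshold Pseudo-extinction threshold in cells.
#' @param establish_factor,establish_frac Establishment thresholds, see
#'   [invasion_success()].
#' @param rtol,atol Solver tolerances.
#' @return A list with `trajectory` (a `tumor_trajectory`) and `record`
#'   (class `tumor_record`: `seed`, `events` — one row per arrival with
#'   its `resident` community and `outcome` —, `fate`, `fate_time` and
#'   `final_state`).
#' @seealso [run_ensemble()] for the multi-tumor experiment.
#' @examples
#' sim <- simulate_tumor(model_params(), mutation_params(rate = 0),
#'                       horizon = 400, seed = 1)
#' sim$record$fate   # no mutations: stays cheater-only
#' @export
simulate_tumor <- function(params, mp = mutation_params(), horizon = 3650,
                           seed = NULL, initial = NULL, chunk_days = 50,
                           extinction_threshold = 1,
                           establish_factor = 100, establish_frac = 1e-3,
                           rtol = 1e-8, atol = 1e-6) {
  if (horizon <= 0) stop("horizon must be positive")
  horizon <- as.integer(ceiling(horizon))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(initial)) initial <- tumor_state(c(1000, 0, 0, 0), R = 1)
  tt <- mp$transitions
  src_idx <- .type_index(tt$source)
  tgt_idx <- .type_index(tt$target)
  ntr <- nrow(tt)
  states <- matrix(NA_real_, horizon + 1L, 5L,
                   dimnames = list(NULL, c(.TYPES, "R")))
  y <- c(initial$n, initial$R)
  states[1L, ] <- y
  arr <- list()
  ev_time <- numeric(0); ev_label <- character(0)
  day <- 0L
  while (day < horizon) {
    end <- min(day + chunk_days, horizon)
    tr <- integrate_tumor(params, tumor_state(y[1:4], y[5L]),
                          horizon = end - day, sample_dt = 1,
                          rtol = rtol, atol = atol,
                          extinction_threshold = extinction_threshold)
    chunk <- tr$states
    if (nrow(tr$events)) {
      ev_time <- c(ev_time, tr$events$time + day)
      ev_label <- c(ev_label, tr$events$label)
    }
    ndays <- nrow(chunk) - 1L
    # one Poisson draw per transition per day of the chunk, each using
    # that day's starting populations
    means <- chunk[1:ndays, src_idx, drop = FALSE] *
      matrix(mp$rate * tt$prob, ndays, ntr, byrow = TRUE)
    counts <- matrix(stats::rpois(ndays * ntr, means), ndays, ntr)
    hit <- which(rowSums(counts) > 0)
    j <- if (length(hit)) hit[1L] else ndays
    states[(day + 2L):(day + j + 1L), ] <- chunk[2:(j + 1L), ,
                                                 drop = FALSE]
    y <- chunk[j + 1L, ]
    if (length(hit)) {
      for (m in which(counts[j, ] > 0)) {
        mv <- min(counts[j, m], y[src_idx[m]])
        if (mv <= 0) next
        y[src_idx[m]] <- y[src_idx[m]] - mv
        y[tgt_idx[m]] <- y[tgt_idx[m]] + mv
        arr[[length(arr) + 1L]] <- data.frame(
          t = day + j, source = tt$source[m], target = tt$target[m],
          count = mv,
          resident = .community_label(chunk[j, 1:4], establish_factor),
          stringsAsFactors = FALSE)
      }
      states[day + j + 1L, ] <- y
    }
    day <- day + j
  }
  traj <- .new_trajectory(0:horizon, states,
                          data.frame(time = ev_time, label = ev_label,
                                     stringsAsFactors = FALSE), params)
  events <- if (length(arr)) do.call(rbind, arr) else
    data.frame(t = numeric(0), source = character(0),
               target = character(0), count = numeric(0),
               resident = character(0), stringsAsFactors = FALSE)
  events <- .score_arrivals(events, traj, params, establish_factor,
                            establish_frac)
  record <- .classify_record(events, traj, params, seed,
                             extinction_threshold)
  list(trajectory = traj, record = record)
}

# outcome and outcome time for every recorded arrival
.score_arrivals <- function(events, traj, params, establish_factor,
                            establish_frac) {
  m <- nrow(traj$states)
  if (nrow(events) == 0L) {
    events$outcome <- character(0)
    events$outcome_t <- numeric(0)
    return(events)
  }
  events$outcome <- character(nrow(events))
  events$outcome_t <- NA_real_
  final_n <- traj$states[m, 1:4]
  final_dn <- .rhs_cells(final_n, traj$states[m, 5L], params)
  tumor_percap <- sum(final_dn) / max(sum(final_n), .Machine$double.eps)
  # growth advantage over the tumor as a whole (frequency dynamics)
  final_percap <- final_dn / pmax(final_n, .Machine$double.eps) -
    tumor_percap
  for (i in seq_len(nrow(events))) {
    tgt <- .type_index(events$target[i])
    from <- events$t[i] + 1L   # row index of the seeding day boundary
    pop <- traj$states[from:m, tgt]
    N <- rowSums(traj$states[from:m, 1:4, drop = FALSE])
    res <- invasion_success(pop, N, seeded_cells = events$count[i],
                            establish_factor = establish_factor,
                            establish_frac = establish_frac,
                            final_percap = final_percap[tgt])
    events$outcome[i] <- res$status
    events$outcome_t[i] <- if (is.na(res$index)) NA_real_
                           else traj$times[from + res$index - 1L]
  }
  events
}

.classify_record <- function(events, traj, params, seed, thr) {
  m <- nrow(traj$states)
  final <- traj$states[m, ]
  est_meta <- events$target %in% c("01", "11") &
    events$outcome == "established"
  if (any(est_meta)) {
    fate <- "metastasis_competent"
    fate_time <- min(events$outcome_t[est_meta], na.rm = TRUE)
  } else {
    # label by the resident community of the final state: a dwindling
    # remnant undergoing competitive exclusion is not a resident
    comm <- .community_label(final[1:4])
    has00 <- final[1L] > 0
    has_prod <- final[3L] > 0 || final[4L] > 0
    fate <- if (comm %in% c("cheater_only", "producer_only",
                            "coexistence")) comm
            else if (has00 && has_prod) "coexistence"
            else if (has_prod) "producer_only"
            else "cheater_only"
    fate_time <- if (fate == "producer_only" && nrow(traj$events))
      min(traj$events$time[traj$events$label == "extinction:00"],
          Inf)[1L] else NA_real_
    if (is.infinite(fate_time)) fate_time <- NA_real_
  }
  structure(list(seed = seed, events = events, fate = fate,
                 fate_time = fate_time,
                 final_state = tumor_state(final[1:4], unname(final[5L]),
                                           t = traj$times[m])),
            class = "tumor_record")
}

#' Classify the fate of a finished tumor run
#'
#' `"metastasis_competent"` — a secondary (`"01"`) or global (`"11"`)
#' producer lineage established at some point; the existence of such a
#' lineage is the necessary condition for metastasis and dominates every
#' other label. Otherwise the label reflects the resident community of the
#' final state: `"producer_only"` (cheaters extinct, or reduced to a
#' non-resident remnant undergoing competitive exclusion),
#' `"coexistence"`, or `"cheater_only"`.
#'
#' @param record A `tumor_record` from [simulate_tumor()].
#' @return The fate label (character).
#' @export
classify_fate <- function(record) record$fate

#' @export
print.tumor_record <- function(x, ...) {
  cat("tumor record — fate:", x$fate,
      if (!is.na(x$fate_time)) sprintf("(at day %g)", x$fate_time) else "",
      "\n")
  cat(sprintf("  %d mutant arrival(s), %d established\n",
              nrow(x$events), sum(x$events$outcome == "established")))
  print(x$final_state)
  invisible(x)
}

#' Mutation-arrival ensemble experiment
#'
#' Simulates `n_tumors` independent tumors, each starting from the founding
#' cheater-only state, with per-tumor RNG substreams derived from
#' `master_seed`. The summary tabulates tumor fates and stratifies
#' secondary/global-producer arrivals and establishments by the resident
#' community at arrival time — the arrival-versus-invasion trade-off:
#' small cheater-only tumors see few mutations but those mutants invade,
#' while large producer-only tumors accumulate many mutant arrivals that
#' all fail.
#'
#' @param n_tumors Number of tumors (>= 1).
#' @param params A [model_params()] object.
#' @param mp A [mutation_params()] object.
#' @param horizon Run length in days (default one decade).
#' @param master_seed Integer master seed; identical seeds reproduce the
#'   ensemble bit for bit.
#' @param keep_trajectories Keep each tumor's full trajectory (memory-
#'   hungry; default `FALSE` retains records only).
#' @param ... Further arguments passed to [simulate_tumor()].
#' @return An object of class `tumor_ensemble`: `records` (list of
#'   `tumor_record`), `arrivals` (pooled event table with `tumor_id`),
#'   `summary` (fate counts and the arrival/establishment-by-community
#'   table) and, optionally, `trajectories`.
#' @examples
#' \donttest{
#' ens <- run_ensemble(5, model_params(), mutation_params(),
#'                     horizon = 365, master_seed = 1)
#' ens$summary$fates
#' }
#' @export
run_ensemble <- function(n_tumors, params, mp = mutation_params(),
                         horizon = 3650, master_seed = 1,
                         keep_trajectories = FALSE, ...) {
  if (n_tumors < 1L) stop("n_tumors must be at least 1")
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_tumors)
  records <- vector("list", n_tumors)
  trajs <- if (keep_trajectories) vector("list", n_tumors) else NULL
  arr <- vector("list", n_tumors)
  for (i in seq_len(n_tumors)) {
    sim <- simulate_tumor(params, mp, horizon = horizon, seed = seeds[i],
                          ...)
    records[[i]] <- sim$record
    if (keep_trajectories) trajs[[i]] <- sim$trajectory
    ev <- sim$record$events
    if (nrow(ev)) arr[[i]] <- cbind(tumor_id = i, ev)
  }
  arrivals <- if (length(Filter(Negate(is.null), arr)))
    do.call(rbind, Filter(Negate(is.null), arr))
  else cbind(tumor_id = integer(0),
             data.frame(t = numeric(0), source = character(0),
                        target = character(0), count = numeric(0),
                        resident = character(0), outcome = character(0),
                        outcome_t = numeric(0)))
  meta <- arrivals[arrivals$target %in% c("01", "11"), , drop = FALSE]
  tab <- table(factor(meta$resident,
                      levels = c("cheater_only", "producer_only",
                                 "coexistence")),
               factor(meta$outcome == "established",
                      levels = c(FALSE, TRUE),
                      labels = c("failed", "established")))
  fates <- table(factor(vapply(records, classify_fate, character(1L)),
                        levels = c("cheater_only", "producer_only",
                                   "coexistence", "metastasis_competent")))
  structure(list(records = records, arrivals = arrivals,
                 summary = list(fates = fates,
                                arrivals_by_resident = tab,
                                n_tumors = n_tumors,
                                master_seed = master_seed,
                                horizon = horizon),
                 trajectories = trajs),
            class = "tumor_ensemble")
}

#' @export
print.tumor_ensemble <- function(x, ...) {
  s <- x$summary
  cat(sprintf("tumor ensemble: %d tumors, horizon %g days, master seed %s\n",
              s$n_tumors, s$horizon, s$master_seed))
  cat("fates:\n"); print(s$fates)
  cat("secondary/global-producer arrivals by resident community:\n")
  print(s$arrivals_by_resident)
  invisible(x)
}

#' Flat per-tumor summary of an ensemble
#'
#' @param x A `tumor_ensemble`.
#' @param ... Unused.
#' @return A data frame: `tumor_id`, `seed`, `fate`, `fate_time`,
#'   `n_arrivals_01_11`, `n_establishments`, `first_establishment_day`,
#'   final abundances, `R` and `N`.
#' @export
as.data.frame.tumor_ensemble <- function(x, ...) {
  rows <- lapply(seq_along(x$records), function(i) {
    r <- x$records[[i]]
    ev <- r$events
    meta <- ev[ev$target %in% c("01", "11"), , drop = FALSE]
    est <- meta[meta$outcome == "established", , drop = FALSE]
    fin <- r$final_state
    data.frame(tumor_id = i, seed = r$seed, fate = r$fate,
               fate_time = r$fate_time,
               n_arrivals_01_11 = nrow(meta),
               n_establishments = nrow(est),
               first_establishment_day =
                 if (nrow(est)) min(est$outcome_t) else NA_real_,
               n00 = fin$n[[1L]], n01 = fin$n[[2L]],
               n10 = fin$n[[3L]], n11 = fin$n[[4L]],
               R = fin$R, N = sum(fin$n),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write ensemble outputs
#'
#' Writes the flat per-tumor CSV and a JSON file of per-tumor records
#' (arrival events with outcomes, fate, final state).
#'
#' @param ens A `tumor_ensemble`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_ensemble <- function(ens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(ens), file.path(dir, "tumors.csv"),
                   row.names = FALSE)
  recs <- lapply(seq_along(ens$records), function(i) {
    r <- ens$records[[i]]
    list(tumor_id = i, seed = r$seed, fate = r$fate,
         fate_time = r$fate_time, events = r$events,
         final_state = c(as.list(r$final_state$n), R = r$final_state$R))
  })
  jsonlite::write_json(recs, file.path(dir, "records.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
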