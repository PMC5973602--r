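# Configuration files: one flat, human-readable YAML dialect with named
# registries; unknown keys are rejected so typos cannot silently fall back
# to defaults.

.CONFIG_KEYS <- c("registry", "model", "mutation", "initial", "horizon",
                  "seed", "solver", "outputs")
.MODEL_KEYS <- c(.PARAM_FIELDS, "structure", "dispersal_beta")
.MUTATION_KEYS <- c("rate", "p_major", "p_double")
.INITIAL_KEYS <- c("n00", "n01", "n10", "n11", "R")
.SOLVER_KEYS <- c("rtol", "atol", "sample_dt", "extinction_threshold",
                  "chunk_days")

.check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown configuration key", if (length(bad) > 1) "s", " in ",
         where, ": ", paste(bad, collapse = ", "))
  x
}

#' Load (and resolve) a run configuration
#'
#' Reads a YAML configuration with optional sections `model`, `mutation`,
#' `initial`, `horizon`, `seed`, `solver` and `outputs`, resolves it
#' against a named parameter registry (top-level key `registry`, or the
#' `registry` argument; default `"fig3_defaults"`), validates every model
#' invariant (warning on growth-cost ordering violations) and rejects
#' unknown keys by name. An empty (or absent) file yields the registry
#' defaults.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param registry Registry entry used for unspecified model parameters.
#' @return An object of class `run_config` with elements `model`
#'   ([model_params()]), `mutation` ([mutation_params()] or `NULL` when
#'   the file has no `mutation` section), `initial` ([tumor_state()]),
#'   `horizon`, `seed`, `solver` and `outputs`.
#' @examples
#' cfg <- load_config(NULL)          # the default registry configuration
#' cfg$model$r00
#' @export
load_config <- function(path = NULL, registry = "fig3_defaults") {
  y <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    y <- yaml::read_yaml(path)
    if (is.null(y)) y <- list()
  }
  .check_keys(y, .CONFIG_KEYS, "configuration")
  if (!is.null(y$registry)) registry <- y$registry
  base <- unclass(param_registry(registry))
  over <- .check_keys(as.list(y$model), .MODEL_KEYS, "model")
  base[names(over)] <- over
  model <- validate_model_params(base)
  mutation <- NULL
  if (!is.null(y$mutation)) {
    mk <- .check_keys(as.list(y$mutation), .MUTATION_KEYS, "mutation")
    mutation <- do.call(mutation_params, mk)
  }
  ini <- .check_keys(as.list(y$initial), .INITIAL_KEYS, "initial")
  n <- c(`00` = 1000, `01` = 0, `10` = 0, `11` = 0)
  for (f in c("n00", "n01", "n10", "n11"))
    if (!is.null(ini[[f]])) n[[sub("^n", "", f)]] <- ini[[f]]
  initial <- tumor_state(stats::setNames(as.numeric(n), .TYPES),
                         R = if (is.null(ini$R)) 1 else ini$R)
  solver <- .check_keys(as.list(y$solver), .SOLVER_KEYS, "solver")
  solver_full <- list(rtol = 1e-8, atol = 1e-6, sample_dt = 1,
                      extinction_threshold = 1, chunk_days = 50)
  solver_full[names(solver)] <- solver
  structure(list(model = model,
                 mutation = mutation,
                 initial = initial,
                 horizon = if (is.null(y$horizon)) 3650 else y$horizon,
                 seed = y$seed,
                 solver = solver_full,
                 outputs = as.list(y$outputs)),
            class = "run_config")
}

#' Write a resolved configuration
#'
#' Serializes a `run_config` back to YAML with every value resolved, so
#' that the file written into an output directory is a complete,
#' re-loadable provenance record: `load_config(write_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param cfg A `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  m <- unclass(cfg$model)
  out <- list(model = m[c(.MODEL_KEYS)])
  if (!is.null(cfg$mutation))
    out$mutation <- list(rate = cfg$mutation$rate,
                         p_major = cfg$mutation$p_major,
                         p_double = cfg$mutation$p_double)
  out$initial <- list(n00 = cfg$initial$n[[1L]], n01 = cfg$initial$n[[2L]],
                      n10 = cfg$initial$n[[3L]], n11 = cfg$initial$n[[4L]],
                      R = cfg$initial$R)
  out$horizon <- cfg$horizon
  if (!is.null(cfg$seed)) out$seed <- cfg$seed
  out$solver <- cfg$solver
  if (length(cfg$outputs)) out$outputs <- cfg$outputs
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run configuration\n")
  print(x$model)
  if (!is.null(x$mutation))
    cat(sprintf("  mutation: rate=%g, p_major=%g, p_double=%g\n",
                x$mutation$rate, x$mutation$p_major, x$mutation$p_double))
  cat(sprintf("  initial: n=(%s), R=%g; horizon %g days; seed %s\n",
              paste(x$initial$n, collapse = ", "), x$initial$R,
              x$horizon, if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}
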