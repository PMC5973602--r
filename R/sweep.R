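#' Phase-diagram sweep of the analytic condition grid
#'
#' Evaluates [table3_grid()] over a grid of one or two model parameters,
#' producing the raw material for phase diagrams of stability and
#' invasibility (e.g. `theta` against the specificity `beta1/beta0`).
#'
#' @param params Baseline [model_params()] object.
#' @param sweep Named list of one or two numeric vectors; names must be
#'   [model_params()] fields (e.g. `list(theta = seq(0.1, 0.9, 0.1))`).
#' @param structures Competition structures to evaluate (default: the
#'   baseline's).
#' @return A data frame: the swept parameter values, `structure`,
#'   `resident`, `question`, `verdict`, `margin`.
#' @examples
#' head(condition_sweep(model_params(),
#'                      list(theta = c(0.5, 0.9))))
#' @export
condition_sweep <- function(params, sweep,
                            structures = params$structure) {
  if (!length(sweep) || length(sweep) > 2L)
    stop("sweep must name one or two parameters")
  bad <- setdiff(names(sweep), .PARAM_FIELDS)
  if (length(bad))
    stop("unknown sweep parameter: ", paste(bad, collapse = ", "))
  grid <- expand.grid(sweep, KEEP.OUT.ATTRS = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    p <- unclass(params)
    p[names(grid)] <- as.list(grid[i, , drop = FALSE])
    p <- suppressWarnings(validate_model_params(p))
    cbind(grid[rep(i, 1L), , drop = FALSE],
          table3_grid(p, structures = structures),
          row.names = NULL)
  })
  do.call(rbind, out)
}
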