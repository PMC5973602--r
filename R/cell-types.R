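# Canonical clone ordering used by every vector, matrix and file column in
# the package: (x, y) with x = local niche construction, y = pre-metastatic
# niche construction.
.TYPES <- c("00", "01", "10", "11")
.TYPE_X <- c(`00` = 0, `01` = 0, `10` = 1, `11` = 1)
.TYPE_Y <- c(`00` = 0, `01` = 1, `10` = 0, `11` = 1)
.TYPE_ROLE <- c(`00` = "cheater", `01` = "secondary producer",
                `10` = "local producer", `11` = "global producer")

# numeric fields of a tumor_model_params object, in constructor order
.PARAM_FIELDS <- c("r00", "r01", "r10", "r11", "k", "beta0", "beta1",
                   "alpha", "g", "l", "theta", "phi", "psi",
                   "omega", "mu", "nu")

#' The four clonal phenotypes
#'
#' Clones are indexed by a pair of binary flags `(x, y)`: `x = 1` means the
#' clone pays a growth-rate cost to construct the local niche (secreting the
#' shared resource `R` that raises the primary tumor's carrying capacity);
#' `y = 1` means it pays a cost to construct the distant pre-metastatic
#' niche. That gives cheaters `"00"`, secondary producers `"01"`, local
#' producers `"10"` and global producers `"11"`. All vectors and matrices in
#' the package use the fixed order `c("00", "01", "10", "11")`.
#'
#' @return A data frame with one row per clone in canonical order and
#'   columns `label`, `x`, `y` and `role`.
#' @examples
#' cell_types()
#' @export
cell_types <- function() {
  data.frame(label = .TYPES,
             x = unname(.TYPE_X),
             y = unname(.TYPE_Y),
             role = unname(.TYPE_ROLE),
             stringsAsFactors = FALSE)
}

# Resolve a clone given as label ("10"), role ("local producer") or index.
.type_index <- function(ct) {
  if (is.numeric(ct)) {
    idx <- as.integer(ct)
    if (any(idx < 1L | idx > 4L)) stop("cell type index out of range 1..4")
    return(idx)
  }
  ct <- as.character(ct)
  idx <- match(ct, .TYPES)
  miss <- is.na(idx)
  idx[miss] <- match(ct[miss], .TYPE_ROLE)
  if (anyNA(idx)) {
    stop("unknown cell type: ", paste(ct[is.na(idx)], collapse = ", "),
         " (use one of ", paste(.TYPES, collapse = ", "), ")")
  }
  idx
}
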