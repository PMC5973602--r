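# Closed-form stability/invasion verdicts in the limit regime assumed by
# the analytic summary grid: alpha ~ 0, R >> k at producer-containing
# residents and k >> R (R ~ 0) at the cheater-only resident.

.RESIDENT_COMMUNITIES <- c("cheater_only", "producer_only", "coexistence")
.QUESTIONS <- c("stability", "invade_01", "invade_11")

# each entry returns list(expr) where verdict = expr > 0 and the
# dimensionless |expr| is the distance from the condition boundary
.limit_exprs <- function(p) {
  ratio <- p$beta0 / p$beta1   # inverse specificity
  b0 <- p$beta0; b1 <- p$beta1
  th <- p$theta; ph <- p$phi; ps <- p$psi
  om <- p$omega; mu <- p$mu
  bs <- b0 + b1                # scale for the beta-linear forms
  list(
    producer_only = list(
      # stable against cheaters iff theta > beta0/beta1 (all structures)
      stability = list(I = th - ratio, II = th - ratio, III = th - ratio),
      invade_01 = list(I = ratio - om,          # omega < beta0/beta1
                       II = (b0 - b1) / bs,     # beta0 > beta1
                       III = ratio - th),       # theta < beta0/beta1
      invade_11 = list(I = 1 - mu,              # mu < 1
                       II = -Inf,               # never
                       III = -Inf)),            # never
    cheater_only = list(
      stability = list(I = -Inf, II = -Inf, III = -Inf),  # never stable
      invade_01 = list(I = 1 - ph, II = 1 - ph,
                       # order-alpha tie-break at the cheater equilibrium:
                       # sign(lambda_01) = sign(r01 - r00)
                       III = (p$r01 - p$r00) / p$r00),
      invade_11 = list(I = 1 - ps, II = 1 - ps, III = 1 - ph)),
    coexistence = list(
      stability = list(I = NA_real_, II = NA_real_, III = NA_real_),
      invade_01 = list(
        I = (b1 * (ph * th - om) + b0 * (om * th - ph - th^2 + 1)) / bs,
        II = (b0 * (1 + th - ph - th^2) - b1 * (1 - ph * th)) / bs,
        III = (p$r01 - p$r00) / p$r00),
      invade_11 = list(
        I = (b0 * (mu * th - ps) + b1 * (ps * th - mu - th^2 + 1)) / bs,
        II = ((ps - th) * (th * b1 - b0)) / bs,
        # structure III: the global producer's competition row equals the
        # local producer's resident equation, so the index vanishes at
        # order alpha^0 and the tie-break is r11 > r10 — impossible while
        # global producers pay the double construction cost
        III = (p$r11 - p$r10) / p$r10))
  )
}

#' Limit-form stability and invasion conditions
#'
#' The closed-form verdict grid for the three resident communities of a
#' local tumor (cheaters only, local producers only, coexistence) under
#' each competition structure, valid in the separation-of-timescales limit
#' regime: intravasation negligible (`alpha ~ 0`), `R >> k` at
#' producer-containing residents and `R ~ 0` at the cheater-only resident.
#' Representative cells: producer-only stability requires
#' `theta > beta0/beta1` in every structure; secondary producers invade a
#' producer-only tumor iff `omega < beta0/beta1` (structure I),
#' `beta0 > beta1` (II) or `theta < beta0/beta1` (III); global producers
#' can never invade producer-only tumors under structures II and III; the
#' cheater-only community is never stable and is invadable by any producer
#' whenever the corresponding interclonal coefficient is below 1.
#' Coexistence stability has no tractable closed form and yields `NA`
#' (decide it numerically via [is_stable()]).
#'
#' Some structure-III cells are decided at order `alpha` because the
#' invader's competition row coincides with a resident's own equilibrium
#' condition, so every competition term cancels: invasion of secondary
#' producers into cheater-only and coexistence residents reduces to
#' `r01 > r00`, and invasion of global producers into the coexistence
#' resident reduces to `r11 > r10`. All of these fail whenever producers
#' pay their growth-rate costs.
#'
#' @param structure `"I"`, `"II"` or `"III"` (defaults to
#'   `params$structure`).
#' @param resident One of `"cheater_only"`, `"producer_only"`,
#'   `"coexistence"`.
#' @param question One of `"stability"`, `"invade_01"`, `"invade_11"`.
#' @param params A [model_params()] object.
#' @return `TRUE`/`FALSE` with attribute `margin` (dimensionless distance
#'   from the condition boundary; `Inf` for unconditional cells), or `NA`
#'   for the intractable coexistence-stability cells.
#' @examples
#' analytic_condition_limit("I", "producer_only", "stability", model_params())
#' @export
analytic_condition_limit <- function(structure = NULL, resident, question,
                                     params) {
  if (is.null(structure)) structure <- params$structure
  if (!(structure %in% c("I", "II", "III")))
    stop("unknown competition structure: ", structure)
  resident <- match.arg(resident, .RESIDENT_COMMUNITIES)
  question <- match.arg(question, .QUESTIONS)
  expr <- .limit_exprs(params)[[resident]][[question]][[structure]]
  if (is.na(expr)) return(NA)
  structure(expr > 0, margin = abs(expr))
}

#' Full verdict grid for one parameter set
#'
#' Tabulates [analytic_condition_limit()] over every resident community and
#' question for the parameter set's competition structure (or all three
#' structures).
#'
#' @param params A [model_params()] object.
#' @param structures Structures to include; defaults to
#'   `params$structure`.
#' @return A data frame with columns `structure`, `resident`, `question`,
#'   `verdict` (logical, `NA` for the intractable cells) and `margin`.
#' @examples
#' table3_grid(model_params())
#' @export
table3_grid <- function(params, structures = params$structure) {
  grid <- expand.grid(structure = structures,
                      resident = .RESIDENT_COMMUNITIES,
                      question = .QUESTIONS,
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    v <- analytic_condition_limit(grid$structure[i], grid$resident[i],
                                  grid$question[i], params)
    data.frame(verdict = as.logical(v),
               margin = if (is.na(v)[1L]) NA_real_ else attr(v, "margin"))
  })
  cbind(grid, do.call(rbind, out))
}
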