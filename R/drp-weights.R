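#' De-regression constant lambda
#'
#' The shrinkage constant used in de-regression of proofs,
#' \eqn{\lambda = (4 - h^2) / h^2}.
#'
#' @param h2 Trait heritability, in (0, 1].
#' @return The constant \eqn{\lambda}, a positive scalar.
#' @export
lambda_shrinkage <- function(h2) {
  if (!is.numeric(h2) || anyNA(h2) || any(h2 <= 0) || any(h2 > 1)) {
    stop("'h2' must lie in (0, 1]", call. = FALSE)
  }
  (4 - h2) / h2
}

#' Reliability of a de-regressed proof
#'
#' Computes the DRP reliability of a bull from its effective daughter
#' contribution (EDC):
#' \deqn{r^2_{DRP} = EDC / (EDC + \lambda), \quad \lambda = (4 - h^2)/h^2.}
#' Reliability is 0 when EDC is 0 and approaches 1 as EDC grows.
#'
#' @param edc Effective daughter contribution, non-negative (vectorised).
#' @param h2 Trait heritability in (0, 1] (scalar or same length as `edc`).
#' @return Reliability values in `[0, 1)`.
#' @seealso [residual_weight()]
#' @export
drp_reliability <- function(edc, h2) {
  if (!is.numeric(edc) || anyNA(edc) || any(edc < 0)) {
    stop("'edc' must be non-negative", call. = FALSE)
  }
  lam <- lambda_shrinkage(h2)
  edc / (edc + lam)
}

#' Residual weight from DRP reliability
#'
#' Diagonal element of the residual weight matrix D,
#' \eqn{d_i = (1 - r^2_{DRP,i}) / r^2_{DRP,i}}, which scales the residual
#' variance of bull i so that low-reliability DRPs carry less information.
#' Identity: `residual_weight(drp_reliability(edc, h2))` equals
#' `lambda_shrinkage(h2) / edc` exactly.
#'
#' @param reliability DRP reliability in (0, 1) (vectorised).
#' @return Positive weights, strictly decreasing in reliability.
#' @export
residual_weight <- function(reliability) {
  if (!is.numeric(reliability) || anyNA(reliability) ||
      any(reliability <= 0) || any(reliability >= 1)) {
    stop("'reliability' must lie strictly in (0, 1)", call. = FALSE)
  }
  (1 - reliability) / reliability
}

#' Attach DRP reliabilities and residual weights to a phenotype table
#'
#' Adds columns `r2_drp` (from [drp_reliability()]) and `wt` (from
#' [residual_weight()]) to a DRP phenotype table. Reliabilities at or above
#' `r_max` are clamped to `r_max` so the weight stays positive and the mixed
#' model equations remain well posed.
#'
#' @param pheno Data frame with columns `id`, `trait`, `drp`, `edc`, `h2`.
#' @param r_max Maximum admissible reliability (default 0.999).
#' @return The table with `r2_drp` and `wt` columns appended.
#' @export
add_drp_weights <- function(pheno, r_max = 0.999) {
  stopifnot(is.data.frame(pheno),
            all(c("id", "drp", "edc", "h2") %in% names(pheno)))
  r <- drp_reliability(pheno$edc, pheno$h2)
  r <- pmin(r, r_max)
  pheno$r2_drp <- r
  # zero-EDC rows carry no information; weight left infinite would break the
  # solver, so they must be dropped by the caller — flag them clearly
  if (any(r <= 0)) {
    stop("phenotypes with EDC = 0 have zero DRP reliability; remove them first",
         call. = FALSE)
  }
  pheno$wt <- residual_weight(r)
  pheno
}
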