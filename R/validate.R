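#' Forward-validation split at a birth-year boundary
#'
#' Splits phenotyped individuals into a training set (born before `cutoff`)
#' and a validation set (born in or after `cutoff`). Birth years are taken
#' from the pedigree. Deterministic; errors when either side is empty.
#'
#' @param pheno Phenotype table (column `id`).
#' @param ped Pedigree carrying `birth_year` for every phenotyped id.
#' @param cutoff First birth year assigned to validation (default 2010).
#' @return List with character vectors `train` and `validation`.
#' @export
split_by_birth_year <- function(pheno, ped, cutoff = 2010L) {
  ids <- unique(as.character(pheno$id))
  yr <- ped$birth_year[match(ids, ped$id)]
  if (anyNA(yr)) {
    stop("phenotyped ids without a birth year: ",
         paste(utils::head(ids[is.na(yr)], 5), collapse = ", "),
         call. = FALSE)
  }
  val <- ids[yr >= cutoff]
  trn <- ids[yr < cutoff]
  if (!length(trn)) stop("empty training set at cutoff ", cutoff,
                         call. = FALSE)
  if (!length(val)) stop("empty validation set at cutoff ", cutoff,
                         call. = FALSE)
  list(train = trn, validation = val)
}

#' Total genomic breeding value
#'
#' Sums the per-component breeding values from a fit for the requested
#' individuals; for models with the lethal random-regression term the
#' marker effects are mapped through the individuals' lethal genotype codes
#' and added (\eqn{total_i = \sum_k \hat g_{k,i} + \sum_j M_{ij}\hat b_j}).
#'
#' @param fit A `"blup_fit"`.
#' @param ids Individuals to report (must be present in every component).
#' @param lethal_genotypes Lethal-SNP genotype codes for `ids` (required
#'   when the fit has a lethal term).
#' @return Named numeric vector of total (G)EBVs.
#' @export
total_gebv <- function(fit, ids, lethal_genotypes = NULL) {
  stopifnot(inherits(fit, "blup_fit"))
  ids <- as.character(ids)
  tot <- numeric(length(ids))
  for (term in names(fit$effects)) {
    g <- fit$effects[[term]]
    miss <- setdiff(ids, names(g))
    if (length(miss)) stop("ids absent from component '", term, "': ",
                           paste(utils::head(miss, 5), collapse = ", "),
                           call. = FALSE)
    tot <- tot + unname(g[ids])
  }
  if (!is.null(fit$b)) {
    if (is.null(lethal_genotypes)) {
      stop("fit has a lethal-regression term; supply lethal genotype codes",
           call. = FALSE)
    }
    miss <- setdiff(ids, rownames(lethal_genotypes))
    if (length(miss)) stop("ids absent from lethal genotypes", call. = FALSE)
    M <- lethal_genotypes[ids, names(fit$b), drop = FALSE]
    tot <- tot + drop(M %*% fit$b)
  }
  stats::setNames(tot, ids)
}

#' Predictive reliability of genomic breeding values
#'
#' The squared Pearson correlation between predicted breeding values and
#' DRPs, divided by the mean DRP reliability of the validation animals.
#' Values slightly above 1 can occur by sampling noise and are reported
#' as-is.
#'
#' @param gebv Predicted breeding values of the validation animals.
#' @param drp Their DRPs.
#' @param drp_reliability Their DRP reliabilities (the mean is the
#'   denominator).
#' @return The reliability (typically in `[0, 1]`); `NA` when either vector
#'   has zero variance.
#' @export
predictive_reliability <- function(gebv, drp, drp_reliability) {
  if (length(gebv) < 3L || length(gebv) != length(drp)) {
    stop("need >= 3 matched validation animals", call. = FALSE)
  }
  if (stats::sd(gebv) == 0 || stats::sd(drp) == 0) return(NA_real_)
  stats::cor(gebv, drp)^2 / mean(drp_reliability)
}

#' Dispersion bias of genomic predictions
#'
#' Ordinary least-squares regression coefficient of DRP on predicted
#' breeding value. A slope of 1.00 indicates neither inflation nor
#' deflation of the predictions.
#'
#' @param drp DRPs of the validation animals (response).
#' @param gebv Their predicted breeding values (covariate).
#' @return The OLS slope; `NA` when the predictions have zero variance.
#' @export
prediction_bias <- function(drp, gebv) {
  if (length(gebv) != length(drp)) stop("length mismatch", call. = FALSE)
  if (stats::var(gebv) == 0) return(NA_real_)
  stats::cov(drp, gebv) / stats::var(gebv)
}
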