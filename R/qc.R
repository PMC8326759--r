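#' Minor-allele-frequency filter
#'
#' Computes the allele frequency of each SNP from the coded genotypes,
#' \eqn{p_j = \sum_i m_{ij} / (2n)}, and retains SNP j when
#' \eqn{\min(p_j, 1 - p_j) \ge} `threshold` (inclusive boundary by default;
#' set `strict = TRUE` for a strict inequality). Optionally mean-imputes
#' missing codes (rounded to the nearest legal code) before filtering.
#'
#' @param geno Genotype matrix, codes 0/1/2 (NA allowed only with
#'   `impute_missing = TRUE`).
#' @param threshold MAF threshold (default 0.05).
#' @param strict Use `>` instead of `>=` at the boundary.
#' @param impute_missing Replace missing codes by the rounded SNP mean
#'   before filtering.
#' @return List with `genotypes` (the filtered matrix) and `removed`
#'   (character vector of dropped SNP ids).
#' @export
maf_filter <- function(geno, threshold = 0.05, strict = FALSE,
                       impute_missing = FALSE) {
  if (nrow(geno) == 0L || ncol(geno) == 0L) {
    stop("empty genotype matrix", call. = FALSE)
  }
  if (anyNA(geno)) {
    if (!impute_missing) {
      stop("missing genotype codes; set impute_missing = TRUE to mean-impute",
           call. = FALSE)
    }
    mns <- colMeans(geno, na.rm = TRUE)
    for (j in which(colSums(is.na(geno)) > 0L)) {
      geno[is.na(geno[, j]), j] <- as.integer(round(mns[j]))
    }
  }
  p <- colMeans(geno) / 2
  maf <- pmin(p, 1 - p)
  keep <- if (strict) maf > threshold else maf >= threshold
  list(genotypes = geno[, keep, drop = FALSE],
       removed = colnames(geno)[!keep])
}

#' Imputation accuracy of one SNP
#'
#' Pearson correlation between observed and imputed additive codes, and the
#' concordance (proportion of exactly matching codes). When either vector
#' has zero variance the correlation is undefined and reported as `NA`
#' (distinct from 0); the concordance is still returned.
#'
#' @param observed,imputed Equal-length genotype code vectors.
#' @return List with `correlation` (in `[-1, 1]` or `NA`) and `concordance`
#'   (in `[0, 1]`).
#' @export
imputation_accuracy <- function(observed, imputed) {
  if (length(observed) != length(imputed) || length(observed) < 2L) {
    stop("vectors must have equal length >= 2", call. = FALSE)
  }
  conc <- mean(observed == imputed)
  r <- if (stats::sd(observed) == 0 || stats::sd(imputed) == 0) NA_real_
       else stats::cor(observed, imputed)
  list(correlation = r, concordance = conc)
}

#' Per-SNP imputation accuracy table
#'
#' Applies [imputation_accuracy()] column-wise to matched observed/imputed
#' genotype matrices.
#'
#' @param observed,imputed Genotype matrices with identical dimnames.
#' @return Data frame with columns `snp`, `correlation`, `concordance`.
#' @export
imputation_accuracy_table <- function(observed, imputed) {
  stopifnot(identical(dim(observed), dim(imputed)),
            identical(colnames(observed), colnames(imputed)))
  res <- lapply(seq_len(ncol(observed)), function(j) {
    imputation_accuracy(observed[, j], imputed[, j])
  })
  data.frame(snp = colnames(observed),
             correlation = vapply(res, `[[`, numeric(1), "correlation"),
             concordance = vapply(res, `[[`, numeric(1), "concordance"))
}

#' Keep rule on imputation accuracy
#'
#' A SNP is retained only when both its correlation and its concordance are
#' strictly higher than the threshold (default 0.80). An undefined (`NA`)
#' correlation fails the rule.
#'
#' @param metrics Data frame with columns `snp`, `correlation`, `concordance`
#'   (as from [imputation_accuracy_table()]).
#' @param threshold The cutoff both metrics must exceed (default 0.80).
#' @return Character vector of kept SNP ids.
#' @export
imputation_keep_rule <- function(metrics, threshold = 0.80) {
  stopifnot(all(c("snp", "correlation", "concordance") %in% names(metrics)))
  ok <- !is.na(metrics$correlation) &
    metrics$correlation > threshold & metrics$concordance > threshold
  as.character(metrics$snp[ok])
}
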