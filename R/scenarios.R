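#' Run the PBLUP/GBLUP scenario suite on a dataset
#'
#' Reproduces the study design on one dataset: for each trait it fits the
#' requested prediction scenarios, predicts the forward-validation bulls
#' (born at or after the cutoff year) from the training bulls only, and
#' tabulates predictive reliability, dispersion bias and AIC with traits in
#' rows and scenarios in columns.
#'
#' Available scenarios:
#' \describe{
#'   \item{`PBLUP`}{pedigree relationship matrix, five-generation trace.}
#'   \item{`54K`}{one-component GBLUP on the chip SNPs.}
#'   \item{`54K+YSS`, `54K+DFS`, `54K+YSS+DFS`}{one-component GBLUP with the
#'     selected SNP set(s) pooled into the chip GRM.}
#'   \item{`54K*+YSS+DFS+LET`}{one-component GBLUP on the pooled set with
#'     the lethal SNPs removed from the GRM and fitted as a random
#'     regression on their raw genotype codes.}
#'   \item{`2c:54K+YSS`, `2c:54K+DFS`, `2c:54K+YSS+DFS`,
#'     `2c:54K*+YSS+DFS+LET`}{two-component counterparts keeping the chip
#'     and the selected SNPs as separate genetic components.}
#'   \item{`3c:54K+YSS+DFS`}{three-component model used for the
#'     genomic-variance decomposition (adds a `shares` table).}
#' }
#'
#' @param data A dataset as returned by [simulate_population()] (or an
#'   equivalently named list of pedigree, genotypes, snp_sets, phenotypes,
#'   cutoff).
#' @param traits Traits to analyse (default: all in the phenotype table).
#' @param scenarios Scenario names (see above).
#' @param cutoff Validation birth-year boundary (default `data$cutoff`).
#' @param generations_back Pedigree trace depth for PBLUP.
#' @param pd_epsilon Ridge used to keep small-set GRMs positive definite.
#' @param ... Passed to [fit_reml()] (e.g. `maxit`).
#' @return List of data frames `reliability`, `bias`, `aic` (traits x
#'   scenarios), `shares` (variance proportions, three-component scenarios
#'   only), plus `n_train`, `n_validation`, and `varcomp` (per trait x
#'   scenario, long format).
#' @export
run_scenario_suite <- function(data,
                               traits = NULL,
                               scenarios = c("PBLUP", "54K", "54K+YSS",
                                             "54K+DFS", "54K+YSS+DFS",
                                             "54K*+YSS+DFS+LET",
                                             "2c:54K+YSS", "2c:54K+DFS",
                                             "2c:54K+YSS+DFS",
                                             "2c:54K*+YSS+DFS+LET"),
                               cutoff = NULL,
                               generations_back = 5L,
                               pd_epsilon = 1e-6,
                               ...) {
  pheno <- data$phenotypes
  if (!"wt" %in% names(pheno)) pheno <- add_drp_weights(pheno)
  if (is.null(traits)) traits <- unique(pheno$trait)
  if (is.null(cutoff)) cutoff <- data$cutoff
  split <- split_by_birth_year(pheno, data$pedigree, cutoff)
  geno <- data$genotypes
  sets <- data$snp_sets
  chip <- sets$CHIP54K
  chip_star <- exclude_snp_set(chip, sets$LET, name = "CHIP54K*")
  Mlet <- if (length(sets$LET)) geno[, as.character(sets$LET), drop = FALSE]
          else NULL

  cache <- new.env(parent = emptyenv())
  grm <- function(set) {
    key <- attr(set, "name")
    if (is.null(cache[[key]])) {
      cache[[key]] <- repair_positive_definite(
        build_grm_vanraden1(geno, set), pd_epsilon)
    }
    cache[[key]]
  }
  amat <- function() {
    if (is.null(cache[["__A__"]])) {
      cache[["__A__"]] <- build_a_matrix(data$pedigree, rownames(geno),
                                         generations_back)
    }
    cache[["__A__"]]
  }

  scenario_spec <- function(sc) {
    switch(sc,
      "PBLUP" = list(terms = list(a = amat()), lethal = NULL),
      "54K" = list(terms = list(g = grm(chip)), lethal = NULL),
      "54K+YSS" = list(terms = list(
        g = grm(pool_snp_sets(chip, sets$YSS))), lethal = NULL),
      "54K+DFS" = list(terms = list(
        g = grm(pool_snp_sets(chip, sets$DFS))), lethal = NULL),
      "54K+YSS+DFS" = list(terms = list(
        g = grm(pool_snp_sets(chip, sets$YSS, sets$DFS))), lethal = NULL),
      "54K*+YSS+DFS+LET" = list(terms = list(
        g = grm(pool_snp_sets(chip_star, sets$YSS, sets$DFS))),
        lethal = Mlet),
      "2c:54K+YSS" = list(terms = list(
        g54K = grm(chip), gWGS = grm(sets$YSS)), lethal = NULL),
      "2c:54K+DFS" = list(terms = list(
        g54K = grm(chip), gWGS = grm(sets$DFS)), lethal = NULL),
      "2c:54K+YSS+DFS" = list(terms = list(
        g54K = grm(chip),
        gWGS = grm(pool_snp_sets(sets$YSS, sets$DFS))), lethal = NULL),
      "2c:54K*+YSS+DFS+LET" = list(terms = list(
        g54K = grm(chip_star),
        gWGS = grm(pool_snp_sets(sets$YSS, sets$DFS))), lethal = Mlet),
      "3c:54K+YSS+DFS" = list(terms = list(
        g54K = grm(chip), gYSS = grm(sets$YSS), gDFS = grm(sets$DFS)),
        lethal = NULL),
      stop("unknown scenario '", sc, "'", call. = FALSE)
    )
  }

  rel <- bias <- aic <- matrix(NA_real_, length(traits), length(scenarios),
                               dimnames = list(traits, scenarios))
  shares <- list()
  varcomp <- list()
  for (tr in traits) {
    ph_tr <- pheno[pheno$trait == tr, , drop = FALSE]
    ph_train <- ph_tr[ph_tr$id %in% split$train, , drop = FALSE]
    ph_val <- ph_tr[ph_tr$id %in% split$validation, , drop = FALSE]
    for (sc in scenarios) {
      parts <- scenario_spec(sc)
      spec <- model_spec(parts$terms, lethal = parts$lethal, trait = tr)
      fit <- tryCatch(fit_reml(spec, ph_train, ...), error = function(e) {
        stop("scenario '", sc, "', trait '", tr, "': ",
             conditionMessage(e), call. = FALSE)
      })
      gebv <- total_gebv(fit, ph_val$id, lethal_genotypes = Mlet)
      rel[tr, sc] <- predictive_reliability(gebv, ph_val$drp, ph_val$r2_drp)
      bias[tr, sc] <- prediction_bias(ph_val$drp, gebv)
      aic[tr, sc] <- compute_aic(fit)
      varcomp[[paste(tr, sc, sep = "|")]] <-
        data.frame(trait = tr, scenario = sc,
                   parameter = names(fit$varcomp),
                   estimate = unname(fit$varcomp))
      if (startsWith(sc, "3c:")) {
        shares[[paste(tr, sc, sep = "|")]] <-
          data.frame(trait = tr, scenario = sc,
                     term = names(fit$effects),
                     percent = unname(variance_proportions(fit)))
      }
    }
  }
  list(reliability = as.data.frame(rel), bias = as.data.frame(bias),
       aic = as.data.frame(aic),
       shares = if (length(shares)) do.call(rbind, c(shares,
         make.row.names = FALSE)) else NULL,
       varcomp = do.call(rbind, c(varcomp, make.row.names = FALSE)),
       n_train = length(split$train), n_validation = length(split$validation),
       mean_val_drp_reliability = {
         v <- pheno[pheno$id %in% split$validation, , drop = FALSE]
         stats::setNames(vapply(traits, function(tr)
           mean(v$r2_drp[v$trait == tr]), numeric(1)), traits)
       })
}
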