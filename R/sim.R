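#' Configuration of the synthetic Holstein-like population
#'
#' Bundles the knobs of the gene-drop simulator. The defaults describe a
#' scaled-down progeny-tested dairy population: five discrete generations of
#' 500 genotyped bulls after 200 founders (the last generation, born at the
#' validation cutoff year, forms a ~20% forward-validation set), 5,000 chip
#' SNPs plus small selected whole-genome-sequencing-like sets of 98 and 300
#' SNPs planted to carry 6% and 11% of the additive genetic variance, 20
#' recessive-lethal chip SNPs segregating at founder frequency 0.05, four
#' low-heritability survival sub-traits (BP1/BP2/HP1/HP2) and an index trait
#' (YSS), and effective-daughter-contribution (EDC) distributions calibrated
#' so each trait's mean DRP reliability matches its target.
#'
#' @param n_founders Number of founder animals.
#' @param n_generations Number of discrete offspring generations.
#' @param matings_per_generation Matings per generation.
#' @param offspring_per_mating Offspring per mating.
#' @param base_year Founder birth year.
#' @param years_per_generation Birth-year increment per generation.
#' @param n_chip_snps,n_yss_snps,n_dfs_snps Sizes of the chip set and the
#'   two selected SNP sets.
#' @param share_yss,share_dfs Planted shares of the additive genetic
#'   variance for the selected sets (the chip carries the remainder).
#' @param n_lethal Number of recessive-lethal SNPs (a subset of the chip).
#' @param lethal_freq Founder frequency of each lethal allele.
#' @param lethal_penalty Liability penalty for a code-2 (homozygous lethal)
#'   genotype, in genetic standard deviations per locus.
#' @param h2 Named per-trait heritabilities (liability scale).
#' @param drp_target_r2 Named per-trait target mean DRP reliabilities.
#' @param incidence Named per-sub-trait mortality incidences used to
#'   threshold liability into binary survival.
#' @param edc_shape Gamma shape of the EDC distribution.
#' @param index_weights Relative economic weights of the four sub-traits in
#'   the index.
#' @param genetic_var Additive genetic variance of each sub-trait liability.
#' @param validation_cutoff First birth year of the validation set (default:
#'   the last generation's birth year).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_founders = 200L,
                       n_generations = 5L,
                       matings_per_generation = 500L,
                       offspring_per_mating = 1L,
                       base_year = 2000L,
                       years_per_generation = 2L,
                       n_chip_snps = 5000L,
                       n_yss_snps = 98L,
                       n_dfs_snps = 300L,
                       share_yss = 0.06,
                       share_dfs = 0.11,
                       n_lethal = 20L,
                       lethal_freq = 0.05,
                       lethal_penalty = 0.5,
                       h2 = c(YSS = 0.014, BP1 = 0.007, BP2 = 0.027,
                              HP1 = 0.009, HP2 = 0.011),
                       drp_target_r2 = c(YSS = 0.698, BP1 = 0.611,
                                         BP2 = 0.742, HP1 = 0.626,
                                         HP2 = 0.737),
                       incidence = c(BP1 = 0.03, BP2 = 0.04,
                                     HP1 = 0.05, HP2 = 0.08),
                       edc_shape = 8,
                       index_weights = c(BP1 = 1, BP2 = 1, HP1 = 1, HP2 = 1),
                       genetic_var = 1,
                       validation_cutoff = NULL) {
  cfg <- as.list(environment())
  if (is.null(cfg$validation_cutoff)) {
    cfg$validation_cutoff <- base_year + years_per_generation * n_generations
  }
  stopifnot(n_founders >= 2L, n_generations >= 1L,
            matings_per_generation >= 1L, offspring_per_mating >= 1L,
            n_chip_snps >= 1L, n_lethal <= n_chip_snps,
            share_yss >= 0, share_dfs >= 0)
  if (share_yss + share_dfs >= 1) {
    stop("planted variance shares must sum to < 1", call. = FALSE)
  }
  if (any(h2 <= 0 | h2 >= 1)) stop("h2 must lie in (0, 1)", call. = FALSE)
  if (any(drp_target_r2 <= 0 | drp_target_r2 >= 1)) {
    stop("target DRP reliabilities must lie in (0, 1)", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a discrete-generation pedigree
#'
#' Founders (unknown parents, 50/50 sexes) followed by `n_generations`
#' rounds of random mating: each mating samples a sire and a dam from the
#' previous generation; every mating leaves `offspring_per_mating`
#' offspring. Birth years advance by `years_per_generation` per generation,
#' so a birth-year cutoff at the final generation splits it off as a
#' forward-validation set.
#'
#' @param config A [sim_config()].
#' @param seed Optional RNG seed for determinism.
#' @return A [as_pedigree()] data frame; founder ids start with `F`,
#'   generation-g ids with `G<g>_`.
#' @export
simulate_pedigree <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nf <- config$n_founders
  ids <- sprintf("F%04d", seq_len(nf))
  sex <- rep_len(c("M", "F"), nf) # deterministic half-and-half founders
  rec <- data.frame(id = ids, sire = NA_character_, dam = NA_character_,
                    birth_year = config$base_year, stringsAsFactors = FALSE)
  prev_ids <- ids
  prev_sex <- sex
  for (g in seq_len(config$n_generations)) {
    males <- prev_ids[prev_sex == "M"]
    females <- prev_ids[prev_sex == "F"]
    if (!length(males) || !length(females)) {
      stop("generation ", g, " has no available sires or dams; ",
           "increase population sizes", call. = FALSE)
    }
    nm <- config$matings_per_generation
    sires <- sample(males, nm, replace = TRUE)
    dams <- sample(females, nm, replace = TRUE)
    off_sire <- rep(sires, each = config$offspring_per_mating)
    off_dam <- rep(dams, each = config$offspring_per_mating)
    n_off <- length(off_sire)
    off_ids <- sprintf("G%d_%04d", g, seq_len(n_off))
    rec <- rbind(rec, data.frame(
      id = off_ids, sire = off_sire, dam = off_dam,
      birth_year = config$base_year + g * config$years_per_generation,
      stringsAsFactors = FALSE))
    prev_ids <- off_ids
    prev_sex <- sample(c("M", "F"), n_off, replace = TRUE)
  }
  as_pedigree(rec)
}

#' Gene-drop genotypes through a pedigree
#'
#' Founders are sampled in Hardy-Weinberg equilibrium at per-SNP allele
#' frequencies (drawn uniformly on `freq_range` unless given); descendants
#' inherit one allele per parent per locus by Mendelian sampling. Founder
#' SNPs are unlinked, so linkage disequilibrium arises only through
#' cosegregation within the pedigree.
#'
#' @param ped Pedigree (parents need not precede offspring in row order).
#' @param n_snps Number of SNPs (ignored when `founder_freq` is given).
#' @param founder_freq Optional vector of founder allele frequencies, one
#'   per SNP (names become SNP ids).
#' @param freq_range Range for uniform founder frequencies.
#' @param seed Optional RNG seed.
#' @return Genotype matrix (all pedigree individuals x SNPs, codes 0/1/2);
#'   the frequency draw is attached as attribute `founder_freq`.
#' @export
gene_drop_genotypes <- function(ped, n_snps = 1000L, founder_freq = NULL,
                                freq_range = c(0.05, 0.95), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ped <- sort_pedigree(ped)
  n <- nrow(ped)
  if (is.null(founder_freq)) {
    founder_freq <- stats::runif(n_snps, freq_range[1], freq_range[2])
    names(founder_freq) <- sprintf("snp%05d", seq_len(n_snps))
  }
  m <- length(founder_freq)
  snp_ids <- names(founder_freq) %||% sprintf("snp%05d", seq_len(m))
  pos <- stats::setNames(seq_len(n), ped$id)
  si <- unname(pos[ped$sire])
  di <- unname(pos[ped$dam])
  # topological levels: all parents of a level-L individual sit below L, so
  # each level can be drawn in one vectorised block
  lev <- integer(n)
  for (i in seq_len(n)) {
    ps <- c(if (!is.na(si[i])) lev[si[i]], if (!is.na(di[i])) lev[di[i]])
    lev[i] <- if (length(ps)) max(ps) + 1L else 0L
  }
  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)
  draw_gamete <- function(H1p, H2p, k) {
    pick <- matrix(stats::rbinom(k * m, 1L, 0.5), k, m)
    pick * H1p + (1L - pick) * H2p
  }
  for (L in sort(unique(lev))) {
    idx <- which(lev == L)
    k <- length(idx)
    sL <- si[idx]
    founder_side <- is.na(sL)
    if (any(founder_side)) {
      kk <- sum(founder_side)
      H1[idx[founder_side], ] <-
        matrix(stats::rbinom(kk * m, 1L, rep(founder_freq, each = kk)), kk, m)
    }
    if (any(!founder_side)) {
      j <- idx[!founder_side]
      H1[j, ] <- draw_gamete(H1[si[j], , drop = FALSE],
                             H2[si[j], , drop = FALSE], length(j))
    }
    dL <- di[idx]
    founder_side <- is.na(dL)
    if (any(founder_side)) {
      kk <- sum(founder_side)
      H2[idx[founder_side], ] <-
        matrix(stats::rbinom(kk * m, 1L, rep(founder_freq, each = kk)), kk, m)
    }
    if (any(!founder_side)) {
      j <- idx[!founder_side]
      H2[j, ] <- draw_gamete(H1[di[j], , drop = FALSE],
                             H2[di[j], , drop = FALSE], length(j))
    }
  }
  geno <- H1 + H2
  dimnames(geno) <- list(ped$id, snp_ids)
  structure(as_genotypes(geno), founder_freq = founder_freq)
}

#' Standardized weighted index of sub-trait values
#'
#' Standardizes each sub-trait column (mean 0, sd 1), combines them with
#' the supplied relative weights, and standardizes the result, mirroring
#' how a total-merit-style survival index combines sub-trait breeding
#' values weighted by relative economic values.
#'
#' @param values Matrix of sub-trait (estimated or true) breeding values,
#'   individuals in rows.
#' @param weights Numeric weight per column.
#' @return Named numeric vector with mean 0 and sd 1.
#' @export
make_index_trait <- function(values, weights) {
  stopifnot(is.matrix(values), length(weights) == ncol(values))
  sds <- apply(values, 2L, stats::sd)
  if (any(sds == 0)) stop("zero-variance sub-trait", call. = FALSE)
  std <- scale(values)
  idx <- drop(std %*% as.numeric(weights))
  idx <- (idx - mean(idx)) / stats::sd(idx)
  stats::setNames(idx, rownames(values))
}

# Partition SNP ids into the chip / YSS-like / DFS-like / lethal sets, with
# lethal SNPs drawn from the chip, and founder frequencies per set.
.sim_snp_layout <- function(config) {
  chip <- sprintf("chip%05d", seq_len(config$n_chip_snps))
  yss <- if (config$n_yss_snps > 0) sprintf("yss%03d", seq_len(config$n_yss_snps)) else character(0)
  dfs <- if (config$n_dfs_snps > 0) sprintf("dfs%04d", seq_len(config$n_dfs_snps)) else character(0)
  let <- if (config$n_lethal > 0) chip[seq_len(config$n_lethal)] else character(0)
  list(chip = chip, yss = yss, dfs = dfs, let = let)
}

#' Simulate sub-trait genetic values, liabilities and survival
#'
#' Draws additive SNP effects so the chip, YSS-like and DFS-like sets carry
#' the configured shares of the additive genetic variance for each survival
#' sub-trait (effects are rescaled on the realized sample so component
#' variances hit their targets); adds a recessive liability penalty of
#' `lethal_penalty` per homozygous lethal locus; realizes liabilities with
#' environmental noise set by the liability-scale heritability; and records
#' binary survival by thresholding each liability at its incidence
#' quantile. The index trait's true breeding value is the standardized
#' weighted combination of the four sub-trait genetic values.
#'
#' @param geno Genotype matrix from [gene_drop_genotypes()] covering the
#'   chip, YSS-like and DFS-like SNPs.
#' @param config A [sim_config()].
#' @param seed Optional RNG seed.
#' @return A list of class `"sim_truth"`: `tbv` (individuals x traits total
#'   genetic values, lethal contribution included; column `YSS` is the
#'   index), `tbv_polygenic`, `lethal_value`, `liability` and `survival`
#'   matrices for the sub-traits, per-set `effects`, `snp_sets`, and
#'   `realized_shares` (traits x sets).
#' @export
simulate_traits <- function(geno, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lay <- .sim_snp_layout(config)
  sub <- names(config$incidence)
  shares <- c(chip = 1 - config$share_yss - config$share_dfs,
              yss = config$share_yss, dfs = config$share_dfs)
  sets <- list(chip = lay$chip, yss = lay$yss, dfs = lay$dfs)
  sets <- sets[vapply(sets, length, integer(1)) > 0 & shares > 0]
  shares <- shares[names(sets)]
  if (sum(shares) <= 0) stop("no genetic variance planted", call. = FALSE)
  shares <- shares / sum(shares)
  n <- nrow(geno)
  p <- colMeans(geno) / 2
  effects <- stats::setNames(vector("list", length(sub)), sub)
  tbv_poly <- matrix(0, n, length(sub), dimnames = list(rownames(geno), sub))
  comp_var <- matrix(0, length(sub), length(sets),
                     dimnames = list(sub, names(sets)))
  # center each set's genotype block once and reuse it across sub-traits
  for (si in seq_along(sets)) {
    ids <- sets[[si]]
    Z <- sweep(geno[, ids, drop = FALSE], 2L, 2 * p[ids])
    for (tr in sub) {
      a <- stats::rnorm(length(ids))
      cc <- drop(Z %*% a)
      v <- stats::var(cc)
      if (v <= 0) stop("degenerate genetic component for set ",
                       names(sets)[si], call. = FALSE)
      sc <- sqrt(shares[si] * config$genetic_var / v)
      effects[[tr]][[names(sets)[si]]] <- stats::setNames(a * sc, ids)
      tbv_poly[, tr] <- tbv_poly[, tr] + cc * sc
      comp_var[tr, si] <- shares[si] * config$genetic_var
    }
  }
  # recessive penalty: homozygous lethal genotypes lower survival liability
  lethal_value <- matrix(0, n, length(sub),
                         dimnames = list(rownames(geno), sub))
  if (length(lay$let)) {
    hom2 <- rowSums(geno[, lay$let, drop = FALSE] == 2L)
    pen <- -config$lethal_penalty * sqrt(config$genetic_var) * hom2
    lethal_value[] <- pen # same recessive burden acts on every period
  }
  gv <- tbv_poly + lethal_value
  liab <- gv
  surv <- matrix(NA_integer_, n, length(sub),
                 dimnames = list(rownames(geno), sub))
  for (tr in sub) {
    h2 <- config$h2[[tr]]
    e <- stats::rnorm(n, 0, sqrt(config$genetic_var * (1 - h2) / h2))
    liab[, tr] <- gv[, tr] + e
    thr <- stats::quantile(liab[, tr], config$incidence[[tr]])
    surv[, tr] <- as.integer(liab[, tr] > thr)
  }
  idx <- make_index_trait(gv, config$index_weights[sub])
  tbv <- cbind(YSS = idx, gv)
  realized <- comp_var / rowSums(comp_var)
  structure(list(tbv = tbv, tbv_polygenic = tbv_poly,
                 lethal_value = lethal_value, liability = liab,
                 survival = surv, effects = effects,
                 snp_sets = lay, realized_shares = realized),
            class = "sim_truth")
}

#' Calibrate the EDC gamma scale for a target mean reliability
#'
#' Solves for the gamma scale parameter such that the expected DRP
#' reliability \eqn{E[EDC/(EDC+\lambda)]} equals `target_r2` (quantile-grid
#' quadrature + uniroot).
#'
#' @param target_r2 Target mean DRP reliability in (0, 1).
#' @param h2 Trait heritability.
#' @param shape Gamma shape parameter.
#' @return The gamma scale.
#' @export
calibrate_edc_scale <- function(target_r2, h2, shape = 8) {
  stopifnot(target_r2 > 0, target_r2 < 1)
  lam <- lambda_shrinkage(h2)
  grid <- stats::qgamma((seq_len(4096) - 0.5) / 4096, shape, scale = 1)
  mean_rel <- function(th) mean(grid * th / (grid * th + lam)) - target_r2
  th0 <- lam * target_r2 / ((1 - target_r2) * shape)
  stats::uniroot(mean_rel, c(th0 / 50, th0 * 50), tol = 1e-10)$root
}

#' Simulate de-regressed proofs from true breeding values
#'
#' Draws each bull's EDC from a gamma distribution calibrated so the mean
#' DRP reliability matches the trait target, computes the reliability
#' \eqn{r^2_i = EDC_i/(EDC_i + \lambda)}, and sets
#' \eqn{DRP_i = TBV_i + \varepsilon_i} with
#' \eqn{var(\varepsilon_i) = \sigma^2_a (1 - r^2_i)/r^2_i}, so the squared
#' correlation between DRP and TBV matches the reliability in expectation.
#'
#' @param tbv Named vector of true breeding values for one trait.
#' @param trait Trait tag (one of the names in `config$h2`).
#' @param config A [sim_config()].
#' @param seed Optional RNG seed.
#' @return Phenotype data frame (`id`, `trait`, `drp`, `edc`, `h2`).
#' @export
simulate_drp <- function(tbv, trait, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!trait %in% names(config$h2) ||
      !trait %in% names(config$drp_target_r2)) {
    stop("trait '", trait, "' not configured", call. = FALSE)
  }
  h2 <- config$h2[[trait]]
  target <- config$drp_target_r2[[trait]]
  n <- length(tbv)
  scale <- calibrate_edc_scale(target, h2, config$edc_shape)
  edc <- stats::rgamma(n, config$edc_shape, scale = scale)
  r2 <- drp_reliability(edc, h2)
  va <- stats::var(tbv)
  eps <- stats::rnorm(n, 0, sqrt(va * (1 - r2) / r2))
  data.frame(id = names(tbv), trait = trait, drp = unname(tbv) + eps,
             edc = edc, h2 = h2, stringsAsFactors = FALSE)
}

#' Simulate a complete study population
#'
#' Runs the full generator: pedigree, gene-dropped genotypes for the
#' genotyped bulls (all post-founder generations), planted trait
#' architecture, and DRPs for every configured trait. Fully deterministic
#' given `seed`.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @return List with `pedigree`, `genotypes` (genotyped bulls only),
#'   `snp_sets` (named [snp_set()]s: `CHIP54K`, `YSS`, `DFS`, `LET`),
#'   `phenotypes` (all traits stacked, with reliabilities and weights
#'   attached), `truth` (the [simulate_traits()] record restricted to
#'   genotyped bulls), and `cutoff` (the validation birth-year boundary).
#' @export
simulate_population <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  ped <- simulate_pedigree(config)
  lay <- .sim_snp_layout(config)
  all_ids <- c(lay$chip, lay$yss, lay$dfs)
  freq <- stats::runif(length(all_ids), 0.05, 0.95)
  names(freq) <- all_ids
  if (length(lay$let)) freq[lay$let] <- config$lethal_freq
  geno_all <- gene_drop_genotypes(ped, founder_freq = freq)
  genotyped <- ped$id[!is.na(ped$sire) | !is.na(ped$dam)]
  geno <- geno_all[genotyped, , drop = FALSE]
  truth <- simulate_traits(geno, config)
  phen <- do.call(rbind, lapply(colnames(truth$tbv), function(tr) {
    simulate_drp(truth$tbv[, tr], tr, config)
  }))
  phen <- add_drp_weights(phen)
  sets <- list(CHIP54K = snp_set("CHIP54K", lay$chip),
               YSS = snp_set("YSS", lay$yss),
               DFS = snp_set("DFS", lay$dfs),
               LET = snp_set("LET", lay$let))
  list(pedigree = ped, genotypes = geno, snp_sets = sets,
       phenotypes = phen, truth = truth, cutoff = config$validation_cutoff,
       config = config, seed = seed)
}
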