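tiny_cfg <- function(...) {
  sim_config(n_founders = 20, matings_per_generation = 30,
             n_generations = 2, n_chip_snps = 120, n_yss_snps = 10,
             n_dfs_snps = 15, n_lethal = 3, ...)
}

test_that("pedigree simulation has exact counts and is deterministic", {
  cfg <- sim_config(n_founders = 2, matings_per_generation = 1,
                    n_generations = 1, n_chip_snps = 10, n_yss_snps = 0,
                    n_dfs_snps = 0, n_lethal = 0)
  ped <- simulate_pedigree(cfg, seed = 1)
  expect_equal(nrow(ped), 3) # 2 founders + 1 offspring
  cfg2 <- sim_config(n_founders = 30, matings_per_generation = 25,
                     offspring_per_mating = 2, n_generations = 3,
                     n_chip_snps = 10, n_yss_snps = 0, n_dfs_snps = 0,
                     n_lethal = 0)
  ped2 <- simulate_pedigree(cfg2, seed = 2)
  expect_equal(nrow(ped2), 30 + 3 * 25 * 2) # matings x offspring, exact
  expect_identical(simulate_pedigree(cfg2, seed = 7),
                   simulate_pedigree(cfg2, seed = 7))
  # birth years advance by generation so a cutoff isolates the last one
  expect_setequal(unique(ped2$birth_year), c(2000, 2002, 2004, 2006))
})

test_that("gene drop respects Mendelian constraints and founder frequencies", {
  cfg <- tiny_cfg()
  ped <- simulate_pedigree(cfg, seed = 3)
  freq <- setNames(rep(0.5, 50), paste0("s", 1:50))
  g <- gene_drop_genotypes(ped, founder_freq = freq, seed = 4)
  expect_true(all(g %in% 0:2))
  # offspring of 0 x 0 parents are always 0
  offs <- ped[!is.na(ped$sire), ]
  for (j in sample(50, 10)) {
    zz <- offs[g[offs$sire, j] == 0 & g[offs$dam, j] == 0, "id"]
    if (length(zz)) expect_true(all(g[zz, j] == 0))
  }
  # founder-only population: frequencies within binomial sampling error
  fcfg <- sim_config(n_founders = 400, matings_per_generation = 1,
                     n_generations = 1, n_chip_snps = 30, n_yss_snps = 0,
                     n_dfs_snps = 0, n_lethal = 0)
  fped <- simulate_pedigree(fcfg, seed = 5)
  founders <- fped$id[is.na(fped$sire)]
  fg <- gene_drop_genotypes(fped, founder_freq = setNames(rep(0.3, 40),
                                                          paste0("m", 1:40)),
                            seed = 6)
  phat <- colMeans(fg[founders, ]) / 2
  se <- sqrt(0.3 * 0.7 / (2 * 400))
  expect_true(all(abs(phat - 0.3) < 5 * se))
})

test_that("mean GRM tracks the pedigree relationship matrix (gene drop)", {
  set.seed(7)
  ped <- as_pedigree(data.frame(
    id = c("f1", "f2", "f3", "f4", "o1", "o2", "o3", "x1"),
    sire = c(NA, NA, NA, NA, "f1", "f1", "f3", "o1"),
    dam = c(NA, NA, NA, NA, "f2", "f2", "f4", "o3"),
    birth_year = c(rep(2000L, 4), rep(2002L, 3), 2004L)))
  A <- unclass(build_a_matrix(ped))
  freq <- setNames(runif(2000, 0.05, 0.95), paste0("s", 1:2000))
  acc <- matrix(0, nrow(ped), nrow(ped))
  reps <- 30
  for (r in seq_len(reps)) {
    g <- gene_drop_genotypes(ped, founder_freq = freq)
    # center by founder frequencies (the gene-drop base population)
    Z <- sweep(g[ped$id, ], 2, 2 * freq)
    s <- 2 * sum(freq * (1 - freq))
    acc <- acc + tcrossprod(Z) / s
  }
  expect_lt(max(abs(acc / reps - A)), 0.05)
  # founders under Hardy-Weinberg: mean G diagonal near 1 + mean inbreeding
  expect_lt(abs(mean(diag(acc / reps)) - mean(diag(A))), 0.05)
})

test_that("trait simulation plants variance shares and recessive penalties", {
  cfg <- sim_config(n_founders = 100, matings_per_generation = 200,
                    n_generations = 2, n_chip_snps = 400, n_yss_snps = 40,
                    n_dfs_snps = 60, n_lethal = 10, lethal_freq = 0.3)
  sim <- simulate_population(cfg, seed = 8)
  tr <- sim$truth
  # regression oracle for the realized share of the planted sets
  for (t in c("BP1", "HP2")) {
    comp <- lapply(c("chip", "yss", "dfs"), function(s) {
      ids <- tr$snp_sets[[s]]
      p <- colMeans(sim$genotypes[, ids, drop = FALSE]) / 2
      Z <- sweep(sim$genotypes[, ids, drop = FALSE], 2, 2 * p)
      drop(Z %*% tr$effects[[t]][[s]][ids])
    })
    v <- vapply(comp, var, numeric(1))
    expect_equal(v / sum(v), c(0.83, 0.06, 0.11), tolerance = 0.001)
  }
  # homozygous lethal carriers sit strictly lower in liability
  hom <- rowSums(sim$genotypes[, tr$snp_sets$let, drop = FALSE] == 2L) > 0
  expect_true(any(hom))
  expect_lt(mean(tr$lethal_value[hom, "BP1"]), 0)
  expect_true(all(tr$lethal_value[!hom, "BP1"] == 0))
  expect_lt(mean(tr$liability[hom, "BP1"]) - mean(tr$liability[!hom, "BP1"]), 0)
  # survival is binary at the configured incidence
  expect_equal(mean(sim$truth$survival[, "HP2"] == 0),
               cfg$incidence[["HP2"]], tolerance = 0.01)
})

test_that("degenerate trait configurations behave as specified", {
  cfg <- sim_config(n_founders = 40, matings_per_generation = 60,
                    n_generations = 2, n_chip_snps = 150, n_yss_snps = 0,
                    n_dfs_snps = 0, n_lethal = 0, share_yss = 0,
                    share_dfs = 0)
  sim <- simulate_population(cfg, seed = 9)
  expect_equal(unname(sim$truth$realized_shares[, "chip"]),
               rep(1, 4)) # purely polygenic chip trait
  expect_error(sim_config(share_yss = 0.6, share_dfs = 0.5), "< 1")
})

test_that("DRP simulation is calibrated, deterministic and limits to TBV", {
  cfg <- tiny_cfg()
  tbv <- setNames(rnorm(200), paste0("i", 1:200))
  d1 <- simulate_drp(tbv, "BP2", cfg, seed = 10)
  d2 <- simulate_drp(tbv, "BP2", cfg, seed = 10)
  expect_identical(d1, d2)
  # reliability -> 1 limit: DRP converges to TBV
  cfg_hi <- tiny_cfg(drp_target_r2 = c(YSS = 0.9999, BP1 = 0.9999,
                                       BP2 = 0.9999, HP1 = 0.9999,
                                       HP2 = 0.9999))
  dhi <- simulate_drp(tbv, "BP2", cfg_hi, seed = 11)
  expect_gt(cor(dhi$drp, tbv), 0.999)
  expect_error(simulate_drp(tbv, "NOPE", cfg), "NOPE")
})

test_that("EDC calibration hits the target mean reliability", {
  for (tr in c("YSS", "BP1", "BP2")) {
    cfg <- sim_config()
    h2 <- cfg$h2[[tr]]
    target <- cfg$drp_target_r2[[tr]]
    sc <- calibrate_edc_scale(target, h2, cfg$edc_shape)
    set.seed(12)
    edc <- rgamma(2e5, cfg$edc_shape, scale = sc)
    expect_equal(mean(drp_reliability(edc, h2)), target, tolerance = 0.003)
  }
})

test_that("index trait is a standardized weighted combination", {
  set.seed(13)
  m <- matrix(rnorm(400), 100, 4,
              dimnames = list(paste0("i", 1:100), c("a", "b", "c", "d")))
  idx <- make_index_trait(m, c(1, 1, 1, 1))
  expect_equal(mean(idx), 0, tolerance = 1e-10)
  expect_equal(sd(idx), 1, tolerance = 1e-10)
  # single-weight index is the standardized sub-trait
  idx1 <- make_index_trait(m, c(1, 0, 0, 0))
  expect_equal(unname(idx1), unname(scale(m[, 1])[, 1]), tolerance = 1e-10)
  # identical sub-traits with equal weights collapse to one standardization
  mm <- m[, c(1, 1, 1, 1)]
  expect_equal(unname(make_index_trait(mm, rep(1, 4))), unname(idx1),
               tolerance = 1e-10)
  m0 <- m; m0[, 2] <- 3
  expect_error(make_index_trait(m0, rep(1, 4)), "zero-variance")
})

test_that("the full generator is deterministic given a seed", {
  cfg <- tiny_cfg()
  s1 <- simulate_population(cfg, seed = 14)
  s2 <- simulate_population(cfg, seed = 14)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$truth$tbv, s2$truth$tbv)
  s3 <- simulate_population(cfg, seed = 15)
  expect_false(identical(s1$genotypes, s3$genotypes))
})
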