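# Small positive-definite relationship matrix over n ids (random genotypes).
rand_relmat <- function(ids, m = 40, eps = 1e-4) {
  g <- matrix(sample(0:2, length(ids) * m, TRUE), length(ids), m,
              dimnames = list(ids, paste0("s", seq_len(m))))
  repair_positive_definite(build_grm_vanraden1(as_genotypes(g)), eps)
}

test_that("BLUP solutions equal the dense Henderson MME oracle", {
  set.seed(41)
  ids <- sprintf("i%02d", 1:24)
  obs <- ids[1:18] # last six unphenotyped, predicted via covariances
  K1 <- rand_relmat(ids)
  K2 <- rand_relmat(ids)
  ph <- flat_pheno(obs, rnorm(18))
  ph$wt <- runif(18, 0.2, 2) # heterogeneous DRP weights
  # one component
  fit1 <- solve_blup(model_spec(list(g = K1)), ph,
                     c(g = 0.4, residual = 0.6))
  o1 <- mme_oracle(list(g = K1), ph, c(g = 0.4, residual = 0.6))
  expect_equal(fit1$mu, o1$mu, tolerance = 1e-8)
  expect_equal(fit1$effects$g, o1$g, tolerance = 1e-8)
  # two components
  fit2 <- solve_blup(model_spec(list(g54K = K1, gWGS = K2)), ph,
                     c(g54K = 0.3, gWGS = 0.1, residual = 0.6))
  o2 <- mme_oracle(list(g54K = K1, gWGS = K2), ph,
                   c(g54K = 0.3, gWGS = 0.1, residual = 0.6))
  expect_equal(fit2$effects$g54K, o2$g54K, tolerance = 1e-8)
  expect_equal(fit2$effects$gWGS, o2$gWGS, tolerance = 1e-8)
})

test_that("lethal random regression matches the MME oracle", {
  set.seed(42)
  ids <- sprintf("i%02d", 1:20)
  obs <- ids[1:16]
  K <- rand_relmat(ids)
  M <- matrix(sample(0:2, 20 * 5, TRUE, prob = c(0.8, 0.15, 0.05)), 20, 5,
              dimnames = list(ids, paste0("let", 1:5)))
  ph <- flat_pheno(obs, rnorm(16))
  v <- c(g = 0.4, lethal = 0.05, residual = 0.6)
  fit <- solve_blup(model_spec(list(g = K), lethal = M), ph, v)
  o <- mme_oracle(list(g = K), ph, v, M = M)
  expect_equal(fit$mu, o$mu, tolerance = 1e-8)
  expect_equal(fit$effects$g, o$g, tolerance = 1e-8)
  expect_equal(fit$b, o$lethal, tolerance = 1e-8)
})

test_that("three-animal toy with K = I matches the hand-solvable MME", {
  m3 <- diag(3)
  dimnames(m3) <- list(c("a", "b", "c"), c("a", "b", "c"))
  K <- relmat(m3, kind = "genomic")
  ph <- flat_pheno(c("a", "b", "c"), c(1, 2, 3))
  fit <- solve_blup(model_spec(list(g = K)), ph, c(g = 1, residual = 1))
  o <- mme_oracle(list(g = K), ph, c(g = 1, residual = 1))
  expect_equal(fit$mu, o$mu, tolerance = 1e-10)
  expect_equal(fit$effects$g, o$g, tolerance = 1e-10)
  # with K = I and equal variances the shrinkage is (y - mu)/2 around mu = 2
  expect_equal(fit$mu, 2, tolerance = 1e-10)
  expect_equal(unname(fit$effects$g), c(-0.5, 0, 0.5), tolerance = 1e-10)
})

test_that("duplicated component splits the one-component solution in half", {
  set.seed(43)
  ids <- sprintf("i%02d", 1:15)
  K <- rand_relmat(ids)
  ph <- flat_pheno(ids, rnorm(15))
  one <- solve_blup(model_spec(list(g = K)), ph, c(g = 0.8, residual = 0.5))
  two <- solve_blup(model_spec(list(g1 = K, g2 = K)), ph,
                    c(g1 = 0.4, g2 = 0.4, residual = 0.5))
  expect_equal(two$effects$g1, two$effects$g2, tolerance = 1e-10)
  expect_equal(two$effects$g1 + two$effects$g2, one$effects$g,
               tolerance = 1e-8)
})

test_that("as residual variance vanishes the fit interpolates the data", {
  set.seed(44)
  ids <- sprintf("i%02d", 1:12)
  K <- rand_relmat(ids)
  y <- rnorm(12)
  ph <- flat_pheno(ids, y)
  fit <- solve_blup(model_spec(list(g = K)), ph,
                    c(g = 1, residual = 1e-10))
  expect_equal(unname(fit$mu + fit$effects$g[ids]), y, tolerance = 1e-4)
})

test_that("GBLUP equals SNP-BLUP ridge regression (small instance)", {
  set.seed(45)
  n <- 40; m <- 60
  g <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.9)[rep(1:m, each = n)]),
              n, m, dimnames = list(sprintf("i%02d", 1:n), paste0("s", 1:m)))
  g <- as_genotypes(g)
  ph <- flat_pheno(rownames(g)[1:30], rnorm(30))
  ph$wt <- runif(30, 0.5, 1.5)
  G <- build_grm_vanraden1(g)
  fit <- solve_blup(model_spec(list(g = G)), ph, c(g = 0.5, residual = 0.8))
  o <- snpblup_oracle(g, ph, 0.5, 0.8)
  expect_equal(fit$mu, o$mu, tolerance = 1e-6)
  expect_equal(unname(fit$effects$g[rownames(g)]),
               unname(o$gebv[rownames(g)]), tolerance = 1e-6)
})

test_that("REML recovers variances and reports a monotone trajectory", {
  set.seed(46)
  ids <- sprintf("i%03d", 1:300)
  K <- rand_relmat(ids, m = 250)
  y <- draw_gaussian_trait(K, sigma2_g = 0.5, sigma2_e = 0.5)
  fit <- fit_reml(model_spec(list(g = K)), flat_pheno(ids, y))
  expect_true(fit$converged)
  expect_true(all(diff(fit$trajectory) >= -1e-7)) # non-decreasing logL
  expect_gt(fit$varcomp[["g"]], 0.15)
  expect_lt(fit$varcomp[["g"]], 1.2)
  # solve_blup at the REML optimum reproduces the fit's solutions
  fixed <- solve_blup(model_spec(list(g = K)), flat_pheno(ids, y),
                      fit$varcomp)
  expect_equal(fixed$mu, fit$mu, tolerance = 1e-8)
  expect_equal(fixed$effects$g, fit$effects$g, tolerance = 1e-8)
  expect_equal(fixed$logLik, fit$logLik, tolerance = 1e-8)
})

test_that("estimates are invariant to permuting individual order", {
  set.seed(47)
  ids <- sprintf("i%02d", 1:80)
  K <- rand_relmat(ids, m = 100)
  y <- draw_gaussian_trait(K, 0.4, 0.6)
  ph <- flat_pheno(ids, y)
  fit1 <- fit_reml(model_spec(list(g = K)), ph)
  perm <- sample(80)
  K2 <- relmat(unclass(K)[perm, perm], kind = "genomic")
  fit2 <- fit_reml(model_spec(list(g = K2)), ph[perm, ])
  expect_equal(fit1$varcomp, fit2$varcomp, tolerance = 1e-6)
  expect_equal(fit1$logLik, fit2$logLik, tolerance = 1e-7)
  expect_equal(fit1$effects$g[ids], fit2$effects$g[ids], tolerance = 1e-6)
})

test_that("non-convergence raises a condition carrying the trajectory", {
  set.seed(48)
  ids <- sprintf("i%02d", 1:50)
  K <- rand_relmat(ids, m = 60)
  y <- draw_gaussian_trait(K, 0.5, 0.5)
  err <- tryCatch(fit_reml(model_spec(list(g = K)), flat_pheno(ids, y),
                           maxit = 1L),
                  error = identity)
  expect_s3_class(err, "reml_nonconvergence")
  expect_true(length(err$trajectory) >= 2)
})

test_that("AIC is -2 logL + 2 k and deterministic", {
  fake <- structure(list(logLik = -10, k = 2, converged = TRUE),
                    class = "blup_fit")
  expect_equal(compute_aic(fake), 24)
  fake$converged <- FALSE
  expect_error(compute_aic(fake), "converge")
  set.seed(49)
  ids <- sprintf("i%02d", 1:60)
  K <- rand_relmat(ids, m = 80)
  y <- draw_gaussian_trait(K, 0.5, 0.5)
  f1 <- fit_reml(model_spec(list(g = K)), flat_pheno(ids, y))
  f2 <- fit_reml(model_spec(list(g = K)), flat_pheno(ids, y))
  expect_identical(compute_aic(f1), compute_aic(f2))
})

test_that("variance proportions follow the component-share definition", {
  fake <- structure(list(
    varcomp = c(g54K = 0.80, gYSS = 0.06, gDFS = 0.14,
                lethal = 0.3, residual = 2),
    effects = list(g54K = 1, gYSS = 1, gDFS = 1), converged = TRUE),
    class = "blup_fit")
  p <- variance_proportions(fake)
  expect_equal(unname(p), c(80, 6, 14))
  expect_equal(sum(p), 100, tolerance = 1e-9) # residual & lethal excluded
  single <- structure(list(varcomp = c(g = 0.2, residual = 1),
                           effects = list(g = 1), converged = TRUE),
                      class = "blup_fit")
  expect_equal(unname(variance_proportions(single)), 100)
  zero <- structure(list(varcomp = c(g = 0, residual = 1),
                         effects = list(g = 1), converged = TRUE),
                    class = "blup_fit")
  expect_error(variance_proportions(zero), "zero")
})
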