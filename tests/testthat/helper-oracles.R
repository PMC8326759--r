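# Independent oracles used to cross-check the implementation.

# Recursive (top-down, memoised) kinship oracle: phi(i, j) computed by
# descending on the younger individual; A = 2 * phi. Structurally
# independent of the bottom-up tabular method in build_a_matrix().
kinship_oracle <- function(ped) {
  ord <- sort_pedigree(ped)
  gen <- stats::setNames(seq_len(nrow(ord)), ord$id) # topological rank
  sire <- stats::setNames(ord$sire, ord$id)
  dam <- stats::setNames(ord$dam, ord$id)
  memo <- new.env(parent = emptyenv())
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(sort(c(i, j)), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      0.5 * (1 + phi(sire[[i]], dam[[i]]))
    } else {
      # recurse on the individual with the larger topological rank: it can
      # never be an ancestor of the other
      if (gen[[i]] < gen[[j]]) { tmp <- i; i <- j; j <- tmp }
      0.5 * (phi(sire[[i]], j) + phi(dam[[i]], j))
    }
    memo[[key]] <- val
    val
  }
  ids <- ped$id
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (a in ids) for (b in ids) A[a, b] <- 2 * phi(a, b)
  A
}

# Random valid pedigree on n animals (parents always earlier animals).
random_pedigree <- function(n, p_known = 0.7) {
  id <- sprintf("a%02d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i >= 3 && stats::runif(1) < p_known) {
      pick <- sample(i - 1L, 2L)
      sire[i] <- id[pick[1]]
      dam[i] <- id[pick[2]]
    }
  }
  as_pedigree(data.frame(id = id, sire = sire, dam = dam,
                         birth_year = 2000L + seq_len(n)))
}

# Dense Henderson mixed-model-equations oracle. terms: named list of PD
# covariance matrices over all ids (phenotyped or not); M: optional lethal
# code matrix; pheno: data.frame(id, drp, wt); variances: named vector with
# one entry per term (+ "lethal") + "residual". Returns mu, effect vectors
# over all ids of each term, and b.
mme_oracle <- function(terms, pheno, variances, M = NULL) {
  obs <- as.character(pheno$id)
  y <- pheno$drp
  Rinv <- diag(1 / (pheno$wt * variances[["residual"]]),
               length(obs))
  blocks <- list()
  Zs <- list()
  for (nm in names(terms)) {
    K <- unclass(terms[[nm]])
    N <- nrow(K)
    Z <- matrix(0, length(obs), N, dimnames = list(obs, rownames(K)))
    Z[cbind(seq_along(obs), match(obs, rownames(K)))] <- 1
    Zs[[nm]] <- Z
    blocks[[nm]] <- solve(K) / variances[[nm]]
  }
  if (!is.null(M)) {
    Zs[["lethal"]] <- M[obs, , drop = FALSE]
    blocks[["lethal"]] <- diag(1 / variances[["lethal"]], ncol(M))
  }
  X <- matrix(1, length(obs), 1)
  design <- c(list(mu = X), Zs)
  k <- length(design)
  C <- NULL
  rows <- list()
  for (i in seq_len(k)) {
    row_i <- NULL
    for (j in seq_len(k)) {
      blk <- crossprod(design[[i]], Rinv %*% design[[j]])
      row_i <- cbind(row_i, blk)
    }
    rows[[i]] <- row_i
  }
  C <- do.call(rbind, rows)
  sizes <- vapply(design, ncol, integer(1))
  offs <- cumsum(c(0, sizes))
  for (i in seq_along(blocks)) {
    idx <- (offs[i + 1] + 1):(offs[i + 2]) # skip the mu block
    C[idx, idx] <- C[idx, idx] + blocks[[i]]
  }
  rhs <- do.call(rbind, lapply(design, function(Dm) crossprod(Dm, Rinv %*% y)))
  sol <- solve(C, rhs)
  out <- list(mu = sol[1])
  for (i in seq_along(Zs)) {
    idx <- (offs[i + 1] + 1):(offs[i + 2])
    v <- drop(sol[idx])
    names(v) <- colnames(Zs[[i]])
    out[[names(Zs)[i]]] <- v
  }
  out
}

# Ridge-regression SNP-BLUP oracle: marker-effect MME with per-SNP variance
# sigma2_g / s, s the VanRaden scaling constant; GEBV = Zc alpha-hat.
snpblup_oracle <- function(geno, pheno, sigma2_g, sigma2_e) {
  obs <- as.character(pheno$id)
  p <- colMeans(geno) / 2
  keep <- p > 0 & p < 1
  geno <- geno[, keep, drop = FALSE]
  p <- p[keep]
  Zc <- sweep(geno, 2L, 2 * p)
  s <- 2 * sum(p * (1 - p))
  Zo <- Zc[obs, , drop = FALSE]
  Rinv <- diag(1 / (pheno$wt * sigma2_e), length(obs))
  X <- matrix(1, length(obs), 1)
  m <- ncol(Zo)
  C <- rbind(
    cbind(crossprod(X, Rinv %*% X), crossprod(X, Rinv %*% Zo)),
    cbind(crossprod(Zo, Rinv %*% X),
          crossprod(Zo, Rinv %*% Zo) + diag(s / sigma2_g, m)))
  rhs <- rbind(crossprod(X, Rinv %*% pheno$drp),
               crossprod(Zo, Rinv %*% pheno$drp))
  sol <- solve(C, rhs)
  list(mu = sol[1],
       gebv = stats::setNames(drop(Zc %*% sol[-1]), rownames(Zc)))
}

# Equal-information phenotype table (unit weights) for simulation tests.
flat_pheno <- function(ids, y, trait = "T") {
  data.frame(id = as.character(ids), trait = trait, drp = as.numeric(y),
             wt = 1, stringsAsFactors = FALSE)
}

# Draw y = mu + u + e with u ~ N(0, sigma2_g * K), e ~ N(0, sigma2_e * I).
draw_gaussian_trait <- function(K, sigma2_g, sigma2_e, mu = 0) {
  n <- nrow(K)
  L <- chol(unclass(K) + diag(1e-8, n))
  u <- drop(crossprod(L, stats::rnorm(n)) * sqrt(sigma2_g))
  y <- mu + u + stats::rnorm(n, 0, sqrt(sigma2_e))
  stats::setNames(y, rownames(K))
}
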