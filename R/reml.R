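#' Specify a weighted mixed model for DRP analysis
#'
#' Defines the linear mixed model
#' \deqn{y = 1\mu + \sum_k Z g_k + M b + e}
#' with \eqn{g_k \sim N(0, K_k \sigma^2_k)} for each relationship matrix
#' \eqn{K_k} (pedigree A or a genomic G), optionally a random regression on
#' raw recessive-lethal genotype codes \eqn{b \sim N(0, I\sigma^2_b)}, and
#' heteroscedastic residuals \eqn{e \sim N(0, D\sigma^2_e)} with diagonal
#' weights \eqn{d_i = (1 - r^2_{DRP,i})/r^2_{DRP,i}}. The fixed part is the
#' overall mean only. Individuals present in the relationship matrices but
#' absent from the phenotype table (e.g. validation bulls) receive predicted
#' effects through the covariance structure.
#'
#' @param terms Named list of [relmat] matrices, one per random genetic
#'   component (e.g. `list(g54K = G, gYSS = G_yss)` or `list(a = A)`).
#' @param lethal Optional genotype-code matrix M (individuals x lethal SNPs,
#'   raw 0/1/2 codes, not centered) for the random-regression term.
#' @param center_lethal Center the lethal codes by their column means
#'   (affects only the intercept; off by default because the model regresses
#'   on the raw codes).
#' @param trait Optional trait tag carried through to reports.
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(terms, lethal = NULL, center_lethal = FALSE,
                       trait = NULL) {
  stopifnot(is.list(terms))
  if (length(terms) == 0L && is.null(lethal)) {
    stop("model needs at least one random term", call. = FALSE)
  }
  if (is.null(names(terms)) || any(!nzchar(names(terms)))) {
    stop("'terms' must be a named list of relationship matrices",
         call. = FALSE)
  }
  for (nm in names(terms)) {
    K <- terms[[nm]]
    if (!is.matrix(K) || is.null(rownames(K))) {
      stop("term '", nm, "' is not a relationship matrix with id dimnames",
           call. = FALSE)
    }
  }
  if (!is.null(lethal)) {
    stopifnot(is.matrix(lethal), !is.null(rownames(lethal)))
    if (center_lethal) lethal <- sweep(lethal, 2L, colMeans(lethal))
  }
  structure(list(terms = terms, lethal = lethal, trait = trait),
            class = "model_spec")
}

.prepare_mm <- function(spec, pheno) {
  stopifnot(inherits(spec, "model_spec"), is.data.frame(pheno),
            all(c("id", "drp") %in% names(pheno)))
  if (!"wt" %in% names(pheno)) {
    if (all(c("edc", "h2") %in% names(pheno))) {
      pheno <- add_drp_weights(pheno)
    } else {
      stop("phenotypes need a 'wt' column (or 'edc' and 'h2' to derive it)",
           call. = FALSE)
    }
  }
  ids <- as.character(pheno$id)
  if (anyDuplicated(ids)) stop("duplicate phenotype ids", call. = FALSE)
  for (nm in names(spec$terms)) {
    miss <- setdiff(ids, rownames(spec$terms[[nm]]))
    if (length(miss)) {
      stop("phenotyped ids missing from term '", nm, "': ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    }
  }
  B <- lapply(spec$terms, function(K) unclass(K)[ids, ids, drop = FALSE])
  q <- rep.int(length(ids), length(B))
  if (!is.null(spec$lethal)) {
    miss <- setdiff(ids, rownames(spec$lethal))
    if (length(miss)) stop("phenotyped ids missing from lethal genotypes",
                           call. = FALSE)
    Mo <- spec$lethal[ids, , drop = FALSE]
    B <- c(B, list(lethal = tcrossprod(Mo)))
    q <- c(q, ncol(Mo))
  } else {
    Mo <- NULL
  }
  list(y = as.numeric(pheno$drp), d = as.numeric(pheno$wt), ids = ids,
       B = B, q = q, Mo = Mo)
}

# One evaluation of the restricted likelihood and its AI-REML ingredients at
# variance vector theta = (sigma2 per B term, sigma2_e).
.reml_eval <- function(theta, mm) {
  n <- length(mm$y)
  k <- length(mm$B)
  V <- matrix(0, n, n)
  for (i in seq_len(k)) V <- V + theta[i] * mm$B[[i]]
  diag(V) <- diag(V) + theta[k + 1L] * mm$d
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(NULL)
  Vinv <- chol2inv(cV)
  logdetV <- 2 * sum(log(diag(cV)))
  u <- Vinv %*% rep(1, n)
  t1V1 <- sum(u)
  P <- Vinv - tcrossprod(u) / t1V1
  Py <- drop(P %*% mm$y)
  yPy <- sum(mm$y * Py)
  logL <- -0.5 * (logdetV + log(t1V1) + yPy + (n - 1) * log(2 * pi))
  trPB <- numeric(k + 1L)
  yPBPy <- numeric(k + 1L)
  W <- matrix(0, n, k + 1L)
  for (i in seq_len(k)) {
    trPB[i] <- sum(P * mm$B[[i]])
    W[, i] <- mm$B[[i]] %*% Py
  }
  trPB[k + 1L] <- sum(diag(P) * mm$d)
  W[, k + 1L] <- mm$d * Py
  yPBPy <- drop(crossprod(W, Py))
  PW <- P %*% W
  AI <- 0.5 * crossprod(W, PW)
  score <- -0.5 * (trPB - yPBPy)
  list(logL = logL, score = score, AI = AI, trPB = trPB, yPBPy = yPBPy,
       Py = Py, u = drop(u), t1V1 = t1V1)
}

.mm_solutions <- function(spec, mm, theta, ev) {
  k <- length(mm$B)
  mu <- sum(ev$u * mm$y) / ev$t1V1
  effects <- list()
  tn <- names(spec$terms)
  for (i in seq_along(tn)) {
    K <- unclass(spec$terms[[tn[i]]])
    g <- theta[i] * drop(K[, mm$ids, drop = FALSE] %*% ev$Py)
    effects[[tn[i]]] <- stats::setNames(g, rownames(K))
  }
  b <- NULL
  if (!is.null(mm$Mo)) {
    b <- stats::setNames(theta[k] * drop(crossprod(mm$Mo, ev$Py)),
                         colnames(mm$Mo))
  }
  list(mu = mu, effects = effects, b = b)
}

#' Estimate variance components by REML
#'
#' Average-information (AI) REML with step halving and a fallback to the
#' expectation-maximisation update whenever an AI step would decrease the
#' restricted likelihood or leave the parameter space, so the log-likelihood
#' is non-decreasing across iterations. Variances are floored at
#' `1e-8 * var(y)`. Convergence requires both an absolute log-likelihood
#' change below `tol_logl` and a relative parameter change below `tol_par`.
#'
#' Starting values: half the phenotypic variance to the residual, the rest
#' split equally over the random terms (overridable via `init`).
#'
#' @param spec A [model_spec()].
#' @param pheno Phenotype table for the *training* individuals, with columns
#'   `id`, `drp` and `wt` (or `edc` + `h2` from which weights are derived).
#' @param init Optional named starting values
#'   (`c(<term names>, "lethal"?, "residual")`).
#' @param maxit Iteration cap (default 200).
#' @param tol_logl,tol_par Convergence tolerances.
#' @param verbose Print the likelihood trajectory.
#' @return An object of class `"blup_fit"`: variance components
#'   (`$varcomp`), REML log-likelihood (`$logLik`), `$aic`, the intercept
#'   `$mu`, per-term effect vectors over *all* individuals in each
#'   relationship matrix (`$effects`), lethal regression coefficients
#'   (`$b`), and convergence diagnostics.
#' @references VanRaden-style GBLUP with heterogeneous residual weights;
#'   Johnson & Thompson (1995) for the AI/EM updates.
#' @export
fit_reml <- function(spec, pheno, init = NULL, maxit = 200L,
                     tol_logl = 1e-8, tol_par = 1e-6, verbose = FALSE) {
  mm <- .prepare_mm(spec, pheno)
  k <- length(mm$B)
  vy <- stats::var(mm$y)
  floor_v <- 1e-8 * vy
  par_names <- c(names(mm$B), "residual")
  theta <- c(rep(0.5 * vy / k, k), 0.5 * vy)
  names(theta) <- par_names
  if (!is.null(init)) {
    stopifnot(all(names(init) %in% par_names))
    theta[names(init)] <- init
  }
  theta <- pmax(theta, floor_v)
  ev <- .reml_eval(theta, mm)
  if (is.null(ev)) stop("covariance matrix not positive definite at start",
                        call. = FALSE)
  traj <- ev$logL
  converged <- FALSE
  iter <- 0L
  final_dl <- NA_real_
  qvec <- c(mm$q, length(mm$y))
  while (iter < maxit) {
    iter <- iter + 1L
    cand <- NULL
    # AI (Newton on the average information) with step halving
    delta <- tryCatch(solve(ev$AI, ev$score), error = function(e) NULL)
    if (!is.null(delta) && all(is.finite(delta))) {
      step <- 1
      for (h in 1:5) {
        prop <- pmax(theta + step * delta, floor_v)
        pe <- .reml_eval(prop, mm)
        if (!is.null(pe) && is.finite(pe$logL) &&
            pe$logL >= ev$logL - 1e-12) {
          cand <- list(theta = prop, ev = pe)
          break
        }
        step <- step / 2
      }
    }
    if (is.null(cand)) { # EM fallback: guaranteed ascent direction
      prop <- pmax(theta + theta^2 * (ev$yPBPy - ev$trPB) / qvec, floor_v)
      pe <- .reml_eval(prop, mm)
      if (is.null(pe)) stop("covariance matrix lost positive definiteness",
                            call. = FALSE)
      cand <- list(theta = prop, ev = pe)
    }
    dl <- cand$ev$logL - ev$logL
    dpar <- max(abs(cand$theta - theta) / pmax(abs(theta), floor_v))
    theta <- cand$theta
    ev <- cand$ev
    traj <- c(traj, ev$logL)
    final_dl <- dl
    if (verbose) message(sprintf("it %3d  logL %.8f  dlogL %.2e", iter,
                                 ev$logL, dl))
    if (abs(dl) < tol_logl && dpar < tol_par) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(errorCondition(
      sprintf("REML did not converge in %d iterations (last dlogL = %.3e)",
              maxit, final_dl),
      trajectory = traj, class = "reml_nonconvergence"))
  }
  sol <- .mm_solutions(spec, mm, theta, ev)
  kpar <- length(theta)
  structure(list(varcomp = theta, logLik = ev$logL,
                 aic = -2 * ev$logL + 2 * kpar, k = kpar,
                 mu = sol$mu, effects = sol$effects, b = sol$b,
                 converged = TRUE, iterations = iter,
                 final_dlogl = final_dl, trajectory = traj,
                 trait = spec$trait, n_obs = length(mm$y),
                 method = "reml"),
            class = "blup_fit")
}

#' Solve the mixed model at fixed variance components
#'
#' One generalized-least-squares/BLUP pass at user-supplied variances; with
#' the REML estimates it reproduces the [fit_reml()] solutions.
#'
#' @param spec A [model_spec()].
#' @param pheno Training phenotype table (as in [fit_reml()]).
#' @param variances Named vector: one value per term in `spec`, plus
#'   `"lethal"` when the lethal term is present, plus `"residual"`.
#' @return A `"blup_fit"` (with `method = "fixed"`).
#' @export
solve_blup <- function(spec, pheno, variances) {
  mm <- .prepare_mm(spec, pheno)
  par_names <- c(names(mm$B), "residual")
  miss <- setdiff(par_names, names(variances))
  if (length(miss)) stop("missing variances for: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  theta <- variances[par_names]
  if (any(theta < 0)) stop("variances must be non-negative", call. = FALSE)
  ev <- .reml_eval(theta, mm)
  if (is.null(ev)) stop("singular or non-positive-definite covariance matrix",
                        call. = FALSE)
  sol <- .mm_solutions(spec, mm, theta, ev)
  kpar <- length(theta)
  structure(list(varcomp = theta, logLik = ev$logL,
                 aic = -2 * ev$logL + 2 * kpar, k = kpar,
                 mu = sol$mu, effects = sol$effects, b = sol$b,
                 converged = TRUE, iterations = 0L,
                 final_dlogl = NA_real_, trajectory = ev$logL,
                 trait = spec$trait, n_obs = length(mm$y),
                 method = "fixed"),
            class = "blup_fit")
}

#' @export
print.blup_fit <- function(x, ...) {
  cat(sprintf("Weighted BLUP fit (%s), n = %d%s\n", x$method, x$n_obs,
              if (!is.null(x$trait)) paste0(", trait ", x$trait) else ""))
  print(round(x$varcomp, 6))
  cat(sprintf("logLik %.4f  AIC %.4f  (%d iterations)\n",
              x$logLik, x$aic, x$iterations))
  invisible(x)
}

#' Akaike information criterion of a fit
#'
#' `AIC = -2 logL + 2k` on the REML log-likelihood, `k` counting the
#' estimated variance parameters (the mean is absorbed by REML). Only
#' differences between models fitted to the same data are meaningful.
#'
#' @param fit A converged `"blup_fit"`.
#' @return The AIC (lower is better).
#' @export
compute_aic <- function(fit) {
  stopifnot(inherits(fit, "blup_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  -2 * fit$logLik + 2 * fit$k
}

#' Genomic variance proportions
#'
#' Percentage of the total genomic variance attributed to each genetic
#' component: \eqn{100\,\sigma^2_i / \sum_j \sigma^2_j}, the sum running
#' over the genomic terms only (residual and lethal-regression variances are
#' excluded from the denominator).
#'
#' @param fit A `"blup_fit"` from a multi-component model.
#' @param terms Which components to decompose (default: all genetic terms).
#' @return Named vector of percentages summing to 100.
#' @export
variance_proportions <- function(fit, terms = NULL) {
  stopifnot(inherits(fit, "blup_fit"))
  if (is.null(terms)) terms <- names(fit$effects)
  miss <- setdiff(terms, names(fit$varcomp))
  if (length(miss)) stop("no such term(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  v <- fit$varcomp[terms]
  tot <- sum(v)
  if (tot <= 0) stop("all genomic variances are zero", call. = FALSE)
  100 * v / tot
}
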