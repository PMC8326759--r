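#' Relationship matrix container
#'
#' A symmetric matrix of additive relationships among a set of individuals,
#' either pedigree-derived (the numerator relationship matrix A) or
#' marker-derived (a genomic relationship matrix G). Genomic matrices carry
#' the SNP-set name and the VanRaden scaling constant
#' \eqn{s = 2 \sum_j p_j (1 - p_j)}.
#'
#' @param m Symmetric numeric matrix with individual ids as dimnames.
#' @param kind `"pedigree"` or `"genomic"`.
#' @param set Name of the SNP set used (genomic matrices).
#' @param scale_const The scaling constant s (genomic matrices).
#' @return The matrix with class `"relmat"` and metadata attributes.
#' @export
relmat <- function(m, kind = c("genomic", "pedigree"), set = NULL,
                   scale_const = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(rownames(m))) stop("relationship matrix needs id dimnames",
                                 call. = FALSE)
  if (max(abs(m - t(m))) > 1e-10) {
    stop("relationship matrix is not symmetric", call. = FALSE)
  }
  structure(m, kind = kind, set = set, scale_const = scale_const,
            class = c("relmat", "matrix", "array"))
}

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf("%s relationship matrix, %d individuals",
              attr(x, "kind"), nrow(x)))
  if (!is.null(attr(x, "set"))) {
    cat(sprintf(" [set %s, s = %.6g]", attr(x, "set"), attr(x, "scale_const")))
  }
  cat("\n")
  invisible(x)
}

#' VanRaden method-1 genomic relationship matrix
#'
#' Centers the 0/1/2 genotype codes by twice the allele frequency computed
#' from the data themselves (Z = M - 2p) and scales the cross-product:
#' \deqn{G = Z Z' / s, \qquad s = 2 \sum_j p_j (1 - p_j).}
#' Monomorphic SNPs in the requested set carry no information and are
#' dropped with a warning; a set that is entirely monomorphic is an error
#' (s would be zero).
#'
#' @param geno Genotype matrix (individuals x SNPs, codes 0/1/2).
#' @param set Optional [snp_set()] (or character vector of SNP ids)
#'   selecting the columns to use; default all SNPs.
#' @return A [relmat] of kind `"genomic"` with the scaling constant recorded.
#' @export
build_grm_vanraden1 <- function(geno, set = NULL) {
  if (!is.null(set)) {
    miss <- setdiff(as.character(set), colnames(geno))
    if (length(miss)) {
      stop("SNP ids not in genotype matrix: ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    }
    geno <- geno[, as.character(set), drop = FALSE]
  }
  if (nrow(geno) == 0L || ncol(geno) == 0L) {
    stop("empty genotype matrix", call. = FALSE)
  }
  p <- colMeans(geno) / 2
  # non-segregating in the data: no genotypic variance (covers fixed alleles
  # and all-heterozygote columns alike)
  mono <- colMeans(geno^2) - colMeans(geno)^2 <= 0
  if (all(mono)) stop("all SNPs in the set are monomorphic (s = 0)",
                      call. = FALSE)
  if (any(mono)) {
    warning(sprintf("dropping %d monomorphic SNP(s) from the GRM", sum(mono)),
            call. = FALSE)
    geno <- geno[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  Z <- sweep(geno, 2L, 2 * p)
  s <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / s
  relmat(G, kind = "genomic",
         set = if (is.null(set)) "ALL" else attr(set, "name") %||% "subset",
         scale_const = s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pool SNP sets into one component
#'
#' Union of the sets with duplicates removed, preserving first-appearance
#' order. Used to build one-component GRMs that treat the chip and the
#' selected whole-genome-sequencing SNPs as a single genetic component.
#'
#' @param ... [snp_set()] objects (or character vectors).
#' @param name Name for the pooled set (default: names joined by `+`).
#' @return A [snp_set()].
#' @export
pool_snp_sets <- function(..., name = NULL) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "snp_set")) sets <- sets[[1]]
  ids <- unique(unlist(lapply(sets, as.character), use.names = FALSE))
  if (is.null(name)) {
    nms <- vapply(sets, function(s) attr(s, "name") %||% "set", character(1))
    name <- paste(nms, collapse = "+")
  }
  snp_set(name, ids)
}

#' Remove a SNP set from another
#'
#' Set difference by SNP id, preserving order; used to build the reduced
#' chip set that excludes markers inside recessive lethal haplotypes.
#'
#' @param set,remove [snp_set()] objects (or character vectors).
#' @param name Name for the result (default `"<set>*"`).
#' @return A [snp_set()].
#' @export
exclude_snp_set <- function(set, remove, name = NULL) {
  if (is.null(name)) name <- paste0(attr(set, "name") %||% "set", "*")
  snp_set(name, setdiff(as.character(set), as.character(remove)))
}

#' Ridge repair to positive definiteness
#'
#' Adds `epsilon * mean(diag)` to the diagonal so the smallest eigenvalue is
#' strictly positive. Needed for genomic matrices built from fewer SNPs than
#' individuals (rank deficient). Off-diagonal entries are untouched.
#'
#' @param G A symmetric [relmat] (or plain symmetric matrix).
#' @param epsilon Relative ridge (default 1e-6).
#' @return The repaired matrix, attributes preserved.
#' @export
repair_positive_definite <- function(G, epsilon = 1e-6) {
  if (max(abs(G - t(G))) > 1e-10) stop("input is not symmetric", call. = FALSE)
  out <- G + diag(epsilon * mean(diag(G)), nrow(G))
  dimnames(out) <- dimnames(G)
  attributes(out)[c("kind", "set", "scale_const", "class")] <-
    attributes(G)[c("kind", "set", "scale_const", "class")]
  out
}

#' Export a relationship matrix as text
#'
#' Either a whitespace-delimited lower triangle (`format = "lower"`:
#' `id_i id_j value` rows, diagonal included) or a dense CSV with an id
#' header.
#'
#' @param G A [relmat].
#' @param file Output path.
#' @param format `"lower"` or `"csv"`.
#' @export
write_relmat <- function(G, file, format = c("lower", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(id = rownames(G),
                     apply(unclass(G), 2L, .fmt_real),
                     check.names = FALSE)
    utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  } else {
    idx <- which(lower.tri(G, diag = TRUE), arr.ind = TRUE)
    lines <- sprintf("%s %s %s", rownames(G)[idx[, 1]],
                     colnames(G)[idx[, 2]], .fmt_real(G[idx]))
    writeLines(lines, file)
  }
  invisible(file)
}
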