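#' @title File formats
#' @description
#' Readers and writers for the package's plain-text formats:
#' pedigree CSV (`id,sire,dam,birth_year`; unknown parent `0` or empty),
#' genotype TSV (first column `id`, then one column per SNP, codes 0/1/2,
#' optionally the PLINK additive `.raw` dialect), SNP-set lists (one id per
#' line, `#` comments), and DRP phenotype CSV (`id,trait,drp,edc,h2`).
#' All readers validate their invariants and refuse malformed files rather
#' than coercing. Reals are serialised with 12 significant digits so a
#' write/read round trip is an identity to that precision.
#' @name multiblup-io
NULL

.fmt_real <- function(x) formatC(x, digits = 12, format = "g")

.as_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | x == "0"] <- NA_character_
  x
}

#' Validate a pedigree table
#'
#' Checks id uniqueness, that every named parent appears as an individual,
#' and acyclicity (no individual is its own ancestor). Returns the table
#' with class `"pedigree"`, columns `id`, `sire`, `dam` (character,
#' `NA` = unknown) and integer `birth_year`.
#'
#' @param df Data frame with columns `id`, `sire`, `dam`, `birth_year`.
#' @return A validated `pedigree` data frame.
#' @export
as_pedigree <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("id", "sire", "dam") %in% names(df)))
  ped <- data.frame(
    id = as.character(df$id),
    sire = .as_parent(df$sire),
    dam = .as_parent(df$dam),
    birth_year = if ("birth_year" %in% names(df))
      as.integer(df$birth_year) else NA_integer_,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ped$id)) {
    stop("duplicate individual ids in pedigree: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "),
         call. = FALSE)
  }
  named <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$id)
  if (length(named)) {
    stop("parents named but absent from pedigree: ",
         paste(named, collapse = ", "), call. = FALSE)
  }
  sort_pedigree(ped) # errors on cycles; order-free input accepted
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Read a pedigree CSV
#'
#' @param file Path to a CSV with header `id,sire,dam,birth_year`;
#'   unknown parents coded `0` or left empty.
#' @return A validated [as_pedigree()] data frame.
#' @export
read_pedigree <- function(file) {
  df <- utils::read.csv(file, colClasses = "character", strip.white = TRUE)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df))) {
    stop("pedigree file must have columns id, sire, dam[, birth_year]",
         call. = FALSE)
  }
  as_pedigree(df)
}

#' Write a pedigree CSV
#'
#' @param ped A `pedigree` data frame.
#' @param file Output path.
#' @export
write_pedigree <- function(ped, file) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

.check_geno_codes <- function(m) {
  bad <- which(!(m %in% c(0L, 1L, 2L)) | is.na(m))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(m)) + 1
    j <- ((bad[1] - 1) %/% nrow(m)) + 1
    stop(sprintf(
      "invalid genotype code at individual '%s', SNP '%s' (must be 0, 1 or 2)",
      rownames(m)[i], colnames(m)[j]), call. = FALSE)
  }
  invisible(m)
}

#' Construct a genotype matrix
#'
#' @param m Numeric matrix of additive codes 0/1/2, individuals in rows
#'   (rownames = ids), SNPs in columns (colnames = SNP ids).
#' @return An integer matrix with validated dimnames and codes.
#' @export
as_genotypes <- function(m) {
  stopifnot(is.matrix(m))
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("genotype matrix needs individual ids as rownames and SNP ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) stop("duplicate individual ids", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("duplicate SNP ids", call. = FALSE)
  storage.mode(m) <- "integer"
  .check_geno_codes(m)
  m
}

#' Read a genotype matrix
#'
#' Tab-separated layout: first column `id`, remaining columns one SNP each,
#' cells in \{0,1,2\}. With `format = "raw"` the PLINK additive `.raw`
#' dialect is accepted (whitespace-separated, `FID IID PAT MAT SEX PHENOTYPE`
#' prefix columns skipped, `IID` used as the individual id).
#'
#' @param file Path to the genotype file.
#' @param format `"tsv"` (default) or `"raw"`.
#' @return An integer genotype matrix (see [as_genotypes()]).
#' @export
read_genotypes <- function(file, format = c("tsv", "raw")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(file, check.names = FALSE,
                            colClasses = "character")
    if (names(df)[1] != "id") stop("first genotype column must be 'id'",
                                   call. = FALSE)
    ids <- df$id
    body <- df[-1]
  } else {
    df <- utils::read.table(file, header = TRUE, check.names = FALSE,
                            colClasses = "character")
    pre <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(pre %in% names(df))) {
      stop("PLINK .raw file must carry FID/IID/PAT/MAT/SEX/PHENOTYPE columns",
           call. = FALSE)
    }
    ids <- df$IID
    body <- df[setdiff(names(df), pre)]
  }
  m <- suppressWarnings(
    matrix(as.numeric(as.matrix(body)), nrow = length(ids),
           dimnames = list(ids, names(body))))
  as_genotypes(m)
}

#' Write a genotype matrix as TSV
#'
#' @param geno Genotype matrix.
#' @param file Output path.
#' @export
write_genotypes <- function(geno, file) {
  df <- data.frame(id = rownames(geno), geno, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Construct a named SNP set
#'
#' A SNP set maps marker ids to a model component (e.g. `CHIP54K`, `YSS`,
#' `DFS`, `LET`). Sets may overlap.
#'
#' @param name Set name.
#' @param ids Character vector of SNP ids (duplicates removed, order kept).
#' @return A character vector of class `"snp_set"` with a `name` attribute.
#' @export
snp_set <- function(name, ids) {
  ids <- unique(as.character(ids))
  structure(ids, name = as.character(name)[1], class = "snp_set")
}

#' @export
print.snp_set <- function(x, ...) {
  cat(sprintf("SNP set '%s': %d markers\n", attr(x, "name"), length(x)))
  invisible(x)
}

#' Read a SNP-set file
#'
#' One SNP id per line; `#` starts a comment; blank lines ignored.
#'
#' @param file Path to the list file.
#' @param name Set name (default: file base name without extension).
#' @return A [snp_set()].
#' @export
read_snp_set <- function(file, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(file))
  lines <- readLines(file)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  snp_set(name, lines[nzchar(lines)])
}

#' Write a SNP-set file
#'
#' @param set A [snp_set()].
#' @param file Output path.
#' @export
write_snp_set <- function(set, file) {
  writeLines(c(paste0("# SNP set: ", attr(set, "name")), as.character(set)),
             file)
  invisible(file)
}

#' Read a DRP phenotype CSV
#'
#' Header `id,trait,drp,edc[,h2]`; when the file lacks an `h2` column the
#' per-trait heritabilities must be supplied.
#'
#' @param file Path to the CSV.
#' @param h2 Optional named vector of per-trait heritabilities used when the
#'   file has no `h2` column.
#' @return Data frame with columns `id`, `trait`, `drp`, `edc`, `h2`.
#' @export
read_phenotypes <- function(file, h2 = NULL) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("id", "trait", "drp", "edc")
  if (!all(need %in% names(df))) {
    stop("phenotype file must have columns id, trait, drp, edc[, h2]",
         call. = FALSE)
  }
  df$id <- as.character(df$id)
  if (!"h2" %in% names(df)) {
    if (is.null(h2)) stop("no 'h2' column and no per-trait h2 supplied",
                          call. = FALSE)
    missing_tr <- setdiff(unique(df$trait), names(h2))
    if (length(missing_tr)) {
      stop("no heritability supplied for trait(s): ",
           paste(missing_tr, collapse = ", "), call. = FALSE)
    }
    df$h2 <- unname(h2[df$trait])
  }
  if (any(df$edc < 0)) stop("negative EDC in phenotype file", call. = FALSE)
  if (any(df$h2 <= 0 | df$h2 > 1)) stop("h2 outside (0, 1]", call. = FALSE)
  if (anyDuplicated(df[c("id", "trait")])) {
    stop("duplicate (id, trait) rows in phenotype file", call. = FALSE)
  }
  df
}

#' Write a DRP phenotype CSV
#'
#' @param pheno Phenotype data frame.
#' @param file Output path.
#' @export
write_phenotypes <- function(pheno, file) {
  out <- pheno[intersect(c("id", "trait", "drp", "edc", "h2"), names(pheno))]
  for (cl in c("drp", "edc", "h2")) out[[cl]] <- .fmt_real(out[[cl]])
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a fitted-model report
#'
#' Writes one CSV with the variance components, log-likelihood and AIC, and
#' (optionally) one with the solutions (mean, per-term effects, lethal
#' regression coefficients).
#'
#' @param fit A [fit_reml()] / [solve_blup()] result.
#' @param file Output path for the variance-component report.
#' @param solutions_file Optional output path for the solutions.
#' @export
write_fit_result <- function(fit, file, solutions_file = NULL) {
  vc <- data.frame(parameter = names(fit$varcomp),
                   estimate = .fmt_real(unname(fit$varcomp)))
  vc <- rbind(vc,
              data.frame(parameter = c("logLik", "AIC", "iterations"),
                         estimate = c(.fmt_real(fit$logLik),
                                      .fmt_real(fit$aic),
                                      fit$iterations)))
  utils::write.csv(vc, file, row.names = FALSE, quote = FALSE)
  if (!is.null(solutions_file)) {
    eff <- do.call(rbind, lapply(names(fit$effects), function(term) {
      data.frame(term = term, level = names(fit$effects[[term]]),
                 solution = .fmt_real(unname(fit$effects[[term]])))
    }))
    mu <- data.frame(term = "mu", level = "(intercept)",
                     solution = .fmt_real(fit$mu))
    b <- NULL
    if (!is.null(fit$b)) {
      b <- data.frame(term = "lethal", level = names(fit$b),
                      solution = .fmt_real(unname(fit$b)))
    }
    utils::write.csv(rbind(mu, eff, b), solutions_file,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(file)
}
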