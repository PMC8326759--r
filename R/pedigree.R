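#' Topologically sort a pedigree (parents before offspring)
#'
#' Kahn's algorithm over the parent->offspring graph. Errors on a cycle,
#' naming the individuals involved, so an animal can never be its own
#' ancestor. Input row order is irrelevant.
#'
#' @param ped Pedigree data frame (`id`, `sire`, `dam`, `birth_year`).
#' @return The pedigree reordered so every parent precedes its offspring.
#' @export
sort_pedigree <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- unname(idx[ped$sire]) # NA when unknown
  di <- unname(idx[ped$dam])
  indeg <- as.integer(!is.na(si)) + as.integer(!is.na(di))
  children <- vector("list", n)
  for (i in idx) {
    if (!is.na(si[i])) children[[si[i]]] <- c(children[[si[i]]], i)
    if (!is.na(di[i])) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    cyc <- ped$id[setdiff(idx, order)]
    stop("pedigree contains a cycle involving: ",
         paste(cyc, collapse = ", "), call. = FALSE)
  }
  out <- ped[order, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trace the ancestor closure of a set of individuals
#'
#' Walks up the pedigree from `ids` for at most `generations` parent steps.
#' Ancestors beyond the horizon are treated as unknown founders: individuals
#' at the last traced depth keep their records but their parents are set to
#' unknown. This reproduces the usual practice of building the numerator
#' relationship matrix from genotyped animals traced a fixed number of
#' generations back.
#'
#' @param ped Pedigree data frame.
#' @param ids Target individuals (must all be in the pedigree).
#' @param generations Maximum number of parent steps to follow (>= 1).
#' @return The pruned pedigree restricted to the traced closure.
#' @export
trace_pedigree <- function(ped, ids, generations = 5L) {
  stopifnot(generations >= 1L)
  missing_ids <- setdiff(ids, ped$id)
  if (length(missing_ids)) {
    stop("ids not in pedigree: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  depth <- stats::setNames(rep.int(NA_integer_, nrow(ped)), ped$id)
  depth[ids] <- 0L
  frontier <- unique(as.character(ids))
  d <- 0L
  while (length(frontier) && d < generations) {
    d <- d + 1L
    r <- match(frontier, ped$id)
    parents <- unique(stats::na.omit(c(ped$sire[r], ped$dam[r])))
    new <- parents[is.na(depth[parents]) | depth[parents] > d]
    depth[new] <- d
    frontier <- new
  }
  keep <- !is.na(depth)
  out <- ped[keep, , drop = FALSE]
  # parents of horizon individuals become unknown founders
  horizon <- out$id[depth[out$id] == generations]
  cut <- out$id %in% horizon
  out$sire[cut] <- NA_character_
  out$dam[cut] <- NA_character_
  # parents dropped from the closure (reachable only past the horizon)
  out$sire[!out$sire %in% out$id] <- NA_character_
  out$dam[!out$dam %in% out$id] <- NA_character_
  rownames(out) <- NULL
  out
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Builds the additive (numerator) relationship matrix A by the tabular
#' method with inbreeding: with parents ordered before offspring,
#' \eqn{a_{ii} = 1 + 0.5\,a_{sd}} and \eqn{a_{ij} = 0.5 (a_{j,s} + a_{j,d})}
#' for \eqn{j < i}, unknown parents contributing zero. When `ids` is given
#' the pedigree is first pruned to their ancestor closure over at most
#' `generations_back` generations ([trace_pedigree()]) and the returned
#' matrix is restricted to `ids` (computed on the full closure).
#'
#' @param ped Pedigree data frame.
#' @param ids Optional individuals to trace from and report.
#' @param generations_back Ancestor-trace depth when `ids` is given.
#' @return A [relmat] of kind `"pedigree"`; diagonal is `1 + F` with
#'   inbreeding coefficient `F >= 0`.
#' @export
build_a_matrix <- function(ped, ids = NULL, generations_back = 5L) {
  if (!is.null(ids)) ped <- trace_pedigree(ped, ids, generations_back)
  ped <- sort_pedigree(ped)
  n <- nrow(ped)
  if (n == 0L) stop("empty pedigree", call. = FALSE)
  pos <- seq_len(n)
  names(pos) <- ped$id
  si <- unname(pos[ped$sire])
  di <- unname(pos[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in pos) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      contrib <- numeric(i - 1L)
      if (!is.na(s)) contrib <- contrib + A[j, s]
      if (!is.na(d)) contrib <- contrib + A[j, d]
      A[j, i] <- A[i, j] <- 0.5 * contrib
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  if (!is.null(ids)) A <- A[ids, ids, drop = FALSE]
  relmat(A, kind = "pedigree")
}
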