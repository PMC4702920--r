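#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the root-mean-square
#' deviation between two point sets in correspondence, via SVD of the
#' cross-covariance matrix with the determinant correction (the smallest
#' singular direction is flipped when the optimal orthogonal map would be a
#' reflection), so mirror images are never superposed onto each other.
#'
#' @param p,q Numeric n x 3 matrices of corresponding coordinates, n >= 3.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length-3),
#'   and `rmsd` in Angstrom, such that `p %*% rotation + translation`
#'   (row-wise) best fits `q`.
#' @export
#' @examples
#' p <- matrix(rnorm(30), 10, 3)
#' th <- pi / 3
#' R <- rbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0), c(0, 0, 1))
#' kabsch_superpose(p, p %*% R + 5)$rmsd   # ~0
kabsch_superpose <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (ncol(p) != 3L || ncol(q) != 3L) stop("coordinates must be n x 3")
  n <- nrow(p)
  if (n != nrow(q)) stop("point sets must have equal size")
  if (n < 3L) stop("superposition needs at least 3 points, got ", n)
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2L, cp); qc <- sweep(q, 2L, cq)
  if (svd(pc)$d[2L] < 1e-9 * max(1, svd(pc)$d[1L]) ||
      svd(qc)$d[2L] < 1e-9 * max(1, svd(qc)$d[1L]))
    stop("degenerate point set (all points collinear): rotation is not determined")
  s <- svd(crossprod(pc, qc))
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  rmsd <- sqrt(max(0, mean(rowSums((pc %*% R - qc)^2))))
  list(rotation = R, translation = as.numeric(cq - cp %*% R), rmsd = rmsd)
}

#' C-alpha RMSD between two chains over an alignment
#'
#' Superposes the C-alpha atoms of all aligned, resolved residue pairs and
#' returns the minimal RMSD.  Pairs with fewer than 3 usable residues are
#' ill-posed and reported as undefined (`NA`), not as an error.
#'
#' @param a,b [chain_record()] objects.
#' @param aln A resolved-restricted [pairwise_alignment] between them
#'   (default: computed with [align_chains()]).
#' @return List with `rmsd` (Angstrom, `NA` if undefined) and `n_aligned`.
#' @export
pair_rmsd <- function(a, b, aln = align_chains(a, b)) {
  keep <- a$resolved[aln$matched$i] & b$resolved[aln$matched$j]
  m <- aln$matched[keep, , drop = FALSE]
  if (nrow(m) < 3L)
    return(list(rmsd = NA_real_, n_aligned = nrow(m)))
  fit <- kabsch_superpose(a$xyz[m$i, , drop = FALSE],
                          b$xyz[m$j, , drop = FALSE])
  list(rmsd = fit$rmsd, n_aligned = nrow(m))
}

#' All-vs-all C-alpha RMSD matrix of a cluster
#'
#' Computes [pair_rmsd()] for every unordered member pair (each pair aligned
#' all-to-all, then restricted to resolved residues) and summarizes the
#' cluster's global structural diversity: the average over defined
#' off-diagonal pairs and the most dissimilar pair (argmax RMSD).
#'
#' @param cluster An analyzable `flex_cluster`.
#' @return An object of class `rmsd_matrix`: list with `member_ids`,
#'   `values` (symmetric RMSD matrix, Angstrom, zero diagonal, `NA` where
#'   undefined), `n_aligned` (aligned-residue counts), `avg_rmsd`,
#'   `max_rmsd` and `most_dissimilar` (ids of the argmax pair).
#' @export
pairwise_rmsd_matrix <- function(cluster) {
  stopifnot(inherits(cluster, "flex_cluster"))
  ids <- names(cluster$members)
  m <- length(ids)
  V <- matrix(0, m, m, dimnames = list(ids, ids))
  N <- matrix(0L, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m)) {
    N[i, i] <- sum(cluster$members[[i]]$resolved)
    for (j in seq_len(m)[-seq_len(i)]) {
      pr <- pair_rmsd(cluster$members[[i]], cluster$members[[j]])
      V[i, j] <- V[j, i] <- pr$rmsd
      N[i, j] <- N[j, i] <- pr$n_aligned
    }
  }
  off <- V[upper.tri(V)]
  def <- off[!is.na(off)]
  most <- c(NA_character_, NA_character_)
  if (length(def)) {
    W <- V; diag(W) <- NA
    arg <- which(W == max(def), arr.ind = TRUE)
    arg <- arg[order(arg[, 1L], arg[, 2L]), , drop = FALSE][1L, ]
    most <- sort(ids[arg])
  }
  structure(list(member_ids = ids, values = V, n_aligned = N,
                 avg_rmsd = if (length(def)) mean(def) else NA_real_,
                 max_rmsd = if (length(def)) max(def) else NA_real_,
                 most_dissimilar = most),
            class = "rmsd_matrix")
}

#' @export
print.rmsd_matrix <- function(x, ...) {
  cat(sprintf("<rmsd_matrix> %d members: avg %.2f A, max %.2f A (%s vs %s)\n",
              length(x$member_ids), x$avg_rmsd, x$max_rmsd,
              x$most_dissimilar[1L], x$most_dissimilar[2L]))
  invisible(x)
}

#' Write an RMSD matrix as CSV
#'
#' Member ids appear as both header row and first column.
#'
#' @param rm An [pairwise_rmsd_matrix()] result.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_rmsd_csv <- function(rm, file) {
  stopifnot(inherits(rm, "rmsd_matrix"))
  utils::write.csv(as.data.frame(rm$values), file, row.names = TRUE)
  invisible(file)
}

#' Read an RMSD matrix written by [write_rmsd_csv()]
#'
#' @param file CSV path.
#' @return An `rmsd_matrix` (summary fields recomputed; `n_aligned` unknown).
#' @export
read_rmsd_csv <- function(file) {
  df <- utils::read.csv(file, row.names = 1L, check.names = FALSE)
  V <- as.matrix(df)
  ids <- rownames(V)
  off <- V[upper.tri(V)]
  def <- off[!is.na(off)]
  most <- c(NA_character_, NA_character_)
  if (length(def)) {
    W <- V; diag(W) <- NA
    arg <- which(W == max(def), arr.ind = TRUE)[1L, ]
    most <- sort(ids[arg])
  }
  structure(list(member_ids = ids, values = V,
                 n_aligned = matrix(NA_integer_, nrow(V), ncol(V)),
                 avg_rmsd = if (length(def)) mean(def) else NA_real_,
                 max_rmsd = if (length(def)) max(def) else NA_real_,
                 most_dissimilar = most),
            class = "rmsd_matrix")
}
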