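#' Conformational landscape configuration
#'
#' @param bandwidth Mean-shift kernel radius in embedding-distance units
#'   (Angstrom-scaled, since the embedding approximates RMSDs), or `"auto"`
#'   (default) to use the `auto_quantile` quantile of all pairwise embedding
#'   distances -- a scale-free rule that adapts to the spread of the
#'   cluster.
#' @param auto_quantile Quantile used by the automatic bandwidth
#'   (default 0.30).
#' @param max_iter Maximum mean-shift iterations (default 300).
#' @param mode_merge_factor Converged positions closer than this fraction of
#'   the bandwidth are merged into one mode (default 0.5).
#' @return An object of class `landscape_config`.
#' @export
landscape_config <- function(bandwidth = "auto", auto_quantile = 0.30,
                             max_iter = 300L, mode_merge_factor = 0.5) {
  stopifnot(auto_quantile > 0, auto_quantile < 1, max_iter >= 1,
            mode_merge_factor > 0)
  if (!identical(bandwidth, "auto")) stopifnot(is.numeric(bandwidth),
                                               bandwidth > 0)
  structure(list(bandwidth = bandwidth, auto_quantile = auto_quantile,
                 max_iter = as.integer(max_iter),
                 mode_merge_factor = mode_merge_factor),
            class = "landscape_config")
}

#' Embed an RMSD matrix in 2D by classical multidimensional scaling
#'
#' Classical (Torgerson) scaling: double-center `-D^2 / 2`, keep the top two
#' eigenpairs, scale eigenvectors by the square roots of the (clamped
#' nonnegative) eigenvalues.  RMSD matrices need not be Euclidean; mass on
#' negative eigenvalues simply ends up in the reported stress.  Axis signs
#' are fixed so the largest-magnitude coordinate on each axis is positive,
#' making the embedding fully deterministic.
#'
#' @param matrix An [pairwise_rmsd_matrix()] result (or plain symmetric
#'   numeric matrix), fully defined, n >= 3.
#' @return An object of class `embedding2d`: `member_ids`, `coords` (n x 2),
#'   `eig` (the two retained eigenvalues) and `stress`
#'   (`sqrt(sum (d_ij - dhat_ij)^2 / sum d_ij^2)`, 0 for an exactly
#'   2D-embeddable input; defined as 0 when all distances are 0).
#' @export
embed_mds <- function(matrix) {
  D <- if (inherits(matrix, "rmsd_matrix")) matrix$values else as.matrix(matrix)
  ids <- if (inherits(matrix, "rmsd_matrix")) matrix$member_ids
         else rownames(D) %||% as.character(seq_len(nrow(D)))
  n <- nrow(D)
  if (n < 3L) stop("embedding needs at least 3 members")
  if (anyNA(D))
    stop("RMSD matrix has undefined entries; drop the affected members first")
  mds <- suppressWarnings(cmdscale(D, k = 2L, eig = TRUE))
  coords <- matrix(0, n, 2L)
  if (ncol(mds$points) > 0L)
    coords[, seq_len(ncol(mds$points))] <- mds$points
  for (ax in 1:2) {
    v <- coords[, ax]
    if (any(v != 0) && v[which.max(abs(v))] < 0) coords[, ax] <- -v
  }
  rownames(coords) <- ids
  dhat <- as.matrix(dist(coords))
  denom <- sum(D^2)
  stress <- if (denom > 0) sqrt(sum((D - dhat)^2) / denom) else 0
  structure(list(member_ids = ids, coords = coords,
                 eig = utils::head(c(mds$eig, 0, 0), 2L), stress = stress),
            class = "embedding2d")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.embedding2d <- function(x, ...) {
  cat(sprintf("<embedding2d> %d members, stress %.4g\n",
              length(x$member_ids), x$stress))
  invisible(x)
}

#' Mean-shift sub-cluster detection
#'
#' Flat-kernel mean shift on the 2D embedding: every point repeatedly moves
#' to the mean of the *original* points within `bandwidth` of its current
#' position until displacement falls below `tol` or `max_iter` is reached.
#' Converged positions closer than `mode_merge_factor * bandwidth` are
#' merged (single-linkage) into modes, and each member is labelled by its
#' nearest mode.  The number of sub-clusters emerges from the bandwidth --
#' no cluster count or cut threshold has to be chosen.
#'
#' @param coords n x 2 numeric matrix (or an [embed_mds()] result).
#' @param cfg A [landscape_config()].
#' @param tol Convergence displacement (default 1e-6).
#' @return An object of class `sub_clustering`: `labels` (integer per
#'   member, modes numbered by decreasing sub-cluster size, ties by first
#'   member), `modes` (k x 2), `bandwidth` (the value actually used),
#'   `representatives` (per mode, see [pick_representatives()]).
#' @export
mean_shift <- function(coords, cfg = landscape_config(), tol = 1e-6) {
  emb <- NULL
  if (inherits(coords, "embedding2d")) { emb <- coords; coords <- emb$coords }
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 1L) stop("mean shift needs at least one point")
  ids <- rownames(coords) %||% as.character(seq_len(n))

  h <- cfg$bandwidth
  if (identical(h, "auto")) {
    pd <- as.numeric(dist(coords))
    h <- if (length(pd)) unname(quantile(pd, cfg$auto_quantile)) else 0
  }
  if (h <= 0) {           # all points coincide (or a single point)
    labels <- rep(1L, n); names(labels) <- ids
    modes <- matrix(colMeans(coords), 1L, 2L)
    out <- structure(list(labels = labels, modes = modes, bandwidth = h,
                          representatives = NULL), class = "sub_clustering")
    out$representatives <- pick_representatives(out, coords)
    return(out)
  }

  y <- coords
  for (it in seq_len(cfg$max_iter)) {
    d2 <- outer(rowSums(y^2), rowSums(coords^2), "+") - 2 * y %*% t(coords)
    within <- d2 <= h^2 + 1e-12
    y_new <- (within %*% coords) / rowSums(within)
    shift <- sqrt(max(rowSums((y_new - y)^2)))
    y <- y_new
    if (shift < tol) break
  }

  # merge converged positions into modes (single linkage, permutation-safe)
  merge_r <- cfg$mode_merge_factor * h
  grp <- if (n == 1L) 1L else {
    hc <- hclust(dist(y), method = "single")
    cutree(hc, h = merge_r)
  }
  modes <- do.call(rbind, lapply(sort(unique(grp)), function(g)
    colMeans(y[grp == g, , drop = FALSE])))

  # label every member by its nearest mode
  d2m <- outer(rowSums(coords^2), rowSums(modes^2), "+") -
    2 * coords %*% t(modes)
  raw <- max.col(-d2m, ties.method = "first")
  # renumber modes by decreasing sub-cluster size (ties: first occurrence)
  sizes <- tabulate(raw, nbins = nrow(modes))
  ord <- order(-sizes, seq_along(sizes))
  relabel <- match(seq_along(sizes), ord)
  labels <- relabel[raw]
  names(labels) <- ids
  modes <- modes[ord, , drop = FALSE]
  keep <- sizes[ord] > 0L
  modes <- modes[keep, , drop = FALSE]

  out <- structure(list(labels = labels, modes = modes, bandwidth = h,
                        representatives = NULL), class = "sub_clustering")
  out$representatives <- pick_representatives(out, coords)
  out
}

#' @export
print.sub_clustering <- function(x, ...) {
  k <- nrow(x$modes)
  cat(sprintf("<sub_clustering> %d sub-cluster(s) (bandwidth %.3g): sizes %s\n",
              k, x$bandwidth,
              paste(tabulate(x$labels, nbins = k), collapse = ", ")))
  invisible(x)
}

#' Representative member of each sub-cluster
#'
#' The representative is the member whose embedding coordinates are closest
#' to the sub-cluster's mode; exact ties go to the lexicographically
#' smallest id.
#'
#' @param sub A [mean_shift()] result.
#' @param coords The embedding coordinates the labels refer to.
#' @return Character vector, one member id per sub-cluster.
#' @export
pick_representatives <- function(sub, coords) {
  coords <- as.matrix(coords)
  ids <- rownames(coords) %||% as.character(seq_len(nrow(coords)))
  vapply(seq_len(nrow(sub$modes)), function(g) {
    members <- which(sub$labels == g)
    d <- sqrt(rowSums((coords[members, , drop = FALSE] -
                         matrix(sub$modes[g, ], length(members), 2L,
                                byrow = TRUE))^2))
    cand <- ids[members[d <= min(d) + 1e-12]]
    sort(cand)[1L]
  }, character(1))
}

#' Export a conformational landscape as JSON
#'
#' @param emb An [embed_mds()] result.
#' @param sub A [mean_shift()] result on it.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_landscape_json <- function(emb, sub, file) {
  payload <- list(
    member_ids = emb$member_ids,
    coords = unname(apply(emb$coords, 1L, as.numeric, simplify = FALSE)),
    stress = emb$stress,
    labels = unname(as.integer(sub$labels)),
    modes = unname(apply(sub$modes, 1L, as.numeric, simplify = FALSE)),
    bandwidth = sub$bandwidth,
    representatives = sub$representatives)
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
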