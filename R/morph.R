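#' Morphing configuration
#'
#' Controls trajectory generation between two conformers.  Intermediate
#' distance matrices act as harmonic restraints; a chain-geometry term keeps
#' consecutive C-alpha distances near the canonical trans value and a soft
#' repulsion keeps non-bonded residues from passing through each other, so
#' intermediates stay protein-like instead of being straight-line coordinate
#' blends.
#'
#' @param n_frames Number of frames including the endpoints (default 11,
#'   i.e. t = 0, 0.1, ..., 1).
#' @param w_dm Weight of the distance-matrix restraint term (default 1).
#' @param w_bond Weight of the consecutive-C-alpha bond term (default 10).
#' @param bond_length Target consecutive C-alpha distance in Angstrom
#'   (default 3.8, the trans-peptide value).
#' @param w_rep Weight of the non-bonded repulsion term (default 10).
#' @param rep_radius Repulsion onset distance in Angstrom (default 4).
#' @param grad_tol Convergence threshold on the RMS gradient, Angstrom per
#'   step (default 1e-4).
#' @param max_iter Maximum minimizer iterations per frame (default 2000).
#' @param dm_pair_cutoff `"all"` (default) to restrain every aligned pair,
#'   or a distance in Angstrom to restrain only pairs whose target distance
#'   is below it (useful for very large chains).
#' @return An object of class `morph_config`.
#' @export
morph_config <- function(n_frames = 11L, w_dm = 1.0, w_bond = 10.0,
                         bond_length = 3.8, w_rep = 10.0, rep_radius = 4.0,
                         grad_tol = 1e-4, max_iter = 2000L,
                         dm_pair_cutoff = "all") {
  stopifnot(n_frames >= 2, w_dm >= 0, w_bond >= 0, w_rep >= 0,
            bond_length > 0, rep_radius > 0, grad_tol > 0, max_iter >= 1)
  if (!identical(dm_pair_cutoff, "all")) stopifnot(is.numeric(dm_pair_cutoff),
                                                   dm_pair_cutoff > 0)
  structure(list(n_frames = as.integer(n_frames), w_dm = w_dm,
                 w_bond = w_bond, bond_length = bond_length, w_rep = w_rep,
                 rep_radius = rep_radius, grad_tol = grad_tol,
                 max_iter = as.integer(max_iter),
                 dm_pair_cutoff = dm_pair_cutoff),
            class = "morph_config")
}

#' Linear interpolation between two distance matrices
#'
#' `D_t = (1 - t) d_a + t d_b`, elementwise.  The interpolated matrix is in
#' general not exactly realizable by any 3D structure; the minimizer of
#' [reconstruct_frame()] finds the conformation that best satisfies it.
#'
#' @param d_a,d_b Symmetric distance matrices of equal shape.
#' @param t Interpolation fraction in `[0, 1]`.
#' @return The interpolated matrix.
#' @export
interpolate_dm <- function(d_a, d_b, t) {
  d_a <- as.matrix(d_a); d_b <- as.matrix(d_b)
  if (!all(dim(d_a) == dim(d_b)))
    stop("distance matrices differ in shape: ",
         paste(dim(d_a), collapse = "x"), " vs ",
         paste(dim(d_b), collapse = "x"))
  stopifnot(t >= 0, t <= 1)
  (1 - t) * d_a + t * d_b
}

#' Morphing energy and its analytic gradient
#'
#' \deqn{E = w_{dm} \sum_{restrained\ i<j} (\|x_i - x_j\| - D_t(i,j))^2
#'       + w_{bond} \sum_{consecutive} (\|x_i - x_{i+1}\| - b)^2
#'       + w_{rep} \sum_{|i-j| \ge 2,\ \|x_i-x_j\| < r} (r - \|x_i-x_j\|)^2}
#'
#' Restrained pairs are the aligned positions (all of them, or those with
#' target distance below `cfg$dm_pair_cutoff`); the bonded and repulsion
#' terms run over *all* positions using their chain separation, so
#' unaligned residues keep protein-like geometry without being pulled
#' toward any target.
#'
#' @param coords n x 3 coordinate matrix.
#' @param d_target Target distance matrix over the aligned positions.
#' @param aligned_idx Row indices of `coords` the rows of `d_target`
#'   correspond to (default: all rows).
#' @param cfg A [morph_config()].
#' @param seq_pos Chain positions of the rows (default `1:n`); bonds join
#'   separation-1 pairs, repulsion applies at separation >= 2.
#' @return List with `energy` (scalar) and `gradient` (n x 3, exact
#'   analytic derivative).
#' @export
morph_energy <- function(coords, d_target, aligned_idx = seq_len(nrow(coords)),
                         cfg = morph_config(), seq_pos = seq_len(nrow(coords))) {
  X <- as.matrix(coords)
  n <- nrow(X)
  D <- as.matrix(dist(X))
  sep <- abs(outer(seq_pos, seq_pos, "-"))
  Dsafe <- pmax(D, 1e-9)

  # harmonic distance-matrix restraints on aligned pairs
  Tg <- matrix(NA_real_, n, n)
  if (length(aligned_idx))
    Tg[aligned_idx, aligned_idx] <- as.matrix(d_target)
  restr <- !is.na(Tg) & upper.tri(Tg)
  if (is.numeric(cfg$dm_pair_cutoff)) restr <- restr & Tg <= cfg$dm_pair_cutoff
  restr <- restr | t(restr)
  diag(restr) <- FALSE
  dev <- D - Tg
  e_dm <- cfg$w_dm * sum(dev[restr & upper.tri(dev)]^2)
  C <- matrix(0, n, n)
  C[restr] <- 2 * cfg$w_dm * dev[restr] / Dsafe[restr]

  # consecutive C-alpha bond term
  bond <- sep == 1L
  bdev <- D - cfg$bond_length
  e_bond <- cfg$w_bond * sum(bdev[bond & upper.tri(bond)]^2)
  C[bond] <- C[bond] + 2 * cfg$w_bond * bdev[bond] / Dsafe[bond]

  # soft non-bonded repulsion
  rep_pair <- sep >= 2L & D < cfg$rep_radius
  rdev <- cfg$rep_radius - D
  e_rep <- cfg$w_rep * sum(rdev[rep_pair & upper.tri(rep_pair)]^2)
  C[rep_pair] <- C[rep_pair] - 2 * cfg$w_rep * rdev[rep_pair] / Dsafe[rep_pair]

  grad <- rowSums(C) * X - C %*% X
  list(energy = e_dm + e_bond + e_rep, gradient = grad)
}

#' Reconstruct a conformation satisfying a target distance matrix
#'
#' Local minimization of [morph_energy()] by gradient descent with
#' Barzilai--Borwein step proposals and Armijo backtracking, which keeps the
#' energy strictly non-increasing across iterations.  Stops when the RMS
#' gradient falls below `cfg$grad_tol` or after `cfg$max_iter` iterations.
#'
#' @inheritParams morph_energy
#' @param init_coords Starting coordinates (finite).
#' @return List with `coords`, `dm_residual` (max absolute deviation of a
#'   restrained pair distance from its target, Angstrom), `energy_trace`
#'   (energy per accepted iteration, monotone non-increasing), `converged`.
#' @export
reconstruct_frame <- function(d_target, init_coords,
                              aligned_idx = seq_len(nrow(init_coords)),
                              cfg = morph_config(),
                              seq_pos = seq_len(nrow(init_coords))) {
  X <- as.matrix(init_coords)
  if (!all(is.finite(X))) stop("init_coords must be finite")
  ev <- morph_energy(X, d_target, aligned_idx, cfg, seq_pos)
  e <- ev$energy; g <- ev$gradient
  trace <- e
  alpha <- 1e-3
  s_prev <- y_prev <- NULL
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    gnorm2 <- sum(g^2)
    if (sqrt(gnorm2 / length(g)) < cfg$grad_tol) { converged <- TRUE; break }
    if (!is.null(s_prev)) {
      sy <- sum(s_prev * y_prev)
      if (sy > 1e-12) alpha <- min(max(sum(s_prev^2) / sy, 1e-8), 10)
    }
    a <- alpha
    accepted <- FALSE
    for (bt in seq_len(40L)) {
      Xn <- X - a * g
      en <- morph_energy(Xn, d_target, aligned_idx, cfg, seq_pos)
      if (!is.finite(en$energy))
        stop("non-finite energy at iteration ", it)
      if (en$energy <= e - 1e-4 * a * gnorm2) { accepted <- TRUE; break }
      a <- a / 2
    }
    if (!accepted) break          # no descent possible at machine precision
    s_prev <- Xn - X
    y_prev <- en$gradient - g
    X <- Xn; e <- en$energy; g <- en$gradient
    trace <- c(trace, e)
  }
  n <- nrow(X)
  D <- as.matrix(dist(X))
  Tg <- matrix(NA_real_, n, n)
  if (length(aligned_idx))
    Tg[aligned_idx, aligned_idx] <- as.matrix(d_target)
  restr <- !is.na(Tg); diag(restr) <- FALSE
  if (is.numeric(cfg$dm_pair_cutoff)) restr <- restr & Tg <= cfg$dm_pair_cutoff
  list(coords = X,
       dm_residual = if (any(restr)) max(abs(D[restr] - Tg[restr])) else 0,
       energy_trace = trace, converged = converged)
}

#' Generate a morphing trajectory between two conformers
#'
#' Distance-geometry morphing: for each interpolation fraction
#' `t_k = k / (n_frames - 1)` the target distance matrix
#' `D_t = (1 - t) d_a + t d_b` over the aligned, resolved positions is
#' imposed as harmonic restraints and the frame is obtained by restrained
#' minimization, warm-started from the previous frame so the trajectory is
#' continuous.  Frame 0 is the start structure verbatim.  Unaligned
#' resolved residues of `a` are carried along under the bonded and
#' repulsion terms only.  Rigid regions (whose internal distances agree
#' between the endpoints) have constant restraint targets and therefore
#' stay internally rigid along the whole path.
#'
#' @param a,b [chain_record()] objects (start and end conformers).
#' @param aln Resolved-restricted alignment (default [align_chains()]).
#' @param cfg A [morph_config()].
#' @return An object of class `morph_trajectory`: `frames` (list of m x 3
#'   matrices over `positions`, the resolved SEQRES positions of `a`),
#'   `ts`, `per_frame_dm_residual`, `aligned` (logical over positions),
#'   `aa`, `a_id`, `b_id`.
#' @export
generate_morph <- function(a, b, aln = align_chains(a, b),
                           cfg = morph_config()) {
  keep <- a$resolved[aln$matched$i] & b$resolved[aln$matched$j]
  m <- aln$matched[keep, , drop = FALSE]
  if (nrow(m) < 4L)
    stop("morphing needs at least 4 aligned resolved pairs, got ", nrow(m))
  pos <- which(a$resolved)
  X0 <- a$xyz[pos, , drop = FALSE]
  aligned_idx <- match(m$i, pos)
  d_a <- as.matrix(dist(a$xyz[m$i, , drop = FALSE]))
  d_b <- as.matrix(dist(b$xyz[m$j, , drop = FALSE]))

  ts <- seq(0, 1, length.out = cfg$n_frames)
  frames <- vector("list", cfg$n_frames)
  resid <- numeric(cfg$n_frames)
  frames[[1L]] <- X0
  D0 <- as.matrix(dist(X0))[aligned_idx, aligned_idx]
  resid[1L] <- max(abs(D0 - d_a))
  for (k in seq_len(cfg$n_frames)[-1L]) {
    Dt <- interpolate_dm(d_a, d_b, ts[k])
    rec <- reconstruct_frame(Dt, frames[[k - 1L]], aligned_idx, cfg,
                             seq_pos = pos)
    frames[[k]] <- rec$coords
    resid[k] <- rec$dm_residual
  }
  structure(list(frames = frames, ts = ts, per_frame_dm_residual = resid,
                 positions = pos, aligned = seq_along(pos) %in% aligned_idx,
                 aa = a$aa[pos], a_id = a$source_id, b_id = b$source_id),
            class = "morph_trajectory")
}

#' @export
print.morph_trajectory <- function(x, ...) {
  cat(sprintf("<morph_trajectory> %s -> %s: %d frames over %d residues (%d restrained); max DM residual %.3f A\n",
              x$a_id, x$b_id, length(x$frames), length(x$positions),
              sum(x$aligned), max(x$per_frame_dm_residual)))
  invisible(x)
}

#' Write a morphing trajectory as a multi-model C-alpha PDB file
#'
#' One MODEL/ENDMDL block per frame, readable by standard molecular
#' viewers as an animation.
#'
#' @param traj A [generate_morph()] result.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_morph_pdb <- function(traj, file) {
  stopifnot(inherits(traj, "morph_trajectory"))
  xyz <- do.call(rbind, lapply(traj$frames, function(f) as.numeric(t(f))))
  m <- length(traj$positions)
  bio3d::write.pdb(file = file, xyz = xyz, resno = traj$positions,
                   resid = bio3d::aa123(traj$aa),
                   elety = rep("CA", m),
                   chain = rep(substr(traj$a_id, nchar(traj$a_id),
                                      nchar(traj$a_id)), m))
  invisible(file)
}
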