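# shared geometric helpers: random rigid motions and brute-force oracles

rotation_from_angles <- function(a, b, c) {
  Rz <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rx <- rbind(c(1, 0, 0), c(0, cos(c), -sin(c)), c(0, sin(c), cos(c)))
  Rz %*% Ry %*% Rx
}

random_rotation <- function() {
  rotation_from_angles(runif(1, 0, 2 * pi), runif(1, 0, 2 * pi),
                       runif(1, 0, 2 * pi))
}

apply_rigid <- function(x, R = random_rotation(), t = rnorm(3, sd = 10)) {
  sweep(x %*% R, 2L, t, "+")
}

# plain RMSD of two centered sets under a given rotation
rmsd_under <- function(p, q, R) {
  pc <- sweep(p, 2L, colMeans(p)); qc <- sweep(q, 2L, colMeans(q))
  sqrt(mean(rowSums((pc %*% R - qc)^2)))
}

# numeric superposition oracle, independent of the SVD route: optimal
# translation is centroid alignment; the rotation is found by multi-start
# Nelder-Mead over Euler angles.  allow_reflection also tries the mirror.
oracle_min_rmsd <- function(p, q, n_starts = 40, allow_reflection = FALSE) {
  obj <- function(ang, qq) rmsd_under(p, qq, rotation_from_angles(ang[1], ang[2], ang[3]))
  best <- Inf
  qs <- list(q)
  if (allow_reflection) qs <- c(qs, list(q %*% diag(c(-1, 1, 1))))
  for (qq in qs) for (s in seq_len(n_starts)) {
    st <- runif(3, 0, 2 * pi)
    fit <- optim(st, obj, qq = qq, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    fit <- optim(fit$par, obj, qq = qq, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# a compact random 3D blob with full rank
random_points <- function(n, sd = 5) matrix(rnorm(3 * n, sd = sd), n, 3)
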