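#' Local flexibility profile configuration
#'
#' @param window Window length in residues (default 10).  Local RMSD is
#'   computed over sliding windows of this many consecutive master
#'   positions; 10 residues is short enough to localize loop motions yet
#'   long enough for a well-posed superposition.
#' @param min_members_per_window Minimum number of members with a defined
#'   value required for an averaged profile position (default 1).
#' @return An object of class `profile_config`.
#' @export
profile_config <- function(window = 10L, min_members_per_window = 1L) {
  stopifnot(window >= 3, min_members_per_window >= 1)
  structure(list(window = as.integer(window),
                 min_members_per_window = as.integer(min_members_per_window)),
            class = "profile_config")
}

#' Contact-map configuration
#'
#' Two residues are in contact when their C-alpha atoms are within `cutoff`
#' and they are at least `min_seq_sep` positions apart in sequence (nearest
#' neighbours are trivially always in contact and carry no structural
#' signal).
#'
#' @param cutoff Contact distance cutoff in Angstrom (default 8).
#' @param min_seq_sep Minimum sequence separation `|i - j|` (default 3).
#' @return An object of class `contact_config`.
#' @export
contact_config <- function(cutoff = 8.0, min_seq_sep = 3L) {
  stopifnot(cutoff > 0, min_seq_sep >= 1)
  structure(list(cutoff = cutoff, min_seq_sep = as.integer(min_seq_sep)),
            class = "contact_config")
}

#' Windowed local C-alpha RMSD track of one member against the master
#'
#' For every window of `cfg$window` consecutive master positions that are
#' all aligned and resolved in both chains, that window alone is superposed
#' (local Kabsch fit) and its RMSD recorded; each position's value is the
#' mean over all complete windows containing it.  The per-window fit is
#' deliberate: it measures local structural deformation, whereas residuals
#' in a single global frame would conflate rigid-body domain motion with
#' local change.  Positions covered by no complete window are `NA`.
#'
#' @param master,member [chain_record()] objects.
#' @param aln Resolved-restricted alignment master vs member (default
#'   [align_chains()]).
#' @param cfg A [profile_config()].
#' @param frame `"local"` (default, per-window superposition) or
#'   `"global"` (one whole-chain superposition, then per-window RMS of the
#'   residuals) -- exposed for comparison.
#' @return Numeric vector over master SEQRES positions (NA = undefined).
#' @export
local_rmsd_track <- function(master, member, aln = align_chains(master, member),
                             cfg = profile_config(), frame = c("local", "global")) {
  frame <- match.arg(frame)
  n <- length(master$aa)
  w <- cfg$window
  map <- rep(NA_integer_, n)
  keep <- master$resolved[aln$matched$i] & member$resolved[aln$matched$j]
  map[aln$matched$i[keep]] <- aln$matched$j[keep]
  track <- rep(NA_real_, n)
  if (n < w) return(track)
  ok <- !is.na(map)
  residual2 <- NULL
  if (frame == "global") {
    if (sum(ok) < 3L) return(track)
    P_all <- master$xyz[which(ok), , drop = FALSE]
    Q_all <- member$xyz[map[ok], , drop = FALSE]
    fit <- kabsch_superpose(P_all, Q_all)
    fitted <- sweep(P_all %*% fit$rotation, 2L, fit$translation, "+")
    residual2 <- rep(NA_real_, n)
    residual2[which(ok)] <- rowSums((fitted - Q_all)^2)
  }
  sums <- rep(0, n); cnt <- rep(0L, n)
  for (s in seq_len(n - w + 1L)) {
    idx <- s:(s + w - 1L)
    if (!all(ok[idx])) next
    r <- if (frame == "local")
      kabsch_superpose(master$xyz[idx, , drop = FALSE],
                       member$xyz[map[idx], , drop = FALSE])$rmsd
    else sqrt(mean(residual2[idx]))
    sums[idx] <- sums[idx] + r
    cnt[idx] <- cnt[idx] + 1L
  }
  track[cnt > 0L] <- sums[cnt > 0L] / cnt[cnt > 0L]
  track
}

#' Average local flexibility profile of a cluster
#'
#' Per master position, the mean of the members' local RMSD tracks over
#' members with a defined value there (the master's trivial all-zero
#' self-track is excluded).  Positions with fewer than
#' `cfg$min_members_per_window` contributing members are undefined.
#'
#' @param cluster A `flex_cluster` with `msa` built ([build_msmsa()]).
#' @param tracks Optional precomputed member-track matrix (positions x
#'   members); computed from the cluster when `NULL`.
#' @param cfg A [profile_config()].
#' @return An object of class `flexibility_profile`: `master_id`,
#'   `positions`, `mean_local_rmsd`, `member_tracks`, `n_contributing`.
#' @export
average_profile <- function(cluster, tracks = NULL, cfg = profile_config()) {
  stopifnot(inherits(cluster, "flex_cluster"))
  master <- cluster$members[[cluster$master_id]]
  slaves <- setdiff(names(cluster$members), cluster$master_id)
  if (is.null(tracks)) {
    tracks <- vapply(slaves, function(id)
      local_rmsd_track(master, cluster$members[[id]], cfg = cfg),
      numeric(length(master$aa)))
    tracks <- matrix(tracks, nrow = length(master$aa),
                     dimnames = list(NULL, slaves))
  }
  n_def <- rowSums(!is.na(tracks))
  mean_rmsd <- rowMeans(tracks, na.rm = TRUE)
  mean_rmsd[n_def < cfg$min_members_per_window] <- NA_real_
  structure(list(master_id = cluster$master_id,
                 positions = seq_len(nrow(tracks)),
                 mean_local_rmsd = mean_rmsd,
                 member_tracks = tracks,
                 n_contributing = n_def),
            class = "flexibility_profile")
}

#' @export
print.flexibility_profile <- function(x, ...) {
  def <- x$mean_local_rmsd[!is.na(x$mean_local_rmsd)]
  cat(sprintf("<flexibility_profile> master %s, %d positions (%d defined), mean %.2f A, peak %.2f A\n",
              x$master_id, length(x$positions), length(def),
              mean(def), if (length(def)) max(def) else NA))
  invisible(x)
}

#' @export
plot.flexibility_profile <- function(x, ...) {
  plot(x$positions, x$mean_local_rmsd, type = "l",
       xlab = "master SEQRES position", ylab = "average local RMSD [A]",
       main = paste("Local flexibility,", x$master_id), ...)
  invisible(x)
}

#' Rank members by local structural diversity
#'
#' Members ranked by the maximum of their local RMSD track, highest first --
#' the selection used to show the most locally diverse conformers when a
#' cluster is large.
#'
#' @param profile A [average_profile()] result.
#' @param top Number of members to keep (default 20).
#' @return Character vector of member ids.
#' @export
top_diverse_members <- function(profile, top = 20L) {
  peaks <- apply(profile$member_tracks, 2L, function(v)
    if (all(is.na(v))) -Inf else max(v, na.rm = TRUE))
  names(sort(peaks, decreasing = TRUE))[seq_len(min(top, length(peaks)))]
}

#' Difference distance map between two conformers
#'
#' Over the aligned, resolved positions, `values[i, j]` is the internal
#' C-alpha distance in `a` minus the same distance in `b`.  Internal
#' distances are invariant under rigid motion, so the map isolates genuine
#' conformational change without any superposition: blocks of near-zero
#' entries are rigid units, and the off-diagonal blocks between them show
#' how the units rearrange.
#'
#' @param a,b [chain_record()] objects.
#' @param aln Resolved-restricted alignment (default [align_chains()]).
#' @return An object of class `ddm`: `a_id`, `b_id`, `positions` (a-side
#'   SEQRES indices of the aligned pairs), `values` (antisymmetric-in-
#'   arguments matrix, zero diagonal, Angstrom).
#' @export
difference_distance_map <- function(a, b, aln = align_chains(a, b)) {
  keep <- a$resolved[aln$matched$i] & b$resolved[aln$matched$j]
  m <- aln$matched[keep, , drop = FALSE]
  if (nrow(m) < 2L) stop("difference distance map needs at least 2 aligned pairs")
  da <- as.matrix(dist(a$xyz[m$i, , drop = FALSE]))
  db <- as.matrix(dist(b$xyz[m$j, , drop = FALSE]))
  v <- da - db
  dimnames(v) <- list(m$i, m$i)
  structure(list(a_id = a$source_id, b_id = b$source_id,
                 positions = m$i, values = v),
            class = "ddm")
}

#' @export
print.ddm <- function(x, ...) {
  cat(sprintf("<ddm> %s vs %s over %d positions; max |d| = %.2f A\n",
              x$a_id, x$b_id, length(x$positions), max(abs(x$values))))
  invisible(x)
}

#' Write a difference distance map as TSV
#'
#' @param x A [difference_distance_map()] result.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_ddm_tsv <- function(x, file) {
  stopifnot(inherits(x, "ddm"))
  utils::write.table(x$values, file, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(file)
}

#' Contact map overlap between two conformers
#'
#' Contacts are computed for each structure over the aligned positions
#' (master-frame, i.e. a-side, indexing for the sequence-separation test)
#' and compared as sets:
#' `CMO = 2 |C_a intersect C_b| / (|C_a| + |C_b|)`,
#' a symmetric Dice-type fraction in `[0, 1]`.  1 means identical contact
#' topology; the value is defined as 1 when both contact sets are empty.
#'
#' @param a,b [chain_record()] objects.
#' @param aln Resolved-restricted alignment (default [align_chains()]).
#' @param cfg A [contact_config()].
#' @return A single number in `[0, 1]`.
#' @export
contact_map_overlap <- function(a, b, aln = align_chains(a, b),
                                cfg = contact_config()) {
  keep <- a$resolved[aln$matched$i] & b$resolved[aln$matched$j]
  m <- aln$matched[keep, , drop = FALSE]
  if (nrow(m) < 2L) return(1.0)
  sep_ok <- abs(outer(m$i, m$i, "-")) >= cfg$min_seq_sep
  ca <- as.matrix(dist(a$xyz[m$i, , drop = FALSE])) <= cfg$cutoff & sep_ok
  cb <- as.matrix(dist(b$xyz[m$j, , drop = FALSE])) <= cfg$cutoff & sep_ok
  na <- sum(ca); nb <- sum(cb)
  if (na + nb == 0L) return(1.0)
  2 * sum(ca & cb) / (na + nb)
}

#' Summarize a cluster's structural diversity
#'
#' Collects the size, RMSD and contact-map-overlap statistics of a cluster
#' and assigns a flexibility class from the maximum pairwise C-alpha RMSD:
#' `rigid` below 0.5 Angstrom, `flexible` above 3 Angstrom, `intermediate`
#' between.
#'
#' @param cluster An analyzable `flex_cluster`.
#' @param matrix An [pairwise_rmsd_matrix()] result for it.
#' @param cmos Optional named numeric vector of pairwise CMO values (names
#'   `"idA|idB"`); computed from the cluster when `NULL`.
#' @param cfg A [contact_config()] (used only when computing `cmos`).
#' @return An object of class `cluster_summary`: `size`, `master_id`,
#'   `avg_rmsd`, `max_rmsd`, `most_dissimilar_pair`, `avg_cmo`, `min_cmo`,
#'   `flexibility_class`.
#' @export
summarize_cluster <- function(cluster, matrix = pairwise_rmsd_matrix(cluster),
                              cmos = NULL, cfg = contact_config()) {
  stopifnot(inherits(cluster, "flex_cluster"), inherits(matrix, "rmsd_matrix"))
  if (!cluster$analyzable)
    stop("cluster is not analyzable: it has ", length(cluster$members),
         " member(s), and flexibility statistics need more than 3")
  if (is.null(cmos)) cmos <- cluster_cmos(cluster, cfg)
  structure(list(size = length(cluster$members),
                 master_id = cluster$master_id,
                 avg_rmsd = matrix$avg_rmsd,
                 max_rmsd = matrix$max_rmsd,
                 most_dissimilar_pair = matrix$most_dissimilar,
                 avg_cmo = mean(cmos),
                 min_cmo = if (length(cmos)) min(cmos) else NA_real_,
                 flexibility_class = classify_flexibility(matrix$max_rmsd)),
            class = "cluster_summary")
}

#' Pairwise contact-map overlaps of a cluster
#'
#' @param cluster A `flex_cluster`.
#' @param cfg A [contact_config()].
#' @return Named numeric vector over unordered member pairs (`"idA|idB"`).
#' @export
cluster_cmos <- function(cluster, cfg = contact_config()) {
  ids <- names(cluster$members)
  out <- numeric(0)
  for (i in seq_along(ids)) for (j in seq_along(ids)[-seq_len(i)]) {
    out[paste(ids[i], ids[j], sep = "|")] <-
      contact_map_overlap(cluster$members[[i]], cluster$members[[j]],
                          cfg = cfg)
  }
  out
}

#' Flexibility class from maximum cluster RMSD
#'
#' @param max_rmsd Maximum pairwise C-alpha RMSD in Angstrom.
#' @param rigid_below,flexible_above Class boundaries in Angstrom
#'   (defaults 0.5 and 3).
#' @return `"rigid"`, `"intermediate"` or `"flexible"`.
#' @export
classify_flexibility <- function(max_rmsd, rigid_below = 0.5,
                                 flexible_above = 3.0) {
  if (is.na(max_rmsd)) return(NA_character_)
  if (max_rmsd < rigid_below) "rigid"
  else if (max_rmsd > flexible_above) "flexible"
  else "intermediate"
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf(paste0("<cluster_summary> %d members, master %s: avg RMSD %.2f A, ",
                     "max %.2f A (%s vs %s), avg CMO %.3f, min CMO %.3f -> %s\n"),
              x$size, x$master_id, x$avg_rmsd, x$max_rmsd,
              x$most_dissimilar_pair[1L], x$most_dissimilar_pair[2L],
              x$avg_cmo, x$min_cmo, x$flexibility_class))
  invisible(x)
}
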