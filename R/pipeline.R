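#' Run the full flexibility-analysis pipeline
#'
#' Orchestrates the whole analysis over a set of PDB files: ingest ->
#' quality filter -> sequence clustering -> master--slave alignment ->
#' all-vs-all RMSD -> local flexibility profile -> difference distance map
#' and contact-map overlap -> cluster summary -> 2D landscape with
#' mean-shift sub-clusters -> optional morph between the two most
#' dissimilar conformers.  Every analyzable cluster gets its own output
#' subdirectory (named by its master id); a `manifest.json` lists every
#' written file with its MD5 checksum.  All outputs are deterministic for
#' fixed inputs and configuration.
#'
#' @param inputs Character vector of PDB file paths, or a list of
#'   [chain_record()] objects.
#' @param out_dir Output directory (created if needed).
#' @param filter_cfg,cluster_cfg,profile_cfg,contact_cfg,landscape_cfg,morph_cfg
#'   Stage configurations (see the respective constructors).
#' @param morph Whether to generate a morph between the most dissimilar pair
#'   of each analyzable cluster (default `TRUE`).
#' @param verbose Print progress (default `TRUE`).
#' @return Invisibly, a list with `clusters` (analyzed `flex_cluster`s),
#'   `summaries`, `rejected` and `manifest` (data.frame of file, md5).
#' @export
run_pipeline <- function(inputs, out_dir,
                         filter_cfg = quality_filter_config(),
                         cluster_cfg = clustering_config(),
                         profile_cfg = profile_config(),
                         contact_cfg = contact_config(),
                         landscape_cfg = landscape_config(),
                         morph_cfg = morph_config(),
                         morph = TRUE, verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  records <- if (is.character(inputs)) {
    say("ingesting ", length(inputs), " file(s)")
    do.call(c, lapply(inputs, read_chain_records))
  } else inputs
  say(length(records), " chain(s) ingested")

  filt <- apply_quality_filters(records, filter_cfg)
  say(length(filt$kept), " chain(s) kept, ", nrow(filt$rejected), " rejected")

  clusters <- cluster_chains(filt$kept, cluster_cfg)
  analyzable <- Filter(function(cl) cl$analyzable, clusters)
  if (!length(analyzable))
    stop("no analyzable cluster: every cluster has fewer than ",
         cluster_cfg$min_cluster_size,
         " members, and flexibility statistics need more than 3 conformers ",
         "of the same protein", call. = FALSE)

  files <- character(0)
  put <- function(path) { files[[length(files) + 1L]] <<- path; path }

  write_chains_json(filt$kept, put(file.path(out_dir, "chains.json")))
  jsonlite::write_json(filt$rejected,
                       put(file.path(out_dir, "rejected.json")),
                       auto_unbox = TRUE, digits = NA)

  summaries <- list()
  out_clusters <- list()
  for (cl in analyzable) {
    cl <- build_msmsa(cl)
    cdir <- file.path(out_dir, cl$master_id)
    dir.create(cdir, showWarnings = FALSE)
    say("analyzing cluster ", cl$master_id, " (", length(cl$members),
        " members)")

    rm_ <- pairwise_rmsd_matrix(cl)
    write_rmsd_csv(rm_, put(file.path(cdir, "rmsd.csv")))

    prof <- average_profile(cl, cfg = profile_cfg)
    write_profile_json(prof, cl, put(file.path(cdir, "profile.json")))

    pair <- rm_$most_dissimilar
    a <- cl$members[[pair[1L]]]; b <- cl$members[[pair[2L]]]
    ddm <- difference_distance_map(a, b)
    write_ddm_tsv(ddm, put(file.path(cdir, "ddm.tsv")))

    cmos <- cluster_cmos(cl, contact_cfg)
    summ <- summarize_cluster(cl, rm_, cmos, contact_cfg)
    jsonlite::write_json(unclass(summ), put(file.path(cdir, "summary.json")),
                         auto_unbox = TRUE, digits = NA)

    if (length(cl$members) >= 3L && !anyNA(rm_$values)) {
      emb <- embed_mds(rm_)
      sub <- mean_shift(emb, landscape_cfg)
      write_landscape_json(emb, sub, put(file.path(cdir, "landscape.json")))
    }

    if (morph) {
      traj <- generate_morph(a, b, cfg = morph_cfg)
      write_morph_pdb(traj, put(file.path(cdir, "morph.pdb")))
      jsonlite::write_json(list(ts = traj$ts,
                                dm_residual = traj$per_frame_dm_residual),
                           put(file.path(cdir, "morph_residuals.json")),
                           digits = NA)
    }
    summaries[[cl$master_id]] <- summ
    out_clusters[[cl$master_id]] <- cl
  }

  manifest <- data.frame(file = unname(vapply(files, function(f)
                           sub(paste0("^", out_dir, "/?"), "", f, fixed = FALSE), "")),
                         md5 = unname(tools::md5sum(unlist(files))))
  rownames(manifest) <- NULL
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("wrote ", nrow(manifest) + 1L, " file(s) to ", out_dir)
  invisible(list(clusters = out_clusters, summaries = summaries,
                 rejected = filt$rejected, manifest = manifest))
}

#' Serialize / deserialize clusters as JSON
#'
#' Chains are embedded so a clusters file is self-contained: downstream
#' command-line stages (RMSD, profile, morph, ...) need no other input.
#'
#' @param clusters List of `flex_cluster` objects.
#' @param file Path of the JSON file.
#' @return `write_clusters_json()` returns `file` invisibly;
#'   `read_clusters_json()` the list of clusters.
#' @export
write_clusters_json <- function(clusters, file) {
  chains <- do.call(c, lapply(clusters, function(cl) unname(cl$members)))
  tmp <- tempfile(); on.exit(unlink(tmp))
  write_chains_json(chains, tmp)
  payload <- list(
    chains = jsonlite::read_json(tmp, simplifyVector = TRUE),
    clusters = lapply(clusters, function(cl)
      list(member_ids = names(cl$members), master_id = cl$master_id,
           representative_id = cl$representative_id,
           analyzable = cl$analyzable)))
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(file)
}

#' @rdname write_clusters_json
#' @export
read_clusters_json <- function(file) {
  payload <- jsonlite::read_json(file, simplifyVector = TRUE)
  tmp <- tempfile(); on.exit(unlink(tmp))
  jsonlite::write_json(payload$chains, tmp, auto_unbox = TRUE, digits = NA,
                       na = "null")
  chains <- read_chains_json(tmp)
  lapply(seq_len(nrow(payload$clusters)), function(k) {
    row <- payload$clusters[k, ]
    ids <- unlist(row$member_ids)
    structure(list(members = chains[ids],
                   representative_id = row$representative_id,
                   master_id = row$master_id,
                   analyzable = row$analyzable, msa = NULL),
              class = "flex_cluster")
  })
}

#' Export a flexibility profile as JSON
#'
#' Writes the averaged track, the per-member tracks, and per-member
#' secondary-structure/disorder annotation tracks (labels `H`, `E`, `L`,
#' `D`) in master-frame indexing -- the data a local-flexibility viewer
#' needs.
#'
#' @param profile An [average_profile()] result.
#' @param cluster The `flex_cluster` it came from (with `msa` built).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_profile_json <- function(profile, cluster, file) {
  # ss/disorder tracks use the sequence-level alignment (not the resolved-
  # restricted msMSA) so unresolved member residues show up as D rather
  # than as gaps
  master <- cluster$members[[profile$master_id]]
  ss_tracks <- lapply(names(cluster$members), function(id) {
    mem <- cluster$members[[id]]
    ss <- mem$ss %||% ifelse(mem$resolved, "L", "D")
    aln <- global_align(master$sequence, mem$sequence,
                        master$source_id, id)
    out <- rep(NA_character_, length(master$aa))
    out[aln$matched$i] <- ss[aln$matched$j]
    out
  })
  names(ss_tracks) <- names(cluster$members)
  payload <- list(master_id = profile$master_id,
                  positions = profile$positions,
                  mean_local_rmsd = profile$mean_local_rmsd,
                  n_contributing = profile$n_contributing,
                  member_tracks = as.data.frame(profile$member_tracks),
                  ss_tracks = ss_tracks)
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "columns")
  invisible(file)
}

#' Export a flexibility profile as TSV
#'
#' @param profile An [average_profile()] result.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_profile_tsv <- function(profile, file) {
  df <- data.frame(position = profile$positions,
                   mean_local_rmsd = profile$mean_local_rmsd,
                   n_contributing = profile$n_contributing,
                   profile$member_tracks, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
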