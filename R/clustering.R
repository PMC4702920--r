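#' Sequence clustering configuration
#'
#' @param identity_threshold Fraction in (0, 1]; chains joining a cluster
#'   must match its representative at at least this sequence identity
#'   (default 0.95, loose enough to absorb construct-boundary differences,
#'   crystallization tags and a few point mutations while still grouping
#'   "the same protein").
#' @param min_cluster_size Minimum members for a cluster to be analyzable
#'   (default 4: flexibility statistics on fewer conformers are not
#'   meaningful).
#' @return An object of class `clustering_config`.
#' @export
clustering_config <- function(identity_threshold = 0.95,
                              min_cluster_size = 4L) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            min_cluster_size >= 1)
  structure(list(identity_threshold = identity_threshold,
                 min_cluster_size = as.integer(min_cluster_size)),
            class = "clustering_config")
}

#' Group chains into clusters of (near-)identical sequences
#'
#' Greedy incremental clustering in the style of cd-hit: chains are sorted
#' by decreasing SEQRES length (ties by `source_id`), and each chain joins
#' the *first* existing cluster, in creation order, whose representative
#' (its founding, longest member) it matches at `identity_threshold` or
#' better, else founds a new cluster.  The internal sort makes the result
#' invariant to input order.  Every chain instance is a distinct member --
#' two identical chains from one deposition count twice, since each carries
#' its own coordinates.
#'
#' @param records List of quality-filtered [chain_record()] objects.
#' @param cfg A [clustering_config()].
#' @return A list of `flex_cluster` objects, each with `members` (named list
#'   of records), `representative_id` (founder used for the identity test),
#'   `master_id` (see [select_master()]) and `analyzable` (at least
#'   `min_cluster_size` members).  `msa` is `NULL` until [build_msmsa()].
#' @export
cluster_chains <- function(records, cfg = clustering_config()) {
  stopifnot(inherits(cfg, "clustering_config"))
  records <- unname(records)
  if (!length(records)) return(list())
  ids  <- vapply(records, `[[`, "", "source_id")
  lens <- vapply(records, function(r) length(r$aa), 0L)
  ord  <- order(-lens, ids)
  reps <- list()          # founding record per cluster, in creation order
  membership <- integer(length(records))
  for (k in ord) {
    r <- records[[k]]
    placed <- FALSE
    for (c in seq_along(reps)) {
      aln <- global_align(reps[[c]]$sequence, r$sequence,
                          reps[[c]]$source_id, r$source_id)
      if (aln$identity >= cfg$identity_threshold) {
        membership[k] <- c; placed <- TRUE; break
      }
    }
    if (!placed) {
      reps[[length(reps) + 1L]] <- r
      membership[k] <- length(reps)
    }
  }
  lapply(seq_along(reps), function(c) {
    idx <- ord[membership[ord] == c]     # keep length-sorted member order
    members <- records[idx]
    names(members) <- ids[idx]
    cl <- structure(list(members = members,
                         representative_id = reps[[c]]$source_id,
                         master_id = NA_character_,
                         analyzable = length(members) >= cfg$min_cluster_size,
                         msa = NULL),
                    class = "flex_cluster")
    cl$master_id <- select_master(cl)
    cl
  })
}

#' @export
print.flex_cluster <- function(x, ...) {
  cat(sprintf("<flex_cluster> %d member(s), master %s%s\n",
              length(x$members), x$master_id,
              if (x$analyzable) "" else " (not analyzable)"))
  invisible(x)
}

#' Select the master chain of a cluster
#'
#' The master is the longest (most complete) member: maximal SEQRES length,
#' ties broken by larger resolved-residue count, remaining ties by
#' lexicographically smallest `source_id`.  It anchors the indexing frame of
#' the master--slave alignment and of flexibility profiles.
#'
#' @param cluster A `flex_cluster`.
#' @return The master's `source_id`.
#' @export
select_master <- function(cluster) {
  m <- cluster$members
  if (!length(m)) stop("empty cluster")
  ids  <- unname(vapply(m, `[[`, "", "source_id"))
  lens <- vapply(m, function(r) length(r$aa), 0L)
  resv <- vapply(m, function(r) sum(r$resolved), 0L)
  ids[order(-lens, -resv, ids)][1L]
}

#' Build the master--slave multiple alignment of a cluster
#'
#' Each member is globally aligned to the master sequence and the alignment
#' is restricted to residues resolved in both chains, so a column of the
#' resulting msMSA maps a master SEQRES position to the member position
#' whose coordinates can actually be compared there (or to a gap).  Member
#' positions aligned to no master position are dropped.
#'
#' @param cluster A `flex_cluster` with `master_id` set.
#' @return The cluster with `msa` filled in: an integer matrix of dimensions
#'   master length x members (`NA` = gap), column names = member ids, plus
#'   attribute `"master_id"`.
#' @export
build_msmsa <- function(cluster) {
  stopifnot(inherits(cluster, "flex_cluster"))
  master <- cluster$members[[cluster$master_id]]
  n <- length(master$aa)
  msa <- matrix(NA_integer_, n, length(cluster$members),
                dimnames = list(NULL, names(cluster$members)))
  for (id in names(cluster$members)) {
    aln <- align_chains(master, cluster$members[[id]])
    msa[aln$matched$i, id] <- aln$matched$j
  }
  attr(msa, "master_id") <- cluster$master_id
  cluster$msa <- msa
  cluster
}

#' Match a query sequence against ingested chains
#'
#' Aligns the query globally against every chain sequence and ranks hits by
#' identity (ties by id), dropping matches below `floor`.  This is the
#' small-corpus counterpart of searching a structure collection by sequence:
#' it lets a modeler locate the flexibility record of a protein for which
#' only the sequence is known.
#'
#' @param query Amino-acid string (or path of a single-record FASTA file).
#' @param records List of [chain_record()] objects.
#' @param floor Minimum identity to report (default 0.3).
#' @return data.frame of `source_id`, `identity`, `n_aligned`, best first.
#' @export
match_sequence <- function(query, records, floor = 0.3) {
  if (length(query) == 1L && file.exists(query)) {
    q <- Biostrings::readAAStringSet(query)
    if (!length(q)) stop("empty FASTA query")
    query <- as.character(q[[1L]])
  }
  if (!nzchar(query)) stop("empty query sequence")
  hits <- lapply(records, function(r) {
    aln <- global_align(query, r$sequence, "query", r$source_id)
    data.frame(source_id = r$source_id, identity = aln$identity,
               n_aligned = nrow(aln$matched))
  })
  hits <- do.call(rbind, c(hits, list(make.row.names = FALSE)))
  if (is.null(hits)) return(data.frame(source_id = character(0),
                                       identity = numeric(0),
                                       n_aligned = integer(0)))
  hits <- hits[hits$identity >= floor, , drop = FALSE]
  hits[order(-hits$identity, hits$source_id), , drop = FALSE]
}
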