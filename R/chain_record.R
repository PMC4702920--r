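#' Construct a chain record
#'
#' A `chain_record` is the unit of analysis: one protein chain from one
#' deposition, with the SEQRES-defined sequence as the indexing frame.
#' Residue `i` always means the `i`-th SEQRES position; author residue
#' numbers are carried only as metadata.  Residues present in SEQRES but
#' lacking a C-alpha coordinate are *disordered* (unresolved).
#'
#' @param source_id Identifier like `"2hphA"` (entry id + chain id).
#' @param aa Character vector of one-letter amino-acid codes (`"X"` for
#'   unknown), one per SEQRES position.
#' @param xyz Numeric matrix, `length(aa)` x 3, of C-alpha coordinates in
#'   Angstrom; rows of `NA` for unresolved residues.
#' @param ss Optional character vector of secondary-structure labels, one of
#'   `"H"` (helix), `"E"` (strand), `"L"` (loop), `"D"` (disordered).
#'   Unresolved positions are forced to `"D"`.
#' @param resno Optional integer/character vector of author residue numbers
#'   (metadata only).
#'
#' @return An object of class `chain_record`: a list with elements
#'   `source_id`, `sequence` (collapsed string), `aa`, `resolved` (logical
#'   mask), `xyz`, `ss`, `resno`.
#' @export
#' @examples
#' r <- chain_record("toy_A", c("A", "G", "C"),
#'                   rbind(c(0, 0, 0), c(3.8, 0, 0), NA))
#' r$resolved
chain_record <- function(source_id, aa, xyz, ss = NULL, resno = NULL) {
  stopifnot(is.character(source_id), length(source_id) == 1L)
  aa <- toupper(as.character(aa))
  n <- length(aa)
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  if (nrow(xyz) != n)
    stop("xyz must have one row per SEQRES position (", n, "), got ",
         nrow(xyz))
  resolved <- stats::complete.cases(xyz)
  xyz[!resolved, ] <- NA_real_
  if (!is.null(ss)) {
    ss <- toupper(as.character(ss))
    if (length(ss) != n) stop("ss length must match sequence length")
    bad <- !ss %in% c("H", "E", "L", "D")
    if (any(bad)) stop("invalid ss label(s): ", paste(unique(ss[bad]), collapse = ", "))
    ss[!resolved] <- "D"
    if (any(ss == "D" & resolved))
      stop("ss label 'D' on a resolved residue")
  }
  structure(list(source_id = source_id,
                 sequence  = paste(aa, collapse = ""),
                 aa        = aa,
                 resolved  = resolved,
                 xyz       = xyz,
                 ss        = ss,
                 resno     = resno),
            class = "chain_record")
}

#' @export
print.chain_record <- function(x, ...) {
  cat("<chain_record> ", x$source_id, ": ", length(x$aa), " residues, ",
      sum(x$resolved), " resolved", sep = "")
  segs <- disorder_segments(x)
  if (nrow(segs)) cat(", ", nrow(segs), " disordered segment(s)", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.chain_record <- function(x) length(x$aa)

#' Resolved C-alpha coordinates of a chain
#'
#' @param record A [chain_record()].
#' @param positions Optional SEQRES positions to extract (must be resolved).
#' @return Numeric matrix of coordinates, rownames = SEQRES positions.
#' @export
resolved_xyz <- function(record, positions = NULL) {
  if (is.null(positions)) positions <- which(record$resolved)
  if (!all(record$resolved[positions]))
    stop("requested positions include unresolved residues")
  m <- record$xyz[positions, , drop = FALSE]
  rownames(m) <- positions
  m
}

#' Disordered (unresolved) segments of a chain
#'
#' Maximal runs of SEQRES residues with no C-alpha coordinate, i.e. the
#' regions an X-ray experiment could not resolve.
#'
#' @param record A [chain_record()].
#' @return A data.frame with columns `start`, `end` (1-based, inclusive,
#'   SEQRES indexing), sorted and non-overlapping; zero rows if fully
#'   resolved.
#' @export
#' @examples
#' r <- chain_record("toy_A", c("A", "G", "C", "K", "L"),
#'                   rbind(NA, NA, c(0, 0, 0), c(3.8, 0, 0), NA))
#' disorder_segments(r)   # rows (1,2) and (5,5)
disorder_segments <- function(record) {
  stopifnot(inherits(record, "chain_record"))
  r <- rle(!record$resolved)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Attach secondary-structure labels to a chain record
#'
#' Labels use the alphabet `H` (helix), `E` (strand), `L` (loop); unresolved
#' residues are always relabelled `D` regardless of the input.  The
#' annotation file is a two-column whitespace-separated table
#' `position label` in SEQRES indexing (`#` comments allowed); positions not
#' listed default to `L`.
#'
#' @param record A [chain_record()].
#' @param labels Either a character vector of per-residue labels or the path
#'   of an annotation file.
#' @return The record with `$ss` set.
#' @export
set_ss_labels <- function(record, labels) {
  stopifnot(inherits(record, "chain_record"))
  n <- length(record$aa)
  if (length(labels) == 1L && file.exists(labels)) {
    tab <- utils::read.table(labels, header = FALSE, comment.char = "#",
                             col.names = c("pos", "label"),
                             colClasses = c("integer", "character"))
    ss <- rep("L", n)
    ok <- tab$pos >= 1L & tab$pos <= n
    ss[tab$pos[ok]] <- toupper(tab$label[ok])
  } else {
    ss <- toupper(as.character(labels))
    if (length(ss) != n) stop("ss label vector length must be ", n)
  }
  ss[!record$resolved] <- "D"
  bad <- !ss %in% c("H", "E", "L", "D")
  if (any(bad)) stop("invalid ss label(s): ", paste(unique(ss[bad]), collapse = ", "))
  if (any(ss == "D" & record$resolved))
    stop("ss label 'D' is reserved for unresolved residues")
  record$ss <- ss
  record
}
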