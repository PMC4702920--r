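.aa_letters <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y","X")

# match +1, mismatch 0; X never scores as a match
.aa_score_matrix <- local({
  M <- matrix(0, 21L, 21L, dimnames = list(.aa_letters, .aa_letters))
  diag(M) <- 1
  M["X", "X"] <- 0
  M
})

sanitize_aa <- function(seq) {
  s <- toupper(seq)
  chartr(paste(setdiff(LETTERS, .aa_letters), collapse = ""),
         strrep("X", length(setdiff(LETTERS, .aa_letters))), s)
}

#' Global (end-gap-free) pairwise sequence alignment
#'
#' Optimal global alignment with free end gaps, scoring match +1, mismatch 0,
#' affine internal gaps (open 5, extend 0.5 subtracted) -- a scheme adequate
#' for the near-identical sequences this package clusters, where the only
#' expected differences are construct boundaries, tags and point mutations.
#' Sequence identity is the number of identical aligned residues (`X` never
#' counts) divided by the length of the shorter sequence, the "global
#' sequence identity" convention of greedy incremental clustering tools.
#'
#' @param seq_a,seq_b Non-empty amino-acid strings (one-letter codes;
#'   characters outside the 20 standard letters are treated as `X`).
#' @param a_id,b_id Optional sequence identifiers carried in the result.
#' @return An object of class `pairwise_alignment`: list with `a_id`, `b_id`,
#'   `len_a`, `len_b`, `matched` (data.frame of aligned position pairs `i`,
#'   `j` with residues `a`, `b`; strictly increasing in both columns), and
#'   `identity` in `[0, 1]`.
#' @export
#' @examples
#' global_align("ACDEFG", "XXACDEFG")$identity   # 1: end gaps are free
global_align <- function(seq_a, seq_b, a_id = "a", b_id = "b") {
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("sequences must be non-empty")
  sa <- sanitize_aa(seq_a); sb <- sanitize_aa(seq_b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb), type = "overlap",
    substitutionMatrix = .aa_score_matrix, gapOpening = 5, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  i <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  j <- Biostrings::start(Biostrings::subject(aln)) - 1L
  ii <- jj <- integer(length(pa)); keep <- logical(length(pa))
  for (k in seq_along(pa)) {
    if (pa[k] != "-") i <- i + 1L
    if (pb[k] != "-") j <- j + 1L
    keep[k] <- pa[k] != "-" && pb[k] != "-"
    ii[k] <- i; jj[k] <- j
  }
  matched <- data.frame(i = ii[keep], j = jj[keep],
                        a = pa[keep], b = pb[keep],
                        stringsAsFactors = FALSE)
  new_pairwise_alignment(a_id, b_id, nchar(sa), nchar(sb), matched)
}

new_pairwise_alignment <- function(a_id, b_id, len_a, len_b, matched,
                                   denom = min(len_a, len_b)) {
  n_match <- sum(matched$a == matched$b & matched$a != "X")
  structure(list(a_id = a_id, b_id = b_id, len_a = len_a, len_b = len_b,
                 matched = matched,
                 identity = if (denom > 0) n_match / denom else 0),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s vs %s: %d aligned pairs, identity %.3f\n",
              x$a_id, x$b_id, nrow(x$matched), x$identity))
  invisible(x)
}

#' Restrict an alignment to resolved residues
#'
#' Drops aligned pairs where either residue lacks a C-alpha coordinate, the
#' correction needed before any coordinate-based comparison: an aligned pair
#' is only usable if both structures actually resolved it.  Identity is
#' recomputed over the surviving pairs relative to the smaller resolved
#' count.
#'
#' @param aln A [global_align()] result.
#' @param mask_a,mask_b Logical resolved masks for the two sequences (lengths
#'   must equal `aln$len_a` / `aln$len_b`).
#' @return A `pairwise_alignment` over resolved pairs only.
#' @export
restrict_to_resolved <- function(aln, mask_a, mask_b) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  if (length(mask_a) != aln$len_a || length(mask_b) != aln$len_b)
    stop("mask length mismatch: need ", aln$len_a, " and ", aln$len_b,
         ", got ", length(mask_a), " and ", length(mask_b))
  keep <- mask_a[aln$matched$i] & mask_b[aln$matched$j]
  new_pairwise_alignment(aln$a_id, aln$b_id, aln$len_a, aln$len_b,
                         aln$matched[keep, , drop = FALSE],
                         denom = min(sum(mask_a), sum(mask_b)))
}

# Place a (possibly interrupted) subsequence onto its parent sequence.
# Used to map ATOM-derived residues onto SEQRES positions: unlike the
# clustering scorer, mismatches and gaps are penalized (mismatch -2,
# gap open 1 / extend 0.1, free end gaps) so scattered unresolved residues
# open gaps instead of sliding the register.
map_subsequence <- function(full, sub) {
  M <- .aa_score_matrix * 3 - 2       # match +1 -> +3/-2 contrast
  diag(M) <- 3; M["X", "X"] <- 0
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sanitize_aa(full)),
    Biostrings::AAString(sanitize_aa(sub)), type = "overlap",
    substitutionMatrix = M, gapOpening = 1, gapExtension = 0.1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  i <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  j <- Biostrings::start(Biostrings::subject(aln)) - 1L
  out_i <- out_j <- integer(0)
  for (k in seq_along(pa)) {
    if (pa[k] != "-") i <- i + 1L
    if (pb[k] != "-") j <- j + 1L
    if (pa[k] != "-" && pb[k] != "-") { out_i <- c(out_i, i); out_j <- c(out_j, j) }
  }
  data.frame(i = out_i, j = out_j)
}

#' Resolved-restricted alignment between two chain records
#'
#' Convenience wrapper: [global_align()] on the SEQRES sequences followed by
#' [restrict_to_resolved()] on the chains' resolved masks.
#'
#' @param a,b [chain_record()] objects.
#' @return A `pairwise_alignment`.
#' @export
align_chains <- function(a, b) {
  aln <- global_align(a$sequence, b$sequence, a$source_id, b$source_id)
  restrict_to_resolved(aln, a$resolved, b$resolved)
}
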