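#' Read protein chains from a PDB file
#'
#' Parses a PDB-format coordinate file (via \pkg{bio3d}) into one
#' [chain_record()] per polymer chain.  The SEQRES-defined sequence is the
#' indexing frame: C-alpha atoms are mapped onto SEQRES positions by an
#' end-gap-free global alignment of the ATOM-derived sequence against the
#' SEQRES sequence, so residues deposited without coordinates come out
#' unresolved (`has_ca = FALSE`, label `D`).  When SEQRES records are absent
#' the sequence is reconstructed from the ATOM records and the resolved mask
#' is all-`TRUE`.
#'
#' Only single-model content is analysed: for multi-model files the first
#' MODEL is read (solution-NMR ensembles are outside the method's scope).
#' For alternate locations the first-listed conformer's C-alpha is kept.
#' Non-standard residues with a C-alpha are mapped to their parent amino
#' acid where a standard 3-to-1 mapping exists, else to `"X"`.
#'
#' @param file Path to a PDB-format file.
#' @return A list of [chain_record()] objects, one per chain, with
#'   `source_id` = lowercased file stem (clipped to 4 characters) + chain id.
#'   Chains with zero C-alpha atoms are skipped with a warning.
#' @export
read_chain_records <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  lines <- readLines(file, warn = FALSE)
  rec_types <- c("ATOM", "HETA", "SEQR", "MODE", "HEAD", "TER", "END",
                 "REMA", "TITL", "COMP", "SOUR", "EXPD", "ENDM", "CRYS",
                 "SCAL", "ORIG", "HELI", "SHEE", "SSBO", "LINK", "CONE",
                 "MAST", "AUTH", "REVD", "JRNL", "KEYW", "DBRE", "SEQA",
                 "FORM", "HET ", "HETN", "HETS", "ANIS", "CISP", "SITE",
                 "MDLT", "SPRS", "CAVE", "OBSL", "SPLT", "MTRI")
  known <- substr(lines, 1, 4) %in% rec_types | !nzchar(trimws(lines))
  if (!any(startsWith(lines, "ATOM") | startsWith(lines, "HETATM")))
    stop("not PDB format (no ATOM records): first offending line: ",
         utils::head(lines[!known], 1L), call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(file, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse '", file, "' as PDB: ",
                             conditionMessage(e), call. = FALSE))

  stem <- tolower(sub("\\.(pdb|ent)$", "", basename(file), ignore.case = TRUE))
  stem <- substr(stem, 1L, 4L)

  atoms <- pdb$atom
  # candidate C-alphas: backbone CA of standard or mappable modified residues;
  # excludes e.g. calcium ions (HETATM, resid "CA", unmappable)
  aa1 <- suppressWarnings(bio3d::aa321(atoms$resid))
  is_ca <- atoms$elety == "CA" & (atoms$type == "ATOM" | aa1 != "X")
  chains <- unique(atoms$chain[is_ca])
  chains <- chains[!is.na(chains)]
  seqres_chain <- names(pdb$seqres)

  out <- list()
  for (ch in chains) {
    sel <- which(is_ca & atoms$chain == ch)
    # altloc: keep the first-listed conformer per residue
    key <- paste(atoms$resno[sel], atoms$insert[sel])
    sel <- sel[!duplicated(key)]
    if (!length(sel)) {
      warning("chain ", ch, " of ", basename(file),
              " has no C-alpha atoms; skipped")
      next
    }
    atom_aa  <- aa1[sel]
    atom_xyz <- as.matrix(atoms[sel, c("x", "y", "z")])
    atom_res <- atoms$resno[sel]

    sr <- if (!is.null(seqres_chain) && ch %in% seqres_chain)
      suppressWarnings(bio3d::aa321(pdb$seqres[seqres_chain == ch])) else NULL

    id <- paste0(stem, ch)
    if (is.null(sr)) {
      rec <- chain_record(id, atom_aa, atom_xyz, resno = atom_res)
    } else {
      n <- length(sr)
      # author residue numbers are trusted when they index SEQRES directly
      # (1-based, increasing, amino acids agree); otherwise the ATOM-derived
      # sequence is placed on SEQRES by alignment
      ins <- atoms$insert[sel]
      direct <- !anyNA(atom_res) && all(is.na(ins)) &&
        all(atom_res >= 1L & atom_res <= n) && all(diff(atom_res) > 0) &&
        all(sr[atom_res] == atom_aa | sr[atom_res] == "X" | atom_aa == "X")
      map <- if (direct) data.frame(i = atom_res, j = seq_along(atom_res))
        else map_subsequence(paste(sr, collapse = ""),
                             paste(atom_aa, collapse = ""))
      xyz <- matrix(NA_real_, n, 3L)
      resno <- rep(NA_integer_, n)
      xyz[map$i, ] <- atom_xyz[map$j, , drop = FALSE]
      resno[map$i] <- atom_res[map$j]
      if (nrow(map) < length(sel))
        warning(length(sel) - nrow(map), " C-alpha atom(s) of chain ",
                ch, " could not be placed on the SEQRES sequence; dropped")
      rec <- chain_record(id, sr, xyz, resno = resno)
    }
    out[[rec$source_id]] <- rec
  }
  if (!length(out))
    warning("no usable polymer chains in ", basename(file))
  out
}

#' Write a chain record as a C-alpha-only PDB file
#'
#' Emits SEQRES records for the full SEQRES sequence plus one CA ATOM record
#' per resolved residue, numbered by SEQRES position, so re-reading the file
#' reproduces the sequence, the resolved mask and the coordinates (to the
#' fixed-width precision of the PDB format, 1e-3 Angstrom).
#'
#' @param record A [chain_record()].
#' @param file Output path.
#' @param chain Single-character chain id (default: last character of
#'   `source_id`).
#' @return `file`, invisibly.
#' @export
write_chain_pdb <- function(record, file, chain = NULL) {
  stopifnot(inherits(record, "chain_record"))
  if (is.null(chain))
    chain <- substr(record$source_id, nchar(record$source_id),
                    nchar(record$source_id))
  aa3 <- bio3d::aa123(record$aa)
  n <- length(aa3)
  seqres <- character(0)
  idx <- split(seq_len(n), ceiling(seq_len(n) / 13))
  for (k in seq_along(idx)) {
    seqres <- c(seqres, sprintf("SEQRES %3d %s %4d  %s", k, chain, n,
                                paste(aa3[idx[[k]]], collapse = " ")))
  }
  res <- which(record$resolved)
  tmp <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = tmp,
                   xyz = as.numeric(t(record$xyz[res, , drop = FALSE])),
                   resno = res, resid = aa3[res],
                   elety = rep("CA", length(res)),
                   chain = rep(chain, length(res)))
  writeLines(c(seqres, readLines(tmp, warn = FALSE)), file)
  unlink(tmp)
  invisible(file)
}

#' Write chain sequences as FASTA
#'
#' @param records List of [chain_record()] objects.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_chains_fasta <- function(records, file) {
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, `[[`, "", "source_id")
  Biostrings::writeXStringSet(seqs, file)
  invisible(file)
}

#' Quality-filter configuration
#'
#' Thresholds applied to ingested chains before clustering, with strict
#' boundary semantics: a chain is kept iff it has *more than* `min_residues`
#' SEQRES residues, its longest run of unknown (`X`) residues is at most
#' `max_unknown_run`, and it has *more than* `min_ca` resolved C-alpha
#' coordinates.
#'
#' @param min_residues Minimum SEQRES length, exclusive (default 25: a
#'   25-residue chain is rejected, a 26-residue chain kept).
#' @param max_unknown_run Longest tolerated run of consecutive `X` residues
#'   (default 20; a run of 21 rejects).
#' @param min_ca Minimum resolved C-alpha count, exclusive (default 25).
#' @return An object of class `quality_filter_config`.
#' @export
quality_filter_config <- function(min_residues = 25L, max_unknown_run = 20L,
                                  min_ca = 25L) {
  stopifnot(min_residues > 0, max_unknown_run > 0, min_ca > 0)
  structure(list(min_residues = as.integer(min_residues),
                 max_unknown_run = as.integer(max_unknown_run),
                 min_ca = as.integer(min_ca)),
            class = "quality_filter_config")
}

longest_x_run <- function(aa) {
  r <- rle(aa == "X")
  if (any(r$values)) max(r$lengths[r$values]) else 0L
}

#' Apply chain quality filters
#'
#' @param records List of [chain_record()] objects.
#' @param cfg A [quality_filter_config()].
#' @return A list with `kept` (the surviving records) and `rejected`
#'   (data.frame of `source_id`, `reason`; reason is the first failing test
#'   among `too_short`, `unknown_run`, `too_few_ca`).
#' @export
apply_quality_filters <- function(records, cfg = quality_filter_config()) {
  stopifnot(inherits(cfg, "quality_filter_config"))
  kept <- list()
  rej_id <- character(0); rej_why <- character(0)
  for (r in records) {
    reason <- if (length(r$aa) <= cfg$min_residues) "too_short"
      else if (longest_x_run(r$aa) > cfg$max_unknown_run) "unknown_run"
      else if (sum(r$resolved) <= cfg$min_ca) "too_few_ca"
      else NA_character_
    if (is.na(reason)) kept[[r$source_id]] <- r
    else { rej_id <- c(rej_id, r$source_id); rej_why <- c(rej_why, reason) }
  }
  list(kept = kept,
       rejected = data.frame(source_id = rej_id, reason = rej_why))
}

#' Serialize / deserialize chain records as JSON
#'
#' The on-disk format used by the command-line pipeline between stages.
#'
#' @param records List of [chain_record()] objects.
#' @param file Path of the JSON file.
#' @return `write_chains_json()` returns `file` invisibly;
#'   `read_chains_json()` returns the list of records.
#' @export
write_chains_json <- function(records, file) {
  payload <- lapply(unname(records), function(r) {
    out <- list(source_id = r$source_id, aa = r$aa,
                x = r$xyz[, 1L], y = r$xyz[, 2L], z = r$xyz[, 3L])
    if (!is.null(r$ss)) out$ss <- r$ss
    if (!is.null(r$resno)) out$resno <- r$resno
    out
  })
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(file)
}

#' @rdname write_chains_json
#' @export
read_chains_json <- function(file) {
  payload <- jsonlite::read_json(file, simplifyVector = TRUE)
  pick <- function(row, what) {
    v <- row[[what]]
    if (is.null(v) || !length(v) || all(is.na(unlist(v)))) NULL else unlist(v)
  }
  recs <- lapply(seq_len(nrow(payload)), function(k) {
    row <- payload[k, ]
    xyz <- cbind(unlist(row$x), unlist(row$y), unlist(row$z))
    chain_record(row$source_id, unlist(row$aa), xyz,
                 ss = pick(row, "ss"), resno = pick(row, "resno"))
  })
  names(recs) <- vapply(recs, `[[`, "", "source_id")
  recs
}

#' Download PDB entries from the RCSB archive
#'
#' An explicit network operation (nothing else in the package touches the
#' network): fetches `<id>.pdb` for each entry id from
#' `https://files.rcsb.org/download/`.
#'
#' @param ids Character vector of 4-character PDB entry ids.
#' @param dir Output directory (created if needed).
#' @return Character vector of downloaded file paths.
#' @export
fetch_pdb <- function(ids, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vapply(ids, function(id) {
    id <- toupper(id)
    dest <- file.path(dir, paste0(tolower(id), ".pdb"))
    url <- paste0("https://files.rcsb.org/download/", id, ".pdb")
    status <- tryCatch(utils::download.file(url, dest, quiet = TRUE,
                                            mode = "wb"),
                       error = function(e) -1L, warning = function(w) -1L)
    if (!identical(status, 0L) || !file.exists(dest) || !file.size(dest))
      stop("failed to download ", id, " from RCSB (", url, ")", call. = FALSE)
    dest
  }, character(1))
}
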