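## Peptide design: turn an interface residue map into contiguous binding
## segments, join them with a flexible Gly-Ser linker sized to the
## inter-segment gap, and enumerate the exhaustive single-point mutant
## library of the assembled peptide.

validate_sequence <- function(seq, what = "sequence") {
  letters <- strsplit(seq, "")[[1]]
  bad <- setdiff(letters, AA_LETTERS)
  if (length(bad) > 0)
    stop(what, " contains non-standard letters: ", paste(bad, collapse = ""))
  invisible(letters)
}

#' Extract contiguous binding segments from an interface map
#'
#' Maximal runs of residues that are consecutive in their chain's
#' residue-key order (insertion-code residues count as chain neighbours)
#' become binding segments, ordered by chain then start position.
#'
#' @param interface residue-key data.frame of interface residues.
#' @param s the `pep_structure` the keys refer to.
#' @param min_len minimal run length to keep.
#' @return list of segments; each has `chain`, `start`, `end` (single-row
#'   residue-key data.frames), `keys` and `sequence`.
#' @export
extract_segments <- function(interface, s, min_len = 1) {
  if (is.null(interface) || nrow(interface) == 0) return(list())
  res <- structure_residues(s)
  res_id <- paste0(res$chain, "|", res$resseq, "|", res$icode)
  ifc_id <- paste0(interface$chain, "|", interface$resseq, "|",
                   interface$icode)
  missing <- setdiff(ifc_id, res_id)
  if (length(missing) > 0)
    stop("interface residues absent from structure: ",
         paste(missing, collapse = ", "))
  segments <- list()
  for (ch in sort(unique(interface$chain))) {
    chain_res <- res[res$chain == ch, , drop = FALSE]
    pos <- which(paste0(chain_res$chain, "|", chain_res$resseq, "|",
                        chain_res$icode) %in% ifc_id)
    if (length(pos) == 0) next
    pos <- sort(pos)
    run_id <- cumsum(c(1, diff(pos) != 1))
    for (run in split(pos, run_id)) {
      if (length(run) < min_len) next
      keys <- chain_res[run, c("chain", "resseq", "icode"), drop = FALSE]
      rownames(keys) <- NULL
      segments[[length(segments) + 1]] <- list(
        chain = ch,
        start = keys[1, , drop = FALSE],
        end = keys[nrow(keys), , drop = FALSE],
        keys = keys,
        sequence = paste(chain_res$one_letter[run], collapse = ""))
    }
  }
  segments
}

#' Choose a Gly-Ser linker spanning a gap
#'
#' The linker length is `ceiling(gap / 3.8)` residues (3.8 Angstrom is the
#' extended-chain C-alpha step), minimum one; the sequence is the repeating
#' "GS" pattern truncated to that length, so the printed 4.8 Angstrom gap
#' yields the two-residue "GS" linker.
#'
#' @param gap inter-segment gap in Angstrom (> 0).
#' @return linker sequence string.
#' @export
choose_linker <- function(gap) {
  if (!is.numeric(gap) || length(gap) != 1 || !is.finite(gap) || gap <= 0)
    stop("gap must be a positive distance in Angstrom")
  n <- max(1L, as.integer(ceiling(gap / 3.8)))
  substr(strrep("GS", ceiling(n / 2)), 1, n)
}

#' Measure the gap between two binding segments
#'
#' Distance between the nearest terminal C-alpha atoms of consecutive
#' segments (end of the first vs start of the second).
#'
#' @param seg1,seg2 segments as returned by [extract_segments()].
#' @param s the `pep_structure`.
#' @return distance in Angstrom.
#' @export
segment_gap <- function(seg1, seg2, s) {
  ca <- function(key) {
    a <- s$atoms
    sel <- a$chain == key$chain & a$resseq == key$resseq &
      a$icode == key$icode & a$name == "CA"
    if (!any(sel)) stop("no CA atom for residue ",
                        format_residue_keys(key))
    c(a$x[sel][1], a$y[sel][1], a$z[sel][1])
  }
  combos <- expand.grid(a = c("start", "end"), b = c("start", "end"),
                        stringsAsFactors = FALSE)
  min(apply(combos, 1, function(cb)
    sqrt(sum((ca(seg1[[cb[["a"]]]]) - ca(seg2[[cb[["b"]]]]))^2))))
}

#' Assemble a designed peptide from segments and a linker
#'
#' @param segments list of segments ([extract_segments()]) or plain
#'   character vector of segment sequences.
#' @param linker linker sequence inserted between consecutive segments.
#' @return a `designed_peptide`: `sequence`, `segments`, `linker` and a
#'   per-position `provenance` vector (`"segment<i>"` or `"linker"`).
#' @export
assemble_peptide <- function(segments, linker = "") {
  if (length(segments) == 0) stop("need at least one segment")
  seqs <- if (is.character(segments)) segments
          else vapply(segments, function(x) x$sequence, "")
  for (sq in seqs) validate_sequence(sq, "segment")
  if (nchar(linker) > 0) validate_sequence(linker, "linker")
  parts <- character(0)
  provenance <- character(0)
  for (i in seq_along(seqs)) {
    if (i > 1 && nchar(linker) > 0) {
      parts <- c(parts, linker)
      provenance <- c(provenance, rep("linker", nchar(linker)))
    }
    parts <- c(parts, seqs[i])
    provenance <- c(provenance, rep(paste0("segment", i), nchar(seqs[i])))
  }
  structure(list(sequence = paste(parts, collapse = ""),
                 segments = seqs, linker = linker,
                 provenance = provenance),
            class = "designed_peptide")
}

#' @export
print.designed_peptide <- function(x, ...) {
  cat(sprintf("<designed_peptide> %s (%d aa, %d segment(s), linker '%s')\n",
              x$sequence, nchar(x$sequence), length(x$segments), x$linker))
  invisible(x)
}

#' Exhaustive single-point mutant library
#'
#' Every position of the parent is substituted with each of the 19
#' non-parental standard amino acids, giving `19 * nchar(parent)` variants
#' ordered by position then substituted letter; names follow the
#' `<original><position><substituted>` convention (e.g. "G10C").
#'
#' @param parent parent sequence (standard 20 letters).
#' @return a `mutant_library` data.frame with columns `name`, `position`,
#'   `original`, `substituted`, `sequence`; the parent is stored as an
#'   attribute.
#' @export
saturation_mutagenesis <- function(parent) {
  if (!is.character(parent) || length(parent) != 1 || nchar(parent) == 0)
    stop("parent must be a non-empty sequence string")
  letters <- validate_sequence(parent, "parent")
  rows <- vector("list", length(letters))
  for (pos in seq_along(letters)) {
    subs <- setdiff(AA_LETTERS, letters[pos])
    seqs <- vapply(subs, function(aa) {
      v <- letters; v[pos] <- aa; paste(v, collapse = "")
    }, "")
    rows[[pos]] <- data.frame(
      name = paste0(letters[pos], pos, subs),
      position = pos, original = letters[pos], substituted = subs,
      sequence = unname(seqs), stringsAsFactors = FALSE)
  }
  lib <- do.call(rbind, rows)
  rownames(lib) <- NULL
  attr(lib, "parent") <- parent
  class(lib) <- c("mutant_library", "data.frame")
  lib
}

#' @export
print.mutant_library <- function(x, ...) {
  cat(sprintf("<mutant_library> parent=%s, %d single-point variants\n",
              attr(x, "parent"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' Write a mutant library as FASTA
#'
#' @param library a `mutant_library`.
#' @param path output path; headers carry the variant names.
#' @return `invisible(path)`.
#' @export
write_library_fasta <- function(library, path) {
  seqs <- stats::setNames(library$sequence, library$name)
  write_fasta(seqs, path)
}
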