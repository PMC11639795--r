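## Hierarchical protein structures stored as a flat atom table. One row per
## atom; residues are identified by the (chain, resseq, icode) triple so that
## PDB insertion codes (e.g. 53A between 53 and 54) survive every operation.

PDB_WATER_NAMES <- c("HOH", "WAT", "H2O", "DOD", "TIP", "TIP3", "SOL")

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
AA_ONE_TO_THREE <- structure(names(AA_THREE_TO_ONE), names = AA_THREE_TO_ONE)
AA_LETTERS <- sort(unname(AA_THREE_TO_ONE))

## Element van der Waals radii (Angstrom) used as fallback and as the
## "element" radius set.
ELEMENT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                   P = 1.80, SE = 1.90)
ELEMENT_RADIUS_FALLBACK <- 1.80

## Standard atomic masses; 12.011 fallback for unknown elements.
ELEMENT_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06, SE = 78.971)
ELEMENT_MASS_FALLBACK <- 12.011

#' Build a residue-key table
#'
#' Residue keys are the package-wide currency for naming residues: a chain
#' identifier, an integer sequence number and a (possibly blank) insertion
#' code. The ordering is (resseq, icode) with a blank icode sorting before
#' any letter, so 53 < 53A < 54.
#'
#' @param chain character vector of chain identifiers.
#' @param resseq integer vector of residue sequence numbers.
#' @param icode character vector of insertion codes; `""` for none.
#' @return a data.frame with columns `chain`, `resseq`, `icode`.
#' @examples
#' residue_keys("H", c(53, 53, 54), c("", "A", ""))
#' @export
residue_keys <- function(chain, resseq, icode = "") {
  n <- max(length(chain), length(resseq))
  df <- data.frame(chain = rep_len(as.character(chain), n),
                   resseq = rep_len(as.integer(resseq), n),
                   icode = rep_len(as.character(icode), n),
                   stringsAsFactors = FALSE)
  df$icode[is.na(df$icode)] <- ""
  df
}

#' Format residue keys as strings
#'
#' @param keys a residue-key data.frame (see [residue_keys()]).
#' @return character vector like `"H:53A"`.
#' @export
format_residue_keys <- function(keys) {
  paste0(keys$chain, ":", keys$resseq, keys$icode)
}

## Sortable index for (resseq, icode): blank icode before "A" before "B" ...
residue_key_rank <- function(resseq, icode) {
  ic <- ifelse(icode == "" | is.na(icode), 0L,
               match(toupper(icode), LETTERS, nomatch = 27L))
  as.numeric(resseq) * 32 + ic
}

#' Order residue keys
#'
#' Strict total order by chain, then (resseq, icode) with blank insertion
#' codes first.
#'
#' @param keys residue-key data.frame.
#' @return integer permutation, as from [order()].
#' @export
order_residue_keys <- function(keys) {
  order(keys$chain, residue_key_rank(keys$resseq, keys$icode))
}

residue_id_of <- function(atoms) {
  paste0(atoms$chain, "|", atoms$resseq, "|", atoms$icode)
}

new_structure <- function(atoms) {
  required <- c("model", "serial", "name", "altloc", "resname", "chain",
                "resseq", "icode", "x", "y", "z", "occupancy", "bfactor",
                "element", "hetero", "radius")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0)
    stop("structure atom table missing columns: ",
         paste(missing, collapse = ", "))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "pep_structure")
}

#' @export
print.pep_structure <- function(x, ...) {
  a <- x$atoms
  nmod <- length(unique(a$model))
  cat(sprintf("<pep_structure> %d atoms, %d chain(s) [%s], %d residue(s), %d model(s)\n",
              nrow(a), length(unique(a$chain)),
              paste(sort(unique(a$chain)), collapse = ","),
              length(unique(residue_id_of(a))), nmod))
  invisible(x)
}

#' Number of models in a structure
#' @param s a `pep_structure`.
#' @return integer count of coordinate models.
#' @export
n_models <- function(s) length(unique(s$atoms$model))

## Infer element symbol from a PDB atom name when columns 77-78 are blank.
infer_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  el <- ifelse(substr(gsub("[^A-Za-z0-9]", "", toupper(name)), 1, 1) %in%
                 as.character(0:9),
               "H", NA)
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  el <- ifelse(is.na(el) & two %in% c("FE", "ZN", "MG", "MN", "SE", "CL",
                                      "BR", "NA", "CA", "CU", "NI", "CO"),
               two, el)
  ## Heuristic: names beginning with H followed by letters/digits are
  ## hydrogens (HB2, HG11); metals were caught above.
  el <- ifelse(is.na(el) & one == "H", "H", el)
  el <- ifelse(is.na(el), one, el)
  el
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM/MODEL/ENDMDL/TER records into a structure, preserving
#' insertion-code residue numbering. Waters and other hetero records are
#' dropped by default (the usual cleanup before interface analysis). When a
#' residue has alternate locations only the highest-occupancy altloc is
#' kept, ties broken by altloc letter.
#'
#' @param path path to a PDB file.
#' @param keep_waters keep water molecules (resname HOH/WAT/...)?
#' @param keep_hetero keep non-water HETATM records?
#' @return a `pep_structure`.
#' @export
read_pdb <- function(path, keep_waters = FALSE, keep_hetero = FALSE) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  model_no <- cumsum(rec == "MODEL ")
  model_no[model_no == 0] <- 1L
  atom_lines <- lines[is_atom]
  if (length(atom_lines) == 0) stop("no ATOM/HETATM records in ", path)
  pad <- function(s, width) formatC(s, width = width, flag = "-")
  atom_lines <- pad(atom_lines, 80)
  fld <- function(a, b) trimws(substr(atom_lines, a, b))
  atoms <- data.frame(
    model = model_no[is_atom],
    serial = suppressWarnings(as.integer(fld(7, 11))),
    name = fld(13, 16),
    altloc = fld(17, 17),
    resname = fld(18, 20),
    chain = fld(22, 22),
    resseq = suppressWarnings(as.integer(fld(23, 26))),
    icode = fld(27, 27),
    x = as.numeric(fld(31, 38)),
    y = as.numeric(fld(39, 46)),
    z = as.numeric(fld(47, 54)),
    occupancy = suppressWarnings(as.numeric(fld(55, 60))),
    bfactor = suppressWarnings(as.numeric(fld(61, 66))),
    element = fld(77, 78),
    hetero = substr(atom_lines, 1, 6) == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$bfactor[is.na(atoms$bfactor)] <- 0
  blank_el <- atoms$element == ""
  atoms$element[blank_el] <- infer_element(atoms$name[blank_el])
  atoms$element <- toupper(atoms$element)

  is_water <- atoms$resname %in% PDB_WATER_NAMES
  keep <- rep(TRUE, nrow(atoms))
  if (!keep_waters) keep <- keep & !is_water
  if (!keep_hetero) keep <- keep & (!atoms$hetero | is_water & keep_waters)
  atoms <- atoms[keep, , drop = FALSE]
  if (nrow(atoms) == 0) stop("no atoms left after water/hetero filtering: ", path)

  ## altloc resolution: keep highest occupancy, ties -> first altloc letter
  if (any(atoms$altloc != "")) {
    key <- paste(atoms$model, atoms$chain, atoms$resseq, atoms$icode,
                 atoms$name, sep = "|")
    ord <- order(key, -atoms$occupancy, atoms$altloc)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$model, atoms$chain, atoms$resseq,
                                     atoms$icode, atoms$name, sep = "|")), ,
                   drop = FALSE]
    atoms$altloc <- ""
  }
  ## canonical ordering: model, chain, residue key, serial
  atoms <- atoms[order(atoms$model, atoms$chain,
                       residue_key_rank(atoms$resseq, atoms$icode),
                       atoms$serial), , drop = FALSE]
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in ", path)
  atoms$radius <- NA_real_
  new_structure(atoms)
}

#' Write a structure to a PDB file
#'
#' Emits fixed-width ATOM/HETATM records (MODEL/ENDMDL wrappers for
#' multi-model structures, TER after each chain) that re-parse to an equal
#' structure: atom names, residue keys and coordinates round-trip to the
#' PDB's 3-decimal precision.
#'
#' @param s a `pep_structure`.
#' @param path output file path.
#' @return `invisible(path)`.
#' @export
write_pdb <- function(s, path) {
  a <- s$atoms
  models <- sort(unique(a$model))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write PDB file: ", path))
  on.exit(close(con))
  multi <- length(models) > 1
  for (m in models) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    am <- a[a$model == m, , drop = FALSE]
    for (ch in unique(am$chain)) {
      ac <- am[am$chain == ch, , drop = FALSE]
      name4 <- ifelse(nchar(ac$name) < 4 & nchar(ac$element) == 1,
                      paste0(" ", formatC(ac$name, width = 3, flag = "-")),
                      formatC(ac$name, width = 4, flag = "-"))
      lines <- sprintf(
        "%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        ifelse(ac$hetero, "HETATM", "ATOM"), ac$serial %% 100000L, name4,
        "", formatC(ac$resname, width = 3, flag = "-"), ch,
        ac$resseq, ifelse(ac$icode == "", " ", ac$icode),
        ac$x, ac$y, ac$z, ac$occupancy, ac$bfactor,
        formatC(ac$element, width = 2))
      writeLines(lines, con)
      writeLines("TER", con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## ProtOr-style united-atom radii: classify heavy atoms by chemical class
## from atom name + residue, with element radii as fallback. The class
## radii follow Tsai et al. (1999) as used by FreeSASA's default set.
protor_radius <- function(resname, name, element) {
  n <- length(name)
  r <- rep(NA_real_, n)
  aromatic_ch <- list(
    PHE = c("CD1", "CD2", "CE1", "CE2", "CZ"),
    TYR = c("CD1", "CD2", "CE1", "CE2"),
    HIS = c("CD2", "CE1"),
    TRP = c("CD1", "CE3", "CZ2", "CZ3", "CH2"))
  sp2_c <- list(
    ASP = "CG", ASN = "CG", GLU = "CD", GLN = "CD", ARG = "CZ",
    PHE = "CG", TYR = c("CG", "CZ"), HIS = "CG",
    TRP = c("CG", "CD2", "CE2"))
  for (i in seq_len(n)) {
    el <- element[i]; nm <- name[i]; rs <- resname[i]
    r[i] <- switch(el,
      C = {
        if (nm == "C") 1.61
        else if (nm %in% (sp2_c[[rs]] %||% character())) 1.61
        else if (nm %in% (aromatic_ch[[rs]] %||% character())) 1.76
        else 1.88
      },
      N = 1.64,
      O = if (nm %in% c("OG", "OG1", "OH")) 1.46 else 1.42,
      S = 1.77,
      H = 1.20,
      NA_real_)
  }
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign van der Waals radii to every atom
#'
#' @param s a `pep_structure`.
#' @param radius_set `"protor"` (default; ProtOr-style united-atom class
#'   radii, element fallback) or `"element"` (plain element radii:
#'   C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, P 1.80 Angstrom).
#' @return the structure with a positive `radius` for every atom. Atoms of
#'   unknown element get the 1.80 Angstrom fallback with a warning.
#' @export
assign_radii <- function(s, radius_set = c("protor", "element")) {
  radius_set <- match.arg(radius_set)
  a <- s$atoms
  el_r <- ELEMENT_RADII[a$element]
  unknown <- is.na(el_r)
  if (any(unknown)) {
    warning("unknown element(s) ",
            paste(unique(a$element[unknown]), collapse = ", "),
            ": using fallback radius ", ELEMENT_RADIUS_FALLBACK, " A")
    el_r[unknown] <- ELEMENT_RADIUS_FALLBACK
  }
  r <- unname(el_r)
  if (radius_set == "protor") {
    pr <- protor_radius(a$resname, a$name, a$element)
    r <- ifelse(is.na(pr), r, pr)
  }
  a$radius <- r
  stopifnot(all(a$radius > 0))
  s$atoms <- a
  s
}

#' Select chains and an optional residue-key interval
#'
#' The residue interval is closed and interpreted in residue-key order
#' (so 50--57 on a chain containing 53A yields 9 residues).
#'
#' @param s a `pep_structure`.
#' @param chains character vector of chain ids to keep.
#' @param residue_range optional `list(start =, end =)` of single-row
#'   residue-key data.frames, or a 2-row residue-key data.frame
#'   (first row = start, second = end).
#' @return the sub-structure (possibly with zero residues).
#' @export
select_structure <- function(s, chains, residue_range = NULL) {
  a <- s$atoms
  missing <- setdiff(chains, unique(a$chain))
  if (length(missing) > 0)
    stop("chain(s) not present in structure: ", paste(missing, collapse = ", "))
  keep <- a$chain %in% chains
  if (!is.null(residue_range)) {
    if (is.data.frame(residue_range)) {
      start <- residue_range[1, , drop = FALSE]
      end <- residue_range[2, , drop = FALSE]
    } else {
      start <- residue_range$start
      end <- residue_range$end
    }
    lo <- residue_key_rank(start$resseq, start$icode)
    hi <- residue_key_rank(end$resseq, end$icode)
    rk <- residue_key_rank(a$resseq, a$icode)
    keep <- keep & rk >= lo & rk <= hi
  }
  s$atoms <- a[keep, , drop = FALSE]
  s
}

#' Residue table of a structure
#'
#' @param s a `pep_structure`.
#' @param model model number (default: first).
#' @return residue-key data.frame with extra columns `resname` and
#'   `one_letter`, one row per residue in key order.
#' @export
structure_residues <- function(s, model = NULL) {
  a <- s$atoms
  if (is.null(model)) model <- min(a$model)
  a <- a[a$model == model, , drop = FALSE]
  id <- residue_id_of(a)
  first <- !duplicated(id)
  res <- data.frame(chain = a$chain[first], resseq = a$resseq[first],
                    icode = a$icode[first], resname = a$resname[first],
                    stringsAsFactors = FALSE)
  res$one_letter <- unname(AA_THREE_TO_ONE[res$resname])
  res$one_letter[is.na(res$one_letter)] <- "X"
  res[order_residue_keys(res), , drop = FALSE]
}

#' One-letter sequence of a chain
#'
#' @param s a `pep_structure`.
#' @param chain chain identifier.
#' @return single string; non-standard residues appear as `"X"`.
#' @export
structure_sequence <- function(s, chain) {
  res <- structure_residues(s)
  res <- res[res$chain == chain, , drop = FALSE]
  paste(res$one_letter, collapse = "")
}

## Coordinates of one model as an n x 3 matrix.
structure_coords <- function(s, model = NULL) {
  a <- s$atoms
  if (is.null(model)) model <- min(a$model)
  a <- a[a$model == model, , drop = FALSE]
  cbind(x = a$x, y = a$y, z = a$z)
}

#' Merge two structures into one complex
#'
#' Chains must be disjoint; used to combine a receptor with a docked ligand
#' pose before computing bound-state surface areas.
#'
#' @param a,b `pep_structure` objects with disjoint chain ids.
#' @return combined `pep_structure`.
#' @export
merge_structures <- function(a, b) {
  if (length(intersect(unique(a$atoms$chain), unique(b$atoms$chain))) > 0)
    stop("cannot merge structures with overlapping chain ids")
  atoms <- rbind(a$atoms, b$atoms)
  atoms <- atoms[order(atoms$model, atoms$chain,
                       residue_key_rank(atoms$resseq, atoms$icode),
                       atoms$serial), , drop = FALSE]
  new_structure(atoms)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `invisible(path)`.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i] %||% paste0("seq", i)), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path)
  grp <- cumsum(hdr)
  names <- sub("^>\\s*", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(gsub("\\s", "", x), collapse = ""), "")
  stats::setNames(unname(seqs), names)
}
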