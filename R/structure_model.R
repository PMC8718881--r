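# Structure data model: PDB parsing (via bio3d), declared (SEQRES) sequences,
# disorder segments, and B-factor primitives.

#' Parse PDB-format text into a protein structure
#'
#' Reads ATOM/HETATM/SEQRES records into a light-weight structure model.
#' Alternate locations are resolved to the highest-occupancy conformer (ties
#' broken alphabetically by altloc id). Waters are excluded from polymer
#' chains and kept, with other non-polymer groups, as heteroatoms.
#'
#' Author (PDB) residue numbering is authoritative throughout the package; a
#' declared-sequence position is recovered as `resno - seqres_offset`, so a
#' structure whose deposited SEQRES starts at full-length residue 1 uses the
#' default offset 0.
#'
#' @param text character: PDB-format content (single string or vector of lines)
#' @param seqres_offset integer: author residue number minus declared-sequence
#'   index (0 when author numbering is 1-based on the SEQRES)
#' @return object of class `protein_structure`: list with `atoms` (one row per
#'   atom: record, elety, resid, chain, resno, icode, x/y/z, o, b, element,
#'   het, water), `seqres` (per-chain three-letter vectors, or NULL), and
#'   `seqres_offset`
#' @export
parse_pdb <- function(text, seqres_offset = 0) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  rec <- substr(lines, 1, 6)
  atom_lines <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(atom_lines) == 0L)
    stop_pegsite("no ATOM records found: empty structure")
  for (ln in atom_lines) {
    l <- lines[ln]
    if (nchar(l) < 54)
      stop_pegsite("malformed ATOM/HETATM record at line %d (shorter than 54 columns)", ln)
    xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54))))
    if (any(is.na(xyz)))
      stop_pegsite("malformed ATOM/HETATM record at line %d (non-numeric coordinates)", ln)
  }

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- NULL
  invisible(capture.output(
    pdb <- suppressWarnings(bio3d::read.pdb(tf, rm.alt = FALSE, verbose = FALSE))
  ))
  at <- pdb$atom
  if (nrow(at) == 0L) stop_pegsite("no ATOM records found: empty structure")

  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0

  # altloc: keep highest occupancy, ties broken alphabetically; atoms without
  # any altloc marker are untouched
  if (any(at$alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "\r")
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[at$alt != ""])) {
      rows <- which(key == k & at$alt != "")
      best <- rows[order(-at$o[rows], at$alt[rows])][1]
      keep[setdiff(rows, best)] <- FALSE
    }
    at <- at[keep, , drop = FALSE]
  }

  element <- at$elesy
  bad <- is.na(element) | element == ""
  element[bad] <- sub("^[0-9 ]*([A-Za-z]).*$", "\\1", at$elety[bad])
  element <- toupper(trimws(element))

  atoms <- data.frame(
    record = at$type, eleno = at$eleno, elety = at$elety, resid = at$resid,
    chain = at$chain, resno = at$resno, icode = at$insert,
    x = at$x, y = at$y, z = at$z, o = at$o, b = at$b,
    element = element,
    het = at$type == "HETATM",
    water = at$resid %in% c("HOH", "WAT", "DOD"),
    stringsAsFactors = FALSE
  )

  seqres <- NULL
  if (!is.null(pdb$seqres) && length(pdb$seqres) > 0) {
    seqres <- split(unname(pdb$seqres), names(pdb$seqres))
  }

  structure(
    list(atoms = atoms, seqres = seqres, seqres_offset = as.integer(seqres_offset)),
    class = "protein_structure"
  )
}

#' Read a PDB file
#' @param path file path
#' @param ... passed to [parse_pdb()]
#' @return a `protein_structure`
#' @export
read_pdb_file <- function(path, ...) parse_pdb(readLines(path, warn = FALSE), ...)

#' @export
print.protein_structure <- function(x, ...) {
  pol <- x$atoms[!x$atoms$het, , drop = FALSE]
  cat("<protein_structure> ", length(unique(pol$chain)), " chain(s), ",
      nrow(unique(pol[, c("chain", "resno", "icode")])), " polymer residues, ",
      sum(x$atoms$het & !x$atoms$water), " het atoms, ",
      sum(x$atoms$water), " water atoms\n", sep = "")
  invisible(x)
}

# polymer atoms of one chain (waters and het groups excluded)
polymer_atoms <- function(structure, chain = NULL) {
  a <- structure$atoms
  a <- a[!a$het & !a$water, , drop = FALSE]
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  a
}

#' Chain ids of a structure
#' @param structure a `protein_structure`
#' @return character vector of polymer chain ids
#' @export
structure_chains <- function(structure) unique(polymer_atoms(structure)$chain)

#' Per-residue table of a chain
#'
#' One row per resolved polymer residue in author order, with the residue id,
#' three- and one-letter codes (non-standard residues get NA one-letter code),
#' and mean B-factor.
#' @param structure a `protein_structure`
#' @param chain chain id (default: first chain)
#' @return data.frame
#' @export
residue_table <- function(structure, chain = NULL) {
  chain <- chain %||% structure_chains(structure)[1]
  a <- polymer_atoms(structure, chain)
  if (nrow(a) == 0L) stop_pegsite("chain '%s' has no polymer atoms", chain)
  key <- paste(a$chain, a$resno, a$icode, sep = "\r")
  idx <- !duplicated(key)
  data.frame(
    id = residue_id(a$chain[idx], a$resno[idx], a$icode[idx]),
    chain = a$chain[idx], resno = a$resno[idx], icode = a$icode[idx],
    resid = a$resid[idx],
    aa = unname(AA_3TO1[a$resid[idx]]),
    b = as.numeric(tapply(a$b, factor(key, levels = key[idx]), mean)),
    stringsAsFactors = FALSE
  )
}

#' Declared sequence of a chain
#'
#' SEQRES-derived one-letter sequence when SEQRES records are present,
#' otherwise the sequence of resolved residues. Non-standard residues are
#' rendered as "X".
#' @inheritParams residue_table
#' @return single character string
#' @export
declared_sequence <- function(structure, chain = NULL) {
  chain <- chain %||% structure_chains(structure)[1]
  if (!is.null(structure$seqres) && chain %in% names(structure$seqres)) {
    three <- structure$seqres[[chain]]
  } else {
    three <- residue_table(structure, chain)$resid
  }
  one <- AA_3TO1[three]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

#' Unresolved (disordered) segments of a chain
#'
#' Maximal runs of declared-sequence residues without coordinates. With SEQRES
#' present, positions are declared-sequence indices (1-based) and terminal
#' segments are labelled `N` / `C`. Without SEQRES, only internal gaps in
#' author numbering are detectable (a documented limitation) and positions are
#' author residue numbers.
#'
#' @inheritParams residue_table
#' @return data.frame with columns chain_id, start, end, terminal
#' @export
unresolved_segments <- function(structure, chain = NULL) {
  chain <- chain %||% structure_chains(structure)[1]
  rt <- residue_table(structure, chain)
  empty <- data.frame(chain_id = character(), start = integer(),
                      end = integer(), terminal = character(),
                      stringsAsFactors = FALSE)

  has_seqres <- !is.null(structure$seqres) && chain %in% names(structure$seqres)
  if (has_seqres) {
    L <- length(structure$seqres[[chain]])
    idx <- rt$resno - structure$seqres_offset
    bad <- idx < 1 | idx > L
    if (any(bad))
      warn_pegsite("%d resolved residue(s) of chain '%s' fall outside the declared sequence and were treated as unmappable",
                   sum(bad), chain)
    resolved <- rep(FALSE, L)
    resolved[idx[!bad]] <- TRUE
    missing_run <- rle(!resolved)
    pos <- cumsum(c(1L, missing_run$lengths))
    segs <- empty
    for (k in seq_along(missing_run$values)) {
      if (!missing_run$values[k]) next
      s <- pos[k]; e <- pos[k] + missing_run$lengths[k] - 1L
      terminal <- if (s == 1L) "N" else if (e == L) "C" else "internal"
      segs <- rbind(segs, data.frame(chain_id = chain, start = s, end = e,
                                     terminal = terminal, stringsAsFactors = FALSE))
    }
    return(segs)
  }

  # no SEQRES: author-numbering gaps give internal segments only
  rn <- sort(unique(rt$resno))
  gaps <- which(diff(rn) > 1L)
  if (length(gaps) == 0L) return(empty)
  data.frame(chain_id = chain,
             start = rn[gaps] + 1L, end = rn[gaps + 1L] - 1L,
             terminal = "internal", stringsAsFactors = FALSE)
}

#' Per-residue B-factor z-scores
#'
#' Residue B = mean over its atoms; z = (B - chain mean) / chain sample SD.
#' Used as the flexibility readout for the flexible-loop rule.
#'
#' @inheritParams residue_table
#' @return named numeric vector (names are residue ids) with attribute "B"
#'   holding the raw per-residue means
#' @export
bfactor_zscores <- function(structure, chain = NULL) {
  chain <- chain %||% structure_chains(structure)[1]
  rt <- residue_table(structure, chain)
  if (nrow(rt) < 3L)
    stop_pegsite("chain '%s' has fewer than 3 resolved residues", chain)
  s <- sd(rt$b)
  if (is.na(s) || s == 0) {
    warn_pegsite("chain '%s' has zero B-factor variance; all z-scores set to 0", chain)
    z <- rep(0, nrow(rt))
  } else {
    z <- (rt$b - mean(rt$b)) / s
  }
  structure(setNames(z, rt$id), B = setNames(rt$b, rt$id))
}

#' Write a structure as PDB-format text
#'
#' Emits standard 80-column SEQRES/ATOM/HETATM/TER records. Coordinates keep 3
#' decimals, occupancies and B-factors 2.
#'
#' @param structure a `protein_structure`
#' @param file optional path; when NULL the text is returned invisibly
#' @return character vector of lines (invisibly when writing to file)
#' @export
write_pdb <- function(structure, file = NULL) {
  out <- character()
  if (!is.null(structure$seqres)) {
    for (ch in names(structure$seqres)) {
      res <- structure$seqres[[ch]]
      n <- length(res)
      rows <- split(res, ceiling(seq_along(res) / 13))
      for (k in seq_along(rows)) {
        out <- c(out, sprintf("SEQRES %3d %1s %4d  %-51s", k, ch, n,
                              paste(sprintf("%-3s", rows[[k]]), collapse = " ")))
      }
    }
  }
  a <- structure$atoms
  fmt_name <- function(n) ifelse(nchar(n) >= 4, substr(n, 1, 4), sprintf(" %-3s", n))
  prev_chain <- NULL
  for (i in seq_len(nrow(a))) {
    if (!is.null(prev_chain) && !a$het[i] && a$chain[i] != prev_chain)
      out <- c(out, "TER")
    if (!a$het[i]) prev_chain <- a$chain[i]
    out <- c(out, sprintf(
      "%-6s%5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$record[i], i %% 100000L, fmt_name(a$elety[i]), a$resid[i], a$chain[i],
      a$resno[i], ifelse(a$icode[i] == "", " ", a$icode[i]),
      a$x[i], a$y[i], a$z[i], a$o[i], a$b[i], a$element[i]))
  }
  out <- c(out, "TER", "END")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' @importFrom utils capture.output
NULL
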