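# Alignment-based conservation scoring and its mapping onto structure
# residues.

MSA_ALPHABET <- c(names(AA_1TO3), "X", "-")

#' Read an aligned FASTA file or text
#'
#' Validates equal record lengths and the amino-acid alphabet (20 standard
#' residues, `X`, gap `-`; `.` is normalised to `-`). Duplicate ids are
#' deduplicated with numeric suffixes and a warning.
#'
#' @param input path to an aligned-FASTA file, or its text content
#' @return object of class `msa`: list(ids, seqs, length)
#' @export
read_alignment <- function(input) {
  if (length(input) == 1L && !grepl(">", input, fixed = TRUE) && file.exists(input)) {
    lines <- readLines(input, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(input, collapse = "\n"), "\n", fixed = TRUE))
  }
  hdr <- grepl("^>", lines)
  if (sum(hdr) < 2L) stop_pegsite("alignment needs at least 2 records")
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  seqs <- vapply(seq_len(sum(hdr)), function(k)
    paste(lines[!hdr & grp == k], collapse = ""), "")
  seqs <- toupper(gsub("[ .]", "-", gsub("\\s", "", seqs)))

  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    off <- which(widths != widths[1])[1]
    stop_pegsite("ragged alignment: record '%s' has %d columns, expected %d",
                 ids[off], widths[off], widths[1])
  }
  bad <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    any(!ch %in% MSA_ALPHABET)
  }, TRUE)
  if (any(bad))
    stop_pegsite("record '%s' contains symbols outside the amino-acid alphabet",
                 ids[which(bad)[1]])

  if (anyDuplicated(ids)) {
    warn_pegsite("duplicate record ids deduplicated with suffixes: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
    ids <- make.unique(ids, sep = "_")
  }
  structure(list(ids = ids, seqs = unname(seqs), length = widths[1]), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa> ", length(x$ids), " sequences x ", x$length, " columns\n", sep = "")
  invisible(x)
}

#' Per-column conservation relative to a query sequence
#'
#' Identity fraction = fraction of non-gap symbols in the column equal to the
#' query's symbol (query included). Shannon entropy (bits) over non-gap symbol
#' frequencies is reported as a secondary metric. Columns where the query has
#' a gap, and all-gap columns, are inapplicable (NA).
#'
#' @param aln an `msa`
#' @param query_id id of the query record
#' @return object of class `conservation_profile`: data.frame(column,
#'   query_symbol, identity, entropy) with attribute `query_id`
#' @export
column_conservation <- function(aln, query_id) {
  qi <- match(query_id, aln$ids)
  if (is.na(qi)) stop_pegsite("query id '%s' not in alignment", query_id)
  mat <- do.call(rbind, strsplit(aln$seqs, ""))
  q <- mat[qi, ]
  identity <- entropy <- rep(NA_real_, aln$length)
  for (j in seq_len(aln$length)) {
    col <- mat[, j]
    ng <- col[col != "-"]
    if (length(ng) == 0L || q[j] == "-") next
    identity[j] <- mean(ng == q[j])
    p <- table(ng) / length(ng)
    entropy[j] <- -sum(p * log2(p))
  }
  out <- data.frame(column = seq_len(aln$length), query_symbol = q,
                    identity = identity, entropy = entropy,
                    stringsAsFactors = FALSE)
  attr(out, "query_id") <- query_id
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Map a conservation profile onto structure residues
#'
#' The ungapped query sequence must match the chain's declared sequence,
#' optionally shifted: declared-sequence position `d` corresponds to query
#' position `d - offset` (e.g. `offset = 33` for a construct missing the
#' first 33 residues). Author numbering follows the structure's
#' `seqres_offset`. Residues whose query position is gapped or out of range
#' get NA.
#'
#' @param profile a `conservation_profile`
#' @param aln the `msa` the profile came from
#' @param structure a `protein_structure`
#' @param chain chain id
#' @param offset declared-sequence index minus query position (default 0)
#' @return named numeric vector: residue id -> identity fraction
#' @export
map_conservation <- function(profile, aln, structure, chain = NULL, offset = 0) {
  chain <- chain %||% structure_chains(structure)[1]
  query_id <- attr(profile, "query_id")
  q <- strsplit(aln$seqs[match(query_id, aln$ids)], "")[[1]]
  qpos_cols <- which(q != "-")                     # column of each query position
  qseq <- q[qpos_cols]

  decl <- strsplit(declared_sequence(structure, chain), "")[[1]]
  for (d in seq_along(decl)) {
    p <- d - offset
    if (p < 1 || p > length(qseq)) next
    if (decl[d] != "X" && qseq[p] != "X" && decl[d] != qseq[p])
      stop_pegsite("query/chain sequence mismatch at declared position %d ('%s' vs '%s'); check the offset",
                   d, decl[d], qseq[p])
  }

  rt <- residue_table(structure, chain)
  didx <- rt$resno - structure$seqres_offset
  p <- didx - offset
  ok <- p >= 1 & p <= length(qseq)
  score <- rep(NA_real_, nrow(rt))
  score[ok] <- profile$identity[qpos_cols[p[ok]]]
  setNames(score, rt$id)
}
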