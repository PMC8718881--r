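# N-terminal truncation construct design: global alignment to an ortholog,
# proline-run (translational stalling) motifs, and disorder-boundary
# candidates.

get_submatrix <- function(name) {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(name, envir = e))
    stop_pegsite("unknown substitution matrix '%s'", name)
  get(name, envir = e)
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' A gap run of length L costs `gap_open + L * gap_extend`; end gaps are
#' penalised (true global alignment). Identity is reported both as matches
#' over aligned columns (gaps included) and matches over the shorter
#' sequence, since published percent identities rarely state their
#' denominator.
#'
#' @param seq_a,seq_b one-letter protein sequences
#' @param matrix substitution matrix name (default "BLOSUM62")
#' @param gap_open,gap_extend affine gap penalties (positive costs)
#' @return object of class `pairwise_alignment`: list(aligned_a, aligned_b,
#'   score, identity (percent over aligned columns), identity_shorter,
#'   matrix, gap_open, gap_extend)
#' @export
global_align <- function(seq_a, seq_b, matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  for (s in c(seq_a, seq_b)) {
    if (nchar(s) == 0L) stop_pegsite("empty sequence")
    bad <- setdiff(strsplit(s, "")[[1]], names(AA_1TO3))
    if (length(bad) > 0)
      stop_pegsite("non-amino-acid symbol(s): %s", paste(bad, collapse = ", "))
  }
  sm <- get_submatrix(matrix)
  al <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  pa <- as.character(Biostrings::alignedPattern(al))
  sa <- as.character(Biostrings::alignedSubject(al))
  ca <- strsplit(pa, "")[[1]]; cb <- strsplit(sa, "")[[1]]
  matches <- sum(ca == cb & ca != "-")
  structure(list(
    aligned_a = pa, aligned_b = sa,
    score = Biostrings::score(al),
    identity = 100 * matches / length(ca),
    identity_shorter = 100 * matches / min(nchar(seq_a), nchar(seq_b)),
    matrix = matrix, gap_open = gap_open, gap_extend = gap_extend
  ), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> score ", x$score, ", identity ",
      sprintf("%.1f%%", x$identity), " (", sprintf("%.1f%%", x$identity_shorter),
      " over shorter)\n", sep = "")
  invisible(x)
}

#' Flag proline-rich windows
#'
#' Position i is flagged when any sequence window of `window` residues
#' covering i contains at least `min_pro` prolines. Successive prolines near
#' the start codon are a known ribosome-stalling motif, which is why flagged
#' runs feed the truncation design.
#'
#' @param sequence one-letter protein sequence
#' @param window window length (default 5)
#' @param min_pro minimum prolines per window (default 3)
#' @return logical vector, one flag per position
#' @export
proline_run_flags <- function(sequence, window = 5, min_pro = 3) {
  stopifnot(window >= min_pro, min_pro >= 2)
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  flags <- rep(FALSE, n)
  isP <- s == "P"
  if (n < window) return(flags)
  for (st in seq_len(n - window + 1L)) {
    if (sum(isP[st:(st + window - 1L)]) >= min_pro)
      flags[st:(st + window - 1L)] <- TRUE
  }
  flags
}

#' Propose N-terminal truncation constructs
#'
#' Candidate start positions (full-length numbering) come from three signals
#' within the first `limit` residues: the residue after each structurally
#' unresolved N-terminal/internal disorder boundary, the first unflagged
#' residue after each proline run, and the query residue aligned to the
#' ortholog's first residue in `ortholog_alignment` (query must be the
#' pattern, the ortholog's sequence starting at its first resolved residue
#' the subject). Candidates sharing a start merge their rationale flags; the
#' ranking is by number of supporting flags, ties broken toward the larger
#' truncation.
#'
#' @param structure a `protein_structure` (for disorder segments)
#' @param full_sequence the full-length one-letter sequence the numbering
#'   refers to
#' @param ortholog_alignment optional `pairwise_alignment` of full_sequence
#'   vs the ortholog
#' @param chain chain id
#' @param limit only starts at or below this position are proposed
#' @param window,min_pro passed to [proline_run_flags()]
#' @return data.frame of class `truncation_candidates`: start_position,
#'   removed_prefix, ends_disorder, removes_proline_run,
#'   aligns_to_ortholog_start, n_flags, new_n_terminal_window
#' @export
propose_truncations <- function(structure, full_sequence, ortholog_alignment = NULL,
                                chain = NULL, limit = 60, window = 5, min_pro = 3) {
  n <- nchar(full_sequence)
  flags <- proline_run_flags(full_sequence, window, min_pro)
  starts <- list()
  add <- function(start, flag) {
    if (start < 2 || start > min(limit, n)) return()
    # never begin inside a flagged proline run
    while (start <= n && flags[start]) start <- start + 1L
    key <- as.character(start)
    cur <- starts[[key]] %||% c(ends_disorder = FALSE, removes_proline_run = FALSE,
                                aligns_to_ortholog_start = FALSE)
    cur[flag] <- TRUE
    starts[[key]] <<- cur
  }

  if (!is.null(structure)) {
    segs <- unresolved_segments(structure, chain)
    for (k in seq_len(nrow(segs)))
      if (segs$terminal[k] %in% c("N", "internal") && segs$start[k] <= limit)
        add(segs$end[k] + 1L, "ends_disorder")
  }
  runs <- rle(flags)
  ends <- cumsum(runs$lengths)
  for (k in seq_along(runs$values))
    if (runs$values[k] && ends[k] < limit) add(ends[k] + 1L, "removes_proline_run")

  if (!is.null(ortholog_alignment)) {
    ca <- strsplit(ortholog_alignment$aligned_a, "")[[1]]
    cb <- strsplit(ortholog_alignment$aligned_b, "")[[1]]
    first_sub <- which(cb != "-")[1]
    if (!is.na(first_sub)) {
      qpos <- sum(ca[seq_len(first_sub)] != "-")
      if (qpos >= 1) add(max(qpos, 2L), "aligns_to_ortholog_start")
    }
  }

  if (length(starts) == 0L) {
    out <- data.frame(start_position = 1L, removed_prefix = "",
                      ends_disorder = FALSE, removes_proline_run = FALSE,
                      aligns_to_ortholog_start = FALSE, n_flags = 0L,
                      new_n_terminal_window = substr(full_sequence, 1, 5),
                      stringsAsFactors = FALSE)
    class(out) <- c("truncation_candidates", "data.frame")
    return(out)
  }

  sp <- as.integer(names(starts))
  fl <- do.call(rbind, starts)
  out <- data.frame(
    start_position = sp,
    removed_prefix = substring(full_sequence, 1, sp - 1L),
    ends_disorder = fl[, "ends_disorder"],
    removes_proline_run = fl[, "removes_proline_run"],
    aligns_to_ortholog_start = fl[, "aligns_to_ortholog_start"],
    n_flags = rowSums(fl),
    new_n_terminal_window = substring(full_sequence, sp, sp + 4L),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$n_flags, -out$start_position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("truncation_candidates", "data.frame")
  out
}
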