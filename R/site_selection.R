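# The criteria engine: engineer-in (Arg->Lys) and engineer-out (Lys->Arg)
# classification with a per-criterion audit trail.

#' Selection criteria thresholds
#'
#' All thresholds the criteria engine uses, with documented defaults. An
#' engineer-in arginine must: (1) not be highly conserved (identity fraction
#' below `conservation_max`), (2) have solvent accessibility strictly above
#' `sasa_min` (strict, so marginal sites show their margin in the audit),
#' (3) not sit on a loop, (4) form no salt bridge with Asp/Glu (PEGylation of
#' a salt-bridged amine would require alkaline reaction pH due to the
#' perturbed pKa), and (5) lie at least `active_site_min_distance` from the
#' active site. An engineer-out lysine must be PEG-accessible
#' (`engineer_out_sasa_min`) and either sit on a flexible loop (coil with
#' B-factor z >= `loop_bz_min`) or within `active_site_min_distance` of the
#' active site.
#'
#' @param sasa_min engineer-in accessibility threshold, Angstrom^2
#' @param conservation_max identity-fraction bound ("highly conserved" at or
#'   above this value)
#' @param active_site_min_distance Angstrom
#' @param require_non_loop apply the loop exclusion to engineer-in sites
#' @param forbid_salt_bridge apply the salt-bridge exclusion
#' @param loop_bz_min flexible-loop B-factor z threshold
#' @param engineer_out_sasa_min accessibility threshold for engineer-out
#'   lysines (defaults to `sasa_min`)
#' @param sasa_metric `"total"` (default) or `"sidechain"`: which per-residue
#'   SASA the accessibility criteria read
#' @return object of class `selection_criteria`
#' @export
selection_criteria <- function(sasa_min = 75, conservation_max = 0.7,
                               active_site_min_distance = 10,
                               require_non_loop = TRUE, forbid_salt_bridge = TRUE,
                               loop_bz_min = 1.0,
                               engineer_out_sasa_min = sasa_min,
                               sasa_metric = c("total", "sidechain")) {
  stopifnot(sasa_min > 0, conservation_max > 0, active_site_min_distance > 0,
            engineer_out_sasa_min > 0)
  structure(list(
    sasa_min = sasa_min, conservation_max = conservation_max,
    active_site_min_distance = active_site_min_distance,
    require_non_loop = isTRUE(require_non_loop),
    forbid_salt_bridge = isTRUE(forbid_salt_bridge),
    loop_bz_min = loop_bz_min,
    engineer_out_sasa_min = engineer_out_sasa_min,
    sasa_metric = match.arg(sasa_metric)
  ), class = "selection_criteria")
}

sasa_column <- function(criteria) {
  if (criteria$sasa_metric == "sidechain") "sasa_sidechain" else "sasa_total"
}

# one audited criterion: measured value, pass/fail, applicability
criterion_row <- function(name, value, pass, applicable = TRUE) {
  data.frame(criterion = name, value = value,
             pass = ifelse(applicable, pass, NA),
             applicable = applicable, stringsAsFactors = FALSE)
}

finish_recommendations <- function(rows, audits, direction) {
  if (length(rows) == 0L) {
    warn_pegsite("no %s residues to evaluate",
                 if (direction == "engineer_in") "arginine" else "lysine")
    out <- data.frame(id = character(), resno = integer(), chain = character(),
                      direction = character(), sasa = numeric(), verdict = logical(),
                      n_criteria = integer(), n_pass = integer(),
                      partial = logical(), stringsAsFactors = FALSE)
    attr(out, "audit") <- list()
    class(out) <- c("site_recommendations", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$sasa, out$resno)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- audits[out$id]
  class(out) <- c("site_recommendations", "data.frame")
  out
}

#' Evaluate engineer-in (Arg -> Lys) candidates
#'
#' One recommendation per arginine in the feature table. The verdict is the
#' hard conjunction of all applicable criteria; a criterion without data
#' (e.g. no conservation because no alignment was supplied) is reported
#' inapplicable, excluded from the conjunction, and flagged via the `partial`
#' column so a partial evaluation is never mistaken for a full one. Output is
#' sorted by accessibility (descending), ties by residue number.
#'
#' @param features a `residue_features` table
#' @param criteria a `selection_criteria`
#' @return data.frame of class `site_recommendations`; attribute `audit`
#'   holds the per-residue criterion table (measured value, pass, applicable)
#' @export
evaluate_engineer_in <- function(features, criteria = selection_criteria()) {
  scol <- sasa_column(criteria)
  args <- features[features$aa %in% "R", , drop = FALSE]
  rows <- list(); audits <- list()
  for (k in seq_len(nrow(args))) {
    r <- args[k, ]
    aud <- rbind(
      criterion_row("not_conserved", r$conservation,
                    isTRUE(r$conservation < criteria$conservation_max),
                    applicable = !is.na(r$conservation)),
      criterion_row("sasa", r[[scol]], r[[scol]] > criteria$sasa_min),
      criterion_row("not_on_loop", as.numeric(r$loop), !r$loop,
                    applicable = criteria$require_non_loop),
      criterion_row("no_salt_bridge", as.numeric(r$salt_bridge), !r$salt_bridge,
                    applicable = criteria$forbid_salt_bridge),
      criterion_row("active_site_distance", r$active_site_dist,
                    r$active_site_dist >= criteria$active_site_min_distance,
                    applicable = is.finite(r$active_site_dist))
    )
    app <- aud$applicable
    rows[[k]] <- data.frame(
      id = r$id, resno = r$resno, chain = r$chain, direction = "engineer_in",
      sasa = r[[scol]], verdict = all(aud$pass[app]),
      n_criteria = sum(app), n_pass = sum(aud$pass[app]),
      partial = any(!app), stringsAsFactors = FALSE
    )
    audits[[r$id]] <- aud
  }
  finish_recommendations(rows, audits, "engineer_in")
}

#' Evaluate engineer-out (Lys -> Arg) candidates
#'
#' A lysine is recommended for removal when it is PEG-accessible and its
#' modification is expected to harm activity: it sits on a flexible loop
#' (coil with elevated B-factor z) or close to the active site. Active-site
#' proximity is inapplicable (and the evaluation partial) when no active site
#' was defined.
#'
#' @inheritParams evaluate_engineer_in
#' @return data.frame of class `site_recommendations` (see
#'   [evaluate_engineer_in()])
#' @export
evaluate_engineer_out <- function(features, criteria = selection_criteria()) {
  scol <- sasa_column(criteria)
  lys <- features[features$aa %in% "K", , drop = FALSE]
  rows <- list(); audits <- list()
  for (k in seq_len(nrow(lys))) {
    r <- lys[k, ]
    accessible <- r[[scol]] > criteria$engineer_out_sasa_min
    flex_loop <- r$loop && !is.na(r$bz) && r$bz >= criteria$loop_bz_min
    near_app <- is.finite(r$active_site_dist)
    near <- near_app && r$active_site_dist <= criteria$active_site_min_distance
    aud <- rbind(
      criterion_row("peg_accessible", r[[scol]], accessible),
      criterion_row("flexible_loop", r$bz, flex_loop),
      criterion_row("near_active_site", r$active_site_dist, near, applicable = near_app)
    )
    verdict <- accessible && (flex_loop || near)
    rows[[k]] <- data.frame(
      id = r$id, resno = r$resno, chain = r$chain, direction = "engineer_out",
      sasa = r[[scol]], verdict = verdict,
      n_criteria = sum(aud$applicable),
      n_pass = sum(aud$pass[aud$applicable]),
      partial = any(!aud$applicable), stringsAsFactors = FALSE
    )
    audits[[r$id]] <- aud
  }
  finish_recommendations(rows, audits, "engineer_out")
}

#' @export
print.site_recommendations <- function(x, ...) {
  if (!all(c("verdict", "partial") %in% names(x))) return(print.data.frame(x, ...))
  cat("<site_recommendations> ", nrow(x), " candidates, ",
      sum(x$verdict), " verdict-true", sep = "")
  if (nrow(x) > 0 && any(x$partial))
    cat("  [PARTIAL: some criteria lacked data and were skipped]")
  cat("\n")
  print.data.frame(x, ...)
  invisible(x)
}

parse_mutation <- function(m) {
  ok <- grepl("^[A-Z][0-9]+[A-Z]$", m)
  if (!all(ok)) stop_pegsite("malformed mutation string(s): %s", paste(m[!ok], collapse = ", "))
  data.frame(pos = as.integer(gsub("[A-Z]", "", m)),
             from = substr(m, 1, 1), to = substring(m, nchar(m)),
             stringsAsFactors = FALSE)
}

#' Apply point substitutions to a protein sequence
#'
#' Positions are full-length residue numbers; `numbering_offset` reconciles
#' construct numbering (sequence index = position - offset). A mismatch
#' between the stated source residue and the sequence is an error, guarding
#' against numbering-offset mistakes.
#'
#' @param sequence one-letter protein sequence
#' @param subs character vector of mutations in standard notation (`"K139R"`)
#'   or a data.frame with columns pos, from, to
#' @param numbering_offset full-length position minus sequence index
#' @return list(sequence = variant sequence, mutations = canonical mutation
#'   string, e.g. `"K139R-R342K"`)
#' @export
apply_substitutions <- function(sequence, subs, numbering_offset = 0) {
  s <- strsplit(sequence, "")[[1]]
  if (is.character(subs)) subs <- parse_mutation(subs)
  if (nrow(subs) == 0L)
    return(list(sequence = sequence, mutations = ""))
  for (k in seq_len(nrow(subs))) {
    i <- subs$pos[k] - numbering_offset
    if (i < 1 || i > length(s))
      stop_pegsite("position %d outside sequence (offset %d)", subs$pos[k], numbering_offset)
    if (s[i] != subs$from[k])
      stop_pegsite("expected '%s' at position %d but sequence has '%s' (check numbering offset)",
                   subs$from[k], subs$pos[k], s[i])
    s[i] <- subs$to[k]
  }
  list(sequence = paste(s, collapse = ""),
       mutations = paste(sprintf("%s%d%s", subs$from, subs$pos, subs$to), collapse = "-"))
}
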