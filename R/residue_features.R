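# Geometric per-residue features feeding the selection criteria: secondary
# structure from C-alpha geometry, salt bridges, active-site proximity, and
# the joined feature table.

# default C-alpha distance windows (Angstrom) and helix pseudo-torsion window
# (degrees); an ideal alpha-helix (rise 1.5 A, 100 deg twist, radius 2.3 A)
# gives d14 ~ 5.05, d15 ~ 6.20, tau ~ 50 deg, an extended strand d14 ~ 9.9-12
SS_WINDOWS <- list(
  helix_d14 = c(4.2, 5.8), helix_d15 = c(5.0, 6.9), helix_tau = c(20, 80),
  strand_d14 = c(9.0, 12.5), strand_d15 = c(12.0, 16.5)
)

ca_coords <- function(structure, chain) {
  a <- polymer_atoms(structure, chain)
  a <- a[a$elety == "CA", , drop = FALSE]
  a <- a[order(a$resno, a$icode), , drop = FALSE]
  list(xyz = cbind(a$x, a$y, a$z), id = residue_id(a$chain, a$resno, a$icode))
}

pseudo_torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3], b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3], b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) return(NA_real_)
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3], n1[1] * b2[2] - n1[2] * b2[1])
  nb2 <- sqrt(sum(b2^2))
  atan2(sum(m1 * n2) / nb2, sum(n1 * n2)) * 180 / pi
}

#' Secondary-structure assignment from C-alpha geometry
#'
#' A distance-window assignment in the spirit of P-SEA: residue i is helix
#' when the two C-alpha spans covering it (i-2..i+1 and i-1..i+2 start-to-end
#' distances over 3 peptide steps, plus the 4-step spans) sit in the helix
#' windows and the local pseudo-torsion is helical; strand analogously on
#' wider windows; everything else (including termini) is coil `C`. Chains
#' shorter than 5 residues are entirely coil. Windows are config-overridable.
#'
#' @param structure a `protein_structure`
#' @param chain chain id (NULL: all chains)
#' @param windows named list of class windows, see `SS_WINDOWS` defaults
#' @return named character vector (residue id -> "H"/"E"/"C")
#' @export
assign_secondary_structure <- function(structure, chain = NULL, windows = SS_WINDOWS) {
  chains <- chain %||% structure_chains(structure)
  out <- character(0)
  for (ch in chains) {
    ca <- ca_coords(structure, ch)
    n <- nrow(ca$xyz)
    cls <- rep("C", n)
    if (n >= 5) {
      d <- function(i, j) sqrt(sum((ca$xyz[i, ] - ca$xyz[j, ])^2))
      d14 <- vapply(seq_len(n - 3), function(i) d(i, i + 3), 0)
      d15 <- vapply(seq_len(n - 4), function(i) d(i, i + 4), 0)
      tau <- vapply(seq_len(n - 3), function(i)
        pseudo_torsion(ca$xyz[i, ], ca$xyz[i + 1, ], ca$xyz[i + 2, ], ca$xyz[i + 3, ]), 0)
      inw <- function(x, w) !is.na(x) & x >= w[1] & x <= w[2]
      for (i in 3:(n - 2)) {
        w1 <- i - 2; w2 <- i - 1   # the two 4-residue spans covering i
        helix <- inw(d14[w1], windows$helix_d14) && inw(d14[w2], windows$helix_d14) &&
          (w1 <= n - 4 && inw(d15[w1], windows$helix_d15)) &&
          inw(tau[w1], windows$helix_tau) && inw(tau[w2], windows$helix_tau)
        strand <- inw(d14[w1], windows$strand_d14) && inw(d14[w2], windows$strand_d14) &&
          (w1 <= n - 4 && inw(d15[w1], windows$strand_d15))
        cls[i] <- if (helix) "H" else if (strand) "E" else "C"
      }
    }
    out <- c(out, setNames(cls, ca$id))
  }
  out
}

# side-chain atoms carrying the formal charges screened for salt bridges
BASIC_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"))
ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Detect salt bridges
#'
#' A bridge exists between a basic residue (Lys NZ; Arg NE/NH1/NH2; His
#' ND1/NE2) and an acidic residue (Asp OD1/OD2; Glu OE1/OE2) when the minimum
#' nitrogen-oxygen distance is at or below `cutoff`. Basic or acidic residues
#' whose charged side-chain atoms are absent from the model are skipped with a
#' warning. One row per residue pair.
#'
#' @param structure a `protein_structure`
#' @param cutoff distance cutoff in Angstrom (default 4.0)
#' @return data.frame: basic_id, basic_resid, acidic_id, acidic_resid,
#'   min_N_O_distance
#' @export
find_salt_bridges <- function(structure, cutoff = 4.0) {
  stopifnot(cutoff > 0)
  a <- polymer_atoms(structure)
  empty <- data.frame(basic_id = character(), basic_resid = character(),
                      acidic_id = character(), acidic_resid = character(),
                      min_N_O_distance = numeric(), stringsAsFactors = FALSE)

  pick <- function(groups) {
    keep <- rep(FALSE, nrow(a))
    for (res in names(groups))
      keep <- keep | (a$resid == res & a$elety %in% groups[[res]])
    a[keep, , drop = FALSE]
  }
  bas <- pick(BASIC_ATOMS)
  aci <- pick(ACIDIC_ATOMS)

  # warn on charged residues with no usable side-chain atoms
  for (side in list(c("basic", "LYS|ARG|HIS"), c("acidic", "ASP|GLU"))) {
    all_res <- a[grepl(side[2], a$resid), , drop = FALSE]
    have <- if (side[1] == "basic") bas else aci
    miss <- setdiff(unique(residue_id(all_res$chain, all_res$resno, all_res$icode)),
                    unique(residue_id(have$chain, have$resno, have$icode)))
    if (length(miss) > 0)
      warn_pegsite("%s residue(s) without charged side-chain atoms skipped: %s",
                   side[1], paste(miss, collapse = ", "))
  }
  if (nrow(bas) == 0L || nrow(aci) == 0L) return(empty)

  d2 <- outer(bas$x, aci$x, "-")^2 + outer(bas$y, aci$y, "-")^2 + outer(bas$z, aci$z, "-")^2
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  out <- data.frame(
    basic_id = residue_id(bas$chain[hit[, 1]], bas$resno[hit[, 1]], bas$icode[hit[, 1]]),
    basic_resid = bas$resid[hit[, 1]],
    acidic_id = residue_id(aci$chain[hit[, 2]], aci$resno[hit[, 2]], aci$icode[hit[, 2]]),
    acidic_resid = aci$resid[hit[, 2]],
    min_N_O_distance = sqrt(d2[hit]),
    stringsAsFactors = FALSE
  )
  # deduplicate per residue pair, keeping the minimum distance
  out <- out[order(out$min_N_O_distance), , drop = FALSE]
  out <- out[!duplicated(paste(out$basic_id, out$acidic_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Define the active-site residue set
#'
#' Either an explicit residue-id list (passed through after an existence
#' check) or a ligand-proximity rule: all polymer residues with any atom
#' within `cutoff` of any atom of the named het group.
#'
#' @param structure a `protein_structure`
#' @param residues character vector of residue ids (e.g. `"A:116"`)
#' @param ligand het residue name (e.g. `"TMP"`) for the proximity rule
#' @param cutoff proximity cutoff in Angstrom (default 4.5)
#' @return character vector of residue ids
#' @export
active_site_set <- function(structure, residues = NULL, ligand = NULL, cutoff = 4.5) {
  if (is.null(residues) && is.null(ligand))
    stop_pegsite("active-site definition is empty: give 'residues' or 'ligand'")
  a <- polymer_atoms(structure)
  all_ids <- unique(residue_id(a$chain, a$resno, a$icode))
  if (!is.null(residues)) {
    missing <- setdiff(residues, all_ids)
    if (length(missing) > 0)
      stop_pegsite("active-site residue(s) not in structure: %s", paste(missing, collapse = ", "))
    return(residues)
  }
  lig <- structure$atoms[structure$atoms$het & structure$atoms$resid == ligand, , drop = FALSE]
  if (nrow(lig) == 0L) stop_pegsite("het group '%s' not found", ligand)
  d2 <- outer(a$x, lig$x, "-")^2 + outer(a$y, lig$y, "-")^2 + outer(a$z, lig$z, "-")^2
  near <- apply(d2, 1, min) <= cutoff^2
  unique(residue_id(a$chain[near], a$resno[near], a$icode[near]))
}

#' Minimum distance from one residue to a residue set
#'
#' Minimum over all atom pairs; `Inf` for an empty target set.
#' @param structure a `protein_structure`
#' @param residue residue id
#' @param target_set character vector of residue ids
#' @return distance in Angstrom
#' @export
min_distance_to_set <- function(structure, residue, target_set) {
  if (length(target_set) == 0L) return(Inf)
  a <- polymer_atoms(structure)
  ids <- residue_id(a$chain, a$resno, a$icode)
  src <- a[ids == residue, , drop = FALSE]
  tgt <- a[ids %in% target_set, , drop = FALSE]
  if (nrow(src) == 0L) stop_pegsite("residue '%s' not found", residue)
  if (nrow(tgt) == 0L) return(Inf)
  d2 <- outer(src$x, tgt$x, "-")^2 + outer(src$y, tgt$y, "-")^2 + outer(src$z, tgt$z, "-")^2
  sqrt(min(d2))
}

#' Build the per-residue feature table
#'
#' Joins solvent accessibility, secondary structure, B-factor z-scores, salt
#' bridges, active-site distance and (optional) conservation into one row per
#' resolved polymer residue. The loop flag is simply `ss == "C"`. Missing
#' conservation stays missing (NA) and is never imputed.
#'
#' @param structure a `protein_structure`
#' @param sasa a `sasa_result` (default: computed with package defaults)
#' @param ss named vector from [assign_secondary_structure()]
#' @param bridges data.frame from [find_salt_bridges()]
#' @param active_site residue-id set, or NULL (distances become Inf and the
#'   active-site criterion is reported inapplicable downstream)
#' @param bz named vector from [bfactor_zscores()] (all chains accepted)
#' @param conservation named vector residue id -> identity fraction, or NULL
#' @param chain chains to include (default all)
#' @return data.frame of class `residue_features`
#' @export
build_feature_table <- function(structure, sasa = NULL, ss = NULL, bridges = NULL,
                                active_site = NULL, bz = NULL, conservation = NULL,
                                chain = NULL) {
  chains <- chain %||% structure_chains(structure)
  sasa <- sasa %||% compute_sasa(structure)
  ss <- ss %||% assign_secondary_structure(structure)
  bridges <- bridges %||% find_salt_bridges(structure)
  if (is.null(bz))
    bz <- do.call(c, lapply(chains, function(ch) bfactor_zscores(structure, ch)))

  rows <- do.call(rbind, lapply(chains, function(ch) residue_table(structure, ch)))
  if (anyDuplicated(rows$id))
    stop_pegsite("duplicate residue ids in structure: %s",
                 paste(rows$id[duplicated(rows$id)], collapse = ", "))

  m <- match(rows$id, sasa$residue$id)
  bridged <- rows$id %in% c(bridges$basic_id, bridges$acidic_id)
  partners <- vapply(rows$id, function(id) {
    p <- c(bridges$acidic_id[bridges$basic_id == id], bridges$basic_id[bridges$acidic_id == id])
    paste(p, collapse = ";")
  }, "")
  asd <- vapply(rows$id, function(id)
    min_distance_to_set(structure, id, active_site %||% character(0)), 0)

  out <- data.frame(
    id = rows$id, chain = rows$chain, resno = rows$resno, icode = rows$icode,
    resid = rows$resid, aa = rows$aa,
    sasa_total = sasa$residue$sasa_total[m],
    sasa_sidechain = sasa$residue$sasa_sidechain[m],
    ss = unname(ss[rows$id]),
    loop = unname(ss[rows$id]) == "C",
    bz = unname(bz[rows$id]),
    salt_bridge = bridged,
    salt_bridge_partners = unname(partners),
    active_site_dist = unname(asd),
    conservation = if (is.null(conservation)) NA_real_ else unname(conservation[rows$id]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("residue_features", "data.frame")
  out
}

#' Write a feature table as TSV
#' @param features a `residue_features` data.frame
#' @param path output path
#' @export
write_feature_table <- function(features, path) {
  write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
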