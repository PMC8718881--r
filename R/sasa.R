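# Shrake-Rupley solvent-accessible surface area with a deterministic
# golden-spiral quadrature.

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' For every atom, the fraction of quasi-uniform test points on the expanded
#' sphere of radius `r_vdW + probe_radius` not falling inside any neighbour's
#' expanded sphere, times the expanded-sphere area. The test-point set is a
#' deterministic golden-spiral lattice, so results are exactly reproducible
#' for a fixed `points_per_atom`. A point lying exactly on a neighbour's
#' expanded sphere counts as buried.
#'
#' Waters are always excluded; other het groups (ligands, synthetic occluder
#' atoms) participate as occluders. In `context = "monomer"` only the atoms of
#' `chain` (and its het groups) are present, so per-residue values are those
#' of the isolated chain; `"assembly"` (default) uses the full deposited
#' assembly, the relevant context for a physiological homodimer.
#'
#' @param structure a `protein_structure`
#' @param probe_radius probe sphere radius in Angstrom (water: 1.4)
#' @param points_per_atom number of quadrature points per atom
#' @param context `"assembly"` or `"monomer"`
#' @param chain chain to report (monomer context) or NULL for all chains
#' @param vdw named vector of van der Waals radii by element; unknown elements
#'   are an error listing the offending atoms
#' @return object of class `sasa_result`: list with `atom` (per-atom areas,
#'   aligned with the atom rows used), `residue` (data.frame: id, chain,
#'   resno, resid, sasa_total, sasa_sidechain)
#' @export
compute_sasa <- function(structure, probe_radius = 1.4, points_per_atom = 960,
                         context = c("assembly", "monomer"), chain = NULL,
                         vdw = DEFAULT_VDW) {
  context <- match.arg(context)
  stopifnot(probe_radius > 0, points_per_atom >= 1)
  a <- structure$atoms
  a <- a[!a$water, , drop = FALSE]
  if (context == "monomer") {
    ch <- chain %||% structure_chains(structure)[1]
    a <- a[a$chain == ch, , drop = FALSE]
  }
  if (nrow(a) == 0L) stop_pegsite("no atoms to compute SASA for")

  unknown <- !(a$element %in% names(vdw))
  if (any(unknown))
    stop_pegsite("no van der Waals radius for element(s) %s (atoms: %s)",
                 paste(unique(a$element[unknown]), collapse = ", "),
                 paste(head(paste0(a$elety[unknown], "/", a$resid[unknown]), 5), collapse = ", "))

  xyz <- cbind(a$x, a$y, a$z)
  R <- unname(vdw[a$element]) + probe_radius
  pts <- golden_spiral_points(points_per_atom)
  n <- nrow(a)
  area <- numeric(n)
  maxR <- max(R)

  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 + (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (R[i] + R)^2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      area[i] <- 4 * pi * R[i]^2
      next
    }
    p <- pts * R[i]
    p[, 1] <- p[, 1] + xyz[i, 1]
    p[, 2] <- p[, 2] + xyz[i, 2]
    p[, 3] <- p[, 3] + xyz[i, 3]
    free <- rep(TRUE, points_per_atom)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (p[free, 1] - xyz[j, 1])^2 + (p[free, 2] - xyz[j, 2])^2 + (p[free, 3] - xyz[j, 3])^2
      free[free] <- dj2 > R[j]^2   # boundary counts as buried
    }
    area[i] <- 4 * pi * R[i]^2 * sum(free) / points_per_atom
  }

  pol <- !a$het
  backbone <- a$elety %in% c("N", "CA", "C", "O", "OXT")
  key <- paste(a$chain, a$resno, a$icode, sep = "\r")
  upos <- !duplicated(key) & pol
  ids <- residue_id(a$chain[upos], a$resno[upos], a$icode[upos])
  f <- factor(key, levels = key[upos])
  tot <- tapply(ifelse(pol, area, 0), f, sum)
  sc <- tapply(ifelse(pol & !backbone, area, 0), f, sum)
  res <- data.frame(
    id = ids, chain = a$chain[upos], resno = a$resno[upos],
    icode = a$icode[upos], resid = a$resid[upos],
    sasa_total = as.numeric(tot), sasa_sidechain = as.numeric(sc),
    stringsAsFactors = FALSE
  )
  structure(list(
    atom = data.frame(chain = a$chain, resno = a$resno, icode = a$icode,
                      elety = a$elety, het = a$het, sasa = area,
                      stringsAsFactors = FALSE),
    residue = res,
    probe_radius = probe_radius, points_per_atom = points_per_atom,
    context = context
  ), class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat("<sasa_result> ", nrow(x$atom), " atoms, ", nrow(x$residue),
      " residues; probe ", x$probe_radius, " A, ", x$points_per_atom,
      " pts/atom, context ", x$context, "\n", sep = "")
  invisible(x)
}
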