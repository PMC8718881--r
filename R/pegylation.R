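# Amine-targeted PEG conjugation model: reactive-site inventory, PEG-mer
# mass ladder, and the effect of engineered substitutions.

#' Inventory of PEG-reactive primary amines
#'
#' NHS-ester PEG reagents react with lysine epsilon-amines and the N-terminal
#' alpha-amine. The inventory lists lysines whose accessibility exceeds the
#' threshold (strict), sorted by residue number, plus optionally the
#' N-terminus.
#'
#' @param features a `residue_features` table (one chain)
#' @param sasa_threshold accessibility threshold, Angstrom^2
#' @param include_n_terminus count the alpha-amine as a site
#' @param chain chain to inventory (default: first chain in the table)
#' @param sasa_metric `"total"` or `"sidechain"`
#' @return object of class `amine_inventory`: list(lysine_sites = named
#'   integer vector ("K139" -> 139), n_terminus_site, total_sites)
#' @export
amine_inventory <- function(features, sasa_threshold = 75, include_n_terminus = TRUE,
                            chain = NULL, sasa_metric = c("total", "sidechain")) {
  sasa_metric <- match.arg(sasa_metric)
  scol <- if (sasa_metric == "sidechain") "sasa_sidechain" else "sasa_total"
  chain <- chain %||% features$chain[1]
  f <- features[features$chain == chain, , drop = FALSE]
  lys <- f[f$aa %in% "K" & f[[scol]] > sasa_threshold, , drop = FALSE]
  lys <- lys[order(lys$resno), , drop = FALSE]
  sites <- setNames(lys$resno, sprintf("K%d", as.integer(lys$resno)))
  structure(list(
    lysine_sites = sites,
    n_terminus_site = isTRUE(include_n_terminus),
    total_sites = length(sites) + as.integer(isTRUE(include_n_terminus))
  ), class = "amine_inventory")
}

#' @export
print.amine_inventory <- function(x, ...) {
  cat("<amine_inventory> ", x$total_sites, " reactive sites: ",
      paste(names(x$lysine_sites), collapse = ", "),
      if (x$n_terminus_site) " + N-terminus", "\n", sep = "")
  invisible(x)
}

#' PEG-mer mass ladder
#'
#' Masses of the 0..total_sites conjugate species: `base_mass + k * peg_mass`.
#' The PEG adduct is treated at its nominal polymer mass (linker mass
#' ignored), the approximation under which four exposed lysines plus the
#' N-terminus and a 5-kDa PEG turn a ~50-kDa monomer into a ~75-kDa top
#' species.
#'
#' @param base_mass unconjugated monomer mass, Da
#' @param inventory an `amine_inventory`, or an integer site count
#' @param peg_mass PEG adduct mass, Da (default 5000)
#' @return object of class `peg_ladder`: list(base_mass, peg_mass, n_sites,
#'   species_masses)
#' @export
peg_ladder <- function(base_mass, inventory, peg_mass = 5000) {
  stopifnot(base_mass > 0, peg_mass > 0)
  n <- if (inherits(inventory, "amine_inventory")) inventory$total_sites else as.integer(inventory)
  stopifnot(n >= 0)
  structure(list(
    base_mass = base_mass, peg_mass = peg_mass, n_sites = n,
    species_masses = base_mass + (0:n) * peg_mass
  ), class = "peg_ladder")
}

#' @export
print.peg_ladder <- function(x, ...) {
  cat("<peg_ladder> ", x$n_sites, " sites; species (kDa): ",
      paste(sprintf("%.1f", x$species_masses / 1000), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Average protein monomer mass
#'
#' Sum of average residue masses plus one water (18.02 Da).
#' @param sequence one-letter protein sequence
#' @return mass in Da
#' @export
monomer_mass <- function(sequence) {
  if (nchar(sequence) == 0L) stop_pegsite("empty sequence")
  s <- strsplit(sequence, "")[[1]]
  bad <- setdiff(s, names(AA_AVG_MASS))
  if (length(bad) > 0) stop_pegsite("non-standard symbol(s): %s", paste(bad, collapse = ", "))
  sum(AA_AVG_MASS[s]) + WATER_MASS
}

#' Reactive-site inventory of an engineered variant
#'
#' K->R substitutions remove a site (with a warning when the lysine was not
#' in the inventory, e.g. a buried lysine); R->K substitutions add a site iff
#' that arginine's accessibility in `features` exceeds `sasa_threshold`.
#' Idempotent for repeated identical substitutions.
#'
#' @param inventory parent `amine_inventory`
#' @param subs mutation strings (`"K139R"`) or data.frame(pos, from, to)
#' @param features `residue_features` of the parent structure (needed for
#'   R->K additions)
#' @param sasa_threshold accessibility threshold for added sites
#' @param sasa_metric `"total"` or `"sidechain"`
#' @return updated `amine_inventory`
#' @export
variant_inventory <- function(inventory, subs, features = NULL, sasa_threshold = 75,
                              sasa_metric = c("total", "sidechain")) {
  sasa_metric <- match.arg(sasa_metric)
  scol <- if (sasa_metric == "sidechain") "sasa_sidechain" else "sasa_total"
  if (is.character(subs)) subs <- parse_mutation(subs)
  sites <- inventory$lysine_sites
  for (k in seq_len(nrow(subs))) {
    pos <- subs$pos[k]
    if (subs$from[k] == "K" && subs$to[k] == "R") {
      if (pos %in% sites) {
        sites <- sites[sites != pos]
      } else {
        warn_pegsite("K%dR removes no inventory site (lysine not accessible or absent)", pos)
      }
    } else if (subs$from[k] == "R" && subs$to[k] == "K") {
      if (pos %in% sites) next
      if (is.null(features))
        stop_pegsite("R->K additions need the parent feature table")
      row <- features[features$resno == pos & features$aa %in% "R", , drop = FALSE]
      if (nrow(row) == 0L)
        stop_pegsite("R%dK: no arginine %d in the feature table", pos, pos)
      if (max(row[[scol]]) > sasa_threshold)
        sites <- c(sites, setNames(pos, paste0("K", pos)))
    }
    # other substitutions do not touch the amine inventory
  }
  sites <- sites[order(sites)]
  structure(list(
    lysine_sites = sites,
    n_terminus_site = inventory$n_terminus_site,
    total_sites = length(sites) + as.integer(inventory$n_terminus_site)
  ), class = "amine_inventory")
}
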