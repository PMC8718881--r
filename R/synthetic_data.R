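# Synthetic fixtures with planted ground truth: toy structures exercising
# every geometric feature, alignments with controlled per-column
# conservation, and Michaelis-Menten datasets with multiplicative noise.

HELIX_RISE <- 1.5
HELIX_TWIST <- 100 * pi / 180
HELIX_RADIUS <- 2.3

helix_ca <- function(n, origin) {
  j <- seq_len(n) - 1
  # clockwise viewed down +z: right-handed helix (CA pseudo-torsion ~ +50 deg)
  cbind(origin[1] + HELIX_RADIUS * cos(-j * HELIX_TWIST),
        origin[2] + HELIX_RADIUS * sin(-j * HELIX_TWIST),
        origin[3] + HELIX_RISE * j)
}

# sharp zigzag (step 3.8 A, direction turning 150 deg per step in the
# xz-plane): start-to-end spans over 3-4 steps fall below every helix/strand
# window, so interior residues are classed coil
zigzag_ca <- function(n, origin) {
  p <- matrix(0, n, 3)
  p[1, ] <- origin
  ang <- 0
  for (k in 2:n) {
    p[k, ] <- p[k - 1, ] + 3.8 * c(cos(ang), 0, sin(ang))
    ang <- ang + 150 * pi / 180
  }
  p
}

side_chain <- function(resid, ca, u, buried = FALSE) {
  w <- c(-u[3], 0, u[1])                       # any perpendicular in-plane
  if (sqrt(sum(w^2)) < 1e-6) w <- c(1, 0, 0)
  w <- w / sqrt(sum(w^2))
  at <- function(elety, d, off = c(0, 0, 0), element = "C")
    data.frame(elety = elety, x = ca[1] + d * u[1] + off[1],
               y = ca[2] + d * u[2] + off[2], z = ca[3] + d * u[3] + off[3],
               element = element, stringsAsFactors = FALSE)
  if (buried) {
    tip <- switch(resid, ARG = "NH1", LYS = "NZ", "CB")
    return(rbind(at("CB", 1.5), if (tip != "CB") at(tip, 2.6, element = "N")))
  }
  switch(resid,
    LYS = rbind(at("CB", 1.5), at("CG", 2.8), at("CD", 4.1), at("CE", 5.3),
                at("NZ", 6.5, element = "N")),
    ARG = rbind(at("CB", 1.5), at("CG", 2.8), at("CD", 4.1),
                at("NE", 5.3, element = "N"), at("CZ", 6.3),
                at("NH1", 7.3, off = 0.8 * w, element = "N"),
                at("NH2", 7.3, off = -0.8 * w, element = "N")),
    ASP = rbind(at("CB", 1.5), at("CG", 2.7),
                at("OD1", 3.6, off = 0.6 * w, element = "O"),
                at("OD2", 3.6, off = -0.6 * w, element = "O")),
    NULL)
}

occluder_cage <- function(center, radius = 4.5, n = 42) {
  p <- golden_spiral_points(n) * radius
  data.frame(elety = "C", x = center[1] + p[, 1], y = center[2] + p[, 2],
             z = center[3] + p[, 3], element = "C", stringsAsFactors = FALSE)
}

#' Generate a toy structure with planted ground truth
#'
#' Builds a single-chain structure from canonical geometry templates (three
#' alpha-helices on parallel axes, two connecting coil segments, helix rise
#' 1.5 A / 100 deg twist) with an unresolved N-terminal prefix in SEQRES, and
#' plants, at fixed topological positions: three engineer-in arginines that
#' pass every criterion; one conserved, one buried (enclosed by a shell of
#' occluder pseudo-atoms), one loop-located, one salt-bridged (Asp
#' carboxylate at 3.4 A) and one active-site-proximal arginine that each fail
#' exactly the intended criterion; two engineer-out lysines on a flexible
#' high-B loop; one rigid-helix and one buried lysine that must not be
#' selected; and a one-atom ligand defining the active site. B-factors are
#' drawn (seeded) around 20 on ordered segments and 55 on the flexible loop;
#' coordinates get a small seeded jitter so replicate fixtures differ while
#' every planted class is preserved.
#'
#' Residue numbering is author numbering = declared-sequence index (prefix
#' included), so author resno = `disorder_prefix + local position`.
#'
#' @param seed integer seed (fully determines the fixture)
#' @param disorder_prefix length of the unresolved N-terminal segment
#' @param prefix_seq optional one-letter sequence for the prefix; the default
#'   starts with a proline-rich stalling motif (M G A P P A P) padded with
#'   serines
#' @param chain chain id
#' @return list(structure = `protein_structure`, truth = list of planted
#'   labels, conservation_targets = per-declared-position identity targets
#'   for [make_msa()])
#' @export
make_toy_structure <- function(seed = 1, disorder_prefix = 34, prefix_seq = NULL,
                               chain = "A") {
  stopifnot(disorder_prefix >= 0)
  set.seed(seed)
  n_res <- 68
  seg <- rep("H1", n_res)
  seg[19:26] <- "L1"; seg[27:44] <- "H2"; seg[45:50] <- "L2"; seg[51:68] <- "H3"

  ca <- matrix(0, n_res, 3)
  ca[1:18, ] <- helix_ca(18, c(0, 0, 0))
  ca[19:26, ] <- zigzag_ca(8, c(4, -12, 10))
  ca[27:44, ] <- helix_ca(18, c(14, 0, 0))
  ca[45:50, ] <- zigzag_ca(6, c(20, -12, -6))
  ca[51:68, ] <- helix_ca(18, c(28, 0, 0))
  ca <- ca + matrix(rnorm(3 * n_res, 0, 0.08), n_res, 3)

  plant <- list(
    arg_pass = c(6, 53, 63), arg_conserved = 10, arg_buried = 14,
    arg_loop = 24, arg_near_active = 40, arg_salt = 57, asp_partner = 58,
    lys_out = c(21, 23), lys_rigid = 3, lys_buried = 30
  )
  resid <- rep("GLY", n_res)
  resid[c(plant$arg_pass, plant$arg_conserved, plant$arg_buried,
          plant$arg_loop, plant$arg_near_active, plant$arg_salt)] <- "ARG"
  resid[c(plant$lys_out, plant$lys_rigid, plant$lys_buried)] <- "LYS"
  resid[plant$asp_partner] <- "ASP"

  # outward side-chain directions: away from the neighbouring helix columns
  out_dir <- function(i) {
    switch(seg[i],
           H1 = c(-1, 0, 0), H2 = c(0, 1, 0), H3 = c(1, 0, 0),
           if (i == plant$arg_loop) c(0, 1, 0) else c(0, -1, 0))
  }

  rows <- list()
  add_atoms <- function(df, resid, resno, record = "ATOM", b) {
    df$record <- record; df$resid <- resid; df$resno <- resno; df$b <- b
    rows[[length(rows) + 1L]] <<- df
  }

  b_res <- ifelse(seg == "L1", rnorm(n_res, 55, 3), rnorm(n_res, 20, 2))
  buried_set <- c(plant$arg_buried, plant$lys_buried)

  for (i in seq_len(n_res)) {
    resno <- disorder_prefix + i
    add_atoms(data.frame(elety = "CA", x = ca[i, 1], y = ca[i, 2], z = ca[i, 3],
                         element = "C", stringsAsFactors = FALSE),
              resid[i], resno, b = b_res[i])
    if (resid[i] == "GLY") next
    buried <- i %in% buried_set
    sc <- side_chain(resid[i], ca[i, ], out_dir(i), buried = buried)
    if (i == plant$asp_partner) {
      # carboxylate placed to bridge the planted arginine's NH1 at 3.4 A
      u_arg <- out_dir(plant$arg_salt)
      arg_ca <- ca[plant$arg_salt, ]
      w <- c(-u_arg[3], 0, u_arg[1])
      nh1 <- arg_ca + 7.3 * u_arg + 0.8 * w
      od1 <- nh1 + 3.4 * u_arg
      od2 <- od1 + 1.2 * u_arg
      sc[sc$elety == "OD1", c("x", "y", "z")] <- as.list(od1)
      sc[sc$elety == "OD2", c("x", "y", "z")] <- as.list(od2)
    }
    add_atoms(sc, resid[i], resno, b = b_res[i])
    if (buried)
      add_atoms(occluder_cage(ca[i, ] + 1.5 * out_dir(i)), "DUM", 900 + i,
                record = "HETATM", b = 20)
  }

  # one-atom ligand defining the active site, off the surface of helix 2
  lig_anchor <- (ca[37, ] + ca[38, ]) / 2
  add_atoms(data.frame(elety = "P", x = lig_anchor[1], y = lig_anchor[2] + 2.8,
                       z = lig_anchor[3], element = "P", stringsAsFactors = FALSE),
            "LIG", 501, record = "HETATM", b = 15)

  atoms <- do.call(rbind, rows)
  atoms$chain <- chain
  atoms$icode <- ""
  atoms$o <- 1
  atoms$eleno <- seq_len(nrow(atoms))
  atoms$het <- atoms$record == "HETATM"
  atoms$water <- FALSE
  atoms <- atoms[, c("record", "eleno", "elety", "resid", "chain", "resno",
                     "icode", "x", "y", "z", "o", "b", "element", "het", "water")]

  if (is.null(prefix_seq)) {
    base <- c("M", "G", "A", "P", "P", "A", "P")
    prefix_seq <- paste(c(base, rep("S", max(0, disorder_prefix - length(base))))[
      seq_len(disorder_prefix)], collapse = "")
  }
  stopifnot(nchar(prefix_seq) == disorder_prefix)
  seqres3 <- c(AA_1TO3[strsplit(prefix_seq, "")[[1]]], resid)
  seqres <- setNames(list(unname(seqres3)), chain)
  if (disorder_prefix == 0) seqres <- setNames(list(unname(resid)), chain)

  st <- structure(list(atoms = atoms, seqres = seqres, seqres_offset = 0L),
                  class = "protein_structure")

  p <- disorder_prefix
  rid <- function(i) residue_id(chain, p + i)
  targets <- rep(0.30, p + n_res)
  targets[p + plant$arg_conserved] <- 0.95

  truth <- list(
    chain = chain, disorder_prefix = p, n_resolved = n_res,
    engineer_in_true = rid(plant$arg_pass),
    engineer_out_true = rid(plant$lys_out),
    arg_all = rid(sort(unlist(plant[c("arg_pass", "arg_conserved", "arg_buried",
                                      "arg_loop", "arg_near_active", "arg_salt")]))),
    lys_all = rid(sort(unlist(plant[c("lys_out", "lys_rigid", "lys_buried")]))),
    buried = rid(buried_set),
    exposed_lys = rid(c(plant$lys_out, plant$lys_rigid)),
    salt_bridge = c(basic = rid(plant$arg_salt), acidic = rid(plant$asp_partner)),
    conserved = rid(plant$arg_conserved),
    flexible_loop = rid(19:26), rigid_loop = rid(45:50),
    ligand = "LIG",
    helix_interior = rid(c(3:16, 29:42, 53:66))
  )
  list(structure = st, truth = truth, conservation_targets = targets)
}

#' Generate an alignment with controlled per-column conservation
#'
#' Gap-free alignment of `depth` sequences over the query. For a column with
#' target identity t, `round(t * depth)` sequences (query included) carry the
#' query symbol and the rest draw a random different residue, so the realized
#' identity fraction is within 0.5/depth of the target.
#'
#' @param query one-letter query sequence
#' @param depth number of sequences including the query (>= 2)
#' @param conservation per-column identity targets in `[1/depth, 1]` (recycled)
#' @param seed integer seed
#' @param query_id id for the query record
#' @return an `msa`
#' @export
make_msa <- function(query, depth = 60, conservation = 0.3, seed = 1,
                     query_id = "query") {
  stopifnot(depth >= 2, all(conservation >= 1 / depth), all(conservation <= 1))
  set.seed(seed)
  q <- strsplit(toupper(query), "")[[1]]
  L <- length(q)
  conservation <- rep_len(conservation, L)
  aa <- names(AA_1TO3)
  mat <- matrix("", depth, L)
  mat[1, ] <- q
  for (j in seq_len(L)) {
    m <- max(1L, min(depth, round(conservation[j] * depth)))
    match_rows <- if (m > 1) 1 + sample.int(depth - 1, m - 1) else integer(0)
    for (r in 2:depth) {
      mat[r, j] <- if (r %in% match_rows) q[j] else sample(setdiff(aa, q[j]), 1)
    }
  }
  structure(list(
    ids = c(query_id, sprintf("homolog_%03d", seq_len(depth - 1))),
    seqs = apply(mat, 1, paste, collapse = ""),
    length = L
  ), class = "msa")
}

#' Simulate a Michaelis-Menten initial-velocity dataset
#'
#' v/[E] = kcat*S/(KM+S) times (1 + eps), eps ~ Normal(0, noise_cv), seeded;
#' negative draws are clipped at zero and counted in the `clipped` attribute.
#'
#' @param kcat 1/s
#' @param KM uM
#' @param S_uM substrate concentrations, uM
#' @param noise_cv multiplicative noise coefficient of variation
#' @param replicates replicates per concentration
#' @param seed integer seed
#' @return data.frame(S_uM, v_over_E_per_s, replicate) with attribute
#'   `clipped`
#' @export
simulate_mm_dataset <- function(kcat, KM, S_uM, noise_cv = 0.02, replicates = 3,
                                seed = 1) {
  stopifnot(noise_cv >= 0, replicates >= 1)
  set.seed(seed)
  S <- rep(S_uM, each = replicates)
  v0 <- mm_velocity(kcat, KM, S)
  v <- v0 * (1 + rnorm(length(S), 0, noise_cv))
  clipped <- sum(v < 0)
  v[v < 0] <- 0
  out <- data.frame(S_uM = S, v_over_E_per_s = v,
                    replicate = rep(seq_len(replicates), times = length(S_uM)))
  attr(out, "clipped") <- clipped
  out
}

#' Simulate a depyrimidination progress curve
#'
#' Integrates the Michaelis-Menten rate law exactly (implicit closed form
#' KM*ln(S0/S) + (S0-S) = Vmax*t, inverted numerically) and converts
#' substrate to absorbance via the supplied extinction coefficient, emulating
#' a continuous spectrophotometric assay.
#'
#' @param kcat 1/s
#' @param KM_uM Michaelis constant, uM
#' @param E_M total enzyme concentration, M
#' @param S0_M initial substrate, M
#' @param times sampling times, s
#' @param delta_epsilon extinction-coefficient change, 1/M/cm (290 nm dThd:
#'   1000; 282 nm dUrd: 1370)
#' @param pathlength cm
#' @return progress-curve list: time, absorbance, S0, delta_epsilon,
#'   pathlength, v0_M_per_s (the analytic initial rate)
#' @export
simulate_progress_curve <- function(kcat, KM_uM, E_M, S0_M, times,
                                    delta_epsilon = 1000, pathlength = 1) {
  KM <- KM_uM * 1e-6
  Vmax <- kcat * E_M
  S_at <- function(t) {
    if (t <= 0) return(S0_M)
    f <- function(S) KM * log(S0_M / S) + (S0_M - S) - Vmax * t
    if (f(S0_M * 1e-12) < 0) return(S0_M * 1e-12)   # substrate exhausted
    uniroot(f, c(S0_M * 1e-12, S0_M), tol = 1e-15)$root
  }
  S <- vapply(times, S_at, 0)
  list(time = times, absorbance = delta_epsilon * pathlength * S,
       S0 = S0_M, delta_epsilon = delta_epsilon, pathlength = pathlength,
       v0_M_per_s = Vmax * S0_M / (KM + S0_M))
}
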