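# Independent oracles and fixture builders shared across tests. These stay
# deliberately naive: brute-force scans, Monte-Carlo surface integration, and
# exhaustive alignment enumeration, never the package's own algorithms.

# Monte-Carlo SASA: uniform random points on each atom's expanded sphere,
# fraction outside all neighbours, times the sphere area.
mc_sasa <- function(xyz, elements, probe = 1.4, n_samples = 2e5, seed = 42,
                    vdw = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80),
                    subset = NULL) {
  set.seed(seed)
  R <- unname(vdw[elements]) + probe
  n <- nrow(xyz)
  out <- rep(NA_real_, n)
  if (is.null(subset)) subset <- seq_len(n)
  for (i in subset) {
    u <- matrix(rnorm(3 * n_samples), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    p <- sweep(u * R[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_samples)
    for (j in seq_len(n)[-i]) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 + (p[, 3] - xyz[j, 3])^2
      free <- free & d2 > R[j]^2
    }
    out[i] <- 4 * pi * R[i]^2 * mean(free)
  }
  out
}

# Exhaustive global-alignment enumeration with affine gaps (gap run of
# length L costs open + L * ext; end gaps penalised). Exponential recursion,
# only usable on tiny sequences.
enumerate_align_score <- function(a, b, sm, open = 11, ext = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b))
      best <- max(best, sm[a[i], b[j]] + rec(i + 1L, j + 1L, "M"))
    if (i <= length(a))
      best <- max(best, -(ext + if (prev == "D") 0 else open) + rec(i + 1L, j, "D"))
    if (j <= length(b))
      best <- max(best, -(ext + if (prev == "I") 0 else open) + rec(i, j + 1L, "I"))
    best
  }
  rec(1L, 1L, "S")
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# Minimal PDB text from a compact atom spec (independent of write_pdb).
pdb_text <- function(atoms, seqres = NULL, seqres_chain = "A") {
  lines <- character()
  if (!is.null(seqres)) {
    n <- length(seqres)
    chunks <- split(seqres, ceiling(seq_along(seqres) / 13))
    for (k in seq_along(chunks))
      lines <- c(lines, sprintf("SEQRES %3d %1s %4d  %s", k, seqres_chain, n,
                                paste(sprintf("%-3s", chunks[[k]]), collapse = " ")))
  }
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    rec <- if (isTRUE(a$het)) "HETATM" else "ATOM"
    alt <- if (is.null(atoms$alt)) " " else ifelse(a$alt == "", " ", a$alt)
    occ <- if (is.null(atoms$o)) 1 else a$o
    b <- if (is.null(atoms$b)) 20 else a$b
    name <- if (nchar(a$elety) >= 4) substr(a$elety, 1, 4) else sprintf(" %-3s", a$elety)
    lines <- c(lines, sprintf("%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                              rec, i, name, alt, a$resid, a$chain, a$resno,
                              a$x, a$y, a$z, occ, b, a$element))
  }
  c(lines, "END")
}

atom_row <- function(elety, resid, chain, resno, x, y, z, element = substr(elety, 1, 1),
                     het = FALSE, o = 1, b = 20, alt = "") {
  data.frame(elety = elety, resid = resid, chain = chain, resno = resno,
             x = x, y = y, z = z, element = element, het = het, o = o, b = b,
             alt = alt, stringsAsFactors = FALSE)
}

# One full fixture run: features + both selection directions at defaults.
run_fixture <- function(seed, disorder_prefix = 34) {
  fx <- make_toy_structure(seed = seed, disorder_prefix = disorder_prefix)
  msa <- make_msa(declared_sequence(fx$structure), depth = 60,
                  conservation = fx$conservation_targets, seed = seed)
  res <- run_selection_pipeline(fx$structure, msa = msa, query_id = "query",
                                active_site = list(ligand = "LIG", cutoff = 4.5))
  list(fx = fx, res = res)
}
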