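test_that("a minimal one-residue PDB parses to one chain with one residue", {
  txt <- pdb_text(atom_row("CA", "GLY", "A", 1, 1, 2, 3))
  st <- parse_pdb(txt)
  expect_s3_class(st, "protein_structure")
  expect_equal(structure_chains(st), "A")
  rt <- residue_table(st)
  expect_equal(nrow(rt), 1L)
  expect_equal(rt$resid, "GLY")
  expect_equal(declared_sequence(st), "G")
})

test_that("SEQRES with partial coordinates gives declared length and N-terminal disorder", {
  seqres <- rep("GLY", 50)
  atoms <- do.call(rbind, lapply(35:50, function(i)
    atom_row("CA", "GLY", "A", i, i * 3.8, 0, 0)))
  st <- parse_pdb(pdb_text(atoms, seqres = seqres))
  expect_equal(nchar(declared_sequence(st)), 50L)
  expect_equal(nrow(residue_table(st)), 16L)
  segs <- unresolved_segments(st)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$start, 1L)
  expect_equal(segs$end, 34L)
  expect_equal(segs$terminal, "N")
  # disorder + resolved residues partition the declared sequence
  expect_equal(sum(segs$end - segs$start + 1) + nrow(residue_table(st)), 50)
})

test_that("a fully resolved chain has no unresolved segments", {
  atoms <- do.call(rbind, lapply(1:6, function(i)
    atom_row("CA", "GLY", "A", i, i * 3.8, 0, 0)))
  st <- parse_pdb(pdb_text(atoms, seqres = rep("GLY", 6)))
  expect_equal(nrow(unresolved_segments(st)), 0L)
})

test_that("without SEQRES, author-numbering gaps give internal segments only", {
  atoms <- do.call(rbind, lapply(c(1:3, 7:9), function(i)
    atom_row("CA", "GLY", "A", i, i * 3.8, 0, 0)))
  st <- parse_pdb(pdb_text(atoms))
  segs <- unresolved_segments(st)
  expect_equal(segs$start, 4L)
  expect_equal(segs$end, 6L)
  expect_equal(segs$terminal, "internal")
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  atoms <- rbind(
    atom_row("CA", "LYS", "A", 1, 0, 0, 0),
    atom_row("NZ", "LYS", "A", 1, 5, 0, 0, element = "N", o = 0.4, alt = "A"),
    atom_row("NZ", "LYS", "A", 1, 6, 0, 0, element = "N", o = 0.6, alt = "B")
  )
  st <- parse_pdb(pdb_text(atoms))
  nz <- st$atoms[st$atoms$elety == "NZ", ]
  expect_equal(nrow(nz), 1L)
  expect_equal(nz$x, 6)
  # occupancy tie breaks alphabetically
  atoms$o <- c(1, 0.5, 0.5)
  st2 <- parse_pdb(pdb_text(atoms))
  expect_equal(st2$atoms[st2$atoms$elety == "NZ", "x"], 5)
})

test_that("malformed and empty inputs raise informative parse errors", {
  bad <- c("ATOM      1  CA  GLY A   1      xx.xxx   0.000   0.000  1.00 20.00           C", "END")
  expect_error(parse_pdb(bad), "line 1")
  expect_error(parse_pdb(c("REMARK nothing here", "END")), "no ATOM records")
  expect_error(parse_pdb("ATOM      1  CA GLY"), "line 1")
})

test_that("B-factor z-scores match hand arithmetic and degenerate cases warn", {
  atoms <- do.call(rbind, lapply(1:4, function(i)
    atom_row("CA", "GLY", "A", i, i * 3.8, 0, 0, b = c(10, 10, 10, 40)[i])))
  st <- parse_pdb(pdb_text(atoms))
  z <- bfactor_zscores(st)
  expect_equal(unname(z["A:4"]), 1.5)   # sample SD of {10,10,10,40} is 15
  expect_equal(mean(z), 0, tolerance = 1e-12)

  atoms$b <- 20
  expect_warning(z0 <- bfactor_zscores(parse_pdb(pdb_text(atoms))), "zero B-factor")
  expect_true(all(z0 == 0))

  expect_error(bfactor_zscores(parse_pdb(pdb_text(atoms[1:2, ]))), "fewer than 3")
})

test_that("z-scores are invariant to positive affine rescaling of B-factors", {
  for (seed in 1:3) {
    set.seed(seed)
    b <- runif(8, 10, 60)
    atoms <- do.call(rbind, lapply(1:8, function(i)
      atom_row("CA", "GLY", "A", i, i * 3.8, 0, 0, b = b[i])))
    z1 <- bfactor_zscores(parse_pdb(pdb_text(atoms)))
    atoms$b <- 2.5 * b + 7
    z2 <- bfactor_zscores(parse_pdb(pdb_text(atoms)))
    # PDB records carry B to 2 decimals, so invariance holds to that precision
    expect_equal(as.numeric(z1), as.numeric(z2), tolerance = 2e-3)
    expect_equal(names(z1), names(z2))
  }
})

test_that("write/parse round trip preserves identifiers, coordinates and B-factors", {
  st <- make_toy_structure(seed = 5)$structure
  st2 <- parse_pdb(write_pdb(st))
  expect_equal(residue_table(st2)$id, residue_table(st)$id)
  expect_equal(st2$atoms$x, st$atoms$x, tolerance = 5e-4)
  expect_equal(st2$atoms$y, st$atoms$y, tolerance = 5e-4)
  expect_equal(st2$atoms$z, st$atoms$z, tolerance = 5e-4)
  expect_equal(st2$atoms$b, st$atoms$b, tolerance = 5e-3)
  expect_equal(unname(st2$seqres[["A"]]), unname(st$seqres[["A"]]))
})
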