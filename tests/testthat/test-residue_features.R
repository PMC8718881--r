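straight_chain <- function(n, resid = "GLY", b = 20) {
  do.call(rbind, lapply(seq_len(n), function(i)
    atom_row("CA", resid, "A", i, i * 3.8, 0, 0, b = b)))
}

test_that("an ideal alpha-helix is assigned H at all interior residues", {
  fx <- make_toy_structure(seed = 4)
  ss <- assign_secondary_structure(fx$structure)
  expect_true(all(ss[fx$truth$helix_interior] == "H"))
})

test_that("an extended straight chain gets no helix assignments", {
  st <- parse_pdb(pdb_text(straight_chain(12)))
  ss <- assign_secondary_structure(st)
  expect_false(any(ss == "H"))
})

test_that("loop residues between helices are classed coil", {
  fx <- make_toy_structure(seed = 4)
  ss <- assign_secondary_structure(fx$structure)
  expect_true(all(ss[fx$truth$flexible_loop] == "C"))
  expect_true(all(ss[fx$truth$rigid_loop] == "C"))
})

test_that("chains shorter than five residues are entirely coil", {
  st <- parse_pdb(pdb_text(straight_chain(4)))
  expect_true(all(assign_secondary_structure(st) == "C"))
})

test_that("a lysine-aspartate pair at 3.5 A is a bridge and at 4.5 A is not", {
  base <- rbind(
    atom_row("CA", "LYS", "A", 1, -2, 0, 0),
    atom_row("NZ", "LYS", "A", 1, 0, 0, 0, element = "N"),
    atom_row("CA", "ASP", "A", 5, 6, 0, 0),
    atom_row("OD1", "ASP", "A", 5, 3.5, 0, 0, element = "O")
  )
  sb <- find_salt_bridges(parse_pdb(pdb_text(base)))
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$min_N_O_distance, 3.5, tolerance = 1e-6)
  expect_equal(sb$basic_id, "A:1")
  expect_equal(sb$acidic_id, "A:5")

  base$x[base$elety == "OD1"] <- 4.5
  expect_equal(nrow(find_salt_bridges(parse_pdb(pdb_text(base)), cutoff = 4.0)), 0L)
})

test_that("bridge detection on a 3-basic / 2-acidic fixture matches a brute-force scan", {
  atoms <- rbind(
    atom_row("NZ", "LYS", "A", 1, 0, 0, 0, element = "N"),
    atom_row("NH1", "ARG", "A", 2, 10, 0, 0, element = "N"),
    atom_row("NE2", "HIS", "A", 3, 20, 0, 0, element = "N"),
    atom_row("OD1", "ASP", "A", 4, 3.2, 0, 0, element = "O"),   # bridges K1
    atom_row("OE1", "GLU", "A", 5, 10, 3.6, 0, element = "O")   # bridges R2
  )
  st <- parse_pdb(pdb_text(atoms))
  sb <- find_salt_bridges(st, cutoff = 4.0)
  expect_setequal(paste(sb$basic_id, sb$acidic_id), c("A:1 A:4", "A:2 A:5"))

  # brute-force all-pairs oracle
  bas <- atoms[1:3, ]; aci <- atoms[4:5, ]
  hits <- c()
  for (i in 1:3) for (j in 1:2) {
    d <- sqrt((bas$x[i] - aci$x[j])^2 + (bas$y[i] - aci$y[j])^2 + (bas$z[i] - aci$z[j])^2)
    if (d <= 4) hits <- c(hits, paste0("A:", bas$resno[i], " A:", aci$resno[j]))
  }
  expect_setequal(paste(sb$basic_id, sb$acidic_id), hits)
})

test_that("salt-bridge detection is invariant under rigid rotation and translation", {
  fx <- make_toy_structure(seed = 6)
  sb0 <- find_salt_bridges(fx$structure)
  th <- 0.9
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  st <- fx$structure
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")]) %*% Rz
  st$atoms$x <- xyz[, 1] + 5; st$atoms$y <- xyz[, 2] - 3; st$atoms$z <- xyz[, 3] + 11
  sb1 <- find_salt_bridges(st)
  expect_equal(sb1$basic_id, sb0$basic_id)
  expect_equal(sb1$min_N_O_distance, sb0$min_N_O_distance, tolerance = 1e-9)
})

test_that("active-site definitions: explicit list, ligand proximity, degenerate cutoff", {
  atoms <- rbind(
    straight_chain(6),
    atom_row("P", "LIG", "A", 501, 3.8 * 2.5, 3, 0, element = "P", het = TRUE)
  )
  st <- parse_pdb(pdb_text(atoms))
  expect_equal(active_site_set(st, residues = "A:3"), "A:3")
  expect_error(active_site_set(st, residues = "A:99"), "not in structure")
  expect_error(active_site_set(st), "empty")
  # ligand sits 3.04 A from residues 2 and 3 only
  near <- active_site_set(st, ligand = "LIG", cutoff = 4.5)
  expect_setequal(near, c("A:2", "A:3"))
  expect_length(active_site_set(st, ligand = "LIG", cutoff = 0.1), 0L)
})

test_that("minimum distance to a residue set matches an exhaustive scan", {
  atoms <- straight_chain(6)
  st <- parse_pdb(pdb_text(atoms))
  expect_equal(min_distance_to_set(st, "A:1", "A:1"), 0)
  expect_equal(min_distance_to_set(st, "A:1", character(0)), Inf)
  # 1-atom target at a known distance
  expect_equal(min_distance_to_set(st, "A:1", "A:4"), 3 * 3.8, tolerance = 1e-9)
  # lattice fixture vs brute force
  fx <- make_toy_structure(seed = 7)
  tgt <- fx$truth$flexible_loop
  got <- min_distance_to_set(fx$structure, fx$truth$engineer_in_true[1], tgt)
  a <- fx$structure$atoms[!fx$structure$atoms$het, ]
  ids <- residue_id(a$chain, a$resno, a$icode)
  src <- a[ids == fx$truth$engineer_in_true[1], ]
  t2 <- a[ids %in% tgt, ]
  brute <- Inf
  for (i in seq_len(nrow(src))) for (j in seq_len(nrow(t2)))
    brute <- min(brute, sqrt((src$x[i] - t2$x[j])^2 + (src$y[i] - t2$y[j])^2 + (src$z[i] - t2$z[j])^2))
  expect_equal(got, brute, tolerance = 1e-9)
})

test_that("the feature table has one fully populated row per resolved residue", {
  atoms <- straight_chain(10)
  atoms$resid[4] <- "LYS"
  st <- parse_pdb(pdb_text(atoms))
  # uniform B-factors and a side-chain-less lysine legitimately warn here
  f <- suppressWarnings(build_feature_table(st, active_site = "A:1"))
  expect_equal(nrow(f), 10L)
  expect_true(all(!is.na(f$sasa_total)))
  expect_true(all(f$ss %in% c("H", "E", "C")))
  expect_true(all(is.na(f$conservation)))          # no alignment supplied
  expect_true(all(f$loop == (f$ss == "C")))
  expect_true(all(f$active_site_dist >= 0))
})

test_that("duplicate residue ids in the feature build are an error", {
  fx <- make_toy_structure(seed = 1)
  expect_error(build_feature_table(fx$structure, chain = c("A", "A")),
               "duplicate residue ids")
})
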