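# feature rows built directly, for engine-only tests
feature_row <- function(id, resno, aa, sasa = 120, ss = "H", bz = 0,
                        bridge = FALSE, asd = 30, cons = 0.3) {
  data.frame(id = id, chain = "A", resno = resno, icode = "", resid = "",
             aa = aa, sasa_total = sasa, sasa_sidechain = sasa * 0.8, ss = ss,
             loop = ss == "C", bz = bz, salt_bridge = bridge,
             salt_bridge_partners = "", active_site_dist = asd,
             conservation = cons, stringsAsFactors = FALSE)
}

test_that("planted engineer-in and engineer-out sites are recovered exactly on a fixture", {
  run <- run_fixture(seed = 1)
  ein <- run$res$engineer_in; eout <- run$res$engineer_out
  expect_setequal(ein$id[ein$verdict], run$fx$truth$engineer_in_true)
  expect_setequal(eout$id[eout$verdict], run$fx$truth$engineer_out_true)
  # every planted decoy fails for its intended reason, not several
  decoys <- setdiff(run$fx$truth$arg_all, run$fx$truth$engineer_in_true)
  aud <- attr(ein, "audit")
  for (d in decoys) {
    a <- aud[[d]]
    expect_equal(sum(!a$pass[a$applicable]), 1L, info = d)
  }
})

test_that("an all-buried feature table yields zero engineer-in verdicts", {
  f <- rbind(feature_row("A:1", 1, "R", sasa = 10),
             feature_row("A:2", 2, "R", sasa = 40),
             feature_row("A:3", 3, "K", sasa = 50))
  class(f) <- c("residue_features", "data.frame")
  ein <- evaluate_engineer_in(f)
  expect_equal(sum(ein$verdict), 0L)
})

test_that("recommendations sort by accessibility with residue-number tie-break", {
  f <- rbind(feature_row("A:9", 9, "R", sasa = 100),
             feature_row("A:2", 2, "R", sasa = 150),
             feature_row("A:5", 5, "R", sasa = 150))
  class(f) <- c("residue_features", "data.frame")
  ein <- evaluate_engineer_in(f)
  expect_equal(ein$id, c("A:2", "A:5", "A:9"))
})

test_that("missing conservation makes the criterion inapplicable and flags a partial evaluation", {
  f <- feature_row("A:1", 1, "R", cons = NA)
  class(f) <- c("residue_features", "data.frame")
  ein <- evaluate_engineer_in(f)
  expect_true(ein$partial)
  expect_true(ein$verdict)               # remaining criteria all pass
  aud <- attr(ein, "audit")[["A:1"]]
  expect_false(aud$applicable[aud$criterion == "not_conserved"])
})

test_that("the SASA comparison is strict so marginal sites show their margin", {
  f <- feature_row("A:1", 1, "R", sasa = 75)
  class(f) <- c("residue_features", "data.frame")
  expect_false(evaluate_engineer_in(f)$verdict)
  f2 <- feature_row("A:1", 1, "R", sasa = 75.01)
  class(f2) <- c("residue_features", "data.frame")
  expect_true(evaluate_engineer_in(f2)$verdict)
})

test_that("engineer-out requires accessibility plus flexibility or active-site proximity", {
  rigid_far <- feature_row("A:1", 1, "K", ss = "H", bz = -0.5, asd = 30)
  flex <- feature_row("A:2", 2, "K", ss = "C", bz = 2.1, asd = 30)
  near <- feature_row("A:3", 3, "K", ss = "H", bz = 0, asd = 6)
  buried_flex <- feature_row("A:4", 4, "K", sasa = 20, ss = "C", bz = 2.5)
  f <- rbind(rigid_far, flex, near, buried_flex)
  class(f) <- c("residue_features", "data.frame")
  eout <- evaluate_engineer_out(f)
  expect_equal(sort(eout$id[eout$verdict]), c("A:2", "A:3"))
})

test_that("tightening any threshold never grows the verdict-true sets", {
  for (seed in c(3, 8)) {
    run <- run_fixture(seed)
    f <- run$res$features
    base <- selection_criteria()
    base_in <- evaluate_engineer_in(f, base)
    base_out <- evaluate_engineer_out(f, base)
    # tightening means the opposite thing for the active-site distance in the
    # two directions: engineer-in requires being far (raise the floor),
    # engineer-out counts proximity as a liability (shrink the radius)
    tighter_in <- list(
      selection_criteria(sasa_min = 120),
      selection_criteria(conservation_max = 0.4),
      selection_criteria(active_site_min_distance = 18)
    )
    tighter_out <- list(
      selection_criteria(engineer_out_sasa_min = 110),
      selection_criteria(loop_bz_min = 2.0),
      selection_criteria(active_site_min_distance = 4)
    )
    for (crit in tighter_in) {
      ein <- evaluate_engineer_in(f, crit)
      expect_true(all(ein$id[ein$verdict] %in% base_in$id[base_in$verdict]))
    }
    for (crit in tighter_out) {
      eout <- evaluate_engineer_out(f, crit)
      expect_true(all(eout$id[eout$verdict] %in% base_out$id[base_out$verdict]))
    }
  }
})

test_that("every verdict is reproducible from its audit trail alone", {
  run <- run_fixture(seed = 2)
  # engineer-in: conjunction of all applicable criteria
  ein <- run$res$engineer_in
  aud <- attr(ein, "audit")
  for (k in seq_len(nrow(ein))) {
    a <- aud[[ein$id[k]]]
    expect_equal(ein$verdict[k], all(a$pass[a$applicable]), info = ein$id[k])
  }
  # engineer-out: accessible AND (flexible loop OR active-site proximal)
  eout <- run$res$engineer_out
  aud <- attr(eout, "audit")
  for (k in seq_len(nrow(eout))) {
    a <- aud[[eout$id[k]]]
    p <- setNames(a$pass, a$criterion)
    expect_equal(eout$verdict[k],
                 isTRUE(p["peg_accessible"]) &&
                   (isTRUE(p["flexible_loop"]) || isTRUE(p["near_active_site"])),
                 info = eout$id[k])
  }
})

test_that("substitutions apply in full-length numbering with source-residue guards", {
  expect_equal(apply_substitutions("AKRA", data.frame(pos = c(2, 3),
                                                      from = c("K", "R"),
                                                      to = c("R", "K")))$sequence, "ARKA")
  expect_equal(apply_substitutions("AKRA", character(0))["sequence"],
               list(sequence = "AKRA"))
  expect_error(apply_substitutions("AKRA", "K3R"), "expected 'K' at position 3")

  # the full seven-substitution engineer-in/engineer-out set on a synthetic
  # full-length-numbered sequence
  s <- strsplit(paste(rep("A", 500), collapse = ""), "")[[1]]
  s[c(139, 275)] <- "K"
  s[c(329, 342, 345, 358, 453)] <- "R"
  res <- apply_substitutions(paste(s, collapse = ""),
                             c("K139R", "K275R", "R329K", "R342K", "R345K",
                               "R358K", "R453K"))
  expect_equal(res$mutations, "K139R-K275R-R329K-R342K-R345K-R358K-R453K")
  v <- strsplit(res$sequence, "")[[1]]
  expect_true(all(v[c(139, 275)] == "R"))
  expect_true(all(v[c(329, 342, 345, 358, 453)] == "K"))
})

test_that("an empty candidate set warns and returns an empty recommendation table", {
  f <- feature_row("A:1", 1, "G")
  class(f) <- c("residue_features", "data.frame")
  expect_warning(ein <- evaluate_engineer_in(f), "no arginine")
  expect_equal(nrow(ein), 0L)
})
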