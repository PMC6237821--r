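test_that("PDB round trip preserves residues and coordinates", {
  fx <- gen_structure_fixture(placement("salt_bridge", c("Asp", "A", 10),
                                        c("Arg", "A", 20), distance = 3.5),
                              file = withr::local_tempfile(fileext = ".pdb"))
  s2 <- read_structure(fx$file)
  expect_equal(as.data.frame(s2), as.data.frame(fx$structure))
  expect_error(read_structure(tempfile()), "no such file")
})

test_that("insertion codes and atom-less files are rejected", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1      11.104   6.134  -6.504  1.00  0.00           C",
    "ATOM      2  CA AGLY A   2A     12.104   6.134  -6.504  1.00  0.00           C",
    "END"), f)
  expect_error(read_structure(f), "insertion")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", f2)
  expect_error(read_structure(f2))
})

test_that("salt bridges are detected at the placed distance and only within cutoff", {
  fx <- gen_structure_fixture(placement("salt_bridge", c("Asp", "A", 1),
                                        c("Arg", "A", 2), distance = 3.5))
  e <- detect_salt_bridges(fx$structure)
  expect_equal(nrow(e), 1L)
  expect_equal(e$distance, 3.5, tolerance = 1e-6)
  expect_equal(e$kind, "salt_bridge")
  # rigid translation leaves the edge list unchanged
  s <- fx$structure
  s$x <- s$x + 100
  expect_equal(detect_salt_bridges(s)$distance, e$distance, tolerance = 1e-9)
  # beyond the cutoff: nothing
  far <- gen_structure_fixture(placement("salt_bridge", c("Asp", "A", 1),
                                         c("Arg", "A", 2), distance = 4.5))
  expect_equal(nrow(detect_salt_bridges(far$structure)), 0L)
  # His counts as cationic
  his <- gen_structure_fixture(placement("salt_bridge", c("Glu", "A", 1),
                                         c("His", "A", 2), distance = 3.8))
  expect_equal(nrow(detect_salt_bridges(his$structure)), 1L)
})

test_that("stacking requires parallel rings within the centroid cutoff", {
  fx <- gen_structure_fixture(placement("stacking", c("Trp", "A", 104),
                                        c("Trp", "B", 104), distance = 4.0))
  e <- detect_stacking(fx$structure)
  expect_equal(nrow(e), 1L)
  expect_equal(e$distance, 4.0, tolerance = 1e-6)
  expect_false(e$same_chain)
  expect_lt(e$angle, 1e-6)
  far <- gen_structure_fixture(placement("stacking", c("Trp", "A", 1),
                                         c("Trp", "B", 1), distance = 8))
  expect_equal(nrow(detect_stacking(far$structure)), 0L)
  perp <- gen_structure_fixture(placement("stacking", c("Trp", "A", 1),
                                          c("Trp", "B", 1), distance = 4.5,
                                          angle = 90))
  expect_equal(nrow(detect_stacking(perp$structure)), 0L)
  # a 20-degree tilt is still parallel stacking under the default
  tilt <- gen_structure_fixture(placement("stacking", c("Phe", "A", 1),
                                          c("Tyr", "B", 1), distance = 4.5,
                                          angle = 20))
  et <- detect_stacking(tilt$structure)
  expect_equal(nrow(et), 1L)
  # coordinates carry PDB-style 3-decimal precision, so allow a small slack
  expect_equal(et$angle, 20, tolerance = 0.01)
})

test_that("hydrophobic contacts pair apolar side-chain carbons only", {
  fx <- gen_structure_fixture(placement("hydrophobic", c("Val", "A", 1),
                                        c("Leu", "A", 2), distance = 4.0))
  e <- detect_hydrophobic(fx$structure)
  expect_equal(nrow(e), 1L)
  expect_equal(e$distance, 4.0, tolerance = 1e-6)
  polar <- gen_structure_fixture(placement("pair", c("Ser", "A", 1),
                                           c("Ser", "A", 2), distance = 4.0))
  expect_equal(nrow(detect_hydrophobic(polar$structure)), 0L)
})

test_that("detectors match exhaustive-scan oracles on random structures", {
  for (seed in 1:20) {
    s <- random_structure(seed, n_res = 12)
    expect_equal(edge_keys(detect_salt_bridges(s)), oracle_salt_bridges(s),
                 label = paste("salt bridges, seed", seed))
    expect_equal(edge_keys(suppressWarnings(detect_stacking(s))),
                 oracle_stacking(s), label = paste("stacking, seed", seed))
    expect_equal(edge_keys(detect_hydrophobic(s)), oracle_hydrophobic(s),
                 label = paste("hydrophobic, seed", seed))
  }
})

test_that("edge lists are invariant under rigid motions", {
  for (seed in 1:10) {
    s <- random_structure(seed, n_res = 10)
    sm <- rigid_motion(s, seed + 1000)
    e0 <- suppressWarnings(detect_interactions(s))
    e1 <- suppressWarnings(detect_interactions(sm))
    expect_equal(edge_keys(e0), edge_keys(e1))
    expect_equal(sort(e0$distance), sort(e1$distance), tolerance = 1e-6)
  }
})

test_that("enlarging a cutoff never removes edges", {
  s <- random_structure(5, n_res = 14)
  for (cut in list(c(3, 4), c(4, 5.5))) {
    small <- edge_keys(detect_salt_bridges(s, cut[1]))
    big <- edge_keys(detect_salt_bridges(s, cut[2]))
    expect_true(all(small %in% big))
    smallh <- edge_keys(detect_hydrophobic(s, cut[1]))
    bigh <- edge_keys(detect_hydrophobic(s, cut[2]))
    expect_true(all(smallh %in% bigh))
  }
  s2 <- suppressWarnings({
    small <- edge_keys(detect_stacking(s, 4.5, 20))
    big <- edge_keys(detect_stacking(s, 6.5, 40))
    expect_true(all(small %in% big))
  })
})

test_that("residue profiles equal the filtered full edge list", {
  fx <- gen_structure_fixture(list(
    placement("salt_bridge", c("Asp", "A", 210), c("Arg", "A", 476),
              distance = 3.4),
    placement("isolated", c("Gly", "A", 999))))
  prof <- residue_profile(fx$structure, "A", 210)
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$res_b, 476L)
  expect_equal(prof$kind, "salt_bridge")
  expect_equal(nrow(residue_profile(fx$structure, "A", 999)), 0L)
  expect_error(residue_profile(fx$structure, "A", 5), "no residue")
  all_edges <- detect_interactions(fx$structure)
  touch <- all_edges[all_edges$res_a == 210 | all_edges$res_b == 210, ]
  expect_equal(prof$distance, touch$distance)
})

test_that("the closure-network audit reports present, absent and missing pairs", {
  cp <- closure_pairs()
  expect_equal(nrow(cp), 6L)
  mk <- function(i, acid_to_tyr = FALSE) {
    pa <- strsplit(as.character(cp$pos_a[i]), ";")[[1]][1]
    ca <- strsplit(as.character(cp$code_a[i]), ";")[[1]][1]
    if (acid_to_tyr && ca == "Asp") ca <- "Tyr"
    kind <- if (acid_to_tyr && ca == "Tyr") "pair" else "salt_bridge"
    placement(kind, c(ca, "A", pa), c(cp$code_b[i], "A", cp$pos_b[i]),
              distance = 3.2)
  }
  full <- gen_structure_fixture(lapply(1:6, mk))
  r <- check_closure_network(full$structure)
  expect_true(all(r$present))
  expect_equal(attr(r, "fraction_present"), 1)

  # Asp210 with a tyrosine side chain: no carboxylate, contact lost
  mut <- gen_structure_fixture(c(list(mk(1, acid_to_tyr = TRUE)),
                                 lapply(2:6, mk)))
  rm <- check_closure_network(mut$structure)
  expect_false(rm$present[rm$pair_id == 1])
  expect_true(all(rm$present[rm$pair_id != 1]))

  # a structure without the listed residues: all pairs reported missing
  lone <- gen_structure_fixture(placement("isolated", c("Gly", "A", 1)))
  r0 <- check_closure_network(lone$structure)
  expect_true(all(!r0$present))
  expect_true(all(r0$note == "missing residue"))
})

test_that("the mechanism map partitions the 11 positions as published", {
  m <- mechanism_map()
  expect_equal(nrow(m), 11L)
  expect_equal(as.vector(table(m$category)[c("gtp_site_rearrangement",
                                             "dimerization", "hydrolysis",
                                             "closure", "unknown")]),
               c(1L, 5L, 1L, 2L, 2L))
  expect_equal(classify_mechanism(277)$category, "gtp_site_rearrangement")
  expect_equal(classify_mechanism(259)$category, "dimerization")
  expect_equal(classify_mechanism(127)$category, "hydrolysis")
  expect_equal(classify_mechanism(210)$category, "closure")
  out <- classify_mechanism(999)
  expect_equal(out$category, "unknown")
  expect_false(out$mapped)
  # mapped "unknown" positions are distinguishable from unmapped ones
  expect_true(classify_mechanism(244)$mapped)
})

test_that("profile diffs report lost and gained interactions", {
  wild <- gen_structure_fixture(placement("salt_bridge", c("His", "A", 165),
                                          c("Glu", "A", 268), distance = 3.5))
  mut <- gen_structure_fixture(placement("pair", c("Leu", "A", 165),
                                         c("Glu", "A", 268), distance = 3.5))
  d <- diff_profiles(wild$structure, mut$structure, "A", 165)
  expect_equal(nrow(d$lost), 1L)
  expect_equal(d$lost$kind, "salt_bridge")
  expect_equal(nrow(d$gained), 0L)
  # identical structures diff to nothing
  d0 <- diff_profiles(wild$structure, wild$structure, "A", 165)
  expect_equal(nrow(d0$lost) + nrow(d0$gained), 0L)
  # the diff equals an independently computed symmetric set difference
  key <- function(p) paste(p$kind, p$chain_a, p$res_a, p$chain_b, p$res_b)
  pw <- residue_profile(wild$structure, "A", 165)
  pm <- residue_profile(mut$structure, "A", 165)
  expect_setequal(key(d$lost), setdiff(key(pw), key(pm)))
  expect_setequal(key(d$gained), setdiff(key(pm), key(pw)))
  # numbering mismatches away from the mutated residue are an error
  bad <- gen_structure_fixture(placement("pair", c("Leu", "A", 165),
                                         c("Gln", "A", 268), distance = 3.5))
  expect_error(diff_profiles(wild$structure, bad$structure, "A", 165),
               "identity differs")
})
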