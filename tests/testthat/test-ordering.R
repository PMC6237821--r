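test_that("chain parsing handles relations, unicode and malformed input", {
  c1 <- parse_chain("Asp > Arg > Leu = Tyr")
  expect_equal(c1$labels, c("Asp", "Arg", "Leu", "Tyr"))
  expect_equal(c1$relations, c(">", ">", "="))
  expect_equal(parse_chain("Trp")$labels, "Trp")
  expect_equal(parse_chain("Leu ≥ Met")$relations, ">=")
  expect_equal(parse_chain("Leu >= Met")$relations, ">=")
  expect_error(parse_chain("Leu > "), "dangling")
  expect_error(parse_chain("Leu > Leu"), "repeated")
  expect_error(parse_chain(""), "empty")
})

test_that("parse and serialize round-trip on random chains", {
  for (seed in 1:500) {
    ch <- random_chain(seed)
    expect_true(parse_chain(format(ch)) == ch)
  }
})

test_that("clinical chains derive from score intervals by the midpoint rule", {
  expect_equal(format(derive_clinical_chain(data.frame(
    alt = c("Asp", "Arg", "Leu", "Tyr"), score_min = c(3, 2, 1, 1),
    score_max = c(3.5, 2, 1, 1)))), "Asp > Arg > Leu = Tyr")
  # two point scores exactly 0.5 apart -> weak inequality
  expect_equal(format(derive_clinical_chain(data.frame(
    alt = c("Leu", "Met"), score_min = c(2, 1.5), score_max = c(2, 1.5)))),
    "Leu >= Met")
  # a 0.5 midpoint gap involving intervals stays strict
  expect_equal(format(derive_clinical_chain(data.frame(
    alt = c("Trp", "Gln"), score_min = c(1, 0.5), score_max = c(1.5, 1)))),
    "Trp > Gln")
  expect_equal(format(derive_clinical_chain(data.frame(
    alt = "X", score_min = 2, score_max = 2))), "X")
  # midpoint ties break alphabetically
  expect_equal(format(derive_clinical_chain(data.frame(
    alt = c("Val", "Tyr"), score_min = c(7, 7), score_max = c(7, 7)))),
    "Tyr = Val")
})

test_that("all 11 bundled clinical chains derive from the bundled scores", {
  t1 <- apply_exclusions(filter_domain(mfn2_table1_catalog()))
  groups <- group_by_position(t1)
  scores <- score_table(mfn2_table1_clinical())
  t2 <- mfn2_table2()
  for (i in seq_len(nrow(groups))) {
    subs <- ungroup_positions(groups[i, ])
    idx <- match(subs$label, scores$mutation)
    chain <- derive_clinical_chain(data.frame(alt = subs$alt,
                                              score_min = scores$score_min[idx],
                                              score_max = scores$score_max[idx]))
    expect_equal(format(chain),
                 t2$clinical[t2$position == groups$position[i]],
                 label = paste("clinical chain at", groups$position[i]))
  }
})

test_that("chain comparison distinguishes concordant, partial and discordant", {
  expect_equal(compare_chains(parse_chain("Tyr = Val"),
                              parse_chain("Tyr > Val"))$status, "partial")
  expect_equal(compare_chains(parse_chain("Trp > Gln"),
                              parse_chain("Trp > Gln"))$status, "concordant")
  # a weak clinical claim subsumes both strict and equal structural calls
  expect_equal(compare_chains(parse_chain("Leu >= Met"),
                              parse_chain("Leu = Met"))$status, "concordant")
  expect_equal(compare_chains(parse_chain("Leu >= Met"),
                              parse_chain("Leu > Met"))$status, "concordant")
  expect_equal(compare_chains(parse_chain("Ala > Val"),
                              parse_chain("Val > Ala"))$status, "discordant")
  expect_error(compare_chains(parse_chain("Ala > Val"),
                              parse_chain("Ala > Leu")), "label sets")
  # every chain is concordant with itself
  for (seed in 1:100) {
    ch <- random_chain(seed)
    expect_equal(compare_chains(ch, ch)$status, "concordant")
  }
})

test_that("bundled ordering comparison yields 8/11 with partial set {210,251,277}", {
  t2 <- mfn2_table2()
  comps <- lapply(seq_len(nrow(t2)), function(i)
    compare_chains(parse_chain(t2$clinical[i]), parse_chain(t2$structural[i]),
                   position = t2$position[i]))
  status <- vapply(comps, `[[`, character(1), "status")
  expect_equal(t2$position[status == "partial"], c(210L, 251L, 277L))
  expect_false(any(status == "discordant"))
  s <- concordance_summary(comps)
  expect_equal(s$n_groups, 11L)
  expect_equal(s$n_concordant, 8L)
  expect_equal(s$agreement_percent, 73)
  # invariant to group order
  s2 <- concordance_summary(rev(comps))
  expect_equal(s2$agreement_percent, 73)
})

test_that("concordance summary counts and rounds half-up", {
  all_c <- replicate(3, compare_chains(parse_chain("A > B"), parse_chain("A > B")),
                     simplify = FALSE)
  s <- concordance_summary(all_c)
  expect_equal(c(s$n_groups, s$n_concordant, s$agreement_percent), c(3, 3, 100))
  expect_error(concordance_summary(list()), "no comparisons")
})

test_that("predictor compatibility mirrors the in-house comparison", {
  t1 <- apply_exclusions(filter_domain(mfn2_table1_catalog()))
  groups <- group_by_position(t1)
  scores <- score_table(mfn2_table1_clinical())
  chains <- lapply(seq_len(nrow(groups)), function(i) {
    subs <- ungroup_positions(groups[i, ])
    idx <- match(subs$label, scores$mutation)
    derive_clinical_chain(data.frame(alt = subs$alt,
                                     score_min = scores$score_min[idx],
                                     score_max = scores$score_max[idx]))
  })
  names(chains) <- as.character(groups$position)

  # a tool replicating the structural orderings must reach the same 73%
  t2 <- mfn2_table2()
  subs <- ungroup_positions(groups)
  rows <- lapply(seq_len(nrow(t2)), function(i) {
    ch <- parse_chain(t2$structural[i])
    val <- numeric(length(ch$labels)); v <- length(ch$labels)
    for (k in seq_along(ch$labels)) {
      if (k > 1 && ch$relations[k - 1] != "=") v <- v - 1
      val[k] <- v
    }
    data.frame(mutation = paste0("p.", t2$wt[i], t2$position[i], ch$labels),
               tool = "structural_as_scores", score = val,
               stringsAsFactors = FALSE)
  })
  pc <- predictor_compatibility(do.call(rbind, rows), groups, chains)
  expect_equal(pc$percent, 73)

  # identical scores everywhere: only groups whose clinical chain makes no
  # strict claim (relations all "=" or ">=") can be concordant
  flat <- data.frame(mutation = subs$label, tool = "flat", score = 1)
  pc0 <- predictor_compatibility(flat, groups, chains)
  n_weak <- sum(vapply(chains, function(ch) all(ch$relations %in% c("=", ">=")),
                       logical(1)))
  expect_equal(pc0$n_concordant, n_weak)
  expect_equal(pc0$percent, floor(100 * n_weak / length(chains) + 0.5))

  # toy: one concordant group, one reversed -> 50%
  toy_groups <- group_by_position(mutation_catalog(
    c("p.Ala100Val", "p.Ala100Leu", "p.Gly200Ser", "p.Gly200Trp")))
  toy_chains <- list("100" = parse_chain("Val > Leu"),
                     "200" = parse_chain("Ser > Trp"))
  toy_scores <- data.frame(
    mutation = c("p.Ala100Val", "p.Ala100Leu", "p.Gly200Ser", "p.Gly200Trp"),
    tool = "toy", score = c(2, 1, 1, 2))
  expect_equal(predictor_compatibility(toy_scores, toy_groups, toy_chains)$percent, 50)

  # missing scores are an error naming the mutation
  expect_error(predictor_compatibility(flat[-1, ], groups, chains),
               flat$mutation[1], fixed = TRUE)
})
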