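#!/usr/bin/env Rscript
# Stage 1: run the bundled genotype-phenotype analysis end to end.
#
# Parses the 26-mutation GTPase-domain catalogue, scores the clinical
# records on the internal severity scale, derives the per-position
# clinical severity chains and compares them against the bundled
# structural-impairment chains. Writes the per-stage tables to results/.

library(mfn2sev)

dir.create("results", showWarnings = FALSE)

rep <- run_paper_reproduction()
print(rep)

write.csv(rep$groups, "results/groups.csv", row.names = FALSE)
write.csv(rep$scores, "results/scores.csv", row.names = FALSE)
ct <- comparison_table(rep)
write.csv(ct, "results/comparisons.csv", row.names = FALSE)
jsonlite::write_json(
  list(counts = as.list(rep$counts), summary = unclass(rep$summary)),
  "results/summary.json", auto_unbox = TRUE, digits = NA)

cat("\nPer-group comparison:\n")
print(ct)

cat(sprintf(
  "\nFindings: %d missense records group into %d positions; the derived\n",
  rep$counts[["n_grouped"]], rep$counts[["n_groups"]]),
  sprintf(
  "clinical chains agree fully with the structural orderings in %d/%d groups\n",
  rep$summary$n_concordant, rep$summary$n_groups),
  sprintf(
  "(%d%% agreement); the remaining %d groups (positions %s) disagree only\n",
  rep$summary$agreement_percent, rep$summary$n_partial,
  paste(ct$position[ct$status == "partial"], collapse = ", ")),
  "in strictness, never in rank order.\n")
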