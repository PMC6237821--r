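#!/usr/bin/env Rscript
# Stage 3: static structure-interaction evidence. Builds idealized
# coordinate fixtures for the curated interaction narratives — the
# Trp104-Trp104 stacking contact across the dimer interface, the
# His165-Glu268 dimer salt bridge and its loss in the Leu165 variant,
# and the six-pair closure network — then runs the geometric detectors
# and the mechanism classification. Writes edge tables to results/.

library(mfn2sev)

dir.create("results", showWarnings = FALSE)

# mutant dimer interface: Trp104 of two subunits stack
trp <- gen_structure_fixture(placement("stacking", c("Trp", "A", 104),
                                       c("Trp", "B", 104), distance = 4.0))
stack_edges <- detect_stacking(trp$structure)
cat("Trp104-Trp104 dimer contact:\n"); print(stack_edges)

# dimer tightening contact His165-Glu268, lost on substitution to Leu
wild <- gen_structure_fixture(placement("salt_bridge", c("His", "A", 165),
                                        c("Glu", "A", 268), distance = 3.5))
mut <- gen_structure_fixture(placement("pair", c("Leu", "A", 165),
                                       c("Glu", "A", 268), distance = 3.5))
d <- diff_profiles(wild$structure, mut$structure, "A", 165)
cat("\nHis165Leu interaction diff: lost", nrow(d$lost), "edge(s), gained",
    nrow(d$gained), "\n")
print(d$lost)

# closure network: all six pairs in contact, then Asp210 -> Tyr
cp <- closure_pairs()
mk <- function(i, tyr210 = FALSE) {
  pa <- strsplit(as.character(cp$pos_a[i]), ";")[[1]][1]
  ca <- strsplit(as.character(cp$code_a[i]), ";")[[1]][1]
  if (tyr210 && pa == "210") {
    return(placement("pair", c("Tyr", "A", pa), c(cp$code_b[i], "A", cp$pos_b[i]),
                     distance = 3.2))
  }
  placement("salt_bridge", c(ca, "A", pa), c(cp$code_b[i], "A", cp$pos_b[i]),
            distance = 3.2)
}
closed <- check_closure_network(gen_structure_fixture(lapply(1:6, mk))$structure)
tyr <- check_closure_network(
  gen_structure_fixture(lapply(1:6, mk, tyr210 = TRUE))$structure)
cat("\nClosure network, wild-type geometry:\n"); print(closed)
cat("\nClosure network with Tyr at 210 (carboxylate lost):\n"); print(tyr)

# mechanism classification of the analyzed positions
mech <- classify_mechanism(mechanism_map()$position)
cat("\nMechanism categories:\n"); print(table(mech$category))

write.csv(stack_edges, "results/stacking_edges.csv", row.names = FALSE)
write.csv(d$lost, "results/his165leu_lost_edges.csv", row.names = FALSE)
write.csv(closed, "results/closure_network_wt.csv", row.names = FALSE)
write.csv(tyr, "results/closure_network_tyr210.csv", row.names = FALSE)
write.csv(mech, "results/mechanism_classification.csv", row.names = FALSE)

cat(sprintf("\nFindings: %d/6 closure pairs present in the wild-type geometry;\n",
            sum(closed$present)),
    sprintf("the Tyr210 variant loses the Asp210-Arg476 contact (%d/6 remain).\n",
            sum(tyr$present)))
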