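# mfn2sev

Genotype–phenotype analysis of missense mutations in the GTPase domain of
mitofusin 2 (*MFN2*), the gene mutated in Charcot-Marie-Tooth disease type
2A (CMT2A). The package is written for neurogenetics and structural-biology
researchers who need to compare the clinical severity of different amino-acid
substitutions at the same residue position, and to ask whether that ordering
matches a ranking of predicted structural impairment.

The pipeline has four parts:

1. **Catalogue** — parse HGVS-style protein changes (`p.Arg274Trp`), filter
   to the GTPase domain (residues 95–339, inclusive), apply a curated
   exclusion list, and group substitutions by residue position, keeping
   positions with ≥ 2 distinct substitutions.
2. **Severity scoring** — a rule-based additive scale over structured
   clinical records: an onset base term (early < 6 y: 1.5; classical
   6–20 y: 1; late > 20 y: 0.5) plus major features (pyramidal signs 2,
   mild pyramidal signs 1.5, sudden visual loss 1.5, optic atrophy 1,
   mental retardation 1, wheelchair dependency 1, subcortical MRI lesions
   0.5) plus 0.5 per distinct minor symptom. Ambiguous onset gives an
   interval score.
3. **Ordering and concordance** — per position, substitutions are ranked
   into a chain (`Asp > Arg > Leu = Tyr`) by decreasing score midpoint;
   the chain is compared against a structural-impairment chain. Groups are
   `concordant`, `partial` (strictness-only mismatch) or `discordant`
   (rank reversal); only fully concordant groups count toward the agreement
   percentage.
4. **Static structure analysis** — salt-bridge, aromatic-stacking and
   hydrophobic-contact detectors over PDB coordinates, a curated
   closure-pair audit and a mechanism map for the analyzed positions.

Seed-controlled synthetic generators (`gen_catalog`, `gen_cohort`,
`gen_structure_fixture`, `gen_concordance_scenario`) produce inputs with
known truth for every stage.

## Worked example

```r
library(mfn2sev)
rep <- run_paper_reproduction()
print(rep)
#> <run_report> mfn2sev 0.1.0
#>   records: 26 in -> 26 in domain -> 26 after exclusions -> 26 in 11 groups
#>   concordance: 8/11 groups (73%), 3 partial, 0 discordant
head(comparison_table(rep), 5)
#>   position              clinical            structural     status n_mismatched
#> 1      104             Trp > Gln             Trp > Gln concordant            0
#> 2      127             Asp > Val             Asp > Val concordant            0
#> 3      165 Asp > Arg > Leu = Tyr Asp > Arg > Leu = Tyr concordant            0
#> 4      210             Tyr = Val             Tyr > Val    partial            1
#> 5      244            Leu >= Met             Leu = Met concordant            0
```

26 bundled missense records pass the domain filter and group into 11
positions. The rule-based scale scores each mutation (e.g. `p.His277Tyr`,
classical onset with pyramidal signs and vasomotor troubles, scores
1 + 2 + 0.5 = 3.5); the derived clinical chains agree fully with the
structural-impairment orderings in 8 of 11 groups (73%), and the three
mismatching groups (positions 210, 251, 277) differ only in strictness,
never in rank order.

Scoring a new patient record:

```r
r <- clinical_record("p.Asp210Val", onset_age = 1.5,
                     major = c("pyramidal_signs", "optic_atrophy"),
                     minor = c("cerebellar_ataxia", "hearing_impairment",
                               "cataracts", "learning_difficulties",
                               "mitochondrial_myopathy"))
score_record(r)
#> <severity_score> 7
```

## Analysis workflow

The `analysis/` directory holds the numbered drivers that produce the
tables under `results/`:

* `01_reproduce_severity_pipeline.R` — the end-to-end run above
  (`groups.csv`, `scores.csv`, `comparisons.csv`, `summary.json`);
* `02_synthetic_validation.R` — synthetic truth recovery for grouping,
  scoring and concordance;
* `03_structure_interactions.R` — interaction fixtures and detector runs
  for the curated structural narratives (Trp104 stacking, His165–Glu268
  loss, closure network, mechanism classification);
* `04_predictor_compatibility.R` — the generic predictor-compatibility
  comparison with a calibration pseudo-tool.

Run each with `Rscript analysis/<script>` from the repository root.

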