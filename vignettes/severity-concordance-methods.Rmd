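---
title: "Methods: clinical severity scoring and structural concordance for MFN2 GTPase-domain mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clinical severity scoring and structural concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfn2sev)
```

## The problem

Charcot-Marie-Tooth disease type 2A (CMT2A) is an autosomal dominant axonal
neuropathy caused by mutations in *MFN2*, the gene encoding mitofusin 2, an
outer-mitochondrial-membrane GTPase required for mitochondrial fusion. Most
reported missense mutations fall in the GTPase domain (residues 95–339 of
the structural model used by the bundled annotations), and patients carrying
different substitutions at the *same* residue position can present anywhere
from classical, adult-onset neuropathy to severe early-onset multisystem
mitochondrial disease. `mfn2sev` implements a desk-scale genotype–phenotype
pipeline around that observation: substitutions are compared only within
their own residue position, where the wild-type context is identical, and
the within-position clinical severity ranking is checked for concordance
against a within-position ranking of predicted structural impairment.

## The severity scale

Clinical reports of CMT2A patients come from many groups using incompatible
examination schemes, and the standard CMT neuropathy score (CMTNS) and
Functional Disability Scale are reported for too few patients and do not
capture the multisystem, mitochondrial character of the severe phenotypes.
The pipeline therefore uses a rule-based additive scale over structured
clinical records. A record's score is

* an **onset base term** — 1.5 points for early onset (before age 6),
  1 point for classical onset (6–20 years), 0.5 for late onset (after 20);
* plus **major features** — pyramidal signs or extensor plantar responses
  (2), mild pyramidal signs (1.5), sudden visual loss (1.5), optic-nerve
  atrophy (1), mental retardation or developmental delay (1), wheelchair
  dependency (1), subcortical MRI lesions (0.5);
* plus **0.5 per distinct minor symptom** (hearing impairment/deafness,
  sensorineural hearing loss, cerebellar ataxia, vasomotor troubles,
  tremor, cataracts, learning difficulties, mitochondrial myopathy,
  microcephaly, periventricular leukomalacia, proximal weakness, markedly
  reduced motor-nerve conduction velocity), with no cap — the most severe
  bundled record accumulates five such terms.

When a report leaves the onset category ambiguous ("early or classical"),
the record carries both alternatives and the score is the interval spanned
by them; five of the 26 bundled mutations have interval scores. Two
conventions close gaps in the scale as stated: the early/classical
boundary is taken as *onset before age 6* (the verbal definitions leave age
5–6 unassigned, and no bundled case distinguishes them), and a confirmed
asymptomatic carrier scores 0 through an explicit flag rather than through
an onset term. The bundled vocabulary also contains a generic `other_minor`
token for a minor symptom reported without identity. Scores attach to
mutations, aggregated over patients: when several records describe one
mutation, the interval hull is reported.

```{r scale-example}
score_record(clinical_record("p.His277Tyr", onset_categories = "classical",
                             major = "pyramidal_signs",
                             minor = "vasomotor_troubles"))
```

## Ordering chains and the concordance rule

Within each residue position carrying at least two distinct substitutions,
the alternatives are ranked into a chain such as `Asp > Arg > Leu = Tyr`,
with relations from `>`, `>=` and `=`. The clinical chain is derived from
the score intervals: alternatives sort by decreasing interval midpoint
(midpoint ties break alphabetically and become `=`), and an adjacent pair
of *point* scores exactly 0.5 apart is written `>=` while any gap involving
an interval stays `>`. This derivation rule is inferred, not stated, by the
source material; it is the unique simple rule we found that reproduces all
11 bundled clinical chains, including the pair that is otherwise
inconsistent (a 0.5 gap between two point scores prints as `Leu >= Cys`,
while the same midpoint gap between two intervals prints as `Trp > Gln`).

The structural chains rank the same substitutions by predicted structural
impairment. They summarise molecular-dynamics severity judgements that this
package deliberately does not recompute — they are consumed as annotations,
and the static interaction detectors below provide supporting evidence
only.

Comparison walks the adjacent pairs of the clinical chain and looks up the
relation the structural chain implies for the same two labels (relations
compose along the chain: any `>` on the path makes it strict). A pair
matches if the relations are equal, or if the clinical relation is `>=`
and the structural one is `>` or `=` — the weak clinical claim subsumes
both. A `>`-versus-`=` disagreement in either direction makes the group
*partial* ("incomplete but not discordant"); an order reversal makes it
*discordant*. Only fully concordant groups enter the agreement numerator,
and the percentage is rounded half-up, so the bundled comparison yields
8/11 = 73% with partial groups at positions 210, 251 and 277 and no
discordant group.

```{r concordance}
rep <- run_paper_reproduction()
rep$summary
```

The same rule drives the generic predictor-compatibility operation: an
external tool's per-mutation scores are ranked within each group (exact
ties give `=`, otherwise `>`) and compared against the clinical chains.
The procedure is methodology-dependent — tools rank variants genome-wide,
not within positions — so its output should be read as compatibility, not
accuracy.

## Static structure analysis

The structural module is a coordinate-based surrogate for interaction
analysis of modelled structures: it never runs dynamics, docking or
homology modelling. Three detectors operate on PDB coordinates (read
through `bio3d`, first model only, insertion codes rejected, alternate
locations resolved by occupancy then altloc `A`):

* **salt bridges** — minimum distance between Asp/Glu carboxylate oxygens
  and Arg/Lys/His side-chain nitrogens at or below 4.0 Å. Histidine is
  treated as protonatable (cationic), an approximation needed because the
  curated dimer contacts involve His165/His168;
* **aromatic stacking** — ring-centroid distance at or below 5.5 Å with
  interplanar angle at most 30° (parallel stacking); Trp uses its
  six-membered-ring centroid. Plane normals come from an SVD of the
  centered ring coordinates;
* **hydrophobic contacts** — side-chain carbon pairs of apolar residues
  (Ala, Val, Leu, Ile, Met, Pro, Phe, Trp) within 4.5 Å, collapsed to one
  edge per residue pair.

The cutoffs are not dictated by the source analysis; they follow common
structural-biology practice, are arguments on every detector, and enlarging
any cutoff can only add edges (a tested invariant, along with rigid-motion
invariance and exact agreement with exhaustive-scan oracles). Hydrogen
bonds are only represented implicitly: models carry no hydrogens, so a
heavy-atom distance proxy would duplicate the salt-bridge and hydrophobic
criteria, and no separate detector is exposed.

Two curated maps accompany the detectors: the *mechanism map* assigning
the 11 analyzed positions to the fusion step their mutations impair
(1 GTP-site rearrangement, 5 dimerization, 1 hydrolysis, 2 closure,
2 unknown), and the *closure pair set* of six long-range electrostatic
contacts holding the closed conformation, one of which (Arg564) accepts
either of two acidic partners. `check_closure_network()` audits those pairs
in any structure, and `diff_profiles()` reports interactions lost or gained
at a mutated position between two structures sharing numbering.

## Synthetic data

Every pipeline input can be generated with seed-controlled synthetic
modules, so all round-trip guarantees are testable without downloads:

* `gen_catalog()` draws per-position substitution groups (defaults: 11
  group positions, 2–4 substitutions each, inside residues 95–339 —
  mirroring the bundled catalogue's layout);
* `gen_cohort()` composes, for each mutation, a clinical record whose
  score equals a drawn target exactly. Composition is greedy and
  deterministic (largest feasible onset base, then majors in decreasing
  point order, then 0.5-point minors), which keeps goldens reproducible;
  targets default to the 0.5–7 range the bundled scores span;
* `gen_structure_fixture()` places idealized side chains at exact
  distances and orientations, each placement in its own region 25 Å from
  the next, writing valid PDB files whose re-read coordinates match to the
  format's 3-decimal precision. Side-chain geometry uses approximate bond
  lengths with no backbone realism beyond a 1.5 Å clash check — the
  detectors only consume atom positions;
* `gen_concordance_scenario()` perturbs structural chains into clinical
  ones with known comparison status (identity, one strictness flip, or
  one adjacent swap across a strict relation).

What the generators do *not* emulate: correlated symptom co-occurrence,
reporting noise, real backbone geometry, or crystallographic artefacts.
Passing round-trips therefore demonstrate internal consistency of the
scoring/ordering/detection rules, not robustness to messy real-world
records or experimental structures.

## Numerical choices and edge cases

* Scores are multiples of 0.5; interval arithmetic is exact in doubles.
* Chain derivation breaks midpoint ties alphabetically *before* assigning
  `=`, making the output deterministic.
* The agreement percentage rounds half-up (72.7 → 73).
* Degenerate inputs: an empty catalogue yields an empty report with a
  notice; positions with a single substitution are dropped and logged;
  conflicting wild-type residues at one position are an error; duplicate
  catalogue records de-duplicate with a warning.
* Problem sizes in the test suite (1,000 random catalogues, 1,000 chain
  round-trips, 10–20 random structures of 12–15 residues, 500+ synthetic
  clinical records) keep the whole suite around half a minute on one CPU
  while exercising every code path.

## Known limitations

The 68 → 26 mutation reduction from the original database search is not
reproducible from bundled data and is not attempted; the catalogue starts
from the curated 26. The structural severity orderings are inputs, not
outputs — reproducing them would require molecular dynamics on full-length
models, which is out of scope. The exact computation behind published
predictor-compatibility percentages is not described in the source
material; only the generic within-position comparison is provided, and a
calibration pseudo-tool (structural orderings encoded as scores) is used
to pin its behaviour. Whether markedly reduced motor NCV is always a minor
feature is unresolved; the bundled vocabulary treats it as minor.
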