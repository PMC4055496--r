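---
title: "Authenticating whitefish products with dual DNA assays: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Authenticating whitefish products with dual DNA assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Retail fish products — fillets, breaded portions, fish fingers, pre-cooked
meals, fishcakes — carry a species name on the label but rarely any
morphology by which to check it. `fishaudit` implements the two standard
molecular routes for auditing such labels and the bookkeeping for turning
per-sample results into defensible mislabelling rates: species-specific
real-time PCR (cod, *Gadus morhua*, and haddock, *Melanogrammus aeglefinus*,
the two dominant whitefish species in the UK market) and COI barcode
sequencing against a species-labelled reference panel. This vignette
explains the statistical model of each stage, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the design
choices made where the methodology left room.

## 1. Endpoint real-time PCR calling

Each 96-well plate carries both TaqMan probes in every reaction, read on two
dye layers (one reporting the cod probe, one the haddock probe), eight
no-template controls (NTCs) and two positive controls per target species.
Rather than estimating Ct values, positivity is decided on the endpoint
(cycle 40) baseline-corrected fluorescence ΔRn. For each plate and dye
layer the NTC endpoints give a background distribution with mean `M` and
standard deviation `SD`, and the positivity threshold is

```
z*M = M + 3.89 * SD + C
```

`3.89` is the one-tailed normal quantile for 99.999% confidence: a well
without template should exceed `M + 3.89*SD` with probability 1e-5. It is
stored as a literal constant, not recomputed from `qnorm()`, so the
statistic matches the published formula digit for digit. `C` (default 0.3
ΔRn units) is a constant guard band absorbing spectral bleed-through —
the small fluorescence increase a non-amplifying well shows when the other
dye layer in the same well amplifies strongly. A sample is positive on a
dye iff its endpoint is **strictly** greater than `z*M`; a tie is negative
("larger than" taken literally). The two probe calls combine into exactly
one of four categories: `COD`, `HADDOCK`, `INCONCLUSIVE` (both probes
amplified — typical of mixed-composition products), `NEGATIVE` (neither —
the sample is some other species, not an assay failure).

Thresholds are computed within each plate and dye layer, never pooled:
background fluorescence varies between runs, and pooling would let a noisy
plate contaminate its neighbours' thresholds. A plate passes QC iff it has
at least 8 NTC wells, every positive control calls positive against its own
dye's threshold, and no NTC calls positive; samples on a failing plate are
marked `UNRESOLVED` rather than silently dropped. Useful properties (both
tested): `z*M` is strictly increasing in `M`, `SD` and `C`, and rescaling
all fluorescence values and `C` by a common factor preserves every call.

The qPCR calls corroborate; they never decide a verdict. Sequencing is
authoritative (section 3), because the probes only answer "cod?"/"haddock?"
while the barcode identifies any species in the panel.

## 2. Pairwise alignment and the identity score

COI barcode identification needs a percent identity between a query
amplicon (~655 bp of the 5' COI region) and each reference. The package
aligns semi-globally (global alignment with free end gaps), scoring match
+1, mismatch −1, gap column −2, so that a query sequenced slightly short or
long is not penalised at its ends. Identity is

> matched columns / aligned columns, excluding terminal-gap columns;
> internal gap columns count as mismatches; `N` matches nothing.

This definition suits fixed-region amplicons: the aligned span is the
shared barcode window, end overhangs carry no information, and an internal
indel in a coding mitochondrial gene is either a real frameshift or a
sequencing artefact — both evidence against identity. Tie-breaking is
deterministic (substitution preferred over gap, fixed gap order, earliest
optimal end cell), so identical inputs give byte-identical alignments. The
DP kernel is compiled (Rcpp) with the row recurrence split so the
diagonal/up phase vectorises; scores live comfortably in 16-bit integers.
Queries are checked in both orientations: a cheap ungapped prescreen picks
the orientation (the reverse complement of a COI amplicon scores near
random, ~25% identity, so the margin is enormous), then one full alignment
pass runs on the chosen orientation.

## 3. Species assignment, congener groups, mixtures

`assign_species()` scans the whole panel — deliberately brute force, no
seeding or k-mer heuristics, so the result is exactly what the identity
definition implies (a property the tests enforce against an independent
oracle). The decision rule:

* best identity ≥ 0.995 and one winning group → `UNAMBIGUOUS`;
* references from different groups tied at the best identity →
  `AMBIGUOUS_GROUP` (the union of tied groups is reported);
* best identity < 0.995 → `BELOW_THRESHOLD`.

The 99.5% acceptance threshold is the barcoding convention for gadoids,
where interspecific COI divergence exceeds 2% except for two congener pairs
with **identical** COI haplotypes: Pacific/Greenland cod
(*G. macrocephalus* / *G. ogac*) and Alaskan/Norwegian pollock
(*G. chalcogrammus* / *G. finnmarchica*). These pairs are unassignable at
COI by construction, so the panel groups them and every identification is
reported at group level. The threshold is inclusive at exactly 0.995: the
historic sub-threshold identifications sat at 99.49% and 98.6%, both
strictly below, so inclusivity is unconstrained by data; we include the
boundary and document it.

**Mixed-composition detection.** A minced or pressed product can contain
two species. Two signatures arise, and both are implemented:

1. *Replicate disagreement*: independent re-extractions of the product pull
   different species. `reconcile_replicates()` returns `MIXED` whenever the
   two replicate groups differ.
2. *Sub-threshold mosaic*: the Sanger consensus of a two-species template is
   a mosaic whose best hit falls below 99.5%. Divergence from sequencing
   noise alone leaves the best species' nearest relative (its *sister*) as
   runner-up; a genuine mosaic pulls the contaminant — a non-sister — into
   second place. `detect_mixed()` therefore flags a query iff it is
   `BELOW_THRESHOLD` **and** the runner-up's group differs from the sister's
   group. The sister map is explicit configuration (derived once from panel
   distances, overridable), not read off the NJ tree, so the rule is
   deterministic and testable in isolation. The comparison is at group
   level because congeners are byte-identical, making the species-level
   runner-up among tied congeners arbitrary.

A `MIXED` reconciliation always counts as mislabelled — a product sold as
one species that contains another is misdescribed whichever component
matches the label.

## 4. Distance trees

`neighbor_joining()` is a from-scratch Saitou–Nei implementation: join the
pair minimising `Q_ij = (n−2) d_ij − r_i − r_j`, with ties broken by
lexicographic label order (a merged cluster inherits its smaller label), so
the topology is deterministic and invariant to input order. Negative branch
lengths are clamped to zero. For additive matrices the tree reproduces the
input distances exactly — the tests verify this on hundreds of random trees
and cross-check the topology against an independent implementation.

The default distance is Kimura 2-parameter,
`d = −½ ln((1 − 2P − Q) √(1 − 2Q))` with `P`/`Q` the transition/
transversion fractions (sites with `N` or gaps excluded pairwise), the
convention in barcoding software; p-distance is selectable. Saturation
(non-positive log argument) raises an error naming the pair rather than
returning `NaN`.

`bootstrap_support()` resamples alignment columns with replacement,
rebuilds the tree per replicate (1000 replicates by default), and maps onto
each internal edge of the full-data tree the percentage of replicates
containing that bipartition — the supports-on-full-tree convention, not a
consensus tree. Replicates whose distance matrix is undefined are skipped
and counted. Internally taxa are sorted alphabetically, making supports
independent of input order; column classes per pair are precomputed so each
replicate's distance matrix is three matrix–vector products.

## 5. Concordance and stratified rates

A congruence rule table maps (label, declared catch area) to acceptable
genetic groups. The default table encodes the accounting a label audit
needs: a generic "Cod" accepts either cod species; "Cod" declared Atlantic
must be *G. morhua* — a Pacific-cod identification in an Atlantic-labelled
product cannot be a catch error (the species live in different oceans) and
counts as mislabelled; haddock, Alaskan pollack, hake (*M. capensis*) and
whiting map to their single groups. Verdicts are `CORRECT`, `MISLABELLED`
(reason: substitution / mixed / ambiguous) or `UNRESOLVED` (no DNA result;
excluded from rate denominators). An ambiguous, non-mixed multi-group
identification is correct only if every tied group is acceptable — with the
congener pairs already grouped this case is essentially theoretical.

`summarize_mislabelling()` reports counts and percentages overall, per
label (cod split by declared area), per processing level (1 fresh/frozen
fillet … 5 fishcake) and for the recurring substitution patterns. Raw
fractions are retained; display rounds half-up to two decimals. The
package ships a transcription of the mislabelled-product records of a
386-sample UK supermarket survey (21 mislabelled of 371 DNA-analysable;
checksummed at load) with its stratum denominators, so the full rate table
is reproducible offline — `audit_survey_fixture()` recomputes it from the
per-sample records through the same verdict machinery used for synthetic
studies. Two published inconsistencies are preserved rather than repaired:
the printed DNA-success share (97.4%) does not match 371/386, and the
fish-finger/pre-cooked stratum counts cannot be reconciled exactly with the
per-row product types; the loader flags the former, and the tests pin only
the strata whose arithmetic closes.

`excess_landings()` is the policy-facing extrapolation: if a fraction `r`
of products labelled as species A are in fact species B, and the reference
landings of A are `L` tonnes, then `r·L` tonnes of B are being landed and
recorded as A, optionally expressed against the stock's quota (TAC).
Reference landings and quota are user inputs.

## 6. The synthetic-data generator

Every stage must be testable offline, so the generator produces studies
whose ground truth is known. Its defaults are the study conditions the
package is calibrated to: 371 analysable samples; label mix cod 179 (57
Atlantic-declared, 20 Pacific, 102 unspecified), haddock 155, Alaskan
pollack 32, hake 4, whiting 1; processing levels 84/84/31/128/44; planted
substitutions (Atlantic cod→Pacific cod 6/57, generic cod→haddock 1/102,
haddock→cod 6/155, haddock→Pacific cod 1/155, hake→*M. paradoxus* 1/4,
whiting→blue whiting 1/1) plus a 5/371 chimera fraction, for an expected
overall mislabelling of 21/371 = 5.66%.

**Reference panel.** Eleven gadoid-plus-outgroup species with pairwise
p-distance targets taken from a fixed guide tree (congeners at exactly 0;
all cross-group pairs > 2%; the haddock lineage sister to whiting; hakes
and the pangasiid catfish progressively further out). Sequences are built
by fitting an NJ tree to the target matrix and planting *disjoint* mutated
site sets on each branch, so realized p-distances add exactly along paths
and land within ±0.005 of every target; triangle violations and
non-additive target sets are rejected with a diagnostic. Substitutions are
uniform across sites and bases — no transition bias, no rate heterogeneity
— which is the simplest model consistent with p-distance targets (a
K2P-aware simulator would change nothing the identity classifier sees).

**Queries.** Two replicates per sample (independent re-extractions), each
with independent per-base substitution error (default 0.002, about 1.3
errors per 655 bp read — Sanger-consensus scale). Chimeric samples use the
two modes of section 3; a mosaic's contaminant block is 20–50% of sites.
Mosaic mode is only planted when the runner-up rule could in principle flag
it (contaminant group ≠ sister group, enough minor signal at the smallest
block fraction, margin 0.005 for noise); geometrically undetectable
mixtures are planted as replicate disagreement, the mode such mixtures
surface as in real data.

**Plates.** Wells amplify iff the template contains the dye's target
species, following a logistic sigmoid `ΔRn(c) = A/(1+exp(−(c−c50)/k))`
with defaults `A = 3`, `c50 = 25`, `k = 1.5` (plateau well before cycle
40); non-amplifying wells sit at the bleed offset (0.05) with per-cycle
Gaussian noise (sd 0.02). No raw ΔRn magnitudes are published for this
assay family, so the fluorescence scale is free; what matters for the
calling logic is the separation `A ≫ z*M`, which these defaults provide
(~19 noise SDs). Real plates fail in ways this model does not emulate —
drift, evaporation edges, partial inhibition producing late sigmoids —
so passing tests demonstrate the calling logic, not robustness to every
laboratory pathology.

**What passing tests show.** On these synthetics the pipeline recovers
planted rates (estimate inside the exact binomial 95% CI of the planted
rate in ≥ 93/100 seeded studies), detects ≥ 95% of chimeras with no false
`MIXED` calls at error ≤ 0.003, and keeps qPCR probe error rates below 1%.
Real data add intraspecific haplotype variation, indels/length variation
from primer slippage, heteroplasmy and reference-database error, none of
which are simulated; the identity threshold and sister-map rules are
exactly the knobs one would retune against such data.

**Determinism.** One master seed; each component (panel, metadata, queries,
plates) draws its own child stream, so identical config + seed gives
byte-identical studies, and `run_pipeline()` reruns are byte-identical
(checksums recorded in a manifest).

## 7. Numerical choices and problem sizes

* Ties at the identity maximum are exact double comparisons — identities
  are ratios of small integers, so congener ties are exact, not
  tolerance-based.
* NJ Q-criterion ties use a 1e-12 absolute tolerance before the
  lexicographic rule; branch lengths are clamped at 0; Newick is written at
  17 significant digits so round-trips through `ape` preserve path lengths
  to ~1e-12.
* `z*M` uses the sample standard deviation (n−1); at least two NTCs are
  required, eight expected.
* Degenerate inputs: empty studies produce empty, valid outputs; an
  alignment with no non-terminal columns (disjoint sequences) errors on
  identity rather than returning 0/0; K2P saturation errors, naming the
  pair.
* Test-suite problem sizes: alignment oracle up to length 7 by exhaustive
  enumeration; classifier oracle on 50-reference panels; NJ on 200 random
  additive matrices of ≤ 12 taxa; parameter recovery on 100 seeded studies
  of n = 371; sensitivity/specificity on 200 chimeric plus 200 clean
  samples. Bootstrap defaults to 1000 replicates in `run_pipeline()`;
  tests and the acceptance script use fewer (25–200), which is ample for
  the split geometries they assert.

## 8. Known limitations

* Identity is computed against a local panel; BOLD-style database search
  semantics (best-hit windows, intraspecific clouds) are out of scope.
* The sister map is static configuration; on a panel where the true nearest
  relative is absent, mixture detection degrades to replicate disagreement.
* The generator's label mix, substitution matrix and chimera behaviour are
  point estimates of one survey design; the rate-recovery guarantees are
  statements about that design, not about arbitrary surveys.
* No Ct estimation, amplification-efficiency or melt-curve modelling: the
  endpoint statistic is the method, by design.
* Mixed products are detected, not quantified; relative abundance of the
  two components needs a quantitative assay and is not attempted.
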