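---
title: "Methods: inferring rhodopsin gene-family duplication and loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring rhodopsin gene-family duplication and loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhodup)
```

## The inference problem

Teleost fishes carry a fish-specific, intron-less rod opsin gene (*rh1*),
and a second intron-less copy has been found in several lineages: the
"deep-sea" and "freshwater" paralogs (*rh1-dso*, *rh1-fwo*) of eels and
relatives (Elopomorpha), two copies in *Hiodon* (Osteoglossomorpha), and the
*rh1-A*/*rh1-B* pair of some clupeocephalans. Whether these copies arose
once — at the fish-specific genome duplication (FSGD) on the teleost stem —
or repeatedly in individual lineages is a gene tree / species tree
reconciliation question. rhodup implements the full inference chain:

1. codon-position base-composition diagnostics and third-position
   RY-recoding of the nucleotide matrix;
2. a GTR+Γ maximum-likelihood engine (Felsenstein pruning with IUPAC
   ambiguity, discrete gamma rates, coordinate-ascent optimisation);
3. constrained topology search and nonparametric bootstrap;
4. RELL multiscale bootstrap and the approximately unbiased (AU) test over
   a candidate set of constrained best trees;
5. LCA reconciliation with duplication and loss counting;
6. Fitch parsimony ancestral-state reconstruction of opsin gene characters;
7. key-site comparison of paralog pairs in bovine rhodopsin numbering;

together with a synthetic gene-family generator so that every stage is
testable without sequence downloads.

## Duplication/loss hypotheses

Twelve scenarios (`A1`–`C4`) describe where the duplications sit relative to
the divergences of the three major teleost lineages. Family A places three
duplications, family B two, family C one (the FSGD itself):

* **A1** — independent duplications in the ancestors of the Elopomorpha,
  Osteoglossomorpha and Clupeocephala; **A2** moves the elopomorph
  duplication onto the teleost stem.
* **B1/B2** — one elopomorph duplication plus one in the ancestor of
  Osteoglossomorpha + Clupeocephala; **B3/B4** — teleost stem plus
  Osteoglossomorpha + Clupeocephala ancestor; **B5/B6** — teleost stem plus
  Clupeocephala ancestor.
* **C1–C4** — a single duplication on the teleost stem.

Each scenario is encoded as a rooted lineage-level topology over seven gene
lineage tags (`Elops_dso`, `Elops_fwo`, `Hiodon_rh1_1`, `Hiodon_rh1_2`,
`Osteo_rh1`, `Clupeo_rh1_A`, `Clupeo_rh1_B`). The within-family variants
differ in which observed lineage tracks which duplicate copy. The
duplication placements, the observed lineage content and the B6 pairing
(*Elops rh1-dso* groups with *Hiodon rh1-2*, matching the empirically
supported gene tree) pin down most of the set; the remaining variant
pairings are not uniquely determined, so we enumerate them systematically:
within B1/B2 and B3/B4 the two clupeocephalan copies swap partners, within
B5/B6 the two elopomorph paralogs swap, and C1–C4 cross both choices. Every
topology in a family reconciles to the same duplication count, so these
assignments do not affect any counted quantity.

Scenario-implied copy absences are part of the scenario definition: for B6,
for example, the older paralog survives only in the Elopomorpha and
*Hiodon*, implying exactly two losses (non-*Hiodon* osteoglossomorphs;
Clupeocephala stem). `lca_reconcile()` recovers these counts from the
realised gene trees, and `simulate_gene_tree()` records them as ground
truth.

## The synthetic gene-family generator

`simulate_gene_tree()` grafts the scenario's lineage topology onto a species
tree: speciation nodes take the species-tree node heights, each duplication
sits at the midpoint of its designated species branch (the scenarios specify
only the branch, not a position), and each lineage tag expands into the full
species subtree of its carrier group. Additional, user-specified losses
prune whole clades from one copy; the relative timing of losses within a
scenario is not specified by the hypotheses, so loss branches are an input
rather than a guess. A loss that would empty a gene lineage entirely is
rejected, because the scenario's duplication count would no longer be
observable. Post-duplication branches can be scaled by a rate multiplier
(default 1: paralogs keep the species-tree rate, as nothing in the
hypotheses specifies a paralog-specific rate model).

`simulate_alignment()` evolves sites independently under GTR+Γ with exact
transition probabilities. Defaults emulate an rh1-like in-frame coding
fragment: 996 columns, transition-rich exchangeabilities
(AC, AG, AT, CG, CT, GT = 1.5, 4, 1, 1.2, 6, 1), slightly CT-rich base
frequencies (0.23, 0.28, 0.23, 0.26) and strong among-site rate variation
(gamma shape 0.4 with 4 categories) — values typical of vertebrate
rod-opsin coding sequence rather than fitted to any particular data set.
Two independent random streams are derived from the user seed so the tree
and the sequences can be varied independently; identical seeds give
byte-identical output.

The optional `third_position_freq_override` reproduces the phenomenon the
RY-recoding strategy targets: lineage-specific base-composition bias at the
(nearly saturated) third codon position. A stationary override shared by
every branch cannot produce *across-taxon* heterogeneity — which is what
the chi-squared homogeneity test measures — so the override drives
position-3 substitutions only on the branches of a designated taxon set
(all branches by default, which instead yields root-to-tip compositional
drift). With a strongly skewed override (e.g. 0.05/0.45/0.45/0.05) on one
clade, position 3 departs from homogeneity while positions 1–2 do not.

What the generator does **not** emulate: indels and alignment error (the
real matrix was aligned and trimmed by hand), codon structure beyond the
position-3 frequency override (no dN/dS), retrotransposition mechanics,
synteny, and base-composition drift at positions 1–2. Tests passing on
synthetic data therefore validate the inference machinery, not the
upstream curation of a real alignment.

## Likelihood engine

`site_log_likelihoods()` implements Felsenstein pruning over discrete gamma
categories. Numerical choices:

* The GTR rate matrix is scaled to one expected substitution per site at
  equilibrium; its π-symmetrised eigendecomposition gives exact
  `exp(Qt)` per branch and rate.
* Gamma discretisation uses means of equal-probability classes (the "+G"
  convention of the common ML tree programs), renormalised to mean 1.
* IUPAC ambiguity codes (and gaps, treated as fully missing) set the tip
  conditional likelihood to 1 on every compatible state. RY-recoded columns
  are therefore handled as ambiguities under the 4-state model — exactly how
  the standard ML software ingests R/Y characters — which is why recoding
  can only raise a site's likelihood (marginalisation adds non-negative
  terms); a property test asserts this dominance.
* Partial likelihoods are rescaled per pattern when they drift below
  1e-150, so deep trees do not underflow.
* Identical site patterns are collapsed and weighted; compression is exact.

`optimize_parameters()` uses coordinate ascent: bracketed univariate
optimisation of each branch length (clamped to [1e-8, 20]) interleaved with
Nelder–Mead steps on log-transformed exchangeabilities, frequencies and
gamma shape. The log-likelihood is non-decreasing across sweeps and
iteration stops when a sweep gains less than 1e-4 log units. Correctness is
pinned by three oracles: exhaustive ancestral-state enumeration on quartets,
invariance to re-rooting (reversibility), and the closed-form two-taxon
Jukes–Cantor distance.

`ml_search()` hill-climbs over NNI rearrangements (optional SPR with
regraft radius 3 — more is unnecessary at the ≤ 60-taxon scale this
package targets) from random-addition or neighbour-joining starts.
Constraint trees may be multifurcating; a move is rejected when any
constraint bipartition, restricted to shared taxa, disappears. Ties between
equally likely topologies are broken by lexicographic Newick order for
determinism. At the lineage scale used throughout (one representative per
lineage), the hypothesis constraints fully resolve the topology and the
search reduces to branch-length/model optimisation, which is also why the
hypothesis evaluation stays fast.

Whether model parameters should be re-optimised for every constrained tree
is not specified by the procedure this package re-implements; we re-optimise
per tree by default (`optimize_model = TRUE`), warm-starting from the first
fitted model, and expose a flag to share one model across trees.

## RELL and the AU test

`rell_bp()` resamples site log-likelihood sums (no re-optimisation) with
multinomial site weights; `round(n·r)` sites per replicate at scale `r`;
argmax credit is split equally among ties, which is unbiased under
exchangeability. `au_test()` computes bootstrap proportions BP at scales
0.5–1.4 (step 0.1; scale 1 always included, since the non-scaled
probability *np* is by definition the selection proportion at the original
length), transforms `z = Φ⁻¹(1 − BP)`, and fits `z ≈ d√r + c/√r` by
weighted least squares with delta-method binomial weights — WLS rather than
maximum likelihood because it is simple, reproducible and standard for this
test family. The AU p-value is `1 − Φ(d − c)`.

Scales where BP hit 0 or 1 carry no information about the signed distance
and curvature, so they are excluded from the fit; a tree whose BP is pinned
at 0 (or 1) at essentially every scale is assigned the clamp-implied bound
`1/(2B)` (or `1 − 1/(2B)`) and flagged `degenerate`. Under an exchangeable
null (two trees, mean-zero iid site differences, n = 100, B = 1000) the
test rejects at the nominal 5% level at an observed rate of about 4–5%
(500-simulation calibration, re-run by the acceptance script).

The package reports *au* and *np* side by side and applies no further
accept/reject policy beyond a configurable α: the two columns can disagree
(np is far more conservative for near-tied trees), and that disagreement is
part of the result, not something to resolve silently.

## Reconciliation and ancestral states

`lca_reconcile()` maps each gene node to the species-tree LCA of its
descendant species; a node is a duplication iff it maps where one of its
children maps, and losses follow the path-depth formula along each edge
(which automatically counts duplication-implied whole-clade absences).
Species absent from the alignment are pruned from the species tree first:
unsampled is not lost — the distinction between a gene loss event and
experimental failure is real at this locus, so the machinery never counts
missing taxa as losses. On trees of ≤ 6 leaves an exhaustive search over
all valid maps confirms that the LCA map attains the minimum duplication
and loss counts simultaneously.

`fitch_acr()` performs unordered equal-cost parsimony with '?' as the full
state set; copy number is treated as an unordered 3-state character (0/1/2)
under equal costs, the default of the parsimony tools this analysis class
uses. `count_gains()` reports the minimum, across all most-parsimonious
reconstructions, of branches inside a clade whose parent resolves to one
state and child to another — computed exactly by dynamic programming over
Pareto-optimal (changes, gains) pairs, so the claim "three independent
copy-number gains within the Teleostei" does not depend on an arbitrary
ACCTRAN/DELTRAN choice.

The packaged jawed-vertebrate backbone encodes only relationships stated in
the literature the character matrix summarises (Elopomorpha sister to the
remaining teleosts; Osteoglossomorpha sister to Clupeocephala); taxa whose
character states are not stated there are coded '?', and an invariant test
confirms all-missing taxa cannot change the reconstruction.

## Key sites

`map_to_bovine()` aligns a query protein globally (BLOSUM62, affine gaps
10/0.5, deterministic tie-breaking) against the packaged 348-residue bovine
rod opsin reference and excludes gapped columns from the coordinate map;
queries covering less than half of the key-site region (positions 83–317)
are flagged unmappable. `compare_paralog_key_sites()` reports the residue
pair at the twelve spectral-tuning sites plus site 210 (the V/C contrast
separating "deep-sea" from "freshwater" rhodopsins). Reproducing the
empirical five-variable-site result requires the study's GenBank
accessions, which this package deliberately does not download; the
machinery is exercised on constructed and simulated pairs instead.

## Problem sizes and reproducibility

All randomness flows from a single integer seed through deterministic
stream derivation; every simulation, search, bootstrap and AU test is
bit-for-bit reproducible under a fixed seed.

Desk-scale sizes used by the test-suite and the acceptance script, chosen
so the full chain demonstrates its statistical claims in minutes on one
core: quartet oracles at 21–50 sites; JC closed form at 4000 sites;
re-rooting at 300 sites; AU calibration with 500 simulations of 100 sites
at B = 1000; scenario recovery with 10 replicates of 2000 sites on the
compact (lineage-representative) species tree, evaluating all twelve
hypotheses with per-tree model re-optimisation and B = 1000 per AU scale.
Under those conditions B6-simulated data rank B6 first and leave it
unrejected by the AU test in ≥ 80% of replicates, while the losing
hypotheses are rejected by *np* — the same qualitative pattern the
hypothesis table of the motivating analysis shows at full scale. The
24-taxon species tree exercises multi-taxon lineage expansion,
user-specified losses, and orthology placement.

## Known limitations

* The ML search is a desk-scale NNI/SPR hill-climb, not a RAxML
  replacement; it is validated on ≤ 24 taxa.
* The AU implementation uses the WLS variant with fixed default scales;
  p-values for trees at the clamp are bounds, not estimates, and are
  flagged.
* Losses are counted under LCA parsimony; no event-cost optimisation
  (NOTUNG-style) is attempted.
* The generator's realism limits are listed above; in particular nothing in
  the synthetic data can validate manual alignment and trimming choices.
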