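---
title: "Mapping polysaccharide degradation potential: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping polysaccharide degradation potential: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CAZymap)
```

CAZymap asks a systems-level question about saprobic fungi such as
*Aspergillus niger*: given the structure of a plant polysaccharide, which
enzymatic activities are needed to take it apart completely, which genes
provide those activities, and does the transcriptome on a given carbon
source switch on a *complete* set of them? This vignette documents the
models behind each layer, the tunable parameters, the numerical choices,
and the limits of what the synthetic benchmarks can show.

## Structures as rooted residue trees

A polysaccharide is represented as a rooted tree: residues are nodes with
a monosaccharide code, ring size (six carbons for hexoses, five for the
pentoses arabinose and xylose — the polygon convention of the printed
schematics), an anomeric carbon (C1, or C2 for ketoses such as fructose,
so inulin's β-2,1 fructan chains are representable without special
cases), and ester/ether substituents (acetyl, methyl, feruloyl) held
separately from glycosidic linkages. The root is the reducing-end
residue; every linkage records the child's anomeric configuration and the
parent carbon, which yields display labels such as `Gal-α-1,6-Man`.

Choosing a tree (single parent per residue, `|E| = |V| − 1`, connected,
acyclic) is not a restriction in practice: all sixteen packaged types are
branch-decorated backbones. It buys a clean definition of the
*non-reducing ends* (the leaves), which is the direction exo-acting
glycosidases work in, and an O(n) validator that rejects cycles, dangling
ids, duplicate attachment carbons and substituent/linkage carbon
collisions by naming the offending record.

The sixteen packaged types are starch, cellulose, pullulan, inulin,
galactomannan, insoluble and soluble galactoglucomannan, smooth pectin,
xylogalacturonan, xylan, the two xyloglucan repeat types (XXGG and XXXG),
arabinogalactan types I and II, arabinan, and rhamnogalacturonan I.
Rhamnogalacturonan II is deliberately excluded: it is built largely from
rare, heavily modified sugars and there is no usable body of degradation
data for this organism. Printed schematics depict repeating units, not
molecules of fixed size, so each packaged file is a finite
*representative instance*: a backbone of 20 residues decorated by the
type's generator, using the first generator seed whose instance realizes
the full required-activity set of its type (a representative must display
every feature of its schematic; a draw that happens to miss, say, its
rare feruloylated side chain would under-state the activity demand).

### Parametric generators

Each type has a generator that draws decorations independently per
backbone residue. Where the literature states the composition of the
actual growth substrate, those numbers are the defaults:

* **Sugar-beet arabinan** — a 1,5-α-L-arabinan in which about 50% of
  backbone residues carry a single 1,2- or 1,3-linked arabinofuranose
  branch (`branch_prob = 0.5`, branch carbon chosen uniformly), and whose
  preparation contains arabinose:galactose:rhamnose:galacturonic acid at
  88:4:2:6. The non-arabinose share is modelled as a residual pectic core
  at the reducing end (a short galacturonan/rhamnose stem plus a galactan
  stub) with Poisson-drawn counts whose means are tied to the realized
  arabinose count, so the pooled ensemble composition converges to the
  stated ratios. This is also biologically consequential: the
  contaminating pectic residues are exactly why arabinan cultures induce
  pectinolytic enzymes.
* **Oat spelt xylan** — β-1,4 xylan with arabinofuranose branches
  (`ara_prob = 0.10`, on C2 or C3), 4-O-methyl-glucuronosyl branches
  (`glcA_prob = 0.08`), acetylation of free C3 positions
  (`acetyl_prob = 0.10`) and feruloylation of arabinosyl branches
  (`feruloyl_prob = 0.30`). The resulting ensembles are ~85% xylose,
  inside the "≥ 70% D-xylose" specification of the commercial substrate.
  The preparation's up-to-15% glucan content is a co-purified polymer,
  not part of the xylan molecule, and is not modelled.

Other structures default to their repeating-unit stoichiometry (e.g.
galactomannan with galactosyl branches on every other mannose, a
Man₃Glc backbone pattern for the galactoglucomannans arranged so two
glucoses are never adjacent, XXGG/XXXG substitution patterns for the
xyloglucans). All probabilities are per-residue Bernoulli draws; with a
fixed seed the output is byte-identical, and ensemble decoration
frequencies converge to the parameters at the usual √n rate.

## The activity registry and required-activity sets

The join between structures and enzymes is the *bond class*: (child
sugar, anomeric configuration, linkage carbons, parent sugar, and the
context backbone / branch point / within-side-chain), plus modification
classes such as `acetyl@Man`. The registry maps bond patterns to named
activities (EC numbers where they exist) in four modes: endo (interior
backbone cleavage), exo (non-reducing terminal release), debranching
(removal of single-residue side chains) and esterase. Matching is by
bond pattern, *not* CAZy family — one EC can span several families (GH5
and GH26 endomannanases) and one family several activities.

`requiredActivities()` is a pure function of the bond-class set: backbone
classes demand an endo activity and an exo activity for the releasable
child sugar, branch points a debranching activity, side-chain interior
linkages an exo activity, and each modification class an esterase. A
class with no registry template is reported in an `unmapped` attribute,
never dropped — silently shrinking the requirement would fake coverage
downstream. Isofunctional alternatives (glucoamylase and α-glucosidase
both release glucose from α-1,4 bonds) are both listed; "required" is
therefore the union of matching templates, while `minimalSufficientSets()`
answers the stricter question of which subsets actually suffice.

## Digestion as a monotone rule closure

Degradation is modelled as reachability, not kinetics. Four rules fire
until nothing changes: esterases remove matching substituents;
debranching activities remove unsubstituted single-residue side chains;
exo activities remove unsubstituted leaves whose linkage matches; endo
activities cleave a backbone linkage if both flanking residues were
interior in the *original* backbone and both are currently free of side
chains and substituents. Substituents block cleavage at the carrying
residue — the literature's activity tables list esterases and
debranching enzymes as required, and this blocking convention is what
makes that requirement operative in the model.

Anchoring the endo rule to original-backbone interiority (a static
property) makes every enabling condition monotone — removals only ever
enable further removals — so the closure is confluent and the result is
independent of rule order. The test suite verifies this directly by
replaying shuffled single-step schedules through an independent oracle.
A fragment-relative alternative ("processive" mode) is provided for
comparison; it re-evaluates interiority against the current fragment, is
order-sensitive by construction, and therefore applies rules in a fixed
canonical order (lowest linkage first). Under that semantics an
endo-only digest of a hexamer ends in dimers rather than the
2-monomers-plus-fragments fixpoint of the default rule.

*Completeness* is the fraction of input residues ending as free
monomers; cellobiose and larger products count as incomplete, matching
the industrial notion of full conversion to fermentable monosaccharides.
Exo action is modelled from the non-reducing end only; reducing-end exo
enzymes are out of scope. One deliberate consequence of walking exo
enzymes down a chain one residue at a time is that an exo glycosidase
alone can finish an unbranched chain — minimal sufficient sets for
cellulose therefore contain β-glucosidase alone, with endoglucanase an
accelerator rather than a requirement. Real processivity and synergy are
kinetic phenomena outside a reachability model.

## Differential expression

The expression layer consumes log2 expression indices (probe-level TSVs
can first be passed through `quantileNormalize()` and
`medianPolishSummarize()`; array-image processing and convolution
background correction are upstream of this package and out of scope).
Comparisons are pairwise per the six-carbon-source design — biological
triplicates except a duplicate on starch; unequal group sizes are
handled by `d_g = n_A + n_B − 2`.

Per gene, the pooled variance `s²_g` is shrunk towards a prior: `log s²_g`
is a shifted log-F variate under a scaled inverse-chi-square prior, so
the prior parameters `(d₀, s²₀)` follow from the mean and excess
variance of `log s²_g` by method of moments (the excess over
`trigamma(d_g/2)` is inverted through the trigamma function with Newton
iterations). The posterior variance `(d₀ s²₀ + d_g s²_g)/(d₀ + d_g)`
yields a moderated t on `d₀ + d_g` degrees of freedom. Two boundary
behaviours are intentional: `prior_df = 0` reproduces the classical
pooled t exactly, and a *negative* moment excess (variances more
homogeneous than chi-square sampling alone explains) estimates
`d₀ = ∞`, pooling all genes onto a common variance with normal-tail
p-values — the natural limit of the model rather than an error. Only
when fewer than two positive variances exist does the fit fall back to
no shrinkage, with a warning. No variance trend over intensity is
fitted. Benjamini–Hochberg adjustment and an adjusted-p < 0.05 cut-off
give the up/down/ns calls, summarized in the "n (k↑/m↓)" format used for
pairwise-comparison overviews.

## Profile clustering

Genes are clustered on condition-mean profiles (replicate means, with
the standard error of each mean retained). Profiles are standardized to
zero mean and unit norm across conditions, where the Pearson distance
`1 − r` equals half the squared Euclidean distance, so Lloyd iterations
remain exact; centroids are re-standardized every iteration (spherical
k-means), keeping the distance well defined. "Accounting for biological
replicates" — a stated but algorithmically unpublished feature of the
clustering tools used on such arrays — is implemented as per-gene weights
equal to the inverse mean within-condition variance, with an unweighted
fallback flag. Genes with zero variance across conditions cannot be
standardized; they are flagged and left unassigned rather than silently
dropped. Empty clusters are re-seeded at the worst-fitted profile. Runs
are best-of-50 restarts under a caller seed; `scanK()` additionally
warm-starts each k from the previous solution plus the worst-fitted
profile, which makes the reported dispersion provably non-increasing in
k. k itself is a user choice (published analyses of this gene set have
used 24 clusters for 161 genes); the scan reports dispersion and mean
silhouette but never auto-selects.

## Coverage overlays and the full-set criterion

`overlayStatus()` joins required activities, catalog genes and a status
table. An activity is covered when at least one of its gene *units* is
up-regulated; genes whose array probes cannot be distinguished (the
three near-identical α-amylase genes) form one unit via their
`ambiguous_probe_group` tag. Down-regulated genes never count towards
coverage. Activities with no catalog gene are excluded from the coverage
denominator but reported prominently — otherwise a curation gap could
never be distinguished from a biological absence. `full_set` is true
when every mapped required activity is covered; esterase activities are
in the denominator whenever the structure instance actually carries the
modification. DOT maps colour gene boxes red (up), green (down), gray
(present in the CBS 513.88 annotation but without a bidirectional best
hit in ATCC 1015 — identifier pairs are data, never computed here) and
unfilled (not significant).

## The synthetic benchmark and what it does not show

`simulateExpression()` emulates the study design: six carbon sources,
triplicates except a starch duplicate (17 arrays), Gaussian log2 noise
(default sd 0.3 — microarray-appropriate; count noise would suit
sequencing data, not expression indices), baseline levels N(8, 1.5²),
and regulons induced at +2 log2 by default. The default scenario plants
a xylanolytic regulon induced on xylan *and* arabinose (arabinose
cross-induces the xylan set), an amylolytic regulon induced on starch
and glucose (starch is rapidly hydrolyzed, so the two conditions look
alike), and a pectinolytic regulon on arabinan. Regulons may overlap —
the arabinofuranosidases and feruloyl esterases genuinely belong to both
the xylanolytic and pectinolytic sets — and overlapping effects combine
as a maximum, not a sum. The gene universe is the demo catalog plus 200
decoys, so fixtures build in milliseconds.

The benchmark shows that the pipeline recovers planted truth:
simulate → moderated t → BH → coverage flags the xylan structure as
fully covered, and not starch, in ≥ 19 of 20 seeds, and planted profile
archetypes are recovered at adjusted Rand index ≥ 0.95. It does *not*
show robustness to the things real arrays add: probe-level artifacts,
intensity-dependent variance, correlated genes within operon-like
regulons, or effect sizes near the noise floor. Conclusions about real
data should lean on the statistics (which reduce to published, standard
forms at their boundaries) rather than on the synthetic recovery rates.

The packaged catalog extract transcribes the published 15-gene activity
table for soluble galactoglucomannan, genome identifiers included. The
full 188-gene framework and its per-structure tables are curated from
the primary literature and are not redistributed here; the
demo catalog (`catalog_synthetic.tsv`) instead covers every registry
activity with plausibly named genes under clearly synthetic identifiers
(`SYN####`), which is sufficient for the simulation and coverage
machinery and is labelled as synthetic wherever it appears.

## Problem sizes and numerical choices

Packaged instances use 20-residue backbones; generator-fidelity checks
use ensembles of 200 structures; oracle-equivalence tests enumerate
shuffled schedules on ≤ 8-residue structures; statistical calibration
uses 2000-gene simulations. Median polish stops when no effect moves by
more than 0.01 (10 sweeps maximum) by default, returning a flagged
result on non-convergence. Quantile-normalization ties receive the mean
of the order-statistic means across their tie run. The trigamma
inversion runs Newton steps to a relative tolerance of 1e-10. Structure
serialization is canonical (sorted ids, fixed key order), so
save → load → save is byte-identical and generator determinism can be
asserted at the file level.

```{r example}
ggm <- loadStructure("soluble_galactoglucomannan")
requiredActivities(ggm)[, c("ec", "name", "mode")]
completeness(digestStructure(ggm, requiredActivities(ggm)))
```
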