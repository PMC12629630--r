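---
title: "Methods: structure-based metacaspase substrate screening and DEG dependence partitioning"
author: "MCwound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metacaspase substrate screening and DEG partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MCwound)
```

# Scope

Type II plant metacaspases (MCs) are Arg/Lys-specific cysteine proteases.
In *Arabidopsis*, AtMC4 converts the propeptide Propep1 into the
phytocytokine Pep1 upon wounding, and the six family members (AtMC4-AtMC9)
differ in which of the eight Propeps they can cleave. MCwound implements
two computational procedures around this biology:

1. a **structure-based substrate screen** that decides whether a predicted
   enzyme-propeptide complex is a plausible cleavage pair, and ranks
   candidate P1 cleavage sites; and
2. a **transcriptome dependence classifier** that partitions wound- and
   elicitor-induced differentially expressed genes (DEGs) by their
   requirement for AtMC4 and AtMC9 and by Pep1 responsiveness.

Neither procedure fits models to data: both are deterministic pipelines
over their inputs (coordinate files; per-contrast DE summary tables).
Structure prediction, count-level DE modelling and p-value adjustment all
happen upstream and are out of scope.

# The substrate screen

## Inputs and preparation

The screen consumes one PDB coordinate file per candidate pair, with the
protease on one chain and the propeptide on the other. Because the zymogen
linker between the p20 and p10 domains can occlude the catalytic site in
predicted models, `exciseLinker()` removes a stated residue range from the
enzyme sequence *before* structure prediction. The linker boundaries differ
between the six enzymes and are supplied by the user per enzyme; they are
deliberately not hard-coded.

Reading is strict about roles (both named chains must exist), drops waters
and keeps only blank/'A' alternate locations. Hydrogens are retained on
read but excluded from all metrics by default, since predicted models carry
none; the switch exists because robustness against H-containing files is
cheap.

## The three filters

Each pair is evaluated with three metrics, computed unconditionally, and
filtered in a fixed order; the first violated filter is recorded:

1. **Clash filter** -- reject if the inter-chain clash count exceeds 50.
   A clash is an unordered heavy-atom pair across the interface with van
   der Waals overlap $(r_i + r_j) - d_{ij} \ge 0.4$ angstrom, the
   MolProbity convention. The cutoff of 50 is read as a raw inter-chain
   count because that is how it is phrased; the per-1000-atom normalised
   score is also computed and reported, and the choice is configurable,
   since usage varies between structure-validation tools. Intra-chain
   clashes are ignored: the question is whether the *pair* is sterically
   plausible, not whether the monomer models are clean.
2. **Interface filter** -- reject if the buried interface area is below
   500 angstrom^2, removing loosely bound poses. BSA is
   $(\mathrm{SASA}_{enzyme} + \mathrm{SASA}_{substrate} -
   \mathrm{SASA}_{complex})/2$; halving reports one interface's area (the
   PISA-style convention). Because it is not universally obvious whether an
   interface-area cutoff refers to the halved or summed value, the halving
   is exposed as a switch (`halve`); the default applies the cutoff to the
   halved value.
3. **Proximity filter** -- reject if the catalytic thiol sulfur (SG of the
   active-site cysteine; C139 in AtMC4, or the equivalent residue in the
   other MCs) is 4.5 angstrom or more from every substrate heavy atom.

Boundary semantics are applied exactly as printed: reject when
clashes $> 50$, when BSA $< 500$, when distance $\ge 4.5$; so 50 clashes,
500 angstrom^2 and 4.4 angstrom all pass. These are knife-edge
comparisons on floating-point values; the test suite asserts them with
metric values far enough from the boundaries that floating-point noise
cannot flip them.

Within a passing (or failing) pair, candidate P1 sites are ranked rather
than filtered: all substrate Arg/Lys residues possessing a main-chain
carbonyl O are ordered by SG-to-O distance ascending, ties broken by
residue number. Since metacaspases cleave after Arg/Lys, and the
nucleophilic attack is on the scissile carbonyl, a shorter SG-carbonyl
distance marks the more plausible register. "Carbonyl oxygen" means the
main-chain O: Arg and Lys side chains have none, so no other reading is
possible. No numeric cutoff is applied to this ranking because none is
defined for it.

## SASA implementation and numerical choices

SASA uses the Shrake-Rupley construction: each atom's sphere is expanded
by the probe radius (1.4 angstrom, water) and sampled with a deterministic
golden-spiral point set; the fraction of points outside all other expanded
spheres, times $4\pi(r+p)^2$, is that atom's area. Radii are Bondi-style
values (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, H 1.20; unknown 1.70)
shipped as an editable text table.

Numerical decisions worth knowing:

* **Fixed quadrature frame.** The point set is fixed in the model's
  coordinate frame, never randomly rotated. Consequence: results are
  exactly deterministic and translation-invariant, but only approximately
  rotation-invariant (tested at 2% relative). The quadrature error is
  quasi-random in the cap orientation: for symmetry-aligned geometries it
  can vanish exactly at particular densities, so convergence checks in the
  tests use a symmetry-free orientation, where the two-sphere closed-form
  error falls from about 0.6% at 240 points through 0.07% at 960 to 0.02%
  at 3840.
* **Default density 960 points.** Single-sphere error is within 1% (in
  fact exact, as no point can be buried), two-sphere cap error about 0.07%;
  doubling the density further was not worth the 4x cost for a screen whose
  cutoff margin is hundreds of square angstroms.
* **Clamping.** Numerically negative BSA (quadrature noise on disjoint
  chains) clamps to 0.
* **Clash acceleration.** The clash counter bins substrate atoms on a
  uniform grid with cell size equal to the largest clash-capable centre
  distance and scans the 27 neighbouring cells per enzyme atom. It is an
  exact algorithm, not an approximation; the tests assert exact equality
  with an independent all-pairs oracle on 100 random fixtures.
* **Distances** are plain Euclidean angstroms; no periodic boundaries.

## Batch screening

`screenBatch()`/`runScreen()` assemble an enzymes-by-substrates prediction
matrix, one cell per pair, labelled from the file name pattern
`<enzyme>__<substrate>.pdb`. Verdicts are a pure function of per-pair
metrics -- there is no cross-pair coupling -- and all metrics are computed
even for rejected pairs, because relative cleavage propensities and
downstream re-analysis need the full metric vector. A corrupt input flags
its own cell as an error and leaves the rest of the batch untouched.
Outputs (`matrix.tsv`, `metrics.json`) are byte-deterministic; the run log
adds wall-clock timings per pair and is the only output with
non-deterministic content. The screen processes whatever single model file
it is given per pair; reduction over multiple predicted models per pair
(seeds, rankings, confidence) is upstream of this package.

# The dependence classifier

## Significance and the Venn partition

A gene is a DEG in a contrast when log2 fold change $> 2$ (or $> 3$ for the
high-stringency analyses) and BH-adjusted $p < 0.05$, strict inequalities
as printed; down-regulated genes use log2FC $< -2$ via
`direction = "down"`. Missing adjusted p values (genes dropped by
independent filtering upstream) are never significant, and a gene absent
from a contrast table is treated as not significant there.

"Depends on AtMC4" is operationalised purely set-theoretically:
significant in the WT contrast and not in the *atmc4-1* contrast under the
same rule. No fold-change-ratio or interaction test is used -- the
partition is the three-way Venn over the WT/*atmc4-1*/*atmc9-1*
significant sets, whose eight cells map to named dependence classes
(MC4-specific, MC9-specific, co-dependent, MC-independent, MC9-repressed,
the two remaining mutant-only cells, and NOT_DEG). Direction mismatches
beyond the one-sided thresholds are ignored: a gene significant in a
mutant in the opposite direction simply does not enter that mutant's
one-sided significant set.

## Pep1 status and marker groups

Pep1 responsiveness splits the AtMC4-dependent wound DEGs into the part of
the wound response routed through Propep1 cleavage (pep_plus: also induced
by direct Pep1 infiltration in WT) and the remainder (pep_minus),
implicating other AtMC4 substrates. The default `pep_plus_mode =
"pep1_only"` uses the WT Pep1-infiltration contrast alone;
`"pep1_or_propep1"` unions in the WT Propep1+wound contrast. Both are
implemented because the published set algebra combining these treatments is
not fully specified in the main text; the ambiguity is documented rather
than resolved, and the default is the narrower, more conservative reading.

Marker groups cross the two wound-induced AtMC4-dependent classes with
Pep1 status: Group 1 = MC4-specific and Pep1-responsive, Group 2 =
co-dependent and Pep1-responsive, Groups 3 and 4 their Pep1-unresponsive
counterparts. All other combinations are NONE; Pep1 status itself is only
defined for WT-significant genes.

Reported percentages are rounded half-up to integer percent -- the
convention under which 128 of 377 prints as 34% -- with full precision
retained in the JSON summary.

# The synthetic generators

## Structures

`generateComplexFixture()` and `makeVerdictSuite()` build two parallel
slab-shaped chains facing each other across a gap along x: the enzyme slab
carries one CYS whose SG is positioned either near the interface edge
(within the proximity cutoff) or behind the slab (beyond it); the
substrate slab has one CA and one main-chain O per residue, with LYS/ARG
residue names when cleavage-site ranking is exercised. These are *not*
physically realistic proteins -- they are geometric scaffolds with just
enough PDB semantics (chains, residue names, atom names CA/O/SG) for every
operation to run. Passing tests on them demonstrates the geometry and the
set algebra are correct; they say nothing about how AlphaFold-predicted
complexes behave (packing, plDDT-dependent geometry, interface chemistry).

Every fixture is stamped with truth metrics from independent oracles:
all-pairs clash enumeration, an exhaustive minimum-distance scan, and BSA
at four times the production quadrature density. The verdict suite tunes
its geometry (slab size, gap) by a bounded deterministic search until the
oracles confirm the designed outcome with margin -- e.g. the pass fixture
must show a clash-free contact, oracle BSA comfortably above 500
angstrom^2 and SG comfortably inside 4.5 angstrom -- so that the
production path, at lower quadrature density, cannot disagree at the
boundary. At the defaults the pass fixture is a pair of 7x7 slabs at a
3.3 angstrom gap with BSA near 790 angstrom^2.

A small Gaussian coordinate jitter (0.05 angstrom) controlled by the seed
keeps fixtures from being perfectly degenerate lattices. Generators draw
from a private RNG stream and restore the caller's random state.

## DE tables

`generateDeTables()` plants genes of each dependence class by inducing
them (log2FC drawn around 4 with sd 0.25, adjusted p $10^{-6}$) in exactly
the wound contrasts that class prescribes, with pep_plus genes also
induced in the WT Pep1 contrast; everything else is null (log2FC around 0
with sd 0.1, adjusted p 0.99). Effect 4 against cutoff 2 leaves more than
3 sd of margin, so recovery is exact by construction, and the generator
refuses an effect mean at or below the rule's cutoff. Adjusted p values
are planted directly rather than derived from simulated counts: the
count-level model and BH adjustment are upstream of this package, and the
classifier consumes only the thresholded summaries. The default design
plants 10 genes per (class, Pep1-status) cell and 1000 nulls.

What the simulation does *not* emulate: count noise, dispersion,
independent-filtering NA patterns, correlated genes, borderline effect
sizes. Perfect recovery on these tables validates the partition algebra,
not the upstream statistics.

# Command-line layer

`runScreen()`, `runClassify()` and `runSimulate()` are the scriptable
entry points (a thin wrapper lives in `inst/scripts/mcwound.R`).
Configuration is YAML with every screen constant defaulted to the values
above but overridable, and unknown keys rejected rather than ignored.
All commands are idempotent and deterministic given their inputs; the only
randomness is the simulation seed, which is logged.

# Problem sizes and limitations

The test suite and the acceptance script run at deliberately small scale:
slab fixtures of 50-200 atoms, 960-point quadrature (3840 for oracles),
100 random 50+50-atom clash fixtures, DE universes of 1000-1700 genes,
10 recovery seeds. At these sizes the full suite completes in about a
minute on one core.

Known limitations:

* PDB input only; mmCIF, multi-model files and hydrogen addition are out
  of scope, as are docking, AlphaFold confidence handling and any
  interface energetics beyond buried area.
* The screen's verdicts inherit whatever systematic errors the upstream
  structure predictor makes; the published comparison of predictions
  against in vitro cleavage shows both agreements and disagreements, and
  this package reproduces the decision procedure, not its accuracy.
* The classifier is threshold-based set algebra; genes near the cutoffs
  flip classes with the thresholds, which is why both cutoffs (2 and 3)
  are first-class parameters rather than constants.
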