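---
title: "Scoring Ca-Ca distance conservation in 7TM bundles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring Ca-Ca distance conservation in 7TM bundles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caconserve)
```

## The model

G protein-coupled receptors share a seven-transmembrane (7TM) helical core
while diverging widely in sequence and in the details of helix placement.
`caconserve` asks which *internal spacings* of that core are conserved across
an ensemble of structures. The object of study is the intramolecular Ca
distance matrix of each chain, which is invariant under rotation and
translation, so the analysis needs no structural superposition and is immune
to the choices that make superposition-based comparisons ambiguous.

Every chain is reduced to a fixed frame of 200 Ballesteros-Weinstein (BW)
positions: seven helices, each indexed serially in both directions from its
most conserved `*.50` anchor, with no gap insertion. For an ensemble of $m$
chains and each unordered position pair $(i, j)$ present in *all* members,
the distance sample $d_{ij}^{(1)}, \dots, d_{ij}^{(m)}$ yields

$$\mathrm{score}(i,j) \;=\; \frac{\overline{d_{ij}}}{\sigma(d_{ij})},$$

the inverse coefficient of variation. The score is dimensionless,
scale-free, and grows as the spacing becomes more reproducible: a pair
averaging 20 Å with a 0.4 Å standard deviation scores exactly 50. Pairs of
consecutive BW positions within one helix ("adjacent" pairs, the ~3.8 Å
backbone neighbours) are trivially invariant; they are flagged and removed
before ranks are assigned. The ranked list's head — 1,000 pairs by default,
about 5% of the 19,900-pair universe — is the population everything
downstream analyses.

Two decompositions normalise that population for comparability:

* **helix pairs** — 28 bins (7 intrahelical, 21 interhelical);
* **section pairs** — each helix is partitioned into five contiguous
  sections, numbered 1 (extracellular) to 5 (intracellular); the 35 sections
  give 630 unordered bins (105 intrahelical, 525 interhelical).

Each bin reports `count_top` (its pairs in the top-N), `count_all` (all the
pairs it could contribute) and their ratio. For the default frame the
section-pair totals range from 9 (I.1 × VII.5, three positions each) to 90
(VI.1 × VII.1, ten by nine).

The companion torsion analysis computes backbone $\phi$ (C(i−1)-N-CA-C) and
$\psi$ (N-CA-C-N(i+1)) dihedrals per position per member, their circular
deviation across members, and the arithmetic mean of those deviations per
section. It measures local backbone regularity, complementing the
distance-based (global) view.

## The bundle frame and its defaults

`default_bundle()` fixes the frame: per-helix BW ranges, membrane
orientation, and the five section sizes. The published combinatorics pin
down part of it exactly — 200 positions in total; helix III spanning
3.22-3.55 (34 positions) with section sizes 8, 8, 4, 7, 7 (the unique
positive-integer solution to the tabulated pairwise products 64, 32, 28,
C(s,2)=21, 49); section sizes I.1 = 3, VI.1 = 10, VII.1 = 9, VII.5 = 3; and
193 adjacent pairs, which forces the definition of adjacency to be
*consecutive within one helix only* (199 sequence neighbours minus 6
junctions). The remaining ranges and boundaries are package defaults chosen
to respect standard BW helix spans and the alternating membrane topology
(odd helices run extracellular to intracellular with increasing BW index,
even helices the reverse); all of them are editable via a YAML config
(`load_bundle_definition()`, example shipped in `inst/extdata/`). Sanity
anchors of the defaults: N1.50 falls in section I.4; the conserved helix II
and III positions 2.46 and 3.43 fall in sections 4; VI.1-VI.2 span the
extracellular half of helix VI down to the 6.50 proline.

Note on one recurring figure: a 34-residue helix admits C(34,2) = 561
intrahelical pairs; a sometimes-quoted total of 581 for such a helix is
arithmetically inconsistent and 561 is used throughout.

Missing positions are handled by intersection: the scoreable universe of a
set is the pairs over positions present in *every* member, so one chain
lacking 4.39 gives 19,701 pairs and additional gaps at 2.66, 2.67, 6.59,
6.60 give 18,915. Denominators (`count_all`) shrink accordingly.

## Numerical and convention choices

* **Standard deviation**: population form (divide by $n$). With ensembles of
  19-59 members the difference from the sample form is immaterial, but the
  convention must be fixed; `sd_convention = "sample"` is available. The
  test suite's brute-force oracle implements the same convention
  independently.
* **Zero spread**: identical coordinates across members give $\sigma = 0$;
  the score is capped at a configurable sentinel (`score_cap = 1e6`,
  far above the realistic few-hundred range) and flagged, never infinite.
* **Ties**: ranking breaks score ties by canonical pair order (lower BW id
  first), so results are independent of input order and exactly `top_n`
  rows are kept.
* **Adjacency and denominators**: adjacent pairs are excluded from the
  *ranking*; by default the bin denominators still count every combinatorial
  pair (so the helix III total reads 561, not 528). That asymmetry matches
  the tabulated normalisation convention and is switchable
  (`denominator = "nonadjacent"`).
* **Dihedrals** follow the IUPAC sign convention (validated against
  `bio3d::torsion.xyz`), are computed directly from N/CA/C coordinates, and
  are undefined at helix termini — helices are separate segments; loop
  residues are not part of the bundle model. Collinear triplets raise an
  error rather than returning an arbitrary value.
* **Circular deviation** defaults to the circular standard deviation
  $\sqrt{-2\ln \bar R}$ (degrees), which respects wrap-around (−179° and
  +179° deviate by 2°); a minimal-arc `"range"` option exists. The choice of
  dispersion statistic is a genuine free choice here; the SD form was
  preferred as the same dispersion family used by the distance score.
  Positions defined in fewer than two members are excluded from their
  section mean.

## What the synthetic generator emulates — and what it does not

`generate_ensemble()` builds each helix as an ideal right-handed α-helix
from internal coordinates (bond lengths 1.458/1.525/1.329 Å, angles
111.2°/116.2°/121.7°, ω = 180°, base torsions φ = −57°, ψ = −47°), giving
≈1.5 Å rise, ≈100° twist and ≈2.3 Å Ca radius, with exact ground-truth
torsions for recovery tests. Helix axes sit on an ~11 Å circle with
alternating direction. Stochastic structure, drawn deterministically from
one seeded stream in a documented order:

* per-helix rigid-body jitter (translation σ in Å, small rotation σ in
  degrees) — *interhelical* variability;
* coupling groups whose members share one rigid draw per ensemble member,
  conserving their mutual distances (the `rhodopsin_like` preset couples
  helices I and VI);
* per-helix, per-atom isotropic coordinate noise — *intrahelical*
  variability;
* optional per-section torsion noise, kinks, missing positions, and a
  B-factor model.

The presets encode the study conditions the package is validated under:
`rhodopsin_like` (20 members — a homogeneous family-scale set; helix III
quiet at 0.05 Å coordinate noise, helices IV and VII noisy at 0.35 Å,
I+VI coupled), `mixed_family` (19 members, all noise ×1.8 — a
heterogeneous multi-family set) and `gapped` (adds the 4.39 and
2.66/2.67/6.59/6.60 gap patterns, shrinking the universe to 18,915). The
per-helix sigmas were chosen once to produce the qualitative conservation
hierarchy the method is meant to detect — a conserved helix III, variable
IV/VII, coupled I-VI spacing — at effect sizes a crystallographic family
ensemble plausibly shows; they are inputs of the validation scenario, not
fitted quantities.

What passing tests on synthetic data show: the scoring, ranking,
classification and torsion machinery recover known conservation structure,
are invariant where they must be (scale, rigid motion, input order,
wrap-around), and agree with independent brute-force oracles to 1e-9. What
they cannot show: anything about real receptors. Real ensembles have
correlated deviations (hinge and kink motions, crystal-contact artefacts,
subfamily structure), non-ideal helix geometry, and data-quality gradients
that the generator deliberately does not model. Data-dependent published
quantities (specific top-1000 numerators and ratios, a mean score of 29.4,
specific per-section torsion deviations) therefore cannot be reproduced
without the original curated structure sets, and the package replaces them
by the property-based checks in `tests/testthat/test-acceptance.R`.

## Problem sizes used in the checks

The validation suite runs entirely on generated data: oracle comparisons on
5-member, 12-position ensembles; invariance checks at similar sizes;
parameter-recovery and headline-ordering checks on ten independent
20-member, 200-position ensembles; torsion-noise recovery (5° injected,
recovered within ±1.5°) at 20 members; and a full
simulate→extract→score→classify→torsion byte-identity run at 8 members.
These sizes were chosen as the smallest at which the statistical assertions
are stable across seeds.

## Known limitations

* BW assignments are inputs; the package performs no sequence alignment.
* Only the first model of multi-model files and only conformer A of
  alternate locations are used; occupancies are otherwise ignored.
* The five-section partition is fixed per helix; it does not adapt to kinked
  or irregular helices.
* The torsion analysis requires N and C atoms; Ca-only inputs support the
  distance analysis only.
* Active-state ensembles, molecular-dynamics trajectories and non-GPCR
  7TM families are untested territory for the shipped defaults, though the
  machinery itself only assumes "a frame of indexed positions over helical
  segments".
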