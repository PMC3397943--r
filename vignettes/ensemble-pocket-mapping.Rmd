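---
title: "Ensemble mapping of small-molecule binding pockets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble mapping of small-molecule binding pockets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketscan)
```

## The problem

Small GTPases such as the Rho family act as conformational switches: the
protein cycles between an active GTP-bound form, an inactive GDP-bound form
and a nucleotide-free (APO) form, with the largest rearrangements in the two
"switch" loops adjacent to the nucleotide site. A binding pocket that opens
in only one of these states is a candidate site for state-selective
inhibition, which single-structure pocket finders systematically miss.
`pocketscan` therefore works on *ensembles*: many crystallographic (or
simulated) conformers of the same protein, labeled by nucleotide state, with
fragment-probe poses mapped onto each conformer. Its central statistic is
per-residue **probe occupancy** — the fraction of structures in which a
residue contacts any probe — compared between state-labeled sub-ensembles.

## The pipeline and its model

### Superposition and covariance PCA

All conformers are reduced to their shared C-alpha positions
(`extract_calpha`), superposed by least-squares rigid-body fitting
(`superpose`, Kabsch algorithm with an explicit determinant +1 constraint so
reflections can never enter), and iterated onto the ensemble mean
(`superpose_ensemble`). The coordinate covariance matrix

$$C_{ij} = \langle (r_i - \langle r_i \rangle)(r_j - \langle r_j \rangle)\rangle$$

is an ensemble average over the $n$ superposed structures; we use the
population divisor $n$, matching the ensemble-average form (users wanting
the $n-1$ sample form can multiply by $n/(n-1)$). Its eigenvectors are the
principal components; eigenvalues are variances in Å², and the
cumulative variance fraction summarizes how low-dimensional the conformer
distribution is. Because an eigenvector's sign is arbitrary, each mode's
largest-magnitude component is made positive so projections are
reproducible.

Two open choices were resolved as follows: PCA uses C-alpha atoms only (the
coarsest representation that still captures loop rearrangements, and the one
that tolerates the heterogeneous side-chain coverage of real crystal
structures), and every chain in the manifest enters the ensemble (rather
than one chain per entry), since chains of one crystal are genuinely
distinct conformers.

The default superposition core is *all* shared positions. An iterated-core
refinement (drop the top-variance 10% of positions, re-fit, repeat, never
below half the positions) is available via `refine_core = TRUE` but is off
by default: with a fit core that excludes mobile regions, apparent
fluctuations concentrate in the excluded regions and the covariance model
changes meaning, so this should be a deliberate user decision.

### Clustering, representatives, fluctuations, correlations

`pairwise_rmsd` re-superposes every pair before measuring RMSD (a shared
frame systematically overestimates pair distances). `cluster_rmsd` cuts an
average-linkage dendrogram at exactly *k* groups — the conventional
trajectory-partition depth of 24 is the default, but the benchmark analyses
use the *k* that matches their generative design — and renumbers clusters by
decreasing population, ties broken by the lowest member index so the
labeling is deterministic. Each cluster's representative is the member
closest (RMSD) to the cluster average; the average is computed after fitting
members to the first member and once more after re-fitting to the
provisional mean, since a cluster has no canonical frame.

`rmsf_profile` reports $\mathrm{RMSF}_i = \sqrt{\langle |r_i - \langle r_i
\rangle|^2\rangle}$ together with the mean crystallographic B-factor per
position; the two are independent flexibility estimates and their agreement
is a useful sanity check on real data. `cross_correlation` normalizes the
3×3-block traces of the covariance into $[-1, 1]$; residues with zero
fluctuation have no defined correlation and are reported `NA` rather than
silently zeroed.

### Probe occupancy and state-differential statistics

A residue is in contact with a probe when any heavy-atom pair is **strictly
closer than 5.0 Å**; the contact datum is binary per structure no matter
how many probes touch. Occupancy is the column mean of the per-structure
binary contact matrix, so 1 means a proximal probe in every structure and 0
complete absence. The contact matrix is retained on the profile object
because the differential test needs the per-structure data, not just the
means.

`differential_occupancy` offers two tests of the per-residue null "equal
contact probability in both states":

* **fisher** (default): a two-sided exact test on the 2×2 table of contact
  counts versus structure counts. The underlying datum is a Bernoulli draw
  per structure, which is exactly the sampling model of the exact test, and
  the result is deterministic.
* **permutation**: the null distribution of |Δoccupancy| from random
  relabelings of structures across the two sets, with
  $p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + n_\mathrm{perm})$,
  seeded and reproducible.

Residues with $p < 0.05$ (strict) are flagged. No multiple-testing
correction drives the flag — ensemble hot-spot mapping conventionally
reports the raw per-residue criterion — but a Benjamini–Hochberg column is
emitted alongside for users who want it.

A caveat worth stating explicitly: with binary contacts the permutation
statistic is coarsely discrete, so the achieved false-positive rate sits
*below* the nominal 0.05 — exact enumeration of the null gives 0.020 at 20
structures per state, 0.027 at 30, approaching 0.05 only for much larger
ensembles. The test is valid (never anti-conservative) but conservative;
the calibration analysis in the acceptance suite measures exactly this.

`profile_correlation` is plain Pearson correlation between two occupancy
profiles over shared residues (`NA` with a warning when a profile is
constant), and `occupancy_set_difference` lists residues contacted
exclusively in one set — the two summaries used to compare ensembles of
different provenance (e.g. crystals versus trajectory snapshots).

### Probe sources

Probe poses from any external fragment-mapping tool are ingested from
multi-model PDB-style files (`read_probe_poses`; atom counts may vary per
model, hydrogens dropped). When no external tool is available,
`geometric_probe_scan` provides pseudo-probes: grid points that hug the
surface (nearest heavy atom within [2.5 Å, `shell`]) and are sheltered
from solvent (at least `burial` heavy atoms within 8 Å), connected-component
clustered on the grid with components under 3 points discarded. The scan is
deterministic and order-invariant. Its defaults (1 Å spacing, 4.5 Å shell,
burial 50) suit all-atom structures; coarse C-alpha models need a lower
burial count. Both probe sources feed the same `residue_contacts` path, so
the grid-point variant of the occupancy rule ("a favorable grid point within
5.0 Å of any heavy atom") is the same code with pseudo-probe points.

### Sequence conservation

Per-column Shannon entropy is computed under a 21-letter alphabet (20 amino
acids + gap) and a reduced 7-letter alphabet (aliphatic AVLIMC, aromatic
FWYH, polar STNQ, positive KR, negative DE, special GP, plus gap). `X` is
treated as missing and dropped from the column before frequencies are
formed. Scores are normalized as $C = 1 - S/\log_2 N$, which pins fully
conserved columns at 1 and maximally diverse columns at 0; any logarithm
base cancels. Several normalizations with these boundary
properties circulate; the form above is the simplest one satisfying both
anchors, and the alignment depth is kept as profile metadata only. Columns with a gap fraction
strictly above 30% are masked; a position is called conserved when either
normalized score strictly exceeds 0.6 *and* the column is unmasked. Gap
characters count as a regular letter inside unmasked columns, exactly as
the 21st letter of the alphabet.

### Solvent exposure

`sasa` is a Shrake–Rupley-style calculator: each atom's sphere of radius
$r_\mathrm{vdw} + 1.4$ Å is sampled with a deterministic golden-spiral
lattice (no RNG anywhere) and the unoccluded fraction scales the sphere
area. The default density is 1920 points per atom: the package's
convergence contract is that doubling the density changes per-residue areas
by less than 1%, and on tightly packed fixtures 960 points leave worst-case
per-residue discrepancies of 1.5–1.7%, while 1920 meets the contract
(0.75%) at about 2 s per 1000-atom structure. The vdW radii table is a
published Bondi-style protein set, user-replaceable per call.

A residue is classified **exposed** when its area strictly exceeds 40% of a
reference maximum for its residue type in an extended tripeptide context.
The shipped reference is the published theoretical maximum-ASA table of
Tien et al. (2013, PLoS ONE 8:e80635) rather than areas from internally
constructed Ala-X-Ala tripeptides: building all twenty side-chain
geometries from internal coordinates is a large, error-prone sub-project
whose output the classification barely depends on, whereas the published
table is transparent and exactly reproducible. Users who prefer a
tripeptide-derived reference can compute one from their own coordinates
with `reference_sasa_from_structures` and pass it to `relative_exposure`;
only the >40% classification, not the absolute reference areas, carries
scientific weight here.

### Compound filters

`filter_library` applies the six descriptor criteria conjunctively in one
pass — MW < 553 Da (strict), rotatable bonds ≤ 14, H-bond donors ≤ 6,
acceptors ≥ 3, polar surface area ≥ 30 Ų, predicted logP ≥ −0.5 — with
every violated criterion of a rejected record counted, and records missing
a descriptor rejected as "incomplete". Descriptors are consumed, never
computed: computing them requires cheminformatics machinery far outside
this package's scope. `filter_by_score` keeps docking scores of −8 *or
lower* (inclusive) and ranks ascending, ties broken by compound id.

## The synthetic benchmark

`synthetic_spec` fixes the study conditions; its defaults are the conditions
under which the pipeline is validated and are not tuned per analysis:

* 200 residues (GTPase-domain scale), 30 structures per state;
* a helical C-alpha backbone with 3.8 Å spacing;
* a planted inter-state mode: every residue of a contiguous switch block
  (default 24–40, the span of a GTPase switch 1 loop) displaced 3 Å along
  its outward radial direction;
* isotropic within-state Gaussian noise of 0.2 Å — crystal-structure scale
  coordinate scatter;
* a planted pocket (default residues 57–70, a switch 2-like span) whose
  probe is present with probability 0.9 in GDP-state members and 0.1 in
  GTP-state members, placed all-or-none per structure to match the binary
  per-structure contact datum;
* for calibration studies on contact statistics, `make_contact_ensemble`
  samples per-residue Bernoulli contacts directly, with non-pocket residues
  sharing a background contact probability of 0.2 in both states — a
  realistic surface-contact rate that makes the false-positive bound a real
  test rather than a vacuous one (the geometric probe generator gives null
  residues exactly zero occupancy);
* alignment columns sampled i.i.d. from user-specified letter
  distributions, so every column's true entropy is known.

Two states suffice for every differential contract; a three-state benchmark
is a configuration away (`states`, `n_per_state`) but not a default. All
generators are deterministic given `seed`, and different seeds change
realizations, never ground-truth parameters.

What the benchmark does *not* emulate — and therefore what passing tests do
not show about real data: physically realistic protein geometry and packing,
side chains, correlated (non-isotropic) coordinate noise, heterogeneous
crystal quality, probe chemistry, or alignment phylogeny. The benchmark
validates the statistics and the geometry code paths, not force-field-level
realism.

## Numerical choices

* Superposition requires ≥3 non-collinear core positions; degeneracy is
  detected from the singular values of the centered core and raised as an
  error rather than returning an arbitrary rotation.
* Altloc resolution keeps the highest-occupancy conformer, ties broken by
  file order. Hydrogens are dropped at parse time, everywhere.
* All boundary rules are strict exactly where their printed sources are
  strict: contact at < 5.0 Å, exposure at > 40%, conservation at > 0.6,
  gap masking at > 30%, significance at p < 0.05, MW < 553; the docking
  cutoff (≤ −8) and the remaining descriptor bounds are inclusive.
* Cluster and representative tie-breaks always go to the lowest structure
  index; eigenvector signs are canonicalized — every path that could be
  nondeterministic is pinned.
* Problem sizes in the shipped analyses (60 × 200-residue conformers, 300 ×
  120 alignments, 10-seed calibration batches, 1920-point SASA) keep each
  script in the seconds-to-a-minute range while leaving every statistical
  margin wide; they are the package's chosen desk-scale defaults, and all
  scale up linearly.

## Known limitations

* Whether the input ensemble is superposed cannot be verified from the
  covariance matrix itself; `covariance_matrix` documents this contract
  instead of guessing.
* The flagged set near the 0.05 threshold depends on the chosen test; the
  original analyses never named theirs, so fisher/permutation disagreement
  within a few borderline residues is expected and documented.
* The geometric pseudo-probe scan marks sheltered surface concavities; it is
  a geometric stand-in for energetic mapping tools, not a docking surrogate,
  and its pockets carry no affinity information.
* mmCIF input, assembly expansion, pocket volumes/druggability scores, and
  molecular-surface (Connolly) areas are out of scope.
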