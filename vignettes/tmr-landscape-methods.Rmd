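---
title: "Methods: consensus models and conformational landscapes of transmembrane hairpin bundles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus models and conformational landscapes of transmembrane hairpin bundles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Multiple structure predictors applied to the same membrane protein often
disagree about how its transmembrane helices pack. For a two-hairpin bundle —
four transmembrane helices TM1..TM4, where TM1-TM2 form hairpin HP1 and
TM3-TM4 form hairpin HP2 — the scientifically meaningful disagreement is the
*cross-hairpin contact interface*: which helix of HP1 touches which helix of
HP2. `tmrscape` turns the informal workflow used to resolve such
disagreements into tested, reusable code:

1. compare predicted models quantitatively (pairwise Kabsch RMSD matrices,
   per-residue pLDDT confidence, PAE block statistics for multimers);
2. type each model's contact interface from inter-helix contact maps;
3. quality-control coarse-grained trajectories for membrane ejection and
   exclude compromised replicas;
4. embed the retained trajectories and the static models into one joint
   PCA (and TICA) space;
5. partition the landscape with K-medoids, pick k by an elbow rule, and
   characterise each state by its medoid and mean contact fingerprint.

Everything is exercised end-to-end against a synthetic four-helix-bundle
generator with planted ground truth, so a green test suite certifies the
machinery, not any particular biological claim.

## Coordinate conventions

Structures live in Angstrom with the membrane normal along z. Residue
intervals are 1-based and half-open `[start, end)`. The default subdomain map
uses TM1 `[600,615)`, TM2 `[615,636)`, TM3 `[715,736)`, TM4 `[736,751)` inside
a transmembrane region `[550,777)`. Published helix boundaries are usually
quoted inclusively ("615-635"), which leaves boundary residues such as 615
formally shared between adjacent helices; the half-open policy assigns each
boundary residue to exactly one subdomain (the later helix claims a shared
start). This is an artifact decision — deterministic, documented,
configurable — not a biological statement.

pLDDT is read from the PDB B-factor column, the convention of AlphaFold-family
predictors. Models without a confidence channel are refused by
confidence-dependent operations rather than imputed.

## Contact analysis

Distances between residue sets use either C-alpha atoms (`metric = "CA"`;
coarse-grained BB beads count as C-alpha) or mass-weighted residue centres of
mass (`metric = "residue_COM"`, unit masses for beads). Both metrics are
available everywhere; the defaults follow common practice — C-alpha for
static models, centres of mass for trajectories — and every output records
which was used.

A pair is in contact when its distance is at most the cutoff (boundary
inclusive). The default cutoff of 12 A is deliberately generous: it
accommodates the coarser effective radii of coarse-grained representations,
where helix-helix interactions span longer apparent distances than in
all-atom models.

Interface typing is a decision rule over the four cross-hairpin pairs
(TM1-TM3, TM1-TM4, TM2-TM3, TM2-TM4). Each pair gets a contact fraction
(contacts / pairs); pairs at or above `min_fraction` (default 0.05) count as
"in contact". The call is `TM2-TM3` or `TM1-TM4` when that pair is the unique
dominant in-contact pair (dominant = maximal fraction at least 1.5 times the
runner-up), `none` when nothing passes, `other` otherwise. Published
interface assignments of this kind are typically made by visual inspection of
contact maps; `min_fraction` and the dominance factor are explicit,
config-exposed stand-ins for that judgement and are flagged as artifact
parameters in reports.

## Membrane-ejection QC

Coarse-grained hairpins occasionally leave the bilayer during long
simulations and never re-enter; such replicas distort every downstream
average. The detector works on the hairpin centre-of-mass z-series against
the phosphate slab (per-leaflet mean phosphate z per frame, leaflets assigned
by sign relative to the frame-0 midplane): a hairpin is ejected when its z
leaves `[lower - margin, upper + margin]` and stays outside for at least
`persistence` consecutive frames. Defaults: margin 5 A (tolerates
interfacial breathing), persistence 50 frames (rejects spikes). Detection is
sticky — once a sustained exit is seen the replica stays flagged — matching
the observation that ejected hairpins do not re-insert. Because published
exit calls are made by eye from z-series plots, margin and persistence are
artifact defaults, recorded in output metadata and configurable.

## The joint landscape

Features are the flattened Cartesian coordinates of the membrane-embedded
backbone particles (HP1 and HP2 residues only): BB beads for coarse-grained
trajectories, C-alpha for atomistic or static models. The 1:1
residue-to-particle mapping is what lets static predictor models be projected
into a space trained on coarse-grained trajectories.

Each retained replica is rigid-body aligned (Kabsch) frame-by-frame onto a
common reference over the feature particles, so principal components describe
packing motion rather than diffusion of the bundle. PCA is the
eigendecomposition of the pooled feature covariance; eigenvector signs are
fixed (largest-magnitude loading positive) for reproducibility. A static
model is first Kabsch-fitted onto the PCA reference coordinates and then
projected — without that superposition its location in the landscape would be
meaningless. Explained-variance fractions are computed from trajectories
only; static models are projected afterwards and never enter the covariance.

TICA uses the symmetrized estimator: lagged covariance symmetrized and
whitened against the instantaneous covariance, with lagged pairs drawn within
replica segments only. Under this estimator eigenvalues lie in [-1, 1] and
time-reversing the input changes nothing. The default lag is 100 frames —
large enough to suppress fast bead jitter, small enough to leave typical
segments usable — and is config-exposed since there is no canonical choice.

The 2-D density over (PC1, PC2) is a normalized 60x60 histogram. Basin
counting does not use raw histogram maxima (sampling noise splinters basins);
modes are local maxima of a Gaussian KDE (normal-reference bandwidth)
filtered by topological persistence: a peak counts only if it rises at least
`mode_rel_min` (default 0.1) of the global maximum above the saddle that
connects it to a higher peak. Shoulder satellites and noise die at their
saddles; genuinely separated basins survive.

## Clustering

K-medoids follows the PAM recipe: a seeded initialisation, alternation of
nearest-medoid assignment and in-cluster medoid update, then a
swap-refinement phase (steepest-descent medoid/non-medoid swaps with a
bounded, cycle-safe walk along equal-cost plateaus — equal-cost swaps often
unlock a strictly improving one on small data sets). Swap refinement is
O(k n^2) per sweep and is applied when n <= 500; above that, seeded restarts
plus alternation stand alone. Two initialisations exist: the default greedy
max-min heuristic (only the first pick is random, so it admits at most n
distinct starts) and a seeded random subset. Restart schemes — including the
elbow scan — mix one greedy start with random ones, because pure max-min
starts can all funnel into the same single-swap local optimum. All ties
break to the lowest point index and the total cost is asserted
non-increasing at every step. Clustering operates on the first two PCs by
default (configurable).

The number of clusters comes from an elbow rule: for each k the best cost
over five seeded restarts plus a warm start from the previous k's medoids
(which guarantees a non-increasing cost curve), then the k maximising the
second difference of the *log* cost curve. The logarithm makes the knee a
statement about successive cost ratios, so the large but structureless drop
from k=1 to k=2 on any spread-out data set does not mask the true plateau
onset. The cost at `min(k_range) - 1` is computed internally so a knee at
the smallest scanned k is detectable. "Elbow method" is not a uniquely
defined procedure; this operationalisation is the package's own and the full
curve is returned for audit.

Cluster representatives are the medoid frame (or static model), the mean
HP1 x HP2 contact map over the cluster's trajectory members (deterministically
subsampled to at most 500 frames), and an interface call on the medoid.

## The synthetic generator and what a green test establishes

The generator plants a stated world:

* **Geometry.** Ideal rigid alpha-helices (rise 1.5 A/residue, 100
  degrees/residue twist, radius 2.3 A), four antiparallel TM helices
  numbered with the default subdomain map; only TM residues are emitted
  because no downstream analysis here reads loop residues.
* **Architectures.** `TM2-TM3`, `TM1-TM4`, `TM1-TM3`, `mixed_B` (TM2
  touching both TM3 and TM4) and `separated`, realised by axis placements
  with contact spacing 8 A, intra-hairpin spacing 10 A and non-contact
  spacing 18 A. The fifth architecture exists so that a five-state ensemble
  with five distinct fingerprints can be planted.
* **Dynamics.** Per-helix xy positions relax toward the current
  architecture's targets as an Ornstein-Uhlenbeck process (stationary sd
  sigma = 1 A per axis, relaxation time tau = 20 frames by default — small
  thermal breathing that never flips an interface by itself). Architecture
  switching is a Markov jump process; the landscape acceptance world uses a
  rate of 0.001 per frame, i.e. a couple of jumps across a whole ensemble,
  emulating basins explored by replicas that mostly stay where they started.
* **Ejection.** Optional irreversible +z translation of one hairpin at 1
  A/frame from a planted onset; the slab sits at +/-20 A, a generic
  bilayer half-width.

Real data differ in ways the generator deliberately ignores: helices are not
rigid, loops and amphipathic helices exist, lipids are absent, and the
"dynamics" is not a force field. A green suite therefore establishes that
the *analysis machinery* recovers planted truth under realistic noise — not
that any particular protein behaves this way.

## Numerical choices and degenerate inputs

* Kabsch uses the SVD construction with the determinant sign correction, so
  the returned rotation is always proper; reflection-degenerate inputs get
  the best proper rotation.
* RMSD matrices use the intersection of residue sets when models disagree on
  coverage (at least 10 shared residues required; the shared set is reported).
  Multimer whole-model RMSD uses chain A unless told otherwise.
* PCA eigenvalues are clipped at zero; covariance is the unbiased (n-1)
  estimator.
* TICA whitening drops covariance directions below 1e-10 of the leading
  eigenvalue; zero-variance DCC particles get correlation 0 with a warning.
* `detect_ejection` requires the full persistence run inside the series; an
  excursion truncated by the end of the trajectory shorter than
  `persistence` is not called.
* All randomness (generator, clustering restarts) flows through explicit
  seeds; two runs with the same seeds are bit-identical.

## Known limitations

* Only the PDB dialect is parsed (plus AF2/AF3-style PAE JSON); mmCIF and
  binary trajectory formats (XTC) are out of scope — trajectories enter as
  multi-model PDB.
* Interface typing is residue-level; no hydrogen-bond or salt-bridge typing.
* The elbow rule, contact thresholds and QC margins are explicit
  operationalisations of judgements that are usually made visually; they are
  exposed as parameters and echoed in outputs so downstream users can audit
  them.
* Free-energy surfaces, Markov state models beyond TICA, and membrane
  energetics are out of scope.
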