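---
title: "Methods: interface-derived peptide design and binding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interface-derived peptide design and binding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepforge)
```

# Scope and model of the pipeline

pepforge covers the desk-side computation of a peptide-inhibitor design
campaign that starts from an antibody--antigen crystal structure: mapping
the buried interface, lifting the contact loops into a linker-joined
peptide, exhaustively mutating it, screening the variants with a
sequence-encoded regression model, re-scoring docked poses by interface
burial, keeping the MM-GBSA bookkeeping, and post-processing MD
trajectories. The external engines such a campaign calls — peptide
folding servers, docking servers, MD packages, QM codes — are *not*
reimplemented; their outputs are consumed as files, and the synthetic-data
module generates stand-ins with known ground truth so that every stage is
testable offline.

# Structures and residue identity

Structures are flat atom tables; residues are identified everywhere by the
triple (chain, residue number, insertion code), ordered with the blank
insertion code before any letter so that 53 < 53A < 54. Antibody loops use
inserted residues routinely, and dropping or merging them silently changes
which residues a designed peptide copies, so the key type is threaded
through every interface rather than collapsed to an integer.

PDB reading honours ATOM/HETATM/MODEL/ENDMDL/TER; waters and hetero
records are removed by default (the usual cleanup before surface
analysis), and alternate locations keep the highest-occupancy conformer
(ties: first altloc letter). Radii come from a ProtOr-style united-atom
table (carbonyl/sp2 C 1.61, aromatic CH 1.76, aliphatic C 1.88, N 1.64,
carbonyl O 1.42, hydroxyl O 1.46, S 1.77 Å) with element-based fallback
(C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, P 1.80, other 1.80 Å); the
surface tool the field uses defaults to the same family of radii but the
choice is configurable (`radius_set = "element"`). Hydrogens, when
present, are kept in the structure but excluded from surface computations
by default.

# Solvent-accessible surface area

Two independent algorithms are implemented over the same probe-expanded
sphere model (probe 1.4 Å by default):

* **Shrake–Rupley**: each atom's expanded sphere carries a deterministic
  Fibonacci (golden-angle) lattice of test points (default 100); points
  inside no other expanded sphere are accessible, and the area is the
  accessible fraction of $4\pi(r+p)^2$. The lattice replaces random
  sampling so results are bit-stable for fixed parameters.
* **Lee–Richards**: the expanded sphere is cut into z-slices (default
  0.25 Å); per slice the accessible arc of the circle is accumulated as
  $\frac{L_{acc}}{2\pi} \cdot 2\pi R\,\Delta z$ (the lateral area of a
  sphere slab depends only on its thickness).

Numerical behaviour worth knowing: an isolated sphere is *exact* under
both algorithms at any resolution; occluded geometries converge with
point count / slice width (the tests verify monotone error decay against
the closed-form two-intersecting-spheres area). Translation invariance is
exact because the quadrature rides on the atom centres. Rotation
invariance is *not* exact at default resolution — the lattice and the
slicing direction live in the lab frame — and reaches the 0.1% level only
in the converged regime (≈4000 points, 0.05 Å slices); the invariance
test therefore runs there, and users comparing areas of differently
oriented copies of one structure should do the same or accept ≈1–2%
orientation jitter at defaults.

Interface burial (ΔSASA) computes the site's area in the unbound receptor
and in the receptor–ligand complex; their difference is the buried
surface. Interface detection thresholds the per-residue burial at 1.0 Ų,
a standard buried-surface convention. Hydrogen bonds use residue-template
N/O donors and acceptors with d(D…A) ≤ 3.5 Å and, when explicit hydrogens
exist, a D–H…A angle ≥ 120°; without hydrogens the distance criterion
stands alone.

# Peptide design

Interface residues are grouped into maximal runs that are consecutive in
their chain's residue-key order (insertion codes ride along). The linker
joining consecutive segments is the repeating Gly–Ser pattern with length
$\lceil \mathrm{gap}/3.8 \rceil$ residues, 3.8 Å being the extended-chain
Cα–Cα step; a 4.8 Å gap therefore takes the two-residue "GS" linker. The
gap is measured between the nearest terminal Cα atoms of the two
segments. Saturation mutagenesis enumerates all $19L$ single-point
variants, ordered position-major then alphabetically by substituted
letter, named `<orig><pos><new>` (e.g. G10C).

The worked example used throughout the tests is the antibody heavy-chain
loop 50–57 (with inserted 53A; sequence YIDPKHGGT) and light-chain loop
91–96 (NNEDLR), which assemble to the 17-mer YIDPKHGGTGSNNEDLR and a
323-variant library. One published account of that design prints the
heavy-chain segment once as "YIDPKHAGT"; the residue list and the final
peptide both imply YIDPKHGGT, which is what the package reproduces — the
discrepancy is documented here rather than resolved.

# Screening

Sequences are encoded with the Conjoint Triad scheme: residues map to 7
physicochemical classes ({A,G,V}, {I,L,F,P}, {Y,M,T,S}, {H,N,Q,W}, {R,K},
{D,E}, {C}), and every overlapping window of three classes increments one
of $7^3 = 343$ bins. `"frequency"` normalisation divides by the window
count $L-2$ for cross-length comparability; `"count"` keeps raw counts
and is the natural scale when all sequences share one length (the mutant
libraries). Peptide–target pairs concatenate the two 343-vectors.

Four regressors run behind one interface with the reference
hyperparameters (100 estimators, random state 42, ridge alpha 1):

* **ridge** — closed-form, intercept unpenalised. Columns are
  standardised before penalisation (the glmnet convention); without it an
  alpha of 1 crushes frequency-scale triad features, whose centred
  columns have variances around $10^{-3}$.
* **random forest / gradient boosting / XGBoost-style** — a compact Rcpp
  regression-tree engine (exact greedy variance-reduction splits;
  bootstrap + feature subsampling for the forest; first-order shrinkage
  boosting; second-order leaf weights with L2 regularisation for the
  XGBoost variant). The engine exists because no tree-ensemble learner
  could be assumed installed; it is deliberately minimal and
  reproducible, not a performance clone.

Metrics ($R^2$, MSE, MAE, Pearson) are computed by one shared routine for
train and test splits; the 80:20 split is a seeded shuffle. Ranking
predicts every variant paired with the target, sorts ascending (more
negative = stronger binding), breaks ties by library order, truncates to
k.

# Pose selection and the energy ledger

Docked poses are scored by site ΔSASA with the unbound term computed once
per ensemble; the best pose maximises burial, ties resolved to the lowest
model id. The MM-GBSA ledger implements the end-state identities
$G_{GAS} = E_{EL} + E_{VDWAALS}$, $G_{SOLV} = E_{GB} + E_{SURF}$,
$\Delta H = G_{GAS} + G_{SOLV}$, $\Delta G = \Delta H - (-T\Delta S)$,
with $E_{SURF} = \gamma \cdot SASA$ ($\gamma$ defaults to
0.0072 kcal mol⁻¹ Å⁻², the common non-polar surface coefficient, with
zero offset) and the entropy term defaulting to 0 because end-state
pipelines rarely estimate it. Force-field and GB terms are consumed from
external tables (`read_energy_table`), never computed: reimplementing a
generalized-Born solver is out of scope, the bookkeeping is in scope. On
the published component set (EEL −10.59, VDWAALS −28.34, EGB 29.49,
ESURF −3.43 kcal/mol) the ledger closes to GGAS −38.93, GSOLV 26.06 and
ΔH −12.87 kcal/mol at full precision; sources that print −12.88 rounded
the components first.

# Trajectory analytics

Internally everything is Å; reported series follow MD convention (nm,
nm²; times in ns, default 10 ps frame spacing). Superposition is the
Kabsch SVD construction with the determinant correction excluding
reflections. RMSF superposes frames onto an iteratively refined mean
structure; from the second iteration the fit is weighted by inverse
per-atom variance so the least mobile atoms anchor the reference frame.
Plain unweighted superposition lets a high-amplitude residue leak
rigid-body error into quiet residues and breaks exact amplitude-rank
recovery already at modest ladders — the weighted scheme restores it for
1.5-ratio ladders over an 8-residue chain; very wide ladders (amplitude
span ≫ 20×) still mix, a known limitation.

PCA flattens superposed frames to 3N-vectors and eigendecomposes their
covariance; the trace identity (eigenvalue sum = total positional
variance) is exact and tested. Each eigenvector's largest-magnitude entry
is made positive to pin the projection sign. The free-energy landscape is
the Boltzmann inversion $F = -k_B T \ln(P/P_{max})$ over a 2D histogram
of the leading projections, so the modal bin sits at exactly 0; empty
bins are capped at the maximal occupied value plus $k_B T$ to keep the
grid finite and plottable rather than infinite.

# The synthetic stated world

Each generator is a pure function of its arguments including the seed,
and returns its ground truth alongside the data.

**Toy complexes.** Two idealised poly-alanine chains (3.8 Å Cα spacing,
heavy backbone + Cβ; atom offsets confined to the xz-plane so inter-chain
separations are exact). The designated contact-patch residues of chain B
sit 3.9 Å above their chain-A partners; chain-A flanks bend away by 5 Å
steps and off-patch chain-B residues start 10 Å away, which exceeds the
maximal occlusion range of two expanded carbon spheres (≈6.6 Å), so *by
construction* only the designated residues lose accessible surface on
binding — interface recovery can therefore be demanded exactly. A 0.05 Å
in-plane jitter avoids degenerate symmetric geometry. What this toy does
not emulate: side-chain packing, realistic loop geometry, partial burial
gradations at interface rims; a green recovery test certifies the
burial/threshold logic, not performance on real interfaces.

**Pose ensembles.** Pose 0 is the constructed contact placement; pose k
displaces the ligand rigidly by k·step along a seeded random unit vector
flipped, if needed, to point away from the receptor centroid — without
the flip a random direction can push the ligand *into* the receptor and
bury more surface than the contact pose, destroying the known-best-pose
property the ensemble exists to provide.

**Affinity corpora.** Records are random single/double point mutants of a
parent; the true affinity is linear in the peptide's triad counts with
seeded N(0,1) weights, offset to a mean of −10 (free-energy-like units,
lower = stronger), plus Gaussian noise. Two design choices make the truth
*recoverable*: (i) double mutations are kept ≥3 positions apart so no
encoding window holds two substitutions — otherwise adjacent pairs create
window classes seen nowhere else and no learner can predict them; (ii)
the default corpus size is 1000 because a substitution treatment
(position × class, the finest unit the encoding can resolve) falls
entirely into the 20% test split with expected count
$\approx 102\,(e^{-0.8\lambda} - e^{-\lambda})$, $\lambda = 1.5n/102$ —
about 2 unseen treatments at n = 300 (an irreducible test error even for
least squares) and essentially none at n = 1000. The 10%-noise Spearman
check runs at its stated n = 300, where ranking is robust even though
exact $R^2$ recovery is not. An optional centred-quadratic term makes the
truth non-linear; note that on single/double mutants of one parent *any*
bounded truth is nearly linear in triad counts (features are close to
disjoint indicators), so benchmarks where tree models must beat ridge use
diverse random sequences with interaction truths instead.

**Trajectories.** Harmonic mode displaces each residue rigidly and
isotropically per frame with a per-residue amplitude (per-coordinate
standard deviation); hopping mode visits n seeded rigid conformers in
contiguous blocks with small jitter. The closed-form expectation used in
testing: the RMSD between two harmonic frames has per-coordinate variance
$2\sigma^2$ and superposition removes ≈6 of the 3N_res degrees of
freedom, giving $E[\mathrm{RMSD}] \approx \sqrt{2\sigma^2 (3N-6)/(3N)}$
per residue-level mode. These trajectories emulate amplitude structure
and state multiplicity, not dynamics: no inertia, no correlation time, no
anharmonicity.

# Pipeline and reproducibility

`run_pipeline()` chains interface-map → design → mutate → screen →
select-pose → energetics from a JSON config validated against the full
schema before anything runs (unknown keys abort). Every output directory
carries a manifest (version, seed, full config, per-stage summaries) and
a log; reruns from one config are byte-identical, which the tests assert.
The config format is JSON rather than YAML because the R environment
provides jsonlite but no YAML parser; the structure is the same nested
map a YAML file would carry.

# Known limitations

* SASA is O(n²) in atoms per frame; adequate for interfaces and toy
  trajectories, not for long all-atom trajectories of large systems.
* The tree learners are minimal reference implementations; absolute
  accuracies will differ from the mature libraries they stand in for,
  and only behaviours the tests pin down (reproducibility, interface,
  relative performance on constructed truths) should be relied on.
* No mmCIF, no symmetry expansion, no structure repair; hydrogen-bond
  geometry without explicit hydrogens is distance-only.
* Published headline numbers that depend on an unpublished training
  corpus, external docking servers or 300 ns simulations are not
  reproduction targets; the package reproduces the arithmetic-closed
  results (variant counts, ΔSASA table arithmetic, ledger totals) and
  validates everything else against constructed ground truth.
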