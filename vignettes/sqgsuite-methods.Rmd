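---
title: "Methods: defining and characterising an NAD+-dependent sulfoquinovosidase family"
author: "sqgsuite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: defining and characterising an NAD+-dependent sulfoquinovosidase family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sqgsuite)
```

# Scope and model

Sulfoquinovose (SQ, 6-deoxy-6-sulfoglucose) is released from its
glycosides by sulfoquinovosidases (SQases).  Alongside the classical GH31
family, a second SQase family (GH188) uses an oxidoreductive mechanism
with a catalytic NAD+ cofactor: transient oxidation at C3, elimination,
rehydration and reduction, which in D2O deposits a non-exchangeable
deuterium at C2 of the product.  `sqgsuite` implements the computational
workflow by which such a family is defined and characterised:

1. **Family definition** by iterative profile search until the retrieved
   sequence set is stable.
2. **Sequence similarity networks (SSNs)** over an alignment-score (AS)
   metric, with centrality-guided threshold selection and
   taxonomy/genome-context colouring.
3. **Genome neighbourhoods** (ORF ±10 around the SQase gene) classified
   into sulfoglycolytic (sulfo-EMP, sulfo-ED, sulfo-SFT) and sulfolytic
   (sulfo-SMO, sulfo-SDO) pathways by domain-signature rules, with
   GH31/GH188 presence calls.
4. **Saturation kinetics**: Michaelis–Menten fits for substrates and a
   hyperbolic activation model for the NAD+ cofactor.
5. **Deuterium-position inference** from tandem-MS fragment m/z shifts.
6. **Structural geometry**: distances, χ1 side-chain rotation, Kabsch
   superposition RMSD, Shrake–Rupley SASA, and dimer interface area.

Every analysis stage has a synthetic-data generator so the whole pipeline
is testable without downloads.

# Synthetic data: what it emulates, and what it does not

`makeFamily()` derives members from a common ancestor by i.i.d.
substitutions, uniform over the 19 alternative residues.  The per-site
substitution probability $p$ is solved from the target mean pairwise
identity $t$ by inverting $t = (1-p)^2 + p^2/19$ (two independently
mutated copies agree if neither site mutated, or if both mutated to the
same of 19 alternatives).  This controls identity — which is all the
downstream tests require — but deliberately ignores indels, rate
heterogeneity, phylogenetic correlation and realistic amino-acid exchange
propensities.  Decoys (`makeDecoys()`) are Fisher–Yates shuffles of real
sequences, preserving length and composition: the natural null model for
E-value calibration.  Passing tests on these fixtures therefore
demonstrate correctness of the algorithms under controlled signal, not
performance on real, indel-rich databases.

`makeGenome()` lays out non-overlapping ORFs on one contig, 1-based
inclusive with explicit strand (GenBank convention, used everywhere in
the package), and plants the pathway's signature genes within ten ORFs of
the seed SQase gene so that classification round-trips by construction.
Background genes carry decoy `DUF` tags.

`makeKineticData()` draws $v_i = V_{max} s_i/(K_M + s_i) + \varepsilon_i$
with Gaussian noise; `noiseSd = 0` gives the exact hyperbola used by the
recovery tests.  Default designs use eight concentrations spanning
0.5–20 mM (substrate) or 0.02–2 mM (cofactor), bracketing the
half-saturation constants several-fold on both sides as a practitioner
would design an assay.

`makeToyStructure()` builds coordinate fixtures with analytically known
geometry (separations, χ1 rotations via Rodrigues' formula, cages that
fully occlude an atom, CA-only helix dimers).

# Pairwise alignment and the AS metric

Pairwise alignment is exact affine-gap dynamic programming (BLOSUM62,
gap opening 11, extension 1; the ambiguity code X scores 0).  On top of
the raw score $S$ the package computes a bit score
$S' = (\lambda S - \ln K)/\ln 2$ with the standard gapped BLOSUM62-11-1
Karlin–Altschul constants $\lambda = 0.267$, $K = 0.041$, an
E-value-like quantity $E = m\,n\,2^{-S'}$ over the pairwise search space
$m \times n$, and the SSN edge metric $\mathrm{AS} = -\log_{10} E$.
Keeping the constants fixed (and exposed as arguments) makes AS
reproducible without a database search engine; since published SSN
alignment scores depend on the search tool and database size, specific
printed AS values (such as a 133 threshold corresponding to >53\%
identity on a particular database) are treated as dataset-specific
observations, not reproduction targets.  Percent identity is identities
over aligned columns in which neither sequence is gapped — stated
explicitly because identity conventions differ between tools.

Optimal alignments are frequently tied; the DP tie-break depends on
argument order, so `alignPair()` canonicalises the orientation of each
pair before aligning.  Every reported field is then symmetric under
argument swap.

# SSNs and threshold selection

`buildSSN()` retains edges with AS at or above the threshold and numbers
connected components deterministically (decreasing size, then smallest
member id) so outputs are reproducible across edge orderings.
Centralities are computed exactly (no sampling); betweenness is kept as
unnormalised pair counts internally to avoid normalisation-convention
bugs, and property tests compare it against exhaustive shortest-path
enumeration on small graphs.

Threshold selection was a genuinely open design point: the
centrality-guided approach we mirror is only cited, not specified, in
the literature this package follows.  The implemented rule scans a
strictly increasing AS grid and computes, per threshold, cluster count,
singleton count, mean degree and mean betweenness.  A candidate is a
*plateau* — at least three consecutive grid points with an unchanged
cluster count — whose starting mean betweenness has *collapsed* below a
configurable fraction (default 0.1) of the maximum betweenness seen
earlier in the sweep (exactly zero when betweenness never rose).  The
selected threshold is the first grid point of the **last** qualifying
plateau.  The rationale: as the threshold rises, inter-cluster bridges
first thin out (betweenness rises on the surviving bridges) and then
disappear (betweenness collapses while the cluster count stabilises); the
plateau after the final collapse is the stable clustering.  Referencing
the pre-plateau maximum rather than the grid-minimum value matters
because dense low-threshold graphs are near-complete and have *zero*
betweenness, which would make a grid-minimum reference vacuous.  On a
sweep where betweenness never rises (families already separated, or one
clique) the grid minimum is selected; an edgeless sweep selects nothing
and is flagged degenerate.  The full sweep table is always returned so a
human can re-select manually (`strategy = "manual"`).

Exports are GraphML (via igraph) and a Cytoscape-dialect XGMML written
and re-read losslessly by the package, with colour classes assigned per
taxonomy or per genome-context pathway label from a deterministic
palette.

# Iterative profile search

The family-definition procedure builds a position-specific scoring model
from a seed alignment, searches, enlarges the set, rebuilds, and stops
when the retrieved id set is exactly equal to the previous round's (the
"stable set" criterion; score equality is not required).  The seed set
counts as round zero, so a database containing only the seed converges in
one iteration.  Non-consecutive recurrence of a set flags oscillation;
`maxIters` bounds the loop either way.

The model is a PSSM with Henikoff position-based sequence weights and
background-frequency pseudocounts (Robinson–Robinson background,
pseudocount weight 0.5 effective counts), searched by local
profile-vs-sequence affine-gap DP (compiled; gap open 10, extend 1 in
profile bit units).  Columns with more than 50% gaps are masked.  This
is a deliberate simplification of a full profile HMM
(match/insert/delete states with forward-algorithm scoring): it preserves
the iterative rebuild-to-stability procedure at a fraction of the
engineering, and the package documents it as such rather than claiming
HMM equivalence.  E-values are calibrated per search by fitting a Gumbel
distribution, by the method of moments
($\lambda = \pi/(\sigma\sqrt{6})$, $\mu = \bar s - \gamma/\lambda$), to
the scores of 200 composition-preserving shuffles of database sequences,
and scaled by database size.  Calibration quality is tested as a
conservative bound: on pure-decoy databases the mean number of hits at
cutoff $E$ stays below $2E$ across 50 seeds.  The E-value cutoff
(default $10^{-3}$) is explicit configuration, not an inferred value.

# Genome neighbourhoods and pathway rules

`extractNeighborhood()` returns the seed gene plus up to $k = 10$ ORFs on
each side, on the same contig, in genomic order; the window is positional
(not strand-relative) and never crosses contig boundaries.  Rules are
data, not code: a YAML file maps each pathway to required enzyme groups
with accepted domain tags and minimum hit counts.  The shipped defaults
transcribe the pathway enzyme complements — isomerase/kinase/aldolase/
dehydrogenase for sulfo-EMP; dehydrogenase/lactonase/dehydratase/aldolase
for sulfo-ED; transaldolase (SFT), monooxygenase (SMO), dioxygenase (SDO)
as single signatures — using descriptive tags, because the authoritative
external accession list lives in supplementary material that is versioned
separately; users with PFAM-annotated feature tables should substitute
accessions in the YAML.  Multi-enzyme pathways require all their groups;
single-signature pathways require their one diagnostic enzyme.  When
several rule sets are satisfied the call goes to the pathway with the
most matched groups, and exact ties return an explicit `"ambiguous"`
status rather than an arbitrary winner (conflict resolution was
unspecified in the source analyses).  Domain tags are consumed from the
feature table, never computed: running a domain scanner is out of scope.

# Kinetics

The estimator is nonlinear least squares on $v = V_{max}S/(K_M+S)$ (or
$v = V_{max}A/(K_A+A)$ for cofactor activation) via Levenberg–Marquardt.
The Lineweaver–Burk double-reciprocal line provides starting values
only — the linearised fit is statistically biased and is never the
estimator.  If the positive-orthant fit fails, a log-parameter fallback
re-fits with $\log V_{max}, \log K_M$ and back-transforms (delta-method
standard errors).  Standard errors come from the linearised covariance at
the optimum; residual sums of squares and convergence status are
reported.  $k_{cat} = V_{max}/e_0$ and $k_{cat}/K_M$ are exact arithmetic
on the fit.  Because the enzyme concentration behind published $V_{max}$
values is typically not printed, recovery tests treat $k_{cat}$ as a
generating parameter (pick $e_0$, generate, refit, divide) rather than
re-deriving it from raw signals.  Stability effects of additives (e.g.
Mn2+) are out of scope: they alter enzyme lifetime, not the rate law.

Noise-free recovery is exact to $10^{-6}$ relative across four
log-decades of $(V_{max}, K_M)$; under 5% Gaussian noise on an 8-point
design the median $K_M$ bias stays below 5% over 500 simulations.

# Deuterium-position inference

Formulas track D separately from H; nominal masses are integer mass
numbers and monoisotopic masses use IUPAC isotope masses with electron
mass included for ions (values cross-checked against an independent
element-mass summation before implementation).  Instrument-printed values
such as m/z 243.00 for the SQ [M−H]⁻ ion are nominal-scale; the
monoisotopic value (243.0180) differs in the second decimal and is
reported, not "corrected".

Label-position inference is constraint propagation over the six carbon
hypotheses: a Δm/z = 1 ion restricts the label to the carbons it retains
(minus carbons whose hydrogens left in neutral losses); a Δm/z = 0 ion
with no loss excludes its whole coverage; a Δm/z = 0 ion reached through
a loss pathway (labelled and unlabelled precursors converging on one
product m/z) restricts the label to carbons outside the coverage or
inside the loss set.  The feasible set is the intersection; an empty
intersection reports `"inconsistent"` and the absence of any shifted ion
reports `"no label detected"` — never an exception.  A property test
checks the propagation against brute-force enumeration of all six
hypotheses on random panels.  Carbon coverage of the reference SQ
fragment series (nominal m/z 183/153/123, jointly covering C3–C6) is
fixture data transcribed from a CID fragmentation scheme, kept visible
and editable rather than computed from fragmentation chemistry.
Exchangeable protons (OH, SO3H) are excluded as label positions: they
wash out on return to water.

# Structural geometry

Coordinates load from PDB or mmCIF via bio3d; alternate locations
resolve to the highest-occupancy conformer and waters are dropped by
default.  χ1 is the N–CA–CB–CG dihedral (falling back to OG/OG1/CG1/SG),
and rotations are reported as minimal angular difference on the circle,
in [0°, 180°].  Superposition is Kabsch (SVD with the determinant forced
to +1 — reflections excluded), over N, CA, C, O of residues matched by
chain and residue number, with an explicit chain-override map because
protomer pairing conventions differ between deposits; the residue count
used is always reported alongside the RMSD so superposition claims are
checkable.  A quaternion-method (Horn) eigen-solution serves as the test
oracle at $10^{-8}$ agreement.

SASA is Shrake–Rupley with a deterministic golden-section (Fibonacci)
sphere lattice — no RNG, so results are bit-reproducible — at 960 points
per atom by default (within 1% of the 10⁴-point value on test fixtures;
a random-direction Monte-Carlo oracle agrees within 2% on interface
burial).  The van der Waals radii are fixed and printed (C 1.70, N 1.55,
O 1.52, S 1.80, P 1.80, H 1.20 Å) precisely so that systematic offsets
against other tools' unstated radii are explainable.  Interface burial
is reported as the total over both protomers,
$A + B - AB$, together with the percent of the summed monomer surface
and the per-side value ($\div 2$); this convention is the one consistent
with pairing a total buried area with a "percent of the monomer surface"
statement.  Ligands, waters and ions are excluded by default.

Published structural measurements for the deposited SqgA complexes (the
3.4 Å C3–nicotinamide-C4 contact, the 72° Tyr136 rotation, the 0.5 Å
binary-vs-ternary backbone RMSD, the 7468 Å² dimer interface) require
the deposited coordinate files; the package's operators accept those
files directly (`readStructure("8QC6.cif")` etc.), and the test suite
verifies each operator against synthetic fixtures with analytically
known answers instead of bundling third-party coordinates.

# Pipeline and reproducibility

`runPipeline()` executes syndata → profile search → all-vs-all alignment
→ SSN sweep/export → neighbourhood cohort report into a plain directory
of files with a JSON manifest (package version, full configuration,
seeds, MD5 checksum per artefact).  Identical configurations give
identical checksums; unknown stage names fail validation before any work.
A workflow engine was deliberately not used — the value is in the
computation, not orchestration.  All generators consume explicit seeds
and restore the caller's RNG state.

Problem sizes in the shipped tests and demo configuration (families of
8–20 members at 150–300 residues, 200 decoys, cohorts of 10–102 genomes,
8-point kinetic designs, 500-replicate noise studies) were chosen so the
full suite exercises every contract in a few minutes while keeping the
statistical checks (separation, calibration, bias) well-powered.

# Known limitations

* The substitution model has no indels; profile search is a PSSM, not a
  full profile HMM; E-value calibration is moment-based Gumbel.
* AS values are tool- and database-relative; absolute published
  thresholds are not reproduction targets.
* Pathway rules ship with descriptive tags and must be mapped to the
  user's annotation vocabulary (e.g. PFAM accessions) for real genomes.
* Fragment carbon coverage is declared input; no fragmentation chemistry
  is predicted.
* SASA differences versus other tools reflect radii and sampling
  conventions; expect small systematic offsets.
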