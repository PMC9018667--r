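---
title: "Validating multi-state NMR ensembles with structural correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating multi-state NMR ensembles with structural correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscorval)
```

## The problem

Exact NOEs (eNOEs) measure time-averaged proton-proton distances to about
0.1 Å.  When a protein exchanges between `N` conformational states, a
multi-state structure calculation fits `N` states per conformer so that the
r^-6 ensemble average of the state distances,

$$ d^\*_{\alpha\beta} = \Big(\tfrac{1}{N}\sum_{i=1}^N
   (d^i_{\alpha\beta})^{-6}\Big)^{-1/6}, $$

matches the averaged experimental restraints.  The conventional quality
score is the distance target function — the weighted sum of squared
violations of upper (`u`), lower (`l`) and steric (`v`) limits over the
currently violated restraints,

$$ V_d = \sum_{c=u,l,v} \omega_c \sum_{(\alpha,\beta)\in I_c}
   (d^\*_{\alpha\beta} - b_{\alpha\beta})^2 . $$

`V_d` tells you whether the data are satisfied; it says very little about
whether the modelled *states* are real.  This package implements a
complementary, superposition-free score: the **structural correlation
parameter μ**.

## The correlation engine

Every state of every conformer is one *entity* (`M` conformers × `N`
states).  For each residue, the entities are clustered into `N` groups by a
Gaussian mixture model on the distances from that residue to all other
residues; features whose standard deviation across entities falls below a
significance threshold (default 0.5 Å, screening out thermal noise) are
discarded.  Two residues that sense the same underlying state exchange
produce *consistent* clusterings; their agreement is measured by adjusted
mutual information (AMI) in bits:

* mutual information `I(X,Y) = Σ p(x,y) log2 p(x,y)/(p(x)p(y))`;
* AMI rescales `I` by the expected mutual information under the
  fixed-marginals permutation model, so random clusterings score ≈ 0 and
  identical non-degenerate clusterings score exactly 1.

The `L × L` AMI matrix `A` averages to μ.  Two conventions exist for the
average: the literal double sum over all `i, j` includes the unit diagonal
and cannot reach 0 for uncorrelated ensembles, so the package excludes the
diagonal by default (`include_diagonal = TRUE` restores the literal sum;
both are tested).  Negative means (finite-sample anticorrelation) are
clamped to 0 for reporting, with the raw value retained.  The residue whose
clustering agrees best with all others (maximal off-diagonal row mean, ties
to the lowest index) is the *key residue*, and its clustering is the global
state assignment of the bundle.

Degenerate cases are defined, not left to chance: a residue whose features
are all filtered out yields a single-label clustering, AMI 0 against
everything, and a zero row in `A` (included in the μ average by default —
the conservative choice; `exclude_empty = TRUE` drops such rows).

### Numerical choices

* GMM: diagonal covariances with a variance floor of 1e-6 (features often
  outnumber entities, so full covariances are not identifiable), EM from 10
  seeded k-means initializations, best log-likelihood kept.  Deterministic
  given the seed.
* AMI: arithmetic-mean normalization of the entropies; log base 2
  throughout.  The expected-MI sum is evaluated with `lgamma` in log space.
* All randomness flows through one integer seed per operation; repeated
  calls are bit-identical.

## The toy structure-calculation backend

The assays need a restraint-driven structure engine.  The licensed
torsion-angle-dynamics engines used for published multi-state structures
are out of scope, so the package ships a coarse-grained Cartesian
minimizer: one bead per residue (Cα), and an objective consisting of

1. the distance target function on r^-6 state-averaged bead distances
   (restraints naming non-Cα atoms map to their residue's bead with a
   +1.5 Å bound relaxation per non-Cα atom — the coarse-graining
   correction);
2. harmonic chain connectivity toward 3.8 Å virtual bonds (weight 10);
3. steric repulsion below 4.0 Å between non-neighbour beads;
4. flat-bottom "bundling" between corresponding beads of different states:
   zero inside a 1.2 Å-wide bottom, harmonic outside, weight 0.02.  The
   weight is deliberately weak: a handful of systematically violated
   restraints must be able to pay for splitting the states apart, which is
   the entire mechanism the assays probe.  With a two-group
   `grouping_scheme`, in-group bundling is strong (5) and between-group
   bundling nearly zero (0.01), which collapses each group onto one
   position and emulates populations `k/N`.

Each conformer is initialized from a distance-geometry scaffold — the
upper-limit graph completed by shortest-path smoothing and embedded in 3D
by classical MDS — plus Gaussian jitter (1 Å by default), which is the only
source of conformer diversity.  Random-chain initializations were found to
leave the bundle trapped in scattered local minima (ensemble RMSD ~4 Å)
even for restraint networks that determine the fold to well under 1 Å; the
scaffold puts every minimization inside the fold's basin while the jitter
preserves genuine heterogeneity.  Minimization uses L-BFGS-B with the
analytic gradient (compiled); an adaptive backtracking gradient-descent
mode (`optimizer = "gd"`) is available and guarantees a monotone objective
trace, which the tests verify.  Conformers are ranked by final objective
and the best `n_conformers_kept` (default 20 of 500) form the bundle.

The backend reproduces the *logic* of a multi-state calculation — r^-6
averaging, weak bundling, select-best-conformers — not the numerics of any
torsion-angle engine; bundling acts on beads, not all heavy atoms.

## The synthetic ground truth

`make_two_state_model()` builds a compact self-avoiding Cα chain (3.8 Å
bonds, 4.0 Å minimum separation, confined to a sphere of radius
`2.55 L^(1/3)` Å so that a protein-like contact density arises) and a
second state in which a contiguous segment (40% of residues by default)
swings rigidly about the hinge axis through its two anchor residues.  A
hinge is used because it preserves every bond exactly and produces a
smooth displacement field vanishing at the segment ends.  Candidate chains
and hinges are screened until the motion *trades contacts in both
directions* — close pairs broken in state B and new close pairs formed —
because a motion that changes no short interresidual distance is invisible
to distance restraints no matter how large it is.  The default peak
displacement of 6 Å (with 0.3 Å thermal noise) models an unambiguously
two-state system.

`restraints_from_model()` converts the truth into eNOE-like restraints:
for every residue pair whose population-weighted r^-6 average distance
lies within the contact range, an upper limit at that average + 0.1 Å and
(by default) the paired lower limit at the average − 0.1 Å.  Exact
distances (both limits) are essential: upper limits alone are satisfiable
by a single compact state and carry no state information.  The contact
range is the 5 Å proton NOE range plus a 3 Å bead-level correction
(1.5 Å per atom, the same correction the backend applies), because protons
5 Å apart sit on residues whose Cα atoms are farther apart; without this
correction the bead-level network stays below the rigidity threshold of a
3D structure and determines neither fold nor states.  Corruptions (bound
rescalings) emulate misassigned NOEs; a corrupted contact loses its paired
lower limit so it acts as a plain too-short upper bound.

What the generator does *not* emulate: proton-level restraint geometry,
spin diffusion, restraint-intensity noise, more than two ground-truth
states, and side-chain degrees of freedom.  Passing assays on this test
bed therefore demonstrates the machinery end to end under controlled
conditions, not performance on experimental eNOE data sets.

## The validation assays

* `states_scan()` recalculates with 1..S states; the normalized target
  function (V_d per restraint — the normalization convention is a package
  choice, so raw and normalized are both reported) drops at the true state
  count and flattens, while μ (computed with as many clusters as states,
  and only defined for ≥ 2 states) peaks at the true count and falls off as
  extra states fuse.
* `population_scan()` runs grouped 10-state calculations (group-A sizes
  1..9 emulating populations 10..90%), selects one representative state per
  group (the state closest to its group mean) and evaluates the resulting
  two-state bundles.
* `titration()` subsamples restraint fractions (fresh random subset per
  replicate, seeded per condition) and tracks ensemble RMSD (fold
  acquisition) against μ (state separation).
* `loo_ranking()` recalculates once per long-range restraint (sequence
  separation ≥ 5 by default — "long-range" is not pinned by any standard,
  so it is configurable) with that *measured distance* removed, i.e. both
  limits on the atom pair.  Sorting by μ-after-removal yields the key
  restraints (bottom set) and suspect restraints (top set); a common
  backend seed is used across removals by default so differences reflect
  the removed restraint, not initialization noise.
* `distance_profile()` bins residue pairs into equal-count groups by mean
  Cα–Cα distance and averages `A` per bin, showing the spatial range of
  correlations.
* `convergence_scan()` grids optimizer steps × calculated conformers and
  flags the cheapest cell whose μ is within 5% of the maximal-effort cell.

## Problem sizes used in the tests

The package's own validation runs on 30-residue chains with bundles of
10–20 kept conformers, 6–50 calculated conformers and a few hundred
optimizer iterations; scans aggregate 10 pipeline seeds.  These sizes were
chosen so that the full suite exercises every assay end to end in minutes
on one core while leaving the qualitative behaviour — fold convergence
below 1 Å ensemble RMSD, state recovery, titration monotonicity — intact.

## Known limitations

* μ depends on bundle convergence: under-converged calculations show
  spurious conformer-family correlations (high μ at too-large state
  counts) — which is precisely why `convergence_scan()` exists.
* Population estimation by μ is the weakest assay, here as on experimental
  systems.  On this test bed the μ-versus-group-size curve is typically
  U-shaped: singleton groups (emulated populations of 10% or 90%) separate
  artificially cleanly at the bead level, because the small violations they
  incur (~10⁻³ Å² per restraint) distort but do not smear the bundle the
  way all-atom annealing does.  The *normalized target function* computed
  by the same scan does recover equal populations reliably (its minimum
  sits at the 50/50 group split in most runs, reported as `tf_optimum`),
  so the scan reports both and the target-function optimum should be
  trusted first.
* In `loo_ranking()`, a corrupted (misassigned) exact distance is reliably
  pushed to an *extreme* of the ranking, but not reliably to the suspect
  (μ-increase) end: a wrong window conflicts with the surrounding clean
  averaged windows, and the multi-state model can absorb that strain by
  splitting states around the corrupted pair, so removing it sometimes
  *lowers* μ — the corruption masquerades as a correlation-orchestrating
  key restraint.  Both extremes of the ranking therefore deserve manual
  inspection.
* The Cα-bead backend cannot express side-chain state splitting; restraints
  between side-chain protons are blurred by the bead mapping.
* Insertion codes and mmCIF input are unsupported; multi-state PDB input
  must encode states either as consecutive MODELs or as chains within each
  MODEL.
```
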