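---
title: "Chromatin polymer models in chrom4d: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin polymer models in chrom4d: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

chrom4d simulates chromatin as a bead-spring polymer whose folding is
driven by two mechanisms acting simultaneously:

* **Binder-mediated phase separation** (the Strings-and-Binders picture):
  beads carry typed binding sites; diffusing binder particles of matching
  type bridge them.  A binder attracts cognate beads through a truncated,
  energy-shifted Lennard-Jones well; the reported *affinity* of an
  interaction is the depth of that well in units of kBT.  Homo-typic
  affinities above the hetero-typic background drive micro-phase
  separation of compartment blocks; near the coil-globule transition a
  few tenths of kBT decide whether a block condenses.
* **Loop extrusion**: mobile harmonic springs (cohesin-like factors)
  bridge bead pairs `(i, j)` and step outward to `(i-1, j+1)` every
  `stepInterval` MD steps.  Legs never pass through each other, halt
  permanently at engaged anchors of opposing orientation, detach at rate
  `kOff` per update and rebind at random positions, keeping their number
  constant.  The processivity (mean extruded loop) is `2 g / kOff` bp.

All quantities are dimensionless: bead diameter sigma = 1, mass = 1,
energy in kBT.  Physical units enter only through the length mapping
`sigma = (g / G)^(1/3) D` (nuclear diameter D = 7 um, genome size
G = 6.6 Gbp), which gives sigma of about 30 nm for 500 bp beads, and the
Brownian-time relation `tau = 6 pi eta sigma^3 / kBT`.  Evaluating the
latter with eta = 0.2 cP and sigma = 30 nm yields a much smaller number
than the half-millisecond scale quoted in coarse-grained chromatin work;
the constant factor (effective viscosity and reference length inside the
nucleus) is ambiguous at this level of description, so the package
evaluates the relation literally and uses it only to label time axes.

## Force field and integration

Bonds are FENE (`R0 = 1.6`, `K = 30 kBT/sigma^2`); every particle pair,
bonded pairs included, feels a purely repulsive truncated LJ core (WCA);
binder-bead attraction uses the energy-shifted LJ with cutoff
`rInt = 1.3 sigma` for compartment/TAD-class models and `2.5 sigma` for
locus-class models; extruder springs are harmonic (`K = 10`,
`r_eq = 1.1`).  The equations of motion are integrated with the BAOAB
Langevin splitting at `dt = 0.01`, friction 0.5 and temperature 1.  With
zero friction the O-step is the identity and the scheme is exactly
velocity Verlet, which the energy-conservation tests exploit.  Two
numerical safeguards matter:

* initial binders are placed with a hard clearance of 1.1 sigma from all
  particles, so no pair ever starts on the steep side of an eps ~ 10
  core;
* pair forces are capped at 1000 kBT/sigma.  The capped region carries
  negligible Boltzmann weight, so equilibrium averages are unaffected,
  but a rare thermal overshoot can no longer break a FENE bond.

The attraction is truncated with an energy shift only, so its force is
discontinuous at the cutoff; under the thermostat this is harmless, and
the NVE drift bound in the tests (5% over 1e4 steps) reflects it.
Non-bonded interactions use a Verlet neighbour list (skin 0.4 sigma,
rebuilt when any particle has moved half a skin) built over cells on
minimum-image wrapped coordinates; the tests verify the listed forces
against an all-pairs reference exactly.  Bonded terms act on unwrapped
coordinates, which are also what all analysis consumes.

## Binder concentration

The study conditions fix affinities, not binder numbers ("above the
coil-globule threshold").  The package's default is a declared fraction
of cognate beads per binder type: 0.5 where a deep collapse is wanted
(the coil-globule calibration test shows a clear collapse at affinity
3.8); 0.15 for the comparative compartment experiments, where sparser
binders keep the system near the coil-globule transition so that tenths
of kBT in affinity translate into differential condensation rather than
one kinetically arrested mixed globule; and 0.08 for the locus models,
whose wider 2.5 sigma attraction range makes each binder more
multivalent, so fewer binders reach the same effective valence near the
transition.  These constants were fixed once, from those physical
considerations, and are exposed as the `fraction` argument of
`defaultBinderCounts()`.

## Loop-extrusion conventions

Several details are underdetermined by a verbal description and are
fixed here once:

* a *forward* anchor blocks legs travelling leftward into it, a
  *reverse* anchor blocks rightward travel, so convergent forward/reverse
  pairs enclose a domain;
* anchor engagement is drawn once per extruder-anchor encounter, with
  the anchor's probability, and remembered until that extruder detaches
  (re-rolling every update would erode probabilistic boundaries);
* the halted leg's partner continues extruding (one-sided continuation),
  exposed as `oneSided`;
* detachment converts the rate to a per-update probability
  `1 - exp(-kOff)`;
* extruders update in a freshly randomised order each round, which
  breaks ties when two legs compete for a bead;
* anchor probabilities derived from a signal track are normalised by the
  track maximum ("proportional to signal height"); a global scale is
  available as an argument.

# Analysis layer

Contact maps threshold Euclidean distances at `A` sigma (default 3, the
mid-range of the conventional 2-3.5 band; triplets use 5 sigma) and are
averaged per replica, then across replicas with equal weight.  The
observed/expected transform divides each diagonal by its mean; diagonals
with fewer than 10 cells inherit the nearest estimated expected value.
E1 is the leading eigenvector of the Pearson correlation of the O/E
map, sign-oriented against any track that is higher in A.  Saddle plots
rank bins by E1 into equal-occupancy bins (default 50); compartment
strength is `(AA + BB) / (2 AB)` over the outer 20% corner bins.
The log2 fold-change pseudocount defaults to 1e-2 times the smallest
nonzero entry.  Triplet significance compares binary per-conformation
indicators of the target triple against a control triple shifted 100 kb
downstream with a one-sided Mann-Whitney test; the binary-per-
conformation indicator is a documented choice.

Mixture fitting is exact: both the simplex-constrained least squares
(saddles, E1 profiles) and the nonnegative-cone fit with a shared scale
(contact-probability curves, chi-square in a genomic fit range defaulting
to 15 kb - 2.5 Mb) enumerate active sets of the convex problem, so the
reported coefficients are global minimisers, with mass assigned to the
first of any duplicated basis elements.  Nonnegativity is imposed
because coefficients are interpreted as population fractions.

Shape descriptors come from the gyration tensor; note that the common
textbook asphericity expression with ascending-ordered eigenvalues is
negative for rods, so the package computes it against the largest
eigenvalue (`l3 - (l1 + l2)/2`): zero for spheres, positive for rods.
Convex-hull volumes are computed by incremental insertion and verified
against analytic solids and an external reference implementation.
Contact times partition a distance series at 150 nm into below-threshold
runs (durations) and above-threshold runs (gaps); runs touching the
series edges are censored and excluded from means by default
(toggleable).  Co-occurrence of a hub is the fraction of frames in which
*all* pairwise distances are below the threshold — a strict definition,
chosen and documented here.

## Binding-site inference

`inferBindingSites()` anneals a site profile against a target map under
a mean-field forward model: predicted contact = power-law background
`(1+s)^-gamma` plus `beta` times the type-wise co-occupancy, capped at
1.  This is deliberately the simplest forward model consistent with
binder-mediated bridging; no attempt is made to reproduce the published
thermodynamic inference machinery.  The cost adds `lambda` per site to
the sum of squared residuals (overfitting control); moves are
add/remove, relocate within type and type switch, accepted by
Metropolis under geometric cooling; the number of types is chosen as the
smallest candidate whose penalised cost is within 1% of the best
(parsimony rule).  Inferred type labels are only identifiable up to
permutation, so evaluation matches rows by exhaustive permutation.

## Epigenetic cross-correlation

Tracks are binned to the working resolution (5 kb) by length-weighted
means.  Significance of a type/mark Pearson correlation uses a
positional null: the site placements of each type are permuted along
the locus (site counts preserved, per type — a documented choice where
joint permutation would also be defensible), the observed value joins
its own null, and correlations inside the 15th-85th percentile band are
zeroed.  Condition changes are ranked by one-sided permutation p-values
of the absolute correlation difference, ties broken by larger change.

# Synthetic data

The generators plant known structure in the same containers the
analysis consumes: checkerboard compartment maps (multiplicative
log-normal noise, optional A-weakening factor that makes the BB saddle
corner exceed AA), locus maps built from the inference forward model
plus anchor-pair corner peaks, and epigenetic tracks with a chosen
correlation to a profile row.  They emulate the *statistical* signatures
(decay, checkerboard, corner loops, planted correlations) — not
sequencing depth, mappability, balancing artefacts or cis/trans
structure of real Hi-C — so green tests on synthetic data demonstrate
correctness of the machinery, not fidelity to any particular
experimental dataset.

# Reduced-scale experiment design

The directional physics experiments run at deliberately reduced scale:
polymers of N = 400 (compartment and TAD-compartment models) or N = 150
(locus models), 10^5 equilibration plus 0.6-1 x 10^5 production steps,
with 10 replicas for directional comparisons and 20 per condition for
the one-sided locus tests.  Full-scale equilibration of micro-phase
separation takes orders of magnitude longer than a desk run; at this
scale individual replicas are partially arrested, so the experiments
are designed around that fact:

* replicas are paired across conditions by common seeds (same initial
  walk and noise stream), cancelling much of the arrested-structure
  variance in condition differences;
* condition-level maps are pooled over replicas before saddle analysis;
* saddles for the directional criteria are ranked by the planted block
  labels (the limit that computed E1 approaches at full scale), which
  conditions the corner readout on the known ground truth rather than
  on a noisy desk-scale eigenvector;
* E1 recovery itself is validated on the synthetic checkerboard maps,
  where the planted labels are recovered at better than 95% accuracy
  away from block edges;
* the mock/infected locus comparisons test distances and their spread
  (Brown-Forsythe absolute deviations) over the pooled single-molecule
  population of all replicas, and contact times over the pooled contact
  events, the way trajectory ensembles are usually analysed in this
  field; intra-domain contact frequency is compared across replicas;
* the extruder-depletion comparison (small-block copolymer, unanchored
  1 Mb-processivity extruders, kept versus removed) is reported as
  measured.  Its expected equilibrium direction — extruder removal
  strengthening compartments — did not reproduce at this scale in any
  of the configurations examined: across repeated seed batches the
  difference fluctuates around zero, and a paired in-silico depletion
  experiment (branching one equilibrated state into kept/removed arms,
  supported by `runSimulation(initialState = ...)`) shows the
  short-time transient actually runs the other way, because extruder
  compaction transiently concentrates the demixed blocks.  Recovering
  the equilibrium effect needs relaxation far beyond these windows, so
  this check can fail at desk scale; the package reports the honest
  number.

Known limitations: the compartment-strength differences measured this
way are directional, not quantitative; the tau time mapping carries the
constant-factor ambiguity discussed above; and the annealer's schedule
is tuned for the few-hundred-bin maps used here, so much larger maps
need a slower schedule.
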