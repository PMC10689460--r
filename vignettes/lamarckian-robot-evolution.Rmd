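---
title: "Lamarckian versus Darwinian evolution of modular robots: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lamarckian versus Darwinian evolution of modular robots: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamevo)
```

`lamevo` is a desk-scale simulator for a classic what-if question in
evolutionary robotics: what changes when traits acquired by *lifetime
learning* become heritable? The package evolves modular robots — bodies and
brains together — under two inheritance regimes that differ in exactly one
mechanism. In the **Lamarckian** regime the controller weights a robot learns
after birth are written back into its genome before it reproduces; in the
**Darwinian** regime learning improves the phenotype but the genome passed on
is the one present at birth. Everything else (operators, rates, selection,
task) is identical, so any difference between the regimes is attributable to
the inheritance of acquired traits.

This vignette documents the models, the tunable parameters, the numerical
choices, and what the built-in locomotion surrogate does and does not
emulate.

## Bodies: CPPN genotype, module-tree phenotype

A body is a tree of modules on an integer grid: one *core* at the origin, and
up to ten *bricks* and *active hinges*. The genotype is a compositional
pattern-producing network (CPPN) with four inputs — the grid coordinates
(x, y, z) of a candidate module and its tree distance d to the core — and
five outputs: scores for the module being a brick, an active hinge, or empty
space, and for its rotation being 0 or 90 degrees. Decisions are the argmax
of the scores; no randomness is involved.

`decode_body()` expands breadth-first from the core over open sockets,
querying the CPPN per slot. Choices the underlying model leaves open, fixed
here for determinism:

* **Socket order.** Core: front, back, left, right, top, bottom; brick:
  front, left, right; hinge: front. The BFS queue follows this order, so
  equal genomes always decode to identical bodies.
* **Argmax ties** break by fixed output order (brick < joint < empty;
  0 < 90). This only matters for degenerate genomes (e.g. all-zero weights).
* **The 10-module cap counts non-core modules.** A 21 x 21 brain grid
  implies reachable offsets up to +/-10 from the core, which is consistent
  with ten steps away from the core; the cap is a `decode_body()` argument.
* **Rotation semantics.** A 90-degree rotation rolls the child's frame about
  the attachment axis and composes down the subtree, which is how 3D bodies
  arise from a tree of orthogonal steps.
* **Distance input.** d is tree depth (hops to the core), not Euclidean
  distance; the encoding describes it as distance "in the tree structure".
* **Collisions.** A module whose target cell is occupied is simply not
  placed; the branch ends. One extra rule of the same kind: an active hinge
  whose 2D-projected position would be the grid centre is not placed either,
  because the brain genotype (below) cannot address a joint at the centre.

Variation is NEAT-style: weight perturbation, add-connection and add-node
mutations (overall per-individual probability 0.8), and crossover aligned on
innovation ids (probability 0.8, otherwise a clone of the fitter parent).
Innovation ids are derived from a deterministic pairing of the endpoint node
ids rather than a global counter, so the same structural gene receives the
same id in every lineage — crossover alignment is stable and whole runs are
reproducible from a seed. Exact parity with any particular NEAT library is a
non-goal.

## Brains: a reversible, grid-indexed genotype

Each active hinge carries one central pattern generator (CPG) with states
(x_i, y_i):

$$\dot x_i = w_i y_i + \sum_{j \in N_i} w_{ji} x_j, \qquad \dot y_i = -w_i x_i$$

with antisymmetric couplings (w_ij = -w_ji) between *neighbouring* joints —
joints at distance at most two in the module tree (edges of the tree; this is
one of the places where the convention had to be fixed). The commanded joint
angle is tanh(x_i), bounded in (-1, 1). All states start at sqrt(2)/2, which
makes an uncoupled unit-weight CPG trace a sine wave of amplitude exactly 1.

The brain genotype is a fixed **440 x 14** table. Dropping the z dimension
projects every joint onto a 21 x 21 grid whose centre is the core, leaving
440 possible joint cells. Per cell the table stores 12 weights for couplings
to joints in the distance-2 neighbourhood (the 13-cell Delannoy neighbourhood
minus the centre), 1 weight for couplings to joints at the *same* 2D cell
(stacked in z), and 1 internal CPG weight. Layout choices (any fixed
bijection works; these are chosen once for determinism):

* `grid_row()` is row-major with x fastest and the centre skipped;
* offsets map to columns 0–11 in lexicographic (dx, dy) order; column 12 is
  the same-coordinate slot, column 13 the internal weight;
* each coupling is stored in the row of the joint that comes first in decode
  order; the reverse coupling is its negation;
* joints sharing a 2D cell share that row and couple through the
  same-coordinate slot;
* weights are not clipped — the tanh output stage bounds behaviour anyway.

`develop_brain()` reads the expressed entries into a network;
`encode_brain()` writes a network's weights back into a copy of the genome,
touching only the expressed entries. The pair is exactly inverse on those
entries — this bit-level reversibility is the mechanism that makes Lamarckian
write-back possible at all, and it is property-tested on random
(body, genome) pairs. Entries a body does not express ride along silently and
can be expressed by offspring with different bodies.

Brain variation: per-entry Gaussian mutation (probability 0.8, sd 0.5).
A uniform crossover operator is provided for completeness, but reproduction
uses asexual brain inheritance from the fittest parent by default (sexual
body reproduction, asexual brain reproduction), which preliminary work in
this line of research found superior.

## Lifetime learning: RevDE

Newborn robots optimize their expressed weight vector with Reversible
Differential Evolution: population K = 10 (the inherited vector plus nine
Gaussian mutants; the mutant sd is this package's choice, set equal to the
brain-mutation sd of 0.5), scaling factor F = 0.5, crossover rate CR = 0.9,
10 iterations. Each iteration after the first draws K triplets
(w_i, w_j, w_k), produces three candidates per triplet through the invertible
linear map

$$v_1 = w_i + F(w_j - w_k),\quad v_2 = w_j + F(w_k - v_1),\quad
v_3 = w_k + F(v_1 - v_2),$$

crosses each candidate with its triplet member (the standard binomial
crossover of the original differential-evolution method: a Bernoulli(CR)
mask decides per dimension between mutant and parent), assesses the 3K
trials and keeps the best K of parents
and offspring. Choices made where the procedure is underspecified: K triplets
per iteration (this yields exactly 30 new candidates per iteration and
reproduces the documented budget of 10 + 30 x 9 = 280 assessments per robot),
and elitist selection over parents plus offspring (which makes the
best-so-far reward provably monotone, a tested invariant).

## Task, fitness, and the locomotion surrogate

The task is point navigation on a flat 10 x 10 m arena: pass through
P1(1,-1) then P2(0,-2), within 0.01 m, in 40 s, with the trajectory sampled
at 5 Hz. Fitness with k of N targets reached, final position P_T and path
length L:

$$F=\sum_{i=1}^{k} d(P_i,P_{i-1}) + \big[d(P_{k+1},P_k) - d(P_T,P_{k+1})\big] - \omega L$$

with omega = 0.1 and the bracket dropped when k = N: completed segments
count at full inter-target distance, plus progress toward the next unreached
target. Under this semantics the default two-target task has maximum
1.8 sqrt(2) (about 2.54), attained by the shortest path through both
targets, and the tests assert it exactly. Reaching is tested against the
5 Hz samples only, matching how the trajectory data are collected.

Physics is pluggable. The built-in **surrogate** is a deterministic planar
unicycle: forward speed is proportional to the mean absolute rate of change
of the (steered) joint outputs times an efficiency factor n/(n+2) in the
hinge count; heading turns toward the side with the larger actuation after
target steering (the side the target is on is slowed by
max(0, 1 - |bearing|/pi)). Its coefficients (speed gain 0.15 m per unit
vigour, turn gain 2, steering gain 1) are package choices exposed in
`surrogate_backend()`; they are *not* measured constants. The surrogate
preserves the structure of the problem — a body-dependent, controller-
dependent, steerable reward with the real fitness function — but makes no
claim to physical fidelity: absolute fitness levels, gaits and contact
dynamics of a physics engine are out of its scope, and conclusions about
real robots should not be read off surrogate fitness values. An external
engine can be plugged in as any list with a
`simulate(body, network, task)` function; `external_backend()` fails loudly
rather than falling back silently.

### Numerical choices

The CPG system is linear and autonomous, so the integrator is classical
fixed-step RK4 (dt = 0.005 s), implemented through the exact one-step
transition matrix (the degree-4 Taylor polynomial of the matrix
exponential) — bit-identical to stepwise RK4 but far cheaper over thousands
of steps. RK4 keeps the uncoupled oscillator's conserved radius to well under
1e-3 over 40 s, a tested invariant. Control outputs are sampled every 8
integrator steps (25 Hz), an integer multiple of both the integrator rate and
the 5 Hz kinematic update of the surrogate; the kinematic state (position,
heading, steering) updates at the 5 Hz trajectory rate using per-interval
mean actuation.

## Evolution loop and bookkeeping

Generational loop with mu = 50, lambda = 25: binary tournament parents (with
replacement), sexual body and asexual brain reproduction, every newborn
evaluated before learning, learned with RevDE, evaluated after learning
(selection uses post-learning fitness), and — Lamarckian mode only — written
back. Survivors are the deterministic best mu - lambda; with at least one
survivor slot the population maximum is monotone, a tested invariant.
Generation-0 brains are i.i.d. N(0, 0.5^2) per entry (this package's
choice; the sd matches the mutation sd). Fitness ties
break by lower id; survivor ties by older generation, then id.

Bookkeeping reproduces the documented arithmetic from configuration alone:
280 assessments per robot; 25 + 25 x 30 = 775 evolution evaluations per run
in the *printed convention* (which counts only lambda individuals at
initialization although mu are created — `budget_report()` reports both this
number and the observed mu + lambda x generations counter and surfaces the
discrepancy rather than resolving it); 775 x 280 x 2 = 434,000 campaign
evaluations; 4,822 simulated hours at 40 s each; and savings of
25 x 16 x 280 x 20 = 2,240,000 evaluations at a generation-14 quality
crossover. Pre-learning evaluations are booked in a separate counter and not
charged against the printed budget, which its own arithmetic implies.

## Morphometrics

Morphological similarity and diversity use the tree-edit distance between
canonical ordered labelled trees (labels: module kind plus rotation, toggleable;
children ordered by socket index; unit costs), computed with the Zhang–Shasha
dynamic programme and verified in the tests against an independent exhaustive
recursive oracle on small random trees. Diversity is the mean distance over
all population pairs; parent–child similarity uses the fittest parent.
The learning delta — post- minus pre-learning fitness — quantifies how much a
body facilitates learning ("morphological intelligence"), and the
random-body control experiment (`control_experiment()`) replaces every
newborn's inherited body with a random one while keeping the inherited brain,
separating body-driven from controller-robustness-driven growth of the delta.

The eight [0, 1] traits are documented reconstructions (their original
definitions live outside the source describing this system): with m non-core
modules — size m/10; joints hinges/m; limbs leaves/m; limb length
max depth/m; branching (modules with >= 3 children)/max(1, floor(m/3));
coverage modules/bounding-box cells; proportion short/long side of the 2D
bounding box; symmetry the best matched-cell fraction under an x- or y-mirror
of the 2D projection. All are reflection-invariant and config-replaceable.
Statistical comparison between regimes uses per-generation Welch t-tests with
Bonferroni correction (alpha/m; for the conventional six comparisons this is
0.05/6 ≈ 0.0083 — reported as computed, even where related work quotes a
rounder 0.006) and 95% t confidence bands.

## Problem sizes and what the tests show

The test-suite and example campaigns are deliberately scaled down — mu = 8,
lambda = 4, 5 generations, 3 repetitions per mode on the surrogate (a few
minutes on one core) — while the study-scale settings (mu = 50, lambda = 25,
30 generations, 20 repetitions) remain the `evo_config()` defaults, one
argument away. Passing tests therefore demonstrate the *mechanisms*: exact
genotype reversibility, correct mode-dependent inheritance, ledger identities,
monotone elitism, metric properties of the distance, and learner behaviour on
closed-form rewards. They do not demonstrate physics-dependent outcomes
(absolute fitness levels, which regime wins by how much at full scale); those
require an external physics backend and study-scale compute.

Known limitations: the surrogate's kinematics are first-order and contactless;
NEAT operator parity with any specific library is not attempted; trait
formulas are reconstructions; and the two evaluation-count conventions at
initialization are both reported rather than reconciled.

One behavioural limitation of the learner deserves emphasis. With its small
population (K = 10) and deterministic truncation selection, RevDE loses
population diversity geometrically on smooth unimodal rewards: the
best-so-far reward is monotone and improves substantially (the robot-learning
sessions in this package routinely gain 0.5–2.5 fitness units), but the
population collapses around a point short of the optimum and then stalls, so
the learner should not be expected to locate optima to high numerical
precision regardless of iteration budget. The property tests exercise both
sides of this: monotone improvement always holds, while precise recovery of a
known quadratic optimum holds only in low dimension. This premature
convergence of greedy, small-population differential evolution is a known
effect and is inherited here by design, since the learner's parameters are
part of the study conditions.
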