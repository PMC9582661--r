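---
title: "Semi-rigid domain decomposition: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-rigid domain decomposition: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semirigid)
```

## The problem and the model

A molecular dynamics trajectory superimposes two kinds of motion: slow,
large-amplitude collective displacement of quasi-rigid portions of the
molecule, and fast, small-amplitude oscillation of individual atoms inside
them. Analyses of minute motion patterns need a reference region that does
not deform; `semirigid` finds such regions without supervision, from the
dynamics alone.

The only observable used is the variability of pairwise distances. For Cα
atoms $i, j$ and a window of $N_f$ frames,

$$D_{ij} = \sqrt{\tfrac{N_f}{N_f-1}\,\bigl\langle (d_{ij} - \langle d_{ij}
\rangle)^2 \bigr\rangle},$$

the Bessel-corrected sample standard deviation of the distance series
$d_{ij}(t)$ (STDDV, in nm). Two atoms riding the same rigid body have
$D_{ij} = 0$ regardless of how far the body travels; $D_{ij}$ is invariant
under per-frame rigid transforms and hence under any fitting of the
trajectory to a reference frame — the test suite asserts both to $10^{-12}$.

Because molecular systems switch between metastable states, a single
clustering of the whole-trajectory STDDV matrix can hide exactly the pairs
of interest: two atoms may be close neighbours in one conformational regime
and strangers in the next. The package therefore clusters *segments* and
forms a consensus:

1. **Per-segment crisp clustering.** The $N_t$ frames are split into $N_s$
   contiguous segments of $N_f = N_t/N_s$ frames. Within each segment, atoms
   are decomposed into $k$ clusters minimising
   $q(c) = \mathrm{tr}(c^\top D c)$ with crisp memberships
   $c_{im} \in \{0,1\}$. Crispness is not an approximation: for this target
   the optimal memberships are necessarily crisp, which reduces the search
   space to label assignments and makes single-atom moves a complete move
   set for local search.
2. **Time-wise consensus.** $\Delta_{ij}$ = fraction of segments in which
   $i$ and $j$ sit in *different* clusters; cluster identity is ignored, so
   no label matching across segments is ever needed. Each per-segment term
   is the indicator pseudo-metric of a partition, so $\Delta$ (their
   average) satisfies the triangle inequality — unlike the STDDV matrix
   itself, which is one reason agglomeration happens here and not in step 1.
   $\Delta$ is agglomerated (average or complete linkage) and cut into
   $N_G$ groups.
3. **Cross-trajectory consolidation.** Group labels of replicate
   trajectories are aligned to a reference by solving the assignment problem
   under the symmetric-difference loss; the per-group intersections across
   replicates (stable kernels) are the final semi-rigid domains.

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `discard_time` | 100 000 | ps | initial-equilibration discard (100 ns of a 600 ns run) |
| `n_segments` ($N_s$) | 500 | — | with 20 ps frames and 500 ns of data: 1 ns per segment |
| $N_f$ | derived | frames | must be ≥ 2; ~50 gives a usable variance estimate; segment length has only minor influence on the result |
| `k` | 7 | — | spatial clusters per segment; enters the consensus matrix as an input |
| `n_trials` | 100 000 | — | restarts per segment; a production safety margin — on planted data a handful suffice (the acceptance suite uses 10 and still recovers exactly) |
| `linkage` | average | — | "complete" also valid for non-Euclidean dissimilarities; "single" tends to shatter into many small clusters and is deliberately not offered |
| `n_groups` ($N_G$) | 24 | — | cut level; large enough to hold several big sheet-like domains plus small free loops |
| `delta_th` | 0.04, 0.1 | — | consensus-edge export thresholds (edge sets are nested in the threshold) |

All randomness flows from one integer master seed: per-segment optimiser
seeds are derived with a multiplicative hash (`derive_seed`), kept below
$2^{31}$, so segment results are independent of execution order and a rerun
with the same seed is bit-identical (asserted in the suite).

## Numerical and algorithmic choices

* **Bessel factor inside the root.** The flat typesetting of the STDDV
  definition leaves ambiguous whether the $N_f/(N_f-1)$ correction sits
  inside or outside the square root. We place it inside (plain sample
  standard deviation): only then is $D_{ij}$ in nm, dimensionally consistent
  with reporting STDDV on a nm colour scale. At $N_f = 50$ the two readings
  differ by a constant factor ≈ 1.01 and cannot change any clustering ranks.
* **Exact consensus arithmetic.** $\Delta_{ij}$ is computed as an integer
  disagreement count divided by $N_s$ (not as $1 - \text{agreement}/N_s$),
  so printed values like $30/500 = 0.06$ are reproduced exactly.
* **Two-pass STDDV.** Mean first, then squared deviations: the one-pass
  $E[d^2]-E[d]^2$ form loses up to half the significant digits when
  distances are large and variances small (exactly the semi-rigid regime).
* **Optimiser stall rule.** The random-move phase stops after `50 * n`
  consecutive rejections (configurable), then exhaustive single-atom sweeps
  run to a verified local optimum (no single move lowers $q$). The sweep
  composition (single-atom moves only, no pair swaps) is a design choice;
  the restart mechanism compensates, and the suite checks equality with the
  brute-force global optimum on small instances.
* **Empty clusters are legal.** $q$ carries no occupancy penalty and its
  optimum may genuinely use fewer than $k$ blocks; the result reports the
  number of non-empty clusters.
* **Tie-breaking, everywhere deterministic.** Optimiser: first-found among
  equal $q$ (seed-determined). Agglomeration: among equal-height merges, the
  lexicographically smallest slot pair. Group numbering: descending size,
  ties by smallest member index. Assignment: the lexicographically smallest
  optimal permutation, obtained by fixing rows to the smallest column that
  still admits an optimal completion.
* **Cut-point.** For $N_G$ groups the reported cut level is the midpoint of
  the two merge heights straddling the cut (undefined at $N_G = 1$ or
  $N_G = N_\alpha$, which raise errors).
* **Degenerate inputs.** Superposition requires ≥ 3 non-collinear atoms
  (reflections are excluded by forcing $\det R = +1$); STDDV requires ≥ 2
  frames; segmentation requires exact divisibility (the pipeline trims the
  trailing remainder); trajectories with inconsistent atom lists, altlocs or
  insertion codes are rejected as format errors.

## Open design decisions

* **Disparity symmetry.** With the symmetric-difference loss and a full
  square assignment, the minimal total disparity is necessarily symmetric in
  the two trajectories, and the package's property tests assert
  $D(t_1,t_2) = D(t_2,t_1)$. General-purpose assignment routines that allow
  unassigned rows (at a cost) can break this symmetry; we implement the
  equations as written and keep the full bijection.
* **In-package agglomeration and assignment.** Both algorithms are
  implemented here rather than delegated (`stats::hclust` has no
  deterministic tie policy across platforms; no linear-assignment solver is
  available in the dependency set). `stats::hclust` and factorial
  enumeration serve as independent oracles in the tests instead.
* **Indexing.** All internal indices are 1-based (the R language invariant);
  every report and export uses 1-based continuous residue numbers, as in the
  packaged PD-1/PD-L1 tables.
* **Trajectory formats.** Multi-model PDB and multi-frame GRO (both text)
  are supported with full write/read round-trip tests at 10⁻³ nm. The binary
  XTC format is not: no reader exists in the supported dependency set and
  reimplementing its lossy compression is out of scope. Inputs are assumed
  whole (periodic-boundary imaging already removed); there is no PBC
  handling.

## What the synthetic generator does and does not establish

`generate_planted_trajectory()` emulates the statistical structure the
method assumes: several internally rigid atom groups (uniform clouds of
radius 1 nm around centres ≥ 4 nm apart) undergoing independent slow
rigid-body random walks (Gaussian per-frame translation steps and rotation
angles scaled by `domain_motion_amplitude`, default 0.3 nm), fast i.i.d.
Gaussian jitter per atom (`atom_jitter_sigma`, default 0.02 nm), and
optionally atoms that switch their governing domain at a set frame
(re-anchored continuously, mimicking a metastable transition). With zero
jitter, within-domain STDDV entries are exactly zero at any motion amplitude
— the separation the method exploits — and switched atoms show strictly
larger consensus dissimilarity to their original domain than unswitched
pairs; both are asserted in the suite.

The generator's defaults are the stated validation world (3 domains × 30
atoms, 2500 frames at 20 ps). What it does *not* emulate: bonded chain
connectivity, anisotropic or correlated thermal noise, solvent drag,
gradual (rather than instantaneous) state switching, or domains with
internal flexibility gradients. A green recovery test therefore establishes
that the pipeline implements the intended mathematics and recovers planted
structure under its own assumptions — not that those assumptions hold for
any particular protein system.

## Known limitations

* Cost is $O(N_\alpha^2)$ in memory and $O(N_s \cdot \text{trials} \cdot
  N_\alpha^2)$ in time; fine for hundreds of Cα atoms, not for whole-complex
  all-atom matrices.
* $k$ and $N_G$ are user inputs; no automatic model selection is attempted.
* Comparison across trajectories requires equal $N_G$; partial or
  overlapping group matching is out of scope.
* The consensus ignores *when* segments disagree; ordering information about
  metastable states is only visible through the switch annotations of the
  synthetic truth, not recovered from data.

## A minimal run

```{r, eval = FALSE}
sims <- lapply(1:3, function(i) generate_planted_trajectory(
  planted_spec(seed = i)))
res <- run_pipeline(lapply(sims, `[[`, "trajectory"),
                    pipeline_config(discard_time = 0, n_segments = 50,
                                    k = 3, n_trials = 10, n_groups = 3,
                                    seed = 42))
res$kernels
adjusted_rand_index(as.integer(res$partitions[[1]]),
                    sims[[1]]$truth$true_label)
```
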