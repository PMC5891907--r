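---
title: "A two-scale logical model of the innate immune response to sterile injury"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-scale logical model of the innate immune response to sterile injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlr4net)
```

## The biological question

Sterile ischemic injury kills cells, and dying cells release
danger-associated molecular patterns (DAMPs) that activate the pattern
recognition receptor TLR4 on tissue macrophages. TLR4 fires two intracellular
arms: the plasma-membrane, MyD88-dependent arm
(MyD88 → pIRAK → NF-κB → CCL2), whose chemokine output recruits
pro-inflammatory M1 macrophages from the circulation, and the endosomal,
MyD88-independent arm (TRIF → IRF3 → IFN-β), regulated by the endocytic
receptor CD13, whose hyperactivation produces reactive oxygen species (ROS)
that damage tissue further. M1 macrophages differentiate into pro-healing M2
macrophages that shut down NF-κB signaling, clear DAMPs and resolve the
injury. Whether an injury resolves or locks into chronic inflammation depends
on the balance of these arms — a balance that in-vivo knockout experiments
perturb one node at a time.

This package encodes that circuit as a *multi-valued logical model*: each
species is a node with 2 or 3 discrete levels (absent/present, or
low/medium/high), and each node's next level is a deterministic function of
its regulators' current levels, applied synchronously. No kinetic parameters
are needed; the model is a qualitative map from regulatory logic to long-run
outcomes. TLR4 itself is not a node — it only relays the DAMP signal — and
neutrophils, fibrosis and other known contributors are deliberately out of
scope of this acute, macrophage-centred model.

## Model structure

**Intracellular scale (11 nodes).** Inputs DAMPs (0–2) and M2 (0/1) are held
constant while the cell model runs; CD13, TRIF, IRF3, IFN-β (0–2 each,
ROS 0/1) form the MyD88-independent arm and MyD88, pIRAK, NF-κB (0–2) the
MyD88-dependent arm, terminating in the outputs ROS and CCL2. With the
inputs held, the wiring is feed-forward, so every input combination has a
unique fixed point, reached in at most the network depth (5 steps) from any
internal initialization.

**Tissue scale (6 nodes).** Injury (0/1), DAMPs (0–2), M1 (0–2), M2 (0/1),
ROS (0/1), CCL2 (0–2). Injury is resolved by M2 and otherwise persists (it
never arises spontaneously); DAMPs integrate injury, ROS and M2 with a
memory effect (an overwhelming DAMP load, level 2, is not reduced to 1 by a
single remaining source); M1 tracks CCL2; M2 arises from a standard M1
population only (M1 = 2 overwhelms it).

**Two-scale coupling.** The intracellular scale is assumed much faster than
tissue turnover. Each tissue step therefore (1) iterates the cell model to
its fixed point given the current tissue DAMPs and M2, (2) substitutes that
fixed point's ROS and CCL2 into the tissue state, and (3) applies one
synchronous tissue update. Because the cell fixed point is a pure function
of (DAMPs, M2) and the clamps, step (1) is precomputed once as a pair of
input/output transition tables (`derive_io_tables()`), and the two-scale
step becomes an ordinary synchronous step of the six-node tissue model with
those tables as the ROS and CCL2 rules. The ROS and CCL2 fed into tissue
step *t + 1* are computed from DAMPs and M2 at step *t*.

```{r io}
derive_io_tables()
```

## Rules as extensional tables

Update rules are stored extensionally — a total mapping from every input
tuple to an output level — rather than as logic expressions. The prose form
of the rules mixes XOR, thresholds and precedence ("unless..."), which is
easy to misread; a full truth table has no precedence to argue about, makes
totality and admissibility mechanically checkable (`validate_model()`), and
serializes canonically to the JSON model dialect (`write_model()` /
`read_model()` round-trips byte-exactly; the bundled
`inst/extdata/models/*.json` files are tested to agree with the builders).

Two readings of the prose rules were genuinely open and were fixed as
follows, because each is required for the published tissue steady states to
be fixed points at all:

* **Injury persistence.** Only the resolution condition (M2 present) is
  stated for Injury; absent that, Injury holds its previous value. The
  inflamed steady state (Injury = 1 with M2 = 0) is only a fixed point under
  persistence.
* **DAMP memory.** "Medium DAMPs from a single source *unless* the previous
  load was overwhelming" is read as *the load stays at 2*. The rare
  ROS-sustained steady state (DAMPs = 2, Injury = 0, ROS = 1, M2 = 0) is
  only a fixed point under this reading.

## Clamping and knockouts

A clamp holds a node at a fixed level (knockout = level 0) at *every* time,
including the current state a step reads. One visible consequence: forcing
DAMPs on from quiescence transiently hyperactivates TRIF for one step,
because TRIF's rule reads CD13 = 0 before CD13 has activated; the fixed
point is unaffected. Knockouts clamp the node at both scales — for CCL2,
both the intracellular node and the tissue node.

The knockout panel (`knockout_panel()`) starts each genotype from injury
present (level 1), the genotype's starting DAMP level, and the clamped
intracellular fixed point's ROS and CCL2. Where the underlying in-vivo
studies determined M1 and M2 (wild type and the CD13 knockout, both (1, 1)),
those levels are used; where they did not, all six (M1, M2) completions are
enumerated. "Resolved" means the trajectory reaches the all-zero tissue
fixed point; "unresolved" means its fixed point retains DAMPs ≥ 1. The IRAK
knockout clamps pIRAK, the model's only IRAK species. These contexts are
bundled as data (`inst/extdata/reference/knockout_contexts.tsv`), not
hard-coded.

```{r ko}
knockout_panel()
```

A note on the published account of the MyD88-arm knockouts: the computed
non-resolving completions are exactly (M1, M2) = (0, 0) and (2, 0) — the
corners where M2 is absent and M1 cannot generate it — and the resolving
set is therefore {(0, 1), (1, 1), (1, 0), (2, 1)}. A published listing of
the resolving set names "(0, 0)" in place of (1, 0), which contradicts both
its own 66%/33% split and its own non-resolving list; the package reports
the computed partition.

## Enumeration, basins and percent formatting

Attractors are found by iterating the synchronous map and detecting the
first revisited state (a hash set of visited states; the space is finite, so
termination is guaranteed). Exhaustive enumeration memoizes the
state-to-attractor map, so each state is stepped at most once across an
entire basin computation. Basin counts are exact integers that partition the
enumerated space; this is asserted, not assumed.

Two enumeration spaces matter here. The tissue analysis enumerates all
216 = 3·3·2·2·2·3 configurations, *including* biologically improbable ones
(e.g. ROS without injury) — that is the denominator behind the published
basin shares, and the rare third steady state exists precisely because of
such initializations. The intracellular analysis enumerates the six
(DAMPs, M2) input combinations with internal nodes at 0; enumerating all
52,488 internal initializations instead gives the same six fixed points with
the same equal shares (the wiring is feed-forward), and the report records
which space was used.

Percentages are **truncated**, not rounded, at two decimals for basin tables
(1/6 → 16.66%, 12/216 → 5.55%, 200/216 → 92.59%) and at zero decimals for
the knockout panel (4/6 → 66%, 2/6 → 33%), matching the convention of the
reference tables; `format_percent_trunc()` does the arithmetic in exact
integer division so no floating-point representation can flip a digit.

```{r basins}
as.data.frame(tissue_attractors())
```

## The random-network generator

`random_model()` produces seeded random multistate logical networks (node
cardinalities sampled from {2, 3}, up to a configurable number of inputs per
rule, uniformly sampled total truth tables, an expected fraction of
rule-less hold nodes). These networks are *not* biologically meaningful;
they exist so the engine's guarantees are tested independently of the
hand-built model: basin counts partition the space, trajectories terminate
within the state-space size, repeated runs are identical, and synchronous
fixed points coincide with states invariant under every single-node update —
the update-order independence that makes "steady state" well-defined
regardless of scheduling. All randomness is scoped with `withr::with_seed()`,
so generation is reproducible and never perturbs the caller's RNG. Passing
these properties says nothing about real signaling data — the biological
content of this package is validated instead by the reference tables and
the knockout panel.

The test suite runs 200 such networks of 2–6 nodes (state spaces up to 729),
a size at which full-space enumeration and the fixed-point characterization
stay fast while still exercising mixed cardinalities, hold nodes, cycles and
multi-attractor landscapes.

## Numerical and degenerate-input choices

* Enumeration order is the mixed-radix count over nodes in model order
  (first node most significant); results are order-independent, the
  ordering only fixes report row order.
* Cycles are reported starting from their lexicographically smallest state,
  so the same cycle found from different entry points compares equal.
* `max_steps` guards the (impossible, but guarded) non-convergence of the
  feed-forward cell model and caps pathological user inputs; any value at
  least the state-space size guarantees a revisit.
* Non-total or mis-keyed rule tables, unknown nodes in states or clamps,
  conflicting clamps, and empty enumeration spaces are rejected with the
  offending names; `validate_model()` returns diagnostics rather than
  throwing, so a model file's problems can all be reported at once.

## Limitations

The model is qualitative: levels are ordinal categories, steps are not
calibrated time, and basin percentages measure the share of *initial
configurations*, not probabilities over biologically realistic starts. The
tissue is treated as homogeneous — one intracellular state serves all
macrophages — so spatial heterogeneity, neutrophils, the delayed
TRIF-mediated NF-κB route, and fibrosis are outside its scope. Published
knockout experiments measure defined post-injury time points, whereas this
model reports eventual steady states; the two agree on resolution outcomes
but not necessarily on intermediate magnitudes.
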