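---
title: "Evolving animats and measuring their integrated causal structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving animats and measuring their integrated causal structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(animatphi)
```

## The model

`animatphi` simulates the adaptation of minimal embodied agents
("animats") and quantifies, generation by generation, how much integrated
causal structure their control networks develop. An animat brain is a
fixed scaffold of 8 binary elements -- 2 sensors, 4 hidden elements
(labelled A--D), 2 motors -- whose dynamics are deterministic logic
functions encoded on a genome. Three ingredients interact:

1. **A genome-to-network encoding.** Genomes are strings of 1,000--20,000
   integer loci in [0, 255]. Each occurrence of the start codon (42, 213)
   opens a gene encoding one *hidden Markov gate*: 1--4 inputs drawn from
   sensors and hidden elements, 1--4 outputs writing hidden elements and
   motors, and a deterministic logic table. All gates update synchronously;
   when several gates write the same element their outputs combine by OR.
   Sensors are written only by the environment and motors are read only by
   it, so no feedback reaches sensors and none leaves the motors.
2. **A block-catching environment.** The animat sits at the bottom of a
   16-column periodic world; one block per trial falls for 36 steps, moving
   one column sideways per step. The 3-unit-wide animat senses the block
   only through two upward-looking sensors with a one-unit blind spot
   between them, and moves left or right via its motor pattern (01 right,
   10 left, 00/11 stay). Fitness is the fraction of the 128 trials (16
   starting columns x 2 directions x 4 block-size slots) in which the
   animat correctly catches (overlaps) a block it should catch and avoids
   one it should not. Four tasks grade the memory requirements, from Task 1
   (catch size 1, avoid size 3 -- momentarily distinguishable) to Task 4
   (catch 3 and 6, avoid 4 and 5 -- requiring integration over several
   steps). Variants disable a sensor or motor or flip each sensor with 1%
   probability per step.
3. **A genetic algorithm.** Populations of 100 animats evolve by
   roulette-wheel selection on the exponential score S = 1.02^(F x 128)
   (every additional correct trial multiplies the score by 1.02), without
   elitism, followed by point mutations (0.5% per locus), deletions (2% per
   genome) and duplications (5%) of 16--512-locus fragments, under the
   1,000--20,000 locus bounds. Ancestral genomes are all-zero: they encode
   no gates, so generation 0 scores the stationary baseline (56/128 = 43.75%
   on Task 1) and all connectivity is discovered by evolution. Because
   reproduction is asexual, each final animat has a unique line of descent
   (LOD) which coalesces across picks within a few generations; measures
   are computed every `lod_sample_interval` generations along one LOD.

## The causal measures

For a network in a state, the engine computes the full IIT 3.0 analysis:

* **Cause/effect repertoires.** The cause repertoire of a mechanism (a set
  of elements in its current sub-state) over a purview is the Bayesian
  inversion of the element-wise transition probabilities under a uniform
  perturbation prior, factorized over mechanism elements; the effect
  repertoire is the distribution of the purview's next state with the
  mechanism clamped and all other inputs uniformly perturbed, factorized
  over purview elements.
* **phi and concepts.** Mechanism-level integrated information is the
  earth-mover's distance (EMD, Hamming ground metric) between the intact
  repertoire and that of the minimum information partition, maximized over
  purviews on the cause and effect side separately; phi^max is the smaller
  of the two maxima and a mechanism with phi^max > 0 specifies a concept.
  Exact transport costs come from a successive-shortest-path min-cost-flow
  solver (effect-side distributions are products, for which the EMD reduces
  to the summed marginal differences).
* **Big Phi and complexes.** The conceptual structure of a candidate set is
  compared against every unidirectional partition of the set (connections
  from one part to the other replaced by noise) with an extended EMD that
  transports phi^max mass between concepts; the ground distance between two
  concepts is the EMD between their cause repertoires plus that between
  their effect repertoires, expanded over the candidate set, with surplus
  mass absorbed by the null concept (the unconstrained repertoires). The
  candidate set with maximal big Phi is the main complex. Feed-forward
  candidate sets are reducible by construction, so a strong-connectivity
  check short-circuits them to Phi = 0.

Whole-brain summaries evaluate all 15 mechanisms over the hidden elements
(sensors and motors lack causes or effects, respectively, and cannot form
concepts) with cause purviews over sensors+hidden and effect purviews over
hidden+motors. Main-complex summaries search the hidden-element subsets of
size >= 2. Per-state values are averaged over every brain state
experienced during the 128 trials, weighted by frequency of occurrence.

### Elements outside a candidate set

When a proper subset of elements is analyzed as a candidate complex, the
remaining elements must be made causally inert. Two conventions exist:
clamping them to their current state, or replacing them by independent
uniform noise. This package marginalizes (noises) them. The choice is not
cosmetic: in the worked three-element example below, clamping element A
turns the pair BC into a bare negation loop with Phi = 1.0, which would
overtake the full system ABC (Phi = 0.9167) as the main complex; with
marginalization Phi(BC) = 0 and ABC wins, matching the reference analysis
of these example systems. Since candidate elements' own inputs from outside
carry the same convention, the whole-network analysis (no outside elements)
is unaffected.

### Worked examples

Two hand-constructed networks anchor the engine numerically.
`three_node_example()` is a three-element loop -- A = B AND NOT C,
B = A AND NOT C, C = XOR(A, B) -- analyzed in state ABC = 101. Its gate
logic was recovered by exhaustively searching all deterministic gate pairs
for A and B (with C fixed as the XOR closing the loop) for the unique
assignment reproducing the full set of reference values: phi_effect = 0.25
for AB = 10 over ABC, a maximally irreducible cause over ABC with
phi = 1/3 whose minimum partition transports mass 1/3 from state 010 to
000, a maximally irreducible effect over C alone with phi = 1/2, exactly
four concepts (A, B, C, AB), and big Phi = 11/12 = 0.9167.

```{r three-node}
ex <- three_node_example()
compute_concept(ex$network, ex$state, c(1, 2))
system_phi(ex$network, ex$state)$big_phi
```

`animat_example()` embeds the same three-element core as hidden elements
A--C of a full 8-element animat, adds a weakly selective memory element D
(written by two dense sensor/hidden gates, read by a motor) and a motor
gate over sensors+A+C that gives the second-order mechanism AC a weak
irreducible effect. In state 00-1010-10 the whole brain specifies 6
concepts ([A], [B], [C], [D], [AB], [AC]) with summed phi^max of 1.078 and
its main complex is ABC with Phi = 0.9167 and 4 concepts. The auxiliary
gates were found by searching gate tables under the constraint that the
core's analysis stays intact; the reference values only pin the analysis
results, not the artwork-level wiring, so the shipped network is one
representative of the matching equivalence class.

## Numerical choices

* States are little-endian integers (element 1 is bit 0); repertoires are
  vectors over the sorted purview's states.
* Undefined cause repertoires (mechanism states unreachable under every
  perturbation) contribute phi = 0.
* Ties in phi between purviews are broken toward the larger purview, then
  lexicographically smallest element set. Printed phi/Phi values never
  depend on this, but reported core purviews and the expanded repertoires
  entering the extended EMD do.
* Purviews containing elements with no (effective) connection to the
  mechanism provably have phi = 0 and are pruned; mechanisms whose
  elements lack inputs or outputs in the admissible spaces are skipped for
  the same reason. The test suite cross-checks the pruned engine against
  an unpruned reference implementation.
* Transport problems are solved exactly; shared mass between the two
  distributions is cancelled first (optimal under a metric ground
  distance).

## Scaled-down study conditions

The full-scale experiments (50 independent runs x 60,000 generations per
condition) are supported but deliberately not the default. The test suite
and examples run the same generative process at reduced scale -- typically
10 runs x 5,000 generations, the regime in which Task 1 fitness first
plateaus near 82% -- which preserves every qualitative property
(fitness growth above the 43.75% stationary baseline, the rise of concept
counts from the concept-free ancestors) while keeping a complete run in
minutes. The ancestral genome length (5,000 loci of zeros) is a free
choice within the 1,000--20,000 bounds; the reference experiments specify
only that ancestors encode no gates.

What the synthetic fixtures do *not* emulate: evolved genomes from the
original experiments (unpublished), probabilistic gate tables, worlds of
other sizes, and crossover. Passing tests therefore demonstrate
correctness of the measures and the generative pipeline, not agreement
with any particular evolved genotype.

## Statistics

`lod_correlations()` uses Spearman rank correlations of each measure
against fitness along a LOD (fitness gains are not expected to be linear
in any measure); constant series are reported as NA and excluded from
averages. `compare_conditions()` reduces each LOD to its mean over the
final 3,000 generations (6 samples at 512-generation spacing), applies a
Kruskal-Wallis omnibus test and pairwise Mann-Whitney U tests (normal
approximation with tie correction), without multiple-testing correction.
`fitness_matched_subset()` matches conditions at equal fitness by scanning
prefixes of the fitness-ranked LODs and choosing the prefix whose mean
best matches the reference condition; ties favour the larger subset.
Behavioral distinctness (`count_distinct_structures()`) fingerprints a
brain by the animat's column at every step of the 128 noise-free trials,
and compares TPMs and wiring diagrams in a label-invariant normal form
(causally inactive hidden elements removed, all within-class relabelings
enumerated, lexicographic minimum kept).

## Known limitations

* The exact IIT analysis enumerates purviews and partitions; it is meant
  for networks of at most ~8 elements (the animat scaffold), not as a
  general-purpose Phi solver.
* Only deterministic gate tables are generated by the genome encoding;
  the analysis engine itself accepts probabilistic TPMs (they arise
  internally from partitions and marginalized backgrounds).
* The Mann-Whitney Z uses the normal approximation, adequate for the
  50-LOD scale of the reference experiments but coarse for very small
  samples.
```
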