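---
title: "Methods: the BiSDL language, its nets-within-nets semantics, and the simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the BiSDL language, its nets-within-nets semantics, and the simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bisdl)
```

## Scope and model

`bisdl` models multicellular synthetic designs at two coupled levels. The
*spatial* level is a two-dimensional grid of compartments (cells or
structures such as a pilus); the *intracellular* level is a gene-circuit
description per compartment. Both levels share one formalism —
place/transition Petri nets over multiset markings — and are coupled by
hosting each compartment's net as a *net token* inside a place of the
grid net. This nets-within-nets construction gives encapsulation (a
scope's entities are private), while two mechanisms cross the membrane:

* **diffusion**: top-level transitions move one colored token (labelled by
  entity name) between adjacent grid places per firing; *mirror bindings*
  keep the entity content of a grid place and of its hosted scope net
  equal, so intracellular production becomes visible to diffusion and
  arriving tokens become visible to the intracellular circuit;
* **synchronous channels** (juxtacrine signalling): an emit transition in
  one scope net and a receive transition in a grid-adjacent partner scope
  net are interlocked — either both fire in the same tick, moving one
  signal token across, or neither does.

## Language and grammar choices

The grammar is keyword-led and indentation-delimited (children are the
following lines with deeper indentation), with `#` comments and a
`k*entity` multiplier syntax where an omitted `k` is 1. Entity base types
(GENE, MRNA, PROTEIN, COMPLEX, MOLECULE) are inferred from the
conventional name suffix (`_gene`, `_mRNA`, ...); unknown suffixes default
to MOLECULE with a validation warning. Reaction-like constructs use an
explicit `inputs -> outputs` arrow (`ENZYMATIC_REACTION(enzyme, a + b ->
c)`), since comma-positional substrate/product lists would be ambiguous.
Grid coordinates are 0-based `(x, y)` with the origin top-left; the
orientation is a convention only — nothing in the semantics depends on it.

One deliberate extension: `MARKING(entity, count)` lines inside a scope
declare initial token counts (default 0). The case studies are described
in the literature without printed initial markings, so the fixtures state
theirs explicitly: one token per gene place, substrates replenished by
source processes, and a plasmid-free recipient cell.

A `PROCESS` line with no body re-instantiates, by name, a process defined
elsewhere in the module; `bisdl_resolve_reuse()` requires the definition
to be unique. Compilation numbers instances module-wide in source order:
the i-th instantiation of process `P` becomes `P_process_<i-1>`, and all
generated places/transitions embed those names for interpretability.

## Construct templates

Each construct kind expands to a fixed net fragment; arc weights always
equal the term multipliers, and within a scope all fragments touching the
same entity name share a single place (stitching):

| construct | template |
|---|---|
| `TRANSCRIPTION(g, m)` | read arc from the gene place (genes persist), output to the mRNA place |
| `TRANSLATION(m, p)` | read arc from mRNA, output to protein |
| `DEGRADATION(x)` | consume, no output (sink) |
| `PROTEIN_COMPLEX_FORMATION(a.., c)` | consume all components, produce the product (last term) |
| `ENZYMATIC_REACTION(e, s.. -> p..)` | enzyme read arc; substrates consumed, products produced |
| `CUSTOM_PROCESS(i.. -> o..)` | literal inputs/outputs (sources/sinks allowed) |

`INDUCERS` and `ACTIVATORS` become read arcs and `INHIBITORS` become
inhibitor arcs (enabled only while the place holds *fewer* matching tokens
than the threshold), on every template. The source language lists inducers
and activators as distinct role keywords without distinguishing their
semantics; this package treats them identically, as presence requirements.

## Time, randomness, and numerical choices

**Timescales.** The module `TIMESCALE` N sets the base pace: a net with
timescale N advances once every N simulator ticks. A process timescale is
a multiplier of the module's, so a construct transition is visited at
ticks divisible by `N_module * N_process`. Over K ticks a net with
timescale T is visited exactly `floor(K/T)` times; two always-enabled
processes at timescales 2 and 5 with firing probability 1 accumulate
firings in the exact ratio 2.5 over 1000 ticks.

**Firing.** Each visited, enabled transition makes *one* firing attempt
per visit, succeeding with probability `p` (default 0.6, overridable per
transition or per run). One attempt per visit keeps the long-run firing
frequency of an always-enabled transition equal to `p`, which makes the
default interpretable and testable. Conflicts between transitions
competing for tokens are resolved by re-shuffling the sweep order of each
net at every visit. Tokens of one colour are indistinguishable here
(markings are label→count multisets), so "pick random tokens among those
available" is the identity and consumes no randomness.

**RNG.** One seeded global stream drives everything. Determinism follows
from a canonical iteration order (top net first, then scope nets in
compilation order) rather than per-net substreams: R's RNG API offers no
cheap independent substreams, and a fixed sweep order gives the same
guarantee — identical model, config, stimuli and seed produce bit-identical
traces and byte-identical trace CSVs.

**Mirrors.** A mirror binding stores the last value both levels agreed
on; on repair, the side that moved becomes the source of truth. If both
sides moved inconsistently within one repair interval the *upper* (grid)
level wins and a warning is raised. The stepper repairs all bindings after
every net's sweep, so at most one side can have moved between repairs and
the conflict branch is unreachable during normal stepping — it exists (and
is tested) as a deterministic safety net.

**Stimuli.** A schedule `(n, r)` adds `Uniform{0..r}` tokens (expected
`r/2`) to its target place at ticks `n, 2n, ...`, *before* the tick's
transition sweep. Tick indexing starts at 1, so `n = 3` first fires at
tick 3.

**Terminal summaries.** Scalar readouts are means over the last 20% of
ticks — long enough to smooth single-tick noise, late enough to reflect
steady behaviour.

## What the fixtures emulate — and what they do not

The three case-study generators reconstruct published designs
behaviourally, not line-for-line (the original sources are not printed in
full anywhere reproducible). Kinetic constants are package choices, fixed
once, with these rationales:

* **Bacterial consortium**: producer process at timescale 2 and sensor
  process at timescale 3 (half and one-third of the base pace). The
  catalytic step yields 3 AHL tokens per firing so that synthesis outruns
  the single-token diffusion and sensor-side decay and the uninduced
  readout is robustly high; LacI turnover sits in the fast timescale-1
  process so a low stimulus (`n=3, r=3`, mean 0.5 tokens/tick) is roughly
  balanced by decay (capacity 0.6/tick) while a high stimulus (`r=10`)
  overwhelms it — yielding the graded, inverse LacI→GFP response.
* **RGB morphogen**: 5×5 grid (the smallest with complete first- and
  second-degree rings); adjacency is the Moore 8-neighbourhood. The
  central receiver translates 8 GFP-ligand copies per firing so its
  display is not supply-limited across 8 simultaneous contacts; the
  mCherry "on" threshold is 5 tokens at tick 60, far below the typical
  induced level (~25–35) and far above the second-degree level (exactly 0,
  since no channel reaches those cells).
* **Plasmid transfer**: replication (`plasmid -> plasmid + ss_strand`,
  activated by the pilus protein) conserves the donor's plasmid count, so
  donor retention is structural, not statistical; the recipient can only
  obtain the plasmid through the two chained channels and must
  circularize the strand before expressing resistance, which makes the
  transfer-before-expression ordering structural too.

A green test therefore establishes ordinal/structural claims — response
ordering across stimulus levels, which cells pattern, event ordering —
under the package's own kinetics. It does **not** establish quantitative
agreement with any published trajectory: absolute token counts depend on
the chosen stoichiometries, and real systems add growth, division, spatial
crowding, resource competition and gradient decay, none of which are
modelled. Paracrine gradients in particular do not decay with distance
here (no decay parameter is defined anywhere in the language).

## Degenerate inputs and tie-breaks

Empty modules (zero scopes) compile to an empty grid. A juxtacrine emit
without a matching receiver is dropped with a warning rather than an
error. Within-scope transition name collisions (e.g. two degradations of
the same entity in one process) are uniquified with a numeric suffix.
The reachability oracle (`nwn_reachable`) ignores probabilities and
timescales — it enumerates the *possibility* semantics, which is exactly
what makes it an independent check on the stochastic stepper.

## Known limitations

* Two hierarchy levels only (grid + scopes); no nets inside scope nets.
* No continuous-time (Gillespie) semantics, no timed transitions, no
  formal verification; reachability is exhaustive only for small nets.
* Channels carry exactly one token per joint firing; multi-token payloads
  must be modelled as repeated firings.
* Simulation configs are JSON rather than YAML (no YAML reader in the
  supported dependency set); field names are unchanged.
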