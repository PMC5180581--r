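---
title: "Model and methods: genome-encoded controllers in an energy-limited swarm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: genome-encoded controllers in an energy-limited swarm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`grnswarm` simulates a swarm of digital organisms ("robots") competing for
regrowing food on a toroidal grid, under purely energetic selection: there
is no fitness function, only an energy ledger, and a population is scored by
how far it can run the habitat down before collapsing below the extinction
threshold of 100 robots. Each robot is steered either by a gene regulatory
network (GRN) read from an artificial genome, or by a fixed-topology neural
network used as the reference controller. This vignette documents the model,
the tunable parameters and their defaults, the numerical choices, and the
limits of what the packaged experiments show.

## The artificial genome

A genome is a set of chromosomes (by default 10 chromosomes of 10,000
characters) over the four-letter digit alphabet `{0,1,2,3}` with positional
complement pairing `0<->3`, `1<->2` — a nucleotide-like space in which
binding is complementarity. Genes are found by scanning each chromosome left
to right for the promoter motif (default `0101`); an accepted gene occupies
`promoter | type field | binding site | payload` (4 + 2 + 4 + 8 characters
by default) and scanning resumes after it, so overlapping promoter hits
resolve to the first one. The two-character type field, taken modulo 3,
assigns one of three gene classes:

* **signalling** genes translate sensor input into the network: a sensor
  channel expresses every signalling gene whose binding site its fixed
  signature matches;
* **regulatory** genes route activation: their product binds other genes'
  binding sites and either activates or represses them (the fifth payload
  character, modulo 2, sets the mode);
* **structural** genes are end products: the payload encodes an actuator
  index and a binary output value (0 or 1), and the expressed product votes
  on that actuator.

A signature matches a binding site when the character-wise complement
distance is at most `genome.match_tolerance` (default 1 of 4 positions), and
the match quality `(4 - mismatches) / 4` scales the transferred dosage.
Binary structural output values were chosen over graded ones because an
actuator output is a dosage-weighted mean: with graded values every mean
collapses towards the middle of the range and all behaviour gates sit on
the decision threshold, whereas 0/1 votes make gating decisive and make the
wiring (which is what mutation acts on) behaviourally consequential.

At replication each character mutates independently with probability
`mutation.point_rate` (always to a different letter), and each chromosome
duplicates a contiguous segment (geometric length, mean
`mutation.duplication_mean_len`, uniform source and insertion point) with
probability `mutation.duplication_rate`. Deletions and inversions are not
modelled.

## The agent layer

Only the environment-activated part of the encoded network is instantiated
at runtime, as *agents* — the gene products. An agent carries its gene's
payload signature and a non-negative concentration (dosage). Every
controller step is the composition

1. `encode_sensors` — map raw readings to bounded channel magnitudes,
2. `activate_signalling` — active channels express matching signalling genes
   (dosage = magnitude x match quality, floored at `grn.c_init`),
3. `transduce` — living signalling/regulatory agents bind matching loci;
   a bound repressor blocks its target outright this step, otherwise a
   regulatory or structural locus with positive summed activation is
   expressed with that activation as dosage,
4. `actuator_outputs` — each actuator emits the concentration-weighted mean
   of its structural agents' values (0 with no contributor),
5. `update_concentrations` — decay, fitness feedback, and deletion of agents
   below `grn.c_min`.

Re-expression of a living agent adds to its dosage (capped at `grn.c_max`)
instead of spawning a duplicate, so a locus never carries more than one
agent. The genome itself is never modified by the controller: a subnetwork
that falls silent remains encoded and is re-expressed whenever its channels
return — this storage property is the central difference from the neural
baseline.

### The feedback law

The concentration update is

`c <- c * (1 - d) * (1 + beta * sign(f) * min(|f| / F, 1) * a)`

with decay `d = grn.decay`, gain `beta = grn.feedback_gain`, scale
`F = grn.feedback_scale`, `f` the robot's net energy change over the last
step, and `a` the agent's *alignment* with the behaviour that earned the
feedback: for a structural agent with value `v` on an actuator currently
emitting `o`, `a = 2(1 - |v - o|) - 1`; signalling and regulatory agents
have `a = 0` and feel pure decay. The alignment weighting implements
per-agent credit — each agent's dosage responds to its own effect on
fitness. A uniform feedback factor would be behaviourally inert here
(actuator outputs are weighted means, invariant under rescaling all
dosages), so it could never produce the within-life adaptation the
architecture is meant to exhibit; with alignment, a robot that gains energy
locks in its current behaviour and a robot that keeps losing energy
gradually rotates towards the dissenting minority of its network —
behavioural switching under starvation.

`F = 5` makes routine living costs (a few tenths of a unit per step) a weak
signal and meals or successful attacks (tens of units) a saturating one;
`beta = 0.3` gives a 30% dosage swing on a saturating event; `d = 0.02`
(half-life ~34 steps) keeps behavioural phases long enough for persistent
search walks; `c_max = 50` lets repeatedly reinforced agents dominate their
actuator rather than pinning every agent at the same ceiling.

### Sensors and actions

Eight channels feed both controller types identically: neighbouring robots
and food sources within the Chebyshev sensing radius (radius 1; the focal
robot is excluded from the robot count, food in the robot's own cell is
included — a robot senses what it stands on, which is what makes a
food-conditioned eating response selectable at all), the energy level, four
decaying traces of recent successful attacks, defences, replications and
feedings, and a constitutive channel of constant magnitude 1. The
constitutive channel is the regulatory analogue of the network bias input:
without it, sensory silence (no food, no neighbours, low energy) would
de-express the whole network exactly when action is most needed.

Seven actuators (`direction`, `move`, `eat`, `attack`, `defend`,
`replicate`, `aggregate`) are read every step. Gates fire above the
threshold 0.5 and exactly one action is taken, by the fixed priority
eat > attack > defend > replicate > aggregate > move; the fractional part of
the direction channel selects one of the eight headings. At execution time
the engine attempts the fired gates in priority order until one succeeds
against the world — an eat on a cell with no accessible food, an attack with
no co-located target, a replication below threshold or an aggregation
without a consenting partner falls through to the next fired gate, with
movement the last resort. Without the fall-through, any robot whose eat gate
stays up on an empty cell would starve in place; with it, a robot with eat
and move gates up is a competent forager: walk, cross food, consume, walk on.

## The world and the energy ledger

The habitat is a 90 x 90 toroidal grid holding typed food sources. Each type
has an access threshold (a robot needs at least that much energy to consume
it) and an energy content; the defaults are thresholds 0/30/60 with contents
30/60/120 and 200 sources scattered initially. Every source replicates into
a uniformly chosen neighbouring cell with probability
`r0 * max(0, 1 - k/K)`, where `k` counts the other sources within its
radius-1 neighbourhood — the higher the local density, the lower the
replication rate. Seasons are 100-step blocks cycling extra survival and
movement costs (`fall and winter differ`).

All selection is energetic. A robot pays a basic living cost plus seasonal
extras every step, movement and attacks and defences cost extra, replication
costs a fee plus the endowment transferred to the offspring (spawned in the
parent's cell), and a robot that cannot cover its upkeep dies the same step
(ending exactly at zero is survival). Successful attacks require strictly
greater strength (energy, plus a defence bonus if the target's defend gate
fired; ties favour the defender) and transfer the fraction
`energy.prey_transfer` of the victim's energy. Robots at full storage
(`energy.satiety`) do not consume food: bounded storage ties the swarm's
food consumption to its actual energetic need, without which populations
strip-mine the habitat in runaway booms. Co-located consenting robots can
fuse into an aggregate that pools and shares energy, is steered by the
unweighted mean of its members' controller outputs, acts (and is attacked)
as one organism with pooled strength, and dissolves below two members.

An instrumented run verifies exact conservation each step: robot energy plus
on-grid food energy plus cumulative dissipated costs (and the untransferred
fraction of prey energy) minus energy created by food growth or restoration
equals the initial total.

## The neural baseline

The reference controller is a feed-forward network over the same sensor and
actuator vectors: 8 inputs (+bias) -> 12 tanh hidden units (+bias) -> 7 tanh
outputs, with weights drawn uniformly from [-1, 1] as a flat heritable
vector, Gaussian-mutated (sigma 0.05) at replication. Within a lifetime the
weights receive reward-modulated per-edge nudges (`eta` times the reward
times a decaying eligibility trace of the edge's pre x post activity), and
rewiring is restricted to zeroing: an edge whose running contribution stays
below `ann.zero_threshold` for `ann.zero_window` consecutive steps is set to
zero and stays zero until replication re-randomises it. `eta = 3e-4` keeps
the baseline competent: at larger rates the chronic small negative rewards
of ordinary living, amplified by the always-on bias eligibility,
systematically depress every active edge and the whole swarm converges to
idleness within ~150 steps, which is a strawman rather than a baseline. The
structural contrast with the GRN is that the network is a single shared
substrate — behaviour lost to weight drift or zeroing is gone for the
lifetime, whereas the genome-backed controller re-expresses stored
subnetworks whenever their cues return.

## The engine

A run is a pure function of (configuration, seed). The step pipeline is
frozen: sense on the start-of-step world; controller updates (the GRN
kernel and the genome scan/wiring run in compiled code; the neural arm is
updated as one batched matrix computation — both are held equal to their
plain-R reference implementations by the test suite); action decisions;
conflict-prone actions in seeded random order over acting units; movement as
one batch (movement is conflict-free, so batching is equivalent to
interleaving and attacks resolve against start-of-step positions); upkeep,
energy sharing and deaths; food growth and scheduled restoration; metrics
every 10 steps; extinction check (strictly fewer than 100 robots). Replicate
experiments derive per-run seeds from a master seed with a counter-based
split, so the two arms use disjoint streams and logging cannot perturb
dynamics.

## Calibrated study conditions and what they show

At full scale this system is characterised by group means for the food
remaining at extinction near 78 (GRN arm) and 120 (neural arm) over 50 runs
per arm, with runs extending to ~3,000 steps; those are the reference values
the package calibrates against, and all ecological and energetic constants
here are the package's own calibrated defaults. The
calibration targeted the group means and the direction and significance of
their difference at desk scale: 10 replicate runs per arm, 800 founding
robots with random genomes, and runs that collapse after roughly 200-350
steps — orders of magnitude less compute than the full-scale horizon. Under these conditions the regulatory-network arm reproducibly
exhausts the habitat to around 60-90 remaining sources before collapsing
while the neural arm collapses with roughly twice as much food left, and
the Welch test separates the arms by several orders of magnitude below the
0.05 level; `scripts/acceptance.R` recomputes exactly these quantities.

Two caveats are part of the honest record. First, at this scale population
persistence is carried by the initial standing crop and the founding
cohort's energy buffer rather than by multi-generation evolution; the slow
multi-season arc of the full-scale system, with extinctions near step
3,000, is out of desk-scale reach because the 100-robot extinction line sits close to the
carrying capacity that the calibrated economy can sustain. The packaged
food-restoration scenario therefore replenishes the habitat shortly before
the collapse point (keeping the full-scale restoration step, 2,600, in the
schedule), and demonstrates the qualitative property — populations that
evolved preying persist past a restoration and keep preying afterwards — on
the desk-scale arc. Second, preying in these short runs peaks while the
large founding population is still crowded and food is already scarce, and
fades as the population thins; the per-run correlation between prey
frequency and food count over the food-scarce tail therefore comes out
positive here, not negative as in full-scale runs where preying builds up
late. The acceptance suite tests the negative-majority property
as specified and reports its failure rather than weakening the check.

## Numerical choices and degenerate inputs

* Complement-mismatch counts between binding codes are precomputed once per
  (alphabet, length) pair and cached; code spaces above 4096 fall back to
  direct digit comparison.
* Genomes are stored as raw digit vectors; the text format (one chromosome
  per line under an alphabet header) round-trips bit-exactly.
* A genome with no promoter occurrences is valid and yields a controller
  that emits neutral outputs forever; a population below the extinction
  threshold at step 0 terminates immediately with the initial food count.
* Aggregates share energy by equalisation before upkeep, so members die
  together rather than piecemeal; an aggregate reduced below two members
  dissolves.
* Ties: equal attack strength favours the defender; the weakest co-located
  robot is targeted (lowest id on ties); gates fire on strictly greater
  than the threshold.
* All randomness flows through R's RNG seeded once per run; derived seeds
  stay below 2^31.

## Session use

```{r example}
library(grnswarm)

cfg <- default_config()
log <- run_simulation(cfg, seed = 1)
print(log)
tail(log$metrics)

ex <- run_experiment(cfg, n_per_arm = 10, master_seed = 1)
print(ex)
```
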