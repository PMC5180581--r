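# grnswarm

An artificial-life platform for studying how controller architecture shapes
the evolution of collective behaviour. A swarm of digital organisms
("robots") forages, preys, aggregates and replicates on a 90 x 90 toroidal
grid holding typed, regrowing food sources under seasonal cost cycles.
Selection is purely energetic — there is no fitness function — and a run
ends when the population falls below the extinction threshold of 100 robots.

Each robot carries one of two controllers over identical sensors and
actuators:

* a **gene regulatory network (GRN)** read from a heritable artificial
  genome: 10 chromosomes of 10,000 characters over the digit alphabet
  `{0,1,2,3}` encode signalling, regulatory and structural genes
  (promoter + type field + binding site + payload). The environment
  activates part of this network, which is instantiated as *agents* — gene
  products with a signature and a decaying concentration *c* updated as

  *c ← c (1 − d) (1 + β sign(f) min(|f|/F, 1) a)*

  where *f* is the robot's energy change and *a* the agent's alignment with
  the behaviour that earned it. Matching is complementarity: a product binds
  a gene whose binding site is within one complement mismatch of its
  signature. Silent subnetworks remain stored in the genome and re-express
  when their cues return.
* a **feed-forward neural network** baseline (8 sensors → 12 tanh hidden →
  7 actuators) with heritable weights, reward-modulated per-edge learning,
  and rewiring restricted to zeroing persistently idle edges.

The headline statistic is the **food remaining at extinction**: better
foragers run the habitat further down before collapsing. Under the packaged
study conditions the GRN arm exhausts food to a mean near 71 sources while
the neural arm collapses with roughly 178 left, a difference the Welch
two-sample t-test separates at p ~ 2e-7.

## Worked example

```r
library(grnswarm)

# one seeded run under the default study conditions
log <- run_simulation(default_config(), seed = 1)
print(log)
#> run_log: seed 1 - 237 step(s), extinct (food at extinction: 66)

subset(log$metrics, step %in% c(0, 100, 200),
       c(step, population, food, preys, prey_freq, mean_energy))
#>    step population food preys prey_freq mean_energy
#> 1     0        800  200     0  0.000000   130.00000
#> 11  100        368   87    14  3.804348    61.46024
#> 21  200        152   69     3  1.973684    48.00892
```

The population of 800 random-genome founders is culled to its viable core
while the standing crop of 200 food sources is grazed down; preying tracks
crowding and scarcity, and the run ends when fewer than 100 robots
remain — here after 237 steps with 66 food sources left.

```r
# the two-arm comparison (10 replicate runs per arm, ~10 minutes)
ex <- run_experiment(default_config(), n_per_arm = 10, master_seed = 1)
print(ex)
#> swarm_experiment: 10 run(s) per arm, master seed 1
#>   grn: 10/10 extinct, mean food at extinction 71.00
#>   ann: 10/10 extinct, mean food at extinction 178.50
#>   Welch t-test (extinct runs): t = -10.865, p = 1.92e-07
```

Every run is a pure function of (configuration, seed): the same pair gives
bit-identical logs. `default_config()` exposes all ecological, energetic and
controller constants as a nested list; see the methods vignette
(`vignettes/grnswarm-methods.Rmd`) for what each parameter means and why the
defaults are what they are.

A thin command-line front end ships in `inst/exec/grnswarm`
(`run`, `experiment`, `analyze` subcommands over YAML configurations and
tab-separated logs).

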