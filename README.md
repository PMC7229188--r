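# netreconfig

Dynamic reconfiguration analysis of functional brain networks during
block-design working-memory tasks, for cognitive-neuroscience researchers
working with ROI-level task fMRI.

Working-memory training changes not just how well people perform an
n-back task but how their brain networks reorganize while they do it.
`netreconfig` implements the full analysis chain used to study that
reorganization, plus a synthetic-data generator that makes every stage
testable against planted ground truth without access to raw fMRI:

* **HRF-weighted functional connectivity** — per-condition and per-block
  weighted Pearson correlations, with weights from the block regressor
  convolved with a canonical double-gamma HRF, Fisher z-transformed,
  positive weights retained;
* **Static modularity** — maximization of
  `Q = (1/2m) Σ_ij (A_ij − γ k_i k_j / 2m) δ(g_i, g_j)`
  by a best-of-restarts Louvain optimizer, normalized against
  degree-preserving rewired null networks (Maslov–Sneppen double-edge
  swaps with weights riding on edges);
* **Multilayer communities** — the 20 block-wise matrices as layers of a
  categorical multilayer network with condition-dependent interslice
  coupling (ω = 1 same condition, ω = 0.5 different), optimized with a
  generalized Louvain over the supra-modularity matrix;
* **Module-allegiance cartography** — co-assignment matrix
  `P_ij = (1/OT) Σ_o Σ_t 1[g_io,t = g_jo,t]` over an ensemble of
  optimizations, summarized as system **recruitment**
  `R_S = n_S⁻² Σ_{i,j∈S} P_ij` and pairwise **integration**
  `I_kl = (n_k n_l)⁻¹ Σ_{i∈S_k, j∈S_l} P_ij`, each normalized by a
  ROI→system label-permutation null;
* **Behavioral scoring** — signal-detection `d′ = Z(H) − Z(F)` with
  0.01/0.99 clamping of extreme rates, modality averaging, session-change
  summaries; and a thin contrast layer (paired/two-sample t-tests,
  Pearson brain–behavior correlations, Bonferroni/BH adjustment).

A config-driven orchestrator (`run_study()`) chains everything for a
whole study, reproducibly from a single master seed.  Any ROI atlas works
— the 264-ROI / 13-system and 300-ROI parcellations common in this
literature are just atlas tables here.

## Worked example

Simulate one session with four planted systems, estimate connectivity,
and measure segregation and system dynamics:

```r
library(netreconfig)

atlas <- system_atlas(rep(c("frontoparietal", "default-mode",
                            "salience", "visual"), each = 15))
spec  <- scenario_spec(n_nodes = 60, atlas = atlas,
                       rho_within = 0.6, rho_between = 0.05, seed = 42)
panel <- generate_panel(spec)
panel
#> ROI time-series panel: 60 ROIs x 300 volumes (TR = 2 s)
#> Blocks: 20  Conditions: 1-back, 2-back

A  <- condition_connectivity(panel, "2-back")
nm <- normalized_modularity(A, n_runs = 20, n_null = 10, seed = 1)
nm
#> Modularity result: Q = 0.44796  Q_normalized = 3.4912
#> Modules: 4  (n_runs = 20 , n_null = 10 , gamma = 1 , seed = 1 )
adjusted_rand_index(nm$partition, atlas$system)
#> [1] 1
```

The optimizer recovers the four planted systems exactly (ARI = 1), and
modularity is ~3.5× what rewired networks of identical degrees and
weights achieve — strong segregation.  Now the dynamic side:

```r
net  <- multilayer_network(block_connectivity(panel))
ens  <- run_ensemble(net, n_opt = 10, seed = 2)
P    <- allegiance(ens)
cart <- permutation_normalize(P, atlas, n_perm = 200, seed = 3)
head(as.data.frame(cart)[, c("measure", "system_k", "system_l",
                             "raw", "normalized")], 5)
#>       measure       system_k       system_l       raw normalized
#> 1 recruitment   default-mode   default-mode 0.9395556  3.2515573
#> 2 recruitment frontoparietal frontoparietal 0.9511111  3.3070623
#> 3 recruitment       salience       salience 0.9626667  3.3252990
#> 4 recruitment         visual         visual 0.9413333  3.2133267
#> 5 integration   default-mode frontoparietal 0.0400000  0.1667439
```

Each planted system stays in its own module across nearly all blocks and
optimizations (raw recruitment ~0.95, more than 3× the size-matched
permutation null), while different systems almost never merge
(normalized integration ≪ 1) — exactly the planted dynamics.  Behavior:

```r
trials <- simulate_trial_table(n_subjects = 21, seed = 4)
d      <- subject_dprime(trials)
dprime_change(d, from = "Naive", to = "Late")[
  , c("condition", "mean_before", "mean_after", "pct_improvement")]
#>   condition mean_before mean_after pct_improvement
#> 1    1-back    2.215349   2.940485        32.73234
#> 2    2-back    2.087699   3.047601        45.97891
```

With the generator's default training trajectory (hit rate 0.7 → 0.9),
group-mean d′ improves by ~46% in the 2-back condition from the first to
the last session.

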