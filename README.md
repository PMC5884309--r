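# apathynet

Structural-connectome analysis of apathy in cerebral small vessel disease
(SVD), as a tested, reusable R pipeline.

Apathy in SVD is hypothesised to reflect disruption of the *reward
circuit* — anterior cingulate, orbitofrontal and medial frontal cortex,
putamen (incorporating the accumbens), amygdala and temporal poles —
rather than global disconnection. Testing that hypothesis with diffusion
MRI requires a chain of methods that are rarely available together as
tested code:

* **Deterministic tensor tractography** on voxelized principal-direction /
  FA fields, terminating at inter-voxel angles ≥ 40° or FA < 0.2;
* **Length-weighted connectomes** over the 90 cerebral AAL nodes, with
  edge weights
  `w_ij = 1/2 * Σ_m 1/l_m`
  (half the sum of inverse streamline lengths) and a group mask keeping
  edges present in ≥ 30 subjects;
* the **network-based statistic (NBS)**: edgewise correlation of weights
  with the apathy score, thresholded at |t| ≥ 2.5, connected components
  scored by extent against a permutation null of maximal extents
  (family-wise-error-corrected cluster p-values);
* **weighted global efficiency** `E = (1/(k(k-1))) Σ_{i≠j} 1/d_ij`
  (edge length 1/w, disconnected pairs contribute 0) and sum-of-weights
  on three a-priori sub-networks — reward (16 nodes), motor (6) and
  visual (10);
* **apathy scoring** from six yes/no Geriatric Depression Scale items,
  and **partial correlations** (residualization) testing whether reward
  efficiency explains apathy variance beyond the control networks, and
  beyond age + four vascular risk factors.

Because the original patient MRI cannot be redistributed, the package
includes a first-class synthetic-cohort generator (`simulate_cohort()`)
producing 90-node connectomes with realistic noise structure, a
discretized apathy score (mean 2.9, SD 1.7 at the defaults), demographic
covariates, and a configurable planted effect that weakens
reward-network edges with increasing apathy. Tensor phantoms
(`make_straight_bundle_phantom()`, `make_bent_bundle_phantom()`) provide
tractography substrates with known geometry.

## Worked example

Simulate a 114-subject cohort with the calibrated reward effect, run the
whole chain, and inspect the results:

```r
library(apathynet)

co <- simulate_cohort(cohort_spec(effect_beta = calibrated_effect_beta(),
                                  rng_seed = 7))
co
#> svd_cohort: 114 subjects, 90 nodes, 25% edge density, apathy 2.73 (1.69), effect_beta = 0.03

mask <- group_edge_mask(co, min_subjects = 30)
res <- nbs(co, mask, co$table$apathy,
           nbs_config(n_permutations = 5000, tail = "negative", rng_seed = 8))
res
#> nbs_result: t >= 2.50, 5000 permutations, tails: negative
#>   negative tail, component 1: 31 edges, 16 nodes, p_fwer = 0.004599 *
#>   negative tail, component 2: 1 edges, 2 nodes, p_fwer = 0.858
#>   negative tail, component 3: 1 edges, 2 nodes, p_fwer = 0.858

m <- network_metrics(co)
pearson(m$reward_eff, co$table$apathy)
#> r = -0.3137 (df = 112, t = -3.496, p = 0.0006777)

tab <- specificity_table(m, co$table$apathy)
subset(tab, metric == "efficiency" & control != "none")[, c(1, 2, 4, 6, 7)]
#>   network control            r            p significant
#> 2  reward   motor -0.319982295 0.0005504152        TRUE
#> 3  reward  visual -0.315228878 0.0006718696        TRUE
#> 5   motor  reward  0.067183601 0.4795476806       FALSE
#> 6   motor  visual  0.005143162 0.9568833514       FALSE
#> 8  visual  reward  0.073784992 0.4373453051       FALSE
#> 9  visual   motor  0.065654998 0.4896232143       FALSE
```

The NBS finds one significant negative cluster (31 edges among 16 nodes,
p = 0.0046, FWER-corrected), concentrated in the reward sub-network where
the effect was planted; the two stray single-edge components are not
significant. Reward efficiency correlates negatively with apathy
(r = −0.31 in this cohort; ≈ −0.35 in population) and remains significant
when controlling for either control network, while motor and visual
efficiencies explain nothing once reward is controlled — the specificity
pattern the pipeline is designed to detect.

`run_all(run_config(...))` performs the same chain from a single seeded
configuration and writes `metrics.csv`, `specificity.csv`,
`nbs_report.json`, `t_matrix.csv`, `report.json` and a hash-carrying
`MANIFEST.json`; outputs are byte-reproducible given the seed. A thin
command-line wrapper ships at `inst/scripts/run_pipeline.R`.

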