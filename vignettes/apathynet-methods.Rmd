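---
title: "Methods: reward-network efficiency and apathy in simulated SVD connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reward-network efficiency and apathy in simulated SVD connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apathynet)
```

## The scientific question

Apathy — diminished motivation and goal-directed behaviour — is common in
cerebral small vessel disease (SVD), where diffuse white-matter damage
disconnects grey-matter regions. A mechanistic hypothesis is that apathy
arises specifically from disruption of the *reward circuit* (anterior
cingulate, orbitofrontal and medial frontal cortex, ventral striatum,
amygdala and temporal poles) rather than from global disconnection.
`apathynet` implements the analysis chain used to test this hypothesis
with structural connectomes:

1. deterministic tensor tractography with angle/FA termination rules,
2. length-weighted connectome construction over the 90 cerebral AAL nodes,
3. the network-based statistic (NBS) correlating every edge with apathy,
   with permutation family-wise error control,
4. weighted global efficiency and sum-of-weights of three a-priori
   sub-networks (reward, plus motor and visual as experimental controls),
5. Pearson and partial correlations testing whether the reward network
   explains variance in apathy beyond the control networks and beyond
   age and vascular risk factors.

Patient MRI of this kind is not publicly available, so the package ships a
synthetic-cohort generator whose planted effects make every stage testable
end-to-end, including its false-positive control and its power to recover
a reward-specific association.

## Apathy score

Apathy is measured as the count of apathetic responses over six yes/no
Geriatric Depression Scale items ("prefer to stay at home", "avoid social
gatherings", "dropped activities and interests", "find life very
exciting", "hard to start new projects", "full of energy"), the last two
reverse-scored because they are positively phrased. `apathy_score()`
refuses incomplete item sets rather than imputing. The integer score runs
0–6.

## Tractography model

`track()` implements FACT-style deterministic propagation on a voxel grid
of principal directions and FA values (a `tensor_phantom`): seeds at every
voxel center with FA ≥ `fa_stop`, bidirectional stepping of `step_mm`
along the current voxel's principal direction (nearest-voxel lookup — no
interpolation, matching the per-voxel phrasing of the termination rule),
with the eigenvector sign realigned at each step. A streamline terminates
when it would enter a voxel with FA < `fa_stop` (default 0.2, below which
tensor directions are unreliable), when the angle between the current and
next voxel's principal directions — compared as undirected axes — reaches
`angle_stop_deg` (default 40°), or when it would exit the volume. The
offending point is never appended, so every retained point sits in a
trackable voxel. Defaults the termination thresholds do not fix:
`step_mm` = half the smallest voxel dimension, `min_length_mm` = two voxel
lengths, one seed per voxel. Whether the 40° rule applies per step or per
voxel transition is ambiguous in the usual description; per voxel
transition is implemented.

Tensor fitting, registration and real acquisitions are out of scope; the
phantoms (`make_straight_bundle_phantom()`, `make_bent_bundle_phantom()`)
provide corridors with known geometry so each termination rule can be
exercised in isolation: a straight corridor must be traversed end-to-end,
a 45°-per-voxel bend must stop every streamline, a 39.9° bend must not.

## Edge weights and the group mask

Streamlines are assigned to the unordered pair of AAL labels at their two
endpoints (background or same-label streamlines are dropped; intermediate
crossings do not count). The edge weight is

$$w_{ij} = \frac{1}{2} \sum_{m=1}^{N} \frac{1}{l_m},$$

increasing in streamline count and decreasing in streamline length.
Group-level analysis keeps only edges present (weight strictly positive)
in at least 30 of the subjects — absent edges enter the statistics as
exact zeros, since a disconnected pair's natural connectivity value is 0.

## Network-based statistic

For each masked-in edge, the Pearson correlation between edge weight and
apathy across subjects is converted to
$t = r\sqrt{n-2}/\sqrt{1-r^2}$; edges with $|t| \ge 2.5$ (≈ two-tailed
p ≤ 0.01 at n = 114) are supra-threshold. Connected components of
supra-threshold edges are scored by *extent* (edge count) and referred to
a permutation null: the apathy vector is shuffled (5000 permutations by
default), the maximal component extent recorded each time, and

$$p_{\text{FWER}} = \frac{1 + \#\{\text{perm max extent} \ge \text{observed extent}\}}{B + 1}.$$

The +1 correction keeps p above zero; ties count against the observed
component (conservative). Tails are analysed separately (never on
$|t|$ jointly); perfect correlations are capped at $t = \pm 10^9$, which
affects no ordering. Nuisance covariates do not enter the NBS stage; they
enter the partial-correlation stage below.

## Sub-network metrics

The three a-priori sub-networks resolve against the AAL-90 atlas to
16 (reward), 6 (motor) and 10 (visual) nodes; reward and motor share the
bilateral putamen (AAL-90 has no separate accumbens node — the putamen
node incorporates it). Weighted global efficiency of a sub-network is the
mean inverse shortest-path length over its ordered node pairs, with edge
length $1/w$ and $1/d = 0$ for disconnected pairs. Two choices the verbal
definition leaves open are made explicit: the connectivity-to-distance map
is $1/w$ (the standard choice of the usual toolbox), and paths are
restricted to the induced subgraph — efficiency of the reward network may
not route through non-reward nodes. Because efficiency is sensitive to
disconnection, the simpler sum of within-subnetwork weights is computed
alongside. Shortest paths are delegated to igraph's Dijkstra; the test
suite checks them against an independent Floyd–Warshall implementation on
hundreds of random graphs.

## Partial-correlation specificity testing

`partial_correlation()` residualizes both variables on an intercept plus
the controls by least squares and correlates the residuals — equivalent to
the recursive formula, generalizing to any number of controls, with
df = n − 2 − #controls and two-tailed t-based p-values. Binary risk
factors enter as 0/1 columns; rank-deficient designs are refused with the
collinear columns named. `specificity_table()` assembles the full matrix:
each network's metric against apathy, marginally, controlling for each
other network, and controlling for age plus the four vascular risk
factors (hypertension, hypercholesterolemia, diabetes, smoking).

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions the pipeline is meant
for: 114 subjects, 90 nodes, and an apathy score with mean 2.9 and
SD 1.7. Its pieces, and what they do and do not emulate:

* **Base connectome.** Node coordinates uniform in a 120 mm cube;
  baseline weights decay exponentially with distance (30 mm scale) and
  the strongest 25% of pairs are kept, giving a shared sparsity pattern
  of realistic density. Real connectomes have community structure and
  hemispheric symmetry this does not reproduce.
* **Apathy.** A discretized normal truncated to 0–6. The published-style
  summary (mean 2.9, SD 1.7) fixes only two moments; the latent normal is
  moment-matched numerically (`optim`) so the *realized* discrete score
  attains them. Skewness is a free choice; the symmetric choice is made.
* **Noise.** Multiplicative log-normal, unit mean, in three parts: a
  small global per-subject factor (CV 0.02), a per-subject factor for
  each anatomical *system* — by default the three sub-network node sets —
  applied to edges wholly inside that system (CV 0.15), and independent
  per-edge noise (CV 0.05). The system factors model per-subject
  variation in the integrity of the fiber systems supporting each circuit
  (cingulum/uncinate for reward, corticospinal for motor, optic
  radiations for visual). This structure was chosen because the generator
  must support three properties at once: a population reward-efficiency
  correlation near −0.35, edge-level t-statistics able to cross 2.5 so
  NBS can find clusters, and control networks that do *not* explain
  apathy variance once reward is controlled. Pure per-edge noise fails
  the first two jointly (it averages out of efficiency); a single strong
  global factor fails the third (controlling for reward then induces a
  spurious positive partial correlation in the control networks — a
  collider — and occasionally fires the entire network in NBS).
* **Planted effect.** Every edge with both endpoints in the target
  sub-network (default: reward) is scaled by
  $\max(0, 1 - \beta \cdot \text{apathy})$ — damage lowers connectivity,
  which lowers efficiency, mirroring the causal framing. The calibrated
  slope `calibrated_effect_beta()` = 0.030 was fixed once by a pilot
  sweep at large n so the population reward-efficiency–apathy correlation
  is ≈ −0.35; at n = 114 this yields a significant negative marginal
  correlation and a majority-reward NBS component in at least 90% of
  simulated cohorts, and the specificity pattern (reward survives control
  for motor/visual, motor/visual do not survive control for reward) in at
  least 80% (both rates recomputed by the acceptance script and the test
  suite). In rare cohorts the sparsification leaves a control sub-network
  with no edges at all; its constant metric makes the partial correlation
  degenerate and such cohorts count as specificity failures.
* **Covariates.** Age ~ N(70, 9.6²); risk factor prevalences 88.6%
  (hypertension), 91.2% (hypercholesterolemia), 19.3% (diabetes), 52.6%
  (smoking), independent of apathy by default so covariate adjustment is
  testable under a known null; `age_apathy_r` optionally couples age to
  apathy through a Gaussian copula.

Passing tests on these cohorts show the machinery is correct and well
calibrated under the stated noise model; they cannot show that real SVD
cohorts satisfy that model (no registration error, no tractography bias,
no lesion topology, linear effect of apathy on weights).

`cohort_to_streamlines()` inverts the edge-weight equation (bundle count
`max(1, round(S·w))`, all lengths `N/(2w)`) so the connectome builder can
be exercised against known weights; the round trip is exact up to
floating point, comfortably within the 5% that count rounding alone would
allow.

## Numerical and procedural choices

* Eigenvector sign ambiguity: directions are compared as axes
  (absolute dot product) and re-signed along the direction of travel.
* Zero-variance edges get t = 0 (no evidence), zero-variance scores are
  an error.
* Permutation count defaults to 5000; simulation studies in the tests use
  1000 to keep runtimes reasonable, which only coarsens the p-value grid.
* The FWER of the cluster test is assessed on the negative tail (the tail
  of scientific interest); per-tail alpha is 0.05. Running both tails
  doubles the family.
* One master seed spawns per-stage child seeds (`spawn_seeds()`), so any
  stage can be re-run in isolation with the stream it had in a full run;
  `run_all()` output is byte-reproducible given a seed.
* Problem sizes used by the simulation studies: 200 null cohorts for the
  empirical FWER, 100 effect cohorts for power and specificity, 500
  random graphs for the efficiency oracle, 2000 replicates for p-value
  uniformity — sizes at which the binomial noise of the estimated rates
  is well inside the margins being checked.

## Known limitations

* Tractography is nearest-voxel FACT on a supplied direction field; no
  tensor fit, interpolation, or probabilistic variant.
* Endpoint-only streamline-to-node assignment; a streamline crossing a
  node mid-course does not contribute to that node's edges.
* The NBS stage supports correlation with a score only, not general
  linear model contrasts.
* Efficiency restricted to the induced subgraph is one reading of the
  verbal definition; the alternative (paths through out-of-network nodes)
  is not implemented.
* The generator's planted effect is linear in the score and confined to
  within-subnetwork edges; real disease effects are neither.
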