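---
title: "Methods: the compositional landscape of replicated community trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the compositional landscape of replicated community trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question

When a bacterial community is revived from cryopreservation and grown
repeatedly under identical conditions, do the replicates wander apart
(stochastic assembly), or do they converge on a reproducible final
composition determined by where the community started? `mclandscape`
implements the statistical machinery for answering this with replicated
16S amplicon data: each *trajectory* is one starting (parent) community
plus four replicate final communities, and the analysis asks whether
final compositions are predictable from starting ones, whether both
occupy a small number of compositional *classes* (operational stand-ins
for attractors), and which individual ASVs carry the information that
decides a trajectory's fate.

# Data model and quality filters

Counts are held as plain integer matrices (samples × ASVs) validated by
`count_table()`; compositions by `rel_abund()`. Two filters are applied
before any statistics, in this order: ASVs with fewer than 100 reads
summed across all samples are removed, then samples with fewer than
10,000 sequences. "Fewer than" is strict, so totals equal to the
threshold survive. The ASV filter is applied jointly across every table
of a study (start, final, and any additional sequenced pool) so all
stages share one ASV universe; this is configurable. Rarefaction
(`rarefy()`, default 10,000 reads, without replacement via
`vegan::rrarefy`) exists for visualisation and for the resampled class
centroids only — the propensity and superposition stages always use
unrarefied data.

# Community classes

Pairwise dissimilarity is the Jensen–Shannon divergence
$\mathrm{JSD}(p,q) = \tfrac12 KL(p\|m) + \tfrac12 KL(q\|m)$, $m=(p+q)/2$,
with $0\log 0 = 0$ so zeros need no pseudocounts. We use log base 2, which
bounds the divergence in $[0,1]$, and hand downstream stages the square
root, which is a metric — the standard enterotyping choice, and a
requirement for principal-coordinates analysis to behave. Both choices
are exposed (`base`, `as_distance`).

Classes come from partition-around-medoids (`pam_cluster()`): a
deterministic greedy BUILD seeding followed by steepest-descent SWAP.
SWAP is a local search; `restarts` extra descents from random seeds are
available and recover the exhaustive optimum on all small instances we
test, but the default is 0 restarts so the pipeline is deterministic
without a seed. The number of classes is chosen by scanning k
(`scan_k()`) and scoring each partition with the Calinski–Harabasz index
$CH = \frac{B/(k-1)}{W/(n-k)}$. CH needs a Euclidean embedding, so it is
computed in the principal-coordinates space of the same distance matrix
(all positive-eigenvalue axes; negative eigenvalues are dropped and the
negative-inertia fraction recorded). Both the global CH maximum and all
local maxima are reported, because real data sets can present several
defensible class numbers and a smaller local maximum is often preferred
for interpretability; `pin_k` pins the choice.

Class sharpness is quantified by ANOSIM (`anosim_test()`): all
$M=n(n-1)/2$ dissimilarities are ranked (average ranks on ties) and
$R = (\bar r_B - \bar r_W) / (n(n-1)/4)$, near 0 for random groupings
and 1 when groups are completely separated. Significance uses label
permutations preserving group sizes with the add-one estimator
$p = (\#\{R^\ast \ge R\} + 1)/(B+1)$, 1000 permutations by default.

Each final replicate is typed independently (mirroring a design where
each replicate is a complete sample set); labels are then harmonised
across replicates by pairing classes with minimal Jensen–Shannon
distance between medoid profiles, and renumbered so class 1 is the most
populated final class. That convention anchors the later group
definitions ("SF1" is the class-1 core) to a fixed side.

# Rigid-body superposition

To ask whether the final composition is a geometrically simple image of
the starting one, `kabsch_fit()` finds the translation and proper
rotation minimising the RMSD between the paired matrices: centre both on
their column means, take the SVD of the cross-covariance
$X_c^\top Y_c = USV^\top$, and set $Q = U\,\mathrm{diag}(1,\dots,1,
\det(UV^\top))\,V^\top$ (the determinant correction forbids
reflections; no scaling is applied — this is superposition, not full
Procrustes). The rotation matrix is materialised explicitly: at the ASV
dimensions this package operates on after filtering (a few hundred
columns) the $p \times p$ SVD costs well under a second, so the added
transparency of an explicit operator is worth the memory. The null model
(`randomised_rmsd_ci()`) refits after shuffling all cells of the
starting matrix — destroying sample and ASV structure while keeping the
value distribution — 50 times, and reports the 2.5/97.5 percentiles. An
observed RMSD below that interval means the pairing carries real
geometric signal. Prediction quality on held-out replicates is judged by
correlating the first two SVD component scores (left singular vectors ×
singular values, matrices centred on their own column means by default)
of the transformed starts against each holdout; component signs are
aligned to non-negative correlation, which cannot change $R^2$.

# Attractor geometry

The centroid of a final class (`class_centroid()`) follows a
resample-then-median recipe: every member is resampled once as a
multinomial draw of 10,000 reads from its relative abundances, the
per-ASV median is taken across members, and the result renormalised.
Medians are taken on resampled *counts* (not on relative abundances),
which makes members commensurate regardless of their original depth and
keeps the centroid robust to a few outlying communities; an
`n_resamples` option averages several rounds. Each starting community is then
positioned by its distance to each final-class centroid and to the class
*border*, the closest member community of that class. A query that is
itself part of the reference class is excluded from its own border
search. Note that no inequality links border and centroid distances in
general. `class_mean_distance()` summarises the geometry at class level.

# Trajectory types and ASV propensities

A trajectory is convergent to class c when all four replicate final
classes equal c ("C1", "C2"), and divergent ("D") otherwise; parents
with missing replicates are excluded with a warning. For each ASV $i$,
trajectory type $T$ and time point $t$, the propensity is

$$\mathrm{Prop}_i(T, t) = \log\frac{P(X_i > 0 \mid a \in T)}
{P(X_i > 0)}$$

with presence meaning at least one read (threshold configurable) and
probabilities estimated as occurrence fractions; natural log by default.
A type in which an ASV never occurs gives $-\infty$, carried explicitly
and never significant. Confidence intervals come from resampling
communities with replacement (labels travelling with rows), 1000
bootstrap tables per time point, 2.5/97.5 percentiles; draws that lose a
whole type stratum are redrawn and counted. An ASV is positively
associated with a type when the lower CI bound is positive.

One subtlety deserves emphasis. If every community in the table belongs
to exactly one of the three types, the law of total probability forces
$\sum_T P(T)\,e^{\mathrm{Prop}(T)} = 1$, so an ASV can never be
significantly positive for all three types at once — yet a
"cosmopolitan" group (positive for all three types at both time points)
is a meaningful and observed category. The resolution is that real
studies sequence more communities than they assay: the marginal
$P(X_i>0)$ is estimated from *every* sequenced community (including
starting communities that were never revived, and any samples excluded
from trajectory typing), while the conditional uses only the typed ones.
`propensity()` therefore accepts a `marginal_extra` table; with the
default `NULL` the identity above holds exactly and is enforced by a
test. In `run_all()` the marginal pool is the union of all tables, and
the simulator generates an unassayed starting pool (383 communities by
default) precisely so this mechanism has something to detect.

Groups are assigned from the twelve-cell significance signature (6 cells
per ASV: three types × two time points): `cosmopolitan` = all six cells;
`SF1` = class-1-convergent at both time points, not cosmopolitan, and
not also class-2-convergent at both time points (an ASV pointing at both
attractors is near-cosmopolitan, not a core); `SF2` mirrored; everything
else keeps its raw signature string so users can aggregate as they
please.

# Tipping points

`threshold_classify()` encodes the headline decision rule: a community
is predicted convergent-to-class-1 when its summed SF1 relative
abundance exceeds 0.125 while its cosmopolitan sum stays at or below
0.2; mirrored for class 2; and unpredictable when both sums are high or
both low — imbalance between the two groups is what makes a fate
predictable. The thresholds are configuration defaults, not fitted
values; an accuracy-maximising threshold search is deliberately *not*
bundled into the pipeline.

# The synthetic study fixture

`simulate_communities()` generates data with the statistical structure
the analysis assumes, as study conditions rather than tuning dials: 275
parents in 5 starting classes, 4 replicates each (1100 microcosms),
15,000 reads per sample, 2 final classes, 300 ASVs of which 25 are
planted SF1 and 25 cosmopolitan, plus 383 unassayed starting
communities. The generative family is Dirichlet-multinomial — the
minimal model giving compositional classes with overdispersion; the
analysis asserts class structure, not a generative law, so this is an
explicit modelling assumption. Start classes share one background
composition (Dirichlet with a uniform floor keeping background ASVs
present everywhere) tilted per class by a log-normal factor
(sd 1.2), and differ in their planted group shares: classes 1, 2 and 4
are SF1-rich (class-1 side of the tipping point), class 3 is
cosmopolitan-rich, and class 5 sits on the knife edge. Communities are
Dirichlet draws around their class base (concentration 2000, chosen so
classes are tight enough for the CH scan to recover k = 5 reliably at
n = 150); reads are multinomial.

Fates implement the tipping point generatively: the probability that a
replicate lands in final class 1 is
$\mathrm{logit}^{-1}(\mathrm{logit}(\pi_{k1}) + \gamma(z - z_0))$ where
$\pi$ is a baseline transition matrix (uniform by default), $z$ is the
parent's SF1-minus-cosmopolitan summed abundance and $\gamma$
(`tipping_noise`, default 25) the gain; $\gamma = 0$ reduces to the
bare transition matrix, which is how forced-convergence and fair-coin
sanity cases are constructed. Final compositions mix the final-class
base (SF1 boosted ×12 in class 1, cosmopolitan ×12 in class 2) with a
15% carryover of the parent profile, which is what makes replicates of
one parent cluster (ANOSIM R ≈ 0.7 over 275 groups) and the start→final
map approximately rigid. The two final classes share one background
tilt, so background ASVs carry no fate association and planted-group
recovery is a fair test. The unassayed pool lacks both planted groups,
giving the cosmopolitan group its wide-marginal signal.

What the simulator does *not* emulate: real taxonomic abundance
distributions (no long neutral tail beyond 300 ASVs), sequencing-depth
variation between samples, chimeras or other artefacts upstream of the
ASV table, and any mechanistic dynamics (no Lotka–Volterra). Passing
tests on this fixture shows the estimators recover structure of the
planted kind at realistic sizes — not that real communities have that
structure.

# Numerical choices and degenerate inputs

* Pairwise JSD uses the entropy identity
  $H(\tfrac{p+q}{2}) - \tfrac12 H(p) - \tfrac12 H(q)$ in compiled code,
  clamped at 0 against rounding; a naive double-loop KL oracle in the
  test suite pins it to 1e-12.
* PAM ties (BUILD, SWAP, nearest-medoid) all resolve to the lowest
  index; swaps require an improvement larger than 1e-12.
* Permutation and bootstrap p-values/CIs use add-one and percentile
  conventions respectively; bootstrap draws losing a type stratum are
  redrawn, not silently skipped.
* Zero-sum samples are rejected before normalisation; empty filter
  results are legal (with a warning for samples) but downstream stages
  refuse them.
* All randomness flows through explicit seeds; `run_all()` derives one
  child seed per stage from the global seed, so single stages can be
  reproduced in isolation and reruns are byte-identical.

# Problem sizes used in the checks

The bundled tests exercise the oracle comparisons at n = 10–40 samples,
Kabsch recovery at n = 100 × p = 50, superposition signal detection over
40 simulated runs (n = 60 × p = 40, 50 shuffles each), class-number
recovery over 20 seeds at n = 150, bootstrap calibration over 100 runs
of n = 200 communities with 200 bootstrap tables, and one full-scale
end-to-end run (275 + 383 + 1100 samples, 1000 bootstrap tables). These
sizes keep a complete run of the suite around a minute on one core
while leaving every statistical claim testable at the fixture's scale.

# Known limitations

* PAM without restarts is a deterministic local search; on adversarial
  instances it can land a few percent above the global optimum.
* The CH criterion inherits its known bias towards well-separated
  spherical classes in the embedding; strongly nested or elongated
  class structures may favour other k than a human would.
* Propensity significance is a per-cell marginal test; no multiplicity
  correction is applied across ASVs, so group membership lists should
  be read as enrichment summaries, not per-ASV discoveries.
* The bootstrap CI degenerates for ASVs present in every community of a
  stratum (zero variance on one side); with a wide marginal pool this
  can flag minute effects as significant. The grouping rules mitigate
  this, but very large marginal pools deserve a sensitivity check.
* Border distances depend on sampling density of the reference class:
  sparse classes have optimistic (large) borders.
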