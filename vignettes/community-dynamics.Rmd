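---
title: "Modeling synthetic gut community dynamics with recurrent networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling synthetic gut community dynamics with recurrent networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(micos)
```

## The problem

Synthetic microbial communities assembled from defined species pools are a
central tool for understanding and engineering microbiome functions such as
the production of fermentation end products (butyrate, lactate, acetate,
succinate). Classical ecological models -- foremost the generalized
Lotka-Volterra (gLV) equations -- describe community assembly through
per-species growth rates and pairwise interactions, but cannot represent
higher-order interactions (a third species modifying a pairwise effect) or
feedbacks between metabolites and growth. micos implements a recurrent
neural network (LSTM) alternative: a data-driven nonlinear dynamical system
trained directly on time-resolved abundance (and optionally metabolite)
measurements, together with the surrounding toolchain a practitioner needs
-- a ground-truth simulator for benchmarking, interpretation methods that
recover interaction structure from the trained network, model-guided
community design, and clustering of metabolite trajectories.

## The ground-truth simulator

The generator integrates

$$\frac{dx_i}{dt} = \Big(r_i + \sum_j a_{ij} x_j + \sum_{j \ne i}
\sum_{k \ne i,j} b_{ijk}\, x_j x_k\Big)\, x_i ,$$

with abundances $x_i$ in OD-equivalent units, growth rates $r_i$ (1/h), a
pairwise interaction matrix $a_{ij}$ and an optional third-order tensor
$b_{ijk}$ whose entries with $j = i$ or $k \in \{i, j\}$ are structurally
zero. Metabolite trajectories, when requested, follow linear
production/consumption dynamics $dc_m/dt = \sum_i p_{mi} x_i$ (mM), a
deliberately simple cross-feeding surrogate.

Choices a user should know about:

* **Parameter distributions.** `generate_ground_truth()` draws
  $r_i \sim U(0.1, 0.8)$ 1/h, self-limitation $a_{ii} \sim U(-1.5, -0.5)$,
  and off-diagonal $a_{ij} \sim N(-0.15, 0.2)$. The competition-dominated
  off-diagonal distribution mirrors the character of published gLV fits to
  real gut communities, where most inter-species effects are weakly negative
  and much smaller than self-limitation. This matters twice: strongly mixed
  random interaction matrices make random high-richness communities
  dynamically unbounded, and they make high-richness behavior an emergent
  property that no model class can learn from low-richness data. All three
  distributions are arguments.
* **Third-order levels.** `mild` and `moderate` draw every admissible
  $b_{ijk}$ uniformly with support bounded by 25% and 50% of the largest
  off-diagonal $|a_{ij}|$. The bound is anchored to the *interaction*
  coefficients: the self-limitation diagonal is not an interaction between
  species, and anchoring to it makes every dense moderate draw blow up. The
  tensor is dense by default, with an optional sparsity fraction.
* **Initial conditions.** Present species start from an equal split of a
  configurable total, by default 0.0066 OD per species, echoing a typical
  experimental inoculum. Absent species are exactly zero and stay exactly
  zero through simulation, passaging and observation noise (the gLV flow
  and the multiplicative noise model both preserve zeros).
* **Integration.** Adaptive Runge-Kutta (deSolve `ode45`) with
  rtol $10^{-6}$, atol $10^{-9}$, states clipped at zero at reporting
  times; a trajectory that becomes non-finite (or exceeds $10^6$) raises an
  error naming the species and time. Strong random mutualism can genuinely
  diverge in finite time; the benchmark therefore rejects a drawn ground
  truth whose training or hold-out simulations blow up and redraws with the
  next derived seed.
* **Passaging.** `simulate_with_passaging()` divides all abundances by
  `dilution_fold` (default 20) every `period` hours (default 24) and resets
  metabolites to fresh-medium values; a sample falling exactly on a passage
  time reports the pre-dilution state.
* **Observation noise.** Multiplicative log-normal,
  $x \mapsto x\,e^{\sigma z}$ with $\sigma = 0.1$ by default, applied to
  sampled abundances only.

## The LSTM dynamical model

Each shared-weight LSTM unit advances the community state by one sampling
interval:

$$\begin{aligned}
i_t &= \sigma(W_{ii} x_t + b_{ii} + W_{hi} h_{t-1} + b_{hi}) &
f_t &= \sigma(W_{if} x_t + b_{if} + W_{hf} h_{t-1} + b_{hf}) \\
g_t &= \tanh(W_{ig} x_t + b_{ig} + W_{hg} h_{t-1} + b_{hg}) &
o_t &= \sigma(W_{io} x_t + b_{io} + W_{ho} h_{t-1} + b_{ho}) \\
c_t &= f_t \odot c_{t-1} + i_t \odot g_t &
h_t &= o_t \odot \tanh(c_t)
\end{aligned}$$

and the *output gate* is mapped linearly to the next state,
$y_t = W_{yo}\, o_t + b_{yo}$. Mapping $o_t$ rather than $h_t$ is a
deliberate architectural choice of this model family; it is what
`lstm_cell_step()` implements and what all gradients assume. During
free-running prediction $y_t$ is fed back as the next input, so a whole
trajectory is forecast from the state at time zero.

**Standardization.** Every feature (species, metabolite) is standardized to
zero mean and unit variance *per time point*, with the population (1/N)
variance convention and a $\sigma$ floor of $10^{-8}$ (constant features map
to 0). Statistics come from training data only; a `normalize_all` argument
can pool additional tables, mirroring the common toggle, but hold-out
statistics are never used implicitly. Metrics are always computed on the
de-standardized scale.

**Teacher forcing.** `train_teacher_forcing()` minimizes the mean squared
error of standardized outputs at every observed time point. At each step of
each sequence, with probability `teacher_forcing_prob` (default 0.5; never
published for the original models, so exposed in the configuration) the true
observation replaces the fed-back prediction as input. The randomization is
a per-step, per-sequence Bernoulli draw. Gradients are exact: backpropagation
through time includes the feedback path of every free-running step, which we
verify against central finite differences in the test suite.

**Optimization.** Adam with the canonical schedule: learning rate from
\{0.005, 0.001, 0.0001\} decayed by 0.25 every 25 epochs, L2 weight decay
$10^{-5}$, minibatches of 10-20 sequences. The historical full-scale models
used 2048 hidden units (abundance-only) or 4096 (joint); the package
defaults are desk-scale (tens to hundreds of units) and every value is a
`training_config()` argument. Weights are initialized uniformly on
$(\pm 1/\sqrt{H})$ under a fixed seed; a fixed seed makes the whole loss
history bitwise reproducible on CPU. One practical note encoded in the
defaults of our tests: endpoint-only training (below) has a much sparser
gradient signal than trajectory training and needs a longer, flatter
schedule (e.g. halving every few hundred epochs) than the 0.25/25 schedule,
which is tuned for per-step losses.

**Model variants.**

* *Trajectory model* -- features are the species abundances; one LSTM unit
  per sampling interval.
* *Endpoint model with metabolite head* (`train_endpoint()`,
  `attach_metabolite_head()`) -- when only initial and final observations
  exist, the model unrolls `n_steps` units free-running and a feed-forward
  network (ReLU hidden layers, linear output) maps the final abundance
  output to metabolite concentrations; abundance and metabolite losses are
  weighted equally on standardized scales and trained end-to-end. With no
  intermediate truths a per-timepoint scaler is undefined mid-rollout, so
  endpoint mode uses one global per-feature scaler.
* *Joint model* (`build_joint_model()`) -- species and metabolites are
  concatenated into one feature vector (29-dimensional for the full
  25-species, 4-metabolite system) that the rollout propagates, letting
  metabolite concentrations feed back into growth predictions.

## Interpretation

* `lime_explain()` draws binary perturbations of a community's presence
  vector (presence bits, not abundances: the question is what a species'
  *presence* does), queries the model, and fits an exponentially
  kernel-weighted ridge surrogate (defaults: 5000 perturbations, kernel
  width $0.75\sqrt{d}$, ridge penalty 1). On models that are exactly linear
  in presence the coefficients are recovered within a few percent.
* `build_explanation_network()` aggregates explanations into a signed
  network: edge weight is the median explanation across instances, targets
  must pass a cross-validated predictability gate ($R^2 > 0.5$, strict),
  species-to-species weights are normalized by the target's self-impact,
  and edges below 5 mM (metabolite targets) or 0.2 (species targets) are
  dropped.
* `gradient_sensitivity()` freezes the trained weights and computes exact
  reverse-mode derivatives of every output at every rollout step with
  respect to the inputs at a chosen time. The sign gives the direction of
  the local effect, the magnitude its strength; agreement with central
  finite differences to $10^{-4}$ relative is part of the test contract.
* `subsample_sensitivity()` and `pairwise_sensitivity()` quantify how
  prediction performance depends on training-set size and on species
  co-occurrence. The pairwise statistic is
  $100/N^2 \sum_i \sum_{j \ne i} (R^2_{ij} - R^2_i)/R^2_i$, implemented
  with the $N^2$ normalizer exactly as conventionally printed even though
  the sum has $N(N-1)$ terms; `normalizer = "pairs"` selects the
  alternative. Pairs whose community subset is empty or too small for a
  defined correlation are skipped with a warning -- real datasets guarantee
  dozens to hundreds of communities per pair, synthetic ones may not.

## Model-guided community design

`enumerate_designs()` streams all presence/absence combinations above a
richness cutoff without materializing them (the 25-species pool has
26,434,916 designs of richness $\ge$ 11). Two selection schemes operate on a
table of predicted metabolite profiles:

* *Distributed*: k-means (k-means++ initialization, 10 seeded restarts) in
  the four-dimensional metabolite space, then the unique nearest community
  per centroid.
* *Corners*: sequential two-level tail binning -- the 5% lowest lactate then
  lowest/highest butyrate of those (and the symmetric pair anchored on
  butyrate), then within each of the four corners the same construction on
  acetate/succinate -- yielding 16 sub-corner classes; each contributes one
  seed-random design plus four designs greedily maximizing the minimum
  Hamming distance to those already picked (ties broken lexicographically;
  an exhaustive max-min search is available for small candidate sets).
  Percentile boundaries are closed on the extreme side, and every bin is
  floored at `min_bin` rows (default: the per-sub-corner count) so that the
  construction remains well defined on tables much smaller than the tens of
  millions of predictions it was conceived for: with strict 5% bins a
  $10^5$-row table would leave sub-corners with less than one expected row.
* `classify_corners()` treats the 16 groups as classes (centroids = mean
  predicted profile), assigns each community the centroid nearest its
  predicted and its measured profile, and reports the confusion structure
  against inter-class centroid distance -- nearby classes are confused
  first.

## Trajectory clustering and design rules

`trajectory_vectors()` flattens each community's metabolite trajectories
(e.g. 4 metabolites x 3 time points = 12 dimensions; the dimension is
data-driven, not hard-coded), averaging replicate communities by default.
`mst_cluster()` builds the complete Euclidean graph, takes its minimum
spanning tree (Kruskal with ties broken by the smaller index pair, so the
result is fully deterministic; zero-weight edges between duplicate
trajectories are kept), and divisively removes the largest remaining edge
whose removal leaves every component at least `min_cluster_size` strong
(default 6 clusters, minimum size 5); inadmissible edges are returned and
logged. `elbow_curve()` tabulates the size-weighted mean of within-cluster
average pairwise distances over a grid (an unweighted variant is an option)
and `elbow_point()` picks the largest second difference.
`decision_tree_rules()` fits an unpruned CART tree (Gini, no depth limit,
features in pool order) on presence bits and extracts, per cluster, the
condition conjunction on the path to the leaf holding most of that
cluster's communities, together with rule coverage and the deviating
communities.

## The benchmark and the scales used

`run_insilico_benchmark()` is the end-to-end comparison: a drawn ground truth
generates noise-free training data over all monospecies, all pairs and
random 3-/5-/6-member communities, and high-richness hold-out communities;
a pairwise-only gLV is fitted by multistart Adam on a differentiable
RK4-unrolled least-squares loss (one start is a log-derivative regression
warm start); an LSTM is trained on the identical data; both are scored by
the squared Pearson correlation of predicted vs. true abundances at the
final time, pooled over hold-out communities and species. Under pairwise
truth the two are expected to be comparable; under moderate third-order
truth the misspecified gLV degrades; adding high-richness communities to
the LSTM's training set removes its richness-extrapolation bias.

Default problem sizes, chosen once as the package's desk scale: a
12-species pool (large enough that 200 distinct hold-out designs of
richness $\ge$ 9 and 40 disjoint augmentation designs of richness 9-10
exist, which an 8-10 species pool cannot provide), 150 training
communities (12 + 66 + 24 + 24 + 24), 6 time points every 8 h, LSTM with
192 hidden units trained 200 epochs in minibatches of 10, and a gLV fit
with 3 starts x 300 iterations. A full two-scenario run takes a few
CPU-minutes.

Two caveats the defaults encode honestly. First, at this scale and with
noise-free data the multistart gLV fit converges essentially to the global
optimum, so under pairwise truth its hold-out accuracy is near-perfect --
historically reported gaps between the two model families under pairwise
truth partly reflect the difficulty of optimizing a 649-parameter ODE fit,
which a 156-parameter fit does not reproduce. Second, among *bounded*
random ground truths the realized third-order contribution is limited by
the very stability that makes them simulable, so the fitted pairwise model
retains much of its accuracy and the LSTM's advantage under moderate
third-order truth is measured in hundredths of $R^2$, not the tenths seen
with the original (unpublished) ground-truth parameters. The benchmark
still asserts the stated margins; where a margin is unattainable under
these study conditions the corresponding check reports a failure rather
than a softened threshold.

## What passing tests do and do not show

The synthetic generator emulates gLV dynamics with known structure, exact
zeros for absent species, equal inocula, and simple linear metabolite
kinetics. Real communities violate all of these: measurement noise is
heteroscedastic and compositional (sequencing depth), inocula vary,
metabolite kinetics saturate, and environmental drift changes interactions
over time. Passing the package's tests shows the algorithms are implemented
correctly and behave as designed on data of known provenance; it does not
certify prediction accuracy on experimental data, which must be established
per dataset (the trajectory CSV dialect accepts such data unchanged).

## Known limitations

* Pure-R training: comfortable up to a few hundred hidden units and a few
  thousand sequences; the full-scale 2048/4096-unit configurations are
  supported but slow on CPU.
* No Bayesian posteriors over gLV parameters and no ensemble/Bayesian LSTM.
* The gLV fit assumes the pairwise model class; it reports its best loss
  but no identifiability diagnostics.
* Corner selection assumes unimodal-ish tails; with strongly multimodal
  prediction clouds the 5% bins may mix modes.
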