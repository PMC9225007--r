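# micos

Predicting and designing the dynamics of synthetic microbial communities —
species abundances and fermentation end products (butyrate, lactate,
acetate, succinate) — with a recurrent neural network, and benchmarking it
against the generalized Lotka-Volterra (gLV) model it is meant to surpass.

micos is aimed at microbiome researchers who assemble defined bacterial
communities bottom-up (e.g. from a 25-member human gut species pool) and
want to (i) forecast whole community trajectories from the inoculum alone,
(ii) understand which species drive which metabolites, (iii) choose the
next set of communities to build, and (iv) group communities by their
temporal metabolite behavior.

## The models

**Ground truth / benchmark simulator.** Generalized Lotka-Volterra dynamics
with optional third-order interactions,

    dx_i/dt = ( r_i + Σ_j a_ij x_j + Σ_{j≠i} Σ_{k≠i,j} b_ijk x_j x_k ) x_i ,

plus periodic 20-fold dilution ("passaging"), multiplicative observation
noise, and linear metabolite production — everything needed to emulate a
bottom-up community experiment with known truth.

**LSTM dynamical model.** One shared-weight LSTM unit per sampling
interval,

    i_t = σ(W_ii x_t + b_ii + W_hi h_{t-1} + b_hi)      (input gate)
    f_t = σ(W_if x_t + b_if + W_hf h_{t-1} + b_hf)      (forget gate)
    g_t = tanh(W_ig x_t + b_ig + W_hg h_{t-1} + b_hg)   (cell gate)
    o_t = σ(W_io x_t + b_io + W_ho h_{t-1} + b_ho)      (output gate)
    c_t = f_t ⊙ c_{t-1} + i_t ⊙ g_t
    h_t = o_t ⊙ tanh(c_t)
    y_t = W_yo o_t + b_yo ,

with the prediction `y_t` fed back as the next input, so whole trajectories
are forecast from time zero. Training uses randomized teacher forcing
(truth replaces the fed-back prediction with configurable probability at
each step), per-timepoint feature standardization, and Adam with the
0.25-per-25-epochs learning-rate schedule; the forward pass, full
backpropagation through time (including the feedback path) and the
optimizer are implemented in the package and verified against finite
differences. Variants: an endpoint model with a feed-forward metabolite
head trained end-to-end, and a joint model that propagates the
concatenated species+metabolite vector (29-dimensional at full scale).

Around the two model families: LIME-style local surrogate explanations and
their network aggregation, exact gradient sensitivities, training-size and
species-pair prediction-sensitivity statistics, exhaustive design
enumeration with k-means ("distributed") and extreme-tail ("corner")
selection, and minimum-spanning-tree divisive clustering of metabolite
trajectories with decision-tree design rules. See the methods vignette
(`vignettes/community-dynamics.Rmd`) for the science and every default.

## Worked example

```r
library(micos)

# draw a ground truth with third-order interactions and metabolite kinetics
truth <- generate_ground_truth(8, third_order = "mild", seed = 7,
                               metabolites = TRUE)
#> <glv_params> 8 species; max|a| = 1.32; max|b| = 0.114; 4 metabolites

# simulate the canonical low-richness training design, scaled to 8 species
pool <- gut_species_pool()[1:8]
designs <- design_training_communities(pool, n3 = 15, n5 = 15, n6 = 10, seed = 1)
tab <- simulate_glv(truth, designs, times = seq(0, 48, by = 16))
#> <trajectory_table> 76 sample(s), 4 time points (0-48 h), 8 species, 4 metabolites

# train the joint species+metabolite LSTM with randomized teacher forcing
cfg <- training_config(hidden_dim = 48, epochs = 120, batch_size = 10,
                       lr_decay_every = 50, seed = 2)
model <- train_teacher_forcing(tab, cfg,
                               model = build_joint_model(8, 4, 48, seed = 2))
tail(model$loss_history, 1)
#> 0.0408

# forecast unseen 6-8 member communities from their initial state alone
test_d <- design_test_communities(pool, n = 20, min_richness = 6,
                                  exclude = designs, seed = 3)
test_tab <- simulate_glv(truth, test_d, times = seq(0, 48, by = 16))
x0 <- cbind(test_tab$X[, 1, ], test_tab$C[, 1, ])
pred <- rollout(model, x0, n_steps = 3)
pearson_r2(as.numeric(pred[, 4, 1:8]), as.numeric(test_tab$X[, 4, ]))  # abundance, 48 h
#> 0.987
pearson_r2(pred[, 4, 9], test_tab$C[, 4, 1])                           # butyrate, 48 h
#> 0.991

# which species' inocula drive endpoint butyrate? (standardized derivatives)
g <- gradient_sensitivity(model, c(rep(0.0066, 8), rep(0, 4)),
                          scale = "standardized")
sort(g[3, "butyrate", 1:8], decreasing = TRUE)[1:3]
#>   PC   BT   PJ
#> 0.28 0.15 0.03
```

The hold-out numbers mean the trained network, given only which species
were inoculated, reproduces 98–99% of the variance in both community
composition and butyrate concentration at 48 h for communities it never
saw; the gradient panel ranks PC and BT as the strongest positive butyrate
drivers under this particular ground truth.

A thin command-line wrapper over the same functions ships in
`inst/cli/micos.R` (subcommands `groundtruth`, `simulate`, `designs`,
`cluster`).

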