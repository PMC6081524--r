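---
title: "Swarm-calibrated topic models and diversity-based ensemble pruning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swarm-calibrated topic models and diversity-based ensemble pruning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`swarmlda` implements a two-stage pipeline for categorizing bag-of-words
documents, of the kind used for biomedical abstract collections. Stage one
represents documents in a low-dimensional topic space whose hyperparameters
are calibrated by a population metaheuristic scoring candidate
configurations with internal cluster-validity indices. Stage two classifies
documents in that space with a committee of base classifiers that has been
*pruned* for diversity: pairwise diversity measures are averaged into a
combined diversity matrix, classifiers are clustered in diversity space,
and only the most accurate member of each cluster votes.

This vignette explains the models, the tunable parameters and the numerical
decisions, in the order the pipeline runs them.

## The topic model and its sampler

Latent Dirichlet allocation assumes each document `d` mixes `k` topics with
proportions $\theta_d \sim \mathrm{Dirichlet}(\alpha \mathbf{1}_k)$, and
each topic `t` is a distribution over the `V` vocabulary terms
$\phi_t \sim \mathrm{Dirichlet}(\beta \mathbf{1}_V)$. Every token draws a
topic $z \sim \mathrm{Cat}(\theta_d)$ and then a word
$w \sim \mathrm{Cat}(\phi_z)$. Both priors are symmetric: nothing in the
method requires asymmetric concentrations, and symmetric priors keep the
configuration vector at four numbers, `[k, alpha, beta, n_iter]`.

`fit_lda()` runs a collapsed Gibbs sampler: $\theta$ and $\phi$ are
integrated out and each token's topic is resampled from

$$p(z_i = t \mid \cdot) \propto (n_{d,t}^{-i}+\alpha)\,
  \frac{n_{t,w}^{-i}+\beta}{n_t^{-i}+V\beta},$$

where the counts exclude token `i`. Point estimates are read off the final
state, $\theta_{d,t} = (n_{d,t}+\alpha)/(N_d+k\alpha)$ and
$\phi_{t,w} = (n_{t,w}+\beta)/(n_t+V\beta)$. We use a single final-state
estimate — no burn-in discarding, no averaging across samples — because it
makes a fit a pure function of `(corpus, config, seed)`, which the outer
calibration loop relies on: a candidate configuration must always map to
the same fitness. The cost is extra Monte-Carlo variance in any single fit;
the calibration treats that variance as part of the objective.

Correctness of the sampler is established at desk scale: on a two-document,
two-term, two-topic corpus the distribution of assignment states after one
sweep, over ten thousand seeded restarts, is compared by a chi-square test
against the exact distribution obtained by enumerating all sixteen initial
states and every per-token transition.

Held-out documents are *folded in*: their tokens are resampled with
$\phi$ frozen at the trained estimates, so
$p(z_i = t \mid \cdot) \propto (n_{d,t}^{-i}+\alpha)\, \phi_{t,w}$. Test
documents therefore never influence the topics — the evaluation protocol
depends on this to be leak-free.

## Rating a configuration: internal validity indices

A configuration is rated by clustering quality: documents are partitioned
by dominant topic ($\arg\max_t \theta_{d,t}$, ties to the smallest index)
and the partition is scored with one of four internal indices — BIC of a
spherical-Gaussian cluster model, Calinski-Harabasz, Davies-Bouldin, or
Silhouette. All use Euclidean distance. CH and SI are
larger-is-better; BIC and DB are negated so the optimizer always
maximizes.

Two decisions here deserve explanation.

**The points being clustered are fixed term-frequency rows, not the
candidate's own topic rows.** Internal indices compare partitions of a
fixed data set. If each candidate's partition were scored on that
candidate's own $\theta$ rows, the data representation would change with
`k`, and lower-dimensional embeddings win for free: on a five-topic
synthetic corpus the silhouette of $\theta$-row partitions *decreases*
monotonically in `k` (about 0.74 at `k = 2` against 0.62 at the true
`k = 5`), so every search collapses to the smallest admissible `k`.
Scoring the same partitions on length-normalized term-frequency rows
(`document_points()`) removes the self-reference; the silhouette then peaks
sharply at the generative topic count (0.52 at `k = 5` against 0.22 at
`k = 2`).

**A candidate must use all `k` of its topics.** The indices only see the
partition, so a 15-topic model in which ten topics dominate no document is
indistinguishable from the induced 5-cluster model — measured over an
alpha/beta grid, every `k` from 5 to 15 ties at the same maximal silhouette
once surplus topics go unused, which would make the calibrated `k`
arbitrary within the tie. A candidate whose partition has fewer non-empty
clusters than its nominal `k` therefore receives the degenerate-fitness
sentinel (−10^18), as does any partition an index cannot rate (a single
cluster, coincident centroids, and so on). The sentinel repels the
optimizer without crashing it.

Printed-formula ambiguities in the indices' sources are resolved toward
the canonical definitions: Davies-Bouldin uses the within-cluster mean
scatter $S_i$ in its numerator, and the silhouette's between-cluster term
divides by the size of the *compared* cluster. BIC's sample-size term `n`
is the number of points, with `v = K·d + 1` free parameters (cluster means
plus one shared variance, floored at 10^-8 so identical points stay
finite).

## The metaheuristics

Five population optimizers are provided over a box-bounded real vector:
genetic algorithm, particle swarm, firefly, cuckoo search and bat
algorithm. The shipped defaults are, per stage:

| algorithm | calibration stage | clustering stage |
|---|---|---|
| GA | crossover 0.6, mutation 0.033 | same |
| PSO | inertia 0.33, c1 0.34, c2 0.33 | inertia 0.70, c1 = c2 = 1.5 |
| FA | alpha 0.8, gamma 0.5, delta 0.85 | alpha 0.6, gamma 0.3, delta 0.95 |
| CSA | p_a 0.5 | p_a 0.3 |
| BA | loudness 0.4, pulse 0.4, fq in [0, 2] | loudness 0.5, pulse 0.5 |

with population 20 evolved for 20 iterations in both stages. All five share
one contract: uniform random initialization in the box, exactly
`n_iterations` generation updates, clipping to the box before every
evaluation, elitist global-best tracking (the fitness trace is monotone
non-decreasing by construction), and determinism given the seed. `NaN`
fitness values are demoted to −∞ with a warning. Equal lower and upper
bounds pin a dimension to a constant, which is how a user fixes `k` while
calibrating the rest.

Update rules are the canonical real-coded forms: tournament selection
(size 2) with uniform crossover and per-gene Gaussian mutation (sd = 10% of
the range) for GA; the standard velocity update for PSO; brightness-ranked
pairwise attraction with geometrically decaying randomization for the
firefly algorithm; Mantegna Lévy flights (exponent 1.5) with re-randomized
worst nests for cuckoo search; frequency-tuned velocity updates with
loudness-gated acceptance for the bat algorithm. One numerical choice is
not canonical textbook form: the firefly attractiveness
$\exp(-\gamma r^2)$ uses $\gamma$ *per squared box diagonal*. A raw
$\gamma$ makes the exponent scale with both the units and the
dimensionality of the search space — in a hundred-dimensional box the
attraction term vanishes and the swarm degenerates to a random walk — while
the scaled form makes the same $\gamma$ value meaningful in any space.

## Calibrating the topic model

`search_lda_config()` wraps an optimizer around the fitness above. The
search box defaults to `k` in [2, 100], `alpha` and `beta` in [0.01, 1] and
`n_iter` in [50, 500]; `k` and `n_iter` are rounded at decode. One Gibbs
fit is run per candidate, always with the same `lda_seed` — a deliberate
bias/variance trade: averaging several fits per candidate would smooth the
fitness but multiply its cost, while a fixed seed at least makes the
fitness a deterministic function of the candidate. A cache keyed by the
decoded configuration absorbs the frequent collisions that rounding
produces.

On the standard synthetic corpus (five topics, 200 documents of 50 tokens,
alpha 0.1, beta 0.01), a silhouette-guided bat search with the deliberately
small budget of population 10 and 10 iterations recovers `k = 5` in ten of
ten seeds (`scripts/acceptance.R` recomputes this).

## Diversity-based pruning

The classifier library is trained on the training split and evaluated on
the validation split, yielding the binary *oracle matrix* (classifier ×
instance correctness). For each pair, the 2×2 joint correctness counts
(n11, n10, n01, n00) feed five measures: Q-statistic, correlation,
disagreement, double fault, and Cohen's kappa on the correct/incorrect
table. Kappa has no printed formula in the sources naming it, so the
standard two-rater kappa is used. The correlation coefficient is the
standard phi coefficient — with the square root in the denominator, which
one printed rendering omits; the worked value on counts (6, 2, 2, 0) is
−4/16 = −0.25. A denominator of zero in Q, rho or kappa only occurs when
the numerator also vanishes and is returned as 0 (no measurable
association).

To combine measures into one matrix, each component is min-max normalized
over its off-diagonal entries and direction-aligned — Q, rho, DF and kappa
grow with *similarity*, so they enter as one minus the normalized value;
disagreement already grows with diversity — then averaged, with the
diagonal forced to zero. Direction alignment is an interpretation (the
sources say only that the values are "normalized" before averaging), but
without it the average of a similarity and a dissimilarity is meaningless.
A component that is constant off-diagonal carries no ranking information
and contributes a flat 0.5 with a warning. The default component set is
Q-statistic, correlation, disagreement and double fault; all 31 non-empty
subsets of the five measures can be enumerated for experimentation
(`enumerate_measure_subsets()`).

Classifiers are then clustered in diversity space: classifier `i` is the
`i`-th row of the combined matrix. An optimizer agent encodes `k` cluster
centres and is scored by the negative total Euclidean distance of
classifiers to their nearest centre. Centres are parameterized as
*medoids*: the agent is a vector of `k` row indices, continuous during the
search and rounded at decode. This keeps the search `k`-dimensional
whatever the library size. The free-coordinate alternative (`k × L`
numbers) was measured and rejected: on a 12-classifier library with `k`
clamped to 11, all five optimizers at the default budget left only 2–4
centres in use, because almost all of a high-dimensional bounding box is
empty space that attracts no classifier — the pruned ensemble collapsed to
two members. With medoid encoding the same budget reaches near-optimal
coverage. Requested `k` (default 20) is clamped to `L − 1` when the library
has `L ≤ k` members.

From each non-empty cluster the member with the highest validation
accuracy survives (ties to the smallest index). The pruned committee votes
by majority; voting ties break toward the class with the larger
training-set prior, then the smaller class id.

## Evaluation protocol

`make_fold_plan()` shuffles instances within class and deals them
round-robin into ten folds. Rotation `r` tests on folds `{2r, 2r+1}`,
validates on `{2r+2, 2r+3} (mod 10)` and trains on the remaining six — a
6/2/2 split in which every fold is a test fold exactly once over five
rotations, so each document is tested exactly once. A `single_split` flag
restricts to the first rotation. Metrics are accuracy, macro-averaged F
(one-versus-all F per class, 0/0 counted as 0, unweighted mean) and
micro-averaged F (pooled counts; identical to accuracy for single-label
prediction — both are reported because they diverge under missing or
multi-label predictions).

`run_pipeline()` chains everything per rotation: calibrate (or accept) the
LDA configuration on the training split, represent all three splits in
topic space, build the oracle, combine diversity, cluster, prune, vote,
score. Aggregates are plain means over rotations. A failed rotation is
reported as incomplete rather than aborting the run.

## The synthetic-data generator

`generate_synthetic_corpus()` draws corpora from the LDA generative process
itself and returns the ground truth (`theta_true`, `phi_true`, per-token
assignments, dominant topics). Class labels are the dominant topic of each
document, which gives the classification stages a label signal consistent
with the representation the pipeline learns. The standard test conditions
are five topics with `alpha = 0.1`, `beta = 0.01` — sparse mixtures and
concentrated topics, i.e. documents mostly about one thing and topics with
distinctive vocabulary, the regime topic models are designed for — at two
scales: 200 documents × 50 tokens (V = 100) for recovery experiments and
500 documents × 60 tokens (V = 150) for classification experiments. Problem
sizes were chosen so the whole suite, including the ten-seed calibration
experiment, runs in minutes on one core.

What the generator does *not* emulate: real abstracts have heavy-tailed
document lengths (here fixed), burstiness and stop-word structure (here
multinomial draws from smooth topics), label noise (here labels are exact
functions of theta), and class imbalance (here classes are as balanced as
Dirichlet draws allow). Passing tests therefore demonstrate that the
machinery is correct and that the method recovers planted structure under
its own model assumptions — not that it attains any particular accuracy on
real corpora.

## Known limitations

- Nominal-`k` calibration relies on the all-topics-used validity rule; on
  corpora where the sampler leaves topics empty at the true `k` (very small
  alpha and short documents), the search will prefer the largest fully-used
  `k`, which can sit below the generative count.
- The single-fit fitness inherits sampler variance; a configuration at a
  fitness plateau boundary can flip rank between `lda_seed`s.
- Medoid-encoded clustering cannot place a centre between classifiers; for
  very small libraries with `k` close to `L` this is exactly what one
  wants, but for large libraries with few clusters a free-centroid encoding
  could in principle do better than any medoid set.
- Majority voting ignores classifier confidence by design (soft and
  weighted voting are out of scope).
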