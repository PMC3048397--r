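---
title: "Maximum-entropy null models for bipartite degree distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-entropy null models for bipartite degree distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Bipartite ecological networks — plants and their pollinators, seed
dispersers, or herbivores — typically show strongly skewed degree
distributions: many specialists with one or two partners, a few generalists
with many. Skewness is often read as the footprint of ecological or
co-evolutionary processes. `bimaxent` implements the opposing null
hypothesis: that the shape of a degree distribution carries no information
beyond the sizes of the two groups and the number of links, so the least
biased expectation is the maximum-entropy distribution under exactly those
constraints. Departures from this null — not skewness per se — are then the
interesting signal.

## The null model

For the animal (consumer) side of a network with $S_P$ plants, $S_A$
animals and $L$ links, a degree can take values $\{1, \dots, S_P\}$ (a
taxon with no links is not part of an observed network) and the mean degree
is $L/S_A$. The MaxEnt distribution maximizes Shannon entropy
$-\sum_i p_i \log p_i$ subject to $\sum_i p_i = 1$ and
$\sum_i i\,p_i = \mu$; by Lagrange multipliers it has the exponential form
$p_i = C e^{-\lambda i}$. The plant side is symmetric with the roles of
$S_P$ and $S_A$ exchanged. With $\mu$ below the support midpoint
$(n+1)/2$, $\lambda > 0$ and the distribution is decreasing — the
"many-specialists, few-generalists" shape arises with no ecology in it.

`solve_maxent(n, mu)` finds $\lambda$ as the unique root of
$\mathrm{mean}(\lambda) = \mu$. Since the mean is strictly decreasing in
$\lambda$, a geometrically grown bracket plus Brent's method is globally
convergent; a Newton polish tightens the constraint residual to
$10^{-10}$. The pmf is assembled in log space with a log-sum-exp
normalizer, so supports of $10^4$ and extreme $\lambda$ do not overflow.
Boundary means ($\mu = 1$ or $\mu = n$) return explicit point masses
flagged `degenerate` instead of failing: very small webs do reach these
bounds, and sampling and $\sigma_M = 0$ stay well defined. The tests
cross-check the solver against an independent constrained-optimization
oracle (barrier method on the simplex with the constraints eliminated
exactly) to $10^{-6}$ for $n \le 12$, and check the $n \to \infty$
geometric limit.

## Measuring fit

Two complementary statistics compare an observed degree sequence with its
MaxEnt null.

**Randomized G test.** $G = 2\sum_i O_i \ln(O_i/E_i)$ over the support,
with $O_i$ the observed count of degree $i$ and $E_i = N p_i$. Because the
usual asymptotics are unreliable at ecological sample sizes, significance
comes from randomization: `trials` (default 10,000) same-length sequences
are drawn from the null and $f_G$ is the fraction of trials whose $G$ lies
strictly below the observed one (ties count as non-exceeding; they have
measure zero in floating point). Under the null $f_G$ is approximately
uniform, so $f_G \ge 0.95$ rejects at the 95% level and the type-I rate is
~5% — the suite verifies this at 1,000 replicates.

**Calibrated relative width.** $W = \log(\sigma_O/\sigma_M)$ measures
whether the observed distribution is broader ($W > 0$) or narrower
($W < 0$) than the model. Population standard deviations (divide by $N$)
are used on both sides, so the ratio compares like with like; the
convention cancels in $W$. The null distribution of $W$ is simulated with
the same draw machinery and $W_{95}$ anchors the observed $W$ at the null
median, normalized by the half-width of the central 95% interval on the
matching side (linear-interpolation quantiles):
$$W_{95} = \frac{W_{obs} - \tilde W}{q_{97.5} - \tilde W} \;\;
  (W_{obs} \ge \tilde W), \qquad
  W_{95} = \frac{W_{obs} - \tilde W}{\tilde W - q_{2.5}} \;\;
  (W_{obs} < \tilde W).$$
By construction $|W_{95}| > 1$ for about 5% of null sequences — also
verified by the suite. A constant observed sequence has $\sigma_O = 0$ and
propagates as $W_{95} = -\infty$: maximally narrow, never a good fit.

A distribution counts as **well fit** only if both criteria are
unremarkable: $f_G < 0.95$ and $-1 < W_{95} < 1$ (`classify_fit()`).
`maxent_fit()` computes both statistics from one shared ensemble of null
draws; the two statistics are functionals of the same null, so sharing the
ensemble halves the cost without changing either calibration (the
standalone `goodness_of_fit()` and `w95()` draw independently).

## Food webs as bipartite networks

Mutualistic webs are bipartite by nature; food webs are not, but their
basal taxa (plants and detritus — taxa that consume nothing) and the
consumers of those basal taxa form a natural bipartite counterpart.
`reduce_foodweb()` keeps exactly that subgraph: basal status is "no
outgoing consumption links", with an explicit `detritus_labels` override
for webs that record outflows from detritus; cannibalistic self-loops are
ignored; consumers with no basal prey, and basal taxa nobody eats, drop
out entirely (degree distributions start at 1). Reducing an
already-bipartite web is a no-op, which the tests assert.

## The heterogeneous-system model

Large pollination webs assembled across islands or across years are often
unions of sub-communities glued together by one ubiquitous generalist.
`coupled_spec()` / `evaluate_coupled()` model this: one sub-web animal
degree sequence of length `sub_SA` is drawn from the MaxEnt null on
$\{1..S_P\}$ with mean `sub_CB * sub_SP`, duplicated (`k_subwebs`
identical copies, default 2), and the copies' most general animals are
merged into a single shared animal whose plant sets are disjoint across
copies — so its degree is the sum and the merged system has
$k\,S_A - (k-1)m$ animals and $k\,S_P$ plants (39 and 40 at the default
$20 \times 20$ sub-webs with one shared generalist). Ties for "most
general" are broken by position; identical copies make any consistent rule
equivalent. The merged sequence is then fit exactly as an empirical web
would be: support $\{1..k\,S_P\}$, mean = realized links / animals.

Two opposing effects shape the outcome. The shared super-generalist
broadens the distribution (positive $W_{95}$), while duplicating one
sample narrows it and doubles the weight of its sampling fluctuations
(inflating $G$). At the default connectance 0.25 the simulation shows a
consistently positive mean $W_{95}$ and majority rejection by the dual
criterion even though every sub-web is itself MaxEnt — heterogeneity alone
manufactures apparent structure. At higher sub-web connectance the
narrowing effect dominates the width statistic while $G$-rejection
strengthens; the broadening-with-connectance intuition does not survive
the calibration, which is why the package reports both statistics
per iteration.

## Synthetic networks

`generate_network()` realizes explicit link sets for five regimes:
`maxent_null` (animal degrees from the null, links to distinct plants
uniformly at random), `hub_injected` (a null web plus one super-generalist
touching a set fraction of plants), `truncated_narrow` (degrees above a
null quantile redrawn below it), `coupled_subwebs` (the heterogeneity
model as an explicit graph), and `random_binomial` (independent links —
the classical random bipartite graph, whose binomial degree law the tests
verify by chi-square). Only the animal side is controlled; the plant side
is *emergent*, close to binomial, and for larger or denser webs it is
significantly narrower than a MaxEnt null — a realistic feature (random
link placement is not entropy-maximizing for the partner side) that tests
must not treat as a defect. Plants left unlinked by random assignment are
handled by redrawing the assignment up to 100 times, then dropped, with
realized sizes reported; empirical incidence matrices likewise contain
only interacting taxa. Generation is bit-reproducible from a seed.
`generate_foodweb()` builds layered webs (basal / consumers / top
consumers) and records the ground-truth bipartite reduction alongside, so
the reducer is tested against construction rather than against itself.

## Survey statistics

`analyze_network()` fits both sides of one web and attaches a size class
(`small` $S < 135$, `large` $S > 140$, `excluded` in the 135–140 gap —
published bipartite food-web compilations stop near 134 taxa, so
like-with-like comparisons split there, and the gap is labeled rather than
silently assigned). `survey_networks()` derives one seed per network from
a master seed and the network's name, making surveys order-independent and
reproducible. `tabulate_fits()` produces good-fit counts and fractions per
stratum and side; `fisher_exact_2x2()` (sum-of-smaller-probabilities
two-tailed rule, cross-checked against full enumeration in the tests),
`binomial_sign_test()` (one-tailed by default, matching its use for
directional sign counts of $W_{95}$) and `regress_w95_on_S()` (OLS with
two-sided slope $p$) cover the cross-network comparisons.

## Numerical and design choices

- $\lambda$ solver: bracket growth + `uniroot` + Newton polish,
  $|\mathrm{mean}(\lambda) - \mu| \le 10^{-10}$; log-space pmf.
- Quantiles: type-7 linear interpolation (stable at $10^4$ trials).
- $f_G$ ties count as non-exceeding; $W_{95}$ with a zero-width
  denominator returns $0$ or $\pm\infty$ by sign.
- The merged-system model mean uses the *realized* link count, mirroring
  how an observed web is fit (its $L$ is whatever was observed).
- Default trials 10,000; every `maxent_fit` records its trials and seed.
- Documentation examples use small trial counts; the test suite uses
  400–2,000 trials for calibration loops (1,000 replicates), 10,000 for
  the full coupled-system run, and $10^5$ draws for sampling checks —
  sizes at which the Monte-Carlo error is well inside the asserted
  tolerances.

## What passing tests do and do not show

The suite establishes internal correctness: the solver agrees with an
independent optimizer; both fit statistics are correctly calibrated under
their own null; the generator's controlled side passes its own test at the
advertised rate; the reducer matches construction ground truth; readers
and writers round-trip. It does not establish anything about real
communities: sampling effort, abundance, forbidden links and aggregation
all shape empirical matrices and are outside the model. The emergent plant
side of the generator is a reminder that a network can fail the null on
one side for purely combinatorial reasons. $W_{95}$ values here are on the
calibrated scale defined above; width statistics normalized differently
(e.g. by a tighter or looser null interval) are not comparable
unit-for-unit, so cross-study comparisons should be made on $f_G$ and on
the sign and significance of $W_{95}$, not its magnitude.

## Limitations

Binary interactions only (quantitative matrices binarize at $> 0$);
single-constraint MaxEnt (no variance or joint two-side constraints); the
coupled model constructs degree sequences, not link placements, except
through the `coupled_subwebs` generator mode; and the randomization tests
assume exchangeable sampling of degrees, which ignores the one-constraint
dependence induced by a fixed total link count.
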