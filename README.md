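# bimaxent

Maximum-entropy null models for the degree distributions of bipartite
ecological networks.

Plant–pollinator, seed-dispersal and plant–consumer webs almost always show
skewed degree distributions — many specialists, few generalists — and that
skew is routinely attributed to ecological or co-evolutionary processes.
`bimaxent` implements the null hypothesis against which such claims should
be tested: given only the group sizes $S_P$, $S_A$ and the link count $L$,
the least biased expectation for a degree distribution on
$\{1, \dots, n\}$ with mean $\mu$ (animal side: $n = S_P$,
$\mu = L/S_A$; plant side symmetric) is the maximum-entropy distribution

$$p_i = C\,e^{-\lambda i}, \qquad \sum_i p_i = 1, \quad \sum_i i\,p_i = \mu,$$

which is already skewed for any $\mu$ below the support midpoint. The
package provides:

- `solve_maxent()`, `maxent_sd()`, `sample_degree_sequence()` — solve,
  summarize and sample the null distribution (log-space, degenerate bounds
  handled);
- `g_statistic()`, `goodness_of_fit()`, `relative_width()`, `w95()`,
  `classify_fit()`, `maxent_fit()` — the randomized likelihood-ratio test
  $f_G$ and the Monte-Carlo-calibrated relative width $W_{95}$, with the
  dual good-fit criterion $f_G < 0.95$ and $-1 < W_{95} < 1$;
- `read_incidence()`, `read_edgelist()`, `reduce_foodweb()`,
  `degree_sequences()` — network I/O and the basal–consumer bipartite
  reduction of food webs;
- `coupled_spec()`, `build_coupled_animal_sequence()`,
  `evaluate_coupled()` — the heterogeneous-system model: identical MaxEnt
  sub-webs coupled through a shared super-generalist animal;
- `analyze_network()`, `survey_networks()`, `tabulate_fits()`,
  `fisher_exact_2x2()`, `binomial_sign_test()`, `regress_w95_on_S()` —
  cross-network surveys and their comparative statistics;
- `generate_network()`, `generate_foodweb()` — synthetic networks with
  controlled degree structure for testing every pipeline stage.

A thin command-line front end is installed as `exec/bimax`
(`bimax fit | survey | hetero-sim | simulate`).

## Worked example

```r
library(bimaxent)

d <- solve_maxent(20, 4)
d
#> MaxEnt distribution on {1..20}, mean 4
#>   lambda = 0.281843, sd = 3.32716

net <- generate_network(S_A = 40, S_P = 30, C_B = 0.15, seed = 101)
net
#> Bipartite network (synthetic): S_P = 30, S_A = 40, L = 175, C_B = 0.1458

analyze_network(net, name = "demo", trials = 2000, seed = 1)$animal_fit
#> MaxEnt fit: f_G = 0.3310, W = -0.1544, W95 = -0.2098 -> good fit (2000 trials)
```

The animal degrees were drawn from the MaxEnt null, and the fit statistics
agree: $f_G$ well below 0.95 (the observed $G$ beats only 33% of null
draws) and $W_{95}$ comfortably inside the 95% width band. Injecting a
super-generalist animal that visits 80% of all plants shifts the width
statistic upward:

```r
hub <- generate_network(S_A = 40, S_P = 30, C_B = 0.15,
                        mode = "hub_injected", seed = 101)
analyze_network(hub, name = "hub", trials = 2000, seed = 1)$animal_fit
#> MaxEnt fit: f_G = 0.5235, W = 0.03989, W95 = 0.2596 -> good fit (2000 trials)
```

The heterogeneous-system simulation couples two identical MaxEnt sub-webs
(here $20 \times 20$ at connectance 0.25) through their most general
animal and asks whether the merged 39-animal, 40-plant system still looks
MaxEnt:

```r
evaluate_coupled(coupled_spec(20, 20, 0.25, iterations = 25,
                              trials = 2000, seed = 9))
#> Coupled-subweb evaluation (2 x [S_A = 20, S_P = 20, C_B = 0.25], 25 iterations):
#>   mean W95 = 0.399 (sd 0.430), f_G rejection fraction = 0.640
```

Even though every sub-web is MaxEnt by construction, the merged system is
broader than its own null on average (positive mean $W_{95}$) and the
randomized $G$ test rejects in most iterations — spatial or temporal
heterogeneity alone can manufacture apparent structure. See the vignette
(`vignettes/maxent-null-models.Rmd`) for the model, calibration details
and the two opposing effects (shared-hub broadening vs duplication
narrowing) at work in this simulation.

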