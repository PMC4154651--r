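# burstnet

Directed, weighted functional connectivity from burst-structured
activation sequences, as recorded from clustered neuronal cultures by
calcium imaging.

Cultured neurons that aggregate into *clusters* show spontaneous activity
dominated by bursts: a group of clusters ignites sequentially within a few
hundred milliseconds, then the network falls silent for tens of seconds.
The delays between ignitions carry causal information. `burstnet` turns
onset-time tables (or raw fluorescence traces) into a directed weighted
functional network and quantifies its topology, for experimentalists and
modellers who want the full chain — event detection, burst segmentation,
network construction, assortativity and rich-club statistics, and an
information-theoretic cross-check — in one reproducible package.

## The method

Within each burst (maximal run of events with consecutive gaps at or below
a cut-off, 0.2 s by default), every ordered pair of ignitions (a → b)
separated by lag Δt contributes a weight

> g(Δt) = exp(−Δt² / 2σ²)

to the link a → b, where σ is fitted from the culture's own distribution
of consecutive-firing lags (half-normal maximum likelihood,
σ = √mean(Δt²), or a histogram fit). Weights are reinforced each time a
pair recurs; simultaneous ignitions become bi-directional unit links;
pairs with lags beyond 2.5σ are treated as functionally disconnected.

Topology is summarized by four directed assortativity coefficients —
Pearson and Spearman, on degrees and on strengths, the strength variants
weighting each edge by its link weight:

> r^w = Σ_e w_e (x_e − x̄)(y_e − ȳ) / √(Σ_e w_e (x_e − x̄)² · Σ_e w_e (y_e − ȳ)²),

with x_e = s_out(source), y_e = s_in(target), and weighted means x̄, ȳ —
plus bootstrap errors, and by the weighted directed rich-club ratio
φ(s) = W(s) / W_null(s) against the uncorrelated-strength null
W_null = (Σ s_out Σ s_in − Σ s_out s_in)/S over the club of nodes with
strength above s.

An alternative construction scores every ordered pair by the maximum
time-delayed mutual information of their activation series against 200
temporally reshuffled surrogates, keeping the z-score where significant —
the package's independent cross-check of the delay-based network.

A synthetic-data module generates ground-truth networks with planted
assortativity, sequential-ignition burst cascades, and fluorescence-like
traces, so every stage is testable end to end without external data.

## Worked example

```r
library(burstnet)

gt    <- generate_planted_network(30, 6, target_assortativity = 0.5, seed = 1)
train <- simulate_bursts(gt, cascade_params(n_bursts = 200), seed = 2)
report <- run_pipeline(run_config(seed = 7), events = train)
```

The report prints (values from this exact run):

```
bursts: 200, sigma: 30.9 ms
N = 30, E = 512, average degree 17.07, average strength 19.45
pearson-degree               -0.078 +/- 0.044
spearman-degree              -0.066 +/- 0.044
pearson-strength-weighted     0.220 +/- 0.056
spearman-strength-weighted    0.198 +/- 0.055
rich-club phi at the top third of strengths: 1.37
```

Read: 200 bursts of sequential ignitions yield a culture-specific lag
width of ~31 ms; the inferred functional network on 30 active clusters
has positive *weighted* assortativity (0.220 ± 0.056 Pearson,
0.198 ± 0.055 Spearman) — strong links preferentially join clusters of
similar strength, as planted — while the unweighted degree coefficient is
near zero, showing why the weighted variants matter; and the
strongest-third clusters interconnect ~1.4× more than the uncorrelated
expectation (a rich club).

The `analysis/` scripts run the same machinery as a narrative workflow
(simulation → event detection → networks → topology → MI cross-check),
writing tables under `results/`. Stage 4, for instance, contrasts the
clustered (conditional-burst) regime, weighted assortativity ≈ 0.81 ±
0.03, with the homogeneous (coherent-burst) regime, ≈ 0.04 ± 0.05.

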