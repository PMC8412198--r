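# gpcomm — compositional Gaussian process models of pattern communication

`gpcomm` is an R package for studying how function-shaped patterns survive a
describe-and-redraw communication channel: one person sees a pattern and
describes it in words, another redraws it from the description alone, and a
third rates the result. The package is aimed at computational cognitive
scientists who want to test whether *compositional structure* — patterns
built from a few interpretable primitives — is what makes a pattern
communicable.

## The models at its core

A pattern is a function observed at 100 equidistant points, modeled as a
draw from a zero-mean Gaussian process with kernel *k*. Two model classes
compete:

* a **compositional grammar** over three base kernels —
  linear `k(x,x') = (x−θ₁)(x'−θ₁)`,
  RBF `k(x,x') = θ₂² exp(−(x−x')²/2θ₃²)`, and
  periodic `k(x,x') = θ₄² exp(−2 sin²(π|x−x'|/θ₅)/θ₆²)` —
  closed under `+` and `×`, at most three non-repeating components;
  canonicalization under commutativity/associativity leaves exactly **17
  structures**;
* a **spectral mixture** `k(τ) = Σ_q w_q exp(−2π²τ²v_q) cos(2πτμ_q)`
  (Q = 2..6): equally expressive, but with no structural building blocks.

Each structure's hyperparameters are fit by maximizing the log marginal
likelihood `−½ yᵀK_y⁻¹y − ½ log|K_y| − (n/2) log 2π` with gradient-based
optimization; model comparison uses the marginal likelihood directly
(uniform prior over structures) and, at the regression level,
BIC-approximate Bayes factors. Reconstructions are scored by mean absolute
error and a Haar-wavelet distance that is invariant to scaling and shifting;
descriptions are scored by lexical metrics (type–token ratio, differential
and component-specific vocabularies). A synthetic communication-game
simulator with known ground truth makes every stage testable end to end.

## Worked example

Sample a pattern from a known compositional generator (linear trend plus
period-0.25 oscillation), add observation noise, and run the grammar
search:

```r
library(gpcomm)
spec <- kernel_spec(k_sum(k_lin(), k_per()),
                    list(theta1 = 0.2, theta4 = 1, theta5 = 0.25,
                         theta6 = 1.5, noise_var = 0.01))
pat <- sample_pattern(spec, seed = 42)
y   <- pat$y + rnorm(100, 0, 0.1)
fit <- gp_grammar(x = pat$x, y = y, n_restarts = 2, seed = 1,
                  include_spectral = TRUE)
print(fit)
#> Compositional GP grammar fit (n = 100, 17 structures)
#>   best structure: PER+RBF  (log ML 48.82)
head(summary(fit)$table, 3)
#>      structure  log_ml converged
#>        PER+RBF 48.8200      TRUE
#>    LIN*RBF+PER 46.9041      TRUE
#>    LIN*PER+RBF 43.0346      TRUE
fit$spectral$log_ml                     # noncompositional alternative
#> [1] 21.03
coef(fit)[["theta5"]]                   # recovered period
#> [1] 0.25
sapply(c("LIN","RBF","PER"), function(b)
  component_probability(fit, b, mode = "softmax"))
#>   LIN   RBF   PER
#> 0.131 1.000 1.000
```

The grammar recovers the periodicity exactly (θ₅ = 0.25) and beats the
spectral mixture by ~28 nats; the periodic component is certain under the
posterior structure weights, while the gentle sampled trend is absorbed by
a long-length-scale RBF — a realistic near-tie between `LIN` and smooth
structure. `predict`, `plot`, `simulate` and `residuals` methods work on
the fitted object as for any R model.

Simulating a full game and analyzing it:

```r
ds   <- simulate_game(game_config(seed = 1))          # 40 matched stimuli,
                                                      # 7 describers, ratings
fits <- fit_dataset_patterns(ds, n_restarts = 1, seed = 9)
tab  <- build_table(ds, fits)
regress_errors(tab, "wavelet_distance", "loglik_comp")
```

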