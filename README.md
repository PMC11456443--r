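# laminarDecoding

Depth-resolved analysis of columnar population recordings from primary
visual cortex (V1): which cortical layer encodes stimulus orientation
best, and why?

High-density probes (hundreds of contacts at 20 um pitch) record entire
cortical columns in one penetration. This package implements the full
analysis chain for such a session:

* **Laminar assignment.** The stimulus-triggered LFP is reduced to a
  current-source-density (CSD) profile with the five-contact stencil
  `CSD_i = -(phi_{i-2} - 2 phi_i + phi_{i+2}) / (2h)^2` on 4-channel
  groups, Gaussian-smoothed across depth (sigma = 120 um). The lower
  boundary of the major early current sink marks the border between layer
  4C and layers 5/6; the remaining compartment borders (2/3, 4A/B, 4C,
  5/6) follow by offsetting compartment thicknesses (defaults 650, 311,
  281, 489 um).
* **Single-neuron metrics.** Orientation tuning is fit with the von Mises
  function `y = a0 + a1 * exp(a2 * (cos(2x - 2 a3) - 1))` after Hanning
  smoothing (HWHH 20 deg); bandwidth is the half-separation of the
  flanking orientations at a criterion fraction of the peak (1/sqrt(2)
  default, 180 deg sentinel). Orientation/direction indices, F1/F0
  modulation ratio, and the Fano factor (variance/mean of 100 ms window
  counts across repeats) complete the per-neuron table.
* **Population decoding.** All 153 pairs of the 18 stimulus orientations
  are discriminated from 10 depth-adjacent neurons per subpopulation,
  with five classifier families (L2 logistic regression, shrinkage LDA,
  Gaussian naive Bayes, RBF SVM, random forest) under stratified 10-fold
  cross-validation; logistic regression and the SVM pick their C on an
  11-value grid (1e-6 ... 1e4) by 6-fold inner validation. Neuron-dropping
  curves, a 60%-threshold sensitivity statistic (1/delta-theta_min),
  trial-shuffling and single-neuron controls round out the suite.
* **Synthetic sessions.** A seeded generator builds columnar sessions
  with von Mises tuning, gamma-Poisson spike counts hitting
  per-compartment Fano-factor targets (1.87 / 1.62 / 1.28 / 1.94 for
  2/3, 4A/B, 4C, 5/6), sinusoidal simple-cell modulation, optional
  copula-imposed noise correlations, and a forward-modeled LFP dipole
  whose sink ends at the true 4C/5-6 border — so the whole pipeline is
  testable without any recorded data.

The scientific point the pipeline exposes: layer 4C's lower spike-count
variability (Fano factor) makes its subpopulations the best orientation
decoders in a column, an advantage that survives removal of noise
correlations (trial shuffling, correlation-blind NB) and is present in
single neurons.

## Worked example

```r
library(laminarDecoding)

cfg <- sessionConfig(nNeurons = 24, repsPerDirection = 5, sfSet = 1,
                     seed = 42, lfpEpochs = 8)
s <- simulateSession(cfg)
s
#> ColumnSession with 24 neurons, 180 trials
#>   directions: 36  sf: 1  eye: right
#>   depth range: 14-1694 um
#>   LFP: 97 channels x 25625 samples @ 2500 Hz

lam <- estimateLaminarModel(s)
round(lam$boundary46)   # true border is at 650+311+281 = 1242 um
#> [1] 1222
lam$model
#> LaminarModel (um below pia)
#>   2/3   [  -20.3,   629.7)
#>   4A/B  [  629.7,   940.7)
#>   4C    [  940.7,  1221.7)
#>   5/6   [ 1221.7,  1710.7)

met <- neuronMetrics(s, lam$model)
round(c(medianOI = median(met$oi), medianR2 = median(met$rSquared)), 2)
#> medianOI medianR2
#>      0.7      1.0
table(met$compartment == neuronInfo(s)$compartmentTrue)
#> FALSE  TRUE
#>     1    23

pairs20 <- subset(orientationPairs(), dtheta == 20)
dec <- decodeSession(s, lam$model, metrics = met, k = 10, stride = 4,
                     families = "lda", pairs = pairs20, seed = 1)
aggregate(accuracy ~ compartment, dec$results, mean)
#>   compartment  accuracy
#> 1         2/3 0.6750000
#> 2        4A/B 0.7305556
#> 3          4C 0.7569444
```

The sink boundary lands within one 80 um channel group (20 um here) of
the generative truth; all neurons except one lying within that margin of
a border are assigned back to their generating compartments; and the LDA
decoder already shows the layer-4C advantage on this 24-neuron session
(mean pairwise accuracy over the 20-degree orientation pairs, per
subpopulation compartment).

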