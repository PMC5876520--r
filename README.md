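# motionseg

On-line detection and single-frame phase segmentation of sports motions from
one wearable inertial sensor.

## What problem this solves

Phase analysis — splitting a performance into sub-motions and inspecting the
instants between them — is how coaches and movement scientists observe
technique. Doing it by hand means scrubbing video frame by frame.
`motionseg` automates the observation step from a single body-worn IMU
(tri-axis accelerometer ±16 g in the earth frame, tri-axis gyroscope
±2000 °/s, 100 Hz): it watches a continuous stream, detects each occurrence
of a modeled motion, and localizes every phase boundary to a single 10 ms
frame, on-line.

The method, in brief:

* **Motion model.** A motion with *N* sub-motions is a chain
  *M = (m_s1, m_p1, m_e1=s2, …, m_eN)*: each sub-motion has start,
  performing and end states; transitions are instantaneous, so each boundary
  state occupies exactly one frame and is shared by adjacent sub-motions.
  That gives 2N+1 states, N+1 boundary states, and 2N+2 classifier classes
  (class 0 = none/unknown). Models are small YAML files; a five-phase
  soccer-kick model (LS1–LS11) and a three-phase two-handed throw model
  (LT1–LT7) are bundled.
* **Per-timestep classifier.** Each sample becomes an 11-element feature
  vector (vertical acceleration; magnitudes of acceleration, angular rate
  and their first/second differences; angles between successive vectors). A
  window of L=100 feature vectors is labeled per frame by a
  dense(48, ELU) → bidirectional GRU(48) → bidirectional GRU(32) → softmax(K)
  network (batch norm on hidden layers, dropout everywhere but the output),
  trained with Adam on class-weighted cross-entropy
  ℒ(y, ŷ) = −Σᵢ αᵢ yᵢ log ŷᵢ, with αᵢ inverse to state i's frame count —
  single-frame boundary states are far too rare for unweighted training.
  The network, including backpropagation through time, is implemented in
  the package's compiled core (RcppArmadillo).
* **On-line accumulation and matching.** Window outputs are stitched into an
  accumulated state sequence (each sample's final estimate comes from the
  last window containing it). The discretized sequence is scanned backwards
  for the model's boundary pattern (exactly, or tolerantly via longest
  common subsequence). On a match, boundary k′ gets the frame
  b_k′ = argmaxₗ y_l^k′ subject to strictly increasing b — solved as a
  dynamic program over summed log-probabilities, which reduces to the plain
  per-state argmax whenever the unconstrained peaks are already ordered.
* **Synthetic corpus.** A seeded generator produces ~5 s labeled recordings
  (one motion instance inside walking-like clutter, per-state signal
  signatures, single-frame transitional boundaries) so training, streaming
  and evaluation run with no external data.

## Worked example

Train on a small synthetic corpus of kicks and stream a held-out recording:

```r
library(motionseg)

kick <- read_motion_model(system.file("extdata", "soccer_kick.yaml",
                                      package = "motionseg"))
spec   <- synthetic_spec(kick)
corpus <- generate_corpus(spec, n_recordings = 40, seed = 7)

cfg <- classifier_config(num_classes = n_classes(kick), epochs = 6, seed = 7)
cl  <- fit_motion_classifier(corpus$train, kick, config = cfg, stride = 8)

rec <- corpus$test[[1]]
res <- run_stream(rec$stream, cl, kick)
res[[1]]
#> <motion_segmentation> soccer_kick
#> # A tibble: 6 × 4
#>   label class_index frame  prob
#>   <chr>       <int> <int> <dbl>
#> 1 LS1             1   132 0.469
#> 2 LS3             3   144 0.462
#> 3 LS5             5   193 0.532
#> 4 LS7             7   258 0.340
#> 5 LS9             9   338 0.803
#> 6 LS11           11   377 0.405
```

One kick was detected; `frame` is the estimated single-frame index of each
boundary state (LS1 = landing of the kicking leg, LS3 = toe-off, LS5 =
maximum hip extension, LS7 = ball impact, LS9 = toe-speed inflection,
LS11 = end of kicking). The generator's ground truth for this recording puts
LS1–LS9 at 132, 144, 193, 258, 338 — matched exactly — and LS11 at 376, one
frame off. Scoring the whole held-out split:

```r
det <- detect_corpus(corpus$test, cl, kick)
evaluate_segmentation(det$est, corpus_truth(corpus$test, kick))
#> <segmentation_evaluation>
#>   detection rate: 8/8 = 1.000
#>   per-boundary mean absolute segmentation error (frames):
#> # A tibble: 6 × 3
#>   label mean_abs_error     n
#>   <chr>          <dbl> <int>
#> 1 LS1              0       8
#> 2 LS3              0       8
#> 3 LS5              0       8
#> 4 LS7              0       8
#> 5 LS9              0       8
#> 6 LS11            14.8     8
```

Every test kick was detected; interior boundaries are localized exactly,
while the motion's final boundary — whose signature blends into the
surrounding clutter — carries the error, the same pattern reported for
start/end states on real recordings. Errors are in frames (10 ms each).

A command-line wrapper with `simulate`, `train`, `detect`, `evaluate` and
`report` subcommands ships at
`system.file("cli", "motionseg.R", package = "motionseg")`.

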