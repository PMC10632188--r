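---
title: "dnaflex: models, null models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dnaflex: models, null models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the model it
fits, the null models it provides, the conventions it commits to, what the
synthetic-data generator does and does not emulate, and where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The quantity being modeled

Loop-seq assays measure, for a library of 50-bp probe sequences (flanked by
fixed 25-base adapters), how readily each fragment closes into a loop. The
resulting intrinsic cyclizability score C0 is a dimensionless log-ratio:
high values mean mechanically flexible DNA, low values rigid DNA. C0 is a
sequence property; the working hypothesis of this whole analysis family is
that the sequence→C0 map is universal across genomes, so a model trained on
one library can score any genome.

`dnaflex` treats "a predictor" as a contract: a deterministic map from a
50-base window to a real score, always consumed through reverse-complement
averaging

$$\hat C_0(s) = \tfrac12\left(f(s) + f(\mathrm{revcomp}(s))\right),$$

because measured cyclizability differs between a fragment and its reverse
complement while a genomic window has no preferred strand. The averaged
score is *exactly* invariant under reverse complementation, which the tests
assert for every predictor type.

Two realizations live behind the contract.

### 1.1 The linear dinucleotide surrogate

$$C_0(s) = b + \sum_{i=1}^{L-1} w[s_i s_{i+1}]$$

with 16 weights indexed by dinucleotide step and an intercept. This model is
deliberately simple: dinucleotide composition is the dominant determinant of
*averaged* flexibility profiles, and a score that is a pure function of the
16 dinucleotide counts gives the package its strongest oracle — any shuffle
that preserves dinucleotide counts provably cannot change the score, so
randomized-profile machinery can be tested for *exact* equality rather than
statistical closeness.

The default ground-truth weights (`default_truth_model()`) encode the
field's qualitative ordering — TA (+0.20) most flexible, AT (+0.12), CA/TG
(+0.08) and CG/GC mildly flexible, A-tract steps AA/TT (−0.15) most rigid,
GA/TC (−0.09) rigid — made strand-symmetric by construction
(w[d] = w[revcomp d]), with intercept −0.2. Over random 50-mers this gives a
score SD of ≈ 0.63, comparable in magnitude to measured C0 distributions.
These values were chosen once, before any acceptance measurement, and are
not tuned. An `asymmetry` knob breaks strand symmetry to exercise the
rc-averaging contract in tests.

### 1.2 The neural regressor

No deep-learning framework is available to R in the supported environment,
so the network is implemented from scratch (`R/nn.R`) with base matrix
algebra:

one-hot (n × 50 × 4) → conv blocks (1D convolution + ReLU, optional max
pooling) → **global average pooling** over the position axis → dense ReLU
(+ inverted dropout) → linear output; minimized by Adam on MSE over a
seeded uniform 70/30 train/test split, with early stopping on a validation
slice of the training split (best weights restored).

Design notes:

* The published architecture family for this problem uses conv → max-pool →
  LSTM → dense. The recurrent layer's role — aggregating the position axis —
  is played here by global average pooling. This is a deliberate
  substitution, not an approximation of an LSTM: with one-hot input, a
  kernel-2 convolution filter can realize an exact dinucleotide-step
  detector (ReLU(x_i + x_{i+1} − 1)), so conv + GAP + linear *contains* all
  additive dinucleotide models exactly, trains in minutes of pure R on one
  CPU, and backpropagation stays simple enough to verify against finite
  differences (which the test suite does).
* Default hyperparameters: conv blocks (32 filters, kernel 2, no pool) and
  (16 filters, kernel 3, pool 2), dense 32, dropout 0.1, learning rate
  1e-3, batch 128, ≤ 40 epochs, patience 5, validation fraction 0.1. Chosen
  for CPU-trainability; all configurable via `neural_net_config()`.
* Determinism: one seed controls split, initialization, batch order and
  dropout; the same seed and library give a bit-identical training
  trajectory on one platform. Cross-platform bitwise reproducibility is not
  promised.
* The 70/30 split is uniform at random (unstratified); whether the original
  analyses split randomly or positionally along the tiling library is
  unknown, and at the synthetic library's i.i.d. design the two coincide in
  distribution.

On a synthetic library of 20 000 records with noise SD 0.2 the attainable
correlation is bounded by the noise ceiling
$r_{\max} = \sigma_s/\sqrt{\sigma_s^2 + 0.04} \approx 0.95$; the acceptance
suite requires r ≥ 0.9 there and r ≥ 0.95 at noise 0 — a desk-scale analog
of the high train/test correspondence reported for loop-seq regressors.

## 2. The null-model zoo

Flexibility profiles around genomic landmarks confound two things: *which*
bases a region contains and *how they are ordered*. The package separates
them with four nulls:

* `shuffle_mono()` — uniform permutation of a window's letters. Preserves
  base composition only.
* `shuffle_dinuc()` — exact dinucleotide-preserving shuffle via the
  Eulerian-path (Altschul–Erickson) construction: the sequence is an
  Eulerian walk on the 4-vertex base graph; a random arborescence of
  last-exit edges toward the final base is drawn (rejection-sampled for
  connectivity), remaining out-edges are shuffled, and the walk is rebuilt.
  All 16 dinucleotide counts and both termini are preserved *exactly* on
  every input — property-tested across lengths 2–200. Naive dimer-swapping
  does not guarantee this, which is why the graph construction is used.
* `matched_distance_shuffle()` — mononucleotide shuffle constrained to an
  exact number of matching positions with the parent. Dinucleotide shuffles
  are, on average, closer to their parent than mono shuffles; pairing each
  dinucleotide shuffle with a mono shuffle at the *same* distance removes
  that confound. Implementation: start from the parent, propose random
  unequal-letter swaps, reject any swap that would drop the match count
  below the target, stop on exact equality; budget 10 000·L proposals.
  Unreachable targets (homopolymers; parity dead-ends such as a length-4
  all-distinct sequence and target 3) fail explicitly with the best
  achieved count — they are reported, never silently approximated.
* `fit_positional_model()` / `sample_vertical()` — "vertical" nulls: from a
  set of anchor-aligned regions, estimate per-offset base probabilities and
  per-offset conditional probabilities of each base given its predecessor,
  then draw whole synthetic regions (marginal or first-order chain). These
  preserve the position-specific average composition across the set rather
  than any single sequence's content. Transition rows conditioned on a base
  never observed at an offset fall back to uniform and are flagged; with a
  pseudocount of 0 (the default) an offset with no usable observations at
  all is an error.

`randomized_profile()` applies these to anchored profiles: `mono_h`/`dinuc_h`
shuffle every 50-bp window in place ("horizontal"), `mono_v`/`dinuc_v`
profile freshly sampled regions, and `matched_pair` returns the paired
dinucleotide / distance-matched-mono difference distributions.

## 3. Conventions

* **Coordinates** are 0-based half-open internally; GFF3 is converted from
  1-based inclusive at the boundary, BED/bedGraph read as 0-based half-open.
* **TSS**: the first base of the annotated 5′ UTR; one isoform per gene,
  preferring the ID ending ".1", else the lexicographically first (the
  annotation convention "isoform 1" has no universal ID rule). Genes without
  a 5′ UTR are skipped.
* **Profile registration**: the value at offset *o* averages windows whose
  25th base (1-based within the window) is at *o*, i.e. the window spans
  offsets o−24..o+25; the profile domain is every offset whose full window
  fits in the ±flank region, `[24 − flank, flank − 25]`. The same "window
  containing a position = window whose 25th base is the position" rule is
  used for tracks, methylation sites and break-site correlation. (The
  upstream description of this analysis contains an off-by-one — a 1050-bp
  region is said to yield 1000 windows, though 1051 positions hold 1002
  fitting windows; committing to the registration rule rather than the
  count resolves it without guessing.)
* **Minus-strand regions are reverse-complemented** so profile offsets run
  5′→3′ of the gene. Whether the original analyses did this is unstated;
  without it, strand-asymmetric features (TATA at −35..−28) would smear
  across strands, so orientation is the defensible choice.
* **Tiling**: windows of 50 bp at step 50 on the plus strand; windows with
  any IUPAC ambiguity code are discarded; chromosome-end remainders are
  dropped, never padded.
* **Scan sign**: D = C_actual − C_shuffled; D < 0 means the genomic window
  is stiffer than its shuffled (composition-matched) counterpart. Both the
  pooled distribution and per-window means are reported, since pooling
  convention is ambiguous upstream.
* **Methylation contexts**: the standard plant rule — CG if base 2 is G,
  CHG if base 3 is G, else CHH (H ∈ {A,C,T}); every 3-mer starting with C
  maps to exactly one class, on either strand (a genomic G is a
  minus-strand C). A published context list that files "CGC" under CHG/CHH
  conflicts with this rule; the standard rule is followed.
* **Exon stratification**: windows partially overlapping the interval set
  are labelled `straddling` and excluded from inside/outside comparisons
  (the upstream rule is unstated; exclusion avoids diluting either class).
  Intervals are merged before containment is evaluated.
* **Variants**: a variant occupies its reference span
  `[pos, pos + ref_span)`; insertions anchor at one base (VCF-style);
  SNPs have span 1. Window classes: none / SNP-only / indel-only / both.
* **TF sites** are consumed as intervals with a precomputed `bound` flag
  (motif scanning and binding-assay overlap are upstream of this package);
  the anchor is the interval midpoint, rounded down for even lengths;
  profiles use ±200 bp flanks and warn below 100 sites.
* **Statistics**: Cohen's d uses the pooled SD with n−1 sample SDs; the
  pooled-flavor t equals d·√(n₁n₂/(n₁+n₂)) identically (tested on random
  inputs). Welch is the default test flavor, robust to the very unequal
  group sizes typical here; effect sizes are always reported beside
  p-values because genome-scale n makes trivial differences significant. A
  pooled SD of zero with equal means yields d = 0 (a zero difference is
  zero at any scale); with unequal means d is undefined and flagged.
* **Dinucleotide log-ratio profiles** report ln(observed/expected); the
  default expected model is the product of position-pooled mononucleotide
  frequencies ("what composition alone would give"), with pooled
  dinucleotide frequencies or a user 16-vector as alternatives — the
  upstream definition of "randomly expected dinucleotide composition" is
  ambiguous, so the expected model is an explicit parameter. Cells with
  zero observed or expected counts are flagged undefined, never infinite.

## 4. The synthetic world

`simulate_genome()` draws background sequence from a first-order chain
(default: i.i.d. with 30/20/20/30 A/C/G/T, a mildly AT-rich, plant-like
composition) and plants promoter regions at regularly spaced TSSs, half on
each strand, written in transcription orientation, with a GFF3 annotation
whose 5′ UTR features recover the planted TSSs exactly (a tested
round-trip identity).

The planted promoter model (`promoter_markov_model()`) is the scientifically
load-bearing choice: inside a band of offsets (default −60..−10, upstream of
the TSS where core-promoter elements live) transitions follow
θ·P_alt + (1−θ)/4·J, where P_alt maps A↔T and C↔G. This matrix is doubly
stochastic, so the mononucleotide composition stays exactly uniform at every
offset — the planted flexibility signal is carried *only* by dinucleotide
arrangement. That makes the generator a discriminating fixture: a
mononucleotide shuffle must flatten the profile (acceptance requires a
variance ratio < 0.2), a dinucleotide-preserving shuffle must reproduce it
exactly, and the mean profile has a closed form
(`expected_profile_markov()`: propagate marginals through the chain, sum
pair probabilities against symmetrized weights) that the simulate → write →
read → profile round trip must match (r ≥ 0.9).

A `tata_fraction` subset of promoters (default 0.29, the reported TATA-box
frequency in plant promoters) receives a TATAWAWR-consensus insert at
offsets −35..−28, supporting TATA/TATA-less stratified profiles.

Scored libraries (`simulate_loopseq_library()`) are 50-bp i.i.d.-uniform
probes wrapped in fixed 25-base adapters, with C0 = truth score + N(0, σ);
default σ = 0.2, on the order of the median prediction error reported for
loop-seq regressors.

Planted associations (`simulate_variant_set()`,
`simulate_methylation_set()`) select case windows / methylation flags with
probability monotone in the standardized truth score (logistic mechanism)
and calibrate the slope by redrawing until the *realized* Cohen's d is
within ±0.02 of the target before emitting records; calibration failure is
an error naming the achieved d, not a silent near-miss. Null modes assign
flags independently of sequence.

What the generator does **not** emulate: real genome composition (GC
heterogeneity, repeats, isochores), overlapping genes and alternative TSSs,
linked variants, context-dependent methylation rates, experimental batch
structure, and any methylation effect *on* flexibility (the score model is
unmethylated-DNA-only throughout). A green end-to-end test therefore
establishes that the machinery is correct on a stated world, not that any
biological effect size in a real genome has been reproduced — the
published headline numbers (training r on real libraries, cross-species
scan effect sizes 0.029–0.183, variant effect sizes 0.121–0.334,
methylation d ≈ 0.04–0.06, break-site r ≈ 0) all require the original
external datasets and are deliberately out of the acceptance surface.

## 5. Numerical choices and degenerate inputs

* Undefined correlations (constant predictions or targets) and undefined
  effect sizes are flagged (`r_defined`, `d_defined`), never silently NA'd
  or zeroed; degenerate t-tests use the t = 0, p = 1 convention for equal
  constant groups.
* The ACF is the standard mean-removed, variance-normalized biased sample
  estimator, computed by the direct O(N·lag) sum; it matches an FFT route
  to 1e-8 in the tests and errors on zero variance.
* Window scoring propagates NA for ambiguity-containing windows inside
  profile machinery (they are dropped per offset with counts reported) but
  errors on ambiguous input at the user-facing `predict_c0()` unless
  `na_ambiguous = TRUE`.
* Anchors too close to a chromosome edge are skipped with a single summary
  warning; anchored regions on the minus strand containing ambiguity codes
  cannot be oriented and are skipped likewise.
* Adam uses β₁ = 0.9, β₂ = 0.999, ε = 1e-8; conv weights use He
  initialization; early stopping compares validation MSE with a 1e-9
  improvement margin.
* Max-pool gradient ties route to the first maximal element (standard
  subgradient choice); the finite-difference gradient test conditions away
  from ReLU/pool kinks where subgradients legitimately differ.

## 6. Known limitations

* The neural regressor is a CPU-scale model; it is not the published
  architecture and its absolute accuracy on real loop-seq data is untested
  here (no real data ships with the package). Its contract-level properties
  (determinism, rc-symmetry, parameter recovery on the synthetic world) are
  what the tests establish.
* `shuffle_dinuc()` draws from Eulerian arrangements via random last-edge
  arborescences; approximate, not proven-exact, uniformity over
  arrangements.
* The matched-distance shuffle can fail on short or low-complexity
  sequences (parity/multiset constraints); callers must handle the explicit
  failure (the paired-profile mode retries with fresh dinucleotide shuffles
  and then skips the window).
* GFF3 handling is minimal by design: ID/Parent attributes only, no
  attribute-schema inference, no compressed/indexed FASTA.
* k > 2 compositional preservation, motif discovery, importance scores,
  nucleosome-occupancy processing and binding-site calling are out of
  scope; bound/unbound calls and per-base tracks are consumed as inputs.
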