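# dreamdyn

Phase-transition analysis of ordered short-document series.

`dreamdyn` is built for psychotherapy process researchers who have a
*temporally ordered* corpus of short narratives — prototypically the
dream reports a patient brings to sessions across a long therapy — and
want to know whether, and **when**, the dynamics of those narratives
change qualitatively. The package turns the corpus into a single
per-document time series (the "affective charge"), models its trend,
and then asks four different nonlinear representations of that series
to vote on a common change point.

## The method

1. **Corpus preparation.** Each document is one elementary context unit
   (ECU). Tokens are lemmatized, lemmas are ranked by corpus frequency,
   the top 5% are discarded (function words carry no discrimination)
   and the 10% most frequent of the remainder are retained. The corpus
   becomes a binary matrix with `x_ij = 1` iff lemma *j* occurs in
   document *i*.
2. **Factor space.** Simple correspondence analysis of the indicator
   matrix: SVD of the standardized residuals
   `S = D_r^{-1/2}(P - rc')D_c^{-1/2}`, eigenvalues `λ_k = σ_k²`,
   explained inertia `λ_k / Σλ`. Each document gets a squared-cosine
   vector `cos²_ik` over the first *K* axes (default *K* = 10): its
   quality of representation on each latent meaning dimension.
3. **Affective charge.** `ed_i = ‖(cos²_i1 … cos²_iK)‖₂` — the
   Euclidean distance of the document from the origin of the factor
   space. Polarized documents (one dominant factor) have high charge.
   The **centroid radius** is `mean(ed)`; documents above it are
   "outside" (label 2), the rest "inside" (label 1).
4. **Trend models.** Binary logistic regression of the outside
   indicator on time (Wald and likelihood-ratio tests, odds ratios,
   concordance) and an ARIMA(1,1,1) with drift on the charge series
   (ACF/PACF identification helpers, Ljung–Box residual diagnostics).
5. **Nonlinear dynamics.** Three complexity representations of the
   charge series: windowed **dynamic complexity** `C = F·D` (window 7,
   step 1), the unthresholded **recurrence distance matrix** of a delay
   embedding (*m* = 3, *τ* = 1), and the **Stockwell transform**
   time–frequency amplitude matrix.
6. **Change points.** Exhaustive single-split search with a Gaussian
   changing-variance cost `C(x) = N·log var(x)` (the least-squares
   mean-change cost `C(x) = N·var(x)` is also available), thresholds
   calibrated so white noise of length 95 false-alarms in ≤ 10% of
   runs. The charge series, the DC profile, every line and column of
   the recurrence matrix, and the spectral energy of the
   time–frequency matrix each contribute a change index; their mean,
   rounded half-up, is the **ensemble transition**.

A synthetic-corpus generator with a known polarization regime shift
(`sim_params()` / `generate_corpus()`) makes the whole pipeline
testable end to end without clinical data.

## Worked example

```r
library(dreamdyn)

sim <- generate_corpus(sim_params(seed = 11))   # 95 docs, shift at 58
rep <- run_pipeline(run_config(corpus = sim$corpus, seed = 11))
print(rep)
```

```
transition_report (corpus mode)
  charge: radius 0.2829, inside 55 (57.9%), outside 40 (42.1%)
  change points [variance cost]: ed=58 dc=67 rp=57 tfd=61
  ensemble transition: index 61 (mean 60.75)
```

Reading the output: the mean affective charge over the 95 synthetic
dreams is 0.283; 40 documents exceed it. The charge series itself and
the recurrence plot date the variance change at documents 58 and 57 —
the generator's true shift is at 58 — while the dynamic-complexity
profile (which by construction reacts only after its 7-wide window has
filled with post-shift data) and the time–frequency energy place it a
few documents later; the ensemble average lands at 61. The logistic
trend on this run is positive and significant (β_time = 0.043,
p ≈ 1.5e-05): highly charged documents become more frequent with time.

The same machinery works on a precomputed matrix
(`run_config(matrix = ...)`) or directly on any numeric series
(`run_config(series = ...)`), and from the shell via the CLI in
`inst/cli/dreamdyn` (`simulate`, `prep`, `run`, `detect`).

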