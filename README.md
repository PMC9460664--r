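# eegscrub

Removal of ocular (EOG) and muscular (EMG) artifacts from a
**single-channel** EEG recording.

Portable EEG systems often record one channel, which rules out the usual
multi-channel blind source separation workflow. `eegscrub` follows the
decompose–separate–identify–reconstruct strategy: the single channel is
first expanded into a multichannel dataset by variational mode
decomposition (VMD), that mode matrix is separated by second-order blind
identification (SOBI), artifact components are identified by their fuzzy
entropy, and the clean EEG is rebuilt from the retained components.

The intended users are researchers processing contaminated scalp EEG
(e.g. motor-imagery BCI data at 250 Hz) who need an automated,
reproducible cleaning step plus quality metrics.

## Method

**VMD.** The signal f is decomposed into K band-limited AM–FM modes
u_k with center frequencies ω_k by minimizing the summed mode
bandwidths subject to Σ_k u_k = f. The augmented-Lagrangian saddle point
is found in the frequency domain by alternating updates

- û_k ← (f̂ − Σ_{i≠k} û_i + λ̂/2) / (1 + 2α(ω − ω_k)²)   (Wiener filter)
- ω_k ← ∫ ω |û_k(ω)|² dω / ∫ |û_k(ω)|² dω                (power centroid)
- λ̂ ← λ̂ + γ (f̂ − Σ_k û_k)                                (residual, weight γ)

until Σ_k ‖û_k^{n+1} − û_k^n‖² / ‖û_k^n‖² < ε. α sets the mode
bandwidth (large α → narrow modes); γ ∈ [0, 1] is the noise tolerance
(γ = 0 drops the residual, which is robust at low SNR).

**SOBI.** The K mode channels x are whitened (z = Qx), covariance
matrices R(τ) = E[z(t+τ) z(t)ᵀ] are computed for a set of lags, and one
orthogonal matrix V jointly diagonalizes them (Givens-rotation sweeps).
Sources are y = Vᵀ Q x and the mixing matrix is A = Q⁻¹ V. Second-order
statistics make no Gaussianity assumption, which suits EMG.

**Fuzzy entropy.** Each separated component is scored by
FE = ln Φ_m − ln Φ_{m+1}, where Φ_m is the mean pairwise similarity of
baseline-removed m-length embedding vectors under the membership
exp(−(d/r)^n) with Chebyshev distance d. Irregular (muscular) activity
scores high, slow regular (ocular) activity scores low; the min-FE
component is labeled EOG, the max-FE component EMG, the rest EEG (an
optional spectral sanity check can veto implausible labels). Artifact
components are zeroed, back-projected through A, and the cleaned mode
channels are summed.

**Choosing K.** For K in [2, 10] the signal is decomposed and the
judgment accuracy ε_{K,a} = ω_{K,a} / ω_{K+1,a} is formed between
same-order center frequencies of successive decompositions. An entry
with ε ≥ 1.2 or ε ≤ 1 is an *invalid center frequency*; the selected K
is the first K whose row contains one.

## Worked example

```r
library(eegscrub)
rec <- simulate_recording(sim_config(seed = 7, snr_db = -1))  # 250 Hz, 8 s
res <- run_pipeline(rec$mixture)
print(res)
```

```
<pipeline_result>
  K = 3 modes, center frequencies: 0.005029, 0.1328, 0.4298
 component      fe label removed
         1 0.06609   EOG    TRUE
         2 1.51300   EEG   FALSE
         3 1.77600   EMG    TRUE
```

The three modes sit at 1.3, 33 and 107 Hz (normalized frequency × 250).
The slow, regular component (FE 0.066) is flagged as ocular, the most
irregular one (FE 1.776) as muscular; both are removed.

```r
before <- compute_metrics(rec$eeg, rec$mixture)
after  <- compute_metrics(rec$eeg, res$cleaned)
```

```
cc  before: 0.6653  after: 0.7040
SNR before: -1.0000 dB  after: 2.4181 dB
RRMSE before: 1.1220  after: 0.7570
```

Cleaning raises the correlation with the known pure EEG and gains about
3.4 dB at this operating point. Automatic mode-count selection on the
shipped worked-example accuracy table:

```r
sel <- select_k_from_accuracy(kselect_example()$accuracy)
sel$selected_k
#> [1] 3
```

## Command line

```sh
inst/cli/eegscrub simulate --seed 7 --snr -1 --duration 8 --out sim/
inst/cli/eegscrub clean --input sim/mixture.csv --fs 250 \
    --out cleaned.csv --report report.json --reference sim/eeg.csv
inst/cli/eegscrub fe --input sim/eeg.csv
inst/cli/eegscrub selectk --input sim/mixture.csv --fs 250
```

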