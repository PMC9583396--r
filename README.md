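# imcoh

Wavelet intermuscular coherence and antagonist co-contraction analysis
for multichannel surface EMG recorded during discrete elbow extensions.

## The problem

When two synergistic muscles receive a partially shared ("common")
descending drive, their surface EMG signals are correlated at the
frequencies that drive carries. **Intermuscular coherence (IMC)** — the
frequency-resolved magnitude-squared coherence between two EMG signals —
is the standard estimate of that shared drive, and in the **beta band
(13–31 Hz)** it indexes the command underlying voluntary contraction.
This package implements, end to end, the analysis used to compare IMC
between the elbow flexors (biceps brachii BB, brachioradialis BR) and
the extensor (triceps brachii TB) of stroke and control subjects during
active elbow extension, together with the **antagonist co-contraction
index** — flexor RMS during extension as a percentage of its
maximal-voluntary-contraction (MVC) reference — and the group-level
inference relating the two. It is aimed at motor-control and
neurorehabilitation researchers working with movement-locked EMG.

The core quantity, per muscle pair and session, is the trial-averaged
Morlet-wavelet coherence

R²(ω,u) = |S₁₂(ω,u)|² / ( S₁(ω,u) · S₂(ω,u) )

(S₁₂ the trial-averaged wavelet cross-spectrum over the K ≈ 20 movements,
S₁ and S₂ the auto-spectra; ω on a 350-bin linear grid spanning
0.23–79.97 Hz, Morlet wavenumber 10), masked at the analytic K-trial
significance threshold 1 − α^(1/(K−1)) and integrated over the beta band
in the 200 ms before peak angular velocity:

IMC volume = Σ_{ω∈β, u∈[−0.2,0]} R²·mask · Δf · Δu.

Because the clinical recordings are not publicly deposited, the package
ships a first-class synthetic-data generator that plants a band-limited
common drive with known theoretical coherence
(a₁a₂Pₛ)² / ((a₁²Pₛ+P₁)(a₂²Pₛ+P₂)) and a known co-contraction ratio, so
every stage is verifiable against ground truth.

## Worked example

Simulate one paretic-limb session (20 extensions, EMG at 1000 Hz,
kinematics at 125 Hz, equal source/noise spectral density so the planted
in-band coherence is 0.25, planted co-contraction 30 % MVC), then run
the single-session chain:

```r
library(imcoh)

ses <- simulate_session(synth_config(seed = 42), subject = "S01",
                        group = "stroke", limb = "paretic")
ses$recording
#> <emg_recording> subject S01 (stroke, paretic limb, age NA)
#>   EMG: 537225 samples @ 1000 Hz (emg_tb_v, emg_bb_v, emg_br_v)
#>   kinematics: 67153 samples @ 125 Hz

res <- process_session(ses$recording, ses$mvc,
                       pipeline_config(freq_range = c(11, 33)))
res$coherence$bb_br
#> <imc_coherence> pair bb_br, K = 20 trials
#>   96 freqs x 1137 times; analytic threshold 0.1459; 71.5% cells significant
res$cocontraction
#> <cocontraction_index> 30.4% of MVC over 20 movements

res$metrics[, c("pair", "imc_volume", "cocontraction_pct")]
#>    pair imc_volume cocontraction_pct
#> 1 bb_br      0.982              30.4
#> 2 tb_br      0.720              30.4
```

Reading the numbers: the analytic significance threshold for K = 20
trials at α = 0.05 is 1 − 0.05^(1/19) = 0.1459; with the planted
coherence of 0.25 in the beta band, 71.5 % of all map cells (87.8 %
within the band × window region) are significant, and integrating the
significant coherence over 13–31 Hz × 200 ms gives a volume of 0.98
coherence·Hz·s for the BB–BR pair. The planted 30 % co-contraction
ratio is recovered as 30.4 % of MVC. `autoplot(res$coherence$bb_br)`
draws the masked coherence map; `tidy()`/`glance()` return the results
as tibbles.

Group-level analysis chains the same pieces over many sessions:

```r
sessions <- simulate_dataset(n_per_group = 10, seed = 7)   # stroke vs control
out <- run_pipeline(sessions, pipeline_config(freq_range = c(11, 33)))
out$stats$cocontraction_t          # pooled t, Cohen's d with 95% CI
tidy(out$stats$ancova_paretic_vs_dominant)   # type-III F, p, partial eta^2
tidy(out$stats$volume_cocontraction_rho)     # partial Spearman, +/- outliers
```

A thin command-line front end over the same functions lives at
`inst/scripts/imc_pipeline.R` (`simulate` and `run-all` verbs).

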