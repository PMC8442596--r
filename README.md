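# salnet

Time-varying brain-network centrality and visual saliency analysis for
parcellated fMRI time series.

During movie watching, the moment-to-moment topology of the brain's
functional-connectivity network changes with the stimulus. `salnet`
implements an analysis that asks whether a parcel's *network centrality over
time* tracks the *bottom-up visual saliency* of the movie: it builds binary
undirected networks from parcel-wise correlation matrices, computes static
and sliding-window centralities, extracts a per-TR mean saliency signal
from the movie frames with an Itti–Koch saliency model, and tests the
parcel-wise centrality–saliency correlations at the group level. A
synthetic-data module generates cohorts with known modular structure and a
known saliency-coupled community, so every stage of the pipeline can be
validated against ground truth without any neuroimaging downloads.

It is aimed at researchers doing naturalistic-stimulus fMRI and
graph-theoretic network analysis who want a tested, scriptable R
implementation of this pipeline.

## The model

Nodes are cortical parcels; the network is built per participant by

1. z-scoring each parcel's signal per run and concatenating runs,
2. Pearson correlation between all parcel pairs,
3. proportional thresholding: keep the strongest fraction *p* of the
   N(N−1)/2 possible edges (default *p* = 7.5%, selected as the maximizer
   of the mean flow coefficient over candidate densities
   2.5%–15%), giving a binary undirected adjacency matrix **A**.

On **A** the package computes:

- **Eigenvector centrality** — EC<sub>i</sub> = (1/λ₁) Σ<sub>j</sub>
  a<sub>ij</sub> μ<sub>1j</sub>, the leading eigenvector of **A**,
  non-negative with unit norm; a parcel is central when connected to
  central parcels.
- **Participation coefficient** — PC<sub>i</sub> = 1 − Σ<sub>m∈M</sub>
  (K<sub>i</sub>(m)/K<sub>i</sub>)² over the Louvain community partition
  M; high PC marks connector hubs whose edges spread across modules.
- **Flow coefficient** — the fraction of a node's neighbor pairs not
  directly linked to each other (equal to 1 − local clustering); its mean
  across nodes selects the edge density.

Time-varying versions (tEC, tPC) repeat correlation → threshold →
centrality inside a 50 s sliding window advanced one TR at a time, with
communities re-estimated per window.

The stimulus side derives a saliency map per movie frame (intensity,
color-opponency and Gabor-orientation center–surround contrast across a
dyadic Gaussian pyramid, max-norm feature normalization, 1/16 output
scale — 64 × 45 for 1024 × 720 content), averages it over pixels and the
F = fps · TR frames of each TR bin into a mean saliency signal s̄(t), and
low-passes it at 0.1 Hz with a zero-phase order-5 Butterworth filter.

Per participant, each parcel's tEC/tPC series is correlated with s̄(t);
correlations are Fisher-z transformed (z = atanh r) and tested across
participants (one-sample or paired t tests) with Bonferroni correction
over parcels; results are reported as signed standard-normal Z equivalents
with the family-wise-error cutoff computed from the configured level
(Z ≈ 4.19 at FWE 0.01 over 360 parcels).

## Worked example

Generate a 5-participant synthetic cohort in which one 6-parcel community's
cross-community coupling is driven by a slow sinusoid, then run the full
tEC pipeline against that driver:

```r
library(salnet)

spec   <- planted_cohort_spec(seed = 42, n_participants = 5)
cohort <- generate_coupled_cohort(spec)
res    <- run_pipeline(cohort$cohort, spec$driver, pipeline_config(seed = 42),
                       metrics = "EC")
res
#> <pipeline_result> 5 participants, metrics: EC
#>   group tEC: 6 significant parcel(s) at FWE 0.01

gt <- res$group$EC
head(gt$table[order(-gt$table$Z),
              c("parcel_id", "mean", "t", "Z", "p_corrected", "significant")], 8)
#>    parcel_id       mean         t        Z p_corrected significant
#> 1       P001 0.61314018 20.535702 4.150253 0.001992644        TRUE
#> 2       P002 0.63675380 19.985041 4.125502 0.002219565        TRUE
#> 5       P005 0.61988816 19.786228 4.116366 0.002309356        TRUE
#> 6       P006 0.62394205 18.871353 4.072878 0.002786146        TRUE
#> 4       P004 0.64240623 16.797535 3.964283 0.004417007        TRUE
#> 3       P003 0.61997073 15.305535 3.875762 0.006377480        TRUE
#> 45      P045 0.06438765  3.086476 2.089088 1.000000000       FALSE
#> 53      P053 0.08913222  3.042723 2.071630 1.000000000       FALSE
```

The six significant parcels are exactly the planted coupled community
(P001–P006): their group-mean Fisher-z correlation with the driver is
≈ 0.62 (r ≈ 0.55), the per-parcel t statistics clear the Bonferroni-corrected
threshold, and every uncoupled parcel stays far below it.

The saliency side works the same way from frames:

```r
movie <- generate_synthetic_movie(movie_spec(
  width = 1024, height = 720, fps = 24, duration = 2,
  blob_events = list(list(onset_s = 0.5, offset_s = 1.5, cx = 512, cy = 360,
                          radius_px = 30, contrast = 0.7, color = c(1, 1, 1)))))
maps <- saliency_map_stack(movie)        # one 64 x 45 map per frame
sbar <- mean_saliency_signal(maps, fps = 24, tr_seconds = 1)
sbar_f <- lowpass_filter(sbar, 0.1)
```

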