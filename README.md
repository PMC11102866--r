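# nucseen

Quantitative analysis of how a pioneer transcription factor engages
nucleosomes, for groups characterizing factor-nucleosome interactions in
vitro. Pioneer factors bind their DNA motif on nucleosomal (closed)
chromatin; establishing where they bind, what that does to DNA wrapping and
what the bound geometry implies sterically takes four separate readouts,
each with its own estimator. `nucseen` implements all four as tested,
reusable R code, plus seeded synthetic-data generators with ground-truth
sidecars so every estimator is validated by parameter recovery.

## What it computes

* **SeEN-seq enrichment** — a 9-bp motif tiled at 1-bp steps across the
  147-bp Widom 601 positioning sequence (139 constructs); per construct the
  score is the log2 ratio of spike-in-normalized bound vs unbound read
  counts, `log2((n_b/spike_b)/(n_u/spike_u))`, with no pseudocounts (zero
  counts report as missing) and exact library-size invariance.
* **Nucleosome coordinate geometry** — signed base-pair distance from the
  dyad and superhelical location labels, `SHL = round_half(d_center/10.4)`
  with ties away from zero; plus relocation of a label when the nucleosome
  changes register on fixed DNA.
* **In vitro MNase dyad mapping** — keep 145-147-bp protected fragments,
  take half-open-interval midpoints as dyads, express per-bp dyad density in
  percent, call positions by greedy suppressed peak picking, and compare
  conditions by per-bp log2 fold change.
* **smFRET two-state kinetics** — per-molecule photobleach QC via largest
  change points, corrected efficiency
  `E = (I_A - alpha I_D)/(gamma I_D + I_A - alpha I_D)`, segmentation at
  E = 0.48, and exponential dwell means with a discrete-sampling correction:
  the frame-sampled two-state process is a Markov chain with persistence
  `p_stay = pi + (1 - pi) exp(-(k_low + k_high) dt)`, inverted in closed form
  for both rates (a naive mean of frame-quantized dwells is biased by >60%
  at 10-s frames and ~16-s dwells). Half-life is `tau ln2`; rates follow the
  half-life-inversion convention.
* **Structural geometry** — Kabsch superposition, per-residue C-alpha RMSD,
  van der Waals clash detection (Bondi radii, 0.4 A tolerance), DNA-frame
  docking of a DNA-binding domain onto nucleosomal DNA, minor-groove anchor
  contacts (purine N3 / pyrimidine O2 floor atoms), and DNA unwrap angles
  from line fits through base-pair centers.

See `vignettes/nucleosome-engagement.Rmd` for the models, assumptions,
parameter defaults and their rationale.

## Worked example

```r
library(nucseen)

# A 9-bp motif starting at bp 128 of a 147-bp core (dyad at bp 74):
frame <- nucleosome_frame()                    # 147 bp, dyad 74, 10.4 bp/turn
distance_from_dyad(128, frame)                 # 54
shl_of_motif(128, frame = frame)               # 5.5
# The same motif after the nucleosome shifts register (dyad 87 -> 108 / 73):
relocate_shl(2.5, 87, 108); relocate_shl(2.5, 87, 73)   # 0.5, 4

# MNase dyad mapping on a simulated three-register ensemble (n = 1e5):
sim  <- simulate_fragments(fragment_sim_spec(seed = 1))
kept <- filter_fragments(sim$fragments)                  # 145-147 bp
prof <- dyad_density(dyad_positions(kept), 180, n_total = nrow(sim$fragments))
call_positions(prof)
#>   dyad_1based  weight
#> 1          73 0.50008
#> 2          87 0.29951
#> 3         108 0.20041

# smFRET kinetics on the wild-type preset (300 molecules, 10-s frames):
fret <- simulate_fret_traces(fret_preset("WT", seed = 1))
res  <- fret_dwell_pipeline(fret$traces, correction_factors(alpha = 0.1, gamma = 1))
res$fits$low
#> DwellFit (markov): tau 16.374 s, half-life 11.350 s, rate 0.0881 /s, n=381
res$fits$high
#> DwellFit (markov): tau 21.489 s, half-life 14.895 s, rate 0.0671 /s, n=354
```

The dyad calls recover the generator's registers (73/87/108 at weights
0.5/0.3/0.2) exactly, and the low-FRET dwell fit recovers the preset's
16.4-s unwrapped-state mean within 0.2% on this seed (the high-FRET state,
true mean 20.27 s, lands within 6%); 70 of 300 molecules pass the
photobleach QC, matching realistic single-molecule yields.

## Command line

```sh
inst/cli/nucseen geom shl --motif-start 128          # distance + SHL
inst/cli/nucseen seen tile --backbone 601.fa --motif TCAAGGCCA --o library.fa
inst/cli/nucseen seen score --counts counts.tsv --spike-id widom601 --o profile.tsv
inst/cli/nucseen dyad --fragments frags.tsv --o density.tsv
inst/cli/nucseen fret --traces traces.csv --alpha 0.1 --gamma 1 --o dwells.tsv
```
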