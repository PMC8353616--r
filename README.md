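# pasflow

Alternative polyadenylation (APA) from 3′ tag-based single-cell RNA-seq.

Oligo(dT)-primed single-cell protocols pile their read 5′ starts a few
hundred nucleotides upstream of each cleavage-and-polyadenylation site
(PAS). `pasflow` turns that geometry into a stepwise pipeline for anyone
who wants transcript-level 3′-end resolution out of standard 10x-style
alignments:

1. **Peak calling** — strand-specific, fixed-width (400 nt) greedy window
   calling on read-start coverage in spliced transcript coordinates (plus
   a genomic scan for intronic candidates), with a dip-statistic
   multimodality test to split merged peaks, ≥50 % within-gene overlap
   aggregation, a ≤1 % low-coverage filter, and removal of intronic peaks
   with ≥8 consecutive adenines near the 3′ end (internal-priming
   artifacts).
2. **Sequence classification** — a CNN + BiLSTM network
   (softmax ∘ dense(ReLU, dropout 0.3) ∘ BiLSTM(128) ∘ maxpool(4) ∘
   conv(64×6, ReLU) ∘ conv(128×12, ReLU), one-hot input, channels
   A/T/G/C) scores the 200-nt window around each candidate 3′ end;
   `probability > 0.5` keeps a site. Training windows are shifted around
   annotated sites with round(N(0, 10)) offsets, 10 distinct windows per
   site, which makes the classifier tolerant to window placement.
3. **Quantification** — surviving sites become transcripts truncated at
   the cleavage site (a PAS-based GTF), and UMIs are counted per cell
   barcode per feature (largest-overlap assignment, sense strand,
   distinct UMI strings) into a sparse cell × PAS matrix (MTX export).
4. **APA statistics** — proximal PAS usage
   `log2((CPM_proximal + 1)/(Σ CPM_rest + 1))` per gene per cell,
   Z-scored per-cell global preference, Wilcoxon differential usage
   between cell groups (significant at |logFC| ≥ 1.2, P ≤ 0.05,
   min.pct ≥ 0.3), and poly(A)-signal motif statistics
   (AAUAAA + variants in [−50, +25]).

A synthetic-data module (`sim_config()`, `simulate_genome()`,
`simulate_reads()`, `make_training_benchmark()`) generates genomes,
GTFs, and barcoded/UMI-tagged SAM/BAM with planted cleavage sites and
internal-priming artifacts, so the whole pipeline is testable without
any external download.

## Worked example

```r
library(pasflow)

# a reference-scale synthetic experiment: 50 genes, 2-3 PASs each,
# 200 cells, intronic internal-priming artifacts included
sim   <- simulate_genome(sim_config(seed = 1))
reads <- simulate_reads(sim)
sim
#> pas_sim: 2 chromosome(s), 50 genes, 122 planted PASs, 13 internal-priming loci

# stage 1: call, aggregate, filter
peaks <- call_peaks(reads, sim$gm, sim$genome)
nrow(peaks); table(peaks$category)
#> [1] 124
#> exonic
#>    124

# stage 2: train a reduced classifier on a planted-signal corpus and
# keep high-probability sites
bm    <- make_training_benchmark(n_sites = 500, seed = 1)
model <- pasnet_train(bm$shifted, pasnet_spec(scale = 0.125),
                      batch_size = 256, max_epochs = 12, seed = 1)
win   <- vapply(seq_len(nrow(peaks)), function(i)
  fetch_seq(sim$genome, peaks$chrom[i],
            peaks$three_prime_end[i] - 100, peaks$three_prime_end[i] + 100,
            peaks$strand[i]), "")
keep  <- pasnet_predict(model, win)
mean(keep$label)
#> [1] 0.9596774

# stages 3-4: quantify per cell and score proximal usage
feats <- assign_peaks_to_transcripts(peaks[keep$label, ], sim$gm)
m     <- count_umis(reads, feats)
dim(m)
#> [1] 119 200
pref  <- cell_preference(m, feats, sim$gm)
summary(pref$z)
#>     Min.  1st Qu.   Median     Mean  3rd Qu.     Max.
#> -2.66295 -0.75837 -0.03467  0.00000  0.68529  2.71075
```

The numbers above are what the code printed for seed 1: the 122 planted
sites yield 124 surviving exonic peaks (all 13 intronic artifact loci
are called but removed by the adenine-run filter), ~96 % of peak windows
pass the classifier, and the cell × PAS matrix covers all 200 cells with
exactly standardized per-cell proximal-usage preference. `run_pipeline()` (or the
`exec/pasflow` subcommand CLI: `simulate`, `callpeak`, `train`,
`predict`, `quantify`, `evaluate`, `apa`, `run`) chains the same stages
from files on disk and stamps a JSON manifest.

## Design notes

The methods vignette (`vignettes/pasflow-methods.Rmd`) documents the
models, parameter choices (window sizes, thresholds, the AT-rich
background of the generator, the equal-budget training protocol behind
the tolerance comparison) and known limitations.
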