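# Synthetic-data generator: determinism, signal geometry, file formats.

test_that("simulation is reproducible and internally consistent", {
  s1 <- small_sim(seed = 3)
  s2 <- small_sim(seed = 3)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$truth, s2$truth)
  s3 <- small_sim(seed = 4)
  expect_false(identical(s1$genome, s3$genome))
  # truth sites sit on their transcript's terminal exon
  for (i in seq_len(nrow(s1$truth))) {
    tr <- s1$truth[i, ]
    ex <- s1$gm$exons[s1$gm$exons$transcript_id == tr$transcript_id, ]
    expect_true(any(tr$site >= ex$start & tr$site < ex$end))
  }
  # distal PAS is the gene 3' end
  for (g in unique(s1$truth$gene_id)) {
    tg <- s1$truth[s1$truth$gene_id == g, ]
    distal <- tg$site[which.max(tg$pas_rank)]
    expect_equal(distal,
                 s1$gm$genes$three_prime_end[s1$gm$genes$gene_id == g])
  }
})

test_that("planted signal occurrence tracks the configured strength", {
  s_full <- simulate_genome(sim_config(n_genes = 40, n_chroms = 1,
                                       chrom_length = 350000,
                                       polya_signal_strength = 1, seed = 5))
  occ <- polya_signal_occurrence(s_full$truth, s_full$genome)
  expect_equal(occ$fraction, 1)
  s_half <- simulate_genome(sim_config(n_genes = 40, n_chroms = 1,
                                       chrom_length = 350000,
                                       polya_signal_strength = 0.5, seed = 6))
  # ~0.5 planted plus chance hexamers in the AT-rich background window
  occ2 <- polya_signal_occurrence(s_half$truth, s_half$genome)
  expect_gt(occ2$fraction, 0.45)
  expect_lt(occ2$fraction, 0.95)
})

test_that("simulated reads have the advertised geometry and tags", {
  sim <- small_sim(seed = 3)
  reads <- simulate_reads(sim, seed = 11)
  expect_true(all(nchar(reads$ub) == sim$config$umi_length))
  expect_true(all(nchar(reads$cb) == 16L))
  expect_lte(length(unique(reads$cb)), sim$config$n_cells)
  # read 5' starts lie in [-400, -50] of their site, in spliced coordinates
  fp <- pasflow:::read_five_prime(reads)
  for (i in sample(which(!reads$is_artifact), 50)) {
    tr <- sim$truth[sim$truth$gene_id == sub(":PAS.*", "", reads$origin[i]) &
                      sprintf("%s:PAS%d", sim$truth$gene_id,
                              sim$truth$pas_rank) == reads$origin[i], ]
    map <- pasflow:::tx_map(sim$gm, tr$transcript_id)
    d <- pasflow:::genomic_to_tx(map, fp[i]) - tr$site_tx
    expect_gte(d, -400L); expect_lte(d, -50L)
  }
  # artifact reads are intron-contained
  art <- reads[reads$is_artifact, ]
  if (nrow(art) > 0) {
    ex <- sim$gm$exons
    for (i in sample(seq_len(nrow(art)), min(20, nrow(art)))) {
      hit <- ex$chrom == art$chrom[i] & art$start[i] < ex$end &
        art$end[i] > ex$start
      expect_false(any(hit))
    }
  }
  # with duplicates, extra copies are emitted but collapse to distinct
  # molecules in the truth table
  cfg_dup <- sim$config; cfg_dup$duplicate_rate <- 0.5
  sim_dup <- sim; sim_dup$config <- cfg_dup
  reads_dup <- simulate_reads(sim_dup, seed = 11)
  expect_gt(nrow(reads_dup), nrow(reads))
  expect_lt(sum(truth_umi_matrix(reads_dup)),
            sum(!reads_dup$is_artifact))
})

test_that("emitted files parse with the package's own readers and samtools", {
  sim <- small_sim(seed = 3)
  reads <- simulate_reads(sim, seed = 11)
  dir <- tempfile("simout")
  files <- write_sim(sim, reads, dir, bam = TRUE)
  g <- read_genome(files$fasta)
  expect_identical(g, sim$genome)
  gm <- read_gtf(files$gtf)
  expect_equal(sort(gm$transcripts$transcript_id),
               sort(sim$gm$transcripts$transcript_id))
  back <- read_alignments(files$bam)
  expect_equal(nrow(back), nrow(reads))
  # tags survive the SAM -> BAM -> reader round trip
  key <- function(df) sort(paste(df$chrom, df$start, df$cb, df$ub))
  expect_identical(key(back), key(reads))
  # junction-spanning reads keep split blocks
  nb <- vapply(back$blocks, nrow, 0L)
  if (any(vapply(reads$blocks, nrow, 0L) > 1)) expect_gt(max(nb), 1L)
})

test_that("training benchmark corpora are balanced, reproducible, leak-free", {
  bm <- make_training_benchmark(n_sites = 50, n_val_sites = 30,
                                n_per_site = 4, seed = 9)
  expect_equal(table(bm$shifted$label), table(factor(rep(0:1, each = 200))),
               ignore_attr = TRUE)
  expect_equal(sum(bm$fixed$label == 1), 50L)
  expect_equal(sum(bm$fixed$label == 0), 50L)
  bm2 <- make_training_benchmark(n_sites = 50, n_val_sites = 30,
                                 n_per_site = 4, seed = 9)
  expect_identical(bm$shifted, bm2$shifted)
  # negatives carry no planted arrangement: compare signal rates
  neg <- bm$shifted$sequence[bm$shifted$label == 0]
  pos_hit <- grepl("AATAAA", bm$fixed$sequence[bm$fixed$label == 1])
  expect_true(all(pos_hit))
  neg_df <- data.frame(sequence = neg)
  # positives place the hexamer 26-30 nt upstream of the window center
  p1 <- bm$fixed$sequence[bm$fixed$label == 1][1]
  core <- substr(p1, 100 - 30 + 1, 100 - 20)
  expect_true(grepl("AATAAA", core))
})
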