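# Peak caller: planted pileups, junction mapping, aggregation and filters.

test_that("a single pileup yields exactly one peak with the full count", {
  gm <- gene_models(data.frame(gene_id = "g1", transcript_id = "t1",
                               chrom = "c1", start = 0L, end = 5000L,
                               strand = "+", stringsAsFactors = FALSE))
  set.seed(1)
  starts <- sample(1000:1350, 100, replace = TRUE)
  reads <- reads_from_starts(starts)
  pk <- call_raw_peaks(reads, gm, min_count = 10)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$read_count, 100L)
  expect_equal(pk$category, "exonic")
  # most 3' placement among maximal windows: end just past the last start
  expect_equal(pk$three_prime_end, min(starts) + 399L)
})

test_that("empty alignments give an empty peak list, not an error", {
  gm <- toy_gene_models()
  pk <- call_raw_peaks(reads_from_starts(integer(0)), gm)
  expect_equal(nrow(pk), 0L)
})

test_that("two distant pileups give two peaks at the planted positions", {
  gm <- gene_models(data.frame(gene_id = "g1", transcript_id = "t1",
                               chrom = "c1", start = 0L, end = 6000L,
                               strand = "+", stringsAsFactors = FALSE))
  set.seed(2)
  reads <- reads_from_starts(c(sample(500:850, 80, TRUE),
                               sample(3000:3350, 60, TRUE)))
  pk <- call_raw_peaks(reads, gm)
  expect_equal(nrow(pk), 2L)
  expect_equal(sort(pk$read_count), c(60L, 80L))
  # 3' end abuts the downstream edge of each pileup (ends at 850 and 3350,
  # plus the ~50 nt gap modeling read-start offset from the cleavage site)
  e80 <- pk$three_prime_end[pk$read_count == 80L][1]
  e60 <- pk$three_prime_end[pk$read_count == 60L][1]
  expect_lt(abs(e80 - 900), 50)
  expect_lt(abs(e60 - 3400), 50)
})

test_that("peaks map back through exon junctions on both strands", {
  gm <- toy_gene_models()        # gA: exons [100,300) [500,900) on '+'
  set.seed(3)
  # spliced length 600; pile near spliced position 250-550 crosses the junction
  tx_starts <- sample(150:500, 120, replace = TRUE)
  map <- pasflow:::tx_map(gm, "tA")
  gpos <- pasflow:::tx_to_genomic(map, tx_starts)
  reads <- reads_from_starts(gpos)
  pk <- call_raw_peaks(reads, gm)
  expect_equal(nrow(pk), 1L)
  expect_gt(nrow(pk$blocks[[1]]), 1L)          # junction-spanning footprint
  expect_equal(pk$category, "exonic")
  # minus-strand gene: mirror pileup, 3' end is the genomic start side
  mapB <- pasflow:::tx_map(gm, "tB")
  txB <- sample(150:500, 120, replace = TRUE)
  gposB <- pasflow:::tx_to_genomic(mapB, txB)
  readsB <- reads_from_starts(gposB, strand = "-")
  pkB <- call_raw_peaks(readsB, gm)
  expect_equal(nrow(pkB), 1L)
  expect_equal(pkB$strand, "-")
  expect_equal(pkB$gene_id, "gB")
})

test_that("intron-contained pileups are called and categorized intronic", {
  gm <- toy_gene_models()        # gA intron: [300, 500)
  gm2 <- gene_models(data.frame(gene_id = "g1", transcript_id = "t1",
                                chrom = "c1",
                                start = c(0L, 3000L), end = c(1000L, 4000L),
                                strand = "+", stringsAsFactors = FALSE))
  set.seed(4)
  reads <- reads_from_starts(sample(1500:1850, 60, TRUE))  # inside intron
  pk <- call_raw_peaks(reads, gm2)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$category, "intronic")
})

test_that("gene-level aggregation matches a brute-force grouping oracle", {
  mk <- function(start, end, count, gene = "g") {
    df <- data.frame(chrom = "c1", start = start, end = end, strand = "+",
                     gene_id = gene, transcript_id = "t", read_count = count,
                     three_prime_end = end - 1L, category = "exonic",
                     modality = "unimodal", dip_p = NA_real_, ad_p = NA_real_,
                     stringsAsFactors = FALSE)
    df$blocks <- list(matrix(c(start, end), 1L))
    df
  }
  # planted example: 60% overlap keeps only the stronger peak
  p <- rbind(mk(0L, 400L, 100L), mk(160L, 560L, 80L))
  agg <- aggregate_gene_peaks(p)
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$read_count, 100L)
  # 10% overlap keeps both
  p2 <- rbind(mk(0L, 400L, 100L), mk(360L, 760L, 80L))
  expect_equal(nrow(aggregate_gene_peaks(p2)), 2L)
  # randomized oracle: transitive grouping by >= 50% of the shorter width
  set.seed(12)
  for (r in 1:10) {
    n <- sample(2:12, 1)
    s <- sample(0:2000, n, TRUE)
    w <- sample(100:400, n, TRUE)
    pks <- do.call(rbind, lapply(seq_len(n), function(i)
      mk(s[i], s[i] + w[i], sample(10:500, 1))))
    got <- aggregate_gene_peaks(pks)
    adj <- matrix(FALSE, n, n)
    for (i in 1:n) for (j in 1:n) {
      ov <- min(pks$end[i], pks$end[j]) - max(pks$start[i], pks$start[j])
      adj[i, j] <- ov / min(pks$end[i] - pks$start[i],
                            pks$end[j] - pks$start[j]) >= 0.5
    }
    comp <- seq_len(n)                       # transitive closure by iteration
    repeat {
      old <- comp
      for (i in 1:n) comp[adj[i, ]] <- min(comp[c(i, which(adj[i, ]))])
      if (identical(old, comp)) break
    }
    want <- vapply(split(seq_len(n), comp), function(mem)
      pks$read_count[mem][order(-pks$read_count[mem], pks$start[mem])][1],
      0L)
    expect_setequal(got$read_count, unname(want))
    # idempotence
    expect_equal(nrow(aggregate_gene_peaks(got)), nrow(got))
  }
})

test_that("low-coverage filter removes <=1% peaks within genes", {
  mk <- function(count, gene) {
    df <- data.frame(chrom = "c1", start = 0L, end = 400L, strand = "+",
                     gene_id = gene, transcript_id = "t", read_count = count,
                     three_prime_end = 399L, category = "exonic",
                     modality = "unimodal", dip_p = NA_real_, ad_p = NA_real_,
                     stringsAsFactors = FALSE)
    df$blocks <- list(matrix(c(0L, 400L), 1L))
    df
  }
  p <- rbind(mk(990L, "g1"), mk(10L, "g1"),      # 1% exactly -> removed
             mk(50L, "g2"), mk(50L, "g2"),       # symmetric -> kept
             mk(3L, "g3"))                       # single peak -> kept
  out <- filter_low_coverage(p)
  expect_equal(sort(out$read_count), c(3L, 50L, 50L, 990L))
})

test_that("internal-priming filter removes intronic A-rich peaks only", {
  set.seed(6)
  base <- random_dna(2000)
  run8 <- paste0(substr(base, 1, 1000), strrep("A", 8), substr(base, 1009, 2000))
  run7 <- paste0(substr(base, 1, 1000), strrep("A", 7), substr(base, 1008, 2000))
  mk <- function(cat, genome_end = 999L) {
    df <- data.frame(chrom = "c1", start = 600L, end = 1000L, strand = "+",
                     gene_id = "g", transcript_id = "t", read_count = 100L,
                     three_prime_end = genome_end, category = cat,
                     modality = "unimodal", dip_p = NA_real_, ad_p = NA_real_,
                     stringsAsFactors = FALSE)
    df$blocks <- list(matrix(c(600L, 1000L), 1L))
    df
  }
  g8 <- c(c1 = run8); g7 <- c(c1 = run7)
  expect_equal(nrow(filter_internal_priming(mk("intronic"), g8)), 0L)
  expect_equal(nrow(filter_internal_priming(mk("intronic"), g7)), 1L)
  expect_equal(nrow(filter_internal_priming(mk("exonic"), g8)), 1L)
  # minus-strand: the transcript's A-run is a genomic T-run; the oriented
  # scan must catch it
  runT <- paste0(substr(base, 1, 1000), strrep("T", 8),
                 substr(base, 1009, 2000))
  dfm <- mk("intronic")
  dfm$strand <- "-"; dfm$three_prime_end <- 1020L
  expect_equal(nrow(filter_internal_priming(dfm, c(c1 = runT))), 0L)
  expect_equal(nrow(filter_internal_priming(dfm, g8)), 1L)
})

test_that("mirror-image genome yields mirror-image peak calls", {
  L <- 5000L
  gm_p <- gene_models(data.frame(gene_id = "g", transcript_id = "t",
                                 chrom = "c1", start = 500L, end = 4500L,
                                 strand = "+", stringsAsFactors = FALSE))
  gm_m <- gene_models(data.frame(gene_id = "g", transcript_id = "t",
                                 chrom = "c1", start = 500L, end = 4500L,
                                 strand = "-", stringsAsFactors = FALSE))
  set.seed(8)
  starts <- sample(1000:1350, 80, TRUE)
  pk_p <- call_raw_peaks(reads_from_starts(starts), gm_p)
  pk_m <- call_raw_peaks(reads_from_starts(L - 1L - starts, strand = "-"),
                         gm_m)
  expect_equal(nrow(pk_p), 1L)
  expect_equal(nrow(pk_m), 1L)
  expect_equal(pk_m$three_prime_end, L - 1L - pk_p$three_prime_end)
  expect_equal(pk_m$read_count, pk_p$read_count)
})
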