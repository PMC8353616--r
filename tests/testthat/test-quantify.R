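# PAS feature construction, PAS GTF round trip, UMI counting, RPM.

mk_peak <- function(start, end, tpe, gene = "g1", tx = "t1", strand = "+",
                    chrom = "c1", blocks = NULL) {
  df <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                   gene_id = gene, transcript_id = tx, read_count = 50L,
                   three_prime_end = tpe, category = "exonic",
                   modality = "unimodal", dip_p = NA_real_, ad_p = NA_real_,
                   stringsAsFactors = FALSE)
  df$blocks <- list(blocks %||% matrix(c(start, end), 1L,
                                       dimnames = list(NULL,
                                                       c("start", "end"))))
  df
}

test_that("features truncate the assigned transcript at the PAS", {
  gm <- toy_gene_models()     # tA exons [100,300) [500,900) '+'
  # peak inside the last exon
  pk <- mk_peak(600L, 800L, 799L, gene = "gA", tx = "tA")
  ft <- assign_peaks_to_transcripts(pk, gm)
  expect_equal(nrow(ft), 1L)
  expect_equal(ft$transcript_id, "tA")
  b <- ft$blocks[[1]]
  expect_equal(b[, 2][nrow(b)], 800L)           # clipped at pas_site + 1
  expect_equal(b[, 1][1], 100L)                 # upstream exon retained
  expect_false(ft$unspliced)
  # no feature extends 3' of its PAS
  expect_true(all(b[, 2] <= ft$pas_site + 1L))
})

test_that("junction-spanning peaks produce multi-exon features and ids rank 5'->3'", {
  gm <- toy_gene_models()
  pk <- rbind(
    mk_peak(200L, 600L, 599L, gene = "gA", tx = "tA",
            blocks = matrix(c(200L, 300L, 500L, 600L), 2L)),
    mk_peak(700L, 899L, 898L, gene = "gA", tx = "tA"))
  ft <- assign_peaks_to_transcripts(pk, gm)
  expect_equal(nrow(ft), 2L)
  expect_equal(ft$feature_id, c("gA:PAS1", "gA:PAS2"))
  expect_equal(ft$gene_id, c("gA", "gA"))
  b1 <- ft$blocks[[which(ft$pas_site == 599)]]
  expect_equal(nrow(b1), 2L)                    # two-exon feature
  # a peak overlapping no transcript becomes an unspliced feature
  pk2 <- mk_peak(1200L, 1600L, 1599L, gene = "gA", tx = "tA")
  ft2 <- assign_peaks_to_transcripts(pk2, gm)
  expect_true(ft2$unspliced)
})

test_that("ties between transcripts go to the longest one", {
  gm <- gene_models(data.frame(
    gene_id = "g", transcript_id = c("short", "long", "long"),
    chrom = "c1", start = c(0L, 0L, 1500L), end = c(1000L, 1000L, 2000L),
    strand = "+", stringsAsFactors = FALSE))
  pk <- mk_peak(200L, 600L, 599L, gene = "g", tx = "short")
  ft <- assign_peaks_to_transcripts(pk, gm)
  expect_equal(ft$transcript_id, "long")
})

test_that("PAS GTF round-trips exon chains through read_gtf", {
  gm <- toy_gene_models()
  pk <- rbind(
    mk_peak(200L, 600L, 599L, gene = "gA", tx = "tA",
            blocks = matrix(c(200L, 300L, 500L, 600L), 2L)),
    mk_peak(700L, 899L, 898L, gene = "gA", tx = "tA"))
  ft <- assign_peaks_to_transcripts(pk, gm)
  f <- tempfile(fileext = ".gtf")
  write_pas_gtf(ft, f)
  back <- read_gtf(f)
  expect_setequal(back$transcripts$transcript_id, ft$feature_id)
  for (i in seq_len(nrow(ft))) {
    ex <- back$exons[back$exons$transcript_id == ft$feature_id[i], ]
    ex <- ex[order(ex$start), ]
    expect_equal(as.matrix(ex[, c("start", "end")]),
                 ft$blocks[[i]], ignore_attr = TRUE)
  }
  # empty feature set -> header-only file
  f2 <- tempfile(fileext = ".gtf")
  write_pas_gtf(ft[0, ], f2)
  expect_equal(length(readLines(f2)), 1L)
})

test_that("UMI counting collapses duplicates and resolves overlap by size", {
  gm <- toy_gene_models()
  pk <- rbind(mk_peak(500L, 700L, 699L, gene = "gA", tx = "tA"),
              mk_peak(700L, 899L, 898L, gene = "gA", tx = "tA"))
  ft <- assign_peaks_to_transcripts(pk, gm)
  # 3 reads same CB+UB on feature 1 -> 1; 2 reads distinct UBs -> 2
  rd <- reads_from_starts(c(600L, 610L, 620L, 630L, 640L), len = 30L,
                          cb = "AAA", ub = c("u1", "u1", "u1", "u2", "u3"))
  m <- count_umis(rd, ft)
  expect_equal(sum(m), 3)
  expect_equal(unname(m["gA:PAS1", "AAA"]), 3)
  # largest overlap wins: read covering 60 nt of PAS2 tail vs 30 of PAS1
  rd2 <- reads_from_starts(670L, len = 90L, cb = "BBB", ub = "u9")
  m2 <- count_umis(rd2, ft)
  expect_equal(unname(m2["gA:PAS2", "BBB"]), 1)
  expect_equal(sum(m2), 1)
  # antisense reads never count
  rd3 <- reads_from_starts(650L, len = 30L, strand = "-", cb = "CCC",
                           ub = "u1")
  rd3$start <- 620L; rd3$end <- 650L
  rd3$blocks <- list(matrix(c(620L, 650L), 1L))
  expect_equal(sum(count_umis(rd3, ft)), 0)
  # missing tags are skipped and tallied
  rd4 <- rd
  rd4$ub[1] <- NA_character_
  m4 <- count_umis(rd4, ft)
  expect_equal(attr(m4, "qc")$n_missing_tags, 1L)
})

test_that("UMI conservation against an exhaustive triple count", {
  sim <- small_sim(seed = 8)
  reads <- simulate_reads(sim, seed = 9)
  ft <- truth_features(sim)
  m <- count_umis(reads, ft)
  truth <- truth_umi_matrix(reads, rownames(m), colnames(m))
  expect_equal(as.matrix(m), as.matrix(truth))
  expect_equal(sum(m),
               nrow(unique(reads[!reads$is_artifact,
                                 c("cb", "ub", "origin")])))
})

test_that("RPM follows its definition and multi-overlap semantics", {
  rd <- reads_from_starts(seq(0L, 999L, by = 10L), len = 5L)  # 100 reads
  regions <- data.frame(chrom = "c1", start = c(0L, 2000L, 0L),
                        end = c(1000L, 3000L, 1000L),
                        strand = c("+", "+", "+"))
  rpm <- compute_rpm(rd, regions, min_mapq = 0)
  expect_equal(rpm[1], 100 / 100 * 1e6)
  expect_equal(rpm[2], 0)
  expect_equal(rpm[3], rpm[1])            # identical region, identical RPM
  # mapq filter removes reads from numerator and denominator
  rd$mapq[1:50] <- 0L
  expect_equal(compute_rpm(rd, regions[1, ], min_mapq = 3), 1e6)
  expect_error(compute_rpm(rd[0, ], regions), "zero mapped reads")
})
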