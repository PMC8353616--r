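test_that("FASTA read-back, case normalization and malformed input", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT", ">c2 description", "acgtacgt"), fa)
  g <- read_genome(fa)
  expect_identical(g[["c1"]], "ACGT")
  expect_identical(g[["c2"]], "ACGTACGT")  # uppercased, name truncated
  bad <- tempfile(fileext = ".fa")
  writeLines(c("ACGT", ">c1"), bad)
  expect_error(read_genome(bad), "line 1")
})

test_that("strand-oriented fetch agrees with a brute-force revcomp oracle", {
  fa <- tempfile(fileext = ".fa")
  set.seed(11)
  s <- random_dna(80)
  writeLines(c(">c1", s), fa)
  g <- read_genome(fa)
  for (i in 1:25) {
    a <- sample(0:70, 1); b <- a + sample(1:9, 1)
    expect_identical(fetch_seq(g, "c1", a, b, "+"), substr(s, a + 1, b))
    expect_identical(fetch_seq(g, "c1", a, b, "-"),
                     oracle_revcomp(substr(s, a + 1, b)))
  }
  expect_error(fetch_seq(g, "c1", 70, 90), "outside")
  expect_identical(fetch_seq(g, "c1", 70, 90, clip = TRUE),
                   substr(s, 71, 80))
})

test_that("GTF coordinates convert to 0-based half-open and round-trip", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'c1\tx\tgene\t101\t900\t.\t+\t.\tgene_id "g1";',
    'c1\tx\ttranscript\t101\t900\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'c1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'c1\tx\texon\t501\t900\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'), gtf)
  gm <- read_gtf(gtf)
  expect_equal(gm$exons$start, c(100L, 500L))
  expect_equal(gm$exons$end, c(200L, 900L))
  # round trip preserves all intervals and strands
  out <- tempfile(fileext = ".gtf")
  write_gtf(gm, out)
  gm2 <- read_gtf(out)
  expect_equal(gm2$exons[names(gm$exons)], gm$exons)
  # minus-strand exon_rank runs 3' -> descending start
  gmB <- toy_gene_models()
  exB <- gmB$exons[gmB$exons$gene_id == "gB", ]
  expect_equal(exB$start[order(exB$exon_rank)], c(2600L, 2000L))
  out2 <- tempfile(fileext = ".gtf")
  write_gtf(gmB, out2)
  gmB2 <- read_gtf(out2)
  expect_equal(sort(gmB2$exons$start), sort(gmB$exons$start))
})

test_that("exons outside explicit transcript bounds are rejected", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'c1\tx\ttranscript\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'c1\tx\texon\t101\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'), gtf)
  expect_error(read_gtf(gtf), "outside transcript bounds")
})

test_that("known-set membership follows the two-database-or-annotation rule", {
  rec <- data.frame(
    chrom = "c1",
    site = c(10L, 10L, 20L, 30L, 40L, 40L, 40L, 50L),
    strand = "+",
    source = c("DB1", "DB2", "DB1", "GENCODE", "DB1", "DB2", "DB3", "DB3"),
    stringsAsFactors = FALSE)
  known <- build_known_pas_set(rec)
  expect_setequal(known$site, c(10L, 30L, 40L))   # 20 (1 db) and 50 dropped
  expect_setequal(known$sources[known$site == 10][[1]], c("DB1", "DB2"))
  expect_error(build_known_pas_set(transform(rec, source = "DBX")),
               "unknown PAS source")
})

test_that("stringent set needs all three databases or the annotation", {
  rec <- data.frame(
    chrom = "c1", strand = "+",
    site = c(rep(1L, 3), rep(2L, 2), rep(3L, 2), 4L),
    source = c("DB1", "DB2", "DB3", "DB1", "DB2", "GENCODE", "DB1", "GENCODE"),
    stringsAsFactors = FALSE)
  known <- build_known_pas_set(rec)
  stringent <- build_stringent_set(known)
  expect_setequal(stringent$site, c(1L, 3L, 4L))  # {DB1,DB2} only is not stringent
  expect_true(all(stringent$site %in% known$site))
  expect_identical(attr(stringent, "tier"), "stringent")
})

test_that("train/validation split size and partition property", {
  pas <- pas_set("c1", seq_len(1000), "+", "GENCODE", tier = "stringent")
  sp <- split_train_validation(pas, 0.9, seed = 4)
  expect_equal(nrow(sp$train), 900L)
  expect_equal(nrow(sp$validation), 100L)
  expect_setequal(c(sp$train$site, sp$validation$site), pas$site)
  expect_length(intersect(sp$train$site, sp$validation$site), 0L)
  # deterministic under a seed; different seeds differ
  sp2 <- split_train_validation(pas, 0.9, seed = 4)
  expect_identical(sp$train$site, sp2$train$site)
  sp3 <- split_train_validation(pas, 0.9, seed = 5)
  expect_false(identical(sp$train$site, sp3$train$site))
  # round-half-up at awkward sizes, e.g. 10 -> 9/1
  sp10 <- split_train_validation(pas[1:10, ], 0.9, seed = 1)
  expect_equal(nrow(sp10$train), 9L)
  expect_error(split_train_validation(pas[0, ], 0.9), "empty")
})

test_that("overlaps_known matches an exhaustive per-site scan", {
  set.seed(21)
  known <- pas_set(sample(c("c1", "c2"), 400, TRUE),
                   sample(0:5000, 400, TRUE),
                   sample(c("+", "-"), 400, TRUE), "GENCODE")
  chrom <- sample(c("c1", "c2"), 200, TRUE)
  end <- sample(0:5000, 200, TRUE)
  strand <- sample(c("+", "-"), 200, TRUE)
  got <- overlaps_known(chrom, end, strand, known)
  want <- vapply(seq_along(end), function(i) {
    d <- known$site - end[i]                      # genomic offset
    d_or <- if (strand[i] == "+") d else -d       # oriented offset
    any(known$chrom == chrom[i] & known$strand == strand[i] &
          d_or >= -50 & d_or <= 25)
  }, logical(1))
  expect_identical(got, want)
  # boundary behavior: inclusive at -50 and +25
  k1 <- pas_set("c1", c(950L, 949L, 1025L, 1026L), "+", "DB1")
  expect_true(overlaps_known("c1", 1000L, "+", k1[1, ]))
  expect_false(overlaps_known("c1", 1000L, "+", k1[2, ]))
  expect_true(overlaps_known("c1", 1000L, "+", k1[3, ]))
  expect_false(overlaps_known("c1", 1000L, "+", k1[4, ]))
})

test_that("PAS BED round-trip preserves sites and sources", {
  pas <- pas_set("c1", c(5L, 9L), c("+", "-"),
                 list(c("DB1", "DB2"), "GENCODE"))
  f <- tempfile(fileext = ".bed")
  write_pas_bed(pas, f)
  back <- read_pas_bed(f)
  expect_equal(back$site, pas$site)
  expect_equal(back$strand, pas$strand)
  expect_equal(back$sources, pas$sources)
})
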