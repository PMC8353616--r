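# Proximal-usage statistics, cell preference, differential usage, motifs.

# two-PAS gene on each strand with a simple count matrix
apa_fixture <- function() {
  gm <- gene_models(data.frame(
    gene_id = c("gP", "gM"), transcript_id = c("tP", "tM"), chrom = "c1",
    start = c(0L, 5000L), end = c(2000L, 7000L), strand = c("+", "-"),
    stringsAsFactors = FALSE))
  ft <- data.frame(
    feature_id = c("gP:PAS1", "gP:PAS2", "gM:PAS1", "gM:PAS2"),
    gene_id = c("gP", "gP", "gM", "gM"),
    chrom = "c1", strand = c("+", "+", "-", "-"),
    pas_site = c(499L, 1999L, 6500L, 5000L),
    stringsAsFactors = FALSE)
  ft$blocks <- list(matrix(c(0L, 500L), 1L), matrix(c(0L, 2000L), 1L),
                    matrix(c(6500L, 7000L), 1L), matrix(c(5000L, 7000L), 1L))
  list(gm = gm, ft = ft)
}

test_that("distance ordering marks the farthest PAS proximal on both strands", {
  fx <- apa_fixture()
  ord <- order_pas_by_distance(fx$ft, fx$gm)
  # gP (gene 3' end 1999): PAS at 499 is 1500 away -> proximal
  expect_true(ord$proximal[ord$feature_id == "gP:PAS1"])
  expect_true(ord$distal[ord$feature_id == "gP:PAS2"])
  expect_equal(ord$distance_to_gene_end[ord$feature_id == "gP:PAS1"], 1500)
  # gM ('-' strand, gene 3' end 5000): PAS at 6500 is 1500 away -> proximal
  expect_true(ord$proximal[ord$feature_id == "gM:PAS1"])
  expect_equal(ord$distance_to_gene_end[ord$feature_id == "gM:PAS1"], 1500)
  expect_equal(ord$distance_to_gene_end[ord$feature_id == "gM:PAS2"], 0)
})

test_that("proximal usage follows its formula, with oracle spot values", {
  expect_equal(proximal_usage_value(0, 0), 0)
  expect_equal(proximal_usage_value(7, 7), 0)
  expect_equal(proximal_usage_value(99, 0), log2(100))
  fx <- apa_fixture()
  m <- Matrix::Matrix(matrix(c(3, 1, 0, 0,
                               1, 3, 0, 0), ncol = 2,
                             dimnames = list(fx$ft$feature_id,
                                             c("cellA", "cellB"))),
                      sparse = TRUE)
  pu <- proximal_usage(m, fx$ft, fx$gm)
  # cellA: total 4 -> proximal CPM 750000, rest 250000
  expect_equal(pu$usage["gP", "cellA"],
               log2((3 / 4 * 1e6 + 1) / (1 / 4 * 1e6 + 1)))
  expect_equal(pu$usage["gP", "cellB"],
               -pu$usage["gP", "cellA"], tolerance = 1e-9)  # 2-PAS antisymmetry
  # single-PAS genes and zero-total cells are excluded
  m2 <- m; m2[, "cellB"] <- 0
  pu2 <- proximal_usage(m2, fx$ft, fx$gm)
  expect_equal(pu2$cells, "cellA")
})

test_that("cell preference Z-scores have mean 0 and sd 1", {
  fx <- apa_fixture()
  set.seed(7)
  n_cells <- 30
  counts <- matrix(rpois(4 * n_cells, 5), nrow = 4,
                   dimnames = list(fx$ft$feature_id,
                                   sprintf("c%02d", seq_len(n_cells))))
  m <- Matrix::Matrix(counts, sparse = TRUE)
  pref <- cell_preference(m, fx$ft, fx$gm)
  expect_equal(mean(pref$z), 0, tolerance = 1e-9)
  expect_equal(sd(pref$z), 1, tolerance = 1e-9)
  # identical cells -> zero variance convention: all z = 0
  same <- Matrix::Matrix(matrix(rep(c(4, 2, 3, 5), n_cells), nrow = 4,
                                dimnames = dimnames(counts)), sparse = TRUE)
  expect_true(all(cell_preference(same, fx$ft, fx$gm)$z == 0))
  # hand-computed two-cell case: usages z = +-1/sqrt(2) under sample sd
  two <- Matrix::Matrix(matrix(c(8, 2, 0, 0, 2, 8, 0, 0), ncol = 2,
                               dimnames = list(fx$ft$feature_id,
                                               c("x", "y"))), sparse = TRUE)
  pz <- cell_preference(two, fx$ft, fx$gm)
  expect_equal(sort(pz$z), c(-1, 1) / sqrt(2), tolerance = 1e-9)
})

test_that("differential usage nulls stay quiet and planted shifts are found", {
  set.seed(8)
  n <- 60
  counts <- matrix(rpois(20 * 2 * n, 8), nrow = 20,
                   dimnames = list(sprintf("f%02d", 1:20),
                                   sprintf("c%03d", seq_len(2 * n))))
  a <- colnames(counts)[1:n]; b <- colnames(counts)[(n + 1):(2 * n)]
  m <- Matrix::Matrix(counts, sparse = TRUE)
  du0 <- differential_usage(m, a, b)
  expect_false(any(du0$significant))            # identical groups
  # plant a 4-fold shift in one feature
  counts2 <- counts
  counts2["f01", b] <- rpois(n, 32)
  du1 <- differential_usage(Matrix::Matrix(counts2, sparse = TRUE), a, b)
  expect_true(du1$significant[du1$feature_id == "f01"])
  expect_false(any(du1$significant[du1$feature_id != "f01"]))
  # logFC below threshold is never significant, whatever the P value
  expect_true(all(abs(du1$logfc[du1$significant]) >= 1.2))
  expect_error(differential_usage(m, a[1:2], b), "at least 3")
  expect_error(differential_usage(m, character(0), b), "empty")
})

test_that("poly(A)-signal occurrence respects the scan window", {
  set.seed(9)
  base <- gsub("A", "C", random_dna(4000))      # A-free background
  g <- c(c1 = base)
  put <- function(g, at, motif) {               # 0-based position
    substr(g[["c1"]], at + 1, at + nchar(motif)) <- motif; g
  }
  # site at 1000, '+': motif start at -25 (in window), +26 (outside)
  g1 <- put(g, 1000 - 25, "AATAAA")
  pas <- data.frame(chrom = "c1", site = 1000L, strand = "+",
                    stringsAsFactors = FALSE)
  expect_equal(polya_signal_occurrence(pas, g1)$fraction, 1)
  g2 <- put(g, 1000 + 26, "AATAAA")
  expect_equal(polya_signal_occurrence(pas, g2)$fraction, 0)
  # boundary: start at +20 keeps the hexamer inside [-50, +25]
  g3 <- put(g, 1000 + 20, "AATAAA")
  expect_equal(polya_signal_occurrence(pas, g3)$fraction, 1)
  g4 <- put(g, 1000 + 21, "AATAAA")
  expect_equal(polya_signal_occurrence(pas, g4)$fraction, 0)
  # all-C window has no signal; variant motifs are counted per motif
  expect_equal(polya_signal_occurrence(pas, g)$fraction, 0)
  g5 <- put(g, 1000 - 30, "ATTAAA")
  occ <- polya_signal_occurrence(pas, g5)
  expect_equal(occ$per_motif$n_sites[occ$per_motif$motif == "ATTAAA"], 1L)
  # minus strand: motif must be on the sense strand
  pasm <- data.frame(chrom = "c1", site = 2000L, strand = "-",
                     stringsAsFactors = FALSE)
  g6 <- put(g, 2000 + 20, oracle_revcomp("AATAAA"))  # 25 nt upstream on '-'
  expect_equal(polya_signal_occurrence(pasm, g6)$fraction, 1)
})

test_that("positional profiles normalize and localize a planted motif", {
  set.seed(10)
  g <- c(c1 = random_dna(50000))
  sites <- seq(2000L, 40000L, by = 2000L)
  for (s in sites)                              # plant AATAAA starting at -25
    substr(g[["c1"]], s - 25 + 1, s - 25 + 6) <- "AATAAA"
  pas <- data.frame(chrom = "c1", site = sites, strand = "+",
                    stringsAsFactors = FALSE)
  prof <- positional_profiles(pas, g)
  expect_equal(unname(rowSums(prof$base_freq)), rep(1, 200),
               tolerance = 1e-9)
  dens <- prof$motif_density[, "AATAAA"]
  expect_equal(unname(dens[as.character(-25)]), 1)
  expect_true(all(dens[setdiff(names(dens), "-25")] < 1))
  empty <- positional_profiles(pas[0, ], g)
  expect_equal(length(empty$positions), 0L)
})
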