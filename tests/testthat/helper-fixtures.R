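# Shared fixture builders: everything is generated in code at test time.

# independent reverse-complement oracle (no Biostrings)
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

random_dna <- function(n, prob = NULL) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# two-exon plus-strand gene and a mirrored minus-strand gene on a toy genome
toy_gene_models <- function() {
  gene_models(data.frame(
    gene_id = c("gA", "gA", "gB", "gB"),
    transcript_id = c("tA", "tA", "tB", "tB"),
    chrom = "c1",
    start = c(100L, 500L, 2000L, 2600L),
    end = c(300L, 900L, 2400L, 3000L),
    strand = c("+", "+", "-", "-"),
    stringsAsFactors = FALSE))
}

# reads data.frame from explicit 5' start positions (single-block reads)
reads_from_starts <- function(starts, chrom = "c1", strand = "+", len = 1L,
                              cb = "CB1", ub = NULL) {
  n <- length(starts)
  if (n == 0L) {
    df <- data.frame(chrom = character(), start = integer(), end = integer(),
                     strand = character(), mapq = integer(), cb = character(),
                     ub = character(), stringsAsFactors = FALSE)
    df$blocks <- list()
    return(df)
  }
  if (is.null(ub)) ub <- sprintf("U%06d", seq_len(n))
  start <- if (strand == "+") starts else starts - len + 1L
  df <- data.frame(chrom = chrom, start = start, end = start + len,
                   strand = strand, mapq = 255L,
                   cb = rep_len(cb, n), ub = rep_len(ub, n),
                   stringsAsFactors = FALSE)
  df$blocks <- lapply(seq_len(n), function(i)
    matrix(c(df$start[i], df$end[i]), 1L,
           dimnames = list(NULL, c("start", "end"))))
  df
}

# small default simulation used by several suites (cheap: 10 genes)
small_sim <- function(seed = 3, ...) {
  simulate_genome(sim_config(n_genes = 10, n_chroms = 1,
                             chrom_length = 120000, n_cells = 20,
                             reads_per_pas = 40, seed = seed, ...))
}

# a tiny trained classifier shared across tests (cached per session)
cached_benchmark_model <- function() {
  env <- pasflow:::.pasflow_env
  if (is.null(env$test_model)) {
    bm <- make_training_benchmark(n_sites = 150, n_val_sites = 100,
                                  n_per_site = 10, seed = 7)
    spec <- pasnet_spec(scale = 0.0625)
    m <- pasnet_train(bm$shifted, spec, batch_size = 256, max_epochs = 6,
                      patience = 6, seed = 7)
    env$test_model <- list(model = m, bm = bm)
  }
  env$test_model
}
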