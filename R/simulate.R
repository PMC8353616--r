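# Fully synthetic genomes, annotations, PAS truth sets and barcoded,
# UMI-tagged alignments with the statistical structure the pipeline
# assumes: multi-exon genes, cleavage sites carrying AATAAA ~25 nt
# upstream / CA at the site / a U-rich stretch downstream, read 5' starts
# piled in the 400 nt upstream of each site, and intronic A-rich
# internal-priming artifact loci with their own read pileups.

#' Simulation configuration
#'
#' Defaults define the package's reference fixture: 2 chromosomes of
#' 250 kb, 50 multi-exon genes with 2-3 cleavage sites each (spaced 900 nt
#' so adjacent peaks stay resolvable), 200 cells, ~60 reads per site,
#' 90-nt reads, 10-nt UMIs, every site carrying the canonical signal, and
#' 30% of genes carrying an intronic 10-adenine internal-priming locus.
#'
#' @param n_chroms,chrom_length genome shape.
#' @param n_genes number of genes.
#' @param exons_per_gene integer range (min, max).
#' @param pas_per_gene integer range (min, max) of cleavage sites per gene.
#' @param pas_spacing distance (nt) between successive sites in a gene.
#' @param reads_per_pas expected total reads per site (over all cells).
#' @param n_cells,umi_length,read_length library shape.
#' @param internal_priming_rate fraction of genes with an intronic A-run
#'   artifact locus (plus artifact reads).
#' @param polya_signal_strength probability a planted site carries AATAAA
#'   upstream, CA at the site and a downstream U-rich stretch.
#' @param duplicate_rate probability scale for extra PCR copies per
#'   molecule (geometric; 0 = no duplicates).
#' @param base_probs background base composition (default AT-rich,
#'   intergenic-like).
#' @param seed master seed.
#' @export
sim_config <- function(n_chroms = 2, chrom_length = 250000, n_genes = 50,
                       exons_per_gene = c(3, 5), pas_per_gene = c(2, 3),
                       pas_spacing = 900, reads_per_pas = 60, n_cells = 200,
                       umi_length = 10, read_length = 90,
                       internal_priming_rate = 0.3,
                       polya_signal_strength = 1, duplicate_rate = 0,
                       base_probs = .default_base_probs, seed = 1) {
  cfg <- list(n_chroms = n_chroms, chrom_length = chrom_length,
              n_genes = n_genes, exons_per_gene = exons_per_gene,
              pas_per_gene = pas_per_gene, pas_spacing = pas_spacing,
              reads_per_pas = reads_per_pas, n_cells = n_cells,
              umi_length = umi_length, read_length = read_length,
              internal_priming_rate = internal_priming_rate,
              polya_signal_strength = polya_signal_strength,
              duplicate_rate = duplicate_rate, base_probs = base_probs,
              seed = seed)
  stopifnot(all(unlist(cfg[1:10]) > 0),
            internal_priming_rate >= 0, internal_priming_rate <= 1,
            polya_signal_strength >= 0, polya_signal_strength <= 1,
            duplicate_rate >= 0, duplicate_rate < 1)
  structure(cfg, class = "sim_config")
}

# background composition defaults to the AT-rich makeup of intergenic
# sequence, so chance poly(A)-hexamers and T-runs occur at realistic rates
.default_base_probs <- c(A = 0.35, C = 0.15, G = 0.15, T = 0.35)

# i.i.d. draws underrepresent homopolymer tracts by orders of magnitude
# relative to real genomes, so scatter A/T runs (8-20 nt) at roughly one
# per 1.5 kb on top of the base composition
.random_dna <- function(n, base_probs = .default_base_probs,
                        homopolymer_per_nt = 1 / 1500) {
  s <- paste(sample(names(base_probs), n, replace = TRUE, prob = base_probs),
             collapse = "")
  k <- rpois(1, n * homopolymer_per_nt)
  if (k > 0) {
    for (i in seq_len(k)) {
      len <- sample(8:20, 1)
      at <- sample(max(1, n - len), 1)
      substr(s, at, at + len - 1) <- strrep(sample(c("A", "T"), 1), len)
    }
  }
  s
}

# Cleavage-site sequence architecture, as offsets relative to the site:
# an upstream U-rich element (USE), the AATAAA hexamer ~25 nt upstream,
# CA at the site, the downstream U-rich stretch, and a GU-rich element
# further downstream.  The auxiliary elements extend the signal footprint
# to roughly +-85 nt, as at real sites; windows shifted far off-center
# therefore lose part of the evidence.
.pas_signal_pieces <- function() {
  rich <- function(n, p) paste(sample(names(p), n, TRUE, p), collapse = "")
  list(
    list(offset = -85L, seq = rich(31, c(T = 0.55, A = 0.15, G = 0.15,
                                         C = 0.15))),
    list(offset = sample(-30:-26, 1L), seq = "AATAAA"),
    list(offset = -1L, seq = "CA"),
    list(offset = 5L, seq = rich(21, c(T = 0.7, A = 0.1, G = 0.1,
                                       C = 0.1))),
    list(offset = 28L, seq = rich(21, c(T = 0.45, G = 0.35, A = 0.1,
                                        C = 0.1))))
}

# overwrite `motif` (given 5'->3' on `strand`) so its first oriented base
# sits at oriented genomic position `gpos` (for '-' this writes the reverse
# complement leftward of gpos)
.plant_oriented <- function(seqs, chrom, strand, gpos, motif) {
  len <- nchar(motif)
  if (strand == "+") {
    a <- gpos
    substr(seqs[[chrom]], a + 1L, a + len) <- motif
  } else {
    a <- gpos - len + 1L
    substr(seqs[[chrom]], a + 1L, a + len) <- revcomp(motif)
  }
  seqs
}

#' Simulate a genome, gene annotation and PAS truth set
#'
#' @param config a [sim_config()].
#' @return list of class `pas_sim` with `genome` (named sequences), `gm`
#'   ([gene_models()]), `truth` (data.frame of planted cleavage sites with
#'   genomic and spliced coordinates and `has_signal`), `artifacts`
#'   (planted intronic A-run loci; `site` is the expected artifact-peak 3'
#'   end) and `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  cfg <- config
  with_seed(cfg$seed, {
    seqs <- setNames(vapply(seq_len(cfg$n_chroms), function(i)
      .random_dna(cfg$chrom_length, cfg$base_probs), ""),
      sprintf("chr%d", seq_len(cfg$n_chroms)))
    cursor <- setNames(rep(2000L, cfg$n_chroms), names(seqs))
    exon_rows <- list(); truth <- list(); artifacts <- list()
    for (g in seq_len(cfg$n_genes)) {
      gid <- sprintf("gene%03d", g)
      tid <- paste0(gid, ".t1")
      chrom <- names(seqs)[(g - 1L) %% cfg$n_chroms + 1L]
      strand <- sample(c("+", "-"), 1L)
      n_ex <- sample(cfg$exons_per_gene[1]:cfg$exons_per_gene[2], 1L)
      n_pas <- sample(cfg$pas_per_gene[1]:cfg$pas_per_gene[2], 1L)
      ex_len <- c(sample(400:600, 1L),
                  if (n_ex > 2L) sample(150:300, n_ex - 2L, replace = TRUE),
                  300L + (n_pas - 1L) * cfg$pas_spacing + 1L)
      in_len <- sample(600:900, n_ex - 1L, replace = TRUE)
      span <- sum(ex_len) + sum(in_len)
      g0 <- cursor[[chrom]]
      if (g0 + span + 2000L > cfg$chrom_length)
        stop("genes do not fit chromosome; increase chrom_length")
      cursor[[chrom]] <- g0 + span + sample(1500:3000, 1L)
      # oriented segment layout: e1 i1 e2 i2 ... en
      seg_len <- integer(0)
      for (i in seq_len(n_ex)) {
        seg_len <- c(seg_len, ex_len[i])
        if (i < n_ex) seg_len <- c(seg_len, in_len[i])
      }
      seg_start <- cumsum(c(0L, seg_len))[seq_along(seg_len)]
      is_exon <- rep(c(TRUE, FALSE), length.out = length(seg_len))
      ori2gen <- function(p) if (strand == "+") g0 + p else g0 + span - 1L - p
      # exon rows (genomic)
      for (i in which(is_exon)) {
        ga <- ori2gen(seg_start[i]); gb <- ori2gen(seg_start[i] + seg_len[i] - 1L)
        exon_rows[[length(exon_rows) + 1L]] <- data.frame(
          gene_id = gid, transcript_id = tid, chrom = chrom,
          start = min(ga, gb), end = max(ga, gb) + 1L, strand = strand,
          stringsAsFactors = FALSE)
      }
      # PAS sites in the terminal exon (oriented spliced coordinates)
      last_ex_ori <- seg_start[length(seg_len)]
      cum_ex <- cumsum(c(0L, ex_len))[seq_along(ex_len)]
      for (k in seq_len(n_pas)) {
        off_in_last <- 300L + (k - 1L) * cfg$pas_spacing
        ori <- last_ex_ori + off_in_last          # unspliced oriented pos
        txpos <- cum_ex[n_ex] + off_in_last       # spliced oriented pos
        gsite <- ori2gen(ori)
        has_sig <- runif(1) < cfg$polya_signal_strength
        if (has_sig) {
          for (piece in .pas_signal_pieces())
            seqs <- .plant_oriented(seqs, chrom, strand,
                                    ori2gen(ori + piece$offset), piece$seq)
        }
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = gid, transcript_id = tid, chrom = chrom, strand = strand,
          site = gsite, site_tx = txpos, pas_rank = k, has_signal = has_sig,
          stringsAsFactors = FALSE)
      }
      # intronic internal-priming locus in the first intron: a 20-adenine
      # stretch, the scale of run an oligo(dT) primer mis-anneals to
      if (n_ex > 1L && runif(1) < cfg$internal_priming_rate) {
        i1 <- seg_start[2L]                      # first intron, oriented
        run_ori <- i1 + 450L
        seqs <- .plant_oriented(seqs, chrom, strand, ori2gen(run_ori),
                                strrep("A", 20L))
        artifacts[[length(artifacts) + 1L]] <- data.frame(
          gene_id = gid, chrom = chrom, strand = strand,
          site = ori2gen(run_ori - 1L),          # expected artifact 3' end
          run_ori = run_ori, gene_start_ori = g0, span = span,
          run_length = 20L, stringsAsFactors = FALSE)
      }
    }
    gm <- gene_models(do.call(rbind, exon_rows))
    structure(list(genome = seqs, gm = gm, truth = do.call(rbind, truth),
                   artifacts = if (length(artifacts))
                     do.call(rbind, artifacts) else NULL,
                   config = cfg), class = "pas_sim")
  })
}

#' @export
print.pas_sim <- function(x, ...) {
  cat("pas_sim:", length(x$genome), "chromosome(s),",
      nrow(x$gm$genes), "genes,", nrow(x$truth), "planted PASs,",
      if (is.null(x$artifacts)) 0L else nrow(x$artifacts),
      "internal-priming loci\n")
  invisible(x)
}

.random_barcodes <- function(n, len) {
  out <- character(0)
  while (length(out) < n)
    out <- unique(c(out, vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), "")))
  out[seq_len(n)]
}

# n distinct UMIs
.distinct_umis <- function(n, len) {
  out <- character(0)
  while (length(out) < n)
    out <- unique(c(out, vapply(seq_len(n - length(out)), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), "")))
  out
}

#' Simulate barcoded, UMI-tagged reads from a simulated genome
#'
#' Per planted PAS and cell, molecule counts are Poisson with mean
#' `reads_per_pas / n_cells`; each molecule gets a distinct UMI within its
#' (cell, site) pair, a 5' start uniform in the spliced window
#' `[site - 400, site - 50]` (clipped at the transcript start) and a
#' sense-strand footprint clipped at the cleavage site, mapped through the
#' exon structure (reads may span junctions).  Internal-priming artifact
#' loci receive intron-contained pileups with the same geometry.  With a
#' positive duplicate rate, molecules emit extra identical copies.
#'
#' @param sim a `pas_sim` from [simulate_genome()].
#' @param seed RNG seed (defaults to the simulation seed + 1).
#' @return data.frame of alignments with chrom, start, end, strand, mapq,
#'   cb, ub, `blocks` list column, and truth columns `origin` (gene:PAS
#'   rank or artifact id) and `is_artifact`.
#' @export
simulate_reads <- function(sim, seed = sim$config$seed + 1L) {
  cfg <- sim$config
  with_seed(seed, {
    cells <- .random_barcodes(cfg$n_cells, 16L)
    rows <- list()
    mol_rate <- cfg$reads_per_pas / cfg$n_cells
    emit <- function(chrom, strand, blocks, cb, ub, origin, art) {
      data.frame(chrom = chrom, start = blocks[1L, 1L],
                 end = blocks[nrow(blocks), 2L], strand = strand, mapq = 255L,
                 cb = cb, ub = ub, origin = origin, is_artifact = art,
                 blocks = I(list(blocks)), stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(sim$truth))) {
      tr <- sim$truth[i, ]
      map <- tx_map(sim$gm, tr$transcript_id)
      origin <- sprintf("%s:PAS%d", tr$gene_id, tr$pas_rank)
      lo <- max(0L, tr$site_tx - 400L)
      hi <- tr$site_tx - 50L
      n_mol <- rpois(cfg$n_cells, mol_rate)
      for (ci in which(n_mol > 0L)) {
        umis <- .distinct_umis(n_mol[ci], cfg$umi_length)
        for (mi in seq_len(n_mol[ci])) {
          s <- sample(lo:hi, 1L)
          b <- tx_interval_blocks(map, s, min(s + cfg$read_length,
                                              tr$site_tx + 1L))
          copies <- 1L + if (cfg$duplicate_rate > 0)
            stats::rgeom(1L, 1 - cfg$duplicate_rate) else 0L
          for (cp in seq_len(copies))
            rows[[length(rows) + 1L]] <- emit(tr$chrom, tr$strand, b,
                                              cells[ci], umis[mi], origin,
                                              FALSE)
        }
      }
    }
    if (!is.null(sim$artifacts)) for (i in seq_len(nrow(sim$artifacts))) {
      ar <- sim$artifacts[i, ]
      origin <- sprintf("%s:ART%d", ar$gene_id, i)
      ori2gen <- function(p) if (ar$strand == "+") ar$gene_start_ori + p
                             else ar$gene_start_ori + ar$span - 1L - p
      n_mol <- rpois(cfg$n_cells, mol_rate)
      for (ci in which(n_mol > 0L)) {
        umis <- .distinct_umis(n_mol[ci], cfg$umi_length)
        for (mi in seq_len(n_mol[ci])) {
          s_ori <- ar$run_ori + sample(-400:-50, 1L)
          ga <- ori2gen(s_ori); gb <- ori2gen(s_ori + cfg$read_length - 1L)
          b <- matrix(c(min(ga, gb), max(ga, gb) + 1L), 1L,
                      dimnames = list(NULL, c("start", "end")))
          rows[[length(rows) + 1L]] <- emit(ar$chrom, ar$strand, b,
                                            cells[ci], umis[mi], origin, TRUE)
        }
      }
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(chrom = character(), start = integer(),
                        end = integer(), strand = character(),
                        mapq = integer(), cb = character(), ub = character(),
                        origin = character(), is_artifact = logical(),
                        stringsAsFactors = FALSE)
      out$blocks <- list()
      attr(out, "cells") <- cells
      return(out)
    }
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "cells") <- cells
    out
  })
}

#' PAS features derived from the simulation truth
#'
#' Builds the peak-like records for the planted sites (footprint = spliced
#' 400 nt ending at the cleavage site) and runs
#' [assign_peaks_to_transcripts()], yielding the reference feature set
#' against which quantification can be checked exactly.
#'
#' @param sim a `pas_sim`.
#' @export
truth_features <- function(sim) {
  rows <- lapply(seq_len(nrow(sim$truth)), function(i) {
    tr <- sim$truth[i, ]
    map <- tx_map(sim$gm, tr$transcript_id)
    blocks <- tx_interval_blocks(map, max(0L, tr$site_tx - 399L),
                                 tr$site_tx + 1L)
    df <- data.frame(chrom = tr$chrom, start = min(blocks[, 1L]),
                     end = max(blocks[, 2L]), strand = tr$strand,
                     gene_id = tr$gene_id, transcript_id = tr$transcript_id,
                     read_count = NA_integer_, three_prime_end = tr$site,
                     category = "exonic", modality = "unimodal",
                     dip_p = NA_real_, ad_p = NA_real_,
                     stringsAsFactors = FALSE)
    df$blocks <- list(blocks)
    df
  })
  assign_peaks_to_transcripts(do.call(rbind, rows), sim$gm)
}

#' Truth UMI count matrix
#'
#' Distinct (barcode, UMI) pairs per origin feature among the simulated
#' reads (artifact reads excluded) -- the exact table [count_umis()] must
#' reproduce.
#'
#' @param reads output of [simulate_reads()].
#' @param feature_ids,barcodes row/column universe (defaults: observed).
#' @export
truth_umi_matrix <- function(reads, feature_ids = NULL, barcodes = NULL) {
  rd <- reads[!reads$is_artifact, , drop = FALSE]
  trip <- unique(data.frame(origin = rd$origin, cb = rd$cb, ub = rd$ub,
                            stringsAsFactors = FALSE))
  feature_ids <- feature_ids %||% sort(unique(trip$origin))
  barcodes <- barcodes %||% sort(unique(trip$cb))
  cnt <- stats::aggregate(list(n = rep(1L, nrow(trip))),
                          by = list(origin = trip$origin, cb = trip$cb),
                          FUN = sum)
  m <- Matrix::sparseMatrix(i = match(cnt$origin, feature_ids),
                            j = match(cnt$cb, barcodes), x = cnt$n,
                            dims = c(length(feature_ids), length(barcodes)))
  rownames(m) <- feature_ids
  colnames(m) <- barcodes
  m
}

#' Write simulated genome / annotation / alignments to standard files
#'
#' @param sim a `pas_sim`.
#' @param reads alignments from [simulate_reads()].
#' @param dir output directory.
#' @param bam also convert the SAM to a sorted, indexed BAM.
#' @return named list of file paths.
#' @export
write_sim <- function(sim, reads, dir, bam = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  con <- file(fa, "w")
  for (ch in names(sim$genome)) {
    writeLines(paste0(">", ch), con)
    s <- sim$genome[[ch]]
    starts <- seq(1L, nchar(s), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
  }
  close(con)
  gtf <- file.path(dir, "genes.gtf")
  write_gtf(sim$gm, gtf)
  truth <- file.path(dir, "truth_pas.tsv")
  write.table(sim$truth, truth, sep = "\t", quote = FALSE, row.names = FALSE)
  sam <- file.path(dir, "reads.sam")
  write_sam(reads, sim$genome, sam)
  out <- list(fasta = fa, gtf = gtf, truth = truth, sam = sam)
  if (!is.null(sim$artifacts)) {
    out$artifacts <- file.path(dir, "truth_artifacts.tsv")
    write.table(sim$artifacts, out$artifacts, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (bam) {
    out$bam <- Rsamtools::asBam(sam, file.path(dir, "reads"),
                                overwrite = TRUE, indexDestination = TRUE)
  }
  out
}

#' Write alignments as a coordinate-sorted SAM file
#'
#' Emits CB/UB tags and N-gapped cigars for junction-spanning reads; SEQ is
#' taken from the forward genome over the read's blocks.
#'
#' @param reads alignment data.frame with `blocks`.
#' @param genome named sequences (for SEQ and header lengths).
#' @param path output SAM path.
#' @export
write_sam <- function(reads, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (ch in names(genome))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch, nchar(genome[[ch]])), con)
  if (nrow(reads) == 0L) return(invisible(path))
  o <- order(reads$chrom, reads$start)
  reads <- reads[o, , drop = FALSE]
  lines <- vapply(seq_len(nrow(reads)), function(i) {
    b <- reads$blocks[[i]]
    cig <- character(0)
    for (j in seq_len(nrow(b))) {
      cig <- c(cig, sprintf("%dM", b[j, 2L] - b[j, 1L]))
      if (j < nrow(b)) cig <- c(cig, sprintf("%dN", b[j + 1L, 1L] - b[j, 2L]))
    }
    sq <- paste(vapply(seq_len(nrow(b)), function(j)
      substr(genome[[reads$chrom[i]]], b[j, 1L] + 1L, b[j, 2L]), ""),
      collapse = "")
    paste(sprintf("r%06d", i), if (reads$strand[i] == "-") 16L else 0L,
          reads$chrom[i], reads$start[i] + 1L,
          reads$mapq[i] %||% 255L, paste(cig, collapse = ""), "*", 0L, 0L,
          sq, strrep("I", nchar(sq)),
          paste0("CB:Z:", reads$cb[i]), paste0("UB:Z:", reads$ub[i]),
          sep = "\t")
  }, "")
  writeLines(lines, con)
  invisible(path)
}

#' Generate a desk-scale labeled training benchmark
#'
#' Positive context sequences carry the planted cleavage-site signal
#' (AATAAA starting 26-30 nt upstream, CA at the site, a downstream U-rich
#' stretch) at the context center; negatives are signal-free random
#' sequence.  The shifted corpus applies the normal-shift scheme
#' (`n_per_site` distinct windows per site), the fixed corpus takes the
#' centered window only; negatives are matched in number to each corpus,
#' so classes stay balanced.
#'
#' @param n_sites training sites (shifted corpus size = `n_sites *
#'   n_per_site`).
#' @param n_val_sites held-out validation sites (and negatives).
#' @param n_per_site windows per site in the shifted corpus.
#' @param width model window (nt).
#' @param context_len context length around each site.
#' @param sigma normal shift sd (nt).
#' @param signal_strength probability a positive site carries the signal.
#' @param base_probs background base composition; the AT-rich default puts
#'   chance poly(A)-hexamers and T-runs into the negative class at
#'   intergenic-like rates, so centered-only training has to key on window
#'   position.
#' @param seed RNG seed.
#' @return list with `shifted`, `fixed`, `validation` (window data.frames
#'   with `sequence`, `label`), and `val_pos_contexts` /
#'   `val_neg_contexts` for offset evaluation.
#' @export
make_training_benchmark <- function(n_sites = 500, n_val_sites = 500,
                                    n_per_site = 10, width = 200,
                                    context_len = 400, sigma = 10,
                                    signal_strength = 1,
                                    base_probs = .default_base_probs,
                                    seed = 1) {
  ctr <- context_len %/% 2L
  with_seed(seed, {
    make_context <- function(positive) {
      s <- .random_dna(context_len, base_probs)
      if (positive && runif(1) < signal_strength) {
        for (piece in .pas_signal_pieces())
          substr(s, ctr + piece$offset + 1L,
                 ctr + piece$offset + nchar(piece$seq)) <- piece$seq
      }
      s
    }
    pos_ctx <- vapply(seq_len(n_sites), function(i) make_context(TRUE), "")
    vpos_ctx <- vapply(seq_len(n_val_sites), function(i) make_context(TRUE), "")
    n_neg <- n_sites * n_per_site + n_sites + n_val_sites
    neg_ctx <- vapply(seq_len(n_neg), function(i) make_context(FALSE), "")
    window_at <- function(ctx, off) substr(ctx, ctr - width %/% 2L + off + 1L,
                                           ctr + width - width %/% 2L + off)
    off <- draw_shift_offsets(n_sites, n_per_site, 0, sigma,
                              max_offset = ctr - width %/% 2L,
                              seed = seed + 1L)
    shifted_pos <- unlist(lapply(seq_len(n_sites), function(i)
      vapply(off[i, ], function(o) window_at(pos_ctx[i], o), "")))
    fixed_pos <- vapply(pos_ctx, window_at, "", off = 0L, USE.NAMES = FALSE)
    negs <- vapply(neg_ctx, window_at, "", off = 0L, USE.NAMES = FALSE)
    i1 <- seq_len(n_sites * n_per_site)
    i2 <- n_sites * n_per_site + seq_len(n_sites)
    i3 <- n_sites * n_per_site + n_sites + seq_len(n_val_sites)
    val_pos <- vapply(vpos_ctx, window_at, "", off = 0L, USE.NAMES = FALSE)
    list(
      shifted = data.frame(sequence = c(shifted_pos, negs[i1]),
                           label = rep(1:0, c(length(shifted_pos),
                                              length(i1)))),
      fixed = data.frame(sequence = c(fixed_pos, negs[i2]),
                         label = rep(1:0, c(n_sites, n_sites))),
      validation = data.frame(sequence = c(val_pos, negs[i3]),
                              label = rep(1:0, c(n_val_sites, n_val_sites))),
      val_pos_contexts = vpos_ctx,
      val_neg_contexts = neg_ctx[i3])
  })
}
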