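# PAS-based transcript construction, PAS GTF emission, per-cell UMI
# counting and RPM quantification.

# total bp overlap between a read's blocks and a feature's blocks
.blocks_overlap <- function(a, b) {
  tot <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    ov <- min(a[i, 2L], b[j, 2L]) - max(a[i, 1L], b[j, 1L])
    if (ov > 0L) tot <- tot + ov
  }
  tot
}

#' Assign surviving PAS peaks to transcripts and build PAS features
#'
#' Each positive PAS call is assigned to the transcript of its gene whose
#' exon chain overlaps the peak footprint most (ties broken toward the
#' longest spliced transcript); the feature's exon chain is the assigned
#' transcript's chain truncated at the PAS 3' end, so no feature extends 3'
#' of its cleavage site.  Peaks overlapping no transcript become unspliced
#' features over their genomic interval.
#'
#' @param peaks positive PAS peak data.frame (see [call_raw_peaks()]).
#' @param gm a [gene_models()] object.
#' @return data.frame of class `pas_features`: feature_id
#'   (`gene:PAS<k>`, ranked by strand-oriented 3'-end position), gene_id,
#'   transcript_id, chrom, strand, pas_site, peak_start, peak_end,
#'   unspliced flag and `blocks` list column (truncated exon chain).
#' @export
assign_peaks_to_transcripts <- function(peaks, gm) {
  if (nrow(peaks) == 0L) stop("no peaks to assign")
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    pk <- peaks[i, ]
    txs <- gm$transcripts[gm$transcripts$gene_id == pk$gene_id, , drop = FALSE]
    pk_blocks <- pk$blocks[[1L]]
    ov <- vapply(txs$transcript_id, function(tid) {
      ex <- gm$exons[gm$exons$transcript_id == tid, , drop = FALSE]
      as.numeric(.blocks_overlap(pk_blocks, as.matrix(ex[, c("start", "end")])))
    }, numeric(1))
    if (nrow(txs) == 0L || max(ov) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = pk$gene_id, transcript_id = NA_character_,
        chrom = pk$chrom, strand = pk$strand, pas_site = pk$three_prime_end,
        peak_start = pk$start, peak_end = pk$end, unspliced = TRUE,
        blocks = I(list(matrix(c(pk$start, pk$end), 1L,
                               dimnames = list(NULL, c("start", "end"))))),
        stringsAsFactors = FALSE)
      next
    }
    best <- which(ov == max(ov))
    if (length(best) > 1L) best <- best[which.max(txs$width[best])]
    tid <- txs$transcript_id[best]
    ex <- gm$exons[gm$exons$transcript_id == tid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    ps <- pk$three_prime_end
    if (pk$strand == "+") {
      ex <- ex[ex$start <= ps, , drop = FALSE]
      ex$end <- pmin(ex$end, ps + 1L)
    } else {
      ex <- ex[ex$end > ps, , drop = FALSE]
      ex$start <- pmax(ex$start, ps)
    }
    blocks <- as.matrix(ex[, c("start", "end")])
    rownames(blocks) <- NULL
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = pk$gene_id, transcript_id = tid, chrom = pk$chrom,
      strand = pk$strand, pas_site = ps, peak_start = pk$start,
      peak_end = pk$end, unspliced = FALSE, blocks = I(list(blocks)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  # rank features within gene along the strand (5' -> 3') for stable ids
  ord <- order(out$gene_id,
               ifelse(out$strand == "+", 1L, -1L) * out$pas_site)
  out <- out[ord, , drop = FALSE]
  k <- stats::ave(seq_len(nrow(out)), out$gene_id, FUN = seq_along)
  out$feature_id <- sprintf("%s:PAS%d", out$gene_id, k)
  out <- out[, c("feature_id", setdiff(names(out), "feature_id"))]
  rownames(out) <- NULL
  class(out) <- c("pas_features", "data.frame")
  out
}

#' Write PAS features as a GTF annotation
#'
#' Gene, transcript and exon rows; the feature id is emitted as the
#' `transcript_id` attribute.  Round-trips through [read_gtf()].
#'
#' @param features a `pas_features` data.frame.
#' @param path output file.
#' @export
write_pas_gtf <- function(features, path) {
  if (nrow(features) == 0L) {
    writeLines("##format: gtf", path)
    return(invisible(path))
  }
  ex <- do.call(rbind, lapply(seq_len(nrow(features)), function(i) {
    b <- features$blocks[[i]]
    data.frame(gene_id = features$gene_id[i],
               transcript_id = features$feature_id[i],
               chrom = features$chrom[i], start = b[, 1L], end = b[, 2L],
               strand = features$strand[i], stringsAsFactors = FALSE)
  }))
  write_gtf(gene_models(ex), path)
}

#' Count UMIs per cell barcode and PAS feature
#'
#' Reads are assigned to sense-strand features by largest base-pair
#' overlap; ties are broken toward the feature whose 3' end is nearest the
#' read's 3' end (natural for 3'-tag chemistry), then by feature order.
#' Within a (barcode, feature) pair, distinct UMI strings count once.
#' Reads without both tags are skipped and tallied in the `qc` attribute.
#'
#' @param reads alignment data.frame (columns chrom, start, end, strand,
#'   cb, ub, optional blocks).
#' @param features `pas_features` from [assign_peaks_to_transcripts()].
#' @return sparse `dgCMatrix` (features x barcodes) with a `qc` attribute.
#' @export
count_umis <- function(reads, features) {
  has_tags <- !is.na(reads$cb) & !is.na(reads$ub)
  qc <- list(n_reads = nrow(reads), n_missing_tags = sum(!has_tags))
  rd <- reads[has_tags, , drop = FALSE]
  # flatten feature blocks into a GRanges keyed by feature index
  fb <- do.call(rbind, lapply(seq_len(nrow(features)), function(i) {
    b <- features$blocks[[i]]
    cbind(feature = i, start = b[, 1L], end = b[, 2L])
  }))
  fgr <- GenomicRanges::GRanges(
    features$chrom[fb[, "feature"]],
    IRanges::IRanges(fb[, "start"] + 1L, fb[, "end"]),
    strand = features$strand[fb[, "feature"]])
  rblocks <- if ("blocks" %in% names(rd)) rd$blocks else
    lapply(seq_len(nrow(rd)), function(i)
      matrix(c(rd$start[i], rd$end[i]), 1L))
  rb <- do.call(rbind, lapply(seq_along(rblocks), function(i)
    cbind(read = i, start = rblocks[[i]][, 1L], end = rblocks[[i]][, 2L])))
  if (is.null(rb)) {
    m <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(nrow(features), 0L))
    rownames(m) <- features$feature_id
    attr(m, "qc") <- qc
    return(m)
  }
  rgr <- GenomicRanges::GRanges(
    rd$chrom[rb[, "read"]],
    IRanges::IRanges(rb[, "start"] + 1L, rb[, "end"]),
    strand = rd$strand[rb[, "read"]])
  hits <- GenomicRanges::findOverlaps(rgr, fgr)  # strand-aware (sense only)
  if (length(hits) == 0L) {
    m <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(nrow(features),
                                       length(unique(rd$cb))))
    rownames(m) <- features$feature_id
    colnames(m) <- sort(unique(rd$cb))
    attr(m, "qc") <- qc
    return(m)
  }
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ovw <- GenomicRanges::width(GenomicRanges::pintersect(rgr[qh], fgr[sh]))
  ri <- rb[qh, "read"]; fi <- fb[sh, "feature"]
  key <- paste(ri, fi)
  agg <- rowsum(ovw, key)
  parts <- strsplit(rownames(agg), " ", fixed = TRUE)
  ri2 <- as.integer(vapply(parts, `[[`, "", 1L))
  fi2 <- as.integer(vapply(parts, `[[`, "", 2L))
  w2 <- agg[, 1L]
  # per read: max overlap, tie -> nearest 3' end, then feature order
  r3p <- ifelse(rd$strand == "+", rd$end - 1L, rd$start)[ri2]
  f3p <- features$pas_site[fi2]
  o <- order(ri2, -w2, abs(r3p - f3p), fi2)
  first <- !duplicated(ri2[o])
  ri_keep <- ri2[o][first]; fi_keep <- fi2[o][first]
  trip <- data.frame(cb = rd$cb[ri_keep], ub = rd$ub[ri_keep],
                     feature = fi_keep, stringsAsFactors = FALSE)
  trip <- trip[!duplicated(trip), , drop = FALSE]
  barcodes <- sort(unique(rd$cb))
  cnt <- stats::aggregate(list(n = rep(1L, nrow(trip))),
                          by = list(feature = trip$feature,
                                    cb = trip$cb), FUN = sum)
  m <- Matrix::sparseMatrix(i = cnt$feature, j = match(cnt$cb, barcodes),
                            x = cnt$n,
                            dims = c(nrow(features), length(barcodes)))
  rownames(m) <- features$feature_id
  colnames(m) <- barcodes
  attr(m, "qc") <- qc
  m
}

#' Reads-per-million over regions
#'
#' RPM = region read count / total mapped reads x 1e6.  Reads below
#' `min_mapq` are excluded; a read overlapping several regions counts in
#' each (multi-overlap semantics); only sense-strand reads count.
#'
#' @param reads alignment data.frame.
#' @param regions data.frame with chrom, start, end, strand.
#' @param min_mapq mapping-quality cutoff.
#' @return numeric RPM vector, one per region.
#' @export
compute_rpm <- function(reads, regions, min_mapq = 3) {
  rd <- reads[is.na(reads$mapq) | reads$mapq >= min_mapq, , drop = FALSE]
  total <- nrow(rd)
  if (total == 0L) stop("zero mapped reads")
  if (nrow(regions) == 0L) return(numeric(0))
  rgr <- GenomicRanges::GRanges(rd$chrom,
                                IRanges::IRanges(rd$start + 1L, rd$end),
                                strand = rd$strand)
  ggr <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(pmax(regions$start, 0) + 1L,
                                                 regions$end),
                                strand = regions$strand)
  cnt <- GenomicRanges::countOverlaps(ggr, rgr)
  cnt / total * 1e6
}

#' Upstream regions of annotated PAS sites
#'
#' The expression proxy for a database PAS: the `flank` nt strand-oriented
#' upstream of the annotated cleavage site.
#'
#' @param pas a `pas_set` or data.frame with chrom, site, strand.
#' @param flank upstream width (nt).
#' @export
pas_upstream_regions <- function(pas, flank = 400) {
  data.frame(chrom = pas$chrom,
             start = ifelse(pas$strand == "+", pas$site - flank, pas$site + 1L),
             end = ifelse(pas$strand == "+", pas$site, pas$site + 1L + flank),
             strand = pas$strand, stringsAsFactors = FALSE)
}

#' Export a cell x PAS matrix as MTX plus feature/barcode TSVs
#'
#' @param m sparse matrix from [count_umis()].
#' @param dir output directory (created if missing).
#' @param wide also write a wide-format TSV.
#' @export
write_matrix <- function(m, dir, wide = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  if (wide) {
    df <- as.data.frame(as.matrix(m))
    df <- cbind(feature = rownames(m), df)
    write.table(df, file.path(dir, "counts_wide.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
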