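# Transcript-level fixed-width peak calling from strand-specific read-start
# coverage, with modality assessment, gene-level aggregation and
# coverage / internal-priming filters.
#
# Exonic reads are projected through the splice structure of each transcript
# and scanned in spliced coordinates (so a peak may map back across an exon
# junction); intron-contained reads are scanned in genomic coordinates.  The
# caller is greedy: candidate fixed-width windows are ranked by the number of
# unclaimed read 5' starts they contain, the best window (ties broken toward
# the most 3' placement) claims its reads, and calling stops when no window
# reaches `min_count` starts.

# ---- alignment input -------------------------------------------------------

#' Read tagged alignments from a BAM or SAM file
#'
#' @param path coordinate-sorted BAM (or plain SAM, converted on the fly).
#' @param cb_tag,umi_tag tag names holding the cell barcode and UMI.
#' @return data.frame with columns chrom, start, end (0-based half-open
#'   reference footprint), strand, mapq, cb, ub and a list column `blocks`
#'   (reference blocks split at N cigar operations, 0-based half-open).
#' @export
read_alignments <- function(path, cb_tag = "CB", umi_tag = "UB") {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = TRUE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "strand", "cigar", "mapq"),
    tag = c(cb_tag, umi_tag))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(b$pos)
  blocks <- cigar_blocks(b$cigar[keep], b$pos[keep] - 1L)
  tg <- b$tag
  df <- data.frame(chrom = as.character(b$rname[keep]),
                   start = b$pos[keep] - 1L,
                   end = vapply(blocks, function(m) m[nrow(m), 2L], 0L),
                   strand = as.character(b$strand[keep]),
                   mapq = b$mapq[keep],
                   cb = (tg[[cb_tag]] %||% rep(NA_character_, length(b$pos)))[keep],
                   ub = (tg[[umi_tag]] %||% rep(NA_character_, length(b$pos)))[keep],
                   stringsAsFactors = FALSE)
  df$blocks <- blocks
  df
}

# Parse cigar strings into reference-space blocks (split at N).
cigar_blocks <- function(cigar, start0) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  mapply(function(cg, om, s) {
    toks <- regmatches(cg, list(om))[[1]]
    lens <- as.integer(sub("[A-Z=]", "", toks))
    op <- substr(toks, nchar(toks), nchar(toks))
    blocks <- list()
    bs <- s; pos <- s
    for (i in seq_along(op)) {
      if (op[i] %in% c("M", "=", "X", "D")) {
        pos <- pos + lens[i]
      } else if (op[i] == "N") {
        if (pos > bs) blocks[[length(blocks) + 1L]] <- c(bs, pos)
        pos <- pos + lens[i]
        bs <- pos
      }
    }
    if (pos > bs) blocks[[length(blocks) + 1L]] <- c(bs, pos)
    matrix(unlist(blocks), ncol = 2L, byrow = TRUE,
           dimnames = list(NULL, c("start", "end")))
  }, cigar, ops, start0, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

# 5' start of a read (0-based): leftmost base on '+', rightmost on '-'.
read_five_prime <- function(reads) {
  ifelse(reads$strand == "+", reads$start, reads$end - 1L)
}

# ---- transcript coordinate machinery ---------------------------------------

# Oriented exon map for one transcript: blocks in 5'->3' order with
# cumulative spliced offsets.
tx_map <- function(gm, transcript_id) {
  ex <- gm$exons[gm$exons$transcript_id == transcript_id, , drop = FALSE]
  ex <- ex[order(ex$exon_rank), , drop = FALSE]
  w <- ex$end - ex$start
  list(chrom = ex$chrom[1], strand = ex$strand[1], start = ex$start,
       end = ex$end, cum = cumsum(c(0L, w))[seq_along(w)], width = w,
       tx_len = sum(w))
}

# Genomic positions -> spliced transcript coordinates (NA outside exons).
genomic_to_tx <- function(map, pos) {
  out <- rep(NA_integer_, length(pos))
  for (i in seq_along(map$start)) {
    inside <- !is.na(pos) & pos >= map$start[i] & pos < map$end[i]
    if (!any(inside)) next
    off <- if (map$strand == "+") pos[inside] - map$start[i]
           else map$end[i] - 1L - pos[inside]
    out[inside] <- map$cum[i] + off
  }
  out
}

# Spliced transcript position -> genomic position.
tx_to_genomic <- function(map, txpos) {
  out <- rep(NA_integer_, length(txpos))
  for (i in seq_along(map$start)) {
    inside <- !is.na(txpos) & txpos >= map$cum[i] &
      txpos < map$cum[i] + map$width[i]
    if (!any(inside)) next
    off <- txpos[inside] - map$cum[i]
    out[inside] <- if (map$strand == "+") map$start[i] + off
                   else map$end[i] - 1L - off
  }
  out
}

# Spliced interval [a, b) -> genomic blocks (matrix, 0-based half-open,
# ascending genomic order).
tx_interval_blocks <- function(map, a, b) {
  blocks <- list()
  for (i in seq_along(map$start)) {
    lo <- max(a, map$cum[i])
    hi <- min(b, map$cum[i] + map$width[i])
    if (lo >= hi) next
    if (map$strand == "+") {
      gs <- map$start[i] + (lo - map$cum[i]); ge <- map$start[i] + (hi - map$cum[i])
    } else {
      ge <- map$end[i] - (lo - map$cum[i]); gs <- map$end[i] - (hi - map$cum[i])
    }
    blocks[[length(blocks) + 1L]] <- c(gs, ge)
  }
  m <- matrix(unlist(blocks), ncol = 2L, byrow = TRUE,
              dimnames = list(NULL, c("start", "end")))
  m[order(m[, 1L]), , drop = FALSE]
}

# ---- greedy fixed-width window calling -------------------------------------

# Greedy fixed-width caller on integer positions in [0, len).  Returns a
# data.frame of windows (a, count) plus the claimed positions per window.
greedy_windows <- function(positions, len, size = 400, min_dist = 10,
                           min_count = 10) {
  if (length(positions) == 0L) return(NULL)
  size <- as.integer(size)
  claimed <- rep(FALSE, length(positions))
  summits <- integer(0)
  out <- list()
  repeat {
    rem <- positions[!claimed]
    if (length(rem) < min_count) break
    nbins <- max(len, max(rem) + 1L)
    cov <- tabulate(rem + 1L, nbins)
    cs <- cumsum(c(0L, cov))
    a_cand <- 0:(nbins - 1L)
    cnt <- cs[pmin(a_cand + size, nbins) + 1L] - cs[a_cand + 1L]
    best <- max(cnt)
    if (best < min_count) break
    a <- max(a_cand[cnt == best])          # most 3' placement among ties
    summit <- a + size %/% 2L
    take <- !claimed & positions >= a & positions < a + size
    claimed[take] <- TRUE                  # claim even if summit rejected
    if (length(summits) && any(abs(summits - summit) <= min_dist)) next
    summits <- c(summits, summit)
    out[[length(out) + 1L]] <- list(a = a, b = min(a + size, len),
                                    count = sum(take),
                                    positions = positions[take])
  }
  out
}

#' Assess the modality of a peak coverage profile
#'
#' Computes a dip statistic (sup-norm distance from the empirical cdf of
#' read 5'-start positions to the nearest unimodal cdf) with a Monte Carlo
#' p-value calibrated on uniform null samples, plus an Anderson-Darling
#' normality statistic as metadata.  The profile is quantile-subsampled to a
#' fixed size so one cached null table serves all peaks.
#'
#' @param positions integer read-start positions within the peak window.
#' @param alpha rejection level for the dip test.
#' @param n_sub largest sample size used for the dip statistic; larger
#'   profiles are quantile-downsampled.  The statistic is never computed
#'   on more points than the profile holds (the dip scales with sample
#'   size, so comparing against a larger-n null would anti-conservatively
#'   reject).
#' @param B Monte Carlo replicates for the null table.
#' @return list with `modality` ("unimodal"/"multimodal"), `dip`, `dip_p`,
#'   `ad_p` (NA when not computable).
#' @export
assess_modality <- function(positions, alpha = 0.05, n_sub = 201L, B = 200L) {
  positions <- as.numeric(positions)
  n <- length(positions)
  if (n < 2L || length(unique(positions)) == 1L)
    return(list(modality = "unimodal", dip = 0, dip_p = 1, ad_p = NA_real_))
  # downsample to the largest grid size <= n so a handful of null tables
  # (cached per size) covers every peak
  grid <- c(30L, 50L, 75L, 100L, 150L, n_sub)
  n_use <- if (n < min(grid)) n else max(grid[grid <= min(n, n_sub)])
  xs <- if (n_use < n)
    as.numeric(quantile(positions, ppoints(n_use), type = 1L))
  else positions
  # deterministic dithering so integer ties approximate a continuous sample
  xs <- sort(xs + seq_along(xs) * 1e-9)
  dip <- cpp_dip_stat(xs)
  key <- sprintf("dipnull_%d_%d", n_use, B)
  if (is.null(.pasflow_env[[key]]))
    .pasflow_env[[key]] <- sort(cpp_dip_null(n_use, B, 20260921L))
  null <- .pasflow_env[[key]]
  p <- (1 + sum(null >= dip)) / (B + 1)
  ad_p <- NA_real_
  if (n >= 8L && stats::sd(positions) > 0)
    ad_p <- tryCatch(nortest::ad.test(positions)$p.value, error = function(e) NA_real_)
  list(modality = if (p <= alpha) "multimodal" else "unimodal",
       dip = dip, dip_p = p, ad_p = ad_p)
}

# Split one called window at the deepest smoothed-coverage minimum between
# its two highest modes.  The second mode must sit at least `min_sep`
# positions from the first so smoothing noise within one mode cannot fake
# a pair.  Returns a list of (a, b, count, positions).
split_window <- function(win, smooth_k = 21L, min_sep = 50L) {
  pos <- win$positions
  prof <- tabulate(pos - win$a + 1L, win$b - win$a)
  k <- min(smooth_k, length(prof))
  if (k %% 2L == 0L) k <- k - 1L
  sm <- stats::filter(prof, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- 0
  sm <- as.numeric(sm)
  n <- length(sm)
  is_max <- which(vapply(seq_len(n), function(i) {
    l <- if (i > 1L) sm[i - 1L] else -Inf
    r <- if (i < n) sm[i + 1L] else -Inf
    sm[i] > l && sm[i] >= r
  }, logical(1)))
  if (length(is_max) < 2L) return(list(win))
  first <- is_max[which.max(sm[is_max])]
  cand <- is_max[abs(is_max - first) >= min_sep]
  if (length(cand) == 0L) return(list(win))
  second <- cand[which.max(sm[cand])]
  top2 <- c(first, second)
  lo <- min(top2); hi <- max(top2)
  valley <- lo + which.min(sm[lo:hi]) - 1L
  cut <- win$a + valley - 1L
  left <- pos[pos < cut]; right <- pos[pos >= cut]
  if (length(left) == 0L || length(right) == 0L) return(list(win))
  list(list(a = win$a, b = cut, count = length(left), positions = left),
       list(a = cut, b = win$b, count = length(right), positions = right))
}

#' Split a multimodal peak profile
#'
#' Splits at the deepest internal smoothed-coverage minimum between the two
#' highest modes; children partition the parent's reads, so counts are
#' conserved.  Unimodal input is returned unchanged.
#'
#' @param a,b window bounds (0-based half-open) in the calling coordinate
#'   space.
#' @param positions read 5'-start positions inside the window.
#' @param modality modality label from [assess_modality()].
#' @return list of windows, each a list with `a`, `b`, `count`, `positions`.
#' @export
split_multimodal <- function(a, b, positions, modality = "multimodal") {
  win <- list(a = a, b = b, count = length(positions), positions = positions)
  if (!identical(modality, "multimodal")) return(list(win))
  split_window(win)
}

# ---- full per-transcript calling -------------------------------------------

empty_peaks <- function() {
  df <- data.frame(chrom = character(), start = integer(), end = integer(),
                   strand = character(), gene_id = character(),
                   transcript_id = character(), read_count = integer(),
                   three_prime_end = integer(), category = character(),
                   modality = character(), dip_p = numeric(),
                   ad_p = numeric(), stringsAsFactors = FALSE)
  df$blocks <- list()
  df
}

#' Call raw fixed-width peaks per transcript
#'
#' @param reads alignment data.frame (see [read_alignments()]).
#' @param gm a [gene_models()] object.
#' @param size fixed window width (nt) in the calling coordinate space.
#' @param min_dist minimal summit separation between accepted windows.
#' @param min_count minimal read-start count for a window.
#' @param alpha dip-test level for modality assessment.
#' @param split_multimodal_peaks split windows judged multimodal.
#' @return data.frame of peaks ordered by descending read count with columns
#'   chrom, start, end (genomic footprint), strand, gene_id, transcript_id,
#'   read_count, three_prime_end (0-based position of the 3'-terminal base),
#'   category ("exonic"/"intronic"), modality, dip_p, ad_p and a `blocks`
#'   list column (genomic footprint split at exon junctions).
#' @export
call_raw_peaks <- function(reads, gm, size = 400, min_dist = 10,
                           min_count = 10, alpha = 0.05,
                           split_multimodal_peaks = TRUE) {
  if (nrow(reads) == 0L) return(empty_peaks())
  fp <- read_five_prime(reads)
  res <- list()
  for (ti in seq_len(nrow(gm$transcripts))) {
    tx <- gm$transcripts[ti, ]
    map <- tx_map(gm, tx$transcript_id)
    on_str <- reads$chrom == tx$chrom & reads$strand == tx$strand
    if (!any(on_str)) next
    p5 <- fp[on_str]
    # exonic branch: spliced coordinates
    txpos <- genomic_to_tx(map, p5)
    exonic <- !is.na(txpos)
    wins <- greedy_windows(txpos[exonic], map$tx_len, size, min_dist, min_count)
    for (w in wins %||% list())
      res[[length(res) + 1L]] <- .finish_tx_windows(w, map, tx, gm, alpha,
                                                    split_multimodal_peaks,
                                                    spliced = TRUE)
    # intronic branch: genomic coordinates inside the transcript span
    span_in <- p5 >= tx$start & p5 < tx$end & is.na(txpos)
    if (any(span_in)) {
      gpos <- p5[span_in]
      orient <- if (tx$strand == "+") gpos - tx$start
                else tx$end - 1L - gpos
      wins <- greedy_windows(orient, tx$end - tx$start, size, min_dist,
                             min_count)
      gmap <- list(chrom = tx$chrom, strand = tx$strand, start = tx$start,
                   end = tx$end, cum = 0L, width = tx$end - tx$start,
                   tx_len = tx$end - tx$start)
      for (w in wins %||% list())
        res[[length(res) + 1L]] <- .finish_tx_windows(w, gmap, tx, gm, alpha,
                                                      split_multimodal_peaks,
                                                      spliced = FALSE)
    }
  }
  if (length(res) == 0L) return(empty_peaks())
  out <- do.call(rbind, res)
  out <- out[order(-out$read_count), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Turn one greedy window into one or two peak rows (after modality split)
# mapped back to genomic coordinates.
.finish_tx_windows <- function(win, map, tx, gm, alpha, do_split, spliced) {
  mod <- assess_modality(win$positions, alpha = alpha)
  parts <- if (do_split && mod$modality == "multimodal")
    split_window(win) else list(win)
  rows <- lapply(parts, function(p) {
    blocks <- tx_interval_blocks(map, p$a, p$b)
    tpe_tx <- p$b - 1L
    tpe <- tx_to_genomic(map, tpe_tx)
    exs <- gm$exons[gm$exons$transcript_id == tx$transcript_id, , drop = FALSE]
    in_exon <- any(tpe >= exs$start & tpe < exs$end)
    df <- data.frame(chrom = map$chrom, start = min(blocks[, 1L]),
                     end = max(blocks[, 2L]), strand = map$strand,
                     gene_id = tx$gene_id, transcript_id = tx$transcript_id,
                     read_count = p$count, three_prime_end = tpe,
                     category = if (in_exon) "exonic" else "intronic",
                     modality = if (length(parts) > 1L) "multimodal"
                                else mod$modality,
                     dip_p = mod$dip_p, ad_p = mod$ad_p,
                     stringsAsFactors = FALSE)
    df$blocks <- list(blocks)
    df
  })
  do.call(rbind, rows)
}

# ---- aggregation and filters -----------------------------------------------

#' Aggregate overlapping peaks within genes
#'
#' Within each gene, peaks whose genomic overlap is at least `min_overlap`
#' of the shorter peak's width are grouped transitively and each group is
#' replaced by its most highly expressed member, so surviving peaks within
#' a gene pairwise overlap less than the threshold.
#'
#' @param peaks peak data.frame from [call_raw_peaks()].
#' @param min_overlap overlap fraction threshold (default 0.5).
#' @return filtered peak data.frame.
#' @export
aggregate_gene_peaks <- function(peaks, min_overlap = 0.5) {
  if (nrow(peaks) == 0L) return(peaks)
  keep <- logical(nrow(peaks))
  for (g in unique(peaks$gene_id)) {
    gi <- which(peaks$gene_id == g)
    n <- length(gi)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      a <- peaks[gi[i], ]; b <- peaks[gi[j], ]
      ov <- min(a$end, b$end) - max(a$start, b$start)
      shorter <- min(a$end - a$start, b$end - b$start)
      if (ov / shorter >= min_overlap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    for (r in unique(roots)) {
      mem <- gi[roots == r]
      best <- mem[order(-peaks$read_count[mem], peaks$start[mem])][1L]
      keep[best] <- TRUE
    }
  }
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove low-coverage peaks within genes
#'
#' Drops peaks contributing at most `max_fraction` (default 1%) of the
#' summed read count of their gene's peaks.
#'
#' @inheritParams aggregate_gene_peaks
#' @param max_fraction removal threshold on the within-gene count fraction.
#' @export
filter_low_coverage <- function(peaks, max_fraction = 0.01) {
  if (nrow(peaks) == 0L) return(peaks)
  tot <- stats::ave(peaks$read_count, peaks$gene_id, FUN = sum)
  out <- peaks[peaks$read_count / tot > max_fraction, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove intronic internal-priming peaks
#'
#' Drops intronic peaks whose strand-oriented sequence in the window
#' `[3' end - upstream, 3' end + downstream]` contains a run of at least
#' `min_run` consecutive adenines.  Exonic peaks are untouched.  The scan
#' reaches 30 nt upstream because the fixed-width caller places the
#' reported 3' end with a few tens of nt of jitter around the priming
#' locus, and 20 nt downstream to cover the oligo(dT) annealing stretch.
#'
#' @inheritParams aggregate_gene_peaks
#' @param genome named sequence vector from [read_genome()].
#' @param min_run adenine run length triggering removal (default 8).
#' @param upstream,downstream scan window around the 3' end.
#' @export
filter_internal_priming <- function(peaks, genome, min_run = 8, upstream = 30,
                                    downstream = 20) {
  if (nrow(peaks) == 0L) return(peaks)
  run <- strrep("A", min_run)
  drop <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (peaks$category[i] != "intronic") next
    e <- peaks$three_prime_end[i]
    if (peaks$strand[i] == "+") {
      s <- fetch_seq(genome, peaks$chrom[i], e - upstream, e + downstream + 1L,
                     "+", clip = TRUE)
    } else {
      s <- fetch_seq(genome, peaks$chrom[i], e - downstream, e + upstream + 1L,
                     "-", clip = TRUE)
    }
    drop[i] <- grepl(run, s, fixed = TRUE)
  }
  out <- peaks[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full peak-calling stage
#'
#' Runs [call_raw_peaks()], [aggregate_gene_peaks()],
#' [filter_low_coverage()] and, when a genome is supplied,
#' [filter_internal_priming()].
#'
#' @inheritParams call_raw_peaks
#' @param genome optional genome for the internal-priming filter.
#' @export
call_peaks <- function(reads, gm, genome = NULL, size = 400, min_dist = 10,
                       min_count = 10, alpha = 0.05) {
  pk <- call_raw_peaks(reads, gm, size = size, min_dist = min_dist,
                       min_count = min_count, alpha = alpha)
  pk <- aggregate_gene_peaks(pk)
  pk <- filter_low_coverage(pk)
  if (!is.null(genome)) pk <- filter_internal_priming(pk, genome)
  pk
}

#' Write peaks as BED6 plus annotation TSV
#'
#' @param peaks peak data.frame.
#' @param prefix output path prefix; writes `<prefix>.bed` and
#'   `<prefix>.tsv`.
#' @export
write_peaks <- function(peaks, prefix) {
  bed <- data.frame(peaks$chrom, peaks$start, peaks$end,
                    sprintf("peak_%d", seq_len(nrow(peaks))),
                    peaks$read_count, peaks$strand)
  write.table(bed, paste0(prefix, ".bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  tsv <- peaks[, setdiff(names(peaks), "blocks")]
  write.table(tsv, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}
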