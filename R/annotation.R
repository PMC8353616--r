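# Genome / annotation data model and I/O.
#
# All internal coordinates are 0-based half-open; GTF I/O converts to and
# from the 1-based inclusive convention of the format.  Strand-oriented
# sequence extraction reverse-complements minus-strand windows so position 0
# of a returned window is always its 5' end.

#' Read a genome FASTA into a named vector of uppercase sequences
#'
#' @param path path to a FASTA file.
#' @return named character vector, one element per sequence.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 50L)
  nonblank <- which(nzchar(trimws(first)))
  if (length(nonblank) == 0L || !startsWith(trimws(first[nonblank[1]]), ">"))
    stop("malformed FASTA (no header at line ", if (length(nonblank)) nonblank[1] else 1L,
         "): ", path)
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Reverse complement of DNA strings
#' @param x character vector of DNA sequences.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Strand-oriented subsequence extraction
#'
#' Extracts `[start, end)` (0-based half-open) from `chrom` and
#' reverse-complements the result when `strand == "-"`, so the returned
#' string always reads 5' to 3' along the requested strand.
#'
#' @param genome named character vector from [read_genome()].
#' @param chrom,start,end,strand window definition.
#' @param clip clip the window at the contig bounds instead of erroring.
#' @export
fetch_seq <- function(genome, chrom, start, end, strand = "+", clip = FALSE) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  n <- nchar(genome[[chrom]])
  if (clip) {
    start <- max(0L, start)
    end <- min(n, end)
    if (start >= end) return("")
  } else if (start < 0 || end > n || start >= end) {
    stop("window [", start, ",", end, ") outside ", chrom, " (length ", n, ")")
  }
  s <- substr(genome[[chrom]], start + 1L, end)
  if (strand == "-") revcomp(s) else s
}

# ---- gene models -----------------------------------------------------------

#' Construct a gene-model object from an exon table
#'
#' @param exons data.frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`.
#' @return object of class `gene_models`: the exon table (with `exon_rank`
#'   ordered 5' to 3' per transcript) plus per-transcript and per-gene
#'   summaries.  A gene's 3' end is the strand-oriented downstream-most
#'   transcript end.
#' @export
gene_models <- function(exons) {
  need <- c("gene_id", "transcript_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(exons))
  if (length(miss)) stop("exon table lacks columns: ", paste(miss, collapse = ", "))
  if (any(exons$start >= exons$end)) stop("exon with start >= end")
  if (!all(exons$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  exons <- exons[, need]
  # 5'->3' exon order: ascending start on '+', descending on '-'
  o <- order(exons$transcript_id, ifelse(exons$strand == "+", 1, -1) * exons$start)
  exons <- exons[o, , drop = FALSE]
  exons$exon_rank <- stats::ave(seq_len(nrow(exons)), exons$transcript_id,
                                FUN = seq_along)
  # non-overlap within transcript
  by_tx <- split(exons, exons$transcript_id)
  for (tx in by_tx) {
    s <- sort(tx$start); e <- tx$end[order(tx$start)]
    if (nrow(tx) > 1 && any(s[-1] < e[-nrow(tx)]))
      stop("overlapping exons in transcript ", tx$transcript_id[1])
  }
  transcripts <- do.call(rbind, lapply(by_tx, function(tx) {
    data.frame(transcript_id = tx$transcript_id[1], gene_id = tx$gene_id[1],
               chrom = tx$chrom[1], strand = tx$strand[1],
               start = min(tx$start), end = max(tx$end),
               exon_count = nrow(tx), width = sum(tx$end - tx$start),
               stringsAsFactors = FALSE)
  }))
  rownames(transcripts) <- NULL
  by_g <- split(transcripts, transcripts$gene_id)
  genes <- do.call(rbind, lapply(by_g, function(g) {
    tpe <- if (g$strand[1] == "+") max(g$end) - 1L else min(g$start)
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1], strand = g$strand[1],
               start = min(g$start), end = max(g$end),
               three_prime_end = tpe, stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  structure(list(exons = exons, transcripts = transcripts, genes = genes),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts,", nrow(x$exons), "exons\n")
  invisible(x)
}

#' Read gene models from a GTF file
#'
#' Imports gene/transcript/exon features (GENCODE-style attributes) and
#' converts 1-based inclusive coordinates to the internal 0-based half-open
#' convention.  If explicit transcript features are present, exons falling
#' outside their transcript's bounds raise a validation error.
#'
#' @param path GTF file.
#' @return a [gene_models()] object.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  ex <- gr[md$type == "exon"]
  if (length(ex) == 0L) stop("no exon features in ", path)
  exons <- data.frame(
    gene_id = as.character(S4Vectors::mcols(ex)$gene_id),
    transcript_id = as.character(S4Vectors::mcols(ex)$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    stringsAsFactors = FALSE)
  tx <- gr[md$type == "transcript"]
  if (length(tx)) {
    ts <- GenomicRanges::start(tx) - 1L
    te <- GenomicRanges::end(tx)
    names(ts) <- names(te) <- as.character(S4Vectors::mcols(tx)$transcript_id)
    hit <- exons$transcript_id %in% names(ts)
    bad <- hit & (exons$start < ts[exons$transcript_id] |
                  exons$end > te[exons$transcript_id])
    if (any(bad))
      stop("exon outside transcript bounds for ",
           paste(unique(exons$transcript_id[bad]), collapse = ", "))
  }
  gene_models(exons)
}

#' Write gene models as GTF
#'
#' Emits gene, transcript and exon rows with 1-based inclusive coordinates;
#' round-trips through [read_gtf()].
#'
#' @param gm a [gene_models()] object.
#' @param path output file.
#' @export
write_gtf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##format: gtf", con)
  fmt <- function(chrom, feat, start0, end, strand, attrs) {
    sprintf("%s\tpasflow\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, feat, start0 + 1L, end, strand, attrs)
  }
  for (gi in seq_len(nrow(gm$genes))) {
    g <- gm$genes[gi, ]
    writeLines(fmt(g$chrom, "gene", g$start, g$end, g$strand,
                   sprintf('gene_id "%s";', g$gene_id)), con)
    txs <- gm$transcripts[gm$transcripts$gene_id == g$gene_id, , drop = FALSE]
    for (ti in seq_len(nrow(txs))) {
      tx <- txs[ti, ]
      at <- sprintf('gene_id "%s"; transcript_id "%s";', g$gene_id,
                    tx$transcript_id)
      writeLines(fmt(tx$chrom, "transcript", tx$start, tx$end, tx$strand, at),
                 con)
      exs <- gm$exons[gm$exons$transcript_id == tx$transcript_id, , drop = FALSE]
      exs <- exs[order(exs$start), , drop = FALSE]
      for (ei in seq_len(nrow(exs)))
        writeLines(fmt(exs$chrom[ei], "exon", exs$start[ei], exs$end[ei],
                       exs$strand[ei], at), con)
    }
  }
  invisible(path)
}

# ---- PAS sets --------------------------------------------------------------

.pas_source_labels <- c("DB1", "DB2", "DB3", "GENCODE")

#' Construct a PAS set
#'
#' @param chrom,site,strand per-record cleavage-site coordinates (`site` is
#'   the 0-based position of the cleavage site).
#' @param sources list of character vectors (or a single character vector,
#'   recycled per record) of source labels.
#' @param tier `"known"` or `"stringent"`.
#' @return data.frame of class `pas_set` with a list column `sources`.
#' @export
pas_set <- function(chrom, site, strand, sources, tier = "known") {
  if (!is.list(sources)) sources <- as.list(sources)
  stopifnot(all(strand %in% c("+", "-")))
  bad <- setdiff(unique(unlist(sources)), .pas_source_labels)
  if (length(bad)) stop("unknown PAS source label(s): ", paste(bad, collapse = ", "))
  df <- data.frame(chrom = as.character(chrom), site = as.integer(site),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  df$sources <- sources
  class(df) <- c("pas_set", "data.frame")
  attr(df, "tier") <- tier
  df
}

#' Build the known PAS set from per-source records
#'
#' Records carrying a single source label each are merged by exact
#' (chrom, site, strand) key; a site enters the known set if it is reported
#' by at least two of the three databases, or by the curated gene
#' annotation (GENCODE label), whichever holds.
#'
#' @param records data.frame with columns `chrom`, `site`, `strand`, `source`.
#' @param db_labels labels counting as databases.
#' @param annot_label label of the curated annotation source.
#' @return `pas_set` with tier `"known"`; `sources` holds the union of labels
#'   per site.
#' @export
build_known_pas_set <- function(records, db_labels = c("DB1", "DB2", "DB3"),
                                annot_label = "GENCODE") {
  stopifnot(all(c("chrom", "site", "strand", "source") %in% names(records)))
  bad <- setdiff(unique(records$source), c(db_labels, annot_label))
  if (length(bad)) stop("unknown PAS source label(s): ", paste(bad, collapse = ", "))
  key <- paste(records$chrom, records$site, records$strand, sep = "\r")
  src <- lapply(split(records$source, key), function(s) sort(unique(s)))
  keys <- names(src)
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  n_db <- vapply(src, function(s) sum(s %in% db_labels), integer(1))
  has_annot <- vapply(src, function(s) annot_label %in% s, logical(1))
  keep <- n_db >= 2L | has_annot
  out <- pas_set(parts[keep, 1], as.integer(parts[keep, 2]), parts[keep, 3],
                 unname(src[keep]), tier = "known")
  out[order(out$chrom, out$site, out$strand), , drop = FALSE]
}

#' Restrict a known PAS set to the stringent tier
#'
#' Stringent sites are reported by all three databases, or present in the
#' curated annotation.
#'
#' @param known a `pas_set` built by [build_known_pas_set()].
#' @inheritParams build_known_pas_set
#' @export
build_stringent_set <- function(known, db_labels = c("DB1", "DB2", "DB3"),
                                annot_label = "GENCODE") {
  keep <- vapply(known$sources, function(s) {
    all(db_labels %in% s) || annot_label %in% s
  }, logical(1))
  out <- known[keep, , drop = FALSE]
  class(out) <- c("pas_set", "data.frame")
  attr(out, "tier") <- "stringent"
  out
}

#' Split a PAS set into training and validation subsets
#'
#' Uniform random partition; the training size is `N * ratio` rounded half
#' up, so 251,071 sites at ratio 0.9 give 225,964 training and 25,107
#' validation sites.
#'
#' @param pas a `pas_set`.
#' @param ratio training fraction in (0, 1).
#' @param seed RNG seed making the partition reproducible.
#' @return list with elements `train` and `validation`.
#' @export
split_train_validation <- function(pas, ratio = 0.9, seed = 1) {
  n <- nrow(pas)
  if (n == 0L) stop("cannot split an empty PAS set")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  n_train <- as.integer(floor(n * ratio + 0.5))
  idx <- with_seed(seed, sample.int(n, n_train))
  keep_class <- function(x) {
    class(x) <- c("pas_set", "data.frame")
    attr(x, "tier") <- attr(pas, "tier")
    x
  }
  list(train = keep_class(pas[sort(idx), , drop = FALSE]),
       validation = keep_class(pas[setdiff(seq_len(n), idx), , drop = FALSE]))
}

#' Does a peak 3' end overlap a known PAS?
#'
#' A known site overlaps when it lies between `upstream` nt 5' and
#' `downstream` nt 3' of the peak's strand-oriented 3' end (both boundaries
#' inclusive; defaults 50 and 25).
#'
#' @param chrom,end,strand vectors describing peak 3' ends (`end` is the
#'   0-based position of the 3'-terminal base).
#' @param known a `pas_set`.
#' @param upstream,downstream window half-widths in nt.
#' @return logical vector.
#' @export
overlaps_known <- function(chrom, end, strand, known, upstream = 50,
                           downstream = 25) {
  lo <- ifelse(strand == "+", end - upstream, end - downstream)
  hi <- ifelse(strand == "+", end + downstream, end + upstream)
  .any_site_in_window(chrom, lo, hi, strand, known)
}

# For each query window [lo, hi] (inclusive), is there a site of `sites`
# (data.frame chrom/site/strand) on the same chrom and strand inside it?
.any_site_in_window <- function(chrom, lo, hi, strand, sites) {
  out <- logical(length(chrom))
  key_q <- paste(chrom, strand)
  key_s <- paste(sites$chrom, sites$strand)
  for (k in unique(key_q)) {
    qi <- which(key_q == k)
    ss <- sort(sites$site[key_s == k])
    if (length(ss) == 0L) next
    n_lo <- findInterval(lo[qi] - 1L, ss)   # sites <= lo-1
    n_hi <- findInterval(hi[qi], ss)        # sites <= hi
    out[qi] <- n_hi > n_lo
  }
  out
}

#' Write / read a PAS set as a BED-like TSV
#'
#' Columns: chrom, site, site+1, name, score, strand, comma-joined sources.
#'
#' @param pas a `pas_set`.
#' @param path file path.
#' @export
write_pas_bed <- function(pas, path) {
  df <- data.frame(chrom = pas$chrom, start = pas$site, end = pas$site + 1L,
                   name = sprintf("pas_%d", seq_len(nrow(pas))), score = 0L,
                   strand = pas$strand,
                   sources = vapply(pas$sources, paste, "", collapse = ","),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_pas_bed
#' @param tier tier label to attach on read.
#' @export
read_pas_bed <- function(path, tier = "known") {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "name", "score",
                                 "strand", "sources"))
  pas_set(df$chrom, df$start, df$strand, strsplit(df$sources, ","), tier = tier)
}
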