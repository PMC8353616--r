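# APA analytics: proximal PAS usage per gene per cell, per-cell global
# proximal preference, differential PAS usage between cell groups, and
# poly(A)-signal motif statistics.

#' Order a gene's PAS features by distance to the gene 3' end
#'
#' Distance is measured along the strand from each feature's cleavage site
#' to the annotated gene 3' end; the proximal PAS is the one farthest from
#' the gene end (shortest 3'UTR), the distal one the closest.
#'
#' @param features `pas_features` data.frame.
#' @param gm a [gene_models()] object.
#' @return `features` with added `distance_to_gene_end` and logical
#'   `proximal` / `distal` flags, sorted within gene by decreasing
#'   distance (proximal first).
#' @export
order_pas_by_distance <- function(features, gm) {
  g3 <- setNames(gm$genes$three_prime_end, gm$genes$gene_id)
  known <- features$gene_id %in% names(g3)
  d <- rep(NA_real_, nrow(features))
  d[known] <- ifelse(features$strand[known] == "+",
                     g3[features$gene_id[known]] - features$pas_site[known],
                     features$pas_site[known] - g3[features$gene_id[known]])
  features$distance_to_gene_end <- d
  o <- order(features$gene_id, -features$distance_to_gene_end)
  features <- features[o, , drop = FALSE]
  first <- !duplicated(features$gene_id)
  last <- !duplicated(features$gene_id, fromLast = TRUE)
  features$proximal <- first
  features$distal <- last
  rownames(features) <- NULL
  features
}

#' Proximal PAS usage from CPM values
#'
#' `log2((cpm_proximal + 1) / (sum(cpm_rest) + 1))`.
#'
#' @param cpm_proximal CPM of the proximal feature.
#' @param cpm_rest vector (or scalar) of CPM for the gene's other features.
#' @export
proximal_usage_value <- function(cpm_proximal, cpm_rest) {
  log2((cpm_proximal + 1) / (sum(cpm_rest) + 1))
}

#' Per-gene, per-cell proximal PAS usage
#'
#' CPM is computed per cell over all PAS features (counts / cell total x
#' 1e6); usage per multi-PAS gene is
#' `log2((CPM_proximal + 1) / (sum CPM_rest + 1))`.  Single-PAS genes are
#' excluded; cells with zero total counts are dropped.
#'
#' @param counts features x cells matrix from [count_umis()].
#' @param features `pas_features` ordered by [order_pas_by_distance()] (the
#'   ordering is applied if the `proximal` column is absent).
#' @param gm gene models (needed only when ordering is applied here).
#' @return list with `usage` (genes x cells matrix), `features` (ordered),
#'   `cells` (barcodes scored).
#' @export
proximal_usage <- function(counts, features, gm = NULL) {
  if (!"proximal" %in% names(features)) {
    if (is.null(gm)) stop("supply gene models or pre-ordered features")
    features <- order_pas_by_distance(features, gm)
  }
  counts <- counts[features$feature_id, , drop = FALSE]
  tot <- Matrix::colSums(counts)
  cells <- colnames(counts)[tot > 0]
  cpm <- sweep(as.matrix(counts[, cells, drop = FALSE]), 2L, tot[cells],
               "/") * 1e6
  multi <- names(which(table(features$gene_id) >= 2L))
  genes <- sort(multi)
  usage <- matrix(NA_real_, length(genes), length(cells),
                  dimnames = list(genes, cells))
  for (g in genes) {
    fi <- which(features$gene_id == g)
    prox <- fi[features$proximal[fi]]
    rest <- setdiff(fi, prox)
    rest_sum <- if (length(rest) > 1L) colSums(cpm[rest, , drop = FALSE])
                else cpm[rest, ]
    usage[g, ] <- log2((cpm[prox, ] + 1) / (rest_sum + 1))
  }
  list(usage = usage, features = features, cells = cells)
}

#' Per-cell global preference for proximal PAS usage
#'
#' Mean proximal usage over a cell's expressed multi-PAS genes (genes with
#' nonzero total count in that cell), Z-scored across the scored cells.
#' Cells scoring fewer than `min_expressed_genes` genes are dropped with a
#' warning; with zero variance all Z-scores are 0.
#'
#' @param counts features x cells count matrix.
#' @param features ordered `pas_features`.
#' @param gm gene models.
#' @param groups optional named vector (by barcode) of group labels carried
#'   through to the output.
#' @param min_expressed_genes minimal number of scored genes per cell.
#' @return data.frame with barcode, group, n_genes, mean_usage, z.
#' @export
cell_preference <- function(counts, features, gm = NULL, groups = NULL,
                            min_expressed_genes = 1) {
  pu <- proximal_usage(counts, features, gm)
  feats <- pu$features
  cm <- as.matrix(counts[feats$feature_id, pu$cells, drop = FALSE])
  gene_tot <- rowsum(cm, feats$gene_id)
  gene_tot <- gene_tot[rownames(pu$usage), , drop = FALSE]
  expressed <- gene_tot > 0
  n_genes <- colSums(expressed)
  mean_usage <- vapply(seq_along(pu$cells), function(j) {
    gi <- expressed[, j]
    if (!any(gi)) return(NA_real_)
    mean(pu$usage[gi, j])
  }, 0)
  ok <- n_genes >= min_expressed_genes & !is.na(mean_usage)
  if (any(!ok))
    warning(sum(!ok), " cell(s) dropped (fewer than ", min_expressed_genes,
            " scored genes)")
  bc <- pu$cells[ok]
  mu <- mean_usage[ok]
  sdv <- stats::sd(mu)
  z <- if (is.na(sdv) || sdv == 0) rep(0, length(mu)) else (mu - mean(mu)) / sdv
  data.frame(barcode = bc,
             group = if (is.null(groups)) NA_character_ else
               as.character(groups[bc]),
             n_genes = n_genes[ok], mean_usage = mu, z = z,
             stringsAsFactors = FALSE)
}

#' Differential PAS usage between two cell groups
#'
#' Per feature: log2 fold change of (mean CPM + 1) between groups, a
#' two-sided Wilcoxon rank-sum P value on per-cell CPM, and the fraction
#' of expressing cells per group.  A feature is significant when
#' `|logFC| >= logfc_min`, `P <= p_max` and the expressing fraction
#' reaches `min_pct` in at least one group.
#'
#' @param counts features x cells count matrix.
#' @param cells_a,cells_b barcodes of the two groups (each >= 3 cells).
#' @param logfc_min,p_max,min_pct significance thresholds.
#' @return data.frame with feature_id, mean_a, mean_b, logfc, p, pct_a,
#'   pct_b, significant.
#' @export
differential_usage <- function(counts, cells_a, cells_b, logfc_min = 1.2,
                               p_max = 0.05, min_pct = 0.3) {
  if (length(cells_a) == 0L || length(cells_b) == 0L)
    stop("empty cell group")
  if (length(cells_a) < 3L || length(cells_b) < 3L)
    stop("each group needs at least 3 cells")
  A <- as.matrix(counts[, cells_a, drop = FALSE])
  B <- as.matrix(counts[, cells_b, drop = FALSE])
  cpm <- function(m) {
    tot <- colSums(m)
    tot[tot == 0] <- 1
    sweep(m, 2L, tot, "/") * 1e6
  }
  Ac <- cpm(A); Bc <- cpm(B)
  res <- lapply(seq_len(nrow(counts)), function(i) {
    ma <- mean(Ac[i, ]); mb <- mean(Bc[i, ])
    lfc <- log2((ma + 1) / (mb + 1))
    p <- suppressWarnings(wilcox.test(Ac[i, ], Bc[i, ])$p.value)
    pa <- mean(A[i, ] > 0); pb <- mean(B[i, ] > 0)
    data.frame(feature_id = rownames(counts)[i], mean_a = ma, mean_b = mb,
               logfc = lfc, p = p, pct_a = pa, pct_b = pb,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- abs(out$logfc) >= logfc_min &
    !is.na(out$p) & out$p <= p_max & pmax(out$pct_a, out$pct_b) >= min_pct
  out
}

# ---- poly(A) signal motifs -------------------------------------------------

.polya_motifs <- c("AATAAA", "ATTAAA", "AGTAAA", "ACTAAA", "AAGAAA", "AACAAA")

# oriented sequence covering offsets [-upstream, +downstream] around each
# 3' end (inclusive), NA when outside the contig
.signal_windows <- function(pas, genome, upstream, downstream) {
  e <- if ("three_prime_end" %in% names(pas)) pas$three_prime_end else pas$site
  vapply(seq_len(nrow(pas)), function(i) {
    if (pas$strand[i] == "+") {
      a <- e[i] - upstream; b <- e[i] + downstream + 1L
    } else {
      a <- e[i] - downstream; b <- e[i] + upstream + 1L
    }
    n <- nchar(genome[[pas$chrom[i]]])
    fetch_seq(genome, pas$chrom[i], max(0L, a), min(n, b), pas$strand[i])
  }, "")
}

#' Poly(A)-signal occurrence around 3' ends
#'
#' Searches the canonical AATAAA hexamer and its variants (ATTAAA, AGTAAA,
#' ACTAAA, AAGAAA, AACAAA; DNA alphabet) on the sense strand in the window
#' from `upstream` nt 5' to `downstream` nt 3' of each site.  A site counts
#' once if any motif occurs; per-motif tallies are also reported.
#'
#' @param pas data.frame with chrom, site (or three_prime_end), strand.
#' @param genome genome from [read_genome()].
#' @param upstream,downstream window bounds (nt, inclusive).
#' @return list with `fraction`, `n`, `per_motif` (data.frame motif,
#'   n_sites) and logical `has_signal` per site.
#' @export
polya_signal_occurrence <- function(pas, genome, upstream = 50,
                                    downstream = 25) {
  if (nrow(pas) == 0L)
    return(list(fraction = NA_real_, n = 0L,
                per_motif = data.frame(motif = .polya_motifs, n_sites = 0L),
                has_signal = logical(0)))
  win <- .signal_windows(pas, genome, upstream, downstream)
  hits <- vapply(.polya_motifs, function(m) grepl(m, win, fixed = TRUE),
                 logical(length(win)))
  hits <- matrix(hits, nrow = length(win))
  any_hit <- rowSums(hits) > 0
  list(fraction = mean(any_hit), n = length(win),
       per_motif = data.frame(motif = .polya_motifs,
                              n_sites = colSums(hits)),
       has_signal = any_hit)
}

#' Positional motif density and nucleotide profiles around 3' ends
#'
#' Extracts the oriented `2 * flank` nt window around each site (offsets
#' `-flank .. flank-1`) and reports, per offset, the per-motif start
#' density and the A/C/G/T frequencies (N excluded from the denominator).
#'
#' @inheritParams polya_signal_occurrence
#' @param flank half-window (nt).
#' @return list with `positions`, `base_freq` (positions x 4, rows sum to
#'   1) and `motif_density` (positions x motifs).
#' @export
positional_profiles <- function(pas, genome, flank = 100) {
  if (nrow(pas) == 0L)
    return(list(positions = integer(0),
                base_freq = matrix(numeric(0), 0, 4),
                motif_density = matrix(numeric(0), 0,
                                       length(.polya_motifs))))
  e <- if ("three_prime_end" %in% names(pas)) pas$three_prime_end else pas$site
  width <- 2L * flank
  sq <- vapply(seq_len(nrow(pas)), function(i)
    oriented_window(genome, pas$chrom[i], e[i], pas$strand[i], 0L, flank,
                    flank) %||% NA_character_, "")
  sq <- sq[!is.na(sq)]
  positions <- seq(-flank, flank - 1L)
  chars <- do.call(rbind, strsplit(sq, "", fixed = TRUE))
  base_freq <- t(apply(chars, 2L, function(col) {
    tab <- table(factor(col, levels = c("A", "C", "G", "T")))
    tot <- sum(tab)
    if (tot == 0) rep(NA_real_, 4) else as.numeric(tab) / tot
  }))
  colnames(base_freq) <- c("A", "C", "G", "T")
  rownames(base_freq) <- positions
  md <- sapply(.polya_motifs, function(m) {
    dens <- numeric(width)
    for (s in sq) {
      # lookahead so overlapping occurrences count at each start
      at <- gregexpr(paste0("(?=", m, ")"), s, perl = TRUE)[[1]]
      at <- at[at > 0]
      dens[at] <- dens[at] + 1
    }
    dens / length(sq)
  })
  rownames(md) <- positions
  list(positions = positions, base_freq = base_freq, motif_density = md)
}
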