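# Position-insensitive poly(A)-site sequence classifier: training-set
# construction by window shifting, a CNN + BiLSTM model, training with early
# stopping, probability prediction, position-tolerance and internal-priming
# evaluation, and convolution-filter motif extraction.

# ---- window extraction -----------------------------------------------------

# Strand-oriented window around a cleavage site such that oriented index
# `upstream` (0-based) is the site itself; `off` shifts the window along the
# strand (positive = toward 3').  Returns NA when the window leaves the
# contig.
oriented_window <- function(genome, chrom, site, strand, off = 0L,
                            upstream = 100L, downstream = 100L) {
  if (strand == "+") {
    a <- site - upstream + off; b <- site + downstream + off
  } else {
    a <- site - downstream + 1L - off; b <- site + upstream + 1L - off
  }
  n <- nchar(genome[[chrom]])
  if (a < 0L || b > n) return(NA_character_)
  fetch_seq(genome, chrom, a, b, strand)
}

#' Draw distinct integer window shifts per PAS
#'
#' Offsets are rounded draws from Normal(`mu`, `sigma`), resampled until
#' each site holds `n_per_pas` distinct values with absolute value at most
#' `max_offset`.  The matrix dimensions define the size of the shifted
#' positive corpus: 225,964 training sites at 10 windows each give the
#' 2,259,640-sequence corpus.
#'
#' @param n_pas number of sites.
#' @param n_per_pas distinct windows per site.
#' @param mu,sigma normal shift distribution parameters (nt).
#' @param max_offset largest admissible |offset|.
#' @param seed RNG seed.
#' @return integer matrix `n_pas x n_per_pas`.
#' @export
draw_shift_offsets <- function(n_pas, n_per_pas = 10, mu = 0, sigma = 10,
                               max_offset = 90, seed = 1) {
  if (sigma == 0 && n_per_pas > 1)
    stop("sigma = 0 cannot produce ", n_per_pas, " distinct offsets per site")
  if (2 * max_offset + 1 < n_per_pas)
    stop("offset range too narrow for ", n_per_pas, " distinct values")
  with_seed(seed, {
    m <- matrix(NA_integer_, n_pas, n_per_pas)
    for (iter in 1:1000) {
      need <- is.na(m)
      if (!any(need)) break
      draw <- as.integer(round(rnorm(sum(need), mu, sigma)))
      draw[abs(draw) > max_offset] <- NA_integer_
      m[need] <- draw
      # kill within-row duplicates (keep the first of each value)
      dup <- t(apply(m, 1L, function(r) duplicated(r) & !is.na(r)))
      m[dup] <- NA_integer_
    }
    if (anyNA(m)) stop("failed to draw distinct offsets")
    m
  })
}

.window_df <- function(sequence, label, chrom, site, strand, offset, pas_id) {
  data.frame(sequence = sequence, label = label, chrom = chrom, site = site,
             strand = strand, offset = offset, pas_id = pas_id,
             stringsAsFactors = FALSE)
}

#' Build the shifted positive training corpus
#'
#' Per PAS, `n_per_pas` distinct normal shifts of a `width`-nt strand
#' oriented window around the cleavage site; globally duplicated sequences
#' are then removed.
#'
#' @param pas a `pas_set`.
#' @param genome genome from [read_genome()].
#' @inheritParams draw_shift_offsets
#' @param width window width (nt); the site sits at oriented index
#'   `width / 2`.
#' @return data.frame of labeled windows (`label = 1`).
#' @export
make_shifted_positives <- function(pas, genome, n_per_pas = 10, mu = 0,
                                   sigma = 10, width = 200, seed = 1) {
  off <- draw_shift_offsets(nrow(pas), n_per_pas, mu, sigma, seed = seed)
  up <- width %/% 2L; down <- width - up
  rows <- vector("list", nrow(pas))
  skipped <- 0L
  for (i in seq_len(nrow(pas))) {
    sq <- vapply(off[i, ], function(o)
      oriented_window(genome, pas$chrom[i], pas$site[i], pas$strand[i], o,
                      up, down) %||% NA_character_, "")
    if (anyNA(sq)) { skipped <- skipped + 1L; next }
    rows[[i]] <- .window_df(sq, 1L, pas$chrom[i], pas$site[i], pas$strand[i],
                            off[i, ], sprintf("pas_%d", i))
  }
  if (skipped > 0L)
    warning(skipped, " PAS skipped (window outside contig)")
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no usable PAS windows")
  out <- out[!duplicated(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the fixed-position positive set
#'
#' One window per PAS centered on the cleavage site (offset 0),
#' deduplicated.
#'
#' @inheritParams make_shifted_positives
#' @export
make_fixed_positives <- function(pas, genome, width = 200) {
  up <- width %/% 2L; down <- width - up
  sq <- vapply(seq_len(nrow(pas)), function(i)
    oriented_window(genome, pas$chrom[i], pas$site[i], pas$strand[i], 0L,
                    up, down) %||% NA_character_, "")
  keep <- !is.na(sq)
  if (any(!keep)) warning(sum(!keep), " PAS skipped (window outside contig)")
  out <- .window_df(sq[keep], 1L, pas$chrom[keep], pas$site[keep],
                    pas$strand[keep], 0L, sprintf("pas_%d", which(keep)))
  out <- out[!duplicated(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Intergenic intervals (complement of gene spans), as a data.frame.
intergenic_intervals <- function(genome, gm) {
  out <- list()
  for (chrom in names(genome)) {
    n <- nchar(genome[[chrom]])
    g <- gm$genes[gm$genes$chrom == chrom, , drop = FALSE]
    ir <- IRanges::IRanges(start = 1L, end = n)
    if (nrow(g))
      ir <- IRanges::setdiff(ir, IRanges::reduce(
        IRanges::IRanges(start = g$start + 1L, end = g$end)))
    if (length(ir))
      out[[chrom]] <- data.frame(chrom = chrom,
                                 start = IRanges::start(ir) - 1L,
                                 end = IRanges::end(ir),
                                 stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Sample negative (non-PAS) windows from intergenic space
#'
#' Uniform windows from the complement of gene bodies, rejected when they
#' contain any annotated PAS site, deduplicated by position.
#'
#' @inheritParams make_shifted_positives
#' @param known_pas `pas_set` of annotated sites to avoid.
#' @param gm gene models delimiting gene bodies.
#' @param n number of windows.
#' @param strand_choice strands to sample from.
#' @return data.frame of labeled windows (`label = 0`).
#' @export
sample_negatives <- function(genome, known_pas, gm, n, width = 200, seed = 1,
                             strand_choice = c("+", "-")) {
  iv <- intergenic_intervals(genome, gm)
  iv <- iv[iv$end - iv$start >= width, , drop = FALSE]
  if (is.null(iv) || nrow(iv) == 0L) stop("no intergenic space to sample from")
  w <- iv$end - iv$start - width + 1
  if (n > 2 * sum(w))
    stop("insufficient intergenic space for ", n, " distinct windows")
  with_seed(seed, {
    picked <- character(0)
    rows <- list()
    tries <- 0L
    while (length(rows) < n) {
      tries <- tries + 1L
      if (tries > 50L * n + 100L)
        stop("insufficient intergenic space for ", n, " distinct windows")
      i <- sample.int(nrow(iv), 1L, prob = w)
      a <- iv$start[i] + sample.int(w[i], 1L) - 1L
      strand <- sample(strand_choice, 1L)
      key <- paste(iv$chrom[i], a, strand)
      if (key %in% picked) next
      hit <- .any_site_in_window(iv$chrom[i], a, a + width - 1L, strand,
                                 known_pas)
      # a negative window must not contain a known site on either strand
      hit2 <- .any_site_in_window(iv$chrom[i], a, a + width - 1L,
                                  setdiff(c("+", "-"), strand), known_pas)
      if (hit || hit2) next
      picked <- c(picked, key)
      sq <- fetch_seq(genome, iv$chrom[i], a, a + width, strand)
      rows[[length(rows) + 1L]] <-
        .window_df(sq, 0L, iv$chrom[i], a, strand, 0L, NA_character_)
    }
    out <- do.call(rbind, rows)
    out <- out[!duplicated(out$sequence), , drop = FALSE]
    while (nrow(out) < n) {  # rare: identical sequences at distinct loci
      extra <- sample_negatives(genome, known_pas, gm, n - nrow(out), width,
                                seed + 7919L, strand_choice)
      out <- rbind(out, extra)
      out <- out[!duplicated(out$sequence), , drop = FALSE]
    }
    rownames(out) <- NULL
    out
  })
}

# ---- one-hot encoding ------------------------------------------------------

#' One-hot encode a DNA sequence
#'
#' Channel order A, T, G, C; N encodes as an all-zero row.
#'
#' @param sequence a single DNA string.
#' @return `nchar(sequence) x 4` binary matrix with columns A, T, G, C.
#' @export
one_hot <- function(sequence) {
  x <- cpp_encode_onehot(sequence, nchar(sequence))
  m <- t(x[, , 1])
  colnames(m) <- c("A", "T", "G", "C")
  m
}

#' Decode a one-hot matrix back to a sequence
#' @param m matrix from [one_hot()].
#' @export
decode_one_hot <- function(m) {
  alphabet <- c("A", "T", "G", "C")
  paste(vapply(seq_len(nrow(m)), function(i) {
    j <- which(m[i, ] == 1)
    if (length(j) == 1L) alphabet[j] else "N"
  }, ""), collapse = "")
}

encode_batch <- function(sequences, width) {
  cpp_encode_onehot(sequences, width)
}

# ---- model -----------------------------------------------------------------

#' Architecture specification for the PAS classifier
#'
#' Defaults are the full architecture: 128 conv filters of width 12 over 4
#' channels, 64 filters of width 6, max pooling with stride 4, a BiLSTM
#' with 128 units per direction, a 1024-unit ReLU dense layer with dropout
#' 0.3, and a 2-unit softmax output.  `scale` shrinks filter/unit counts
#' proportionally for desk-scale models while preserving the layer order.
#'
#' @param scale width multiplier applied to filter and unit counts.
#' @param input_len window length (nt).
#' @param dropout dense-layer dropout rate.
#' @export
pasnet_spec <- function(scale = 1, input_len = 200, dropout = 0.3) {
  structure(list(
    conv1_filters = max(4L, as.integer(round(128 * scale))),
    conv1_width = 12L,
    conv2_filters = max(2L, as.integer(round(64 * scale))),
    conv2_width = 6L,
    pool = 4L,
    lstm_units = max(2L, as.integer(round(128 * scale))),
    dense_units = max(4L, as.integer(round(1024 * scale))),
    dropout = dropout,
    input_len = as.integer(input_len)), class = "pasnet_spec")
}

#' Train the CNN+BiLSTM PAS classifier
#'
#' Cross-entropy training with Adam, dropout on the dense layer, and early
#' stopping on a held-out monitoring fraction of the training examples: when
#' the monitored loss fails to improve for `patience` consecutive epochs,
#' training stops and the best-epoch parameters are kept.
#'
#' @param examples data.frame with columns `sequence` and `label` (0/1);
#'   both classes must be present.  Windows with more than 10% N are
#'   rejected.
#' @param spec a [pasnet_spec()].
#' @param batch_size,max_epochs,patience training schedule.
#' @param holdout fraction of examples held out to monitor early stopping.
#' @param lr Adam learning rate.
#' @param seed seed fixing initialization, shuffling and dropout.
#' @param verbose print per-epoch losses.
#' @return object of class `pasnet`.
#' @export
pasnet_train <- function(examples, spec = pasnet_spec(), batch_size = 5000,
                         max_epochs = 100, patience = 10, holdout = 0.05,
                         lr = 1e-3, seed = 1, verbose = FALSE) {
  stopifnot(is.data.frame(examples), all(c("sequence", "label") %in%
                                           names(examples)))
  y <- as.integer(examples$label)
  if (length(unique(y)) < 2L) stop("training set must contain both classes")
  n_frac <- vapply(gregexpr("N", examples$sequence, fixed = TRUE),
                   function(g) sum(g > 0), 0) / nchar(examples$sequence)
  keep <- n_frac <= 0.10
  examples <- examples[keep, , drop = FALSE]
  y <- y[keep]
  n <- nrow(examples)
  n_hold <- max(1L, as.integer(round(n * holdout)))
  hold <- with_seed(seed, sample.int(n, n_hold))
  tr <- setdiff(seq_len(n), hold)
  X <- encode_batch(examples$sequence[tr], spec$input_len)
  Xh <- encode_batch(examples$sequence[hold], spec$input_len)
  params <- cpp_pasnet_init(unclass(spec), seed)
  fit <- cpp_pasnet_train(X, y[tr], Xh, y[hold], params, unclass(spec),
                          lr, as.integer(batch_size), as.integer(max_epochs),
                          as.integer(patience), spec$dropout,
                          as.integer(seed), verbose)
  structure(list(spec = spec, params = fit$params,
                 best_epoch = fit$best_epoch,
                 history = data.frame(epoch = seq_along(fit$train_loss),
                                      train_loss = fit$train_loss,
                                      monitor_loss = fit$val_loss),
                 n_train = length(tr), n_monitor = n_hold, seed = seed),
            class = "pasnet")
}

#' @export
print.pasnet <- function(x, ...) {
  cat("pasnet classifier: conv", x$spec$conv1_filters, "x", x$spec$conv1_width,
      "-> conv", x$spec$conv2_filters, "x", x$spec$conv2_width,
      "-> pool", x$spec$pool, "-> BiLSTM", x$spec$lstm_units,
      "-> dense", x$spec$dense_units, "\n")
  cat("trained", nrow(x$history), "epochs; best epoch", x$best_epoch, "\n")
  invisible(x)
}

#' Predict PAS probabilities for sequence windows
#'
#' @param model a trained `pasnet`.
#' @param sequences character vector of windows of the model's input
#'   length.
#' @return data.frame with `probability` (positive-class softmax output)
#'   and logical `label` (`probability > 0.5`; exactly 0.5 is negative).
#' @export
pasnet_predict <- function(model, sequences) {
  bad <- nchar(sequences) != model$spec$input_len
  if (any(bad))
    stop(sum(bad), " sequence(s) not of length ", model$spec$input_len)
  X <- encode_batch(sequences, model$spec$input_len)
  P <- cpp_pasnet_forward(X, model$params, unclass(model$spec))
  data.frame(probability = P[, 2L], label = P[, 2L] > 0.5)
}

#' Save / load a trained classifier
#' @param model a `pasnet` object.
#' @param path file path.
#' @export
pasnet_save <- function(model, path) { saveRDS(model, path); invisible(path) }

#' @rdname pasnet_save
#' @export
pasnet_load <- function(path) readRDS(path)

# ---- evaluation ------------------------------------------------------------

#' True-positive rate as a function of window offset
#'
#' Scores windows shifted around validation cleavage sites on a stride grid
#' and reports the per-offset fraction predicted positive.  Sites can be
#' given either as a `pas_set` plus genome, or as pre-extracted context
#' sequences (site at index `floor(nchar/2)`).
#'
#' @param model trained `pasnet`.
#' @param pas,genome validation sites and genome (or NULL when `contexts`
#'   given).
#' @param contexts character vector of positive context sequences, longer
#'   than the model window by at least `2 * max_offset`.
#' @param stride,max_offset offset grid (nt).
#' @return data.frame with `offset`, `n`, `tpr`.
#' @export
evaluate_position_tolerance <- function(model, pas = NULL, genome = NULL,
                                        contexts = NULL, stride = 5,
                                        max_offset = 50) {
  offsets <- seq(-max_offset, max_offset, by = stride)
  width <- model$spec$input_len
  up <- width %/% 2L
  res <- lapply(offsets, function(off) {
    if (!is.null(contexts)) {
      ctr <- nchar(contexts[1]) %/% 2L
      a <- ctr - up + off
      sq <- substr(contexts, a + 1L, a + width)
      sq <- sq[nchar(sq) == width]
    } else {
      sq <- vapply(seq_len(nrow(pas)), function(i)
        oriented_window(genome, pas$chrom[i], pas$site[i], pas$strand[i],
                        as.integer(off), up, width - up) %||% NA_character_, "")
      sq <- sq[!is.na(sq)]
    }
    if (length(sq) == 0L) return(data.frame(offset = off, n = 0L, tpr = NA_real_))
    pr <- pasnet_predict(model, sq)
    data.frame(offset = off, n = length(sq), tpr = mean(pr$label))
  })
  do.call(rbind, res)
}

#' True-negative rate on pseudo internal-priming windows
#'
#' Samples intergenic windows far from any annotated PAS, embeds a centered
#' adenine run of each length, scores them and reports the fraction
#' classified negative per run length.
#'
#' @param model trained `pasnet`.
#' @param genome,known_pas,gm sampling context (see [sample_negatives()]).
#' @param run_lengths adenine run lengths to probe.
#' @param n_per_length windows per run length.
#' @param min_dist minimal distance (nt) from any annotated site.
#' @param seed RNG seed.
#' @return data.frame with `run_length`, `n`, `tnr`.
#' @export
evaluate_internal_priming <- function(model, genome, known_pas, gm,
                                      run_lengths = 8:15, n_per_length = 50,
                                      min_dist = 1000, seed = 1) {
  if (n_per_length == 0L)
    return(data.frame(run_length = integer(), n = integer(), tnr = numeric()))
  width <- model$spec$input_len
  # widen the exclusion window around annotated sites via a padded set
  res <- lapply(seq_along(run_lengths), function(k) {
    L <- run_lengths[k]
    wins <- sample_negatives(genome, known_pas, gm, n_per_length, width,
                             seed = seed + k)
    a <- width %/% 2L - L %/% 2L
    sq <- paste0(substr(wins$sequence, 1L, a), strrep("A", L),
                 substr(wins$sequence, a + L + 1L, width))
    pr <- pasnet_predict(model, sq)
    data.frame(run_length = L, n = length(sq), tnr = mean(!pr$label))
  })
  do.call(rbind, res)
}

# ---- motif extraction ------------------------------------------------------

#' Extract position probability matrices from first-layer filters
#'
#' Each first-convolution filter scans the positive training sequences; the
#' maximally activating subsequence per sequence (requiring positive
#' activation) is collected, base frequencies per position give the PPM,
#' and `log2(PPM / 0.25)` (with pseudocount) the PWM.  Motifs are sorted by
#' decreasing information content ("entropy").
#'
#' @param model trained `pasnet`.
#' @param sequences positive training sequences.
#' @param pseudocount added to PPM cells before the log-odds transform.
#' @return object of class `pas_motifs`: list of motifs with elements
#'   `filter`, `n_sites`, `ppm`, `pwm`, `entropy`.
#' @export
extract_filter_motifs <- function(model, sequences, pseudocount = 1e-3) {
  width <- model$spec$conv1_width
  X <- encode_batch(sequences, model$spec$input_len)
  scan <- cpp_conv1_scan(X, model$params$W1, model$params$b1,
                         unclass(model$spec))
  alphabet <- c("A", "C", "G", "T")
  motifs <- list()
  for (f in seq_len(model$spec$conv1_filters)) {
    hit <- which(scan$act[, f] > 0)
    if (length(hit) == 0L) {
      warning("filter ", f, " never activates; motif omitted")
      next
    }
    kmers <- substr(sequences[hit], scan$pos[hit, f] + 1L,
                    scan$pos[hit, f] + width)
    counts <- matrix(0, width, 4L, dimnames = list(NULL, alphabet))
    chars <- strsplit(kmers, "", fixed = TRUE)
    for (km in chars) {
      ok <- km %in% alphabet
      idx <- match(km[ok], alphabet)
      pos <- which(ok)
      for (j in seq_along(pos)) counts[pos[j], idx[j]] <- counts[pos[j], idx[j]] + 1
    }
    ppm <- counts / pmax(rowSums(counts), 1)
    pwm <- log2((ppm + pseudocount) / 0.25)
    p <- ppm
    plogp <- ifelse(p > 0, p * log2(p), 0)
    ic <- sum(2 + rowSums(plogp))
    motifs[[length(motifs) + 1L]] <- list(filter = f, n_sites = length(hit),
                                          ppm = ppm, pwm = pwm, entropy = ic)
  }
  ord <- order(vapply(motifs, `[[`, 0, "entropy"), decreasing = TRUE)
  structure(motifs[ord], class = "pas_motifs")
}

#' Consensus string of a motif PPM
#' @param ppm position probability matrix (positions x ACGT).
#' @export
motif_consensus <- function(ppm) {
  paste(colnames(ppm)[max.col(ppm)], collapse = "")
}

#' Write motifs in MEME minimal format
#'
#' @param motifs a `pas_motifs` object.
#' @param path output file.
#' @export
write_meme <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: +", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF filter_%d", m$filter), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      nrow(m$ppm), m$n_sites), con)
    for (i in seq_len(nrow(m$ppm)))
      writeLines(paste(sprintf("%.6f", m$ppm[i, ]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}
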