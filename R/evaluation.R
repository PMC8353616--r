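# Enrichment-score evaluation of candidate PASs, confusion-matrix metrics
# and ROC/AUC utilities.

#' Enrichment score of a candidate cleavage site
#'
#' `log2((rpm_up + 0.1) / (rpm_down + 0.1))`: a true 3' boundary has high
#' upstream and low downstream read density, hence a high score.
#'
#' @param rpm_up,rpm_down nonnegative RPM over the 400-nt windows upstream
#'   and downstream of the site.
#' @export
enrichment_score <- function(rpm_up, rpm_down) {
  if (any(rpm_up < 0) || any(rpm_down < 0)) stop("RPM must be nonnegative")
  log2((rpm_up + 0.1) / (rpm_down + 0.1))
}

#' Enrichment scores for called peaks
#'
#' Computes RPM over the strand-oriented `flank` nt upstream and downstream
#' of each peak 3' end (windows clipped at contig bounds are still counted
#' over their clipped extent) and derives the enrichment score.
#'
#' @param reads alignment data.frame.
#' @param peaks peak data.frame with chrom, three_prime_end, strand.
#' @param flank window width (nt).
#' @param min_mapq mapping-quality cutoff for RPM counting.
#' @return data.frame with rpm_upstream, rpm_downstream, score, and the
#'   RPM over the peak's own region (`rpm_peak`).
#' @export
pas_enrichment <- function(reads, peaks, flank = 400, min_mapq = 3) {
  e <- peaks$three_prime_end
  up <- data.frame(chrom = peaks$chrom,
                   start = ifelse(peaks$strand == "+", e - flank, e + 1L),
                   end = ifelse(peaks$strand == "+", e, e + 1L + flank),
                   strand = peaks$strand)
  dn <- data.frame(chrom = peaks$chrom,
                   start = ifelse(peaks$strand == "+", e + 1L, e - flank),
                   end = ifelse(peaks$strand == "+", e + 1L + flank, e),
                   strand = peaks$strand)
  pk <- data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
                   strand = peaks$strand)
  rpm_up <- compute_rpm(reads, up, min_mapq)
  rpm_dn <- compute_rpm(reads, dn, min_mapq)
  data.frame(rpm_upstream = rpm_up, rpm_downstream = rpm_dn,
             score = enrichment_score(rpm_up, rpm_dn),
             rpm_peak = compute_rpm(reads, pk, min_mapq))
}

#' Confusion matrix of predicted vs enrichment-defined PAS labels
#'
#' Peaks expressed at `rpm >= expr_min_rpm` are classified as predicted
#' positive when `probability > 0.5` and as actually positive when the
#' enrichment score is at least `score_cutoff`; sensitivity, specificity
#' and F1 follow from the resulting confusion matrix.
#'
#' @param probability classifier probabilities per peak.
#' @param score enrichment scores per peak (same order).
#' @param rpm expression (RPM) per peak used for the expression filter.
#' @param expr_min_rpm expression cutoff.
#' @param score_cutoff enrichment-score cutoff defining actual positives.
#' @return list with TP, FP, TN, FN, sensitivity, specificity, F1, n.
#' @export
confusion_from_scores <- function(probability, score, rpm = NULL,
                                  expr_min_rpm = 1, score_cutoff = 2) {
  if (length(probability) != length(score))
    stop("probability and score must be keyed by the same peaks")
  keep <- if (is.null(rpm)) rep(TRUE, length(score)) else rpm >= expr_min_rpm
  if (!any(keep)) stop("no peaks pass the expression filter")
  pred <- probability[keep] > 0.5
  actual <- score[keep] >= score_cutoff
  tp <- sum(pred & actual); fp <- sum(pred & !actual)
  tn <- sum(!pred & !actual); fn <- sum(!pred & actual)
  list(TP = tp, FP = fp, TN = tn, FN = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       F1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
       n = sum(keep))
}

#' Confusion metrics across a sweep of enrichment-score cutoffs
#'
#' @inheritParams confusion_from_scores
#' @param cutoffs enrichment-score cutoffs to sweep.
#' @return data.frame, one row per cutoff.
#' @export
confusion_sweep <- function(probability, score, rpm = NULL, expr_min_rpm = 1,
                            cutoffs = c(1.5, 1.75, 2, 2.25, 2.5)) {
  do.call(rbind, lapply(cutoffs, function(ct) {
    cs <- confusion_from_scores(probability, score, rpm, expr_min_rpm, ct)
    data.frame(cutoff = ct, TP = cs$TP, FP = cs$FP, TN = cs$TN, FN = cs$FN,
               sensitivity = cs$sensitivity, specificity = cs$specificity,
               F1 = cs$F1)
  }))
}

#' ROC curve and AUC by threshold sweep
#'
#' Thresholds sweep the distinct score values (equal scores grouped); the
#' AUC is the trapezoidal integral of TPR over FPR.
#'
#' @param labels binary labels (0/1 or logical).
#' @param scores real-valued scores, higher = more positive.
#' @return list with `points` (data.frame fpr, tpr, threshold) and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to compute a ROC curve")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  np <- sum(y == 1L); nn <- sum(y == 0L)
  grp_last <- c(which(diff(s) != 0), length(s))  # last index of each tie group
  tp <- cumsum(y == 1L)[grp_last]
  fp <- cumsum(y == 0L)[grp_last]
  pts <- data.frame(fpr = c(0, fp / nn), tpr = c(0, tp / np),
                    threshold = c(Inf, s[grp_last]))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Fraction of expressed annotated PASs recaptured by identified sites
#'
#' An annotated site is expressed when the RPM over its 400-nt upstream
#' region reaches `expr_min_rpm`, and recaptured when it lies within the
#' overlap window (upstream 50 / downstream 25 nt, inclusive) of any
#' identified 3' end.
#'
#' @param identified data.frame of identified sites (chrom,
#'   three_prime_end, strand).
#' @param annotated `pas_set` of reference sites.
#' @param reads alignment data.frame for the expression filter.
#' @param expr_min_rpm expression cutoff.
#' @param upstream,downstream overlap window around identified ends.
#' @param flank upstream window width for expression.
#' @return fraction in [0, 1] (NA when nothing is expressed).
#' @export
recapture_rate <- function(identified, annotated, reads, expr_min_rpm = 1,
                           upstream = 50, downstream = 25, flank = 400) {
  rpm <- compute_rpm(reads, pas_upstream_regions(annotated, flank))
  expressed <- rpm >= expr_min_rpm
  if (!any(expressed)) return(NA_real_)
  ann <- annotated[expressed, , drop = FALSE]
  # site recaptured <=> some identified end e has site in oriented
  # [e - upstream, e + downstream] <=> e in site + oriented [-downstream, upstream]
  ends <- data.frame(chrom = identified$chrom,
                     site = identified$three_prime_end,
                     strand = identified$strand, stringsAsFactors = FALSE)
  lo <- ifelse(ann$strand == "+", ann$site - downstream, ann$site - upstream)
  hi <- ifelse(ann$strand == "+", ann$site + upstream, ann$site + downstream)
  hit <- .any_site_in_window(ann$chrom, lo, hi, ann$strand, ends)
  mean(hit)
}
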