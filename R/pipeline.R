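# Stage orchestration: callpeak -> classify/filter -> quantify -> APA,
# driven by a flat YAML/list configuration, with a JSON run manifest
# stamped next to every run's outputs.

#' Build a pipeline configuration
#'
#' @param genome,gtf,alignments input paths (FASTA, GTF, BAM/SAM).
#' @param model path to a trained classifier saved by [pasnet_save()]
#'   (NULL skips classifier filtering).
#' @param known_pas optional PAS BED-like TSV (see [read_pas_bed()]) for
#'   overlap annotation.
#' @param outdir output directory.
#' @param seed seed forwarded to every stochastic stage.
#' @param peak,classify,apa per-stage parameter lists overriding the
#'   defaults.
#' @export
pipeline_config <- function(genome, gtf, alignments, model = NULL,
                            known_pas = NULL, outdir = "pasflow_out",
                            seed = 1, peak = list(), classify = list(),
                            apa = list()) {
  cfg <- list(genome = genome, gtf = gtf, alignments = alignments,
              model = model, known_pas = known_pas, outdir = outdir,
              seed = seed,
              peak = utils::modifyList(list(size = 400, min_dist = 10,
                                            min_count = 10, alpha = 0.05),
                                       peak),
              classify = utils::modifyList(list(prob_cutoff = 0.5), classify),
              apa = utils::modifyList(list(min_expressed_genes = 1), apa))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with the fields of [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full pipeline
#'
#' Executes peak calling, classifier filtering (when a model is
#' configured), PAS-transcript quantification and APA statistics in order,
#' writing each stage's outputs plus a JSON manifest (package version,
#' seed, parameters and parameter-file checksum) under `outdir`.
#' Re-running an identical configuration reproduces identical outputs.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @return invisibly, a list with the stage outputs.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  for (f in c("genome", "gtf", "alignments"))
    if (!file.exists(config[[f]]))
      stop("stage input missing: ", f, " file not found at ", config[[f]])
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  genome <- read_genome(config$genome)
  gm <- read_gtf(config$gtf)
  reads <- read_alignments(config$alignments)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  peaks <- stage("callpeak", call_peaks(
    reads, gm, genome, size = config$peak$size,
    min_dist = config$peak$min_dist, min_count = config$peak$min_count,
    alpha = config$peak$alpha))
  write_peaks(peaks, file.path(config$outdir, "peaks"))

  calls <- peaks
  if (!is.null(config$model)) {
    model <- pasnet_load(config$model)
    calls <- stage("classify", {
      up <- model$spec$input_len %/% 2L
      sq <- vapply(seq_len(nrow(peaks)), function(i)
        oriented_window(genome, peaks$chrom[i], peaks$three_prime_end[i],
                        peaks$strand[i], 0L, up,
                        model$spec$input_len - up) %||% NA_character_, "")
      ok <- !is.na(sq)
      pr <- pasnet_predict(model, sq[ok])
      out <- peaks[ok, , drop = FALSE]
      out$probability <- pr$probability
      out[pr$probability > config$classify$prob_cutoff, , drop = FALSE]
    })
  }
  if (!is.null(config$known_pas)) {
    known <- read_pas_bed(config$known_pas)
    calls$overlaps_known <- overlaps_known(calls$chrom,
                                           calls$three_prime_end,
                                           calls$strand, known)
  }
  write_peaks(calls, file.path(config$outdir, "pas_calls"))

  quant <- stage("quantify", {
    features <- assign_peaks_to_transcripts(calls, gm)
    write_pas_gtf(features, file.path(config$outdir, "pas_annotation.gtf"))
    m <- count_umis(reads, features)
    write_matrix(m, file.path(config$outdir, "matrix"))
    list(features = features, matrix = m)
  })

  apa <- stage("apa", {
    feats <- order_pas_by_distance(quant$features, gm)
    pref <- tryCatch(
      cell_preference(quant$matrix, feats,
                      min_expressed_genes = config$apa$min_expressed_genes),
      error = function(e) NULL)
    if (!is.null(pref))
      write.table(pref, file.path(config$outdir, "cell_preference.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    sig <- polya_signal_occurrence(calls, genome)
    write.table(sig$per_motif, file.path(config$outdir, "polya_motifs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(preference = pref, signal = sig)
  })

  cfg_json <- file.path(config$outdir, "config.json")
  jsonlite::write_json(unclass(config)[c("genome", "gtf", "alignments",
                                         "model", "known_pas", "seed",
                                         "peak", "classify", "apa")],
                       cfg_json, auto_unbox = TRUE, null = "null")
  manifest <- list(
    package = "pasflow",
    version = as.character(utils::packageVersion("pasflow")),
    seed = config$seed,
    parameter_hash = unname(tools::md5sum(cfg_json)),
    inputs = list(genome = config$genome, gtf = config$gtf,
                  alignments = config$alignments),
    outputs = list.files(config$outdir),
    n_peaks = nrow(peaks), n_pas_calls = nrow(calls),
    n_features = nrow(quant$features),
    matrix_dim = dim(quant$matrix))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(list(peaks = peaks, calls = calls, features = quant$features,
                 matrix = quant$matrix, apa = apa,
                 manifest = manifest))
}
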