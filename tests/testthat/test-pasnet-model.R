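# Model mechanics: gradients, softmax normalization, threshold convention,
# early stopping, determinism, motif extraction.

test_that("analytic gradients match finite differences", {
  spec <- list(conv1_filters = 3L, conv1_width = 3L, conv2_filters = 2L,
               conv2_width = 2L, pool = 2L, lstm_units = 2L,
               dense_units = 4L, dropout = 0, input_len = 12L)
  set.seed(42)
  seqs <- vapply(1:6, function(i) random_dna(12), "")
  y <- c(0L, 1L, 0L, 1L, 1L, 0L)
  X <- pasflow:::cpp_encode_onehot(seqs, 12L)
  params <- pasflow:::cpp_pasnet_init(spec, 7L)
  # keep pre-activations away from ReLU kinks so finite differences are clean
  params$b2 <- params$b2 + 0.3
  params$b1 <- params$b1 + 0.1
  lg <- pasflow:::cpp_pasnet_loss_grad(X, y, params, spec)
  h <- 1e-6
  for (nm in names(params)) {
    idx <- if (length(params[[nm]]) > 4) sample(length(params[[nm]]), 4)
           else seq_along(params[[nm]])
    for (k in idx) {
      p2 <- params; p2[[nm]][k] <- p2[[nm]][k] + h
      l1 <- pasflow:::cpp_pasnet_loss_grad(X, y, p2, spec)$loss
      p2[[nm]][k] <- p2[[nm]][k] - 2 * h
      l0 <- pasflow:::cpp_pasnet_loss_grad(X, y, p2, spec)$loss
      num <- (l1 - l0) / (2 * h)
      ana <- lg$grads[[nm]][k]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("softmax probabilities sum to one and the 0.5 threshold is strict", {
  spec <- pasnet_spec(scale = 0.03125, input_len = 60)
  set.seed(1)
  seqs <- vapply(1:20, function(i) random_dna(60), "")
  X <- pasflow:::cpp_encode_onehot(seqs, 60L)
  P <- pasflow:::cpp_pasnet_forward(X, pasflow:::cpp_pasnet_init(
    unclass(spec), 3L), unclass(spec))
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
  # threshold: probability exactly 0.5 is negative, just above is positive
  expect_identical(c(0.5, 0.500001, 0.49) > 0.5, c(FALSE, TRUE, FALSE))
  model <- structure(list(spec = spec,
                          params = pasflow:::cpp_pasnet_init(unclass(spec), 3L)),
                     class = "pasnet")
  pr <- pasnet_predict(model, seqs)
  expect_identical(pr$label, pr$probability > 0.5)
  expect_error(pasnet_predict(model, "ACGT"), "length")
})

test_that("training requires both classes and a tiny model can overfit", {
  spec <- pasnet_spec(scale = 0.03125, input_len = 60)
  set.seed(2)
  pos <- vapply(1:40, function(i) {
    s <- random_dna(60); substr(s, 26, 31) <- "AATAAA"; s
  }, "")
  neg <- vapply(1:40, function(i) random_dna(60), "")
  ex <- data.frame(sequence = c(pos, neg), label = rep(1:0, each = 40))
  expect_error(pasnet_train(ex[1:40, ], spec), "both classes")
  m <- pasnet_train(ex, spec, batch_size = 16, max_epochs = 40, patience = 40,
                    holdout = 0.1, seed = 5)
  pr <- pasnet_predict(m, ex$sequence)
  expect_gt(roc_auc(ex$label, pr$probability)$auc, 0.9)
  # same seed reproduces the fit exactly
  m2 <- pasnet_train(ex, spec, batch_size = 16, max_epochs = 40,
                     patience = 40, holdout = 0.1, seed = 5)
  expect_identical(m$params, m2$params)
})

test_that("early stopping halts after `patience` flat epochs and keeps the best", {
  mod <- cached_benchmark_model()$model
  h <- mod$history
  expect_lte(nrow(h), 6L)
  expect_equal(mod$best_epoch, which.min(h$monitor_loss))
})

test_that("filter motifs recover the planted hexamer", {
  tm <- cached_benchmark_model()
  pos <- tm$bm$shifted$sequence[tm$bm$shifted$label == 1][1:400]
  motifs <- extract_filter_motifs(tm$model, pos)
  expect_lte(length(motifs), tm$model$spec$conv1_filters)
  for (m in motifs[1:3]) {
    expect_equal(rowSums(m$ppm), rep(1, nrow(m$ppm)), tolerance = 1e-9)
    expect_equal(dim(m$ppm), c(12L, 4L))
  }
  ent <- vapply(motifs, `[[`, 0, "entropy")
  expect_true(all(diff(ent) <= 1e-12))           # sorted decreasing
  top <- vapply(motifs[seq_len(min(10, length(motifs)))],
                function(m) motif_consensus(m$ppm), "")
  match6 <- vapply(top, function(cs) {
    best <- 0L
    for (a in 1:(nchar(cs) - 5)) {
      k <- substr(cs, a, a + 5)
      best <- max(best, sum(strsplit(k, "")[[1]] ==
                              strsplit("AATAAA", "")[[1]]))
    }
    best
  }, 0L)
  expect_gte(max(match6), 5L)                    # planted AATAAA captured
  f <- tempfile(fileext = ".meme")
  write_meme(motifs, f)
  txt <- readLines(f)
  expect_true(any(grepl("^MEME version", txt)))
  expect_equal(sum(grepl("^MOTIF", txt)), length(motifs))
})
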