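# The distillation study conditions: a 2,000 grid-year corpus with the
# default scenario mixture, the 184x5x(32,64) surrogate trained with
# three seeds. Built lazily and cached for the session so the
# distillation and saliency checks share one set of trained models.

.distill_cache <- new.env(parent = emptyenv())

distillation_study <- function() {
  if (!is.null(.distill_cache$res)) return(.distill_cache$res)
  params <- cultivar_params()
  wx <- synth_grid(40, 50, seed = 2026)
  batch <- simulate_batch(wx, params)
  corpus <- build_corpus(wx, batch, seed = 2026)
  kept <- batch$results[!batch$results$excluded, ]

  fits <- lapply(1:3, function(s) {
    distill(corpus, config = train_config(batch_size = 128L,
                                          max_epochs = 20L,
                                          patience = 10L, seed = s))
  })
  yv <- corpus$y[corpus$validation]
  r2 <- vapply(fits, function(f) {
    pr <- predict(f, corpus$X[, , corpus$validation, drop = FALSE])
    1 - mean((pr - yv)^2) / mean((yv - mean(yv))^2)
  }, numeric(1))

  .distill_cache$res <- list(params = params, corpus = corpus,
                             kept = kept, fits = fits, r2 = r2)
  .distill_cache$res
}

# Saliency window contrast for one case/factor under one trained model.
case_window_test <- function(study, fit, case, factor, window,
                             n = 500L, seed = 1L) {
  idx <- select_case(study$kept, case, percentile = 10)
  pool <- intersect(idx, study$corpus$train)
  picked <- sample_inputs(pool, n, seed = seed)
  maps <- positive_saliency(fit, study$corpus$X[, , picked, drop = FALSE])
  saliency_window_test(maps, study$corpus$dvi[, picked, drop = FALSE],
                       study$corpus$maturity_day[picked],
                       factor, window, seed = seed)
}
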