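# Desk-scale fixtures shared by the acceptance tests: one generated
# dataset and one 20-epoch pretraining run per seed, memoized so the
# contrastive, decoder and predictor checks reuse the same pipeline state.

.desk_cache <- new.env(parent = emptyenv())

desk_fixture <- function(seed) {
  key <- paste0("s", seed)
  if (!is.null(.desk_cache[[key]])) return(.desk_cache[[key]])
  sim <- generate_multiome(lag_frac = 0.2, seed = 101 + seed)
  proc <- preprocess_multiome(sim$dataset)
  par0 <- init_encoder_params(ncol(proc$rna_norm), ncol(proc$atac_norm),
                              d = 128L, seed = seed)
  fit <- train_pretrain(proc, contrastive_config(epochs = 20L, dim = 128L,
                                                 seed = seed))
  out <- list(sim = sim, proc = proc, par0 = par0,
              params = fit$params, history = fit$history)
  .desk_cache[[key]] <- out
  out
}
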