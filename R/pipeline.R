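# End-to-end pipeline: simulate -> preprocess -> pretrain -> {embed,
# interact, predict} -> {evaluate, potential}. Every run emits a manifest
# carrying the configuration hash and the seeds actually used, so
# identical configurations give identical artifacts.

#' Pipeline configuration
#'
#' All module defaults in one validated object. Unknown keys are rejected.
#' The single \code{seed} is fanned out deterministically to the stages.
#'
#' @param ... overrides of the defaults (see the function body for keys):
#'   \code{dim} (128), \code{tau} (0.1), \code{batch_size} (32),
#'   \code{epochs_pretrain} (20), \code{epochs_decoder} (5),
#'   \code{epochs_predictor} (40), \code{lr_start} (1e-4), \code{lr_end}
#'   (1e-6), \code{threshold_bp} (1.2e6), \code{k} (30), \code{acore}
#'   (0.5), \code{dropout} (0.1), \code{n_hvg} (2000),
#'   \code{min_cell_frac} (0.05), \code{seed} (1), plus the
#'   \code{sim_*} generator settings.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(...) {
  cfg <- list(dim = 128L, tau = 0.1, batch_size = 32L,
              epochs_pretrain = 20L, epochs_decoder = 5L,
              epochs_predictor = 40L, lr_start = 1e-4, lr_end = 1e-6,
              threshold_bp = 1.2e6, k = 30L, acore = 0.5, dropout = 0.1,
              n_hvg = 2000L, min_cell_frac = 0.05, seed = 1L,
              sim_n_cells = 600L, sim_n_genes = 300L, sim_n_peaks = 600L,
              sim_n_types = 3L, sim_links_per_gene = 1L,
              sim_lag_frac = 0.1, sim_noise = 0.5)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

# deterministic per-stage seeds fanned out from the master seed
stage_seed <- function(cfg, stage) {
  offs <- c(simulate = 101L, preprocess = 0L, pretrain = 211L,
            interact = 307L, predict = 401L, potential = 503L,
            evaluate = 601L)
  (cfg$seed * 7L + offs[[stage]]) %% .Machine$integer.max
}

# stable polynomial hash of a serialized object (manifest identity);
# kept within double precision (2^31 * 31 + 255 << 2^53)
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", h)
}

#' Run the pipeline
#'
#' Executes the requested stages in dependency order. Later stages require
#' the artifacts of earlier ones, either from this call or passed in via
#' \code{state}; a missing upstream artifact raises an error naming the
#' stage that must run first.
#'
#' @param config a [run_config()].
#' @param stages character vector of stages to run, from
#'   \code{"simulate"}, \code{"preprocess"}, \code{"pretrain"},
#'   \code{"embed"}, \code{"interact"}, \code{"predict"},
#'   \code{"evaluate"}, \code{"potential"}.
#' @param state optional list of artifacts from a previous call (e.g. a
#'   \code{dataset} read from disk instead of simulated).
#' @param out_dir optional directory: key tables are written as TSV/JSON
#'   alongside a \code{manifest.json}.
#' @param verbose print stage progress.
#' @return The updated \code{state} list, including \code{manifest}.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "preprocess", "pretrain",
                                    "embed", "evaluate"),
                         state = list(), out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  need <- function(artifact, producer) {
    if (is.null(state[[artifact]]))
      stop("stage requires '", artifact, "': run the '", producer,
           "' stage first")
    state[[artifact]]
  }
  for (stage in stages) {
    say("stage: %s", stage)
    state <- switch(
      stage,
      simulate = {
        sim <- generate_multiome(
          n_cells = config$sim_n_cells, n_genes = config$sim_n_genes,
          n_peaks = config$sim_n_peaks, n_types = config$sim_n_types,
          n_links_per_gene = config$sim_links_per_gene,
          lag_frac = config$sim_lag_frac, noise = config$sim_noise,
          seed = stage_seed(config, "simulate"))
        c(state, list(dataset = sim$dataset, truth = sim$truth))
      },
      preprocess = {
        ds <- need("dataset", "simulate")
        state$proc <- preprocess_multiome(ds,
                                          min_cell_frac = config$min_cell_frac,
                                          n_hvg = config$n_hvg)
        state
      },
      pretrain = {
        proc <- need("proc", "preprocess")
        cc <- contrastive_config(tau = config$tau,
                                 batch_size = config$batch_size,
                                 epochs = config$epochs_pretrain,
                                 lr_start = config$lr_start,
                                 lr_end = config$lr_end,
                                 dim = config$dim, dropout = config$dropout,
                                 seed = stage_seed(config, "pretrain"))
        fit <- train_pretrain(proc, cc, verbose = verbose)
        state$enc_params <- fit$params
        state$pretrain_history <- fit$history
        state
      },
      embed = {
        proc <- need("proc", "preprocess")
        par <- need("enc_params", "pretrain")
        state$embeddings <- compute_embeddings(proc, par)
        state
      },
      interact = {
        proc <- need("proc", "preprocess")
        par <- need("enc_params", "pretrain")
        state$mask <- build_attention_mask(proc$genes, proc$peaks,
                                           config$threshold_bp)
        dc <- decoder_config(epochs = config$epochs_decoder,
                             batch_size = config$batch_size,
                             lr_start = config$lr_start,
                             lr_end = config$lr_end,
                             tau_cls = config$tau,
                             seed = stage_seed(config, "interact"))
        fit <- train_decoder(par, proc, state$mask, dc, verbose = verbose)
        state$dparams <- fit$dparams
        state$enc_params_ft <- fit$enc_params
        att <- decoder_attention(fit$dparams, fit$enc_params, proc,
                                 state$mask)
        state$global_attention <- att$global
        state
      },
      predict = {
        proc <- need("proc", "preprocess")
        par <- need("enc_params", "pretrain")
        head <- fine_tune_predictor(par, proc,
                                    epochs = config$epochs_predictor,
                                    seed = stage_seed(config, "predict"),
                                    verbose = verbose)
        pred <- predict_expression(head, proc)
        state$pred_head <- head
        state$predicted <- pred
        state$residuals <- compute_residuals(pred, as.matrix(proc$rna_norm),
                                             proc$genes$gene_id)
        state
      },
      evaluate = {
        proc <- need("proc", "preprocess")
        emb <- need("embeddings", "embed")
        report <- metric_report(emb, proc$cells$cell_type, proc = proc,
                                k = config$k)
        if (!is.null(state$predicted)) {
          pm <- prediction_metrics(state$predicted, as.matrix(proc$rna_norm))
          report$rmse <- pm$rmse
          report$pearson_genewise <- pm$pearson_genewise
          report$spearman_genewise <- pm$spearman_genewise
        }
        state$report <- report
        state
      },
      potential = {
        proc <- need("proc", "preprocess")
        emb <- need("embeddings", "embed")
        pt <- proc$cells$pseudotime
        if (anyNA(pt)) stop("'potential' stage needs pseudotime metadata")
        state$pbulk_peaks <- pseudobulk(as.matrix(proc$atac_norm), pt,
                                        cell_types = proc$cells$cell_type)
        state$pbulk_genes <- pseudobulk(as.matrix(proc$rna_norm), pt)
        state$soft_clusters <- soft_cluster(state$pbulk_peaks,
                                            acore = config$acore,
                                            seed = stage_seed(config, "potential"))
        state$cosine_states <- modality_cosine_states(emb$Z_teacher_RNA,
                                                      emb$Z_teacher_ATAC)
        state
      },
      stop("unknown stage: ", stage))
  }
  state$manifest <- list(config_hash = config_hash(unclass(config)),
                         seed = config$seed, stages = stages,
                         package_version = as.character(utils::packageVersion("scDuet")))
  if (!is.null(out_dir)) write_pipeline_outputs(state, out_dir)
  state
}

write_pipeline_outputs <- function(state, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(x, file.path(out_dir, f),
                                          sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  if (!is.null(state$embeddings)) {
    emb <- state$embeddings
    wt(data.frame(barcode = rep(state$proc$cells$barcode, 2),
                  modality = rep(c("RNA", "ATAC"),
                                 each = nrow(emb$Z_teacher_RNA)),
                  emb$Z_joint), "joint_embedding.tsv")
  }
  if (!is.null(state$global_attention) && !is.null(state$mask))
    wt(global_attention_table(state$global_attention, state$mask),
       "global_attention.tsv")
  if (!is.null(state$report))
    jsonlite::write_json(unclass(state$report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(state$cosine_states))
    wt(state$cosine_states, "cosine_states.tsv")
  jsonlite::write_json(state$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Save / load model checkpoints
#'
#' Checkpoints are native R serializations (RDS) of the parameter
#' objects; they round-trip exactly.
#'
#' @param object any parameter object (\code{encoder_params},
#'   \code{decoder_params}, \code{prediction_head}).
#' @param path file path.
#' @return \code{path} (save) or the restored object (load).
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  path
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
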