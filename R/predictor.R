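# ATAC -> RNA modality prediction and chromatin-potential residuals.
#
# A two-layer MLP (d -> 1000 -> G, ReLU hidden) maps the ATAC student
# embedding to normalized expression, trained with mean squared error.
# Residuals (predicted - measured) carry the chromatin-potential signal:
# genes whose transcription lags the accessibility of their regulatory
# peaks show systematically larger residual magnitudes.

#' Fine-tune the expression prediction head
#'
#' Trains the prediction MLP on the ATAC student embedding of the supplied
#' cells. With \code{from_scratch}, the student encoder is re-initialized
#' at random (the de-novo ablation) instead of using the pretrained
#' weights; the encoder itself is not updated in either mode.
#'
#' @param enc_params (pretrained) \code{encoder_params}.
#' @param proc \code{multiome_processed} data.
#' @param cells optional training subset (row indices); all cells by
#'   default.
#' @param epochs training epochs (40 by default).
#' @param hidden hidden layer width (1000 by default).
#' @param batch_size mini-batch size.
#' @param lr_start,lr_end learning-rate schedule endpoints.
#' @param from_scratch use a randomly re-initialized encoder.
#' @param seed RNG seed.
#' @param verbose print per-epoch losses.
#' @return Object of class \code{prediction_head} with the trained weights,
#'   the encoder used to embed and the loss \code{history}.
#' @export
fine_tune_predictor <- function(enc_params, proc, cells = NULL,
                                epochs = 40L, hidden = 1000L,
                                batch_size = 32L, lr_start = 1e-3,
                                lr_end = 1e-5, from_scratch = FALSE,
                                seed = 1, verbose = FALSE) {
  set.seed(seed)
  if (from_scratch)
    enc_params <- init_encoder_params(enc_params$n_genes, enc_params$n_peaks,
                                      d = enc_params$d,
                                      dropout = enc_params$dropout,
                                      seed = seed + 1L)
  X <- as.matrix(proc$rna_norm)
  Z <- student_forward(as.matrix(proc$atac_norm), enc_params, "ATAC")
  if (is.null(cells)) cells <- seq_len(nrow(X))
  Ztr <- Z[cells, , drop = FALSE]
  Xtr <- X[cells, , drop = FALSE]
  d <- ncol(Z); G <- ncol(X)
  w <- list(W1 = glorot(d, hidden), b1 = rep(0, hidden),
            W2 = glorot(hidden, G), b2 = rep(0, G))
  opt <- adam_new(w)
  N <- nrow(Ztr)
  history <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    lr <- lr_schedule(epoch, epochs, lr_start, lr_end)
    ord <- sample.int(N)
    starts <- seq(1L, N, by = batch_size)
    bl <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      rows <- ord[starts[bi]:min(N, starts[bi] + batch_size - 1L)]
      tp <- tp_new()
      ids <- tp_leaves(tp, w)
      zin <- tp_leaf(tp, Ztr[rows, , drop = FALSE])
      h <- tp_relu(tp, tp_add_rowvec(tp, tp_matmul(tp, zin, ids$W1), ids$b1))
      pred <- tp_add_rowvec(tp, tp_matmul(tp, h, ids$W2), ids$b2)
      err <- tp_sub(tp, pred, tp_leaf(tp, Xtr[rows, , drop = FALSE]))
      loss <- tp_mean(tp, tp_mul(tp, err, err))
      grads <- tp_backward(tp, loss)
      st <- adam_step(opt, w, tp_collect(tp, grads, ids, w), lr = lr)
      w <- st$params; opt <- st$opt
      bl[bi] <- tp_val(tp, loss)
      if (!is.finite(bl[bi]))
        stop("non-finite prediction loss at epoch ", epoch)
    }
    history[epoch] <- mean(bl)
    if (verbose)
      message(sprintf("predictor epoch %d/%d  mse %.4f",
                      epoch, epochs, history[epoch]))
  }
  structure(list(w = w, enc_params = enc_params, hidden = hidden,
                 n_genes = G, history = history, trained = TRUE),
            class = "prediction_head")
}

#' Predict expression from the ATAC student embedding
#'
#' @param head a trained \code{prediction_head}.
#' @param Z_student_ATAC N x d embedding matrix (or a
#'   \code{multiome_processed} object, in which case the embedding is
#'   computed with the head's encoder).
#' @return N x G matrix of predicted normalized expression.
#' @export
predict_expression <- function(head, Z_student_ATAC) {
  if (!isTRUE(head$trained)) stop("prediction head is not trained")
  if (inherits(Z_student_ATAC, "multiome_processed"))
    Z_student_ATAC <- student_forward(as.matrix(Z_student_ATAC$atac_norm),
                                      head$enc_params, "ATAC")
  h <- Z_student_ATAC %*% head$w$W1
  h <- sweep(h, 2L, head$w$b1, "+")
  h <- h * (h > 0)
  sweep(h %*% head$w$W2, 2L, head$w$b2, "+")
}

#' Residuals between predicted and measured expression
#'
#' \code{predicted - measured}, elementwise, both on the normalized scale.
#'
#' @param pred,measured N x G matrices.
#' @param gene_ids optional gene identifiers for the columns.
#' @return Object of class \code{residual_matrix}: \code{values} (N x G),
#'   \code{gene_ids}, and per-gene standard deviations \code{gene_sd}.
#' @export
compute_residuals <- function(pred, measured, gene_ids = colnames(pred)) {
  measured <- as.matrix(measured)
  if (!identical(dim(pred), dim(measured))) stop("shape mismatch")
  values <- pred - measured
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(pred)))
  structure(list(values = values, gene_ids = gene_ids,
                 gene_sd = apply(values, 2L, stats::sd)),
            class = "residual_matrix")
}

#' Residual trend along pseudotime for one gene
#'
#' Fits a penalized-spline generalized additive model
#' (\code{mgcv::gam(residual ~ s(pseudotime))}, GCV-smoothed) to the
#' gene's residuals, locates the interior local extrema of the smooth, and
#' flags the gene if its residual standard deviation exceeds the given
#' quantile of the distribution over genes.
#'
#' @param residuals a \code{residual_matrix}.
#' @param pseudotime per-cell pseudotime (no missing values).
#' @param gene gene id or column index.
#' @param sd_quantile flag threshold on the per-gene residual sd (0.90 by
#'   default).
#' @param n_grid evaluation grid size for the smooth.
#' @return list with \code{grid}, \code{smooth}, \code{maxima},
#'   \code{minima} (pseudotime locations) and \code{high_sd} flag.
#' @export
residual_trend <- function(residuals, pseudotime, gene, sd_quantile = 0.90,
                           n_grid = 100L) {
  if (anyNA(pseudotime)) stop("pseudotime required for all cells")
  j <- if (is.character(gene)) match(gene, residuals$gene_ids) else gene
  if (is.na(j)) stop("unknown gene: ", gene)
  y <- residuals$values[, j]
  if (length(y) < 10) stop("refusing to smooth fewer than 10 cells")
  n_unique <- length(unique(pseudotime))
  if (n_unique < 3) stop("needs at least 3 distinct pseudotime values")
  k <- min(10L, n_unique)
  fit <- mgcv::gam(y ~ s(t, k = k), data = data.frame(y = y, t = pseudotime))
  grid <- seq(min(pseudotime), max(pseudotime), length.out = n_grid)
  sm <- as.vector(stats::predict(fit, newdata = data.frame(t = grid)))
  interior <- 2:(n_grid - 1)
  eps <- 1e-10 * max(1, diff(range(sm)))
  is_max <- sm[interior] > sm[interior - 1] + eps &
    sm[interior] > sm[interior + 1] + eps
  is_min <- sm[interior] < sm[interior - 1] - eps &
    sm[interior] < sm[interior + 1] - eps
  thr <- stats::quantile(residuals$gene_sd, sd_quantile, names = FALSE)
  list(grid = grid, smooth = sm,
       maxima = grid[interior][is_max], minima = grid[interior][is_min],
       high_sd = residuals$gene_sd[j] > thr)
}
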