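# Cross-modal NT-Xent contrastive pretraining.
#
# A mini-batch of N paired cells yields 2N points on the unit hypersphere
# (one per modality). For an anchor m with positive m+, the loss term is
#
#   l(m, m+) = -log exp(s_{m,m+}) /
#              sum_{k != m} [ exp(s_{k,m}) + exp(s_{k,m+}) ]
#
# with s the temperature-scaled cosine similarity: the denominator pools
# the exp-similarities of all 2N in-batch points against both the anchor's
# and the positive's columns, excluding only the anchor index itself (the
# positive's self-similarity therefore appears; for N = 1 identical pairs
# the loss is log 2). The full loss averages l(m, m+) + l(m+, m) over the N
# pairs, i.e. over 2N ordered terms.

#' Temperature-scaled cosine similarity
#'
#' \code{(h1 . h2) / (tau * |h1| * |h2|)}.
#'
#' @param h1,h2 non-zero numeric vectors of equal length.
#' @param tau temperature (> 0).
#' @return Scalar similarity.
#' @export
cosine_sim_scaled <- function(h1, h2, tau = 0.1) {
  stopifnot(tau > 0, length(h1) == length(h2))
  n1 <- sqrt(sum(h1^2)); n2 <- sqrt(sum(h2^2))
  if (n1 == 0 || n2 == 0) stop("zero-norm vector in cosine similarity")
  sum(h1 * h2) / (tau * n1 * n2)
}

#' Cross-modal NT-Xent loss
#'
#' Normalized temperature-scaled cross-entropy over a batch of paired
#' embeddings; row i of \code{Z_a} and \code{Z_b} must be the same cell.
#' See the convention note in the package vignette: the denominator of each
#' term sums exp-similarities over the 2N in-batch points against both the
#' anchor's and its positive's columns, excluding only the anchor.
#'
#' @param Z_a,Z_b N x d embedding matrices (rows paired).
#' @param tau temperature.
#' @return Scalar loss.
#' @export
nt_xent_cross_modal <- function(Z_a, Z_b, tau = 0.1) {
  Z_a <- as.matrix(Z_a); Z_b <- as.matrix(Z_b)
  N <- nrow(Z_a)
  if (N == 0) stop("empty batch")
  stopifnot(identical(dim(Z_a), dim(Z_b)), tau > 0)
  W <- rbind(Z_a, Z_b)
  nrm <- sqrt(rowSums(W^2))
  if (any(nrm == 0)) stop("zero-norm embedding row")
  Wn <- W / nrm
  S <- tcrossprod(Wn) / tau
  E <- exp(S)
  Tj <- colSums(E)
  i <- seq_len(N); p <- N + i
  d1 <- (Tj[i] - E[cbind(i, i)]) + (Tj[p] - E[cbind(i, p)])
  d2 <- (Tj[p] - E[cbind(p, p)]) + (Tj[i] - E[cbind(p, i)])
  l1 <- -S[cbind(i, p)] + log(d1)
  l2 <- -S[cbind(p, i)] + log(d2)
  (sum(l1) + sum(l2)) / (2 * N)
}

# tape version (za, zb are node ids of N x d matrices)
tape_nt_xent <- function(tp, za, zb, tau) {
  N <- nrow(tp_val(tp, za))
  w <- tp_l2norm_rows(tp, tp_vcat(tp, za, zb))
  s <- tp_scale(tp, tp_matmul(tp, w, w, transb = TRUE), 1 / tau)
  e <- tp_exp(tp, s)
  tj <- tp_colsums(tp, e)
  i <- seq_len(N); p <- N + i
  ex <- function(ii, jj) tp_extract(tp, e, cbind(ii, jj))
  sx <- function(ii, jj) tp_extract(tp, s, cbind(ii, jj))
  d1 <- tp_sub(tp, tp_add(tp, tp_subset(tp, tj, i), tp_subset(tp, tj, p)),
               tp_add(tp, ex(i, i), ex(i, p)))
  d2 <- tp_sub(tp, tp_add(tp, tp_subset(tp, tj, p), tp_subset(tp, tj, i)),
               tp_add(tp, ex(p, p), ex(p, i)))
  l1 <- tp_sub(tp, tp_log(tp, d1), sx(i, p))
  l2 <- tp_sub(tp, tp_log(tp, d2), sx(p, i))
  tp_scale(tp, tp_add(tp, tp_sum(tp, l1), tp_sum(tp, l2)), 1 / (2 * N))
}

#' Contrastive pretraining configuration
#'
#' @param tau NT-Xent temperature.
#' @param batch_size mini-batch size.
#' @param epochs training epochs.
#' @param lr_start,lr_end endpoints of the exponential per-epoch learning
#'   rate decay.
#' @param pairing_scheme which embedding pairs are contrasted:
#'   \code{"teacher_teacher_student_student"} (cross-modal teacher pair +
#'   cross-modal student pair, the default), \code{"crossed_teacher_student"}
#'   (teacher RNA vs student ATAC + student RNA vs teacher ATAC), or
#'   \code{"within_modality"} (teacher vs student inside each modality).
#' @param dim embedding dimension.
#' @param dropout dropout rate.
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @return list of class \code{contrastive_config}.
#' @export
contrastive_config <- function(tau = 0.1, batch_size = 32L, epochs = 20L,
                               lr_start = 1e-4, lr_end = 1e-6,
                               pairing_scheme = c("teacher_teacher_student_student",
                                                  "crossed_teacher_student",
                                                  "within_modality"),
                               dim = 128L, dropout = 0.1, seed = 1L) {
  stopifnot(tau > 0, lr_start >= lr_end, lr_end > 0, batch_size >= 1,
            epochs >= 1)
  structure(list(tau = tau, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr_start = lr_start,
                 lr_end = lr_end,
                 pairing_scheme = match.arg(pairing_scheme),
                 dim = as.integer(dim), dropout = dropout,
                 seed = as.integer(seed)),
            class = "contrastive_config")
}

# the two contrasted pairs under a pairing scheme (ablation designs)
pairing_pairs <- function(scheme) {
  switch(scheme,
         teacher_teacher_student_student =
           list(c("t_rna", "t_atac"), c("s_rna", "s_atac")),
         crossed_teacher_student =
           list(c("t_rna", "s_atac"), c("s_rna", "t_atac")),
         within_modality =
           list(c("t_rna", "s_rna"), c("t_atac", "s_atac")),
         stop("unknown pairing scheme"))
}

#' Full pretraining loss for a set of embeddings
#'
#' Mean of the two NT-Xent components dictated by the pairing scheme
#' (teacher-level and student-level contrast by default).
#'
#' @param embeddings list with elements \code{Z_teacher_RNA},
#'   \code{Z_teacher_ATAC}, \code{Z_student_RNA}, \code{Z_student_ATAC}.
#' @param config a [contrastive_config()].
#' @return Scalar loss.
#' @export
pretrain_loss <- function(embeddings, config = contrastive_config()) {
  z <- list(t_rna = embeddings$Z_teacher_RNA, t_atac = embeddings$Z_teacher_ATAC,
            s_rna = embeddings$Z_student_RNA, s_atac = embeddings$Z_student_ATAC)
  prs <- pairing_pairs(config$pairing_scheme)
  l1 <- nt_xent_cross_modal(z[[prs[[1]][1]]], z[[prs[[1]][2]]], config$tau)
  l2 <- nt_xent_cross_modal(z[[prs[[2]][1]]], z[[prs[[2]][2]]], config$tau)
  (l1 + l2) / 2
}

#' Pretrain the teacher-student encoders
#'
#' Adam optimization of the cross-modal contrastive objective over
#' shuffled mini-batches, with an exponential learning-rate decay between
#' \code{lr_start} and \code{lr_end}. Seed-reproducible; the last
#' incomplete batch of each epoch is kept.
#'
#' @param proc a \code{multiome_processed} object
#'   (see [preprocess_multiome()]).
#' @param config a [contrastive_config()].
#' @param params optional pre-initialized \code{encoder_params} (e.g. to
#'   continue training); defaults to a fresh initialization from the
#'   config seed.
#' @param verbose print per-epoch losses.
#' @return list with \code{params} (trained \code{encoder_params}) and
#'   \code{history} (per-epoch mean batch loss).
#' @export
train_pretrain <- function(proc, config = contrastive_config(),
                           params = NULL, verbose = FALSE) {
  N <- nrow(proc$rna_norm)
  if (is.null(params))
    params <- init_encoder_params(ncol(proc$rna_norm), ncol(proc$atac_norm),
                                  d = config$dim, dropout = config$dropout,
                                  seed = config$seed)
  set.seed(config$seed + 1L)
  rna_dense <- as.matrix(proc$rna_norm)
  atac_dense <- as.matrix(proc$atac_norm)
  opt <- adam_new(params$w)
  history <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_schedule(epoch, config$epochs, config$lr_start, config$lr_end)
    ord <- sample.int(N)
    starts <- seq(1L, N, by = config$batch_size)
    batch_losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      cells <- ord[starts[bi]:min(N, starts[bi] + config$batch_size - 1L)]
      st <- pretrain_step(params, proc, rna_dense, atac_dense, cells, config, lr, opt)
      params <- st$params; opt <- st$opt
      batch_losses[bi] <- st$loss
      if (!is.finite(st$loss))
        stop("non-finite pretraining loss at epoch ", epoch, ", batch ", bi)
    }
    history[epoch] <- mean(batch_losses)
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f  lr %.2e",
                      epoch, config$epochs, history[epoch], lr))
  }
  params$pretrained <- TRUE
  list(params = params, history = history)
}

pretrain_step <- function(params, proc, rna_dense, atac_dense, cells,
                          config, lr, opt) {
  nb <- length(cells)
  tp <- tp_new(512L)
  ids <- tp_leaves(tp, params$w)
  tok_r <- token_table(proc$encoded, "RNA", cells)
  tok_a <- token_table(proc$encoded, "ATAC", cells)
  tr <- tape_teacher(tp, ids$teacher_rna, tok_r, nb, params$d,
                     params$bn$teacher_rna, params$dropout)
  ta <- tape_teacher(tp, ids$teacher_atac, tok_a, nb, params$d,
                     params$bn$teacher_atac, params$dropout)
  sr <- tape_student(tp, ids$student_rna, rna_dense[cells, , drop = FALSE],
                     params$bn$student_rna, params$dropout)
  sa <- tape_student(tp, ids$student_atac, atac_dense[cells, , drop = FALSE],
                     params$bn$student_atac, params$dropout)
  z <- list(t_rna = tr$z, t_atac = ta$z, s_rna = sr$z, s_atac = sa$z)
  prs <- pairing_pairs(config$pairing_scheme)
  l1 <- tape_nt_xent(tp, z[[prs[[1]][1]]], z[[prs[[1]][2]]], config$tau)
  l2 <- tape_nt_xent(tp, z[[prs[[2]][1]]], z[[prs[[2]][2]]], config$tau)
  loss <- tp_scale(tp, tp_add(tp, l1, l2), 0.5)
  grads <- tp_backward(tp, loss)
  gw <- tp_collect(tp, grads, ids, params$w)
  st <- adam_step(opt, params$w, gw, lr = lr)
  params$w <- st$params
  params$bn$teacher_rna <- bn_update(params$bn$teacher_rna, tr$bn_stats)
  params$bn$teacher_atac <- bn_update(params$bn$teacher_atac, ta$bn_stats)
  params$bn$student_rna <- bn_update(params$bn$student_rna, sr$bn_stats)
  params$bn$student_atac <- bn_update(params$bn$student_atac, sa$bn_stats)
  list(params = params, opt = st$opt, loss = tp_val(tp, loss))
}

#' Compute the four embeddings (eval mode) for a processed dataset
#'
#' @param proc a \code{multiome_processed} object.
#' @param params trained (or freshly initialized) \code{encoder_params}.
#' @return list of class \code{embedding_set} with \code{Z_teacher_RNA},
#'   \code{Z_teacher_ATAC}, \code{Z_student_RNA}, \code{Z_student_ATAC} and
#'   \code{Z_joint} (2N x d row-stack of the teacher embeddings).
#' @export
compute_embeddings <- function(proc, params) {
  zt_r <- teacher_forward(proc$encoded, params, "RNA")$embedding
  zt_a <- teacher_forward(proc$encoded, params, "ATAC")$embedding
  zs_r <- student_forward(as.matrix(proc$rna_norm), params, "RNA")
  zs_a <- student_forward(as.matrix(proc$atac_norm), params, "ATAC")
  structure(list(Z_teacher_RNA = zt_r, Z_teacher_ATAC = zt_a,
                 Z_student_RNA = zs_r, Z_student_ATAC = zs_a,
                 Z_joint = joint_embedding(zt_r, zt_a)),
            class = "embedding_set")
}

#' Joint embedding of the two teacher outputs
#'
#' Row-stack with RNA rows first: rows 1..N are RNA cells, rows N+1..2N the
#' matched ATAC cells.
#'
#' @param Z_teacher_RNA,Z_teacher_ATAC N x d matrices of equal shape.
#' @return 2N x d matrix.
#' @export
joint_embedding <- function(Z_teacher_RNA, Z_teacher_ATAC) {
  if (!identical(dim(Z_teacher_RNA), dim(Z_teacher_ATAC)))
    stop("shape mismatch between modalities")
  rbind(Z_teacher_RNA, Z_teacher_ATAC)
}

#' Map query cells through a pretrained model
#'
#' Eval-mode forward pass only; no parameters are updated. The query's
#' feature spaces must match those the model was trained on.
#'
#' @param params trained \code{encoder_params}.
#' @param query an \code{encoded_cells} batch for the query cells.
#' @return list with \code{Z_teacher_RNA} and \code{Z_teacher_ATAC}
#'   (N_query x d each).
#' @export
map_query <- function(params, query) {
  if (query$n_genes != params$n_genes || query$n_peaks != params$n_peaks)
    stop("query feature space does not match the trained model")
  if (length(query$gene_indices) == 0)
    return(list(Z_teacher_RNA = matrix(0, 0, params$d),
                Z_teacher_ATAC = matrix(0, 0, params$d)))
  list(Z_teacher_RNA = teacher_forward(query, params, "RNA")$embedding,
       Z_teacher_ATAC = teacher_forward(query, params, "ATAC")$embedding)
}

#' Alignment and uniformity of paired embeddings
#'
#' Hypersphere representation diagnostics (Wang-Isola): on L2-normalized
#' rows, alignment is the mean squared distance between matched cross-modal
#' pairs (lower = tighter pairs) and uniformity is
#' \code{log mean exp(-2 ||z_i - z_j||^2)} over all distinct pairs of the
#' pooled 2N points (lower = more uniformly spread).
#'
#' @param Z_a,Z_b paired N x d embeddings, N >= 2.
#' @return list with \code{align} and \code{uniform}.
#' @export
alignment_uniformity <- function(Z_a, Z_b) {
  N <- nrow(Z_a)
  # uniformity needs at least one distinct pair among the 2N pooled points
  if (N < 1) stop("uniformity needs at least 2 pooled points")
  l2 <- function(m) m / sqrt(rowSums(m^2))
  A <- l2(Z_a); B <- l2(Z_b)
  align <- mean(rowSums((A - B)^2))
  W <- rbind(A, B)
  d2 <- as.vector(stats::dist(W))^2
  uniform <- log(mean(exp(-2 * d2)))
  list(align = align, uniform = uniform)
}
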