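# Asymmetric teacher-student encoder pair.
#
# Teacher: per-token embedding lookup scaled by the token's normalized
# count, a one-hidden-layer tanh attention MLP dotted with a cellular
# context vector, softmax over the cell's tokens, attention-weighted sum,
# then batch-norm -> dropout -> dense+ReLU to d dims.
# Student: batch-norm over the dense count vector -> dropout -> dense+ReLU.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

#' Initialize encoder parameters
#'
#' Dense and embedding tables use Glorot-uniform initialization; the
#' cellular context vectors are drawn N(0, 1/d). Each modality's teacher
#' has its own context vector unless \code{share_context} is set, in which
#' case the RNA teacher's vector is reused by the ATAC teacher.
#'
#' @param n_genes,n_peaks feature-space sizes after preprocessing.
#' @param d embedding dimension (128 by default).
#' @param dropout dropout rate used in training mode.
#' @param share_context share the attention context vector across
#'   modalities.
#' @param seed RNG seed for the initialization.
#' @return Object of class \code{encoder_params}.
#' @export
init_encoder_params <- function(n_genes, n_peaks, d = 128L, dropout = 0.1,
                                share_context = FALSE, seed = 1) {
  stopifnot(d > 0, dropout >= 0, dropout < 1)
  set.seed(seed)
  teacher <- function(nf) list(
    E = glorot(nf, d),
    W1 = glorot(d, d), b1 = rep(0, d),
    u = stats::rnorm(d, 0, 1 / sqrt(d)),
    bn_gamma = rep(1, d), bn_beta = rep(0, d),
    W2 = glorot(d, d), b2 = rep(0, d))
  student <- function(nf) list(
    bn_gamma = rep(1, nf), bn_beta = rep(0, nf),
    W = glorot(nf, d), b = rep(0, d))
  w <- list(teacher_rna = teacher(n_genes), teacher_atac = teacher(n_peaks),
            student_rna = student(n_genes), student_atac = student(n_peaks))
  if (share_context) w$teacher_atac$u <- w$teacher_rna$u
  bn0 <- function(nf) list(mean = rep(0, nf), var = rep(1, nf))
  structure(list(d = as.integer(d), dropout = dropout,
                 n_genes = n_genes, n_peaks = n_peaks,
                 share_context = share_context,
                 w = w,
                 bn = list(teacher_rna = bn0(d), teacher_atac = bn0(d),
                           student_rna = bn0(n_genes),
                           student_atac = bn0(n_peaks)),
                 pretrained = FALSE),
            class = "encoder_params")
}

#' @export
print.encoder_params <- function(x, ...) {
  cat(sprintf("encoder_params: d=%d, %d genes, %d peaks, dropout=%.2f%s\n",
              x$d, x$n_genes, x$n_peaks, x$dropout,
              if (isTRUE(x$pretrained)) ", pretrained" else ""))
  invisible(x)
}

# flatten an encoded_cells batch into a token table for one modality
token_table <- function(batch, modality, cells = NULL) {
  idx <- if (modality == "RNA") batch$gene_indices else batch$peak_indices
  val <- if (modality == "RNA") batch$gene_values else batch$peak_values
  if (!is.null(cells)) { idx <- idx[cells]; val <- val[cells] }
  len <- lengths(idx)
  list(idx = unlist(idx, use.names = FALSE) %||% integer(0),
       val = unlist(val, use.names = FALSE) %||% numeric(0),
       cell = rep(seq_along(idx), len),
       n = length(idx))
}

#' Teacher network forward pass
#'
#' @param batch an \code{encoded_cells} object (see [encode_cells()]).
#' @param params \code{encoder_params}.
#' @param modality \code{"RNA"} or \code{"ATAC"}.
#' @param train_mode if TRUE, uses batch statistics for batch norm and
#'   applies dropout (draws from the current RNG); if FALSE the pass is
#'   deterministic, using running statistics.
#' @return list with \code{embedding} (N x d), \code{token_hidden}
#'   (per-cell list of token x d matrices) and \code{attention} (per-cell
#'   softmax weights over tokens, each summing to 1).
#' @export
teacher_forward <- function(batch, params, modality = c("RNA", "ATAC"),
                            train_mode = FALSE) {
  modality <- match.arg(modality)
  pm <- params$w[[if (modality == "RNA") "teacher_rna" else "teacher_atac"]]
  bn <- params$bn[[if (modality == "RNA") "teacher_rna" else "teacher_atac"]]
  nf <- if (modality == "RNA") params$n_genes else params$n_peaks
  tok <- token_table(batch, modality)
  if (length(tok$idx) && (min(tok$idx) < 1 || max(tok$idx) > nf))
    stop("token index out of range for ", modality)
  if (any(lengths(if (modality == "RNA") batch$gene_indices
                  else batch$peak_indices) == 0))
    warning("empty cell(s): zero aggregate used")
  H0 <- pm$E[tok$idx, , drop = FALSE] * tok$val
  s <- as.vector(tanh(sweep(H0 %*% pm$W1, 2L, pm$b1, "+")) %*% pm$u)
  a <- group_softmax_vec(s, tok$cell)
  C <- matrix(0, tok$n, params$d)
  if (length(a)) {
    r <- rowsum(H0 * a, tok$cell)
    C[as.integer(rownames(r)), ] <- r
  }
  Z <- dense_head(C, pm, bn, params$dropout, train_mode)
  list(embedding = Z,
       token_hidden = split.data.frame(H0, factor(tok$cell, levels = seq_len(tok$n))),
       attention = split(a, factor(tok$cell, levels = seq_len(tok$n))),
       token_index = split(tok$idx, factor(tok$cell, levels = seq_len(tok$n))))
}

#' Student network forward pass
#'
#' @param values dense N x F matrix of normalized counts for the modality.
#' @param params \code{encoder_params}.
#' @param modality \code{"RNA"} or \code{"ATAC"}.
#' @param train_mode as in [teacher_forward()].
#' @return N x d embedding matrix.
#' @export
student_forward <- function(values, params, modality = c("RNA", "ATAC"),
                            train_mode = FALSE) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  pm <- params$w[[if (modality == "RNA") "student_rna" else "student_atac"]]
  bn <- params$bn[[if (modality == "RNA") "student_rna" else "student_atac"]]
  nf <- if (modality == "RNA") params$n_genes else params$n_peaks
  if (ncol(values) != nf) stop("feature count mismatch for ", modality)
  xn <- bn_apply(values, pm, bn, train_mode)
  if (train_mode && params$dropout > 0) {
    mask <- matrix(stats::rbinom(length(xn), 1, 1 - params$dropout),
                   nrow(xn)) / (1 - params$dropout)
    xn <- xn * mask
  }
  z <- sweep(xn %*% pm$W, 2L, pm$b, "+")
  z * (z > 0)
}

# batchnorm -> dropout -> dense + ReLU (the teacher's head)
dense_head <- function(C, pm, bn, dropout, train_mode) {
  xn <- bn_apply(C, pm, bn, train_mode)
  if (train_mode && dropout > 0) {
    mask <- matrix(stats::rbinom(length(xn), 1, 1 - dropout),
                   nrow(xn)) / (1 - dropout)
    xn <- xn * mask
  }
  z <- sweep(xn %*% pm$W2, 2L, pm$b2, "+")
  z * (z > 0)
}

bn_apply <- function(x, pm, bn, train_mode) {
  if (train_mode && nrow(x) > 1) {
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2L, mu)^2)
  } else {
    mu <- bn$mean; v <- bn$var
  }
  xn <- sweep(sweep(x, 2L, mu), 2L, sqrt(v + BN_EPS), "/")
  sweep(sweep(xn, 2L, pm$bn_gamma, "*"), 2L, pm$bn_beta, "+")
}

group_softmax_vec <- function(s, group) {
  if (!length(s)) return(numeric(0))
  m <- stats::ave(s, group, FUN = max)
  e <- exp(s - m)
  e / stats::ave(e, group, FUN = sum)
}

## ---- tape (training) forwards -----------------------------------------

# teacher forward on a tape; ids = node ids for this modality's weights.
# Returns list(z = node id of N x d embedding, bn_stats = batch mean/var to
# fold into running statistics, cls-level intermediates for reuse).
tape_teacher <- function(tp, ids, tok, n_cells, d, bn, dropout, train = TRUE) {
  h0 <- tp_mul_colvec(tp, tp_rows(tp, ids$E, tok$idx), tp_leaf(tp, tok$val))
  pre <- tp_tanh(tp, tp_add_rowvec(tp, tp_matmul(tp, h0, ids$W1), ids$b1))
  s <- tp_matmul(tp, pre, tp_reshape_col(tp, ids$u))
  a <- tp_group_softmax(tp, tp_as_vector(tp, s), tok$cell)
  c_agg <- tp_rowsum_group(tp, tp_mul_colvec(tp, h0, a), tok$cell, n_cells)
  tape_head(tp, c_agg, ids, bn, dropout, n_cells, d, train,
            w_name = "W2", b_name = "b2")
}

tape_student <- function(tp, ids, values, bn, dropout, train = TRUE) {
  x <- tp_leaf(tp, values)
  tape_head(tp, x, ids, bn, dropout, nrow(values), ncol(values), train,
            w_name = "W", b_name = "b")
}

# shared BN -> dropout -> dense+ReLU head on the tape
tape_head <- function(tp, x, ids, bn, dropout, n, nf, train, w_name, b_name) {
  stats_out <- NULL
  if (train && n > 1) {
    mu <- tp_scale(tp, tp_colsums(tp, x), 1 / n)
    xc <- tp_add_rowvec(tp, x, tp_scale(tp, mu, -1))
    v <- tp_scale(tp, tp_colsums(tp, tp_mul(tp, xc, xc)), 1 / n)
    sd_ <- tp_sqrt(tp, tp_addc(tp, v, BN_EPS))
    xn <- tp_div_rowvec(tp, xc, sd_)
    stats_out <- list(mean = tp_val(tp, mu), var = tp_val(tp, v))
  } else {
    xc <- tp_add_rowvec(tp, x, tp_leaf(tp, -bn$mean))
    xn <- tp_div_rowvec(tp, xc, tp_leaf(tp, sqrt(bn$var + BN_EPS)))
  }
  y <- tp_add_rowvec(tp, tp_mul_rowvec(tp, xn, ids$bn_gamma), ids$bn_beta)
  if (train && dropout > 0) {
    mask <- matrix(stats::rbinom(n * ncol(tp_val(tp, y)), 1, 1 - dropout),
                   n) / (1 - dropout)
    y <- tp_mulc(tp, y, mask)
  }
  z <- tp_relu(tp, tp_add_rowvec(tp, tp_matmul(tp, y, ids[[w_name]]),
                                 ids[[b_name]]))
  list(z = z, bn_stats = stats_out)
}

# fold batch statistics into running statistics (momentum update)
bn_update <- function(bn, stats) {
  if (is.null(stats)) return(bn)
  bn$mean <- BN_MOMENTUM * bn$mean + (1 - BN_MOMENTUM) * stats$mean
  bn$var <- BN_MOMENTUM * bn$var + (1 - BN_MOMENTUM) * stats$var
  bn
}
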