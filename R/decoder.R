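# Gene-peak interaction decoder.
#
# Token sequences are per-cell: the embeddings of the cell's non-zero
# features scaled by their normalized counts (the teacher's token hiddens),
# with a learned CLS token prepended. Gene tokens pass one self-attention
# layer; a cross-attention pass with genes as queries and peaks as keys
# (additively masked beyond a genomic distance threshold) produces the
# gene-side CLS attention over peaks; a symmetric pass with peaks as
# queries (sharing projections) produces the peak-side CLS attention over
# genes. The two CLS attention row sets, contracted over cells, give the
# G x P global attention matrix used to rank candidate regulatory links.

MASK_NEG <- -1e9

#' Initialize decoder parameters
#'
#' @param d embedding dimension (must match the encoder).
#' @param tau_cls temperature of the CLS contrastive loss.
#' @param heads number of attention heads (d must be divisible by heads).
#' @param seed RNG seed.
#' @return Object of class \code{decoder_params}.
#' @export
init_decoder_params <- function(d = 128L, tau_cls = 0.1, heads = 1L,
                                seed = 1) {
  stopifnot(d %% heads == 0)
  set.seed(seed)
  structure(list(
    d = as.integer(d), tau_cls = tau_cls, heads = as.integer(heads),
    w = list(Wq_s = glorot(d, d), Wk_s = glorot(d, d), Wv_s = glorot(d, d),
             Wq_c = glorot(d, d), Wk_c = glorot(d, d), Wv_c = glorot(d, d),
             cls_rna = stats::rnorm(d, 0, 1 / sqrt(d)),
             cls_atac = stats::rnorm(d, 0, 1 / sqrt(d)),
             Wm = glorot(2L * d, 2L), bm = rep(0, 2L))),
    class = "decoder_params")
}

#' Prepend a CLS token to a token sequence
#'
#' @param tokens T x d matrix of token hiddens for one cell, or a list of
#'   such matrices.
#' @param cls_embedding length-d CLS vector (identical across cells).
#' @return (T+1) x d matrix (or list), CLS in row 1, original order kept.
#' @export
prepend_cls <- function(tokens, cls_embedding) {
  if (is.list(tokens))
    return(lapply(tokens, prepend_cls, cls_embedding = cls_embedding))
  rbind(matrix(cls_embedding, 1L), tokens)
}

softmax_rows_mat <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / rowSums(e)
}

attend <- function(Q, K, V, d, mask = NULL, heads = 1L) {
  dh <- ncol(Q) / heads
  out <- matrix(0, nrow(Q), ncol(Q))
  wsum <- matrix(0, nrow(Q), nrow(K))
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    scores <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE])
    if (!is.null(mask)) scores <- scores + mask
    A <- softmax_rows_mat(scores / sqrt(dh))
    out[, cols] <- A %*% V[, cols, drop = FALSE]
    wsum <- wsum + A
  }
  list(hidden = out, weights = wsum / heads)
}

#' Self-attention over a token sequence
#'
#' \code{softmax(Q K' / sqrt(d)) V} with Q, K, V linear projections of the
#' tokens; every attention row sums to 1.
#'
#' @param tokens (T x d) matrix (one cell, CLS included) or list of such.
#' @param params \code{decoder_params}.
#' @param heads number of heads (columns split into blocks; the returned
#'   weights are head-averaged).
#' @return list(s) with \code{hidden} (T x d) and \code{weights} (T x T).
#' @export
self_attention <- function(tokens, params, heads = params$heads) {
  if (is.list(tokens))
    return(lapply(tokens, self_attention, params = params, heads = heads))
  w <- params$w
  attend(tokens %*% w$Wq_s, tokens %*% w$Wk_s, tokens %*% w$Wv_s,
         params$d, mask = NULL, heads = heads)
}

#' Cross-attention between two token sequences
#'
#' Queries come from the (self-attended) gene sequence, keys and values
#' from the peak sequence; the additive distance mask is applied before the
#' softmax so masked entries receive vanishing weight.
#'
#' @param query_tokens Tq x d matrix.
#' @param key_tokens Tk x d matrix.
#' @param mask Tq x Tk additive mask (0 or \code{-1e9}); NULL for none.
#' @param params \code{decoder_params}.
#' @param heads number of heads.
#' @return list with \code{hidden} (Tq x d) and \code{weights} (Tq x Tk).
#' @export
cross_attention <- function(query_tokens, key_tokens, mask, params,
                            heads = params$heads) {
  if (!is.null(mask) &&
      (nrow(mask) != nrow(query_tokens) || ncol(mask) != nrow(key_tokens)))
    stop("mask shape does not match the token sequences")
  w <- params$w
  attend(query_tokens %*% w$Wq_c, key_tokens %*% w$Wk_c,
         key_tokens %*% w$Wv_c, params$d, mask = mask, heads = heads)
}

#' Build the genomic distance attention mask
#'
#' Entry (g, p) is unmasked (0) iff gene g and peak p are on the same
#' chromosome and |TSS - peak midpoint| <= \code{threshold_bp} (inclusive);
#' otherwise \code{-1e9}. Row 1 and column 1 correspond to the CLS tokens
#' and are always unmasked. The mask is shared by all cells.
#'
#' @param genes gene annotation data.frame (\code{chrom}, \code{tss}).
#' @param peaks peak annotation data.frame (\code{chrom}, \code{midpoint}
#'   or \code{start}/\code{end}).
#' @param threshold_bp distance threshold in bp (1.2 Mb by default).
#' @return list of class \code{attention_mask}: \code{values}
#'   ((G+1) x (P+1) additive mask), \code{threshold_bp}, \code{gene_ids},
#'   \code{peak_ids}.
#' @export
build_attention_mask <- function(genes, peaks, threshold_bp = 1.2e6) {
  if (anyNA(genes$chrom) || anyNA(genes$tss))
    stop("missing gene annotation: ",
         paste(genes$gene_id[is.na(genes$chrom) | is.na(genes$tss)],
               collapse = ", "))
  peaks <- validate_peaks(peaks)
  if (anyNA(peaks$chrom))
    stop("missing peak annotation: ",
         paste(peaks$peak_id[is.na(peaks$chrom)], collapse = ", "))
  same <- outer(genes$chrom, peaks$chrom, "==")
  near <- abs(outer(genes$tss, peaks$midpoint, "-")) <= threshold_bp
  core <- ifelse(same & near, 0, MASK_NEG)
  values <- rbind(0, cbind(0, core))
  structure(list(values = values, threshold_bp = threshold_bp,
                 gene_ids = genes$gene_id, peak_ids = peaks$peak_id),
            class = "attention_mask")
}

#' CLS contrastive loss
#'
#' NT-Xent on the paired per-cell CLS embeddings of the two modalities
#' (same engine and index convention as the pretraining loss).
#'
#' @param gene_cls,peak_cls N x d matrices of CLS outputs (rows paired).
#' @param tau temperature.
#' @return Scalar loss.
#' @export
cls_contrastive_loss <- function(gene_cls, peak_cls, tau = 0.1) {
  nt_xent_cross_modal(gene_cls, peak_cls, tau)
}

#' Total decoder training objective
#'
#' @param cls_loss,match_loss the two component losses.
#' @return Their sum.
#' @export
interaction_loss <- function(cls_loss, match_loss) cls_loss + match_loss

## ---- per-cell token assembly ------------------------------------------

# token matrices (embedding row x normalized count) for one cell
cell_tokens <- function(enc_params, batch, cell) {
  gi <- batch$gene_indices[[cell]]; gv <- batch$gene_values[[cell]]
  pi <- batch$peak_indices[[cell]]; pv <- batch$peak_values[[cell]]
  list(gene = enc_params$w$teacher_rna$E[gi, , drop = FALSE] * gv,
       peak = enc_params$w$teacher_atac$E[pi, , drop = FALSE] * pv,
       gidx = gi, pidx = pi)
}

# mask sub-matrix for one cell's token subset (CLS row/col kept)
mask_subset <- function(mask, gidx, pidx) {
  mask$values[c(1L, gidx + 1L), c(1L, pidx + 1L), drop = FALSE]
}

## ---- matching loss ----------------------------------------------------

#' RNA-ATAC modality matching loss
#'
#' For each cell the true (gene, peak) pairing forms a positive example;
#' one negative is sampled per cell from the non-matching in-batch cells
#' with probability proportional to the softmaxed CLS similarity (hard
#' negatives), so positives and negatives are balanced. A linear classifier
#' on the concatenated gene-side/peak-side CLS outputs predicts
#' matched/mismatched; the loss is the mean cross-entropy.
#'
#' @param gene_tokens,peak_tokens per-cell lists of token matrices
#'   (without CLS).
#' @param gidx,pidx per-cell lists of the tokens' feature indices
#'   (for masking).
#' @param dparams \code{decoder_params}.
#' @param mask an \code{attention_mask}.
#' @param seed seed for negative sampling.
#' @return list with \code{loss}, \code{logits} (2N x 2), \code{labels}
#'   (1 = mismatched, 2 = matched) and \code{negatives} (sampled index per
#'   cell).
#' @export
matching_loss <- function(gene_tokens, peak_tokens, gidx, pidx, dparams,
                          mask, seed = 1) {
  N <- length(gene_tokens)
  if (N < 2) stop("matching loss needs at least 2 cells to form negatives")
  w <- dparams$w
  # positive-pair forward passes
  pos <- lapply(seq_len(N), function(i)
    decoder_cell_forward(gene_tokens[[i]], peak_tokens[[i]],
                         mask_subset(mask, gidx[[i]], pidx[[i]]), dparams))
  gcls <- do.call(rbind, lapply(pos, `[[`, "gene_cls"))
  pcls <- do.call(rbind, lapply(pos, `[[`, "peak_cls"))
  negatives <- sample_hard_negatives(gcls, pcls, dparams$tau_cls, seed)
  neg <- lapply(seq_len(N), function(i) {
    j <- negatives[i]
    decoder_cell_forward(gene_tokens[[i]], peak_tokens[[j]],
                         mask_subset(mask, gidx[[i]], pidx[[j]]), dparams)
  })
  feats <- rbind(
    do.call(rbind, lapply(pos, function(x) c(x$gene_cls, x$peak_cls))),
    do.call(rbind, lapply(neg, function(x) c(x$gene_cls, x$peak_cls))))
  logits <- sweep(feats %*% w$Wm, 2L, w$bm, "+")
  labels <- rep(c(2L, 1L), each = N)
  lse <- apply(logits, 1L, function(r) max(r) + log(sum(exp(r - max(r)))))
  loss <- mean(lse - logits[cbind(seq_len(2 * N), labels)])
  list(loss = loss, logits = logits, labels = labels, negatives = negatives)
}

# hard negatives: P(j | i) proportional to softmax of CLS cosine sim, j != i
sample_hard_negatives <- function(gcls, pcls, tau, seed) {
  N <- nrow(gcls)
  l2 <- function(m) m / pmax(sqrt(rowSums(m^2)), 1e-12)
  S <- tcrossprod(l2(gcls), l2(pcls)) / tau
  set.seed(seed)
  vapply(seq_len(N), function(i) {
    p <- exp(S[i, ] - max(S[i, -i]))
    p[i] <- 0
    sample.int(N, 1L, prob = p / sum(p))
  }, integer(1))
}

# full eval-mode forward for one cell (or one mismatched pair)
decoder_cell_forward <- function(gtok, ptok, msub, dparams) {
  w <- dparams$w
  g <- prepend_cls(gtok, w$cls_rna)
  p <- prepend_cls(ptok, w$cls_atac)
  sg <- self_attention(g, dparams)$hidden
  c1 <- cross_attention(sg, p, msub, dparams)
  c2 <- cross_attention(p, sg, t(msub), dparams)
  list(gene_cls = c1$hidden[1L, ], peak_cls = c2$hidden[1L, ],
       attn_rna = c1$weights[1L, ],   # CLS attention over (CLS, peaks)
       attn_atac = c2$weights[1L, ])  # CLS attention over (CLS, genes)
}

## ---- global attention extraction ---------------------------------------

#' Contract CLS attention rows into the global gene-peak attention matrix
#'
#' \code{Global[g, p] = sum_cells attn_atac[cell, g] * attn_rna[cell, p]}
#' where \code{attn_rna} (N x (P+1)) is the gene-side CLS attention over
#' peaks and \code{attn_atac} (N x (G+1)) the peak-side CLS attention over
#' genes. The CLS row/column are dropped and masked pairs forced to zero.
#'
#' @param cls_attn_rna N x (P+1) matrix.
#' @param cls_attn_atac N x (G+1) matrix.
#' @param mask optional \code{attention_mask} used to zero masked pairs and
#'   attach feature identifiers.
#' @return Object of class \code{global_attention}: \code{values} (G x P,
#'   non-negative), \code{gene_ids}, \code{peak_ids}.
#' @export
extract_global_attention <- function(cls_attn_rna, cls_attn_atac,
                                     mask = NULL) {
  if (nrow(cls_attn_rna) != nrow(cls_attn_atac))
    stop("attention matrices must cover the same cells")
  full <- crossprod(cls_attn_atac, cls_attn_rna)   # (G+1) x (P+1)
  values <- full[-1L, -1L, drop = FALSE]
  gene_ids <- paste0("gene", seq_len(nrow(values)))
  peak_ids <- paste0("peak", seq_len(ncol(values)))
  if (!is.null(mask)) {
    values[mask$values[-1L, -1L, drop = FALSE] < 0] <- 0
    gene_ids <- mask$gene_ids
    peak_ids <- mask$peak_ids
  }
  rownames(values) <- gene_ids
  colnames(values) <- peak_ids
  structure(list(values = values, gene_ids = gene_ids, peak_ids = peak_ids),
            class = "global_attention")
}

#' @export
print.global_attention <- function(x, ...) {
  cat(sprintf("global_attention: %d genes x %d peaks, %d non-zero\n",
              nrow(x$values), ncol(x$values), sum(x$values > 0)))
  invisible(x)
}

## ---- training -----------------------------------------------------------

#' Decoder training configuration
#'
#' @param epochs training epochs (5 by default).
#' @param batch_size mini-batch size.
#' @param lr_start,lr_end learning-rate schedule endpoints.
#' @param tau_cls CLS contrastive temperature.
#' @param heads attention heads.
#' @param freeze_encoder if TRUE the encoder embedding tables are not
#'   updated during decoder training (fine-tuning updates them by
#'   default).
#' @param seed RNG seed.
#' @return list of class \code{decoder_config}.
#' @export
decoder_config <- function(epochs = 5L, batch_size = 32L, lr_start = 1e-4,
                           lr_end = 1e-6, tau_cls = 0.1, heads = 1L,
                           freeze_encoder = FALSE, seed = 1L) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_start = lr_start, lr_end = lr_end, tau_cls = tau_cls,
                 heads = as.integer(heads),
                 freeze_encoder = isTRUE(freeze_encoder),
                 seed = as.integer(seed)),
            class = "decoder_config")
}

#' Train the gene-peak interaction decoder
#'
#' Fine-tunes a transformer decoder on top of pretrained encoder embedding
#' tables, minimizing the CLS contrastive loss plus the modality matching
#' loss. Unless \code{freeze_encoder}, gradients also flow into the
#' embedding tables.
#'
#' @param enc_params pretrained \code{encoder_params}.
#' @param proc \code{multiome_processed} data.
#' @param mask an \code{attention_mask} built on \code{proc$genes} /
#'   \code{proc$peaks}.
#' @param config a [decoder_config()].
#' @param verbose print per-epoch losses.
#' @return list with \code{dparams} (trained \code{decoder_params}),
#'   \code{enc_params} (possibly fine-tuned) and \code{history}.
#' @export
train_decoder <- function(enc_params, proc, mask,
                          config = decoder_config(), verbose = FALSE) {
  N <- nrow(proc$rna_norm)
  dparams <- init_decoder_params(enc_params$d, config$tau_cls,
                                 config$heads, seed = config$seed)
  set.seed(config$seed + 1L)
  trainables <- list(dec = dparams$w)
  if (!config$freeze_encoder)
    trainables$emb <- list(E_rna = enc_params$w$teacher_rna$E,
                           E_atac = enc_params$w$teacher_atac$E)
  opt <- adam_new(trainables)
  history <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_schedule(epoch, config$epochs, config$lr_start, config$lr_end)
    ord <- sample.int(N)
    starts <- seq(1L, N, by = config$batch_size)
    bl <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      cells <- ord[starts[bi]:min(N, starts[bi] + config$batch_size - 1L)]
      st <- decoder_step(trainables, enc_params, proc, mask, cells,
                         config, lr, opt)
      trainables <- st$trainables; opt <- st$opt
      bl[bi] <- st$loss
      if (!is.finite(st$loss))
        stop("non-finite decoder loss at epoch ", epoch, ", batch ", bi)
    }
    history[epoch] <- mean(bl)
    if (verbose)
      message(sprintf("decoder epoch %d/%d  loss %.4f", epoch,
                      config$epochs, history[epoch]))
  }
  dparams$w <- trainables$dec
  if (!config$freeze_encoder) {
    enc_params$w$teacher_rna$E <- trainables$emb$E_rna
    enc_params$w$teacher_atac$E <- trainables$emb$E_atac
  }
  list(dparams = dparams, enc_params = enc_params, history = history)
}

# one fine-tuning step on a mini-batch of cells
decoder_step <- function(trainables, enc_params, proc, mask, cells, config,
                         lr, opt) {
  nb <- length(cells)
  batch <- proc$encoded
  tp <- tp_new(4096L)
  ids <- tp_leaves(tp, trainables)
  e_rna <- if (is.null(ids$emb)) tp_leaf(tp, enc_params$w$teacher_rna$E)
           else ids$emb$E_rna
  e_atac <- if (is.null(ids$emb)) tp_leaf(tp, enc_params$w$teacher_atac$E)
            else ids$emb$E_atac
  dd <- ncol(enc_params$w$teacher_rna$E)

  # per-cell projected tensors, computed once and shared between the
  # positive pass and any negative pair the cell participates in
  project <- function(ci) {
    gi <- batch$gene_indices[[ci]]; gv <- batch$gene_values[[ci]]
    pj <- batch$peak_indices[[ci]]; pv <- batch$peak_values[[ci]]
    g0 <- tp_mul_colvec(tp, tp_rows(tp, e_rna, gi), tp_leaf(tp, gv))
    p0 <- tp_mul_colvec(tp, tp_rows(tp, e_atac, pj), tp_leaf(tp, pv))
    g <- tp_vcat(tp, tp_reshape_row(tp, ids$dec$cls_rna), g0)
    p <- tp_vcat(tp, tp_reshape_row(tp, ids$dec$cls_atac), p0)
    sg <- tape_attend(tp, tp_matmul(tp, g, ids$dec$Wq_s),
                      tp_matmul(tp, g, ids$dec$Wk_s),
                      tp_matmul(tp, g, ids$dec$Wv_s), dd, NULL)$hidden
    list(gidx = gi, pidx = pj,
         q1 = tp_matmul(tp, sg, ids$dec$Wq_c),      # gene-side queries
         k1 = tp_matmul(tp, p, ids$dec$Wk_c),       # peak-side keys
         v1 = tp_matmul(tp, p, ids$dec$Wv_c),       # peak-side values
         q2 = tp_matmul(tp, p, ids$dec$Wq_c),       # peak-side queries
         k2 = tp_matmul(tp, sg, ids$dec$Wk_c),      # gene-side keys
         v2 = tp_matmul(tp, sg, ids$dec$Wv_c))      # gene-side values
  }

  # cross passes for a (gene side of pi, peak side of pj) pairing
  fwd <- function(pi_, pj_) {
    msub <- mask_subset(mask, pi_$gidx, pj_$pidx)
    c1 <- tape_attend(tp, pi_$q1, pj_$k1, pj_$v1, dd, msub)
    c2 <- tape_attend(tp, pj_$q2, pi_$k2, pi_$v2, dd, t(msub))
    list(gcls = tp_rows(tp, c1$hidden, 1L), pcls = tp_rows(tp, c2$hidden, 1L))
  }

  proj <- lapply(cells, project)
  pos <- lapply(proj, function(pc) fwd(pc, pc))
  gmat <- Reduce(function(a, b) tp_vcat(tp, a, b),
                 lapply(pos, `[[`, "gcls"))
  pmat <- Reduce(function(a, b) tp_vcat(tp, a, b),
                 lapply(pos, `[[`, "pcls"))
  cls_loss <- tape_nt_xent(tp, gmat, pmat, config$tau_cls)

  negatives <- sample_hard_negatives(tp_val(tp, gmat), tp_val(tp, pmat),
                                     config$tau_cls,
                                     seed = sample.int(.Machine$integer.max, 1))
  neg <- lapply(seq_len(nb), function(i)
    fwd(proj[[i]], proj[[negatives[i]]]))
  feat_rows <- c(lapply(pos, function(x) tp_hcat(tp, x$gcls, x$pcls)),
                 lapply(neg, function(x) tp_hcat(tp, x$gcls, x$pcls)))
  feats <- Reduce(function(a, b) tp_vcat(tp, a, b), feat_rows)
  logits <- tp_add_rowvec(tp, tp_matmul(tp, feats, ids$dec$Wm), ids$dec$bm)
  labels <- rep(c(2L, 1L), each = nb)
  lse <- tp_logsumexp_rows(tp, logits)
  picked <- tp_extract(tp, logits, cbind(seq_len(2L * nb), labels))
  match_loss <- tp_mean(tp, tp_sub(tp, lse, picked))

  loss <- tp_add(tp, cls_loss, match_loss)
  grads <- tp_backward(tp, loss)
  g <- tp_collect(tp, grads, ids, trainables)
  st <- adam_step(opt, trainables, g, lr = lr)
  list(trainables = st$params, opt = st$opt, loss = tp_val(tp, loss))
}

# attention block on the tape; mask is a constant additive matrix
tape_attend <- function(tp, q, k, v, d, mask) {
  scores <- tp_matmul(tp, q, k, transb = TRUE)
  if (!is.null(mask)) scores <- tp_addc(tp, scores, mask)
  a <- tp_softmax_rows(tp, tp_scale(tp, scores, 1 / sqrt(d)))
  list(hidden = tp_matmul(tp, a, v), weights = a)
}

#' Eval-mode decoder pass: CLS attention and global attention
#'
#' Runs the trained decoder over all cells, assembles the dense CLS
#' attention matrices (absent tokens get zero attention) and contracts
#' them into the global gene-peak attention matrix.
#'
#' @param dparams trained \code{decoder_params}.
#' @param enc_params (fine-tuned) \code{encoder_params}.
#' @param proc \code{multiome_processed} data.
#' @param mask the \code{attention_mask} used during training.
#' @return list with \code{global} (a \code{global_attention}),
#'   \code{cls_attn_rna} (N x (P+1)), \code{cls_attn_atac} (N x (G+1)).
#' @export
decoder_attention <- function(dparams, enc_params, proc, mask) {
  batch <- proc$encoded
  N <- length(batch$gene_indices)
  G <- ncol(proc$rna_norm); P <- ncol(proc$atac_norm)
  attn_rna <- matrix(0, N, P + 1L)
  attn_atac <- matrix(0, N, G + 1L)
  for (i in seq_len(N)) {
    tk <- cell_tokens(enc_params, batch, i)
    out <- decoder_cell_forward(tk$gene, tk$peak,
                                mask_subset(mask, tk$gidx, tk$pidx), dparams)
    attn_rna[i, c(1L, tk$pidx + 1L)] <- out$attn_rna
    attn_atac[i, c(1L, tk$gidx + 1L)] <- out$attn_atac
  }
  list(global = extract_global_attention(attn_rna, attn_atac, mask),
       cls_attn_rna = attn_rna, cls_attn_atac = attn_atac)
}

#' Export the unmasked entries of a global attention matrix as a table
#'
#' @param global a \code{global_attention}.
#' @param mask the \code{attention_mask} (defines the candidate pairs).
#' @return data.frame with \code{gene_id}, \code{peak_id}, \code{weight}.
#' @export
global_attention_table <- function(global, mask) {
  un <- which(mask$values[-1L, -1L, drop = FALSE] >= 0, arr.ind = TRUE)
  data.frame(gene_id = global$gene_ids[un[, 1]],
             peak_id = global$peak_ids[un[, 2]],
             weight = global$values[un],
             stringsAsFactors = FALSE)
}
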