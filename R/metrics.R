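# Integration and prediction metric suite.
#
# All neighbor-based metrics use Euclidean distance on the embedding and
# k = 30 neighbors by default. Bounded metrics live in [0, 1].

euclid_dist <- function(A, B = A) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

# indices of the k nearest rows of the same matrix (self excluded)
knn_index <- function(Z, k) {
  D <- euclid_dist(Z)
  diag(D) <- Inf
  nn <- apply(D, 1L, function(r) order(r)[seq_len(k)])
  if (k == 1L) matrix(nn, ncol = 1L) else t(nn)
}

#' Fraction of samples closer than the true match (FOSCTTM)
#'
#' For each cell in each direction, the fraction of other-modality cells
#' strictly closer (Euclidean) than the cell's true cross-modal match,
#' averaged over all cells and both directions. 0 = perfect alignment,
#' 0.5 = random.
#'
#' @param Z_a,Z_b paired N x d embeddings, N >= 2.
#' @return Scalar in \code{[0, 1]}.
#' @export
foscttm <- function(Z_a, Z_b) {
  N <- nrow(Z_a)
  if (N < 2) stop("FOSCTTM needs at least 2 cells")
  D <- euclid_dist(Z_a, Z_b)
  dt <- diag(D)
  f_ab <- (rowSums(D < dt) ) / (N - 1)
  f_ba <- (colSums(D < rep(dt, each = N)) ) / (N - 1)
  mean(c(f_ab, f_ba))
}

#' Mean average precision of cell-type neighborhoods
#'
#' Per cell, the average precision of same-type cells among its k nearest
#' neighbors (self excluded), averaged over cells. Cells with no same-type
#' neighbor in the k-list contribute 0.
#'
#' @param Z embedding matrix (e.g. the joint embedding).
#' @param cell_types label per row.
#' @param k neighborhood size.
#' @return Scalar in \code{[0, 1]}.
#' @export
mean_average_precision <- function(Z, cell_types, k = 30L) {
  if (length(unique(cell_types)) < 2) {
    warning("single cell type: MAP is trivially 1")
    return(1)
  }
  k <- min(k, nrow(Z) - 1L)
  nn <- knn_index(Z, k)
  ap <- vapply(seq_len(nrow(Z)), function(i) {
    hit <- cell_types[nn[i, ]] == cell_types[i]
    if (!any(hit)) return(0)
    mean(cumsum(hit)[hit] / which(hit))
  }, numeric(1))
  mean(ap)
}

#' Cell-type and modality silhouette scores
#'
#' Cell-type ASW is the average silhouette width of the cell-type labeling,
#' rescaled to \code{[0, 1]} as \code{(asw + 1) / 2}. Batch (modality) ASW
#' follows the scIB formulation: within each cell type, silhouettes are
#' computed for the modality labeling and scored as \code{1 - |s|} per
#' cell; the within-type means are averaged. 1 = modalities perfectly
#' mixed inside each cell type.
#'
#' @param Z embedding matrix (rows = cells across modalities).
#' @param cell_types,modality_labels label per row.
#' @return list with \code{cell_type_asw} and \code{batch_asw}.
#' @export
silhouette_scores <- function(Z, cell_types, modality_labels) {
  if (length(unique(cell_types)) < 2 || length(unique(modality_labels)) < 2)
    stop("need at least 2 cell types and 2 modalities")
  D <- stats::dist(Z)
  sil <- cluster::silhouette(as.integer(factor(cell_types)), D)
  ct_asw <- (mean(sil[, "sil_width"]) + 1) / 2
  per_type <- vapply(unique(cell_types), function(ct) {
    i <- which(cell_types == ct)
    m <- modality_labels[i]
    if (length(unique(m)) < 2 || length(i) < 3) return(NA_real_)
    s <- cluster::silhouette(as.integer(factor(m)),
                             stats::dist(Z[i, , drop = FALSE]))
    mean(1 - abs(s[, "sil_width"]))
  }, numeric(1))
  list(cell_type_asw = ct_asw,
       batch_asw = mean(per_type, na.rm = TRUE))
}

#' Neighbor consistency between unimodal and integrated embeddings
#'
#' Mean Jaccard overlap of each cell's k-nearest-neighbor set before
#' (unimodal embedding) and after integration, averaged over cells. When a
#' list of pre-embeddings is given (one per modality, each row-aligned with
#' the matching block of \code{Z_post}), the per-modality scores are
#' averaged.
#'
#' @param Z_post integrated embedding for one modality's cells
#'   (or a modality block).
#' @param Z_pre unimodal embedding, row-aligned with \code{Z_post}; or a
#'   list of such matrices paired with a list in \code{Z_post}.
#' @param k neighborhood size; must be < N.
#' @return Scalar in \code{[0, 1]}.
#' @export
neighbor_consistency <- function(Z_post, Z_pre, k = 30L) {
  if (is.list(Z_pre)) {
    return(mean(mapply(neighbor_consistency, Z_post, Z_pre,
                       MoreArgs = list(k = k))))
  }
  N <- nrow(Z_post)
  if (k >= N) stop("k must be smaller than the number of cells")
  nn_post <- knn_index(Z_post, k)
  nn_pre <- knn_index(as.matrix(Z_pre), k)
  mean(vapply(seq_len(N), function(i) {
    a <- nn_post[i, ]; b <- nn_pre[i, ]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1)))
}

#' Seurat alignment score
#'
#' Subsamples modalities to equal size, counts same-modality cells among
#' each cell's k nearest neighbors in the subsample, and rescales so that
#' perfectly mixed modalities score about 1 and fully separated modalities
#' about 0. Clipped to \code{[0, 1]}.
#'
#' @param Z embedding matrix over all modalities' cells.
#' @param modality_labels modality per row (>= 2 distinct values).
#' @param k neighborhood size.
#' @param seed subsampling seed.
#' @return Scalar in \code{[0, 1]}.
#' @export
seurat_alignment_score <- function(Z, modality_labels, k = 30L, seed = 0L) {
  groups <- split(seq_along(modality_labels), modality_labels)
  M <- length(groups)
  if (M < 2) stop("need at least 2 modalities")
  n_min <- min(lengths(groups))
  set.seed(seed)
  keep <- unlist(lapply(groups, function(g) sample(g, n_min)))
  Zs <- Z[keep, , drop = FALSE]
  lab <- modality_labels[keep]
  k <- min(k, nrow(Zs) - 1L)
  nn <- knn_index(Zs, k)
  same <- vapply(seq_len(nrow(Zs)), function(i)
    sum(lab[nn[i, ]] == lab[i]), numeric(1))
  xbar <- mean(same)
  score <- 1 - (xbar - k / M) / (k - k / M)
  min(1, max(0, score))
}

#' Graph connectivity of cell types
#'
#' For each cell type, the fraction of its cells in the largest connected
#' component of the type-restricted k-nearest-neighbor graph; averaged over
#' types. 1 when every type forms a single connected cluster across
#' modalities.
#'
#' @param Z embedding matrix.
#' @param cell_types label per row.
#' @param k neighborhood size.
#' @return Scalar in \code{[0, 1]}.
#' @export
graph_connectivity <- function(Z, cell_types, k = 30L) {
  per_type <- vapply(unique(cell_types), function(ct) {
    i <- which(cell_types == ct)
    n <- length(i)
    if (n == 1) return(1)
    kk <- min(k, n - 1L)
    nn <- knn_index(Z[i, , drop = FALSE], kk)
    edges <- cbind(rep(seq_len(n), each = kk), as.vector(t(nn)))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    max(igraph::components(g)$csize) / n
  }, numeric(1))
  mean(per_type)
}

#' Composite integration scores
#'
#' Biology conservation averages MAP, cell-type ASW and neighbor
#' consistency; omics mixing averages the Seurat alignment score, batch ASW
#' and graph connectivity; the overall score is the weighted average
#' \code{0.6 * bio + 0.4 * omics}. When \code{peer_values} (a data.frame or
#' matrix of the six components across methods) is supplied, each component
#' is min-max scaled over the peer set first; with a single method the
#' scaling is the identity.
#'
#' @param components named list or vector with \code{map},
#'   \code{cell_type_asw}, \code{nc}, \code{sas}, \code{batch_asw},
#'   \code{gc}.
#' @param peer_values optional peers for min-max scaling (rows = methods,
#'   named columns as above).
#' @return list with \code{bio}, \code{omics}, \code{overall}.
#' @export
composite_scores <- function(components, peer_values = NULL) {
  need <- c("map", "cell_type_asw", "nc", "sas", "batch_asw", "gc")
  components <- unlist(components)[need]
  if (anyNA(components))
    stop("missing components: ", paste(need[is.na(components)], collapse = ", "))
  sc <- components
  if (!is.null(peer_values)) {
    pv <- as.matrix(as.data.frame(peer_values)[, need, drop = FALSE])
    for (nm in need) {
      lo <- min(pv[, nm], components[nm]); hi <- max(pv[, nm], components[nm])
      sc[nm] <- if (hi > lo) (components[nm] - lo) / (hi - lo) else 1
    }
  }
  bio <- mean(sc[c("map", "cell_type_asw", "nc")])
  omics <- mean(sc[c("sas", "batch_asw", "gc")])
  list(bio = bio, omics = omics, overall = 0.6 * bio + 0.4 * omics)
}

#' Cross-modal prediction metrics
#'
#' Global root-mean-square error plus the mean per-gene Pearson and
#' Spearman correlations across cells; genes constant in either matrix are
#' excluded from the correlation means (their count is reported).
#'
#' @param pred,truth N x G matrices of predicted and measured (normalized)
#'   expression.
#' @return list with \code{rmse}, \code{pearson_genewise},
#'   \code{spearman_genewise}, \code{n_constant_genes}.
#' @export
prediction_metrics <- function(pred, truth) {
  stopifnot(identical(dim(pred), dim(truth)))
  rmse <- sqrt(mean((pred - truth)^2))
  sd0 <- function(m) apply(m, 2L, stats::sd) == 0
  const <- sd0(pred) | sd0(truth)
  if (all(const)) stop("all genes constant: correlations undefined")
  use <- which(!const)
  pear <- vapply(use, function(j) stats::cor(pred[, j], truth[, j]), numeric(1))
  spear <- vapply(use, function(j)
    stats::cor(pred[, j], truth[, j], method = "spearman"), numeric(1))
  list(rmse = rmse, pearson_genewise = mean(pear),
       spearman_genewise = mean(spear), n_constant_genes = sum(const))
}

#' Full integration metric report
#'
#' Computes every integration metric for an embedding set plus the
#' composite scores, and optionally the prediction block.
#'
#' @param emb an \code{embedding_set} (see [compute_embeddings()]).
#' @param cell_types per-cell labels (length N; reused for both modality
#'   blocks of the joint embedding).
#' @param Z_pre optional list of unimodal pre-integration embeddings
#'   (RNA, ATAC) for neighbor consistency; defaults to PCA computed from
#'   the embeddings' source data when supplied via \code{proc}.
#' @param proc optional \code{multiome_processed} used to build default
#'   unimodal PCA embeddings.
#' @param k neighborhood size.
#' @return list of class \code{metric_report}.
#' @export
metric_report <- function(emb, cell_types, Z_pre = NULL, proc = NULL,
                          k = 30L) {
  N <- nrow(emb$Z_teacher_RNA)
  joint <- emb$Z_joint
  types2 <- rep(cell_types, 2)
  modal <- rep(c("RNA", "ATAC"), each = N)
  fos <- foscttm(emb$Z_teacher_RNA, emb$Z_teacher_ATAC)
  mapv <- mean_average_precision(joint, types2, k)
  sil <- silhouette_scores(joint, types2, modal)
  if (is.null(Z_pre) && !is.null(proc)) {
    pca <- function(m, dmax = 20L) {
      p <- stats::prcomp(as.matrix(m), rank. = min(dmax, ncol(m), nrow(m)))
      p$x
    }
    Z_pre <- list(pca(proc$rna_norm), pca(proc$atac_norm))
  }
  nc <- if (!is.null(Z_pre))
    neighbor_consistency(list(emb$Z_teacher_RNA, emb$Z_teacher_ATAC),
                         Z_pre, k = min(k, N - 1L))
  else NA_real_
  sas <- seurat_alignment_score(joint, modal, k)
  gc <- graph_connectivity(joint, types2, k)
  au <- alignment_uniformity(emb$Z_teacher_RNA, emb$Z_teacher_ATAC)
  comp <- if (!is.na(nc))
    composite_scores(list(map = mapv, cell_type_asw = sil$cell_type_asw,
                          nc = nc, sas = sas, batch_asw = sil$batch_asw,
                          gc = gc))
  else list(bio = NA_real_, omics = NA_real_, overall = NA_real_)
  structure(list(map = mapv, cell_type_asw = sil$cell_type_asw,
                 batch_asw = sil$batch_asw, nc = nc, sas = sas, gc = gc,
                 foscttm = fos, alignment = au$align,
                 uniformity = au$uniform,
                 biology_conservation = comp$bio, omics_mixing = comp$omics,
                 overall = comp$overall),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("metric_report\n")
  for (nm in names(x))
    cat(sprintf("  %-22s %s\n", nm,
                ifelse(is.na(x[[nm]]), "NA", sprintf("%.4f", x[[nm]]))))
  invisible(x)
}
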