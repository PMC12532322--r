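#' Filter features by detection rate
#'
#' Keeps a feature iff it is non-zero in at least
#' \code{ceiling(min_cell_frac * N)} cells; the default drops genes or peaks
#' detected in fewer than 5\% of cells. Column order is preserved.
#'
#' @param counts cell x feature matrix (sparse or dense).
#' @param min_cell_frac minimum fraction of cells, in \code{[0, 1]}.
#' @return list with \code{matrix} (filtered) and \code{kept}
#'   (column indices retained).
#' @export
filter_features <- function(counts, min_cell_frac = 0.05) {
  stopifnot(min_cell_frac >= 0, min_cell_frac <= 1)
  counts <- as_csparse(counts)
  need <- ceiling(min_cell_frac * nrow(counts))
  nnz <- Matrix::colSums(counts != 0)
  kept <- which(nnz >= need)
  if (length(kept) == 0) stop("no features survive the detection filter")
  list(matrix = counts[, kept, drop = FALSE], kept = kept)
}

#' Depth-normalize and log-transform counts
#'
#' Scales each cell to a total of \code{target} counts (10,000 by default),
#' then applies \code{log1p}. All-zero cells are left at zero with a
#' warning; they carry no depth information to normalize.
#'
#' @param counts cell x feature non-negative matrix.
#' @param target per-cell total after scaling.
#' @return Sparse normalized matrix of the same shape.
#' @export
normalize_log <- function(counts, target = 1e4) {
  counts <- as_csparse(counts)
  if (length(counts@x) && min(counts@x) < 0)
    stop("counts must be non-negative")
  tot <- Matrix::rowSums(counts)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero cell(s) left unnormalized")
    tot[zero] <- 1
  }
  scaled <- Matrix::Diagonal(x = target / tot) %*% counts
  out <- as_csparse(scaled)
  out@x <- log1p(out@x)
  out
}

#' Select highly variable genes
#'
#' Ranks genes by mean-binned normalized dispersion: per gene, the mean and
#' dispersion (variance/mean) of \code{expm1(normalized)} are computed,
#' genes are grouped into \code{n_bins} equal-frequency mean bins, and the
#' dispersion is z-scored within each bin. The top \code{n_top} genes by
#' normalized dispersion are returned (ties broken by gene index), sorted.
#'
#' @param normalized cell x gene log-normalized matrix
#'   (see [normalize_log()]).
#' @param n_top number of genes to keep; must not exceed the gene count.
#' @param n_bins number of mean bins for dispersion normalization.
#' @return Sorted integer vector of selected gene column indices.
#' @export
select_hvg <- function(normalized, n_top = 2000, n_bins = 20) {
  G <- ncol(normalized)
  if (n_top > G) stop("n_top exceeds the number of genes")
  x <- as_csparse(normalized)
  x@x <- expm1(x@x)
  mu <- Matrix::colMeans(x)
  ex2 <- Matrix::colMeans(x^2)
  v <- pmax(0, (ex2 - mu^2) * nrow(x) / max(1, nrow(x) - 1))
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- as.integer(cut(rank(mu, ties.method = "first"),
                         breaks = min(n_bins, G), labels = FALSE))
  zd <- disp
  gmu <- mean(disp); gsd <- stats::sd(disp)
  for (b in unique(bins)) {
    i <- bins == b
    s <- stats::sd(disp[i])
    zd[i] <- if (is.na(s) || s == 0) {
      # singleton or constant bin: fall back to the global z-score
      if (is.na(gsd) || gsd == 0) 0 else (disp[i] - gmu) / gsd
    } else (disp[i] - mean(disp[i])) / s
  }
  ord <- order(-zd, seq_len(G))
  sort(ord[seq_len(n_top)])
}

#' Drop features on sex chromosomes
#'
#' @param features data.frame with a \code{chrom} column (gene or peak
#'   annotation).
#' @param sex_chroms chromosome names treated as sex chromosomes.
#' @return Integer indices of the retained (autosomal) features.
#' @export
remove_sex_chromosomes <- function(features,
                                   sex_chroms = c("chrX", "chrY", "X", "Y")) {
  which(!(features$chrom %in% sex_chroms))
}

#' Sparse per-cell index/value encoding
#'
#' Converts row-aligned normalized matrices to the per-cell index/count
#' representation consumed by the encoders: for each cell, the sorted
#' indices of its non-zero features and the matching values; zero entries
#' are omitted.
#'
#' @param rna_norm,atac_norm row-aligned cell x feature normalized matrices.
#' @return Object of class \code{encoded_cells} with per-cell lists
#'   \code{gene_indices}, \code{gene_values}, \code{peak_indices},
#'   \code{peak_values}, plus \code{n_genes}, \code{n_peaks}.
#' @export
encode_cells <- function(rna_norm, atac_norm) {
  if (nrow(rna_norm) != nrow(atac_norm))
    stop("modalities must be row-aligned")
  enc1 <- function(m) {
    m <- methods::as(Matrix::t(as_csparse(m)), "CsparseMatrix")
    # column c of t(m) is cell c; @i already sorted within column
    idx <- split_sparse(m)
    idx
  }
  r <- enc1(rna_norm); a <- enc1(atac_norm)
  structure(list(gene_indices = r$indices, gene_values = r$values,
                 peak_indices = a$indices, peak_values = a$values,
                 n_genes = ncol(rna_norm), n_peaks = ncol(atac_norm)),
            class = "encoded_cells")
}

split_sparse <- function(tm) {
  # tm: feature x cell CsparseMatrix; returns per-cell index/value lists
  n <- ncol(tm)
  ptr <- tm@p
  indices <- vector("list", n)
  values <- vector("list", n)
  for (c in seq_len(n)) {
    sel <- if (ptr[c + 1] > ptr[c]) (ptr[c] + 1):ptr[c + 1] else integer(0)
    indices[[c]] <- tm@i[sel] + 1L
    values[[c]] <- tm@x[sel]
  }
  list(indices = indices, values = values)
}

#' Reconstruct dense matrices from an encoding
#'
#' Inverse of [encode_cells()], mainly for round-trip checks.
#'
#' @param enc an \code{encoded_cells} object.
#' @return list with dense \code{rna} and \code{atac} matrices.
#' @export
decode_cells <- function(enc) {
  n <- length(enc$gene_indices)
  rna <- matrix(0, n, enc$n_genes)
  atac <- matrix(0, n, enc$n_peaks)
  for (c in seq_len(n)) {
    rna[c, enc$gene_indices[[c]]] <- enc$gene_values[[c]]
    atac[c, enc$peak_indices[[c]]] <- enc$peak_values[[c]]
  }
  list(rna = rna, atac = atac)
}

#' Full preprocessing pipeline
#'
#' Applies, per modality: detection-rate filter, sex-chromosome removal,
#' depth normalization with log1p, and (RNA only) highly variable gene
#' selection. The requested HVG count is clamped to the number of genes
#' that survive filtering.
#'
#' @param ds a [multiome_dataset()].
#' @param min_cell_frac detection-rate threshold for both modalities.
#' @param n_hvg number of highly variable genes to retain.
#' @param target normalization target per cell.
#' @return Object of class \code{multiome_processed}: normalized matrices
#'   \code{rna_norm}, \code{atac_norm}, subset annotations \code{genes},
#'   \code{peaks}, the untouched \code{cells} table and the sparse
#'   \code{encoded} batch.
#' @export
preprocess_multiome <- function(ds, min_cell_frac = 0.05, n_hvg = 2000,
                                target = 1e4) {
  fr <- filter_features(ds$rna_counts, min_cell_frac)
  genes <- ds$genes[fr$kept, , drop = FALSE]
  keep_g <- remove_sex_chromosomes(genes)
  genes <- genes[keep_g, , drop = FALSE]
  rna <- fr$matrix[, keep_g, drop = FALSE]

  fa <- filter_features(ds$atac_counts, min_cell_frac)
  peaks <- ds$peaks[fa$kept, , drop = FALSE]
  keep_p <- remove_sex_chromosomes(peaks)
  peaks <- peaks[keep_p, , drop = FALSE]
  atac <- fa$matrix[, keep_p, drop = FALSE]

  rna_norm <- normalize_log(rna, target)
  atac_norm <- normalize_log(atac, target)

  n_hvg <- min(n_hvg, ncol(rna_norm))
  hvg <- select_hvg(rna_norm, n_top = n_hvg)
  rna_norm <- rna_norm[, hvg, drop = FALSE]
  genes <- genes[hvg, , drop = FALSE]

  structure(list(rna_norm = rna_norm, atac_norm = atac_norm,
                 genes = genes, peaks = peaks, cells = ds$cells,
                 encoded = encode_cells(rna_norm, atac_norm)),
            class = "multiome_processed")
}

#' @export
print.multiome_processed <- function(x, ...) {
  cat(sprintf("multiome_processed: %d cells, %d genes (HVG), %d peaks\n",
              nrow(x$rna_norm), ncol(x$rna_norm), ncol(x$atac_norm)))
  invisible(x)
}
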