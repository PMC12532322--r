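# Downstream lineage analysis: pseudo-bulk aggregation along pseudotime,
# fuzzy c-means soft clustering of peak profiles, matched-background
# co-occurrence tests for cluster-associated genes, per-cell cross-modal
# cosine states and one-vs-rest differential expression.

#' Pseudo-bulk aggregation along pseudotime
#'
#' Cells are sorted by pseudotime and split into \code{n_groups}
#' equal-size bins (remainder cells go to the earliest bins). Group means
#' are computed per feature and z-standardized across groups; constant
#' features are dropped with a warning.
#'
#' @param features cell x feature matrix (e.g. normalized accessibility).
#' @param pseudotime per-cell pseudotime (complete).
#' @param n_groups number of bins (10 by default).
#' @return Object of class \code{pseudo_bulk}: \code{values}
#'   (groups x features, standardized), \code{means} (raw group means),
#'   \code{groups} (bin of each cell), \code{composition} (cell counts per
#'   type per group, when a \code{cell_type} attribute is supplied via the
#'   \code{cell_types} argument), \code{dropped} (constant features).
#' @param cell_types optional per-cell labels for the composition table.
#' @export
pseudobulk <- function(features, pseudotime, n_groups = 10L,
                       cell_types = NULL) {
  features <- as.matrix(features)
  N <- nrow(features)
  if (anyNA(pseudotime)) stop("pseudotime required for every cell")
  if (n_groups > N) stop("more groups than cells")
  ord <- order(pseudotime)
  base <- N %/% n_groups
  extra <- N %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, extra), rep(0L, n_groups - extra))
  grp <- integer(N)
  grp[ord] <- rep(seq_len(n_groups), times = sizes)
  means <- rowsum(features, grp) / as.vector(sizes)
  sds <- apply(means, 2L, stats::sd)
  mus <- colMeans(means)
  dropped <- which(sds == 0)
  if (length(dropped))
    warning(length(dropped), " constant feature(s) dropped from pseudo-bulk")
  keep <- which(sds > 0)
  values <- sweep(sweep(means[, keep, drop = FALSE], 2L, mus[keep]),
                  2L, sds[keep], "/")
  comp <- if (!is.null(cell_types)) table(group = grp, type = cell_types)
  structure(list(values = values, means = means, groups = grp,
                 sizes = sizes, composition = comp, kept = keep,
                 dropped = dropped),
            class = "pseudo_bulk")
}

# Fuzzifier estimate for fuzzy c-means in the Schwammle-Jensen style used
# for temporal profile clustering: depends on the number of profiles N and
# the profile dimension D.
estimate_fuzzifier <- function(N, D) {
  1 + (1418 / N + 22.05) * D^(-2) +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
}

#' Fuzzy c-means soft clustering of pseudo-bulk profiles
#'
#' Runs fuzzy c-means over a range of cluster numbers on the standardized
#' peak x group profiles, picks the cluster number at the elbow of the
#' minimum inter-centroid distance curve (override with \code{c_fixed}),
#' and extracts each cluster's alpha core (profiles whose maximum
#' membership exceeds \code{acore}).
#'
#' @param pbulk a \code{pseudo_bulk} (profiles are its transposed
#'   standardized values: one row per feature) or a feature x group
#'   matrix.
#' @param c_range candidate cluster numbers (2..20 by default).
#' @param acore alpha-core membership threshold (0.5).
#' @param m fuzzifier; estimated from the data dimensions when NULL.
#' @param c_fixed optional override of the chosen cluster number.
#' @param seed RNG seed (fuzzy c-means is initialization-dependent).
#' @return Object of class \code{soft_cluster}: \code{membership}
#'   (features x c, rows sum to 1), \code{centroids} (c x groups),
#'   \code{chosen_c}, \code{assignment} (argmax cluster),
#'   \code{alpha_core} (list of feature names per cluster), \code{m},
#'   \code{min_centroid_dist} (per candidate c).
#' @export
soft_cluster <- function(pbulk, c_range = 2:20, acore = 0.5, m = NULL,
                         c_fixed = NULL, seed = 1) {
  X <- if (inherits(pbulk, "pseudo_bulk")) t(pbulk$values) else as.matrix(pbulk)
  n <- nrow(X)
  c_range <- c_range[c_range < n]
  if (!length(c_range)) stop("need more profiles than clusters")
  if (is.null(m)) m <- max(1.1, estimate_fuzzifier(n, ncol(X)))
  if (nrow(unique(X)) == 1) {
    warning("degenerate input: all profiles identical, single trivial cluster")
    memb <- matrix(1, n, 1, dimnames = list(rownames(X), NULL))
    return(structure(list(membership = memb,
                          centroids = X[1, , drop = FALSE],
                          chosen_c = 1L,
                          assignment = rep(1L, n),
                          alpha_core = list(rownames(X)), m = m,
                          min_centroid_dist = numeric(0), acore = acore),
                     class = "soft_cluster"))
  }
  run_c <- function(c) {
    set.seed(seed + c)
    e1071::cmeans(X, centers = c, m = m, iter.max = 200L)
  }
  fits <- lapply(c_range, run_c)
  mind <- vapply(fits, function(f) {
    dc <- as.matrix(stats::dist(f$centers))
    min(dc[upper.tri(dc)])
  }, numeric(1))
  chosen_i <- if (!is.null(c_fixed)) match(c_fixed, c_range)
              else elbow_index(mind)
  if (is.na(chosen_i)) stop("c_fixed outside c_range")
  fit <- fits[[chosen_i]]
  memb <- fit$membership
  rownames(memb) <- rownames(X)
  amax <- apply(memb, 1L, max)
  assign_ <- apply(memb, 1L, which.max)
  cores <- lapply(seq_len(ncol(memb)), function(k)
    rownames(memb)[assign_ == k & amax > acore])
  structure(list(membership = memb, centroids = fit$centers,
                 chosen_c = c_range[chosen_i], assignment = assign_,
                 alpha_core = cores, m = m,
                 min_centroid_dist = stats::setNames(mind, c_range),
                 acore = acore),
            class = "soft_cluster")
}

#' @export
print.soft_cluster <- function(x, ...) {
  cat(sprintf("soft_cluster: %d profiles, chosen c=%d (m=%.2f); alpha-core sizes: %s\n",
              nrow(x$membership), x$chosen_c, x$m,
              paste(lengths(x$alpha_core), collapse = ", ")))
  invisible(x)
}

#' Cluster-associated genes by matched-background co-occurrence
#'
#' For each cluster, computes the Spearman correlation between each
#' cluster peak's pseudo-bulk profile and every gene's pseudo-bulk
#' profile, averaging over peaks per gene. The null draws
#' \code{n_background} background peaks per cluster peak, matched on
#' GC-content x coverage decile bins (the focal peak is excluded;
#' under-filled bins are widened to neighboring bins with a warning). A
#' one-sided Wilcoxon rank-sum test compares the cluster correlations
#' against the background correlations per gene; p-values are BH-adjusted
#' and genes ranked by mean correlation.
#'
#' @param cluster_peaks character vector of peak ids in the cluster (e.g.
#'   an alpha core).
#' @param pbulk_peaks \code{pseudo_bulk} of the peaks (standardized).
#' @param pbulk_genes \code{pseudo_bulk} of the genes.
#' @param peak_annotations data.frame with \code{peak_id}, \code{gc} and
#'   \code{coverage} for every peak column of \code{pbulk_peaks}.
#' @param n_background background peaks per cluster peak (50 by default).
#' @param n_bins deciles by default.
#' @param seed sampling seed.
#' @return data.frame, one row per gene, with \code{gene_id},
#'   \code{mean_cor}, \code{bg_mean_cor}, \code{p_value}, \code{p_adj},
#'   ordered by decreasing \code{mean_cor}.
#' @export
cluster_associated_genes <- function(cluster_peaks, pbulk_peaks, pbulk_genes,
                                     peak_annotations, n_background = 50L,
                                     n_bins = 10L, seed = 1) {
  P <- pbulk_peaks$values   # groups x peaks
  Gm <- pbulk_genes$values  # groups x genes
  ann <- peak_annotations
  stopifnot(all(c("peak_id", "gc", "coverage") %in% names(ann)))
  pk_ids <- colnames(P)
  if (is.null(pk_ids)) stop("pbulk_peaks must carry peak ids as colnames")
  ann <- ann[match(pk_ids, ann$peak_id), , drop = FALSE]
  bin_of <- function(x) {
    q <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
    as.integer(cut(x, breaks = q, include.lowest = TRUE))
  }
  gcb <- bin_of(ann$gc); cvb <- bin_of(ann$coverage)
  bin_key <- paste(gcb, cvb)
  set.seed(seed)
  sample_background <- function(focal) {
    i <- match(focal, pk_ids)
    pool <- setdiff(which(bin_key == bin_key[i]), i)
    if (length(pool) < n_background) {
      # widen: same GC decile, any coverage; then any peak
      pool <- union(pool, setdiff(which(gcb == gcb[i]), i))
      if (length(pool) < n_background) {
        warning("background bin widened beyond GC bin for peak ", focal)
        pool <- setdiff(seq_along(pk_ids), i)
      }
    }
    pk_ids[sample(pool, n_background, replace = length(pool) < n_background)]
  }
  cluster_peaks <- intersect(cluster_peaks, pk_ids)
  if (!length(cluster_peaks)) stop("no cluster peaks found in pseudo-bulk")
  bg <- lapply(cluster_peaks, sample_background)
  cor_block <- function(ids)
    stats::cor(P[, ids, drop = FALSE], Gm, method = "spearman")
  rho_cl <- cor_block(cluster_peaks)      # cluster peaks x genes
  rho_bg <- cor_block(unique(unlist(bg))) # background peaks x genes
  bg_rows <- lapply(bg, function(ids) match(ids, rownames(rho_bg)))
  genes <- colnames(Gm)
  res <- lapply(seq_along(genes), function(j) {
    x <- rho_cl[, j]
    y <- rho_bg[unlist(bg_rows), j]
    p <- stats::wilcox.test(x, y, alternative = "greater", exact = FALSE)$p.value
    c(mean_cor = mean(x), bg_mean_cor = mean(y), p_value = p)
  })
  out <- data.frame(gene_id = genes, do.call(rbind, res),
                    stringsAsFactors = FALSE)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out[order(-out$mean_cor), , drop = FALSE]
}

#' Per-cell cross-modal cosine states
#'
#' Cosine similarity between each cell's RNA and ATAC teacher embeddings;
#' cells with cosine distance (1 - similarity) above the cutoff are
#' flagged as cross-modally discordant (actively transitioning states).
#'
#' @param Z_teacher_RNA,Z_teacher_ATAC paired N x d embeddings.
#' @param distance_cutoff flag threshold on cosine distance (0.1).
#' @return data.frame with \code{cosine_sim}, \code{cosine_dist},
#'   \code{flagged}.
#' @export
modality_cosine_states <- function(Z_teacher_RNA, Z_teacher_ATAC,
                                   distance_cutoff = 0.1) {
  n1 <- sqrt(rowSums(Z_teacher_RNA^2))
  n2 <- sqrt(rowSums(Z_teacher_ATAC^2))
  if (any(n1 == 0) || any(n2 == 0)) stop("zero-norm embedding row")
  sim <- rowSums(Z_teacher_RNA * Z_teacher_ATAC) / (n1 * n2)
  dist <- 1 - sim
  data.frame(cosine_sim = sim, cosine_dist = dist,
             flagged = dist > distance_cutoff)
}

#' One-vs-rest differential expression
#'
#' Per gene and group: Wilcoxon rank-sum test of the group's cells against
#' all other cells, natural-log fold change of \code{expm1} means with a
#' pseudocount of 1, BH adjustment across all tests; rows passing both
#' cutoffs are flagged as DEGs. Groups with a single cell are skipped with
#' a warning.
#'
#' @param expr cell x gene normalized (log) expression matrix.
#' @param group_labels per-cell group labels (>= 2 groups).
#' @param p_adj_cutoff adjusted p-value cutoff (0.01).
#' @param logfc_cutoff log fold-change cutoff (0.25).
#' @return data.frame with \code{gene_id}, \code{group}, \code{logfc},
#'   \code{p_value}, \code{p_adj}, \code{significant}.
#' @export
differential_expression <- function(expr, group_labels, p_adj_cutoff = 0.01,
                                    logfc_cutoff = 0.25) {
  expr <- as.matrix(expr)
  groups <- unique(group_labels)
  if (length(groups) < 2) stop("need at least 2 groups")
  gene_ids <- colnames(expr)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(expr)))
  rows <- list()
  for (g in groups) {
    ing <- group_labels == g
    if (sum(ing) < 2) {
      warning("group ", g, " has fewer than 2 cells: skipped")
      next
    }
    mu1 <- colMeans(expm1(expr[ing, , drop = FALSE]))
    mu0 <- colMeans(expm1(expr[!ing, , drop = FALSE]))
    logfc <- log((mu1 + 1) / (mu0 + 1))
    pv <- vapply(seq_len(ncol(expr)), function(j) {
      x <- expr[ing, j]; y <- expr[!ing, j]
      if (all(x == x[1]) && all(y == x[1])) return(1)
      stats::wilcox.test(x, y, exact = FALSE)$p.value
    }, numeric(1))
    rows[[g]] <- data.frame(gene_id = gene_ids, group = g, logfc = logfc,
                            p_value = pv, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adj < p_adj_cutoff & out$logfc > logfc_cutoff
  rownames(out) <- NULL
  out
}
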