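# Promoter-capture Hi-C style evaluation of inferred gene-peak links.
#
# A truth set labels a candidate pair positive when the gene's TSS lies
# within 1 kb of a bait fragment, the peak lies within 1 kb of the same
# record's other end, and the interaction score passes the cutoff in at
# least one cell type. Candidates are all same-chromosome pairs within the
# genomic distance window; attention weights are scored by rank-based
# AUROC with midrank tie handling.

#' Enumerate candidate gene-peak pairs within a distance window
#'
#' All same-chromosome pairs with |TSS - peak midpoint| <=
#' \code{threshold_bp} (inclusive at the boundary).
#'
#' @param genes gene annotation (\code{gene_id}, \code{chrom}, \code{tss}).
#' @param peaks peak annotation (validated; midpoint derived).
#' @param threshold_bp window size in bp.
#' @return data.frame with \code{gene_id}, \code{peak_id},
#'   \code{distance}.
#' @export
candidate_pairs <- function(genes, peaks, threshold_bp = 1.2e6) {
  peaks <- validate_peaks(peaks)
  same <- outer(genes$chrom, peaks$chrom, "==")
  dist <- abs(outer(genes$tss, peaks$midpoint, "-"))
  hit <- which(same & dist <= threshold_bp, arr.ind = TRUE)
  out <- data.frame(gene_id = genes$gene_id[hit[, 1]],
                    peak_id = peaks$peak_id[hit[, 2]],
                    distance = dist[hit], stringsAsFactors = FALSE)
  out[order(out$gene_id, out$peak_id), , drop = FALSE]
}

#' Build a gene-peak interaction truth set from a PCHi-C style table
#'
#' @param pchic data.frame with columns \code{bait_chrom},
#'   \code{bait_start}, \code{bait_end}, \code{oe_chrom}, \code{oe_start},
#'   \code{oe_end} and one or more \code{score_*} columns (one per cell
#'   type).
#' @param genes,peaks feature annotations sharing the pchic table's
#'   assembly (checked by chromosome-name overlap).
#' @param score_cutoff a record supports an interaction when its maximum
#'   score over cell types is >= this cutoff (5 by default).
#' @param proximity_bp maximum distance (inclusive) between TSS and bait,
#'   and between peak and other end (1 kb by default).
#' @param threshold_bp candidate window passed to [candidate_pairs()].
#' @return Object of class \code{interaction_truth}: \code{pairs}
#'   (gene_id, peak_id, label) over all candidates, and provenance counts
#'   \code{n_baited}, \code{n_otherend}, \code{n_pass_score}.
#' @export
build_truth_set <- function(pchic, genes, peaks, score_cutoff = 5,
                            proximity_bp = 1000, threshold_bp = 1.2e6) {
  peaks <- validate_peaks(peaks)
  score_cols <- grep("^score", names(pchic), value = TRUE)
  if (!length(score_cols)) stop("pchic table has no score_* columns")
  if (!length(intersect(unique(pchic$bait_chrom), unique(genes$chrom))))
    stop("no chromosome-name overlap: check genome assemblies")
  smax <- do.call(pmax, pchic[score_cols])
  pass <- smax >= score_cutoff
  rec <- pchic[pass, , drop = FALSE]

  bait <- GenomicRanges::GRanges(rec$bait_chrom,
                                 IRanges::IRanges(rec$bait_start + 1L,
                                                  rec$bait_end))
  oe <- GenomicRanges::GRanges(rec$oe_chrom,
                               IRanges::IRanges(rec$oe_start + 1L,
                                                rec$oe_end))
  tss <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$tss + 1L,
                                                 genes$tss + 1L))
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L,
                                                peaks$end))
  # gene g is baited by record r iff distance(tss_g, bait_r) <= proximity
  gb <- GenomicRanges::findOverlaps(tss, bait, maxgap = proximity_bp)
  po <- GenomicRanges::findOverlaps(pk, oe, maxgap = proximity_bp)
  gene_by_rec <- split(S4Vectors::queryHits(gb), S4Vectors::subjectHits(gb))
  peak_by_rec <- split(S4Vectors::queryHits(po), S4Vectors::subjectHits(po))
  recs <- intersect(names(gene_by_rec), names(peak_by_rec))
  pos <- unique(do.call(rbind, lapply(recs, function(r)
    expand.grid(g = gene_by_rec[[r]], p = peak_by_rec[[r]]))))
  cand <- candidate_pairs(genes, peaks, threshold_bp)
  pos_key <- if (!is.null(pos) && nrow(pos))
    paste(genes$gene_id[pos$g], peaks$peak_id[pos$p]) else character(0)
  cand$label <- as.integer(paste(cand$gene_id, cand$peak_id) %in% pos_key)
  if (!any(cand$label == 1))
    warning("no positive pairs in the truth set")
  structure(list(pairs = cand[c("gene_id", "peak_id", "label")],
                 n_baited = length(unique(unlist(gene_by_rec))),
                 n_otherend = length(unique(unlist(peak_by_rec))),
                 n_pass_score = nrow(rec)),
            class = "interaction_truth")
}

#' @export
print.interaction_truth <- function(x, ...) {
  cat(sprintf("interaction_truth: %d pairs (%d positive); %d scored records, %d baited genes, %d other-end peaks\n",
              nrow(x$pairs), sum(x$pairs$label), x$n_pass_score,
              x$n_baited, x$n_otherend))
  invisible(x)
}

#' Rank-based AUROC with midrank tie handling
#'
#' @param scores numeric scores, higher = more link-like.
#' @param labels binary labels aligned with \code{scores} (or an
#'   \code{interaction_truth}, in which case \code{scores} must be a named
#'   vector or a data.frame with gene_id/peak_id/weight).
#' @return AUROC in \code{[0, 1]}.
#' @export
auroc <- function(scores, labels) {
  if (inherits(labels, "interaction_truth")) {
    tr <- labels$pairs
    if (is.data.frame(scores)) {
      key <- paste(tr$gene_id, tr$peak_id)
      skey <- paste(scores$gene_id, scores$peak_id)
      scores <- scores$weight[match(key, skey)]
      scores[is.na(scores)] <- 0
    }
    labels <- tr$label
  }
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUROC needs both classes")
  r <- rank(scores)   # midranks
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Select top gene-peak pairs by attention weight
#'
#' Quantile mode keeps the top \code{ceiling(frac * n)} pairs, ties broken
#' lexicographically by (gene_id, peak_id); elbow mode finds the knee of
#' the sorted weight curve (maximum distance to the chord between its
#' endpoints) and keeps pairs above it.
#'
#' @param global a \code{global_attention} or a data.frame with
#'   \code{gene_id}, \code{peak_id}, \code{weight}.
#' @param mask \code{attention_mask} (needed when \code{global} is a
#'   \code{global_attention}, to restrict to unmasked pairs).
#' @param frac fraction kept in quantile mode.
#' @param method \code{"quantile"} or \code{"elbow"}.
#' @return data.frame of selected pairs, ordered by decreasing weight.
#' @export
select_top_attention <- function(global, mask = NULL, frac = 0.10,
                                 method = c("quantile", "elbow")) {
  method <- match.arg(method)
  tab <- if (is.data.frame(global)) global
         else global_attention_table(global, mask)
  if (!nrow(tab)) stop("no unmasked pairs to select from")
  ord <- order(-tab$weight, tab$gene_id, tab$peak_id)
  tab <- tab[ord, , drop = FALSE]
  n_keep <- if (method == "quantile") {
    ceiling(frac * nrow(tab))
  } else {
    elbow_index(tab$weight)
  }
  tab[seq_len(n_keep), , drop = FALSE]
}

# knee of a non-increasing curve: point of maximum perpendicular distance
# to the chord joining the first and last point (kneedle-style)
elbow_index <- function(y) {
  n <- length(y)
  if (n < 3) return(n)
  x <- seq_len(n)
  x1 <- 1; y1 <- y[1]; x2 <- n; y2 <- y[n]
  d <- abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  which.max(d)
}

#' Dense peak-associated genes (DPAG)
#'
#' Genes linked to at least \code{min_peaks} distinct peaks among the
#' selected high-attention pairs.
#'
#' @param selected data.frame of selected pairs
#'   (see [select_top_attention()]).
#' @param min_peaks minimum number of distinct peaks (10 by default).
#' @return Character vector of gene ids.
#' @export
dense_peak_associated_genes <- function(selected, min_peaks = 10L) {
  if (!nrow(selected)) return(character(0))
  cnt <- tapply(selected$peak_id, selected$gene_id,
                function(p) length(unique(p)))
  sort(names(cnt)[cnt >= min_peaks])
}
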