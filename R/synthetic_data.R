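# Synthetic paired multiome generator.
#
# Latent model: cells sit on a single pseudotime axis in [0,1] cut into
# n_types contiguous stages. Each regulatory program k has a Gaussian bump
# of activity centred on stage k. Peaks belong to one program and their
# accessibility follows a Bernoulli-Gamma-Poisson cascade on the program
# activity; each gene reads the realized activity of its planted peaks (a
# monotone link), lag genes read the program activity at pseudotime t - dt,
# emulating chromatin opening ahead of transcription.

#' Generate a paired multiome dataset with planted structure
#'
#' Produces matched RNA and ATAC count matrices with planted cell types,
#' gene-peak regulatory links placed within a genomic window, pseudotime,
#' and a configurable fraction of genes whose expression lags the
#' accessibility of their peaks. Deterministic given \code{seed}.
#'
#' @param n_cells,n_genes,n_peaks,n_types problem dimensions. Defaults give
#'   the desk-scale profile used throughout the package's examples and
#'   tests: 600 cells, 300 genes, 600 peaks, 3 types.
#' @param n_links_per_gene planted peaks per gene;
#'   \code{n_genes * n_links_per_gene} must not exceed \code{n_peaks}.
#'   Remaining peaks are decoys placed near genes but driven by their own
#'   (random) program.
#' @param lag_frac fraction of genes whose expression reads program
#'   activity at \code{t - lag_dt} instead of the instantaneous activity of
#'   their peaks.
#' @param lag_dt pseudotime lag for lag genes (pseudotime spans
#'   \code{[0, 1]}).
#' @param noise overdispersion level: 0 means Poisson sampling of the clean
#'   rates; positive values add a Gamma rate multiplier
#'   (\code{cv = noise}) and activity-dependent Bernoulli dropout.
#' @param link_window_bp maximum |TSS - peak midpoint| for planted links.
#' @param seed RNG seed.
#' @return list with \code{dataset} (a [multiome_dataset()]) and
#'   \code{truth} (class \code{sim_truth}: \code{cell_type},
#'   \code{pseudotime}, \code{planted_links}, \code{lag_genes},
#'   \code{program_of_gene}, \code{program_of_peak}, plus copies of the
#'   coordinate tables and the realized sparsity of each modality).
#' @export
generate_multiome <- function(n_cells = 600, n_genes = 300, n_peaks = 600,
                              n_types = 3, n_links_per_gene = 1,
                              lag_frac = 0.1, lag_dt = 0.25, noise = 0.5,
                              link_window_bp = 1.2e6, seed = 1) {
  stopifnot(n_cells > 0, n_genes > 0, n_peaks > 0, n_types > 0,
            lag_frac >= 0, lag_frac <= 1, noise >= 0)
  if (n_links_per_gene * n_genes > n_peaks)
    stop("infeasible link budget: n_links_per_gene * n_genes > n_peaks")
  set.seed(seed)

  ## cells: pseudotime and contiguous stage labels
  pt <- stats::runif(n_cells)
  type_idx <- pmin(n_types, floor(pt * n_types) + 1L)
  cell_type <- sprintf("type%d", type_idx)
  barcode <- sprintf("cell%05d", seq_len(n_cells))

  ## program activity: Gaussian bump per stage along pseudotime
  centers <- (seq_len(n_types) - 0.5) / n_types
  width <- 0.6 / n_types
  act <- function(t, k) exp(-(t - centers[k])^2 / (2 * width^2))

  ## gene coordinates: three autosomes, evenly spaced TSS
  chroms <- paste0("chr", seq_len(3))
  gene_chrom <- chroms[(seq_len(n_genes) - 1) %% 3 + 1]
  gene_rank <- ave(seq_len(n_genes), gene_chrom, FUN = seq_along)
  gene_tss <- 2e6 + (gene_rank - 1) * 2.5e6
  genes <- data.frame(gene_id = sprintf("gene%04d", seq_len(n_genes)),
                      symbol = sprintf("Gene%04d", seq_len(n_genes)),
                      chrom = gene_chrom, tss = as.integer(gene_tss),
                      strand = rep(c("+", "-"), length.out = n_genes),
                      stringsAsFactors = FALSE)

  ## gene programs; linked peaks inherit the gene's program
  program_of_gene <- sample.int(n_types, n_genes, replace = TRUE)
  n_linked <- n_links_per_gene * n_genes
  peak_gene <- c(rep(seq_len(n_genes), each = n_links_per_gene),
                 sample.int(n_genes, n_peaks - n_linked, replace = TRUE))
  is_link <- c(rep(TRUE, n_linked), rep(FALSE, n_peaks - n_linked))
  program_of_peak <- ifelse(is_link, program_of_gene[peak_gene],
                            sample.int(n_types, n_peaks, replace = TRUE))

  ## peak placement near the anchor gene, min 2.5 kb apart on a chromosome
  half <- min(link_window_bp, 1.2e6) - 1e5
  peak_mid <- integer(n_peaks)
  occupied <- lapply(stats::setNames(chroms, chroms), function(x) numeric(0))
  for (p in seq_len(n_peaks)) {
    g <- peak_gene[p]
    ch <- genes$chrom[g]
    for (try in seq_len(200)) {
      mid <- genes$tss[g] + round(stats::runif(1, -half, half))
      if (mid < 1000) next
      if (!length(occupied[[ch]]) || min(abs(occupied[[ch]] - mid)) > 2500) break
    }
    occupied[[ch]] <- c(occupied[[ch]], mid)
    peak_mid[p] <- mid
  }
  peaks <- data.frame(chrom = genes$chrom[peak_gene],
                      start = as.integer(peak_mid - 250L),
                      end = as.integer(peak_mid + 250L),
                      stringsAsFactors = FALSE)
  peaks <- validate_peaks(peaks)
  peaks$gc <- round(stats::runif(n_peaks, 0.3, 0.7), 4)

  ## accessibility: Bernoulli-Gamma-Poisson on program activity
  A <- vapply(seq_len(n_peaks), function(p) act(pt, program_of_peak[p]),
              numeric(n_cells))                      # cells x peaks
  lib_atac <- exp(stats::rnorm(n_cells, 0, 0.3))
  gmult <- if (noise > 0)
    matrix(stats::rgamma(n_cells * n_peaks, shape = 1 / noise^2,
                         scale = noise^2), n_cells, n_peaks)
  else matrix(1, n_cells, n_peaks)
  keep <- if (noise > 0)
    matrix(stats::rbinom(n_cells * n_peaks, 1,
                         pmin(1, 1 - 0.5 * noise * (1 - A))),
           n_cells, n_peaks)
  else matrix(1, n_cells, n_peaks)
  mu_atac <- lib_atac * (0.03 + 1.2 * A) * gmult * keep
  atac_counts <- matrix(stats::rpois(n_cells * n_peaks, mu_atac),
                        n_cells, n_peaks)

  ## expression: genes read the realized activity of their planted peaks;
  ## lag genes read program activity at t - delta_i with a random per-cell
  ## delay (mean lag_dt) -- transcription catches up to chromatin
  ## asynchronously, so the delay is not decodable from the ATAC side
  n_lag <- round(lag_frac * n_genes)
  lag_genes <- sort(sample.int(n_genes, n_lag))
  is_lag <- seq_len(n_genes) %in% lag_genes
  delay <- stats::runif(n_cells, 0, 2 * lag_dt)
  gene_act <- matrix(0, n_cells, n_genes)
  link_rows <- which(is_link)
  for (g in seq_len(n_genes)) {
    own <- link_rows[peak_gene[link_rows] == g]
    coupling <- rowMeans(gmult[, own, drop = FALSE])
    tt <- if (is_lag[g]) pmax(0, pt - delay) else pt
    gene_act[, g] <- act(tt, program_of_gene[g]) * coupling
  }
  lib_rna <- exp(stats::rnorm(n_cells, 0, 0.3))
  # RNA-side overdispersion is milder than the peak-level Gamma: the
  # peak Gamma is the regulatory coupling signal shared with expression,
  # the gene-level one only models residual technical noise
  cv_rna <- noise / 2
  gg <- if (noise > 0)
    matrix(stats::rgamma(n_cells * n_genes, shape = 1 / cv_rna^2,
                         scale = cv_rna^2), n_cells, n_genes)
  else matrix(1, n_cells, n_genes)
  mu_rna <- lib_rna * (0.1 + 5 * gene_act) * gg
  rna_counts <- matrix(stats::rpois(n_cells * n_genes, mu_rna),
                       n_cells, n_genes)

  cells <- data.frame(barcode = barcode, cell_type = cell_type,
                      pseudotime = pt, stringsAsFactors = FALSE)
  ds <- multiome_dataset(rna_counts, atac_counts, genes, peaks, cells)

  planted <- data.frame(gene_id = genes$gene_id[peak_gene[link_rows]],
                        peak_id = peaks$peak_id[link_rows],
                        effect = 4, stringsAsFactors = FALSE)
  stopifnot(all(abs(genes$tss[peak_gene[link_rows]] -
                      peaks$midpoint[link_rows]) <= link_window_bp))
  truth <- structure(list(
    cell_type = cell_type, pseudotime = pt,
    planted_links = planted,
    lag_genes = data.frame(gene_id = genes$gene_id[lag_genes],
                           lag_dt = rep(lag_dt, length(lag_genes)),
                           stringsAsFactors = FALSE),
    lag_delay = delay,
    program_of_gene = program_of_gene, program_of_peak = program_of_peak,
    genes = genes, peaks = peaks,
    sparsity = c(rna = mean(rna_counts == 0), atac = mean(atac_counts == 0))),
    class = "sim_truth")
  list(dataset = ds, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d cells, %d planted links, %d lag genes; sparsity rna %.2f atac %.2f\n",
              length(x$cell_type), nrow(x$planted_links), nrow(x$lag_genes),
              x$sparsity["rna"], x$sparsity["atac"]))
  invisible(x)
}

#' Emit a promoter-capture Hi-C style interaction table from planted truth
#'
#' One row per planted link: the bait straddles the gene TSS, the other end
#' straddles the linked peak, and the interaction score passes the
#' conventional cutoff of 5 in at least one cell-type column. A
#' \code{fp_rate} fraction of additional decoy rows is appended, half with
#' sub-threshold scores and half with anchors that match no TSS/peak.
#'
#' @param truth a \code{sim_truth} from [generate_multiome()].
#' @param fp_rate decoy rows as a fraction of the planted rows.
#' @param seed RNG seed.
#' @return data.frame with columns \code{bait_chrom}, \code{bait_start},
#'   \code{bait_end}, \code{oe_chrom}, \code{oe_start}, \code{oe_end} and
#'   one score column per cell type.
#' @export
generate_pchic_like <- function(truth, fp_rate = 0, seed = 1) {
  set.seed(seed)
  genes <- truth$genes; peaks <- truth$peaks
  pl <- truth$planted_links
  gi <- match(pl$gene_id, genes$gene_id)
  pi <- match(pl$peak_id, peaks$peak_id)
  n <- nrow(pl)
  types <- sort(unique(truth$cell_type))
  mk_scores <- function(n, pass) {
    s <- matrix(stats::runif(n * length(types), 0, 4.9), n, length(types))
    if (pass) {
      hit <- sample.int(length(types), n, replace = TRUE)
      s[cbind(seq_len(n), hit)] <- stats::runif(n, 5, 15)
    }
    colnames(s) <- paste0("score_", types)
    as.data.frame(s)
  }
  pos <- data.frame(bait_chrom = genes$chrom[gi],
                    bait_start = genes$tss[gi] - 400L,
                    bait_end = genes$tss[gi] + 400L,
                    oe_chrom = peaks$chrom[pi],
                    oe_start = peaks$start[pi] - 200L,
                    oe_end = peaks$end[pi] + 200L,
                    stringsAsFactors = FALSE)
  out <- cbind(pos, mk_scores(n, pass = TRUE))
  n_fp <- round(fp_rate * n)
  if (n_fp > 0) {
    gi2 <- sample.int(nrow(genes), n_fp, replace = TRUE)
    pi2 <- sample.int(nrow(peaks), n_fp, replace = TRUE)
    low_score <- seq_len(n_fp) <= n_fp / 2
    fp <- data.frame(bait_chrom = genes$chrom[gi2],
                     bait_start = genes$tss[gi2] - 400L,
                     bait_end = genes$tss[gi2] + 400L,
                     oe_chrom = peaks$chrom[pi2],
                     oe_start = peaks$start[pi2] - 200L,
                     oe_end = peaks$end[pi2] + 200L,
                     stringsAsFactors = FALSE)
    # "unlinked anchor" decoys: shift the bait away from any promoter
    far <- !low_score
    fp$bait_start[far] <- fp$bait_start[far] + 1.2e6
    fp$bait_end[far] <- fp$bait_end[far] + 1.2e6
    sc <- mk_scores(n_fp, pass = FALSE)
    sc[far, ] <- mk_scores(sum(far), pass = TRUE)[seq_len(sum(far)), ]
    out <- rbind(out, cbind(fp, sc))
  }
  rownames(out) <- NULL
  out
}
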