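#' Paired multiome dataset container
#'
#' Bundles row-aligned cell x gene and cell x peak count matrices with their
#' feature annotations and per-cell metadata. Row i of both matrices is the
#' same cell (matched multiome profiling).
#'
#' @param rna_counts cell x gene matrix of non-negative integer counts
#'   (dense or \code{Matrix} sparse).
#' @param atac_counts cell x peak matrix of non-negative integer counts.
#' @param genes data.frame with columns \code{gene_id}, \code{symbol},
#'   \code{chrom}, \code{tss} (0-based bp), \code{strand} (\code{+}/\code{-});
#'   one row per column of \code{rna_counts}.
#' @param peaks data.frame with columns \code{peak_id}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open); one row per column of
#'   \code{atac_counts}. A \code{midpoint} column is derived.
#' @param cells data.frame with column \code{barcode} (unique) and optional
#'   \code{cell_type}, \code{pseudotime}; one row per matrix row.
#' @param paired flag asserting that rows are matched across modalities.
#'
#' @return An object of class \code{multiome_dataset}.
#' @export
multiome_dataset <- function(rna_counts, atac_counts, genes, peaks, cells,
                             paired = TRUE) {
  rna_counts <- as_csparse(rna_counts)
  atac_counts <- as_csparse(atac_counts)
  if (nrow(rna_counts) != nrow(atac_counts))
    stop("rna_counts and atac_counts must have the same number of cells")
  check_counts(rna_counts, "rna_counts")
  check_counts(atac_counts, "atac_counts")
  genes <- validate_genes(genes)
  peaks <- validate_peaks(peaks)
  if (nrow(genes) != ncol(rna_counts))
    stop("gene annotation rows must equal rna_counts columns")
  if (nrow(peaks) != ncol(atac_counts))
    stop("peak annotation rows must equal atac_counts columns")
  cells <- validate_cells(cells, nrow(rna_counts))
  structure(list(rna_counts = rna_counts, atac_counts = atac_counts,
                 genes = genes, peaks = peaks, cells = cells,
                 paired = isTRUE(paired)),
            class = "multiome_dataset")
}

#' @export
print.multiome_dataset <- function(x, ...) {
  cat(sprintf("multiome_dataset: %d cells, %d genes, %d peaks (%s)\n",
              nrow(x$rna_counts), ncol(x$rna_counts), ncol(x$atac_counts),
              if (x$paired) "paired" else "unpaired"))
  invisible(x)
}

check_counts <- function(m, what) {
  x <- if (methods::is(m, "sparseMatrix")) m@x else as.numeric(m)
  if (length(x) && (min(x) < 0 || any(x != floor(x))))
    stop(what, " must contain non-negative integral counts")
  invisible(TRUE)
}

validate_genes <- function(genes) {
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(genes)))
    stop("gene annotation needs columns: ", paste(need, collapse = ", "))
  if (!"symbol" %in% names(genes)) genes$symbol <- genes$gene_id
  if (any(genes$tss < 0)) stop("tss must be >= 0")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  genes
}

validate_peaks <- function(peaks) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(peaks)))
    stop("peak annotation needs columns: ", paste(need, collapse = ", "))
  if (any(peaks$start < 0) || any(peaks$start >= peaks$end))
    stop("peak intervals must satisfy 0 <= start < end")
  if (!"peak_id" %in% names(peaks))
    peaks$peak_id <- sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
  peaks$midpoint <- floor((peaks$start + peaks$end) / 2)
  peaks
}

validate_cells <- function(cells, n) {
  if (!"barcode" %in% names(cells)) stop("cell metadata needs 'barcode'")
  if (nrow(cells) != n) stop("cell metadata rows must equal cell count")
  if (anyDuplicated(cells$barcode)) stop("barcodes must be unique")
  if (!"cell_type" %in% names(cells)) cells$cell_type <- NA_character_
  if (!"pseudotime" %in% names(cells)) cells$pseudotime <- NA_real_
  if (any(!is.na(cells$pseudotime) & cells$pseudotime < 0))
    stop("pseudotime must be >= 0")
  cells
}

## ---- readers / writers ------------------------------------------------

read_mtx_dir <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("no matrix.mtx under ", dir)
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stop("malformed MTX file ", mtx, ": ",
                                         conditionMessage(e)))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  features <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                                header = FALSE, stringsAsFactors = FALSE)[[1]]
  # features x cells on disk (10x layout); cells x features in memory
  if (nrow(m) != length(features) || ncol(m) != length(barcodes))
    stop("MTX dimensions do not match features/barcodes under ", dir)
  m <- Matrix::t(m)
  rownames(m) <- barcodes
  colnames(m) <- features
  m
}

write_mtx_dir <- function(m, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(Matrix::t(m), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "barcodes.tsv"))
  utils::write.table(data.frame(colnames(m)),
                     file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

read_gene_table <- function(path) {
  if (grepl("\\.gtf(\\.gz)?$", path)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GTF requires the rtracklayer package")
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    # GTF is 1-based closed; convert to 0-based: tss = start-1 on '+',
    # end-1 on '-'
    data.frame(gene_id = gr$gene_id,
               symbol = if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id,
               chrom = as.character(GenomicRanges::seqnames(gr)),
               tss = ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                            GenomicRanges::end(gr) - 1L,
                            GenomicRanges::start(gr) - 1L),
               strand = as.character(GenomicRanges::strand(gr)),
               stringsAsFactors = FALSE)
  } else {
    g <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    validate_genes(g)
  }
}

read_peak_bed <- function(path) {
  b <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = b[[1]], start = as.integer(b[[2]]),
                      end = as.integer(b[[3]]), stringsAsFactors = FALSE)
  if (ncol(b) >= 4) peaks$peak_id <- b[[4]]
  validate_peaks(peaks)
}

#' Read a paired multiome dataset from MTX/TSV/BED files
#'
#' Expects two 10x-style directories (\code{matrix.mtx},
#' \code{barcodes.tsv}, \code{features.tsv}; features x cells on disk), a
#' gene table (tab-separated with header columns \code{gene_id},
#' \code{chrom}, \code{tss}, \code{strand}, or a GTF), a BED3+ peak file and
#' an optional cell metadata TSV. Barcodes present in only one modality are
#' dropped with a warning; the intersection is ordered as in the RNA file.
#'
#' @param rna_dir,atac_dir directories with the MTX triplets.
#' @param genes path to the gene annotation table.
#' @param peaks path to the BED peak file.
#' @param cells optional path to a cell metadata TSV with a \code{barcode}
#'   column.
#' @return A [multiome_dataset()].
#' @export
read_mtx_dataset <- function(rna_dir, atac_dir, genes, peaks, cells = NULL) {
  rna <- read_mtx_dir(rna_dir)
  atac <- read_mtx_dir(atac_dir)
  common <- intersect(rownames(rna), rownames(atac))
  if (length(common) == 0)
    stop("no common barcodes between RNA and ATAC: pairing failed")
  if (length(common) < nrow(rna) || length(common) < nrow(atac))
    warning(sprintf("barcode mismatch: keeping %d common cells (RNA %d, ATAC %d)",
                    length(common), nrow(rna), nrow(atac)))
  rna <- rna[common, , drop = FALSE]
  atac <- atac[common, , drop = FALSE]
  gtab <- read_gene_table(genes)
  ptab <- read_peak_bed(peaks)
  ctab <- if (!is.null(cells)) {
    ct <- utils::read.table(cells, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    ct[match(common, ct$barcode), , drop = FALSE]
  } else data.frame(barcode = common, stringsAsFactors = FALSE)
  gtab <- gtab[match(colnames(rna), gtab$gene_id), , drop = FALSE]
  if (anyNA(gtab$gene_id)) stop("gene annotation missing for some features")
  multiome_dataset(rna, atac, gtab, ptab, ctab)
}

#' Write a multiome dataset to MTX/TSV/BED files
#'
#' Inverse of [read_mtx_dataset()]; writes \code{rna/} and \code{atac/} MTX
#' directories plus \code{genes.tsv}, \code{peaks.bed} and \code{cells.tsv}.
#'
#' @param ds a [multiome_dataset()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_mtx_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rna <- ds$rna_counts; atac <- ds$atac_counts
  rownames(rna) <- rownames(atac) <- ds$cells$barcode
  colnames(rna) <- ds$genes$gene_id
  colnames(atac) <- ds$peaks$peak_id
  write_mtx_dir(rna, file.path(dir, "rna"))
  write_mtx_dir(atac, file.path(dir, "atac"))
  utils::write.table(ds$genes[c("gene_id", "symbol", "chrom", "tss", "strand")],
                     file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ds$peaks[c("chrom", "start", "end", "peak_id")],
                     file.path(dir, "peaks.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(ds$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# robust coercion of dense or sparse input to dgCMatrix
as_csparse <- function(m) {
  if (!methods::is(m, "sparseMatrix")) m <- Matrix::Matrix(m, sparse = TRUE)
  methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
}
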