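# Truth-set construction, candidate enumeration, AUROC, top-pair
# selection and dense peak-associated genes.

fixture_path <- function(f) system.file("extdata", f, package = "scDuet")

load_fixture <- function() {
  list(genes = utils::read.table(fixture_path("fixture_genes.tsv"),
                                 header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE),
       peaks = scDuet:::read_peak_bed(fixture_path("fixture_peaks.bed")),
       pchic = utils::read.table(fixture_path("pchic_fixture.tsv"),
                                 header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE))
}

test_that("candidate pairs are same-chromosome pairs within the window", {
  fx <- load_fixture()
  cand <- candidate_pairs(fx$genes, fx$peaks, 1.2e6)
  # hand enumeration: g1-p1 (50,250), g1-p2 (950,250), g2-p1 (749,750),
  # g2-p2 (150,250), g3-p3 (29,750); g3-p4 at 1,350,250 exceeds the window
  expect_setequal(paste(cand$gene_id, cand$peak_id),
                  c("g1 p1", "g1 p2", "g2 p1", "g2 p2", "g3 p3"))
  # exact-boundary distance is included
  g <- data.frame(gene_id = "g", chrom = "c", tss = 0L, strand = "+")
  p <- data.frame(chrom = "c", start = 1199750L, end = 1200250L)
  expect_equal(nrow(candidate_pairs(g, p, 1.2e6)), 1)
  p2 <- data.frame(chrom = "c2", start = 100L, end = 600L)
  expect_equal(nrow(candidate_pairs(g, p2, 1.2e6)), 0)
})

test_that("the 8-row fixture yields exactly the hand-enumerated positives", {
  fx <- load_fixture()
  ts <- build_truth_set(fx$pchic, fx$genes, fx$peaks)
  pos <- ts$pairs[ts$pairs$label == 1, ]
  expect_setequal(paste(pos$gene_id, pos$peak_id),
                  c("g1 p1", "g2 p2", "g3 p3"))
  expect_equal(nrow(ts$pairs), 5)      # labeled over all candidates
  # row order must not matter
  set.seed(41)
  ts2 <- build_truth_set(fx$pchic[sample(nrow(fx$pchic)), ],
                         fx$genes, fx$peaks)
  expect_equal(ts2$pairs[order(ts2$pairs$gene_id, ts2$pairs$peak_id), ],
               ts$pairs[order(ts$pairs$gene_id, ts$pairs$peak_id), ],
               ignore_attr = TRUE)
  # scores below 5 in every cell type never support a positive
  low <- fx$pchic
  low$score_A <- 4.9; low$score_B <- 4.9
  expect_warning(ts3 <- build_truth_set(low, fx$genes, fx$peaks),
                 "no positive")
  expect_equal(sum(ts3$pairs$label), 0)
  # assembly mismatch is caught by chromosome-name overlap
  alt <- fx$genes; alt$chrom <- paste0("scaffold_", alt$chrom)
  expect_error(build_truth_set(fx$pchic, alt, fx$peaks), "assembl")
})

test_that("the TSS-to-bait gap of exactly 1 kb is inclusive", {
  fx <- load_fixture()
  # fixture row 3 places the bait edge exactly 1,000 bp from g3's TSS
  ts <- build_truth_set(fx$pchic, fx$genes, fx$peaks)
  expect_true(any(ts$pairs$gene_id == "g3" & ts$pairs$label == 1))
  # pushing the bait 1 bp farther drops the pair
  shifted <- fx$pchic
  shifted[3, c("bait_start", "bait_end")] <-
    shifted[3, c("bait_start", "bait_end")] - 1L
  ts2 <- build_truth_set(shifted, fx$genes, fx$peaks)
  expect_false(any(ts2$pairs$gene_id == "g3" & ts2$pairs$label == 1))
})

test_that("AUROC handles perfect, inverted, random and tied scores", {
  lab <- rep(c(1, 0), each = 50)
  expect_equal(auroc(c(rnorm(50, 10), rnorm(50, -10)), lab), 1)
  expect_equal(auroc(c(rnorm(50, -10), rnorm(50, 10)), lab), 0)
  set.seed(42)
  sc <- rnorm(200)
  lr <- rbinom(200, 1, 0.5)
  a <- auroc(sc, lr)
  n1 <- sum(lr); n0 <- 200 - n1
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(a - 0.5), 3 * se)
  expect_equal(auroc(rep(1, 10), rep(c(1, 0), 5)), 0.5)  # all tied: midrank
  expect_error(auroc(sc, rep(1, 200)), "both classes")
})

test_that("our midrank AUROC agrees with pROC", {
  set.seed(43)
  sc <- round(rnorm(300), 1)            # ties on purpose
  lab <- rbinom(300, 1, 0.4)
  ours <- auroc(sc, lab)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("top-attention selection honors the quantile, ties and elbow", {
  set.seed(44)
  tab <- data.frame(gene_id = rep(sprintf("g%02d", 1:10), each = 10),
                    peak_id = rep(sprintf("p%02d", 1:10), times = 10),
                    weight = runif(100))
  sel <- select_top_attention(tab, frac = 0.10)
  expect_equal(nrow(sel), 10)
  expect_true(all(sel$weight >= sort(tab$weight, decreasing = TRUE)[10]))
  # all-equal weights: deterministic lexicographic tie-break
  tab2 <- tab; tab2$weight <- 1
  sel2 <- select_top_attention(tab2, frac = 0.10)
  ord <- order(tab2$gene_id, tab2$peak_id)
  expect_equal(paste(sel2$gene_id, sel2$peak_id),
               paste(tab2$gene_id, tab2$peak_id)[ord][1:10])
  # piecewise-linear curve with a single knee at position 20
  y <- c(seq(100, 20, length.out = 20), seq(19.8, 16, length.out = 80))
  tab3 <- tab; tab3$weight <- sort(y, decreasing = TRUE)
  sel3 <- select_top_attention(tab3, method = "elbow")
  expect_equal(nrow(sel3), 20, tolerance = 0)
})

test_that("dense peak-associated genes require the peak-count threshold", {
  sel <- data.frame(
    gene_id = c(rep("gA", 10), rep("gB", 9), rep("gA", 2)),
    peak_id = c(sprintf("p%02d", 1:10), sprintf("q%02d", 1:9), "p01", "p02"))
  dp <- dense_peak_associated_genes(sel, min_peaks = 10)
  expect_equal(dp, "gA")    # gB has 9 distinct peaks; gA's duplicates don't double-count
  expect_equal(dense_peak_associated_genes(sel[0, ], 10), character(0))
})

test_that("pchic emission round-trips the planted links exactly", {
  sim <- generate_multiome(n_cells = 30, n_genes = 40, n_peaks = 80,
                           seed = 45)
  tab <- generate_pchic_like(sim$truth, fp_rate = 0, seed = 1)
  ts <- build_truth_set(tab, sim$truth$genes, sim$truth$peaks)
  pos <- ts$pairs[ts$pairs$label == 1, ]
  want <- sim$truth$planted_links
  expect_setequal(paste(pos$gene_id, pos$peak_id),
                  paste(want$gene_id, want$peak_id))
  # decoys do not add positives
  tab2 <- generate_pchic_like(sim$truth, fp_rate = 0.5, seed = 2)
  ts2 <- build_truth_set(tab2, sim$truth$genes, sim$truth$peaks)
  pos2 <- ts2$pairs[ts2$pairs$label == 1, ]
  expect_setequal(paste(pos2$gene_id, pos2$peak_id),
                  paste(want$gene_id, want$peak_id))
  # forcing all scores below the cutoff kills every positive
  tab3 <- tab
  tab3[grep("^score", names(tab3))] <- 4
  expect_warning(ts3 <- build_truth_set(tab3, sim$truth$genes,
                                        sim$truth$peaks), "no positive")
  expect_equal(sum(ts3$pairs$label), 0)
})
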