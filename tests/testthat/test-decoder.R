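# Transformer decoder: CLS handling, attention oracles, distance mask,
# matching loss, global attention extraction.

test_that("CLS prepending puts the shared token in slot 1 and strips back", {
  dp <- init_decoder_params(d = 8, seed = 1)
  tok <- matrix(rnorm(24), 3, 8)
  out <- prepend_cls(tok, dp$w$cls_rna)
  expect_equal(dim(out), c(4L, 8L))
  expect_equal(out[1, ], dp$w$cls_rna)
  expect_equal(out[-1, ], tok)
  lst <- prepend_cls(list(tok, tok[1:2, ]), dp$w$cls_rna)
  expect_equal(lst[[2]][1, ], lst[[1]][1, ])   # identical CLS across cells
})

test_that("self-attention matches the direct-sum oracle and normalizes", {
  set.seed(21)
  d <- 4
  dp <- init_decoder_params(d = d, seed = 2)
  toks <- matrix(rnorm(3 * d), 3)
  got <- self_attention(toks, dp)
  want <- oracle_attention(toks %*% dp$w$Wq_s, toks %*% dp$w$Wk_s,
                           toks %*% dp$w$Wv_s, d)
  expect_equal(got$hidden, want$hidden, tolerance = 1e-9)
  expect_equal(got$weights, want$weights, tolerance = 1e-9)
  expect_equal(rowSums(got$weights), rep(1, 3))
  # CLS-only sequence: output is V of CLS with weight 1
  one <- matrix(rnorm(d), 1)
  o1 <- self_attention(one, dp)
  expect_equal(o1$weights, matrix(1, 1, 1))
  expect_equal(o1$hidden, one %*% dp$w$Wv_s)
})

test_that("cross-attention obeys the oracle and the additive mask", {
  set.seed(22)
  d <- 4
  dp <- init_decoder_params(d = d, seed = 3)
  q <- matrix(rnorm(3 * d), 3)   # G = 2 + CLS
  k <- matrix(rnorm(4 * d), 4)   # P = 3 + CLS
  mask <- matrix(0, 3, 4)
  got <- cross_attention(q, k, mask, dp)
  want <- oracle_attention(q %*% dp$w$Wq_c, k %*% dp$w$Wk_c,
                           k %*% dp$w$Wv_c, d, mask)
  expect_equal(got$hidden, want$hidden, tolerance = 1e-9)
  expect_equal(rowSums(got$weights), rep(1, 3))
  # masking all peaks for one gene row pushes all weight to the CLS column
  mask2 <- mask
  mask2[2, 2:4] <- -1e9
  got2 <- cross_attention(q, k, mask2, dp)
  expect_equal(got2$weights[2, 1], 1, tolerance = 1e-6)
  expect_true(all(got2$weights[2, 2:4] <= 1e-6))
  expect_error(cross_attention(q, k, mask[, 1:3], dp), "mask shape")
})

test_that("single-head attention equals the multi-head code path with heads=1", {
  set.seed(23)
  d <- 8
  dp <- init_decoder_params(d = d, heads = 1, seed = 4)
  toks <- matrix(rnorm(5 * d), 5)
  a1 <- self_attention(toks, dp, heads = 1)
  want <- oracle_attention(toks %*% dp$w$Wq_s, toks %*% dp$w$Wk_s,
                           toks %*% dp$w$Wv_s, d)
  expect_equal(a1$hidden, want$hidden, tolerance = 1e-9)
  a2 <- self_attention(toks, dp, heads = 2)    # 2 heads differ in general
  expect_equal(rowSums(a2$weights), rep(1, 5))
  expect_false(isTRUE(all.equal(a1$hidden, a2$hidden)))
})

test_that("the distance mask opens same-chromosome pairs within 1.2 Mb", {
  genes <- data.frame(gene_id = c("gA", "gB"),
                      chrom = c("chr1", "chr2"),
                      tss = c(1000000L, 1000000L), strand = c("+", "+"))
  peaks <- data.frame(chrom = c("chr1", "chr1", "chr1"),
                      start = c(2299700L, 2199700L, 999700L),
                      end = c(2300300L, 2200300L, 1000300L))
  m <- build_attention_mask(genes, peaks, 1.2e6)
  expect_equal(dim(m$values), c(3L, 4L))
  expect_true(all(m$values[1, ] == 0))       # CLS row unmasked
  expect_true(all(m$values[, 1] == 0))       # CLS column unmasked
  core <- m$values[-1, -1]
  expect_lt(core[1, 1], 0)   # distance 1,300,000 > threshold: masked
  expect_equal(core[1, 2], 0)  # 1,200,000: inclusive boundary, unmasked
  expect_equal(core[1, 3], 0)  # peak straddling the TSS: distance 0
  expect_true(all(core[2, ] < 0))  # different chromosome: always masked
  genes$tss[2] <- NA
  expect_error(build_attention_mask(genes, peaks), "gB")
})

test_that("matching loss equals direct cross-entropy and its edge values", {
  d <- toy_data()
  enc <- init_encoder_params(ncol(d$proc$rna_norm), ncol(d$proc$atac_norm),
                             d = 16, seed = 5)
  dp <- init_decoder_params(d = 16, seed = 6)
  mask <- build_attention_mask(d$proc$genes, d$proc$peaks)
  cells <- 1:4
  tks <- lapply(cells, function(i) scDuet:::cell_tokens(enc, d$proc$encoded, i))
  gt <- lapply(tks, `[[`, "gene"); pt <- lapply(tks, `[[`, "peak")
  gi <- lapply(tks, `[[`, "gidx"); pi <- lapply(tks, `[[`, "pidx")
  ml <- matching_loss(gt, pt, gi, pi, dp, mask, seed = 1)
  expect_equal(ml$loss, oracle_cross_entropy(ml$logits, ml$labels),
               tolerance = 1e-12)
  expect_true(all(ml$negatives != seq_along(ml$negatives)))
  # a classifier with zero weights answers 0.5/0.5: loss is exactly log 2
  dp0 <- dp
  dp0$w$Wm[] <- 0; dp0$w$bm[] <- 0
  ml0 <- matching_loss(gt, pt, gi, pi, dp0, mask, seed = 1)
  expect_equal(ml0$loss, log(2))
  # near-perfect logits drive the loss toward 0
  perfect <- cbind(c(rep(-20, 4), rep(20, 4)), c(rep(20, 4), rep(-20, 4)))
  expect_lt(oracle_cross_entropy(perfect, rep(c(2L, 1L), each = 4)), 1e-8)
  expect_error(matching_loss(gt[1], pt[1], gi[1], pi[1], dp, mask),
               "at least 2")
})

test_that("interaction loss is the plain sum of its components", {
  expect_equal(interaction_loss(1.5, 2.25), 3.75)
  expect_equal(interaction_loss(0, 0), 0)
  expect_equal(interaction_loss(2.25, 1.5), interaction_loss(1.5, 2.25))
})

test_that("global attention contraction has shape G x P and is non-negative", {
  set.seed(24)
  N <- 5; G <- 3; P <- 4
  rna <- t(apply(matrix(runif(N * (P + 1)), N), 1, function(r) r / sum(r)))
  atac <- t(apply(matrix(runif(N * (G + 1)), N), 1, function(r) r / sum(r)))
  gl <- extract_global_attention(rna, atac)
  expect_equal(dim(gl$values), c(G, P))
  expect_true(all(gl$values >= 0))
  # N = 1 with uniform rows: constant matrix 1/((G+1)(P+1)) before CLS drop
  u_rna <- matrix(1 / (P + 1), 1, P + 1)
  u_atac <- matrix(1 / (G + 1), 1, G + 1)
  gl1 <- extract_global_attention(u_rna, u_atac)
  expect_equal(unname(gl1$values),
               matrix(1 / ((G + 1) * (P + 1)), G, P))
  expect_error(extract_global_attention(rna, atac[1:2, ]), "same cells")
})

test_that("perturbing a masked peak token leaves gene attention unchanged", {
  # one gene on chr1; peak 1 nearby (unmasked), peak 2 on chr2 (masked for
  # the gene, visible only to the CLS row)
  genes <- data.frame(gene_id = "gA", chrom = "chr1", tss = 500000L,
                      strand = "+")
  peaks <- data.frame(chrom = c("chr1", "chr2"),
                      start = c(510000L, 510000L),
                      end = c(510500L, 510500L))
  mask <- build_attention_mask(genes, peaks)
  dp <- init_decoder_params(d = 8, seed = 8)
  set.seed(8)
  gtok <- matrix(rnorm(8), 1)
  ptok <- matrix(rnorm(16), 2)
  msub <- scDuet:::mask_subset(mask, 1L, c(1L, 2L))
  out1 <- scDuet:::decoder_cell_forward(gtok, ptok, msub, dp)
  ptok2 <- ptok
  ptok2[2, ] <- ptok2[2, ] + 100
  out2 <- scDuet:::decoder_cell_forward(gtok, ptok2, msub, dp)
  # the gene row's attention over {CLS, peak1} is untouched by the masked
  # peak's perturbation; the gene row gives peak 2 vanishing weight
  a1 <- cross_attention(self_attention(prepend_cls(gtok, dp$w$cls_rna), dp)$hidden,
                        prepend_cls(ptok, dp$w$cls_atac), msub, dp)$weights
  a2 <- cross_attention(self_attention(prepend_cls(gtok, dp$w$cls_rna), dp)$hidden,
                        prepend_cls(ptok2, dp$w$cls_atac), msub, dp)$weights
  expect_lt(a1[2, 3], 1e-6)
  expect_equal(a1[2, 1:2], a2[2, 1:2], tolerance = 1e-9)
})

test_that("decoder training is reproducible and lowers the loss", {
  d <- toy_data()
  enc <- init_encoder_params(ncol(d$proc$rna_norm), ncol(d$proc$atac_norm),
                             d = 16, seed = 9)
  mask <- build_attention_mask(d$proc$genes, d$proc$peaks)
  cfg <- decoder_config(epochs = 2, seed = 10)
  f1 <- train_decoder(enc, d$proc, mask, cfg)
  f2 <- train_decoder(enc, d$proc, mask, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$dparams$w, f2$dparams$w)
  expect_lt(f1$history[2], f1$history[1])
  expect_equal(decoder_config()$epochs, 5L)
  # frozen-encoder mode leaves the embedding tables untouched
  f3 <- train_decoder(enc, d$proc, mask,
                      decoder_config(epochs = 1, freeze_encoder = TRUE,
                                     seed = 10))
  expect_identical(f3$enc_params$w$teacher_rna$E, enc$w$teacher_rna$E)
  expect_false(identical(f1$enc_params$w$teacher_rna$E, enc$w$teacher_rna$E))
})
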