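# Integration and prediction metrics: closed forms, constructed
# geometries, and null expectations.

test_that("FOSCTTM hits its closed-form extremes and is symmetric", {
  set.seed(31)
  Z <- matrix(rnorm(20), 5)
  expect_equal(foscttm(Z, Z), 0)
  # adversarial swap: each cell's match is the farther of the two points
  A <- rbind(c(1, 0), c(0, 1))
  B <- A[c(2, 1), ]
  expect_equal(foscttm(A, B), 1)
  Za <- matrix(rnorm(40), 10); Zb <- matrix(rnorm(40), 10)
  expect_equal(foscttm(Za, Zb), foscttm(Zb, Za))
  expect_error(foscttm(A[1, , drop = FALSE], B[1, , drop = FALSE]),
               "at least 2")
})

test_that("FOSCTTM is ~0.5 on independent random embeddings", {
  set.seed(32)
  N <- 200
  f <- foscttm(matrix(rnorm(N * 8), N), matrix(rnorm(N * 8), N))
  se <- sqrt(0.25 / (2 * N))
  expect_lt(abs(f - 0.5), 3 * se + 0.02)
})

test_that("MAP rewards pure neighborhoods and collapses to NN accuracy at k=1", {
  set.seed(33)
  Z <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 50), 20))
  types <- rep(c("a", "b"), each = 20)
  expect_equal(mean_average_precision(Z, types, k = 10), 1)
  # k = 1: average precision reduces to nearest-neighbor type accuracy
  nn1 <- apply(as.matrix(dist(Z)) + diag(Inf, 40), 1, which.min)
  expect_equal(mean_average_precision(Z, types, k = 1),
               mean(types[nn1] == types))
  # permuted labels land near the mean type frequency
  perm <- sample(types)
  m <- mean_average_precision(Z, perm, k = 10)
  expect_lt(abs(m - 0.5), 0.15)
  expect_warning(one <- mean_average_precision(Z, rep("a", 40)), "single")
  expect_equal(one, 1)
})

test_that("silhouette scores separate the constructed geometries", {
  set.seed(34)
  # two tight, distant type clusters; modalities interleaved within type
  Z <- rbind(matrix(rnorm(60, 0, 0.1), 30), matrix(rnorm(60, 20, 0.1), 30))
  types <- rep(c("a", "b"), each = 30)
  mods <- rep(c("rna", "atac"), 30)
  s <- silhouette_scores(Z, types, mods)
  expect_gt(s$cell_type_asw, 0.9)
  expect_gt(s$batch_asw, 0.75)
  # modalities fully separated within each type
  Z2 <- Z
  Z2[mods == "atac", 1] <- Z2[mods == "atac", 1] + 5
  s2 <- silhouette_scores(Z2, types, mods)
  expect_lt(s2$batch_asw, 0.2)
  expect_true(s$cell_type_asw >= 0 && s$cell_type_asw <= 1)
  expect_true(s2$batch_asw >= 0 && s2$batch_asw <= 1)
  expect_error(silhouette_scores(Z, rep("a", 60), mods), "at least 2")
})

test_that("neighbor consistency is 1 on identity and k/(N-1) on noise", {
  set.seed(35)
  Z <- matrix(rnorm(200 * 6), 200)
  expect_equal(neighbor_consistency(Z, Z, k = 15), 1)
  R <- matrix(rnorm(200 * 6), 200)
  nc <- neighbor_consistency(Z, R, k = 15)
  # under independence the Jaccard of two k-sets concentrates near
  # k / (2(N-1) - k); loose window around it
  exp_j <- 15 / (2 * 199 - 15)
  expect_lt(abs(nc - exp_j), 0.05)
  expect_error(neighbor_consistency(Z, R, k = 200), "smaller")
})

test_that("neighbor consistency degrades monotonically with noise", {
  set.seed(36)
  Z <- matrix(rnorm(150 * 5), 150)
  ncs <- vapply(c(0.1, 1, 4), function(s)
    neighbor_consistency(Z + matrix(rnorm(750, 0, s), 150), Z, k = 10),
    numeric(1))
  expect_true(all(diff(ncs) < 0))
})

test_that("alignment score separates mixed from split modalities", {
  set.seed(37)
  mixed <- matrix(rnorm(200 * 4), 200)
  mods <- rep(c("rna", "atac"), each = 100)
  expect_gt(seurat_alignment_score(mixed, mods, k = 20), 0.85)
  split_z <- mixed
  split_z[101:200, 1] <- split_z[101:200, 1] + 100
  expect_lt(seurat_alignment_score(split_z, mods, k = 20), 0.05)
  s <- seurat_alignment_score(mixed, mods, k = 20)
  expect_true(s >= 0 && s <= 1)
})

test_that("graph connectivity scores components per cell type", {
  set.seed(38)
  # type a: one tight cluster; type b: two islands of equal size, far apart
  Za <- matrix(rnorm(60, 0, 0.2), 30)
  Zb <- rbind(matrix(rnorm(30, 30, 0.2), 15), matrix(rnorm(30, 90, 0.2), 15))
  Z <- rbind(Za, Zb)
  types <- rep(c("a", "b"), each = 30)
  expect_equal(graph_connectivity(Z, types, k = 5), mean(c(1, 0.5)))
  expect_equal(graph_connectivity(Za, rep("a", 30), k = 5), 1)
})

test_that("composite scores follow the stated weighted arithmetic", {
  comp <- list(map = 0.5, cell_type_asw = 0.5, nc = 0.5,
               sas = 1, batch_asw = 1, gc = 1)
  cs <- composite_scores(comp)
  expect_equal(cs$bio, 0.5)
  expect_equal(cs$omics, 1)
  expect_equal(cs$overall, 0.7)
  all1 <- composite_scores(as.list(setNames(rep(1, 6),
    c("map", "cell_type_asw", "nc", "sas", "batch_asw", "gc"))))
  expect_equal(all1$overall, 1)
  # linear response: d overall / d bio = 0.6 by finite difference
  eps <- 1e-6
  comp2 <- comp; comp2$map <- comp2$map + 3 * eps
  expect_equal((composite_scores(comp2)$overall - cs$overall) / eps, 0.6,
               tolerance = 1e-4)
  expect_error(composite_scores(comp[-1]), "missing")
  # with peers, min-max puts the best method at 1 per component
  peers <- data.frame(map = c(0.2, 0.4), cell_type_asw = c(0.3, 0.5),
                      nc = c(0.2, 0.4), sas = c(0.5, 0.9),
                      batch_asw = c(0.4, 0.8), gc = c(0.3, 0.7))
  best <- composite_scores(list(map = 0.6, cell_type_asw = 0.7, nc = 0.6,
                                sas = 1, batch_asw = 0.9, gc = 0.8),
                           peer_values = peers)
  expect_equal(best$overall, 1)
})

test_that("prediction metrics match closed forms", {
  set.seed(39)
  X <- matrix(rnorm(50), 10)
  pm <- prediction_metrics(X, X)
  expect_equal(pm$rmse, 0)
  expect_equal(pm$pearson_genewise, 1)
  expect_equal(pm$spearman_genewise, 1)
  pm2 <- prediction_metrics(-X, X)
  expect_equal(pm2$pearson_genewise, -1)
  pm3 <- prediction_metrics(X + 0.7, X)
  expect_equal(pm3$rmse, 0.7)
  Xc <- X; Xc[, 1] <- 2      # constant gene excluded and counted
  pm4 <- prediction_metrics(Xc, X)
  expect_equal(pm4$n_constant_genes, 1)
  expect_error(prediction_metrics(matrix(1, 5, 2), matrix(2, 5, 2)),
               "constant")
})

test_that("metric report is bounded and internally consistent", {
  set.seed(40)
  N <- 60
  emb <- structure(list(
    Z_teacher_RNA = matrix(rnorm(N * 8), N),
    Z_teacher_ATAC = matrix(rnorm(N * 8), N)), class = "embedding_set")
  emb$Z_joint <- joint_embedding(emb$Z_teacher_RNA, emb$Z_teacher_ATAC)
  types <- rep(c("a", "b", "c"), each = N / 3)
  rep_ <- metric_report(emb, types,
                        Z_pre = list(matrix(rnorm(N * 8), N),
                                     matrix(rnorm(N * 8), N)), k = 10)
  for (nm in c("map", "cell_type_asw", "batch_asw", "nc", "sas", "gc",
               "foscttm"))
    expect_true(rep_[[nm]] >= 0 && rep_[[nm]] <= 1, label = nm)
  expect_equal(rep_$overall,
               0.6 * rep_$biology_conservation + 0.4 * rep_$omics_mixing)
})
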