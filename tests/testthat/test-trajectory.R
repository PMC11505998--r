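# count preprocessing, batch handling, PCA, pseudotime, correlation,
# enrichment and survival

test_that("expression filter keeps genes detected in at least min_samples samples", {
  set.seed(1)
  counts <- matrix(5L, nrow = 4, ncol = 20,
                   dimnames = list(c("g9", "g10", "gbase", "gnc"),
                                   paste0("s", 1:20)))
  counts["g9", 10:20] <- 0L   # detected in 9 samples
  counts["g10", 11:20] <- 0L  # detected in 10 samples
  annot <- data.frame(gene = rownames(counts),
                      biotype = c("protein_coding", "protein_coding",
                                  "protein_coding", "lncRNA"))
  norm <- preprocess_counts(counts, annot, min_count = 1, min_samples = 10)
  expect_setequal(rownames(norm), c("g10", "gbase"))
})

test_that("median-of-ratios size factors respond to depth, not composition", {
  counts <- matrix(c(10, 20, 40, 80, 160), nrow = 5, ncol = 4,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  counts[, 3] <- counts[, 3] * 2  # doubled library
  annot <- data.frame(gene = rownames(counts), biotype = "protein_coding")
  norm <- preprocess_counts(counts, annot, min_samples = 2)
  sf <- attr(norm, "size_factors")
  expect_equal(unname(sf[3] / sf[1]), 2, tolerance = 1e-12)
  expect_equal(unname(sf[1]), unname(sf[2]), tolerance = 1e-12)
  # identical samples: all size factors 1
  eq <- matrix(c(10, 20, 40, 80, 160), 5, 3,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  n2 <- preprocess_counts(eq, annot, min_samples = 2)
  expect_equal(unname(attr(n2, "size_factors")), rep(1, 3), tolerance = 1e-12)
  # cross-check against the reference size-factor estimator
  sf_ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(sf / sf[1]), unname(sf_ref / sf_ref[1]),
               tolerance = 1e-9)
})

test_that("remove_batch equalizes planted batch shifts and protects the covariate", {
  set.seed(2)
  n <- 40
  x <- matrix(rnorm(20 * n), nrow = 20)
  batch <- rep(c("b1", "b2"), each = n / 2)
  covariate <- rep(c("lo", "hi"), n / 2)  # balanced across batches
  shifted <- x
  shifted[, batch == "b2"] <- shifted[, batch == "b2"] + 0.8
  adj <- remove_batch(shifted, batch, covariate = covariate)
  bm <- apply(adj, 1, function(r) diff(tapply(r, batch, mean)))
  expect_lt(max(abs(bm)), 1e-6)
  # covariate effect estimate unchanged by the correction
  cov_effect <- function(m) apply(m, 1, function(r)
    diff(tapply(r, covariate, mean)))
  expect_equal(cov_effect(adj), cov_effect(x), tolerance = 1e-6)
  # no batch structure: adjustment is a no-op
  adj0 <- remove_batch(x, batch, covariate = covariate)
  resid_shift <- adj0 - x
  expect_lt(max(abs(apply(adj0, 1, function(r) diff(tapply(r, batch, mean))))),
            1e-6)
  # cross-check against the reference linear-model batch remover
  ref <- limma::removeBatchEffect(shifted, batch = batch,
                                  design = stats::model.matrix(~covariate))
  expect_equal(adj, ref, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("a covariate aliased with batch is protected with a warning", {
  set.seed(3)
  x <- matrix(rnorm(10 * 20), nrow = 10)
  batch <- rep(c("b1", "b2"), each = 10)
  covariate <- batch  # perfect aliasing
  expect_warning(adj <- remove_batch(x, batch, covariate = covariate),
                 "aliased")
  expect_equal(adj, x, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("DSC is zero for coincident batches and extreme for separated ones", {
  x <- matrix(rnorm(50 * 30), nrow = 50)
  d0 <- dsc(cbind(x, x), rep(c("b1", "b2"), each = 30), n_perm = 50, seed = 1)
  expect_equal(d0$dsc, 0, tolerance = 1e-9)
  xs <- x
  shifted <- cbind(x, x + 5)
  d1 <- dsc(shifted, rep(c("b1", "b2"), each = 30), n_perm = 200, seed = 1)
  expect_equal(d1$p_perm, 1 / 201, tolerance = 1e-12)
  expect_gt(d1$dsc, d0$dsc)
  expect_error(dsc(x, rep("b1", 30)), "2 batches")
})

test_that("PCA embedding selects high-IQR genes and normalizes variance", {
  set.seed(4)
  x <- matrix(rnorm(500 * 40, sd = 0.5), nrow = 500)
  planted <- sample(500, 100)
  x[planted, ] <- x[planted, ] * 10
  rownames(x) <- paste0("g", 1:500)
  emb <- pca_embed(x, n_top_iqr = 100, n_pc = 5)
  expect_setequal(emb$genes_used, paste0("g", planted))
  expect_equal(sum(emb$variance_explained), 1, tolerance = 1e-9)
  # rank-1 matrix loads everything on PC1
  r1 <- outer(rnorm(100), rnorm(30))
  rownames(r1) <- paste0("g", 1:100)
  emb1 <- pca_embed(r1, n_top_iqr = 100, n_pc = 2)
  expect_gte(emb1$variance_explained[1], 0.999)
  expect_error(pca_embed(x, n_pc = 100), "n_pc")
})

test_that("Prim's MST matches brute-force enumeration on small centroid sets", {
  for (s in 1:10) {
    set.seed(s)
    k <- sample(3:6, 1)
    pts <- matrix(rnorm(k * 3), nrow = k)
    d <- as.matrix(dist(pts))
    edges <- oncoresponse:::prim_mst(d)
    expect_equal(nrow(edges), k - 1)
    expect_equal(mst_weight(d, edges), brute_force_mst_weight(d),
                 tolerance = 1e-12)
  }
})

test_that("collinear clusters give pseudotime perfectly ordered from the seed", {
  set.seed(5)
  pos <- sort(runif(60, 0, 10))
  emb <- cbind(pos, 0, 0)
  rownames(emb) <- paste0("s", 1:60)
  labels <- cut(pos, c(-Inf, 3.3, 6.6, Inf), labels = c("G1", "G2", "G3"))
  tr <- infer_trajectory(emb, labels, "G1")
  expect_equal(cor(tr$pseudotime, pos, method = "spearman"), 1)
  expect_equal(min(tr$pseudotime), 0)
  expect_equal(nrow(tr$mst_edges), 2)
  # seed anchoring: reversed seed flips the ordering
  tr3 <- infer_trajectory(emb, labels, "G3")
  expect_equal(cor(tr3$pseudotime, pos, method = "spearman"), -1)
  means <- tapply(tr$pseudotime, labels, mean)
  expect_true(which.min(means) == 1)
})

test_that("an arc-shaped manifold is recovered by the principal curve", {
  set.seed(6)
  theta <- sort(runif(150, 0, pi / 2))
  emb <- cbind(10 * cos(theta), 10 * sin(theta))
  rownames(emb) <- paste0("s", 1:150)
  labels <- cut(theta, 3, labels = c("G1", "G2", "G3"))
  tr <- infer_trajectory(emb, labels, "G1")
  expect_gte(cor(tr$pseudotime, theta, method = "spearman"), 0.99)
})

test_that("trajectory validates cluster structure", {
  emb <- matrix(rnorm(20), ncol = 2)
  expect_error(infer_trajectory(emb, rep("G1", 10), "G1"), "2 clusters")
  expect_error(infer_trajectory(emb, c(rep("G1", 9), "G2"), "G1"), "single sample")
  expect_error(infer_trajectory(emb, rep(c("G1", "G2"), 5), "G9"), "seed_cluster")
})

test_that("sample order has no effect on the pipeline outputs", {
  co <- make_signal_cohort(seed = 21, n_samples = 120, n_genes = 300,
                           n_loaded = 60)
  norm <- preprocess_counts(co$counts, co$annotation)
  emb <- pca_embed(norm, n_top_iqr = 200, n_pc = 3)
  tr <- infer_trajectory(emb$embedding, co$metadata$grade, "G1")
  perm <- sample(ncol(norm))
  tr_p <- infer_trajectory(emb$embedding[perm, ],
                           co$metadata$grade[perm], "G1")
  expect_equal(unname(tr_p$pseudotime), unname(tr$pseudotime[perm]),
               tolerance = 1e-9)
})

test_that("pseudotime correlation is exact for a perfectly tracking gene", {
  set.seed(7)
  pt <- runif(100)
  x <- rbind(pt, -pt + rnorm(100, sd = 0.1 * sd(pt)), rnorm(100), rep(1, 100))
  rownames(x) <- c("exact", "anti", "null", "const")
  res <- pseudotime_correlation(x, pt, seed = 1)
  expect_equal(res$median_r[res$gene == "exact"], 1, tolerance = 1e-12)
  expect_lt(res$fdr[res$gene == "exact"], 1e-10)
  expect_lte(res$median_r[res$gene == "anti"], -0.95)
  expect_false("const" %in% res$gene)
  expect_equal(attr(res, "excluded"), "const")
  expect_error(pseudotime_correlation(x, pt, n_draws = 0), "n_draws")
  expect_error(pseudotime_correlation(x, pt[1:10]), "per sample")
})

test_that("anti-tracking genes stay strongly negative across resampling seeds", {
  ok <- vapply(1:10, function(s) {
    set.seed(s)
    pt <- runif(120)
    g <- -pt + rnorm(120, sd = 0.1 * sd(pt))
    x <- rbind(g, rnorm(120))
    rownames(x) <- c("anti", "null")
    res <- pseudotime_correlation(x, pt, seed = s)
    res$median_r[res$gene == "anti"] <= -0.95
  }, logical(1))
  expect_true(all(ok))
})

test_that("preranked GSEA finds planted sets and respects boundary cases", {
  set.seed(8)
  stats_vec <- setNames(sort(rnorm(2000), decreasing = TRUE),
                        paste0("g", 1:2000))
  planted <- names(stats_vec)[1:50]
  res <- gsea_preranked(stats_vec, list(planted = planted), n_perm = 1000,
                        seed = 1)
  expect_gt(res$es, 0.9)
  expect_equal(res$p_perm, 1 / 1001, tolerance = 1e-12)
  expect_lt(res$fdr, 0.01)
  # the whole-list set walks back to zero: only small interior deviation for
  # near-flat statistics
  flat <- setNames(rep(1, 500) + rnorm(500, sd = 1e-3), paste0("g", 1:500))
  res_all <- gsea_preranked(flat, list(all = names(flat)), n_perm = 50,
                            seed = 1)
  expect_lt(abs(res_all$es), 0.2)
  expect_error(gsea_preranked(setNames(1:4, c("a", "a", "b", "c")), list()),
               "duplicate")
  expect_error(gsea_preranked(stats_vec, list(none = c("zz1", "zz2"))),
               "no overlap")
})

test_that("the enrichment walk matches a brute-force running sum", {
  set.seed(9)
  stats_vec <- setNames(rnorm(200), paste0("g", 1:200))
  o <- order(stats_vec, decreasing = TRUE)
  sorted <- stats_vec[o]
  hits <- sort(sample(200, 20))
  brute_es <- local({
    w <- abs(sorted)^1
    inset <- seq_along(sorted) %in% hits
    hit_inc <- ifelse(inset, w / sum(w[inset]), 0)
    miss_inc <- ifelse(inset, 0, 1 / (200 - 20))
    walk <- cumsum(hit_inc - miss_inc)
    walk[which.max(abs(walk))]
  })
  es <- oncoresponse:::es_from_positions(abs(sorted), hits, 200)
  expect_equal(es, brute_es, tolerance = 1e-12)
})

test_that("fgsea agrees with the package ES on a common input", {
  set.seed(10)
  stats_vec <- setNames(rnorm(1000), paste0("g", 1:1000))
  sets <- list(up = paste0("g", sample(1000, 40)),
               down = paste0("g", sample(1000, 60)))
  mine <- gsea_preranked(stats_vec, sets, n_perm = 200, seed = 1)
  ref <- suppressWarnings(fgsea::fgsea(sets, stats_vec, nPermSimple = 500))
  expect_equal(mine$es[match(ref$pathway, mine$gene_set)], ref$ES,
               tolerance = 1e-6)
})

test_that("log-rank statistic matches the hand-computed oracle on the toy table", {
  time <- 1:6
  event <- c(1, 1, 1, 1, 0, 1)
  group <- rep(c("A", "B"), each = 3)
  oracle <- logrank_chisq_oracle(time, event, group)
  # expression split reproducing the A/B grouping
  km <- km_twogroup(c(1, 1, 1, 9, 9, 9), time, event)
  expect_equal(km$chisq, oracle, tolerance = 1e-6)
  expect_equal(km$p, stats::pchisq(oracle, 1, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("degenerate survival inputs follow the stated conventions", {
  # identical groups: no signal
  km0 <- km_twogroup(c(1, 1, 1, 9, 9, 9), rep(c(2, 4, 6), 2),
                     rep(c(1, 1, 0), 2))
  expect_lt(km0$chisq, 1e-9)
  expect_equal(km0$p, 1, tolerance = 1e-6)
  # no events: flat curves, p = 1 by convention
  kmn <- km_twogroup(c(1, 2, 8, 9), c(5, 6, 7, 8), rep(0, 4))
  expect_equal(kmn$p, 1)
  expect_true(all(kmn$fit$surv == 1))
  expect_error(km_twogroup(rep(5, 4), 1:4, rep(1, 4)), "tied")
  # missing survival removed first
  kmna <- km_twogroup(c(1, 2, 8, 9, 3), c(5, 6, 7, 8, NA),
                      c(1, 1, 1, 1, 1))
  expect_equal(kmna$n_removed, 1)
})

test_that("stronger survival coupling strengthens the expression split signal", {
  med_p <- vapply(c(0, 1.5), function(link) {
    ps <- vapply(1:8, function(s) {
      co <- gen_expression_cohort(cohort_spec(
        n_samples = 150, n_genes = 10, module_loadings = 1,
        survival_link = link, censor_rate = 0.2, seed = 100 + s))
      norm <- log2(co$counts + 1)
      km_twogroup(norm[1, ], co$metadata$survival_time, co$metadata$event)$p
    }, numeric(1))
    stats::median(ps)
  }, numeric(1))
  expect_lt(med_p[2], med_p[1])
  expect_lt(med_p[2], 0.05)
})
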