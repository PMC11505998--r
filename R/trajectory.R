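#' Filter and normalize a count matrix
#'
#' Keeps protein-coding genes, drops genes without a count of at least
#' `min_count` in at least `min_samples` samples, computes median-of-ratios
#' size factors, and returns `log2(count / size_factor + 1)`. The log
#' transform is a monotone variance stabilization: all downstream operations
#' (IQR gene selection, PCA, correlation) depend only on that property.
#'
#' @param counts genes x samples non-negative integer matrix with rownames.
#' @param annotation data frame with columns `gene`, `biotype` covering all
#'   rows of `counts`.
#' @param min_count,min_samples expression filter: keep genes with a count of
#'   at least `min_count` in at least `min_samples` samples.
#' @return normalized log2 matrix (filtered genes x samples) with attribute
#'   `size_factors`.
#' @export
preprocess_counts <- function(counts, annotation, min_count = 1,
                              min_samples = 10) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!all(rownames(counts) %in% annotation$gene)) {
    stop("annotation must cover every gene in the count matrix")
  }
  bt <- annotation$biotype[match(rownames(counts), annotation$gene)]
  counts <- counts[bt == "protein_coding", , drop = FALSE]
  keep <- rowSums(counts >= min_count) >= min_samples
  counts <- counts[keep, , drop = FALSE]
  if (!nrow(counts)) stop("no genes pass the expression filter")
  if (any(colSums(counts) == 0)) stop("all-zero sample: size factor undefined")
  # median-of-ratios size factors over genes expressed in every sample
  logc <- log(counts)
  loggeo <- rowMeans(logc)
  usable <- is.finite(loggeo)
  if (!any(usable)) stop("no gene expressed in all samples; size factors undefined")
  sf <- apply(logc[usable, , drop = FALSE], 2, function(cl)
    exp(stats::median((cl - loggeo[usable])[is.finite(cl)])))
  out <- log2(sweep(counts, 2, sf, "/") + 1)
  attr(out, "size_factors") <- sf
  out
}

#' Remove additive batch effects while protecting a covariate of interest
#'
#' Per gene, fits `expression ~ covariate + batch (+ batch2)` by least
#' squares (sum-to-zero batch contrasts) and subtracts only the fitted batch
#' terms. The covariate enters the design first, so if a batch factor is
#' aliased with the covariate the aliased batch coefficients are dropped
#' (forced to zero) with a warning and the covariate effect is untouched.
#'
#' @param x genes x samples expression matrix.
#' @param batch primary batch factor (length = samples).
#' @param covariate biological variable of interest to protect (factor or
#'   numeric).
#' @param batch2 optional second batch factor.
#' @return adjusted matrix of the same shape.
#' @export
remove_batch <- function(x, batch, covariate, batch2 = NULL) {
  n <- ncol(x)
  batch <- factor(batch)
  if (any(table(batch) < 2)) warning("batch level(s) with fewer than 2 samples")
  cov_mat <- if (is.numeric(covariate)) matrix(covariate, ncol = 1)
    else stats::model.matrix(~f, data.frame(f = factor(covariate)))[, -1, drop = FALSE]
  bdes <- function(f) {
    f <- factor(f)
    if (nlevels(f) < 2) return(NULL)
    stats::model.matrix(~f, data.frame(f = f),
                        contrasts.arg = list(f = "contr.sum"))[, -1, drop = FALSE]
  }
  b1 <- bdes(batch)
  b2 <- if (!is.null(batch2)) bdes(batch2) else NULL
  X <- cbind(1, cov_mat, b1, b2)
  n_fixed <- 1 + ncol(cov_mat)
  if (ncol(X) <= n_fixed) return(x)   # no usable batch structure
  batch_cols <- seq.int(n_fixed + 1, ncol(X))
  fit <- stats::lm.fit(X, t(x))
  beta <- fit$coefficients
  aliased <- is.na(beta)
  if (any(aliased[batch_cols, , drop = FALSE])) {
    warning("batch term(s) aliased with the covariate; aliased batch ",
            "coefficients set to 0 (covariate protected)")
  }
  beta[aliased] <- 0
  x - t(X[, batch_cols, drop = FALSE] %*% beta[batch_cols, , drop = FALSE])
}

#' Dispersion separability criterion (DSC) for batch structure
#'
#' `DSC = Db / Dw` where `Db = sqrt(sum_b (n_b/N) ||mu_b - mu||^2)` measures
#' between-batch centroid dispersion and
#' `Dw = sqrt(sum_b (n_b/N) mean_i ||x_i - mu_b||^2)` within-batch
#' dispersion. DSC is 0 when all batch centroids coincide; larger values mean
#' stronger batch structure. Significance is assessed by permuting batch
#' labels.
#'
#' @param x genes x samples matrix.
#' @param batch batch labels (length = samples, >= 2 levels).
#' @param n_perm number of label permutations.
#' @param seed integer seed for the permutations.
#' @return list of class `batch_diagnostics`: `dsc`, `p_perm`, `n_perm`,
#'   `dsc_perm` (null values).
#' @export
dsc <- function(x, batch, n_perm = 1000, seed = NULL) {
  batch <- factor(batch)
  if (nlevels(batch) < 2) stop("at least 2 batches required")
  n <- ncol(x)
  ss_col <- colSums(x^2)
  mu <- rowMeans(x)
  dsc_of <- function(lab) {
    tab <- table(lab)
    ind <- stats::model.matrix(~0 + lab)
    cm <- x %*% ind %*% diag(1 / as.numeric(tab), nlevels(lab))
    w <- as.numeric(tab) / n
    db2 <- sum(w * colSums((cm - mu)^2))
    # mean_i ||x_i - mu_b||^2 = mean_i ||x_i||^2 - ||mu_b||^2 within batch
    s_per <- as.numeric(crossprod(ind, ss_col)) / as.numeric(tab)
    dw2 <- sum(w * (s_per - colSums(cm^2)))
    sqrt(db2) / sqrt(max(dw2, .Machine$double.eps))
  }
  obs <- dsc_of(batch)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    dsc_of(sample(batch)), numeric(1)))
  structure(list(dsc = obs,
                 p_perm = (1 + sum(perm >= obs)) / (n_perm + 1),
                 n_perm = n_perm, dsc_perm = perm),
            class = "batch_diagnostics")
}

#' @export
print.batch_diagnostics <- function(x, ...) {
  cat(sprintf("DSC = %.4f (permutation p = %.4g, %d permutations)\n",
              x$dsc, x$p_perm, x$n_perm))
  invisible(x)
}

#' PCA embedding of the most variable genes
#'
#' Selects the `n_top_iqr` genes with highest interquartile range, centers
#' per gene, and computes principal components by SVD. Variance fractions
#' over all components sum to 1.
#'
#' @param x genes x samples expression matrix.
#' @param n_top_iqr number of top-IQR genes used (capped at the gene count).
#' @param n_pc number of components returned.
#' @return list of class `pca_embedding`: `embedding` (samples x n_pc),
#'   `variance_explained` (fractions for all components), `genes_used`.
#' @export
pca_embed <- function(x, n_top_iqr = 2000, n_pc = 5) {
  if (n_pc > min(dim(x))) stop("n_pc exceeds matrix rank bound")
  iqr <- apply(x, 1, stats::IQR)
  sel <- order(iqr, decreasing = TRUE)[seq_len(min(n_top_iqr, nrow(x)))]
  pc <- stats::prcomp(t(x[sel, , drop = FALSE]), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(embedding = pc$x[, seq_len(n_pc), drop = FALSE],
                 variance_explained = ve,
                 genes_used = rownames(x)[sel]),
            class = "pca_embedding")
}

# Prim's algorithm: minimum spanning tree over a symmetric distance matrix;
# returns a 2-column matrix of edges
prim_mst <- function(d) {
  k <- nrow(d)
  if (k == 1) return(matrix(integer(0), ncol = 2))
  in_tree <- c(TRUE, rep(FALSE, k - 1))
  edges <- matrix(0L, nrow = k - 1, ncol = 2)
  for (e in seq_len(k - 1)) {
    dd <- d[in_tree, !in_tree, drop = FALSE]
    j <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    from <- which(in_tree)[j[1]]
    to <- which(!in_tree)[j[2]]
    edges[e, ] <- c(from, to)
    in_tree[to] <- TRUE
  }
  edges
}

# continuous projection of points onto a polyline: for each point, the
# closest position on any segment; returns arc-length coordinate and the
# projected point
project_to_curve <- function(points, curve) {
  m <- nrow(curve)
  seg <- diff(curve)                     # (m-1) x d
  seg_len2 <- rowSums(seg^2)
  cum_len <- c(0, cumsum(sqrt(seg_len2)))
  n <- nrow(points)
  best_d2 <- rep(Inf, n)
  lambda <- numeric(n)
  proj <- matrix(0, n, ncol(points))
  for (j in seq_len(m - 1)) {
    if (seg_len2[j] == 0) next
    rel <- sweep(points, 2, curve[j, ])
    t <- pmin(pmax(as.numeric(rel %*% seg[j, ]) / seg_len2[j], 0), 1)
    pj <- outer(t, seg[j, ]) + matrix(curve[j, ], n, ncol(points), byrow = TRUE)
    d2 <- rowSums((points - pj)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    lambda[upd] <- cum_len[j] + t[upd] * sqrt(seg_len2[j])
    proj[upd, ] <- pj[upd, , drop = FALSE]
  }
  list(lambda = lambda, proj = proj, dist2 = best_d2)
}

# extend a polyline linearly beyond both ends so that samples lying past the
# curve tips project onto a segment (distinct arc lengths) instead of piling
# up on the tip itself
extend_curve <- function(curve, points) {
  m <- nrow(curve)
  dir_from <- function(i, j) {
    d <- curve[j, ] - curve[i, ]
    len <- sqrt(sum(d^2))
    if (len > 0) d / len else NULL
  }
  first_dir <- NULL
  for (j in 2:m) {
    first_dir <- dir_from(1, j)
    if (!is.null(first_dir)) break
  }
  last_dir <- NULL
  for (i in (m - 1):1) {
    last_dir <- dir_from(i, m)
    if (!is.null(last_dir)) break
  }
  if (is.null(first_dir)) return(curve)
  reach <- function(tip) max(sqrt(colSums((t(points) - tip)^2)))
  head_pt <- curve[1, ] - first_dir * reach(curve[1, ])
  tail_pt <- curve[m, ] + last_dir * reach(curve[m, ])
  rbind(head_pt, curve, tail_pt)
}

# symmetric running mean over a window of w neighbours on each side
running_mean <- function(v, w) {
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - w, 1)
  hi <- pmin(seq_len(n) + w, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Infer a single-lineage progression trajectory with pseudotime
#'
#' Builds a minimum spanning tree over the cluster centroids in the PCA
#' embedding, orders it from the seed cluster to form an initial backbone,
#' and then iteratively fits a principal curve: project samples onto the
#' current curve, smooth each coordinate against the projection arc length
#' by a symmetric moving average, and reparametrize by cumulative arc
#' length, until the mean squared projection distance changes by less than a
#' relative `tol` between iterations (or `max_iter` is reached, in which
#' case the last iterate is returned with `converged = FALSE`). Pseudotime
#' is the arc length of
#' each sample's projection, anchored so the seed cluster sits at the
#' low-pseudotime end and the minimum is exactly 0.
#'
#' @param embedding samples x d coordinate matrix (e.g. from [pca_embed()]).
#' @param cluster_labels per-sample cluster labels (e.g. tumor grade);
#'   each cluster needs >= 2 samples.
#' @param seed_cluster label of the starting cluster.
#' @param span smoothing span as a fraction of the sample count.
#' @param tol relative convergence tolerance on the mean squared projection
#'   distance.
#' @param max_iter maximum number of projection/smoothing iterations.
#' @return object of class `trajectory_model`: `pseudotime` (named, min 0),
#'   `curve` (ordered points), `centroids`, `mst_edges`, `converged`,
#'   `n_iter`, `embedding`, `cluster_labels`, `seed_cluster`.
#' @export
infer_trajectory <- function(embedding, cluster_labels, seed_cluster,
                             span = 0.2, tol = 1e-4, max_iter = 50) {
  embedding <- as.matrix(embedding)
  cluster_labels <- as.character(cluster_labels)
  cl_levels <- unique(cluster_labels)
  if (!seed_cluster %in% cl_levels) stop("seed_cluster not among cluster labels")
  if (length(cl_levels) < 2) stop("at least 2 clusters required")
  sizes <- table(cluster_labels)
  if (any(sizes < 2)) {
    stop("cluster(s) with a single sample: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  centroids <- t(vapply(cl_levels, function(l)
    colMeans(embedding[cluster_labels == l, , drop = FALSE]),
    numeric(ncol(embedding))))
  d <- as.matrix(stats::dist(centroids))
  edges <- prim_mst(d)
  # order centroids along the tree from the seed cluster (depth-first;
  # for a single lineage the MST is a path and this is the path order)
  adj <- lapply(seq_len(nrow(centroids)), function(i)
    c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1]))
  start <- match(seed_cluster, cl_levels)
  order_idx <- integer(0)
  visit <- function(i) {
    order_idx <<- c(order_idx, i)
    for (j in adj[[i]]) if (!j %in% order_idx) visit(j)
  }
  visit(start)
  backbone <- centroids[order_idx, , drop = FALSE]
  # densify the backbone so the first projection is smooth
  densify <- function(pts, per_edge = 20) {
    out <- pts[1, , drop = FALSE]
    for (i in seq_len(nrow(pts) - 1)) {
      t <- seq(0, 1, length.out = per_edge + 1)[-1]
      out <- rbind(out, outer(t, pts[i + 1, ] - pts[i, ]) +
                     matrix(pts[i, ], per_edge, ncol(pts), byrow = TRUE))
    }
    out
  }
  curve <- extend_curve(densify(backbone), embedding)
  n <- nrow(embedding)
  w <- max(2L, round(span * n / 2))
  converged <- FALSE
  iter <- 0
  pr <- project_to_curve(embedding, curve)
  prev_fit <- mean(pr$dist2)
  repeat {
    iter <- iter + 1
    # ties in arc length (samples projecting onto the same curve vertex) are
    # broken by coordinates so results do not depend on sample order
    o <- do.call(order, c(list(pr$lambda),
                          lapply(seq_len(ncol(embedding)),
                                 function(j) embedding[, j])))
    curve <- extend_curve(apply(embedding[o, , drop = FALSE], 2,
                                running_mean, w = w), embedding)
    pr <- project_to_curve(embedding, curve)
    # converged when the mean squared projection distance stops moving
    fit <- mean(pr$dist2)
    if (abs(prev_fit - fit) / max(fit, .Machine$double.eps) < tol) {
      converged <- TRUE
      break
    }
    prev_fit <- fit
    if (iter >= max_iter) break
  }
  lambda <- pr$lambda
  seed_samples <- cluster_labels == seed_cluster
  if (mean(lambda[seed_samples]) > mean(lambda[!seed_samples])) {
    lambda <- max(lambda) - lambda
    curve <- curve[rev(seq_len(nrow(curve))), , drop = FALSE]
  }
  lambda <- lambda - min(lambda)
  names(lambda) <- rownames(embedding)
  structure(list(pseudotime = lambda, curve = curve, centroids = centroids,
                 mst_edges = edges, converged = converged, n_iter = iter,
                 embedding = embedding, cluster_labels = cluster_labels,
                 seed_cluster = seed_cluster),
            class = "trajectory_model")
}

#' @export
print.trajectory_model <- function(x, ...) {
  cat("Single-lineage trajectory model\n")
  cat(sprintf("  %d samples, %d clusters (seed: %s), %d MST edge(s)\n",
              nrow(x$embedding), nrow(x$centroids), x$seed_cluster,
              nrow(x$mst_edges)))
  cat(sprintf("  pseudotime range: 0 .. %.3f; converged: %s (%d iterations)\n",
              max(x$pseudotime), x$converged, x$n_iter))
  invisible(x)
}

#' @export
predict.trajectory_model <- function(object, newdata, ...) {
  pr <- project_to_curve(as.matrix(newdata), object$curve)
  pr$lambda
}

#' @export
plot.trajectory_model <- function(x, ...) {
  cl <- factor(x$cluster_labels)
  graphics::plot(x$embedding[, 1], x$embedding[, 2], col = as.integer(cl),
                 pch = 16, cex = 0.6, xlab = "PC1", ylab = "PC2",
                 main = "Progression trajectory", ...)
  graphics::lines(x$curve[, 1], x$curve[, 2], lwd = 2)
  graphics::points(x$centroids[, 1], x$centroids[, 2], pch = 4, cex = 1.5,
                   lwd = 2)
  graphics::legend("topright", legend = levels(cl), col = seq_len(nlevels(cl)),
                   pch = 16, cex = 0.8)
  invisible(x)
}

#' Resampled pseudotime-gene correlation with FDR control
#'
#' Robustified per-gene association with pseudotime: draws `n_draws` random
#' subsets each containing `frac_keep` of the samples (without replacement),
#' computes the Pearson correlation of each gene with pseudotime in every
#' subset, and reports the median correlation across draws. The p-value is
#' computed from the t-statistic of the median correlation at the subset
#' size, with Benjamini-Hochberg FDR across genes. Constant genes are
#' excluded with a flag.
#'
#' @param x genes x samples expression matrix.
#' @param pseudotime per-sample pseudotime (length = samples).
#' @param n_draws number of resampling draws.
#' @param frac_keep fraction of samples per draw.
#' @param seed integer seed.
#' @param p_method `"median_r"` (p of the median correlation, default) or
#'   `"median_p"` (median of the per-draw p-values).
#' @return data frame of class `correlation_table`: `gene`, `median_r`, `p`,
#'   `fdr`, `n_draws`; constant genes are dropped and recorded in the
#'   `excluded` attribute.
#' @export
pseudotime_correlation <- function(x, pseudotime, n_draws = 20,
                                   frac_keep = 2 / 3, seed = NULL,
                                   p_method = c("median_r", "median_p")) {
  p_method <- match.arg(p_method)
  if (n_draws < 1) stop("n_draws must be >= 1")
  n <- ncol(x)
  if (length(pseudotime) != n) stop("pseudotime must have one value per sample")
  const <- apply(x, 1, stats::sd) == 0
  excluded <- rownames(x)[const]
  if (any(const)) x <- x[!const, , drop = FALSE]
  m <- ceiling(frac_keep * n)
  rmat <- with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      idx <- sample.int(n, m)
      as.numeric(stats::cor(pseudotime[idx], t(x[, idx, drop = FALSE])))
    }, numeric(nrow(x)))
  })
  rmat <- matrix(rmat, nrow = nrow(x))
  med_r <- apply(rmat, 1, stats::median)
  p_of_r <- function(r, size) {
    r <- pmin(pmax(r, -1), 1)
    tt <- r * sqrt((size - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = size - 2)
    p[abs(r) >= 1] <- 0
    p
  }
  p <- if (p_method == "median_r") p_of_r(med_r, m)
    else apply(p_of_r(rmat, m), 1, stats::median)
  out <- data.frame(gene = rownames(x), median_r = med_r, p = p,
                    fdr = stats::p.adjust(p, method = "BH"),
                    n_draws = n_draws, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  class(out) <- c("correlation_table", "data.frame")
  out
}

# weighted Kolmogorov-Smirnov enrichment score from sorted hit positions.
# stat_sorted: |statistic|^weight for the full ranked list; pos: hit indices.
es_from_positions <- function(stat_w, pos, n) {
  pos <- sort(pos)
  k <- length(pos)
  w <- stat_w[pos]
  tot <- sum(w)
  cumhit <- if (tot > 0) cumsum(w) / tot else seq_len(k) / k
  # deviation candidates right after each hit and right before each hit;
  # when the set covers the whole list the walk is compared against uniform
  # progress so it still returns to 0
  if (n > k) {
    miss_step <- 1 / (n - k)
    after <- cumhit - (pos - seq_len(k)) * miss_step
    before <- c(0, cumhit[-k]) - (pos - seq_len(k)) * miss_step
  } else {
    after <- cumhit - pos / n
    before <- c(0, cumhit[-k]) - (pos - 1) / n
  }
  cand <- c(after, before)
  unname(cand[which.max(abs(cand))])
}

#' Preranked gene set enrichment with a permutation null
#'
#' Weighted Kolmogorov-Smirnov enrichment: genes are ranked by the supplied
#' statistic (decreasing); walking down the list, hits increment the running
#' score proportionally to `|stat|^weight` (normalized) and misses decrement
#' it by `1/(N - set size)`; the enrichment score (ES) is the maximum
#' deviation of the walk. The null is formed by randomly permuting gene
#' labels (`n_perm` draws per set); the permutation p-value compares `|ES|`
#' against the null magnitudes, `p = (1 + #{|ES_perm| >= |ES|}) /
#' (n_perm + 1)`; NES normalizes ES by the mean magnitude of same-sign null
#' scores. FDR is Benjamini-Hochberg across sets.
#'
#' @param ranked_stats named numeric vector, gene-level statistics (e.g.
#'   pseudotime correlations); names must be unique.
#' @param gene_sets named list of character vectors.
#' @param n_perm permutations per set.
#' @param weight hit-increment exponent (1 = classic weighted).
#' @param min_size minimum overlap with the ranked list.
#' @param seed integer seed.
#' @return data frame of class `enrichment_table`: `gene_set`, `es`, `nes`,
#'   `p_perm`, `fdr`, `size`.
#' @export
gsea_preranked <- function(ranked_stats, gene_sets, n_perm = 1000, weight = 1,
                           min_size = 5, seed = NULL) {
  if (anyDuplicated(names(ranked_stats))) stop("duplicate gene ids in ranked list")
  o <- order(ranked_stats, decreasing = TRUE)
  stats_sorted <- ranked_stats[o]
  genes <- names(stats_sorted)
  n <- length(genes)
  stat_w <- abs(stats_sorted)^weight
  with_seed(seed, {
    rows <- lapply(names(gene_sets), function(gs) {
      pos <- which(genes %in% gene_sets[[gs]])
      k <- length(pos)
      if (k < min_size) {
        if (k == 0) stop("gene set '", gs, "' has no overlap with the ranked list")
        return(NULL)
      }
      es <- es_from_positions(stat_w, pos, n)
      perm <- vapply(seq_len(n_perm), function(i)
        es_from_positions(stat_w, sample.int(n, k), n), numeric(1))
      p <- (1 + sum(abs(perm) >= abs(es))) / (n_perm + 1)
      same <- perm[sign(perm) == sign(es)]
      nes <- if (length(same)) es / mean(abs(same)) else NA_real_
      data.frame(gene_set = gs, es = es, nes = nes, p_perm = p, size = k,
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows)) stop("no gene set reached the minimum overlap of ", min_size)
    rows$fdr <- stats::p.adjust(rows$p_perm, method = "BH")
    rows <- rows[, c("gene_set", "es", "nes", "p_perm", "fdr", "size")]
    class(rows) <- c("enrichment_table", "data.frame")
    rows
  })
}

#' Two-group Kaplan-Meier survival analysis by expression split
#'
#' Removes samples with missing survival data, splits the cohort at the
#' median of the supplied expression values, estimates the Kaplan-Meier
#' curve per group, and tests the difference with the two-group log-rank
#' test. With no events at all the curves are flat at 1 and p is 1 by
#' convention.
#'
#' @param expression per-sample expression values for one gene.
#' @param survival_time follow-up times.
#' @param event event indicator (1 = death, 0 = censored).
#' @param split `"median"` (only supported split).
#' @return list of class `km_twogroup`: `fit` (a `survfit` object or NULL),
#'   `chisq`, `p`, `groups` (per-group n and events), `n_removed`.
#' @export
km_twogroup <- function(expression, survival_time, event, split = "median") {
  stopifnot(split == "median")
  ok <- !(is.na(expression) | is.na(survival_time) | is.na(event))
  n_removed <- sum(!ok)
  expression <- expression[ok]
  survival_time <- survival_time[ok]
  event <- event[ok]
  med <- stats::median(expression)
  group <- factor(ifelse(expression > med, "high", "low"),
                  levels = c("low", "high"))
  if (any(table(group) == 0)) {
    stop("all expression values tied at the median; cannot form two groups")
  }
  groups <- data.frame(group = levels(group),
                       n = as.integer(table(group)),
                       events = as.integer(tapply(event, group, sum)))
  if (sum(event) == 0) {
    fit <- survival::survfit(survival::Surv(survival_time, event) ~ group)
    return(structure(list(fit = fit, chisq = 0, p = 1, groups = groups,
                          n_removed = n_removed), class = "km_twogroup"))
  }
  if (sum(event) < 2) warning("fewer than 2 events; log-rank test is unreliable")
  fit <- survival::survfit(survival::Surv(survival_time, event) ~ group)
  sd <- survival::survdiff(survival::Surv(survival_time, event) ~ group)
  chisq <- unname(sd$chisq)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  structure(list(fit = fit, chisq = chisq, p = p, groups = groups,
                 n_removed = n_removed), class = "km_twogroup")
}

#' @export
print.km_twogroup <- function(x, ...) {
  cat("Two-group Kaplan-Meier analysis (median expression split)\n")
  print(x$groups, row.names = FALSE)
  cat(sprintf("log-rank chi-square = %.4g, p = %.4g %s\n",
              x$chisq, x$p, significance_stars(x$p)))
  if (x$n_removed > 0) cat(x$n_removed, "sample(s) with missing data removed\n")
  invisible(x)
}

#' @export
plot.km_twogroup <- function(x, ...) {
  graphics::plot(x$fit, col = c(1, 2), xlab = "Time", ylab = "Survival",
                 main = "Two-group overall survival", ...)
  graphics::legend("bottomleft", legend = x$groups$group, col = c(1, 2),
                   lty = 1)
  invisible(x)
}
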