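test_that("moderated t matches direct evaluation on a hand-sized toy", {
  vals <- rbind(
    g1 = c(5.0, 5.2, 4.8, 5.1, 1.0, 1.2, 0.9, 1.1),
    g2 = c(2.0, 2.1, 1.9, 2.0, 2.1, 2.0, 2.2, 1.9),
    g3 = c(0.5, 1.5, 1.0, 1.2, 3.0, 2.5, 3.5, 2.8))
  colnames(vals) <- c(paste0("a", 1:4), paste0("b", 1:4))
  m <- log_matrix(vals)
  tab <- moderated_t(m, paste0("a", 1:4), paste0("b", 1:4))

  # oracle: direct arithmetic of the stated formulas
  A <- vals[, 1:4]; B <- vals[, 5:8]
  logfc <- rowMeans(A) - rowMeans(B)
  dg <- 6
  s2 <- (rowSums((A - rowMeans(A))^2) + rowSums((B - rowMeans(B))^2)) / dg
  expect_equal(tab$logFC, unname(logfc))
  d0 <- attr(tab, "d0"); s0 <- attr(tab, "s0_sq")
  s2p <- (d0 * s0 + dg * s2) / (d0 + dg)
  t_or <- logfc / sqrt(s2p * (1 / 4 + 1 / 4))
  expect_equal(tab$t, unname(t_or))
  expect_equal(tab$p, unname(2 * pt(-abs(t_or), df = min(d0 + dg, 1e6))))
  expect_equal(tab$p_adj, pmin(1, tab$p * 3))
})

test_that("moderated t agrees with the limma empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(31)
  n <- 250; nA <- 5; nB <- 7
  sds <- sqrt(1 / rgamma(n, 4, 4))
  vals <- matrix(rnorm(n * (nA + nB), sd = rep(sds, nA + nB)), n, nA + nB,
                 dimnames = list(sprintf("g%03d", 1:n),
                                 sprintf("c%02d", 1:(nA + nB))))
  vals[1:12, 1:nA] <- vals[1:12, 1:nA] + 4
  tab <- moderated_t(log_matrix(vals), sprintf("c%02d", 1:nA),
                     sprintf("c%02d", (nA + 1):(nA + nB)))
  fit <- limma::eBayes(limma::lmFit(vals, cbind(1, rep(c(1, 0), c(nA, nB)))))
  expect_equal(attr(tab, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(tab, "s0_sq"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(tab$t, unname(fit$t[, 2]), tolerance = 1e-9)
  expect_equal(tab$p, unname(fit$p.value[, 2]), tolerance = 1e-9)
})

test_that("swapping cohorts negates logFC and t, preserves p", {
  set.seed(5)
  vals <- matrix(rnorm(50 * 8), 50, 8,
                 dimnames = list(sprintf("g%02d", 1:50),
                                 sprintf("c%02d", 1:8)))
  m <- log_matrix(vals)
  a <- sprintf("c%02d", 1:4); b <- sprintf("c%02d", 5:8)
  t_ab <- moderated_t(m, a, b)
  t_ba <- moderated_t(m, b, a)
  expect_equal(t_ab$logFC, -t_ba$logFC)
  expect_equal(t_ab$t, -t_ba$t)
  expect_equal(t_ab$p, t_ba$p)
  expect_true(all(t_ab$p_adj >= t_ab$p))
})

test_that("homogeneous gene variances collapse to the ordinary pooled t", {
  # all genes share the same sample variance -> shrinkage has a fixed point:
  # the prior absorbs everything (d0 hits its cap) and every gene gets the
  # same posterior variance, so t is the ordinary pooled t up to the finite-
  # sample moment correction of the prior scale, which vanishes as df grows
  run_case <- function(n_per_group, tol) {
    set.seed(7)
    n <- 2 * n_per_group
    base <- rnorm(n)
    base <- (base - mean(base)) / sd(base)
    vals <- t(sapply(1:40, function(i) base + i))
    dimnames(vals) <- list(sprintf("g%02d", 1:40), sprintf("c%03d", 1:n))
    a <- sprintf("c%03d", 1:n_per_group)
    b <- sprintf("c%03d", (n_per_group + 1):n)
    tab <- moderated_t(log_matrix(vals), a, b)
    expect_equal(attr(tab, "d0"), 1e6)          # infinite-shrinkage cap
    expect_lt(diff(range(tab$t)), 1e-10)         # one t for all genes
    ord_t <- t.test(vals[1, seq_len(n_per_group)],
                    vals[1, (n_per_group + 1):n],
                    var.equal = TRUE)$statistic
    expect_equal(tab$t[1], unname(ord_t), tolerance = tol)
  }
  # the moment correction is exp(log(df/2) - digamma(df/2)) ~ 1 + 1/df
  run_case(4, 0.1)
  run_case(25, 0.02)
})

test_that("zero-variance genes are flagged with p = 1", {
  vals <- rbind(g1 = c(1, 1, 1, 2, 2, 2), g2 = c(1, 2, 1.5, 3, 2, 4))
  colnames(vals) <- sprintf("c%02d", 1:6)
  m <- log_matrix(vals)
  tab <- moderated_t(m, sprintf("c%02d", 1:3), sprintf("c%02d", 4:6))
  expect_true(tab$zero_variance[1])
  expect_equal(tab$p[1], 1)
  expect_true(is.na(tab$t[1]))
  expect_error(moderated_t(m, c("c01", "c02"), c("c02", "c03")), "disjoint")
  expect_error(moderated_t(m, "c01", sprintf("c%02d", 2:6)), "at least 2")
})

test_that("deg_filter applies both cutoffs to the significance flag", {
  tab <- data.frame(gene = c("a", "b", "c"),
                    logFC = c(2.5, 1.0, 3.0),
                    t = c(5, 5, 5),
                    p = c(1e-4, 1e-4, 2e-3),
                    p_adj = c(0.004, 0.004, 0.006))
  out <- deg_filter(tab)
  expect_identical(out$significant, c(TRUE, FALSE, FALSE))
  out2 <- deg_filter(tab, alpha = 0.01, lfc_cut = 2)
  expect_identical(out2$significant, c(TRUE, FALSE, TRUE))
})

test_that("top_variable_genes matches a brute-force variance sort", {
  set.seed(11)
  vals <- matrix(rnorm(20 * 15, sd = rep(runif(20, 0.1, 3), 15)), 20, 15,
                 dimnames = list(sprintf("g%02d", 1:20),
                                 sprintf("c%02d", 1:15)))
  m <- log_matrix(vals)
  v <- apply(vals, 1, var)
  oracle <- names(sort(v, decreasing = TRUE))
  expect_identical(top_variable_genes(m, 5), oracle[1:5])
  expect_identical(top_variable_genes(m, 20), oracle)
  expect_error(top_variable_genes(m, 21), "exceeds")

  vals2 <- vals
  vals2["g07", ] <- rnorm(15, sd = 50)
  expect_identical(top_variable_genes(log_matrix(vals2), 1), "g07")
})

test_that("pca separates planted clusters and respects duplication", {
  set.seed(13)
  n_g <- 30
  c1 <- matrix(rnorm(n_g * 10, 0, 0.3), n_g, 10)
  c2 <- matrix(rnorm(n_g * 10, 0, 0.3), n_g, 10) + 5
  vals <- cbind(c1, c2)
  dimnames(vals) <- list(sprintf("g%02d", 1:n_g), sprintf("c%02d", 1:20))
  m <- log_matrix(vals)
  co <- pca_embed(m, k = 3)
  pc1 <- co[, 1]
  between <- abs(mean(pc1[1:10]) - mean(pc1[11:20]))
  within <- mean(c(sd(pc1[1:10]), sd(pc1[11:20])))
  expect_gt(between / within, 5)

  # duplicated cell gets identical coordinates
  vals_dup <- cbind(vals, c21 = vals[, 1])
  co2 <- pca_embed(log_matrix(vals_dup), k = 2)
  expect_equal(co2["c21", ], co2["c01", ])

  # full-rank embedding conserves total centered variance
  small <- log_matrix(vals[1:5, 1:6])
  cofull <- pca_embed(small, k = 5)
  expect_equal(sum(cofull^2), sum(scale(t(small$values), scale = FALSE)^2))
  expect_error(pca_embed(small, k = 10), "rank")
})

test_that("pca embedding is invariant (up to nothing) to cell order", {
  set.seed(14)
  vals <- matrix(rnorm(20 * 12), 20, 12,
                 dimnames = list(sprintf("g%02d", 1:20),
                                 sprintf("c%02d", 1:12)))
  m <- log_matrix(vals)
  co <- pca_embed(m, k = 2)
  perm <- sample(colnames(vals))
  co_p <- pca_embed(log_matrix(vals[, perm]), k = 2)
  expect_equal(co_p[rownames(co), ], co[, ], tolerance = 1e-8)
})

test_that("zscore_rows standardises rows and is idempotent", {
  vals <- rbind(g1 = c(1, 2, 3), g2 = c(4, 4, 4))
  colnames(vals) <- c("c1", "c2", "c3")
  m <- expression_matrix(vals, "TPM")
  expect_warning(z <- zscore_rows(m), "constant")
  expect_equal(unname(z$values["g1", ]), c(-1, 0, 1))
  expect_equal(unname(z$values["g2", ]), c(0, 0, 0))
  expect_identical(z$unit_tag, "ZSCORE")
  z2 <- suppressWarnings(zscore_rows(z))
  expect_equal(z2$values["g1", ], z$values["g1", ])
})

test_that("hierarchical clustering matches brute-force agglomeration", {
  # trivial geometry: the close pair merges first
  x <- matrix(c(0, 0, 1, 0, 10, 0), 3, 2, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"), NULL))
  hc <- hcluster(x, "average")
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))

  # 6-item toy vs an explicit pairwise-merge simulation (average linkage)
  set.seed(17)
  y <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("i", 1:6), NULL))
  hc2 <- hcluster(y, "average")
  clusters <- as.list(1:6)
  d <- as.matrix(dist(y))
  merges <- list()
  heights <- numeric()
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      dd <- mean(d[clusters[[i]], clusters[[j]], drop = FALSE])
      if (dd < best_d) { best_d <- dd; best <- c(j, i) }
    }
    merges <- c(merges, list(sort(unlist(clusters[best]))))
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- unlist(clusters[best])
    clusters[[best[2]]] <- NULL
  }
  # compare merge heights and member sets at each merge
  got_members <- lapply(seq_len(nrow(hc2$merge)), function(k) {
    collect <- function(kk) {
      r <- hc2$merge[kk, ]
      unlist(lapply(r, function(e) if (e < 0) -e else collect(e)))
    }
    sort(collect(k))
  })
  expect_equal(hc2$height, heights)
  expect_equal(got_members, merges)

  # duplicated item merges first at height 0
  z <- rbind(y, i7 = y[1, ])
  hc3 <- hcluster(z, "complete")
  expect_equal(hc3$height[1], 0)
  expect_setequal(hc3$merge[1, ], c(-1, -7))
})

test_that("newick serialisation covers all leaves", {
  set.seed(19)
  y <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("i", 1:5), NULL))
  nwk <- tree_newick(hcluster(y, "average"))
  expect_match(nwk, "^\\(.*\\);$")
  for (lab in rownames(y)) expect_match(nwk, lab, fixed = TRUE)
})

test_that("wilcoxon pairwise matches rank-sum enumeration and extremes", {
  # 5 vs 5: W from first principles (rank sum minus its minimum)
  ref <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  cmp <- c(0.5, 2.8, 1.9, 3.9, 0.1)
  ranks <- rank(c(ref, cmp))
  w_oracle <- sum(ranks[1:5]) - 5 * 6 / 2
  groups <- list(make_group("R", paste0("r", 1:5)),
                 make_group("C", paste0("c", 1:5)))
  sc <- cell_scores("s", stats::setNames(c(ref, cmp),
                                         c(paste0("r", 1:5), paste0("c", 1:5))))
  out <- wilcoxon_pairwise(sc, groups, "R", exact = TRUE)
  expect_equal(out$W, w_oracle)

  # identical distributions: p near 1
  sc_same <- cell_scores("s", stats::setNames(rep(c(1, 2, 3, 4, 5), 2),
                                              c(paste0("r", 1:5),
                                                paste0("c", 1:5))))
  out_same <- wilcoxon_pairwise(sc_same, groups, "R")
  expect_gt(out_same$p, 0.9)

  # complete separation: the minimal attainable p for 5 vs 5 (exact test)
  sc_sep <- cell_scores("s", stats::setNames(c(6:10, 1:5),
                                             c(paste0("r", 1:5),
                                               paste0("c", 1:5))))
  out_sep <- wilcoxon_pairwise(sc_sep, groups, "R", exact = TRUE)
  expect_equal(out_sep$W, 25)
  expect_equal(out_sep$p, 2 / choose(10, 5))
})

test_that("wilcoxon pairwise removes overlap and adjusts p-values", {
  set.seed(23)
  ids_r <- paste0("r", 1:10)
  ids_c <- c("r1", paste0("c", 1:9))
  ids_d <- paste0("d", 1:8)
  all_ids <- unique(c(ids_r, ids_c, ids_d))
  sc <- cell_scores("s", stats::setNames(rnorm(length(all_ids)), all_ids))
  groups <- list(make_group("R", ids_r), make_group("C", ids_c),
                 make_group("D", ids_d))
  expect_warning(out <- wilcoxon_pairwise(sc, groups, "R"), "shared")
  expect_equal(out$n_cmp[out$group == "C"], 9)
  expect_equal(out$p_adj, pmin(1, out$p * 2))
  small <- list(make_group("R", ids_r), make_group("S", c("s1", "s2")))
  sc2 <- cell_scores("s", stats::setNames(rnorm(12), c(ids_r, "s1", "s2")))
  expect_error(wilcoxon_pairwise(sc2, small, "R"), "fewer than 3")
})
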