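make_expr <- function(ind, ctl, genes = sprintf("g%03d", seq_len(nrow(ind)))) {
  colnames(ind) <- paste0("i", seq_len(ncol(ind)))
  colnames(ctl) <- paste0("c", seq_len(ncol(ctl)))
  expr <- dplyr::bind_cols(tibble::tibble(gene = genes),
                           tibble::as_tibble(ind), tibble::as_tibble(ctl))
  samples <- tibble::tibble(
    sample_id = c(colnames(ind), colnames(ctl)),
    tf = "TFX",
    condition = rep(c("induced", "control"), c(ncol(ind), ncol(ctl))),
    replicate = c(seq_len(ncol(ind)), seq_len(ncol(ctl)))
  )
  list(expr = expr, samples = samples)
}

test_that("identical induced and control replicates give zero logratios", {
  set.seed(1)
  m <- matrix(rnorm(60, 2.5, 0.5), 20)
  d <- make_expr(m, m)
  pr <- compute_induction_profile(d$expr, d$samples, "TFX")
  expect_true(all(abs(pr$logratio) < 1e-12))
  expect_true(all(abs(pr$fold - 1) < 1e-12))
})

test_that("logratio is the difference of group means and FDR dominates p", {
  set.seed(2)
  ind <- matrix(rnorm(300, 3, 0.1), 100)
  ctl <- matrix(rnorm(300, 2.8, 0.1), 100)
  d <- make_expr(ind, ctl)
  for (method in c("moderated", "welch")) {
    pr <- compute_induction_profile(d$expr, d$samples, "TFX", method = method)
    expect_equal(pr$logratio, unname(rowMeans(ind) - rowMeans(ctl)))
    expect_true(all(pr$fdr >= pr$p - 1e-15))
    expect_true(all(pr$fold >= 1))
  }
})

test_that("welch p-values match stats::t.test when variances are healthy", {
  set.seed(3)
  ind <- matrix(rnorm(40, 3, 0.6), 10)
  ctl <- matrix(rnorm(40, 3, 0.6), 10)
  d <- make_expr(ind, ctl)
  pr <- compute_induction_profile(d$expr, d$samples, "TFX", method = "welch")
  oracle <- sapply(1:10, function(i) t.test(ind[i, ], ctl[i, ])$p.value)
  expect_equal(pr$p, oracle, tolerance = 1e-12)
})

test_that("a planted effect is recovered as the noise vanishes", {
  set.seed(4)
  base <- rnorm(50, 2.5, 0.7)
  eff <- c(log10(2), rep(0, 49))
  mk <- function(noise) {
    ind <- base + eff + matrix(rnorm(150, 0, noise), 50)
    ctl <- base + matrix(rnorm(150, 0, noise), 50)
    make_expr(ind, ctl)
  }
  d <- mk(1e-7)
  pr <- compute_induction_profile(d$expr, d$samples, "TFX")
  expect_equal(pr$logratio[1], log10(2), tolerance = 1e-5)
})

test_that("missing TF or condition raises a clear error", {
  set.seed(5)
  d <- make_expr(matrix(rnorm(30), 10), matrix(rnorm(30), 10))
  expect_error(compute_induction_profile(d$expr, d$samples, "NOPE"), "NOPE")
  only_ind <- d$samples[d$samples$condition == "induced", ]
  expect_error(compute_induction_profile(d$expr, only_ind, "TFX"), "control")
})

test_that("responder thresholds are inclusive on both boundaries", {
  pr <- make_profile(
    gene = c("a", "b", "c", "d"),
    logratio = c(log10(1.5), -log10(1.49), log10(3), log10(1.2)),
    fdr = c(0.05, 0.049, 0.051, 0.01)
  )
  sig <- significant_genes(pr, fdr_max = 0.05, min_fold = 1.5)
  expect_equal(sig$gene, "a")           # fold 1.5, fdr 0.05: both inclusive
  expect_equal(sig$direction, "up")
})

test_that("responder counts aggregate the per-profile calls", {
  p1 <- make_profile(c("a", "b", "c"), c(0.5, -0.4, 0.01),
                     fdr = c(0.01, 0.02, 0.9), tf = "T1")
  p2 <- make_profile(c("a", "b", "c"), c(0.3, 0.3, -0.3),
                     fdr = c(0.01, 0.01, 0.01), tf = "T2")
  counts <- count_responders(list(p1, p2))
  expect_equal(counts$tf, c("T1", "T2"))
  expect_equal(counts$n_up, c(1L, 2L))
  expect_equal(counts$n_down, c(1L, 1L))
})

test_that("profile PCA satisfies its algebraic identities", {
  set.seed(6)
  genes <- sprintf("g%03d", 1:40)
  # all genes clear the fold threshold so the PCA universe is all 40 genes
  rlr <- function() sample(c(-1, 1), 40, TRUE) * runif(40, 0.2, 0.6)
  mk <- function(tf, lr) make_profile(genes, lr, fdr = rep(0.01, 40), tf = tf)
  profs <- list(mk("T1", rlr()), mk("T2", rlr()),
                mk("T3", rlr()), mk("T4", rlr()))
  pca <- pca_profiles(profs)
  # orthonormal loadings
  G <- pca$loadings
  expect_equal(t(G) %*% G, diag(ncol(G)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # explained variances sum to total variance of the centred data
  lr <- sapply(profs, function(p) p$logratio)
  total <- sum(apply(t(lr), 2, function(x) sum((x - mean(x))^2))) /
    (nrow(t(lr)) - 1)
  expect_equal(sum(pca$var_explained), total, tolerance = 1e-10)
  # deterministic sign: the largest loading of each PC is positive
  for (k in seq_len(ncol(G))) {
    expect_gt(G[which.max(abs(G[, k])), k], 0)
  }
})

test_that("identical profiles map to the same PCA point", {
  set.seed(7)
  genes <- sprintf("g%03d", 1:30)
  lr <- sample(c(-1, 1), 30, TRUE) * runif(30, 0.2, 0.6)
  lr2 <- sample(c(-1, 1), 30, TRUE) * runif(30, 0.2, 0.6)
  p1 <- make_profile(genes, lr, fdr = rep(0.01, 30), tf = "T1")
  p2 <- make_profile(genes, lr, fdr = rep(0.01, 30), tf = "T2")
  p3 <- make_profile(genes, lr2, fdr = rep(0.01, 30), tf = "T3")
  pca <- pca_profiles(list(p1, p2, p3))
  s <- as.matrix(pca$scores[, -1])
  expect_equal(s[1, ], s[2, ], tolerance = 1e-10)
})

test_that("PCA errors when no gene is significant anywhere", {
  genes <- paste0("g", 1:10)
  p1 <- make_profile(genes, rnorm(10), fdr = rep(0.9, 10), tf = "T1")
  p2 <- make_profile(genes, rnorm(10), fdr = rep(0.9, 10), tf = "T2")
  expect_error(pca_profiles(list(p1, p2)), "significant")
})
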