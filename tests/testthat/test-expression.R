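test_that("quantile normalization maps columns onto the mean order statistics", {
  m <- cbind(a = c(1, 3), b = c(2, 4))
  q <- quantileNormalize(m)
  expect_equal(unname(q[, "a"]), c(1.5, 3.5))
  expect_equal(unname(q[, "b"]), c(1.5, 3.5))

  # identical columns are a fixed point; the map is idempotent
  m2 <- cbind(x = c(5, 1, 3), y = c(5, 1, 3))
  expect_equal(quantileNormalize(m2), m2)
  set.seed(1)
  m3 <- matrix(rnorm(60), 20, 3)
  expect_equal(quantileNormalize(quantileNormalize(m3)),
               quantileNormalize(m3))
})

test_that("quantile normalization equalizes sorted columns and preserves ranks", {
  set.seed(2)
  m <- matrix(rexp(100), 25, 4)
  q <- quantileNormalize(m)
  sorted <- apply(q, 2, sort)
  for (j in 2:4) expect_equal(sorted[, j], sorted[, 1])
  for (j in 1:4) expect_identical(order(q[, j]), order(m[, j]))
  expect_error(quantileNormalize(matrix(c(1, NA, 2, 3), 2)), "non-finite")
})

test_that("tied values share the mean of their order-statistic means", {
  m <- cbind(c(1, 1, 5), c(2, 4, 6))
  q <- quantileNormalize(m)
  ref <- rowMeans(apply(m, 2, sort))
  expect_equal(unname(q[1:2, 1]), rep(mean(ref[1:2]), 2))
  skip_if_not_installed("limma")
  expect_equal(unname(q), unname(limma::normalizeQuantiles(m)))
})

test_that("median polish reproduces additive structure exactly", {
  m <- rbind(c(0, 2), c(1, 3))       # value(i,j) = r_i + c_j
  mp <- medianPolishSummarize(m)
  expect_true(mp$converged)
  expect_equal(max(abs(mp$residuals)), 0)
  expect_equal(unname(diff(mp$summary)), 2)

  single <- matrix(c(4, 7, 1), 1)
  expect_equal(unname(medianPolishSummarize(single)$summary), c(4, 7, 1))
})

test_that("median polish matches independent sweep oracles on random data", {
  sweepOracle <- function(m, iters = 200) {
    t <- 0; r <- numeric(nrow(m)); cc <- numeric(ncol(m))
    for (i in seq_len(iters)) {
      rm <- apply(m - t - outer(r, cc, "+"), 1, median); r <- r + rm
      s <- median(r); r <- r - s; t <- t + s
      cm <- apply(m - t - outer(r, cc, "+"), 2, median); cc <- cc + cm
      s <- median(cc); cc <- cc - s; t <- t + s
    }
    list(summary = t + cc, row = r)
  }
  set.seed(3)
  for (i in 1:5) {
    m <- matrix(rnorm(20), 5, 4)
    mine <- medianPolishSummarize(m, tol = 1e-12, max_iter = 500)
    want <- sweepOracle(m)
    expect_equal(unname(mine$summary), want$summary, tolerance = 1e-9)
    ref <- stats::medpolish(m, eps = 1e-12, maxiter = 500, trace.iter = FALSE)
    expect_equal(unname(mine$summary), unname(ref$overall + ref$col),
                 tolerance = 1e-8)
  }
})

simpleDesign <- function(nA, nB, condA = "A", condB = "B") {
  data.frame(sample = c(paste0("a", seq_len(nA)), paste0("b", seq_len(nB))),
             condition = rep(c(condA, condB), c(nA, nB)),
             replicate = c(seq_len(nA), seq_len(nB)))
}

test_that("with shrinkage disabled the moderated t is the classical pooled t", {
  m <- rbind(g1 = c(1, 2, 3, 3, 4, 5))
  colnames(m) <- simpleDesign(3, 3)$sample
  de <- moderatedTTest(m, "A", "B", design = simpleDesign(3, 3),
                       prior_df = 0)
  expect_equal(de$t, -2.449, tolerance = 1e-3)
  expect_equal(de$df_resid, 4)
  expect_equal(de$p, 2 * pt(-abs(de$t), 4))
  expect_equal(de$p, 0.0705, tolerance = 1e-3)
  ref <- t.test(c(1, 2, 3), c(3, 4, 5), var.equal = TRUE)
  expect_equal(de$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(de$p, ref$p.value, tolerance = 1e-12)
})

test_that("a gene identical in both groups gets t = 0, p = 1", {
  m <- rbind(flat = c(2, 2, 2, 2, 2, 2), var = c(1, 2, 3, 1, 2, 3))
  colnames(m) <- simpleDesign(3, 3)$sample
  # with one usable variance the prior cannot be estimated: shrinkage-free
  # fallback, with a warning
  expect_warning(
    de <- moderatedTTest(m, "A", "B", design = simpleDesign(3, 3)),
    "too few")
  expect_identical(de$t[1], 0)
  expect_identical(de$p[1], 1)
  expect_error(
    moderatedTTest(m[, 1:4], "A", "B",
                   design = simpleDesign(3, 1)), "2 replicates")
})

test_that("the d0 -> Inf limit pools all genes onto the prior variance", {
  set.seed(4)
  m <- matrix(rnorm(600), 100, 6)
  colnames(m) <- simpleDesign(3, 3)$sample
  de <- moderatedTTest(m, "A", "B", design = simpleDesign(3, 3),
                       prior_df = Inf)
  expect_equal(length(unique(round(de$s2_post, 12))), 1L)
  expect_equal(de$p, 2 * pnorm(-abs(de$t)), tolerance = 1e-9)
})

test_that("hyperparameters are recovered from a known generative truth", {
  set.seed(5)
  ngene <- 2000; d0 <- 4; s20 <- 0.04
  vars <- s20 * d0 / rchisq(ngene, d0)
  m <- matrix(rnorm(ngene * 6, 0, sqrt(rep(vars, 6))), ngene, 6)
  colnames(m) <- simpleDesign(3, 3)$sample
  de <- moderatedTTest(m, "A", "B", design = simpleDesign(3, 3))
  expect_lt(abs(attr(de, "prior_df") - d0) / d0, 0.25)
  expect_lt(abs(attr(de, "prior_var") - s20) / s20, 0.25)
  # raw p-values approximately uniform under the null
  ks <- suppressWarnings(ks.test(de$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # empirical type-I error at raw p < 0.05 within binomial 99% bounds
  bounds <- qbinom(c(0.005, 0.995), ngene, 0.05) / ngene
  expect_gte(mean(de$p < 0.05), bounds[1])
  expect_lte(mean(de$p < 0.05), bounds[2])
})

test_that("estimates and statistics agree with the limma empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(6)
  ngene <- 300
  vars <- 0.05 * 5 / rchisq(ngene, 5)
  m <- matrix(rnorm(ngene * 6, 0, sqrt(rep(vars, 6))), ngene, 6)
  m[1:20, 1:3] <- m[1:20, 1:3] + 1.5
  rownames(m) <- paste0("g", seq_len(ngene))
  colnames(m) <- simpleDesign(3, 3)$sample
  design <- cbind(B = 1, AvsB = rep(c(1, 0), each = 3))
  fit <- limma::eBayes(limma::lmFit(m, design))
  de <- moderatedTTest(m, "A", "B", design = simpleDesign(3, 3))
  expect_equal(attr(de, "prior_df"), fit$df.prior, tolerance = 0.1)
  expect_equal(attr(de, "prior_var"), fit$s2.prior, tolerance = 0.05)
  # with the prior fixed to limma's values the statistics match exactly
  de2 <- moderatedTTest(m, "A", "B", design = simpleDesign(3, 3),
                        prior_df = fit$df.prior, prior_var = fit$s2.prior)
  expect_equal(de2$t, fit$t[, "AvsB"], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(de2$p, fit$p.value[, "AvsB"], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  stepUp <- function(p) {
    m <- length(p)
    vapply(seq_along(p), function(i) {
      min(1, min(m * p[p >= p[i] - 1e-15] /
                   rank(p, ties.method = "max")[p >= p[i] - 1e-15]))
    }, numeric(1))
  }
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(0.3, 5)), rep(0.3, 5))
  grid <- c(0.01, 0.2, 0.5, 1)
  for (len in 1:6) {
    combos <- expand.grid(rep(list(grid), len))
    pick <- seq(1, nrow(combos),
                length.out = min(nrow(combos), 80))
    for (i in unique(round(pick))) {
      p <- as.numeric(combos[i, ])
      adj <- bhAdjust(p)
      expect_equal(adj, stepUp(p), tolerance = 1e-12)
      expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
      expect_identical(order(adj[order(p)]), seq_along(p))
    }
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("significance calls recover a planted induction at controlled FDR", {
  set.seed(7)
  ngene <- 1050
  m <- matrix(rnorm(ngene * 6, 8, 0.3), ngene, 6)
  m[1:50, 1:3] <- m[1:50, 1:3] + 2        # 50 genes up at +2 log2
  rownames(m) <- paste0("g", seq_len(ngene))
  colnames(m) <- simpleDesign(3, 3)$sample
  de <- moderatedTTest(m, "A", "B", design = simpleDesign(3, 3))
  calls <- callSignificant(de, alpha = 0.05)
  up <- calls$status$gene[calls$status$label == "up"]
  expect_gte(sum(paste0("g", 1:50) %in% up), 45L)
  false_pos <- setdiff(up, paste0("g", 1:50))
  expect_lte(length(false_pos), qbinom(0.995, 1000, 0.05) + 2)
  expect_match(calls$summary, "^\\d+ \\(\\d+↑/\\d+↓\\)$")

  none <- callSignificant(de, alpha = 0)
  expect_identical(none$n, 0L)
  all_ns <- de; all_ns$padj <- rep(1, ngene)
  expect_identical(callSignificant(all_ns)$summary, "0 (0↑/0↓)")
})

test_that("expression matrices and designs round-trip through TSV", {
  cat2 <- readCatalog(system.file("extdata", "catalog_synthetic.tsv",
                                  package = "CAZymap"))
  sim <- simulateExpression(defaultRegulonDesign(cat2, n_decoys = 10),
                            seed = 3)
  fm <- withr::local_tempfile(fileext = ".tsv")
  fd <- withr::local_tempfile(fileext = ".tsv")
  writeExpression(sim$se, fm, fd)
  se2 <- readExpression(fm, fd)
  expect_equal(SummarizedExperiment::assay(se2),
               SummarizedExperiment::assay(sim$se), tolerance = 1e-9)
  expect_identical(se2$condition, sim$se$condition)
})
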