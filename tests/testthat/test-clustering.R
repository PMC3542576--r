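# simulated profile data with planted archetypes over the six carbon
# sources; gene names carry their archetype for truth comparisons
plantedProfiles <- function(n_per = 40, archetypes = 2, noise_sd = 0.1,
                            seed = 1) {
  conds <- c("glucose", "xylose", "arabinose", "starch", "arabinan",
             "xylan")
  shapes <- list(c(0, 0, 0, 0, 2, 0),      # up on arabinan
                 c(0, 0, 0, 2, 0, 0),      # up on starch
                 c(0, 2, 2, 0, 0, 0))      # up on the pentose sugars
  genes <- unlist(lapply(seq_len(archetypes), function(a) {
    sprintf("arch%d_g%02d", a, seq_len(n_per))
  }))
  reps <- rep(3L, 6)
  samples <- unlist(lapply(conds, function(cc) paste0(cc, "_", 1:3)))
  scond <- rep(conds, each = 3)
  m <- withr::with_seed(seed, {
    m <- matrix(8 + rnorm(length(genes) * length(samples), 0, noise_sd),
                length(genes), length(samples),
                dimnames = list(genes, samples))
    for (a in seq_len(archetypes)) {
      rows <- grep(sprintf("^arch%d_", a), genes)
      m[rows, ] <- m[rows, ] + rep(shapes[[a]], each = 3)[col(m[rows, ])]
    }
    m
  })
  list(m = m, design = data.frame(sample = samples, condition = scond,
                                  replicate = rep(1:3, 6)),
       truth = rep(seq_len(archetypes), each = n_per))
}

test_that("profiles are condition means with correct standardization", {
  m <- rbind(gA = c(1, 1, 1, 3, 3, 3), gflat = rep(2, 6))
  design <- data.frame(sample = paste0("s", 1:6),
                       condition = rep(c("c1", "c2"), each = 3),
                       replicate = rep(1:3, 2))
  colnames(m) <- design$sample
  ps <- buildProfiles(m, design)
  expect_identical(ps@conditions, c("c1", "c2"))
  expect_equal(unname(ps@means["gA", ]), c(1, 3))
  expect_equal(unname(ps@std["gA", ]), c(-0.7071068, 0.7071068),
               tolerance = 1e-6)
  # constant gene flagged, not dropped
  expect_identical(unname(ps@zeroVar), c(FALSE, TRUE))
  expect_true(all(is.na(ps@std["gflat", ])))
  expect_length(ps@genes, 2L)
  expect_error(buildProfiles(m, design, genes = "nope"), "not in the matrix")
})

test_that("profile subsets preserve counts", {
  pp <- plantedProfiles(n_per = 20, archetypes = 3)
  sub <- sample(rownames(pp$m), 17)
  ps <- buildProfiles(pp$m, pp$design, genes = sub)
  expect_identical(ps@genes, sub)
  expect_identical(nrow(standardizedProfiles(ps)), 17L)
})

test_that("Pearson distance equals half the squared Euclidean distance on standardized profiles", {
  pp <- plantedProfiles(n_per = 10, archetypes = 3)
  X <- standardizedProfiles(buildProfiles(pp$m, pp$design))
  for (i in 1:5) {
    a <- X[i, ]; b <- X[i + 10, ]
    expect_equal(1 - cor(a, b), sum((a - b)^2) / 2, tolerance = 1e-12)
  }
})

test_that("clustering is invariant to per-gene affine rescaling of raw profiles", {
  pp <- plantedProfiles(n_per = 15, archetypes = 2)
  ps1 <- buildProfiles(pp$m, pp$design)
  scaled <- pp$m * 3 + 11
  ps2 <- buildProfiles(scaled, pp$design)
  expect_equal(ps1@std, ps2@std, tolerance = 1e-12)
  c1 <- clusterProfiles(ps1, k = 2, seed = 5, weights = FALSE)
  c2 <- clusterProfiles(ps2, k = 2, seed = 5, weights = FALSE)
  expect_identical(clusterAssignments(c1), clusterAssignments(c2))
})

test_that("planted archetypes are recovered exactly and deterministically", {
  skip_if_not_installed("mclust")
  pp <- plantedProfiles(n_per = 40, archetypes = 2, noise_sd = 0.1)
  ps <- buildProfiles(pp$m, pp$design)
  cl <- clusterProfiles(ps, k = 2, seed = 42)
  expect_equal(mclust::adjustedRandIndex(clusterAssignments(cl),
                                         pp$truth), 1.0)
  cl2 <- clusterProfiles(ps, k = 2, seed = 42)
  expect_identical(clusterAssignments(cl2), clusterAssignments(cl))
  expect_identical(sum(cl@sizes), 80L)
})

test_that("well-separated planted clusters are recovered across 20 seeds", {
  skip_if_not_installed("mclust")
  pp <- plantedProfiles(n_per = 25, archetypes = 3, noise_sd = 0.1)
  ps <- buildProfiles(pp$m, pp$design)
  ari <- vapply(1:20, function(s) {
    cl <- clusterProfiles(ps, k = 3, seed = s, n_init = 20)
    mclust::adjustedRandIndex(clusterAssignments(cl), pp$truth)
  }, numeric(1))
  expect_true(all(ari >= 0.95))
})

test_that("gene order permutation does not change the partition", {
  pp <- plantedProfiles(n_per = 20, archetypes = 2)
  ps <- buildProfiles(pp$m, pp$design)
  perm <- withr::with_seed(9, sample(nrow(pp$m)))
  psp <- buildProfiles(pp$m[perm, ], pp$design)
  a <- clusterAssignments(clusterProfiles(ps, 2, seed = 3))
  b <- clusterAssignments(clusterProfiles(psp, 2, seed = 4))
  tab <- table(a[names(b)], b)
  expect_identical(sum(apply(tab, 1, max)), length(b))  # label permutation
})

test_that("k equal to the number of distinct genes gives singleton clusters", {
  pp <- plantedProfiles(n_per = 4, archetypes = 2, noise_sd = 0.3)
  ps <- buildProfiles(pp$m, pp$design)
  cl <- clusterProfiles(ps, k = 8, seed = 1, n_init = 40)
  expect_identical(sort(unname(cl@sizes)), rep(1L, 8))
  expect_lt(clusterDispersion(cl), 1e-10)
  expect_error(clusterProfiles(ps, k = 0), "k must be")
  expect_error(clusterProfiles(ps, k = 9), "exceeds")
})

test_that("scanK reports non-increasing dispersion and peaks at the planted k", {
  pp <- plantedProfiles(n_per = 25, archetypes = 3, noise_sd = 0.1)
  ps <- buildProfiles(pp$m, pp$design)
  scan <- scanK(ps, 1:6, seed = 2)
  expect_identical(scan$k, 1:6)
  expect_true(all(diff(scan$dispersion) <= 1e-9))
  expect_identical(scan$k[which.max(scan$silhouette)], 3L)
  expect_true(is.na(scan$silhouette[1]))
  # k = 1: dispersion is the total weighted Pearson dispersion around the
  # global centroid
  one <- clusterProfiles(ps, 1, seed = 2)
  expect_equal(scan$dispersion[1], clusterDispersion(one),
               tolerance = 1e-6)
})

test_that("cluster summaries report mean profiles with dispersion", {
  pp <- plantedProfiles(n_per = 30, archetypes = 2, noise_sd = 0.1)
  ps <- buildProfiles(pp$m, pp$design)
  cl <- clusterProfiles(ps, k = 2, seed = 11)
  sm <- summarizeClusters(cl, ps)
  expect_identical(nrow(sm), 12L)          # 2 clusters x 6 conditions
  members <- attr(sm, "members")
  expect_identical(sort(unlist(members, use.names = FALSE)),
                   sort(rownames(pp$m)))
  # the cluster holding archetype 1 peaks on arabinan
  arch1 <- which(vapply(members, function(g) mean(grepl("^arch1", g)) > 0.5,
                        logical(1)))
  peak <- sm[sm$cluster == arch1, ]
  expect_identical(peak$condition[which.max(peak$mean)], "arabinan")
  expect_true(all(peak$sd < 0.25))
  # k = 1: the summary is the global mean profile
  cl1 <- clusterProfiles(ps, k = 1, seed = 1)
  sm1 <- summarizeClusters(cl1, ps)
  expect_equal(sm1$mean, unname(colMeans(ps@std)), tolerance = 1e-12)
  # singleton clusters have zero dispersion
  few <- buildProfiles(pp$m[1:3, ], pp$design)
  cl3 <- clusterProfiles(few, k = 3, seed = 1)
  expect_true(all(summarizeClusters(cl3, few)$sd == 0))
})
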