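# Replicate-aware k-means clustering of expression profiles under the
# Pearson distance d = 1 - r. Profiles are standardized to zero mean and
# unit norm across conditions, where 1 - r equals half the squared
# Euclidean distance; centroids are re-standardized every iteration
# (spherical k-means), which keeps the Pearson distance well defined.
# "Accounting for biological replicates" is implemented as optional
# per-gene weights equal to the inverse mean within-condition variance.

#' Build condition-mean expression profiles
#'
#' Averages replicates per condition and records the standard error of each
#' condition mean for replicate-aware weighting. Genes with zero variance
#' across conditions cannot be standardized; they are flagged, not dropped.
#'
#' @param x `SummarizedExperiment` or genes x samples matrix.
#' @param design design table when `x` is a matrix.
#' @param genes optional subset of gene ids.
#' @return a [ProfileSet-class].
#' @export
buildProfiles <- function(x, design = NULL, genes = NULL) {
  md <- .asMatrixDesign(x, design)
  m <- md$m
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing)) {
      stop("genes not in the matrix: ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    }
    m <- m[genes, , drop = FALSE]
  }
  cond <- md$design$condition
  conditions <- unique(cond)
  reps <- vapply(conditions, function(cc) sum(cond == cc), integer(1))
  if (any(reps < 1L)) stop("condition without replicates", call. = FALSE)
  means <- vapply(conditions, function(cc) {
    rowMeans(m[, cond == cc, drop = FALSE])
  }, numeric(nrow(m)))
  vars <- vapply(conditions, function(cc) {
    sub <- m[, cond == cc, drop = FALSE]
    if (ncol(sub) < 2L) rep(0, nrow(m)) else apply(sub, 1L, stats::var)
  }, numeric(nrow(m)))
  if (nrow(m) == 1L) {
    means <- matrix(means, nrow = 1L, dimnames = list(rownames(m),
                                                      conditions))
    vars <- matrix(vars, nrow = 1L, dimnames = list(rownames(m),
                                                    conditions))
  }
  se <- sqrt(sweep(vars, 2L, reps, "/"))
  centered <- means - rowMeans(means)
  norms <- sqrt(rowSums(centered^2))
  zeroVar <- norms < 1e-12
  std <- centered / ifelse(zeroVar, NA_real_, norms)
  std[zeroVar, ] <- NA_real_
  meanvar <- rowMeans(vars)
  w <- 1 / pmax(meanvar, 1e-8)
  w <- w / mean(w)
  new("ProfileSet", genes = rownames(m), conditions = conditions,
      means = means, se = se, std = std, weights = unname(w),
      zeroVar = unname(zeroVar))
}

setMethod("show", "ProfileSet", function(object) {
  cat("ProfileSet:", length(object@genes), "genes x",
      length(object@conditions), "conditions\n")
  cat("  conditions:", paste(object@conditions, collapse = ", "), "\n")
  if (any(object@zeroVar)) {
    cat("  zero-variance genes flagged:", sum(object@zeroVar), "\n")
  }
  invisible(NULL)
})

#' @describeIn ProfileSet-class standardized profile matrix.
#' @param x a `ProfileSet`.
#' @export
standardizedProfiles <- function(x) {
  out <- x@std
  rownames(out) <- x@genes
  colnames(out) <- x@conditions
  out
}

.sphericalKmeans <- function(X, w, k, max_iter = 100) {
  n <- nrow(X)
  restandardize <- function(v) {
    v <- v - mean(v)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) NULL else v / nv
  }
  C <- X[sample.int(n, k), , drop = FALSE]
  assign <- rep(0L, n)
  for (iter in seq_len(max_iter)) {
    D <- 1 - X %*% t(C)                 # Pearson distance, rows unit norm
    newassign <- max.col(-D, ties.method = "first")
    # refill empty clusters with the worst-fitted point
    for (j in seq_len(k)) {
      if (!any(newassign == j)) {
        cur <- D[cbind(seq_len(n), newassign)]
        far <- which.max(cur)
        newassign[far] <- j
      }
    }
    if (all(newassign == assign)) break
    assign <- newassign
    for (j in seq_len(k)) {
      mem <- which(assign == j)
      v <- restandardize(colSums(X[mem, , drop = FALSE] * w[mem]))
      if (is.null(v)) v <- X[mem[1L], ]
      C[j, ] <- v
    }
  }
  D <- 1 - X %*% t(C)
  obj <- sum(w * D[cbind(seq_len(n), assign)])
  list(assign = assign, centroids = C, objective = obj)
}

.runKmeans <- function(X, w, k, n_init, warm = NULL) {
  best <- NULL
  for (r in seq_len(n_init)) {
    fit <- .sphericalKmeans(X, w, k)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (!is.null(warm)) {
    fit <- .sphericalKmeansFrom(X, w, warm)
    if (fit$objective < best$objective) best <- fit
  }
  best
}

# Lloyd iterations from given initial centroids (used by scanK warm starts)
.sphericalKmeansFrom <- function(X, w, C0, max_iter = 100) {
  n <- nrow(X)
  k <- nrow(C0)
  C <- C0
  assign <- rep(0L, n)
  restandardize <- function(v) {
    v <- v - mean(v)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) NULL else v / nv
  }
  for (iter in seq_len(max_iter)) {
    D <- 1 - X %*% t(C)
    newassign <- max.col(-D, ties.method = "first")
    for (j in seq_len(k)) {
      if (!any(newassign == j)) {
        cur <- D[cbind(seq_len(n), newassign)]
        newassign[which.max(cur)] <- j
      }
    }
    if (all(newassign == assign)) break
    assign <- newassign
    for (j in seq_len(k)) {
      mem <- which(assign == j)
      v <- restandardize(colSums(X[mem, , drop = FALSE] * w[mem]))
      if (is.null(v)) v <- X[mem[1L], ]
      C[j, ] <- v
    }
  }
  D <- 1 - X %*% t(C)
  obj <- sum(w * D[cbind(seq_len(n), assign)])
  list(assign = assign, centroids = C, objective = obj)
}

#' Cluster expression profiles with Pearson-distance k-means
#'
#' Best-of-restarts spherical k-means on the standardized profiles.
#' Deterministic for a given seed; zero-variance genes are left
#' unassigned (`NA`).
#'
#' @param profiles a [ProfileSet-class].
#' @param k number of clusters.
#' @param seed integer seed.
#' @param weights use inverse-variance gene weights (replicate-aware); set
#'   `FALSE` for the unweighted variant.
#' @param n_init number of random restarts.
#' @return a [ProfileClustering-class].
#' @export
clusterProfiles <- function(profiles, k, seed = 1L, weights = TRUE,
                            n_init = 50L) {
  stopifnot(is(profiles, "ProfileSet"))
  use <- which(!profiles@zeroVar)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > length(use)) {
    stop("k exceeds the number of clusterable genes", call. = FALSE)
  }
  X <- profiles@std[use, , drop = FALSE]
  w <- if (isTRUE(weights)) profiles@weights[use] else rep(1, length(use))
  fit <- withr::with_seed(as.integer(seed),
                          .runKmeans(X, w, k, n_init = n_init))
  assignment <- rep(NA_integer_, length(profiles@genes))
  assignment[use] <- fit$assign
  names(assignment) <- profiles@genes
  colnames(fit$centroids) <- profiles@conditions
  new("ProfileClustering", k = as.integer(k), assignment = assignment,
      centroids = fit$centroids, objective = fit$objective,
      seed = as.integer(seed),
      sizes = as.integer(tabulate(fit$assign, nbins = k)))
}

setMethod("show", "ProfileClustering", function(object) {
  cat("ProfileClustering: k =", object@k, "| dispersion =",
      signif(object@objective, 5), "| seed =", object@seed, "\n")
  cat("  sizes:", paste(object@sizes, collapse = " "), "\n")
  invisible(NULL)
})

#' @describeIn ProfileClustering-class named gene -> cluster vector.
#' @param x a `ProfileClustering`.
#' @export
clusterAssignments <- function(x) x@assignment

#' @describeIn ProfileClustering-class total within-cluster dispersion.
#' @export
clusterDispersion <- function(x) x@objective

.silhouette <- function(D, assign) {
  n <- length(assign)
  ks <- sort(unique(assign))
  if (length(ks) < 2L) return(NA_real_)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- assign == assign[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(D[i, own]) else 0
    b <- min(vapply(setdiff(ks, assign[i]), function(j) {
      mean(D[i, assign == j])
    }, numeric(1)))
    s[i] <- if (any(own)) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Scan a range of cluster counts
#'
#' Reports the within-cluster dispersion and the mean silhouette width
#' (Pearson distance) for each k, as a guide for choosing the number of
#' clusters; no k is selected automatically. Each k is additionally warm-
#' started from the previous solution plus the worst-fitted profile as a
#' new centroid, which makes the best-of-restarts dispersion non-increasing
#' in k.
#'
#' @param profiles a [ProfileSet-class].
#' @param k_range integer vector of cluster counts.
#' @param seed integer seed.
#' @param weights,n_init as in [clusterProfiles()].
#' @return `data.frame` with columns `k`, `dispersion`, `silhouette`.
#' @export
scanK <- function(profiles, k_range, seed = 1L, weights = TRUE,
                  n_init = 20L) {
  stopifnot(is(profiles, "ProfileSet"))
  use <- which(!profiles@zeroVar)
  X <- profiles@std[use, , drop = FALSE]
  w <- if (isTRUE(weights)) profiles@weights[use] else rep(1, length(use))
  D <- 1 - X %*% t(X)
  k_range <- sort(unique(as.integer(k_range)))
  out <- withr::with_seed(as.integer(seed), {
    prev <- NULL
    rows <- lapply(k_range, function(k) {
      warm <- NULL
      if (!is.null(prev) && nrow(prev$centroids) == k - 1L) {
        cur <- 1 - X %*% t(prev$centroids)
        worst <- which.max(cur[cbind(seq_len(nrow(X)), prev$assign)])
        warm <- rbind(prev$centroids, X[worst, ])
      }
      fit <- .runKmeans(X, w, k, n_init = n_init, warm = warm)
      prev <<- fit
      data.frame(k = k, dispersion = fit$objective,
                 silhouette = .silhouette(D, fit$assign))
    })
    do.call(rbind, rows)
  })
  rownames(out) <- NULL
  out
}

#' Summarize clusters as mean +/- sd profiles
#'
#' The per-cluster display of a clustering: for every cluster and
#' condition, the mean and standard deviation of the standardized member
#' profiles, plus the member gene names.
#'
#' @param clustering a [ProfileClustering-class].
#' @param profiles the [ProfileSet-class] that was clustered.
#' @return `data.frame` with columns `cluster`, `condition`, `mean`, `sd`,
#'   `n_genes`; attribute `members` holds the gene names per cluster.
#' @export
summarizeClusters <- function(clustering, profiles) {
  stopifnot(is(clustering, "ProfileClustering"),
            is(profiles, "ProfileSet"))
  assign <- clustering@assignment
  std <- profiles@std
  rows <- list()
  members <- list()
  for (j in seq_len(clustering@k)) {
    mem <- which(!is.na(assign) & assign == j)
    members[[j]] <- profiles@genes[mem]
    sub <- std[mem, , drop = FALSE]
    mu <- colMeans(sub)
    sdv <- if (length(mem) > 1L) apply(sub, 2L, stats::sd) else
      rep(0, ncol(sub))
    rows[[j]] <- data.frame(cluster = j, condition = profiles@conditions,
                            mean = unname(mu), sd = unname(sdv),
                            n_genes = length(mem),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(members) <- as.character(seq_len(clustering@k))
  attr(out, "members") <- members
  out
}
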