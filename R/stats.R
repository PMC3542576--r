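# Expression preprocessing and pairwise differential expression:
# quantile normalization, median-polish summarization, moderated t-tests
# with empirical-Bayes variance shrinkage, Benjamini-Hochberg adjustment.

.asMatrixDesign <- function(x, design = NULL) {
  if (is(x, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(x)
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    design <- data.frame(sample = colnames(m), condition = cd$condition,
                         replicate = cd$replicate,
                         stringsAsFactors = FALSE)
  } else {
    m <- as.matrix(x)
    if (is.null(design)) stop("a design table is required", call. = FALSE)
    design <- as.data.frame(design, stringsAsFactors = FALSE)
  }
  if (is.null(design$condition) || anyNA(design$condition) ||
      any(!nzchar(design$condition))) {
    stop("every sample needs a condition label", call. = FALSE)
  }
  design <- design[match(colnames(m), design$sample), , drop = FALSE]
  if (anyNA(design$sample)) {
    stop("design table does not cover all samples", call. = FALSE)
  }
  list(m = m, design = design)
}

#' Quantile normalization
#'
#' Forces all columns onto a common distribution: value i in the sorted
#' order of every column is replaced by the mean of the i-th order
#' statistics across columns. Tied values receive the mean of the
#' order-statistic means across their tie run, so the map is well defined
#' and rank-preserving within columns. The operation is idempotent.
#'
#' @param x numeric matrix (features x samples) with at least two columns,
#'   or a `SummarizedExperiment` (its first assay is normalized in place).
#' @return object of the same type as `x`.
#' @examples
#' quantileNormalize(cbind(a = c(1, 3), b = c(2, 4)))
#' @export
quantileNormalize <- function(x) {
  se <- NULL
  if (is(x, "SummarizedExperiment")) {
    se <- x
    x <- SummarizedExperiment::assay(x)
  }
  m <- as.matrix(x)
  if (ncol(m) < 2L) stop("need at least two columns", call. = FALSE)
  if (any(!is.finite(m))) stop("non-finite entries", call. = FALSE)
  ref <- rowMeans(apply(m, 2L, sort))
  out <- apply(m, 2L, function(col) {
    o <- order(col)
    v <- numeric(length(col))
    v[o] <- ref
    stats::ave(v, col, FUN = mean)     # tie runs share their mean
  })
  dimnames(out) <- dimnames(m)
  if (!is.null(se)) {
    SummarizedExperiment::assay(se) <- out
    return(se)
  }
  out
}

#' Median-polish probe summarization
#'
#' Fits the additive model value(probe, sample) = overall + probe effect +
#' sample effect by alternating row- and column-median sweeps, and returns
#' the per-sample summaries overall + sample effect. This is the
#' summarization step used for multi-probe expression indices.
#'
#' @param probe_matrix numeric matrix, probes x samples.
#' @param tol stop when no effect changes by more than `tol` in a sweep.
#' @param max_iter maximum number of sweeps; on non-convergence the result
#'   is returned with `converged = FALSE` and a warning.
#' @return list with `summary` (named per-sample values), `overall`, `row`,
#'   `col`, `residuals`, `converged`, `iterations`.
#' @examples
#' medianPolishSummarize(rbind(c(0, 2), c(1, 3)))$summary
#' @export
medianPolishSummarize <- function(probe_matrix, tol = 0.01, max_iter = 10) {
  m <- as.matrix(probe_matrix)
  if (nrow(m) < 1L) stop("need at least one probe row", call. = FALSE)
  r <- numeric(nrow(m))
  cc <- numeric(ncol(m))
  overall <- 0
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    delta <- 0
    rowmed <- apply(m - outer(r, cc, "+") - overall, 1L, stats::median)
    r <- r + rowmed
    delta <- max(delta, max(abs(rowmed)))
    rshift <- stats::median(r)
    r <- r - rshift
    overall <- overall + rshift
    colmed <- apply(m - outer(r, cc, "+") - overall, 2L, stats::median)
    cc <- cc + colmed
    delta <- max(delta, max(abs(colmed)))
    cshift <- stats::median(cc)
    cc <- cc - cshift
    overall <- overall + cshift
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("median polish did not converge in ", max_iter,
                          " sweeps")
  summary <- overall + cc
  names(summary) <- colnames(m)
  list(summary = summary, overall = overall, row = r, col = cc,
       residuals = m - outer(r, cc, "+") - overall,
       converged = converged, iterations = iter)
}

# Newton solve of trigamma(y) = x, vectorized; used by the empirical-Bayes
# hyperparameter fit.
.trigammaInverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

# Method-of-moments fit of the scaled inverse-chi-square prior on the gene
# variances, on the log scale: log s2_g is a shifted log-F variate whose
# mean and excess variance identify (d0, s20).
.fitVariancePrior <- function(s2, dg) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) {
    warning("too few positive variances to estimate a prior; no shrinkage")
    return(list(d0 = 0, s20 = NA_real_))
  }
  e <- log(s2[ok]) - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  evar <- stats::var(e) * (sum(ok) - 1) / sum(ok)
  excess <- evar - trigamma(dg / 2)
  if (excess > 0) {
    d0 <- 2 * .trigammaInverse(excess)
    s20 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf                       # variances look exchangeable
    s20 <- exp(emean)
  }
  list(d0 = d0, s20 = s20)
}

#' Moderated two-sample t-tests with empirical-Bayes variance shrinkage
#'
#' For every gene the pooled within-group variance `s2_g` on
#' `d_g = nA + nB - 2` degrees of freedom is shrunk towards a prior
#' `s2_0` with `d_0` degrees of freedom estimated across genes by method of
#' moments on the log variances (scaled inverse-chi-square prior). The
#' moderated statistic is the mean difference divided by the posterior
#' standard error, referred to a t distribution on `d_0 + d_g` degrees of
#' freedom. P-values are Benjamini-Hochberg adjusted and significance is
#' called at `padj < alpha`.
#'
#' @param x `SummarizedExperiment` (log2 expression, condition/replicate in
#'   `colData`) or a genes x samples matrix.
#' @param condA,condB the two condition labels to compare; the reported
#'   log2 fold change is `mean(condA) - mean(condB)`.
#' @param design design table (`sample`, `condition`, `replicate`) when `x`
#'   is a plain matrix.
#' @param prior_df `NULL` to estimate `d_0` from the data, `0` for the
#'   classical pooled t-test, `Inf` to force all genes onto the prior
#'   variance.
#' @param prior_var prior variance `s2_0`; only used with a fixed positive
#'   `prior_df`.
#' @param alpha significance cut-off on the adjusted p-value.
#' @return `data.frame` (one row per gene): `gene`, `mean_a`, `mean_b`,
#'   `lfc`, `s2`, `df_resid`, `s2_post`, `t`, `p`, `padj`, `direction`,
#'   `significant`; attributes `prior_df`, `prior_var`, `comparison`.
#' @export
moderatedTTest <- function(x, condA, condB, design = NULL,
                           prior_df = NULL, prior_var = NULL,
                           alpha = 0.05) {
  md <- .asMatrixDesign(x, design)
  m <- md$m
  cond <- md$design$condition
  ia <- which(cond == condA)
  ib <- which(cond == condB)
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("both conditions need at least 2 replicates (",
         condA, ": ", length(ia), ", ", condB, ": ", length(ib), ")",
         call. = FALSE)
  }
  if (is.null(rownames(m))) {
    rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
  }
  nA <- length(ia)
  nB <- length(ib)
  meanA <- rowMeans(m[, ia, drop = FALSE])
  meanB <- rowMeans(m[, ib, drop = FALSE])
  varA <- apply(m[, ia, drop = FALSE], 1L, stats::var)
  varB <- apply(m[, ib, drop = FALSE], 1L, stats::var)
  dg <- nA + nB - 2L
  s2 <- ((nA - 1) * varA + (nB - 1) * varB) / dg

  if (is.null(prior_df)) {
    fit <- .fitVariancePrior(s2, dg)
    d0 <- fit$d0
    s20 <- fit$s20
  } else {
    d0 <- prior_df
    s20 <- if (d0 > 0) {
      if (is.null(prior_var)) {
        if (is.infinite(d0)) exp(mean(log(s2[s2 > 0]))) else
          stop("prior_var required for fixed positive prior_df",
               call. = FALSE)
      } else prior_var
    } else NA_real_
  }
  s2post <- if (d0 == 0) s2 else if (is.infinite(d0)) rep(s20, length(s2))
    else (d0 * s20 + dg * s2) / (d0 + dg)
  sed <- sqrt(s2post * (1 / nA + 1 / nB))
  lfc <- meanA - meanB
  tstat <- lfc / sed
  tstat[sed == 0 & lfc == 0] <- 0
  dftot <- d0 + dg
  p <- 2 * stats::pt(-abs(tstat), df = dftot)
  p[sed == 0 & lfc == 0] <- 1
  padj <- bhAdjust(p)
  direction <- ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "ns"))
  significant <- padj < alpha
  out <- data.frame(gene = rownames(m), mean_a = meanA, mean_b = meanB,
                    lfc = lfc, s2 = s2, df_resid = dg, s2_post = s2post,
                    t = tstat, p = p, padj = padj,
                    direction = ifelse(significant, direction, "ns"),
                    significant = significant,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s20
  attr(out, "comparison") <- c(condA, condB)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values controlling the false discovery rate;
#'   order-preserving and never below the raw values.
#' @export
bhAdjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Call significantly regulated genes
#'
#' Applies the adjusted-p cut-off and summarizes the calls in the
#' "n (k up / m down)" format used for pairwise-comparison overviews.
#'
#' @param de result of [moderatedTTest()].
#' @param alpha adjusted-p cut-off.
#' @return list with `status` (a gene status table usable by
#'   [overlayStatus()]: `gene`, `label`, `provenance`), the counts `n`,
#'   `up`, `down`, and a display `summary` string.
#' @export
callSignificant <- function(de, alpha = 0.05) {
  stopifnot(is.data.frame(de), all(c("gene", "lfc", "padj") %in% names(de)))
  sig <- de$padj < alpha
  label <- ifelse(sig & de$lfc > 0, "up",
                  ifelse(sig & de$lfc < 0, "down", "ns"))
  comparison <- attr(de, "comparison")
  provenance <- if (is.null(comparison)) "" else
    paste(comparison, collapse = "_vs_")
  status <- data.frame(gene = de$gene, label = label,
                       provenance = provenance, stringsAsFactors = FALSE)
  up <- sum(label == "up")
  down <- sum(label == "down")
  list(status = status, n = up + down, up = up, down = down,
       summary = sprintf("%d (%d↑/%d↓)", up + down, up, down))
}

#' Read an expression matrix and its design as a SummarizedExperiment
#'
#' @param matrix_path TSV: first column gene id, remaining columns one per
#'   sample.
#' @param design_path TSV with columns `sample`, `condition`, `replicate`.
#' @return a `SummarizedExperiment` with assay `exprs`.
#' @export
readExpression <- function(matrix_path, design_path) {
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  design <- utils::read.delim(design_path, colClasses = "character",
                              stringsAsFactors = FALSE)
  if (!all(c("sample", "condition", "replicate") %in% names(design))) {
    stop("design needs columns sample, condition, replicate", call. = FALSE)
  }
  design <- design[match(colnames(m), design$sample), , drop = FALSE]
  if (anyNA(design$sample)) {
    stop("design does not cover all samples in the matrix", call. = FALSE)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = m),
    colData = S4Vectors::DataFrame(condition = design$condition,
                                   replicate = design$replicate,
                                   row.names = design$sample))
}

#' Write an expression matrix and design to TSV
#'
#' @param se a `SummarizedExperiment` as produced by [simulateExpression()]
#'   or [readExpression()].
#' @param matrix_path,design_path output files.
#' @return invisibly, the two paths.
#' @export
writeExpression <- function(se, matrix_path, design_path) {
  m <- SummarizedExperiment::assay(se)
  tab <- data.frame(gene = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  design <- data.frame(sample = colnames(m), condition = cd$condition,
                       replicate = cd$replicate, stringsAsFactors = FALSE)
  utils::write.table(design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, design_path))
}
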