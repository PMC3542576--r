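# Synthetic expression data with known ground truth, emulating the study
# design: six carbon sources (three monosaccharides, three defined
# polysaccharides), biological triplicates except a duplicate on starch,
# log2 expression indices with condition-specific induction of
# activity-linked gene sets (regulons).

.DEFAULT_CONDITIONS <- c("glucose", "xylose", "arabinose", "starch",
                         "arabinan", "xylan")

.defaultReplicates <- function(conditions = .DEFAULT_CONDITIONS) {
  reps <- stats::setNames(rep(3L, length(conditions)), conditions)
  if ("starch" %in% conditions) reps[["starch"]] <- 2L
  reps
}

# all catalog genes mapped to a structure's required activities
.genesForStructure <- function(catalog, structure,
                               registry = activityRegistry()) {
  req <- requiredActivities(structure, registry = registry)
  unique(unlist(lapply(seq_len(nrow(req)), function(i) {
    rec <- .catalogRowsForActivity(catalog, req[i, ])
    if (nrow(rec)) .geneDisplayId(rec) else character()
  })))
}

#' Default regulon design emulating carbon-source induction
#'
#' Three planted regulons on the six-carbon-source design: the xylan
#' degradation set induced on xylan and on L-arabinose (arabinose
#' cross-induces the xylanolytic genes), the starch set induced on starch
#' and on D-glucose (starch is rapidly hydrolyzed to glucose, so the two
#' conditions look alike), and the arabinan/pectin set induced on arabinan
#' only. Genes claimed by an earlier regulon are not re-used by a later
#' one.
#'
#' @param catalog an [EnzymeCatalog-class] providing the gene universe.
#' @param n_decoys unregulated decoy genes added to the universe.
#' @param effect log2 induction effect size.
#' @param noise_sd replicate noise standard deviation (log2 scale).
#' @param registry activity template table.
#' @return a regulon design list for [simulateExpression()].
#' @export
defaultRegulonDesign <- function(catalog, n_decoys = 200L, effect = 2,
                                 noise_sd = 0.3,
                                 registry = activityRegistry()) {
  xylan_genes <- .genesForStructure(catalog, loadStructure("xylan"),
                                    registry)
  starch_genes <- .genesForStructure(catalog, loadStructure("starch"),
                                     registry)
  # pectic gene set; overlaps with the xylanolytic one (e.g. the
  # arabinofuranosidases and feruloyl esterases act on both substrates)
  pectic <- unique(unlist(lapply(
    c("arabinan", "rhamnogalacturonan_1", "smooth_pectin"),
    function(s) .genesForStructure(catalog, loadStructure(s), registry))))
  pectic <- setdiff(pectic, starch_genes)
  universe <- unique(c(.geneDisplayId(catalog@genes),
                       sprintf("decoy%04d", seq_len(n_decoys))))
  list(conditions = .DEFAULT_CONDITIONS,
       replicates = .defaultReplicates(),
       genes = universe,
       regulons = list(
         list(name = "xylanolytic", genes = xylan_genes,
              conditions = c("xylan", "arabinose"), effect = effect),
         list(name = "amylolytic", genes = starch_genes,
              conditions = c("starch", "glucose"), effect = effect),
         list(name = "pectinolytic", genes = pectic,
              conditions = "arabinan", effect = effect)),
       baseline_mean = 8, baseline_sd = 1.5, noise_sd = noise_sd)
}

#' Simulate an expression matrix with known ground truth
#'
#' Values are baseline + effect x indicator(condition induces the gene's
#' regulon) + Gaussian noise, on the log2 scale appropriate for microarray
#' expression indices. Regulons may overlap: a gene in several regulons is
#' induced on the union of their conditions (effects combine as the
#' maximum, not the sum). The same seed and design give identical
#' matrices.
#'
#' @param design regulon design list: `conditions`, `replicates` (named
#'   integer), `genes`, `regulons` (each `list(name, genes, conditions,
#'   effect)`; empty for a pure null), `baseline_mean`, `baseline_sd`,
#'   `noise_sd`. See [defaultRegulonDesign()].
#' @param seed integer seed.
#' @return list with `se` (a `SummarizedExperiment`, assay `exprs`,
#'   colData `condition`/`replicate`) and `truth` (per-gene true effect
#'   matrix `effects`, regulon membership `regulon`).
#' @export
simulateExpression <- function(design, seed = 1L) {
  conditions <- design$conditions
  reps <- design$replicates
  if (is.null(reps)) reps <- .defaultReplicates(conditions)
  if (any(reps < 2L)) {
    stop("every condition needs at least 2 replicates", call. = FALSE)
  }
  genes <- design$genes
  regulons <- design$regulons
  if (is.null(regulons)) regulons <- list()
  baseline_mean <- design$baseline_mean %||% 8
  baseline_sd <- design$baseline_sd %||% 1.5
  noise_sd <- design$noise_sd %||% 0.3
  for (r in regulons) {
    if (!all(is.finite(r$effect))) {
      stop("regulon effect sizes must be finite", call. = FALSE)
    }
    missing <- setdiff(r$conditions, conditions)
    if (length(missing)) {
      stop("regulon '", r$name, "' references unknown condition(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }

  effects <- matrix(0, nrow = length(genes), ncol = length(conditions),
                    dimnames = list(genes, conditions))
  regulon <- stats::setNames(rep(NA_character_, length(genes)), genes)
  for (r in regulons) {
    g <- intersect(r$genes, genes)
    effects[g, r$conditions] <- pmax(effects[g, r$conditions], r$effect)
    regulon[g] <- ifelse(is.na(regulon[g]), r$name,
                         paste(regulon[g], r$name, sep = ";"))
  }

  samples <- unlist(lapply(conditions, function(cc) {
    paste0(cc, "_", seq_len(reps[[cc]]))
  }))
  scond <- rep(conditions, times = reps[conditions])
  srep <- unlist(lapply(conditions, function(cc) seq_len(reps[[cc]])))

  m <- withr::with_seed(as.integer(seed), {
    baseline <- stats::rnorm(length(genes), baseline_mean, baseline_sd)
    vals <- baseline + effects[, scond, drop = FALSE] +
      matrix(stats::rnorm(length(genes) * length(samples), 0, noise_sd),
             nrow = length(genes))
    vals
  })
  colnames(m) <- samples
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = m),
    colData = S4Vectors::DataFrame(condition = scond,
                                   replicate = as.integer(srep),
                                   row.names = samples))
  truth <- list(effects = effects, regulon = regulon,
                conditions = conditions)
  list(se = se, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gene status fixture from simulation ground truth
#'
#' Derives the up/down/ns labels a perfect differential-expression stage
#' would produce for a pairwise comparison, directly from the true planted
#' effects. Used to test coverage overlays independently of the statistics
#' stage.
#'
#' @param truth `truth` element of [simulateExpression()] output.
#' @param condA,condB conditions compared; `"up"` means higher in `condA`.
#' @return gene status table (`gene`, `label`, `provenance`).
#' @export
makeStatusFixture <- function(truth, condA, condB) {
  missing <- setdiff(c(condA, condB), truth$conditions)
  if (length(missing)) {
    stop("unknown condition(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  diff <- truth$effects[, condA] - truth$effects[, condB]
  data.frame(gene = rownames(truth$effects),
             label = ifelse(diff > 0, "up",
                            ifelse(diff < 0, "down", "ns")),
             provenance = paste0("truth:", condA, "_vs_", condB),
             stringsAsFactors = FALSE)
}
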