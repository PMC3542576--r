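#' @import methods
NULL

#' Rooted-tree representation of a polysaccharide structure
#'
#' A polysaccharide is modelled as a rooted tree of sugar residues. The root
#' is the reducing-end residue; reading direction is from the non-reducing
#' ends towards the root, which is the direction exo-acting glycosidases
#' work in. Backbone residues form the main chain; all other residues are
#' side chains. Ester/ether substituents (acetyl, methyl, feruloyl) are held
#' separately from the glycosidic linkages.
#'
#' @slot name structure name (one of the packaged types or a user label).
#' @slot residues `data.frame` with columns `id`, `sugar`, `ring_carbons`,
#'   `anomeric_carbon`, `backbone`.
#' @slot linkages `data.frame` with columns `parent`, `child`, `config`
#'   (`"alpha"`/`"beta"`), `parent_carbon`, `child_carbon`. The child carbon
#'   is always the child's anomeric carbon.
#' @slot modifications `data.frame` with columns `residue`, `kind`, `carbon`.
#' @slot root id of the reducing-end residue.
#' @export
setClass("GlycanStructure",
         representation(name = "character",
                        residues = "data.frame",
                        linkages = "data.frame",
                        modifications = "data.frame",
                        root = "integer"))

#' Catalog of carbohydrate-active genes
#'
#' One row per gene record: an enzymatic activity (EC number where
#' available, otherwise an enzyme name), the CAZy family, the action mode,
#' and the gene identifiers in the two A. niger genome annotations
#' (CBS 513.88 and ATCC 1015). A missing ATCC id is meaningful: on rendered
#' maps such genes are drawn gray (no bidirectional best hit between the
#' two annotations). Genes whose array probes cannot be distinguished share
#' an `ambiguous_probe_group` tag and are treated jointly by overlays.
#'
#' @slot genes `data.frame` with columns `ec`, `name`, `cazy`, `mode`,
#'   `gene_name`, `uniprot`, `cbs_id`, `atcc_id`, `characterized`, `refs`,
#'   `ambiguous_probe_group`.
#' @export
setClass("EnzymeCatalog", representation(genes = "data.frame"))

#' Result of a simulated enzymatic digestion
#'
#' @slot structure name of the digested structure.
#' @slot n total number of input residues.
#' @slot dp degree-of-polymerization histogram (`data.frame`: `dp`, `count`).
#' @slot monomers free-monosaccharide yield per sugar (`data.frame`:
#'   `sugar`, `count`).
#' @slot completeness fraction of input residues released as free monomers.
#' @slot blockers `data.frame` attributing every unreleased residue to the
#'   bond or modification class left standing and the activity mode needed.
#' @slot log ordered cleavage log (`data.frame`: `step`, `rule`, `activity`,
#'   `detail`).
#' @slot fragments list of residue-id vectors, one per remaining fragment.
#' @export
setClass("DigestResult",
         representation(structure = "character", n = "integer",
                        dp = "data.frame", monomers = "data.frame",
                        completeness = "numeric", blockers = "data.frame",
                        log = "data.frame", fragments = "list"))

#' Condition-mean expression profiles with replicate information
#'
#' @slot genes gene identifiers.
#' @slot conditions condition names, in design order.
#' @slot means gene x condition matrix of replicate means.
#' @slot se gene x condition matrix of standard errors of the mean.
#' @slot std standardized profiles (zero mean, unit norm across conditions);
#'   rows flagged in `zeroVar` are `NA`.
#' @slot weights per-gene weights (inverse mean within-condition variance).
#' @slot zeroVar logical flag per gene: profile constant across conditions.
#' @export
setClass("ProfileSet",
         representation(genes = "character", conditions = "character",
                        means = "matrix", se = "matrix", std = "matrix",
                        weights = "numeric", zeroVar = "logical"))

#' k-means partition of expression profiles under the Pearson distance
#'
#' @slot k number of clusters.
#' @slot assignment named integer vector gene -> cluster (`NA` for
#'   zero-variance genes excluded from clustering).
#' @slot centroids k x condition matrix of standardized centroid profiles.
#' @slot objective total within-cluster dispersion (weighted sum of Pearson
#'   distances to the assigned centroid).
#' @slot seed random seed that produced the partition.
#' @slot sizes cluster sizes.
#' @export
setClass("ProfileClustering",
         representation(k = "integer", assignment = "integer",
                        centroids = "matrix", objective = "numeric",
                        seed = "integer", sizes = "integer"))

#' Required-activity coverage of one polysaccharide by induced genes
#'
#' @slot structure structure name.
#' @slot activities per required activity: genes found in the catalog,
#'   how many are labelled up/down, and whether the activity is covered.
#' @slot coverage covered activities / mapped required activities.
#' @slot fullSet `TRUE` when every mapped required activity has at least one
#'   up-regulated gene (the "full set" condition).
#' @slot unmapped required activities with no catalog gene; excluded from
#'   the coverage denominator but reported.
#' @slot unknownGenes status entries that reference no catalog gene.
#' @export
setClass("CoverageReport",
         representation(structure = "character", activities = "data.frame",
                        coverage = "numeric", fullSet = "logical",
                        unmapped = "character", unknownGenes = "character"))
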