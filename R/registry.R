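# The activity template registry: which enzymatic activity acts on which
# bond pattern. Matching is by (child sugar, anomeric configuration,
# linkage carbons, backbone/side-chain role), not by CAZy family, because
# several families share one EC (GH5 and GH26 mannanases) and vice versa.
#
# Modes:
#   endo            cleaves interior backbone linkages
#   exo_nonreducing removes the terminal residue at a non-reducing end
#   debranching     removes single-residue side chains from the backbone
#   esterase        removes an ester/ether substituent
#
# NA in a pattern column is a wildcard.

.act <- function(ec, name, mode, child = NA, config = NA, pc = NA,
                 parent = NA, role = "any", modification = NA, cazy = "") {
  data.frame(ec = ec, name = name, cazy = cazy, mode = mode,
             child_sugar = child, config = config,
             parent_carbon = as.integer(pc), parent_sugar = parent,
             role = role, modification = modification,
             stringsAsFactors = FALSE)
}

.ACTIVITY_REGISTRY <- rbind(
  # --- endo activities (interior backbone cleavage) ------------------------
  .act("3.2.1.4",  "endo-1,4-β-D-glucanase",      "endo", "Glc", "beta", 4, "Glc", "backbone", cazy = "GH5;GH12"),
  .act("3.2.1.1",  "α-amylase",                   "endo", "Glc", "alpha", 4, "Glc", "backbone", cazy = "GH13"),
  .act("3.2.1.41", "pullulanase",                 "endo", "Glc", "alpha", 6, "Glc", "backbone", cazy = "GH13"),
  .act("3.2.1.7",  "endo-inulinase",              "endo", "Fru", "beta", 1, NA, "backbone", cazy = "GH32"),
  .act("3.2.1.78", "endo-1,4-β-D-mannanase",      "endo", "Man", "beta", 4, NA, "backbone", cazy = "GH5;GH26"),
  .act("3.2.1.78", "endo-1,4-β-D-mannanase",      "endo", "Glc", "beta", 4, "Man", "backbone", cazy = "GH5;GH26"),
  .act("3.2.1.8",  "endo-1,4-β-D-xylanase",       "endo", "Xyl", "beta", 4, "Xyl", "backbone", cazy = "GH10;GH11"),
  .act("3.2.1.15", "endo-polygalacturonase",      "endo", "GalA", "alpha", 4, "GalA", "backbone", cazy = "GH28"),
  .act("3.2.1.99", "endo-1,5-α-L-arabinanase",    "endo", "Ara", "alpha", NA, NA, "backbone", cazy = "GH43"),
  .act("3.2.1.89", "endo-1,4-β-D-galactanase",    "endo", "Gal", "beta", 4, "Gal", "backbone", cazy = "GH53"),
  .act("3.2.1.181", "endo-1,3-β-D-galactanase",   "endo", "Gal", "beta", 3, "Gal", "backbone", cazy = "GH43"),
  .act("3.2.1.171", "rhamnogalacturonan hydrolase", "endo", "Rha", "alpha", NA, NA, "backbone", cazy = "GH28"),
  .act("3.2.1.171", "rhamnogalacturonan hydrolase", "endo", "GalA", "alpha", 2, "Rha", "backbone", cazy = "GH28"),
  # --- exo activities (non-reducing terminal release) ----------------------
  .act("3.2.1.21", "β-glucosidase",               "exo_nonreducing", "Glc", "beta", NA, NA, cazy = "GH3"),
  .act("3.2.1.3",  "glucoamylase",                "exo_nonreducing", "Glc", "alpha", NA, NA, cazy = "GH15"),
  .act("3.2.1.20", "α-glucosidase",               "exo_nonreducing", "Glc", "alpha", 4, NA, cazy = "GH31"),
  .act("3.2.1.25", "β-mannosidase",               "exo_nonreducing", "Man", "beta", NA, NA, cazy = "GH2"),
  .act("3.2.1.37", "β-xylosidase",                "exo_nonreducing", "Xyl", "beta", NA, NA, cazy = "GH3;GH43"),
  .act("3.2.1.37", "β-xylosidase",                "debranching", "Xyl", "beta", NA, NA, role = "side", cazy = "GH3;GH43"),
  .act("3.2.1.23", "β-galactosidase",             "exo_nonreducing", "Gal", "beta", NA, NA, cazy = "GH35"),
  .act("3.2.1.23", "β-galactosidase",             "debranching", "Gal", "beta", NA, NA, role = "side", cazy = "GH35"),
  .act("3.2.1.22", "α-galactosidase",             "debranching", "Gal", "alpha", 6, NA, role = "side", cazy = "GH27;GH36"),
  .act("3.2.1.80", "exo-inulinase",               "exo_nonreducing", "Fru", "beta", NA, NA, cazy = "GH32"),
  .act("3.2.1.67", "exo-polygalacturonase",       "exo_nonreducing", "GalA", "alpha", 4, "GalA", cazy = "GH28"),
  .act("3.2.1.173", "rhamnogalacturonan galacturonohydrolase", "exo_nonreducing", "GalA", "alpha", 2, "Rha", cazy = "GH28"),
  .act("3.2.1.40", "α-L-rhamnosidase",            "exo_nonreducing", "Rha", "alpha", NA, NA, cazy = "GH78"),
  .act("3.2.1.55", "α-L-arabinofuranosidase",     "exo_nonreducing", "Ara", "alpha", NA, NA, cazy = "GH51;GH54"),
  .act("3.2.1.55", "α-L-arabinofuranosidase",     "debranching", "Ara", "alpha", NA, NA, role = "side", cazy = "GH51;GH54"),
  .act("3.2.1.177", "α-xylosidase",               "debranching", "Xyl", "alpha", 6, "Glc", role = "side", cazy = "GH31"),
  .act("3.2.1.51", "α-L-fucosidase",              "exo_nonreducing", "Fuc", "alpha", NA, NA, cazy = "GH29"),
  .act("3.2.1.139", "α-glucuronidase",            "debranching", "MeGlcA", "alpha", NA, NA, role = "side", cazy = "GH67"),
  .act("3.2.1.139", "α-glucuronidase",            "debranching", "GlcA", "alpha", NA, NA, role = "side", cazy = "GH67"),
  # --- esterases -----------------------------------------------------------
  .act("3.1.1.6",  "acetyl esterase",             "esterase", child = "Man", modification = "acetyl", cazy = "CE16"),
  .act("3.1.1.72", "acetyl xylan esterase",       "esterase", child = "Xyl", modification = "acetyl", cazy = "CE1"),
  .act("3.1.1.86", "rhamnogalacturonan acetyl esterase", "esterase", child = "GalA", modification = "acetyl", cazy = "CE12"),
  .act("3.1.1.11", "pectin methylesterase",       "esterase", child = "GalA", modification = "methyl", cazy = "CE8"),
  .act("3.1.1.73", "feruloyl esterase",           "esterase", child = "Ara", modification = "feruloyl", cazy = "CE1")
)

#' The activity template registry
#'
#' One row per (activity, bond pattern): the EC number, activity name, CAZy
#' families, action mode and the bond pattern it acts on. An activity can
#' own several pattern rows (the arabinofuranosidases act both as exo
#' enzymes on the arabinan backbone and as debranching enzymes on side
#' chains). `NA` in a pattern column is a wildcard.
#'
#' @return `data.frame` with columns `ec`, `name`, `cazy`, `mode`,
#'   `child_sugar`, `config`, `parent_carbon`, `parent_sugar`, `role`,
#'   `modification`.
#' @export
activityRegistry <- function() .ACTIVITY_REGISTRY

.matchLinkageRows <- function(registry, modes, class_row,
                              roles = c("any", "backbone", "side")) {
  m <- registry$mode %in% modes & registry$role %in% roles &
    !is.na(registry$child_sugar) &
    registry$child_sugar == class_row$child_sugar &
    registry$config == class_row$config &
    (is.na(registry$parent_carbon) |
       registry$parent_carbon == class_row$parent_carbon) &
    (is.na(registry$parent_sugar) |
       registry$parent_sugar == class_row$parent_sugar)
  registry[which(m), , drop = FALSE]
}

.matchModificationRows <- function(registry, class_row) {
  m <- registry$mode == "esterase" &
    !is.na(registry$modification) &
    registry$modification == class_row$kind &
    (is.na(registry$child_sugar) | registry$child_sugar == class_row$sugar)
  registry[which(m), , drop = FALSE]
}

#' Derive the enzymatic activities required to degrade a structure
#'
#' For every bond class of the structure the registry is queried: backbone
#' linkage classes require an endo activity and an exo activity for the
#' terminal-releasable sugar, branch points require a debranching activity,
#' linkages within multi-residue side chains an exo activity, and each
#' ester modification class an esterase. Bond classes for which the
#' registry holds no template are returned in the `"unmapped"` attribute,
#' never silently dropped.
#'
#' The result is a pure function of [enumerateBondClasses()]: structures
#' with identical bond-class sets have identical required-activity sets.
#'
#' @param structure a [GlycanStructure-class].
#' @param registry activity template table, defaults to
#'   [activityRegistry()].
#' @return `data.frame` with one row per required activity (`ec`, `name`,
#'   `cazy`, `mode`, `classes`), with attribute `unmapped` listing bond
#'   classes without a template.
#' @examples
#' requiredActivities(loadStructure("cellulose"))
#' @export
requiredActivities <- function(structure, registry = activityRegistry()) {
  stopifnot(is(structure, "GlycanStructure"))
  lc <- .linkageClasses(structure)
  mc <- .modificationClasses(structure)
  hits <- list()
  unmapped <- character()
  addHits <- function(rows, label) {
    if (!nrow(rows)) return(FALSE)
    rows$classes <- label
    hits[[length(hits) + 1L]] <<- rows
    TRUE
  }
  for (i in seq_len(nrow(lc))) {
    cls <- lc[i, ]
    ok <- switch(cls$context,
      backbone = {
        e1 <- addHits(.matchLinkageRows(registry, "endo", cls,
                                        roles = "backbone"), cls$label)
        e2 <- addHits(.matchLinkageRows(registry, "exo_nonreducing", cls),
                      cls$label)
        e1 || e2
      },
      branch = addHits(.matchLinkageRows(registry, "debranching", cls),
                       cls$label),
      sidechain = addHits(.matchLinkageRows(registry, "exo_nonreducing",
                                            cls), cls$label))
    if (!ok) unmapped <- c(unmapped, cls$label)
  }
  for (i in seq_len(nrow(mc))) {
    cls <- mc[i, ]
    if (!addHits(.matchModificationRows(registry, cls), cls$label)) {
      unmapped <- c(unmapped, cls$label)
    }
  }
  if (!length(hits)) {
    out <- data.frame(ec = character(), name = character(),
                      cazy = character(), mode = character(),
                      classes = character(), stringsAsFactors = FALSE)
    attr(out, "unmapped") <- unique(unmapped)
    return(out)
  }
  all <- do.call(rbind, hits)
  key <- paste(all$ec, all$name)
  out <- do.call(rbind, lapply(split(all, key), function(g) {
    data.frame(ec = g$ec[1L], name = g$name[1L], cazy = g$cazy[1L],
               mode = paste(unique(g$mode), collapse = ";"),
               classes = paste(sort(unique(g$classes)), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$ec, out$name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmapped") <- unique(unmapped)
  out
}
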