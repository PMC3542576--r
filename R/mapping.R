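# Overlay gene statuses on structures: required-activity coverage,
# full-set detection, and annotated DOT maps.

.STATUS_LABELS <- c("up", "down", "ns", "absent_in_other_genome")

.asStatusTable <- function(statuses) {
  if (is.null(statuses)) {
    return(data.frame(gene = character(), label = character(),
                      provenance = character(), stringsAsFactors = FALSE))
  }
  if (is.list(statuses) && !is.data.frame(statuses) &&
      !is.null(statuses$status)) {
    statuses <- statuses$status      # callSignificant() output
  }
  if (is.character(statuses) && !is.null(names(statuses))) {
    statuses <- data.frame(gene = names(statuses),
                           label = unname(statuses),
                           stringsAsFactors = FALSE)
  }
  statuses <- as.data.frame(statuses, stringsAsFactors = FALSE)
  if (is.null(statuses$provenance)) statuses$provenance <- ""
  bad <- setdiff(unique(statuses$label), .STATUS_LABELS)
  if (length(bad)) {
    stop("unknown status label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  statuses
}

# label per catalog record, matching statuses by any of its ids;
# conflicting labels resolve up > down > absent > ns
.statusPerRecord <- function(catalog_rows, statuses) {
  ids <- .geneAllIds(catalog_rows)
  prio <- c(up = 1L, down = 2L, absent_in_other_genome = 3L, ns = 4L)
  vapply(ids, function(id) {
    hit <- statuses$label[statuses$gene %in% id]
    if (!length(hit)) return("ns")
    hit[order(prio[hit])][1L]
  }, character(1))
}

#' Coverage of a structure's required activities by induced genes
#'
#' Joins [requiredActivities()] with the catalog and a gene status table
#' (typically from [callSignificant()] or [makeStatusFixture()]). An
#' activity is covered when at least `require_n` of its gene units carry
#' the label `"up"`; genes sharing an `ambiguous_probe_group` count as one
#' unit, since their array probes cannot be distinguished. Down-regulated
#' genes never count towards coverage. Required activities with no catalog
#' gene are excluded from the coverage denominator but reported as
#' unmapped.
#'
#' @param catalog an [EnzymeCatalog-class].
#' @param structure a [GlycanStructure-class] or structure name.
#' @param statuses gene status table (`gene`, `label`, optional
#'   `provenance`), a named label vector, or [callSignificant()] output.
#' @param require_n minimum number of induced gene units per activity.
#' @param registry activity template table.
#' @return a [CoverageReport-class].
#' @export
overlayStatus <- function(catalog, structure, statuses, require_n = 1L,
                          registry = activityRegistry()) {
  stopifnot(is(catalog, "EnzymeCatalog"))
  if (is.character(structure)) structure <- loadStructure(structure)
  statuses <- .asStatusTable(statuses)
  req <- requiredActivities(structure, registry = registry)

  g <- catalog@genes
  all_ids <- unique(unlist(.geneAllIds(g)))
  unknown <- setdiff(unique(statuses$gene), all_ids)
  if (length(unknown)) {
    warning("status entries for genes not in the catalog: ",
            paste(utils::head(unknown, 5L), collapse = ", "),
            if (length(unknown) > 5L) " ..." else "")
  }

  rows <- list()
  unmappedAct <- character()
  for (i in seq_len(nrow(req))) {
    act <- req[i, ]
    rec <- .catalogRowsForActivity(catalog, act)
    if (!nrow(rec)) {
      unmappedAct <- c(unmappedAct, paste0(act$ec, " ", act$name))
      rows[[length(rows) + 1L]] <- data.frame(
        ec = act$ec, name = act$name, mode = act$mode, n_genes = 0L,
        n_units = 0L, n_up = 0L, n_down = 0L, covered = FALSE,
        mapped = FALSE, genes = "", stringsAsFactors = FALSE)
      next
    }
    lab <- .statusPerRecord(rec, statuses)
    unit <- ifelse(nzchar(rec$ambiguous_probe_group),
                   paste0("grp:", rec$ambiguous_probe_group),
                   paste0("rec:", seq_len(nrow(rec))))
    unit_up <- vapply(split(lab, unit), function(ls) any(ls == "up"),
                      logical(1))
    unit_down <- vapply(split(lab, unit), function(ls) any(ls == "down"),
                        logical(1))
    rows[[length(rows) + 1L]] <- data.frame(
      ec = act$ec, name = act$name, mode = act$mode,
      n_genes = nrow(rec), n_units = length(unit_up),
      n_up = sum(unit_up), n_down = sum(unit_down),
      covered = sum(unit_up) >= require_n, mapped = TRUE,
      genes = paste(.geneDisplayId(rec), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  acts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ec = character(), name = character(), mode = character(),
               n_genes = integer(), n_units = integer(), n_up = integer(),
               n_down = integer(), covered = logical(), mapped = logical(),
               genes = character(), stringsAsFactors = FALSE)
  mapped <- acts$mapped
  coverage <- if (any(mapped)) mean(acts$covered[mapped]) else 0
  fullSet <- any(mapped) && all(acts$covered[mapped])
  new("CoverageReport", structure = structure@name, activities = acts,
      coverage = coverage, fullSet = fullSet,
      unmapped = c(attr(req, "unmapped"), unmappedAct),
      unknownGenes = unknown)
}

#' @describeIn CoverageReport-class covered / mapped required activities.
#' @param x,object a `CoverageReport`.
#' @export
coverageFraction <- function(x) x@coverage

#' @describeIn CoverageReport-class is every mapped required activity
#'   covered?
#' @export
fullSet <- function(x) x@fullSet

#' @describeIn CoverageReport-class per-activity coverage table.
#' @export
coverageActivities <- function(x) x@activities

setMethod("show", "CoverageReport", function(object) {
  cat("CoverageReport for '", object@structure, "'\n", sep = "")
  cat(sprintf("  coverage %.2f (%d/%d mapped activities), full set: %s\n",
              object@coverage, sum(object@activities$covered &
                                     object@activities$mapped),
              sum(object@activities$mapped),
              if (object@fullSet) "YES" else "no"))
  if (length(object@unmapped)) {
    cat("  unmapped:", paste(object@unmapped, collapse = "; "), "\n")
  }
  invisible(NULL)
})

#' Scan all structures for fully covered degradation enzyme sets
#'
#' Applies [overlayStatus()] to each structure and reports coverage
#' fractions, sorted by coverage; the structures whose complete required
#' set is induced ("full set") are in the `"full_set_structures"`
#' attribute.
#'
#' @param catalog an [EnzymeCatalog-class].
#' @param statuses gene status table; see [overlayStatus()].
#' @param structures structure names or `GlycanStructure` objects
#'   (default: all sixteen packaged types).
#' @param require_n,registry as in [overlayStatus()].
#' @return `data.frame` with columns `structure`, `coverage`,
#'   `n_required`, `n_mapped`, `full_set`; attribute `reports` holds the
#'   individual [CoverageReport-class] objects.
#' @export
fullSetScan <- function(catalog, statuses,
                        structures = listStructures(), require_n = 1L,
                        registry = activityRegistry()) {
  reports <- lapply(structures, function(s) {
    suppressWarnings(overlayStatus(catalog, s, statuses,
                                   require_n = require_n,
                                   registry = registry))
  })
  out <- data.frame(
    structure = vapply(reports, function(r) r@structure, character(1)),
    coverage = vapply(reports, function(r) r@coverage, numeric(1)),
    n_required = vapply(reports, function(r) nrow(r@activities),
                        integer(1)),
    n_mapped = vapply(reports, function(r) sum(r@activities$mapped),
                      integer(1)),
    full_set = vapply(reports, function(r) r@fullSet, logical(1)),
    stringsAsFactors = FALSE)
  ord <- order(-out$coverage, out$structure)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  names(reports) <- vapply(reports, function(r) r@structure, character(1))
  attr(out, "reports") <- reports[ord]
  attr(out, "full_set_structures") <- out$structure[out$full_set]
  out
}

# ---- DOT rendering --------------------------------------------------------

.dotQuote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

.renderDOT <- function(structure, catalog = NULL, statuses = NULL,
                       registry = activityRegistry()) {
  res <- structure@residues
  lnk <- linkages(structure)
  mod <- structure@modifications
  lines <- c(paste0("graph ", .dotQuote(structure@name), " {"),
             "  rankdir=RL;",
             "  node [fontsize=10];")
  shape <- ifelse(res$ring_carbons == 6L, "hexagon", "pentagon")
  for (i in seq_len(nrow(res))) {
    lines <- c(lines, sprintf(
      '  r%d [label=%s, shape=%s%s];', res$id[i],
      .dotQuote(paste0(res$sugar[i], "\\n", res$id[i])), shape[i],
      if (res$backbone[i]) ", style=bold" else ""))
  }
  for (i in seq_len(nrow(lnk))) {
    lines <- c(lines, sprintf('  r%d -- r%d [label=%s];', lnk$parent[i],
                              lnk$child[i], .dotQuote(lnk$bond_label[i])))
  }
  for (i in seq_len(nrow(mod))) {
    node <- sprintf("m%d", i)
    lines <- c(lines, sprintf(
      '  %s [label=%s, shape=note, fontsize=8];', node,
      .dotQuote(paste0(mod$kind[i], "@C", mod$carbon[i]))),
      sprintf('  %s -- r%d [style=dotted];', node, mod$residue[i]))
  }
  if (!is.null(catalog)) {
    statuses <- .asStatusTable(statuses)
    req <- requiredActivities(structure, registry = registry)
    gi <- 0L
    for (i in seq_len(nrow(req))) {
      act <- req[i, ]
      rec <- .catalogRowsForActivity(catalog, act)
      if (!nrow(rec)) next
      anchor <- .activityAnchor(structure, act, lnk, mod, res)
      lab <- .statusPerRecord(rec, statuses)
      for (j in seq_len(nrow(rec))) {
        gi <- gi + 1L
        node <- sprintf("g%d", gi)
        # gray overrides: gene present in CBS 513.88 but without a
        # bidirectional best hit in ATCC 1015
        fill <- if (!nzchar(rec$atcc_id[j]) ||
                    lab[j] == "absent_in_other_genome") "gray"
        else switch(lab[j], up = "red", down = "green", "white")
        lines <- c(lines, sprintf(
          '  %s [label=%s, shape=box, style=filled, fillcolor=%s, fontsize=8];',
          node, .dotQuote(paste0(.geneDisplayId(rec[j, ]), "\\n",
                                 act$ec)), fill),
          sprintf('  %s -- %s [style=dashed, color=gray50];', node, anchor))
      }
    }
  }
  c(lines, "}")
}

# anchor node for an activity's gene boxes: the child residue of the first
# linkage the activity cleaves (or the carrier residue for esterases)
.activityAnchor <- function(structure, act, lnk, mod, res) {
  classes <- strsplit(act$classes, ";", fixed = TRUE)[[1L]]
  if (grepl("esterase", act$mode)) {
    for (i in seq_len(nrow(mod))) {
      lab <- .modClassLabel(mod$kind[i],
                            res$sugar[match(mod$residue[i], res$id)])
      if (lab %in% classes) return(sprintf("r%d", mod$residue[i]))
    }
  }
  hit <- which(lnk$bond_label %in% classes)
  if (length(hit)) return(sprintf("r%d", lnk$child[hit[1L]]))
  sprintf("r%d", structure@root)
}

#' Render an annotated polysaccharide map as DOT
#'
#' Residues are drawn as polygons (six sides for hexoses, five for
#' pentoses) labelled with the sugar code; linkages are edges labelled
#' with the bond type; each required activity's genes appear as boxes
#' attached to a bond the activity cleaves. Box colours follow the map
#' legend: red = significantly up-regulated, green = down-regulated, gray =
#' present in CBS 513.88 but without a bidirectional best hit in ATCC 1015,
#' no fill = not significantly regulated.
#'
#' @param structure a [GlycanStructure-class] or structure name.
#' @param catalog an [EnzymeCatalog-class] (omit for a bare structure map).
#' @param statuses gene status table; see [overlayStatus()].
#' @param file optional output path (DOT text).
#' @param registry activity template table.
#' @return DOT source as a character vector of lines (invisibly when
#'   `file` is given).
#' @export
renderMap <- function(structure, catalog = NULL, statuses = NULL,
                      file = NULL, registry = activityRegistry()) {
  if (is.character(structure)) structure <- loadStructure(structure)
  dot <- .renderDOT(structure, catalog = catalog, statuses = statuses,
                    registry = registry)
  if (!is.null(file)) {
    writeLines(dot, file, useBytes = TRUE)
    return(invisible(dot))
  }
  dot
}

#' Read / write gene status tables
#'
#' @param path TSV with columns `gene`, `label`, optional `provenance`.
#' @return `data.frame` usable by [overlayStatus()].
#' @export
readStatus <- function(path) {
  .asStatusTable(utils::read.delim(path, colClasses = "character",
                                   stringsAsFactors = FALSE))
}

#' @rdname readStatus
#' @param statuses a status table.
#' @export
writeStatus <- function(statuses, path) {
  utils::write.table(.asStatusTable(statuses), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
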