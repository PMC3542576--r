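# Gene <-> activity catalog: reading, validation, lookups.

.CATALOG_COLUMNS <- c("ec", "name", "cazy", "mode", "gene_name", "uniprot",
                      "cbs_id", "atcc_id", "characterized", "refs",
                      "ambiguous_probe_group")
.CATALOG_MANDATORY <- c("ec", "name", "mode", "cbs_id", "atcc_id")

.validEnzymeCatalog <- function(object) {
  g <- object@genes
  msg <- character()
  missing <- setdiff(.CATALOG_COLUMNS, names(g))
  if (length(missing)) {
    return(paste("catalog is missing column(s):",
                 paste(missing, collapse = ", ")))
  }
  if (!nrow(g)) return(TRUE)
  noid <- !nzchar(g$cbs_id) & !nzchar(g$atcc_id)
  if (any(noid)) {
    msg <- c(msg, paste("rows without any genome id:",
                        paste(which(noid), collapse = ", ")))
  }
  for (col in c("cbs_id", "atcc_id")) {
    ids <- g[[col]][nzchar(g[[col]])]
    if (anyDuplicated(ids)) {
      msg <- c(msg, paste0("duplicate ", col, ": ",
                           paste(unique(ids[duplicated(ids)]),
                                 collapse = ", ")))
    }
  }
  badmode <- nzchar(g$mode) &
    !g$mode %in% c("endo", "exo_nonreducing", "debranching", "esterase")
  if (any(badmode)) {
    msg <- c(msg, paste("unknown mode in rows:",
                        paste(which(badmode), collapse = ", ")))
  }
  uncref <- g$characterized & !nzchar(g$refs)
  if (any(uncref)) {
    msg <- c(msg, paste("characterized gene without references in rows:",
                        paste(which(uncref), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
}

setValidity("EnzymeCatalog", .validEnzymeCatalog)

#' @describeIn EnzymeCatalog-class the gene record table.
#' @param x,object an `EnzymeCatalog`.
#' @export
catalogGenes <- function(x) x@genes

setMethod("show", "EnzymeCatalog", function(object) {
  g <- object@genes
  cat("EnzymeCatalog with", nrow(g), "gene records,",
      length(unique(paste(g$ec, g$name))), "distinct activities\n")
  cat("  characterized:", sum(g$characterized),
      "| with CBS 513.88 id:", sum(nzchar(g$cbs_id)),
      "| with ATCC 1015 id:", sum(nzchar(g$atcc_id)), "\n")
  invisible(NULL)
})

#' @describeIn EnzymeCatalog-class number of gene records.
#' @export
setMethod("length", "EnzymeCatalog", function(x) nrow(x@genes))

#' Read a gene catalog from TSV
#'
#' The TSV mirrors the columns of the packaged activity tables: `ec`,
#' `name`, `cazy`, `mode`, `gene_name`, `uniprot`, `cbs_id`, `atcc_id`,
#' `characterized`, `refs` (semicolon-separated citation keys) and
#' `ambiguous_probe_group`. `"N/A"` and empty cells become empty fields; a
#' record must carry at least one genome id.
#'
#' @param path TSV file.
#' @return an [EnzymeCatalog-class].
#' @examples
#' tab1 <- system.file("extdata", "catalog_ggm_table1.tsv",
#'                     package = "CAZymap")
#' readCatalog(tab1)
#' @export
readCatalog <- function(path) {
  g <- utils::read.delim(path, colClasses = "character",
                         stringsAsFactors = FALSE, check.names = TRUE)
  missing <- setdiff(.CATALOG_MANDATORY, names(g))
  if (length(missing)) {
    stop("catalog is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(.CATALOG_COLUMNS, names(g))) g[[col]] <- ""
  g <- g[, .CATALOG_COLUMNS, drop = FALSE]
  for (col in setdiff(.CATALOG_COLUMNS, "characterized")) {
    v <- trimws(g[[col]])
    v[is.na(v) | toupper(v) %in% c("N/A", "NA")] <- ""
    g[[col]] <- v
  }
  g$characterized <- toupper(trimws(g$characterized)) %in%
    c("TRUE", "T", "YES", "1")
  for (col in c("cbs_id", "atcc_id")) {
    ids <- g[[col]][nzchar(g[[col]])]
    if (anyDuplicated(ids)) {
      dup <- unique(ids[duplicated(ids)])
      stop("duplicate ", col, " in catalog rows ",
           paste(which(g[[col]] %in% dup), collapse = ", "), ": ",
           paste(dup, collapse = ", "), call. = FALSE)
    }
  }
  new("EnzymeCatalog", genes = g)
}

#' Write a catalog as canonical TSV
#'
#' Column order and formatting are fixed so read -> write -> read is
#' stable.
#'
#' @param catalog an [EnzymeCatalog-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeCatalog <- function(catalog, path) {
  stopifnot(is(catalog, "EnzymeCatalog"))
  g <- catalog@genes
  g$characterized <- ifelse(g$characterized, "TRUE", "FALSE")
  utils::write.table(g[, .CATALOG_COLUMNS, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.looksLikeEC <- function(x) grepl("^[0-9]+\\.", x)

# non-erroring variant used by overlays
.catalogRowsForActivity <- function(catalog, activity) {
  g <- catalog@genes
  if (is.list(activity) || is.data.frame(activity)) {
    ec <- activity$ec
    nm <- activity$name
  } else if (.looksLikeEC(activity)) {
    ec <- activity
    nm <- ""
  } else {
    ec <- ""
    nm <- activity
  }
  if (nzchar(ec)) {
    hit <- g$ec == ec
    if (!any(hit)) hit <- tolower(g$name) == tolower(nm)
  } else {
    hit <- tolower(g$name) == tolower(nm)
  }
  g[which(hit), , drop = FALSE]
}

#' Genes mapped to an enzymatic activity
#'
#' @param catalog an [EnzymeCatalog-class].
#' @param activity an EC number, an activity name, or one row of
#'   [requiredActivities()] output.
#' @return `data.frame` of matching gene records.
#' @export
genesForActivity <- function(catalog, activity) {
  stopifnot(is(catalog, "EnzymeCatalog"))
  rows <- .catalogRowsForActivity(catalog, activity)
  if (!nrow(rows)) {
    stop("no catalog record for activity '",
         if (is.list(activity)) paste(activity$ec, activity$name)
         else activity,
         "'", call. = FALSE)
  }
  rows
}

#' The activity of a gene
#'
#' @param catalog an [EnzymeCatalog-class].
#' @param gene_id a CBS 513.88 id, ATCC 1015 id, or gene name.
#' @return one-row `data.frame` with the gene's activity fields.
#' @export
activityForGene <- function(catalog, gene_id) {
  stopifnot(is(catalog, "EnzymeCatalog"))
  g <- catalog@genes
  hit <- (nzchar(g$cbs_id) & g$cbs_id == gene_id) |
    (nzchar(g$atcc_id) & g$atcc_id == gene_id) |
    (nzchar(g$gene_name) & g$gene_name == gene_id)
  if (!any(hit)) stop("unknown gene id '", gene_id, "'", call. = FALSE)
  g[which(hit)[1L], , drop = FALSE]
}

# canonical display id of a gene record
.geneDisplayId <- function(rows) {
  ifelse(nzchar(rows$gene_name), rows$gene_name,
         ifelse(nzchar(rows$cbs_id), rows$cbs_id, rows$atcc_id))
}

# all ids a status table may use to refer to each record
.geneAllIds <- function(g) {
  lapply(seq_len(nrow(g)), function(i) {
    ids <- c(g$cbs_id[i], g$atcc_id[i], g$gene_name[i])
    ids[nzchar(ids)]
  })
}
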