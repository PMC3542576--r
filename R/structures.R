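# Construction, validation and I/O of polysaccharide structure graphs.

.emptyResidues <- function() {
  data.frame(id = integer(), sugar = character(), ring_carbons = integer(),
             anomeric_carbon = integer(), backbone = logical(),
             stringsAsFactors = FALSE)
}

.emptyLinkages <- function() {
  data.frame(parent = integer(), child = integer(), config = character(),
             parent_carbon = integer(), child_carbon = integer(),
             stringsAsFactors = FALSE)
}

.emptyModifications <- function() {
  data.frame(residue = integer(), kind = character(), carbon = integer(),
             stringsAsFactors = FALSE)
}

#' Create a polysaccharide structure graph
#'
#' Low-level constructor; most users will call [loadStructure()] or
#' [generateStructure()] instead. Ring size and anomeric carbon are filled
#' in from the sugar code when not supplied, and the full tree validator is
#' run before the object is returned.
#'
#' @param name structure label.
#' @param residues `data.frame` with at least `id` and `sugar`; optional
#'   `backbone` (default `TRUE`), `ring_carbons`, `anomeric_carbon`.
#' @param linkages `data.frame` with `parent`, `child`, `config`,
#'   `parent_carbon`; optional `child_carbon` (defaults to the child's
#'   anomeric carbon).
#' @param modifications optional `data.frame` with `residue`, `kind`,
#'   `carbon`.
#' @param root id of the reducing-end residue; inferred as the unique
#'   residue that is nobody's child when missing.
#' @return a validated [GlycanStructure-class] object.
#' @examples
#' res <- data.frame(id = 1:2, sugar = "Glc")
#' lnk <- data.frame(parent = 1, child = 2, config = "beta", parent_carbon = 4)
#' GlycanStructure("cellobiose", res, lnk)
#' @export
GlycanStructure <- function(name, residues, linkages = .emptyLinkages(),
                            modifications = .emptyModifications(),
                            root = NULL) {
  residues <- as.data.frame(residues, stringsAsFactors = FALSE)
  if (is.null(residues$backbone)) residues$backbone <- TRUE
  info <- .sugarInfo(residues$sugar)
  if (is.null(residues$ring_carbons)) residues$ring_carbons <- info$ring_carbons
  if (is.null(residues$anomeric_carbon)) {
    residues$anomeric_carbon <- info$anomeric_carbon
  }
  residues <- data.frame(id = as.integer(residues$id),
                         sugar = as.character(residues$sugar),
                         ring_carbons = as.integer(residues$ring_carbons),
                         anomeric_carbon = as.integer(residues$anomeric_carbon),
                         backbone = as.logical(residues$backbone),
                         stringsAsFactors = FALSE)
  linkages <- as.data.frame(linkages, stringsAsFactors = FALSE)
  if (nrow(linkages) && is.null(linkages$child_carbon)) {
    i <- match(linkages$child, residues$id)
    linkages$child_carbon <- residues$anomeric_carbon[i]
  }
  linkages <- data.frame(parent = as.integer(linkages$parent),
                         child = as.integer(linkages$child),
                         config = as.character(linkages$config),
                         parent_carbon = as.integer(linkages$parent_carbon),
                         child_carbon = as.integer(linkages$child_carbon),
                         stringsAsFactors = FALSE)
  modifications <- as.data.frame(modifications, stringsAsFactors = FALSE)
  modifications <- data.frame(residue = as.integer(modifications$residue),
                              kind = as.character(modifications$kind),
                              carbon = as.integer(modifications$carbon),
                              stringsAsFactors = FALSE)
  dangling <- setdiff(c(linkages$parent, linkages$child), residues$id)
  if (length(dangling)) {
    stop("linkage references unknown residue id(s): ",
         paste(unique(dangling), collapse = ", "), call. = FALSE)
  }
  if (is.null(root)) {
    cand <- setdiff(residues$id, linkages$child)
    if (length(cand) != 1L) {
      stop("cannot infer root: candidate reducing-end residues: ",
           paste(cand, collapse = ", "), call. = FALSE)
    }
    root <- cand
  }
  new("GlycanStructure", name = as.character(name), residues = residues,
      linkages = linkages, modifications = modifications,
      root = as.integer(root))
}

.validGlycanStructure <- function(object) {
  msg <- character()
  res <- object@residues
  lnk <- object@linkages
  mod <- object@modifications
  if (nrow(res) == 0L) return("structure must contain at least one residue")
  if (anyDuplicated(res$id)) {
    msg <- c(msg, paste("duplicate residue id(s):",
                        paste(unique(res$id[duplicated(res$id)]),
                              collapse = ", ")))
  }
  bad <- setdiff(res$sugar, .SUGARS$sugar)
  if (length(bad)) msg <- c(msg, paste("unknown sugar code(s):",
                                       paste(bad, collapse = ", ")))
  if (!all(res$ring_carbons %in% c(5L, 6L))) {
    msg <- c(msg, "ring_carbons must be 5 or 6")
  }
  if (!all(res$anomeric_carbon %in% c(1L, 2L))) {
    msg <- c(msg, "anomeric_carbon must be 1 or 2")
  }
  if (length(msg)) return(msg)

  if (nrow(lnk)) {
    dangling <- setdiff(c(lnk$parent, lnk$child), res$id)
    if (length(dangling)) {
      return(paste("linkage references unknown residue id(s):",
                   paste(unique(dangling), collapse = ", ")))
    }
    if (!all(lnk$config %in% .CONFIGS)) {
      msg <- c(msg, "linkage config must be 'alpha' or 'beta'")
    }
    ci <- match(lnk$child, res$id)
    wrongac <- lnk$child_carbon != res$anomeric_carbon[ci]
    if (any(wrongac)) {
      msg <- c(msg, paste("child_carbon must equal the child's anomeric",
                          "carbon; offending child id(s):",
                          paste(lnk$child[wrongac], collapse = ", ")))
    }
    pi <- match(lnk$parent, res$id)
    over <- lnk$parent_carbon > res$ring_carbons[pi] | lnk$parent_carbon < 1L
    if (any(over)) {
      msg <- c(msg, paste("parent_carbon out of range for parent id(s):",
                          paste(lnk$parent[over], collapse = ", ")))
    }
    dupchild <- lnk$child[duplicated(lnk$child)]
    if (length(dupchild)) {
      msg <- c(msg, paste("residue(s) are child in more than one linkage:",
                          paste(unique(dupchild), collapse = ", ")))
    }
    key <- paste(lnk$parent, lnk$parent_carbon)
    if (anyDuplicated(key)) {
      msg <- c(msg, paste("more than one child attached at parent carbon:",
                          paste(unique(key[duplicated(key)]),
                                collapse = "; ")))
    }
  }
  if (length(msg)) return(msg)

  # tree shape: |E| = |V| - 1, single root, connected from the root
  if (nrow(lnk) != nrow(res) - 1L) {
    return(sprintf("not a tree: %d residues need %d linkages, found %d",
                   nrow(res), nrow(res) - 1L, nrow(lnk)))
  }
  roots <- setdiff(res$id, lnk$child)
  if (length(roots) != 1L || roots != object@root) {
    return(paste("exactly one root (reducing end) required; found:",
                 paste(roots, collapse = ", "), "declared:", object@root))
  }
  seen <- object@root
  frontier <- object@root
  while (length(frontier)) {
    nxt <- lnk$child[lnk$parent %in% frontier]
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (length(seen) != nrow(res)) {
    return(paste("graph contains a cycle or disconnected residue(s):",
                 paste(setdiff(res$id, seen), collapse = ", ")))
  }

  if (nrow(mod)) {
    dangling <- setdiff(mod$residue, res$id)
    if (length(dangling)) {
      return(paste("modification references unknown residue id(s):",
                   paste(unique(dangling), collapse = ", ")))
    }
    if (!all(mod$kind %in% .MODIFICATIONS)) {
      msg <- c(msg, paste("unknown modification kind(s):",
                          paste(setdiff(mod$kind, .MODIFICATIONS),
                                collapse = ", ")))
    }
    for (r in unique(mod$residue)) {
      carbons <- mod$carbon[mod$residue == r]
      used <- c(res$anomeric_carbon[match(r, res$id)],
                lnk$parent_carbon[lnk$parent == r],
                lnk$child_carbon[lnk$child == r])
      if (anyDuplicated(carbons) || any(carbons %in% used)) {
        msg <- c(msg, paste0("modification carbons on residue ", r,
                             " collide with each other or with linkages"))
      }
    }
  }
  if (length(msg)) msg else TRUE
}

setValidity("GlycanStructure", .validGlycanStructure)

# ---- accessors ------------------------------------------------------------

#' @describeIn GlycanStructure-class structure name.
#' @param x,object a `GlycanStructure`.
#' @export
structureName <- function(x) x@name

#' @describeIn GlycanStructure-class residue table.
#' @export
residues <- function(x) x@residues

#' @describeIn GlycanStructure-class linkage table, with a derived
#'   `bond_label` column.
#' @export
linkages <- function(x) {
  lnk <- x@linkages
  if (nrow(lnk)) {
    res <- x@residues
    lnk$bond_label <- bondLabel(res$sugar[match(lnk$child, res$id)],
                                lnk$config, lnk$child_carbon,
                                lnk$parent_carbon,
                                res$sugar[match(lnk$parent, res$id)])
  } else {
    lnk$bond_label <- character()
  }
  lnk
}

#' @describeIn GlycanStructure-class modification table.
#' @export
modifications <- function(x) x@modifications

#' @describeIn GlycanStructure-class id of the reducing-end residue.
#' @export
rootId <- function(x) x@root

setMethod("show", "GlycanStructure", function(object) {
  res <- object@residues
  cat("GlycanStructure:", object@name, "\n")
  cat("  ", nrow(res), " residues (", sum(res$backbone), " backbone), ",
      nrow(object@linkages), " linkages, ",
      nrow(object@modifications), " modifications\n", sep = "")
  comp <- sort(table(res$sugar), decreasing = TRUE)
  cat("  composition:",
      paste(names(comp), comp, sep = ":", collapse = " "), "\n")
  invisible(NULL)
})

#' @describeIn GlycanStructure-class number of residues.
#' @export
setMethod("length", "GlycanStructure", function(x) nrow(x@residues))

# ---- packaged structures --------------------------------------------------

.STRUCTURE_NAMES <- c(
  "starch", "cellulose", "pullulan", "inulin", "galactomannan",
  "insoluble_galactoglucomannan", "soluble_galactoglucomannan",
  "smooth_pectin", "xylogalacturonan", "xylan",
  "xyloglucan_xxgg", "xyloglucan_xxxg",
  "arabinogalactan_1", "arabinogalactan_2",
  "arabinan", "rhamnogalacturonan_1")

#' List the packaged polysaccharide structures
#'
#' The sixteen plant polysaccharide types of the knowledge base: starch,
#' cellulose, pullulan, inulin, the mannans, the six pectin components,
#' xylan and the two xyloglucan types. Rhamnogalacturonan II is deliberately
#' not part of the library.
#'
#' @return character vector of the 16 structure names accepted by
#'   [loadStructure()] and [generateStructure()].
#' @export
listStructures <- function() .STRUCTURE_NAMES

.structureFile <- function(name) {
  system.file("extdata", "structures", paste0(name, ".json"),
              package = "CAZymap", mustWork = FALSE)
}

#' Load a polysaccharide structure
#'
#' @param path_or_name one of the names in [listStructures()], or the path
#'   to a structure JSON file.
#' @return a validated [GlycanStructure-class].
#' @examples
#' cel <- loadStructure("cellulose")
#' unique(linkages(cel)$bond_label)
#' @export
loadStructure <- function(path_or_name) {
  stopifnot(is.character(path_or_name), length(path_or_name) == 1L)
  path <- path_or_name
  if (!file.exists(path)) {
    if (path_or_name %in% .STRUCTURE_NAMES) {
      path <- .structureFile(path_or_name)
      if (!nzchar(path) || !file.exists(path)) {
        stop("packaged structure file missing for '", path_or_name, "'",
             call. = FALSE)
      }
    } else {
      stop("unknown structure '", path_or_name, "'; expected a file path ",
           "or one of: ", paste(.STRUCTURE_NAMES, collapse = ", "),
           call. = FALSE)
    }
  }
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  res <- as.data.frame(obj$residues, stringsAsFactors = FALSE)
  mods <- .emptyModifications()
  if (!is.null(res$modifications)) {
    ml <- res$modifications
    keep <- vapply(ml, function(m) !is.null(m) && NROW(m) > 0L, logical(1))
    if (any(keep)) {
      mods <- do.call(rbind, lapply(which(keep), function(i) {
        m <- as.data.frame(ml[[i]], stringsAsFactors = FALSE)
        data.frame(residue = res$id[i], kind = m$kind, carbon = m$carbon,
                   stringsAsFactors = FALSE)
      }))
    }
    res$modifications <- NULL
  }
  lnk <- if (is.null(obj$linkages) || NROW(obj$linkages) == 0L) {
    .emptyLinkages()
  } else {
    as.data.frame(obj$linkages, stringsAsFactors = FALSE)
  }
  GlycanStructure(obj$name, res, lnk, mods, root = obj$root)
}

#' Save a structure as JSON
#'
#' The serialization is canonical (residues sorted by id, linkages by child
#' id, fixed key order), so save -> load -> save reproduces the file byte
#' for byte.
#'
#' @param structure a [GlycanStructure-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
saveStructure <- function(structure, path) {
  stopifnot(is(structure, "GlycanStructure"))
  txt <- .structureJSON(structure)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, useBytes = TRUE)
  invisible(path)
}

.structureJSON <- function(structure) {
  res <- structure@residues[order(structure@residues$id), , drop = FALSE]
  lnk <- structure@linkages[order(structure@linkages$child), , drop = FALSE]
  mod <- structure@modifications
  reslist <- lapply(seq_len(nrow(res)), function(i) {
    r <- list(id = res$id[i], sugar = res$sugar[i],
              ring_carbons = res$ring_carbons[i],
              anomeric_carbon = res$anomeric_carbon[i],
              backbone = res$backbone[i])
    m <- mod[mod$residue == res$id[i], , drop = FALSE]
    if (nrow(m)) {
      m <- m[order(m$carbon), , drop = FALSE]
      r$modifications <- lapply(seq_len(nrow(m)), function(j) {
        list(kind = m$kind[j], carbon = m$carbon[j])
      })
    }
    r
  })
  lnklist <- lapply(seq_len(nrow(lnk)), function(i) {
    list(parent = lnk$parent[i], child = lnk$child[i],
         config = lnk$config[i], parent_carbon = lnk$parent_carbon[i],
         child_carbon = lnk$child_carbon[i])
  })
  jsonlite::toJSON(list(name = structure@name, root = structure@root,
                        residues = reslist, linkages = lnklist),
                   auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

# ---- composition and bond classes ----------------------------------------

#' Residue composition of a structure or ensemble
#'
#' Counts residues by monosaccharide code and returns fractions. For an
#' ensemble (a list of structures) the counts are pooled before
#' normalizing, which is the natural analogue of a bulk sugar analysis of
#' the preparation.
#'
#' @param x a [GlycanStructure-class] or a list of them.
#' @return named numeric vector of fractions summing to 1, sorted
#'   decreasingly.
#' @examples
#' residueComposition(generateStructure("cellulose", backbone_length = 5))
#' @export
residueComposition <- function(x) {
  if (is(x, "GlycanStructure")) x <- list(x)
  if (!length(x)) stop("empty ensemble", call. = FALSE)
  sugars <- unlist(lapply(x, function(s) s@residues$sugar))
  tab <- table(sugars)
  frac <- stats::setNames(as.vector(tab) / sum(tab), names(tab))
  sort(frac, decreasing = TRUE)
}

# Internal: unique linkage classes with matching context.
# context: "backbone"  both residues on the main chain
#          "branch"    side residue attached to a backbone residue
#          "sidechain" side residue attached to another side residue
.linkageClasses <- function(structure) {
  lnk <- structure@linkages
  res <- structure@residues
  if (!nrow(lnk)) {
    return(data.frame(child_sugar = character(), config = character(),
                      child_carbon = integer(), parent_carbon = integer(),
                      parent_sugar = character(), context = character(),
                      label = character(), stringsAsFactors = FALSE))
  }
  ci <- match(lnk$child, res$id)
  pi <- match(lnk$parent, res$id)
  context <- ifelse(res$backbone[ci] & res$backbone[pi], "backbone",
                    ifelse(res$backbone[pi], "branch", "sidechain"))
  df <- data.frame(child_sugar = res$sugar[ci], config = lnk$config,
                   child_carbon = lnk$child_carbon,
                   parent_carbon = lnk$parent_carbon,
                   parent_sugar = res$sugar[pi], context = context,
                   stringsAsFactors = FALSE)
  df$label <- bondLabel(df$child_sugar, df$config, df$child_carbon,
                        df$parent_carbon, df$parent_sugar)
  unique(df)
}

.modificationClasses <- function(structure) {
  mod <- structure@modifications
  res <- structure@residues
  if (!nrow(mod)) {
    return(data.frame(kind = character(), sugar = character(),
                      context = character(), label = character(),
                      stringsAsFactors = FALSE))
  }
  i <- match(mod$residue, res$id)
  df <- data.frame(kind = mod$kind, sugar = res$sugar[i],
                   context = ifelse(res$backbone[i], "backbone", "side"),
                   stringsAsFactors = FALSE)
  df$label <- .modClassLabel(df$kind, df$sugar)
  unique(df)
}

#' Enumerate the bond classes of a structure
#'
#' Bond classes are the join key between a structure and the enzymatic
#' activities required to degrade it: every glycosidic linkage class and
#' every ester modification class present is reported once, together with
#' its context (backbone linkage, branch point, within a side chain).
#'
#' @param structure a [GlycanStructure-class].
#' @return `data.frame` with columns `class` (display label), `kind`
#'   (`"linkage"`/`"modification"`) and `context`.
#' @examples
#' enumerateBondClasses(loadStructure("cellulose"))
#' @export
enumerateBondClasses <- function(structure) {
  stopifnot(is(structure, "GlycanStructure"))
  lc <- .linkageClasses(structure)
  mc <- .modificationClasses(structure)
  out <- rbind(
    data.frame(class = lc$label, kind = rep("linkage", nrow(lc)),
               context = lc$context, stringsAsFactors = FALSE),
    data.frame(class = mc$label, kind = rep("modification", nrow(mc)),
               context = mc$context, stringsAsFactors = FALSE))
  out[order(out$kind, out$class), , drop = FALSE]
}

#' Export a structure as DOT
#'
#' Residues become nodes (hexagons for six-carbon sugars, pentagons for
#' five-carbon sugars, labelled with the sugar code and residue id);
#' linkages become edges labelled with the bond type. See [renderMap()] for
#' the annotated variant with gene boxes.
#'
#' @param structure a [GlycanStructure-class].
#' @param file optional output path.
#' @return the DOT source as a character scalar (invisibly when `file` is
#'   given).
#' @export
structureToDOT <- function(structure, file = NULL) {
  dot <- .renderDOT(structure, catalog = NULL, statuses = NULL)
  if (!is.null(file)) {
    writeLines(dot, file, useBytes = TRUE)
    return(invisible(dot))
  }
  dot
}
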