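# Deterministic enzymatic depolymerization as a monotone rule closure.
#
# Rules (default semantics):
#   R1 esterase    removes a matching ester modification.
#   R2 debranching removes an unsubstituted single-residue side chain whose
#                  linkage matches the pattern.
#   R3 endo        cleaves a backbone linkage iff both flanking residues
#                  were interior in the original backbone AND both are
#                  currently free of side chains and modifications.
#   R4 exo         removes a current non-reducing terminal residue (a leaf
#                  of its fragment) iff it is unmodified and its linkage
#                  matches the pattern.
#
# All enabling conditions are monotone (removals only ever enable further
# removals), so the closure is confluent: the fixpoint is independent of
# the order in which applicable rules fire. Degradation completeness is the
# fraction of input residues that end up as free monomers (degree of
# polymerization 1); disaccharides and larger count as incomplete.

.resolveActivities <- function(activities, registry) {
  if (is.data.frame(activities)) {
    need <- c("ec", "name", "mode")
    if (!all(need %in% names(activities))) {
      stop("activity table must have columns ec, name, mode", call. = FALSE)
    }
    if (all(c("child_sugar", "config", "role") %in% names(activities))) {
      rows <- activities          # explicit pattern rows
    } else {
      key <- paste(registry$ec, registry$name)
      rows <- registry[key %in% paste(activities$ec, activities$name), ,
                       drop = FALSE]
    }
  } else if (is.character(activities)) {
    if (!length(activities)) {
      rows <- registry[0L, , drop = FALSE]
    } else {
      hit <- registry$name %in% activities | registry$ec %in% activities
      unknown <- activities[!(activities %in% registry$name |
                                activities %in% registry$ec)]
      if (length(unknown)) {
        stop("unknown activity name(s)/EC(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      rows <- registry[hit, , drop = FALSE]
    }
  } else {
    stop("activities must be a character vector or an activity table",
         call. = FALSE)
  }
  badmode <- setdiff(rows$mode,
                     c("endo", "exo_nonreducing", "debranching", "esterase"))
  if (length(badmode)) {
    stop("unknown activity mode(s): ", paste(badmode, collapse = ", "),
         call. = FALSE)
  }
  rows
}

.linkClassRow <- function(res, lnk, i) {
  ci <- match(lnk$child[i], res$id)
  pi <- match(lnk$parent[i], res$id)
  list(child_sugar = res$sugar[ci], config = lnk$config[i],
       parent_carbon = lnk$parent_carbon[i], parent_sugar = res$sugar[pi],
       label = bondLabel(res$sugar[ci], lnk$config[i], lnk$child_carbon[i],
                         lnk$parent_carbon[i], res$sugar[pi]))
}

.rowsMatchLink <- function(rows, cls) {
  any(!is.na(rows$child_sugar) & rows$child_sugar == cls$child_sugar &
        rows$config == cls$config &
        (is.na(rows$parent_carbon) |
           rows$parent_carbon == cls$parent_carbon) &
        (is.na(rows$parent_sugar) | rows$parent_sugar == cls$parent_sugar))
}

#' Simulate enzymatic digestion of a structure
#'
#' Runs the rule closure of the given activities over the structure and
#' reports the product size distribution, the monomer yield, the
#' completeness (fraction of residues released as free monosaccharides)
#' and, via [explainBlockers()], why any residue was left unreleased.
#'
#' Under the default semantics the result does not depend on rule firing
#' order. The optional `processive = TRUE` variant re-evaluates "interior"
#' against the current fragment (an endo enzyme may then cut bonds that
#' were terminal in the original chain); it applies rules one at a time in
#' a canonical order (lowest linkage id first, non-reducing to reducing)
#' and is order-sensitive by construction.
#'
#' @param structure a [GlycanStructure-class].
#' @param activities character vector of activity names and/or EC numbers,
#'   or a table of registry rows (e.g. [requiredActivities()] output).
#' @param registry activity template table; see [activityRegistry()].
#' @param processive use fragment-relative endo semantics.
#' @return a [DigestResult-class].
#' @examples
#' man6 <- generateStructure("galactomannan", backbone_length = 6,
#'                           gal_prob = 0, seed = 1)
#' completeness(digestStructure(man6, c("endo-1,4-β-D-mannanase",
#'                                      "β-mannosidase")))
#' @export
digestStructure <- function(structure, activities,
                            registry = activityRegistry(),
                            processive = FALSE) {
  stopifnot(is(structure, "GlycanStructure"))
  rows <- .resolveActivities(activities, registry)
  res <- structure@residues
  lnk <- structure@linkages
  mod <- structure@modifications

  alive <- rep(TRUE, nrow(res))          # residue still part of a fragment
  names(alive) <- res$id
  cleaved <- rep(FALSE, nrow(lnk))
  mod_active <- rep(TRUE, nrow(mod))
  released <- character()                # sugars freed as monomers
  log <- list()
  step <- 0L

  # original-backbone interiority (static, drives the default endo rule)
  bb_parent <- vapply(seq_len(nrow(res)), function(i) {
    j <- which(lnk$child == res$id[i])
    length(j) == 1L && res$backbone[match(lnk$parent[j], res$id)] &&
      res$backbone[i]
  }, logical(1))
  bb_child <- vapply(seq_len(nrow(res)), function(i) {
    j <- which(lnk$parent == res$id[i])
    res$backbone[i] &&
      any(res$backbone[match(lnk$child[j], res$id)])
  }, logical(1))
  interior <- bb_parent & bb_child

  erows <- rows[rows$mode == "esterase", , drop = FALSE]
  xrows <- rows[rows$mode == "exo_nonreducing", , drop = FALSE]
  drows <- rows[rows$mode == "debranching", , drop = FALSE]
  nrows <- rows[rows$mode == "endo", , drop = FALSE]

  idx <- function(id) match(id, res$id)
  activeMods <- function(id) which(mod_active & mod$residue == id)
  activeChildren <- function(id) {
    j <- which(!cleaved & lnk$parent == id)
    j[alive[as.character(lnk$child[j])]]
  }
  unsubstituted <- function(id) {
    if (length(activeMods(id))) return(FALSE)
    ch <- activeChildren(id)
    !any(!res$backbone[idx(lnk$child[ch])])
  }
  logEvent <- function(rule, activity, detail) {
    step <<- step + 1L
    log[[step]] <<- data.frame(step = step, rule = rule,
                               activity = activity, detail = detail,
                               stringsAsFactors = FALSE)
  }

  matchEsterase <- function(k) {
    sugar <- res$sugar[idx(mod$residue[k])]
    hit <- erows$modification == mod$kind[k] &
      (is.na(erows$child_sugar) | erows$child_sugar == sugar)
    if (any(hit)) erows$name[which(hit)[1L]] else NA_character_
  }
  matchLeaf <- function(i) {
    # i: linkage index attaching a current leaf; returns activity name
    cls <- .linkClassRow(res, lnk, i)
    is_side <- !res$backbone[idx(lnk$child[i])]
    cand <- if (is_side) rbind(drows, xrows) else xrows
    if (!nrow(cand)) return(NA_character_)
    hit <- !is.na(cand$child_sugar) & cand$child_sugar == cls$child_sugar &
      cand$config == cls$config &
      (is.na(cand$parent_carbon) | cand$parent_carbon == cls$parent_carbon) &
      (is.na(cand$parent_sugar) | cand$parent_sugar == cls$parent_sugar)
    if (any(hit)) cand$name[which(hit)[1L]] else NA_character_
  }
  endoApplicable <- function(i) {
    p <- lnk$parent[i]; ch <- lnk$child[i]
    if (!(res$backbone[idx(p)] && res$backbone[idx(ch)])) return(FALSE)
    if (!processive) {
      if (!(interior[idx(p)] && interior[idx(ch)])) return(FALSE)
    } else {
      # fragment-relative: the child must go on towards a non-reducing end
      # and the parent must not be the fragment's reducing end
      if (!length(activeChildren(ch))) return(FALSE)
      jp <- which(!cleaved & lnk$child == p)
      if (!length(jp)) return(FALSE)
    }
    if (!(unsubstituted(p) && unsubstituted(ch))) return(FALSE)
    cls <- .linkClassRow(res, lnk, i)
    hit <- !is.na(nrows$child_sugar) & nrows$child_sugar == cls$child_sugar &
      nrows$config == cls$config &
      (is.na(nrows$parent_carbon) |
         nrows$parent_carbon == cls$parent_carbon) &
      (is.na(nrows$parent_sugar) | nrows$parent_sugar == cls$parent_sugar)
    if (any(hit)) nrows$name[which(hit)[1L]] else NA_character_
  }

  repeat {
    changed <- FALSE
    # R1: esterases
    for (k in which(mod_active)) {
      act <- matchEsterase(k)
      if (!is.na(act)) {
        mod_active[k] <- FALSE
        logEvent("esterase", act,
                 paste0(.modClassLabel(mod$kind[k],
                                       res$sugar[idx(mod$residue[k])]),
                        " on residue ", mod$residue[k]))
        changed <- TRUE
      }
    }
    # R2/R4: leaf removal (debranching and exo release)
    for (i in which(!cleaved)) {
      ch <- lnk$child[i]
      if (!alive[as.character(ch)]) next
      if (length(activeChildren(ch))) next        # not a leaf
      if (length(activeMods(ch))) next            # substituent blocks
      act <- matchLeaf(i)
      if (!is.na(act)) {
        alive[as.character(ch)] <- FALSE
        cleaved[i] <- TRUE
        released <- c(released, res$sugar[idx(ch)])
        rule <- if (!res$backbone[idx(ch)]) "debranching" else "exo"
        logEvent(rule, act, paste0("released residue ", ch, " (",
                                   res$sugar[idx(ch)], ")"))
        changed <- TRUE
      }
    }
    # R3: endo cleavage
    for (i in which(!cleaved)) {
      if (!alive[as.character(lnk$child[i])]) next
      act <- endoApplicable(i)
      if (isFALSE(act) || is.na(act)) next
      cleaved[i] <- TRUE
      logEvent("endo", act,
               paste0("cleaved ", .linkClassRow(res, lnk, i)$label,
                      " between residues ", lnk$parent[i], "-",
                      lnk$child[i]))
      changed <- TRUE
      if (processive) break      # canonical one-at-a-time order
    }
    if (!changed) break
  }

  # fragments: components of the remaining graph
  comp <- .components(res$id[alive[as.character(res$id)]],
                      lnk[!cleaved & alive[as.character(lnk$child)] &
                            alive[as.character(lnk$parent)], , drop = FALSE])
  sizes <- lengths(comp)
  dp_all <- c(rep(1L, length(released)), sizes)
  dp <- as.data.frame(table(dp = dp_all), stringsAsFactors = FALSE)
  dp$dp <- as.integer(dp$dp)
  names(dp) <- c("dp", "count")
  singleton_sugars <- res$sugar[idx(unlist(comp[sizes == 1L]))]
  mono <- table(c(released, singleton_sugars))
  monomers <- data.frame(sugar = names(mono), count = as.integer(mono),
                         stringsAsFactors = FALSE)
  n <- nrow(res)
  completeness <- (length(released) + sum(sizes == 1L)) / n

  blockers <- .digestBlockers(res, lnk, mod, alive, cleaved, mod_active,
                              sizes, comp, rows)
  new("DigestResult", structure = structure@name, n = as.integer(n),
      dp = dp, monomers = monomers, completeness = completeness,
      blockers = blockers,
      log = if (length(log)) do.call(rbind, log) else
        data.frame(step = integer(), rule = character(),
                   activity = character(), detail = character(),
                   stringsAsFactors = FALSE),
      fragments = comp)
}

.components <- function(ids, lnk) {
  if (!length(ids)) return(list())
  parent <- stats::setNames(ids, ids)
  findp <- function(i) {
    while (parent[[as.character(i)]] != i) i <- parent[[as.character(i)]]
    i
  }
  for (j in seq_len(nrow(lnk))) {
    a <- findp(lnk$parent[j]); b <- findp(lnk$child[j])
    if (a != b) parent[[as.character(b)]] <- a
  }
  roots <- vapply(ids, findp, numeric(1))
  unname(split(ids, roots))
}

.digestBlockers <- function(res, lnk, mod, alive, cleaved, mod_active,
                            sizes, comp, rows) {
  out <- list()
  idx <- function(id) match(id, res$id)
  in_polymer <- rep(FALSE, nrow(res))
  for (k in which(sizes > 1L)) in_polymer[idx(comp[[k]])] <- TRUE
  # surviving modifications on unreleased residues
  for (k in which(mod_active)) {
    if (!in_polymer[idx(mod$residue[k])]) next
    lab <- .modClassLabel(mod$kind[k], res$sugar[idx(mod$residue[k])])
    out[[length(out) + 1L]] <- data.frame(
      class = lab, kind = "modification", needed_mode = "esterase",
      note = "no matching esterase in the activity set; the substituent blocks cleavage at this residue",
      stringsAsFactors = FALSE)
  }
  # surviving linkages inside multi-residue fragments
  for (i in which(!cleaved)) {
    ch <- lnk$child[i]; p <- lnk$parent[i]
    if (!alive[as.character(ch)] || !in_polymer[idx(ch)]) next
    cls <- .linkClassRow(res, lnk, i)
    is_side <- !res$backbone[idx(ch)]
    chj <- which(!cleaved & lnk$parent == ch)
    chj <- chj[alive[as.character(lnk$child[chj])]]
    is_leaf <- !length(chj)
    modded <- any(mod_active & mod$residue == ch)
    if (is_leaf) {
      needed <- if (is_side) "debranching/exo_nonreducing" else
        "exo_nonreducing"
      note <- if (modded) {
        paste0("terminal residue carries ",
               paste(.modClassLabel(mod$kind[mod_active &
                                               mod$residue == ch],
                                    res$sugar[idx(ch)]), collapse = ","),
               "; an esterase must act first")
      } else {
        "no activity in the set matches this terminal linkage"
      }
    } else {
      needed <- "endo"
      side_ch <- chj[!res$backbone[idx(lnk$child[chj])]]
      note <- if (length(side_ch)) {
        paste0("flanking residue still carries side chain(s): ",
               paste(unique(vapply(side_ch, function(j)
                 .linkClassRow(res, lnk, j)$label, character(1))),
                 collapse = ", "),
               "; they block backbone release at ", res$sugar[idx(ch)])
      } else {
        "no endo activity cleaves this interior linkage, or its flanks were never interior"
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      class = cls$label, kind = "linkage", needed_mode = needed,
      note = note, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(class = character(), kind = character(),
                      needed_mode = character(), note = character(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  all <- do.call(rbind, out)
  key <- paste(all$class, all$needed_mode, all$note)
  agg <- do.call(rbind, lapply(split(all, key), function(g) {
    g <- g[1L, , drop = FALSE]; g
  }))
  agg$n <- as.integer(table(key)[paste(agg$class, agg$needed_mode,
                                       agg$note)])
  rownames(agg) <- NULL
  agg[order(agg$kind, agg$class), , drop = FALSE]
}

#' @describeIn DigestResult-class fraction of input residues released as
#'   free monomers.
#' @param x,object a `DigestResult`.
#' @export
completeness <- function(x) x@completeness

#' @describeIn DigestResult-class degree-of-polymerization histogram.
#' @export
dpHistogram <- function(x) x@dp

#' @describeIn DigestResult-class monomer yield per sugar.
#' @export
monomerYield <- function(x) {
  stats::setNames(x@monomers$count, x@monomers$sugar)
}

#' Explain why a digestion is incomplete
#'
#' Attributes every residue not released as a free monomer to at least one
#' blocked or missing rule: a bond class with no matching activity, a
#' terminal residue whose ester substituent was never removed, or a side
#' chain that blocks backbone release.
#'
#' @param result a [DigestResult-class].
#' @return `data.frame` with columns `class`, `kind`, `needed_mode`,
#'   `note`, `n`; zero rows for a complete digest.
#' @export
explainBlockers <- function(result) {
  stopifnot(is(result, "DigestResult"))
  result@blockers
}

setMethod("show", "DigestResult", function(object) {
  cat("DigestResult for '", object@structure, "' (", object@n,
      " residues)\n", sep = "")
  cat(sprintf("  completeness: %.3f\n", object@completeness))
  cat("  DP histogram:",
      paste(object@dp$dp, object@dp$count, sep = ":", collapse = " "), "\n")
  if (nrow(object@blockers)) {
    cat("  blockers:", nrow(object@blockers), "class(es); see",
        "explainBlockers()\n")
  }
  invisible(NULL)
})

#' Minimal sufficient activity sets for complete degradation
#'
#' Enumerates subsets of the candidate activities, in increasing size, that
#' digest the structure to completeness 1.0 and have no sufficient proper
#' subset. Exhaustive for up to 15 candidates; larger candidate sets fall
#' back to a greedy heuristic (flagged via the `"exhaustive"` attribute).
#'
#' @param structure a [GlycanStructure-class].
#' @param candidate_activities character vector of activity names/ECs.
#' @param max_size largest subset size to consider.
#' @param registry activity template table.
#' @return list of character vectors (possibly empty); attribute
#'   `exhaustive` says whether the search enumerated all subsets.
#' @export
minimalSufficientSets <- function(structure, candidate_activities,
                                  max_size = length(candidate_activities),
                                  registry = activityRegistry()) {
  cand <- unique(candidate_activities)
  complete <- function(set) {
    r <- digestStructure(structure, set, registry = registry)
    r@completeness >= 1
  }
  exhaustive <- length(cand) <= 15L
  found <- list()
  if (exhaustive) {
    for (s in seq_len(min(max_size, length(cand)))) {
      combos <- utils::combn(length(cand), s)
      for (j in seq_len(ncol(combos))) {
        sub <- cand[combos[, j]]
        if (any(vapply(found, function(f) all(f %in% sub), logical(1)))) {
          next        # proper superset of a known sufficient set
        }
        if (complete(sub)) found[[length(found) + 1L]] <- sub
      }
    }
  } else {
    set <- cand
    if (complete(set)) {
      for (a in rev(cand)) {
        trial <- setdiff(set, a)
        if (length(trial) && complete(trial)) set <- trial
      }
      found[[1L]] <- set
    }
  }
  attr(found, "exhaustive") <- exhaustive
  found
}
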