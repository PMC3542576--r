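# Independent brute-force closure oracle for the digestion rules.
#
# Works on its own adjacency representation, enumerates every single
# applicable rule instance at each step, and applies them one at a time in
# a caller-controlled (shuffled) order. Shared with the confluence and
# oracle-equivalence tests; deliberately re-derives pattern matching rather
# than calling the package internals.

oracleDigest <- function(structure, activity_rows, shuffle_seed = NULL) {
  res <- residues(structure)
  lnk <- structure@linkages
  mod <- modifications(structure)
  rows <- activity_rows

  alive <- rep(TRUE, nrow(res))
  cut <- rep(FALSE, nrow(lnk))
  mact <- rep(TRUE, nrow(mod))
  released <- character()
  rng <- if (is.null(shuffle_seed)) NULL else shuffle_seed
  if (!is.null(rng)) set.seed(rng)

  sug <- function(id) res$sugar[match(id, res$id)]
  bb <- function(id) res$backbone[match(id, res$id)]
  kids <- function(id) {
    j <- which(!cut & lnk$parent == id)
    j[alive[match(lnk$child[j], res$id)]]
  }
  modsOn <- function(id) which(mact & mod$residue == id)
  clean <- function(id) {
    if (length(modsOn(id))) return(FALSE)
    kk <- kids(id)
    all(bb(lnk$child[kk]))
  }
  # static original-backbone interiority
  isInterior <- vapply(res$id, function(id) {
    up <- which(lnk$child == id)
    has_bp <- length(up) == 1L && bb(lnk$parent[up]) && bb(id)
    dn <- which(lnk$parent == id)
    has_bc <- bb(id) && any(bb(lnk$child[dn]))
    has_bp && has_bc
  }, logical(1))

  matchLink <- function(i, modes) {
    cs <- sug(lnk$child[i]); ps <- sug(lnk$parent[i])
    for (j in seq_len(nrow(rows))) {
      r <- rows[j, ]
      if (!(r$mode %in% modes)) next
      if (is.na(r$child_sugar) || r$child_sugar != cs) next
      if (r$config != lnk$config[i]) next
      if (!is.na(r$parent_carbon) && r$parent_carbon != lnk$parent_carbon[i])
        next
      if (!is.na(r$parent_sugar) && r$parent_sugar != ps) next
      return(TRUE)
    }
    FALSE
  }

  steps <- function() {
    out <- list()
    for (k in which(mact)) {
      s <- sug(mod$residue[k])
      hit <- any(rows$mode == "esterase" &
                   !is.na(rows$modification) &
                   rows$modification == mod$kind[k] &
                   (is.na(rows$child_sugar) | rows$child_sugar == s))
      if (hit) out[[length(out) + 1L]] <- list(type = "mod", k = k)
    }
    for (i in which(!cut)) {
      ch <- lnk$child[i]
      if (!alive[match(ch, res$id)]) next
      if (!length(kids(ch)) && !length(modsOn(ch))) {
        modes <- if (bb(ch)) "exo_nonreducing" else
          c("exo_nonreducing", "debranching")
        if (matchLink(i, modes)) {
          out[[length(out) + 1L]] <- list(type = "leaf", i = i)
        }
      }
      p <- lnk$parent[i]
      if (bb(p) && bb(ch) &&
          isInterior[match(p, res$id)] && isInterior[match(ch, res$id)] &&
          clean(p) && clean(ch) && matchLink(i, "endo")) {
        out[[length(out) + 1L]] <- list(type = "endo", i = i)
      }
    }
    out
  }

  repeat {
    st <- steps()
    if (!length(st)) break
    pick <- st[[sample.int(length(st), 1L)]]
    if (pick$type == "mod") {
      mact[pick$k] <- FALSE
    } else if (pick$type == "leaf") {
      ch <- lnk$child[pick$i]
      alive[match(ch, res$id)] <- FALSE
      cut[pick$i] <- TRUE
      released <- c(released, sug(ch))
    } else {
      cut[pick$i] <- TRUE
    }
  }

  ids <- res$id[alive]
  comp <- list()
  if (length(ids)) {
    remaining <- ids
    while (length(remaining)) {
      grp <- remaining[1L]
      repeat {
        nb <- unique(c(
          lnk$child[!cut & lnk$parent %in% grp],
          lnk$parent[!cut & lnk$child %in% grp]))
        nb <- intersect(setdiff(nb, grp), ids)
        if (!length(nb)) break
        grp <- c(grp, nb)
      }
      comp[[length(comp) + 1L]] <- sort(grp)
      remaining <- setdiff(remaining, grp)
    }
  }
  sizes <- lengths(comp)
  singles <- unlist(lapply(comp[sizes == 1L], identity))
  list(
    completeness = (length(released) + sum(sizes == 1L)) / nrow(res),
    dp = sort(c(rep(1L, length(released)), sizes)),
    monomers = sort(c(released, vapply(singles, sug,
                                       character(1), USE.NAMES = FALSE))))
}

# comparable summary of a DigestResult
digestSummary <- function(result) {
  dp <- dpHistogram(result)
  my <- monomerYield(result)
  list(completeness = completeness(result),
       dp = sort(rep(dp$dp, dp$count)),
       monomers = sort(as.character(rep(names(my), my))))
}

registryRowsFor <- function(activities) {
  reg <- activityRegistry()
  reg[reg$name %in% activities | reg$ec %in% activities, , drop = FALSE]
}
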