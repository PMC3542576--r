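# Parametric generators for the sixteen polysaccharide types.
#
# Every generator builds a finite representative instance: a backbone of
# `backbone_length` residues decorated stochastically according to the
# published composition of the substrate where one is stated (sugar-beet
# arabinan: 88:4:2:6 arabinose:galactose:rhamnose:galacturonic acid with
# about half of the 1,5-linked backbone arabinoses branched; oat spelt
# xylan: >= 70% xylose), and according to the repeating unit of the
# schematic otherwise. With a fixed seed the output is fully deterministic.

# -- small mutable builder --------------------------------------------------

.builder <- function(name) {
  b <- new.env(parent = emptyenv())
  b$name <- name
  b$n <- 0L
  b$res <- list()
  b$lnk <- list()
  b$mod <- list()
  b
}

.addRes <- function(b, sugar, backbone = TRUE) {
  b$n <- b$n + 1L
  b$res[[b$n]] <- data.frame(id = b$n, sugar = sugar, backbone = backbone,
                             stringsAsFactors = FALSE)
  b$n
}

.addLink <- function(b, parent, child, config, parent_carbon) {
  b$lnk[[length(b$lnk) + 1L]] <-
    data.frame(parent = parent, child = child, config = config,
               parent_carbon = parent_carbon, stringsAsFactors = FALSE)
  invisible(NULL)
}

.addMod <- function(b, residue, kind, carbon) {
  b$mod[[length(b$mod) + 1L]] <-
    data.frame(residue = residue, kind = kind, carbon = carbon,
               stringsAsFactors = FALSE)
  invisible(NULL)
}

.attach <- function(b, parent, sugar, config, parent_carbon,
                    backbone = FALSE) {
  id <- .addRes(b, sugar, backbone = backbone)
  .addLink(b, parent, id, config, parent_carbon)
  id
}

.finish <- function(b) {
  res <- do.call(rbind, b$res)
  lnk <- if (length(b$lnk)) do.call(rbind, b$lnk) else .emptyLinkages()
  mod <- if (length(b$mod)) do.call(rbind, b$mod) else .emptyModifications()
  GlycanStructure(b$name, res, lnk, mod)
}

# grow a simple chain of `n` residues; returns the vector of ids, first id
# is the (sub)chain's reducing-side end
.chain <- function(b, sugars, config, parent_carbon, from = NULL,
                   from_carbon = NULL, backbone = TRUE) {
  n <- length(sugars)
  ids <- integer(n)
  for (i in seq_len(n)) {
    if (i == 1L && is.null(from)) {
      ids[i] <- .addRes(b, sugars[i], backbone = backbone)
    } else if (i == 1L) {
      ids[i] <- .attach(b, from, sugars[i], config, from_carbon,
                        backbone = backbone)
    } else {
      ids[i] <- .attach(b, ids[i - 1L], sugars[i], config, parent_carbon,
                        backbone = backbone)
    }
  }
  ids
}

.checkProb <- function(...) {
  p <- c(...)
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

# -- individual generators --------------------------------------------------

.gen_cellulose <- function(n) {
  b <- .builder("cellulose")
  .chain(b, rep("Glc", n), "beta", 4L)
  .finish(b)
}

.gen_starch <- function(n) {
  b <- .builder("starch")
  .chain(b, rep("Glc", n), "alpha", 4L)
  .finish(b)
}

.gen_pullulan <- function(n) {
  # maltotriose units joined alpha-1,6: bonds repeat 1,4 / 1,4 / 1,6
  b <- .builder("pullulan")
  prev <- .addRes(b, "Glc")
  for (i in seq_len(n - 1L)) {
    pc <- if (i %% 3L == 0L) 6L else 4L
    prev <- .attach(b, prev, "Glc", "alpha", pc, backbone = TRUE)
  }
  .finish(b)
}

.gen_inulin <- function(n) {
  # sucrose-terminated beta-2,1 fructan; the glucosyl residue is the root
  b <- .builder("inulin")
  root <- .addRes(b, "Glc")
  .chain(b, rep("Fru", n - 1L), "beta", 1L, from = root, from_carbon = 1L)
  .finish(b)
}

.gen_galactomannan <- function(n, gal_prob = 0.5) {
  .checkProb(gal_prob)
  b <- .builder("galactomannan")
  bb <- .chain(b, rep("Man", n), "beta", 4L)
  for (id in bb) {
    if (stats::runif(1) < gal_prob) .attach(b, id, "Gal", "alpha", 6L)
  }
  .finish(b)
}

.ggm_backbone <- function(n) {
  # Man:Glc roughly 3:1, arranged so that two Glc are never adjacent
  rep_len(c("Man", "Man", "Man", "Glc"), n)
}

.gen_insoluble_ggm <- function(n, gal_prob = 0.2) {
  .checkProb(gal_prob)
  b <- .builder("insoluble_galactoglucomannan")
  sugars <- .ggm_backbone(n)
  bb <- .chain(b, sugars, "beta", 4L)
  for (i in seq_along(bb)) {
    if (sugars[i] == "Man" && stats::runif(1) < gal_prob) {
      .attach(b, bb[i], "Gal", "alpha", 6L)
    }
  }
  .finish(b)
}

.gen_soluble_ggm <- function(n, gal_prob = 0.3, gal_extend_prob = 1 / 3,
                             acetyl_prob = 0.3) {
  .checkProb(gal_prob, gal_extend_prob, acetyl_prob)
  b <- .builder("soluble_galactoglucomannan")
  sugars <- .ggm_backbone(n)
  bb <- .chain(b, sugars, "beta", 4L)
  for (i in seq_along(bb)) {
    if (sugars[i] != "Man") next
    if (stats::runif(1) < gal_prob) {
      g <- .attach(b, bb[i], "Gal", "alpha", 6L)
      if (stats::runif(1) < gal_extend_prob) {
        .attach(b, g, "Gal", "beta", 2L)
      }
    } else if (stats::runif(1) < acetyl_prob) {
      .addMod(b, bb[i], "acetyl", sample(c(2L, 3L), 1L))
    }
  }
  .finish(b)
}

.gen_smooth_pectin <- function(n, methyl_prob = 0.5) {
  .checkProb(methyl_prob)
  b <- .builder("smooth_pectin")
  bb <- .chain(b, rep("GalA", n), "alpha", 4L)
  for (id in bb) {
    if (stats::runif(1) < methyl_prob) .addMod(b, id, "methyl", 6L)
  }
  .finish(b)
}

.gen_xylogalacturonan <- function(n, xyl_prob = 0.4, methyl_prob = 0.3) {
  .checkProb(xyl_prob, methyl_prob)
  b <- .builder("xylogalacturonan")
  bb <- .chain(b, rep("GalA", n), "alpha", 4L)
  for (id in bb) {
    if (stats::runif(1) < xyl_prob) .attach(b, id, "Xyl", "beta", 3L)
    if (stats::runif(1) < methyl_prob) .addMod(b, id, "methyl", 6L)
  }
  .finish(b)
}

.gen_xylan <- function(n, ara_prob = 0.10, glcA_prob = 0.08,
                       acetyl_prob = 0.10, feruloyl_prob = 0.30) {
  .checkProb(ara_prob, glcA_prob, acetyl_prob, feruloyl_prob)
  b <- .builder("xylan")
  bb <- .chain(b, rep("Xyl", n), "beta", 4L)
  for (id in bb) {
    c2free <- TRUE
    c3free <- TRUE
    if (stats::runif(1) < ara_prob) {
      pc <- sample(c(2L, 3L), 1L)
      a <- .attach(b, id, "Ara", "alpha", pc)
      if (pc == 2L) c2free <- FALSE else c3free <- FALSE
      if (stats::runif(1) < feruloyl_prob) .addMod(b, a, "feruloyl", 5L)
    }
    if (c2free && stats::runif(1) < glcA_prob) {
      .attach(b, id, "MeGlcA", "alpha", 2L)
      c2free <- FALSE
    }
    if (c3free && stats::runif(1) < acetyl_prob) {
      .addMod(b, id, "acetyl", 3L)
    }
  }
  .finish(b)
}

.xyloglucan <- function(name, n, substituted, gal_prob, fuc_prob) {
  b <- .builder(name)
  bb <- .chain(b, rep("Glc", n), "beta", 4L)
  for (i in seq_along(bb)) {
    pos <- (i - 1L) %% 4L + 1L           # position within the XXGG/XXXG unit
    if (!(pos %in% substituted)) next
    x <- .attach(b, bb[i], "Xyl", "alpha", 6L)
    if (pos == 3L && gal_prob > 0 && stats::runif(1) < gal_prob) {
      g <- .attach(b, x, "Gal", "beta", 2L)
      if (stats::runif(1) < fuc_prob) .attach(b, g, "Fuc", "alpha", 2L)
    }
  }
  .finish(b)
}

.gen_xyloglucan_xxgg <- function(n) {
  .xyloglucan("xyloglucan_xxgg", n, substituted = c(1L, 2L),
              gal_prob = 0, fuc_prob = 0)
}

.gen_xyloglucan_xxxg <- function(n, gal_prob = 0.75, fuc_prob = 0.5) {
  .checkProb(gal_prob, fuc_prob)
  .xyloglucan("xyloglucan_xxxg", n, substituted = c(1L, 2L, 3L),
              gal_prob = gal_prob, fuc_prob = fuc_prob)
}

.gen_arabinogalactan_1 <- function(n, ara_prob = 0.3) {
  .checkProb(ara_prob)
  b <- .builder("arabinogalactan_1")
  bb <- .chain(b, rep("Gal", n), "beta", 4L)
  for (id in bb) {
    if (stats::runif(1) < ara_prob) .attach(b, id, "Ara", "alpha", 3L)
  }
  .finish(b)
}

.gen_arabinogalactan_2 <- function(n, gal_prob = 0.4, ara_prob = 0.5) {
  # beta-1,3 galactan backbone carrying beta-1,6 galactosyl side chains
  # that are themselves arabinosylated
  .checkProb(gal_prob, ara_prob)
  b <- .builder("arabinogalactan_2")
  bb <- .chain(b, rep("Gal", n), "beta", 3L)
  for (id in bb) {
    if (stats::runif(1) < gal_prob) {
      g <- .attach(b, id, "Gal", "beta", 6L)
      if (stats::runif(1) < ara_prob) .attach(b, g, "Ara", "alpha", 3L)
    }
  }
  .finish(b)
}

.gen_arabinan <- function(n, branch_prob = 0.5, feruloyl_prob = 0.05,
                          composition = c(Ara = 88, Gal = 4, Rha = 2,
                                          GalA = 6)) {
  # Sugar-beet arabinan: 1,5-alpha-L-arabinan, about half of the backbone
  # residues carrying a single 1,2- or 1,3-linked arabinofuranose branch.
  # The preparation also contains galactose, rhamnose and galacturonic acid
  # (88:4:2:6 with arabinose); these are modelled as a residual pectic core
  # at the reducing end plus a short galactan stub, with counts drawn so
  # that the expected pooled composition matches the stated ratios.
  .checkProb(branch_prob, feruloyl_prob)
  if (any(composition < 0)) stop("composition ratios must be non-negative",
                                 call. = FALSE)
  b <- .builder("arabinan")

  branched <- stats::runif(n) < branch_prob
  nAra <- n + sum(branched)
  lam <- nAra * composition[c("Gal", "Rha", "GalA")] / composition[["Ara"]]
  nGal <- stats::rpois(1L, lam[["Gal"]])
  nRha <- stats::rpois(1L, lam[["Rha"]])
  nGalA <- stats::rpois(1L, lam[["GalA"]])

  prev <- NULL
  if (nGalA > 0L) {
    core <- .chain(b, rep("GalA", nGalA), "alpha", 4L)
    prev <- core[length(core)]
  }
  if (nRha > 0L) {
    rha <- .chain(b, rep("Rha", nRha), "alpha", 4L,
                  from = prev, from_carbon = if (is.null(prev)) NULL else 4L)
    prev <- rha[length(rha)]
  }
  bb <- .chain(b, rep("Ara", n), "alpha", 5L, from = prev,
               from_carbon = if (is.null(prev)) NULL else 4L)
  for (i in seq_len(n)) {
    if (branched[i]) {
      pc <- sample(c(2L, 3L), 1L)
      a <- .attach(b, bb[i], "Ara", "alpha", pc)
      if (stats::runif(1) < feruloyl_prob) .addMod(b, a, "feruloyl", 5L)
    }
  }
  if (nGal > 0L) {
    anchor <- b$res[[1L]]$id      # reducing-end residue
    lnks <- do.call(rbind, b$lnk)
    used <- lnks$parent_carbon[lnks$parent == anchor]
    anchor_carbon <- setdiff(c(3L, 2L), used)[1L]
    .chain(b, rep("Gal", nGal), "beta", 4L, from = anchor,
           from_carbon = anchor_carbon, backbone = FALSE)
  }
  .finish(b)
}

.gen_rhamnogalacturonan_1 <- function(n, side_prob = 0.5,
                                      acetyl_prob = 0.3) {
  # alternating [-4)-GalA-(1,2)-Rha-(1-] backbone; rhamnosyl C4 carries
  # single galactosyl or short arabinan side chains; galacturonosyl
  # residues are partially acetylated
  .checkProb(side_prob, acetyl_prob)
  b <- .builder("rhamnogalacturonan_1")
  prev <- .addRes(b, "GalA")
  ids <- prev
  for (i in seq_len(n - 1L)) {
    if (i %% 2L == 1L) {
      prev <- .attach(b, prev, "Rha", "alpha", 4L, backbone = TRUE)
    } else {
      prev <- .attach(b, prev, "GalA", "alpha", 2L, backbone = TRUE)
    }
    ids <- c(ids, prev)
  }
  res <- do.call(rbind, b$res)
  for (id in ids) {
    sugar <- res$sugar[res$id == id]
    if (sugar == "Rha") {
      if (stats::runif(1) < side_prob) {
        if (stats::runif(1) < 0.5) {
          .attach(b, id, "Gal", "beta", 4L)
        } else {
          a1 <- .attach(b, id, "Ara", "alpha", 4L)
          .attach(b, a1, "Ara", "alpha", 5L)
        }
      }
    } else if (stats::runif(1) < acetyl_prob) {
      .addMod(b, id, "acetyl", 3L)
    }
  }
  .finish(b)
}

.GENERATORS <- list(
  starch = .gen_starch,
  cellulose = .gen_cellulose,
  pullulan = .gen_pullulan,
  inulin = .gen_inulin,
  galactomannan = .gen_galactomannan,
  insoluble_galactoglucomannan = .gen_insoluble_ggm,
  soluble_galactoglucomannan = .gen_soluble_ggm,
  smooth_pectin = .gen_smooth_pectin,
  xylogalacturonan = .gen_xylogalacturonan,
  xylan = .gen_xylan,
  xyloglucan_xxgg = .gen_xyloglucan_xxgg,
  xyloglucan_xxxg = .gen_xyloglucan_xxxg,
  arabinogalactan_1 = .gen_arabinogalactan_1,
  arabinogalactan_2 = .gen_arabinogalactan_2,
  arabinan = .gen_arabinan,
  rhamnogalacturonan_1 = .gen_rhamnogalacturonan_1)

#' Generate a polysaccharide structure instance
#'
#' Draws a finite instance of one of the sixteen packaged polysaccharide
#' types. Decoration and composition parameters default to the documented
#' properties of the substrates (see the package vignette); identical
#' `seed` and parameters give a byte-identical structure.
#'
#' @param type one of [listStructures()].
#' @param backbone_length number of main-chain residues.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @param ... type-specific decoration parameters, e.g. `branch_prob` for
#'   arabinan or `ara_prob`/`glcA_prob`/`acetyl_prob` for xylan.
#' @return a validated [GlycanStructure-class].
#' @examples
#' ara <- generateStructure("arabinan", backbone_length = 20, seed = 1)
#' residueComposition(ara)
#' @export
generateStructure <- function(type, backbone_length = 20, seed = NULL, ...) {
  gen <- .GENERATORS[[type]]
  if (is.null(gen)) {
    stop("unknown structure type '", type, "'; see listStructures()",
         call. = FALSE)
  }
  backbone_length <- as.integer(backbone_length)
  if (is.na(backbone_length) || backbone_length < 1L) {
    stop("backbone_length must be a positive integer", call. = FALSE)
  }
  if (is.null(seed)) {
    gen(backbone_length, ...)
  } else {
    withr::with_seed(as.integer(seed), gen(backbone_length, ...))
  }
}
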