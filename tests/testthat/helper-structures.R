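# Hand-built fixture structures, independent of the package generators.

# linear chain of one sugar, e.g. a beta-1,4 mannan oligosaccharide
chainOf <- function(sugar, n, config = "beta", parent_carbon = 4L,
                    name = paste0(sugar, n)) {
  res <- data.frame(id = seq_len(n), sugar = sugar)
  lnk <- if (n > 1L) {
    data.frame(parent = seq_len(n - 1L), child = 2:n, config = config,
               parent_carbon = parent_carbon)
  } else {
    NULL
  }
  GlycanStructure(name, res, lnk)
}

# small soluble-galactoglucomannan-like fixture:
# backbone Man-Man-Glc-Man-Man (beta-1,4), one alpha-1,6 Gal branch carrying
# a beta-1,2 Gal, one single alpha-1,6 Gal branch, one acetylated Man
ggmSmall <- function() {
  res <- data.frame(
    id = 1:8,
    sugar = c("Man", "Man", "Glc", "Man", "Man", "Gal", "Gal", "Gal"),
    backbone = c(rep(TRUE, 5), FALSE, FALSE, FALSE))
  lnk <- data.frame(
    parent = c(1, 2, 3, 4, 2, 6, 4),
    child  = c(2, 3, 4, 5, 6, 7, 8),
    config = c("beta", "beta", "beta", "beta", "alpha", "beta", "alpha"),
    parent_carbon = c(4, 4, 4, 4, 6, 2, 6))
  mod <- data.frame(residue = 5, kind = "acetyl", carbon = 2)
  GlycanStructure("ggm_small", res, lnk, mod)
}

# random small tree over a 3-sugar alphabet for oracle-equivalence checks:
# a backbone chain plus random single-residue branches and acetyl marks
randomSmallStructure <- function(n = 8L) {
  stopifnot(n >= 2L)
  sugars <- c("Glc", "Man", "Gal")
  k <- sample(2:n, 1L)                      # backbone length
  bsug <- sample(c("Man", "Glc"), k, replace = TRUE, prob = c(0.7, 0.3))
  res <- data.frame(id = seq_len(k), sugar = bsug, backbone = TRUE)
  lnk <- data.frame(parent = seq_len(k - 1L), child = 2:k, config = "beta",
                    parent_carbon = 4L)
  mod <- NULL
  nid <- k
  for (extra in seq_len(n - k)) {
    host <- sample(seq_len(k), 1L)
    if (any(lnk$parent == host & lnk$parent_carbon == 6L)) next
    nid <- nid + 1L
    res <- rbind(res, data.frame(id = nid, sugar = "Gal", backbone = FALSE))
    lnk <- rbind(lnk, data.frame(parent = host, child = nid,
                                 config = "alpha", parent_carbon = 6L))
  }
  for (i in seq_len(k)) {
    if (res$sugar[i] == "Man" && runif(1) < 0.2 &&
        !any(lnk$parent == i & lnk$parent_carbon == 2L)) {
      mod <- rbind(mod, data.frame(residue = i, kind = "acetyl",
                                   carbon = 2L))
    }
  }
  if (is.null(mod)) mod <- data.frame(residue = integer(),
                                      kind = character(),
                                      carbon = integer())
  GlycanStructure("random_small", res, lnk, mod)
}
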