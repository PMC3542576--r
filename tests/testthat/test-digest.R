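test_that("a mannan hexamer with endo + exo activities is fully converted", {
  man6 <- chainOf("Man", 6)
  r <- digestStructure(man6, c("endo-1,4-β-D-mannanase", "β-mannosidase"))
  expect_identical(completeness(r), 1)
  expect_identical(unname(monomerYield(r)), 6L)
  expect_identical(dpHistogram(r), data.frame(dp = 1L, count = 6L))
  expect_identical(nrow(explainBlockers(r)), 0L)
})

test_that("endo-only digestion matches the exhaustive closure oracle", {
  man6 <- chainOf("Man", 6)
  r <- digestStructure(man6, "endo-1,4-β-D-mannanase")
  expected <- oracleDigest(man6, registryRowsFor("endo-1,4-β-D-mannanase"),
                           shuffle_seed = 1)
  got <- digestSummary(r)
  expect_equal(got$completeness, expected$completeness)
  expect_equal(as.integer(got$dp), as.integer(expected$dp))
  # interior cuts only: terminal bonds are never endo substrates
  expect_lt(completeness(r), 1)
  expect_equal(completeness(r), 2 / 6)
})

test_that("an empty activity set leaves any polymer untouched", {
  for (s in list(chainOf("Glc", 5, "beta"), loadStructure("xylan"))) {
    r <- digestStructure(s, character())
    expect_identical(completeness(r), 0)
    expect_identical(dpHistogram(r)$dp, length(s))
  }
  single <- GlycanStructure("free", data.frame(id = 1, sugar = "Man"))
  expect_identical(completeness(digestStructure(single, character())), 1)
})

test_that("residues are conserved at the digest fixpoint", {
  acts <- c("endo-1,4-β-D-mannanase", "β-mannosidase", "β-glucosidase",
            "α-galactosidase", "β-galactosidase", "acetyl esterase")
  for (sub in list(character(), acts[1:2], acts[c(2, 4)], acts)) {
    r <- digestStructure(ggmSmall(), sub)
    dp <- dpHistogram(r)
    expect_identical(sum(dp$dp * dp$count), length(ggmSmall()))
  }
})

test_that("the full GGM activity set achieves complete conversion, and the digest is confluent", {
  acts <- c("endo-1,4-β-D-mannanase", "β-mannosidase", "β-glucosidase",
            "α-galactosidase", "β-galactosidase", "acetyl esterase")
  s <- ggmSmall()
  r <- digestStructure(s, acts)
  expect_identical(completeness(r), 1)
  rows <- registryRowsFor(acts)
  base <- oracleDigest(s, rows, shuffle_seed = 1)
  for (seed in 2:40) {
    o <- oracleDigest(s, rows, shuffle_seed = seed)
    expect_identical(o, base)
  }
  expect_equal(digestSummary(r), base)
})

test_that("digestion equals the closure oracle on random small structures", {
  acts <- c("endo-1,4-β-D-mannanase", "β-mannosidase", "β-glucosidase",
            "α-galactosidase", "acetyl esterase")
  subsets <- list(acts, acts[-4], acts[-5], acts[c(1, 2)], acts[c(2, 3)])
  set.seed(99)
  for (i in 1:20) {
    s <- randomSmallStructure(8L)
    sub <- subsets[[(i %% length(subsets)) + 1L]]
    got <- digestSummary(digestStructure(s, sub))
    want <- oracleDigest(s, registryRowsFor(sub), shuffle_seed = i)
    expect_equal(got$completeness, want$completeness, tolerance = 1e-12)
    expect_equal(as.integer(got$dp), as.integer(want$dp))
    expect_equal(got$monomers, want$monomers)
  }
})

test_that("completeness is monotone in the activity set", {
  acts <- c("endo-1,4-β-D-mannanase", "β-mannosidase", "β-glucosidase",
            "α-galactosidase", "β-galactosidase", "acetyl esterase")
  s <- ggmSmall()
  set.seed(11)
  for (i in 1:15) {
    a <- sample(acts, sample.int(length(acts) - 1L, 1L))
    pool <- setdiff(acts, a)
    extra <- sample(pool, sample.int(length(pool), 1L))
    b <- union(a, extra)
    expect_lte(completeness(digestStructure(s, a)),
               completeness(digestStructure(s, b)) + 1e-12)
  }
})

test_that("every packaged structure is fully degraded by its required activities", {
  for (nm in listStructures()) {
    s <- loadStructure(nm)
    req <- requiredActivities(s)
    r <- digestStructure(s, req)
    expect_identical(completeness(r), 1)
  }
})

test_that("an exo glycosidase alone can walk down an unbranched chain", {
  man6 <- chainOf("Man", 6)
  sets <- minimalSufficientSets(man6, c("endo-1,4-β-D-mannanase",
                                        "β-mannosidase"))
  expect_true(attr(sets, "exhaustive"))
  expect_identical(sets[[1]], "β-mannosidase")
  expect_length(sets, 1L)
  # cross-check against plain subset enumeration over the oracle
  all_subsets <- unlist(lapply(1:2, function(k) {
    utils::combn(c("endo-1,4-β-D-mannanase", "β-mannosidase"), k,
                 simplify = FALSE)
  }), recursive = FALSE)
  suff <- Filter(function(ss) {
    oracleDigest(man6, registryRowsFor(ss), 1)$completeness == 1
  }, all_subsets)
  minimal <- Filter(function(ss) {
    !any(vapply(suff, function(o) length(o) < length(ss) &&
                  all(o %in% ss), logical(1)))
  }, suff)
  attr(sets, "exhaustive") <- NULL
  expect_identical(sets, minimal)
})

test_that("irrelevant activities never enter minimal sufficient sets", {
  cel <- chainOf("Glc", 5, "beta")
  sets <- minimalSufficientSets(cel, c("endo-1,4-β-D-glucanase",
                                       "β-glucosidase", "α-amylase"))
  expect_true(length(sets) >= 1L)
  expect_false(any(vapply(sets, function(s) "α-amylase" %in% s,
                          logical(1))))
})

test_that("a blocked modification makes complete degradation unreachable", {
  s <- ggmSmall()   # carries an acetylated mannose
  sets <- minimalSufficientSets(
    s, c("endo-1,4-β-D-mannanase", "β-mannosidase", "β-glucosidase",
         "α-galactosidase", "β-galactosidase"))
  expect_length(sets, 0L)
})

test_that("blockers name the offending class and the missing mode", {
  s <- ggmSmall()
  # lacking the alpha-galactosidase: galactosyl branches block the backbone
  r <- digestStructure(s, c("endo-1,4-β-D-mannanase", "β-mannosidase",
                            "β-glucosidase", "β-galactosidase",
                            "acetyl esterase"))
  bl <- explainBlockers(r)
  expect_true(any(grepl("Gal-α-1,6-Man", paste(bl$class, bl$note))))
  expect_lt(completeness(r), 1)
  # lacking the esterase: the acetyl class is named
  r2 <- digestStructure(s, c("endo-1,4-β-D-mannanase", "β-mannosidase",
                             "β-glucosidase", "α-galactosidase",
                             "β-galactosidase"))
  bl2 <- explainBlockers(r2)
  expect_true(any(grepl("acetyl@Man", bl2$class)))
  expect_true(any(bl2$needed_mode == "esterase"))
  # complete digests have nothing to explain
  r3 <- digestStructure(s, c("endo-1,4-β-D-mannanase", "β-mannosidase",
                             "β-glucosidase", "α-galactosidase",
                             "β-galactosidase", "acetyl esterase"))
  expect_identical(nrow(explainBlockers(r3)), 0L)
})

test_that("unknown activities and modes are rejected", {
  expect_error(digestStructure(chainOf("Man", 3), "no-such-enzyme"),
               "unknown activity")
  bad <- data.frame(ec = "1.1.1.1", name = "x", mode = "sideways",
                    child_sugar = "Man", config = "beta",
                    parent_carbon = 4L, parent_sugar = NA,
                    role = "any", modification = NA)
  expect_error(digestStructure(chainOf("Man", 3), bad), "unknown activity mode")
})

test_that("the processive endo variant is deterministic and conserves residues", {
  man6 <- chainOf("Man", 6)
  r <- digestStructure(man6, "endo-1,4-β-D-mannanase", processive = TRUE)
  dp <- dpHistogram(r)
  expect_identical(sum(dp$dp * dp$count), 6L)
  r2 <- digestStructure(man6, "endo-1,4-β-D-mannanase", processive = TRUE)
  expect_identical(dpHistogram(r2), dp)
  # fragment-relative endo action chews fragments down to dimers here,
  # a different outcome from the static-interiority default
  expect_identical(completeness(r), 0)
  expect_true(all(dp$dp == 2L))
})
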