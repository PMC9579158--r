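ranked_fixture <- function(n = 100, seed = 1) {
  withr::with_seed(seed, {
    v <- sort(rnorm(n, sd = 2), decreasing = TRUE)
    names(v) <- sprintf("G%03d", sample(n))
    v
  })
}

test_that("GMT files parse, deduplicate and round-trip", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tfirst\tG1\tG2", "S2\tsecond\tG3\tG4\tG5\t",
               "S3\t\tG1"), path)
  gsc <- read_gmt(path)
  expect_length(gsc, 3)
  expect_equal(gsc$sets$S1, c("G1", "G2"))
  expect_equal(gsc$sets$S2, c("G3", "G4", "G5"))  # blank trailing field dropped
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gsc, out)
  expect_identical(read_gmt(out)$sets, gsc$sets)
  expect_identical(read_gmt(out)$descriptions, gsc$descriptions)

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tok\tG1", "ONLYNAME"), bad)
  expect_error(read_gmt(bad), "line 2")

  dup <- withr::local_tempfile(fileext = ".gmt")
  writeLines("S1\tdesc\tG1\tG1\tG2", dup)
  expect_warning(gsc2 <- read_gmt(dup), "duplicate")
  expect_equal(gsc2$sets$S1, c("G1", "G2"))
})

test_that("restriction intersects with the universe and applies inclusive size bounds", {
  universe <- sprintf("G%03d", 1:50)
  gsc <- geneset_collection(list(
    outside = c("X1", "X2", "X3"),
    fourteen = sprintf("G%03d", 1:14),
    fifteen = sprintf("G%03d", 1:15),
    mixed = c(sprintf("G%03d", 1:20), "X9")))
  out <- restrict_and_filter(gsc, universe, min_size = 15, max_size = 500)
  expect_setequal(names(out$sets), c("fifteen", "mixed"))
  expect_equal(length(out$sets$mixed), 20)
  expect_error(restrict_and_filter(gsc, character(0)), "empty universe")
})

test_that("enrichment score hits its closed-form anchors", {
  ranked <- ranked_fixture(10)
  top_gene <- names(ranked)[1]
  expect_equal(enrichment_score(ranked, top_gene)$es, 1)
  everything <- enrichment_score(ranked, names(ranked))
  expect_equal(everything$es, 1)  # no misses: running sum climbs to 1
  expect_error(enrichment_score(ranked, c("NOPE")), "ranked")
  zero <- setNames(c(1, 0, 0, -1), c("a", "b", "c", "d"))
  expect_error(enrichment_score(zero, c("b", "c")), "zero")
})

test_that("enrichment score equals the brute-force walk on random instances", {
  set.seed(123)
  for (i in 1:100) {
    n <- sample(10:50, 1)
    ranked <- sort(rnorm(n, sd = 2), decreasing = TRUE)
    names(ranked) <- sprintf("g%02d", sample(n))
    members <- sample(names(ranked), sample(2:min(20, n - 1), 1))
    for (w in c(0, 1)) {
      expect_equal(enrichment_score(ranked, members, w)$es,
                   es_bruteforce(ranked, members, w), tolerance = 1e-12)
    }
  }
})

test_that("the fast hit-position ES used for permutations matches the running-sum ES", {
  set.seed(5)
  ranked <- ranked_fixture(200, seed = 5)
  w <- abs(ranked)
  for (i in 1:50) {
    pos <- sort(sample.int(200, sample(3:50, 1)))
    expect_equal(dysregr:::es_from_positions(pos, w[pos], 200),
                 enrichment_score(ranked, names(ranked)[pos])$es,
                 tolerance = 1e-12)
  }
})

test_that("ES agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(9)
  ranked <- ranked_fixture(80, seed = 9)
  for (i in 1:20) {
    members <- sample(names(ranked), sample(5:30, 1))
    ref <- fgsea::calcGseaStat(unname(ranked),
                               sort(match(members, names(ranked))),
                               gseaParam = 1)
    expect_equal(enrichment_score(ranked, members)$es, ref, tolerance = 1e-10)
  }
})

test_that("ES is invariant to positive rescaling and flips sign on list reversal", {
  ranked <- ranked_fixture(60, seed = 11)
  members <- names(ranked)[c(2, 5, 9, 30, 31)]
  expect_equal(enrichment_score(ranked, members)$es,
               enrichment_score(ranked * 7, members)$es, tolerance = 1e-12)
  rev_ranked <- sort(-ranked, decreasing = TRUE)
  es_fwd <- enrichment_score(ranked, members, weight_exponent = 0)$es
  es_rev <- enrichment_score(rev_ranked, members, weight_exponent = 0)$es
  expect_equal(es_rev, -es_fwd, tolerance = 1e-12)
  expect_equal(sign(enrichment_score(rev_ranked, members, 1)$es),
               -sign(enrichment_score(ranked, members, 1)$es))
})

test_that("leading edge contains the hits driving the extremum", {
  ranked <- setNames(c(5, 4, 3, 2, 1, 0.5, 0.4, 0.3, 0.2, 0.1),
                     paste0("g", 1:10))
  res <- enrichment_score(ranked, c("g1", "g2", "g9"))
  expect_true(all(c("g1", "g2") %in% res$leading_edge))
  expect_false("g9" %in% res$leading_edge)
  neg <- enrichment_score(ranked, c("g8", "g9", "g10"))
  expect_lt(neg$es, 0)
  expect_true(all(neg$leading_edge %in% c("g8", "g9", "g10")))
})

test_that("pre-ranked GSEA is deterministic and validates its inputs", {
  ranked <- ranked_fixture(300, seed = 2)
  gsc <- geneset_collection(list(
    A = names(ranked)[1:20],
    B = sample(names(ranked), 25),
    C = sample(names(ranked), 30)))
  r1 <- preranked_gsea(ranked, gsc, n_permutations = 100, seed = 4)
  r2 <- preranked_gsea(ranked, gsc, n_permutations = 100, seed = 4)
  expect_identical(r1, r2)
  expect_error(preranked_gsea(ranked, gsc, n_permutations = 5),
               "n_permutations")
  empty <- preranked_gsea(ranked, geneset_collection(stats::setNames(list(), character(0))),
                          n_permutations = 100)
  expect_equal(nrow(empty), 0)
})

test_that("a set planted at the top of a ranked list is detected with FWER control", {
  withr::with_seed(31, {
    scores <- sort(c(runif(50, 3, 5), rnorm(1950)), decreasing = TRUE)
    names(scores) <- sprintf("G%04d", 1:2000)  # top 50 carry the signal
    gsc <- geneset_collection(c(
      list(PLANTED = names(scores)[1:50]),
      stats::setNames(lapply(1:10, function(i) sample(names(scores), 40)),
                      sprintf("RAND%02d", 1:10))))
  })
  res <- preranked_gsea(scores, gsc, n_permutations = 500, seed = 6)
  planted <- res[res$set == "PLANTED", ]
  expect_gt(planted$nes, 0)
  expect_lt(planted$fwer_p, 0.05)
  expect_lt(planted$fdr_q, 0.01)
})

test_that("random sets on an exchangeable null ranking stay below significance", {
  withr::with_seed(17, {
    scores <- sort(rnorm(1000), decreasing = TRUE)
    names(scores) <- sprintf("G%04d", sample(1000))
    gsc <- geneset_collection(stats::setNames(
      lapply(1:20, function(i) sample(names(scores), sample(15:60, 1))),
      sprintf("NULL%02d", 1:20)))
  })
  res <- preranked_gsea(scores, gsc, n_permutations = 300, seed = 8)
  expect_equal(sum(res$fdr_q < 0.01), 0)
})

test_that("label permutation preserves set sizes, is reproducible and kills the signal", {
  withr::with_seed(41, {
    scores <- sort(c(runif(40, 3, 5), rnorm(960)), decreasing = TRUE)
    names(scores) <- sprintf("G%04d", 1:1000)
    gsc <- geneset_collection(c(
      list(PLANTED = names(scores)[1:40]),
      stats::setNames(lapply(1:5, function(i) sample(names(scores), 30)),
                      sprintf("RAND%02d", 1:5))))
  })
  ctl1 <- label_permutation_control(scores, gsc, seed = 3,
                                    n_permutations = 300)
  ctl2 <- label_permutation_control(scores, gsc, seed = 3,
                                    n_permutations = 300)
  expect_identical(ctl1, ctl2)
  expect_equal(ctl1$size[match(names(gsc$sets), ctl1$set)],
               unname(lengths(gsc$sets)))
  expect_gte(ctl1$fdr_q[ctl1$set == "PLANTED"], 0.01)
})
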