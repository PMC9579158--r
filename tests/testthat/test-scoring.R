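test_that("p-value desirability maps the stated anchor points", {
  p <- c(1e-6, 0.2, 0.03, 0.05 + 1e-9)
  d <- desirability_pvalue(p)  # dataset minimum 1e-6 anchors d = 1
  expect_equal(d[1], 1)
  expect_equal(d[2], 0.01)
  expect_equal(d[4], 0.01)
  # midpoint of [p_low_cut, 0.05] falls halfway between floor and ceiling
  lo <- 1e-6
  mid <- (lo + 0.05) / 2
  expect_equal(desirability_pvalue(c(lo, mid, 1)) [2], (1 + 0.01) / 2)
  expect_error(desirability_pvalue(c(0.2, 0.5),
                                   desirability_params(p_low_cut = 0.1)),
               "p_low_cut")
})

test_that("fold-change desirability works on magnitude with linear interpolation", {
  expect_equal(desirability_foldchange(1.5), 1)     # FC ~ 2.83 > 2
  expect_equal(desirability_foldchange(0.1), 0.01)  # FC ~ 1.07 < 1.25
  expect_equal(desirability_foldchange(-1.5), 1)    # direction-blind
  fc_mid <- (1.25 + 2) / 2
  expect_equal(desirability_foldchange(log2(fc_mid)), (0.01 + 1) / 2)
})

test_that("midbrain desirability is the stated two-point score", {
  expect_equal(desirability_midbrain(TRUE), 1)
  expect_equal(desirability_midbrain(FALSE), 0.25)
})

test_that("per-dataset score is the weighted geometric mean with floor for unexpressed", {
  expect_equal(d_dataset(1, 1, 1), 1)
  expect_equal(d_dataset(1, 1, 1, expressed = FALSE), 0.01)
  # frozen from 50-digit arithmetic: 0.5^(1/1.51)
  expect_equal(d_dataset(0.5, 1, 1), 0.6318913160363144, tolerance = 1e-12)
  # toggling the midbrain flag rescales D_dataset by 0.25^(0.01/1.51)
  on <- d_dataset(0.3, 0.7, 1)
  off <- d_dataset(0.3, 0.7, 0.25)
  expect_equal(off / on, 0.9908612571212052, tolerance = 1e-12)
  expect_error(d_dataset(0, 1, 1), "positive")
})

test_that("per-dataset score equals brute-force weighted log-mean on random triples", {
  set.seed(7)
  params <- desirability_params()
  w <- params$weights
  for (i in 1:1000) {
    d3 <- runif(3, 0.01, 1)
    expect_equal(d_dataset(d3[1], d3[2], d3[3], params),
                 exp(sum(w * log(d3)) / sum(w)), tolerance = 1e-12)
  }
})

test_that("concordance follows the signed-majority fraction", {
  all_up <- concordance_factor(rep(1.2, 6))
  expect_equal(all_up$concordance, 1)
  expect_equal(all_up$desirability, 1)
  split <- concordance_factor(c(1, 1, 1, -1, -1, -1))
  expect_equal(split$concordance, 0)
  expect_equal(split$desirability, 0.01)
  five_one <- concordance_factor(c(1, 1, 1, 1, 1, -1))
  expect_equal(five_one$concordance, 4 / 6)
  expect_equal(five_one$desirability, 0.67)
  single <- concordance_factor(2.3)
  expect_equal(single$concordance, 1)
  none <- concordance_factor(numeric(0))
  expect_true(none$undefined)
  expect_equal(none$desirability, 0.01)
  # zero fold changes are excluded from both counts
  expect_equal(concordance_factor(c(0, 1, 1))$concordance, 1)
})

test_that("overall score implements the one-tenth concordance weight", {
  expect_equal(d_overall(rep(0.3, 6), 0.3), 0.3)  # idempotence
  # all datasets at 1, concordance floored: 0.01^((2/3)/(6+2/3)) = 0.01^0.1
  expect_equal(d_overall(rep(1, 6), 0.01), 0.6309573444801932,
               tolerance = 1e-12)
  base <- d_overall(c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7), 0.5)
  up <- d_overall(c(0.25, 0.3, 0.4, 0.5, 0.6, 0.7), 0.5)
  expect_gt(up, base)  # monotone in every dataset score
  expect_error(d_overall(numeric(0), 0.5), "empty")
})

test_that("overall score matches brute-force weighted log-mean on random inputs", {
  set.seed(8)
  for (i in 1:1000) {
    d6 <- runif(6, 0.01, 1)
    cd <- runif(1, 0.01, 1)
    expect_equal(d_overall(d6, cd),
                 exp((sum(log(d6)) + (2 / 3) * log(cd)) / (6 + 2 / 3)),
                 tolerance = 1e-12)
  }
})

test_that("group scores are plain geometric means", {
  expect_equal(group_score(0.42), 0.42)
  expect_equal(group_score(c(0.04, 0.25)), 0.1)
  expect_equal(group_score(c(1, 1)), 1)
  expect_error(group_score(numeric(0)), "empty")
})

test_that("ranking is a deterministic permutation with stated tie-breaks", {
  tab <- data.frame(gene = c("B", "A", "C", "D"),
                    D_overall = c(0.5, 0.5, 0.9, 0.1),
                    p_combined_sum = c(0.2, 0.4, 0.1, 0.3),
                    stringsAsFactors = FALSE)
  r1 <- rank_genes(tab)
  expect_equal(r1$gene, c("C", "B", "A", "D"))  # tie broken by lower p sum
  expect_equal(r1$rank, 1:4)
  expect_identical(r1, rank_genes(tab[sample(4), ]))
  tie <- data.frame(gene = c("Z", "Y"), D_overall = c(0.5, 0.5),
                    p_combined_sum = c(0.1, 0.1), stringsAsFactors = FALSE)
  expect_equal(rank_genes(tie)$gene, c("Y", "Z"))  # lexicographic fallback
})

test_that("flipping one dataset's fold-change sign never increases D_overall", {
  set.seed(5)
  params <- desirability_params()
  for (i in 1:200) {
    lfc <- runif(6, 0.2, 3) * sample(c(-1, 1), 6, replace = TRUE)
    d6 <- runif(6, 0.01, 1)
    base <- d_overall(d6, concordance_factor(lfc, params)$desirability, params)
    j <- sample(6, 1)
    flipped <- lfc
    flipped[j] <- -flipped[j]
    alt <- d_overall(d6, concordance_factor(flipped, params)$desirability,
                     params)
    # the flip moves the direction split by one dataset either way
    if (abs(sum(sign(flipped))) <= abs(sum(sign(lfc))))
      expect_lte(alt, base + 1e-12)
  }
})

test_that("score_genes integrates DE tables into a ranked universe", {
  tc <- toy_cohort(seed = 29)
  qc <- lapply(tc$cohort$datasets, apply_qc, thresholds = tc$thresholds)
  de_list <- lapply(qc, function(x) run_de(x$dataset))
  names(de_list) <- vapply(tc$cohort$datasets, `[[`, "", "name")
  scores <- score_genes(de_list, tc$cohort$ground_truth$midbrain_detected)
  expressed_any <- unique(unlist(lapply(de_list, function(d) d$gene[d$expressed])))
  expect_setequal(scores$gene, expressed_any)
  expect_equal(sort(scores$rank), seq_len(nrow(scores)))
  expect_true(all(scores$D_overall > 0 & scores$D_overall <= 1))
  d_cols <- grep("^D_", names(scores), value = TRUE)
  d_cols <- setdiff(d_cols, "D_overall")
  for (col in d_cols)
    expect_true(all(scores[[col]] >= 0.01 & scores[[col]] <= 1))
  # a gene unexpressed everywhere would sit at the 0.01 floor; check via direct call
  floor_score <- d_overall(rep(0.01, 6), 0.01)
  expect_equal(floor_score, 0.01, tolerance = 1e-12)
})
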