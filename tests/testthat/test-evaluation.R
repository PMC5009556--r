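test_that("c-index matches brute-force pair enumeration", {
  expect_equal(c_index(1:5, 1:5), 1.0)
  expect_equal(c_index(1:5, 5:1), 0.0)
  expect_equal(c_index(c(1, 2, 3), c(1, 3, 2)), 2 / 3)
  expect_error(c_index(1:3, 1:4), "length")
  set.seed(11)
  for (i in 1:30) {
    n <- sample(3:12, 1)
    u <- sample(n); v <- sample(n)
    expect_equal(c_index(u, v), brute_c_index(u, v))
  }
  # ties contribute 0.5
  expect_equal(c_index(c(1, 1, 2), c(1, 2, 3)),
               brute_c_index(c(1, 1, 2), c(1, 2, 3)))
})

test_that("SNR classification follows the sign and magnitude rule", {
  expect_equal(snr_classify(4, 1), "synergistic")
  expect_equal(snr_classify(-4, 1), "antagonistic")
  expect_equal(snr_classify(1, 1), "additive")
  expect_equal(snr_classify(c(4, -4, 1, -1), c(1, 1, 1, 1)),
               c("synergistic", "antagonistic", "additive", "additive"))
  expect_error(snr_classify(1, 0))
})

test_that("gold standards derive ranks and classes from EOB", {
  f <- write_tmp(c("drug_a\tdrug_b\teob_mean\teob_sem",
                   "a\tb\t5\t1",
                   "a\tc\t-3\t1",
                   "b\tc\t0.5\t1"))
  gold <- read_gold_standard(f)
  expect_equal(gold$gold_rank, c(1L, 3L, 2L))
  expect_equal(gold$class, c("synergistic", "antagonistic", "additive"))
  # duplicated pairs are rejected
  bad <- write_tmp(c("drug_a\tdrug_b\teob_mean\teob_sem",
                     "a\tb\t5\t1", "b\ta\t4\t1"))
  expect_error(read_gold_standard(bad), "duplicated")
})

test_that("PC-index obeys its limits and symmetries", {
  # near-zero sems and well-separated EOBs: concordant ranking scores ~1
  g2 <- gold_standard(data.frame(drug_a = c("a", "a"), drug_b = c("b", "c"),
                                 eob_mean = c(10, 0), eob_sem = 0.01))
  expect_equal(pc_index(g2, c(1, 2)), 1.0, tolerance = 1e-9)
  expect_equal(pc_index(g2, c(2, 1)), 0.0, tolerance = 1e-9)

  set.seed(31)
  n <- 10
  gold <- gold_standard(data.frame(
    drug_a = sprintf("a%02d", 1:n), drug_b = sprintf("b%02d", 1:n),
    eob_mean = rnorm(n, 0, 3), eob_sem = runif(n, 0.3, 2)))
  for (i in 1:20) {
    v <- sample(n)
    # reversal identity
    expect_equal(pc_index(gold, v) + pc_index(gold, (n + 1) - v), 1,
                 tolerance = 1e-12)
  }
  # erf step-function limit: tiny sems recover the hard c-index on the
  # EOB ordering
  gold_tiny <- gold
  gap <- min(diff(sort(gold$eob_mean)))
  gold_tiny$eob_sem <- rep(1e-9 * gap, n)
  u <- gold$gold_rank
  for (i in 1:10) {
    v <- sample(n)
    expect_lt(abs(pc_index(gold_tiny, v) - c_index(u, v)), 1e-9)
  }
})

test_that("a random ranking has expected PC-index 0.5", {
  set.seed(77)
  n <- 8
  gold <- gold_standard(data.frame(
    drug_a = sprintf("a%d", 1:n), drug_b = sprintf("b%d", 1:n),
    eob_mean = rnorm(n, 0, 2), eob_sem = runif(n, 0.5, 1.5)))
  B <- 1200
  pcs <- vapply(1:B, function(i) pc_index(gold, sample(n)), numeric(1))
  se <- sd(pcs) / sqrt(B)
  expect_lt(abs(mean(pcs) - 0.5), 3 * se)
})

test_that("the erf weighting agrees with an independent erf implementation", {
  skip_if_not_installed("pracma")
  # two-pair gold standard has the closed form
  # t' = 1/2 + 1/2 erf((EOB_1 - EOB_2)/sqrt(sem_1^2 + sem_2^2))
  set.seed(61)
  for (i in 1:20) {
    eob <- rnorm(2, 0, 3); sem <- runif(2, 0.1, 2)
    gold <- gold_standard(data.frame(drug_a = c("a", "a"),
                                     drug_b = c("b", "c"),
                                     eob_mean = eob, eob_sem = sem))
    manual <- 0.5 + 0.5 * pracma::erf((eob[1] - eob[2]) /
                                        sqrt(sum(sem^2)))
    expect_equal(pc_index(gold, c(1, 2)), manual, tolerance = 1e-12)
  }
})

test_that("PC extremes bound the index and normalization maps to [0,1]", {
  set.seed(13)
  n <- 9
  gold <- gold_standard(data.frame(
    drug_a = sprintf("a%d", 1:n), drug_b = sprintf("b%d", 1:n),
    eob_mean = rnorm(n, 0, 3), eob_sem = runif(n, 0.2, 1)))
  ext <- pc_extremes(gold)
  expect_lt(ext["pc_min"], ext["pc_max"])
  for (i in 1:10) {
    pc <- pc_index(gold, sample(n))
    expect_gte(pc, ext["pc_min"] - 1e-12)
    expect_lte(pc, ext["pc_max"] + 1e-12)
  }
  expect_equal(normalize_pc(ext["pc_max"], ext["pc_max"], ext["pc_min"]),
               c(pc_max = 1))
  # negligible sems drive the extremes to the hard limits
  gold0 <- gold; gold0$eob_sem <- rep(1e-12, n)
  ext0 <- pc_extremes(gold0)
  expect_equal(unname(ext0), c(1, 0), tolerance = 1e-9)
  # two-pair gold standard: max and min are mirror images
  g2 <- gold_standard(data.frame(drug_a = c("a", "a"), drug_b = c("b", "c"),
                                 eob_mean = c(3, 1), eob_sem = c(1, 1)))
  e2 <- pc_extremes(g2)
  expect_equal(unname(e2["pc_max"]), 1 - unname(e2["pc_min"]))
  expect_error(normalize_pc(0.5, 0.3, 0.3), "degenerate")
})

test_that("the published evaluation constants reproduce", {
  # normalized PC from the reported index and the gold-standard extremes
  expect_equal(normalize_pc(0.663, 0.90, 0.10), 0.70375)
  # 14 drugs give 91 unordered pairs
  expect_equal(choose(14, 2), 91)
  # random-ranking precision for 16 positives of 91 at k = 16
  expect_equal(round(100 * 16 / 91, 1), 17.6)
})

test_that("ROC staircases and AUC match hand enumeration", {
  labels <- c("synergistic", "additive", "synergistic", "additive")
  # perfect separation
  expect_equal(roc_curve(labels, c(1, 3, 2, 4), "synergy")$auc, 1.0)
  # inverted ranking
  expect_equal(roc_curve(labels, c(4, 2, 3, 1), "synergy")$auc, 0.0)
  # interleaved (+,-,+,-) enumerates to 0.75
  expect_equal(roc_curve(labels, c(1, 2, 3, 4), "synergy")$auc, 0.75)
  expect_error(roc_curve(rep("synergistic", 3), 1:3, "synergy"), "positive")

  # antagonism sweeps from the other end of the ranking
  lab2 <- c("antagonistic", "additive", "antagonistic")
  expect_equal(roc_curve(lab2, c(3, 2, 1), "antagonism")$auc,
               roc_curve(c("synergistic", "additive", "synergistic"),
                         c(1, 2, 3), "synergy")$auc)
})

test_that("ROC agrees with an independent implementation on tie-free data", {
  skip_if_not_installed("pROC")
  set.seed(3)
  n <- 40
  lab <- sample(c("synergistic", "additive"), n, replace = TRUE,
                prob = c(0.3, 0.7))
  v <- sample(n)
  ours <- roc_curve(lab, v, "synergy")$auc
  ref <- pROC::auc(pROC::roc(response = lab == "synergistic",
                             predictor = -v, quiet = TRUE,
                             direction = "<"))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("precision at k counts positives among the top calls", {
  labels <- c("synergistic", "synergistic", "additive", "additive")
  expect_equal(precision_at_k(labels, c(1, 2, 3, 4), 2, "synergy"), 1.0)
  expect_equal(precision_at_k(labels, c(1, 2, 3, 4), 4, "synergy"), 0.5)
  expect_equal(precision_at_k(labels, c(4, 3, 2, 1), 2, "synergy"), 0.0)
  # k = n returns the prevalence of the positive class
  lab <- c(rep("antagonistic", 3), rep("additive", 5))
  expect_equal(precision_at_k(lab, sample(8), 8, "antagonism"), 3 / 8)
})

test_that("evaluate() assembles a consistent report", {
  set.seed(41)
  n <- 6
  drugs <- letters[1:4]
  pairs <- t(combn(drugs, 2))
  gold <- gold_standard(data.frame(
    drug_a = pairs[, 1], drug_b = pairs[, 2],
    eob_mean = c(5, 4, -3, 0.5, 2.5, -4), eob_sem = 1))
  tab <- data.frame(drug_a = pairs[, 1], drug_b = pairs[, 2],
                    co_gene_gs = c(0.5, 0.4, 0.1, 0.2, 0.3, 0.05))
  class(tab) <- c("pair_score_table", "data.frame")
  rep <- evaluate(tab, gold, B = 500, seed = 8)
  expect_s3_class(rep, "synergy_eval")
  expect_equal(rep$n_pairs, 6L)
  expect_gte(rep$pc_index, rep$pc_min)
  expect_lte(rep$pc_index, rep$pc_max)
  expect_equal(rep$pc_index_norm,
               (rep$pc_index - rep$pc_min) / (rep$pc_max - rep$pc_min))
  expect_equal(as.integer(rep$class_counts),
               c(3L, 2L, 1L))  # synergistic, antagonistic, additive
  # a perfectly concordant prediction scores c-index 1
  tab2 <- tab
  tab2$co_gene_gs <- max(gold$eob_mean) + 1 - gold$gold_rank
  class(tab2) <- c("pair_score_table", "data.frame")
  rep2 <- evaluate(tab2, gold, B = 200, seed = 8)
  expect_equal(rep2$c_index, 1.0)
  # mismatched pair keys are a hard error listing the pair
  gold_bad <- gold; gold_bad$drug_b[1] <- "z"
  gold_bad <- gold_standard(as.data.frame(gold_bad)[
    , c("drug_a", "drug_b", "eob_mean", "eob_sem")])
  expect_error(evaluate(tab, gold_bad, B = 10, seed = 1), "a z")
})
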