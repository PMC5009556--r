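test_that("pairwise scores match their defining ratios", {
  a <- toy_signature("A", sig_genes = as.character(1:4),
                     enr_sets = c("S1", "S2", "S3"))
  b <- toy_signature("B", sig_genes = as.character(3:6),
                     enr_sets = c("S2", "S3", "S4"))
  expect_equal(co_gene_score(a, b, G = 10), 0.2)   # |{3,4}|/10
  expect_equal(co_gs_score(a, b, L = 100), 0.02)   # 2 shared of 100
  # disjoint significant genes
  c_ <- toy_signature("C", sig_genes = as.character(7:9), enr_sets = "S9")
  expect_equal(co_gene_score(a, c_, 10), 0)
  expect_equal(co_gs_score(a, c_, 100), 0)
  # self-overlap
  a7 <- toy_signature("A", as.character(1:7), c("S1"))
  expect_equal(co_gene_score(a7, a7, 10), 0.7)
})

test_that("co-gene/GS averages co-significant fractions over co-enriched sets", {
  # two co-enriched sets of sizes 4 and 5 with 2 and 1 co-significant
  # genes: (2/4 + 1/5)/2 = 0.35
  coll <- geneset_collection(
    list(S1 = c("g1", "g2", "g3", "g4"),
         S2 = c("g5", "g6", "g7", "g8", "g9"),
         S3 = c("g10", "g11")),
    universe = sprintf("g%d", 1:12))
  a <- toy_signature("A", c("g1", "g2", "g5", "g10"), c("S1", "S2"))
  b <- toy_signature("B", c("g1", "g2", "g5", "g11"), c("S1", "S2", "S3"))
  expect_equal(co_gene_gs_score(a, b, coll), 0.35)
  # no co-enriched sets -> defined as 0
  d <- toy_signature("D", c("g1", "g2"), "S3")
  expect_equal(co_gene_gs_score(a, d, coll), 0)
  # upper bound: identical signatures with every member significant
  full <- toy_signature("F", sprintf("g%d", 1:12), c("S1", "S2", "S3"))
  expect_equal(co_gene_gs_score(full, full, coll), 1.0)
})

test_that("scores are symmetric, bounded, and co_gene_gs vanishes with co_gs", {
  set.seed(17)
  genes <- sprintf("g%02d", 1:30)
  sets <- lapply(1:8, function(i) sample(genes, sample(3:10, 1)))
  names(sets) <- sprintf("S%d", 1:8)
  coll <- geneset_collection(sets, universe = genes)
  for (i in 1:20) {
    a <- toy_signature("A", sample(genes, sample(0:15, 1)),
                       sample(names(sets), sample(0:4, 1)))
    b <- toy_signature("B", sample(genes, sample(0:15, 1)),
                       sample(names(sets), sample(0:4, 1)))
    for (f in list(function(x, y) co_gene_score(x, y, 30),
                   function(x, y) co_gs_score(x, y, 8),
                   function(x, y) co_gene_gs_score(x, y, coll))) {
      expect_equal(f(a, b), f(b, a))
      expect_gte(f(a, b), 0); expect_lte(f(a, b), 1)
    }
    if (co_gs_score(a, b, 8) == 0)
      expect_equal(co_gene_gs_score(a, b, coll), 0)
  }
})

test_that("adding a set enriched in neither drug changes co_gs only", {
  coll <- geneset_collection(list(S1 = c("g1", "g2")),
                             universe = c("g1", "g2", "g3"))
  a <- toy_signature("A", c("g1"), "S1")
  b <- toy_signature("B", c("g1"), "S1")
  before_gs <- co_gs_score(a, b, L = 1)
  before_gg <- co_gene_gs_score(a, b, coll)
  coll2 <- geneset_collection(list(S1 = c("g1", "g2"), S2 = "g3"),
                              universe = c("g1", "g2", "g3"))
  expect_equal(co_gs_score(a, b, L = 2), before_gs / 2)
  expect_equal(co_gene_gs_score(a, b, coll2), before_gg)
})

test_that("concentration collapse takes the most synergistic instance", {
  expect_equal(collapse_concentrations(c(0.1, 0.4, 0.2)), 0.4)
  expect_equal(collapse_concentrations(0.3), 0.3)
  expect_equal(collapse_concentrations(c(0.2, 0.2), "mean"), 0.2)
  expect_equal(collapse_concentrations(c(0.2, 0.2), "max"), 0.2)
})

test_that("pair ranking is dense, deterministic, and monotone", {
  tab <- data.frame(drug_a = c("a", "a", "b"), drug_b = c("b", "c", "c"),
                    s = c(0.084, 0.036, 0.032))
  expect_equal(rank_pairs(tab, "s"), c(1L, 2L, 3L))
  # all-equal scores fall back to name order
  tab$s <- 0.5
  expect_equal(rank_pairs(tab, "s"), c(1L, 2L, 3L))
  # reversing score signs reverses the (untied) ranking
  tab$s <- c(3, 1, 2)
  r1 <- rank_pairs(tab, "s")
  tab$s <- -tab$s
  expect_equal(rank_pairs(tab, "s"), 4L - r1)
  expect_error(rank_pairs(tab, "nope"), "no such score")
})

test_that("pair table scores agree with a naive set-enumeration oracle", {
  set.seed(23)
  genes <- sprintf("g%02d", 1:40)
  sets <- lapply(1:12, function(i) sample(genes, sample(4:12, 1)))
  names(sets) <- sprintf("S%02d", 1:12)
  coll <- geneset_collection(sets, universe = genes)
  drugs <- c("d1", "d2", "d3", "d4", "d5")
  sigs <- lapply(drugs, function(d)
    toy_signature(d, sample(genes, sample(5:20, 1)),
                  sample(names(sets), sample(0:6, 1))))
  tab <- pair_scores(sigs, coll)
  expect_equal(nrow(tab), choose(5, 2))
  expect_true(all(sort(tab$rank_co_gene_gs) == 1:10))

  by_drug <- setNames(sigs, drugs)
  for (k in seq_len(nrow(tab))) {
    a <- by_drug[[tab$drug_a[k]]]; b <- by_drug[[tab$drug_b[k]]]
    # naive recomputation straight from the definitions
    g <- sum(a$significant_genes %in% b$significant_genes)
    n <- sum(a$enriched_sets %in% b$enriched_sets)
    co <- intersect(a$enriched_sets, b$enriched_sets)
    gg <- if (n == 0) 0 else {
      tot <- 0
      for (s in co) {
        m <- sets[[s]]
        tot <- tot + sum(m %in% a$significant_genes &
                         m %in% b$significant_genes) / length(m)
      }
      tot / n
    }
    expect_equal(tab$co_gene[k], g / 40)
    expect_equal(tab$co_gs[k], n / 12)
    expect_equal(tab$co_gene_gs[k], gg)
  }
})

test_that("multi-concentration drugs collapse to the max instance pair", {
  coll <- geneset_collection(list(S1 = c("g1", "g2"), S2 = c("g3", "g4")),
                             universe = sprintf("g%d", 1:4))
  sigs <- list(
    toy_signature("A", c("g1", "g2"), c("S1"), concentration = "c1"),
    toy_signature("A", character(0), character(0), concentration = "c2"),
    toy_signature("B", c("g1"), c("S1"), concentration = "c1"),
    toy_signature("B", c("g1", "g2", "g3"), c("S1", "S2"),
                  concentration = "c2"))
  tab <- pair_scores(sigs, coll)
  # max over the 4 instance pairs: A.c1 x B.c2 shares S1 with g1,g2
  # co-significant -> co_gene_gs = 1.0
  expect_equal(tab$co_gene_gs, 1.0)
  expect_equal(tab$co_gene, 2 / 4)
  co <- attr(tab, "co_enriched")
  expect_equal(co[["A|B"]], "S1")
})
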