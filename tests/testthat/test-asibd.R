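test_that("IBD block merging respects the 0.6-cM gap rule and the genotype veto", {
  map <- toy_map(100)
  segs <- rbind(toy_segment(1, 5), toy_segment(5.4, 8))   # gap 0.4 cM
  m <- merge_ibd_blocks(segs, map, 0.6)
  expect_equal(nrow(m), 1)
  expect_equal(m$length_cm, 7, tolerance = 1e-6)

  segs2 <- rbind(toy_segment(1, 5), toy_segment(5.7, 8))  # gap 0.7 cM
  expect_equal(nrow(merge_ibd_blocks(segs2, map, 0.6)), 2)

  # three blocks with consecutive 0.5-cM gaps collapse left-to-right
  segs3 <- rbind(toy_segment(1, 3), toy_segment(3.5, 6), toy_segment(6.5, 9))
  m3 <- merge_ibd_blocks(segs3, map, 0.6)
  expect_equal(nrow(m3), 1)
  expect_equal(c(m3$start, m3$end), c(1e6, 9e6))

  # genotype veto: two discordant genotypes in the gap block the merge
  pos <- c(2e6, 5.1e6, 5.2e6, 7e6)
  alleles <- rbind(c(0L, 0L, 0L, 1L), c(0L, 0L, 0L, 1L),
                   c(0L, 1L, 1L, 1L), c(0L, 0L, 0L, 1L))
  panel <- make_panel(alleles, c("X", "Y"), pos = pos)  # s1=x-like, s2=y-like
  segs4 <- rbind(toy_segment(1, 5, "s1", 1, "s2", 1),
                 toy_segment(5.4, 8, "s1", 1, "s2", 1))
  expect_equal(nrow(merge_ibd_blocks(segs4, map, 0.6, panel)), 2)
  # with one discordance the merge goes through
  panel$alleles[3, 3] <- 0L
  expect_equal(nrow(merge_ibd_blocks(segs4, map, 0.6, panel)), 1)
})

test_that("length classes are half-open with sub-1-cM blocks dropped", {
  segs <- rbind(toy_segment(1, 5.99), toy_segment(10, 15), toy_segment(20, 20.8))
  segs$length_cm <- c(4.99, 5.0, 0.8)
  b <- bin_by_length(segs)
  expect_equal(as.character(b$segments$class), c("[1,5)", "[5,10)"))
  expect_equal(b$dropped, 1)
  segs$length_cm <- c(1, 10, 25)
  b2 <- bin_by_length(segs)
  expect_equal(as.character(b2$segments$class), c("[1,5)", ">=10", ">=10"))
})

test_that("ancestry decomposition splits a block into consistent, inconsistent and undefined mass", {
  # 10-cM block; hap A: S on [0,8), B on [8,10); hap B: S on [0,7), B on [7,10)
  fx <- toy_la2(breaks_a_cm = 8, calls_a = c(1, 2),
                breaks_b_cm = 7, calls_b = c(1, 2), len_cm = 10)
  seg <- toy_segment(0, 10)
  d <- decompose_ibd_ancestry(seg, fx$la, fx$map)
  expect_equal(d$anc_S, 7, tolerance = 1e-4)
  expect_equal(d$anc_B, 2, tolerance = 1e-4)
  expect_equal(d$inconsistent_cm, 1, tolerance = 1e-4)
  expect_equal(d$undefined_cm, 0)
  expect_false(d$excluded)   # 10% <= 25%

  # identical single-ancestry haplotypes: full length, kept
  fx2 <- toy_la2(numeric(0), 1, numeric(0), 1, len_cm = 10)
  d2 <- decompose_ibd_ancestry(toy_segment(2, 9), fx2$la, fx2$map)
  expect_equal(d2$anc_S, 7, tolerance = 1e-4)
  expect_equal(d2$inconsistent_cm, 0)

  # entirely different ancestries: 100% inconsistent, excluded
  fx3 <- toy_la2(numeric(0), 1, numeric(0), 2, len_cm = 10)
  d3 <- decompose_ibd_ancestry(toy_segment(0, 10), fx3$la, fx3$map)
  expect_equal(d3$inconsistent_cm, 10, tolerance = 1e-4)
  expect_true(d3$excluded)

  # exactly 25% inconsistent is kept: the rule is strictly greater
  fx4 <- toy_la2(2.5, c(2, 1), numeric(0), 1, len_cm = 10)
  d4 <- decompose_ibd_ancestry(toy_segment(0, 10), fx4$la, fx4$map)
  expect_equal(d4$inconsistent_cm / d4$length_cm_map, 0.25, tolerance = 1e-6)
  expect_false(d4$excluded)

  expect_error(decompose_ibd_ancestry(toy_segment(0, 10, chrom = "chrZ"),
                                      fx$la, fx$map), "coverage")
})

test_that("decomposition matches the per-grid brute force with conservation", {
  for (s in 1:60) {
    inst <- random_decompose_instance(s)
    d <- decompose_ibd_ancestry(inst$seg, inst$la, inst$map)
    o <- grid_decompose_oracle(inst$seg, inst$la, inst$map)
    expect_equal(unname(unlist(d[paste0("anc_", c("S", "B", "G"))])),
                 unname(o$anc_cm), tolerance = 0.05)
    expect_equal(d$inconsistent_cm, o$inconsistent_cm, tolerance = 0.05)
    expect_equal(d$undefined_cm, o$undefined_cm, tolerance = 0.05)
    total <- sum(d[paste0("anc_", c("S", "B", "G"))]) + d$inconsistent_cm +
      d$undefined_cm
    expect_equal(total, d$length_cm_map, tolerance = 1e-6)
  }
})

test_that("aggregation averages per haploid pair and reports zero-sharing pairs", {
  fx <- toy_la2(8, c(1, 2), 7, c(1, 2), len_cm = 10,
                haps = c("x|1", "y|1"))
  md <- data.frame(sample = c("x", "y"), population = c("X", "Y"),
                   pool = c("X", "Y"))
  class(md) <- c("population_metadata", "data.frame")
  d <- decompose_ibd_ancestry(toy_segment(0, 10), fx$la, fx$map)
  agg <- aggregate_asibd(d, md)
  xy <- agg[agg$pop1 == "X" & agg$pop2 == "Y" & agg$class == ">=10", ]
  # 1 diploid each -> 2x2 = 4 haploid pairs; sums divided by 4
  expect_equal(xy$n_pairs, 4)
  expect_equal(xy$anc_S, 7 / 4, tolerance = 1e-4)
  expect_equal(xy$anc_B, 2 / 4, tolerance = 1e-4)
  # within-population rows exist with zero sharing
  xx <- agg[agg$pop1 == "X" & agg$pop2 == "X", ]
  expect_equal(nrow(xx), 3)
  expect_true(all(xx$anc_S == 0))
  # two segments sharing 4 and 8 cM of one ancestry average to 6 over the pair
  fx5 <- toy_la2(numeric(0), 1, numeric(0), 1, len_cm = 100)
  segs <- rbind(toy_segment(0, 4), toy_segment(20, 28))
  d5 <- decompose_ibd_ancestry(segs, fx5$la, fx5$map)
  agg5 <- aggregate_asibd(d5, md)
  xy5 <- agg5[agg5$pop1 == "X" & agg5$pop2 == "Y", ]
  expect_equal(sum(xy5$anc_S) * 4 / 2, 6, tolerance = 1e-3)
  # excluded blocks contribute to the excluded mass only
  fx6 <- toy_la2(numeric(0), 1, numeric(0), 2, len_cm = 10)
  d6 <- decompose_ibd_ancestry(toy_segment(0, 10), fx6$la, fx6$map)
  agg6 <- aggregate_asibd(d6, md)
  r6 <- agg6[agg6$pop1 == "X" & agg6$pop2 == "Y" & agg6$class == ">=10", ]
  expect_equal(r6$excluded_cm, 10 / 4, tolerance = 1e-4)
  expect_equal(r6$anc_S + r6$anc_B, 0)
})

test_that("pooled sharing forms a probability vector over pools", {
  fx <- toy_la2(numeric(0), 1, numeric(0), 1, len_cm = 100,
                haps = c("x|1", "y|1"))
  md <- data.frame(sample = c("x", "y", "z"),
                   population = c("X", "Y", "Z"),
                   pool = c("X", "PoolY", "PoolZ"))
  class(md) <- c("population_metadata", "data.frame")
  d <- decompose_ibd_ancestry(toy_segment(0, 10), fx$la, fx$map)
  agg <- aggregate_asibd(d, md)
  ps <- pool_sharing(agg, md, "X", "S")
  expect_equal(unname(ps$proportions["PoolY"]), 1)   # only sharing is with Y
  expect_equal(sum(ps$proportions), 1)
  # equal sharing with two pools -> 0.5 / 0.5
  segs <- rbind(toy_segment(0, 10, "x", 1, "y", 1),
                toy_segment(20, 30, "x", 1, "z", 1))
  fx2 <- toy_la2(numeric(0), 1, numeric(0), 1, len_cm = 100,
                 haps = c("x|1", "y|1"))
  la2 <- fx2$la
  la2$calls <- cbind(la2$calls, la2$calls[, 1])
  la2$posteriors <- cbind(la2$posteriors, la2$posteriors[, 1])
  la2$haplotypes <- c(la2$haplotypes, "z|1")
  colnames(la2$calls) <- la2$haplotypes
  d2 <- decompose_ibd_ancestry(segs, la2, fx2$map)
  agg2 <- aggregate_asibd(d2, md)
  ps2 <- pool_sharing(agg2, md, "X", "S")
  expect_equal(unname(ps2$proportions[c("PoolY", "PoolZ")]), c(0.5, 0.5),
               tolerance = 1e-6)
  expect_error(pool_sharing(agg2, list(A = character(0)), "X", "S"), "empty")
})

test_that("UPGMA trees match textbook arithmetic and a brute-force oracle", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_tree(d)
  # ((A:1,B:1):1,C:2)
  cf <- ape::cophenetic.phylo(tr)
  expect_equal(cf["A", "B"], 2)
  expect_equal(cf["A", "C"], 4)
  expect_true(ape::is.ultrametric(tr))

  # identical profile rows join first at height 0
  prof <- rbind(A = c(0.5, 0.5), B = c(0.5, 0.5), C = c(0, 1))
  tr2 <- upgma_tree(prof, profiles = TRUE)
  cf2 <- ape::cophenetic.phylo(tr2)
  expect_equal(cf2["A", "B"], 0)

  # 6-leaf random instances equal the quadratic-time oracle
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(runif(36), 6)
    dm <- as.matrix(dist(x))
    tr3 <- upgma_tree(dm)
    expect_equal(ape::cophenetic.phylo(tr3)[rownames(dm), rownames(dm)],
                 brute_agglomerate(dm, "average"), tolerance = 1e-10)
  }
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(upgma_tree(bad), "symmetric")
})

test_that("group IBD summaries separate groups and feed the rank-sum test", {
  # eight 2-person groups; group mean totals fully separated between the
  # first and last four groups
  md <- data.frame(sample = paste0("s", 1:16),
                   population = rep(paste0("g", 1:8), each = 2))
  md$pool <- md$population
  class(md) <- c("population_metadata", "data.frame")
  segs <- do.call(rbind, lapply(1:8, function(g) {
    s <- paste0("s", 2 * g - 1)
    t <- paste0("s", 2 * g)
    len <- if (g <= 4) 12 + g else 30 + g
    toy_segment(1, 1 + len, s, 1, t, 1)
  }))
  map <- toy_map(100)
  gs <- group_ibd_summaries(segs, md, bins = c(1, 5, 10))
  expect_equal(unname(gs$group_means[, ">=10"]),
               c(13:16, 35:38) + 0, tolerance = 1e-4)
  ht <- ibd_ranksum(gs, paste0("g", 1:4), paste0("g", 5:8), ">=10")
  expect_equal(unname(ht$statistic), 0)   # complete separation
  expect_lt(ht$p.value, 0.05)

  # HBD: a single 3-cM block within one individual counts for its group
  md2 <- data.frame(sample = c("a", "b"), population = c("G", "G"),
                    pool = c("G", "G"))
  class(md2) <- c("population_metadata", "data.frame")
  seg2 <- toy_segment(1, 4, "a", 1, "a", 2)
  gs2 <- group_ibd_summaries(seg2, md2)
  expect_equal(gs2$pair_totals$total_cm, 3, tolerance = 1e-4)
  expect_equal(as.character(gs2$pair_totals$class), "[1,5)")
})

test_that("identical group distributions give a non-significant rank-sum test", {
  # null calibration: identical distributions of group means
  reject <- 0
  for (s in 1:100) {
    set.seed(s)
    a <- rnorm(6, 10, 2); b <- rnorm(6, 10, 2)
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE))
    if (ht$p.value <= 0.05) reject <- reject + 1
  }
  expect_lte(reject, 10)
})
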