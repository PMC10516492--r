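test_that("site filters enforce polymorphism, MAF and allele-count rules strictly", {
  # 12 haploid genomes per population (6 diploids), 5 hand-built sites
  a <- matrix(1L, 12, 5)
  a[, 1] <- rep(c(0L, 1L), 6)          # balanced polymorphic
  a[, 2] <- 0L                         # monomorphic in pop A
  a[, 3] <- c(1L, rep(0L, 11))         # MAF 1/12 < 0.10
  a[, 4] <- rep(c(0L, 1L), 6)
  a[1:2, 4] <- NA                      # only 10 alleles: not > 10
  a[, 5] <- rep(c(0L, 0L, 1L), 4)
  b <- a                               # pop B mirrors pop A
  panel <- make_panel(rbind(a, b), rep(c("A", "B"), each = 6))
  idx <- filter_sites(panel, c("A", "B"))
  expect_equal(idx, c(1L, 5L), ignore_attr = TRUE)
  att <- attr(idx, "attrition")
  expect_equal(unname(att["monomorphic"]), 1)
  expect_equal(unname(att["maf"]), 1)
  expect_equal(unname(att["allele_count"]), 1)
  # external mask applied by intersection
  idx2 <- filter_sites(panel, c("A", "B"), site_mask = c(1L, 3L))
  expect_equal(idx2, 1L, ignore_attr = TRUE)
  expect_error(filter_sites(panel, c("A", "B"), site_mask = 99L), "no sites")
})

test_that("site filter attrition equals a brute-force re-count on random panels", {
  for (s in 1:5) {
    set.seed(s)
    al <- matrix(rbinom(24 * 200, 1, runif(200, 0.02, 0.5)[rep(1:200,
      each = 24)]), 24, 200, byrow = FALSE)
    al[sample(length(al), 300)] <- NA
    panel <- make_panel(al, rep(c("A", "B"), each = 6))
    idx <- filter_sites(panel, c("A", "B"))
    expect_equal(as.integer(idx), brute_filter_sites(panel, c("A", "B")))
  }
})

test_that("downsampling converges to 10-12 nonmissing alleles per site", {
  # complete data, 6 diploids = 12 alleles: already in range, untouched
  p6 <- make_panel(matrix(0L, 12, 50), "A")
  d6 <- downsample_individuals(p6, "A", seed = 1)
  expect_equal(length(d6$haplotypes), 12)
  # complete data, 20 diploids: down to 5-6 diploids
  p20 <- make_panel(matrix(0L, 40, 50), "A")
  d20 <- downsample_individuals(p20, "A", seed = 2)
  expect_true((length(d20$haplotypes) / 2) %in% 5:6)
  # 50% missingness, 12 diploids (mean 12 alleles): no removal
  set.seed(3)
  al <- matrix(0L, 24, 400)
  al[sample(length(al), length(al) / 2)] <- NA
  p12 <- make_panel(al, "A")
  d12 <- downsample_individuals(p12, "A", seed = 4)
  expect_equal(length(d12$haplotypes), 24)
})

test_that("quartet pattern counting recognises AABB/ABBA/ABAB fixtures", {
  # every site fixed chimp 0, P1 0, P2 1, P3 1 -> pure AABB
  pan <- panel_from_patterns(rep("AABB", 200))
  cc <- count_quartet_patterns(pan, "P1", "P2", "P3", seed = 1, n_blocks = 10)
  expect_equal(cc$n_conc, 200)
  expect_equal(cc$n_abba + cc$n_abab, 0)
  # chimp 0, P1 1, P2 1, P3 0 -> pure ABBA
  pan2 <- panel_from_patterns(rep("ABBA", 100))
  cc2 <- count_quartet_patterns(pan2, "P1", "P2", "P3", seed = 1, n_blocks = 10)
  expect_equal(cc2$n_abba, 100)
  # simulated patterns are recovered exactly through the panel route
  q <- simulate_quartet_sites(0.5, 5000, seed = 7)
  pan3 <- panel_from_patterns(q$patterns)
  cc3 <- count_quartet_patterns(pan3, "P1", "P2", "P3", seed = 2)
  expect_equal(cc3$n_conc, unname(q$counts["AABB"]))
  expect_equal(cc3$n_abba, unname(q$counts["ABBA"]))
  expect_equal(cc3$n_abab, unname(q$counts["ABAB"]))
  # blocks hold equal informative-site counts (remainder to leading blocks)
  sz <- colSums(cc3$per_block)
  expect_true(all(sz %in% c(100, 101)))
  expect_equal(sum(sz), 5000)
})

test_that("C, jackknife SE and Z match closed-form hand computations", {
  # 60 concordant vs 40 discordant -> C = 0.2
  pat <- c(rep("AABB", 60), rep("ABBA", 40))
  cc <- quartet_counts_from_patterns(pat, n_blocks = 10)
  res <- concordance_test(cc)
  expect_equal(res$C, 0.2)
  # equal counts -> C = 0
  cc0 <- quartet_counts_from_patterns(c(rep("AABB", 50), rep("ABBA", 50)),
                                      n_blocks = 10)
  expect_equal(concordance_test(cc0)$C, 0)
  # perfectly balanced blocks -> identical pseudo-values -> SE 0
  blk <- rep(c(rep("AABB", 6), rep("ABBA", 4)), 10)
  ccb <- quartet_counts_from_patterns(blk, n_blocks = 10)
  resb <- suppressWarnings(concordance_test(ccb))
  expect_equal(resb$se_jack, 0)
  expect_true(all(resb$pseudo_values == resb$pseudo_values[1]))
  expect_true(is.infinite(resb$z))
  # hand-checked jackknife on unbalanced blocks
  pat2 <- c(rep("AABB", 30), rep("ABBA", 10), rep("AABB", 30), rep("ABBA", 30))
  cc2 <- quartet_counts_from_patterns(pat2, n_blocks = 2)
  res2 <- concordance_test(cc2)
  C_hand <- (60 - 40) / (60 + 40)
  # blocks are the first/last 50 sites: (40 AABB, 10 ABBA) and (20, 30)
  Ci <- c((20 - 30) / 50, (40 - 10) / 50)   # delete block 1, delete block 2
  se_hand <- sqrt((2 - 1) / 2 * sum((Ci - mean(Ci))^2))
  expect_equal(res2$C, C_hand)
  expect_equal(res2$se_jack, se_hand)
  expect_equal(res2$z, C_hand / se_hand)
})

test_that("jackknife SE tracks the binomial SE of C on balanced random blocks", {
  q <- simulate_quartet_sites(0.4, 50000, seed = 21)
  cc <- quartet_counts_from_patterns(q$patterns)
  res <- concordance_test(cc)
  # delta method: C = (c - d1)/(c + d1); with p = P(conc | conc or disc1),
  # C = 2p - 1 so SE(C) ~ 2 sqrt(p(1-p)/m)
  m <- res$counts$n_conc + max(res$counts$n_abba, res$counts$n_abab)
  p <- res$counts$n_conc / m
  se_binom <- 2 * sqrt(p * (1 - p) / m)
  expect_lt(abs(res$se_jack - se_binom) / se_binom, 0.2)
})

test_that("topology recovery: ghost outgroup gives Z > 3 and label swaps behave", {
  q <- simulate_quartet_sites(0.3, 20000, seed = 13)
  pan <- panel_from_patterns(q$patterns)
  res <- concordance_test(count_quartet_patterns(pan, "P1", "P2", "P3",
                                                 seed = 3))
  expect_gt(res$C, 0)
  expect_gt(res$z, 3)
  # swapping P2 and P3 leaves C unchanged (ABBA and ABAB trade places)
  res_swap <- concordance_test(count_quartet_patterns(pan, "P1", "P3", "P2",
                                                      seed = 3))
  expect_equal(res_swap$C, res$C, tolerance = 0.02)
  # moving P1 inside the pair flips the sign on strongly resolved data
  res_wrong <- concordance_test(count_quartet_patterns(pan, "P2", "P1", "P3",
                                                       seed = 3))
  expect_lt(res_wrong$C, 0)
})

test_that("the internode-time inversion and unit conversion are exact", {
  expect_equal(internode_time(1 / 3), 0)
  expect_equal(internode_time(0.2), 0)        # floored below the star point
  expect_equal(internode_time(2 / 3), log(2))
  # T = 1 at Ne = 20000 and 29-year generations -> 1.16 My under 2Ne units
  d <- divergence_from_counts(5967, 10000, ne_list = 20000)
  expect_equal(unname(d$years["20000"]),
               internode_time(0.5967) * 2 * 20000 * 29)
})

test_that("divergence estimation inverts simulated concordance fractions", {
  q <- simulate_quartet_sites(0.5, 100000, seed = 32)
  d <- divergence_from_counts(unname(q$counts["AABB"]), 100000)
  expect_gt(d$t_hat, 0.45); expect_lt(d$t_hat, 0.55)
  expect_true(d$ci[1] < 0.5 && d$ci[2] > 0.5)
  expect_error(divergence_from_counts(0, 0), "informative")
})

test_that("panel-level divergence sampling classifies informative sites correctly", {
  # ingroup fixed 1/1, outgroup fixed 0 -> every site concordant
  al <- rbind(matrix(1L, 4, 300), matrix(0L, 4, 300))
  pan <- make_panel(al, rep(c("IN", "OUT"), each = 2),
                    outgroup = rep(0L, 300))
  d <- estimate_divergence(pan, "IN", "OUT", seed = 5)
  expect_equal(d$p_conc, 1)
  expect_equal(d$n_informative, 300)
  # single het ingroup diploid -> i1 != i2 always, never concordant
  al2 <- rbind(rep(0L, 300), rep(1L, 300), matrix(0L, 2, 300))
  pan2 <- make_panel(al2, c("IN", "OUT"), outgroup = rep(0L, 300))
  d2 <- estimate_divergence(pan2, "IN", "OUT", seed = 5)
  expect_equal(d2$p_conc, 0)
  expect_equal(d2$t_hat, 0)
})
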