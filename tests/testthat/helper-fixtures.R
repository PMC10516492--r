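# Programmatic fixtures shared across test files.

# single linear chromosome, 1 cM per Mb
toy_map <- function(len_cm = 100, chrom = "chr1") {
  genetic_map(chrom = c(chrom, chrom), pos = c(1, len_cm * 1e6),
              cm = c(0, len_cm))
}

# local ancestry for two haplotypes from per-haplotype breakpoints given in
# cM on the toy map; calls are ancestry indices per tract, NA = undefined
toy_la2 <- function(breaks_a_cm, calls_a, breaks_b_cm, calls_b,
                    ancestries = c("S", "B"), len_cm = 100,
                    haps = c("x|1", "y|1")) {
  map <- toy_map(len_cm)
  mk <- function(breaks, calls) {
    edges <- c(0, breaks, len_cm) * 1e6
    data.frame(chrom = "chr1", start = pmax(edges[-length(edges)], 1),
               end = edges[-1], ancestry = calls)
  }
  tr <- list(mk(breaks_a_cm, calls_a), mk(breaks_b_cm, calls_b))
  names(tr) <- haps
  la <- tracts_to_local_ancestry(tr, ancestries, map)
  list(la = la, map = map)
}

toy_segment <- function(s_cm, e_cm, s1 = "x", h1 = 1, s2 = "y", h2 = 1,
                        chrom = "chr1") {
  seg <- data.frame(sample1 = s1, hap1 = h1, sample2 = s2, hap2 = h2,
                    chrom = chrom, start = s_cm * 1e6, end = e_cm * 1e6,
                    lod = 10, length_cm = e_cm - s_cm,
                    stringsAsFactors = FALSE)
  seg$start <- pmax(seg$start, 1)
  class(seg) <- c("ibd_segments", "data.frame")
  seg
}

# random decomposition instance on a single 100-cM chromosome: two
# haplotypes with random tract mosaics over 3 ancestries (with occasional
# undefined windows) and a random segment
random_decompose_instance <- function(seed, p_na = 0.1) {
  set.seed(seed)
  map <- toy_map(100)
  rand_tracts <- function() {
    nb <- sample(0:8, 1)
    breaks <- sort(round(runif(nb, 1, 99), 3))
    breaks <- unique(breaks)
    calls <- sample(1:3, length(breaks) + 1, replace = TRUE)
    edges <- c(0, breaks, 100) * 1e6
    data.frame(chrom = "chr1", start = pmax(edges[-length(edges)], 1),
               end = edges[-1], ancestry = calls)
  }
  tr <- list(`x|1` = rand_tracts(), `y|2` = rand_tracts())
  la <- tracts_to_local_ancestry(tr, c("S", "B", "G"), map)
  if (p_na > 0) {
    na_mask <- matrix(runif(length(la$calls)) < p_na, nrow(la$calls))
    la$calls[na_mask] <- NA_integer_
  }
  s <- runif(1, 0, 90)
  e <- s + runif(1, 0.5, 10)
  seg <- toy_segment(round(s, 4), round(e, 4), s2 = "y", h2 = 2)
  list(seg = seg, la = la, map = map)
}

# minimal phased panel built directly from an allele matrix
make_panel <- function(alleles, pops, chrom = "chr1", pos = NULL,
                       outgroup = NULL) {
  n_hap <- nrow(alleles); S <- ncol(alleles)
  stopifnot(n_hap %% 2 == 0)
  samples <- paste0("s", seq_len(n_hap / 2))
  haps <- as.vector(rbind(hap_id(samples, 1L), hap_id(samples, 2L)))
  if (is.null(pos)) pos <- seq_len(S) * 1000
  sites <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G")
  sites$outgroup <- if (is.null(outgroup)) NA_integer_ else outgroup
  haplotype_panel(alleles, sites, haps,
                  stats::setNames(rep(pops, length.out = length(samples)),
                                  samples))
}

# panel realising a vector of quartet site patterns: four populations of
# n_dip diploids each, every individual fixed for its population's pattern
# allele; chimp carries allele 0 everywhere
panel_from_patterns <- function(patterns, n_dip = 6) {
  S <- length(patterns)
  alle <- list(AABB = c(0, 1, 1), ABBA = c(1, 1, 0), ABAB = c(1, 0, 1))
  pa <- vapply(patterns, function(p) alle[[p]], numeric(3))
  block <- function(k) matrix(rep(pa[k, ], each = 2 * n_dip), 2 * n_dip, S)
  alleles <- rbind(block(1), block(2), block(3))
  make_panel(alleles, rep(c("P1", "P2", "P3"), each = n_dip),
             outgroup = rep(0L, S))
}

# small ghost cohort for end-to-end tests
small_ghost_cohort <- function(seed) {
  simulate_ghost_cohort(seed, n_sites = 6000, n_per_pop = 5, n_cross = 20)
}
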