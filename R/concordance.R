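## Quartet genealogical-concordance topology tests and divergence times.

panel_pop_rows <- function(panel, population) {
  which(hap_populations(panel) == population)
}

#' Subset a haplotype panel by sites and/or haploid genomes
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @param sites integer site indices to keep (default all).
#' @param haplotypes haploid genome ids or row indices to keep (default all).
#' @return a \code{\link{haplotype_panel}}.
#' @export
subset_panel <- function(panel, sites = NULL, haplotypes = NULL) {
  if (is.null(sites)) sites <- seq_len(ncol(panel$alleles))
  rows <- if (is.null(haplotypes)) seq_along(panel$haplotypes)
    else if (is.character(haplotypes)) match(haplotypes, panel$haplotypes)
    else haplotypes
  haplotype_panel(panel$alleles[rows, sites, drop = FALSE],
                  panel$sites[sites, , drop = FALSE],
                  panel$haplotypes[rows], panel$populations)
}

#' Filter sites for concordance analyses
#'
#' Retains sites that, within every listed population, are polymorphic,
#' have per-population minor allele frequency strictly above \code{maf_min},
#' and have strictly more than \code{min_alleles} nonmissing alleles. An
#' optional external site subset (e.g. an ascertainment mask) is applied by
#' intersection.
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @param populations populations the filters are evaluated in.
#' @param maf_min minor-allele-frequency threshold (default 0.10, strict).
#' @param min_alleles nonmissing-allele threshold (default 10, strict).
#' @param site_mask optional integer site indices to intersect with.
#' @return integer vector of retained site indices, with an
#'   \code{attrition} attribute counting sites failing each filter.
#' @export
filter_sites <- function(panel, populations, maf_min = 0.10,
                         min_alleles = 10, site_mask = NULL) {
  S <- ncol(panel$alleles)
  poly_ok <- maf_ok <- count_ok <- rep(TRUE, S)
  for (p in populations) {
    rows <- panel_pop_rows(panel, p)
    if (!length(rows)) stop("population '", p, "' not in panel")
    sub <- panel$alleles[rows, , drop = FALSE]
    nm <- colSums(!is.na(sub))
    alt <- colSums(sub, na.rm = TRUE)
    f <- ifelse(nm > 0, alt / nm, NA)
    poly_ok <- poly_ok & (alt > 0 & alt < nm)
    maf_ok <- maf_ok & !is.na(f) & pmin(f, 1 - f) > maf_min
    count_ok <- count_ok & nm > min_alleles
  }
  keep <- poly_ok & maf_ok & count_ok
  idx <- which(keep)
  attrition <- c(monomorphic = sum(!poly_ok),
                 maf = sum(poly_ok & !maf_ok),
                 allele_count = sum(poly_ok & maf_ok & !count_ok))
  if (!is.null(site_mask)) {
    pre <- length(idx)
    idx <- intersect(idx, site_mask)
    attrition <- c(attrition, mask = pre - length(idx))
  }
  if (!length(idx))
    stop("no sites survive the filters (attrition: ",
         paste(names(attrition), attrition, sep = "=", collapse = ", "), ")")
  attr(idx, "attrition") <- attrition
  idx
}

#' Downsample individuals to a target nonmissing-allele count
#'
#' Per population, diploid individuals are removed at random (seeded) until
#' the mean nonmissing allele count per site falls within [10, 12] or only
#' two individuals remain (then a warning is raised). Populations already in
#' range are untouched; populations starting below range get a warning.
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @param populations populations to downsample.
#' @param seed integer seed.
#' @param target_range allowed range of the mean per-site nonmissing allele
#'   count (default \code{c(10, 12)}).
#' @return the downsampled \code{\link{haplotype_panel}}.
#' @export
downsample_individuals <- function(panel, populations, seed,
                                   target_range = c(10, 12)) {
  set.seed(seed)
  drop_haps <- character(0)
  for (p in populations) {
    rows <- panel_pop_rows(panel, p)
    inds <- unique(panel$samples[rows])
    mean_count <- function(keep_inds) {
      r <- rows[panel$samples[rows] %in% keep_inds]
      mean(colSums(!is.na(panel$alleles[r, , drop = FALSE])))
    }
    m <- mean_count(inds)
    if (m < target_range[1]) {
      warning("population '", p, "' already below the target allele count (",
              round(m, 2), ")")
      next
    }
    while (m > target_range[2] && length(inds) > 2) {
      inds <- inds[-sample.int(length(inds), 1)]
      m <- mean_count(inds)
    }
    if (m > target_range[2])
      warning("population '", p, "' hit the 2-individual floor at mean ",
              round(m, 2), " alleles per site")
    gone <- setdiff(unique(panel$samples[rows]), inds)
    drop_haps <- c(drop_haps, hap_id(rep(gone, each = 2), c(1L, 2L)))
  }
  keep <- setdiff(panel$haplotypes, drop_haps)
  subset_panel(panel, haplotypes = keep)
}

# one random nonmissing allele per site from a (haps x sites) matrix;
# u is one uniform per site (a single seeded stream keeps the draw
# independent of iteration order)
sample_allele <- function(sub, u) {
  S <- ncol(sub)
  out <- rep(NA_integer_, S)
  for (s in seq_len(S)) {
    rows <- which(!is.na(sub[, s]))
    if (length(rows))
      out[s] <- sub[rows[ceiling(u[s] * length(rows))], s]
  }
  out
}

#' Count quartet site patterns for a (chimp, P1; P2, P3) test
#'
#' At each usable site (outgroup allele defined, at least one nonmissing
#' allele in each population) one allele is randomly sampled per
#' population. With the quartet ordered (chimp, P1, P2, P3), a 2-2 split
#' pairing P1 with the chimpanzee (AABB) is concordant with the topology
#' placing P1 external to (P2, P3); ABBA and ABAB splits are discordant;
#' uninformative (constant or 3-1) sites are skipped. Informative sites are
#' assigned, in genome order, to \code{n_blocks} contiguous blocks with
#' equal counts (remainder spread one-per-block over the leading blocks)
#' for the block jackknife.
#'
#' @param panel a \code{\link{haplotype_panel}} carrying per-site outgroup
#'   (chimpanzee) alleles in \code{sites$outgroup}.
#' @param p1,p2,p3 population labels; P1 is the putative external lineage.
#' @param seed integer seed for the per-site allele draws.
#' @param n_blocks jackknife block count (default 50).
#' @return object of class \code{concordance_counts}: list with
#'   \code{n_conc}, \code{n_abba}, \code{n_abab}, \code{per_block} (3 x
#'   n_blocks matrix), \code{n_informative}.
#' @export
count_quartet_patterns <- function(panel, p1, p2, p3, seed, n_blocks = 50) {
  chimp <- panel$sites$outgroup
  if (all(is.na(chimp))) stop("panel carries no outgroup (chimpanzee) alleles")
  set.seed(seed)
  S <- ncol(panel$alleles)
  draws <- matrix(stats::runif(3 * S), 3, S)
  a1 <- sample_allele(panel$alleles[panel_pop_rows(panel, p1), , drop = FALSE],
                      draws[1, ])
  a2 <- sample_allele(panel$alleles[panel_pop_rows(panel, p2), , drop = FALSE],
                      draws[2, ])
  a3 <- sample_allele(panel$alleles[panel_pop_rows(panel, p3), , drop = FALSE],
                      draws[3, ])
  usable <- !is.na(chimp) & !is.na(a1) & !is.na(a2) & !is.na(a3)
  conc <- usable & chimp == a1 & a2 == a3 & chimp != a2      # AABB
  abba <- usable & chimp == a3 & a1 == a2 & chimp != a1      # ABBA
  abab <- usable & chimp == a2 & a1 == a3 & chimp != a1      # ABAB
  pattern_counts(conc, abba, abab, n_blocks)
}

# assemble concordance_counts from per-site logical pattern vectors,
# blocking informative sites contiguously with equal counts
pattern_counts <- function(conc, abba, abab, n_blocks) {
  inf_idx <- which(conc | abba | abab)
  n_inf <- length(inf_idx)
  if (n_inf == 0) stop("no informative sites")
  per <- rep(n_inf %/% n_blocks, n_blocks)
  rem <- n_inf %% n_blocks
  if (rem > 0) per[seq_len(rem)] <- per[seq_len(rem)] + 1
  block_of <- rep(seq_len(n_blocks), per)
  pat <- ifelse(conc[inf_idx], "AABB", ifelse(abba[inf_idx], "ABBA", "ABAB"))
  per_block <- vapply(seq_len(n_blocks), function(b)
    c(AABB = sum(pat == "AABB" & block_of == b),
      ABBA = sum(pat == "ABBA" & block_of == b),
      ABAB = sum(pat == "ABAB" & block_of == b)), numeric(3))
  structure(list(n_conc = sum(conc), n_abba = sum(abba), n_abab = sum(abab),
                 per_block = per_block, n_informative = n_inf),
            class = "concordance_counts")
}

#' Concordance counts from a simulated per-site pattern vector
#'
#' Convenience constructor pairing \code{\link{simulate_quartet_sites}}
#' with \code{\link{concordance_test}}.
#'
#' @param patterns character vector of "AABB"/"ABBA"/"ABAB" in genome order.
#' @param n_blocks jackknife block count (default 50).
#' @return a \code{concordance_counts} object.
#' @export
quartet_counts_from_patterns <- function(patterns, n_blocks = 50) {
  pattern_counts(patterns == "AABB", patterns == "ABBA", patterns == "ABAB",
                 n_blocks)
}

c_statistic <- function(n_conc, n_abba, n_abab) {
  n_disc1 <- max(n_abba, n_abab)
  if (n_conc + n_disc1 == 0) return(NA_real_)
  (n_conc - n_disc1) / (n_conc + n_disc1)
}

#' Concordance statistic with block-jackknife standard error and Z score
#'
#' C is the excess of concordant (AABB) topologies over the more frequent
#' discordant class: C = (N_conc - N_disc1) / (N_conc + N_disc1). The
#' standard error is the delete-one block jackknife over the contiguous
#' equal-count blocks, SE = sqrt((n-1)/n * sum((C_i - Cbar)^2)), and
#' Z = C / SE measures the deviation from zero (no topology support).
#'
#' @param counts a \code{concordance_counts} object.
#' @return list of class \code{concordance_result}: \code{C},
#'   \code{se_jack}, \code{z}, \code{n_blocks}, \code{pseudo_values},
#'   \code{pseudo_mean}, plus the input counts.
#' @export
concordance_test <- function(counts) {
  C <- c_statistic(counts$n_conc, counts$n_abba, counts$n_abab)
  if (is.na(C)) stop("no concordant or discordant sites: C undefined")
  pb <- counts$per_block
  n <- ncol(pb)
  Ci <- vapply(seq_len(n), function(b)
    c_statistic(counts$n_conc - pb["AABB", b],
                counts$n_abba - pb["ABBA", b],
                counts$n_abab - pb["ABAB", b]), numeric(1))
  Cbar <- mean(Ci)
  se <- sqrt((n - 1) / n * sum((Ci - Cbar)^2))
  z <- if (se > 0) C / se else if (C == 0) 0 else {
    warning("jackknife SE is 0 with C != 0; Z reported as +/-Inf")
    sign(C) * Inf
  }
  structure(list(C = C, se_jack = se, z = z, n_blocks = n,
                 pseudo_values = Ci, pseudo_mean = Cbar, counts = counts),
            class = "concordance_result")
}

#' Internode time from a concordance fraction
#'
#' Inverts the multispecies-coalescent concordance law
#' P_conc = 1 - (2/3) exp(-T): T = -log((3 - 3 P_conc) / 2), in coalescent
#' units (2 Ne generations). Values of P_conc at or below the star-tree
#' fraction 1/3 floor T at 0; P_conc = 1 gives +Inf.
#'
#' @param p_conc proportion of concordant genealogies, in [0, 1].
#' @return internode time in coalescent units (vectorised).
#' @export
internode_time <- function(p_conc) {
  stopifnot(all(p_conc >= 0 & p_conc <= 1))
  t <- -log((3 - 3 * p_conc) / 2)
  pmax(t, 0)
}

#' Divergence-time estimate from concordant/informative counts
#'
#' Point estimate T-hat = internode_time(n_conc / n_informative); 95%
#' confidence interval from the binomial profile likelihood of P_conc
#' propagated through the same inversion; chronological dates as
#' T-hat x 2 Ne x generation time for each supplied Ne.
#'
#' @param n_conc concordant site count.
#' @param n_informative informative site count (> 0).
#' @param ne_list effective population sizes for the date conversion.
#' @param gen_time generation time in years (default 29).
#' @param conf confidence level (default 0.95).
#' @return list of class \code{divergence_result}: \code{p_conc},
#'   \code{t_hat}, \code{ci} (coalescent units), \code{years} (named by Ne),
#'   \code{years_ci}, counts.
#' @export
divergence_from_counts <- function(n_conc, n_informative, ne_list = c(1000,
                                   5000, 10000, 20000), gen_time = 29,
                                   conf = 0.95) {
  if (n_informative <= 0) stop("zero informative sites")
  p_hat <- n_conc / n_informative
  t_hat <- internode_time(p_hat)
  ll <- function(p) stats::dbinom(n_conc, n_informative, p, log = TRUE)
  crit <- ll(p_hat) - stats::qchisq(conf, 1) / 2
  eps <- 1e-12
  lo <- if (n_conc == 0) 0 else
    stats::uniroot(function(p) ll(p) - crit, c(eps, p_hat))$root
  hi <- if (n_conc == n_informative) 1 else
    stats::uniroot(function(p) ll(p) - crit, c(p_hat, 1 - eps))$root
  ci <- internode_time(c(lo, hi))
  years <- stats::setNames(t_hat * 2 * ne_list * gen_time, ne_list)
  years_ci <- lapply(stats::setNames(ne_list, ne_list), function(ne)
    ci * 2 * ne * gen_time)
  structure(list(p_conc = p_hat, t_hat = t_hat, ci = ci, years = years,
                 years_ci = years_ci, n_conc = n_conc,
                 n_informative = n_informative, conf = conf),
            class = "divergence_result")
}

#' Estimate pairwise divergence time from a haplotype panel
#'
#' At each site, two distinct alleles are sampled from the in-group and one
#' from the out-group, with the chimpanzee allele extracted for
#' polarisation. A site is informative when exactly two of the three
#' sampled alleles agree; it is concordant when the two in-group alleles
#' agree with each other and differ from the out-group allele. The
#' concordant fraction is inverted to the internode time between the two
#' population splits (see \code{\link{divergence_from_counts}}).
#'
#' @param panel a \code{\link{haplotype_panel}} with outgroup alleles.
#' @param ingroup,outgroup population labels.
#' @param seed integer seed.
#' @param ne_list,gen_time,conf passed to
#'   \code{\link{divergence_from_counts}}.
#' @return a \code{divergence_result}.
#' @export
estimate_divergence <- function(panel, ingroup, outgroup, seed,
                                ne_list = c(1000, 5000, 10000, 20000),
                                gen_time = 29, conf = 0.95) {
  chimp <- panel$sites$outgroup
  in_sub <- panel$alleles[panel_pop_rows(panel, ingroup), , drop = FALSE]
  out_sub <- panel$alleles[panel_pop_rows(panel, outgroup), , drop = FALSE]
  S <- ncol(in_sub)
  set.seed(seed)
  u <- matrix(stats::runif(3 * S), 3, S)
  o <- sample_allele(out_sub, u[3, ])
  i1 <- rep(NA_integer_, S); i2 <- rep(NA_integer_, S)
  for (s in seq_len(S)) {
    rows <- which(!is.na(in_sub[, s]))
    if (length(rows) < 2) next
    k1 <- ceiling(u[1, s] * length(rows))
    k2 <- ceiling(u[2, s] * (length(rows) - 1))
    if (k2 >= k1) k2 <- k2 + 1
    i1[s] <- in_sub[rows[k1], s]
    i2[s] <- in_sub[rows[k2], s]
  }
  ok <- !is.na(chimp) & !is.na(o) & !is.na(i1) & !is.na(i2)
  agree2 <- ok & !(i1 == i2 & i2 == o)   # biallelic: not all equal
  conc <- agree2 & i1 == i2
  divergence_from_counts(sum(conc), sum(agree2), ne_list, gen_time, conf)
}
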