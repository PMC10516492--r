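## Ancestry masking, missingness filters, pairwise-difference clustering,
## and copy-profile distances.

#' Mask all ancestries except one in every haploid genome
#'
#' Per haploid genome, a site keeps its allele only when the covering local
#' ancestry window's call equals \code{target} AND its posterior is at
#' least \code{posterior_threshold}; everything else becomes MISSING. The
#' default threshold of 1 drops every window whose marginal probability is
#' below 1, excluding all ambiguous assignments. Sites not covered by any
#' window are masked and counted. Each haploid genome is an independent
#' unit downstream.
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @param la a \code{\link{local_ancestry}} covering the panel's genomes.
#' @param target ancestry label to retain.
#' @param posterior_threshold minimum posterior (default 1.0).
#' @return object of class \code{masked_panel}: the masked
#'   \code{\link{haplotype_panel}} plus \code{missing_fraction} (per haploid
#'   genome), \code{uncovered_sites} (count) and \code{target_ancestry}.
#' @export
mask_by_ancestry <- function(panel, la, target, posterior_threshold = 1.0) {
  k <- match(target, la$ancestries)
  if (is.na(k)) stop("target ancestry '", target, "' not in local ancestry")
  alleles <- panel$alleles
  sites <- panel$sites
  uncovered <- 0L
  for (ch in unique(sites$chrom)) {
    ssel <- which(sites$chrom == ch)
    wsel <- which(la$windows$chrom == ch)
    if (!length(wsel)) {
      alleles[, ssel] <- NA_integer_
      uncovered <- uncovered + length(ssel)
      next
    }
    w <- la$windows[wsel, , drop = FALSE]
    idx <- findInterval(sites$pos[ssel], w$start)
    covered <- idx >= 1 & sites$pos[ssel] <= w$end[pmax(idx, 1L)]
    uncovered <- uncovered + sum(!covered)
    alleles[, ssel[!covered]] <- NA_integer_
    widx <- wsel[idx[covered]]
    for (h in seq_along(panel$haplotypes)) {
      j <- match(panel$haplotypes[h], la$haplotypes)
      if (is.na(j)) stop("haploid genome '", panel$haplotypes[h],
                         "' not covered by local ancestry")
      calls <- la$calls[widx, j]
      post <- la$posteriors[widx, j]
      keep <- !is.na(calls) & calls == k & post >= posterior_threshold
      drop <- ssel[covered][!keep]
      alleles[h, drop] <- NA_integer_
    }
  }
  masked <- haplotype_panel(alleles, sites, panel$haplotypes,
                            panel$populations)
  mf <- rowMeans(is.na(alleles))
  structure(list(panel = masked,
                 missing_fraction = stats::setNames(mf, panel$haplotypes),
                 uncovered_sites = uncovered, target_ancestry = target),
            class = "masked_panel")
}

#' Split masked genomes into core and projectable sets and filter sites
#'
#' Haploid genomes with a missing fraction strictly below
#' \code{genome_max_missing} form the core set; genomes between that cutoff
#' and \code{project_max_missing} (default 0.95, strict) are projectable;
#' the rest are dropped. Sites whose missing rate over the core genomes is
#' strictly above \code{site_max_missing} are removed. All cutoffs are
#' strict, matching their "less than" phrasing; a genome exactly at the
#' core cutoff is not core.
#'
#' @param masked a \code{masked_panel} (or plain \code{haplotype_panel}).
#' @param genome_max_missing core cutoff on the per-genome missing fraction.
#' @param site_max_missing removal cutoff on the per-site missing rate.
#' @param project_max_missing projectable upper cutoff (default 0.95).
#' @return list of class \code{missingness_filter}: \code{core} and
#'   \code{projectable} (haploid genome ids), \code{sites} (retained site
#'   indices), \code{panel} (core genomes x retained sites), and the counts
#'   \code{n_sites_removed}, \code{n_dropped_genomes}.
#' @export
filter_by_missingness <- function(masked, genome_max_missing,
                                  site_max_missing,
                                  project_max_missing = 0.95) {
  stopifnot(genome_max_missing > 0, genome_max_missing <= 1,
            site_max_missing > 0, site_max_missing <= 1)
  panel <- if (inherits(masked, "masked_panel")) masked$panel else masked
  mf <- rowMeans(is.na(panel$alleles))
  core <- panel$haplotypes[mf < genome_max_missing]
  proj <- panel$haplotypes[mf >= genome_max_missing & mf < project_max_missing]
  if (!length(core)) stop("no haploid genome passes the core cutoff")
  core_rows <- match(core, panel$haplotypes)
  site_miss <- colMeans(is.na(panel$alleles[core_rows, , drop = FALSE]))
  sites <- which(site_miss <= site_max_missing)
  structure(list(core = core, projectable = proj, sites = sites,
                 panel = subset_panel(panel, sites = sites,
                                      haplotypes = core),
                 n_sites_removed = sum(site_miss > site_max_missing),
                 n_dropped_genomes = sum(mf >= project_max_missing)),
            class = "missingness_filter")
}

#' Ancestry-specific pairwise difference matrix over haploid genomes
#'
#' Entry (x, y) is the mean absolute allele difference over sites where
#' both genomes are nonmissing. Entries with fewer than \code{min_sites}
#' co-observed sites are set to NA and flagged.
#'
#' @param masked a \code{masked_panel} or \code{\link{haplotype_panel}}.
#' @param min_sites minimum co-observed sites for a defined entry
#'   (default 100).
#' @return symmetric matrix (haploid genomes x haploid genomes) with zero
#'   diagonal; attribute \code{co_observed} holds the co-observation
#'   counts, attribute \code{undefined_pairs} the number of NA'd pairs.
#' @export
pairwise_difference_matrix <- function(masked, min_sites = 100) {
  panel <- if (inherits(masked, "masked_panel")) masked$panel else masked
  M <- panel$alleles
  if (nrow(M) < 2) stop("at least 2 haploid genomes required")
  V <- !is.na(M)
  A <- M; A[!V] <- 0L
  storage.mode(A) <- "double"; storage.mode(V) <- "double"
  co <- V %*% t(V)
  diffs <- A %*% t((1 - A) * V) + ((1 - A) * V) %*% t(A)
  D <- diffs / co
  D[co < min_sites] <- NA
  diag(D) <- 0
  dimnames(D) <- list(panel$haplotypes, panel$haplotypes)
  attr(D, "co_observed") <- co
  attr(D, "undefined_pairs") <- (sum(co < min_sites) -
                                   sum(diag(co) < min_sites)) / 2
  D
}

#' Complete-linkage clustering on a correlation distance
#'
#' The distance between two rows of the input matrix is 1 minus the Pearson
#' correlation of their columns (the \code{as.dist(1 - cor(x))} idiom),
#' followed by complete-linkage agglomeration.
#'
#' @param x square symmetric matrix (e.g. a pairwise-difference matrix).
#' @return an \pkg{ape} \code{phylo} tree.
#' @export
correlation_cluster <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x) || max(abs(x - t(x)), na.rm = TRUE) > 1e-9)
    stop("input must be a square symmetric matrix")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant row/column (correlation undefined): ",
         colnames(x)[which(sds == 0)[1]])
  d <- stats::as.dist(1 - stats::cor(x))
  ape::as.phylo(stats::hclust(d, method = "complete"))
}

#' Total variation distance between two normalized copy profiles
#'
#' TVD = 0.5 * sum_i |p_i - q_i|; a metric on the probability simplex,
#' 0 for identical profiles and 1 for disjoint support.
#'
#' @param profile_x,profile_y numeric vectors over the same donor list
#'   (names, when present, must match).
#' @return TVD in [0, 1].
#' @export
tvd <- function(profile_x, profile_y) {
  if (length(profile_x) != length(profile_y))
    stop("profiles are over different donor lists")
  if (!is.null(names(profile_x)) && !is.null(names(profile_y)) &&
      !identical(names(profile_x), names(profile_y)))
    stop("profiles are over different donor lists")
  0.5 * sum(abs(profile_x - profile_y))
}

#' Pairwise TVD matrix between copy profiles
#'
#' @param profiles a \code{copy_profiles} object.
#' @return symmetric recipients x recipients matrix of TVD values.
#' @export
tvd_matrix <- function(profiles) {
  P <- profiles$normalized
  n <- nrow(P)
  D <- matrix(0, n, n, dimnames = list(rownames(P), rownames(P)))
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- tvd(P[i, ], P[j, ])
  D
}

#' Donor-wise copy-profile contrasts against a baseline recipient
#'
#' For each recipient, the difference of its (unnormalised) chunk counts
#' from the baseline recipient's counts, donor by donor; the baseline's own
#' contrast is the zero vector.
#'
#' @param profiles a \code{copy_profiles} object.
#' @param baseline_population row name of the baseline recipient.
#' @return matrix (recipients x donors) of count differences.
#' @export
profile_contrast <- function(profiles, baseline_population) {
  counts <- profiles$counts
  if (!baseline_population %in% rownames(counts))
    stop("baseline '", baseline_population, "' not among recipients")
  sweep(counts, 2, counts[baseline_population, ], `-`)
}
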