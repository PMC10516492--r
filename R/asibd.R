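#' Configuration for ancestry-specific IBD analysis
#'
#' Defaults follow the standard refinedIBD post-processing conventions: IBD
#' blocks of the same haploid pair separated by less than 0.6 cM are merged,
#' blocks whose ancestry is inconsistent over more than 25% of their defined
#' genetic length are excluded, and blocks are analysed in three length
#' categories (1-5, 5-10, >10 cM; blocks under 1 cM are dropped).
#'
#' @param gap_merge_cm maximum gap (cM) merged between neighbouring blocks.
#' @param inconsistency_threshold exclusion threshold on the inconsistent
#'   fraction of the defined length; exactly the threshold is kept (the rule
#'   is "more than").
#' @param length_bins ordered bin edges in cM; bins are half-open
#'   [edge_i, edge_{i+1}), the last implicitly extending to infinity.
#' @return list of class \code{asibd_config}.
#' @export
asibd_config <- function(gap_merge_cm = 0.6, inconsistency_threshold = 0.25,
                         length_bins = c(1, 5, 10)) {
  stopifnot(!is.unsorted(length_bins, strictly = TRUE),
            inconsistency_threshold >= 0, inconsistency_threshold <= 1,
            gap_merge_cm >= 0)
  structure(list(gap_merge_cm = gap_merge_cm,
                 inconsistency_threshold = inconsistency_threshold,
                 length_bins = length_bins),
            class = "asibd_config")
}

canonical_pair <- function(h1, h2) {
  a <- pmin(h1, h2); b <- pmax(h1, h2)
  paste(a, b, sep = "::")
}

seg_hap_ids <- function(segments) {
  list(hap1 = hap_id(segments$sample1, segments$hap1),
       hap2 = hap_id(segments$sample2, segments$hap2))
}

#' Merge nearby IBD blocks of the same haploid pair
#'
#' Blocks of one haploid-genome pair on one chromosome are merged
#' transitively, left to right, whenever they overlap or the genetic gap
#' between them is smaller than \code{gap_merge_cm}. When a haplotype panel
#' is supplied, a merge is vetoed if more than one discordant genotype
#' between the two haplotypes lies in the combined gap-plus-blocks region.
#' Merged lengths are recomputed from the map.
#'
#' @param segments an \code{ibd_segments} data.frame.
#' @param map a \code{\link{genetic_map}}.
#' @param gap_merge_cm gap threshold in cM (default 0.6).
#' @param panel optional \code{\link{haplotype_panel}} for the discordance
#'   veto.
#' @return merged \code{ibd_segments}.
#' @export
merge_ibd_blocks <- function(segments, map, gap_merge_cm = 0.6, panel = NULL) {
  if (nrow(segments) == 0) return(segments)
  ids <- seg_hap_ids(segments)
  key <- paste(canonical_pair(ids$hap1, ids$hap2), segments$chrom, sep = "@")
  discordant_count <- function(h1, h2, chrom, lo, hi) {
    i1 <- match(h1, panel$haplotypes); i2 <- match(h2, panel$haplotypes)
    sel <- which(panel$sites$chrom == chrom & panel$sites$pos >= lo &
                   panel$sites$pos <= hi)
    a <- panel$alleles[i1, sel]; b <- panel$alleles[i2, sel]
    sum(a != b, na.rm = TRUE)
  }
  out <- lapply(split(seq_len(nrow(segments)), key), function(idx) {
    grp <- segments[idx, , drop = FALSE]
    grp <- grp[order(grp$start), , drop = FALSE]
    h1 <- hap_id(grp$sample1[1], grp$hap1[1])
    h2 <- hap_id(grp$sample2[1], grp$hap2[1])
    acc <- grp[1, , drop = FALSE]
    res <- list()
    for (i in seq_len(nrow(grp))[-1]) {
      gap <- interval_cm(map, grp$chrom[i],
                         min(acc$end, grp$start[i]),
                         max(acc$end, grp$start[i]))
      mergeable <- grp$start[i] <= acc$end || gap < gap_merge_cm
      if (mergeable && !is.null(panel))
        mergeable <- discordant_count(h1, h2, acc$chrom, acc$start,
                                      max(acc$end, grp$end[i])) <= 1
      if (mergeable) {
        acc$end <- max(acc$end, grp$end[i])
        acc$lod <- max(acc$lod, grp$lod[i])
      } else {
        res[[length(res) + 1]] <- acc
        acc <- grp[i, , drop = FALSE]
      }
    }
    res[[length(res) + 1]] <- acc
    do.call(rbind, res)
  })
  merged <- do.call(rbind, out)
  merged$length_cm <- vapply(seq_len(nrow(merged)), function(i)
    interval_cm(map, merged$chrom[i], merged$start[i], merged$end[i]),
    numeric(1))
  merged <- merged[order(merged$sample1, merged$hap1, merged$sample2,
                         merged$hap2, merged$chrom, merged$start), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  class(merged) <- c("ibd_segments", "data.frame")
  merged
}

#' Assign IBD blocks to half-open length classes
#'
#' Classes are [1,5), [5,10), [10, Inf) cM by default; a block of exactly
#' 5 cM falls in the 5-10 class. Blocks shorter than the first edge are
#' dropped and counted.
#'
#' @param segments an \code{ibd_segments} data.frame (\code{length_cm} set).
#' @param bins ordered bin edges in cM (default \code{c(1, 5, 10)}).
#' @return list with \code{segments} (the retained blocks plus a
#'   \code{class} factor column) and \code{dropped} (count below the first
#'   edge).
#' @export
bin_by_length <- function(segments, bins = c(1, 5, 10)) {
  labels <- length_class_labels(bins)
  idx <- findInterval(segments$length_cm, bins)
  dropped <- sum(idx == 0)
  keep <- segments[idx > 0, , drop = FALSE]
  keep$class <- factor(labels[idx[idx > 0]], levels = labels)
  list(segments = keep, dropped = dropped)
}

length_class_labels <- function(bins) {
  n <- length(bins)
  c(paste0("[", bins[-n], ",", bins[-1], ")"), paste0(">=", bins[n]))
}

#' Decompose IBD blocks by local ancestry
#'
#' Each block's interval is intersected with the overlay of both haplotypes'
#' ancestry windows. Sub-intervals where both calls are defined and equal
#' contribute their genetic length to that ancestry; defined-but-different
#' sub-intervals accrue to \code{inconsistent_cm}; sub-intervals with any
#' UNDEFINED call accrue to \code{undefined_cm}. A block is excluded when
#' its inconsistent fraction of the defined length exceeds
#' \code{threshold} (strictly); blocks with no defined length are excluded.
#' Use raw (pre-merge) blocks here: merging loses the haplotype of origin.
#'
#' @param segments an \code{ibd_segments} data.frame (raw blocks).
#' @param la a \code{\link{local_ancestry}} covering both haplotypes.
#' @param map a \code{\link{genetic_map}}.
#' @param threshold inconsistency exclusion threshold (default 0.25).
#' @return data.frame of class \code{decomposed_ibd}: the segment columns
#'   plus one \code{anc_<label>} column per ancestry, \code{inconsistent_cm},
#'   \code{undefined_cm}, \code{excluded}. Per row, ancestry + inconsistent
#'   + undefined mass equals the block's genetic length.
#' @export
decompose_ibd_ancestry <- function(segments, la, map, threshold = 0.25) {
  K <- length(la$ancestries)
  anc_cols <- paste0("anc_", la$ancestries)
  n <- nrow(segments)
  anc_cm <- matrix(0, n, K, dimnames = list(NULL, anc_cols))
  inconsistent <- numeric(n); undefined <- numeric(n); total <- numeric(n)
  ids <- seg_hap_ids(segments)
  for (i in seq_len(n)) {
    ch <- segments$chrom[i]; s <- segments$start[i]; e <- segments$end[i]
    wsel <- which(la$windows$chrom == ch)
    if (!length(wsel) || s < min(la$windows$start[wsel]) ||
        e > max(la$windows$end[wsel]))
      stop("segment ", i, " (", ch, ":", s, "-", e,
           ") outside local-ancestry coverage")
    wend <- la$windows$end[wsel]
    cuts <- sort(unique(c(s, wend[wend >= s & wend < e], e)))
    cm_at <- interpolate_cm(map, ch, cuts)
    lens <- diff(cm_at)
    mids <- (cuts[-length(cuts)] + cuts[-1]) / 2
    ja <- match(hap_id(segments$sample1[i], segments$hap1[i]), la$haplotypes)
    jb <- match(hap_id(segments$sample2[i], segments$hap2[i]), la$haplotypes)
    if (is.na(ja) || is.na(jb))
      stop("segment ", i, ": haploid genome not covered by local ancestry")
    widx <- wsel[findInterval(mids, la$windows$start[wsel])]
    ca <- la$calls[widx, ja]; cb <- la$calls[widx, jb]
    und <- is.na(ca) | is.na(cb)
    eq <- !und & ca == cb
    inc <- !und & !eq
    undefined[i] <- sum(lens[und])
    inconsistent[i] <- sum(lens[inc])
    if (any(eq)) {
      sums <- tapply(lens[eq], ca[eq], sum)
      anc_cm[i, as.integer(names(sums))] <- sums
    }
    total[i] <- cm_at[length(cm_at)] - cm_at[1]
  }
  defined <- total - undefined
  excluded <- defined <= 0 | (inconsistent / pmax(defined, .Machine$double.eps)
                              > threshold)
  out <- cbind(as.data.frame(segments), as.data.frame(anc_cm),
               data.frame(inconsistent_cm = inconsistent,
                          undefined_cm = undefined,
                          length_cm_map = total,
                          excluded = excluded))
  attr(out, "ancestries") <- la$ancestries
  class(out) <- c("decomposed_ibd", "data.frame")
  out
}

#' Aggregate ancestry-specific IBD sharing by population pair and length class
#'
#' For every unordered pair of populations (including within-population
#' pairs) and every length class, reports the mean per haploid-genome pair
#' of the summed per-ancestry cM of kept blocks, the mean inconsistent and
#' undefined mass of kept blocks, and the mean total length of blocks
#' excluded by the inconsistency rule. The mean divides by the number of
#' haploid-genome pairs implied by the metadata roster (zero-sharing pairs
#' included); within-population pairs are unordered haploid pairs excluding
#' self-pairs, so HBD (same sample, different haplotypes) is counted.
#'
#' @param decomposed a \code{decomposed_ibd} data.frame.
#' @param metadata a \code{population_metadata} data.frame (the roster).
#' @param bins length-class edges in cM (default \code{c(1, 5, 10)}).
#' @return data.frame of class \code{asibd_summary}: one row per
#'   (pop1, pop2, class) with \code{anc_*}, \code{inconsistent_cm},
#'   \code{undefined_cm}, \code{excluded_cm} means and \code{n_pairs}.
#' @export
aggregate_asibd <- function(decomposed, metadata, bins = c(1, 5, 10)) {
  ancestries <- attr(decomposed, "ancestries")
  anc_cols <- paste0("anc_", ancestries)
  pops <- sort(unique(metadata$population))
  n_hap <- stats::setNames(2L * as.vector(table(metadata$population)[pops]),
                           pops)
  pop_of <- stats::setNames(metadata$population, metadata$sample)
  miss <- setdiff(unique(c(decomposed$sample1, decomposed$sample2)),
                  metadata$sample)
  if (length(miss))
    stop("sample(s) absent from metadata: ", paste(miss, collapse = ", "))
  decomposed$length_cm <- decomposed$length_cm_map
  binned <- bin_by_length(decomposed, bins)
  d <- binned$segments
  labels <- length_class_labels(bins)
  pair_grid <- expand.grid(i = seq_along(pops), j = seq_along(pops))
  pair_grid <- pair_grid[pair_grid$i <= pair_grid$j, , drop = FALSE]
  rows <- list()
  for (r in seq_len(nrow(pair_grid))) {
    p1 <- pops[pair_grid$i[r]]; p2 <- pops[pair_grid$j[r]]
    n_pairs <- if (p1 == p2) n_hap[p1] * (n_hap[p1] - 1) / 2 else
      n_hap[p1] * n_hap[p2]
    sp1 <- pop_of[d$sample1]; sp2 <- pop_of[d$sample2]
    sel <- (sp1 == p1 & sp2 == p2) | (sp1 == p2 & sp2 == p1)
    for (cl in labels) {
      dd <- d[sel & d$class == cl, , drop = FALSE]
      kept <- dd[!dd$excluded, , drop = FALSE]
      exc <- dd[dd$excluded, , drop = FALSE]
      anc_tot <- if (nrow(kept)) colSums(kept[, anc_cols, drop = FALSE]) else
        stats::setNames(numeric(length(anc_cols)), anc_cols)
      rows[[length(rows) + 1]] <- data.frame(
        pop1 = p1, pop2 = p2, class = cl,
        as.list(anc_tot / max(n_pairs, 1)),
        inconsistent_cm = sum(kept$inconsistent_cm) / max(n_pairs, 1),
        undefined_cm = sum(kept$undefined_cm) / max(n_pairs, 1),
        excluded_cm = sum(exc$length_cm_map) / max(n_pairs, 1),
        n_pairs = n_pairs, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ancestries") <- ancestries
  attr(out, "dropped") <- binned$dropped
  class(out) <- c("asibd_summary", "data.frame")
  out
}

#' Pool ancestry-specific IBD sharing of a target population
#'
#' Sums a target population's mean per-pair sharing of one ancestry over
#' pools of donor populations (pools partition the populations; an
#' "Unknown" pool holding the target's own group is allowed) and normalises
#' to a probability vector over pools.
#'
#' @param asibd an \code{asibd_summary}.
#' @param pools named list: pool label -> character vector of populations,
#'   or a \code{population_metadata} with a \code{pool} column.
#' @param target_pop the recipient population.
#' @param ancestry ancestry label to pool (e.g. the masked target ancestry).
#' @param classes length classes to include (default: all).
#' @return list with \code{proportions} (named, sums to 1 when any sharing)
#'   and \code{raw} (pair-weighted mean cM per pool).
#' @export
pool_sharing <- function(asibd, pools, target_pop, ancestry, classes = NULL) {
  if (inherits(pools, "population_metadata"))
    pools <- split(unique(pools[, c("population", "pool")])$population,
                   unique(pools[, c("population", "pool")])$pool)
  if (any(!lengths(pools))) stop("empty pool: ",
                                 names(pools)[which(!lengths(pools))[1]])
  col <- paste0("anc_", ancestry)
  if (!col %in% names(asibd)) stop("ancestry '", ancestry, "' not in summary")
  if (is.null(classes)) classes <- unique(asibd$class)
  sel <- asibd$class %in% classes &
    (asibd$pop1 == target_pop | asibd$pop2 == target_pop)
  sub <- asibd[sel, , drop = FALSE]
  other <- ifelse(sub$pop1 == target_pop, sub$pop2, sub$pop1)
  raw <- vapply(pools, function(members) {
    rs <- sub[other %in% members, , drop = FALSE]
    if (!nrow(rs)) return(0)
    sum(rs[[col]] * rs$n_pairs) / sum(rs$n_pairs)
  }, numeric(1))
  total <- sum(raw)
  props <- if (total > 0) raw / total else raw
  list(proportions = props, raw = raw)
}

#' UPGMA tree from a distance matrix or profile vectors
#'
#' Average-linkage (UPGMA) agglomeration giving an ultrametric tree. When
#' given profile vectors (a matrix whose rows are units, e.g. pooled IBD
#' sharing proportions), Euclidean distances between rows are computed
#' first.
#'
#' @param x symmetric distance matrix (zero diagonal) or, with
#'   \code{profiles = TRUE}, a units-by-features matrix.
#' @param profiles interpret \code{x} as profile vectors (default FALSE).
#' @return an \pkg{ape} \code{phylo} tree.
#' @export
upgma_tree <- function(x, profiles = FALSE) {
  if (profiles) {
    d <- stats::dist(x, method = "euclidean")
  } else {
    x <- as.matrix(x)
    if (max(abs(x - t(x))) > 1e-9) stop("distance matrix is not symmetric")
    if (any(diag(x) != 0)) stop("distance matrix must have zero diagonal")
    if (any(x < 0)) stop("distances must be non-negative")
    d <- stats::as.dist(x)
  }
  hc <- stats::hclust(d, method = "average")
  ape::as.phylo(hc)
}

#' Within- and between-group IBD sharing summaries
#'
#' Totals merged IBD blocks per pair of diploid individuals (HBD blocks
#' total within an individual paired with itself) and summarises them per
#' length class: within-group distributions over individual pairs, group
#' mean totals, and between-group mean totals.
#'
#' @param segments merged \code{ibd_segments}.
#' @param metadata a \code{population_metadata}.
#' @param bins length-class edges in cM (default \code{c(1, 5, 10)}).
#' @return list of class \code{group_ibd_summary}: \code{pair_totals}
#'   (sample1, sample2, pop1, pop2, class, total_cm), \code{group_means}
#'   (population x class mean of within-group pair totals; NA for groups
#'   with fewer than 2 individuals, with a warning), \code{between_means}
#'   (pop1, pop2, class, mean total), \code{dropped}.
#' @export
group_ibd_summaries <- function(segments, metadata, bins = c(1, 5, 10)) {
  binned <- bin_by_length(segments, bins)
  d <- binned$segments
  labels <- length_class_labels(bins)
  pop_of <- stats::setNames(metadata$population, metadata$sample)
  key1 <- pmin(d$sample1, d$sample2); key2 <- pmax(d$sample1, d$sample2)
  agg <- stats::aggregate(list(total_cm = d$length_cm),
                          by = list(sample1 = key1, sample2 = key2,
                                    class = d$class), FUN = sum)
  agg$pop1 <- unname(pop_of[agg$sample1])
  agg$pop2 <- unname(pop_of[agg$sample2])
  pops <- sort(unique(metadata$population))
  small <- pops[table(factor(metadata$population, pops)) < 2]
  if (length(small))
    warning("group(s) with < 2 individuals, within-group stats absent: ",
            paste(small, collapse = ", "))
  group_means <- matrix(NA_real_, length(pops), length(labels),
                        dimnames = list(pops, labels))
  for (p in setdiff(pops, small)) for (cl in labels) {
    v <- agg$total_cm[agg$pop1 == p & agg$pop2 == p & agg$class == cl]
    group_means[p, cl] <- if (length(v)) mean(v) else 0
  }
  bet <- stats::aggregate(list(mean_cm = agg$total_cm),
                          by = list(pop1 = pmin(agg$pop1, agg$pop2),
                                    pop2 = pmax(agg$pop1, agg$pop2),
                                    class = agg$class), FUN = mean)
  structure(list(pair_totals = agg, group_means = group_means,
                 between_means = bet, dropped = binned$dropped),
            class = "group_ibd_summary")
}

#' Rank-sum comparison of group mean IBD totals
#'
#' Two-sided Wilcoxon rank-sum test comparing per-group mean within-group
#' IBD totals between two sets of groups, for one length class. Exact below
#' a combined n of 20, normal approximation with continuity correction
#' above.
#'
#' @param summary a \code{group_ibd_summary}.
#' @param groups_a,groups_b character vectors of population labels.
#' @param class length-class label (a column of \code{group_means}).
#' @return the \code{htest} object from \code{\link[stats]{wilcox.test}},
#'   with the group mean vectors attached as \code{data_a}/\code{data_b}.
#' @export
ibd_ranksum <- function(summary, groups_a, groups_b, class) {
  gm <- summary$group_means
  a <- gm[groups_a, class]; b <- gm[groups_b, class]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  exact <- (length(a) + length(b)) <= 20
  ht <- stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                           correct = !exact)
  ht$data_a <- a; ht$data_b <- b
  ht
}
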