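# Independent brute-force oracles. These re-derive expected values by
# direct enumeration and never share code paths with the implementation.

# Per-grid-cell decomposition of an IBD segment by local ancestry: walk a
# fine cM grid over the segment, look up both haplotypes' calls at each
# cell midpoint, and accumulate cell lengths per category.
grid_decompose_oracle <- function(seg, la, map, step_cm = 0.01) {
  ch <- seg$chrom
  cm0 <- interpolate_cm(map, ch, seg$start)
  cm1 <- interpolate_cm(map, ch, seg$end)
  edges <- seq(cm0, cm1, by = step_cm)
  if (edges[length(edges)] < cm1) edges <- c(edges, cm1)
  mids_cm <- (edges[-1] + edges[-length(edges)]) / 2
  lens <- diff(edges)
  pos <- interpolate_bp(map, ch, mids_cm)
  hA <- hap_id(seg$sample1, seg$hap1); hB <- hap_id(seg$sample2, seg$hap2)
  ca <- ancestry_at(la, hA, ch, pos)
  cb <- ancestry_at(la, hB, ch, pos)
  und <- is.na(ca) | is.na(cb)
  eq <- !und & ca == cb
  anc <- vapply(seq_along(la$ancestries), function(k)
    sum(lens[eq & ca == k]), numeric(1))
  list(anc_cm = stats::setNames(anc, la$ancestries),
       inconsistent_cm = sum(lens[!und & !eq]),
       undefined_cm = sum(lens[und]))
}

# Quadratic-time agglomeration oracle returning the cophenetic (tip-to-tip
# tree distance) matrix; linkage "average" = UPGMA, "complete" = max.
brute_agglomerate <- function(d, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  clusters <- as.list(seq_len(n))
  sizes <- rep(1, n)
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  active <- rep(TRUE, n)
  dd <- d
  while (sum(active) > 1) {
    idx <- which(active)
    best <- c(NA, NA); bmin <- Inf
    for (i in idx) for (j in idx) if (i < j && dd[i, j] < bmin) {
      bmin <- dd[i, j]; best <- c(i, j)
    }
    i <- best[1]; j <- best[2]
    for (a in clusters[[i]]) for (b in clusters[[j]])
      coph[a, b] <- coph[b, a] <- bmin
    for (k in idx) if (k != i && k != j) {
      dd[i, k] <- dd[k, i] <- if (linkage == "average")
        (sizes[i] * dd[i, k] + sizes[j] * dd[j, k]) / (sizes[i] + sizes[j])
      else max(dd[i, k], dd[j, k])
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
  }
  coph
}

# Site-by-site re-count of the concordance site filters.
brute_filter_sites <- function(panel, populations, maf_min = 0.10,
                               min_alleles = 10) {
  keep <- logical(ncol(panel$alleles))
  for (s in seq_len(ncol(panel$alleles))) {
    ok <- TRUE
    for (p in populations) {
      rows <- which(hap_populations(panel) == p)
      v <- panel$alleles[rows, s]
      v <- v[!is.na(v)]
      if (length(v) <= min_alleles) { ok <- FALSE; break }
      f <- mean(v)
      if (f == 0 || f == 1) { ok <- FALSE; break }
      if (min(f, 1 - f) <= maf_min) { ok <- FALSE; break }
    }
    keep[s] <- ok
  }
  which(keep)
}
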