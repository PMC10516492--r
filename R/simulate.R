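#' Synthetic genetic map over pseudo-chromosomes
#'
#' Builds a linear map (constant cM/Mb) over \code{n_chrom} pseudo-chromosomes
#' whose genetic lengths decrease roughly like human autosomes and sum to
#' \code{morgans} Morgans. Two anchor points per chromosome suffice for a
#' linear map.
#'
#' @param n_chrom number of pseudo-chromosomes (default 22).
#' @param morgans total genetic length in Morgans (default 30).
#' @param cm_per_mb recombination rate (default 1 cM/Mb).
#' @return a \code{\link{genetic_map}}.
#' @export
synthetic_map <- function(n_chrom = 22, morgans = 30, cm_per_mb = 1) {
  rel <- seq(1.7, 0.55, length.out = n_chrom)
  len_cm <- rel / sum(rel) * morgans * 100
  len_bp <- round(len_cm / cm_per_mb * 1e6)
  genetic_map(chrom = rep(paste0("chr", seq_len(n_chrom)), each = 2),
              pos = as.vector(rbind(1, len_bp)),
              cm = as.vector(rbind(0, len_cm)))
}

#' Simulate ancestral allele frequencies under the Balding-Nichols model
#'
#' Per site, a base frequency p is drawn Uniform(0.05, 0.95); each ancestry's
#' frequency is Beta(p(1-F)/F, (1-p)(1-F)/F) for its drift parameter F > 0
#' (variance F p(1-p)), or exactly p when F = 0. Frequencies are clamped away
#' from 0/1 by \code{floor} so minor-allele filters stay meaningful. One
#' ancestry may be flagged as the deeply divergent "ghost" source — it then
#' typically carries a large F and is never used as a reference panel
#' downstream.
#'
#' @param n_sites number of sites.
#' @param ancestries character vector of ancestry labels.
#' @param F_per_ancestry numeric vector in [0, 1), recycled to length K.
#' @param seed integer seed.
#' @param ghost optional label of the ghost ancestry.
#' @param floor frequency clamp (default 1e-4).
#' @return object of class \code{ancestral_frequencies}: list with
#'   \code{ancestries}, \code{freqs} (K x sites), \code{F}, \code{base_freqs},
#'   \code{ghost}.
#' @export
simulate_frequencies <- function(n_sites, ancestries, F_per_ancestry, seed,
                                 ghost = NULL, floor = 1e-4) {
  stopifnot(n_sites >= 1)
  K <- length(ancestries)
  F_per_ancestry <- rep_len(F_per_ancestry, K)
  if (any(F_per_ancestry < 0 | F_per_ancestry >= 1))
    stop("drift parameter F must satisfy 0 <= F < 1")
  if (!is.null(ghost) && !ghost %in% ancestries)
    stop("ghost label not among ancestries")
  set.seed(seed)
  base <- stats::runif(n_sites, 0.05, 0.95)
  freqs <- matrix(NA_real_, K, n_sites, dimnames = list(ancestries, NULL))
  for (k in seq_len(K)) {
    Fk <- F_per_ancestry[k]
    freqs[k, ] <- if (Fk == 0) base else
      stats::rbeta(n_sites, base * (1 - Fk) / Fk, (1 - base) * (1 - Fk) / Fk)
  }
  freqs <- pmin(pmax(freqs, floor), 1 - floor)
  structure(list(ancestries = ancestries, freqs = freqs,
                 F = stats::setNames(F_per_ancestry, ancestries),
                 base_freqs = base, ghost = ghost),
            class = "ancestral_frequencies")
}

# Draw ancestry tracts for one haploid genome on one chromosome.
# Switch events are Poisson with rate g per Morgan; at each event the
# ancestry is redrawn from the individual's proportions (self-transitions
# allowed), so the stationary law equals the proportions exactly and the
# recorded inter-event tracts have mean genetic length 100/g cM.
draw_tracts_chrom <- function(chrom, cm_len, start_bp, end_bp, map, g, props,
                              cm_start = 0) {
  n_events <- stats::rpois(1, g * cm_len / 100)
  breaks_cm <- cm_start + sort(stats::runif(n_events, 0, cm_len))
  anc <- sample.int(length(props), n_events + 1, replace = TRUE, prob = props)
  if (n_events == 0)
    return(data.frame(chrom = chrom, start = start_bp, end = end_bp,
                      ancestry = anc))
  bp <- interpolate_bp(map, chrom, breaks_cm)
  bp <- pmin(pmax(bp, start_bp), end_bp - 1)
  bp <- unique(bp)
  starts <- c(start_bp, bp + 1)
  ends <- c(bp, end_bp)
  data.frame(chrom = chrom, start = starts, end = ends,
             ancestry = anc[seq_along(starts)])
}

#' Simulate phased haplotypes for an admixed cohort
#'
#' Ancestry along each haploid genome is a Markov process in genetic
#' distance: switch points arrive at rate \code{generations} per Morgan and
#' each switch redraws the ancestry from the individual's admixture
#' proportions, so the genome-wide ancestry fraction converges to the target
#' proportions and tract lengths are exponential with mean
#' 100/\code{generations} cM. Alleles are drawn per site from the active
#' ancestry's frequency. The emitted local-ancestry matrix is the truth with
#' posterior 1.
#'
#' @param freqs an \code{\link{simulate_frequencies}} result.
#' @param proportions matrix (individuals x ancestries), rows summing to 1
#'   (tolerance 1e-6); rownames are sample ids.
#' @param map a \code{\link{genetic_map}} (see \code{\link{synthetic_map}}).
#' @param seed integer seed.
#' @param generations generations since admixture (switch rate per Morgan),
#'   default 25.
#' @param populations named character vector sample -> population; defaults
#'   to one population \code{"pop1"}.
#' @return object of class \code{synthetic_cohort}: list with \code{panel}
#'   (\code{\link{haplotype_panel}} including per-site outgroup alleles),
#'   \code{la} (truth \code{\link{local_ancestry}}), \code{truth} (tract
#'   list per haploid genome, planted IBD ledger, seed), \code{map},
#'   \code{freqs}.
#' @export
simulate_admixed_haplotypes <- function(freqs, proportions, map, seed,
                                        generations = 25,
                                        populations = NULL) {
  stopifnot(generations >= 1)
  proportions <- as.matrix(proportions)
  if (is.null(rownames(proportions)))
    rownames(proportions) <- paste0("ind", seq_len(nrow(proportions)))
  if (any(abs(rowSums(proportions) - 1) > 1e-6))
    stop("admixture proportions must sum to 1 per individual (tol 1e-6)")
  K <- length(freqs$ancestries)
  stopifnot(ncol(proportions) == K)
  samples <- rownames(proportions)
  if (is.null(populations))
    populations <- stats::setNames(rep("pop1", length(samples)), samples)
  ext <- map_extents(map)
  n_sites <- ncol(freqs$freqs)
  set.seed(seed)
  # site placement: allocate proportional to genetic length, uniform in bp
  alloc <- round(n_sites * (ext$cm_end - ext$cm_start) /
                   sum(ext$cm_end - ext$cm_start))
  alloc[length(alloc)] <- n_sites - sum(alloc[-length(alloc)])
  sites <- do.call(rbind, lapply(seq_len(nrow(ext)), function(i) {
    pos <- sort(sample(seq(ext$start[i] + 1, ext$end[i] - 1), alloc[i]))
    data.frame(chrom = ext$chrom[i], pos = pos)
  }))
  sites$ref <- "A"; sites$alt <- "G"
  # outgroup (chimp) carries the base-frequency major allele... polarised:
  # ancestral state 0 with prob 1 - base freq (alt is the derived allele)
  sites$outgroup <- as.integer(stats::runif(n_sites) < freqs$base_freqs^2)

  haps <- as.vector(rbind(hap_id(samples, 1L), hap_id(samples, 2L)))
  hap_ind <- rep(seq_along(samples), each = 2)
  tracts <- vector("list", length(haps))
  names(tracts) <- haps
  alleles <- matrix(NA_integer_, length(haps), n_sites)
  site_chrom <- sites$chrom
  for (h in seq_along(haps)) {
    props <- proportions[hap_ind[h], ]
    tr <- do.call(rbind, lapply(seq_len(nrow(ext)), function(i)
      draw_tracts_chrom(ext$chrom[i], ext$cm_end[i] - ext$cm_start[i],
                        ext$start[i], ext$end[i], map, generations, props,
                        cm_start = ext$cm_start[i])))
    tracts[[h]] <- tr
    anc_at_site <- integer(n_sites)
    for (i in seq_len(nrow(ext))) {
      sel <- which(site_chrom == ext$chrom[i])
      tsel <- tr[tr$chrom == ext$chrom[i], , drop = FALSE]
      anc_at_site[sel] <- tsel$ancestry[findInterval(sites$pos[sel],
                                                     tsel$start)]
    }
    p <- freqs$freqs[cbind(anc_at_site, seq_len(n_sites))]
    alleles[h, ] <- as.integer(stats::runif(n_sites) < p)
  }
  panel <- haplotype_panel(alleles, sites, haps, populations)
  la <- tracts_to_local_ancestry(tracts, freqs$ancestries, map)
  truth <- structure(list(tracts = tracts, planted_ibd = NULL,
                          proportions = proportions,
                          generations = generations, seed = seed),
                     class = "synthetic_truth")
  structure(list(panel = panel, la = la, truth = truth, map = map,
                 freqs = freqs),
            class = "synthetic_cohort")
}

#' Build a local-ancestry matrix from truth tracts
#'
#' Windows are the union of all haplotypes' tract breakpoints per
#' chromosome; calls are the tract ancestry at each window (posterior 1).
#' The windows tile each chromosome exactly.
#'
#' @param tracts named list (per haploid genome) of tract data.frames
#'   (\code{chrom}, \code{start}, \code{end}, \code{ancestry}).
#' @param ancestries ancestry labels (code order).
#' @param map a \code{\link{genetic_map}} (defines chromosome extents).
#' @return a \code{\link{local_ancestry}}.
#' @export
tracts_to_local_ancestry <- function(tracts, ancestries, map) {
  ext <- map_extents(map)
  haps <- names(tracts)
  win_list <- vector("list", nrow(ext))
  call_list <- vector("list", nrow(ext))
  for (i in seq_len(nrow(ext))) {
    ch <- ext$chrom[i]
    ends <- sort(unique(unlist(lapply(tracts, function(tr)
      tr$end[tr$chrom == ch]))))
    ends <- unique(c(ends, ext$end[i]))
    starts <- c(ext$start[i], ends[-length(ends)] + 1)
    win_list[[i]] <- data.frame(chrom = ch, start = starts, end = ends)
    calls <- matrix(NA_integer_, length(starts), length(haps))
    for (h in seq_along(haps)) {
      tr <- tracts[[h]]
      tsel <- tr[tr$chrom == ch, , drop = FALSE]
      calls[, h] <- tsel$ancestry[findInterval(starts, tsel$start)]
    }
    call_list[[i]] <- calls
  }
  local_ancestry(ancestries, do.call(rbind, win_list),
                 do.call(rbind, call_list), haps)
}

#' Plant identical-by-descent segments into a synthetic cohort
#'
#' For each requested haploid-genome pair, a random interval of the
#' requested genetic length is placed on a chromosome that can hold it, and
#' the source haplotype's alleles AND ancestry tracts over the interval are
#' copied onto the target haplotype, so the two haplotypes are byte-identical
#' (alleles and ancestry) over the segment. The local-ancestry matrix is
#' rebuilt from the updated tracts and the planted segments are appended to
#' the truth ledger.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param pairs data.frame with columns \code{hap1} (source) and \code{hap2}
#'   (target), haploid genome ids.
#' @param lengths_cm numeric vector of requested genetic lengths (cM),
#'   recycled to \code{nrow(pairs)}.
#' @param seed integer seed.
#' @return the updated \code{synthetic_cohort}.
#' @export
plant_ibd <- function(cohort, pairs, lengths_cm, seed) {
  lengths_cm <- rep_len(lengths_cm, nrow(pairs))
  if (any(lengths_cm <= 0)) stop("planted IBD length must be positive")
  ext <- map_extents(cohort$map)
  chr_cm <- ext$cm_end - ext$cm_start
  if (any(lengths_cm > max(chr_cm)))
    stop("requested length ", max(lengths_cm),
         " cM exceeds the longest chromosome (", round(max(chr_cm), 2), " cM)")
  set.seed(seed)
  sites <- cohort$panel$sites
  seg_rows <- vector("list", nrow(pairs))
  placed <- list()   # (chrom, start, end, haps) of prior plants
  for (r in seq_len(nrow(pairs))) {
    len <- lengths_cm[r]
    feasible <- which(chr_cm >= len)
    src <- pairs$hap1[r]; tgt <- pairs$hap2[r]
    # rejection-sample a placement whose target haplotype is not part of an
    # earlier planted segment on the same interval (overwriting it would
    # destroy the earlier identity)
    for (attempt in 1:200) {
      i <- if (length(feasible) == 1) feasible else sample(feasible, 1)
      ch <- ext$chrom[i]
      start_cm <- ext$cm_start[i] + stats::runif(1, 0, chr_cm[i] - len)
      s_bp <- interpolate_bp(cohort$map, ch, start_cm)
      e_bp <- interpolate_bp(cohort$map, ch, start_cm + len)
      clash <- any(vapply(placed, function(p)
        p$chrom == ch && s_bp <= p$end && e_bp >= p$start &&
          tgt %in% p$haps, logical(1)))
      if (!clash) break
      if (attempt == 200)
        stop("could not place a ", len, " cM segment without disturbing ",
             "previously planted IBD")
    }
    placed[[length(placed) + 1]] <- list(chrom = ch, start = s_bp,
                                         end = e_bp, haps = c(src, tgt))
    hi_s <- match(src, cohort$panel$haplotypes)
    hi_t <- match(tgt, cohort$panel$haplotypes)
    if (is.na(hi_s) || is.na(hi_t)) stop("unknown haploid genome in pair list")
    sel <- which(sites$chrom == ch & sites$pos >= s_bp & sites$pos <= e_bp)
    cohort$panel$alleles[hi_t, sel] <- cohort$panel$alleles[hi_s, sel]
    cohort$truth$tracts[[tgt]] <-
      splice_tracts(cohort$truth$tracts[[tgt]], cohort$truth$tracts[[src]],
                    ch, s_bp, e_bp)
    sp <- split_hap_id(src); tp <- split_hap_id(tgt)
    seg_rows[[r]] <- data.frame(
      sample1 = sp$sample, hap1 = sp$hap, sample2 = tp$sample, hap2 = tp$hap,
      chrom = ch, start = s_bp, end = e_bp, lod = 99,
      length_cm = interval_cm(cohort$map, ch, s_bp, e_bp),
      stringsAsFactors = FALSE)
  }
  planted <- do.call(rbind, seg_rows)
  class(planted) <- c("ibd_segments", "data.frame")
  cohort$truth$planted_ibd <- rbind(cohort$truth$planted_ibd, planted)
  cohort$la <- tracts_to_local_ancestry(cohort$truth$tracts,
                                        cohort$freqs$ancestries, cohort$map)
  cohort
}

# Replace the target's tracts over [s_bp, e_bp] on chrom ch with the
# source's tracts clipped to that interval; tiling is preserved.
splice_tracts <- function(target, source, ch, s_bp, e_bp) {
  on_ch <- target$chrom == ch
  keep <- target[!on_ch, , drop = FALSE]
  tch <- target[on_ch, , drop = FALSE]
  left <- tch[tch$start < s_bp, , drop = FALSE]
  if (nrow(left)) left$end[nrow(left)] <- min(left$end[nrow(left)], s_bp - 1)
  left <- left[left$start <= left$end, , drop = FALSE]
  right <- tch[tch$end > e_bp, , drop = FALSE]
  if (nrow(right)) right$start[1] <- max(right$start[1], e_bp + 1)
  right <- right[right$start <= right$end, , drop = FALSE]
  mid <- source[source$chrom == ch & source$end >= s_bp &
                  source$start <= e_bp, , drop = FALSE]
  mid$start <- pmax(mid$start, s_bp)
  mid$end <- pmin(mid$end, e_bp)
  out <- rbind(keep, left, mid, right)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Simulate quartet site-pattern counts under the multispecies coalescent
#'
#' For the rooted quartet (((P2, P3), P1), outgroup) with internode time
#' \code{t} (coalescent units) between the two splits, each site is
#' independently concordant (AABB) with probability 1 - (2/3) exp(-t); the
#' discordant mass is split equally between ABBA and ABAB by coalescent
#' symmetry. Sites are drawn one by one from a single seeded uniform stream.
#'
#' @param internode_t internode time t >= 0 in coalescent units.
#' @param n_sites number of informative sites to draw.
#' @param seed integer seed.
#' @return list with \code{counts} (named AABB/ABBA/ABAB, summing to
#'   \code{n_sites}) and \code{patterns} (per-site character vector).
#' @export
simulate_quartet_sites <- function(internode_t, n_sites, seed) {
  if (internode_t < 0) stop("internode time must be non-negative")
  p <- 1 - (2 / 3) * exp(-internode_t)
  set.seed(seed)
  u <- stats::runif(n_sites)
  pat <- ifelse(u < p, "AABB", ifelse(u < p + (1 - p) / 2, "ABBA", "ABAB"))
  counts <- c(AABB = sum(pat == "AABB"), ABBA = sum(pat == "ABBA"),
              ABAB = sum(pat == "ABAB"))
  list(counts = counts, patterns = pat)
}

#' Simulate two-pulse admixture proportions for three ancestries
#'
#' Emulates a population where two ancestries mixed first and a third
#' arrived later: the ratio of the two first-pulse ancestries is constant
#' across individuals up to multiplicative (log-normal) noise \code{spread},
#' while the later ancestry's proportion varies independently.
#'
#' @param n_individuals number of individuals.
#' @param first_pair length-2 character subset of \code{labels}: the
#'   ancestries that admixed first.
#' @param spread standard deviation of the log first-pair ratio (0 = exactly
#'   constant).
#' @param seed integer seed.
#' @param labels the three ancestry labels (default A, B, C).
#' @param third_range range of the later ancestry's proportion (uniform).
#' @param ratio target first-pair ratio (default 1).
#' @return matrix (individuals x 3), rows summing to 1, columns named by
#'   \code{labels}.
#' @export
simulate_two_pulse_proportions <- function(n_individuals, first_pair, spread,
                                           seed, labels = c("A", "B", "C"),
                                           third_range = c(0.05, 0.5),
                                           ratio = 1) {
  if (spread < 0) stop("spread must be non-negative")
  stopifnot(length(first_pair) == 2, all(first_pair %in% labels))
  third <- setdiff(labels, first_pair)
  set.seed(seed)
  r <- ratio * exp(stats::rnorm(n_individuals, 0, spread))
  c_prop <- stats::runif(n_individuals, third_range[1], third_range[2])
  p1 <- (1 - c_prop) * r / (1 + r)
  p2 <- (1 - c_prop) / (1 + r)
  out <- matrix(0, n_individuals, 3, dimnames = list(NULL, labels))
  out[, first_pair[1]] <- p1
  out[, first_pair[2]] <- p2
  out[, third] <- c_prop
  out / rowSums(out)
}

#' Simulate a full ghost-ancestry cohort with planted IBD
#'
#' End-to-end scenario generator: three ancestral sources (an autochthonous
#' southern-African-like stratum, a Bantu-like stratum and a deeply
#' divergent ghost), four populations of which exactly one carries ghost
#' ancestry, and planted IBD segments within every population plus
#' cross-population segments sourced from the shared (non-ghost) ancestry
#' mosaic — so ghost-ancestry IBD is private to the ghost-bearing group, as
#' it would be for ancestry inherited from an unsampled source.
#'
#' @param seed integer seed.
#' @param n_sites sites in the panel (default 12000).
#' @param n_per_pop diploid individuals per population (default 8).
#' @param ghost_fraction ghost admixture proportion in the carrier group
#'   (default 0.15).
#' @param morgans total map length in Morgans (default 30).
#' @param generations generations since admixture (default 25).
#' @param n_cross cross-population planted segments (default 40).
#' @return a \code{synthetic_cohort}; populations are \code{Peri} (ghost
#'   carrier), \code{KxaJu}, \code{TuuTaa}, \code{BantuSW}; the metadata
#'   pools put each reference population in its own pool and \code{Peri} in
#'   \code{Unknown}.
#' @export
simulate_ghost_cohort <- function(seed, n_sites = 12000, n_per_pop = 8,
                                  ghost_fraction = 0.15, morgans = 30,
                                  generations = 25, n_cross = 40) {
  map <- synthetic_map(morgans = morgans)
  freqs <- simulate_frequencies(
    n_sites, c("SAf", "Bantu", "Ghost"), c(0.05, 0.05, 0.35),
    seed = seed, ghost = "Ghost")
  pops <- c("Peri", "KxaJu", "TuuTaa", "BantuSW")
  base_props <- rbind(
    Peri    = c(0.85 * (1 - ghost_fraction), 0.15 * (1 - ghost_fraction),
                ghost_fraction),
    KxaJu   = c(0.90, 0.10, 0),
    TuuTaa  = c(0.80, 0.20, 0),
    BantuSW = c(0.15, 0.85, 0))
  samples <- unlist(lapply(pops, function(p) paste0(p, "_", seq_len(n_per_pop))))
  proportions <- base_props[rep(pops, each = n_per_pop), , drop = FALSE]
  rownames(proportions) <- samples
  populations <- stats::setNames(rep(pops, each = n_per_pop), samples)
  cohort <- simulate_admixed_haplotypes(freqs, proportions, map,
                                        seed = seed + 1,
                                        generations = generations,
                                        populations = populations)
  # planted IBD: one segment per within-population individual pair,
  # plus cross-population segments sourced from the non-ghost member
  set.seed(seed + 2)
  within <- do.call(rbind, lapply(pops, function(p) {
    ids <- samples[populations == p]
    cmb <- utils::combn(ids, 2)
    data.frame(hap1 = hap_id(cmb[1, ], sample(1:2, ncol(cmb), TRUE)),
               hap2 = hap_id(cmb[2, ], sample(1:2, ncol(cmb), TRUE)))
  }))
  ref_samples <- samples[populations != "Peri"]
  cross <- data.frame(
    hap1 = hap_id(sample(ref_samples, n_cross, TRUE), sample(1:2, n_cross, TRUE)),
    hap2 = hap_id(sample(samples, n_cross, TRUE), sample(1:2, n_cross, TRUE)))
  cross <- cross[split_hap_id(cross$hap1)$sample !=
                   split_hap_id(cross$hap2)$sample, , drop = FALSE]
  pairs <- rbind(within, cross)
  lengths <- stats::runif(nrow(pairs), 2, 9)
  cohort <- plant_ibd(cohort, pairs, lengths, seed = seed + 3)
  cohort$metadata <- data.frame(
    sample = samples, population = unname(populations),
    pool = ifelse(populations == "Peri", "Unknown", unname(populations)))
  class(cohort$metadata) <- c("population_metadata", "data.frame")
  cohort
}
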