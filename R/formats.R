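#' Haploid genome identifier
#'
#' Haploid genomes are addressed throughout as \code{"<sample>|<hap>"} with
#' hap in \{1, 2\}; each haplotype is a first-class analysis unit.
#'
#' @param sample sample id(s).
#' @param hap haplotype index(es), 1 or 2.
#' @return character vector of haploid genome ids.
#' @export
hap_id <- function(sample, hap) paste(sample, hap, sep = "|")

split_hap_id <- function(id) {
  parts <- regmatches(id, regexpr("\\|[12]$", id))
  sample <- sub("\\|[12]$", "", id)
  list(sample = sample, hap = as.integer(sub("\\|", "", parts)))
}

## ---------------------------------------------------------------- IBD ----

#' Read refinedIBD-style IBD/HBD segments
#'
#' Parses the 9-column whitespace-delimited dialect (sample1, hap1, sample2,
#' hap2, chrom, start bp, end bp, LOD, length cM). Genetic lengths are always
#' recomputed from the supplied map — the stated column is advisory — and a
#' warning is raised for any row whose stated length differs from the
#' recomputed one by more than 0.1 cM.
#'
#' @param path path to the segment file.
#' @param map a \code{\link{genetic_map}} used to recompute lengths.
#' @return data.frame of class \code{ibd_segments} with columns
#'   \code{sample1}, \code{hap1}, \code{sample2}, \code{hap2}, \code{chrom},
#'   \code{start}, \code{end}, \code{lod}, \code{length_cm}.
#' @export
read_ibd_segments <- function(path, map) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(rows, length, 1L) != 9L)
  if (length(bad))
    stop("malformed IBD row at line ", bad[1], ": expected 9 columns, got ",
         length(rows[[bad[1]]]))
  m <- do.call(rbind, rows)
  seg <- data.frame(
    sample1 = m[, 1], hap1 = as.integer(m[, 2]),
    sample2 = m[, 3], hap2 = as.integer(m[, 4]),
    chrom = m[, 5], start = as.numeric(m[, 6]), end = as.numeric(m[, 7]),
    lod = as.numeric(m[, 8]), length_cm = as.numeric(m[, 9]),
    stringsAsFactors = FALSE)
  bad_hap <- which(!(seg$hap1 %in% 1:2) | !(seg$hap2 %in% 1:2))
  if (length(bad_hap))
    stop("IBD row at line ", bad_hap[1], ": haplotype index outside {1,2}")
  bad_int <- which(!(seg$start < seg$end))
  if (length(bad_int))
    stop("IBD row at line ", bad_int[1], ": start must be < end")
  stated <- seg$length_cm
  seg$length_cm <- vapply(seq_len(nrow(seg)), function(i)
    interval_cm(map, seg$chrom[i], seg$start[i], seg$end[i]), numeric(1))
  off <- which(is.finite(stated) & abs(stated - seg$length_cm) > 0.1)
  if (length(off))
    warning(length(off), " segment(s) with stated cM differing from the map ",
            "by > 0.1 cM (first at line ", off[1], "); map lengths used")
  class(seg) <- c("ibd_segments", "data.frame")
  seg
}

#' Write IBD segments in the 9-column refinedIBD dialect
#'
#' @param segments an \code{ibd_segments} data.frame.
#' @param path output path.
#' @export
write_ibd_segments <- function(segments, path) {
  out <- data.frame(segments$sample1, segments$hap1, segments$sample2,
                    segments$hap2, segments$chrom,
                    format(segments$start, scientific = FALSE, trim = TRUE),
                    format(segments$end, scientific = FALSE, trim = TRUE),
                    sprintf("%.2f", segments$lod),
                    sprintf("%.4f", segments$length_cm))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ----------------------------------------------- local ancestry (msp) ----

#' Construct a local-ancestry matrix
#'
#' Per-window, per-haploid-genome ancestry calls with posterior support.
#' Windows tile each chromosome, are non-overlapping and ordered. Calls are
#' indices into \code{ancestries}; \code{NA} encodes UNDEFINED (allowed only
#' after masking). Every call carries a posterior in [0, 1].
#'
#' @param ancestries character vector of ancestry labels (code order).
#' @param windows data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (bp, closed intervals).
#' @param calls integer matrix (windows x haploid genomes), values in
#'   \code{seq_along(ancestries)} or NA.
#' @param haplotypes character vector of haploid genome ids
#'   (\code{"sample|hap"}).
#' @param posteriors numeric matrix like \code{calls}; defaults to 1.
#' @return object of class \code{local_ancestry}.
#' @export
local_ancestry <- function(ancestries, windows, calls, haplotypes,
                           posteriors = NULL) {
  windows <- data.frame(chrom = as.character(windows$chrom),
                        start = as.numeric(windows$start),
                        end = as.numeric(windows$end))
  calls <- as.matrix(calls)
  if (is.null(posteriors)) posteriors <- matrix(1, nrow(calls), ncol(calls))
  stopifnot(nrow(calls) == nrow(windows), ncol(calls) == length(haplotypes),
            all(dim(posteriors) == dim(calls)))
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    if (is.unsorted(w$start, strictly = TRUE))
      stop("local ancestry windows not ordered on chromosome '", ch, "'")
    if (any(w$start[-1] <= w$end[-nrow(w)]))
      stop("overlapping local ancestry windows on chromosome '", ch, "'")
  }
  ok <- is.na(calls) | (calls >= 1 & calls <= length(ancestries))
  if (!all(ok)) stop("ancestry call outside declared code range")
  colnames(calls) <- haplotypes
  structure(list(ancestries = ancestries, windows = windows, calls = calls,
                 posteriors = posteriors, haplotypes = haplotypes),
            class = "local_ancestry")
}

#' Read RFMix v2 msp.tsv local-ancestry calls
#'
#' Line 1 declares the code map (\code{#Subpopulation order/codes: X=0 ...});
#' line 2 is the window header, followed by one row per window with two
#' call columns per sample. Code \code{-1} is accepted as UNDEFINED.
#' Posteriors are set to 1 (the msp dialect does not carry them); assign a
#' posterior matrix separately if available.
#'
#' @param path path to the msp.tsv file.
#' @return a \code{\link{local_ancestry}} object.
#' @export
read_local_ancestry <- function(path) {
  lines <- readLines(path)
  if (!grepl("^#Subpopulation order/codes:", lines[1]))
    stop("msp file must start with '#Subpopulation order/codes:'")
  codes_str <- sub("^#Subpopulation order/codes:\\s*", "", lines[1])
  pairs <- strsplit(strsplit(trimws(codes_str), "[ \t]+")[[1]], "=")
  labels <- vapply(pairs, `[`, "", 1)
  codes <- as.integer(vapply(pairs, `[`, "", 2))
  labels <- labels[order(codes)]
  header <- strsplit(sub("^#", "", lines[2]), "\t")[[1]]
  samp_cols <- header[-(1:6)]
  samples <- sub("\\.[01]$", "", samp_cols)
  hapno <- as.integer(sub("^.*\\.", "", samp_cols)) + 1L
  haps <- hap_id(samples, hapno)
  body <- utils::read.table(text = lines[-(1:2)], sep = "\t", header = FALSE)
  windows <- data.frame(chrom = as.character(body[[1]]),
                        start = as.numeric(body[[2]]),
                        end = as.numeric(body[[3]]))
  calls <- as.matrix(body[, -(1:6), drop = FALSE])
  undeclared <- setdiff(unique(calls[!is.na(calls)]),
                        c(sort(codes), -1L))
  if (length(undeclared))
    stop("ancestry code ", undeclared[1], " in body not declared in header")
  calls[calls == -1L] <- NA_integer_
  calls <- calls + 1L   # 0-based file codes -> 1-based indices
  local_ancestry(labels, windows, calls, haps)
}

#' Write local-ancestry calls in the msp.tsv dialect
#'
#' UNDEFINED calls are written as code \code{-1} (an extension of the RFMix
#' dialect; RFMix itself never emits undefined windows).
#'
#' @param la a \code{\link{local_ancestry}} object.
#' @param path output path.
#' @export
write_local_ancestry <- function(la, path) {
  codes <- paste(la$ancestries, seq_along(la$ancestries) - 1L, sep = "=")
  sh <- split_hap_id(la$haplotypes)
  samp_cols <- paste(sh$sample, sh$hap - 1L, sep = ".")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#Subpopulation order/codes:", paste(codes, collapse = " ")),
             con)
  writeLines(paste0("#", paste(c("chm", "spos", "epos", "sgpos", "egpos",
                                 "n snps", samp_cols), collapse = "\t")), con)
  calls <- la$calls - 1L
  calls[is.na(calls)] <- -1L
  body <- cbind(la$windows$chrom,
                format(la$windows$start, scientific = FALSE, trim = TRUE),
                format(la$windows$end, scientific = FALSE, trim = TRUE),
                "0", "0", "0", calls)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Look up ancestry calls for one haploid genome at physical positions
#'
#' @param la a \code{\link{local_ancestry}} object.
#' @param hap haploid genome id (\code{"sample|hap"}).
#' @param chrom chromosome label.
#' @param position numeric vector of bp positions.
#' @return integer vector of ancestry indices (NA where undefined or
#'   uncovered).
#' @export
ancestry_at <- function(la, hap, chrom, position) {
  j <- match(hap, la$haplotypes)
  if (is.na(j)) stop("haploid genome '", hap, "' not in local ancestry matrix")
  sel <- which(la$windows$chrom == chrom)
  if (!length(sel)) return(rep(NA_integer_, length(position)))
  w <- la$windows[sel, , drop = FALSE]
  idx <- findInterval(position, w$start)
  out <- rep(NA_integer_, length(position))
  hit <- idx >= 1 & position <= w$end[pmax(idx, 1L)]
  out[hit] <- la$calls[sel[idx[hit]], j]
  out
}

## -------------------------------------------------------- VCF panels ----

#' Construct a haplotype panel
#'
#' Phased biallelic haplotypes with optional per-site outgroup
#' (chimpanzee) alleles. Rows of \code{alleles} are haploid genomes, columns
#' sites; values 0 (ref), 1 (alt) or NA (MISSING — a first-class state,
#' distinct from UNDEFINED ancestry).
#'
#' @param alleles integer matrix (haploid genomes x sites).
#' @param sites data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt} and optionally \code{outgroup} (0/1/NA).
#' @param haplotypes character vector of haploid genome ids.
#' @param populations named character vector, sample id -> population.
#' @return object of class \code{haplotype_panel}.
#' @export
haplotype_panel <- function(alleles, sites, haplotypes, populations) {
  alleles <- as.matrix(alleles)
  stopifnot(nrow(alleles) == length(haplotypes), ncol(alleles) == nrow(sites))
  if (is.null(sites$outgroup)) sites$outgroup <- NA_integer_
  rownames(alleles) <- haplotypes
  samples <- split_hap_id(haplotypes)$sample
  miss <- setdiff(unique(samples), names(populations))
  if (length(miss))
    warning("sample(s) absent from metadata: ", paste(miss, collapse = ", "))
  structure(list(alleles = alleles, sites = sites, haplotypes = haplotypes,
                 samples = samples, populations = populations),
            class = "haplotype_panel")
}

#' Population label of each haploid genome in a panel
#' @param panel a \code{\link{haplotype_panel}}.
#' @return character vector aligned with \code{panel$haplotypes}.
#' @export
hap_populations <- function(panel) {
  unname(panel$populations[panel$samples])
}

#' Read phased haplotypes from a VCF
#'
#' Sites must be biallelic SNVs and genotypes phased (\code{|}); an unphased
#' genotype or a multiallelic site is an error. \code{.} alleles become
#' MISSING. An optional VCF sample may be designated as the outgroup
#' (chimpanzee): its first haplotype supplies the per-site outgroup allele
#' and it is dropped from the panel.
#'
#' @param path path to an (uncompressed or bgzipped) VCF.
#' @param metadata optional metadata data.frame from
#'   \code{\link{read_metadata}}; supplies the population map.
#' @param outgroup_sample optional VCF sample name holding outgroup alleles.
#' @return a \code{\link{haplotype_panel}}.
#' @export
read_haplotypes <- function(path, metadata = NULL, outgroup_sample = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))   # single-site VCF
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi))
    stop("multiallelic site at ", fix[which(multi)[1], "CHROM"], ":",
         fix[which(multi)[1], "POS"])
  gt <- vcfR::extract.gt(v, element = "GT")
  gt[is.na(gt) | gt == "." | gt == "./."] <- ".|."   # missing may be unphased
  if (any(grepl("[0-9]/[0-9]", gt), na.rm = TRUE))
    stop("unphased genotype encountered; panel requires phased (|) genotypes")
  sites <- data.frame(chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  samples <- colnames(gt)
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  to_int <- function(x) { y <- suppressWarnings(as.integer(x)); y }
  h1 <- to_int(a1); h2 <- to_int(a2)
  dim(h1) <- dim(gt); dim(h2) <- dim(gt)
  outg <- rep(NA_integer_, nrow(sites))
  if (!is.null(outgroup_sample)) {
    j <- match(outgroup_sample, samples)
    if (is.na(j)) stop("outgroup sample '", outgroup_sample, "' not in VCF")
    outg <- h1[, j]
    h1 <- h1[, -j, drop = FALSE]; h2 <- h2[, -j, drop = FALSE]
    samples <- samples[-j]
  }
  sites$outgroup <- outg
  haps <- as.vector(rbind(hap_id(samples, 1L), hap_id(samples, 2L)))
  alleles <- matrix(NA_integer_, length(haps), nrow(sites))
  alleles[seq(1, length(haps), 2), ] <- t(h1)
  alleles[seq(2, length(haps), 2), ] <- t(h2)
  pops <- if (!is.null(metadata)) {
    stats::setNames(metadata$population, metadata$sample)
  } else stats::setNames(rep("unknown", length(samples)), samples)
  haplotype_panel(alleles, sites, haps, pops)
}

#' Write a haplotype panel as an uncompressed phased VCF
#'
#' MISSING alleles are written as \code{.}; an outgroup column named
#' \code{Chimp} is appended when the panel carries outgroup alleles.
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @param path output path (plain-text VCF).
#' @param outgroup_sample name for the outgroup column (NULL to omit).
#' @export
write_haplotypes <- function(panel, path, outgroup_sample = "Chimp") {
  samples <- unique(panel$samples)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  has_outg <- !is.null(outgroup_sample) && any(!is.na(panel$sites$outgroup))
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples, if (has_outg) outgroup_sample)
  writeLines(paste(cols, collapse = "\t"), con)
  al <- panel$alleles
  al_chr <- matrix(as.character(al), nrow(al), ncol(al))
  al_chr[is.na(al_chr)] <- "."
  i1 <- match(hap_id(samples, 1L), panel$haplotypes)
  i2 <- match(hap_id(samples, 2L), panel$haplotypes)
  gts <- matrix(paste(al_chr[i1, , drop = FALSE], al_chr[i2, , drop = FALSE],
                      sep = "|"),
                nrow = length(samples))
  body <- cbind(panel$sites$chrom,
                format(panel$sites$pos, scientific = FALSE, trim = TRUE),
                ".", panel$sites$ref, panel$sites$alt, ".", "PASS", ".", "GT",
                t(gts))
  if (has_outg) {
    og <- as.character(panel$sites$outgroup)
    og[is.na(og)] <- "."
    body <- cbind(body, paste(og, og, sep = "|"))
  }
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## --------------------------------------------- metadata, chunkcounts ----

#' Read population metadata (sample, population, pool)
#'
#' Tab-separated with a header; columns \code{sample}, \code{population} and
#' optionally \code{pool}. Every sample must map to exactly one population.
#'
#' @param path path to the TSV file.
#' @return data.frame of class \code{population_metadata}.
#' @export
read_metadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "population") %in% names(md)))
    stop("metadata requires 'sample' and 'population' columns")
  if (anyDuplicated(md$sample))
    stop("duplicate sample in metadata: ",
         md$sample[which(duplicated(md$sample))[1]])
  if (is.null(md$pool)) md$pool <- md$population
  class(md) <- c("population_metadata", "data.frame")
  md
}

#' Write population metadata
#' @param metadata a \code{population_metadata} data.frame.
#' @param path output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a CHROMOPAINTER chunkcounts coancestry matrix as copy profiles
#'
#' The chunkcounts dialect is a labelled (possibly rectangular) matrix:
#' header row of donor populations, one row per recipient with its average
#' chunk counts. Returns raw counts plus row-normalised profiles.
#'
#' @param path path to the chunkcounts file.
#' @return object of class \code{copy_profiles}: list with \code{counts}
#'   (recipients x donors matrix) and \code{normalized} (rows sum to 1).
#' @export
read_chunkcounts <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  m <- utils::read.table(text = lines, header = TRUE, row.names = 1,
                         check.names = FALSE)
  counts <- as.matrix(m)
  if (any(counts < 0)) stop("negative chunk count in ", path)
  copy_profiles(counts)
}

#' Construct copy profiles from a chunk-count matrix
#'
#' @param counts numeric matrix, recipients x donors, non-negative.
#' @return a \code{copy_profiles} object.
#' @export
copy_profiles <- function(counts) {
  counts <- as.matrix(counts)
  rs <- rowSums(counts)
  normalized <- counts / ifelse(rs > 0, rs, 1)
  structure(list(counts = counts, normalized = normalized),
            class = "copy_profiles")
}
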