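#' Genetic map: physical to genetic coordinate conversion
#'
#' A genetic map is a per-chromosome table of anchor points (position in bp,
#' cumulative genetic position in cM). Positions must be strictly increasing
#' and genetic positions non-decreasing within each chromosome, with at least
#' two anchor points per chromosome. All interval lengths used downstream
#' (IBD segment lengths, ancestry tract lengths) are recomputed from the map
#' so that interval arithmetic has a single source of truth.
#'
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of physical positions (bp, 1-based).
#' @param cm numeric vector of genetic positions (cM).
#' @return An object of class \code{genetic_map}: a data.frame with columns
#'   \code{chrom}, \code{pos}, \code{cm}.
#' @export
genetic_map <- function(chrom, pos, cm) {
  gm <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   cm = as.numeric(cm), stringsAsFactors = FALSE)
  rownames(gm) <- NULL
  # validated in given order: a non-monotone map is reported, never
  # silently reordered
  validate_genetic_map(gm)
  class(gm) <- c("genetic_map", "data.frame")
  gm
}

validate_genetic_map <- function(gm) {
  for (ch in unique(gm$chrom)) {
    sub <- gm[gm$chrom == ch, , drop = FALSE]
    if (nrow(sub) < 2)
      stop("genetic map: chromosome '", ch, "' has fewer than 2 points")
    dp <- diff(sub$pos)
    if (any(dp <= 0)) {
      i <- which(dp <= 0)[1]
      stop("genetic map: non-increasing position on chromosome '", ch,
           "' at point ", i + 1, " (pos ", sub$pos[i + 1], ")")
    }
    dc <- diff(sub$cm)
    if (any(dc < 0)) {
      i <- which(dc < 0)[1]
      stop("genetic map: decreasing genetic position on chromosome '", ch,
           "' at point ", i + 1, " (cM ", sub$cm[i + 1], ")")
    }
  }
  invisible(gm)
}

#' Read a genetic map from a text file
#'
#' Accepts the 3-column HapMap-style dialect (chrom, position bp, cM) or the
#' 4-column PLINK .map dialect (chrom, id, cM, bp). Columns are
#' whitespace-delimited; a header line is tolerated and skipped when the
#' position column is non-numeric.
#'
#' @param path path to the map file.
#' @return a \code{\link{genetic_map}}.
#' @export
read_genetic_map <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  # positions live in column 2 (3-col dialect) or column 4 (PLINK .map);
  # a non-numeric entry there marks a header line to skip
  pos_col <- if (ncol(raw) >= 4) 4L else 2L
  if (nrow(raw) > 0 &&
      is.na(suppressWarnings(as.numeric(raw[1, pos_col])))) {
    raw <- raw[-1, , drop = FALSE]
    raw[] <- lapply(raw, function(x) utils::type.convert(x, as.is = TRUE))
  }
  if (ncol(raw) == 3) {
    gm <- genetic_map(raw[[1]], raw[[2]], raw[[3]])
  } else if (ncol(raw) >= 4) {
    # PLINK .map: chrom, snp id, cM, bp
    gm <- genetic_map(raw[[1]], raw[[4]], raw[[3]])
  } else {
    stop("genetic map file must have 3 (chrom, bp, cM) or 4 (PLINK .map) columns")
  }
  gm
}

#' Write a genetic map as a 3-column text file
#'
#' cM values are written to 4 decimal places; \code{read_genetic_map} on the
#' output reproduces the map at that precision.
#'
#' @param map a \code{\link{genetic_map}}.
#' @param path output path.
#' @export
write_genetic_map <- function(map, path) {
  out <- data.frame(chrom = map$chrom, pos = format(map$pos, scientific = FALSE,
                                                    trim = TRUE),
                    cm = sprintf("%.4f", map$cm))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Interpolate genetic position (cM) at physical positions
#'
#' Linear interpolation between the flanking anchor points. Positions before
#' the first (after the last) anchor clamp to the terminal genetic position:
#' the map asserts zero recombination beyond its ends rather than
#' extrapolating.
#'
#' @param map a \code{\link{genetic_map}}.
#' @param chrom single chromosome label.
#' @param position numeric vector of physical positions (bp).
#' @return numeric vector of genetic positions (cM).
#' @export
interpolate_cm <- function(map, chrom, position) {
  sub <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("chromosome '", chrom, "' not present in genetic map")
  stats::approx(sub$pos, sub$cm, xout = position, rule = 2, ties = "ordered")$y
}

#' Inverse interpolation: genetic position (cM) to physical position (bp)
#'
#' Used by the simulators to place tract and segment breakpoints drawn in
#' genetic distance. Strictly increasing cM is required over the queried
#' range; plateaus are resolved to their left edge.
#'
#' @inheritParams interpolate_cm
#' @param cm numeric vector of genetic positions.
#' @return numeric vector of physical positions (bp, rounded to integers).
#' @export
interpolate_bp <- function(map, chrom, cm) {
  sub <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("chromosome '", chrom, "' not present in genetic map")
  round(stats::approx(sub$cm, sub$pos, xout = cm, rule = 2, ties = "min")$y)
}

#' Genetic length of closed physical intervals
#'
#' @inheritParams interpolate_cm
#' @param start,end interval endpoints in bp (closed, 1-based).
#' @return numeric vector of lengths in cM.
#' @export
interval_cm <- function(map, chrom, start, end) {
  interpolate_cm(map, chrom, end) - interpolate_cm(map, chrom, start)
}

#' Chromosome extents of a genetic map
#'
#' @param map a \code{\link{genetic_map}}.
#' @return data.frame with one row per chromosome: \code{chrom},
#'   \code{start}, \code{end} (bp), \code{cm_start}, \code{cm_end}.
#' @export
map_extents <- function(map) {
  do.call(rbind, lapply(split(map, map$chrom), function(sub) {
    data.frame(chrom = sub$chrom[1], start = min(sub$pos), end = max(sub$pos),
               cm_start = min(sub$cm), cm_end = max(sub$cm))
  }))
}
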