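#' Admixture History Graph ordering of three ancestry pulses
#'
#' In a population where ancestries A and B admixed first and C arrived
#' later, the proportions of A and B each covary with C across individuals,
#' but the ratio A/B is independent of C. For each of the three
#' configurations the sample covariance (n - 1 denominator) of the pair
#' ratio with the third ancestry is estimated across individuals; the
#' configuration with the smallest absolute covariance identifies the first
#' pair. Individuals with a zero denominator ancestry are excluded from
#' that configuration only (and counted). A margin below 1e-12 between the
#' smallest and second-smallest absolute covariance is reported as
#' unresolved rather than picking an arbitrary winner.
#'
#' @param proportions matrix or data.frame (individuals x 3 ancestries),
#'   rows summing to 1 (tolerance 1e-6); column names are the ancestry
#'   labels (default A, B, C when absent).
#' @return list of class \code{ahg_result}: \code{covariances} (named by
#'   configuration \code{"A/B~C"} etc.), \code{first_pair} (character(2) or
#'   NA when unresolved), \code{unresolved}, \code{margin},
#'   \code{excluded_individuals} (per configuration).
#' @export
ahg_order <- function(proportions) {
  p <- as.matrix(proportions)
  if (ncol(p) != 3) stop("exactly three ancestries required")
  if (is.null(colnames(p))) colnames(p) <- c("A", "B", "C")
  if (any(abs(rowSums(p) - 1) > 1e-6))
    stop("ancestry proportions must sum to 1 per individual (tol 1e-6)")
  labs <- colnames(p)
  configs <- list(c(1, 2, 3), c(1, 3, 2), c(2, 3, 1))
  covs <- numeric(3); excl <- integer(3); names(covs) <- names(excl) <-
    vapply(configs, function(cf)
      paste0(labs[cf[1]], "/", labs[cf[2]], "~", labs[cf[3]]), "")
  for (k in seq_along(configs)) {
    cf <- configs[[k]]
    ok <- p[, cf[2]] > 0
    excl[k] <- sum(!ok)
    if (sum(ok) < 3)
      stop("fewer than 3 usable individuals in configuration ", names(covs)[k])
    covs[k] <- stats::cov(p[ok, cf[1]] / p[ok, cf[2]], p[ok, cf[3]])
  }
  ord <- order(abs(covs))
  margin <- abs(covs)[ord[2]] - abs(covs)[ord[1]]
  unresolved <- margin < 1e-12
  first_pair <- if (unresolved) c(NA_character_, NA_character_) else
    labs[configs[[ord[1]]][1:2]]
  structure(list(covariances = covs, first_pair = first_pair,
                 unresolved = unresolved, margin = margin,
                 excluded_individuals = excl),
            class = "ahg_result")
}
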