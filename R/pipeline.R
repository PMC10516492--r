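#' Default configuration for the end-to-end synthetic pipeline
#'
#' Every stochastic stage carries an explicit seed — seeds are mandatory and
#' never defaulted silently by \code{\link{run_pipeline}}; this constructor
#' derives one per stage from a single base seed.
#'
#' @param base_seed integer base seed.
#' @param out_dir output directory.
#' @return nested configuration list.
#' @export
pipeline_config <- function(base_seed, out_dir) {
  list(
    out_dir = out_dir,
    seeds = list(simulate = base_seed, concordance = base_seed + 101,
                 divergence = base_seed + 202, ahg = base_seed + 303),
    simulate = list(n_sites = 12000, n_per_pop = 8, ghost_fraction = 0.15,
                    morgans = 30, generations = 25),
    mask = list(target = "Ghost", posterior_threshold = 1.0),
    asibd = list(gap_merge_cm = 0.6, inconsistency_threshold = 0.25,
                 length_bins = c(1, 5, 10)),
    concordance = list(p1 = "Peri", p2 = "KxaJu", p3 = "TuuTaa",
                       n_blocks = 50),
    divergence = list(ingroup = "KxaJu", outgroup = "Peri",
                      ne_list = c(1000, 5000, 10000, 20000), gen_time = 29),
    ahg = list(n_individuals = 200, first_pair = c("A", "B"), spread = 0.05)
  )
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic ghost-ancestry pipeline
#'
#' Executes simulate, mask, asibd, concordance, divergence and ahg in
#' dependency order, writing TSV/VCF/Newick artifacts and a manifest
#' (stage, seed, outputs, md5 checksums) to the output directory. The run
#' is fully deterministic given the config; a missing stage seed is a
#' validation error raised before any stage executes.
#'
#' @param config a configuration list (see \code{\link{pipeline_config}})
#'   or the path to a YAML file with the same structure.
#' @return (invisibly) a list with the per-stage results and the manifest
#'   data.frame.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  needed <- c("simulate", "concordance", "divergence", "ahg")
  miss <- needed[!vapply(needed, function(s)
    !is.null(config$seeds[[s]]), logical(1))]
  if (length(miss))
    stop("config validation: missing seed(s) for stage(s): ",
         paste(miss, collapse = ", "))
  if (is.null(config$out_dir)) stop("config validation: out_dir missing")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  op <- function(...) file.path(config$out_dir, paste0(...))

  ## 1. simulate
  cohort <- stage("simulate", do.call(simulate_ghost_cohort,
    c(list(seed = config$seeds$simulate), config$simulate)))
  outputs$simulate <- c(
    write_haplotypes(cohort$panel, op("panel.vcf")),
    write_local_ancestry(cohort$la, op("local_ancestry.msp.tsv")),
    write_ibd_segments(cohort$truth$planted_ibd, op("planted.ibd")),
    write_genetic_map(cohort$map, op("genetic.map")),
    write_metadata(cohort$metadata, op("metadata.tsv")))

  ## 2. mask
  masked <- stage("mask", mask_by_ancestry(
    cohort$panel, cohort$la, config$mask$target,
    config$mask$posterior_threshold))
  outputs$mask <- write_tsv(
    data.frame(haplotype = names(masked$missing_fraction),
               missing_fraction = round(masked$missing_fraction, 6)),
    op("mask_missingness.tsv"))

  ## 3. asibd
  asibd_res <- stage("asibd", {
    dec <- decompose_ibd_ancestry(cohort$truth$planted_ibd, cohort$la,
                                  cohort$map,
                                  config$asibd$inconsistency_threshold)
    agg <- aggregate_asibd(dec, cohort$metadata, config$asibd$length_bins)
    pops <- sort(unique(cohort$metadata$population))
    pooled <- t(vapply(pops, function(p)
      pool_sharing(agg, cohort$metadata, p, config$mask$target)$proportions,
      numeric(length(unique(cohort$metadata$pool)))))
    tree <- upgma_tree(pooled, profiles = TRUE)
    list(decomposed = dec, aggregated = agg, pooled = pooled, tree = tree)
  })
  outputs$asibd <- c(
    write_tsv(format(asibd_res$aggregated, digits = 8), op("asibd_summary.tsv")),
    write_tsv(data.frame(population = rownames(asibd_res$pooled),
                         round(asibd_res$pooled, 6)),
              op("asibd_pooled.tsv")),
    {ape::write.tree(asibd_res$tree, op("asibd_upgma.nwk")); op("asibd_upgma.nwk")})

  ## 4. concordance
  conc <- stage("concordance", {
    cc <- count_quartet_patterns(cohort$panel, config$concordance$p1,
                                 config$concordance$p2, config$concordance$p3,
                                 seed = config$seeds$concordance,
                                 n_blocks = config$concordance$n_blocks)
    concordance_test(cc)
  })
  outputs$concordance <- write_tsv(
    data.frame(n_conc = conc$counts$n_conc, n_abba = conc$counts$n_abba,
               n_abab = conc$counts$n_abab, C = round(conc$C, 6),
               se_jack = round(conc$se_jack, 6), z = round(conc$z, 4)),
    op("concordance.tsv"))

  ## 5. divergence
  div <- stage("divergence", estimate_divergence(
    cohort$panel, config$divergence$ingroup, config$divergence$outgroup,
    seed = config$seeds$divergence, ne_list = config$divergence$ne_list,
    gen_time = config$divergence$gen_time))
  outputs$divergence <- write_tsv(
    data.frame(p_conc = round(div$p_conc, 6), t_hat = round(div$t_hat, 6),
               ci_low = round(div$ci[1], 6), ci_high = round(div$ci[2], 6),
               ne = as.numeric(names(div$years)),
               years = round(div$years, 1)),
    op("divergence.tsv"))

  ## 6. ahg
  ahg_res <- stage("ahg", {
    props <- simulate_two_pulse_proportions(
      config$ahg$n_individuals, config$ahg$first_pair, config$ahg$spread,
      seed = config$seeds$ahg)
    ahg_order(props)
  })
  outputs$ahg <- write_tsv(
    data.frame(configuration = names(ahg_res$covariances),
               covariance = format(ahg_res$covariances, digits = 8),
               winner = paste(ahg_res$first_pair, collapse = "+"),
               unresolved = ahg_res$unresolved),
    op("ahg.tsv"))

  manifest <- do.call(rbind, lapply(names(outputs), function(s) {
    files <- outputs[[s]]
    data.frame(stage = s,
               seed = if (!is.null(config$seeds[[s]]))
                 config$seeds[[s]] else NA,
               file = basename(files), md5 = unname(tools::md5sum(files)))
  }))
  write_tsv(manifest, op("manifest.tsv"))
  invisible(list(cohort = cohort, masked = masked, asibd = asibd_res,
                 concordance = conc, divergence = div, ahg = ahg_res,
                 manifest = manifest))
}
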