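#' Run the whole mapping pipeline on one simulated study
#'
#' Chains every stage on a single simulated dataset: study generation
#' ([scenario_study()]), phenotype genetics (variance components,
#' heritabilities, distribution descriptors, depth rate-of-change), the
#' per-environment CIM scan with permutation thresholds and peak calling,
#' bulked-segregant index mapping with a simulated confidence band, and
#' cQTL integration of the QTL and BSA intervals.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; when given, stage outputs are
#'   written (`qtl_peaks.tsv`, `bsa_windows.tsv`, `bsa_regions.tsv`,
#'   `bsa_regions.bed`, `cqtl.json`) next to the simulated inputs.
#' @param n_perm Permutations for the genome-wide LOD threshold.
#' @param alpha Genome-wide type-I error rate.
#' @param step_cM Scan grid spacing.
#' @param window_cM CIM cofactor exclusion window.
#' @param window_bp,step_bp,min_sites Sliding-window parameters of the BSA
#'   stage.
#' @param ci_level Confidence level of the simulated null band.
#' @param max_gap_bp Evidence-merging gap for cQTL definition.
#' @return A list with `sim`, `phenostats`, `qtl` (per environment:
#'   `threshold`, `curve`, `peaks`), `bsa` (`track`, `windows`, `regions`),
#'   and `cqtl` (list of `cqtl_report`s).
#' @export
run_pipeline <- function(config = sim_config(), dir = NULL,
                         n_perm = 200, alpha = 0.05,
                         step_cM = 1, window_cM = 10,
                         window_bp = 1e6, step_bp = 2e5, min_sites = 10,
                         ci_level = 0.99, max_gap_bp = 2e6) {
  sim <- scenario_study(config, dir)

  vc <- estimate_variance_components(sim$phenotypes)
  envs <- config$environments
  em <- vapply(envs, function(e) mean(family_means(sim$phenotypes, e)), 0)
  phen <- list(
    variance_components = vc,
    H_B2 = broad_sense_heritability(vc),
    H_GE2 = ge_heritability(vc),
    env_means = em,
    rate_of_change = if (length(envs) > 1)
      stats::setNames(rate_of_change(em[[1]], em[-1]),
                      envs[-1]) else NULL,
    distributions = lapply(stats::setNames(envs, envs), function(e)
      describe_distribution(family_means(sim$phenotypes, e))))

  gp <- genotype_probabilities(sim$map, sim$genotypes, step_cM,
                               config$map_function)
  qtl <- lapply(stats::setNames(envs, envs), function(e) {
    y <- family_means(sim$phenotypes, e)
    cof <- select_cofactors(gp, y)
    thr <- permutation_threshold(gp, y, cof, n_perm = n_perm,
                                 alpha = alpha, window_cM = window_cM)
    curve <- cim_scan(gp, y, cof, window_cM = window_cM)
    peaks <- call_qtl_peaks(curve, thr, prefix = "qMES")
    list(threshold = thr, cofactors = cof, curve = curve, peaks = peaks)
  })

  sites <- filter_informative_sites(sim$pools)
  ci <- simulate_null_ci(bulk_size = config$bulk_size, level = ci_level)
  track <- site_ci(index_track(sites), ci)
  bsa <- lapply(c(SNP = "SNP", InDel = "InDel"), function(cl) {
    tr <- track[track$vclass == cl, ]
    win <- sliding_window(tr, window_bp, step_bp, min_sites)
    regs <- call_linked_regions(win, tr,
                                label_prefix = paste0("BSA-", cl))
    list(windows = win, regions = regs)
  })
  bsa_regions <- do.call(rbind, lapply(bsa, `[[`, "regions"))
  rownames(bsa_regions) <- NULL

  qtl_iv <- list()
  for (e in envs) {
    pk <- qtl[[e]]$peaks
    for (i in seq_len(nrow(pk))) {
      reg <- qtl_physical_interval(pk[i, ], sim$map)
      reg$source <- paste0(pk$qtl[i], "@", e)
      reg$pve <- pk$pve[i]
      qtl_iv[[length(qtl_iv) + 1L]] <- evidence_intervals(reg, type = "QTL")
    }
  }
  cqtls <- list()
  if (length(qtl_iv) > 0 || nrow(bsa_regions) > 0) {
    ev <- do.call(rbind, c(qtl_iv,
                           if (nrow(bsa_regions) > 0)
                             list(evidence_intervals(bsa_regions,
                                                     type = "BSA"))))
    cl <- merge_evidence(ev, max_gap_bp)
    for (k in unique(cl$cluster)) {
      rep_k <- define_cqtl(cl[cl$cluster == k, ],
                           name = sprintf("cQ%d", k))
      if (!is.null(rep_k)) cqtls[[rep_k$name]] <- rep_k
    }
  }

  res <- list(sim = sim, phenostats = phen, qtl = qtl,
              bsa = c(bsa, list(track = track, regions = bsa_regions)),
              cqtl = cqtls)
  if (!is.null(dir)) {
    all_peaks <- do.call(rbind, lapply(envs, function(e) {
      pk <- qtl[[e]]$peaks
      if (nrow(pk) > 0) cbind(environment = e, pk) else NULL
    }))
    if (!is.null(all_peaks))
      utils::write.table(all_peaks, file.path(dir, "qtl_peaks.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    win_all <- do.call(rbind, lapply(names(bsa), function(cl)
      cbind(vclass = cl, bsa[[cl]]$windows)))
    utils::write.table(win_all, file.path(dir, "bsa_windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(bsa_regions, file.path(dir, "bsa_regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_regions_bed(bsa_regions, file.path(dir, "bsa_regions.bed"))
    jsonlite::write_json(
      lapply(cqtls, function(x) x[c("name", "chromosome", "start_bp",
                                    "end_bp", "length_mb", "pve_total")]),
      file.path(dir, "cqtl.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  res
}

#' Export regions as BED
#'
#' Converts the package's 1-based inclusive region coordinates to BED's
#' 0-based half-open convention.
#'
#' @param regions A `genomic_regions` data frame.
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chromosome,
                    start = regions$start_bp - 1L,
                    end = regions$end_bp,
                    name = if (!is.null(regions$region)) regions$region
                           else sprintf("region%d", seq_len(nrow(regions))))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
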