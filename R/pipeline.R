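# End-to-end driver binding the stages together, plus the run manifest.
# The exported functions are the package's command surface: a full run is
# simulate_triploid() |> run_pipeline() (or run_pipeline(config) directly).

#' Run the full homoeolog-expression-bias pipeline on simulated data
#'
#' Simulates a triploid genome (unless `sim` is supplied), builds the allele
#' partition from the hit table, computes TPM, filters expressed triads,
#' classifies bias per tissue and combined, computes triad Ka/Ks by group,
#' detects telomeres/centromere candidates/NLR clusters, and returns a
#' combined report. When `out_dir` is given all tables and a run manifest
#' are written there.
#'
#' @param config A [sim_config()].
#' @param sim Optional pre-computed [simulate_triploid()] output.
#' @param counts Optional pre-computed [simulate_expression()] counts.
#' @param out_dir Optional output directory.
#' @param min_identity,min_coverage Pairing thresholds for [best_hits()].
#' @param max_gap,min_loci NLR clustering parameters for [cluster_nlr()].
#' @return A list of class `triadbias_report` with elements `partition`,
#'   `assignments`, `group_summary`, `kaks`, `kaks_groups`, `t2t`,
#'   `centromeres`, `nlr_clusters`, `density` and `truth`.
#' @export
run_pipeline <- function(config = sim_config(), sim = NULL, counts = NULL,
                         out_dir = NULL, min_identity = 60,
                         min_coverage = 0.5, max_gap = 200000L,
                         min_loci = 5L) {
  if (is.null(sim)) sim <- simulate_triploid(config)
  if (is.null(counts)) counts <- simulate_expression(sim, config)

  # triads from the hit table
  best <- best_hits(sim$hits, sim$gene_map, min_identity, min_coverage)
  pairs <- reciprocal_pairs(best)
  partition <- build_partition(pairs, sim$gene_map)

  # expression: TPM -> expressed triads -> classification
  tpm <- compute_tpm(counts)
  tpm_tis <- tpm_by_tissue(tpm)
  te <- triad_tpm(tpm_tis, partition$triads)
  filt <- filter_expressed(te)
  assignments <- filt$triad_expr |>
    combine_tissues() |>
    standardize_triads() |>
    dplyr::filter(.data$defined) |>
    classify_bias()
  group_summary <- summarize_groups(assignments)

  # Ka/Ks per triad and per bias group (combined-tissue assignment)
  kaks <- triad_kaks(partition$triads, sim$cds)
  combined_assign <- dplyr::filter(assignments, .data$tissue == "combined")
  kaks_groups <- kaks_by_group(kaks, combined_assign)

  # genome features
  telomeres <- purrr::map_dfr(names(sim$genomes), function(hap) {
    dplyr::mutate(find_telomeres(sim$genomes[[hap]]), haplotype = hap,
                  .before = 1)
  })
  t2t <- purrr::map_dfr(names(sim$genomes), function(hap) {
    cl <- classify_t2t(dplyr::filter(telomeres, .data$haplotype == hap),
                       sim$genomes[[hap]])
    dplyr::mutate(cl$counts, haplotype = hap, .before = 1)
  })
  cen_range <- range(config$centromere_unit_length)
  centromeres <- purrr::map_dfr(names(sim$genomes), function(hap) {
    dplyr::mutate(
      centromere_candidates(sim$genomes[[hap]], cen_range,
                            min_array_bp = 10000L),
      haplotype = hap, .before = 1
    )
  })
  nlr_clusters <- purrr::map_dfr(names(sim$genomes), function(hap) {
    loci <- dplyr::filter(sim$truth$nlr_loci, .data$haplotype == hap)
    if (nrow(loci) == 0) return(NULL)
    loci_tbl <- tibble::tibble(
      chrom = loci$chrom, start = loci$start, end = loci$end,
      name = sprintf("%s_nlr%03d", hap, seq_len(nrow(loci)))
    )
    genes_hap <- dplyr::filter(sim$genes, .data$haplotype == hap)
    st <- nlr_status(loci_tbl, genes_hap)
    dplyr::mutate(cluster_nlr(st, max_gap, min_loci), haplotype = hap,
                  .before = 1)
  })
  density <- biased_gene_density(combined_assign, partition$triads,
                                 sim$genes)

  report <- list(
    config = config, partition = partition, assignments = assignments,
    group_summary = group_summary, kaks = kaks, kaks_groups = kaks_groups,
    telomeres = telomeres, t2t = t2t, centromeres = centromeres,
    nlr_clusters = nlr_clusters, density = density, truth = sim$truth
  )
  class(report) <- "triadbias_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_simulation(sim, out_dir, counts)
    readr::write_tsv(assignments, file.path(out_dir, "assignments.tsv"))
    readr::write_tsv(group_summary, file.path(out_dir, "group_summary.tsv"))
    readr::write_tsv(kaks, file.path(out_dir, "kaks_pairs.tsv"))
    readr::write_tsv(kaks_groups$by_group,
                     file.path(out_dir, "kaks_by_group.tsv"))
    readr::write_tsv(telomeres, file.path(out_dir, "telomeres.tsv"))
    readr::write_tsv(t2t, file.path(out_dir, "t2t_summary.tsv"))
    if (nrow(centromeres) > 0) {
      readr::write_tsv(centromeres, file.path(out_dir, "centromeres.tsv"))
    }
    if (nrow(nlr_clusters) > 0) {
      readr::write_tsv(nlr_clusters, file.path(out_dir, "nlr_clusters.tsv"))
    }
    readr::write_tsv(density, file.path(out_dir, "bias_density.tsv"))
    write_manifest(file.path(out_dir, "run_manifest.json"),
                   command = "run_pipeline", config = config,
                   seed = config$seed)
  }
  report
}

#' @export
print.triadbias_report <- function(x, ...) {
  cat("triadbias pipeline report\n")
  print(glance(x$partition))
  cat("\nBias groups (combined analysis):\n")
  print(dplyr::filter(x$group_summary, .data$tissue == "combined"))
  cat("\nKa/Ks by group:\n")
  print(x$kaks_groups$by_group)
  cat("\nT2T chromosome counts:\n")
  print(dplyr::filter(x$t2t, .data$status == "T2T"))
  if (nrow(x$nlr_clusters) > 0) {
    cat("\nNLR clusters:\n")
    print(x$nlr_clusters)
  }
  invisible(x)
}

#' Write a JSON run manifest
#'
#' Records the command, a config snapshot, the seed, optional input
#' checksums and the package version, so that identical manifests imply
#' identical outputs for deterministic stages.
#'
#' @param path Output JSON path.
#' @param command Name of the command that ran.
#' @param config Configuration object (serialised as-is).
#' @param seed Integer seed.
#' @param inputs Optional character vector of input file paths; their md5
#'   sums are recorded.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config = NULL, seed = NULL,
                           inputs = NULL) {
  manifest <- list(
    command = command,
    tool = "triadbias",
    version = as.character(utils::packageVersion("triadbias")),
    seed = seed,
    config = config,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  if (!is.null(inputs)) {
    manifest$input_md5 <- as.list(tools::md5sum(inputs))
  }
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
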