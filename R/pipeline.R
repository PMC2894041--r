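#' Run the full physical-mapping pipeline
#'
#' Chains every stage on one configuration: genome simulation, BAC library
#' sampling, marker planting, in-silico HICF fingerprinting and validity
#' filtering, iterated contig assembly, 3D pool construction, panel
#' screening, marker anchoring and the summary report. When `out_dir` is
#' given, the genome FASTA, truth BED tracks, band-size file, FPC-style map,
#' screen tables, summary report and a serialized copy of the configuration
#' are written there.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return List with `genome`, `library`, `panel`, `fingerprints` (valid),
#'   `n_rejected`, `map`, `scheme`, `screens`, `anchored`, `summary`,
#'   `kb_per_band`, `config`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL) {
  genome <- generate_genome(config)
  library <- sample_bac_library(genome, config)
  panel <- plant_markers(genome, n = config$markers$n,
                         dup_fraction = config$markers$dup_fraction,
                         seed = config$seed,
                         class_counts = config$markers$class_counts)
  fpp <- config$fingerprint$params
  fpp$sizing_sd_nt <- config$fingerprint$sizing_sd_nt
  raw_fp <- fingerprint_library(genome, library, params = fpp,
                                fail_rate = config$fingerprint$fail_rate,
                                seed = config$seed)
  qc <- qc_filter(raw_fp, fpp)
  fp <- qc$fingerprints
  kb_per_band <- config$library$insert_mean_bp / 1000 / mean(fp$n_bands)
  map <- iterative_assembly(fp, config$assembly, kb_per_band)
  scheme <- build_pools(library, config$screening$superpool_size)
  screens <- screen_panel(panel, scheme, library,
                          fn_rate = config$screening$fn_rate,
                          fp_rate = config$screening$fp_rate,
                          seed = config$seed)
  anchored <- anchor_markers(map, screens, panel)
  summary <- summarize_map(map, kb_per_band, anchored, screens, library)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(out_dir, "config.yaml"))
    write_genome_fasta(genome, file.path(out_dir, "genome.fasta"))
    write_bed(genome$repeats, file.path(out_dir, "repeats.bed"))
    write_bed(library[!library$empty, ], file.path(out_dir, "clones.bed"))
    write_bed(panel$targets, file.path(out_dir, "marker_targets.bed"))
    write_marker_tables(panel, out_dir)
    write_band_file(fp, file.path(out_dir, "bands.txt"),
                    seed = config$seed)
    write_fpc_map(map, file.path(out_dir, "physical_map.txt"),
                  anchored = anchored, seed = config$seed)
    write.table(map$build_log, file.path(out_dir, "build_log.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(anchored$links, file.path(out_dir, "marker_links.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report <- utils::capture.output(print(summary))
    writeLines(c(sprintf("# seed=%d", config$seed), report),
               file.path(out_dir, "summary.txt"))
  }
  list(genome = genome, library = library, panel = panel,
       fingerprints = fp, n_rejected = qc$n_rejected, map = map,
       scheme = scheme, screens = screens, anchored = anchored,
       summary = summary, kb_per_band = kb_per_band, config = config)
}
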