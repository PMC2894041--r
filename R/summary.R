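#' Contig-size distribution statistics
#'
#' Bins contigs by clone count into the conventional physical-map report
#' bins (=2, 3-9, 10-24, 25-49, 50-99, >=100) and derives the standard
#' derived fractions. Accepts either a vector of per-contig clone counts or
#' a precomputed named bin-count vector.
#'
#' @param sizes integer vector of clone counts per contig, or a named
#'   numeric vector of bin counts with names `"2", "3-9", "10-24", "25-49",
#'   "50-99", ">=100"` (largest-first order also accepted).
#' @return List with `bins` (named counts), `n_contigs`,
#'   `frac_gt9` (contigs of more than 9 clones) and `frac_3_24` (contigs of
#'   3-24 clones), both unrounded fractions.
#' @examples
#' contig_size_stats(c("2" = 107, "3-9" = 706, "10-24" = 428, "25-49" = 102,
#'                     "50-99" = 9, ">=100" = 3))
#' @export
contig_size_stats <- function(sizes) {
  lv <- c("2", "3-9", "10-24", "25-49", "50-99", ">=100")
  if (!is.null(names(sizes))) {
    bins <- setNames(as.numeric(sizes[lv]), lv)
    if (any(is.na(bins))) stop("bin names must be ", paste(lv, collapse = ", "))
  } else {
    cut_bins <- cut(sizes, c(1.5, 2.5, 9.5, 24.5, 49.5, 99.5, Inf),
                    labels = lv)
    bins <- setNames(as.numeric(table(cut_bins)), lv)
  }
  n <- sum(bins)
  list(bins = bins, n_contigs = n,
       frac_gt9 = sum(bins[c("10-24", "25-49", "50-99", ">=100")]) / n,
       frac_3_24 = sum(bins[c("3-9", "10-24")]) / n)
}

#' Summary report of a physical map and its genetic anchoring
#'
#' Computes the standard physical-map summary: clone accounting, contig and
#' singleton counts, contig-size distribution, mean and total physical
#' length, genome coverage, and — when anchoring results are supplied — the
#' marker accounting, multi-contig marker fraction, BACs-per-marker
#' histogram and per-linkage-group anchored contigs/BACs/Mb. Percentages are
#' rounded half away from zero to the conventional printed precision.
#'
#' @param physmap a `physical_map`.
#' @param kb_per_band physical-length calibration; default mean insert size
#'   over mean valid band count when `library` is given.
#' @param anchored optional [anchor_markers()] result.
#' @param screens optional [screen_panel()] result.
#' @param library optional [sample_bac_library()] result (clone accounting,
#'   coverage and default calibration).
#' @return List of class `map_summary`.
#' @export
summarize_map <- function(physmap, kb_per_band = NULL, anchored = NULL,
                          screens = NULL, library = NULL) {
  fp <- physmap$fingerprints
  if (is.null(kb_per_band)) {
    if (is.null(library))
      stop("kb_per_band or library required for physical lengths")
    kb_per_band <- attr(library, "insert_mean_bp") / 1000 / mean(fp$n_bands)
  }
  sizes <- vapply(physmap$contigs, function(cg) length(cg$clones), integer(1))
  units <- vapply(physmap$contigs, function(cg) cg$cb$n_units, numeric(1))
  lens_kb <- units * kb_per_band
  sz <- contig_size_stats(as.integer(sizes))
  qfrac <- vapply(physmap$contigs, contig_q_fraction, numeric(1))

  out <- list(
    n_fingerprints = length(fp$clone_id),
    mean_valid_bands = mean(fp$n_bands),
    n_contigs = length(physmap$contigs),
    n_singletons = length(physmap$singletons),
    size_bins = sz$bins,
    pct_gt9 = round_half_up(100 * sz$frac_gt9),
    pct_3_24 = round_half_up(100 * sz$frac_3_24),
    mean_contig_length_kb = round_half_up(mean(lens_kb), 1),
    total_physical_length_mb = round_half_up(sum(lens_kb) / 1000, 1),
    longest_contig_kb = if (length(lens_kb))
      round_half_up(max(lens_kb), 1) else NA_real_,
    n_contigs_gt5pct_q = sum(qfrac > 0.05),
    kb_per_band = kb_per_band)
  if (!is.null(library)) {
    out$library_clones <- nrow(library)
    out$library_non_empty <- sum(!library$empty)
    out$genome_equivalents <- round_half_up(achieved_equivalents(library), 1)
    out$map_coverage_x <- round_half_up(
      sum(lens_kb) * 1000 / attr(library, "genome_bp"), 2)
  }
  if (!is.null(anchored)) {
    st <- anchored$marker_status
    links <- anchored$links
    per_marker_units <- table(links$marker_id)
    out$n_markers_anchored <- sum(st$status == "anchored")
    out$n_markers_dropout <- sum(st$status == "dropout")
    out$n_markers_no_fingerprint <- sum(st$status == "no_fingerprint")
    to_contig <- tapply(links$unit_type == "contig", links$marker_id, any)
    out$n_anchored_to_contigs <- sum(to_contig)
    out$n_anchored_to_singletons_only <- sum(!to_contig)
    out$n_multi_unit_markers <- sum(per_marker_units > 1)
    out$pct_multi_unit <- round_half_up(
      100 * out$n_multi_unit_markers / max(out$n_markers_anchored, 1))
    pl <- anchored$placements
    pl_len <- vapply(seq_len(nrow(pl)), function(i) {
      if (pl$unit_type[i] == "contig")
        physmap$contigs[[pl$unit[i]]]$cb$n_units * kb_per_band
      else fp$n_bands[match(pl$unit[i], fp$clone_id)] * kb_per_band
    }, numeric(1))
    bacs <- tapply(links$n_clones, links$unit, sum)[pl$unit]
    per_lg <- data.frame(lg = pl$lg, dual = pl$dual_lg,
                         units = 1L, mb = pl_len / 1000,
                         bacs = as.integer(bacs))
    agg <- stats::aggregate(cbind(units, mb, bacs) ~ lg + dual, per_lg, sum)
    out$per_lg <- agg[order(agg$dual, agg$lg), ]
    out$anchored_mb_total <- round_half_up(sum(per_lg$mb), 1)
    uniq <- per_lg[!per_lg$dual, , drop = FALSE]
    n_lg <- length(unique(uniq$lg))
    out$mean_units_per_lg <- round_half_up(sum(uniq$units) / max(n_lg, 1))
    out$mean_bacs_per_lg <- round_half_up(sum(uniq$bacs) / max(n_lg, 1))
    out$mean_mb_per_lg <- round_half_up(sum(uniq$mb) / max(n_lg, 1), 1)
  }
  if (!is.null(screens)) {
    s <- screens$summary
    out$bacs_per_marker_hist <- s$histogram
    out$mean_bacs_per_marker <- round_half_up(s$mean_bacs_per_marker, 1)
    out$class_mean_bacs <- round_half_up(s$class_means, 1)
  }
  class(out) <- "map_summary"
  out
}

#' @export
print.map_summary <- function(x, ...) {
  cat("Physical map summary\n")
  cat(sprintf("  fingerprinted clones retained   %d (mean %.1f bands)\n",
              x$n_fingerprints, x$mean_valid_bands))
  cat(sprintf("  contigs / singletons            %d / %d\n",
              x$n_contigs, x$n_singletons))
  cat(sprintf("  contigs >9 clones               %s%%\n", x$pct_gt9))
  cat(sprintf("  contigs 3-24 clones             %s%%\n", x$pct_3_24))
  cat(sprintf("  mean / total physical length    %.1f kb / %.1f Mb\n",
              x$mean_contig_length_kb, x$total_physical_length_mb))
  if (!is.null(x$genome_equivalents))
    cat(sprintf("  library depth / map coverage    %.1fx / %.2fx\n",
                x$genome_equivalents, x$map_coverage_x))
  if (!is.null(x$n_markers_anchored))
    cat(sprintf("  markers anchored                %d (%d multi-unit, %s%%)\n",
                x$n_markers_anchored, x$n_multi_unit_markers,
                x$pct_multi_unit))
  invisible(x)
}
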