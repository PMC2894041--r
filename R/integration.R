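#' Anchor screened markers to the physical map
#'
#' Links each marker to every contig or singleton containing at least one of
#' its fingerprinted positive clones. Positive clones lacking a valid
#' fingerprint are recorded; markers all of whose positives lack
#' fingerprints are unanchorable, markers with no positives are dropouts.
#' Contigs inherit the linkage groups of their markers; a contig whose
#' markers map to two or more linkage groups is placed in a dual-LG
#' category.
#'
#' @param physmap a `physical_map`.
#' @param screens a [screen_panel()] result (or list of `screen_result`).
#' @param panel the [plant_markers()] panel.
#' @return Object of class `anchored_map`: list with
#'   \describe{
#'     \item{links}{data.frame `marker_id, unit, unit_type, n_clones`}
#'     \item{marker_status}{data.frame `marker_id, status` with status in
#'       `anchored, dropout, no_fingerprint`}
#'     \item{placements}{data.frame `unit, unit_type, n_clones, lg,
#'       dual_lg, n_markers`}
#'   }
#' @export
anchor_markers <- function(physmap, screens, panel) {
  results <- if (inherits(screens, "screen_panel")) screens$results else screens
  members <- map_members(physmap)
  mk <- panel$markers

  links <- list(); status <- list()
  for (r in results) {
    pos <- r$positives
    if (r$dropout || length(pos) == 0) {
      status[[r$marker_id]] <- "dropout"; next
    }
    fpd <- members[members$clone_id %in% pos, , drop = FALSE]
    if (nrow(fpd) == 0) {
      status[[r$marker_id]] <- "no_fingerprint"; next
    }
    status[[r$marker_id]] <- "anchored"
    agg <- table(paste(fpd$unit, fpd$unit_type, sep = "\r"))
    parts <- strsplit(names(agg), "\r", fixed = TRUE)
    links[[r$marker_id]] <- data.frame(
      marker_id = r$marker_id,
      unit = vapply(parts, `[`, character(1), 1),
      unit_type = vapply(parts, `[`, character(1), 2),
      n_clones = as.integer(agg), stringsAsFactors = FALSE)
  }
  links <- if (length(links)) do.call(rbind, links) else
    data.frame(marker_id = character(0), unit = character(0),
               unit_type = character(0), n_clones = integer(0))
  rownames(links) <- NULL
  marker_status <- data.frame(marker_id = names(status),
                              status = unlist(status),
                              stringsAsFactors = FALSE)
  rownames(marker_status) <- NULL

  # per-unit linkage-group placement (duplicated markers may carry a second
  # genetic position; all positions of all linked markers are collected)
  placements <- list()
  for (u in unique(links$unit)) {
    lrows <- links[links$unit == u, , drop = FALSE]
    mrows <- mk[match(lrows$marker_id, mk$marker_id), , drop = FALSE]
    lgs <- unique(c(mrows$linkage_group, mrows$lg2[!is.na(mrows$lg2)]))
    n_clones <- if (lrows$unit_type[1] == "contig")
      length(physmap$contigs[[u]]$clones) else 1L
    placements[[u]] <- data.frame(
      unit = u, unit_type = lrows$unit_type[1], n_clones = n_clones,
      lg = paste(sort(lgs), collapse = "/"),
      dual_lg = length(lgs) > 1, n_markers = nrow(lrows),
      stringsAsFactors = FALSE)
  }
  placements <- if (length(placements)) do.call(rbind, placements) else
    data.frame(unit = character(0), unit_type = character(0),
               n_clones = integer(0), lg = character(0),
               dual_lg = logical(0), n_markers = integer(0))
  rownames(placements) <- NULL
  structure(list(links = links, marker_status = marker_status,
                 placements = placements),
            class = "anchored_map")
}

#' PCR-contig / FPC-contig coincidence
#'
#' For one marker's set of overlapping positive clones (its "PCR contig"),
#' the fraction of fingerprinted positives that fall in the modal physical
#' map unit. Computed for markers linked to at most one FPC contig (extra
#' singleton links do not disqualify, otherwise the statistic is trivially
#' 1); markers with fewer than 2 fingerprinted positives are undefined and
#' excluded from averages. Modal ties resolve toward the unit with more
#' total clones, then lexicographic id.
#'
#' @param positives character vector of a marker's positive clone ids.
#' @param physmap a `physical_map`.
#' @return Fraction in `[0, 1]`, or `NA` when undefined.
#' @export
coincidence <- function(positives, physmap) {
  members <- map_members(physmap)
  fpd <- members[members$clone_id %in% positives, , drop = FALSE]
  if (nrow(fpd) < 2) return(NA_real_)
  tab <- table(fpd$unit)
  best <- names(tab)[tab == max(tab)]
  if (length(best) > 1) {
    sz <- vapply(best, function(u)
      if (!is.null(physmap$contigs[[u]])) length(physmap$contigs[[u]]$clones)
      else 1L, integer(1))
    best <- best[order(-sz, best)][1]
  }
  as.numeric(max(tab)) / nrow(fpd)
}

#' Mean coincidence over eligible markers
#'
#' @param screens a [screen_panel()] result.
#' @param anchored an [anchor_markers()] result.
#' @param physmap a `physical_map`.
#' @return Mean coincidence over markers linked to at most one contig with
#'   at least 2 fingerprinted positives.
#' @export
mean_coincidence <- function(screens, anchored, physmap) {
  links <- anchored$links
  n_contig_links <- tapply(links$unit_type == "contig", links$marker_id, sum)
  eligible <- names(n_contig_links)[n_contig_links <= 1]
  vals <- vapply(eligible, function(m)
    coincidence(screens$results[[m]]$positives, physmap), numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Detect contigs with conflicting genetic anchors
#'
#' A contig conflicts when no assignment of one genetic position per linked
#' marker puts all markers on a single linkage group with pairwise implied
#' physical separations (`cM / cm_per_mb`) no larger than the contig's
#' estimated physical length. Covers both cross-linkage-group conflicts and
#' same-group markers genetically far beyond the contig's span.
#'
#' @param anchored an [anchor_markers()] result.
#' @param panel the marker panel.
#' @param physmap a `physical_map`.
#' @param cm_per_mb genetic-to-physical scaling.
#' @param kb_per_band physical-length calibration.
#' @return data.frame `unit, markers, reason` (zero rows when clean).
#' @export
detect_conflicts <- function(anchored, panel, physmap, cm_per_mb,
                             kb_per_band) {
  mk <- panel$markers
  out <- list()
  multi <- anchored$placements[anchored$placements$n_markers >= 2 &
                                 anchored$placements$unit_type == "contig", ,
                               drop = FALSE]
  for (u in multi$unit) {
    mids <- anchored$links$marker_id[anchored$links$unit == u]
    rows <- mk[match(mids, mk$marker_id), , drop = FALSE]
    # candidate (lg, cm) positions per marker
    cand <- lapply(seq_len(nrow(rows)), function(i) {
      p <- data.frame(lg = rows$linkage_group[i], cm = rows$cm[i])
      if (!is.na(rows$lg2[i]))
        p <- rbind(p, data.frame(lg = rows$lg2[i], cm = rows$cm2[i]))
      p
    })
    len_mb <- estimate_physical_length(physmap$contigs[[u]], kb_per_band) /
      1000
    consistent <- function(choice) {
      lgs <- vapply(seq_along(cand), function(i) cand[[i]]$lg[choice[i]],
                    character(1))
      if (length(unique(lgs)) > 1) return(FALSE)
      cms <- vapply(seq_along(cand), function(i) cand[[i]]$cm[choice[i]],
                    numeric(1))
      (max(cms) - min(cms)) / cm_per_mb <= len_mb
    }
    grid <- do.call(expand.grid, lapply(cand, function(p) seq_len(nrow(p))))
    ok <- any(apply(grid, 1, function(ch) consistent(as.integer(ch))))
    if (!ok) {
      lg_set <- unique(unlist(lapply(cand, function(p) p$lg)))
      reason <- if (length(lg_set) > 1) "markers on different linkage groups"
      else "genetic distance exceeds contig physical length"
      out[[u]] <- data.frame(unit = u,
                             markers = paste(sort(mids), collapse = ","),
                             reason = reason, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(unit = character(0), markers = character(0),
               reason = character(0))
  rownames(res) <- NULL
  res
}
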