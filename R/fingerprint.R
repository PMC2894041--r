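#' Restriction enzyme specifications for HICF
#'
#' The default five-enzyme set used for high-information-content
#' fingerprinting: four six-cutters with sticky ends, each labeled with one
#' of the four SNaPshot dye colors, plus the blunt four-cutter HaeIII which
#' cuts frequently but leaves unlabeled ends. `cut_offset` is the number of
#' bases of the recognition site left of the cut on the forward strand.
#'
#' @param name,site,cut_offset,end_type,color vectors describing custom
#'   enzymes; sites must be palindromic (the scan is forward-strand only,
#'   which is exact for palindromes).
#' @return data.frame of class `enzyme_set` with columns
#'   `name, site, cut_offset, end_type, color`.
#' @examples
#' default_enzymes()
#' @export
default_enzymes <- function() {
  enzyme_set(
    name       = c("BamHI", "EcoRI", "NdeI", "XbaI", "HaeIII"),
    site       = c("GGATCC", "GAATTC", "CATATG", "TCTAGA", "GGCC"),
    cut_offset = c(1L, 1L, 2L, 1L, 2L),
    end_type   = c("sticky", "sticky", "sticky", "sticky", "blunt"),
    color      = c("blue", "green", "yellow", "red", NA)
  )
}

#' @rdname default_enzymes
#' @export
enzyme_set <- function(name, site, cut_offset, end_type, color) {
  stopifnot(length(name) == length(site))
  ok_dna <- grepl("^[ACGT]+$", site)
  if (!all(ok_dna)) stop("enzyme sites must be DNA strings over ACGT")
  pal <- vapply(site, function(s)
    s == as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    logical(1))
  if (!all(pal))
    stop("non-palindromic recognition sites are not supported: ",
         paste(site[!pal], collapse = ", "))
  if (any(cut_offset < 0 | cut_offset > nchar(site)))
    stop("cut_offset must lie within the recognition site")
  if (any(end_type == "blunt" & !is.na(color)))
    stop("blunt enzymes carry no label color")
  df <- data.frame(name = name, site = site, cut_offset = as.integer(cut_offset),
                   end_type = end_type, color = color, stringsAsFactors = FALSE)
  class(df) <- c("enzyme_set", "data.frame")
  df
}

#' Band calling and validity-filter parameters
#'
#' @param min_bands minimum in-window bands for a fingerprint to be valid.
#'   Default 50; 40 is the value used by the FPB fingerprint-processing
#'   convention and can be configured here.
#' @param size_min,size_max retained band-size window in nt.
#' @param tolerance_nt band-matching tolerance on the fractional size scale.
#' @param multiplying_factor integerization factor; `size_int =
#'   round(size_nt * multiplying_factor)` and the integer tolerance is
#'   `tolerance_nt * multiplying_factor` (0.4 x 30 = 12).
#' @param sizing_sd_nt standard deviation of capillary sizing noise in nt.
#' @return List of class `band_calling_params`.
#' @export
band_calling_params <- function(min_bands = 50L, size_min = 50, size_max = 500,
                                tolerance_nt = 0.4, multiplying_factor = 30L,
                                sizing_sd_nt = 0.15) {
  stopifnot(size_min < size_max, tolerance_nt > 0)
  structure(list(min_bands = as.integer(min_bands), size_min = size_min,
                 size_max = size_max, tolerance_nt = tolerance_nt,
                 multiplying_factor = as.integer(multiplying_factor),
                 sizing_sd_nt = sizing_sd_nt),
            class = "band_calling_params")
}

#' Digest a sequence with a set of restriction enzymes
#'
#' Cut positions are the union over enzymes of (site occurrence + cut
#' offset) on the forward strand; fragments are the maximal runs between
#' consecutive cuts and tile the sequence exactly. Terminal fragment ends
#' carry enzyme `NA`. When two enzymes cut at the same position the sticky
#' (labeled) enzyme takes precedence for end assignment.
#'
#' @param sequence character string or [Biostrings::DNAString].
#' @param enzymes an [enzyme_set()].
#' @return data.frame `start, end, length, left_enzyme, right_enzyme`
#'   (1-based closed coordinates).
#' @examples
#' d <- digest("AAAGGATCCAAA", default_enzymes())
#' sum(d$length) == 12
#' @export
digest <- function(sequence, enzymes) {
  seq <- if (is.character(sequence)) Biostrings::DNAString(sequence) else sequence
  n <- length(seq)
  if (n == 0) stop("sequence must be non-empty")
  cuts <- genome_cut_table(seq, enzymes)
  fragments_from_cuts(cuts$pos, cuts$enzyme, n)
}

# site scan for one sequence -> sorted cut positions (bases left of the cut)
# with the cutting enzyme; sticky enzymes win position ties
genome_cut_table <- function(seq, enzymes) {
  pos <- integer(0); enz <- character(0); sticky <- logical(0)
  for (k in seq_len(nrow(enzymes))) {
    hits <- Biostrings::start(Biostrings::matchPattern(enzymes$site[k], seq))
    if (length(hits)) {
      pos <- c(pos, hits - 1L + enzymes$cut_offset[k])
      enz <- c(enz, rep(enzymes$name[k], length(hits)))
      sticky <- c(sticky, rep(enzymes$end_type[k] == "sticky", length(hits)))
    }
  }
  if (length(pos)) {
    o <- order(pos, !sticky)           # sticky first within a tied position
    pos <- pos[o]; enz <- enz[o]
    keep <- !duplicated(pos)
    pos <- pos[keep]; enz <- enz[keep]
    inside <- pos > 0 & pos < length(seq)
    pos <- pos[inside]; enz <- enz[inside]
  }
  list(pos = pos, enzyme = enz)
}

fragments_from_cuts <- function(pos, enzyme, n) {
  bounds <- c(0L, pos, n)
  left <- c(NA_character_, enzyme)
  right <- c(enzyme, NA_character_)
  data.frame(start = head(bounds, -1) + 1L, end = bounds[-1],
             length = diff(bounds),
             left_enzyme = left, right_enzyme = right,
             stringsAsFactors = FALSE)
}

#' Label digest fragments into colored bands
#'
#' Each fragment end produced by a sticky (labeled) enzyme yields one band of
#' that enzyme's color at the fragment's length, so a fragment with two
#' labeled ends is counted twice (one peak per labeled strand end).
#' Blunt-blunt and terminal-only fragments yield no band. Bands outside the
#' retained size window are discarded.
#'
#' @param fragments a [digest()] result.
#' @param enzymes the [enzyme_set()] used for the digest.
#' @param params [band_calling_params()] (size window).
#' @return data.frame `color, size_nt, size_int` sorted by color then size.
#' @export
label_fragments <- function(fragments, enzymes = default_enzymes(),
                            params = band_calling_params()) {
  col_of <- setNames(enzymes$color, enzymes$name)
  lab_l <- col_of[fragments$left_enzyme]
  lab_r <- col_of[fragments$right_enzyme]
  color <- c(lab_l, lab_r)
  size <- c(fragments$length, fragments$length)
  keep <- !is.na(color) & size >= params$size_min & size <= params$size_max
  bands <- data.frame(color = color[keep], size_nt = as.numeric(size[keep]),
                      stringsAsFactors = FALSE)
  bands$size_int <- as.integer(round(bands$size_nt * params$multiplying_factor))
  bands[order(bands$color, bands$size_int), , drop = FALSE]
}

#' Perturb band sizes with capillary sizing noise
#'
#' Adds independent zero-mean Gaussian noise to each fractional band size and
#' re-integerizes. At the default sd of 0.15 nt, two measurements of the same
#' true fragment differ by more than the 0.4 nt tolerance in about 5% of
#' trials.
#'
#' @param bands data.frame with `size_nt` (and `color`).
#' @param sizing_sd_nt noise scale in nt; 0 is the identity.
#' @param seed optional integer seed.
#' @param multiplying_factor integerization factor.
#' @return The bands with perturbed `size_nt` and recomputed `size_int`,
#'   re-sorted by color then size.
#' @export
size_with_noise <- function(bands, sizing_sd_nt, seed = NULL,
                            multiplying_factor = 30L) {
  stopifnot(sizing_sd_nt >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (sizing_sd_nt > 0 && nrow(bands) > 0)
    bands$size_nt <- bands$size_nt + rnorm(nrow(bands), 0, sizing_sd_nt)
  bands$size_int <- as.integer(round(bands$size_nt * multiplying_factor))
  bands[order(bands$color, bands$size_int), , drop = FALSE]
}

#' Fingerprint every clone of a BAC library in silico
#'
#' Scans each chromosome once for restriction sites, derives each clone's
#' fragment set from the cut positions inside its span (clone ends count as
#' unlabeled terminal ends), labels sticky-cut fragment ends with the
#' enzyme's color, applies sizing noise and integerization. A configured
#' fraction of clones suffer a simulated fingerprinting failure (mimicking
#' poor-quality wet-lab profiles): their band list is subsampled so the
#' downstream minimum-band filter rejects them.
#'
#' @param genome a [generate_genome()] result.
#' @param library a [sample_bac_library()] result.
#' @param enzymes an [enzyme_set()].
#' @param params [band_calling_params()].
#' @param fail_rate fraction of non-empty clones with failed fingerprints.
#' @param seed integer seed.
#' @return Object of class `fingerprint_set`: list with `clone_id`
#'   (character), `color` / `size_int` / `size_nt` (band lists per clone,
#'   sorted by color then size) and `n_bands`.
#' @export
fingerprint_library <- function(genome, library, enzymes = default_enzymes(),
                                params = band_calling_params(),
                                fail_rate = 0.2, seed = 1L) {
  set.seed(stage_seed(seed, 41L))
  col_levels <- sort(unique(enzymes$color[!is.na(enzymes$color)]))
  col_of <- setNames(match(enzymes$color, col_levels), enzymes$name)
  sticky <- setNames(enzymes$end_type == "sticky", enzymes$name)

  cut_tab <- lapply(seq_along(genome$seqs), function(k)
    genome_cut_table(genome$seqs[[k]], enzymes))
  names(cut_tab) <- names(genome$seqs)

  n <- nrow(library)
  colors <- vector("list", n)
  sizes_nt <- vector("list", n)
  failed <- !library$empty & runif(n) < fail_rate

  for (ci in seq_len(n)) {
    if (library$empty[ci]) { colors[[ci]] <- integer(0); sizes_nt[[ci]] <- numeric(0); next }
    ct <- cut_tab[[library$chrom[ci]]]
    s <- library$start[ci]; e <- library$end[ci]
    lo <- findInterval(s - 1L, ct$pos) + 1L   # first cut with pos >= s
    hi <- findInterval(e - 1L, ct$pos)        # last cut with pos <= e - 1
    if (hi < lo) { colors[[ci]] <- integer(0); sizes_nt[[ci]] <- numeric(0); next }
    pos <- ct$pos[lo:hi] - (s - 1L)
    enz <- ct$enzyme[lo:hi]
    frag_len <- diff(c(0L, pos, e - s + 1L))
    left_enz <- c(NA_character_, enz)
    right_enz <- c(enz, NA_character_)
    lab_l <- ifelse(!is.na(left_enz) & sticky[left_enz], col_of[left_enz], NA)
    lab_r <- ifelse(!is.na(right_enz) & sticky[right_enz], col_of[right_enz], NA)
    colr <- c(lab_l, lab_r)
    sz <- c(frag_len, frag_len)
    keep <- !is.na(colr) & sz >= params$size_min & sz <= params$size_max
    colors[[ci]] <- as.integer(colr[keep])
    sizes_nt[[ci]] <- as.numeric(sz[keep])
  }

  # simulated fingerprint failures: keep only a small random fraction of bands
  for (ci in which(failed)) {
    nb <- length(colors[[ci]])
    if (nb == 0) next
    keep_n <- floor(runif(1, 0, 0.6) * nb)
    keep <- sort(sample.int(nb, keep_n))
    colors[[ci]] <- colors[[ci]][keep]
    sizes_nt[[ci]] <- sizes_nt[[ci]][keep]
  }

  # sizing noise + integerization, sorted by (color, size)
  size_int <- vector("list", n)
  for (ci in seq_len(n)) {
    sz <- sizes_nt[[ci]]
    if (length(sz) && params$sizing_sd_nt > 0)
      sz <- sz + rnorm(length(sz), 0, params$sizing_sd_nt)
    si <- as.integer(round(sz * params$multiplying_factor))
    o <- order(colors[[ci]], si)
    colors[[ci]] <- colors[[ci]][o]
    sizes_nt[[ci]] <- sz[o]
    size_int[[ci]] <- si[o]
  }

  structure(list(clone_id = library$clone_id, color = colors,
                 size_nt = sizes_nt, size_int = size_int,
                 n_bands = vapply(colors, length, integer(1)),
                 color_levels = col_levels, params = params),
            class = "fingerprint_set")
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat(sprintf("fingerprint_set: %d clones, mean %.1f bands\n",
              length(x$clone_id), mean(x$n_bands)))
  invisible(x)
}

#' Validity-filter fingerprints
#'
#' Rejects empty-profile clones and fingerprints with fewer than `min_bands`
#' bands inside the retained size window; retained fingerprints keep only
#' in-window bands, sorted by color then size.
#'
#' @param fingerprints a [fingerprint_library()] result.
#' @param params [band_calling_params()].
#' @return List with `fingerprints` (a `fingerprint_set` of valid clones
#'   only) and `n_rejected`.
#' @export
qc_filter <- function(fingerprints, params = band_calling_params()) {
  fp <- fingerprints
  lo <- params$size_min * params$multiplying_factor
  hi <- params$size_max * params$multiplying_factor
  for (ci in seq_along(fp$clone_id)) {
    keep <- fp$size_int[[ci]] >= lo & fp$size_int[[ci]] <= hi
    if (!all(keep)) {
      fp$color[[ci]] <- fp$color[[ci]][keep]
      fp$size_nt[[ci]] <- fp$size_nt[[ci]][keep]
      fp$size_int[[ci]] <- fp$size_int[[ci]][keep]
    }
  }
  fp$n_bands <- vapply(fp$color, length, integer(1))
  valid <- fp$n_bands >= params$min_bands
  out <- subset_fingerprints(fp, which(valid))
  list(fingerprints = out, n_rejected = sum(!valid))
}

subset_fingerprints <- function(fp, idx) {
  structure(list(clone_id = fp$clone_id[idx], color = fp$color[idx],
                 size_nt = fp$size_nt[idx], size_int = fp$size_int[idx],
                 n_bands = fp$n_bands[idx], color_levels = fp$color_levels,
                 params = fp$params),
            class = "fingerprint_set")
}

# concatenated representation for the compiled pair scorer
flatten_fingerprints <- function(fp) {
  list(colors = as.integer(unlist(fp$color)),
       sizes = as.integer(unlist(fp$size_int)),
       offsets = as.integer(c(0L, cumsum(fp$n_bands))))
}
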