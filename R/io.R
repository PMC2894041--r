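#' Write and read band-size files
#'
#' The band-size dialect stores one fingerprint per record: a header line
#' `clone_id<TAB>n_bands` followed by one line of whitespace-separated
#' bands, each `size_int/color` (integerized size and color tag). Files
#' written without colors (`colors = FALSE`) are the legacy sizes-only
#' variant; on read such bands are assigned a single default color and the
#' result is flagged. File headers carry `#`-comment lines with the tool
#' version and seed.
#'
#' @param fp a `fingerprint_set`.
#' @param path file path.
#' @param colors write color tags (default) or the sizes-only variant.
#' @param seed optional seed recorded in the header.
#' @return `write_band_file()` returns `path` invisibly; `read_band_file()`
#'   returns a `fingerprint_set` (attribute `colorless` is `TRUE` when the
#'   legacy variant was read).
#' @export
write_band_file <- function(fp, path, colors = TRUE, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hicfmap band file v1; seed=%s",
                     if (is.null(seed)) "NA" else seed), con)
  writeLines(sprintf("# colors=%s", if (colors) "yes" else "no"), con)
  for (i in seq_along(fp$clone_id)) {
    writeLines(sprintf("%s\t%d", fp$clone_id[i], fp$n_bands[i]), con)
    if (fp$n_bands[i] > 0) {
      toks <- if (colors)
        sprintf("%d/%d", fp$size_int[[i]], fp$color[[i]])
      else sprintf("%d", fp$size_int[[i]])
      writeLines(paste(toks, collapse = " "), con)
    } else writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_band_file
#' @export
read_band_file <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  clone_id <- character(0)
  color <- list(); size_int <- list()
  i <- 1L; lineno <- which(!startsWith(lines, "#"))
  colorless <- FALSE
  while (i <= length(body)) {
    hdr <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(hdr) != 2 || is.na(suppressWarnings(as.integer(hdr[2]))))
      stop("malformed record header at line ", lineno[i])
    nb <- as.integer(hdr[2])
    if (i + 1L > length(body)) stop("truncated record at line ", lineno[i])
    toks <- strsplit(trimws(body[i + 1L]), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != nb)
      stop("band count mismatch at line ", lineno[i + 1L], ": declared ",
           nb, ", found ", length(toks))
    has_col <- grepl("/", toks, fixed = TRUE)
    if (nb > 0 && !all(has_col)) {
      if (any(has_col)) stop("mixed color tags at line ", lineno[i + 1L])
      colorless <- TRUE
      sz <- suppressWarnings(as.integer(toks))
      cl <- rep(1L, nb)
    } else {
      parts <- strsplit(toks, "/", fixed = TRUE)
      sz <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 1)))
      cl <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2)))
    }
    if (nb > 0 && (anyNA(sz) || anyNA(cl)))
      stop("non-numeric band at line ", lineno[i + 1L])
    o <- order(cl, sz)
    clone_id <- c(clone_id, hdr[1])
    color[[length(color) + 1L]] <- cl[o]
    size_int[[length(size_int) + 1L]] <- sz[o]
    i <- i + 2L
  }
  fp <- structure(list(clone_id = clone_id, color = color,
                       size_nt = lapply(size_int, function(s) s / 30),
                       size_int = size_int,
                       n_bands = lengths(size_int),
                       color_levels = NULL, params = NULL),
                  class = "fingerprint_set")
  attr(fp, "colorless") <- colorless
  fp
}

#' Write a genome as FASTA and its truth tracks as BED
#'
#' BED output follows the BED convention (0-based half-open); internal
#' coordinates are 1-based closed.
#'
#' @param genome a [generate_genome()] result.
#' @param path output FASTA path.
#' @return `path` invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seqs, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @param df data.frame with `chrom, start, end` and a name column
#'   (`family`, `clone_id` or `marker_id`).
#' @export
write_bed <- function(df, path) {
  name_col <- intersect(c("family", "clone_id", "marker_id", "name"),
                        names(df))[1]
  sel <- !is.na(df$start)
  bed <- data.frame(chrom = df$chrom[sel], start = df$start[sel] - 1L,
                    end = df$end[sel], name = df[[name_col]][sel])
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a physical map as a plain-text FPC-style database
#'
#' A documented text dialect (not byte-compatible with binary FPC
#' databases): per-contig records listing each member clone with its
#' left/right consensus-band coordinates and Q flag, followed by the
#' singleton list and the build log.
#'
#' @param map a `physical_map`.
#' @param path output path.
#' @param anchored optional [anchor_markers()] result; linked markers are
#'   written into each contig record.
#' @param seed optional seed recorded in the header.
#' @return `path` invisibly.
#' @export
write_fpc_map <- function(map, path, anchored = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hicfmap physical map v1; seed=%s; cutoff=%g",
                     if (is.null(seed)) "NA" else seed, map$cutoff), con)
  for (id in names(map$contigs)) {
    cg <- map$contigs[[id]]
    mk <- if (!is.null(anchored)) {
      m <- anchored$links$marker_id[anchored$links$unit == id]
      if (length(m)) paste(sort(m), collapse = ",") else "-"
    } else "-"
    writeLines(sprintf("contig\t%s\tclones=%d\tunits=%d\tmarkers=%s",
                       id, length(cg$clones), cg$cb$n_units, mk), con)
    pl <- cg$cb$placements
    writeLines(sprintf("  %s\t%d\t%d\t%s", pl$clone_id, pl$left, pl$right,
                       ifelse(pl$q, "Q", "-")), con)
  }
  writeLines(sprintf("singleton\t%s",
                     map$fingerprints$clone_id[map$singletons]), con)
  writeLines("# build log", con)
  lg <- map$build_log
  writeLines(sprintf("log\t%s\t%g\t%d\t%d\t%d", lg$step, lg$cutoff,
                     lg$n_contigs, lg$n_singletons, lg$n_q), con)
  invisible(path)
}

#' Read/write the marker panel as tab-separated tables
#'
#' @param panel a [plant_markers()] result.
#' @param dir output directory (writes `markers.tsv` and
#'   `marker_targets.tsv`).
#' @return Paths invisibly / the `marker_panel`.
#' @export
write_marker_tables <- function(panel, dir) {
  p1 <- file.path(dir, "markers.tsv")
  p2 <- file.path(dir, "marker_targets.tsv")
  write.table(panel$markers, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(panel$targets, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}

#' @rdname write_marker_tables
#' @export
read_marker_tables <- function(dir) {
  markers <- read.table(file.path(dir, "markers.tsv"), sep = "\t",
                        header = TRUE, stringsAsFactors = FALSE)
  targets <- read.table(file.path(dir, "marker_targets.tsv"), sep = "\t",
                        header = TRUE, stringsAsFactors = FALSE)
  structure(list(markers = markers, targets = targets),
            class = "marker_panel")
}
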