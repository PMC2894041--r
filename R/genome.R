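#' Generate a synthetic genome with annotated repeat families
#'
#' Produces a random multi-chromosome genome carrying implanted tandem arrays
#' (rDNA-like, >= 5 adjacent near-identical units) and dispersed repeat
#' copies, together with ground-truth repeat annotations, a linkage-group
#' label per chromosome and a uniform genetic-to-physical scaling. The genome
#' is the substrate for BAC library sampling, in-silico fingerprinting and
#' marker planting.
#'
#' @param config a [sim_config()] list (only the `genome` section and `seed`
#'   are used).
#' @return An object of class `genome_model`: a list with
#'   \describe{
#'     \item{seqs}{named [Biostrings::DNAStringSet] of chromosomes}
#'     \item{repeats}{data.frame `chrom, start, end, family, kind` (1-based,
#'       closed intervals); tandem arrays are annotated as one interval per
#'       array, dispersed families one interval per copy}
#'     \item{linkage_groups}{named character vector chromosome -> roman label}
#'     \item{cm_per_mb}{scalar map scaling}
#'   }
#' @examples
#' g <- generate_genome(sim_config(1, genome = list(genome_bp = 1e6, n_chromosomes = 2,
#'   tandem = list(n_families = 1, unit_bp = 1000, n_copies = 6, divergence = 0.01),
#'   dispersed = list(n_families = 0, unit_bp = 0, n_copies = 0, divergence = 0))))
#' sum(Biostrings::width(g$seqs))
#' @export
generate_genome <- function(config) {
  gc <- config$genome
  if (is.null(gc$genome_bp) || gc$genome_bp <= 0)
    stop("configuration error: genome_bp must be positive")
  if (is.null(gc$n_chromosomes) || gc$n_chromosomes <= 0)
    stop("configuration error: n_chromosomes must be positive")
  set.seed(stage_seed(config$seed, 11L))

  n_chr <- as.integer(gc$n_chromosomes)
  total <- as.integer(gc$genome_bp)
  base_len <- total %/% n_chr
  lens <- rep(base_len, n_chr)
  lens[1] <- lens[1] + total - sum(lens)          # length conservation
  chr_names <- sprintf("chr%02d", seq_len(n_chr))

  # integer-coded sequences (1..4 = A,C,G,T); converted to strings once
  seqs_int <- lapply(lens, function(n) sample.int(4L, n, replace = TRUE))
  names(seqs_int) <- chr_names

  repeats <- list()
  occupied <- lapply(lens, function(n) integer(0))  # repeat interval registry

  place_interval <- function(chr_idx, len) {
    # pick a start not colliding with previously implanted repeats
    for (try in 1:200) {
      s <- sample.int(lens[chr_idx] - len + 1L, 1L)
      occ <- occupied[[chr_idx]]
      if (length(occ) == 0 ||
          all(s > occ[c(FALSE, TRUE)] | (s + len - 1L) < occ[c(TRUE, FALSE)]))
        return(s)
    }
    stop("could not place repeat family; genome too small for repeat config")
  }

  mutate_unit <- function(unit, rate) {
    n_mut <- rbinom(1L, length(unit), rate)
    if (n_mut > 0) {
      at <- sample.int(length(unit), n_mut)
      unit[at] <- ((unit[at] - 1L + sample.int(3L, n_mut, replace = TRUE)) %% 4L) + 1L
    }
    unit
  }

  td <- gc$tandem
  if (!is.null(td) && isTRUE(td$n_families > 0)) {
    for (f in seq_len(td$n_families)) {
      if (td$n_copies < 5)
        stop("tandem families must have >= 5 copies")
      unit <- sample.int(4L, td$unit_bp, replace = TRUE)
      arr_len <- as.integer(td$unit_bp * td$n_copies)
      chr_idx <- sample.int(n_chr, 1L)
      s <- place_interval(chr_idx, arr_len)
      arr <- unlist(lapply(seq_len(td$n_copies), function(i)
        mutate_unit(unit, td$divergence)))
      seqs_int[[chr_idx]][s:(s + arr_len - 1L)] <- arr
      occupied[[chr_idx]] <- c(occupied[[chr_idx]], s, s + arr_len - 1L)
      repeats[[length(repeats) + 1L]] <- data.frame(
        chrom = chr_names[chr_idx], start = s, end = s + arr_len - 1L,
        family = sprintf("tandem%02d", f), kind = "tandem",
        stringsAsFactors = FALSE)
    }
  }

  dp <- gc$dispersed
  if (!is.null(dp) && isTRUE(dp$n_families > 0)) {
    for (f in seq_len(dp$n_families)) {
      unit <- sample.int(4L, dp$unit_bp, replace = TRUE)
      for (cp in seq_len(dp$n_copies)) {
        chr_idx <- sample.int(n_chr, 1L)
        s <- place_interval(chr_idx, dp$unit_bp)
        seqs_int[[chr_idx]][s:(s + dp$unit_bp - 1L)] <-
          mutate_unit(unit, dp$divergence)
        occupied[[chr_idx]] <- c(occupied[[chr_idx]], s, s + dp$unit_bp - 1L)
        repeats[[length(repeats) + 1L]] <- data.frame(
          chrom = chr_names[chr_idx], start = s, end = s + dp$unit_bp - 1L,
          family = sprintf("dispersed%02d", f), kind = "dispersed",
          stringsAsFactors = FALSE)
      }
    }
  }

  letters4 <- utf8ToInt("ACGT")
  seq_strings <- vapply(seqs_int, function(v) intToUtf8(letters4[v]),
                        character(1))
  seqs <- Biostrings::DNAStringSet(seq_strings)
  names(seqs) <- chr_names

  repeats <- if (length(repeats)) do.call(rbind, repeats) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               family = character(0), kind = character(0))

  lg <- setNames(as.character(utils::as.roman(seq_len(n_chr))), chr_names)

  structure(list(seqs = seqs, repeats = repeats, linkage_groups = lg,
                 cm_per_mb = gc$cm_per_mb %||% 2.7,
                 seed = config$seed),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosomes, %.1f Mb, %d repeat annotations\n",
              length(x$seqs), sum(Biostrings::width(x$seqs)) / 1e6,
              nrow(x$repeats)))
  invisible(x)
}

genome_length <- function(genome) sum(Biostrings::width(genome$seqs))
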