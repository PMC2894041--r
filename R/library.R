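#' Sample a plated BAC library from a genome
#'
#' Draws clone inserts with uniformly distributed start positions and
#' normally distributed insert sizes, lays the clones out on 384-well plates
#' (16 rows A-P by 24 columns) and marks a configured fraction of wells as
#' empty (vector-only) clones. Clone identifiers follow the
#' `Cm<plate>_<row><column>` plate-coordinate convention.
#'
#' @param genome a [generate_genome()] result.
#' @param config a [sim_config()] list (`library` section and `seed` used).
#' @return Object of class `bac_library`: a data.frame with columns
#'   `clone_id, plate, row, col, chrom, start, end, empty` (1-based closed
#'   spans; empty clones have `NA` coordinates), and attributes
#'   `insert_mean_bp`, `empty_fraction`, `genome_bp`.
#' @examples
#' cfg <- sim_config(1, genome = list(genome_bp = 2e6, n_chromosomes = 2),
#'                   library = list(plates = 1L))
#' g <- generate_genome(cfg)
#' lib <- sample_bac_library(g, cfg)
#' nrow(lib)  # 384 clones
#' @export
sample_bac_library <- function(genome, config) {
  lc <- config$library
  set.seed(stage_seed(config$seed, 23L))
  lens <- Biostrings::width(genome$seqs)
  if (lc$insert_mean_bp > min(lens))
    stop("configuration error: mean insert size exceeds shortest chromosome")
  n <- as.integer(lc$plates) * 384L
  plate <- rep(seq_len(lc$plates), each = 384L)
  row <- rep(rep(LETTERS[1:16], each = 24L), times = lc$plates)
  col <- rep(rep(1:24, times = 16L), times = lc$plates)
  clone_id <- sprintf("Cm%02d_%s%02d", plate, row, col)

  empty <- rbinom(n, 1L, lc$empty_fraction) == 1L
  ins <- pmax(1000, round(rnorm(n, lc$insert_mean_bp, lc$insert_sd_bp)))
  ins <- pmin(ins, min(lens))
  # uniform starts over the genome: chromosomes weighted by length
  chr_idx <- sample.int(length(lens), n, replace = TRUE, prob = lens)
  start <- as.integer(1 + floor(runif(n) * pmax(lens[chr_idx] - ins + 1, 1)))
  end <- start + as.integer(ins) - 1L
  start[empty] <- NA_integer_; end[empty] <- NA_integer_
  chrom <- names(genome$seqs)[chr_idx]
  chrom[empty] <- NA_character_

  lib <- data.frame(clone_id = clone_id, plate = plate, row = row, col = col,
                    chrom = chrom, start = start, end = end, empty = empty,
                    stringsAsFactors = FALSE)
  attr(lib, "insert_mean_bp") <- lc$insert_mean_bp
  attr(lib, "empty_fraction") <- lc$empty_fraction
  attr(lib, "genome_bp") <- sum(lens)
  class(lib) <- c("bac_library", "data.frame")
  lib
}

#' Library depth in genome equivalents
#'
#' Expected per-base coverage of a clone library:
#' `n_clones * (1 - empty_fraction) * mean_insert_bp / genome_bp`.
#'
#' @param n_clones total wells in the library.
#' @param empty_fraction fraction of empty (insert-free) wells.
#' @param mean_insert_bp mean insert size in bp.
#' @param genome_bp haploid genome size in bp.
#' @return Coverage multiple (unrounded; report to one decimal).
#' @examples
#' genome_equivalents(23040, 0.20, 139e3, 445e6)  # ~5.76x
#' @export
genome_equivalents <- function(n_clones, empty_fraction, mean_insert_bp,
                               genome_bp) {
  if (genome_bp <= 0) stop("genome_bp must be positive")
  if (n_clones == 0) return(0)
  n_clones * (1 - empty_fraction) * mean_insert_bp / genome_bp
}

#' Achieved genome equivalents of a sampled library
#'
#' @param library a [sample_bac_library()] result.
#' @return Total non-empty insert length divided by genome length.
#' @export
achieved_equivalents <- function(library) {
  g <- attr(library, "genome_bp")
  sum(as.numeric(library$end - library$start + 1L), na.rm = TRUE) / g
}
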