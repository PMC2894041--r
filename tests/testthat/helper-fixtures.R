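# Shared fixtures, all generated in code.

# small simulation configuration used across module tests (not the desk
# scale; kept small so unit tests stay fast)
small_config <- function(seed = 1) {
  sim_config(seed,
             genome = list(genome_bp = 3e6, n_chromosomes = 3,
                           tandem = list(n_families = 1, unit_bp = 2000,
                                         n_copies = 10, divergence = 0.01),
                           dispersed = list(n_families = 1, unit_bp = 1000,
                                            n_copies = 5, divergence = 0.02)),
             library = list(plates = 2L),
             markers = list(n = 30L),
             screening = list(superpool_size = 2L))
}

# build a fingerprint_set from explicit band lists
make_fp_set <- function(clone_ids, colors, sizes) {
  ord <- lapply(seq_along(clone_ids), function(i) order(colors[[i]], sizes[[i]]))
  structure(list(
    clone_id = clone_ids,
    color = lapply(seq_along(clone_ids), function(i) as.integer(colors[[i]][ord[[i]]])),
    size_nt = lapply(seq_along(clone_ids), function(i) sizes[[i]][ord[[i]]] / 30),
    size_int = lapply(seq_along(clone_ids), function(i) as.integer(sizes[[i]][ord[[i]]])),
    n_bands = vapply(colors, length, integer(1)),
    color_levels = c("blue", "green", "red", "yellow"),
    params = band_calling_params()),
    class = "fingerprint_set")
}

# a staggered tiling of clones over a master band ladder: clone k carries
# bands [start_k, start_k + bands_per_clone) of the ladder
tiling_fp_set <- function(n_clones, bands_per_clone, step, seed = 42,
                          n_ladder = NULL) {
  set.seed(seed)
  if (is.null(n_ladder)) n_ladder <- (n_clones - 1) * step + bands_per_clone
  ladder_size <- sort(sample(1500:15000, n_ladder))
  ladder_color <- sample.int(4L, n_ladder, replace = TRUE)
  ids <- sprintf("T%03d", seq_len(n_clones))
  colors <- list(); sizes <- list()
  for (k in seq_len(n_clones)) {
    sel <- ((k - 1) * step + 1):((k - 1) * step + bands_per_clone)
    colors[[k]] <- ladder_color[sel]
    sizes[[k]] <- ladder_size[sel]
  }
  make_fp_set(ids, colors, sizes)
}

# deterministic small library layout (no genome needed) for pool tests
layout_library <- function(plates, genome_bp = 1e6) {
  plate <- rep(seq_len(plates), each = 384L)
  row <- rep(rep(LETTERS[1:16], each = 24L), times = plates)
  col <- rep(rep(1:24, times = 16L), times = plates)
  lib <- data.frame(clone_id = sprintf("Cm%02d_%s%02d", plate, row, col),
                    plate = plate, row = row, col = col,
                    chrom = "chr01", start = NA_integer_, end = NA_integer_,
                    empty = TRUE, stringsAsFactors = FALSE)
  attr(lib, "genome_bp") <- genome_bp
  class(lib) <- c("bac_library", "data.frame")
  lib
}

# place one clone of the layout library at given coordinates
place_clone <- function(lib, clone_id, chrom, start, end) {
  i <- match(clone_id, lib$clone_id)
  lib$chrom[i] <- chrom; lib$start[i] <- start; lib$end[i] <- end
  lib$empty[i] <- FALSE
  lib
}

# a random DNA string free of all recognition sites of the default enzymes
site_free_seq <- function(len, seed = 1) {
  set.seed(seed)
  enz <- default_enzymes()
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    hits <- vapply(enz$site, function(p)
      length(Biostrings::start(Biostrings::matchPattern(p, Biostrings::DNAString(s)))),
      integer(1))
    if (sum(hits) == 0) return(s)
  }
}

splice_site <- function(seq, site, at0) {
  # overwrite the recognition site at 0-based position at0
  paste0(substr(seq, 1, at0), site, substr(seq, at0 + nchar(site) + 1,
                                           nchar(seq)))
}
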