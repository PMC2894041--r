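#' Plant a genetic-marker panel on a simulated genome
#'
#' Distributes markers evenly across linkage groups and evenly (with jitter)
#' along each chromosome, avoiding annotated repeats, and assigns each marker
#' a PCR target interval of 100-1,000 bp. A configured fraction of markers
#' amplify duplicated loci and receive 2-3 target intervals, the extra copies
#' placed at independent random positions (possibly on other chromosomes, so
#' some duplicated markers genetically map two linkage groups). Genetic
#' positions follow `cm = cm_per_mb * physical Mb` (uniform recombination).
#'
#' @param genome a [generate_genome()] result.
#' @param n number of markers.
#' @param dup_fraction fraction of markers with duplicated loci; the count is
#'   `round(n * dup_fraction)` for reproducible panel composition.
#' @param seed integer seed.
#' @param class_counts named integer vector giving the marker-class mix
#'   (proportions are scaled to `n`).
#' @return Object of class `marker_panel`: list with
#'   \describe{
#'     \item{markers}{data.frame `marker_id, class, linkage_group, cm,
#'       n_loci, lg2, cm2` (secondary genetic position when a duplicated
#'       locus falls on another chromosome, else `NA`)}
#'     \item{targets}{data.frame `marker_id, chrom, start, end` with one row
#'       per amplifiable locus}
#'   }
#' @examples
#' cfg <- sim_config(1, genome = list(genome_bp = 3e6, n_chromosomes = 3))
#' g <- generate_genome(cfg)
#' pan <- plant_markers(g, n = 30, dup_fraction = 0.2, seed = 5)
#' table(pan$markers$n_loci)
#' @export
plant_markers <- function(genome, n, dup_fraction = 0.2, seed = 1L,
                          class_counts = c(RFLP = 117L, SNP = 96L, SSR = 2L)) {
  if (dup_fraction < 0 || dup_fraction > 1)
    stop("dup_fraction must be in [0, 1]")
  set.seed(stage_seed(seed, 37L))
  chrs <- names(genome$seqs)
  lens <- setNames(Biostrings::width(genome$seqs), chrs)
  n <- as.integer(n)

  # even per-LG allocation: n %/% n_chr everywhere, remainder round-robin
  n_chr <- length(chrs)
  per <- rep(n %/% n_chr, n_chr) +
    as.integer(seq_len(n_chr) <= n %% n_chr)

  rep_by_chr <- split(genome$repeats, genome$repeats$chrom)

  in_repeat <- function(chrom, s, e) {
    r <- rep_by_chr[[chrom]]
    if (is.null(r) || nrow(r) == 0) return(FALSE)
    any(s <= r$end & e >= r$start)
  }

  pick_free <- function(chrom, s, len) {
    # jump past any overlapping repeat until a clean placement is found
    r <- rep_by_chr[[chrom]]
    for (try in 1:100) {
      e <- s + len - 1L
      if (e > lens[chrom]) { s <- 1L; next }
      if (is.null(r) || nrow(r) == 0) return(s)
      hit <- which(s <= r$end & e >= r$start)
      if (!length(hit)) return(s)
      s <- max(r$end[hit]) + 1L
    }
    stop("marker count exceeds available non-repeat positions")
  }

  rows <- vector("list", n)
  tgts <- vector("list", n)
  idx <- 0L
  for (k in seq_len(n_chr)) {
    m <- per[k]
    if (m == 0) next
    spacing <- lens[k] / (m + 1)
    if (spacing < 2000)
      stop("marker count exceeds available non-repeat positions")
    for (i in seq_len(m)) {
      idx <- idx + 1L
      len <- sample(100:1000, 1L)
      s <- as.integer(i * spacing + round(runif(1, -0.3, 0.3) * spacing))
      s <- max(1L, min(s, lens[k] - len))
      s <- pick_free(chrs[k], s, len)
      rows[[idx]] <- data.frame(chrom = chrs[k], start = s,
                                end = s + len - 1L, stringsAsFactors = FALSE)
    }
  }
  prim <- do.call(rbind, rows)

  # class labels: scale the configured mix to n, assign round-robin over the
  # genome so each class stays spread across linkage groups
  cls_n <- round(class_counts / sum(class_counts) * n)
  while (sum(cls_n) > n) cls_n[which.max(cls_n)] <- cls_n[which.max(cls_n)] - 1
  while (sum(cls_n) < n) cls_n[which.max(class_counts)] <-
      cls_n[which.max(class_counts)] + 1
  cls <- sample(rep(names(cls_n), cls_n))

  marker_id <- sprintf("%s_%03d", cls, stats::ave(seq_len(n), cls,
                                                  FUN = seq_along))
  lg <- genome$linkage_groups[prim$chrom]
  cm <- genome$cm_per_mb * (prim$start + prim$end) / 2 / 1e6

  n_dup <- round(n * dup_fraction)
  dup_idx <- if (n_dup > 0) sample.int(n, n_dup) else integer(0)
  n_loci <- rep(1L, n)
  # duplicated markers carry 2 loci, occasionally 3
  n_loci[dup_idx] <- 2L + (runif(n_dup) < 0.2)

  targets <- data.frame(marker_id = marker_id, chrom = prim$chrom,
                        start = prim$start, end = prim$end,
                        stringsAsFactors = FALSE)
  lg2 <- rep(NA_character_, n)
  cm2 <- rep(NA_real_, n)
  for (i in dup_idx) {
    for (cpy in seq_len(n_loci[i] - 1L)) {
      len <- sample(100:1000, 1L)
      ch <- sample(chrs, 1L)
      s <- pick_free(ch, sample.int(lens[ch] - len, 1L), len)
      targets <- rbind(targets, data.frame(
        marker_id = marker_id[i], chrom = ch, start = s, end = s + len - 1L,
        stringsAsFactors = FALSE))
      if (cpy == 1L && ch != prim$chrom[i]) {
        lg2[i] <- genome$linkage_groups[[ch]]
        cm2[i] <- genome$cm_per_mb * (s + len / 2) / 1e6
      }
    }
  }

  markers <- data.frame(marker_id = marker_id, class = cls,
                        linkage_group = unname(lg), cm = unname(cm),
                        n_loci = n_loci, lg2 = lg2, cm2 = cm2,
                        stringsAsFactors = FALSE)
  markers <- markers[order(markers$marker_id), ]
  rownames(markers) <- NULL
  targets <- targets[order(targets$marker_id, targets$chrom, targets$start), ]
  rownames(targets) <- NULL
  structure(list(markers = markers, targets = targets),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel: %d markers (%s), %d duplicated\n",
              nrow(x$markers),
              paste(names(table(x$markers$class)),
                    table(x$markers$class), sep = "=", collapse = ", "),
              sum(x$markers$n_loci > 1)))
  invisible(x)
}
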