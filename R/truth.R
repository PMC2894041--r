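#' True-overlap clone pairs from simulator ground truth
#'
#' All pairs of clones whose genomic spans overlap by at least `min_frac` of
#' the shorter span. Used to benchmark assembly sensitivity against the
#' simulator's clone coordinates.
#'
#' @param library a [sample_bac_library()] result.
#' @param clone_ids clones to consider (typically the valid fingerprints).
#' @param min_frac minimum overlap as a fraction of the shorter clone.
#' @return data.frame `a, b` of clone-id pairs (a < b).
#' @export
true_overlap_pairs <- function(library, clone_ids = NULL, min_frac = 0.5) {
  lib <- library[!library$empty, , drop = FALSE]
  if (!is.null(clone_ids)) lib <- lib[lib$clone_id %in% clone_ids, , drop = FALSE]
  out <- list()
  for (ch in unique(lib$chrom)) {
    sub <- lib[lib$chrom == ch, , drop = FALSE]
    ir <- IRanges::IRanges(start = sub$start, end = sub$end)
    ov <- IRanges::findOverlaps(ir, ir)
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    keep <- qi < si
    qi <- qi[keep]; si <- si[keep]
    if (!length(qi)) next
    w <- pmin(sub$end[qi], sub$end[si]) - pmax(sub$start[qi], sub$start[si]) + 1
    minw <- pmin(sub$end[qi] - sub$start[qi], sub$end[si] - sub$start[si]) + 1
    keep2 <- w >= min_frac * minw
    if (!any(keep2)) next
    a <- sub$clone_id[qi[keep2]]; b <- sub$clone_id[si[keep2]]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    out[[ch]] <- data.frame(a = a, b = b, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(a = character(0), b = character(0))
  rownames(res) <- NULL
  res
}

# does a clone span intersect any repeat annotation; returns the families hit
clone_repeat_families <- function(library, genome) {
  fam <- setNames(vector("list", nrow(library)), library$clone_id)
  rp <- genome$repeats
  if (nrow(rp) == 0) return(fam)
  for (ch in unique(rp$chrom)) {
    r <- rp[rp$chrom == ch, , drop = FALSE]
    sel <- which(!library$empty & library$chrom == ch)
    if (!length(sel)) next
    ir_c <- IRanges::IRanges(library$start[sel], library$end[sel])
    ir_r <- IRanges::IRanges(r$start, r$end)
    ov <- IRanges::findOverlaps(ir_c, ir_r)
    for (k in seq_along(ov)) {
      i <- sel[S4Vectors::queryHits(ov)[k]]
      fam[[i]] <- union(fam[[i]], r$family[S4Vectors::subjectHits(ov)[k]])
    }
  }
  fam
}

#' Benchmark an assembly against simulator ground truth
#'
#' Three accuracy metrics computed from the simulator's clone coordinates:
#' \describe{
#'   \item{sensitivity}{fraction of valid-clone pairs with >= `min_frac`
#'     true span overlap that share a contig.}
#'   \item{false_join_rate}{among score edges at the final merge cutoff that
#'     are co-contiged, the fraction joining clones with zero true overlap
#'     that is not explained by a shared annotated repeat family (transitive
#'     non-overlapping pairs inside a correctly assembled long contig are
#'     not false joins, so the rate is measured on the joining edges).}
#'   \item{order_accuracy}{fraction of contigs of >= 4 clones whose
#'     consensus-band order matches the true genomic order up to reversal.
#'     Clone pairs separated by less than `resolution_frac` of the mean
#'     insert are effectively buried: their band-content difference is
#'     within the matching noise (~2 standard deviations of the shared-band
#'     fraction at typical band counts), as are nested pairs (one span
#'     containing >= 90% of the other: buried clones); fingerprints cannot
#'     order either kind, so such pairs are not required to be
#'     concordant.}
#' }
#'
#' @param map a `physical_map`.
#' @param library the [sample_bac_library()] truth.
#' @param genome the [generate_genome()] truth (repeat annotations).
#' @param min_frac true-overlap threshold for sensitivity.
#' @param resolution_frac orderability resolution as a fraction of the mean
#'   insert size (default 0.1, the ~2-sigma positional discrimination limit
#'   of band-share estimates at ~70-100 bands per clone).
#' @return List with the three metrics and their denominators.
#' @export
assembly_accuracy <- function(map, library, genome, min_frac = 0.5,
                              resolution_frac = 0.1) {
  fp <- map$fingerprints
  members <- map_members(map)
  unit_of <- setNames(members$unit, members$clone_id)

  truth <- true_overlap_pairs(library, fp$clone_id, min_frac)
  sens <- mean(unit_of[truth$a] == unit_of[truth$b] &
                 unit_of[truth$a] %in% names(map$contigs))

  # false joins on score edges at the loosest schedule cutoff
  final_cutoff <- max(map$params$merge_schedule)
  sc <- map$scores
  e <- sc[sc$log10_score <= log10(final_cutoff), , drop = FALSE]
  ea <- fp$clone_id[e$i]; eb <- fp$clone_id[e$j]
  same_unit <- unit_of[ea] == unit_of[eb] &
    unit_of[ea] %in% names(map$contigs)
  ea <- ea[same_unit]; eb <- eb[same_unit]
  ia <- match(ea, library$clone_id); ib <- match(eb, library$clone_id)
  ov <- library$chrom[ia] == library$chrom[ib] &
    library$start[ia] <= library$end[ib] & library$end[ia] >= library$start[ib]
  fams <- clone_repeat_families(library, genome)
  rep_explained <- mapply(function(x, y)
    length(intersect(fams[[x]], fams[[y]])) > 0, ea, eb)
  false_join_rate <- if (length(ov))
    sum(!ov & !rep_explained) / length(ov) else 0

  # ordering of >= 4-clone contigs, up to reversal, at fingerprint resolution
  res_bp <- resolution_frac * mean(library$end - library$start + 1, na.rm = TRUE)
  big <- Filter(function(cg) length(cg$clones) >= 4, map$contigs)
  ord_ok <- vapply(big, function(cg) {
    ids <- fp$clone_id[cg$cb$order]
    li <- match(ids, library$clone_id)
    if (length(unique(library$chrom[li])) > 1) return(FALSE)
    concordant_up_to_reversal(library$start[li], library$end[li], res_bp)
  }, logical(1))
  list(sensitivity = sens, n_true_pairs = nrow(truth),
       false_join_rate = false_join_rate, n_join_edges = length(ov),
       order_accuracy = if (length(ord_ok)) mean(ord_ok) else NA_real_,
       n_contigs_ge4 = length(ord_ok))
}

# Are clone spans sorted by start (in either direction)?  Pairs that carry no
# ordering information in band space are skipped: starts closer than the
# resolution limit, and nested pairs (overlap >= 90% of the shorter span,
# i.e. buried clones).
concordant_up_to_reversal <- function(start, end, res_bp) {
  n <- length(start)
  ok_fwd <- TRUE; ok_rev <- TRUE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (abs(start[i] - start[j]) <= res_bp) next
    ov <- min(end[i], end[j]) - max(start[i], start[j]) + 1
    if (ov >= 0.9 * (min(end[i] - start[i], end[j] - start[j]) + 1)) next
    if (start[i] > start[j]) ok_fwd <- FALSE
    if (start[i] < start[j]) ok_rev <- FALSE
    if (!ok_fwd && !ok_rev) return(FALSE)
  }
  ok_fwd || ok_rev
}
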