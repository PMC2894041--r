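#' Three-dimensional pooling decomposition of a BAC library
#'
#' Replicates each 384-well plate (16 rows x 24 columns) into a 96-well
#' plate (8 rows x 12 columns) with the 4 clones of each 2x2 quadrant
#' sharing a well, then forms the screening pools: one pool per plate (384
#' clones at full scale), superpools of `superpool_size` plate pools, and
#' per-plate row pools (12 wells x 4 = 48 clones) and column pools (8 wells
#' x 4 = 32 clones) on the reduced plate.
#'
#' @param library a [sample_bac_library()] result (or any data.frame with
#'   `clone_id, plate, row, col`).
#' @param superpool_size plate pools per superpool; the plate count must be
#'   divisible by it.
#' @return Object of class `pooling_scheme`: list with `assignments` (one
#'   row per clone: `clone_id, plate, superpool, row96, col96, well`) and
#'   `counts` (pools per tier).
#' @examples
#' # a 60-plate library yields 12 superpools, 480 row pools, 720 column pools
#' @export
build_pools <- function(library, superpool_size = 5L) {
  plates <- sort(unique(library$plate))
  if (length(plates) %% superpool_size != 0)
    stop("configuration error: plate count not divisible by superpool size")
  row_idx <- match(library$row, LETTERS[1:16])
  if (any(is.na(row_idx)) || any(library$col < 1 | library$col > 24))
    stop("library must use 384-well coordinates (rows A-P, columns 1-24)")
  row96 <- (row_idx + 1L) %/% 2L           # 1..8
  col96 <- (library$col + 1L) %/% 2L       # 1..12
  assignments <- data.frame(
    clone_id = library$clone_id,
    plate = library$plate,
    superpool = (match(library$plate, plates) - 1L) %/% superpool_size + 1L,
    row96 = row96, col96 = col96,
    well = sprintf("P%02d_%s%02d", library$plate, LETTERS[row96], col96),
    stringsAsFactors = FALSE)
  counts <- c(superpools = length(plates) %/% superpool_size,
              plate_pools = length(plates),
              row_pools = length(plates) * 8L,
              column_pools = length(plates) * 12L,
              wells = length(plates) * 96L)
  structure(list(assignments = assignments, counts = counts,
                 superpool_size = as.integer(superpool_size)),
            class = "pooling_scheme")
}

#' True positive clones of a marker
#'
#' The brute-force containment rule: a clone is positive when its insert
#' span fully contains at least one of the marker's target intervals (both
#' primer sites must lie within the insert). Empty clones are never
#' positive.
#'
#' @param marker_id marker identifier.
#' @param panel a [plant_markers()] result.
#' @param library a [sample_bac_library()] result.
#' @return Character vector of positive clone ids.
#' @export
true_positive_clones <- function(marker_id, panel, library) {
  tg <- panel$targets[panel$targets$marker_id == marker_id, , drop = FALSE]
  lib <- library[!library$empty, , drop = FALSE]
  hits <- character(0)
  for (k in seq_len(nrow(tg))) {
    sel <- lib$chrom == tg$chrom[k] & lib$start <= tg$start[k] &
      lib$end >= tg$end[k]
    hits <- c(hits, lib$clone_id[sel])
  }
  sort(unique(hits))
}

#' Simulate one pooled PCR reaction
#'
#' The true state is positive when any clone of the pool contains one of the
#' marker's target intervals; the observed call flips with the false-negative
#' or false-positive rate.
#'
#' @param pool_clones character vector of clone ids in the pool.
#' @param positive_set precomputed true positive clone ids for the marker
#'   (see [true_positive_clones()]).
#' @param fn_rate,fp_rate error rates in `[0, 1]`.
#' @return Logical: observed PCR call.
#' @export
simulate_pcr <- function(pool_clones, positive_set, fn_rate = 0,
                         fp_rate = 0) {
  stopifnot(fn_rate >= 0, fn_rate <= 1, fp_rate >= 0, fp_rate <= 1)
  truth <- any(pool_clones %in% positive_set)
  if (truth) runif(1) >= fn_rate else runif(1) < fp_rate
}

#' Screen one marker through the four PCR rounds
#'
#' Round 1 tests all superpools; round 2 the plate pools of positive
#' superpools; round 3 the 12 column pools and 8 row pools of each positive
#' plate; candidate wells are the crosses of positive rows and columns, and
#' round 4 tests each clone of each candidate well individually. With zero
#' error rates the decoded positives equal the containment truth exactly.
#'
#' @param marker_id marker identifier.
#' @param scheme a [build_pools()] result.
#' @param panel a [plant_markers()] result.
#' @param library a [sample_bac_library()] result.
#' @param fn_rate,fp_rate per-reaction error rates.
#' @param seed optional integer seed (only relevant with nonzero rates).
#' @return Object of class `screen_result`: list with `marker_id`,
#'   `dropout` (no positive superpool: library dropout), `positives`
#'   (character), `pcr_count`, `ambiguities_resolved` (candidate wells minus
#'   wells that actually contained positives) and `rounds` (per-round call
#'   tables).
#' @export
screen_marker <- function(marker_id, scheme, panel, library,
                          fn_rate = 0, fp_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  asg <- scheme$assignments
  pos_set <- true_positive_clones(marker_id, panel, library)

  call_pool <- function(clones) simulate_pcr(clones, pos_set, fn_rate, fp_rate)

  # round 1: superpools
  sps <- sort(unique(asg$superpool))
  r1 <- vapply(sps, function(sp)
    call_pool(asg$clone_id[asg$superpool == sp]), logical(1))
  pcr <- length(sps)
  rounds <- list(superpool = data.frame(pool = sps, call = r1))
  if (!any(r1)) {
    return(structure(list(marker_id = marker_id, dropout = TRUE,
                          positives = character(0), pcr_count = pcr,
                          ambiguities_resolved = 0L, rounds = rounds),
                     class = "screen_result"))
  }

  # round 2: plate pools of positive superpools
  plates <- sort(unique(asg$plate[asg$superpool %in% sps[r1]]))
  r2 <- vapply(plates, function(p)
    call_pool(asg$clone_id[asg$plate == p]), logical(1))
  pcr <- pcr + length(plates)
  rounds$plate <- data.frame(pool = plates, call = r2)

  # round 3: 12 column + 8 row pools per positive plate
  pos_plates <- plates[r2]
  well_rows <- list(); n_candidate_wells <- 0L
  candidates <- character(0)
  r3 <- list()
  for (p in pos_plates) {
    sub <- asg[asg$plate == p, , drop = FALSE]
    rows <- vapply(1:8, function(r)
      call_pool(sub$clone_id[sub$row96 == r]), logical(1))
    cols <- vapply(1:12, function(cl)
      call_pool(sub$clone_id[sub$col96 == cl]), logical(1))
    pcr <- pcr + 20L
    r3[[as.character(p)]] <- list(rows = rows, cols = cols)
    for (r in which(rows)) for (cl in which(cols)) {
      n_candidate_wells <- n_candidate_wells + 1L
      candidates <- c(candidates,
                      sub$clone_id[sub$row96 == r & sub$col96 == cl])
    }
  }
  rounds$row_col <- r3

  # round 4: individual clones of candidate wells
  r4 <- vapply(candidates, function(cl) call_pool(cl), logical(1))
  pcr <- pcr + length(candidates)
  positives <- sort(candidates[r4])
  pos_wells <- unique(asg$well[match(positives, asg$clone_id)])
  structure(list(marker_id = marker_id, dropout = FALSE,
                 positives = positives, pcr_count = pcr,
                 ambiguities_resolved = n_candidate_wells -
                   length(pos_wells),
                 rounds = rounds),
            class = "screen_result")
}

#' Screen a whole marker panel
#'
#' Runs [screen_marker()] for every marker and aggregates the anchoring
#' summary: markers with positives, dropouts, the BACs-per-marker histogram
#' and per-class means.
#'
#' @param panel a [plant_markers()] result.
#' @param scheme a [build_pools()] result.
#' @param library a [sample_bac_library()] result.
#' @param fn_rate,fp_rate per-reaction error rates.
#' @param seed integer seed.
#' @return List of class `screen_panel` with `results` (named list of
#'   `screen_result`) and `summary` (list: `n_markers`, `n_dropout`,
#'   `n_anchored`, `total_positive_links`, `histogram` — table of markers by
#'   positive-BAC count — and `class_means`).
#' @export
screen_panel <- function(panel, scheme, library, fn_rate = 0, fp_rate = 0,
                         seed = 1L) {
  set.seed(stage_seed(seed, 53L))
  ids <- panel$markers$marker_id
  results <- lapply(ids, screen_marker, scheme = scheme, panel = panel,
                    library = library, fn_rate = fn_rate, fp_rate = fp_rate)
  names(results) <- ids
  npos <- vapply(results, function(r) length(r$positives), integer(1))
  dropout <- vapply(results, function(r) r$dropout, logical(1))
  anchored <- !dropout & npos > 0
  cls <- panel$markers$class[match(ids, panel$markers$marker_id)]
  class_means <- tapply(npos[anchored], cls[anchored], mean)
  summary <- list(
    n_markers = length(ids),
    n_dropout = sum(dropout | npos == 0),
    n_anchored = sum(anchored),
    total_positive_links = sum(npos),
    histogram = table(factor(npos[anchored], levels = 1:max(npos, 1))),
    class_means = class_means,
    mean_bacs_per_marker = mean(npos[anchored]))
  structure(list(results = results, summary = summary),
            class = "screen_panel")
}

#' @export
print.screen_panel <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "screen_panel: %d markers, %d anchored to %d BAC links, %d dropouts\n",
    s$n_markers, s$n_anchored, s$total_positive_links, s$n_dropout))
  invisible(x)
}
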