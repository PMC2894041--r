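#' Build a physical map by single-linkage Sulston clustering
#'
#' Clusters clones whose pairwise Sulston score is at or below the cutoff
#' (single linkage over the score graph); clusters of two or more clones
#' become contigs with consensus-band (CB) maps, size-one clusters are
#' singletons.
#'
#' @param fp a `fingerprint_set` (after [qc_filter()]).
#' @param cutoff Sulston-score cutoff.
#' @param params [assembly_params()].
#' @param scores optional precomputed [pair_scores()] (computed if missing).
#' @param kb_per_band optional physical-length calibration (kb per consensus
#'   unit); defaults to `NA`, in which case physical lengths are not logged.
#' @return Object of class `physical_map`: list with `contigs` (named list;
#'   each contig has `clones` — indices into `fp` — and `cb`, see
#'   [build_cb_map()]), `singletons` (indices), `fingerprints`, `scores`,
#'   `params`, `cutoff`, `kb_per_band` and a `build_log` data.frame.
#' @export
initial_build <- function(fp, cutoff = NULL, params = assembly_params(),
                          scores = NULL, kb_per_band = NA) {
  if (is.null(cutoff)) cutoff <- params$initial_cutoff
  if (is.null(scores)) scores <- pair_scores(fp, params)
  n <- length(fp$clone_id)
  sel <- scores$log10_score <= log10(cutoff)
  comp <- components_cpp(scores$i[sel], scores$j[sel], n)
  groups <- split(seq_len(n), comp)
  sizes <- lengths(groups)
  contig_groups <- groups[sizes >= 2]
  # deterministic ids: largest first, ties by smallest member clone id
  ord <- order(-lengths(contig_groups),
               vapply(contig_groups, function(g) min(fp$clone_id[g]),
                      character(1)))
  contig_groups <- contig_groups[ord]
  map <- structure(list(contigs = list(),
                        singletons = unlist(groups[sizes == 1], use.names = FALSE),
                        fingerprints = fp, scores = scores, params = params,
                        cutoff = cutoff, kb_per_band = kb_per_band,
                        next_id = 1L,
                        build_log = NULL),
                   class = "physical_map")
  for (g in contig_groups) {
    id <- sprintf("Ctg%04d", map$next_id)
    map$next_id <- map$next_id + 1L
    map$contigs[[id]] <- list(clones = g, cb = build_cb_map(fp, g, params))
  }
  map$build_log <- map_log_row(map, "initial", cutoff)
  map
}

#' Build the consensus-band map of a contig
#'
#' A lightweight stand-in for full consensus-band ordering: member clones are
#' ordered by spectral seriation of the shared-band similarity matrix
#' (Fiedler vector of the graph Laplacian, which recovers the linear order of
#' a staggered clone tiling up to reversal), then placed one at a time in
#' that order. Each clone's bands are tolerance-matched against the
#' consensus; unmatched bands extend the consensus unit list, and the clone's
#' matched fraction against the pre-existing consensus is recorded. A clone
#' is flagged questionable (Q) when its matched fraction falls below
#' `q_fit`.
#'
#' @param fp a `fingerprint_set`.
#' @param idx integer indices (or clone ids) of the member clones (>= 2).
#' @param params [assembly_params()].
#' @return List of class `cb_map`: `n_units`, `placements` (data.frame
#'   `clone_id, left, right, matched_frac, q` in seriation order), `order`
#'   (clone indices in map order).
#' @export
build_cb_map <- function(fp, idx, params = assembly_params()) {
  if (is.character(idx)) idx <- match(idx, fp$clone_id)
  n <- length(idx)
  if (n < 2) stop("a contig needs at least 2 clones")
  tol <- params$tolerance_int
  fl <- flatten_subset(fp, idx)
  M <- shared_matrix_cpp(fl$colors, fl$sizes, fl$offsets, tol)
  nb <- fp$n_bands[idx]

  # connectivity at the sparsity threshold used for scoring
  ut <- which(upper.tri(M), arr.ind = TRUE)
  lg <- sulston_log10_cpp(M[ut], pmin(nb[ut[, 1]], nb[ut[, 2]]),
                          pmax(nb[ut[, 1]], nb[ut[, 2]]),
                          tol, params$gellen * params$n_colors)
  conn <- lg <= -8
  comp <- components_cpp(ut[conn, 1], ut[conn, 2], n)
  if (length(unique(comp)) > 1)
    stop("disconnected clone set; split before building a CB map")

  ord <- seriation_order(M, nb, fp$clone_id[idx])
  o_idx <- idx[ord]

  # incremental consensus: per color, sizes sorted with parallel unit ids
  cons_sizes <- list()
  cons_units <- list()
  unit_count <- 0L
  place <- data.frame(clone_id = fp$clone_id[o_idx], left = NA_integer_,
                      right = NA_integer_, matched_frac = NA_real_,
                      q = NA, stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    ci <- o_idx[k]
    cols <- fp$color[[ci]]
    szs <- fp$size_int[[ci]]
    matched <- 0L
    lo_unit <- NA_integer_; hi_unit <- NA_integer_
    for (colr in unique(cols)) {
      key <- as.character(colr)
      a <- szs[cols == colr]
      bsz <- cons_sizes[[key]]
      if (is.null(bsz)) bsz <- integer(0)
      hit <- if (length(bsz)) greedy_match_idx_cpp(a, bsz, tol) else
        integer(length(a))
      got <- hit > 0
      matched <- matched + sum(got)
      if (any(got)) {
        uids <- cons_units[[key]][hit[got]]
        lo_unit <- min(lo_unit, uids, na.rm = TRUE)
        hi_unit <- max(hi_unit, uids, na.rm = TRUE)
      }
      if (any(!got)) {
        new_sz <- a[!got]
        new_id <- unit_count + seq_along(new_sz)
        unit_count <- unit_count + length(new_sz)
        allsz <- c(bsz, new_sz)
        allid <- c(cons_units[[key]], new_id)
        o <- order(allsz)
        cons_sizes[[key]] <- allsz[o]
        cons_units[[key]] <- allid[o]
        lo_unit <- min(lo_unit, new_id, na.rm = TRUE)
        hi_unit <- max(hi_unit, new_id, na.rm = TRUE)
      }
    }
    nb_k <- length(cols)
    frac <- if (k == 1) 1.0 else if (nb_k == 0) 0 else matched / nb_k
    place$left[k] <- lo_unit
    place$right[k] <- hi_unit
    place$matched_frac[k] <- frac
    place$q[k] <- frac < params$q_fit
  }
  structure(list(n_units = unit_count, placements = place, order = o_idx),
            class = "cb_map")
}

flatten_subset <- function(fp, idx) {
  list(colors = as.integer(unlist(fp$color[idx])),
       sizes = as.integer(unlist(fp$size_int[idx])),
       offsets = as.integer(c(0L, cumsum(fp$n_bands[idx]))))
}

# Order clones along the contig by graph geodesics: the shared-band fraction
# f of an overlapping pair falls off linearly with their offset, so edge
# lengths (1 - f) accumulated along shortest paths approximate genomic
# offsets. Clones are ordered by distance from an end clone (the clone with
# the least total similarity); weak edges are kept but heavily penalized so
# they are used only when needed for connectivity. Orientation is
# canonicalized by clone id.
seriation_order <- function(M, nb, ids) {
  n <- length(nb)
  if (n == 2) return(order(ids))
  S <- M / outer(nb, nb, pmin)
  diag(S) <- 0
  # Edge length (1 - S) / S: shared-band fraction saturates with genomic
  # distance, so a linear 1 - S lets shortest paths jump barely-overlapping
  # pairs and collapse the ordering; the odds-style weight diverges as S
  # falls toward the informative floor, making a chain of strong overlaps
  # always cheaper than one long jump. Uninformative edges (S < 0.15) get
  # an additive penalty of n so they serve only as a connectivity fallback.
  W <- (1 - S) / pmax(S, 1e-6)
  W[S < 0.15] <- n + W[S < 0.15]
  diag(W) <- 0
  # double-sweep: the farthest clone from an arbitrary start is a true end
  # of the tiling; ordering by the difference of distances from the two
  # diameter endpoints cancels much of the per-edge estimation noise and is
  # monotone along the whole chain
  d0 <- dijkstra_dist(W, which.min(rowSums(S)))
  u <- which.max(ifelse(is.finite(d0), d0, -Inf))
  dU <- dijkstra_dist(W, u)
  v <- which.max(ifelse(is.finite(dU), dU, -Inf))
  dV <- dijkstra_dist(W, v)
  o <- order(dU - dV, ids)
  o <- polish_order(o, S)
  if (ids[o[1]] > ids[o[n]]) o <- rev(o)
  o
}

# local refinement: a clone belongs left of its successor iff it is more
# similar to the left context and less to the right context; a few
# adjacent-transposition sweeps remove small inversions left by the
# geodesic ordering
polish_order <- function(o, S, max_sweeps = 3L) {
  n <- length(o)
  if (n < 3) return(o)
  for (sweep in seq_len(max_sweeps)) {
    swapped <- FALSE
    for (k in seq_len(n - 1)) {
      x <- o[k]; y <- o[k + 1]
      left <- o[max(1, k - 3):max(1, k - 1)]
      right <- o[min(n, k + 2):min(n, k + 3)]
      left <- setdiff(left, c(x, y)); right <- setdiff(right, c(x, y))
      if (!length(left) || !length(right)) next
      gain <- sum(S[x, left]) - sum(S[y, left]) +
        sum(S[y, right]) - sum(S[x, right])
      if (gain < 0) { o[k] <- y; o[k + 1] <- x; swapped <- TRUE }
    }
    if (!swapped) break
  }
  o
}

dijkstra_dist <- function(W, seed) {
  n <- nrow(W)
  d <- rep(Inf, n); d[seed] <- 0
  visited <- rep(FALSE, n)
  for (step in seq_len(n)) {
    u <- which.min(ifelse(visited, Inf, d))
    if (!is.finite(d[u])) break
    visited[u] <- TRUE
    nd <- d[u] + W[u, ]
    upd <- !visited & nd < d
    d[upd] <- nd[upd]
  }
  d
}

# one build_log row with the current map state
map_log_row <- function(map, step, cutoff) {
  qn <- sum(vapply(map$contigs, function(cg) sum(cg$cb$placements$q),
                   numeric(1)))
  plen <- if (is.na(map$kb_per_band)) NA_real_ else
    sum(vapply(map$contigs, function(cg) cg$cb$n_units, numeric(1))) *
      map$kb_per_band
  data.frame(step = step, cutoff = cutoff,
             n_contigs = length(map$contigs),
             n_singletons = length(map$singletons),
             n_q = qn, physical_length_kb = plen,
             stringsAsFactors = FALSE)
}

append_log <- function(map, step, cutoff) {
  map$build_log <- rbind(map$build_log, map_log_row(map, step, cutoff))
  map
}

contig_q_fraction <- function(cg) mean(cg$cb$placements$q)

#' Break contigs with too many questionable clones (DQer)
#'
#' Every contig whose Q-clone fraction exceeds the threshold is re-clustered
#' at progressively more stringent cutoffs (multiplying by `step_factor` per
#' step) until no offending contig remains or the cutoff floor is reached;
#' compliant contigs are untouched. Clones stranded by the re-clustering
#' become singletons.
#'
#' @param map a `physical_map`.
#' @param q_fraction_threshold maximum tolerated Q fraction.
#' @param step_factor multiplicative cutoff step (default from params).
#' @param floor most stringent cutoff allowed (default from params).
#' @return The updated `physical_map` (with a `build_log` row appended).
#' @export
dqer <- function(map, q_fraction_threshold = NULL, step_factor = NULL,
                 floor = NULL) {
  p <- map$params
  if (is.null(q_fraction_threshold))
    q_fraction_threshold <- p$dq_threshold_initial
  if (is.null(step_factor)) step_factor <- p$dq_step_factor
  if (is.null(floor)) floor <- p$dq_floor
  fp <- map$fingerprints

  offending <- names(map$contigs)[vapply(map$contigs, contig_q_fraction,
                                         numeric(1)) > q_fraction_threshold]
  for (id in offending) {
    idx <- map$contigs[[id]]$clones
    map$contigs[[id]] <- NULL
    parts <- split_at_stringency(map, idx, map$cutoff * step_factor,
                                 q_fraction_threshold, step_factor, floor)
    for (g in parts$groups) {
      nid <- sprintf("Ctg%04d", map$next_id)
      map$next_id <- map$next_id + 1L
      map$contigs[[nid]] <- list(clones = g, cb = build_cb_map(fp, g, p))
    }
    map$singletons <- c(map$singletons, parts$singletons)
  }
  append_log(map, sprintf("DQer %g%%", 100 * q_fraction_threshold),
             map$cutoff)
}

# recursively re-cluster a clone subset at increasing stringency until every
# resulting group complies with the Q threshold (or the floor is reached)
split_at_stringency <- function(map, idx, cutoff, threshold, step, floor) {
  fp <- map$fingerprints
  sc <- map$scores
  keep <- sc$i %in% idx & sc$j %in% idx & sc$log10_score <= log10(cutoff)
  local <- match(c(sc$i[keep], sc$j[keep]), idx)
  ne <- sum(keep)
  comp <- components_cpp(local[seq_len(ne)], local[ne + seq_len(ne)],
                         length(idx))
  groups <- split(idx, comp)
  out_groups <- list(); out_singles <- integer(0)
  for (g in groups) {
    if (length(g) < 2) { out_singles <- c(out_singles, g); next }
    cb <- build_cb_map(fp, g, map$params)
    if (mean(cb$placements$q) > threshold && cutoff > floor) {
      sub <- split_at_stringency(map, g, max(cutoff * step, floor),
                                 threshold, step, floor)
      out_groups <- c(out_groups, sub$groups)
      out_singles <- c(out_singles, sub$singletons)
    } else {
      out_groups <- c(out_groups, list(g))
    }
  }
  list(groups = out_groups, singletons = out_singles)
}

# clone index -> contig id lookup
clone_contig_map <- function(map) {
  n <- length(map$fingerprints$clone_id)
  cc <- rep(NA_character_, n)
  for (id in names(map$contigs)) cc[map$contigs[[id]]$clones] <- id
  cc
}

# end-clone indicator per contig member: placement within from_end units of
# either end of the CB map
end_clones <- function(cg, from_end) {
  pl <- cg$cb$placements
  near <- pl$left <= from_end | pl$right >= cg$cb$n_units - from_end + 1L
  cg$cb$order[near]
}

#' Merge contigs end to end
#'
#' Compares clones placed within `from_end` consensus units of contig ends
#' across all contig pairs; two contigs merge when at least `match_min`
#' cross pairs of end clones score at or below the cutoff. Merging repeats
#' until no qualifying pair remains; the contig count never increases.
#'
#' @param map a `physical_map`.
#' @param cutoff Sulston cutoff for the merge round.
#' @param from_end,match_min see [assembly_params()].
#' @return Updated `physical_map`.
#' @export
end_merge <- function(map, cutoff, from_end = NULL, match_min = NULL) {
  p <- map$params
  if (is.null(from_end)) from_end <- p$from_end
  if (is.null(match_min)) match_min <- p$match_min
  sc <- map$scores
  cand <- sc[sc$log10_score <= log10(cutoff), , drop = FALSE]
  repeat {
    if (length(map$contigs) < 2) break
    cc <- clone_contig_map(map)
    is_end <- rep(FALSE, length(cc))
    for (id in names(map$contigs))
      is_end[end_clones(map$contigs[[id]], from_end)] <- TRUE
    ci <- cc[cand$i]; cj <- cc[cand$j]
    ok <- !is.na(ci) & !is.na(cj) & ci != cj & is_end[cand$i] & is_end[cand$j]
    if (!any(ok)) break
    key <- ifelse(ci[ok] < cj[ok], paste(ci[ok], cj[ok]), paste(cj[ok], ci[ok]))
    cnt <- table(key)
    qual <- names(cnt)[cnt >= match_min]
    if (length(qual) == 0) break
    ids <- names(map$contigs)
    parent <- setNames(ids, ids)
    find <- function(a) { while (parent[[a]] != a) a <- parent[[a]]; a }
    for (q in qual) {
      ab <- strsplit(q, " ", fixed = TRUE)[[1]]
      ra <- find(ab[1]); rb <- find(ab[2])
      if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
    }
    roots <- vapply(ids, find, character(1))
    merged_any <- FALSE
    for (r in unique(roots)) {
      members <- ids[roots == r]
      if (length(members) < 2) next
      merged_any <- TRUE
      all_clones <- unlist(lapply(map$contigs[members], `[[`, "clones"),
                           use.names = FALSE)
      for (m2 in setdiff(members, r)) map$contigs[[m2]] <- NULL
      map$contigs[[r]] <- list(clones = all_clones,
                               cb = build_cb_map(map$fingerprints, all_clones,
                                                 p))
    }
    if (!merged_any) break
  }
  append_log(map, "End-to-End", cutoff)
}

#' Add singletons to contig ends
#'
#' Each singleton scoring at or below the cutoff against an end clone of a
#' contig joins the best-scoring contig (ties broken by lower score, then
#' lexicographic contig id). At most `best_contig` candidate links per
#' singleton are evaluated. The singleton count never increases.
#'
#' @param map a `physical_map`.
#' @param cutoff Sulston cutoff.
#' @return Updated `physical_map`.
#' @export
singles_to_end <- function(map, cutoff) {
  p <- map$params
  if (length(map$contigs) == 0 || length(map$singletons) == 0)
    return(append_log(map, "Singles-to-End", cutoff))
  sc <- map$scores
  cc <- clone_contig_map(map)
  is_end <- rep(FALSE, length(cc))
  for (id in names(map$contigs))
    is_end[end_clones(map$contigs[[id]], p$from_end)] <- TRUE
  sing <- rep(FALSE, length(cc))
  sing[map$singletons] <- TRUE

  cand <- sc[sc$log10_score <= log10(cutoff), , drop = FALSE]
  a <- ifelse(sing[cand$i], cand$i, cand$j)       # singleton side
  b <- ifelse(sing[cand$i], cand$j, cand$i)       # contig side
  ok <- (sing[cand$i] != sing[cand$j]) & is_end[b]
  a <- a[ok]; b <- b[ok]; lg <- cand$log10_score[ok]
  if (length(a) == 0) return(append_log(map, "Singles-to-End", cutoff))

  joined <- list()
  for (s in unique(a)) {
    rows <- which(a == s)
    rows <- rows[order(lg[rows], cc[b[rows]])]
    rows <- head(rows, p$best_contig)
    target <- cc[b[rows[1]]]
    joined[[target]] <- c(joined[[target]], s)
  }
  for (id in names(joined)) {
    map$contigs[[id]]$clones <- c(map$contigs[[id]]$clones, joined[[id]])
    map$contigs[[id]]$cb <- build_cb_map(map$fingerprints,
                                         map$contigs[[id]]$clones, p)
  }
  map$singletons <- setdiff(map$singletons, unlist(joined, use.names = FALSE))
  append_log(map, "Singles-to-End", cutoff)
}

#' Run the full iterated assembly protocol
#'
#' The standard iterated build: a stringent initial assembly, breaking of
#' contigs with more than the initial Q-clone fraction (DQer), then for each
#' cutoff of the merge schedule an End-to-End merge and a Singles-to-End
#' round, with the DQer re-applied at the later threshold whenever some
#' contig exceeds it. The `build_log` records one row per executed step.
#'
#' @param fp a `fingerprint_set` (after [qc_filter()]).
#' @param params [assembly_params()].
#' @param kb_per_band physical-length calibration (kb per consensus unit);
#'   when `NULL` it defaults to mean insert proxy `NA` (lengths unlogged).
#' @return A `physical_map`.
#' @export
iterative_assembly <- function(fp, params = assembly_params(),
                               kb_per_band = NA) {
  scores <- pair_scores(fp, params)
  map <- initial_build(fp, params$initial_cutoff, params, scores,
                       kb_per_band)
  map <- dqer(map, params$dq_threshold_initial)
  for (cutoff in params$merge_schedule) {
    map <- end_merge(map, cutoff)
    map <- singles_to_end(map, cutoff)
    qf <- vapply(map$contigs, contig_q_fraction, numeric(1))
    if (length(qf) && any(qf > params$dq_threshold_later))
      map <- dqer(map, params$dq_threshold_later)
  }
  map
}

#' Initial builds across a range of cutoffs
#'
#' One single-linkage build per cutoff, reported least-stringent first; used
#' to choose the initial cutoff (stricter cutoffs never yield fewer
#' singletons).
#'
#' @param fp a `fingerprint_set`.
#' @param cutoffs numeric vector of at least 2 cutoffs.
#' @param params [assembly_params()].
#' @param kb_per_band optional calibration for the physical-length column.
#' @return data.frame `cutoff, n_contigs, n_singletons, physical_length_kb,
#'   n_q`.
#' @export
cutoff_sweep <- function(fp, cutoffs, params = assembly_params(),
                         kb_per_band = NA) {
  if (length(cutoffs) < 1) stop("need at least one cutoff")
  scores <- pair_scores(fp, params)
  cutoffs <- sort(cutoffs, decreasing = TRUE)
  rows <- lapply(cutoffs, function(co) {
    m <- initial_build(fp, co, params, scores, kb_per_band)
    r <- m$build_log[1, ]
    data.frame(cutoff = co, n_contigs = r$n_contigs,
               n_singletons = r$n_singletons,
               physical_length_kb = r$physical_length_kb, n_q = r$n_q)
  })
  do.call(rbind, rows)
}

#' Physical length of a contig, singleton or map
#'
#' Contig length is its consensus-unit count times the kb-per-band
#' calibration; a singleton's length is its band count times the
#' calibration; a map's total is the sum over contigs (singletons are
#' reported separately).
#'
#' @param x a `physical_map`, a contig (`list(clones, cb)`), a `cb_map`, or
#'   a numeric consensus-unit / band count.
#' @param kb_per_band calibration in kb per consensus unit (e.g. mean insert
#'   size divided by mean valid band count).
#' @return Length in kb (for a map, a list with `total_kb` and
#'   `singleton_kb`).
#' @examples
#' estimate_physical_length(220, 1.363)  # ~300 kb
#' @export
estimate_physical_length <- function(x, kb_per_band) {
  if (kb_per_band <= 0) stop("kb_per_band must be positive")
  if (is.numeric(x)) return(x * kb_per_band)
  if (inherits(x, "cb_map")) return(x$n_units * kb_per_band)
  if (inherits(x, "physical_map")) {
    tot <- sum(vapply(x$contigs, function(cg) cg$cb$n_units, numeric(1))) *
      kb_per_band
    sing <- sum(x$fingerprints$n_bands[x$singletons]) * kb_per_band
    return(list(total_kb = tot, singleton_kb = sing))
  }
  if (is.list(x) && !is.null(x$cb)) return(x$cb$n_units * kb_per_band)
  stop("unsupported input")
}

#' @export
print.physical_map <- function(x, ...) {
  cat(sprintf("physical_map: %d contigs, %d singletons (cutoff %g)\n",
              length(x$contigs), length(x$singletons), x$cutoff))
  invisible(x)
}

#' Contig membership table of a physical map
#'
#' @param map a `physical_map`.
#' @return data.frame `clone_id, unit, unit_type` where `unit` is a contig
#'   id or the clone's own id for singletons.
#' @export
map_members <- function(map) {
  fp <- map$fingerprints
  rows <- lapply(names(map$contigs), function(id)
    data.frame(clone_id = fp$clone_id[map$contigs[[id]]$clones],
               unit = id, unit_type = "contig", stringsAsFactors = FALSE))
  sing <- data.frame(clone_id = fp$clone_id[map$singletons],
                     unit = fp$clone_id[map$singletons],
                     unit_type = rep("singleton", length(map$singletons)),
                     stringsAsFactors = FALSE)
  out <- rbind(do.call(rbind, rows), sing)
  rownames(out) <- NULL
  out
}
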