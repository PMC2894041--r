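#' Assembly parameters for Sulston-score contig building
#'
#' Defaults follow the standard HICF/FPC protocol: integer tolerance 12
#' (= 0.4 nt x 30), initial cutoff 1e-45, merge schedule 1e-40 down to
#' 1e-15, contig breaking (DQer) at 5% questionable clones initially and 10%
#' in later rounds with a 1e-99 floor, End-to-End merging with `from_end` 50
#' consensus units and a minimum of 2 matching clone pairs, and a cap of 100
#' candidate re-evaluations per placement (`best_contig`).
#'
#' @param tolerance_int integer band-matching tolerance.
#' @param initial_cutoff Sulston score for the first automatic build.
#' @param merge_schedule increasing (less stringent) cutoffs for the
#'   End-to-End / Singles-to-End rounds.
#' @param dq_threshold_initial,dq_threshold_later maximum tolerated fraction
#'   of Q-clones per contig at the initial break and in later rounds.
#' @param dq_floor most stringent cutoff the DQer may reach.
#' @param dq_step_factor multiplicative cutoff step per DQer iteration.
#' @param from_end placement distance (consensus units) defining end clones.
#' @param match_min minimum qualifying clone pairs for an End-to-End merge.
#' @param best_contig cap on candidate re-evaluations per clone placement.
#' @param gellen band-space size per label color (size window x multiplying
#'   factor = 13,500 by default).
#' @param n_colors number of label colors; pairwise scoring uses an
#'   effective gel length of `gellen * n_colors` because colors occupy
#'   disjoint band spaces.
#' @param q_fit minimum matched fraction against the consensus-band map
#'   below which a clone is flagged questionable (Q).
#' @return List of class `assembly_params`.
#' @export
assembly_params <- function(tolerance_int = 12L, initial_cutoff = 1e-45,
                            merge_schedule = c(1e-40, 1e-35, 1e-30, 1e-25,
                                               1e-20, 1e-15),
                            dq_threshold_initial = 0.05,
                            dq_threshold_later = 0.10,
                            dq_floor = 1e-99, dq_step_factor = 1e-3,
                            from_end = 50L, match_min = 2L,
                            best_contig = 100L, gellen = 13500,
                            n_colors = 4L, q_fit = 0.5) {
  stopifnot(all(diff(merge_schedule) > 0),
            dq_threshold_initial > 0, dq_threshold_initial < 1,
            dq_threshold_later > 0, dq_threshold_later < 1)
  structure(list(tolerance_int = as.integer(tolerance_int),
                 initial_cutoff = initial_cutoff,
                 merge_schedule = merge_schedule,
                 dq_threshold_initial = dq_threshold_initial,
                 dq_threshold_later = dq_threshold_later,
                 dq_floor = dq_floor, dq_step_factor = dq_step_factor,
                 from_end = as.integer(from_end),
                 match_min = as.integer(match_min),
                 best_contig = as.integer(best_contig),
                 gellen = gellen, n_colors = as.integer(n_colors),
                 q_fit = q_fit),
            class = "assembly_params")
}

#' Count shared bands between two fingerprints
#'
#' Greedy one-to-one matching of same-color bands whose integerized sizes
#' differ by at most `tolerance_int`; each band is used at most once. Bands
#' of different colors never match. For sorted size lists the greedy rule
#' attains the maximum one-to-one matching.
#'
#' @param a,b fingerprints: lists with integer vectors `color` and
#'   `size_int` sorted by (color, size), or single-clone rows of a
#'   `fingerprint_set` extracted with [get_fingerprint()].
#' @param tolerance_int integer tolerance.
#' @return Shared-band count (<= min of the two band counts).
#' @examples
#' a <- list(color = c(1L, 1L, 1L), size_int = c(1000L, 1010L, 1030L))
#' b <- list(color = c(1L, 1L), size_int = c(1005L, 1016L))
#' count_shared_bands(a, b, 12)  # 2
#' @export
count_shared_bands <- function(a, b, tolerance_int = 12L) {
  count_shared_cpp(as.integer(a$color), as.integer(a$size_int),
                   as.integer(b$color), as.integer(b$size_int),
                   as.integer(tolerance_int))
}

#' Extract one clone's fingerprint from a fingerprint set
#'
#' @param fp a `fingerprint_set`.
#' @param clone clone identifier or index.
#' @return List with `clone_id`, `color`, `size_nt`, `size_int`.
#' @export
get_fingerprint <- function(fp, clone) {
  i <- if (is.character(clone)) match(clone, fp$clone_id) else clone
  if (is.na(i)) stop("unknown clone: ", clone)
  list(clone_id = fp$clone_id[i], color = fp$color[[i]],
       size_nt = fp$size_nt[[i]], size_int = fp$size_int[[i]])
}

#' Sulston coincidence score
#'
#' Probability that two unrelated clones with `n_low` and `n_high` bands on
#' a gel of `gellen` size units share at least `M` bands within the
#' tolerance, under the classical binomial approximation:
#' `p1 = 1 - (1 - 2 tol / gellen)^n_high` and
#' `score = sum_{k=M}^{n_low} C(n_low, k) p1^k (1 - p1)^(n_low - k)`,
#' evaluated in log space. Low scores indicate overlap unlikely to be
#' coincidental.
#'
#' @param M shared-band count (`M <= n_low <= n_high`).
#' @param n_low,n_high band counts of the two clones.
#' @param tolerance_int integer tolerance.
#' @param gellen gel (band-space) size in integer units; must exceed
#'   `2 * tolerance_int`.
#' @param log10 return log10 of the score instead of the probability.
#' @return Score in `[0, 1]` (or its log10).
#' @examples
#' sulston_score(0, 10, 10, 12, 13500)   # 1
#' sulston_score(100, 100, 100, 12, 13500, log10 = TRUE)  # << -45
#' @export
sulston_score <- function(M, n_low, n_high, tolerance_int = 12L,
                          gellen = 13500, log10 = FALSE) {
  if (gellen <= 2 * tolerance_int)
    stop("gellen must exceed twice the tolerance")
  if (any(n_low > n_high)) stop("n_low must not exceed n_high")
  n <- max(length(M), length(n_low), length(n_high))
  lg <- sulston_log10_cpp(rep_len(as.integer(M), n),
                          rep_len(as.integer(n_low), n),
                          rep_len(as.integer(n_high), n),
                          as.numeric(tolerance_int),
                          as.numeric(gellen))
  if (log10) lg else 10^lg
}

#' Score all clone pairs of a fingerprint set
#'
#' Computes shared-band counts for every clone pair and the Sulston score for
#' pairs that could conceivably pass a cutoff, keeping pairs with
#' `log10(score) <= keep_log10`. Scoring uses an effective gel length of
#' `gellen * n_colors` since each label color occupies its own band space.
#'
#' @param fp a `fingerprint_set` (after [qc_filter()]).
#' @param params [assembly_params()].
#' @param keep_log10 sparsity threshold; must be at least as permissive as
#'   the loosest cutoff used downstream.
#' @return Object of class `pair_scores`: data.frame `i, j, m, log10_score`
#'   with attribute `clone_id`.
#' @export
pair_scores <- function(fp, params = assembly_params(), keep_log10 = -8) {
  fl <- flatten_fingerprints(fp)
  df <- pair_scores_cpp(fl$colors, fl$sizes, fl$offsets,
                        params$tolerance_int,
                        params$gellen * params$n_colors,
                        keep_log10, m_min = 6L)
  attr(df, "clone_id") <- fp$clone_id
  attr(df, "n_clones") <- length(fp$clone_id)
  class(df) <- c("pair_scores", "data.frame")
  df
}

#' Monte-Carlo oracle for the band-coincidence tail
#'
#' Places `n_low` and `n_high` band sizes independently and uniformly on the
#' continuous interval `(0, gellen]` and counts how many bands of the
#' lower-count clone have at least one band of the other clone within the
#' tolerance -- the per-band coincidence event whose binomial tail the
#' analytic [sulston_score()] describes. Returns the simulated tail
#' probabilities `P(count >= M)`, the empirical reference the formula is
#' validated against.
#'
#' @param n_low,n_high band counts of the two simulated clones.
#' @param reps number of Monte-Carlo draws.
#' @param tolerance_int integer tolerance.
#' @param gellen band-space size.
#' @return data.frame `M, p_mc, se` for `M = 0..n_low` (`se` is the
#'   binomial standard error of `p_mc`).
#' @export
simulate_band_coincidence <- function(n_low, n_high, reps = 1e5,
                                      tolerance_int = 12L, gellen = 13500) {
  tally <- mc_coincidence_cpp(as.integer(n_low), as.integer(n_high),
                              as.integer(reps), as.numeric(tolerance_int),
                              as.numeric(gellen))
  p_ge <- rev(cumsum(rev(tally))) / reps
  data.frame(M = 0:n_low, p_mc = p_ge,
             se = sqrt(pmax(p_ge * (1 - p_ge), 1e-12) / reps))
}
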