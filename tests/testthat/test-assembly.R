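# Many fixtures here are staggered tilings over a master band ladder
# (tiling_fp_set): clone k carries a known window of ladder bands, so true
# overlaps and shared-band counts are exact by construction.

test_that("initial build joins at the cutoff boundary and respects transitivity", {
  p <- assembly_params()
  # two clones sharing a known band count; the cutoff is placed just above
  # and just below their score
  fp2 <- tiling_fp_set(2, 40, 10, seed = 1)
  sc <- pair_scores(fp2, p)
  expect_equal(nrow(sc), 1)
  s <- sc$log10_score[1]
  below <- initial_build(fp2, 10^(s - 0.5), p, sc)
  expect_equal(length(below$contigs), 0)
  expect_equal(length(below$singletons), 2)
  above <- initial_build(fp2, 10^(s + 0.5), p, sc)
  expect_equal(length(above$contigs), 1)
  expect_equal(length(above$singletons), 0)

  # 3-clone chain: adjacent pairs pass, the distant pair does not, yet
  # single linkage puts all three in one contig
  fp3 <- tiling_fp_set(3, 40, 15, seed = 2)
  sc3 <- pair_scores(fp3, p)
  adj <- sc3$log10_score[abs(sc3$j - sc3$i) == 1]
  far <- sc3$log10_score[abs(sc3$j - sc3$i) == 2]
  cut <- 10^((max(adj) + min(far)) / 2)
  expect_true(all(adj < log10(cut)) && all(far > log10(cut)))
  m3 <- initial_build(fp3, cut, p, sc3)
  expect_equal(length(m3$contigs), 1)
  expect_equal(length(m3$contigs[[1]]$clones), 3)
})

test_that("consensus-band maps of identical fingerprints are exact and orders recover tilings", {
  p <- assembly_params()
  sz <- as.integer(seq(1600, 14000, length.out = 60))
  fp <- make_fp_set(c("A", "B"), list(rep(1L, 60), rep(1L, 60)),
                    list(sz, sz))
  cb <- build_cb_map(fp, c("A", "B"), p)
  expect_equal(cb$n_units, 60)
  expect_equal(cb$placements$matched_frac, c(1, 1))
  expect_false(any(cb$placements$q))
  expect_equal(cb$placements$left, c(1, 1))
  expect_equal(cb$placements$right, c(60, 60))

  # a staggered 4-clone tiling is ordered like the genome, up to reversal
  fp4 <- tiling_fp_set(4, 40, 10, seed = 3)
  cb4 <- build_cb_map(fp4, 1:4, p)
  ord <- fp4$clone_id[cb4$order]
  expect_true(identical(ord, sprintf("T%03d", 1:4)) ||
                identical(ord, sprintf("T%03d", 4:1)))
  expect_error(build_cb_map(fp4, 1, p), "at least 2")
})

test_that("a clone matching under half the consensus is Q-flagged and disconnection errors", {
  p <- assembly_params()
  set.seed(9)
  szA <- sort(sample(1500:14500, 60))
  # C shares 20 of A's bands plus 40 alien bands
  szC <- sort(c(sample(szA, 20), sample(20000:25000, 40)))
  fp <- make_fp_set(c("A", "B", "C"),
                    list(rep(1L, 60), rep(1L, 60), rep(1L, 60)),
                    list(szA, szA, szC))
  cb <- build_cb_map(fp, 1:3, p)
  pl <- cb$placements
  expect_false(any(pl$q[pl$clone_id %in% c("A", "B")]))
  expect_true(pl$q[pl$clone_id == "C"])
  expect_lt(pl$matched_frac[pl$clone_id == "C"], 0.5)

  # fully unrelated clone sets cannot share a CB map
  szD <- sort(sample(30000:40000, 60))
  fp2 <- make_fp_set(c("A", "B", "D", "E"),
                     list(rep(1L, 60), rep(1L, 60), rep(1L, 60), rep(1L, 60)),
                     list(szA, szA, szD, szD))
  expect_error(build_cb_map(fp2, 1:4, p), "disconnected")
})

test_that("the DQer leaves compliant maps untouched and breaks a chimera-bridged contig", {
  p <- assembly_params()
  # two unrelated 8-clone stacks bridged by one chimeric clone
  set.seed(21)
  szA <- sort(sample(1500:8000, 60))
  szB <- sort(sample(8500:14500, 60))
  chim <- sort(c(sample(szA, 25), sample(szB, 25), sample(20000:22000, 10)))
  ids <- c(sprintf("A%d", 1:8), sprintf("B%d", 1:8), "XCHIM")
  fp <- make_fp_set(ids,
                    rep(list(rep(1L, 60)), 17),
                    c(rep(list(szA), 8), rep(list(szB), 8), list(chim)))
  sc <- pair_scores(fp, p)
  map <- initial_build(fp, 1e-10, p, sc)
  expect_equal(length(map$contigs), 1)    # chimera bridges both stacks
  expect_equal(length(map$contigs[[1]]$clones), 17)
  qf <- mean(map$contigs[[1]]$cb$placements$q)
  expect_gt(qf, 0.05)

  broken <- dqer(map, 0.05)
  expect_equal(length(broken$contigs), 2)
  expect_setequal(
    broken$fingerprints$clone_id[broken$singletons], "XCHIM")
  sizes <- sort(vapply(broken$contigs, function(cg) length(cg$clones),
                       integer(1)))
  expect_equal(unname(sizes), c(8, 8))
  # postcondition: no contig above the threshold
  expect_true(all(vapply(broken$contigs,
                         function(cg) mean(cg$cb$placements$q),
                         numeric(1)) <= 0.05))

  # a compliant map passes through unchanged
  clean <- initial_build(make_fp_set(c("A", "B"), list(rep(1L, 60), rep(1L, 60)),
                                     list(szA, szA)), 1e-10, p)
  clean2 <- dqer(clean, 0.05)
  expect_equal(lapply(clean2$contigs, `[[`, "clones"),
               lapply(clean$contigs, `[[`, "clones"))
})

test_that("End-to-End merges need match_min qualifying end pairs", {
  p <- assembly_params()
  set.seed(4)
  ladder_sz <- sort(sample(1500:14500, 200))
  ladder_col <- sample.int(4L, 200, replace = TRUE)
  window_fp <- function(ids, starts, width = 40) {
    make_fp_set(ids,
                lapply(starts, function(s) ladder_col[s:(s + width - 1)]),
                lapply(starts, function(s) ladder_sz[s:(s + width - 1)]))
  }
  # group 1 at ladder 1..51, group 2 at 66..116: cross pairs share 25/15/15
  fp <- window_fp(sprintf("C%02d", 1:12),
                  c(seq(1, 51, 10), seq(66, 116, 10)))
  sc <- pair_scores(fp, p)
  # split the groups: build between the within-group adjacent score and the
  # strongest cross-group score
  grp <- rep(1:2, each = 6)
  cross <- sc$log10_score[grp[sc$i] != grp[sc$j]]
  within_adj <- sc$log10_score[grp[sc$i] == grp[sc$j] & sc$j - sc$i == 1]
  cut0 <- 10^((max(within_adj) + min(cross)) / 2)
  map <- initial_build(fp, cut0, p, sc)
  expect_equal(length(map$contigs), 2)
  merged <- end_merge(map, 1e-15)
  expect_equal(length(merged$contigs), 1)
  expect_equal(length(merged$contigs[[1]]$clones), 12)

  # group 2 at 71..121: only one cross pair reaches 1e-20, below match_min
  fp1 <- window_fp(sprintf("D%02d", 1:12),
                   c(seq(1, 51, 10), seq(71, 121, 10)))
  sc1 <- pair_scores(fp1, p)
  map1 <- initial_build(fp1, 1e-33, p, sc1)
  expect_equal(length(map1$contigs), 2)
  not_merged <- end_merge(map1, 1e-20)
  expect_equal(length(not_merged$contigs), 2)

  # disjoint groups never merge
  fp2 <- window_fp(sprintf("E%02d", 1:8),
                   c(seq(1, 31, 10), seq(120, 150, 10)))
  sc2 <- pair_scores(fp2, p)
  map2 <- initial_build(fp2, 1e-33, p, sc2)
  n0 <- length(map2$contigs)
  expect_equal(length(end_merge(map2, 1e-15)$contigs), n0)
})

test_that("Singles-to-End absorbs the best-scoring contig and leaves orphans alone", {
  p <- assembly_params()
  set.seed(6)
  ladder_sz <- sort(sample(1500:14500, 260))
  ladder_col <- sample.int(4L, 260, replace = TRUE)
  window_fp <- function(ids, starts, width = 40) {
    make_fp_set(ids,
                lapply(starts, function(s) ladder_col[s:(s + width - 1)]),
                lapply(starts, function(s) ladder_sz[s:(s + width - 1)]))
  }
  # contig A over ladder 1..90, contig B over 101..190; the singleton at
  # 73..112 shares 18 bands with A's end clone but only 12 with B's, so it
  # must join A; the orphan overlaps nothing
  fp <- window_fp(c(sprintf("A%d", 1:6), sprintf("B%d", 1:6), "S01", "ZZZ"),
                  c(seq(1, 51, 10), seq(101, 151, 10), 73, 221))
  sc <- pair_scores(fp, p)
  map <- initial_build(fp, 1e-38, p, sc)
  expect_equal(length(map$contigs), 2)
  expect_setequal(fp$clone_id[map$singletons], c("S01", "ZZZ"))
  out <- singles_to_end(map, 1e-8)
  expect_setequal(fp$clone_id[out$singletons], "ZZZ")
  joined <- names(which(vapply(out$contigs, function(cg)
    "S01" %in% fp$clone_id[cg$clones], logical(1))))
  a_id <- names(which(vapply(map$contigs, function(cg)
    "A1" %in% fp$clone_id[cg$clones], logical(1))))
  expect_equal(joined, a_id)   # A's end pair scores lower than B's
})

test_that("the iterated schedule is monotone and keeps the clone partition intact", {
  cfg <- small_config(19)
  g <- generate_genome(cfg)
  lib <- sample_bac_library(g, cfg)
  fp <- qc_filter(fingerprint_library(g, lib, seed = 19))$fingerprints
  map <- iterative_assembly(fp, cfg$assembly, kb_per_band = 50 / 70)
  log <- map$build_log
  merges <- log[log$step == "End-to-End", ]
  pre <- log$n_contigs[match(rownames(merges), rownames(log)) - 1]
  expect_true(all(merges$n_contigs <= pre))
  singles <- log[log$step == "Singles-to-End", ]
  pre_s <- log$n_singletons[match(rownames(singles), rownames(log)) - 1]
  expect_true(all(singles$n_singletons <= pre_s))

  # partition invariant: every valid clone in exactly one contig or singleton
  mem <- map_members(map)
  expect_setequal(mem$clone_id, fp$clone_id)
  expect_equal(anyDuplicated(mem$clone_id), 0)
  # contigs all have >= 2 clones
  expect_true(all(vapply(map$contigs, function(cg) length(cg$clones),
                         integer(1)) >= 2))
})

test_that("stricter cutoffs never decrease singleton counts in a sweep", {
  cfg <- small_config(23)
  g <- generate_genome(cfg)
  lib <- sample_bac_library(g, cfg)
  fp <- qc_filter(fingerprint_library(g, lib, seed = 23))$fingerprints
  sweep <- cutoff_sweep(fp, c(1e-35, 1e-45, 1e-55, 1e-65), assembly_params())
  expect_equal(nrow(sweep), 4)
  expect_equal(sweep$cutoff, c(1e-35, 1e-45, 1e-55, 1e-65))
  expect_true(all(diff(sweep$n_singletons) >= 0))
  # a single-cutoff sweep equals the initial build
  one <- cutoff_sweep(fp, 1e-45, assembly_params())
  m <- initial_build(fp, 1e-45, assembly_params())
  expect_equal(one$n_contigs, length(m$contigs))
  expect_equal(one$n_singletons, length(m$singletons))
})

test_that("physical length estimates scale consensus units by the calibration", {
  expect_equal(estimate_physical_length(220, 1.363), 299.86)
  expect_error(estimate_physical_length(220, 0), "positive")
  fp <- tiling_fp_set(4, 40, 10, seed = 8)
  map <- initial_build(fp, 1e-20, assembly_params(), kb_per_band = 1)
  pl <- estimate_physical_length(map, 1.5)
  units <- sum(vapply(map$contigs, function(cg) cg$cb$n_units, numeric(1)))
  expect_equal(pl$total_kb, units * 1.5)
  empty_map <- initial_build(fp, 1e-300, assembly_params())
  expect_equal(estimate_physical_length(empty_map, 1.5)$total_kb, 0)
})
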