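test_that("full-scale pooling yields the published pool counts and a clean partition", {
  lib <- layout_library(60)
  scheme <- build_pools(lib, superpool_size = 5L)
  expect_equal(unname(scheme$counts["superpools"]), 12L)
  expect_equal(unname(scheme$counts["plate_pools"]), 60L)
  expect_equal(unname(scheme$counts["row_pools"]), 480L)
  expect_equal(unname(scheme$counts["column_pools"]), 720L)
  asg <- scheme$assignments
  expect_equal(nrow(asg), 23040)
  # pool sizes: 384 per plate pool, 1920 per superpool, 48 per row pool,
  # 32 per column pool, 4 per well
  expect_true(all(table(asg$plate) == 384))
  expect_true(all(table(asg$superpool) == 1920))
  expect_true(all(table(paste(asg$plate, asg$row96)) == 48))
  expect_true(all(table(paste(asg$plate, asg$col96)) == 32))
  expect_true(all(table(asg$well) == 4))
  # each clone reachable by exactly one path
  expect_equal(anyDuplicated(asg$clone_id), 0)
})

test_that("pool construction validates the plate/superpool geometry", {
  expect_equal(unname(build_pools(layout_library(10), 5L)$counts["superpools"]),
               2L)
  expect_error(build_pools(layout_library(7), 5L), "divisible")
})

test_that("PCR positivity requires full containment of a target interval", {
  lib <- layout_library(1)
  lib <- place_clone(lib, "Cm01_A01", "chr01", 1000, 50000)
  lib <- place_clone(lib, "Cm01_A02", "chr01", 60000, 100000)
  panel <- list(markers = data.frame(marker_id = "M1", class = "SNP",
                                     linkage_group = "I", cm = 1,
                                     n_loci = 1L, lg2 = NA, cm2 = NA,
                                     stringsAsFactors = FALSE),
                targets = data.frame(marker_id = "M1", chrom = "chr01",
                                     start = 49900, end = 50400,
                                     stringsAsFactors = FALSE))
  # interval straddles the end of clone A01: both primer sites must lie
  # inside the insert, so no clone amplifies
  expect_equal(true_positive_clones("M1", panel, lib), character(0))
  panel$targets$start <- 49000; panel$targets$end <- 49600
  expect_equal(true_positive_clones("M1", panel, lib), "Cm01_A01")
  # deterministic calls at zero error rates
  expect_true(simulate_pcr("Cm01_A01", "Cm01_A01"))
  expect_false(simulate_pcr("Cm01_A02", "Cm01_A01"))
  # fn_rate 1 silences every pool
  expect_false(simulate_pcr("Cm01_A01", "Cm01_A01", fn_rate = 1))
  expect_error(simulate_pcr("x", "x", fn_rate = 2), "fn_rate")
})

test_that("a single positive clone is decoded with the expected reaction count", {
  lib <- layout_library(60)
  lib <- place_clone(lib, "Cm23_G14", "chr01", 10000, 60000)
  panel <- list(markers = data.frame(marker_id = "M1", class = "SNP",
                                     linkage_group = "I", cm = 1,
                                     n_loci = 1L, lg2 = NA, cm2 = NA,
                                     stringsAsFactors = FALSE),
                targets = data.frame(marker_id = "M1", chrom = "chr01",
                                     start = 20000, end = 20500,
                                     stringsAsFactors = FALSE))
  scheme <- build_pools(lib, 5L)
  res <- screen_marker("M1", scheme, panel, lib)
  expect_false(res$dropout)
  expect_equal(res$positives, "Cm23_G14")
  # 12 superpools + 5 plate pools + 20 row/column pools + 4 well clones
  expect_equal(res$pcr_count, 12 + 5 + 20 + 4)
  expect_equal(res$ambiguities_resolved, 0L)
})

test_that("two positives in one plate produce four candidate wells, all resolved", {
  lib <- layout_library(60)
  # distinct 96-well rows AND columns: A01 -> row 1 col 1, K20 -> row 6 col 10
  lib <- place_clone(lib, "Cm07_A01", "chr01", 10000, 60000)
  lib <- place_clone(lib, "Cm07_K20", "chr01", 15000, 65000)
  panel <- list(markers = data.frame(marker_id = "M1", class = "RFLP",
                                     linkage_group = "I", cm = 1,
                                     n_loci = 1L, lg2 = NA, cm2 = NA,
                                     stringsAsFactors = FALSE),
                targets = data.frame(marker_id = "M1", chrom = "chr01",
                                     start = 30000, end = 30600,
                                     stringsAsFactors = FALSE))
  scheme <- build_pools(lib, 5L)
  res <- screen_marker("M1", scheme, panel, lib)
  expect_setequal(res$positives, c("Cm07_A01", "Cm07_K20"))
  # 2 positive rows x 2 positive columns = 4 candidate wells; the 2 wells
  # without positives are the resolved ambiguities
  expect_equal(res$pcr_count, 12 + 5 + 20 + 16)
  expect_equal(res$ambiguities_resolved, 2L)
})

test_that("markers with no containing clone are flagged as library dropouts", {
  lib <- layout_library(10)
  panel <- list(markers = data.frame(marker_id = "M1", class = "SSR",
                                     linkage_group = "I", cm = 1,
                                     n_loci = 1L, lg2 = NA, cm2 = NA,
                                     stringsAsFactors = FALSE),
                targets = data.frame(marker_id = "M1", chrom = "chr01",
                                     start = 100, end = 400,
                                     stringsAsFactors = FALSE))
  scheme <- build_pools(lib, 5L)
  res <- screen_marker("M1", scheme, panel, lib)
  expect_true(res$dropout)
  expect_equal(res$positives, character(0))
  expect_equal(res$pcr_count, 2L)  # only the superpool round ran
})

test_that("screening decodes exactly and cheaply on simulated panels", {
  cfg <- small_config(29)
  g <- generate_genome(cfg)
  lib <- sample_bac_library(g, cfg)
  pan <- plant_markers(g, n = 40, dup_fraction = 0.2, seed = 29)
  scheme <- build_pools(lib, 2L)
  scr <- screen_panel(pan, scheme, lib, seed = 29)
  exhaustive <- sum(!lib$empty)
  for (m in pan$markers$marker_id) {
    r <- scr$results[[m]]
    # oracle equivalence at zero error rates, via IRanges containment
    truth <- character(0)
    for (k in which(pan$targets$marker_id == m)) {
      ne <- lib[!lib$empty & lib$chrom == pan$targets$chrom[k], ]
      hit <- IRanges::overlapsAny(
        IRanges::IRanges(pan$targets$start[k], pan$targets$end[k]),
        IRanges::IRanges(ne$start, ne$end), type = "within")
      if (hit) {
        within <- IRanges::findOverlaps(
          IRanges::IRanges(pan$targets$start[k], pan$targets$end[k]),
          IRanges::IRanges(ne$start, ne$end), type = "within")
        truth <- c(truth, ne$clone_id[S4Vectors::subjectHits(within)])
      }
    }
    expect_setequal(r$positives, unique(truth))
    # reaction economy: never worse than clone-by-clone PCR
    expect_lte(r$pcr_count, exhaustive)
  }
  s <- scr$summary
  expect_equal(s$n_anchored + s$n_dropout, s$n_markers)
  expect_equal(sum(as.integer(s$histogram) * as.integer(names(s$histogram))),
               s$total_positive_links)
})

test_that("duplicated markers drive the upper mode of the BACs-per-marker distribution", {
  res <- desk_results()
  pan <- res$panel; scr <- res$screens
  npos <- vapply(scr$results, function(r) length(r$positives), integer(1))
  dup <- pan$markers$n_loci[match(names(npos), pan$markers$marker_id)] > 1
  anchored <- npos > 0
  m_dup <- mean(npos[anchored & dup])
  m_single <- mean(npos[anchored & !dup])
  expect_gt(m_dup / m_single, 1.5)
  # single-locus markers track the library depth
  expect_lt(abs(m_single - achieved_equivalents(res$library)), 1.5)
})
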