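# helpers building minimal physical maps and screens by hand
mini_map <- function() {
  set.seed(55)
  szA <- sort(sample(1500:8000, 60))
  szB <- sort(sample(8500:14500, 60))
  ids <- c("K01", "K02", "K03", "L01", "L02", "M99")
  fp <- make_fp_set(ids, rep(list(rep(1L, 60)), 6),
                    list(szA, szA, szA, szB, szB,
                         sort(sample(20000:26000, 60))))
  initial_build(fp, 1e-10, assembly_params(), kb_per_band = 1)
}

mini_screen <- function(marker_id, positives, dropout = FALSE) {
  structure(list(marker_id = marker_id, dropout = dropout,
                 positives = positives, pcr_count = 0L,
                 ambiguities_resolved = 0L, rounds = list()),
            class = "screen_result")
}

mini_panel <- function(df) {
  list(markers = df,
       targets = data.frame(marker_id = df$marker_id, chrom = "chr01",
                            start = 1, end = 500, stringsAsFactors = FALSE))
}

test_that("markers link to every unit holding a fingerprinted positive", {
  map <- mini_map()   # contigs {K01,K02,K03}, {L01,L02}; singleton M99
  panel <- mini_panel(data.frame(
    marker_id = c("MK1", "MK2", "MK3", "MK4"),
    class = "SNP", linkage_group = c("I", "II", "III", "IV"),
    cm = 1:4, n_loci = c(1L, 2L, 1L, 1L), lg2 = NA_character_,
    cm2 = NA_real_, stringsAsFactors = FALSE))
  screens <- list(
    mini_screen("MK1", c("K01", "K02", "K03")),     # one contig
    mini_screen("MK2", c("K01", "L01")),            # duplicated: two contigs
    mini_screen("MK3", c("ZZ_not_fingerprinted")),  # unanchorable
    mini_screen("MK4", character(0), dropout = TRUE))
  anc <- anchor_markers(map, screens, panel)

  expect_equal(sum(anc$links$marker_id == "MK1"), 1)
  expect_equal(sum(anc$links$marker_id == "MK2"), 2)
  st <- setNames(anc$marker_status$status, anc$marker_status$marker_id)
  expect_equal(unname(st["MK1"]), "anchored")
  expect_equal(unname(st["MK2"]), "anchored")
  expect_equal(unname(st["MK3"]), "no_fingerprint")
  expect_equal(unname(st["MK4"]), "dropout")
  # accounting closure over the panel
  expect_equal(nrow(anc$marker_status), 4)
  # contigs inherit marker linkage groups; the dual-contig marker places
  # both its contigs
  expect_setequal(anc$placements$lg[anc$placements$n_markers > 0],
                  c("I/II", "II"))
})

test_that("coincidence is the modal-unit fraction with the documented edge cases", {
  map <- mini_map()
  # 3 of 4 fingerprinted positives in the modal contig
  expect_equal(coincidence(c("K01", "K02", "K03", "L01"), map), 0.75)
  # all clones in one contig
  expect_equal(coincidence(c("K01", "K02", "K03"), map), 1.0)
  # fewer than 2 fingerprinted clones: undefined
  expect_true(is.na(coincidence(c("K01", "nope"), map)))
})

test_that("conflicts require an inconsistent marker-position assignment", {
  map <- mini_map()
  panel <- mini_panel(data.frame(
    marker_id = c("MKa", "MKb"), class = "RFLP",
    linkage_group = c("XI", "III"), cm = c(10, 40), n_loci = 1L,
    lg2 = NA_character_, cm2 = NA_real_, stringsAsFactors = FALSE))
  screens <- list(mini_screen("MKa", c("K01", "K02")),
                  mini_screen("MKb", c("K02", "K03")))
  anc <- anchor_markers(map, screens, panel)
  conf <- detect_conflicts(anc, panel, map, cm_per_mb = 1, kb_per_band = 1)
  expect_equal(nrow(conf), 1)
  expect_match(conf$reason, "linkage groups")

  # same group, 0.5 cM apart on a contig much longer than the implied
  # physical separation: no conflict
  panel2 <- mini_panel(data.frame(
    marker_id = c("MKa", "MKb"), class = "RFLP",
    linkage_group = "XI", cm = c(10, 10.5), n_loci = 1L,
    lg2 = NA_character_, cm2 = NA_real_, stringsAsFactors = FALSE))
  anc2 <- anchor_markers(map, screens, panel2)
  conf2 <- detect_conflicts(anc2, panel2, map, cm_per_mb = 1,
                            kb_per_band = 15)   # ~900 kb contig
  expect_equal(nrow(conf2), 0)

  # same group but genetically much farther than the contig is long
  panel3 <- mini_panel(data.frame(
    marker_id = c("MKa", "MKb"), class = "RFLP",
    linkage_group = "XI", cm = c(10, 60), n_loci = 1L,
    lg2 = NA_character_, cm2 = NA_real_, stringsAsFactors = FALSE))
  anc3 <- anchor_markers(map, screens, panel3)
  conf3 <- detect_conflicts(anc3, panel3, map, cm_per_mb = 1,
                            kb_per_band = 1)    # ~60 kb contig vs 50 Mb
  expect_equal(nrow(conf3), 1)
  expect_match(conf3$reason, "exceeds")
})

test_that("summary fractions reproduce the published contig-size arithmetic", {
  # published bin counts: 3 contigs of 100-199 clones, 9 of 50-99, 102 of
  # 25-49, 428 of 10-24, 706 of 3-9, 107 of 2
  bins <- c("2" = 107, "3-9" = 706, "10-24" = 428, "25-49" = 102,
            "50-99" = 9, ">=100" = 3)
  st <- contig_size_stats(bins)
  expect_equal(st$n_contigs, 1355)
  expect_equal(round_half_up(100 * st$frac_gt9), 40)
  expect_equal(round_half_up(100 * st$frac_3_24), 84)
  # the same numbers from a raw size vector
  sizes <- rep(c(2, 5, 15, 30, 60, 150), times = c(107, 706, 428, 102, 9, 3))
  st2 <- contig_size_stats(as.integer(sizes))
  expect_equal(st2$bins, bins)
  # 30 multi-contig markers of 169 anchored
  expect_equal(round_half_up(100 * 30 / 169), 18)
})

test_that("rounding used for reports is half away from zero", {
  expect_equal(round_half_up(14.667), 15)
  expect_equal(round_half_up(175.5), 176)
  expect_equal(round_half_up(4.392, 1), 4.4)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(0.125, 2), 0.13)
})

test_that("map summaries close their accounting on a simulated run", {
  res <- desk_results()
  s <- summarize_map(res$map, res$kb_per_band, res$anchored, res$screens,
                     res$library)
  # marker accounting: anchored + dropout + unanchorable = panel size
  expect_equal(s$n_markers_anchored + s$n_markers_dropout +
                 s$n_markers_no_fingerprint, nrow(res$panel$markers))
  # size bins partition the contig list
  expect_equal(sum(s$size_bins), s$n_contigs)
  # per-LG additivity of anchored Mb
  expect_equal(round_half_up(sum(s$per_lg$mb), 1), s$anchored_mb_total)
  # histogram consistency with the raw link table
  expect_equal(sum(as.integer(s$bacs_per_marker_hist) *
                     as.integer(names(s$bacs_per_marker_hist))),
               res$screens$summary$total_positive_links)
  # contig + singleton units linked equals the link table
  expect_equal(nrow(res$anchored$links),
               length(unique(paste(res$anchored$links$marker_id,
                                   res$anchored$links$unit))))
})
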