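ed_profile_of <- function(ed, chrom = "chr1") {
  euclidean_distance(tibble::tibble(
    chrom = chrom, pos = seq_along(ed) * 1000L,
    fa_high = (1 + ed / sqrt(2)) / 2, fa_low = (1 - ed / sqrt(2)) / 2))
}

test_that("allele frequencies are read-count ratios and drop zero depth", {
  mk <- random_marker_table(3, seed = 1)
  mk$bulk_high_ref <- c(50L, 0L, 9L)
  mk$bulk_high_alt <- c(50L, 100L, 3L)
  mk$bulk_low_ref <- c(10L, 10L, 0L)
  mk$bulk_low_alt <- c(10L, 10L, 0L)
  fr <- suppressMessages(allele_frequencies(mk))
  expect_equal(fr$fa_high, c(0.5, 1, NA)[1:2])
  expect_equal(fr$fa_high[2], 1)
  expect_equal(nrow(fr), 2)           # zero-depth marker dropped
  expect_equal(attr(fr, "n_zero_depth"), 1)
  mk$bulk_high_ref[3] <- 9L; mk$bulk_low_ref[3] <- 9L; mk$bulk_low_alt[3] <- 0L
  fr2 <- allele_frequencies(mk)
  expect_equal(fr2$fa_high[3], 3 / 12)
})

test_that("ED matches its closed form and symmetries", {
  fr <- tibble::tibble(chrom = "c", pos = 1:3,
                       fa_high = c(0.3, 1, 0.9), fa_low = c(0.3, 0, 0.1))
  ed <- euclidean_distance(fr)$ed
  expect_equal(ed[1], 0)
  expect_equal(ed[2], sqrt(2))
  expect_equal(ed[3], sqrt(0.64 + 0.64))
  # biallelic identity
  expect_equal(ed, sqrt(2) * abs(fr$fa_high - fr$fa_low))
  # bulk swap
  swapped <- euclidean_distance(
    dplyr::rename(fr, fa_high = "fa_low", fa_low = "fa_high"))$ed
  expect_equal(swapped, ed)
  # global allele relabeling fa <-> fA in both bulks
  relab <- euclidean_distance(
    dplyr::mutate(fr, fa_high = 1 - .data$fa_high,
                  fa_low = 1 - .data$fa_low))$ed
  expect_equal(relab, ed)
})

test_that("windowed statistic handles constant, zero and spike profiles", {
  w <- windowed_statistic(ed_profile_of(rep(0.1, 100)), window = 100)
  expect_equal(nrow(w), 1)
  expect_equal(w$w_stat, (100 * 0.1)^4)
  expect_equal(w$w_stat, 10000)

  w0 <- windowed_statistic(ed_profile_of(rep(0, 150)), window = 100)
  expect_true(all(w0$w_stat == 0))

  spike <- c(rep(0, 100), 1)
  w2 <- windowed_statistic(ed_profile_of(spike), window = 100)
  expect_equal(nrow(w2), 2)
  expect_equal(w2$w_stat, c(0, 1))

  # short chromosome becomes one flagged whole-chromosome window
  ws <- windowed_statistic(ed_profile_of(rep(0.2, 10)), window = 100)
  expect_equal(nrow(ws), 1)
  expect_true(ws$short_chrom)
  expect_equal(ws$w_stat, (10 * 0.2)^4)

  expect_equal(nrow(windowed_statistic(ed_profile_of(numeric(0)))), 0)
})

test_that("sliding windows agree with the brute-force double loop", {
  set.seed(99)
  prof <- dplyr::bind_rows(
    ed_profile_of(runif(180), chrom = "chr1"),
    ed_profile_of(runif(37), chrom = "chr2"),
    ed_profile_of(runif(250), chrom = "chr3"))
  for (win in c(1, 7, 100)) {
    got <- windowed_statistic(prof, window = win)
    want <- brute_force_windows(prof, window = win)
    expect_equal(got$w_stat, want$w_stat, tolerance = 1e-12)
    expect_equal(got$mid_pos, want$mid_pos)
    expect_equal(got$start_idx, want$start_idx)
  }
})

test_that("tiled windows are the disjoint subset of sliding windows", {
  prof <- ed_profile_of(runif(95, 0, 1))
  set.seed(1)
  tiled <- windowed_statistic(ed_profile_of(runif(60)), window = 20,
                              sliding = FALSE)
  expect_equal(tiled$start_idx, c(1L, 21L, 41L))
})

test_that("null threshold is reproducible and decreases with bulk size", {
  sm <- sequencing_model()
  d75 <- cross_design(n_f2 = 737, bulk_size = 75)
  t1 <- null_threshold(d75, sm, n_markers = 500, window = 100,
                       n_sim = 200, seed = 5)
  t2 <- null_threshold(d75, sm, n_markers = 500, window = 100,
                       n_sim = 200, seed = 5)
  expect_equal(as.numeric(t1), as.numeric(t2))

  d500 <- cross_design(n_f2 = 5000, bulk_size = 500)
  t_big <- null_threshold(d500, sm, n_markers = 500, window = 100,
                          n_sim = 500, seed = 6)
  t_small <- null_threshold(d75, sm, n_markers = 500, window = 100,
                            n_sim = 500, seed = 6)
  expect_lt(as.numeric(t_big), as.numeric(t_small))

  expect_error(null_threshold(d75, sm, n_markers = 500, n_sim = 50,
                              seed = 1), "200")
})

test_that("regions merge by flank overlap and clip to the chromosome", {
  win <- tibble::tibble(chrom = "chr1",
                        start_idx = 1:3,
                        mid_pos = c(10e6, 20e6, 200e6),
                        w_stat = c(5, 7, 1), short_chrom = FALSE)
  expect_equal(nrow(call_regions(win, threshold = 10)), 0)

  r <- call_regions(win, threshold = 4, flank = 8e6)
  expect_equal(nrow(r), 1)
  expect_equal(r$start, 2e6)
  expect_equal(r$end, 28e6)
  expect_equal(r$peak_pos, 20e6)
  expect_equal(r$n_significant_markers, 2)

  win2 <- win; win2$mid_pos <- c(10e6, 30e6, 200e6)
  r2 <- call_regions(win2, threshold = 4, flank = 8e6)
  expect_equal(nrow(r2), 2)

  # left/right clipping
  win3 <- tibble::tibble(chrom = "chr1", start_idx = 1,
                         mid_pos = 4e6, w_stat = 5, short_chrom = FALSE)
  r3 <- call_regions(win3, threshold = 4, flank = 8e6,
                     chrom_lengths = c(chr1 = 10e6))
  expect_equal(r3$start, 1)
  expect_equal(r3$end, 10e6)

  # peak ties resolve to the leftmost position
  win4 <- tibble::tibble(chrom = "chr1", start_idx = 1:2,
                         mid_pos = c(10e6, 12e6), w_stat = c(5, 5),
                         short_chrom = FALSE)
  expect_equal(call_regions(win4, threshold = 4)$peak_pos, 10e6)
})

test_that("GWAS hits intersect called regions on closed intervals", {
  regions <- tibble::tibble(chrom = "chr1", start = 2e6, end = 28e6,
                            peak_pos = 10e6, peak_stat = 5,
                            n_significant_markers = 3)
  class(regions) <- c("qtl_regions", class(regions))
  hits <- tibble::tibble(chrom = c("chr1", "chr1", "chr1"),
                         pos = c(10e6, 2e6, 50e6), pvalue = 1e-5)
  res <- intersect_gwas(regions, hits)
  expect_identical(res$hits$matched, c(TRUE, TRUE, FALSE))
  expect_equal(res$region_counts$n_hits, 2)

  none <- call_regions(tibble::tibble(chrom = character(),
                                      start_idx = integer(),
                                      mid_pos = numeric(), w_stat = numeric(),
                                      short_chrom = logical()), 1)
  res2 <- intersect_gwas(none, hits)
  expect_true(all(!res2$hits$matched))

  bad <- dplyr::mutate(hits, chrom = "1")
  expect_error(intersect_gwas(regions, bad), "unmatched")
})
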