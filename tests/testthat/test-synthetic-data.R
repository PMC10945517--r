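test_that("zero genetic distance produces no recombinant gametes", {
  map <- tibble::tibble(chrom = "c1", marker = c("m1", "m2"),
                        pos_cM = c(50, 50), pos_bp = c(100L, 200L))
  class(map) <- c("genetic_map", class(map))
  pop <- simulate_f2_population(map, cross_design(n_f2 = 500, bulk_size = 50),
                                seed = 11)
  # dosages at the two markers must be identical for every individual
  expect_identical(pop$dosage[, 1], pop$dosage[, 2])
})

test_that("single-marker F2 dosages segregate 1:2:1", {
  map <- genetic_map(tibble::tibble(name = "c1", length_cM = 100,
                                    length_bp = 1e6), 1)
  n <- 10000
  pop <- simulate_f2_population(map, cross_design(n_f2 = n, bulk_size = 100),
                                seed = 7)
  counts <- tabulate(pop$dosage[, 1] + 1L, nbins = 3)
  expected <- n * c(0.25, 0.5, 0.25)
  sds <- sqrt(n * c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75))
  expect_true(all(abs(counts - expected) <= 3 * sds))
  # goodness of fit at larger n
  pop2 <- simulate_f2_population(map, cross_design(n_f2 = 50000,
                                                   bulk_size = 100), seed = 8)
  p <- stats::chisq.test(tabulate(pop2$dosage[, 1] + 1L, nbins = 3),
                         p = c(0.25, 0.5, 0.25))$p.value
  expect_gt(p, 0.001)
})

test_that("recombinant gamete fraction matches the Haldane map function", {
  r_true <- (1 - exp(-2 * 10 / 100)) / 2   # closed form at 10 cM
  expect_equal(haldane(10), r_true)
  set.seed(42)
  g <- seedlingqtl:::sim_gametes(50000, c(0, 10))
  r_obs <- mean(g[, 1] != g[, 2])
  expect_lt(abs(r_obs - r_true), 3 * sqrt(r_true * (1 - r_true) / 50000))
})

test_that("chromosomes without markers are rejected", {
  map <- genetic_map(millet_chromosomes(1), 5)
  empty <- map[0, ]
  class(empty) <- class(map)
  expect_error(simulate_f2_population(empty, cross_design(), seed = 1),
               "no markers")
  expect_error(genetic_map(millet_chromosomes(1), 0), "positive")
})

test_that("phenotypes follow the additive-dominance model", {
  map <- genetic_map(millet_chromosomes(1), 11)
  des0 <- cross_design(n_f2 = 50, bulk_size = 5, qtl = NULL, residual_sd = 0)
  pop <- simulate_f2_population(map, des0, seed = 2)
  ph0 <- simulate_phenotypes(pop, des0, seed = 3)
  expect_true(all(ph0$phenotype == 0))

  qtl <- data.frame(chrom = "chr1", pos_bp = 145e6, additive = 5,
                    dominance = 0)
  des1 <- cross_design(n_f2 = 50, bulk_size = 5, qtl = qtl, residual_sd = 0)
  ph1 <- simulate_phenotypes(pop, des1, seed = 3)
  expect_true(all(ph1$phenotype %in% c(-5, 0, 5)))
})

test_that("F2 phenotypic variance equals a^2/2 plus residual variance", {
  # oracle: enumerate dosage probabilities (1/4, 1/2, 1/4) -> genetic
  # variance sum p_i (a (d_i - 1))^2 = a^2 / 2
  a <- 5
  var_gen <- sum(c(0.25, 0.5, 0.25) * (a * (c(0, 1, 2) - 1))^2)
  expect_equal(var_gen, a^2 / 2)
  map <- genetic_map(millet_chromosomes(1), 11)
  qtl <- data.frame(chrom = "chr1", pos_bp = 145e6, additive = a,
                    dominance = 0)
  des <- cross_design(n_f2 = 5000, bulk_size = 500, qtl = qtl,
                      residual_sd = 5)
  pop <- simulate_f2_population(map, des, seed = 4)
  ph <- simulate_phenotypes(pop, des, seed = 5)
  expect_lt(abs(var(ph$phenotype) - (var_gen + 25)) / (var_gen + 25), 0.05)
})

test_that("bulk selection takes the phenotypic tails with index tie-breaks", {
  des <- cross_design(n_f2 = 10, tail_fraction = 0.2, bulk_size = 2)
  ph <- tibble::tibble(individual = 1:10, phenotype = 1:10)
  b <- select_bulks(ph, des)
  expect_identical(b$high, c(9L, 10L))
  expect_identical(b$low, c(1L, 2L))

  ties <- tibble::tibble(individual = 1:10, phenotype = rep(1, 10))
  bt <- select_bulks(ties, des)
  expect_identical(bt$low, c(1L, 2L))
  expect_identical(bt$high, c(3L, 4L))
  expect_length(intersect(bt$low, bt$high), 0)

  expect_error(select_bulks(ph[1:3, ], des), "at least")
})

test_that("the design guards the bulk size against the tail fraction", {
  expect_silent(cross_design(n_f2 = 737, tail_fraction = 0.10,
                             bulk_size = 75))
  expect_error(cross_design(n_f2 = 737, tail_fraction = 0.10,
                            bulk_size = 80), "tail")
})

test_that("pooled read counts reflect true bulk frequencies", {
  map <- genetic_map(tibble::tibble(name = "c1", length_cM = 1000,
                                    length_bp = 1e8), 200)
  des <- cross_design(n_f2 = 40, tail_fraction = 0.25, bulk_size = 10,
                      residual_sd = 1)
  pop <- simulate_f2_population(map, des, seed = 6)
  ph <- simulate_phenotypes(pop, des, seed = 7)
  bulks <- select_bulks(ph, des)

  # degenerate frequencies: force all-ref / all-alt bulks
  pop0 <- pop; pop0$dosage[] <- 0L
  sm0 <- sequencing_model(error_rate = 0)
  mk0 <- simulate_pooled_reads(pop0, bulks, sm0, seed = 8)
  expect_true(all(mk0$bulk_high_alt == 0))
  pop2 <- pop; pop2$dosage[] <- 2L
  mk2 <- simulate_pooled_reads(pop2, bulks, sm0, seed = 8)
  expect_true(all(mk2$bulk_low_ref == 0))

  # f = 0.5 at high depth: mean observed frequency 0.5 within 0.005
  map_big <- genetic_map(tibble::tibble(name = "c1", length_cM = 1e5,
                                        length_bp = 1e8), 10000)
  dos <- matrix(1L, nrow = 40, ncol = 10000,
                dimnames = list(NULL, map_big$marker))
  pop_half <- structure(list(map = map_big, dosage = dos),
                        class = "f2_genotypes")
  mk <- simulate_pooled_reads(pop_half, bulks,
                              sequencing_model(mean_depth_high = 1000,
                                               mean_depth_low = 1000,
                                               error_rate = 0), seed = 9)
  f_obs <- mk$bulk_high_alt / (mk$bulk_high_alt + mk$bulk_high_ref)
  expect_lt(abs(mean(f_obs) - 0.5), 0.005)
  # unbiasedness: |bias| under 3 standard errors over the 10,000 sites
  expect_lt(abs(mean(f_obs) - 0.5), 3 * sd(f_obs) / sqrt(length(f_obs)))

  expect_error(
    simulate_pooled_reads(pop, structure(list(low = integer(), high = 1:10),
                                         class = "bulk_membership"),
                          sequencing_model(), seed = 1),
    "non-empty")
})

test_that("bulk allele frequencies separate at a QTL but not away from it", {
  map <- genetic_map(millet_chromosomes(1), 201)
  qtl <- data.frame(chrom = "chr1", pos_bp = 145e6, additive = 1,
                    dominance = 0)
  des <- cross_design(n_f2 = 737, bulk_size = 75, qtl = qtl, residual_sd = 1)
  pop <- simulate_f2_population(map, des, seed = 10)
  ph <- simulate_phenotypes(pop, des, seed = 11)
  bulks <- select_bulks(ph, des)
  q_idx <- seedlingqtl:::qtl_marker_index(map, qtl)
  f_at <- function(members, j) sum(pop$dosage[members, j]) / (2 * length(members))
  expect_gt(f_at(bulks$high, q_idx) - f_at(bulks$low, q_idx), 0.2)
  # far, unlinked end of the chromosome: both near 0.5
  expect_lt(abs(f_at(bulks$high, 1) - 0.5), 0.15)
  expect_lt(abs(f_at(bulks$low, 1) - 0.5), 0.15)
})

test_that("panel generator honours its variance components", {
  flat <- simulate_panel_phenotypes(n_lines = 5, var_line = 0, var_res = 0,
                                    mu = 3, seed = 1)
  expect_true(all(flat$value == 3))

  panel <- simulate_panel_phenotypes(n_lines = 500, plants_per_line_mean = 10,
                                     var_line = 4, var_res = 1, seed = 2)
  vc <- variance_components(panel)
  expect_lt(abs(vc$var_line - 4) / 4, 0.15)
  expect_lt(abs(vc$var_res - 1) / 1, 0.15)

  study <- simulate_panel_phenotypes(n_lines = 122, plants_per_line_mean = 7,
                                     seed = 3)
  expect_equal(dplyr::n_distinct(study$line), 122)
  expect_lt(abs(mean(table(study$line)) - 7), 1)
})

test_that("cell profile approaches its asymptotes without noise", {
  prof <- simulate_cell_profile(l_min = 10, l_max = 200, k = 0.01, x0 = 600,
                                n_cells = 80, noise_sd = 0, seed = 1)
  expect_lt(abs(prof$length[1] - 10), 0.5)            # x << x0
  expect_lt(abs(tail(prof$length, 1) - 200), 0.5)     # x >> x0
  expect_true(all(diff(prof$distance) > 0))
  # distances are the running sum of preceding lengths
  expect_equal(prof$distance, cumsum(c(0, head(prof$length, -1))))
})

test_that("the soil bucket drains, bounds and conserves water", {
  soil <- bucket_params(ttsw = 100, initial_fill = 1, daily_demand = 5)
  dry <- simulate_ftsw(soil, rep(0, 60))
  expect_true(all(diff(dry$ftsw) <= 0))
  # below the onset transpiration declines linearly, so the store decays
  # geometrically towards zero
  expect_lt(tail(dry$ftsw, 1), 1e-3)
  # hand-iterated crossing: 14 full-demand days take the store to 30 mm
  # (FTSW 0.3); day 15 is the first below the onset
  expect_identical(which(dry$ftsw < 0.3)[1], 15L)

  wet <- simulate_ftsw(soil, rep(6, 60))
  expect_true(all(wet$ftsw >= 1 - 5 / 100))

  rain <- simulate_rain_season(seed = 4)
  fs <- simulate_ftsw(bucket_params(), rain)
  balance <- sum(fs$rain) - sum(fs$transpiration) - sum(fs$overflow)
  expect_equal(balance, tail(fs$atsw, 1) - attr(fs, "atsw0"),
               tolerance = 1e-9)

  expect_error(simulate_ftsw(soil, c(1, -1)), "non-negative")
  expect_error(simulate_ftsw(soil, numeric(0)), "empty")
})

test_that("root-zone growth deepens the bucket without losing water", {
  rain <- simulate_rain_season(seed = 9)
  soil <- bucket_params()
  # growth disabled reduces to the constant shallow bucket
  a <- simulate_ftsw(soil, rain, ttsw0 = 25)
  shallow <- bucket_params(ttsw = 25, initial_fill = soil$initial_fill,
                           daily_demand = soil$daily_demand * 25 / 100)
  b <- simulate_ftsw(shallow, rain)
  expect_equal(a$ftsw, b$ftsw, tolerance = 1e-12)

  grown <- simulate_ftsw(soil, rain, ttsw0 = 25, root_growth_days = 40,
                         growth_start_day = 60)
  balance <- sum(grown$rain) - sum(grown$transpiration) -
    sum(grown$overflow) - attr(grown, "reserve_end")
  expect_equal(balance, tail(grown$atsw, 1) - attr(grown, "atsw0"),
               tolerance = 1e-9)
  # the deepened profile can store more than the sowing horizon
  expect_gt(max(grown$atsw), 25)
})
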