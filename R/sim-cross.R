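#' Describe a bulk-segregant cross design
#'
#' Bundles the design constants of an F2 bulk-segregant experiment:
#' population size, the phenotypic tail fraction sampled into each bulk,
#' the bulk size, the simulated QTLs and the residual phenotype noise.
#' Defaults mirror a 737-plant F2 population with 10% tails and 75-plant
#' bulks.
#'
#' @param n_f2 Number of F2 individuals.
#' @param tail_fraction Proportion of the population in each phenotypic
#'   tail.
#' @param bulk_size Individuals per bulk. Must not exceed
#'   `ceiling(tail_fraction * n_f2) + 2`.
#' @param qtl Data frame of simulated QTLs with columns `chrom`,
#'   `pos_bp`, `additive`, `dominance` (phenotype units), or `NULL` for
#'   a null cross.
#' @param residual_sd Standard deviation of the non-genetic phenotype
#'   component.
#'
#' @return A list of class `cross_design`.
#' @export
cross_design <- function(n_f2 = 737, tail_fraction = 0.10, bulk_size = 75,
                         qtl = NULL, residual_sd = 1) {
  stopifnot(n_f2 >= 2, tail_fraction > 0, tail_fraction < 0.5,
            bulk_size >= 1, residual_sd >= 0)
  if (bulk_size > ceiling(tail_fraction * n_f2) + 2) {
    abort(sprintf(
      "bulk_size %d exceeds the %.0f%% tail of %d individuals (max %d)",
      bulk_size, 100 * tail_fraction, n_f2,
      ceiling(tail_fraction * n_f2) + 2L))
  }
  if (!is.null(qtl)) {
    stopifnot(is.data.frame(qtl),
              all(c("chrom", "pos_bp", "additive", "dominance") %in% names(qtl)))
  }
  structure(
    list(n_f2 = as.integer(n_f2), tail_fraction = tail_fraction,
         bulk_size = as.integer(bulk_size), qtl = qtl,
         residual_sd = residual_sd),
    class = "cross_design")
}

#' Describe the pooled sequencing model
#'
#' Site depth is drawn from a negative binomial (overdispersed, as is
#' typical for reduced-representation sequencing of pools); sequencing
#' error is folded into the binomial read-sampling success probability.
#' Defaults match bulk depths of 1028X (high bulk) and 814X (low bulk).
#'
#' @param mean_depth_high,mean_depth_low Mean site depth in the high- and
#'   low-phenotype bulk.
#' @param depth_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); `0` gives Poisson depths.
#' @param error_rate Per-base miscall probability, below 0.01.
#' @return A list of class `sequencing_model`.
#' @export
sequencing_model <- function(mean_depth_high = 1028, mean_depth_low = 814,
                             depth_dispersion = 0.2, error_rate = 0.001) {
  stopifnot(mean_depth_high > 0, mean_depth_low > 0, depth_dispersion >= 0,
            error_rate >= 0, error_rate < 0.01)
  structure(
    list(mean_depth_high = mean_depth_high, mean_depth_low = mean_depth_low,
         depth_dispersion = depth_dispersion, error_rate = error_rate),
    class = "sequencing_model")
}

# one chromosome of gametes: n_gametes x n_markers matrix of 0/1 alleles,
# Markov chain along the marker order with Haldane switch probabilities
sim_gametes <- function(n_gametes, pos_cM) {
  n_mark <- length(pos_cM)
  alleles <- matrix(0L, nrow = n_gametes, ncol = n_mark)
  alleles[, 1] <- rbinom(n_gametes, 1L, 0.5)
  if (n_mark > 1) {
    r <- haldane(diff(pos_cM))
    for (j in 2:n_mark) {
      switch <- rbinom(n_gametes, 1L, r[j - 1])
      alleles[, j] <- (alleles[, j - 1] + switch) %% 2L
    }
  }
  alleles
}

#' Simulate an F2 population from two homozygous parents
#'
#' The parents are fully homozygous for opposite alleles at every marker
#' (the low-growth parent carries the reference allele, dosage 0; the
#' high-growth parent the alternate allele, dosage 2). Each F2 individual
#' is the sum of two independently simulated gametes; recombination
#' between adjacent markers follows the Haldane map function with no
#' crossover interference.
#'
#' @param map A [genetic_map()].
#' @param design A [cross_design()].
#' @param seed Integer seed; the call is deterministic given the seed.
#'
#' @return A list of class `f2_genotypes` with elements `map` and
#'   `dosage`, an `n_f2 x n_markers` integer matrix of alternate-allele
#'   dosages in `{0, 1, 2}` (columns follow the map row order).
#'
#' @examples
#' map <- genetic_map(millet_chromosomes(1), markers_per_chrom = 20)
#' pop <- simulate_f2_population(map, cross_design(n_f2 = 100), seed = 1)
#' table(pop$dosage[, 1])
#' @export
simulate_f2_population <- function(map, design, seed) {
  stopifnot(inherits(map, "genetic_map"), inherits(design, "cross_design"))
  if (nrow(map) == 0) abort("map has no markers")
  counts <- table(map$chrom)
  if (any(counts == 0)) abort("every chromosome must carry at least one marker")
  set.seed(as.integer(seed))
  chroms <- unique(map$chrom)
  dosage <- matrix(0L, nrow = design$n_f2, ncol = nrow(map))
  for (ch in chroms) {
    idx <- which(map$chrom == ch)
    pos <- map$pos_cM[idx]
    if (is.unsorted(pos)) {
      abort("marker cM positions must be non-decreasing within a chromosome")
    }
    g1 <- sim_gametes(design$n_f2, pos)
    g2 <- sim_gametes(design$n_f2, pos)
    dosage[, idx] <- g1 + g2
  }
  colnames(dosage) <- map$marker
  structure(list(map = map, dosage = dosage), class = "f2_genotypes")
}

# nearest simulated marker to each requested QTL position
qtl_marker_index <- function(map, qtl) {
  purrr::map2_int(qtl$chrom, qtl$pos_bp, function(ch, bp) {
    idx <- which(map$chrom == ch)
    if (length(idx) == 0) {
      abort(sprintf("QTL chromosome '%s' is not on the map", ch))
    }
    idx[which.min(abs(map$pos_bp[idx] - bp))]
  })
}

#' Simulate F2 phenotypes from genotypes
#'
#' Phenotype of individual i is
#' `sum_q a_q (dosage_q - 1) + d_q 1(dosage_q == 1)` plus Gaussian noise
#' with standard deviation `design$residual_sd`. Each QTL acts through
#' the simulated marker nearest to its requested position.
#'
#' @param genos An `f2_genotypes` object from [simulate_f2_population()].
#' @param design The [cross_design()] carrying the QTL effects.
#' @param seed Integer seed for the residual draw.
#' @return A tibble with columns `individual` and `phenotype`.
#' @export
simulate_phenotypes <- function(genos, design, seed) {
  stopifnot(inherits(genos, "f2_genotypes"), inherits(design, "cross_design"))
  set.seed(as.integer(seed))
  n <- nrow(genos$dosage)
  genetic <- numeric(n)
  if (!is.null(design$qtl) && nrow(design$qtl) > 0) {
    q_idx <- qtl_marker_index(genos$map, design$qtl)
    for (k in seq_along(q_idx)) {
      dos <- genos$dosage[, q_idx[k]]
      genetic <- genetic + design$qtl$additive[k] * (dos - 1) +
        design$qtl$dominance[k] * (dos == 1)
    }
  }
  tibble::tibble(
    individual = seq_len(n),
    phenotype  = genetic + rnorm(n, 0, design$residual_sd)
  )
}

#' Select phenotypic tail bulks
#'
#' Picks the `bulk_size` lowest-phenotype individuals into the low bulk
#' and the `bulk_size` highest into the high bulk. Ties are broken by
#' lowest individual index, the low bulk is filled first, and the bulks
#' are disjoint by construction.
#'
#' @param phenos Tibble from [simulate_phenotypes()] (columns
#'   `individual`, `phenotype`).
#' @param design The [cross_design()] giving `bulk_size`.
#' @return A list of class `bulk_membership` with integer vectors `low`
#'   and `high` of individual ids, each sorted increasing.
#' @export
select_bulks <- function(phenos, design) {
  stopifnot(is.data.frame(phenos),
            all(c("individual", "phenotype") %in% names(phenos)),
            inherits(design, "cross_design"))
  n <- nrow(phenos)
  b <- design$bulk_size
  if (n < 2 * b) {
    abort(sprintf("need at least %d individuals for two disjoint bulks of %d",
                  2 * b, b))
  }
  ord_low <- order(phenos$phenotype, phenos$individual)
  low <- phenos$individual[ord_low[seq_len(b)]]
  rest <- phenos[!(phenos$individual %in% low), ]
  ord_high <- order(-rest$phenotype, rest$individual)
  high <- rest$individual[ord_high[seq_len(b)]]
  structure(list(low = sort(low), high = sort(high)),
            class = "bulk_membership")
}

#' Simulate pooled sequencing of the two bulks
#'
#' For every marker and bulk the true alternate-allele frequency is the
#' bulk's mean dosage over two; site depth is negative-binomial with the
#' model's bulk-specific mean; the alternate read count is binomial with
#' success probability `f (1 - e) + (1 - f) e` where `e` is the error
#' rate. The two parents are included as error-free homozygous samples
#' (low parent reference, high parent alternate) at the rounded mean of
#' the two bulk depths.
#'
#' @param genos An `f2_genotypes` object.
#' @param bulks A `bulk_membership` from [select_bulks()].
#' @param seqmodel A [sequencing_model()].
#' @param seed Integer seed.
#' @return A marker table tibble (see [read_variants()] for the column
#'   contract): `chrom`, `pos`, `ref`, `alt`, `multi_allelic`, and
#'   `<sample>_ref` / `<sample>_alt` depths for samples `bulk_high`,
#'   `bulk_low`, `parent_low`, `parent_high`.
#' @export
simulate_pooled_reads <- function(genos, bulks, seqmodel, seed) {
  stopifnot(inherits(genos, "f2_genotypes"),
            inherits(bulks, "bulk_membership"),
            inherits(seqmodel, "sequencing_model"))
  if (length(bulks$low) == 0 || length(bulks$high) == 0) {
    abort("bulks must be non-empty")
  }
  if (length(intersect(bulks$low, bulks$high)) > 0) {
    abort("bulks must be disjoint")
  }
  set.seed(as.integer(seed))
  map <- genos$map
  n_mark <- nrow(map)
  e <- seqmodel$error_rate

  draw_bulk <- function(members, mean_depth) {
    f <- colSums(genos$dosage[members, , drop = FALSE]) /
      (2 * length(members))
    depth <- draw_depth(n_mark, mean_depth, seqmodel$depth_dispersion)
    alt <- rbinom(n_mark, depth, f * (1 - e) + (1 - f) * e)
    list(ref = depth - alt, alt = alt)
  }
  hi <- draw_bulk(bulks$high, seqmodel$mean_depth_high)
  lo <- draw_bulk(bulks$low, seqmodel$mean_depth_low)
  p_depth <- as.integer(round((seqmodel$mean_depth_high +
                                 seqmodel$mean_depth_low) / 2))

  tibble::tibble(
    chrom = map$chrom, pos = map$pos_bp,
    ref = "A", alt = "T", multi_allelic = FALSE,
    bulk_high_ref = hi$ref, bulk_high_alt = hi$alt,
    bulk_low_ref = lo$ref, bulk_low_alt = lo$alt,
    parent_low_ref = p_depth, parent_low_alt = 0L,
    parent_high_ref = 0L, parent_high_alt = p_depth
  )
}

# negative-binomial site depth; dispersion 0 degenerates to Poisson
draw_depth <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(rpois(n, mu))
  rnbinom(n, size = 1 / dispersion, mu = mu)
}
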