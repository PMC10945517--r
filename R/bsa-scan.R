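#' Per-bulk allele frequencies from read counts
#'
#' Converts bulk read depths to alternate-allele frequencies
#' `fa = alt / (alt + ref)` per bulk (the reference-allele frequency is
#' its complement). Markers with zero depth in either bulk carry no
#' frequency information and are dropped; the number dropped is attached
#' as attribute `"n_zero_depth"`.
#'
#' @param markers Marker table with `bulk_high_*` / `bulk_low_*` depths.
#' @return A tibble with columns `chrom`, `pos`, `fa_high`, `fa_low`.
#' @export
allele_frequencies <- function(markers) {
  hi_tot <- markers$bulk_high_ref + markers$bulk_high_alt
  lo_tot <- markers$bulk_low_ref + markers$bulk_low_alt
  keep <- hi_tot > 0 & lo_tot > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("dropped %d marker(s) with zero depth in a bulk", n_dropped))
  }
  out <- tibble::tibble(
    chrom = markers$chrom[keep], pos = markers$pos[keep],
    fa_high = markers$bulk_high_alt[keep] / hi_tot[keep],
    fa_low  = markers$bulk_low_alt[keep] / lo_tot[keep]
  )
  attr(out, "n_zero_depth") <- n_dropped
  out
}

#' Euclidean-distance statistic between bulks
#'
#' Per-marker Euclidean distance between the two bulks' allele-frequency
#' vectors over the two alleles:
#' `ED = sqrt((fa_H - fa_L)^2 + (fA_H - fA_L)^2)`, which for a biallelic
#' site equals `sqrt(2) * |fa_H - fa_L|`. ED is 0 for identical bulks
#' and reaches `sqrt(2)` at fixation for opposite alleles.
#'
#' @param freqs Tibble from [allele_frequencies()].
#' @return The input with an added `ed` column, classed `ed_profile`.
#' @export
euclidean_distance <- function(freqs) {
  stopifnot(all(c("fa_high", "fa_low") %in% names(freqs)))
  d_alt <- freqs$fa_high - freqs$fa_low
  d_ref <- (1 - freqs$fa_high) - (1 - freqs$fa_low)
  out <- dplyr::mutate(freqs, ed = sqrt(d_alt^2 + d_ref^2))
  class(out) <- c("ed_profile", class(out))
  out
}

#' Fourth-power windowed ED statistic
#'
#' Slides a window of `window` consecutive markers along each
#' chromosome (step 1 marker; windows never span chromosomes) and
#' reports the fourth power of the ED sum in the window,
#' `w = (sum ED)^4`, placed at the window's midpoint marker. A
#' chromosome with fewer than `window` markers contributes a single
#' whole-chromosome window, flagged in the `short_chrom` column.
#' Setting `sliding = FALSE` tiles disjoint windows instead.
#'
#' @param profile An `ed_profile` from [euclidean_distance()] (columns
#'   `chrom`, `pos`, `ed`, sorted by position within chromosome).
#' @param window Markers per window (default 100).
#' @param sliding Slide by one marker (default) or tile disjoint
#'   windows.
#' @return A tibble of class `window_profile` with columns `chrom`,
#'   `start_idx`, `mid_pos`, `w_stat`, `short_chrom`.
#' @export
windowed_statistic <- function(profile, window = 100, sliding = TRUE) {
  stopifnot(all(c("chrom", "pos", "ed") %in% names(profile)), window >= 1)
  if (nrow(profile) == 0) {
    out <- tibble::tibble(chrom = character(), start_idx = integer(),
                          mid_pos = integer(), w_stat = numeric(),
                          short_chrom = logical())
    class(out) <- c("window_profile", class(out))
    return(out)
  }
  one_chrom <- function(df) {
    n <- nrow(df)
    if (any(diff(df$pos) < 0)) {
      abort("markers must be position-sorted within each chromosome")
    }
    w <- min(window, n)
    starts <- if (n < window) 1L else if (sliding) {
      seq_len(n - window + 1L)
    } else {
      seq.int(1L, n - window + 1L, by = window)
    }
    csum <- cumsum(c(0, df$ed))
    sums <- csum[starts + w] - csum[starts]
    mid <- starts + (w - 1L) %/% 2L
    tibble::tibble(chrom = df$chrom[1], start_idx = starts,
                   mid_pos = df$pos[mid], w_stat = sums^4,
                   short_chrom = n < window)
  }
  out <- profile |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_split() |>
    purrr::map_dfr(one_chrom)
  class(out) <- c("window_profile", class(out))
  out
}

#' Simulation-based null threshold for the windowed statistic
#'
#' Simulates unlinked null genomes under the experiment's sampling
#' noise: at each marker, each bulk's true alternate frequency is drawn
#' `Binomial(2 * bulk_size, 1/2) / (2 * bulk_size)` (segregation
#' sampling of the finite bulk), read depths from the sequencing model,
#' and alternate read counts binomially from the depth and frequency.
#' The windowed statistic is computed per simulated genome.
#'
#' Two thresholds are available: `"pooled"` (default) takes the
#' `q`-quantile of all null window statistics pooled across
#' simulations, matching a per-window confidence threshold; `"max"`
#' takes the `q`-quantile of each simulation's genome-wide maximum,
#' giving family-wise control of any false region.
#'
#' @param design A [cross_design()] (bulk sizes).
#' @param seqmodel A [sequencing_model()].
#' @param n_markers Markers per simulated null genome.
#' @param window Window size passed to [windowed_statistic()].
#' @param n_sim Number of null genomes (>= 200).
#' @param q Quantile (default 0.95).
#' @param method `"pooled"` or `"max"`.
#' @param seed Integer seed; the threshold is deterministic given it.
#' @return A scalar threshold with attributes `method`, `q`, `n_sim`.
#' @export
null_threshold <- function(design, seqmodel, n_markers, window = 100,
                           n_sim = 500, q = 0.95,
                           method = c("pooled", "max"), seed) {
  method <- match.arg(method)
  stopifnot(inherits(design, "cross_design"),
            inherits(seqmodel, "sequencing_model"), n_markers >= window)
  if (n_sim < 200) abort("n_sim must be at least 200")
  set.seed(as.integer(seed))
  stats <- purrr::map(seq_len(n_sim), function(i) {
    w <- simulate_null_windows(design, seqmodel, n_markers, window)
    if (method == "max") max(w) else w
  })
  pooled <- unlist(stats)
  thr <- unname(quantile(pooled, q, type = 7))
  structure(thr, method = method, q = q, n_sim = n_sim)
}

# one unlinked null genome -> vector of window statistics
simulate_null_windows <- function(design, seqmodel, n_markers, window) {
  ed <- simulate_null_ed(design, seqmodel, n_markers)
  csum <- cumsum(c(0, ed))
  starts <- seq_len(n_markers - window + 1L)
  (csum[starts + window] - csum[starts])^4
}

simulate_null_ed <- function(design, seqmodel, n_markers) {
  b2 <- 2 * design$bulk_size
  f_hi <- rbinom(n_markers, b2, 0.5) / b2
  f_lo <- rbinom(n_markers, b2, 0.5) / b2
  d_hi <- pmax(1, draw_depth(n_markers, seqmodel$mean_depth_high,
                             seqmodel$depth_dispersion))
  d_lo <- pmax(1, draw_depth(n_markers, seqmodel$mean_depth_low,
                             seqmodel$depth_dispersion))
  obs_hi <- rbinom(n_markers, d_hi, f_hi) / d_hi
  obs_lo <- rbinom(n_markers, d_lo, f_lo) / d_lo
  sqrt(2) * abs(obs_hi - obs_lo)
}

#' Call QTL regions from a windowed profile
#'
#' Markers whose window statistic exceeds the threshold are significant;
#' each contributes an interval of `flank` bp either side of its
#' position (clipped to the chromosome), and overlapping intervals on a
#' chromosome are merged into regions. The region peak is the
#' significant marker with the largest window statistic (leftmost on
#' ties).
#'
#' @param windows A `window_profile` from [windowed_statistic()].
#' @param threshold Scalar significance threshold (e.g. from
#'   [null_threshold()]).
#' @param flank Half-width in bp around each significant marker
#'   (default 8e6, i.e. +/- 8 Mbp).
#' @param chrom_lengths Optional named vector of chromosome lengths in
#'   bp for right-clipping.
#' @return A tibble of class `qtl_regions` with columns `chrom`,
#'   `start`, `end`, `peak_pos`, `peak_stat`, `n_significant_markers`
#'   (1-based closed coordinates).
#' @export
call_regions <- function(windows, threshold, flank = 8e6,
                         chrom_lengths = NULL) {
  stopifnot(all(c("chrom", "mid_pos", "w_stat") %in% names(windows)))
  sig <- windows[windows$w_stat > as.numeric(threshold), ]
  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), peak_pos = numeric(),
                          peak_stat = numeric(),
                          n_significant_markers = integer())
  if (nrow(sig) == 0) {
    class(empty) <- c("qtl_regions", class(empty))
    return(empty)
  }
  one_chrom <- function(df) {
    df <- df[order(df$mid_pos), ]
    chrom_end <- if (!is.null(chrom_lengths) && df$chrom[1] %in%
                       names(chrom_lengths)) {
      chrom_lengths[[df$chrom[1]]]
    } else Inf
    lo <- pmax(1, df$mid_pos - flank)
    hi <- pmin(chrom_end, df$mid_pos + flank)
    # merge overlapping closed intervals
    grp <- cumsum(c(1, as.integer(lo[-1] > cummax(hi[-length(hi)]))))
    purrr::map_dfr(split(seq_len(nrow(df)), grp), function(idx) {
      peak <- idx[which.max(df$w_stat[idx])]  # which.max -> leftmost tie
      tibble::tibble(chrom = df$chrom[1], start = min(lo[idx]),
                     end = max(hi[idx]), peak_pos = df$mid_pos[peak],
                     peak_stat = df$w_stat[peak],
                     n_significant_markers = length(idx))
    })
  }
  out <- sig |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_split() |>
    purrr::map_dfr(one_chrom)
  class(out) <- c("qtl_regions", class(out))
  out
}

#' Intersect called regions with an external GWAS hit list
#'
#' Annotates each GWAS marker-trait association with the QTL region
#' containing it (closed intervals), mirroring the co-localization of
#' association hits with bulk-segregant regions.
#'
#' @param regions A `qtl_regions` tibble from [call_regions()].
#' @param gwas_hits Data frame with columns `chrom`, `pos` (and
#'   optionally `pvalue`).
#' @param check_chroms When `TRUE` (default) and regions exist, error if
#'   a hit's chromosome name matches no region chromosome and no
#'   chromosome shared between the two tables exists (catches assembly
#'   naming mismatches).
#' @return A list with `hits` (the hit table with `region_chrom`,
#'   `region_start`, `region_end`, `matched`) and `region_counts`
#'   (hits per region).
#' @export
intersect_gwas <- function(regions, gwas_hits, check_chroms = TRUE) {
  stopifnot(all(c("chrom", "pos") %in% names(gwas_hits)))
  hits <- tibble::as_tibble(gwas_hits)
  if (nrow(regions) > 0 && check_chroms) {
    unmatched <- setdiff(unique(hits$chrom), unique(regions$chrom))
    if (length(unmatched) == length(unique(hits$chrom)) &&
        nrow(hits) > 0) {
      abort(paste0("no GWAS hit chromosome matches the regions; unmatched: ",
                   paste(unmatched, collapse = ", ")))
    }
  }
  match_one <- function(ch, p) {
    idx <- which(regions$chrom == ch & regions$start <= p & regions$end >= p)
    if (length(idx) == 0) NA_integer_ else idx[1]
  }
  ridx <- purrr::map2_int(hits$chrom, hits$pos, match_one)
  hits$matched <- !is.na(ridx)
  hits$region_chrom <- ifelse(hits$matched, regions$chrom[ridx], NA_character_)
  hits$region_start <- ifelse(hits$matched, regions$start[ridx], NA_real_)
  hits$region_end <- ifelse(hits$matched, regions$end[ridx], NA_real_)
  counts <- hits |>
    dplyr::filter(.data$matched) |>
    dplyr::count(.data$region_chrom, .data$region_start, .data$region_end,
                 name = "n_hits")
  list(hits = hits, region_counts = counts)
}

#' Genotype-class percentages at a marker
#'
#' Converts per-class line counts at a SNP into percentages of the
#' panel, e.g. homozygote classes at a locus typed across a diversity
#' panel.
#'
#' @param counts Named integer vector of genotype-class counts.
#' @param n_total Panel size (default `sum(counts)`; pass the full
#'   panel size when some lines are heterozygous or untyped).
#' @return Tibble with `genotype`, `n`, `percent`.
#' @export
genotype_class_percent <- function(counts, n_total = sum(counts)) {
  stopifnot(n_total > 0, all(counts >= 0))
  tibble::tibble(genotype = names(counts), n = as.integer(counts),
                 percent = 100 * as.numeric(counts) / n_total)
}
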