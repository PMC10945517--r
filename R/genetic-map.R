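#' Define a marker map for a simulated genome
#'
#' Builds the marker scaffold used by the cross simulator: a set of
#' chromosomes, each carrying a fixed number of markers at evenly spaced
#' genetic positions with physically co-linear base-pair coordinates.
#' Genetic distance is converted to recombination fraction with the
#' Haldane map function (no crossover interference).
#'
#' @param chromosomes Data frame with one row per chromosome and columns
#'   `name`, `length_cM`, `length_bp`. Lengths must be strictly positive.
#' @param markers_per_chrom Number of markers per chromosome (single
#'   positive integer, recycled across chromosomes).
#'
#' @return A tibble of class `genetic_map` with columns `chrom`,
#'   `marker`, `pos_cM`, `pos_bp`; marker positions are strictly
#'   increasing within each chromosome and cM/bp coordinates are
#'   co-monotone.
#'
#' @examples
#' genetic_map(millet_chromosomes(n_chrom = 2), markers_per_chrom = 50)
#' @export
genetic_map <- function(chromosomes, markers_per_chrom) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length_cM", "length_bp") %in% names(chromosomes)))
  if (any(chromosomes$length_cM <= 0) || any(chromosomes$length_bp <= 0)) {
    abort("chromosome lengths must be strictly positive")
  }
  markers_per_chrom <- as.integer(markers_per_chrom)
  if (length(markers_per_chrom) != 1 || is.na(markers_per_chrom) ||
      markers_per_chrom < 1) {
    abort("`markers_per_chrom` must be a single positive integer")
  }
  map <- purrr::pmap_dfr(
    chromosomes[, c("name", "length_cM", "length_bp")],
    function(name, length_cM, length_bp) {
      n <- markers_per_chrom
      # even spacing, away from the telomeres
      frac <- (seq_len(n) - 0.5) / n
      tibble::tibble(
        chrom  = as.character(name),
        marker = paste0(name, "_m", seq_len(n)),
        pos_cM = frac * length_cM,
        pos_bp = pmax(1L, as.integer(round(frac * length_bp)))
      )
    }
  )
  class(map) <- c("genetic_map", class(map))
  map
}

#' Chromosome scaffold resembling the pearl millet genome
#'
#' Convenience table of seven chromosomes with lengths loosely matching
#' the pearl millet assembly scale (hundreds of Mbp, 100-200 cM each).
#'
#' @param n_chrom Number of chromosomes to keep (1-7).
#' @return Data frame with columns `name`, `length_cM`, `length_bp`.
#' @export
millet_chromosomes <- function(n_chrom = 7) {
  stopifnot(n_chrom >= 1, n_chrom <= 7)
  tbl <- tibble::tibble(
    name      = paste0("chr", 1:7),
    length_cM = c(180, 150, 140, 130, 130, 140, 120),
    length_bp = c(290e6, 250e6, 230e6, 210e6, 200e6, 250e6, 180e6)
  )
  tbl[seq_len(n_chrom), ]
}

#' Haldane map function
#'
#' Converts genetic distance in centimorgans to a recombination fraction
#' assuming no interference: `r = (1 - exp(-2 d / 100)) / 2`.
#'
#' @param d_cM Genetic distance(s) in cM, non-negative.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @export
haldane <- function(d_cM) {
  stopifnot(all(d_cM >= 0))
  (1 - exp(-2 * d_cM / 100)) / 2
}
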