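#' Configuration for the marker filtering cascade
#'
#' Thresholds for [filter_frequency_depth()]. The depth window is given
#' as percentiles of the dataset's total-depth distribution; after a
#' run, the numeric bounds that were used are recorded in the returned
#' object (see `config_used` in [filter_report()]) and can be passed
#' back via `depth_bounds` to re-apply the identical calibrated filter.
#'
#' @param af_min Minimum pooled alternate-allele frequency across the
#'   two bulks (default 0.25).
#' @param depth_low_pct,depth_high_pct Percentile bounds of the total
#'   sequencing depth retained (defaults 25 and 95; nearest-rank,
#'   closed interval).
#' @param missing_max Maximum tolerated fraction of samples with zero
#'   depth at a site (default 0.5; sites strictly above are removed).
#' @param maf_min Minimum minor-allele frequency on the pooled read
#'   counts of all samples (default 0.05).
#' @param depth_bounds Optional numeric `c(low, high)` absolute depth
#'   bounds; when supplied the percentiles are not recomputed.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(af_min = 0.25, depth_low_pct = 25,
                          depth_high_pct = 95, missing_max = 0.5,
                          maf_min = 0.05, depth_bounds = NULL) {
  stopifnot(af_min >= 0, af_min < 1,
            depth_low_pct >= 0, depth_low_pct < depth_high_pct,
            depth_high_pct <= 100,
            missing_max >= 0, missing_max <= 1, maf_min >= 0, maf_min < 1)
  if (!is.null(depth_bounds)) {
    stopifnot(length(depth_bounds) == 2, depth_bounds[1] <= depth_bounds[2])
  }
  structure(list(af_min = af_min, depth_low_pct = depth_low_pct,
                 depth_high_pct = depth_high_pct, missing_max = missing_max,
                 maf_min = maf_min, depth_bounds = depth_bounds),
            class = "filter_config")
}

# nearest-rank percentile: smallest value with at least p% of the data
# at or below it
nearest_rank <- function(x, p) {
  s <- sort(x)
  s[max(1L, ceiling(p / 100 * length(s)))]
}

depth_cols <- function(markers) {
  grep("_(ref|alt)$", names(markers), value = TRUE)
}

#' Keep biallelic markers segregating between the parents
#'
#' Retains sites that are biallelic, where each parent is confidently
#' homozygous (major-allele read fraction >= 0.9 at total depth >= 5)
#' and the two parents carry opposite alleles. Alleles are re-polarized
#' so the low-growth parent carries the reference allele: at sites where
#' it is homozygous alternate, REF/ALT and every sample's ref/alt depths
#' are swapped.
#'
#' @param markers Marker table (see [read_variants()]).
#' @return The filtered, re-polarized marker table. The number of sites
#'   swapped during re-polarization is attached as attribute
#'   `"n_repolarized"`.
#' @export
filter_biallelic_parental <- function(markers) {
  pl_tot <- markers$parent_low_ref + markers$parent_low_alt
  ph_tot <- markers$parent_high_ref + markers$parent_high_alt
  hom <- function(ref, alt, tot) {
    frac <- ifelse(tot > 0, pmax(ref, alt) / tot, 0)
    ok <- tot >= 5 & frac >= 0.9
    allele <- ifelse(alt > ref, "alt", "ref")
    list(ok = ok, allele = allele)
  }
  pl <- hom(markers$parent_low_ref, markers$parent_low_alt, pl_tot)
  ph <- hom(markers$parent_high_ref, markers$parent_high_alt, ph_tot)
  keep <- !markers$multi_allelic & pl$ok & ph$ok & pl$allele != ph$allele
  out <- markers[keep, ]
  flip <- pl$allele[keep] == "alt"
  if (any(flip)) {
    tmp_ref <- out$ref[flip]
    out$ref[flip] <- out$alt[flip]
    out$alt[flip] <- tmp_ref
    for (role in c("bulk_high", "bulk_low", "parent_low", "parent_high")) {
      rc <- paste0(role, "_ref"); ac <- paste0(role, "_alt")
      tmp <- out[[rc]][flip]
      out[[rc]][flip] <- out[[ac]][flip]
      out[[ac]][flip] <- tmp
    }
  }
  attr(out, "n_repolarized") <- sum(flip)
  out
}

#' Apply the frequency, depth, missingness and MAF filters
#'
#' Runs the filtering cascade in its fixed order: (1) multi-allelic
#' sites removed; (2) sites with pooled alternate-allele frequency
#' across the two bulks below `af_min` removed; (3) sites outside the
#' closed total-depth window given by the nearest-rank
#' `depth_low_pct`/`depth_high_pct` percentiles (computed on the table
#' as it stands after step 2, unless `depth_bounds` pins them) removed;
#' (4) sites with more than `missing_max` of the samples at zero depth
#' removed; (5) sites with pooled-count minor-allele frequency below
#' `maf_min` removed.
#'
#' @param markers Marker table.
#' @param cfg A [filter_config()].
#' @return The filtered marker table with attributes `"filter_report"`
#'   (tibble `step`, `removed`, `remaining`) and `"config_used"` (the
#'   config with the resolved numeric `depth_bounds`), both retrievable
#'   with [filter_report()].
#' @export
filter_frequency_depth <- function(markers, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  if (nrow(markers) == 0) abort("marker table is empty")
  steps <- character(); removed <- integer(); remaining <- integer()
  note <- function(tbl, step, n_before) {
    steps <<- c(steps, step)
    removed <<- c(removed, n_before - nrow(tbl))
    remaining <<- c(remaining, nrow(tbl))
    tbl
  }

  n0 <- nrow(markers)
  out <- note(markers[!markers$multi_allelic, ], "multi_allelic", n0)

  bulk_alt <- out$bulk_high_alt + out$bulk_low_alt
  bulk_tot <- bulk_alt + out$bulk_high_ref + out$bulk_low_ref
  af <- ifelse(bulk_tot > 0, bulk_alt / bulk_tot, NA_real_)
  out <- note(out[!(!is.na(af) & af < cfg$af_min), ],
              "allele_frequency", nrow(out))

  total_depth <- rowSums(out[, depth_cols(out)])
  if (is.null(cfg$depth_bounds)) {
    if (nrow(out) == 0) {
      bounds <- c(NA_real_, NA_real_)
    } else {
      bounds <- c(nearest_rank(total_depth, cfg$depth_low_pct),
                  nearest_rank(total_depth, cfg$depth_high_pct))
    }
  } else {
    bounds <- cfg$depth_bounds
  }
  keep_depth <- is.na(bounds[1]) |
    (total_depth >= bounds[1] & total_depth <= bounds[2])
  out <- note(out[keep_depth, ], "depth_percentile", nrow(out))

  roles <- c("bulk_high", "bulk_low", "parent_low", "parent_high")
  n_missing <- Reduce(`+`, lapply(roles, function(role) {
    as.integer((out[[paste0(role, "_ref")]] + out[[paste0(role, "_alt")]]) == 0)
  }))
  out <- note(out[n_missing / length(roles) <= cfg$missing_max, ],
              "missingness", nrow(out))

  alt_all <- rowSums(out[, paste0(roles, "_alt")])
  tot_all <- alt_all + rowSums(out[, paste0(roles, "_ref")])
  f <- ifelse(tot_all > 0, alt_all / tot_all, 0)
  maf <- pmin(f, 1 - f)
  out <- note(out[maf >= cfg$maf_min, ], "maf", nrow(out))

  if (nrow(out) == 0) warn("all sites were removed by the filter cascade")
  cfg$depth_bounds <- bounds
  attr(out, "filter_report") <- tibble::tibble(
    step = steps, removed = removed, remaining = remaining)
  attr(out, "config_used") <- cfg
  out
}

#' Retrieve the report of a filter run
#'
#' @param markers A marker table returned by [filter_frequency_depth()].
#' @return A list with `report` (per-step removal counts) and
#'   `config_used` (the [filter_config()] with resolved depth bounds).
#' @export
filter_report <- function(markers) {
  list(report = attr(markers, "filter_report"),
       config_used = attr(markers, "config_used"))
}
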