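# Independent oracles and fixture builders shared across test files.

# Brute-force windowed statistic: explicit double loop per chromosome,
# independent of the package's cumulative-sum implementation.
brute_force_windows <- function(profile, window = 100) {
  out <- list()
  for (ch in unique(profile$chrom)) {
    df <- profile[profile$chrom == ch, ]
    n <- nrow(df)
    w <- min(window, n)
    starts <- if (n < window) 1L else seq_len(n - window + 1L)
    for (s in starts) {
      total <- 0
      for (j in s:(s + w - 1L)) total <- total + df$ed[j]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_idx = s,
        mid_pos = df$pos[s + (w - 1L) %/% 2L],
        w_stat = total^4, short_chrom = n < window)
    }
  }
  do.call(rbind, out)
}

# Brute-force DTW by recursive enumeration of warping paths (no
# memoization): the minimal accumulated |a_i - b_j| cost over all
# monotone step sequences ending at (i, j).
brute_force_dtw <- function(a, b) {
  rec <- function(i, j) {
    c0 <- abs(a[i] - b[j])
    if (i == 1 && j == 1) return(c0)
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    c0 + best
  }
  rec(length(a), length(b))
}

# Minimal VCF text fixture with AD depths for the four pipeline samples.
# depths: list of per-site lists role -> c(ref, alt).
write_test_vcf <- function(path, sites, samples = c("bulk_high", "bulk_low",
                                                    "parent_low",
                                                    "parent_high")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(sites, function(s) {
    ads <- vapply(samples, function(smp) {
      d <- s$depths[[smp]]
      if (is.null(d)) "." else paste(d, collapse = ",")
    }, character(1))
    paste(c(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", ".", "AD", ads),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# random marker table for filter tests
random_marker_table <- function(n, seed) {
  set.seed(seed)
  depth <- function() rpois(n, 80)
  alt_frac <- runif(n)
  mk_bulk <- function() {
    d <- depth()
    alt <- rbinom(n, d, alt_frac)
    list(ref = d - alt, alt = alt)
  }
  hi <- mk_bulk(); lo <- mk_bulk()
  pl <- depth(); ph <- depth()
  tibble::tibble(
    chrom = "chr1", pos = sort(sample.int(1e6, n)),
    ref = "A", alt = "T",
    multi_allelic = runif(n) < 0.05,
    bulk_high_ref = hi$ref, bulk_high_alt = hi$alt,
    bulk_low_ref = lo$ref, bulk_low_alt = lo$alt,
    parent_low_ref = pl, parent_low_alt = 0L,
    parent_high_ref = 0L, parent_high_alt = ph
  )
}
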