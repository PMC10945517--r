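#' Read bulk and parent allelic depths from a VCF
#'
#' Loads one record per VCF site into the marker-table layout used by
#' the filtering cascade and the scan: chromosome, 1-based position,
#' alleles, a multi-allelic flag, and per-sample reference/alternate
#' read depths taken from the `AD` FORMAT field. For multi-allelic
#' sites the alternate depth is the depth of the first alternate allele;
#' such sites are flagged and removed by the filter cascade.
#'
#' @param path Path to a VCF (4.x) file with per-sample `AD`.
#' @param samples Named character vector mapping the roles `bulk_high`,
#'   `bulk_low`, `parent_low`, `parent_high` to sample names in the VCF.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `multi_allelic`, and `<role>_ref` / `<role>_alt` integer depths for
#'   the four roles. A sample with a missing `AD` value at a site gets
#'   zero depths there (counted as missing data downstream).
#' @export
read_variants <- function(path,
                          samples = c(bulk_high = "bulk_high",
                                      bulk_low = "bulk_low",
                                      parent_low = "parent_low",
                                      parent_high = "parent_high")) {
  roles <- c("bulk_high", "bulk_low", "parent_low", "parent_high")
  stopifnot(all(roles %in% names(samples)))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(empty_marker_table())
  }
  pos <- as.integer(fix$POS)
  for (ch in unique(fix$CHROM)) {
    if (is.unsorted(pos[fix$CHROM == ch])) {
      abort(sprintf("VCF is not position-sorted on chromosome '%s'", ch))
    }
  }
  vcf_samples <- colnames(vcf@gt)[-1]
  missing_samp <- setdiff(unname(samples[roles]), vcf_samples)
  if (length(missing_samp) > 0) {
    abort(paste0("samples not in VCF: ", paste(missing_samp, collapse = ", ")))
  }
  fmt <- strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)
  if (any(!purrr::map_lgl(fmt, ~ "AD" %in% .x))) {
    abort("every site must carry an AD FORMAT field")
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  out <- tibble::tibble(
    chrom = fix$CHROM, pos = pos,
    ref = fix$REF, alt = fix$ALT,
    multi_allelic = grepl(",", fix$ALT, fixed = TRUE)
  )
  for (role in roles) {
    depths <- parse_ad(ad[, samples[[role]]])
    out[[paste0(role, "_ref")]] <- depths$ref
    out[[paste0(role, "_alt")]] <- depths$alt
  }
  out
}

# "ref,alt[,alt2...]" -> integer ref/alt depths; "." or NA -> 0/0
parse_ad <- function(x) {
  parts <- strsplit(ifelse(is.na(x) | x == ".", "0,0", x), ",", fixed = TRUE)
  ref <- purrr::map_int(parts, ~ as.integer(.x[1]))
  alt <- purrr::map_int(parts, ~ if (length(.x) > 1) as.integer(.x[2]) else 0L)
  ref[is.na(ref)] <- 0L
  alt[is.na(alt)] <- 0L
  list(ref = unname(ref), alt = unname(alt))
}

empty_marker_table <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), multi_allelic = logical(),
    bulk_high_ref = integer(), bulk_high_alt = integer(),
    bulk_low_ref = integer(), bulk_low_alt = integer(),
    parent_low_ref = integer(), parent_low_alt = integer(),
    parent_high_ref = integer(), parent_high_alt = integer()
  )
}

#' Write a marker table as a minimal VCF
#'
#' Serializes a marker table (for example from [simulate_pooled_reads()])
#' as a VCF 4.2 file carrying the four samples with `DP` and `AD` FORMAT
#' fields, so simulated data round-trip through [read_variants()].
#'
#' @param markers Marker table tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(markers, path) {
  roles <- c("bulk_high", "bulk_low", "parent_low", "parent_high")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", roles), collapse = "\t")
  )
  sample_cols <- purrr::map(roles, function(role) {
    ref <- markers[[paste0(role, "_ref")]]
    alt <- markers[[paste0(role, "_alt")]]
    sprintf("%d:%d,%d", ref + alt, ref, alt)
  })
  body <- do.call(paste, c(
    list(markers$chrom, markers$pos, ".", markers$ref, markers$alt,
         ".", "PASS", ".", "DP:AD"),
    sample_cols, sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}
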