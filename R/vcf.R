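#' Read a family-scale multi-sample VCF
#'
#' Loads a VCF 4.x file into a long tibble of biallelic SNV calls, one row per
#' site and sample, carrying the genotype fields the IBD filters need: `GT`,
#' `DP` (read depth), `GQ` (genotype quality) and `AD` (allele depths).
#' Multiallelic records, non-SNV records, and records whose FORMAT lacks any
#' of the four fields are skipped and counted (see the `skipped` attribute).
#' Missing genotype *values* (`./.`) are retained as `NA` so that downstream
#' filters can report them as such.
#'
#' @param path Path to a `.vcf` or `.vcf.gz` file.
#' @param samples Optional character vector of sample names to keep; all must
#'   be present in the file (a missing sample is an error). Default: all
#'   samples.
#'
#' @return A tibble of class `variant_sites` with columns `chrom`, `pos`,
#'   `ref`, `alt`, `sample`, `gt`, `a1`, `a2`, `dp`, `gq`, `ad_ref`,
#'   `ad_alt`, sorted by coordinate. Attribute `skipped` is a named integer
#'   vector counting skipped records.
#' @export
read_family_vcf <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  all_samples <- colnames(v@gt)[-1]
  samples <- samples %||% all_samples
  absent <- setdiff(samples, all_samples)
  if (length(absent)) {
    abort(sprintf(
      "Sample(s) not present in VCF: %s.", paste(absent, collapse = ", ")
    ))
  }
  n_rec <- nrow(v@fix)
  if (n_rec == 0) {
    out <- empty_variant_sites()
    attr(out, "skipped") <- c(multiallelic = 0L, non_snv = 0L, missing_format = 0L)
    return(out)
  }
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  alt <- fix$ALT
  ref <- fix$REF
  multi <- is.na(alt) | grepl(",", alt, fixed = TRUE)
  non_snv <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L |
    !ref %in% c("A", "C", "G", "T") | !alt %in% c("A", "C", "G", "T"))
  fmt <- v@gt[, "FORMAT"]
  keys <- strsplit(fmt, ":", fixed = TRUE)
  has_fields <- vapply(
    keys, function(k) all(c("GT", "DP", "GQ", "AD") %in% k), logical(1)
  )
  miss_fmt <- !multi & !non_snv & !has_fields
  keep <- !(multi | non_snv | miss_fmt)
  skipped <- c(
    multiallelic = sum(multi), non_snv = sum(non_snv),
    missing_format = sum(miss_fmt)
  )
  if (any(!keep)) {
    inform(sprintf(
      "Skipped %d record(s): %d multiallelic, %d non-SNV, %d missing FORMAT field(s).",
      sum(!keep), skipped[["multiallelic"]], skipped[["non_snv"]],
      skipped[["missing_format"]]
    ))
  }
  if (!any(keep)) {
    out <- empty_variant_sites()
    attr(out, "skipped") <- skipped
    return(out)
  }
  v <- v[keep, ]
  fix <- fix[keep, , drop = FALSE]

  gt <- vcfR::extract.gt(v, element = "GT")[, samples, drop = FALSE]
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[, samples, drop = FALSE]
  gq <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)[, samples, drop = FALSE]
  ad <- vcfR::extract.gt(v, element = "AD")[, samples, drop = FALSE]
  ad_ref <- vcfR::masplit(ad, record = 1L, sort = 0)
  ad_alt <- vcfR::masplit(ad, record = 2L, sort = 0)

  n <- nrow(fix)
  long <- tibble(
    chrom = rep(fix$CHROM, times = length(samples)),
    pos = rep(as.numeric(fix$POS), times = length(samples)),
    ref = rep(fix$REF, times = length(samples)),
    alt = rep(fix$ALT, times = length(samples)),
    sample = rep(samples, each = n),
    gt = as.vector(gt),
    dp = as.vector(dp),
    gq = as.vector(gq),
    ad_ref = as.vector(ad_ref),
    ad_alt = as.vector(ad_alt)
  )
  alleles <- parse_gt_alleles(long$gt)
  long$a1 <- alleles[, 1]
  long$a2 <- alleles[, 2]
  long <- long[, c(
    "chrom", "pos", "ref", "alt", "sample", "gt", "a1", "a2",
    "dp", "gq", "ad_ref", "ad_alt"
  )]
  long <- arrange(long, .data$chrom, .data$pos, .data$sample)
  class(long) <- c("variant_sites", class(long))
  attr(long, "skipped") <- skipped
  long
}

empty_variant_sites <- function() {
  out <- tibble(
    chrom = character(), pos = numeric(), ref = character(), alt = character(),
    sample = character(), gt = character(), a1 = integer(), a2 = integer(),
    dp = numeric(), gq = numeric(), ad_ref = numeric(), ad_alt = numeric()
  )
  class(out) <- c("variant_sites", class(out))
  out
}

# "0/1", "0|1", "./." -> two integer allele indices (unphased order kept).
# Fast path for the ubiquitous single-digit diploid form; anything longer
# falls back to a split.
parse_gt_alleles <- function(gt) {
  a1 <- rep(NA_integer_, length(gt))
  a2 <- rep(NA_integer_, length(gt))
  simple <- !is.na(gt) & nchar(gt) == 3L & substr(gt, 2, 2) %in% c("/", "|")
  c1 <- substr(gt[simple], 1, 1)
  c2 <- substr(gt[simple], 3, 3)
  a1[simple] <- suppressWarnings(as.integer(ifelse(c1 == ".", NA, c1)))
  a2[simple] <- suppressWarnings(as.integer(ifelse(c2 == ".", NA, c2)))
  other <- which(!is.na(gt) & !simple)
  if (length(other)) {
    parts <- strsplit(gt[other], "[/|]")
    pick <- function(p, i) {
      if (length(p) < i || p[i] %in% c(".", "")) NA_integer_ else as.integer(p[i])
    }
    a1[other] <- vapply(parts, pick, integer(1), i = 1L)
    a2[other] <- vapply(parts, pick, integer(1), i = 2L)
  }
  cbind(a1 = a1, a2 = a2)
}
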