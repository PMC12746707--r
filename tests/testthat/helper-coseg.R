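# Shared fixtures, all built in code.

toy_map <- function() {
  genetic_map(tibble::tibble(
    chrom = "chr3", bp = c(1, 1000001, 2000001), cM = c(0, 1, 2)
  ))
}

# Nuclear family: father I.1, mother I.2, sibs II.1 and II.2.
toy_ped <- function(n_children = 2) {
  kids <- paste0("II.", seq_len(n_children))
  pedigree(tibble::tibble(
    fid = "F1", id = c("I.1", "I.2", kids),
    father = c("0", "0", rep("I.1", n_children)),
    mother = c("0", "0", rep("I.2", n_children)),
    sex = c(1L, 2L, rep(0L, n_children)),
    phenotype = c(1L, 1L, rep(2L, n_children))
  ))
}

# Build a long variant_sites tibble from a genotype matrix (rows = sites,
# columns = samples, entries like "0/1"). Depth/quality/allele depths can be
# scalars or same-shaped matrices; default allele depths are the clean split
# implied by the genotype.
sites_from_gt <- function(gt, dp = 30, gq = 99, ad_ref = NULL, ad_alt = NULL,
                          pos = NULL, chrom = "chr1") {
  gt <- as.matrix(gt)
  n <- nrow(gt)
  samples <- colnames(gt)
  pos <- pos %||% seq_len(n) * 1000
  expand_num <- function(x) {
    if (is.null(dim(x))) matrix(x, n, length(samples)) else as.matrix(x)
  }
  dp <- expand_num(dp)
  gq <- expand_num(gq)
  split_gt <- function(g) {
    p <- strsplit(g, "[/|]")[[1]]
    suppressWarnings(as.integer(ifelse(p %in% c(".", ""), NA, p)))
  }
  rows <- list()
  for (j in seq_along(samples)) {
    al <- t(vapply(gt[, j], split_gt, integer(2)))
    het <- !is.na(al[, 1]) & !is.na(al[, 2]) & al[, 1] != al[, 2]
    # clean default AD: het -> half/half, hom -> all reads on that allele
    d_alt <- ifelse(het, dp[, j] / 2, ifelse(al[, 1] > 0, dp[, j], 0))
    d_ref <- dp[, j] - d_alt
    rows[[j]] <- tibble::tibble(
      chrom = chrom, pos = pos, ref = "A", alt = "C",
      sample = samples[j], gt = gt[, j],
      a1 = al[, 1], a2 = al[, 2], dp = dp[, j], gq = gq[, j],
      ad_ref = if (is.null(ad_ref)) d_ref else expand_num(ad_ref)[, j],
      ad_alt = if (is.null(ad_alt)) d_alt else expand_num(ad_alt)[, j]
    )
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), chrom, pos, sample)
  class(out) <- c("variant_sites", class(out))
  out
}

`%||%` <- rlang::`%||%`

# Textbook Pearson chi-square, the independent oracle for compare_tallies.
pearson_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Total length of the pairwise overlap between two closed interval sets.
overlap_length <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(0)
  }
  tot <- 0
  for (i in seq_len(nrow(a))) {
    tot <- tot + sum(pmax(
      0, pmin(a$end[i], b$end) - pmax(a$start[i], b$start) + 1
    ))
  }
  tot
}

# Recovered-versus-true IBD summary for one simulated family.
ibd_recovery <- function(seed, n_sites = 8000) {
  fam <- simulate_family(2, sim_config(n_sites = n_sites), seed = seed)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_family_vcf(fam, vcf)
  scan <- ibd_segments(read_family_vcf(vcf), fam$pedigree, c("II.1", "II.2"))
  truth <- true_ibd_segments(fam)
  truth_ibd <- truth[truth$state != "IBD0", ]
  seg <- scan$segments
  rec <- data.frame(start = seg$start_bp, end = seg$end_bp)
  tru <- data.frame(start = truth_ibd$start_bp, end = truth_ibd$end_bp)
  known <- scan$states[!is.na(scan$states$pat_share) |
    !is.na(scan$states$mat_share), ]
  list(
    truth_len = sum(tru$end - tru$start + 1),
    recovered_len = sum(rec$end - rec$start + 1),
    overlap = overlap_length(rec, tru),
    max_gap = if (nrow(known) > 1) max(diff(sort(known$pos))) else Inf,
    scan = scan, truth = truth_ibd
  )
}
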