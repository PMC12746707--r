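# Column order used by sites_from_gt matrices: I.1 (father), I.2 (mother),
# II.1, II.2 (sibs).
fam_gt <- function(...) {
  m <- rbind(...)
  colnames(m) <- c("I.1", "I.2", "II.1", "II.2")
  m
}

test_that("site filters pass clean sites and name the first failure", {
  ped <- toy_ped()
  clean <- sites_from_gt(fam_gt(c("0/1", "0/0", "0/1", "0/0")))
  st <- site_passes_filters(clean, ped)
  expect_true(all(st$pass))

  # depth threshold is strict: 14 reads fail DP > 14
  dp <- matrix(30, 1, 4)
  dp[1, 3] <- 14
  st <- site_passes_filters(
    sites_from_gt(fam_gt(c("0/1", "0/0", "0/1", "0/0")), dp = dp), ped
  )
  expect_equal(st$reason, "depth")
  # boundary: 15 reads pass
  dp[1, 3] <- 15
  expect_true(site_passes_filters(
    sites_from_gt(fam_gt(c("0/1", "0/0", "0/1", "0/0")), dp = dp), ped
  )$pass)

  gq <- matrix(99, 1, 4)
  gq[1, 2] <- 30
  st <- site_passes_filters(
    sites_from_gt(fam_gt(c("0/1", "0/0", "0/1", "0/0")), gq = gq), ped
  )
  expect_equal(st$reason, "quality")

  # child 1/1 with parents 0/0 x 0/1 is a Mendelian error
  st <- site_passes_filters(
    sites_from_gt(fam_gt(c("0/0", "0/1", "1/1", "0/0"))), ped
  )
  expect_equal(st$reason, "mendelian")

  # heterozygote with 90% alt reads is imbalanced
  adr <- matrix(15, 1, 4)
  ada <- matrix(15, 1, 4)
  adr[1, 3] <- 3
  ada[1, 3] <- 27
  st <- site_passes_filters(
    sites_from_gt(fam_gt(c("0/1", "0/0", "0/1", "0/0")),
      ad_ref = adr, ad_alt = ada
    ),
    ped
  )
  expect_equal(st$reason, "balance")

  st <- site_passes_filters(
    sites_from_gt(fam_gt(c("0/1", "0/0", "./.", "0/0"))), ped
  )
  expect_equal(st$reason, "missing")

  # precedence: a missing call wins over a depth failure
  st <- site_passes_filters(
    sites_from_gt(fam_gt(c("0/1", "0/0", "./.", "0/0")), dp = 5), ped
  )
  expect_equal(st$reason, "missing")
})

test_that("Mendelian screening agrees with brute-force trio enumeration", {
  trio_ped <- pedigree(data.frame(
    fid = "F", id = c("I.1", "I.2", "II.1"),
    father = c("0", "0", "I.1"), mother = c("0", "0", "I.2"),
    sex = c(1, 2, 0), phenotype = c(1, 1, 2)
  ))
  gts <- c("0/0", "0/1", "1/1")
  allele_sets <- list(c(0, 0), c(0, 1), c(1, 1))
  for (fi in 1:3) {
    for (mi in 1:3) {
      for (ci in 1:3) {
        m <- matrix(c(gts[fi], gts[mi], gts[ci]), 1, 3,
          dimnames = list(NULL, c("I.1", "I.2", "II.1"))
        )
        st <- site_passes_filters(sites_from_gt(m), trio_ped)
        f <- allele_sets[[fi]]
        mo <- allele_sets[[mi]]
        ch <- allele_sets[[ci]]
        # oracle: one child allele from each parent, either assignment
        consistent <- any(
          (ch[1] %in% f & ch[2] %in% mo) | (ch[2] %in% f & ch[1] %in% mo)
        )
        expect_equal(st$pass, consistent, info = paste(gts[fi], gts[mi], gts[ci]))
      }
    }
  }
})

test_that("filtering is an idempotent subset operation", {
  fam <- simulate_family(
    2, sim_config(n_sites = 300, mean_depth = 16, depth_model = "poisson"),
    seed = 3
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  write_family_vcf(fam, path)
  sites <- read_family_vcf(path)
  once <- filter_sites(sites, fam$pedigree)
  twice <- filter_sites(once, fam$pedigree)
  expect_lt(nrow(once), nrow(sites))
  expect_identical(as.data.frame(once), as.data.frame(twice))
})

test_that("informative sites require a het parent and resolvable transmissions", {
  ped <- toy_ped()
  pair <- c("II.1", "II.2")
  both_hom <- sites_from_gt(fam_gt(c("0/0", "0/0", "0/0", "0/0")))
  expect_equal(nrow(informative_sites(both_hom, pair, ped)), 0)

  one_het <- sites_from_gt(fam_gt(c("0/1", "0/0", "0/1", "0/0")))
  expect_equal(nrow(informative_sites(one_het, pair, ped)), 4)

  all_het <- sites_from_gt(fam_gt(c("0/1", "0/1", "0/1", "0/1")))
  expect_equal(nrow(informative_sites(all_het, pair, ped)), 0)
  # ...unless allele-depth tie-breaking is allowed to resolve the phase
  adr <- matrix(c(15, 15, 20, 20), 1, 4)
  ada <- matrix(c(15, 15, 10, 10), 1, 4)
  all_het_ad <- sites_from_gt(fam_gt(c("0/1", "0/1", "0/1", "0/1")),
    ad_ref = adr, ad_alt = ada
  )
  expect_equal(nrow(informative_sites(all_het_ad, pair, ped, ad_tiebreak = TRUE)), 4)
})

test_that("per-site IBD states follow the shared-transmission count", {
  ped <- toy_ped()
  pair <- c("II.1", "II.2")

  # both parents het, both sibs the same homozygote: both transmissions shared
  s <- pairwise_ibd_states(
    sites_from_gt(fam_gt(c("0/1", "0/1", "0/0", "0/0"))), pair, ped
  )
  expect_equal(s$state, "IBD2")
  expect_true(s$pat_share & s$mat_share)

  # opposite homozygotes: neither transmission shared
  s <- pairwise_ibd_states(
    sites_from_gt(fam_gt(c("0/1", "0/1", "0/0", "1/1"))), pair, ped
  )
  expect_equal(s$state, "IBD0")

  # shared paternal allele, different maternal alleles (distinct maternal
  # alleles make both transmissions resolvable)
  s <- pairwise_ibd_states(
    sites_from_gt(fam_gt(c("0/1", "2/3", "0/2", "0/3"))), pair, ped
  )
  expect_equal(s$state, "IBD1")
  expect_true(s$pat_share)
  expect_false(s$mat_share)

  # only one transmission observable: share recorded, state left open
  s <- pairwise_ibd_states(
    sites_from_gt(fam_gt(c("0/1", "0/0", "0/1", "0/1"))), pair, ped
  )
  expect_equal(s$state, "ambiguous")
  expect_true(s$pat_share)
  expect_true(is.na(s$mat_share))
})

test_that("state calls match simulator truth at every unambiguous site", {
  fam <- simulate_family(2, sim_config(n_sites = 4000), seed = 21)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_family_vcf(fam, path)
  sites <- read_family_vcf(path)
  pair <- c("II.1", "II.2")
  inf <- informative_sites(sites, pair, fam$pedigree)
  states <- pairwise_ibd_states(inf, pair, fam$pedigree)

  idx <- match(states$pos, fam$sites$bp)
  truth_pat <- fam$origins[["II.1"]]$pat[idx] == fam$origins[["II.2"]]$pat[idx]
  truth_mat <- fam$origins[["II.1"]]$mat[idx] == fam$origins[["II.2"]]$mat[idx]
  truth_state <- paste0("IBD", truth_pat + truth_mat)
  called <- states$state != "ambiguous"
  expect_gt(sum(called), 50)
  expect_gte(mean(states$state[called] == truth_state[called]), 0.99)
  # per-parent share tracks are exact where observed
  expect_true(all(states$pat_share[!is.na(states$pat_share)] ==
    truth_pat[!is.na(states$pat_share)]))
  expect_true(all(states$mat_share[!is.na(states$mat_share)] ==
    truth_mat[!is.na(states$mat_share)]))
})

test_that("segments collapse state runs with gap and support rules", {
  mk <- function(pos, state) tibble::tibble(chrom = "chr1", pos = pos, state = state)

  ten <- segments_from_states(mk(1:10 * 100, rep("IBD2", 10)))
  expect_equal(nrow(ten), 1)
  expect_equal(ten$n_supporting_sites, 10)
  expect_equal(c(ten$start_bp, ten$end_bp), c(100, 1000))

  interrupted <- segments_from_states(
    mk(1:13 * 100, c(rep("IBD2", 6), "IBD0", rep("IBD2", 6))),
    min_sites = 5
  )
  expect_equal(nrow(interrupted), 2)

  # a run is split by a gap larger than max_gap_bp
  gapped <- segments_from_states(
    mk(c(1:6 * 100, 1e7 + 1:6 * 100), rep("IBD1", 12)),
    min_sites = 5, max_gap_bp = 1e6
  )
  expect_equal(nrow(gapped), 2)

  # ambiguous sites neither support nor interrupt
  amb <- segments_from_states(
    mk(1:11 * 100, c(rep("IBD2", 5), "ambiguous", rep("IBD2", 5)))
  )
  expect_equal(nrow(amb), 1)
  expect_equal(amb$n_supporting_sites, 10)

  # state changes close segments
  mixed <- segments_from_states(
    mk(1:12 * 100, c(rep("IBD2", 6), rep("IBD1", 6)))
  )
  expect_equal(mixed$state, c("IBD2", "IBD1"))
})

test_that("raising min_sites never increases the number of segments", {
  set.seed(5)
  for (i in 1:10) {
    states <- tibble::tibble(
      chrom = "chr1",
      pos = sort(sample.int(1e6, 200)),
      state = sample(c("IBD0", "IBD1", "IBD2", "ambiguous"), 200,
        replace = TRUE, prob = c(0.2, 0.35, 0.35, 0.1)
      )
    )
    counts <- vapply(
      c(1, 2, 5, 10, 20),
      function(ms) nrow(segments_from_states(states, min_sites = ms)),
      integer(1)
    )
    expect_true(all(diff(counts) <= 0))
    seg <- segments_from_states(states, min_sites = 1)
    # non-overlapping and sorted
    if (nrow(seg) > 1) {
      expect_true(all(seg$start_bp[-1] > seg$end_bp[-nrow(seg)]))
    }
  }
})

test_that("the end-to-end scan recovers simulated IBD segments", {
  rec <- ibd_recovery(seed = 42)
  expect_gte(rec$overlap / rec$truth_len, 0.9)
  seg <- rec$scan$segments
  # segment states agree with the truth tiling where they overlap most
  expect_true(all(seg$state %in% c("IBD1", "IBD2")))
  expect_s3_class(tidy(rec$scan), "tbl_df")
  g <- glance(rec$scan)
  expect_equal(g$n_segments, nrow(seg))
  expect_s3_class(autoplot(rec$scan), "ggplot")
})

test_that("IBD segments export as 0-based half-open BED-like rows", {
  rec <- ibd_recovery(seed = 42, n_sites = 2000)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ibd_bed(rec$scan, path)
  bed <- readr::read_tsv(path, show_col_types = FALSE)
  expect_named(bed, c("chrom", "start0", "end", "pair", "state", "n_sites"))
  expect_equal(bed$start0, rec$scan$segments$start_bp - 1)
  expect_equal(bed$end, rec$scan$segments$end_bp)
  expect_equal(unique(bed$pair), "II.1-II.2")
})
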