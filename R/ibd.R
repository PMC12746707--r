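#' Site-level quality and inheritance filters
#'
#' Applies the stringent per-sample site filters used before IBD calling:
#' every pedigree member must be genotyped, have read depth and genotype
#' quality at or above the thresholds (the defaults `dp_min = 15`,
#' `gq_min = 31` encode the strict inequalities DP > 14 and GQ > 30), every
#' parent-child trio must be Mendelian-consistent, and every heterozygous call
#' must show minimal allelic imbalance (alt-allele fraction within
#' `balance_range`; a called heterozygote with zero informative reads also
#' fails). Failures are reported as reasons, never as errors; the first
#' failing check (in the order missing, depth, quality, mendelian, balance)
#' is recorded.
#'
#' @param sites A `variant_sites` tibble from [read_family_vcf()].
#' @param ped A [pedigree()]; all members are required at every site.
#' @param dp_min Minimum acceptable depth (pass requires `dp >= dp_min`).
#' @param gq_min Minimum acceptable genotype quality (`gq >= gq_min`).
#' @param balance_range Closed interval of acceptable alt-allele fractions
#'   for heterozygous calls.
#'
#' @return A site-level tibble `chrom`, `pos`, `pass`, `reason` (`NA` when
#'   passing).
#' @export
site_passes_filters <- function(sites, ped, dp_min = 15, gq_min = 31,
                                balance_range = c(0.25, 0.75)) {
  stop_if_not_df(sites, "sites")
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped)
  members <- ped$id
  s <- sites[sites$sample %in% members, ]
  key <- distinct(sites[, c("chrom", "pos")])

  wide <- site_allele_matrix(s)
  dpm <- with_shape(wide, s, s$dp)
  gqm <- with_shape(wide, s, s$gq)
  present <- intersect(members, wide$samples)
  called <- !is.na(wide$a1[, present, drop = FALSE]) &
    !is.na(wide$a2[, present, drop = FALSE])
  min_dp <- row_min(dpm[, present, drop = FALSE])
  min_gq <- row_min(gqm[, present, drop = FALSE])
  bal <- balance_pass(
    as.vector(wide$a1), as.vector(wide$a2),
    as.vector(wide$ad_ref), as.vector(wide$ad_alt), balance_range
  )
  per_site <- tibble(chrom = wide$key$chrom, pos = wide$key$pos)
  per_site$missing <- rowSums(called) < length(members) |
    is.na(min_dp) | is.na(min_gq)
  per_site$depth_ok <- !is.na(min_dp) & min_dp >= dp_min
  per_site$quality_ok <- !is.na(min_gq) & min_gq >= gq_min
  per_site$balance_ok <- rowSums(!matrix(bal, nrow(wide$key))) == 0

  mendel <- mendelian_site_check(s, ped, wide)
  per_site <- left_join(per_site, mendel, by = c("chrom", "pos"))
  per_site$mendel_ok[is.na(per_site$mendel_ok)] <- TRUE

  reason <- rep(NA_character_, nrow(per_site))
  reason[!per_site$balance_ok] <- "balance"
  reason[!per_site$mendel_ok] <- "mendelian"
  reason[!per_site$quality_ok] <- "quality"
  reason[!per_site$depth_ok] <- "depth"
  reason[per_site$missing] <- "missing"

  out <- tibble(
    chrom = per_site$chrom, pos = per_site$pos,
    pass = is.na(reason), reason = reason
  )
  left_join(key, out, by = c("chrom", "pos")) |>
    arrange(.data$chrom, .data$pos)
}

balance_pass <- function(a1, a2, ad_ref, ad_alt, balance_range) {
  het <- !is.na(a1) & !is.na(a2) & a1 != a2
  ok <- rep(TRUE, length(a1))
  tot <- ad_ref + ad_alt
  bad <- het & (is.na(tot) | tot == 0)
  frac <- ifelse(het & !bad, ad_alt / tot, NA_real_)
  ok[bad] <- FALSE
  in_range <- frac >= balance_range[1] & frac <= balance_range[2]
  ok[het & !bad & !in_range] <- FALSE
  ok
}

# Per-site Mendelian consistency over every parent-child link in the
# pedigree. With both parents genotyped the child's two alleles must be
# assignable one to each parent; with a single genotyped parent the check
# degrades to parent-child allele sharing.
mendelian_site_check <- function(s, ped, wide = NULL) {
  wide <- wide %||% site_allele_matrix(s)
  children <- ped$id[ped$father != "0" | ped$mother != "0"]
  ok <- rep(TRUE, nrow(wide$key))
  for (ch in children) {
    if (!ch %in% wide$samples) next
    pr <- ped_parents(ped, ch)
    c1 <- wide$a1[, ch]; c2 <- wide$a2[, ch]
    has_f <- !is.na(pr$father) && pr$father %in% wide$samples
    has_m <- !is.na(pr$mother) && pr$mother %in% wide$samples
    f1 <- if (has_f) wide$a1[, pr$father] else NULL
    f2 <- if (has_f) wide$a2[, pr$father] else NULL
    m1 <- if (has_m) wide$a1[, pr$mother] else NULL
    m2 <- if (has_m) wide$a2[, pr$mother] else NULL
    res <- if (has_f && has_m) {
      from_f1 <- c1 == f1 | c1 == f2
      from_f2 <- c2 == f1 | c2 == f2
      from_m1 <- c1 == m1 | c1 == m2
      from_m2 <- c2 == m1 | c2 == m2
      (from_f1 & from_m2) | (from_f2 & from_m1)
    } else if (has_f) {
      c1 == f1 | c1 == f2 | c2 == f1 | c2 == f2
    } else if (has_m) {
      c1 == m1 | c1 == m2 | c2 == m1 | c2 == m2
    } else {
      rep(TRUE, length(c1))
    }
    res[is.na(res)] <- TRUE # missing genotypes are handled by the missing check
    ok <- ok & res
  }
  tibble(chrom = wide$key$chrom, pos = wide$key$pos, mendel_ok = ok)
}

# Long variant_sites -> list(key, samples, a1 matrix, a2 matrix, ad matrices)
site_allele_matrix <- function(s) {
  key <- distinct(s[, c("chrom", "pos")]) |> arrange(.data$chrom, .data$pos)
  samples <- sort(unique(s$sample))
  idx_site <- match(
    paste(s$chrom, s$pos, sep = ":"),
    paste(key$chrom, key$pos, sep = ":")
  )
  idx_sample <- match(s$sample, samples)
  shape <- function(v, default = NA_real_) {
    m <- matrix(default, nrow(key), length(samples),
      dimnames = list(NULL, samples)
    )
    m[cbind(idx_site, idx_sample)] <- v
    m
  }
  list(
    key = key, samples = samples,
    idx_site = idx_site, idx_sample = idx_sample,
    a1 = shape(s$a1), a2 = shape(s$a2),
    ad_ref = shape(s$ad_ref), ad_alt = shape(s$ad_alt)
  )
}

# Shape an arbitrary per-row vector of `s` into the site x sample layout.
with_shape <- function(wide, s, v) {
  m <- matrix(NA_real_, nrow(wide$key), length(wide$samples),
    dimnames = list(NULL, wide$samples)
  )
  m[cbind(wide$idx_site, wide$idx_sample)] <- v
  m
}

# Row-wise minimum keeping NA (an uncalled value must not pass a threshold).
row_min <- function(m) {
  if (ncol(m) == 0) {
    return(rep(NA_real_, nrow(m)))
  }
  do.call(pmin, c(lapply(seq_len(ncol(m)), function(j) m[, j]), na.rm = FALSE))
}

#' Keep only sites passing the IBD quality filters
#'
#' Convenience wrapper around [site_passes_filters()] that subsets the long
#' site table to passing sites. The operation is a pure subset and therefore
#' idempotent.
#'
#' @inheritParams site_passes_filters
#' @return The filtered `variant_sites` tibble.
#' @export
filter_sites <- function(sites, ped, dp_min = 15, gq_min = 31,
                         balance_range = c(0.25, 0.75)) {
  status <- site_passes_filters(sites, ped, dp_min, gq_min, balance_range)
  keep <- status[status$pass, c("chrom", "pos")]
  out <- dplyr::semi_join(sites, keep, by = c("chrom", "pos"))
  class(out) <- unique(c("variant_sites", class(out)))
  out
}

# Resolve, for both members of a sib pair at each site, which allele value
# was transmitted by the father and which by the mother. Enumerates the <= 4
# (paternal, maternal) assignments compatible with all four genotypes; a
# transmission is resolved when all compatible assignments agree on the
# transmitted value. Returns a list of per-site vectors.
resolve_pair_transmissions <- function(sites, pair, ped, ad_tiebreak = FALSE) {
  if (length(pair) != 2) abort("`pair` must name exactly two individuals.")
  pr1 <- ped_parents(ped, pair[1])
  pr2 <- ped_parents(ped, pair[2])
  if (!identical(pr1, pr2) || is.na(pr1$father) || is.na(pr1$mother)) {
    abort("`pair` must be full siblings with both parents in the pedigree.")
  }
  father <- pr1$father
  mother <- pr1$mother
  wide <- site_allele_matrix(
    sites[sites$sample %in% c(pair, father, mother), ]
  )
  need <- c(pair, father, mother)
  if (!all(need %in% wide$samples)) {
    abort(sprintf(
      "No genotype rows for: %s.",
      paste(setdiff(need, wide$samples), collapse = ", ")
    ))
  }
  f1 <- wide$a1[, father]; f2 <- wide$a2[, father]
  m1 <- wide$a1[, mother]; m2 <- wide$a2[, mother]

  resolve_child <- function(id) {
    c1 <- wide$a1[, id]; c2 <- wide$a2[, id]
    pat_cand <- cbind(f1, f1, f2, f2)
    mat_cand <- cbind(m1, m2, m1, m2)
    ok <- (pat_cand == c1 & mat_cand == c2) | (pat_cand == c2 & mat_cand == c1)
    ok[is.na(ok)] <- FALSE
    any_ok <- rowSums(ok) > 0
    stat <- function(cand, f) {
      v <- cand
      v[!ok] <- NA
      cols <- lapply(seq_len(ncol(v)), function(j) v[, j])
      do.call(f, c(cols, na.rm = TRUE))
    }
    pat_min <- stat(pat_cand, pmin); pat_max <- stat(pat_cand, pmax)
    mat_min <- stat(mat_cand, pmin); mat_max <- stat(mat_cand, pmax)
    pat <- ifelse(any_ok & pat_min == pat_max, pat_min, NA_real_)
    mat <- ifelse(any_ok & mat_min == mat_max, mat_min, NA_real_)
    if (ad_tiebreak) {
      # heuristic: for an unresolved heterozygous call, take the allele with
      # the higher read support as the paternally transmitted one
      het <- !is.na(c1) & !is.na(c2) & c1 != c2
      unres <- any_ok & is.na(pat) & het
      adr <- wide$ad_ref[, id]; ada <- wide$ad_alt[, id]
      pick <- ifelse(ada > adr, pmax(c1, c2), pmin(c1, c2))
      pat[unres & !is.na(adr) & !is.na(ada) & adr != ada] <-
        pick[unres & !is.na(adr) & !is.na(ada) & adr != ada]
      mat[unres] <- ifelse(pat[unres] == c1[unres], c2[unres], c1[unres])
    }
    list(pat = pat, mat = mat)
  }
  r1 <- resolve_child(pair[1])
  r2 <- resolve_child(pair[2])
  list(
    key = wide$key,
    father_het = !is.na(f1) & !is.na(f2) & f1 != f2,
    mother_het = !is.na(m1) & !is.na(m2) & m1 != m2,
    s1 = r1, s2 = r2
  )
}

#' Informative sites for a sibling pair
#'
#' A site is informative for a pair when at least one parent is heterozygous
#' and the transmitted allele of every pair member is uniquely resolvable
#' from the four genotypes. Double-heterozygous configurations in which a
#' sib's phase cannot be resolved (e.g. all four individuals heterozygous)
#' are ambiguous and dropped, unless allele-depth tie-breaking is enabled.
#' Sites with a missing genotype for any pair member are excluded.
#'
#' @param sites A filtered `variant_sites` tibble (see [filter_sites()]).
#' @param pair Character vector of two sibling ids.
#' @param ped A [pedigree()] containing the pair and both parents.
#' @param ad_tiebreak Resolve otherwise-ambiguous heterozygous transmissions
#'   by taking the allele with the higher allele depth as better supported
#'   (heuristic; default off).
#'
#' @return The subset of `sites` at informative positions.
#' @export
informative_sites <- function(sites, pair, ped, ad_tiebreak = FALSE) {
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped)
  res <- resolve_pair_transmissions(sites, pair, ped, ad_tiebreak)
  informative <- (res$father_het | res$mother_het) &
    !is.na(res$s1$pat) & !is.na(res$s1$mat) &
    !is.na(res$s2$pat) & !is.na(res$s2$mat)
  keep <- res$key[informative, ]
  out <- dplyr::semi_join(sites, keep, by = c("chrom", "pos"))
  class(out) <- unique(c("variant_sites", class(out)))
  out
}

#' Per-site IBD state for a sibling pair
#'
#' Compares the resolved parental transmissions of the two sibs at each site.
#' A parental transmission is shared when both sibs received the same allele
#' from a heterozygous parent (a homozygous parent's two homologs are
#' indistinguishable, so its transmission is unknown at that site). The
#' combined state is called only when both parental transmissions are known:
#' `IBD2` when both are shared, `IBD1` when exactly one is, `IBD0` when
#' neither; otherwise the site is `ambiguous`. Restricting state calls to
#' fully resolved sites keeps the per-site state piecewise constant along the
#' chromosome, which is what the segment builder assumes.
#'
#' @inheritParams informative_sites
#' @return A tibble with columns `chrom`, `pos`, `pat_share`, `mat_share`
#'   (logical, `NA` when unknown) and `state` in
#'   `{"IBD0","IBD1","IBD2","ambiguous"}`.
#' @export
pairwise_ibd_states <- function(sites, pair, ped, ad_tiebreak = FALSE) {
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped)
  res <- resolve_pair_transmissions(sites, pair, ped, ad_tiebreak)
  pat_known <- res$father_het & !is.na(res$s1$pat) & !is.na(res$s2$pat)
  mat_known <- res$mother_het & !is.na(res$s1$mat) & !is.na(res$s2$mat)
  pat_share <- ifelse(pat_known, res$s1$pat == res$s2$pat, NA)
  mat_share <- ifelse(mat_known, res$s1$mat == res$s2$mat, NA)
  n_known <- pat_known + mat_known
  n_shared <- ifelse(pat_known & pat_share, 1L, 0L) +
    ifelse(mat_known & mat_share, 1L, 0L)
  state <- ifelse(n_known == 2L, paste0("IBD", n_shared), "ambiguous")
  tibble(
    chrom = res$key$chrom, pos = res$key$pos,
    pat_share = unname(as.logical(pat_share)),
    mat_share = unname(as.logical(mat_share)),
    state = unname(state)
  )
}

#' Build IBD segments from per-site states
#'
#' Collapses coordinate-sorted per-site IBD states into maximal runs of a
#' constant `IBD1` or `IBD2` state. Ambiguous sites neither support nor close
#' a run; `IBD0` sites and state changes close it, as does a gap larger than
#' `max_gap_bp` between consecutive supporting sites. Runs supported by fewer
#' than `min_sites` sites are discarded. Segment coordinates span the first
#' to the last supporting site (1-based inclusive).
#'
#' @param states A tibble from [pairwise_ibd_states()].
#' @param min_sites Minimum supporting sites per reported segment.
#' @param max_gap_bp Maximum bp gap between consecutive supporting sites.
#'
#' @return A tibble with columns `chrom`, `start_bp`, `end_bp`, `state`,
#'   `n_supporting_sites`, non-overlapping and coordinate-sorted.
#' @export
segments_from_states <- function(states, min_sites = 5, max_gap_bp = 1e6) {
  stop_if_not_df(states, "states")
  require_columns(states, c("chrom", "pos", "state"), "states")
  st <- states |>
    filter(.data$state != "ambiguous") |>
    arrange(.data$chrom, .data$pos)
  if (nrow(st) == 0) {
    return(tibble(
      chrom = character(), start_bp = numeric(), end_bp = numeric(),
      state = character(), n_supporting_sites = integer()
    ))
  }
  st <- st |>
    group_by(.data$chrom) |>
    mutate(
      new_run = dplyr::row_number() == 1L |
        .data$state != dplyr::lag(.data$state) |
        .data$pos - dplyr::lag(.data$pos) > max_gap_bp
    ) |>
    ungroup() |>
    mutate(run = cumsum(.data$new_run)) |>
    filter(.data$state %in% c("IBD1", "IBD2"))
  if (nrow(st) == 0) {
    return(tibble(
      chrom = character(), start_bp = numeric(), end_bp = numeric(),
      state = character(), n_supporting_sites = integer()
    ))
  }
  st |>
    group_by(.data$chrom, .data$run, .data$state) |>
    summarise(
      start_bp = min(.data$pos), end_bp = max(.data$pos),
      n_supporting_sites = dplyr::n(), .groups = "drop"
    ) |>
    filter(.data$n_supporting_sites >= min_sites) |>
    select("chrom", "start_bp", "end_bp", "state", "n_supporting_sites") |>
    arrange(.data$chrom, .data$start_bp)
}

# Segments of a single parental share track: sites with a known share
# status for that parent; shared sites support a run, non-shared sites close
# it. Reuses the generic run collapser by relabelling shared/non-shared as
# IBD1/IBD0.
parent_track_segments <- function(states, share_col, min_sites, max_gap_bp) {
  share <- states[[share_col]]
  known <- !is.na(share)
  track <- tibble(
    chrom = states$chrom[known], pos = states$pos[known],
    state = ifelse(share[known], "IBD1", "IBD0")
  )
  segments_from_states(track, min_sites, max_gap_bp)
}

# Combine the paternal and maternal share-track segments into IBD1/IBD2
# intervals: decompose into elementary intervals at all segment boundaries,
# count covering tracks (1 -> IBD1, 2 -> IBD2), and merge adjacent
# equal-state pieces per chromosome.
combine_track_segments <- function(pat_segs, mat_segs, states) {
  segs <- bind_rows(
    mutate(pat_segs, track = "pat"), mutate(mat_segs, track = "mat")
  )
  if (nrow(segs) == 0) {
    return(tibble(
      chrom = character(), start_bp = numeric(), end_bp = numeric(),
      state = character(), n_supporting_sites = integer()
    ))
  }
  out <- list()
  for (ch in unique(segs$chrom)) {
    s <- segs[segs$chrom == ch, ]
    bounds <- sort(unique(c(s$start_bp, s$end_bp + 1)))
    lo <- head(bounds, -1)
    hi <- tail(bounds, -1) - 1
    cover <- vapply(seq_along(lo), function(i) {
      sum(s$start_bp <= lo[i] & s$end_bp >= hi[i])
    }, integer(1))
    keep <- cover >= 1
    if (!any(keep)) next
    piece <- tibble(lo = lo[keep], hi = hi[keep], state = paste0("IBD", pmin(cover[keep], 2L)))
    # merge touching pieces with equal state
    run <- cumsum(c(
      TRUE,
      piece$state[-1] != piece$state[-nrow(piece)] |
        piece$lo[-1] != piece$hi[-nrow(piece)] + 1
    ))
    pos_ch <- states$pos[states$chrom == ch &
      (!is.na(states$pat_share) | !is.na(states$mat_share))]
    merged <- piece |>
      mutate(run = run) |>
      group_by(.data$run, .data$state) |>
      summarise(start_bp = min(.data$lo), end_bp = max(.data$hi), .groups = "drop") |>
      mutate(
        chrom = ch,
        n_supporting_sites = vapply(seq_along(.data$start_bp), function(i) {
          sum(pos_ch >= .data$start_bp[i] & pos_ch <= .data$end_bp[i])
        }, integer(1))
      )
    out[[ch]] <- merged
  }
  bind_rows(out) |>
    select("chrom", "start_bp", "end_bp", "state", "n_supporting_sites") |>
    arrange(.data$chrom, .data$start_bp)
}

#' Detect IBD segments for a sibling pair from a multi-sample VCF table
#'
#' End-to-end wrapper: applies the site quality filters, restricts to
#' informative sites for the pair, resolves the per-site parental share
#' status and collapses it into segments. Because a biallelic site can
#' demonstrate one specific shared *and* one specific unshared transmission
#' only in degenerate configurations, segmentation works on the two parental
#' share tracks separately — each track's shared sites support a run and its
#' unshared sites close one ([segments_from_states] does the collapsing) —
#' and the two tracks are then combined into intervals labelled `IBD1`
#' (one track covers) or `IBD2` (both cover).
#'
#' @inheritParams site_passes_filters
#' @inheritParams informative_sites
#' @inheritParams segments_from_states
#' @return An object of class `ibd_scan`, a list with elements `segments`,
#'   `states`, `filter_status`, `pair` and `params`. Use [tidy()] for the
#'   segment table, [glance()] for a one-row summary and [autoplot()] for a
#'   segment track.
#' @export
ibd_segments <- function(sites, ped, pair, dp_min = 15, gq_min = 31,
                         balance_range = c(0.25, 0.75), min_sites = 5,
                         max_gap_bp = 1e6, ad_tiebreak = FALSE) {
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped)
  status <- site_passes_filters(sites, ped, dp_min, gq_min, balance_range)
  passed <- dplyr::semi_join(
    sites, status[status$pass, c("chrom", "pos")],
    by = c("chrom", "pos")
  )
  inf <- informative_sites(passed, pair, ped, ad_tiebreak)
  states <- pairwise_ibd_states(inf, pair, ped, ad_tiebreak)
  pat_segs <- parent_track_segments(states, "pat_share", min_sites, max_gap_bp)
  mat_segs <- parent_track_segments(states, "mat_share", min_sites, max_gap_bp)
  segments <- combine_track_segments(pat_segs, mat_segs, states)
  structure(
    list(
      segments = segments, states = states, filter_status = status,
      pair = pair,
      params = list(
        dp_min = dp_min, gq_min = gq_min, balance_range = balance_range,
        min_sites = min_sites, max_gap_bp = max_gap_bp,
        ad_tiebreak = ad_tiebreak
      )
    ),
    class = "ibd_scan"
  )
}

#' @method tidy ibd_scan
#' @export
tidy.ibd_scan <- function(x, ...) {
  mutate(x$segments, pair = paste(x$pair, collapse = "-"), .before = 1)
}

#' @method glance ibd_scan
#' @export
glance.ibd_scan <- function(x, ...) {
  tibble(
    pair = paste(x$pair, collapse = "-"),
    n_sites = nrow(x$filter_status),
    n_pass = sum(x$filter_status$pass),
    n_state_calls = sum(x$states$state != "ambiguous"),
    n_segments = nrow(x$segments),
    ibd_length_bp = sum(x$segments$end_bp - x$segments$start_bp + 1)
  )
}

#' @export
print.ibd_scan <- function(x, ...) {
  cat(sprintf(
    "IBD scan for pair %s: %d segment(s) from %d state call(s)\n",
    paste(x$pair, collapse = "-"), nrow(x$segments),
    sum(x$states$state != "ambiguous")
  ))
  print(x$segments)
  invisible(x)
}

#' @method autoplot ibd_scan
#' @export
autoplot.ibd_scan <- function(object, ...) {
  seg <- object$segments
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$start_bp / 1e6, xend = .data$end_bp / 1e6,
        y = .data$state, yend = .data$state, colour = .data$state
      ),
      linewidth = 4
    ) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(
      x = "Position (Mb)", y = NULL,
      title = sprintf("IBD segments, pair %s", paste(object$pair, collapse = "-"))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Write IBD segments as a BED-like TSV
#'
#' Internally segments are 1-based inclusive; on disk they are written
#' 0-based half-open (`start0 = start_bp - 1`, `end = end_bp`), BED style,
#' with columns `chrom start0 end pair state n_sites`.
#'
#' @param x An `ibd_scan` object or a segment tibble with a `pair` column
#'   (as returned by [tidy()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ibd_bed <- function(x, path) {
  seg <- if (inherits(x, "ibd_scan")) tidy(x) else x
  require_columns(seg, c("chrom", "start_bp", "end_bp", "pair", "state", "n_supporting_sites"), "x")
  out <- tibble(
    chrom = seg$chrom, start0 = as.integer(seg$start_bp - 1),
    end = as.integer(seg$end_bp), pair = seg$pair, state = seg$state,
    n_sites = seg$n_supporting_sites
  )
  readr::write_tsv(out, path)
  invisible(path)
}
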