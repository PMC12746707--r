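#' Validate a genetic map table
#'
#' A genetic map is a table of anchors relating physical position (bp) to
#' cumulative genetic position (cM) per chromosome; genetic positions between
#' anchors are obtained by linear interpolation. Within each chromosome the
#' anchors must be strictly increasing in bp, non-decreasing in cM, and at
#' least two anchors are required for interpolation.
#'
#' @param map A data frame with columns `chrom`, `bp`, `cM`.
#'
#' @return A tibble of class `genetic_map`, sorted by chromosome and bp.
#' @examples
#' genetic_map(data.frame(
#'   chrom = "chr3", bp = c(1, 1000001, 2000001), cM = c(0, 1, 2)
#' ))
#' @export
genetic_map <- function(map) {
  stop_if_not_df(map, "map")
  require_columns(map, c("chrom", "bp", "cM"), "map")
  map <- as_tibble(map) |>
    mutate(
      chrom = as.character(.data$chrom),
      bp = as.numeric(.data$bp),
      cM = as.numeric(.data$cM)
    ) |>
    arrange(.data$chrom, .data$bp)
  if (anyNA(map$bp) || anyNA(map$cM) || anyNA(map$chrom)) {
    abort("Genetic map contains missing values.")
  }
  if (any(map$bp < 1)) abort("Genetic map bp positions must be >= 1.")
  if (any(map$cM < 0)) abort("Genetic map cM positions must be >= 0.")
  check <- map |>
    group_by(.data$chrom) |>
    summarise(
      n = dplyr::n(),
      dup_bp = anyDuplicated(.data$bp) > 0,
      bad_cm = any(diff(.data$cM) < 0),
      bad_rows = paste(
        which(c(FALSE, diff(.data$cM) < 0)), collapse = ","
      ),
      .groups = "drop"
    )
  if (any(check$n < 2)) {
    abort(sprintf(
      "Chromosome(s) with fewer than 2 anchors: %s.",
      paste(check$chrom[check$n < 2], collapse = ", ")
    ))
  }
  if (any(check$dup_bp)) {
    abort(sprintf(
      "Duplicate bp anchors on chromosome(s): %s.",
      paste(check$chrom[check$dup_bp], collapse = ", ")
    ))
  }
  if (any(check$bad_cm)) {
    bad <- check[check$bad_cm, ]
    abort(sprintf(
      "Non-monotone cM values within chromosome(s): %s (offending sorted row index within chromosome: %s).",
      paste(bad$chrom, collapse = ", "), paste(bad$bad_rows, collapse = "; ")
    ))
  }
  class(map) <- c("genetic_map", class(map))
  map
}

#' Read a genetic map from a TSV file
#'
#' Expects a tab-separated table with header columns `chrom`, `bp`, `cM`
#' (cumulative genetic position, not a recombination rate). Rows may be in any
#' order; they are sorted and validated.
#'
#' @param path Path to the TSV file.
#' @return A [genetic_map()] tibble.
#' @export
read_genetic_map <- function(path) {
  map <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  genetic_map(map)
}

#' Interpolate genetic position at physical coordinates
#'
#' Linear interpolation between the flanking map anchors; a bp exactly at an
#' anchor returns that anchor's cM. Positions outside the anchored range are
#' clamped to the terminal anchor's cM with a warning (linear extrapolation
#' can produce negative or absurd genetic positions).
#'
#' @param map A [genetic_map()].
#' @param chrom Chromosome name(s); recycled against `bp`.
#' @param bp Physical position(s), 1-based.
#'
#' @return Numeric vector of genetic positions (cM).
#' @examples
#' m <- genetic_map(data.frame(
#'   chrom = "chr3", bp = c(1, 1000001, 2000001), cM = c(0, 1, 2)
#' ))
#' interpolate_cm(m, "chr3", c(500001, 1000001, 1250001))
#' @export
interpolate_cm <- function(map, chrom, bp) {
  if (!inherits(map, "genetic_map")) map <- genetic_map(map)
  n <- max(length(chrom), length(bp))
  chrom <- rep_len(as.character(chrom), n)
  bp <- rep_len(as.numeric(bp), n)
  missing_chrom <- setdiff(unique(chrom), unique(map$chrom))
  if (length(missing_chrom)) {
    abort(sprintf(
      "Chromosome(s) not present in the map: %s.",
      paste(missing_chrom, collapse = ", ")
    ))
  }
  out <- numeric(n)
  clamped <- FALSE
  for (ch in unique(chrom)) {
    idx <- chrom == ch
    anchors <- map[map$chrom == ch, ]
    x <- bp[idx]
    if (any(x < min(anchors$bp) | x > max(anchors$bp))) clamped <- TRUE
    # rule = 2: clamp to terminal anchor values outside the range
    out[idx] <- approx(anchors$bp, anchors$cM, xout = x, rule = 2)$y
  }
  if (clamped) {
    warn("Some positions fall outside the map anchors; clamped to terminal anchor cM.")
  }
  out
}

#' Validate a locus table
#'
#' Loci are 1-based inclusive bp intervals (`chr3:185,190,624-185,281,990`
#' style) with a name and chromosome.
#'
#' @param loci Data frame with columns `name`, `chrom`, `start`, `end`.
#' @return A validated tibble.
#' @export
loci_table <- function(loci) {
  stop_if_not_df(loci, "loci")
  require_columns(loci, c("name", "chrom", "start", "end"), "loci")
  loci <- as_tibble(loci) |>
    mutate(
      name = as.character(.data$name), chrom = as.character(.data$chrom),
      start = as.numeric(.data$start), end = as.numeric(.data$end)
    )
  if (any(loci$start > loci$end)) {
    abort("Locus start must not exceed end (coordinates are 1-based inclusive).")
  }
  if (any(loci$start < 1)) abort("Locus coordinates must be >= 1.")
  loci
}

#' Read a locus table from a TSV file
#'
#' @param path Path to a TSV with header columns `name`, `chrom`, `start`, `end`.
#' @return A validated tibble of loci.
#' @export
read_loci <- function(path) {
  loci_table(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' Genetic position of loci
#'
#' Appends a `cM` column giving the genetic position of each locus
#' representative point. Genetic maps report a single cM value per gene; the
#' representative point used here is the interval midpoint.
#'
#' @param loci A locus table (see [loci_table()]).
#' @param map A [genetic_map()].
#' @return `loci` with an appended `cM` column.
#' @export
locus_cm_position <- function(loci, map) {
  loci <- loci_table(loci)
  mid <- (loci$start + loci$end) / 2
  loci$cM <- interpolate_cm(map, loci$chrom, mid)
  loci
}

#' Plot a genetic map
#'
#' Anchors and the interpolated bp-to-cM relationship, one panel per
#' chromosome.
#'
#' @param map A [genetic_map()].
#' @return A ggplot object.
#' @export
plot_genetic_map <- function(map) {
  if (!inherits(map, "genetic_map")) map <- genetic_map(map)
  ggplot2::ggplot(map, ggplot2::aes(x = .data$bp / 1e6, y = .data$cM)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::facet_wrap(~chrom, scales = "free") +
    ggplot2::labs(x = "Physical position (Mb)", y = "Genetic position (cM)") +
    ggplot2::theme_minimal()
}
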