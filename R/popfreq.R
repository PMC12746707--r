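#' Allele frequency from allele counts
#'
#' Exact ratio of allele count (AC) to allele number (AN). Frequencies are
#' conventionally reported to three significant figures in scientific
#' notation; see [format_af()].
#'
#' @param ac Allele count(s), integers with `0 <= ac <= an`.
#' @param an Allele number(s) (total called chromosomes), integers > 0.
#' @return Numeric allele frequency AC/AN.
#' @examples
#' allele_frequency(68, 1607608) # 4.23e-05
#' @export
allele_frequency <- function(ac, an) {
  if (any(an <= 0)) abort("`an` must be positive: AF is undefined for AN = 0.")
  if (any(ac < 0) || any(ac > an)) abort("`ac` must satisfy 0 <= AC <= AN.")
  ac / an
}

#' Format an allele frequency to three significant figures
#'
#' @param af Numeric allele frequencies.
#' @param digits Significant figures (default 3).
#' @return Character vector in scientific notation, e.g. `"4.23e-05"`.
#' @export
format_af <- function(af, digits = 3) {
  format_sigfig(af, digits)
}

#' ACMG/AMP frequency tier
#'
#' Assigns the conventional population-frequency tiers: very rare
#' (AF < 1e-4), rare (1e-4 <= AF <= 1e-3) and common (AF > 1e-3). The
#' published interval descriptions overlap at exactly 1e-4 and 1e-3; the
#' boundaries are assigned to the middle ("rare") tier.
#'
#' @param af Numeric allele frequencies in `[0, 1]`.
#' @return Factor with levels `very rare`, `rare`, `common`.
#' @examples
#' frequency_tier(c(4.23e-5, 2.49e-4, 5e-3))
#' @export
frequency_tier <- function(af) {
  if (any(is.na(af)) || any(af < 0) || any(af > 1)) {
    abort("`af` must lie in [0, 1].")
  }
  tier <- ifelse(af < 1e-4, "very rare", ifelse(af <= 1e-3, "rare", "common"))
  factor(tier, levels = c("very rare", "rare", "common"))
}

#' Validate population frequency records
#'
#' One row per variant and population with allele count `AC`, allele number
#' `AN` and homozygote count `nhomalt`. Computes `af`.
#'
#' @param records Data frame with columns `variant`, `population`, `AC`,
#'   `AN`, `nhomalt`.
#' @return A validated tibble with an appended `af` column.
#' @export
popfreq_records <- function(records) {
  stop_if_not_df(records, "records")
  require_columns(records, c("variant", "population", "AC", "AN", "nhomalt"), "records")
  records <- as_tibble(records)
  if (any(records$AN <= 0)) abort("AN must be positive.")
  if (any(records$AC < 0 | records$AC > records$AN)) {
    abort("AC must satisfy 0 <= AC <= AN.")
  }
  if (any(records$nhomalt < 0 | records$nhomalt > floor(records$AC / 2))) {
    abort("Homozygote count must satisfy 0 <= nhomalt <= floor(AC / 2).")
  }
  records$af <- allele_frequency(records$AC, records$AN)
  records
}

#' Read population frequency records from a TSV file
#'
#' @param path TSV with header columns `variant`, `population`, `AC`, `AN`,
#'   `nhomalt`.
#' @return A validated tibble (see [popfreq_records()]).
#' @export
read_popfreq <- function(path) {
  popfreq_records(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' Absence of homozygotes across populations
#'
#' `TRUE` for a variant iff the homozygote count is zero in every population
#' record — the pattern expected under strong negative selection or embryonic
#' lethality of the homozygous state.
#'
#' @param records Population frequency records (see [popfreq_records()]).
#' @return A tibble `variant`, `zero_homozygotes`.
#' @export
zero_homozygote_flag <- function(records) {
  records <- popfreq_records(records)
  if (nrow(records) == 0) {
    abort("No records: the homozygote summary is undefined for an empty set.")
  }
  records |>
    group_by(.data$variant) |>
    summarise(zero_homozygotes = all(.data$nhomalt == 0), .groups = "drop")
}

#' Summarise population frequencies for classification
#'
#' Per variant and population: AF, its three-significant-figure report
#' string, the frequency tier, and the variant-level zero-homozygote flag.
#'
#' @param records Population frequency records (see [popfreq_records()]).
#' @return A tibble, one row per input record.
#' @export
popfreq_summary <- function(records) {
  records <- popfreq_records(records)
  flags <- zero_homozygote_flag(records)
  records |>
    mutate(
      af_formatted = format_af(.data$af),
      tier = frequency_tier(.data$af)
    ) |>
    left_join(flags, by = "variant")
}
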