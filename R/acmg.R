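# Pathogenic-side combining rules from the standard ACMG/AMP framework
# (Richards et al. 2015), encoded as predicate functions over the counts of
# very strong (PVS), strong (PS), moderate (PM) and supporting (PP) criteria.

acmg_strength <- function(codes) {
  strength <- dplyr::case_when(
    grepl("^PVS", codes) ~ "PVS",
    grepl("^PS", codes) ~ "PS",
    grepl("^PM", codes) ~ "PM",
    grepl("^PP", codes) ~ "PP",
    TRUE ~ NA_character_
  )
  if (anyNA(strength)) {
    abort(sprintf(
      "Unknown ACMG criterion code prefix: %s. Pathogenic-side codes (PVS/PS/PM/PP) only.",
      paste(codes[is.na(strength)], collapse = ", ")
    ))
  }
  strength
}

is_pathogenic <- function(nvs, ns, nm, np) {
  (nvs >= 1 && (ns >= 1 || nm >= 2 || (nm == 1 && np == 1) || np >= 2)) ||
    nvs >= 2 ||
    ns >= 2 ||
    (ns == 1 && (nm >= 3 || (nm == 2 && np >= 2) || (nm == 1 && np >= 4)))
}

is_likely_pathogenic <- function(nvs, ns, nm, np) {
  (nvs >= 1 && nm >= 1) ||
    (ns == 1 && nm >= 1) ||
    (ns == 1 && np >= 2) ||
    nm >= 3 ||
    (nm == 2 && np >= 2) ||
    (nm == 1 && np >= 4)
}

#' Combine ACMG/AMP evidence into a classification
#'
#' Applies the standard ACMG/AMP combining rules for the pathogenic side of
#' the framework. Evidence codes carry their strength in the prefix: `PVS`
#' (very strong), `PS` (strong), `PM` (moderate), `PP` (supporting).
#' Evidence not reaching Likely Pathogenic yields VUS; benign-side codes are
#' out of scope and rejected. Adding a criterion can never weaken the
#' classification.
#'
#' @param evidence Character vector of criterion codes (e.g.
#'   `c("PM1", "PM2", "PP2", "PP3")`) or a single comma-separated string.
#'   Duplicated codes are counted once.
#' @return A single character value: `"Pathogenic"`, `"Likely Pathogenic"`
#'   or `"VUS"`.
#' @examples
#' acmg_combine(c("PM1", "PM2", "PP2", "PP3")) # Likely Pathogenic
#' acmg_combine("PM2,PP2,PP3")                 # VUS
#' @export
acmg_combine <- function(evidence) {
  if (length(evidence) == 1 && grepl(",", evidence)) {
    evidence <- strsplit(evidence, ",", fixed = TRUE)[[1]]
  }
  evidence <- unique(trimws(evidence))
  evidence <- evidence[nzchar(evidence)]
  if (length(evidence) == 0) {
    return("VUS")
  }
  strength <- acmg_strength(evidence)
  nvs <- sum(strength == "PVS")
  ns <- sum(strength == "PS")
  nm <- sum(strength == "PM")
  np <- sum(strength == "PP")
  if (is_pathogenic(nvs, ns, nm, np)) {
    "Pathogenic"
  } else if (is_likely_pathogenic(nvs, ns, nm, np)) {
    "Likely Pathogenic"
  } else {
    "VUS"
  }
}

#' Classify variants from frequency records and ACMG evidence
#'
#' Convenience wrapper joining [popfreq_summary()] with [acmg_combine()]:
#' one row per variant with the overall tier (from the supplied overall
#' population record), the zero-homozygote flag and the combined
#' classification.
#'
#' @param records Population frequency records (see [popfreq_records()]).
#' @param evidence Named list (by variant) of criterion-code vectors, or a
#'   tibble with columns `variant`, `criteria` (comma-separated string).
#' @param overall_population Label of the record to report the headline AF
#'   from (default `"overall"`).
#' @return A tibble, one row per variant: `variant`, `af`, `af_formatted`,
#'   `tier`, `zero_homozygotes`, `criteria`, `classification`.
#' @export
classify_variants <- function(records, evidence,
                              overall_population = "overall") {
  summ <- popfreq_summary(records)
  if (is.data.frame(evidence)) {
    require_columns(evidence, c("variant", "criteria"), "evidence")
    evidence <- setNames(
      strsplit(evidence$criteria, ",", fixed = TRUE), evidence$variant
    )
  }
  head_rows <- summ[summ$population == overall_population, ]
  if (nrow(head_rows) == 0) {
    abort(sprintf("No records for population '%s'.", overall_population))
  }
  head_rows |>
    mutate(
      criteria = vapply(
        .data$variant,
        function(v) paste(evidence[[v]] %||% character(0), collapse = ","),
        character(1), USE.NAMES = FALSE
      ),
      classification = vapply(
        .data$variant,
        function(v) acmg_combine(evidence[[v]] %||% character(0)),
        character(1), USE.NAMES = FALSE
      )
    ) |>
    select(
      "variant", "af", "af_formatted", "tier", "zero_homozygotes",
      "criteria", "classification"
    )
}
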