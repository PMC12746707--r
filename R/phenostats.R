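# Larval phenotype feature vocabulary.
pheno_feature_levels <- list(
  swim_bladder = c("inflated", "partial", "absent"),
  tail_curvature = c("none", "mild_ventral", "mild_dorsal", "severe_bidirectional"),
  jaw = c("normal", "protrusion_or_mild_asymmetry", "severe_malformation")
)
pheno_classes <- c("normal", "medium", "strong")

#' Classify larvae into normal / medium / strong phenotypes
#'
#' Applies the standardized severity rules used to score injected larvae at
#' 5 dpf. Severe features are cardiac edema, severe bidirectional tail
#' malformation, severe jaw malformation, cleft-like facial defects and
#' severe body-axis defects; moderate abnormalities are a non-inflated or
#' partially inflated swim bladder, mild (ventral or dorsal) tail curvature
#' and jaw protrusion or mild asymmetry. A larva is `strong` with two or
#' more severe features, `medium` with one or more moderate abnormalities or
#' exactly one severe feature (a single severe feature is not assigned by
#' the published definitions; it is scored as medium), and `normal`
#' otherwise. Severity is monotone: adding an abnormal feature never moves a
#' larva toward normal.
#'
#' @param records Data frame with one row per larva and columns
#'   `swim_bladder` (`inflated`/`partial`/`absent`), `tail_curvature`
#'   (`none`/`mild_ventral`/`mild_dorsal`/`severe_bidirectional`), `jaw`
#'   (`normal`/`protrusion_or_mild_asymmetry`/`severe_malformation`),
#'   `cardiac_edema`, `cleft_like_defect`, `severe_axis_defect` (logical).
#'   Missing values are an error.
#' @return `records` with an appended `class` factor
#'   (`normal`/`medium`/`strong`).
#' @export
classify_larvae <- function(records) {
  stop_if_not_df(records, "records")
  cols <- c(
    "swim_bladder", "tail_curvature", "jaw",
    "cardiac_edema", "cleft_like_defect", "severe_axis_defect"
  )
  require_columns(records, cols, "records")
  records <- as_tibble(records)
  if (anyNA(records[cols])) {
    abort("Phenotype records contain missing feature flags.")
  }
  for (f in names(pheno_feature_levels)) {
    bad <- !records[[f]] %in% pheno_feature_levels[[f]]
    if (any(bad)) {
      abort(sprintf(
        "Invalid %s value(s): %s.", f,
        paste(unique(records[[f]][bad]), collapse = ", ")
      ))
    }
  }
  n_severe <- (records$tail_curvature == "severe_bidirectional") +
    (records$jaw == "severe_malformation") +
    records$cardiac_edema + records$cleft_like_defect +
    records$severe_axis_defect
  n_moderate <- (records$swim_bladder != "inflated") +
    (records$tail_curvature %in% c("mild_ventral", "mild_dorsal")) +
    (records$jaw == "protrusion_or_mild_asymmetry")
  class <- ifelse(
    n_severe >= 2, "strong",
    ifelse(n_moderate >= 1 | n_severe == 1, "medium", "normal")
  )
  records$class <- factor(class, levels = pheno_classes)
  records
}

#' Tally phenotype classes per experimental group
#'
#' Counts and percentages (half-up, one decimal, matching the printed style)
#' of normal, medium and strong larvae per group, plus the total-abnormal
#' percentage (medium + strong).
#'
#' @param records Either classified records (with `group` and `class`
#'   columns; see [classify_larvae()]) or a per-group count table with
#'   columns `group`, `normal`, `medium`, `strong`.
#' @return A tibble of class `phenotype_tally`: `group`, `n`, `n_normal`,
#'   `n_medium`, `n_strong`, `pct_normal`, `pct_medium`, `pct_strong`,
#'   `pct_abnormal`.
#' @examples
#' tally_phenotypes(data.frame(
#'   group = "COMBO-MT", normal = 100, medium = 39, strong = 13
#' ))
#' @export
tally_phenotypes <- function(records) {
  stop_if_not_df(records, "records")
  if (all(c("normal", "medium", "strong") %in% names(records))) {
    require_columns(records, "group", "records")
    counts <- as_tibble(records) |>
      rename(n_normal = "normal", n_medium = "medium", n_strong = "strong")
  } else {
    require_columns(records, c("group", "class"), "records")
    counts <- as_tibble(records) |>
      group_by(.data$group) |>
      summarise(
        n_normal = sum(.data$class == "normal"),
        n_medium = sum(.data$class == "medium"),
        n_strong = sum(.data$class == "strong"),
        .groups = "drop"
      )
  }
  counts$n <- counts$n_normal + counts$n_medium + counts$n_strong
  if (any(counts$n == 0)) {
    abort(sprintf(
      "Empty group(s): %s.", paste(counts$group[counts$n == 0], collapse = ", ")
    ))
  }
  out <- counts |>
    mutate(
      pct_normal = round_half_up(100 * .data$n_normal / .data$n, 1),
      pct_medium = round_half_up(100 * .data$n_medium / .data$n, 1),
      pct_strong = round_half_up(100 * .data$n_strong / .data$n, 1),
      pct_abnormal = round_half_up(
        100 * (.data$n_medium + .data$n_strong) / .data$n, 1
      )
    ) |>
    select(
      "group", "n", "n_normal", "n_medium", "n_strong",
      "pct_normal", "pct_medium", "pct_strong", "pct_abnormal"
    )
  class(out) <- c("phenotype_tally", class(out))
  out
}

#' @method autoplot phenotype_tally
#' @export
autoplot.phenotype_tally <- function(object, ...) {
  long <- as_tibble(object) |>
    select("group", "pct_normal", "pct_medium", "pct_strong") |>
    tidyr::pivot_longer(
      -"group",
      names_to = "class", names_prefix = "pct_", values_to = "pct"
    ) |>
    mutate(class = factor(.data$class, levels = rev(pheno_classes)))
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$group, y = .data$pct, fill = .data$class)
  ) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(normal = "grey80", medium = "orange", strong = "firebrick")
    ) +
    ggplot2::labs(x = NULL, y = "Larvae (%)", fill = "Phenotype") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Chi-square comparison of two phenotype tallies
#'
#' Pearson chi-square (no continuity correction by default) on the
#' group-by-class contingency table built from two tallies, with
#' `length(categories) - 1` degrees of freedom. With `categories =
#' c("normal", "abnormal")` the medium and strong classes are pooled.
#'
#' @param tally_a,tally_b One-group [tally_phenotypes()] rows.
#' @param categories Category partition: any subset of
#'   `c("normal", "medium", "strong")`, or `c("normal", "abnormal")`.
#' @param correct Apply the Yates continuity correction (2x2 tables only).
#' @return A one-row tibble: `statistic`, `df`, `p_value`,
#'   `low_expected_cells` (annotation when any expected count < 1; the
#'   statistic is still returned).
#' @export
compare_tallies <- function(tally_a, tally_b,
                            categories = c("normal", "medium", "strong"),
                            correct = FALSE) {
  row_counts <- function(t) {
    if (nrow(t) != 1) abort("Each tally must contain exactly one group.")
    if (identical(sort(categories), sort(c("normal", "abnormal")))) {
      c(normal = t$n_normal, abnormal = t$n_medium + t$n_strong)
    } else {
      sel <- paste0("n_", categories)
      setNames(as.numeric(t[1, sel]), categories)
    }
  }
  tab <- rbind(row_counts(tally_a), row_counts(tally_b))
  rownames(tab) <- c(tally_a$group, tally_b$group)
  suppressWarnings(res <- chisq.test(tab, correct = correct))
  tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = unname(res$p.value),
    low_expected_cells = any(res$expected < 1)
  )
}

#' Kruskal-Wallis comparison of ceratohyal angle measurements
#'
#' Rank-based H statistic with tie correction and the chi-square
#' approximation for the p-value, across all groups in the measurement
#' table. Angles must lie in (0, 180) degrees and every group needs at least
#' two measurements.
#'
#' @param measurements Data frame with columns `group`, `angle_deg`.
#' @return A one-row tibble: `statistic` (H), `df`, `p_value`, `n_groups`,
#'   `n_total`.
#' @export
compare_angles <- function(measurements) {
  stop_if_not_df(measurements, "measurements")
  require_columns(measurements, c("group", "angle_deg"), "measurements")
  m <- as_tibble(measurements)
  if (any(is.na(m$angle_deg)) || any(m$angle_deg <= 0) || any(m$angle_deg >= 180)) {
    abort("Angles must lie strictly between 0 and 180 degrees.")
  }
  sizes <- table(m$group)
  if (length(sizes) < 2) abort("At least two groups are required.")
  if (any(sizes < 2)) {
    abort(sprintf(
      "Group(s) with fewer than 2 measurements: %s.",
      paste(names(sizes)[sizes < 2], collapse = ", ")
    ))
  }
  res <- kruskal.test(angle_deg ~ group, data = m)
  tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = unname(res$p.value),
    n_groups = length(sizes),
    n_total = nrow(m)
  )
}
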