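normal_larva <- function(n = 1) {
  tibble::tibble(
    swim_bladder = rep("inflated", n), tail_curvature = "none",
    jaw = "normal", cardiac_edema = FALSE, cleft_like_defect = FALSE,
    severe_axis_defect = FALSE
  )
}

test_that("larvae classify by moderate and severe feature counts", {
  expect_equal(as.character(classify_larvae(normal_larva())$class), "normal")

  partial_sb <- normal_larva()
  partial_sb$swim_bladder <- "partial"
  expect_equal(as.character(classify_larvae(partial_sb)$class), "medium")

  two_severe <- normal_larva()
  two_severe$cardiac_edema <- TRUE
  two_severe$tail_curvature <- "severe_bidirectional"
  expect_equal(as.character(classify_larvae(two_severe)$class), "strong")

  one_severe <- normal_larva()
  one_severe$cleft_like_defect <- TRUE
  expect_equal(as.character(classify_larvae(one_severe)$class), "medium")

  missing <- normal_larva()
  missing$jaw <- NA
  expect_error(classify_larvae(missing), "missing")
  bad <- normal_larva()
  bad$jaw <- "weird"
  expect_error(classify_larvae(bad), "Invalid jaw")
})

test_that("adding an abnormal feature never moves a larva toward normal", {
  rank <- c(normal = 1, medium = 2, strong = 3)
  worsen <- list(
    function(r) {
      r$swim_bladder <- "absent"
      r
    },
    function(r) {
      r$tail_curvature <- "severe_bidirectional"
      r
    },
    function(r) {
      r$jaw <- "protrusion_or_mild_asymmetry"
      r
    },
    function(r) {
      r$cardiac_edema <- TRUE
      r
    },
    function(r) {
      r$severe_axis_defect <- TRUE
      r
    }
  )
  set.seed(3)
  for (i in 1:40) {
    r <- tibble::tibble(
      swim_bladder = sample(c("inflated", "partial", "absent"), 1),
      tail_curvature = sample(
        c("none", "mild_ventral", "mild_dorsal", "severe_bidirectional"), 1
      ),
      jaw = sample(
        c("normal", "protrusion_or_mild_asymmetry", "severe_malformation"), 1
      ),
      cardiac_edema = sample(c(TRUE, FALSE), 1),
      cleft_like_defect = sample(c(TRUE, FALSE), 1),
      severe_axis_defect = sample(c(TRUE, FALSE), 1)
    )
    before <- rank[[as.character(classify_larvae(r)$class)]]
    f <- sample(worsen, 1)[[1]]
    after <- rank[[as.character(classify_larvae(f(r))$class)]]
    expect_gte(after, before)
  }
})

test_that("tallies reproduce printed percentages and recompose to counts", {
  combo <- tally_phenotypes(data.frame(
    group = "COMBO-MT", normal = 100, medium = 39, strong = 13
  ))
  expect_equal(combo$n, 152)
  expect_equal(combo$pct_abnormal, 34.2)
  expect_equal(combo$pct_strong, 8.6)
  expect_equal(combo$pct_medium, 25.7)

  gfp <- tally_phenotypes(data.frame(
    group = "GFP", normal = 92, medium = 1, strong = 0
  ))
  expect_equal(gfp$pct_normal, 98.9)

  none <- tally_phenotypes(data.frame(
    group = "x", normal = 50, medium = 0, strong = 0
  ))
  expect_equal(none$pct_abnormal, 0)

  # printed-style percentages recompose to the exact counts
  for (t in list(combo, gfp)) {
    expect_equal(round(t$pct_normal * t$n / 100), t$n_normal)
    expect_equal(round(t$pct_medium * t$n / 100), t$n_medium)
    expect_equal(round(t$pct_strong * t$n / 100), t$n_strong)
  }

  expect_error(
    tally_phenotypes(data.frame(group = "x", normal = 0, medium = 0, strong = 0)),
    "Empty"
  )

  # record-level route through the classifier
  recs <- classify_larvae(normal_larva(5))
  recs$group <- "G"
  t <- tally_phenotypes(recs)
  expect_equal(t$n_normal, 5)
  expect_s3_class(autoplot(t), "ggplot")
})

test_that("tally comparisons equal the textbook Pearson statistic", {
  t1 <- tally_phenotypes(data.frame(group = "a", normal = 100, medium = 39, strong = 13))
  t2 <- tally_phenotypes(data.frame(group = "b", normal = 92, medium = 1, strong = 0))

  # identical distributions give a zero statistic
  same <- compare_tallies(t1, t1)
  expect_equal(same$statistic, 0)

  # 2x2 normal/abnormal partition against the hand formula
  res <- compare_tallies(t1, t2, categories = c("normal", "abnormal"))
  tab <- rbind(c(100, 52), c(92, 1))
  expect_equal(res$statistic, pearson_chisq(tab))
  expect_equal(res$statistic, 37.39, tolerance = 1e-3)
  expect_equal(res$df, 1)

  # 2x3 partition against the hand formula
  res3 <- compare_tallies(t1, t2)
  tab3 <- rbind(c(100, 39, 13), c(92, 1, 0))
  expect_equal(res3$statistic, pearson_chisq(tab3))
  expect_equal(res3$df, 2)
  expect_true(res3$low_expected_cells %in% c(TRUE, FALSE))

  # brute-force oracle across all 2x2 tables with small margins
  for (a in 1:6) {
    for (b in 1:6) {
      for (cc in 1:6) {
        for (d in 1:6) {
          ta <- tally_phenotypes(data.frame(group = "a", normal = a, medium = b, strong = 0))
          tb <- tally_phenotypes(data.frame(group = "b", normal = cc, medium = d, strong = 0))
          got <- compare_tallies(ta, tb, categories = c("normal", "abnormal"))
          expect_equal(got$statistic, pearson_chisq(rbind(c(a, b), c(cc, d))))
        }
      }
    }
  }
})

test_that("angle comparisons use the tie-corrected Kruskal-Wallis test", {
  # fully separated ranks reach the analytic maximum for those sizes
  sep <- data.frame(
    group = rep(c("a", "b"), each = 3),
    angle_deg = c(10, 11, 12, 50, 51, 52)
  )
  res <- compare_angles(sep)
  n1 <- 3
  n2 <- 3
  N <- 6
  h_max <- 12 / (N * (N + 1)) * (n1 * mean(1:3)^2 + n2 * mean(4:6)^2) - 3 * (N + 1)
  expect_equal(res$statistic, h_max)

  expect_error(
    compare_angles(data.frame(group = "a", angle_deg = c(10, 11))),
    "two groups"
  )
  expect_error(
    compare_angles(data.frame(
      group = c("a", "a", "b"), angle_deg = c(10, 11, 12)
    )),
    "fewer than 2"
  )
  expect_error(
    compare_angles(data.frame(
      group = rep(c("a", "b"), each = 2), angle_deg = c(10, 20, 30, 190)
    )),
    "between 0 and 180"
  )
})

test_that("angle test is calibrated under the null and powered under shift", {
  null_params <- data.frame(group = paste0("g", 1:7), mean = 60, sd = 5)
  p_null <- vapply(1:100, function(s) {
    compare_angles(simulate_angles(null_params, n_per_group = 20, seed = s))$p_value
  }, numeric(1))
  expect_lt(mean(p_null < 0.05), 0.15)

  shift_params <- null_params
  shift_params$mean[7] <- 70 # one group shifted by two standard deviations
  hits <- vapply(1:100, function(s) {
    compare_angles(
      simulate_angles(shift_params, n_per_group = 20, seed = s)
    )$p_value < 1e-4
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
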