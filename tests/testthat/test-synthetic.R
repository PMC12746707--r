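test_that("a zero-length map transmits intact parental haplotypes", {
  flat <- genetic_map(data.frame(chrom = "chr1", bp = c(1, 1e6), cM = c(0, 0)))
  cfg <- sim_config(n_sites = 50, chrom_length_bp = 1e6, map = flat)
  fam <- simulate_family(3, cfg, seed = 4)
  for (id in c("II.1", "II.2", "II.3")) {
    expect_equal(length(unique(fam$origins[[id]]$pat)), 1)
    expect_equal(length(unique(fam$origins[[id]]$mat)), 1)
    expect_equal(length(fam$meioses[[id]]$pat$crossovers), 0)
  }
  expect_error(sim_config(n_sites = 0), "empty")
})

test_that("meiosis engine is Haldane-consistent across distances", {
  set.seed(17)
  n <- 100000
  for (d in c(1, 5, 10, 50)) {
    sites <- c(50 - d / 2, 50 + d / 2)
    m <- simulate_meiosis_origins(sites, n, span_cm = c(0, 100))
    frac <- mean(m$origins[, 1] != m$origins[, 2])
    r <- haldane_r(d)
    se <- sqrt(r * (1 - r) / n)
    expect_lt(abs(frac - r), 3 * se)
  }
})

test_that("families are deterministic in the seed and mosaics are legal", {
  cfg <- sim_config(n_sites = 200)
  f1 <- simulate_family(2, cfg, seed = 9)
  f2 <- simulate_family(2, cfg, seed = 9)
  expect_identical(f1$geno, f2$geno)
  expect_identical(f1$meioses, f2$meioses)

  # child haplotypes are mosaics of the parents with breakpoints exactly at
  # the recorded crossovers
  for (id in c("II.1", "II.2")) {
    m <- f1$meioses[[id]]$pat
    expected <- 1L + (m$start - 1L +
      findInterval(f1$sites$cm, m$crossovers)) %% 2L
    expect_equal(f1$origins[[id]]$pat, expected)
    hap <- ifelse(expected == 1L, f1$founder_haps$F1, f1$founder_haps$F2)
    expect_equal(unname(f1$geno[[id]][1, ]), hap)
  }
})

test_that("sib pairs average a quarter of the genome in IBD2", {
  cfg <- sim_config(n_sites = 2)
  frac <- vapply(1:2000, function(s) {
    fam <- simulate_family(2, cfg, seed = s)
    truth <- true_ibd_segments(fam)
    sum((truth$end_cm - truth$start_cm)[truth$state == "IBD2"]) /
      (max(truth$end_cm) - min(truth$start_cm))
  }, numeric(1))
  se <- stats::sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - 0.25), 3 * se)
})

test_that("the meiosis engine reproduces the analytic pattern probability", {
  set.seed(31)
  n_fam <- 200000
  cm <- c(196.1223, 200.6316)
  m <- simulate_meiosis_origins(cm, n_fam * 4, span_cm = c(190, 210))
  o_a <- matrix(m$origins[, 1], n_fam, 4)
  o_b <- matrix(m$origins[, 2], n_fam, 4)
  assigned <- rep(c(1L, 1L, 2L, 2L), each = n_fam)
  ok <- o_a == assigned & o_b == assigned
  est <- mean(rowSums(ok) == 4)
  analytic <- pattern_probability(
    segregation_config(4, cm_a = cm[1], cm_b = cm[2])
  )$total_prob
  se <- sqrt(analytic * (1 - analytic) / n_fam)
  expect_lt(abs(est - analytic), 3 * se)
})

test_that("the Poisson read model feeds the depth filter as expected", {
  cfg <- sim_config(n_sites = 2000, mean_depth = 10, depth_model = "poisson")
  fam <- simulate_family(2, cfg, seed = 12)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_family_vcf(fam, path)
  sites <- read_family_vcf(path)
  # depth is pmax(1, Poisson(10)); expected pass rate for DP > 14
  p_pass <- 1 - stats::ppois(14, 10)
  obs <- mean(sites$dp >= 15)
  se <- sqrt(p_pass * (1 - p_pass) / nrow(sites))
  expect_lt(abs(obs - p_pass), 4 * se)
})

test_that("planted network modules are proximal and reproducible", {
  sim <- simulate_network(n_nodes = 80, planted_module_size = 8, seed = 14)
  sim2 <- simulate_network(n_nodes = 80, planted_module_size = 8, seed = 14)
  expect_identical(sim$network, sim2$network)
  expect_equal(sum(sim$labels$in_module), 8)

  stats_all <- avg_shortest_path_stat(sim$network, sim$seed_pair)
  module <- sim$labels$node[sim$labels$in_module]
  in_mod <- stats_all$statistic[stats_all$node %in% setdiff(module, sim$seed_pair)]
  background <- stats_all$statistic[!stats_all$node %in% module]
  expect_lt(max(in_mod), stats::median(background[is.finite(background)]))

  bare <- simulate_network(n_nodes = 30, planted_module_size = 2, seed = 1)
  expect_setequal(bare$labels$node[bare$labels$in_module], bare$seed_pair)
  expect_error(simulate_network(n_nodes = 10, planted_module_size = 20), "Module")
})

test_that("phenotype records honour class probabilities via the classifier", {
  all_normal <- simulate_phenotype_records(
    data.frame(group = "g", normal = 1, medium = 0, strong = 0),
    n_per_group = 50, seed = 2
  )
  expect_true(all(classify_larvae(all_normal)$class == "normal"))

  combo <- simulate_phenotype_records(
    data.frame(group = "COMBO-MT", normal = 0.657, medium = 0.257, strong = 0.086),
    n_per_group = 152, seed = 6
  )
  reclass <- classify_larvae(combo[, !(names(combo) %in% "class")])
  # generating class and classifier agree by construction
  expect_equal(as.character(reclass$class), as.character(combo$class))
  for (cl in c("normal", "medium", "strong")) {
    p <- c(normal = 0.657, medium = 0.257, strong = 0.086)[[cl]]
    obs <- mean(reclass$class == cl)
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / 152) + 1e-9)
  }

  again <- simulate_phenotype_records(
    data.frame(group = "COMBO-MT", normal = 0.657, medium = 0.257, strong = 0.086),
    n_per_group = 152, seed = 6
  )
  expect_identical(combo, again)
  expect_error(
    simulate_phenotype_records(
      data.frame(group = "g", normal = 0.5, medium = 0.2, strong = 0.2),
      n_per_group = 5
    ),
    "sum to 1"
  )
})

test_that("angle draws are truncated, grouped and seed-deterministic", {
  a1 <- simulate_angles(seed = 3)
  a2 <- simulate_angles(seed = 3)
  expect_identical(a1, a2)
  expect_equal(nrow(a1), 7 * 20)
  expect_true(all(a1$angle_deg > 0 & a1$angle_deg < 180))
  expect_error(
    simulate_angles(data.frame(group = "g", mean = 60, sd = 0)),
    "positive"
  )
})
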