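#' Configuration for the family simulator
#'
#' Defines the site grid, genetic map, founder allele frequency and read
#' model used by [simulate_family()] and [write_family_vcf()]. The default
#' emulates one 100 Mb chromosome with a uniform 1 cM/Mb map and 8000
#' informative biallelic SNV sites — a conservative subset of the
#' informative-site density of real whole-genome data — with a noiseless
#' read model (`depth_model = "fixed"`: every call at `mean_depth` reads,
#' maximal GQ, exact allele depths). Set `depth_model = "poisson"` for
#' sampled depths, binomial allele depths and a depth/balance-dependent GQ.
#'
#' @param n_sites Number of SNV sites (>= 1).
#' @param chrom Chromosome name.
#' @param chrom_length_bp Physical length.
#' @param map Optional [genetic_map()] covering the chromosome; default is a
#'   linear 1 cM/Mb map from 0 to `chrom_length_bp / 1e6` cM.
#' @param founder_af Alternate-allele frequency used to draw the four founder
#'   haplotypes (independent sites).
#' @param mean_depth Read depth (exact under `"fixed"`, Poisson mean under
#'   `"poisson"`).
#' @param depth_model `"fixed"` (noiseless) or `"poisson"`.
#' @param gq_max Genotype-quality cap.
#' @param geno_error Per-genotype error rate for the VCF writer (a wrong
#'   genotype is substituted with this probability).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 8000, chrom = "chr1", chrom_length_bp = 1e8,
                       map = NULL, founder_af = 0.5, mean_depth = 30,
                       depth_model = c("fixed", "poisson"), gq_max = 99,
                       geno_error = 0) {
  depth_model <- match.arg(depth_model)
  if (n_sites < 1) abort("`n_sites` must be >= 1: an empty site grid cannot be simulated.")
  if (founder_af <= 0 || founder_af >= 1) abort("`founder_af` must lie in (0, 1).")
  if (mean_depth <= 0) abort("`mean_depth` must be positive.")
  if (geno_error < 0 || geno_error >= 1) abort("`geno_error` must lie in [0, 1).")
  map <- map %||% genetic_map(tibble(
    chrom = chrom, bp = c(1, chrom_length_bp),
    cM = c(0, chrom_length_bp / 1e6)
  ))
  structure(
    list(
      n_sites = as.integer(n_sites), chrom = chrom,
      chrom_length_bp = chrom_length_bp, map = map, founder_af = founder_af,
      mean_depth = mean_depth, depth_model = depth_model, gq_max = gq_max,
      geno_error = geno_error
    ),
    class = "sim_config"
  )
}

#' Simulate meioses with Poisson crossovers on the genetic map
#'
#' The meiosis engine underlying [simulate_family()]. Each meiosis draws a
#' crossover count from a Poisson law with mean equal to the map span in
#' Morgans, places the crossovers uniformly on the cM scale (no
#' interference), picks the starting homolog at random, and reads off which
#' parental homolog (1 or 2) each site's allele comes from.
#'
#' @param cm_sites Genetic positions (cM) of the sites, sorted.
#' @param n_meioses Number of independent meioses.
#' @param span_cm Length-2 numeric: the cM interval over which crossovers
#'   occur (default: the map range of `cm_sites`).
#' @return A list: `origins` (matrix `n_meioses` x `length(cm_sites)` of
#'   homolog indices 1/2), `starts`, and `crossovers` (list of cM positions
#'   per meiosis).
#' @export
simulate_meiosis_origins <- function(cm_sites, n_meioses,
                                     span_cm = range(cm_sites)) {
  if (length(cm_sites) < 1) abort("`cm_sites` must be non-empty.")
  if (is.unsorted(cm_sites)) abort("`cm_sites` must be sorted.")
  n <- as.integer(n_meioses)
  morgans <- (span_cm[2] - span_cm[1]) / 100
  k <- rpois(n, morgans)
  pos <- runif(sum(k), span_cm[1], span_cm[2])
  mei <- rep.int(seq_len(n), k)
  starts <- sample.int(2L, n, replace = TRUE)
  counts <- vapply(
    cm_sites,
    function(cs) tabulate(mei[pos < cs], nbins = n),
    integer(n)
  )
  if (n == 1L) counts <- matrix(counts, nrow = 1L)
  origins <- 1L + (starts - 1L + counts) %% 2L
  list(
    origins = origins, starts = starts,
    crossovers = split(pos, factor(mei, levels = seq_len(n)))
  )
}

#' Simulate a nuclear family with phased haplotypes
#'
#' Draws four founder haplotypes from the configured allele frequency and
#' transmits them to `n_children` children through meioses with Poisson
#' crossovers on the cM scale (Haldane-consistent, no interference). Every
#' child haplotype is a mosaic of one parent's two haplotypes with
#' breakpoints exactly at the recorded crossover positions. Deterministic
#' given `seed`.
#'
#' @param n_children Number of children (>= 1).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return An object of class `sim_family`: list with `config`, `seed`,
#'   `pedigree` (father `I.1`, mother `I.2`, children `II.k`), `sites`
#'   (tibble `chrom`, `bp`, `cm`), `founder_haps` (list `F1`,`F2`,`M1`,`M2`
#'   of 0/1 allele vectors), `meioses` (per child, the paternal and maternal
#'   crossover positions and starting homologs), `origins` (per child,
#'   per-site homolog indices) and `geno` (per individual, a 2 x n_sites
#'   allele matrix; row 1 is the paternal allele for children).
#' @export
simulate_family <- function(n_children = 2, config = sim_config(), seed = 1) {
  if (!inherits(config, "sim_config")) abort("`config` must come from sim_config().")
  if (n_children < 1) abort("`n_children` must be >= 1.")
  set.seed(seed)
  n_children <- as.integer(n_children)
  S <- config$n_sites
  bp <- sort(sample.int(config$chrom_length_bp, S))
  cm <- interpolate_cm(config$map, config$chrom, bp)
  sites <- tibble(chrom = config$chrom, bp = bp, cm = cm)
  map_chrom <- config$map[config$map$chrom == config$chrom, ]
  span <- range(map_chrom$cM)

  founder_haps <- list(
    F1 = rbinom(S, 1, config$founder_af), F2 = rbinom(S, 1, config$founder_af),
    M1 = rbinom(S, 1, config$founder_af), M2 = rbinom(S, 1, config$founder_af)
  )
  children <- paste0("II.", seq_len(n_children))
  ped <- pedigree(tibble(
    fid = "FAM1",
    id = c("I.1", "I.2", children),
    father = c("0", "0", rep("I.1", n_children)),
    mother = c("0", "0", rep("I.2", n_children)),
    sex = c(1L, 2L, rep(0L, n_children)),
    phenotype = c(1L, 1L, rep(2L, n_children))
  ))
  pat <- simulate_meiosis_origins(cm, n_children, span)
  mat <- simulate_meiosis_origins(cm, n_children, span)

  origins <- meioses <- geno <- list()
  geno[["I.1"]] <- rbind(founder_haps$F1, founder_haps$F2)
  geno[["I.2"]] <- rbind(founder_haps$M1, founder_haps$M2)
  for (i in seq_len(n_children)) {
    id <- children[i]
    po <- pat$origins[i, ]
    mo <- mat$origins[i, ]
    origins[[id]] <- list(pat = po, mat = mo)
    meioses[[id]] <- list(
      pat = list(start = pat$starts[i], crossovers = sort(pat$crossovers[[i]])),
      mat = list(start = mat$starts[i], crossovers = sort(mat$crossovers[[i]]))
    )
    pat_allele <- ifelse(po == 1L, founder_haps$F1, founder_haps$F2)
    mat_allele <- ifelse(mo == 1L, founder_haps$M1, founder_haps$M2)
    geno[[id]] <- rbind(pat_allele, mat_allele)
  }
  structure(
    list(
      config = config, seed = seed, pedigree = ped, sites = sites,
      founder_haps = founder_haps, meioses = meioses, origins = origins,
      geno = geno
    ),
    class = "sim_family"
  )
}

# Homolog origin of a meiosis at arbitrary cM positions.
origin_at <- function(meiosis, x) {
  1L + (meiosis$start - 1L + findInterval(x, meiosis$crossovers)) %% 2L
}

#' True IBD intervals for a simulated sibling pair
#'
#' Reads the IBD state directly off the recorded crossovers: the paternal
#' (maternal) transmissions of the two sibs are shared wherever their origin
#' functions agree, and the combined state counts the shared transmissions.
#' Interval boundaries fall exactly at crossover positions, converted from
#' cM to bp through the simulation map.
#'
#' @param family A [simulate_family()] result.
#' @param pair Two child ids (default: the first two children).
#' @return A tibble `chrom`, `start_bp`, `end_bp`, `start_cm`, `end_cm`,
#'   `state` (`IBD0`/`IBD1`/`IBD2`) tiling the map span.
#' @export
true_ibd_segments <- function(family, pair = NULL) {
  if (!inherits(family, "sim_family")) abort("`family` must come from simulate_family().")
  children <- setdiff(family$pedigree$id, c("I.1", "I.2"))
  pair <- pair %||% children[1:2]
  if (!all(pair %in% children) || length(pair) != 2) {
    abort("`pair` must name two simulated children.")
  }
  m1 <- family$meioses[[pair[1]]]
  m2 <- family$meioses[[pair[2]]]
  map_chrom <- family$config$map[family$config$map$chrom == family$config$chrom, ]
  span <- range(map_chrom$cM)
  breaks <- sort(unique(c(
    span, m1$pat$crossovers, m2$pat$crossovers,
    m1$mat$crossovers, m2$mat$crossovers
  )))
  lo <- head(breaks, -1)
  hi <- tail(breaks, -1)
  mid <- (lo + hi) / 2
  share_pat <- origin_at(m1$pat, mid) == origin_at(m2$pat, mid)
  share_mat <- origin_at(m1$mat, mid) == origin_at(m2$mat, mid)
  state <- paste0("IBD", share_pat + share_mat)
  # merge adjacent intervals with equal state
  run <- cumsum(c(TRUE, state[-1] != state[-length(state)]))
  out <- tibble(lo = lo, hi = hi, state = state, run = run) |>
    group_by(.data$run, .data$state) |>
    summarise(start_cm = min(.data$lo), end_cm = max(.data$hi), .groups = "drop") |>
    arrange(.data$start_cm)
  out$start_bp <- approx(map_chrom$cM, map_chrom$bp, xout = out$start_cm, rule = 2)$y
  out$end_bp <- approx(map_chrom$cM, map_chrom$bp, xout = out$end_cm, rule = 2)$y
  tibble(
    chrom = family$config$chrom,
    start_bp = out$start_bp, end_bp = out$end_bp,
    start_cm = out$start_cm, end_cm = out$end_cm, state = out$state
  )
}

#' Write a simulated family as a multi-sample VCF 4.2 file
#'
#' Emits plain-text VCF with `GT`, `DP`, `GQ` and `AD` per sample according
#' to the configured read model. Under the noiseless `"fixed"` model every
#' call has exactly `mean_depth` reads, a clean half-and-half allele split
#' for heterozygotes and maximal GQ. Under `"poisson"`, depth is Poisson,
#' the alt allele depth is binomial around the true allele balance, and GQ
#' is a simple monotone function of depth penalised by allelic imbalance.
#' Genotype errors are substituted at the configured rate. Reference and
#' alternate bases are arbitrary (`A`/`C`): only genotypes matter downstream.
#'
#' @param family A [simulate_family()] result.
#' @param path Output path (`.vcf`).
#' @param seed Optional seed for the read-model noise (defaults to the
#'   family seed + 1).
#' @return The path, invisibly.
#' @export
write_family_vcf <- function(family, path, seed = NULL) {
  if (!inherits(family, "sim_family")) abort("`family` must come from simulate_family().")
  cfg <- family$config
  set.seed(seed %||% (family$seed + 1L))
  ids <- family$pedigree$id
  S <- nrow(family$sites)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=coseg_simulate_family",
    sprintf("##contig=<ID=%s,length=%d>", cfg$chrom, as.integer(cfg$chrom_length_bp)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
      ids
    ), collapse = "\t")
  )
  if (S == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  sample_fields <- vapply(ids, function(id) {
    al <- family$geno[[id]]
    a1 <- al[1, ]
    a2 <- al[2, ]
    if (cfg$geno_error > 0) {
      flip <- runif(S) < cfg$geno_error
      a1[flip] <- rbinom(sum(flip), 1, 0.5)
      a2[flip] <- rbinom(sum(flip), 1, 0.5)
    }
    frac <- (a1 + a2) / 2
    if (cfg$depth_model == "fixed") {
      dp <- rep(as.integer(round(cfg$mean_depth)), S)
      ad_alt <- as.integer(round(dp * frac))
      gq <- rep(as.integer(cfg$gq_max), S)
    } else {
      dp <- pmax(1L, rpois(S, cfg$mean_depth))
      ad_alt <- rbinom(S, dp, frac)
      imbalance <- abs(ad_alt / dp - frac)
      gq <- pmax(0L, pmin(
        as.integer(cfg$gq_max),
        as.integer(round(3.3 * dp * (1 - 2 * imbalance)))
      ))
    }
    ad_ref <- dp - ad_alt
    gt <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
    paste(gt, dp, gq, paste(ad_ref, ad_alt, sep = ","), sep = ":")
  }, character(S))
  if (S == 1L) sample_fields <- matrix(sample_fields, nrow = 1L)
  body <- paste(
    family$sites$chrom, as.integer(family$sites$bp), ".", "A", "C", ".",
    "PASS", ".", "GT:DP:GQ:AD",
    apply(sample_fields, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a genetic map to a TSV file
#'
#' @param map A [genetic_map()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  readr::write_tsv(as_tibble(map)[, c("chrom", "bp", "cM")], path)
  invisible(path)
}

#' Simulate a weighted gene network with a planted proximal module
#'
#' Background: an Erdos-Renyi graph with the requested mean degree and
#' moderate weights. Planted module: a dense, high-weight subgraph of
#' `planted_module_size` nodes containing both seed genes, emulating a
#' functionally proximal gene set. Any disconnected components are attached
#' to the largest component with single background-weight edges (logged).
#'
#' @param n_nodes Total number of nodes.
#' @param mean_degree Background mean degree.
#' @param planted_module_size Module size including the two seeds (>= 2; 2
#'   plants nothing beyond the seed pair).
#' @param seed_pair Length-2 character vector of seed gene names.
#' @param module_density Edge probability within the module.
#' @param background_weight,module_weight Length-2 ranges for uniform weight
#'   draws.
#' @param seed Integer seed.
#' @return A list: `network` (a [gene_network()]), `labels` (tibble `node`,
#'   `in_module`), `seed_pair`.
#' @export
simulate_network <- function(n_nodes = 200, mean_degree = 4,
                             planted_module_size = 8,
                             seed_pair = c("EHHADH", "MASP1"),
                             module_density = 0.9,
                             background_weight = c(0.5, 1.5),
                             module_weight = c(2.5, 3.5), seed = 1) {
  if (planted_module_size < 2) abort("`planted_module_size` must be >= 2.")
  if (planted_module_size > n_nodes) abort("Module larger than the network.")
  if (n_nodes < 4 || mean_degree <= 0 || mean_degree >= n_nodes - 1) {
    abort("Infeasible network parameters.")
  }
  set.seed(seed)
  nodes <- c(seed_pair, sprintf("G%03d", seq_len(n_nodes - 2)))
  p_bg <- mean_degree / (n_nodes - 1)
  g <- igraph::sample_gnp(n_nodes, p_bg)
  igraph::V(g)$name <- nodes
  el <- igraph::as_edgelist(g)
  edges <- tibble(
    from = el[, 1], to = el[, 2],
    weight = runif(nrow(el), background_weight[1], background_weight[2])
  )
  module_nodes <- c(
    seed_pair,
    sample(setdiff(nodes, seed_pair), planted_module_size - 2)
  )
  mod_pairs <- utils::combn(module_nodes, 2)
  keep <- runif(ncol(mod_pairs)) < module_density
  # the seed pair itself is always linked: the module is built around it
  keep[mod_pairs[1, ] %in% seed_pair & mod_pairs[2, ] %in% seed_pair] <- TRUE
  mod_edges <- tibble(
    from = mod_pairs[1, keep], to = mod_pairs[2, keep],
    weight = runif(sum(keep), module_weight[1], module_weight[2])
  )
  # module edges replace any coinciding background edges
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  ma <- pmin(mod_edges$from, mod_edges$to)
  mb <- pmax(mod_edges$from, mod_edges$to)
  dup <- paste(a, b) %in% paste(ma, mb)
  edges <- bind_rows(edges[!dup, ], mod_edges)
  net <- gene_network(edges)
  g2 <- network_igraph(net)
  comp <- igraph::components(g2)
  isolated <- setdiff(nodes, igraph::V(g2)$name)
  if (comp$no > 1 || length(isolated)) {
    main <- igraph::V(g2)$name[comp$membership == which.max(comp$csize)]
    extra_from <- character(0)
    for (k in seq_len(comp$no)) {
      if (k == which.max(comp$csize)) next
      extra_from <- c(extra_from, igraph::V(g2)$name[comp$membership == k][1])
    }
    extra_from <- c(extra_from, isolated)
    if (length(extra_from)) {
      inform(sprintf(
        "Connected %d stray component(s)/node(s) to the main component.",
        length(extra_from)
      ))
      extra <- tibble(
        from = extra_from,
        to = sample(main, length(extra_from), replace = TRUE),
        weight = runif(length(extra_from), background_weight[1], background_weight[2])
      )
      net <- gene_network(bind_rows(as_tibble(net), extra))
    }
  }
  list(
    network = net,
    labels = tibble(node = nodes, in_module = nodes %in% module_nodes),
    seed_pair = seed_pair
  )
}

#' Default per-group phenotype class probabilities
#'
#' The class mixture each injection group is simulated from, together with
#' the per-group sample sizes of the experimental design (seven conditions;
#' GFP is the injection control).
#'
#' @return A tibble `group`, `normal`, `medium`, `strong`, `n`.
#' @export
default_group_class_probs <- function() {
  t <- tibble(
    group = c(
      "GFP", "EHHADH-WT", "EHHADH-MT", "MASP1-WT", "MASP1-MT",
      "COMBO-WT", "COMBO-MT"
    ),
    medium = c(0.011, 0.110, 0.191, 0.148, 0.192, 0.133, 0.257),
    strong = c(0.000, 0.063, 0.085, 0.081, 0.082, 0.080, 0.086),
    n = c(93L, 127L, 94L, 135L, 146L, 150L, 152L)
  )
  t$normal <- 1 - t$medium - t$strong
  t[, c("group", "normal", "medium", "strong", "n")]
}

# Class-tilted feature proposals for the rejection sampler.
propose_features <- function(class, m) {
  if (class == "normal") {
    return(tibble(
      swim_bladder = rep("inflated", m), tail_curvature = rep("none", m),
      jaw = rep("normal", m), cardiac_edema = rep(FALSE, m),
      cleft_like_defect = rep(FALSE, m), severe_axis_defect = rep(FALSE, m)
    ))
  }
  p <- switch(class,
    medium = list(
      sb = c(0.40, 0.40, 0.20), tail = c(0.35, 0.25, 0.25, 0.15),
      jaw = c(0.50, 0.35, 0.15), severe = 0.10
    ),
    strong = list(
      sb = c(0.30, 0.40, 0.30), tail = c(0.20, 0.20, 0.20, 0.40),
      jaw = c(0.30, 0.30, 0.40), severe = 0.45
    )
  )
  tibble(
    swim_bladder = sample(pheno_feature_levels$swim_bladder, m, TRUE, p$sb),
    tail_curvature = sample(pheno_feature_levels$tail_curvature, m, TRUE, p$tail),
    jaw = sample(pheno_feature_levels$jaw, m, TRUE, p$jaw),
    cardiac_edema = runif(m) < p$severe,
    cleft_like_defect = runif(m) < p$severe,
    severe_axis_defect = runif(m) < p$severe
  )
}

#' Simulate per-larva phenotype records
#'
#' Draws each larva's class from its group's class probabilities, then draws
#' a feature combination consistent with that class by rejection sampling
#' against [classify_larvae()] — the generator never inverts the classifier,
#' so the two stay decoupled.
#'
#' @param group_class_probs Tibble `group`, `normal`, `medium`, `strong`
#'   (probabilities summing to 1 per group) and optionally `n`; default
#'   [default_group_class_probs()].
#' @param n_per_group Larvae per group: a single number, a vector matching
#'   the groups, or `NULL` to use the `n` column.
#' @param seed Integer seed.
#' @param max_rounds Rejection-sampling rounds before declaring a class
#'   unreachable.
#' @return A tibble of phenotype records with `larva`, `group`, the feature
#'   columns and the (generating) `class`.
#' @export
simulate_phenotype_records <- function(group_class_probs = default_group_class_probs(),
                                       n_per_group = NULL, seed = 1,
                                       max_rounds = 100) {
  stop_if_not_df(group_class_probs, "group_class_probs")
  require_columns(group_class_probs, c("group", "normal", "medium", "strong"), "group_class_probs")
  probs <- as_tibble(group_class_probs)
  tot <- probs$normal + probs$medium + probs$strong
  if (any(abs(tot - 1) > 1e-8)) {
    abort("Class probabilities must sum to 1 within each group.")
  }
  n_per_group <- n_per_group %||% probs$n
  if (is.null(n_per_group)) abort("Supply `n_per_group` or an `n` column.")
  n_per_group <- rep_len(n_per_group, nrow(probs))
  set.seed(seed)
  out <- purrr::pmap(
    list(probs$group, probs$normal, probs$medium, probs$strong, n_per_group),
    function(group, p_n, p_m, p_s, n) {
      classes <- sample(pheno_classes, n, TRUE, prob = c(p_n, p_m, p_s))
      recs <- vector("list", length(pheno_classes))
      for (cl in pheno_classes) {
        need <- sum(classes == cl)
        if (need == 0) next
        got <- list()
        rounds <- 0
        while (need > 0) {
          rounds <- rounds + 1
          if (rounds > max_rounds) {
            abort(sprintf("Class '%s' unreachable under the feature model.", cl))
          }
          cand <- classify_larvae(propose_features(cl, max(need * 2, 10)))
          hit <- cand[cand$class == cl, ]
          if (nrow(hit) > 0) {
            got <- c(got, list(head(hit, need)))
            need <- need - min(nrow(hit), need)
          }
        }
        recs[[match(cl, pheno_classes)]] <- bind_rows(got)
      }
      recs <- bind_rows(recs)
      recs$group <- group
      recs
    }
  ) |>
    bind_rows()
  out$larva <- sprintf("L%05d", seq_len(nrow(out)))
  out[, c(
    "larva", "group", "swim_bladder", "tail_curvature", "jaw",
    "cardiac_edema", "cleft_like_defect", "severe_axis_defect", "class"
  )]
}

#' Default ceratohyal angle distribution parameters
#'
#' Group means and a common standard deviation for the seven-condition
#' design; mutant and combined-mutant groups are shifted toward wider
#' angles, the published direction of effect.
#'
#' @return A tibble `group`, `mean`, `sd`.
#' @export
default_angle_params <- function() {
  tibble(
    group = c(
      "GFP", "EHHADH-WT", "EHHADH-MT", "MASP1-WT", "MASP1-MT",
      "COMBO-WT", "COMBO-MT"
    ),
    mean = c(60, 63, 68, 63, 67, 65, 72),
    sd = 5
  )
}

#' Simulate per-larva ceratohyal angle measurements
#'
#' Gaussian draws per group truncated to the meaningful (0, 180) degree
#' range (out-of-range draws are redrawn).
#'
#' @param group_params Tibble `group`, `mean`, `sd`; default
#'   [default_angle_params()].
#' @param n_per_group Measurements per group (default 20, the per-condition
#'   sample size of the design).
#' @param seed Integer seed.
#' @return A tibble `group`, `angle_deg`.
#' @export
simulate_angles <- function(group_params = default_angle_params(),
                            n_per_group = 20, seed = 1) {
  stop_if_not_df(group_params, "group_params")
  require_columns(group_params, c("group", "mean", "sd"), "group_params")
  if (any(group_params$sd <= 0)) abort("`sd` must be positive.")
  set.seed(seed)
  purrr::pmap(
    list(group_params$group, group_params$mean, group_params$sd),
    function(group, mu, sd) {
      x <- stats::rnorm(n_per_group, mu, sd)
      while (any(x <= 0 | x >= 180)) {
        bad <- x <= 0 | x >= 180
        x[bad] <- stats::rnorm(sum(bad), mu, sd)
      }
      tibble(group = group, angle_deg = x)
    }
  ) |>
    bind_rows()
}
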