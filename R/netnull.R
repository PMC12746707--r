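#' Validate a weighted gene network
#'
#' Undirected weighted edge list: gene symbols as nodes, positive association
#' weights. Self-loops are dropped with a warning; duplicate undirected edges
#' are collapsed by summing their weights, with a warning.
#'
#' @param edges Data frame with columns `from`, `to`, `weight`.
#' @return A tibble of class `gene_network`.
#' @export
gene_network <- function(edges) {
  stop_if_not_df(edges, "edges")
  require_columns(edges, c("from", "to", "weight"), "edges")
  edges <- as_tibble(edges) |>
    mutate(
      from = as.character(.data$from), to = as.character(.data$to),
      weight = as.numeric(.data$weight)
    )
  if (any(is.na(edges$weight)) || any(edges$weight <= 0)) {
    abort("Edge weights must be positive.")
  }
  loops <- edges$from == edges$to
  if (any(loops)) {
    warn(sprintf("Dropped %d self-loop(s).", sum(loops)))
    edges <- edges[!loops, ]
  }
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    warn("Collapsed duplicate undirected edge(s) by summing weights.")
    edges <- tibble(from = a, to = b, weight = edges$weight) |>
      group_by(.data$from, .data$to) |>
      summarise(weight = sum(.data$weight), .groups = "drop")
  }
  class(edges) <- c("gene_network", class(edges))
  edges
}

#' Read a weighted edge list from a TSV file
#'
#' @param path TSV with header columns `from`, `to`, `weight` (tab-separated
#'   `nodeA nodeB weight`).
#' @return A [gene_network()] tibble.
#' @export
read_edge_list <- function(path) {
  gene_network(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' Write a weighted edge list to a TSV file
#'
#' @param network A [gene_network()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(network, path) {
  readr::write_tsv(as_tibble(network)[, c("from", "to", "weight")], path)
  invisible(path)
}

network_igraph <- function(network) {
  igraph::graph_from_data_frame(as_tibble(network), directed = FALSE)
}

#' Average shortest-path distance to the seed genes
#'
#' For each node, the mean weighted shortest-path distance to the seed genes
#' (a node that is itself a seed is excluded from its own average). Path
#' lengths use `weight_transform` of the association weight as edge length;
#' the default `1/weight` makes strongly associated genes close. Nodes
#' disconnected from every seed get an infinite statistic.
#'
#' @param network A [gene_network()].
#' @param seed_genes Character vector of seed gene symbols (must be nodes).
#' @param nodes Nodes to score (default: all nodes).
#' @param weight_transform Function mapping association weight to edge
#'   length; default `function(w) 1 / w`.
#' @return A tibble `node`, `statistic` (`Inf` when disconnected from all
#'   seeds).
#' @examples
#' net <- gene_network(data.frame(
#'   from = c("A", "B"), to = c("B", "C"), weight = 1
#' ))
#' avg_shortest_path_stat(net, seed_genes = c("A", "C"))
#' @export
avg_shortest_path_stat <- function(network, seed_genes, nodes = NULL,
                                   weight_transform = function(w) 1 / w) {
  g <- network_igraph(network)
  all_nodes <- igraph::V(g)$name
  missing <- setdiff(seed_genes, all_nodes)
  if (length(missing)) {
    abort(sprintf(
      "Seed gene(s) not in network: %s.", paste(missing, collapse = ", ")
    ))
  }
  nodes <- nodes %||% all_nodes
  missing_n <- setdiff(nodes, all_nodes)
  if (length(missing_n)) {
    abort(sprintf(
      "Node(s) not in network: %s.", paste(missing_n, collapse = ", ")
    ))
  }
  len <- weight_transform(igraph::E(g)$weight)
  if (any(len < 0)) abort("weight_transform produced negative edge lengths.")
  tibble(
    node = nodes,
    statistic = asp_stat_graph(g, seed_genes, nodes, len)
  )
}

# Mean shortest-path distance from each node to the seeds on an igraph
# object with precomputed edge lengths; a seed excludes itself.
asp_stat_graph <- function(g, seed_genes, nodes, len) {
  d <- igraph::distances(g, v = nodes, to = seed_genes, weights = len)
  stat <- rowMeans(d)
  # a node that is itself a seed is excluded from its own average
  for (i in which(nodes %in% seed_genes)) {
    di <- d[i, seed_genes != nodes[i]]
    stat[i] <- if (length(di)) mean(di) else NA_real_
  }
  unname(stat)
}

#' Degree- and weight-preserving network randomization
#'
#' Rewires the topology by repeated degree-preserving double-edge swaps
#' (targeting `nswap_factor` times the edge count) and then randomly permutes
#' the multiset of edge weights over the rewired edges. Every node keeps its
#' exact degree and the weight multiset is exactly preserved; only the
#' connection pattern is randomized. Draws from R's RNG, so results are
#' reproducible under `set.seed()`.
#'
#' @param network A [gene_network()] with at least 2 edges.
#' @param nswap_factor Attempted swaps as a multiple of the edge count.
#' @return A randomized [gene_network()].
#' @export
randomize_network <- function(network, nswap_factor = 10) {
  network <- if (inherits(network, "gene_network")) network else gene_network(network)
  n_edges <- nrow(network)
  if (n_edges < 2) abort("Randomization needs a network with >= 2 edges.")
  g <- network_igraph(network)
  g2 <- igraph::rewire(
    g, igraph::keeping_degseq(loops = FALSE, niter = nswap_factor * n_edges)
  )
  el <- igraph::as_edgelist(g2)
  out <- tibble(
    from = el[, 1], to = el[, 2],
    weight = sample(network$weight, n_edges, replace = FALSE)
  )
  class(out) <- c("gene_network", class(out))
  out
}

#' Empirical p-values against the network-randomization null
#'
#' Builds, for each node, a null distribution of its average shortest-path
#' distance to the seed genes across `n_sim` randomized networks (degree- and
#' weight-preserving, see [randomize_network()]), processed in batches of
#' `batch_size` (an execution detail: the result is identical for any batch
#' size under the same seed). The raw p-value is the proportion of
#' simulations with a simulated distance less than or equal to the observed
#' one — it can be exactly 0; the optional `(r+1)/(n+1)` estimator is
#' available via `estimator = "add_one"`. Draws where a node is disconnected
#' from every seed contribute an infinite distance (never below a finite
#' observed value) and are counted per node. BH-adjusted p-values are
#' appended.
#'
#' @inheritParams avg_shortest_path_stat
#' @param n_sim Number of randomized networks (>= 1).
#' @param batch_size Simulations per batch; the last batch may be short.
#' @param seed Integer seed; fully determines the output.
#' @param estimator `"proportion"` (default) or `"add_one"`.
#' @param nswap_factor Passed to [randomize_network()].
#' @return An object of class `coseg_null`: list with `result` (tibble
#'   `node`, `observed`, `p_raw`, `p_bh`, `n_inf_draws`), `sims` (node x
#'   simulation matrix of null statistics) and `params`. Use [tidy()],
#'   [glance()], [autoplot()] and [significant_nodes()].
#' @export
null_pvalues <- function(network, seed_genes, n_sim = 1000, batch_size = 200,
                         seed = NULL, nodes = NULL,
                         weight_transform = function(w) 1 / w,
                         estimator = c("proportion", "add_one"),
                         nswap_factor = 10) {
  estimator <- match.arg(estimator)
  network <- if (inherits(network, "gene_network")) network else gene_network(network)
  if (n_sim < 1) abort("`n_sim` must be >= 1.")
  if (batch_size < 1) abort("`batch_size` must be >= 1.")
  if (!is.null(seed)) set.seed(seed)
  obs <- avg_shortest_path_stat(network, seed_genes, nodes, weight_transform)
  nodes <- obs$node
  g <- network_igraph(network)
  w <- igraph::E(g)$weight
  niter <- nswap_factor * length(w)
  sims <- matrix(NA_real_, nrow = length(nodes), ncol = n_sim,
                 dimnames = list(nodes, NULL))
  done <- 0L
  while (done < n_sim) {
    this_batch <- min(batch_size, n_sim - done)
    for (b in seq_len(this_batch)) {
      g2 <- igraph::rewire(
        g, igraph::keeping_degseq(loops = FALSE, niter = niter)
      )
      len <- weight_transform(sample(w, length(w), replace = FALSE))
      sims[, done + b] <- asp_stat_graph(g2, seed_genes, nodes, len)
    }
    done <- done + this_batch
  }
  n_le <- rowSums(sims <= obs$statistic)
  p_raw <- switch(estimator,
    proportion = n_le / n_sim,
    add_one = (n_le + 1) / (n_sim + 1)
  )
  result <- tibble(
    node = nodes,
    observed = obs$statistic,
    p_raw = p_raw,
    p_bh = bh_adjust(p_raw),
    n_inf_draws = rowSums(is.infinite(sims))
  )
  structure(
    list(
      result = result, sims = sims,
      params = list(
        seed_genes = seed_genes, n_sim = n_sim, batch_size = batch_size,
        seed = seed, estimator = estimator, nswap_factor = nswap_factor
      )
    ),
    class = "coseg_null"
  )
}

#' @method tidy coseg_null
#' @export
tidy.coseg_null <- function(x, ...) x$result

#' @method glance coseg_null
#' @export
glance.coseg_null <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$result),
    n_sim = x$params$n_sim,
    batch_size = x$params$batch_size,
    seed_genes = paste(x$params$seed_genes, collapse = ","),
    n_significant_0.01 = sum(x$result$p_raw < 0.01)
  )
}

#' @export
print.coseg_null <- function(x, ...) {
  cat(sprintf(
    "Network randomization null: %d node(s), %d simulation(s), seeds: %s\n",
    nrow(x$result), x$params$n_sim,
    paste(x$params$seed_genes, collapse = ", ")
  ))
  print(arrange(x$result, .data$p_raw))
  invisible(x)
}

#' @method autoplot coseg_null
#' @export
autoplot.coseg_null <- function(object, nodes = NULL, ...) {
  res <- arrange(object$result, .data$p_raw)
  nodes <- nodes %||% head(res$node, 6)
  sims <- object$sims[nodes, , drop = FALSE]
  df <- tibble(
    node = rep(nodes, each = ncol(sims)),
    statistic = as.vector(t(sims))
  ) |>
    filter(is.finite(.data$statistic))
  obs <- res[res$node %in% nodes, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(
      data = obs,
      ggplot2::aes(xintercept = .data$observed),
      colour = "red", linetype = 2
    ) +
    ggplot2::facet_wrap(~node, scales = "free") +
    ggplot2::labs(
      x = "Average shortest-path distance to seeds",
      y = "Null simulations"
    ) +
    ggplot2::theme_minimal()
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement; adjusted values are at least the raw values and the input
#' order is preserved.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    abort("`p` must be numeric p-values in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Nodes significant against the randomization null
#'
#' Nodes whose raw empirical p-value is strictly below `alpha` (default 0.01,
#' the call threshold for notably proximal genes).
#'
#' @param x A `coseg_null` object from [null_pvalues()].
#' @param alpha Significance threshold (strict `<`).
#' @return Character vector of node names.
#' @export
significant_nodes <- function(x, alpha = 0.01) {
  if (!inherits(x, "coseg_null")) abort("`x` must come from null_pvalues().")
  x$result$node[x$result$p_raw < alpha]
}
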