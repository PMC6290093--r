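#' Abundance filter for co-occurrence candidates
#'
#' Retains the OTUs entering the co-occurrence network: indicator OTUs whose
#' mean relative abundance across all samples exceeds `cutoff_indicator`
#' (default 0.02%) and normal OTUs above `cutoff_normal` (default 0.1%) —
#' the less abundant background is held to the stricter bar.
#'
#' @param table A rarefied `otu_table`.
#' @param scores [classify_indicators()] output covering all OTUs.
#' @param cutoff_indicator,cutoff_normal Mean relative-abundance cutoffs in
#'   percent (strict `>`).
#' @return Character vector of retained OTU ids.
#' @export
abundance_filter <- function(table, scores, cutoff_indicator = 0.02,
                             cutoff_normal = 0.1) {
  if (!all(rownames(table$counts) %in% scores$otu_id))
    stop("scores do not cover every OTU in the table")
  cat_of <- scores$category[match(rownames(table$counts), scores$otu_id)]
  mean_ra <- rowMeans(rel_abund(table, scale = 100))
  is_ind <- cat_of %in% c("LB_indicator", "UMB_indicator")
  keep <- (is_ind & mean_ra > cutoff_indicator) |
    (!is_ind & mean_ra > cutoff_normal)
  if (!any(keep))
    stop("no OTU passes the abundance cutoffs; review cutoff_indicator/cutoff_normal")
  rownames(table$counts)[keep]
}

#' Thresholded Spearman correlation edges
#'
#' Scores every unordered OTU pair by Spearman rank correlation (midranks for
#' ties) of per-sample relative abundances across all samples, with p-values
#' from the t-distribution approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` on `n - 2` df. Pairs are retained when
#' `|rho| > rho_min` and `p < p_max` (defaults: the strong-and-significant
#' rule `|rho| > 0.8`, `P < 0.01`). P-values are not multiplicity-corrected
#' by default; set `fdr = TRUE` for a Benjamini-Hochberg screen instead.
#'
#' @param table A rarefied `otu_table`.
#' @param otus OTU ids to correlate (e.g. [abundance_filter()] output);
#'   default all.
#' @param rho_min,p_max Retention thresholds.
#' @param fdr Apply Benjamini-Hochberg adjustment to the p-values before the
#'   `p_max` gate (default `FALSE`).
#' @return `data.frame` with columns `otu_a`, `otu_b`, `rho`, `p`, `sign`
#'   (`"positive"`/`"negative"`), one row per surviving unordered pair.
#' @export
spearman_edges <- function(table, otus = rownames(table$counts),
                           rho_min = 0.8, p_max = 0.01, fdr = FALSE) {
  n <- ncol(table$counts)
  if (n < 5) stop("need at least 5 samples for correlation screening")
  ra <- rel_abund(table)[otus, , drop = FALSE]
  novar <- apply(ra, 1, function(x) length(unique(x)) == 1)
  if (any(novar)) {
    warning(sprintf("skipping %d zero-variance OTU(s): %s", sum(novar),
                    paste(utils::head(otus[novar], 5), collapse = ", ")))
    ra <- ra[!novar, , drop = FALSE]
  }
  if (nrow(ra) < 2) stop("fewer than 2 variable OTUs; no pairs to score")
  ranks <- t(apply(ra, 1, rank))  # midranks
  R <- stats::cor(t(ranks))
  ut <- which(upper.tri(R), arr.ind = TRUE)
  rho <- R[ut]
  rho_c <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
  tval <- rho_c * sqrt((n - 2) / (1 - rho_c^2))
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  p[abs(rho) >= 1] <- 0
  if (fdr) p <- stats::p.adjust(p, method = "BH")
  keep <- abs(rho) > rho_min & p < p_max
  out <- data.frame(otu_a = rownames(ra)[ut[keep, 1]],
                    otu_b = rownames(ra)[ut[keep, 2]],
                    rho = rho[keep], p = p[keep],
                    sign = ifelse(rho[keep] > 0, "positive", "negative"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assemble the co-occurrence network
#'
#' Builds an undirected [igraph] graph from surviving correlation edges.
#' Nodes are exactly the OTUs incident to at least one edge (no isolated
#' nodes are injected), labelled with their indicator category and phylum;
#' edge weights are `|rho|`, with the sign kept as an attribute.
#'
#' @param edges [spearman_edges()] output (nonempty).
#' @param scores [classify_indicators()] output (for category labels).
#' @param phylum Optional named character vector of phylum per OTU id (see
#'   [otu_phylum()]); OTUs not covered get `"unclassified"`.
#' @return An `igraph` object with vertex attributes `category`, `phylum`
#'   and edge attributes `rho`, `p`, `sign`, `weight` (`= |rho|`).
#' @export
build_network <- function(edges, scores, phylum = NULL) {
  if (nrow(edges) == 0) stop("no surviving edges; the network is empty")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::E(g)$weight <- abs(igraph::E(g)$rho)
  ids <- igraph::V(g)$name
  igraph::V(g)$category <- scores$category[match(ids, scores$otu_id)]
  if (anyNA(igraph::V(g)$category))
    stop("scores do not cover every OTU incident to an edge")
  igraph::V(g)$phylum <- if (is.null(phylum)) LINEAGE_UNRESOLVED else {
    ph <- unname(phylum[ids])
    ph[is.na(ph)] <- LINEAGE_UNRESOLVED
    ph
  }
  g
}

#' Topology metrics of the co-occurrence network
#'
#' Reports node/edge counts, average weighted degree (sum of `|rho|` weights
#' over incident edges, averaged over nodes), unweighted diameter and average
#' path length over connected node pairs — both for the whole graph and for
#' the largest connected component — mean local clustering coefficient
#' (nodes of degree < 2 contribute 0) and the modularity of a greedy
#' modularity-maximising partition on `|rho|` weights (deterministic
#' agglomeration).
#'
#' @param network [build_network()] output.
#' @return Named list of metrics (`n_nodes`, `n_edges`,
#'   `avg_weighted_degree`, `diameter`, `avg_path_length`, `lcc_diameter`,
#'   `lcc_avg_path_length`, `clustering_coefficient`, `modularity`,
#'   `n_communities`).
#' @export
topology <- function(network) {
  if (igraph::vcount(network) == 0) stop("empty network")
  comp <- igraph::components(network)
  lcc <- igraph::induced_subgraph(network,
                                  which(comp$membership == which.max(comp$csize)))
  cl <- igraph::cluster_fast_greedy(network,
                                    weights = igraph::E(network)$weight)
  local_cc <- igraph::transitivity(network, type = "local", isolates = "zero")
  list(n_nodes = igraph::vcount(network),
       n_edges = igraph::ecount(network),
       avg_weighted_degree = sum(igraph::strength(network)) /
         igraph::vcount(network),
       diameter = igraph::diameter(network, weights = NA),
       avg_path_length = igraph::mean_distance(network, weights = NA),
       lcc_diameter = igraph::diameter(lcc, weights = NA),
       lcc_avg_path_length = igraph::mean_distance(lcc, weights = NA),
       clustering_coefficient = mean(local_cc),
       modularity = igraph::modularity(cl),
       n_communities = length(cl))
}

# Unordered label-pair key, alphabetical.
.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# All unordered pairs (including self-pairs) over a label set, alphabetical.
.all_pairs <- function(labels) {
  labels <- sort(unique(labels))
  idx <- which(upper.tri(diag(length(labels)), diag = TRUE), arr.ind = TRUE)
  data.frame(group_a = labels[idx[, 1]], group_b = labels[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Observed incidence of label pairs among network edges
#'
#' For each unordered pair of node labels `{A, B}` (indicator category or
#' phylum), the observed incidence `O%` is the percentage of edges whose two
#' endpoints carry those labels. Over all unordered pairs the incidences
#' close to 100%.
#'
#' @param network [build_network()] output.
#' @param labelling `"category"` or `"phylum"` — which vertex attribute to
#'   tabulate.
#' @return `data.frame` with columns `group_a`, `group_b`, `n_edges`,
#'   `o_pct`.
#' @export
observed_incidence <- function(network, labelling = c("category", "phylum")) {
  labelling <- match.arg(labelling)
  lab <- igraph::vertex_attr(network, labelling)
  if (is.null(lab) || anyNA(lab)) stop("every node must be labelled")
  ends <- igraph::as_edgelist(network, names = FALSE)
  key <- .pair_key(lab[ends[, 1]], lab[ends[, 2]])
  pairs <- .all_pairs(lab)
  pairs$n_edges <- as.integer(table(factor(key,
    levels = .pair_key(pairs$group_a, pairs$group_b))))
  pairs$o_pct <- 100 * pairs$n_edges / igraph::ecount(network)
  pairs
}

#' Incidence percentages from pre-tabulated edge counts
#'
#' The aggregation step of [observed_incidence()] exposed on its own: given
#' counts of edges per label pair and the total edge count, return each
#' pair's incidence percentage. Useful for auditing published incidence
#' tables.
#'
#' @param pair_edges Named numeric vector of edge counts per label pair.
#' @param n_edges_total Total number of edges in the network.
#' @return Named numeric vector of incidence percentages.
#' @export
incidence_from_counts <- function(pair_edges, n_edges_total) {
  if (any(pair_edges < 0) || n_edges_total <= 0)
    stop("edge counts must be non-negative with a positive total")
  if (sum(pair_edges) > n_edges_total)
    stop("pair edge counts exceed the total")
  100 * pair_edges / n_edges_total
}

#' Observed/random incidence ratio
#'
#' `O/R = o_pct / r_pct`, the non-randomness benchmark: values above 1 mean
#' the label pair co-occurs more often than expected under random label
#' assignment. Undefined (`NA`) when `r_pct` is 0.
#'
#' @param o_pct,r_pct Observed and random incidence percentages.
#' @return The ratio (vectorised).
#' @export
o_r_ratio <- function(o_pct, r_pct) {
  ifelse(r_pct > 0, o_pct / r_pct, NA_real_)
}

#' Random incidence of label pairs under label permutation
#'
#' Expected incidence `R%` of each unordered label pair when node labels are
#' assigned at random to the fixed topology (equivalently: the labels of the
#' two endpoints of a random edge are two distinct nodes drawn without
#' replacement). With `n` nodes of which `n_A` carry label A:
#' `R%(A,A) = 100 n_A (n_A - 1) / (n (n - 1))` and
#' `R%(A,B) = 100 * 2 n_A n_B / (n (n - 1))`.
#'
#' `method = "permutation"` estimates the same quantity by averaging the
#' observed incidence over `n_perm` seeded label shuffles
#' ([simulate_null_labels()]), and additionally reports the permutation
#' standard deviation and 97.5th percentile of each pair's incidence — the
#' null band against which an observed incidence can be judged.
#'
#' @inheritParams observed_incidence
#' @param method `"analytic"` (closed form) or `"permutation"`.
#' @param n_perm Number of label shuffles for the permutation estimate.
#' @param seed Integer seed for the shuffles.
#' @return `data.frame` with columns `group_a`, `group_b`, `r_pct` (plus
#'   `r_sd` and `r_q975` for the permutation method).
#' @export
random_incidence <- function(network, labelling = c("category", "phylum"),
                             method = c("analytic", "permutation"),
                             n_perm = 2000, seed = NULL) {
  labelling <- match.arg(labelling)
  method <- match.arg(method)
  lab <- igraph::vertex_attr(network, labelling)
  if (is.null(lab) || anyNA(lab)) stop("every node must be labelled")
  pairs <- .all_pairs(lab)
  n <- length(lab)
  cnt <- table(lab)
  if (method == "analytic") {
    na <- as.numeric(cnt[pairs$group_a]); nb <- as.numeric(cnt[pairs$group_b])
    same <- pairs$group_a == pairs$group_b
    pairs$r_pct <- ifelse(same,
                          100 * na * (na - 1) / (n * (n - 1)),
                          100 * 2 * na * nb / (n * (n - 1)))
    return(pairs)
  }
  if (!is.null(seed)) set.seed(seed)
  ends <- igraph::as_edgelist(network, names = FALSE)
  lev <- .pair_key(pairs$group_a, pairs$group_b)
  m <- igraph::ecount(network)
  acc <- matrix(0, nrow = n_perm, ncol = length(lev))
  for (b in seq_len(n_perm)) {
    pl <- sample(lab)
    key <- .pair_key(pl[ends[, 1]], pl[ends[, 2]])
    acc[b, ] <- 100 * as.integer(table(factor(key, levels = lev))) / m
  }
  pairs$r_pct <- colMeans(acc)
  pairs$r_sd <- apply(acc, 2, stats::sd)
  pairs$r_q975 <- apply(acc, 2, stats::quantile, probs = 0.975)
  pairs
}

#' Combined observed/random incidence table
#'
#' Joins [observed_incidence()] and [random_incidence()] and attaches the
#' O/R ratio per unordered label pair.
#'
#' @inheritParams random_incidence
#' @return `data.frame` with columns `group_a`, `group_b`, `n_edges`,
#'   `o_pct`, `r_pct` (and permutation columns when applicable), `o_r_ratio`.
#' @export
incidence <- function(network, labelling = c("category", "phylum"),
                      method = c("analytic", "permutation"),
                      n_perm = 2000, seed = NULL) {
  labelling <- match.arg(labelling)
  obs <- observed_incidence(network, labelling)
  ran <- random_incidence(network, labelling, method = method,
                          n_perm = n_perm, seed = seed)
  out <- merge(obs, ran, by = c("group_a", "group_b"), sort = TRUE)
  out$o_r_ratio <- o_r_ratio(out$o_pct, out$r_pct)
  out
}

#' Permutation test of combined intra-category co-occurrence
#'
#' The non-randomness check of the paper-style incidence analysis in one
#' number: the combined observed incidence of all same-label edges
#' (label pairs with `group_a == group_b`) compared against its distribution
#' under `n_perm` label shuffles on the fixed topology.
#'
#' @inheritParams random_incidence
#' @return List with `intra_o_pct` (observed), `intra_r_pct` (null mean),
#'   `o_r` (their ratio), `q975` (97.5th null percentile) and `p`
#'   (one-sided permutation p-value, `(k + 1)/(n_perm + 1)`).
#' @export
intra_incidence_test <- function(network, labelling = c("category", "phylum"),
                                 n_perm = 2000, seed = NULL) {
  labelling <- match.arg(labelling)
  lab <- igraph::vertex_attr(network, labelling)
  ends <- igraph::as_edgelist(network, names = FALSE)
  m <- igraph::ecount(network)
  obs <- 100 * sum(lab[ends[, 1]] == lab[ends[, 2]]) / m
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_perm), function(b) {
    pl <- sample(lab)
    100 * sum(pl[ends[, 1]] == pl[ends[, 2]]) / m
  }, numeric(1))
  list(intra_o_pct = obs, intra_r_pct = mean(null),
       o_r = obs / mean(null),
       q975 = unname(stats::quantile(null, 0.975)),
       p = (sum(null >= obs) + 1) / (n_perm + 1))
}

#' Permute node category labels on a fixed topology
#'
#' The label-shuffling null model behind the random incidence: node category
#' labels are permuted uniformly at random (category counts preserved), the
#' topology is untouched.
#'
#' @param network [build_network()] output.
#' @param seed Integer seed.
#' @return The network with permuted `category` vertex attribute.
#' @export
simulate_null_labels <- function(network, seed = NULL) {
  if (igraph::vcount(network) == 0) stop("empty network")
  if (!is.null(seed)) set.seed(seed)
  igraph::V(network)$category <- sample(igraph::V(network)$category)
  network
}

#' Export / import the network edge list
#'
#' Writes the network's edges as a TSV (`otu_a`, `otu_b`, `rho`, `p`,
#' `sign`); `read_edge_list` reads it back into the [spearman_edges()] form.
#'
#' @param network [build_network()] output.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(network, path) {
  el <- igraph::as_edgelist(network)
  df <- data.frame(otu_a = el[, 1], otu_b = el[, 2],
                   rho = igraph::E(network)$rho, p = igraph::E(network)$p,
                   sign = igraph::E(network)$sign, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
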