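fake_scores <- function(ids, category = "normal") {
  data.frame(otu_id = ids, kw_p = 0.5, lda_score = 0,
             enriched_fraction = "LB", category = category,
             stringsAsFactors = FALSE)
}

edges_df <- function(a, b, rho = 1) {
  data.frame(otu_a = a, otu_b = b, rho = rho, p = 0,
             sign = ifelse(rho > 0, "positive", "negative"),
             stringsAsFactors = FALSE)
}

test_that("abundance cutoffs are category-specific and strict", {
  # mean relative abundances: A 0.03%, B 0.05%, C 0.2%, D the rest
  counts <- matrix(c(30, 50, 200, 99720), ncol = 1,
                   dimnames = list(c("A", "B", "C", "D"), "S1"))
  counts <- cbind(counts, counts)
  colnames(counts) <- c("S1", "S2")
  meta <- data.frame(sample_id = c("S1", "S2"), batch = "DWTP1", unit = "RW",
                     fraction = c("LB", "UMB"))
  tab <- otu_table(counts, meta, rarefied_depth = 100000)
  scores <- fake_scores(c("A", "B", "C", "D"),
                        c("LB_indicator", "normal", "normal", "normal"))
  kept <- abundance_filter(tab, scores)
  expect_true("A" %in% kept)    # indicator above 0.02%
  expect_false("B" %in% kept)   # normal below 0.1%
  expect_true(all(c("C", "D") %in% kept))
  expect_setequal(abundance_filter(tab, scores, 0, 0),
                  c("A", "B", "C", "D"))
  expect_error(abundance_filter(tab, scores, 100, 100), "cutoff")
})

test_that("Spearman screening matches the midrank formula and keeps monotone pairs", {
  # constant column totals keep the relative abundances proportional to the
  # raw counts, so rank structure is designed in directly
  n <- 10
  counts <- rbind(up = 1:10, down = 10:1, flat = rep(50, 10),
                  filler = rep(139, 10))
  colnames(counts) <- paste0("S", 1:n)
  meta <- data.frame(sample_id = colnames(counts),
                     batch = paste0("DWTP", rep(1:5, each = 2)),
                     unit = rep(UNITS_DEFAULT[1:5], 2),
                     fraction = rep(c("LB", "UMB"), 5))
  tab <- otu_table(counts, meta, rarefied_depth = 200)
  expect_warning(ed <- spearman_edges(tab, rho_min = 0.8, p_max = 0.01),
                 "zero-variance")
  mono <- ed[ed$otu_a == "up" & ed$otu_b == "down", ]
  expect_equal(mono$rho, -1)
  expect_equal(mono$p, 0)
  expect_identical(mono$sign, "negative")

  # hand-checked midrank value on a tied pair
  counts2 <- rbind(x = c(1, 2, 3, 4, 5), y = c(5, 6, 7, 8, 7),
                   filler = c(14, 12, 10, 8, 8))
  colnames(counts2) <- paste0("S", 1:5)
  meta2 <- data.frame(sample_id = colnames(counts2),
                      batch = "DWTP1", unit = UNITS_DEFAULT,
                      fraction = "LB")
  tab2 <- otu_table(counts2, meta2, rarefied_depth = 20)
  ed2 <- spearman_edges(tab2, rho_min = 0.5, p_max = 1.1)
  xy <- ed2[ed2$otu_a == "x" & ed2$otu_b == "y", ]
  expect_equal(xy$rho, 0.8207827, tolerance = 1e-6)
})

test_that("under independence the strong-and-significant rule rarely fires", {
  set.seed(8)
  hits <- 0; trials <- 400
  n <- 10
  for (i in seq_len(trials)) {
    x <- rank(rnorm(n)); y <- rank(rnorm(n))
    r <- cor(x, y)
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(abs(t), n - 2, lower.tail = FALSE)
    if (abs(r) > 0.8 && p < 0.01) hits <- hits + 1
  }
  # the joint rule is stricter than P < 0.01 alone
  expect_lte(hits / trials, 0.01 + 3 * sqrt(0.01 * 0.99 / trials))
})

test_that("network construction keeps only incident nodes and round-trips its edge list", {
  ed <- edges_df(c("a", "b"), c("b", "c"), rho = c(0.9, -0.85))
  net <- build_network(ed, fake_scores(c("a", "b", "c", "zzz")))
  expect_equal(igraph::vcount(net), 3)  # zzz never appears
  expect_equal(igraph::ecount(net), 2)
  expect_equal(sort(igraph::E(net)$weight), c(0.85, 0.9))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, path)
  back <- read_edge_list(path)
  net2 <- build_network(back, fake_scores(c("a", "b", "c")))
  expect_identical(igraph::as_edgelist(net2), igraph::as_edgelist(net))
  expect_equal(igraph::E(net2)$rho, igraph::E(net)$rho)
  expect_error(build_network(ed[0, ], fake_scores("a")), "empty")
})

test_that("topology metrics reproduce closed forms on canonical graphs", {
  tri <- build_network(edges_df(c("a", "b", "c"), c("b", "c", "a")),
                       fake_scores(c("a", "b", "c")))
  tt <- topology(tri)
  expect_equal(tt$clustering_coefficient, 1)
  expect_equal(tt$diameter, 1)
  expect_equal(tt$avg_path_length, 1)
  expect_equal(tt$avg_weighted_degree, 2)  # two unit-weight edges per node

  path <- build_network(edges_df(c("a", "b"), c("b", "c")),
                        fake_scores(c("a", "b", "c")))
  tp <- topology(path)
  expect_equal(tp$avg_path_length, 4 / 3)
  expect_equal(tp$clustering_coefficient, 0)
  expect_equal(tp$diameter, 2)

  cliques <- build_network(edges_df(c("a", "b", "c", "d", "e", "f"),
                                    c("b", "c", "a", "e", "f", "d")),
                           fake_scores(letters[1:6]))
  tc <- topology(cliques)
  expect_equal(tc$modularity, 0.5)
  expect_equal(tc$n_communities, 2)
  expect_equal(tc$lcc_diameter, 1)
})

test_that("observed incidence counts label pairs and closes to 100%", {
  # 4 edges: a-b, a-c, b-c within label X except c carries Y
  ed <- edges_df(c("a", "a", "b", "c"), c("b", "c", "c", "d"))
  net <- build_network(ed, fake_scores(c("a", "b", "c", "d"),
                                       c("X", "X", "Y", "Y")))
  obs <- observed_incidence(net, "category")
  expect_equal(sum(obs$o_pct), 100)
  expect_equal(obs$o_pct[obs$group_a == "X" & obs$group_b == "X"], 25)
  expect_equal(obs$o_pct[obs$group_a == "X" & obs$group_b == "Y"], 50)
  expect_equal(obs$o_pct[obs$group_a == "Y" & obs$group_b == "Y"], 25)

  mono <- build_network(ed, fake_scores(c("a", "b", "c", "d"), "Z"))
  obs_mono <- observed_incidence(mono, "category")
  expect_equal(obs_mono$o_pct, 100)
})

test_that("analytic random incidence matches the permutation estimate and closes to 100%", {
  set.seed(2)
  g <- igraph::sample_gnm(40, 60)
  igraph::V(g)$name <- paste0("o", 1:40)
  igraph::V(g)$category <- sample(c("X", "Y", "Z"), 40, replace = TRUE)
  ana <- random_incidence(g, "category", method = "analytic")
  per <- random_incidence(g, "category", method = "permutation",
                          n_perm = 2000, seed = 3)
  expect_equal(sum(ana$r_pct), 100, tolerance = 1e-9)
  expect_equal(sum(per$r_pct), 100, tolerance = 1e-9)
  se <- per$r_sd / sqrt(2000)
  expect_true(all(abs(ana$r_pct - per$r_pct) <= 3 * se + 1e-8))

  # degenerate single-label network: R% = 100 and O/R = 1
  mono <- g
  igraph::V(mono)$category <- "Z"
  inc <- incidence(mono, "category")
  expect_equal(inc$r_pct, 100)
  expect_equal(inc$o_r_ratio, 1)
})

test_that("O/R ratio handles zero random incidence", {
  expect_equal(o_r_ratio(36.4, 37.9), 0.96, tolerance = 5e-3)
  expect_true(is.na(o_r_ratio(10, 0)))
})

test_that("planted same-category blocks co-occur beyond the permutation null", {
  sim <- default_sim()
  scores <- default_scores()
  kept <- abundance_filter(sim$table, scores)
  net <- build_network(spearman_edges(sim$table, kept), scores,
                       otu_phylum(sim$table))
  res <- intra_incidence_test(net, "category", n_perm = 1000, seed = 6)
  expect_gt(res$o_r, 1)
  expect_gt(res$intra_o_pct, res$q975)
  expect_lt(res$p, 0.025)
})
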