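test_that("Kruskal-Wallis wrapper keeps the tie convention and the chi-square approximation", {
  # all values tied across both classes: H = 0, p = 1 by convention
  expect_equal(kruskal_wallis(rep(2, 6), rep(c("LB", "UMB"), 3)),
               list(h = 0, p = 1))
  # on untied data it is exactly the standard test
  set.seed(1)
  x <- rnorm(12); g <- rep(c("LB", "UMB"), 6)
  ref <- kruskal.test(x, factor(g))
  kw <- kruskal_wallis(x, g)
  expect_equal(kw$p, ref$p.value)
  expect_equal(kw$h, unname(ref$statistic))
  # fully separated tiny groups: chi-square p sits near the exact
  # rank-permutation p (2 of 20 assignments are as extreme)
  kw2 <- kruskal_wallis(c(1, 2, 3, 10, 11, 12), rep(c("A", "B"), each = 3))
  expect_lt(abs(kw2$p - 0.1), 0.06)
  expect_error(kruskal_wallis(1:4, rep("A", 4)), "both classes")
})

test_that("effect-size score separates planted gaps and scales as log10", {
  cls <- rep(c("LB", "UMB"), each = 10)
  # identical class distributions: score stays far below the indicator gate
  flat <- rep(c(100, 110), 10)
  expect_lt(lda_effect_size(flat, cls, seed = 1), 2)
  # one class at 1e5 on the per-million scale, the other at zero
  strong <- c(rep(1e5, 10), rep(0, 10))
  expect_gte(lda_effect_size(strong, cls, seed = 1), 4)
  # a tenfold larger class gap raises the score by about one unit
  base <- c(rep(2e4, 10), rep(1e4, 10))
  s1 <- lda_effect_size(base, cls, seed = 1)
  s2 <- lda_effect_size(base * 10, cls, seed = 1)
  expect_equal(s2 - s1, 1, tolerance = 0.05)
})

test_that("effect-size score ignores sample order", {
  set.seed(42)
  x <- c(rnorm(10, 500), rnorm(10, 100))
  cls <- rep(c("LB", "UMB"), each = 10)
  s_ref <- lda_effect_size(x, cls, seed = 5)
  perm <- sample(20)
  expect_equal(lda_effect_size(x[perm], cls[perm], seed = 5), s_ref)
})

test_that("classification applies both gates and never grows with a stricter LDA cut", {
  sim <- default_sim()
  scores <- default_scores()
  expect_setequal(scores$otu_id, rownames(sim$table$counts))
  ind <- scores$category != "normal"
  expect_true(all(scores$kw_p[ind] < 0.05 & scores$lda_score[ind] > 2))
  expect_true(all(scores$kw_p[!ind] >= 0.05 | scores$lda_score[!ind] <= 2))
  expect_true(all(scores$category[ind] ==
                    paste0(scores$enriched_fraction[ind], "_indicator")))
  strict <- classify_indicators(sim$table, lda_min = 3, seed = 11)
  expect_lte(sum(strict$category != "normal"), sum(ind))

  lb_only <- subset_otu_table(sim$table,
    samples = sim$table$samples$sample_id[sim$table$samples$fraction == "LB"])
  expect_error(classify_indicators(lb_only), "both fractions")
})

test_that("classification scores do not depend on OTU order", {
  sim <- simulate_dataset(small_config(seed = 12))
  s1 <- classify_indicators(sim$table, seed = 3)
  shuffled <- subset_otu_table(sim$table,
                               otus = rev(rownames(sim$table$counts)))
  attr(shuffled, "rarefied_depth") <- attr(sim$table, "rarefied_depth")
  s2 <- suppressWarnings(classify_indicators(shuffled, seed = 3))
  m <- match(s1$otu_id, s2$otu_id)
  expect_equal(s1$lda_score, s2$lda_score[m])
  expect_equal(s1$kw_p, s2$kw_p[m])
})

test_that("planted indicators are recovered at the standard thresholds", {
  rec <- indicator_recovery(default_sim()$truth, default_scores())
  expect_gte(rec$recall, 0.8)
  expect_lte(rec$fpr, 0.05)
})

test_that("category trajectories close to 100% per sample and match hand arithmetic", {
  counts <- matrix(c(30, 70,
                     10, 90,
                     50, 50,
                     20, 80), nrow = 2,
                   dimnames = list(c("A", "B"), c("S1", "S2", "S3", "S4")))
  meta <- data.frame(sample_id = paste0("S", 1:4),
                     batch = rep(c("DWTP1", "DWTP2"), 2),
                     unit = rep(c("RW", "CW"), each = 2),
                     fraction = "LB", stringsAsFactors = FALSE)
  tab <- otu_table(counts, meta, rarefied_depth = 100)
  scores <- data.frame(otu_id = c("A", "B"), kw_p = c(0.01, 0.5),
                       lda_score = c(3, 0), enriched_fraction = c("LB", "LB"),
                       category = c("LB_indicator", "normal"))
  fate <- fate_trajectories(tab, scores)
  sums <- rowSums(fate$per_sample[, c("LB_indicator", "UMB_indicator",
                                      "normal")])
  expect_equal(unname(sums), rep(100, 4))
  # RW cell averages samples S1 (30%) and S2 (10%) for the indicator OTU
  rw <- fate$trajectories
  got <- rw$mean_rel_abund_pct[rw$unit == "RW" &
                                 rw$category == "LB_indicator"]
  expect_equal(got, 20)
  cw <- rw$mean_rel_abund_pct[rw$unit == "CW" &
                                rw$category == "LB_indicator"]
  expect_equal(cw, 35)
  # ARA averages the category share over all four samples
  expect_equal(unname(fate$ara["LB_indicator"]), mean(c(30, 10, 50, 20)))

  all_normal <- scores
  all_normal$category <- "normal"
  fate0 <- fate_trajectories(tab, all_normal)
  expect_true(all(fate0$trajectories$mean_rel_abund_pct[
    fate0$trajectories$category != "normal"] == 0))
  expect_equal(unname(fate0$ara["normal"]), 100)
})
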