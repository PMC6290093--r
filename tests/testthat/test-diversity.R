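make_two_otu_table <- function(counts_by_sample) {
  counts <- do.call(cbind, counts_by_sample)
  dimnames(counts) <- list(paste0("OTU", seq_len(nrow(counts))),
                           paste0("S", seq_along(counts_by_sample)))
  meta <- data.frame(sample_id = colnames(counts),
                     batch = paste0("DWTP", seq_along(counts_by_sample)),
                     unit = "RW",
                     fraction = rep(c("LB", "UMB"),
                                    length.out = ncol(counts)),
                     stringsAsFactors = FALSE)
  otu_table(counts, meta)
}

test_that("rarefaction conserves depth, keeps exact-depth samples, drops shallow ones", {
  tab <- make_two_otu_table(list(c(900, 800), c(50, 50), c(30, 10)))
  expect_warning(out <- rarefy(tab, depth = 100, seed = 1), "S3")
  expect_true(all(colSums(out$counts) == 100))
  expect_equal(ncol(out$counts), 2)
  # the sample at exactly the depth is passed through unchanged
  expect_identical(out$counts[, "S2"], tab$counts[, "S2"])
  expect_error(rarefy(tab, depth = 0), "positive")
  # seeded determinism
  r1 <- suppressWarnings(rarefy(tab, depth = 100, seed = 9))
  r2 <- suppressWarnings(rarefy(tab, depth = 100, seed = 9))
  expect_identical(r1$counts, r2$counts)
})

test_that("rarefied counts match the hypergeometric expectation", {
  tab <- make_two_otu_table(list(c(9000, 8000)))
  draws <- vapply(1:300, function(s)
    rarefy(tab, depth = 1700, seed = s)$counts[1, 1], numeric(1))
  # subsampling 1700 of 17000 reads of which 9000 are OTU1: mean 900,
  # hypergeometric sd about 19.5, so 300 draws pin the mean within ~4
  expect_lt(abs(mean(draws) - 900), 4)
})

test_that("alpha diversity reproduces closed forms", {
  tab <- make_two_otu_table(list(c(10, 10, 10, 10), c(100, 0, 0, 0),
                                 c(5, 3, 2, 0)))
  ad <- suppressWarnings(alpha_diversity(tab))
  expect_equal(ad$shannon[1], log(4))
  expect_equal(ad$richness[1], 4L)
  expect_equal(ad$shannon[2], 0)
  expect_equal(ad$richness[2], 1L)
  expect_equal(ad$shannon[3], 1.029653, tolerance = 1e-6)
  expect_true(all(ad$shannon <= log(ad$richness) + 1e-12))
})

test_that("Good's coverage counts per-sample singletons", {
  counts <- matrix(c(94, 1, 1, 1, 3), ncol = 1,
                   dimnames = list(paste0("OTU", 1:5), "S1"))
  meta <- data.frame(sample_id = "S1", batch = "DWTP1", unit = "RW",
                     fraction = "LB")
  ad <- suppressWarnings(alpha_diversity(otu_table(counts, meta)))
  expect_equal(ad$goods_coverage, 1 - 3 / 100)
})

test_that("Shannon increases when a count is split into two even parts", {
  for (s in 1:10) {
    set.seed(s)
    x <- rpois(6, 20) + 1
    x[1] <- 2 * x[1]  # make the split even
    split <- c(x[1] / 2, x[1] / 2, x[-1])
    h <- function(v) { p <- v / sum(v); -sum(p * log(p)) }
    expect_gt(h(split), h(x))
  }
})

test_that("Bray-Curtis matches hand arithmetic and stays a bounded symmetric matrix", {
  tab <- make_two_otu_table(list(c(1, 1, 0), c(0, 1, 1), c(1, 1, 0),
                                 c(2, 0, 0)))
  d <- bray_curtis(tab)
  expect_equal(d["S1", "S2"], 0.5)
  expect_equal(d["S1", "S3"], 0)      # identical samples
  expect_equal(d["S2", "S4"], 1)      # disjoint supports
  expect_identical(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("PERMANOVA pseudo-F agrees with the brute-force partition and enumeration", {
  pts <- matrix(c(0, 0, 0.3, 0.1, 5, 5, 5.2, 4.9), ncol = 2, byrow = TRUE)
  dm <- as.matrix(dist(pts))
  ids <- paste0("S", 1:4)
  dimnames(dm) <- list(ids, ids)
  meta <- data.frame(sample_id = ids, g = c("a", "a", "b", "b"))
  res <- permanova(dm, meta, formula = ~ g, n_perm = 999, seed = 1)
  f_obs <- res$f[res$term == "g"]
  expect_equal(f_obs, brute_pseudo_f(dm, meta$g), tolerance = 1e-8)

  # exhaustive enumeration over all 4! label orders gives the exact p
  perms <- do.call(rbind, combinat_perms(4))
  fs <- apply(perms, 1, function(ix) brute_pseudo_f(dm, meta$g[ix]))
  p_exact <- mean(fs >= f_obs - 1e-12)
  expect_equal(res$p[res$term == "g"], p_exact, tolerance = 1e-8)
})

test_that("PERMANOVA R2 components including the residual sum to one", {
  sim <- default_sim()
  dm <- bray_curtis(sim$table)
  res <- permanova(dm, sim$table$samples, n_perm = 199, seed = 4)
  r2 <- res$r2[res$term != "Total"]
  expect_equal(sum(r2), 1, tolerance = 1e-9)
  expect_true(all(r2 >= 0))
  # the fraction split dominates and is significant
  expect_lt(res$p[res$term == "fraction"], 0.05)
})

test_that("single-level factors are flagged as confounded", {
  sim <- simulate_dataset(small_config(seed = 3))
  dm <- bray_curtis(sim$table)
  meta <- sim$table$samples
  meta$const <- "x"
  expect_warning(permanova(dm, meta, formula = ~ fraction + const,
                           n_perm = 99, seed = 1), "confounded")
})
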