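# Handwritten 3-OTU x 4-sample table with both fractions and taxonomy.
tiny_table <- function() {
  counts <- matrix(c(10, 5, 0,
                     8, 0, 2,
                     0, 7, 3,
                     1, 1, 1),
                   nrow = 3, ncol = 4,
                   dimnames = list(c("OTU1", "OTU2", "OTU3"),
                                   c("S1", "S2", "S3", "S4")))
  meta <- data.frame(sample_id = c("S1", "S2", "S3", "S4"),
                     batch = c("DWTP1", "DWTP1", "DWTP2", "DWTP2"),
                     unit = c("RW", "RW", "RW", "RW"),
                     fraction = c("LB", "UMB", "LB", "UMB"),
                     stringsAsFactors = FALSE)
  tax <- data.frame(otu_id = c("OTU1", "OTU2", "OTU3"),
                    lineage = c("Bacteria;Proteobacteria;unclassified",
                                "Bacteria;Bacteroidetes;unclassified",
                                "Bacteria;Proteobacteria;unclassified"),
                    stringsAsFactors = FALSE)
  otu_table(counts, meta, taxonomy = tax)
}

# Random table with balanced LB/UMB samples, for property-style loops.
rand_table <- function(n_otu = 20, n_samp = 8, seed = 1, lambda = 5) {
  set.seed(seed)
  counts <- matrix(rpois(n_otu * n_samp, lambda), nrow = n_otu,
                   dimnames = list(sprintf("OTU%03d", seq_len(n_otu)),
                                   sprintf("S%02d", seq_len(n_samp))))
  frac <- rep(c("LB", "UMB"), length.out = n_samp)
  meta <- data.frame(sample_id = colnames(counts),
                     batch = paste0("DWTP", rep(seq_len(ceiling(n_samp / 2)),
                                                each = 2)[seq_len(n_samp)]),
                     unit = "RW", fraction = frac, stringsAsFactors = FALSE)
  otu_table(counts, meta)
}

# Reduced-scale simulator config for fast tests.
small_config <- function(...) {
  sim_config(n_otus = 150, depth = 3000, n_corr_blocks = 2, block_size = 4,
             ...)
}

# The default-condition simulation, cached across test files.
.sim_cache <- new.env(parent = emptyenv())
default_sim <- function() {
  if (is.null(.sim_cache$sim))
    .sim_cache$sim <- simulate_dataset(sim_config(seed = 7))
  .sim_cache$sim
}
default_scores <- function() {
  if (is.null(.sim_cache$scores))
    .sim_cache$scores <- classify_indicators(default_sim()$table, seed = 11)
  .sim_cache$scores
}

# All permutations of 1..n, for exhaustive-enumeration oracles.
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i)
    lapply(combinat_perms(n - 1), function(p) c(i, (seq_len(n)[-i])[p]))))
}

# Independent PERMANOVA oracle: one-factor pseudo-F computed directly from
# the squared-dissimilarity partition (no Gower projection machinery).
brute_pseudo_f <- function(dm, groups) {
  n <- nrow(dm)
  a <- length(unique(groups))
  ss_total <- sum(dm[upper.tri(dm)]^2) / n
  ss_within <- sum(vapply(unique(groups), function(g) {
    i <- which(groups == g)
    sub <- dm[i, i, drop = FALSE]
    sum(sub[upper.tri(sub)]^2) / length(i)
  }, numeric(1)))
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}
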