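PHYLUM_POOL <- c(Proteobacteria = 0.45, Planctomycetes = 0.08,
                 Bacteroidetes = 0.08, Actinobacteria = 0.07,
                 Cyanobacteria = 0.05, Firmicutes = 0.05,
                 `Deinococcus-Thermus` = 0.04, Acidobacteria = 0.04,
                 Verrucomicrobia = 0.04, Parcubacteria = 0.05,
                 Saccharibacteria = 0.03, Chloroflexi = 0.02)

#' Configuration for the paired-fraction community simulator
#'
#' Defines the study conditions the generator emulates: 3 sampling batches
#' (DWTP1-3) x 5 treatment units (RW, FS, RSF, BAC, CW) x 2 size fractions,
#' with the (DWTP2, BAC) pair absent — 28 samples — sequenced to a common
#' depth of 17,000 reads. Planted structure: fraction-specific indicator
#' OTUs with a configurable fold change, correlated OTU blocks sharing a
#' latent factor, a fraction-level support restriction that lowers UMB
#' richness, and flow-cytometry density profiles that decline along the
#' treatment train except for a rebound at the biologically active carbon
#' unit, with a rising UMB proportion.
#'
#' @param n_otus Number of OTUs (default 600).
#' @param n_batches Sampling batches, named `DWTP1..k` (default 3).
#' @param units Ordered treatment units (default RW, FS, RSF, BAC, CW).
#' @param depth Reads per sample (default 17000); column sums equal it
#'   exactly.
#' @param frac_lb_indicators,frac_umb_indicators Proportion of OTUs planted
#'   as LB / UMB indicators (defaults 0.075 and 0.025, echoing the roughly
#'   3:1 imbalance seen in fraction-indicator surveys).
#' @param effect_size Fold change of an indicator between fractions (default
#'   8), applied symmetrically on the log scale (`+log(es)/2` in the
#'   enriched, `-log(es)/2` in the depleted fraction) so planted signal
#'   barely perturbs the rest of the composition.
#' @param indicator_band Expected relative-abundance band (proportions) from
#'   which indicator OTUs are drawn (default 2e-4 to 1e-3, i.e. 0.02-0.1%):
#'   detectable minority taxa.
#' @param effect_sd Per-sample sd of each indicator OTU's log enrichment
#'   (default 1): fraction preference is a noisy ecological response, not a
#'   uniform shift, so planted indicators are enriched on average without
#'   being mutually collinear (a deterministic shift would wire every
#'   indicator pair into the co-occurrence network at the correlation
#'   threshold, which real surveys do not show).
#' @param n_corr_blocks,block_size Planted co-occurring blocks (default 4
#'   blocks of 5 OTUs). Blocks are assigned whole to one indicator category,
#'   cycling LB indicator, UMB indicator, normal, normal.
#' @param block_rho Target pairwise latent correlation within a block
#'   (default 0.95). Block OTUs replace their idiosyncratic log-noise with
#'   `sqrt(block_rho) * block_sd * f_block + sqrt(1 - block_rho) * block_sd * z`,
#'   which plants exactly this correlation at a bounded total noise scale.
#' @param block_sd Total log-noise sd of block OTUs (default 0.7; modest, so
#'   a large shared-factor draw cannot make one block dominate a sample and
#'   distort the rest of the composition).
#' @param block_abund Relative-abundance band (percent) block OTUs are
#'   boosted into (default 0.15-0.4%), keeping them above the network
#'   abundance cutoffs.
#' @param noise_dispersion Per-sample log-normal overdispersion sd (default
#'   0.5).
#' @param baseline_sd Across-OTU log-abundance sd (default 2; a heavy-tailed
#'   community dominated by few taxa, as real amplicon surveys are).
#' @param rare_support_threshold,rare_support_drop The UMB support
#'   restriction: among OTUs with expected relative abundance below the
#'   threshold (default 5e-5) and carrying no planted structure, this
#'   fraction (default 0.5) is removed from the UMB support entirely, so UMB
#'   richness sits below LB richness in expectation without creating
#'   indicator-scale abundance signal.
#' @param density_start Raw-water total cell density, cells/mL (default 1e5).
#' @param density_decay Per-unit multiplicative density decline (default
#'   0.45).
#' @param bac_rebound Multiplicative density recovery at the BAC unit
#'   (default 3).
#' @param umb_pct_trend UMB% targets at the first and last unit (default
#'   3 to 15), interpolated linearly and kept non-decreasing.
#' @param drop_missing_bac Omit the (DWTP2, BAC) sample pair (default
#'   `TRUE`).
#' @param seed Integer seed; fixes the full output bit-for-bit. All
#'   randomness flows from this one seed through a single sequential stream
#'   (OTU baselines, planted structure, then samples in grid order, then
#'   taxonomy, then densities).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_otus = 600, n_batches = 3, units = UNITS_DEFAULT,
                       depth = 17000,
                       frac_lb_indicators = 0.075,
                       frac_umb_indicators = 0.025,
                       effect_size = 8, effect_sd = 1,
                       indicator_band = c(2e-4, 1e-3),
                       n_corr_blocks = 4, block_size = 5, block_rho = 0.95,
                       block_sd = 0.7, block_abund = c(0.15, 0.4),
                       noise_dispersion = 0.5, baseline_sd = 2,
                       rare_support_threshold = 5e-5,
                       rare_support_drop = 0.5,
                       density_start = 1e5, density_decay = 0.45,
                       bac_rebound = 3, umb_pct_trend = c(3, 15),
                       drop_missing_bac = TRUE, seed = 1) {
  cfg <- as.list(environment())
  props <- c(frac_lb_indicators, frac_umb_indicators, rare_support_drop)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (depth <= 0) stop("depth must be positive")
  if (block_size < 2) stop("block_size must be at least 2")
  if (block_rho <= 0 || block_rho >= 1) stop("block_rho must lie in (0, 1)")
  if (n_corr_blocks * block_size > n_otus)
    stop("infeasible config: n_corr_blocks * block_size exceeds n_otus")
  if (effect_size < 1) stop("effect_size is a fold change >= 1")
  structure(cfg, class = "sim_config")
}

#' Simulate a paired size-fractionated dataset with planted ground truth
#'
#' Draws latent log-abundances per sample from a common heavy-tailed
#' baseline, adds the planted fraction effects and shared block factors,
#' restricts the UMB support, and samples counts by multinomial draws of
#' `depth` reads per sample (log-normal latent noise provides the
#' overdispersion). Flow-cytometry densities follow the configured
#' decline/rebound profile with the UMB proportion interpolating its trend.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_dataset` with elements `table` (a rarefied
#'   [otu_table()] — every column sums to `depth`), `fcm` (derived density
#'   table, see [fcm_measurements()]), `truth` (`data.frame` with `otu_id`,
#'   `class`, `block`) and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_otus
  ids <- sprintf("OTU%04d", seq_len(n))

  base <- stats::rnorm(n, 0, config$baseline_sd)
  e_rel <- exp(base) / sum(exp(base))  # expected baseline relative abundance

  # planted indicators: detectable minority taxa
  band <- e_rel >= config$indicator_band[1] & e_rel <= config$indicator_band[2]
  n_lb <- round(config$frac_lb_indicators * n)
  n_umb <- round(config$frac_umb_indicators * n)
  pool <- which(band)
  if (length(pool) < n_lb + n_umb) {
    # top up from nearest-abundance OTUs when the band is too sparse
    extra <- order(abs(log(e_rel) - mean(log(config$indicator_band))))
    pool <- union(pool, setdiff(extra, pool))[seq_len(n_lb + n_umb)]
  }
  picked <- sample(pool, n_lb + n_umb)
  lb_ind <- picked[seq_len(n_lb)]
  umb_ind <- picked[n_lb + seq_len(n_umb)]
  cls <- rep("normal", n)
  cls[lb_ind] <- "LB_indicator"
  cls[umb_ind] <- "UMB_indicator"

  # planted co-occurrence blocks, each wholly inside one category
  block_of <- rep(NA_integer_, n)
  block_cat <- rep(c("LB_indicator", "UMB_indicator", "normal"),
                   length.out = config$n_corr_blocks)
  Z <- sum(exp(base))
  for (b in seq_len(config$n_corr_blocks)) {
    avail <- which(cls == block_cat[b] & is.na(block_of))
    if (length(avail) < config$block_size) {
      block_cat[b] <- "normal"
      avail <- which(cls == "normal" & is.na(block_of))
    }
    members <- sample(avail, config$block_size)
    block_of[members] <- b
    target <- stats::runif(config$block_size, config$block_abund[1],
                           config$block_abund[2]) / 100
    base[members] <- log(target * Z)
  }

  # UMB support restriction: drop unstructured ultra-rare OTUs
  rare_pool <- which(e_rel < config$rare_support_threshold &
                       cls == "normal" & is.na(block_of))
  dropped <- sample(rare_pool,
                    round(config$rare_support_drop * length(rare_pool)))

  # sample grid
  batches <- paste0("DWTP", seq_len(config$n_batches))
  grid <- expand.grid(fraction = FRACTIONS, unit = config$units,
                      batch = batches, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$batch, batches),
                     match(grid$unit, config$units),
                     match(grid$fraction, FRACTIONS)), ]
  if (config$drop_missing_bac && config$n_batches >= 2 &&
      "BAC" %in% config$units)
    grid <- grid[!(grid$batch == "DWTP2" & grid$unit == "BAC"), ]
  grid$sample_id <- paste(grid$batch, grid$unit, grid$fraction, sep = "_")
  rownames(grid) <- NULL

  half <- log(config$effect_size) / 2
  counts <- matrix(0L, nrow = n, ncol = nrow(grid),
                   dimnames = list(ids, grid$sample_id))
  in_block <- !is.na(block_of)
  for (j in seq_len(nrow(grid))) {
    f <- stats::rnorm(config$n_corr_blocks)
    eps <- stats::rnorm(n, 0, config$noise_dispersion)
    eta <- base + eps
    # heterogeneous per-sample response of indicator OTUs
    ind_all <- c(lb_ind, umb_ind)
    eta[ind_all] <- eta[ind_all] +
      stats::rnorm(length(ind_all), 0, config$effect_sd)
    if (grid$fraction[j] == "LB") {
      eta[lb_ind] <- eta[lb_ind] + half
      eta[umb_ind] <- eta[umb_ind] - half
    } else {
      eta[lb_ind] <- eta[lb_ind] - half
      eta[umb_ind] <- eta[umb_ind] + half
    }
    # block OTUs swap their idiosyncratic noise for a correlated mix of the
    # shared block factor and a private term at the same total scale
    z <- stats::rnorm(n)
    eta[in_block] <- base[in_block] +
      (if (grid$fraction[j] == "LB") half else -half) *
        (block_cat[block_of[in_block]] == "LB_indicator") +
      (if (grid$fraction[j] == "UMB") half else -half) *
        (block_cat[block_of[in_block]] == "UMB_indicator") +
      sqrt(config$block_rho) * config$block_sd * f[block_of[in_block]] +
      sqrt(1 - config$block_rho) * config$block_sd * z[in_block]
    if (grid$fraction[j] == "UMB") eta[dropped] <- -Inf
    p <- exp(eta - max(eta))
    p <- p / sum(p)
    counts[, j] <- stats::rmultinom(1, config$depth, p)[, 1]
  }

  phyla <- sample(names(PHYLUM_POOL), n, replace = TRUE, prob = PHYLUM_POOL)
  taxonomy <- data.frame(
    otu_id = ids,
    lineage = paste("Bacteria", phyla,
                    paste(rep(LINEAGE_UNRESOLVED, 5), collapse = ";"),
                    sep = ";"),
    stringsAsFactors = FALSE)

  meta <- grid[, c("sample_id", "batch", "unit", "fraction")]
  table <- otu_table(counts, meta, taxonomy = taxonomy,
                     rarefied_depth = config$depth)

  # flow-cytometry profile: multiplicative decline, BAC rebound, rising UMB%
  n_units <- length(config$units)
  mult <- cumprod(c(1, ifelse(config$units[-1] == "BAC",
                              config$bac_rebound, config$density_decay)))
  umb_target <- seq(config$umb_pct_trend[1], config$umb_pct_trend[2],
                    length.out = n_units)
  fcm <- do.call(rbind, lapply(batches, function(bt) {
    cd0 <- config$density_start * mult * exp(stats::rnorm(n_units, 0, 0.15))
    up <- cummax(pmin(umb_target * exp(stats::rnorm(n_units, 0, 0.05)), 95))
    data.frame(batch = bt, unit = config$units,
               cd_original = cd0, cd_umb = cd0 * up / 100,
               stringsAsFactors = FALSE)
  }))
  if (config$drop_missing_bac && config$n_batches >= 2 &&
      "BAC" %in% config$units)
    fcm <- fcm[!(fcm$batch == "DWTP2" & fcm$unit == "BAC"), ]
  rownames(fcm) <- NULL
  fcm <- fcm_measurements(fcm)

  truth <- data.frame(otu_id = ids, class = cls, block = block_of,
                      umb_support = !(seq_len(n) %in% dropped),
                      stringsAsFactors = FALSE)
  structure(list(table = table, fcm = fcm, truth = truth, config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d OTUs x %d samples, depth %d\n",
              nrow(x$table$counts), ncol(x$table$counts), x$config$depth))
  cat("  planted:", paste(sprintf("%s=%d", names(table(x$truth$class)),
                                  table(x$truth$class)), collapse = ", "),
      sprintf("; %d blocks\n", x$config$n_corr_blocks))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the four pipeline inputs (`otu.tsv`, `metadata.tsv`,
#' `taxonomy.tsv`, `fcm.csv`) plus `ground_truth.tsv` into a directory.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(sim$table,
                  file.path(dir, "otu.tsv"),
                  file.path(dir, "metadata.tsv"),
                  file.path(dir, "taxonomy.tsv"))
  utils::write.csv(sim$fcm[, c("batch", "unit", "cd_original", "cd_umb")],
                   file.path(dir, "fcm.csv"), row.names = FALSE, quote = FALSE)
  utils::write.table(sim$truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Recovery of planted indicators
#'
#' Convenience scorer for simulation studies: given the planted classes and
#' the classifier output, reports recall of planted indicators (fraction of
#' planted LB/UMB indicators recovered with the correct enriched fraction)
#' and the false-positive rate among planted normals.
#'
#' @param truth `truth` component of a [simulate_dataset()] result.
#' @param scores [classify_indicators()] output.
#' @return Named list `recall`, `fpr`, `n_planted`, `n_recovered`,
#'   `n_false_positive`.
#' @export
indicator_recovery <- function(truth, scores) {
  m <- merge(truth, scores, by = "otu_id")
  planted <- m$class %in% c("LB_indicator", "UMB_indicator")
  normal <- m$class == "normal"
  hit <- planted & m$category == m$class
  fp <- normal & m$category != "normal"
  list(recall = sum(hit) / sum(planted),
       fpr = sum(fp) / sum(normal),
       n_planted = sum(planted),
       n_recovered = sum(hit),
       n_false_positive = sum(fp))
}
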