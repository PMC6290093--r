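#' Kruskal-Wallis rank test between size fractions
#'
#' Thin wrapper around [stats::kruskal.test()] (H statistic with midrank tie
#' correction, p-value from the chi-square approximation) adding the
#' degenerate-data convention used by the indicator screen: when every value
#' is tied across both classes the statistic is 0 and `p = 1` rather than
#' `NaN`.
#'
#' @param values Numeric vector of per-sample abundances of one feature.
#' @param classes Two-level grouping vector (e.g. the size fraction).
#' @return List with elements `h` (statistic) and `p`.
#' @export
kruskal_wallis <- function(values, classes) {
  classes <- as.factor(classes)
  if (nlevels(droplevels(classes)) < 2)
    stop("kruskal_wallis needs observations in both classes")
  if (min(table(droplevels(classes))) < 2)
    stop("kruskal_wallis needs at least 2 observations per class")
  if (length(unique(values)) == 1) return(list(h = 0, p = 1))
  k <- stats::kruskal.test(values, classes)
  if (is.na(k$p.value)) return(list(h = 0, p = 1))
  list(h = unname(k$statistic), p = k$p.value)
}

# Per-class bootstrap subsample index sets. Indices are drawn from class
# sizes alone (never from the data), so scores depend only on the multiset of
# values within each class.
.draw_subsamples <- function(n_per_class, n_boot, boot_frac) {
  m <- pmax(2L, ceiling(boot_frac * n_per_class))
  m <- pmin(m, n_per_class)
  lapply(seq_len(n_boot), function(b)
    lapply(seq_along(n_per_class), function(k)
      sample.int(n_per_class[k], m[k], replace = FALSE)))
}

# One feature's mean bootstrap effect size on the per-million scale.
# xs: list of 2 sorted numeric vectors (values per class); subs: output of
# .draw_subsamples. The discriminant is fit on the feature joined with a
# class-mean pseudo-feature (constant within class), with a relative ridge on
# the pooled within-class covariance so the fit is defined when a direction
# is degenerate; the per-round effect size averages the discriminant-weighted
# class-mean difference with the raw class-mean difference.
.effect_size_one <- function(xs, subs) {
  effects <- vapply(subs, function(idx) {
    a <- xs[[1]][idx[[1]]]; b <- xs[[2]][idx[[2]]]
    d <- mean(a) - mean(b)
    # pooled within-class covariance of (feature, class-mean pseudo-feature);
    # the pseudo-feature is constant within class, so only the feature
    # contributes variance
    va <- stats::var(a); vb <- stats::var(b)
    s2 <- ((length(a) - 1) * va + (length(b) - 1) * vb) /
      (length(a) + length(b) - 2)
    eps <- 1e-6 * s2 + 1e-12
    S <- matrix(c(s2 + eps, 0, 0, eps), 2, 2)
    mu_diff <- c(d, d)
    w <- solve(S, mu_diff)
    nw <- sqrt(sum(w^2))
    eff_lda <- if (nw > 0) abs(sum(w / nw * mu_diff)) else 0
    (eff_lda + abs(d)) / 2
  }, numeric(1))
  mean(effects)
}

#' Linear-discriminant effect size of one feature
#'
#' Bootstrapped effect-size score in the style of the LEfSe method: the
#' feature (per-sample relative abundance rescaled to a per-million basis) is
#' repeatedly subsampled within each class, a two-class linear discriminant
#' is fit on the feature joined with a class-mean pseudo-feature, and the
#' per-round effect size — the discriminant-weighted class-mean difference
#' averaged with the raw class-mean difference — is averaged over rounds.
#' The reported score is `log10(mean effect + 1)`.
#'
#' The score is invariant to sample order (subsampling acts on the sorted
#' within-class values) and scales like `log10` of the class-mean gap, so a
#' tenfold larger gap raises the score by about one unit.
#'
#' @param x Per-sample feature values on the per-million relative-abundance
#'   scale (see [rel_abund()] with `scale = 1e6`).
#' @param classes Two-level grouping vector aligned with `x`.
#' @param n_boot Bootstrap rounds (default 30).
#' @param boot_frac Fraction of each class subsampled per round (default 2/3).
#' @param seed Integer seed for the subsampling stream.
#' @return The `log10` effect-size score (a non-negative scalar).
#' @export
lda_effect_size <- function(x, classes, n_boot = 30, boot_frac = 2/3,
                            seed = NULL) {
  classes <- as.character(classes)
  lev <- sort(unique(classes))
  if (length(lev) != 2) stop("lda_effect_size needs exactly 2 classes")
  n_per_class <- vapply(lev, function(l) sum(classes == l), integer(1))
  if (any(n_per_class < 2)) stop("need at least 2 samples per class")
  if (!is.null(seed)) set.seed(seed)
  subs <- .draw_subsamples(n_per_class, n_boot, boot_frac)
  xs <- lapply(lev, function(l) sort(x[classes == l]))
  log10(.effect_size_one(xs, subs) + 1)
}

#' Classify OTUs as fraction indicators or normal taxa
#'
#' The two-gate indicator screen: every OTU is tested for a
#' fraction-of-origin difference with the Kruskal-Wallis rank test and scored
#' with the bootstrapped linear-discriminant effect size
#' ([lda_effect_size()]) on per-million relative abundances. An OTU is an
#' indicator of its enriched fraction when `kw_p < alpha` **and**
#' `lda_score > lda_min` (defaults: the conventional LDA > 2, P < 0.05);
#' all other OTUs are "normal" taxa. The enriched fraction is the one with
#' the higher mean relative abundance.
#'
#' One set of bootstrap subsamples is drawn per call and shared by all OTUs,
#' so scores are deterministic given `seed` and invariant to OTU order.
#'
#' @param table A rarefied `otu_table` containing both size fractions.
#' @param alpha Kruskal-Wallis significance gate (default 0.05).
#' @param lda_min Minimum `log10` effect size (default 2).
#' @param n_boot,boot_frac Bootstrap scheme passed to the effect-size scorer.
#' @param seed Integer seed.
#' @return `data.frame` of class `indicator_scores` with columns `otu_id`,
#'   `kw_p`, `lda_score`, `enriched_fraction`, `category`
#'   (`LB_indicator`, `UMB_indicator` or `normal`).
#' @export
classify_indicators <- function(table, alpha = 0.05, lda_min = 2.0,
                                n_boot = 30, boot_frac = 2/3, seed = NULL) {
  frac <- table$samples$fraction
  if (length(unique(frac)) < 2)
    stop("indicator discovery needs samples of both fractions")
  if (is.null(attr(table, "rarefied_depth")))
    warning("table is not rarefied; relative abundances are depth-biased")
  ra <- rel_abund(table, scale = 1e6)
  lev <- sort(unique(frac))  # "LB", "UMB"
  n_per_class <- vapply(lev, function(l) sum(frac == l), integer(1))
  if (!is.null(seed)) set.seed(seed)
  subs <- .draw_subsamples(n_per_class, n_boot, boot_frac)
  idx_by_class <- lapply(lev, function(l) which(frac == l))

  n <- nrow(ra)
  kw_p <- numeric(n); lda <- numeric(n); enriched <- character(n)
  for (i in seq_len(n)) {
    x <- ra[i, ]
    kw_p[i] <- kruskal_wallis(x, frac)$p
    xs <- lapply(idx_by_class, function(j) sort(x[j]))
    lda[i] <- log10(.effect_size_one(xs, subs) + 1)
    means <- vapply(idx_by_class, function(j) mean(x[j]), numeric(1))
    enriched[i] <- lev[which.max(means)]
  }
  category <- ifelse(kw_p < alpha & lda > lda_min,
                     paste0(enriched, "_indicator"), "normal")
  structure(data.frame(otu_id = rownames(ra), kw_p = kw_p, lda_score = lda,
                       enriched_fraction = enriched, category = category,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("indicator_scores", "data.frame"))
}

#' Fate of indicator categories across treatment units
#'
#' Aggregates the summed relative abundance of each indicator category
#' (LB indicator, UMB indicator, normal) per sample, then averages over
#' sampling batches within each (fraction, treatment unit) cell — the fate
#' trajectory of each category along the treatment train. Also reports the
#' ARA of each category (average over **all** samples of the category's
#' summed relative abundance, in percent) and retains per-OTU trajectories
#' for OTUs whose overall mean relative abundance exceeds a display cutoff.
#'
#' Per sample the three category sums close to 100% by construction.
#'
#' @param table A rarefied `otu_table`.
#' @param scores [classify_indicators()] output covering every OTU of `table`.
#' @param display_cutoff Per-OTU trajectory cutoff in percent (default 0.1).
#' @return List of class `indicator_summary` with elements `counts` (OTUs per
#'   category), `ara` (named percent vector), `per_sample`, `trajectories`
#'   and `otu_trajectories` data frames.
#' @export
fate_trajectories <- function(table, scores, display_cutoff = 0.1) {
  if (!all(rownames(table$counts) %in% scores$otu_id))
    stop("scores do not cover every OTU in the table")
  cat_of <- scores$category[match(rownames(table$counts), scores$otu_id)]
  ra <- rel_abund(table, scale = 100)
  cats <- c("LB_indicator", "UMB_indicator", "normal")
  per_sample <- sapply(cats, function(cc)
    colSums(ra[cat_of == cc, , drop = FALSE]))
  if (is.null(dim(per_sample)))
    per_sample <- matrix(per_sample, nrow = 1, dimnames = list(NULL, cats))
  per_sample <- data.frame(table$samples, per_sample, check.names = FALSE,
                           row.names = NULL)

  units <- intersect(UNITS_DEFAULT, unique(table$samples$unit))
  if (length(units) == 0) units <- unique(table$samples$unit)
  grid <- expand.grid(fraction = sort(unique(table$samples$fraction)),
                      unit = units, category = cats,
                      stringsAsFactors = FALSE)
  grid$mean_rel_abund_pct <- mapply(function(f, u, cc) {
    sel <- per_sample$fraction == f & per_sample$unit == u
    if (!any(sel)) return(NA_real_)
    mean(per_sample[[cc]][sel])
  }, grid$fraction, grid$unit, grid$category)

  ara <- vapply(cats, function(cc) mean(per_sample[[cc]]), numeric(1))
  counts <- vapply(cats, function(cc) sum(cat_of == cc), integer(1))

  keep <- rowMeans(ra) > display_cutoff
  otu_traj <- NULL
  if (any(keep)) {
    cells <- unique(per_sample[, c("fraction", "unit")])
    otu_traj <- do.call(rbind, lapply(which(keep), function(i) {
      v <- vapply(seq_len(nrow(cells)), function(r) {
        sel <- table$samples$fraction == cells$fraction[r] &
          table$samples$unit == cells$unit[r]
        mean(ra[i, sel])
      }, numeric(1))
      data.frame(otu_id = rownames(ra)[i], category = cat_of[i],
                 fraction = cells$fraction, unit = cells$unit,
                 mean_rel_abund_pct = v, stringsAsFactors = FALSE)
    }))
    rownames(otu_traj) <- NULL
  }

  structure(list(counts = counts, ara = ara, per_sample = per_sample,
                 trajectories = grid, otu_trajectories = otu_traj),
            class = "indicator_summary")
}

#' @export
print.indicator_summary <- function(x, ...) {
  cat("indicator_summary\n  OTUs per category:",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "), "\n")
  cat("  ARA (%):",
      paste(sprintf("%s=%.2f", names(x$ara), x$ara), collapse = ", "), "\n")
  invisible(x)
}
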