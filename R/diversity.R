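#' Rarefy an OTU table to a common depth
#'
#' Subsamples each sample's reads without replacement to `depth` (single
#' draw, seeded — the mothur subsampling convention, not an average over
#' draws). Samples whose total falls below `depth` are dropped with a
#' warning; samples at exactly `depth` are kept unchanged.
#'
#' @param table An `otu_table`.
#' @param depth Target reads per sample (default 17000).
#' @param seed Integer seed making the draw reproducible.
#' @return A rarefied `otu_table` (every column sum equals `depth`).
#' @export
rarefy <- function(table, depth = 17000, seed = NULL) {
  if (depth <= 0) stop("depth must be positive")
  if (!is.null(seed)) set.seed(seed)
  totals <- colSums(table$counts)
  keep <- totals >= depth
  if (!any(keep)) stop("no sample reaches the rarefaction depth")
  if (any(!keep))
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(!keep), depth,
                    paste(colnames(table$counts)[!keep], collapse = ", ")))
  counts <- table$counts[, keep, drop = FALSE]
  out <- counts
  for (j in seq_len(ncol(counts))) {
    if (totals[keep][j] == depth) next
    reads <- rep.int(seq_len(nrow(counts)), counts[, j])
    drawn <- sample(reads, depth, replace = FALSE)
    out[, j] <- tabulate(drawn, nbins = nrow(counts))
  }
  meta <- table$samples[keep, , drop = FALSE]
  otu_table(out, meta, taxonomy = table$taxonomy, rarefied_depth = depth)
}

#' Alpha diversity per sample
#'
#' Computes, for every sample: species richness `S` (number of OTUs with
#' nonzero count), Shannon diversity `H` in nats (`-sum p_i ln p_i`, the
#' vegan default base) and Good's coverage `C = 1 - F1/N`, where `F1` is the
#' number of OTUs seen exactly once in the sample and `N` the sample total.
#'
#' @param table An `otu_table`; a warning is issued if it has not been
#'   rarefied, since unequal depths bias richness comparisons.
#' @param base Logarithm base for Shannon (default `exp(1)`; use 2 or 10 for
#'   bits/dits).
#' @return `data.frame` with columns `sample_id`, `batch`, `unit`,
#'   `fraction`, `richness`, `shannon`, `goods_coverage`.
#' @export
alpha_diversity <- function(table, base = exp(1)) {
  if (is.null(attr(table, "rarefied_depth")))
    warning("table is not rarefied; diversity values are depth-dependent")
  counts <- table$counts
  totals <- colSums(counts)
  if (any(totals == 0)) stop("alpha diversity is undefined for an empty sample")
  shannon <- vegan::diversity(t(counts), index = "shannon", base = base)
  richness <- colSums(counts > 0)
  f1 <- colSums(counts == 1)
  data.frame(table$samples,
             richness = as.integer(richness),
             shannon = as.numeric(shannon),
             goods_coverage = 1 - f1 / totals,
             row.names = NULL)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `D(a, b) = 1 - 2 sum_i min(x_ai, x_bi) / (sum_i x_ai + sum_i x_bi)`,
#' computed between all sample pairs. Symmetric, zero diagonal, entries in
#' `[0, 1]`; not a metric (the triangle inequality may fail).
#'
#' @param table An `otu_table` with at least two samples and no empty sample.
#' @return Symmetric numeric matrix with sample ids as dimnames.
#' @export
bray_curtis <- function(table) {
  if (ncol(table$counts) < 2) stop("need at least 2 samples")
  if (any(colSums(table$counts) == 0))
    stop("Bray-Curtis is undefined when a sample is all zero")
  d <- vegan::vegdist(t(table$counts), method = "bray")
  m <- as.matrix(d)
  dimnames(m) <- list(colnames(table$counts), colnames(table$counts))
  m
}

#' PERMANOVA variance partitioning on a distance matrix
#'
#' Sequential (Type I) sums of squares on the Gower-centered inner-product
#' form of the distance matrix, with significance from free permutation of
#' sample labels — the standard Adonis analysis, delegated to
#' [vegan::adonis2()] with `by = "terms"`. `R2` values over all terms plus
#' the residual sum to 1.
#'
#' @param dm Symmetric dissimilarity matrix (e.g. [bray_curtis()]) or `dist`.
#' @param meta `data.frame` of factors, one row per sample, aligned with the
#'   dimnames of `dm` via a `sample_id` column (or row order if absent).
#' @param formula Right-hand-side model formula over columns of `meta`
#'   (default `~ fraction + batch + fraction:batch`). Terms enter
#'   sequentially in the order written.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed for the permutation stream.
#' @return `data.frame` with columns `term`, `df`, `ss`, `r2`, `f`, `p`
#'   (residual and total rows carry `NA` for `f` and `p`).
#' @export
permanova <- function(dm, meta, formula = ~ fraction + batch + fraction:batch,
                      n_perm = 999, seed = NULL) {
  if (n_perm < 99) stop("use at least 99 permutations")
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  ids <- rownames(dm)
  if (!is.null(ids) && "sample_id" %in% names(meta)) {
    if (!all(ids %in% meta$sample_id))
      stop("distance-matrix sample ids missing from metadata")
    meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  } else if (nrow(meta) != nrow(dm)) {
    stop("metadata rows do not align with the distance matrix")
  }
  vars <- all.vars(formula)
  for (v in vars) meta[[v]] <- factor(meta[[v]])
  single <- vars[vapply(vars, function(v) nlevels(meta[[v]]) < 2, logical(1))]
  labels <- attr(stats::terms(formula), "term.labels")
  dropped <- character(0)
  if (length(single) > 0) {
    warning(sprintf("factor(s) with a single level are confounded and carry no variance: %s",
                    paste(single, collapse = ", ")))
    involves <- vapply(labels, function(l)
      any(single %in% strsplit(l, ":", fixed = TRUE)[[1]]), logical(1))
    dropped <- labels[involves]
    labels <- labels[!involves]
    if (length(labels) == 0) stop("no testable term remains in the model")
  }
  if (!is.null(seed)) set.seed(seed)
  full <- stats::reformulate(labels, response = quote(stats::as.dist(dm)))
  fit <- vegan::adonis2(full, data = meta, permutations = n_perm,
                        by = "terms")
  out <- data.frame(term = rownames(fit),
                    df = fit$Df,
                    ss = fit$SumOfSqs,
                    r2 = fit$R2,
                    f = fit$F,
                    p = fit$`Pr(>F)`,
                    row.names = NULL)
  if (length(dropped) > 0) {
    na_rows <- data.frame(term = dropped, df = 0, ss = 0, r2 = 0,
                          f = NA_real_, p = NA_real_)
    res_at <- which(out$term == "Residual")
    out <- rbind(out[seq_len(res_at - 1), ], na_rows,
                 out[res_at:nrow(out), ])
    rownames(out) <- NULL
  }
  out
}
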