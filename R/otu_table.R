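# Recognised factor levels shared across the pipeline.
FRACTIONS <- c("LB", "UMB")
UNITS_DEFAULT <- c("RW", "FS", "RSF", "BAC", "CW")
LINEAGE_UNRESOLVED <- "unclassified"

#' Construct a validated OTU table
#'
#' Bundles an integer count matrix (OTUs in rows, samples in columns) with
#' per-sample metadata (sampling batch, treatment unit, size fraction) and an
#' optional taxonomy map. All downstream stages of the pipeline consume this
#' container.
#'
#' @param counts Non-negative integer matrix; rownames are OTU ids, colnames
#'   sample ids.
#' @param samples `data.frame` with columns `sample_id`, `batch`, `unit`,
#'   `fraction`. `fraction` must be `"LB"` (large bacteria, captured on the
#'   0.22-um filter) or `"UMB"` (ultramicrobacteria, passing 0.22 um and
#'   captured on 0.10 um). One row per column of `counts`.
#' @param taxonomy Optional `data.frame` with columns `otu_id`, `lineage`
#'   (semicolon-separated ranks, up to 7, SILVA style; unresolved ranks carry
#'   the sentinel `"unclassified"`).
#' @param rarefied_depth If the table has been rarefied, the common depth;
#'   every column sum must then equal it. `NULL` for raw tables.
#' @return An object of class `otu_table`.
#' @export
otu_table <- function(counts, samples, taxonomy = NULL, rarefied_depth = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry OTU ids as rownames and sample ids as colnames")
  storage.mode(counts) <- "double"
  if (anyNA(counts)) stop("counts contain missing values")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("count for OTU '%s' in sample '%s' is not a non-negative integer",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  storage.mode(counts) <- "integer"
  if (anyDuplicated(rownames(counts)))
    stop(sprintf("duplicated otu_id: '%s'",
                 rownames(counts)[duplicated(rownames(counts))][1]))
  if (anyDuplicated(colnames(counts)))
    stop(sprintf("duplicated sample_id: '%s'",
                 colnames(counts)[duplicated(colnames(counts))][1]))

  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "batch", "unit", "fraction")
  if (!all(need %in% names(samples)))
    stop("samples must have columns sample_id, batch, unit, fraction")
  samples[need] <- lapply(samples[need], as.character)
  if (anyDuplicated(samples$sample_id))
    stop(sprintf("duplicated sample_id in metadata: '%s'",
                 samples$sample_id[duplicated(samples$sample_id)][1]))
  missing_in_counts <- setdiff(samples$sample_id, colnames(counts))
  if (length(missing_in_counts) > 0)
    stop(sprintf("metadata sample '%s' has no column in counts",
                 missing_in_counts[1]))
  missing_in_meta <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing_in_meta) > 0)
    stop(sprintf("counts column '%s' has no metadata row", missing_in_meta[1]))
  bad_frac <- setdiff(unique(samples$fraction), FRACTIONS)
  if (length(bad_frac) > 0)
    stop(sprintf("unknown fraction '%s' (expected LB or UMB)", bad_frac[1]))
  key <- paste(samples$batch, samples$unit, samples$fraction, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (batch, unit, fraction) combination in metadata")
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL

  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
    if (!all(c("otu_id", "lineage") %in% names(taxonomy)))
      stop("taxonomy must have columns otu_id, lineage")
    taxonomy$otu_id <- as.character(taxonomy$otu_id)
    taxonomy$lineage <- as.character(taxonomy$lineage)
    if (anyDuplicated(taxonomy$otu_id))
      stop(sprintf("duplicated otu_id in taxonomy: '%s'",
                   taxonomy$otu_id[duplicated(taxonomy$otu_id)][1]))
    taxonomy <- taxonomy[match(rownames(counts), taxonomy$otu_id), , drop = FALSE]
    if (anyNA(taxonomy$otu_id))
      stop("taxonomy is missing entries for some OTUs in counts")
    rownames(taxonomy) <- NULL
  }

  if (!is.null(rarefied_depth)) {
    cs <- colSums(counts)
    if (any(cs != rarefied_depth))
      stop("rarefied table has a sample whose total differs from the stated depth")
  }

  structure(list(counts = counts, samples = samples, taxonomy = taxonomy),
            class = "otu_table", rarefied_depth = rarefied_depth)
}

#' @export
print.otu_table <- function(x, ...) {
  d <- attr(x, "rarefied_depth")
  cat(sprintf("otu_table: %d OTUs x %d samples%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(d)) "" else sprintf(" (rarefied to %d)", d)))
  tab <- table(x$samples$fraction)
  cat("  fractions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  units:", paste(unique(x$samples$unit), collapse = ", "), "\n")
  invisible(x)
}

#' Number of OTUs / samples in an OTU table
#' @param table An `otu_table`.
#' @return Integer count.
#' @export
n_otus <- function(table) nrow(table$counts)

#' @rdname n_otus
#' @export
n_samples <- function(table) ncol(table$counts)

#' Per-sample relative abundances
#'
#' @param table An `otu_table`.
#' @param scale Multiplier applied to the per-sample proportions (default 1;
#'   use `100` for percent, `1e6` for the per-million scale the effect-size
#'   scorer works on).
#' @return Numeric matrix with the shape of `table$counts`.
#' @export
rel_abund <- function(table, scale = 1) {
  cs <- colSums(table$counts)
  if (any(cs == 0)) stop("cannot compute relative abundance of an empty sample")
  sweep(table$counts, 2, cs, "/") * scale
}

#' Read an OTU table from TSV inputs
#'
#' Expects the three tab/comma-separated artifacts of the processed-amplicon
#' contract: counts (first column `otu_id`, remaining columns sample ids,
#' integer cells), sample metadata (`sample_id`, `batch`, `unit`, `fraction`)
#' and optionally taxonomy (`otu_id`, `lineage`).
#'
#' @param counts_path,metadata_path Paths to TSV files.
#' @param taxonomy_path Optional path to the taxonomy TSV.
#' @return A validated [otu_table()]; OTU and sample order as in the files.
#' @export
read_otu_table <- function(counts_path, metadata_path, taxonomy_path = NULL) {
  raw <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(raw)[1] != "otu_id") stop("counts file must start with an otu_id column")
  ids <- as.character(raw$otu_id)
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(raw[, -1, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    stop(sprintf("non-numeric count at row %d, column '%s'",
                 bad[1, 1], colnames(raw[, -1, drop = FALSE])[bad[1, 2]]))
  }
  rownames(mat) <- ids
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  tax <- if (!is.null(taxonomy_path))
    utils::read.delim(taxonomy_path, stringsAsFactors = FALSE) else NULL
  otu_table(mat, meta, taxonomy = tax)
}

#' Write an OTU table to TSV files
#'
#' Inverse of [read_otu_table()]: `read_otu_table` on the written files
#' reproduces the table exactly.
#'
#' @param table An `otu_table`.
#' @param counts_path,metadata_path,taxonomy_path Output paths; taxonomy is
#'   only written when the table carries one and a path is given.
#' @return Invisibly, the paths written.
#' @export
write_otu_table <- function(table, counts_path, metadata_path,
                            taxonomy_path = NULL) {
  df <- data.frame(otu_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(table$samples, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(counts_path, metadata_path)
  if (!is.null(table$taxonomy) && !is.null(taxonomy_path)) {
    utils::write.table(table$taxonomy, taxonomy_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, taxonomy_path)
  }
  invisible(paths)
}

#' Remove singleton OTUs
#'
#' Drops OTUs whose total count across the whole dataset equals one (the
#' mothur convention: a read observed exactly once anywhere). Sample set and
#' order are untouched; the operation is idempotent. Removing reads from a
#' rarefied table leaves its column sums marginally below the stated depth,
#' so the rarefied flag is cleared whenever any OTU is removed.
#'
#' @param table An `otu_table`.
#' @return An `otu_table` without singleton OTUs.
#' @export
drop_singletons <- function(table) {
  keep <- rowSums(table$counts) != 1L
  tax <- if (!is.null(table$taxonomy)) table$taxonomy[keep, , drop = FALSE]
  depth <- if (all(keep)) attr(table, "rarefied_depth")
  otu_table(table$counts[keep, , drop = FALSE], table$samples, taxonomy = tax,
            rarefied_depth = depth)
}

#' OTU overlap between size fractions
#'
#' Counts OTUs detected (nonzero in at least one sample) in each size
#' fraction and in both, plus the union. The inclusion-exclusion identity
#' `n_total = n_lb + n_umb - n_shared` holds by construction.
#'
#' @param table An `otu_table` containing samples of both fractions.
#' @return Named list with `n_total`, `n_lb`, `n_umb`, `n_shared`.
#' @export
fraction_overlap <- function(table) {
  frac <- table$samples$fraction
  if (!all(FRACTIONS %in% frac))
    stop("fraction_overlap requires samples of both LB and UMB fractions")
  in_lb <- rowSums(table$counts[, frac == "LB", drop = FALSE]) > 0
  in_umb <- rowSums(table$counts[, frac == "UMB", drop = FALSE]) > 0
  list(n_total = sum(in_lb | in_umb),
       n_lb = sum(in_lb),
       n_umb = sum(in_umb),
       n_shared = sum(in_lb & in_umb))
}

#' Union size from per-fraction OTU counts
#'
#' Inclusion-exclusion bookkeeping on already-tabulated per-fraction richness:
#' the number of distinct OTUs overall given the per-fraction counts and their
#' intersection.
#'
#' @param n_lb,n_umb OTUs detected in each fraction.
#' @param n_shared OTUs detected in both.
#' @return `n_lb + n_umb - n_shared`.
#' @export
otu_union <- function(n_lb, n_umb, n_shared) {
  if (n_shared > min(n_lb, n_umb)) stop("shared count exceeds a fraction total")
  n_lb + n_umb - n_shared
}

#' Subset an OTU table by OTU ids or sample ids
#'
#' @param table An `otu_table`.
#' @param otus Character vector of OTU ids to retain (default all).
#' @param samples Character vector of sample ids to retain (default all).
#' @return A validated `otu_table` restricted to the selection.
#' @export
subset_otu_table <- function(table, otus = rownames(table$counts),
                             samples = colnames(table$counts)) {
  stopifnot(all(otus %in% rownames(table$counts)),
            all(samples %in% colnames(table$counts)))
  tax <- if (!is.null(table$taxonomy))
    table$taxonomy[match(otus, table$taxonomy$otu_id), , drop = FALSE]
  meta <- table$samples[match(samples, table$samples$sample_id), , drop = FALSE]
  depth <- attr(table, "rarefied_depth")
  # dropping OTUs breaks the constant column sum, so the flag only survives
  # a pure sample subset
  if (!identical(sort(otus), sort(rownames(table$counts)))) depth <- NULL
  otu_table(table$counts[otus, samples, drop = FALSE], meta, taxonomy = tax,
            rarefied_depth = depth)
}

#' Extract the phylum of each OTU from its lineage
#'
#' Lineages are semicolon-separated SILVA-style rank lists
#' (domain;phylum;...); rank 2 is the phylum. OTUs without taxonomy or with an
#' unresolved phylum get the sentinel `"unclassified"`.
#'
#' @param table An `otu_table` with taxonomy attached.
#' @return Named character vector (names are OTU ids).
#' @export
otu_phylum <- function(table) {
  if (is.null(table$taxonomy)) stop("table carries no taxonomy")
  ranks <- strsplit(table$taxonomy$lineage, ";", fixed = TRUE)
  phy <- vapply(ranks, function(r) if (length(r) >= 2) trimws(r[2]) else
    LINEAGE_UNRESOLVED, character(1))
  phy[phy == "" | is.na(phy)] <- LINEAGE_UNRESOLVED
  stats::setNames(phy, table$taxonomy$otu_id)
}
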