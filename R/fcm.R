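#' Large-bacteria cell density from a two-step filtration
#'
#' Flow cytometry counts total cells in the original water (`cd_original`)
#' and in the 0.22-um filtrate (`cd_umb`, the ultramicrobacteria passing the
#' filter). The large-bacteria density is their difference,
#' `CD_LB = CD_original - CD_UMB`.
#'
#' Replicate flow-cytometry counts carry a coefficient of variation of up to
#' about 2%, so a filtrate count may marginally exceed the original count
#' without the measurements being inconsistent. Violations within
#' `tolerance` are clamped to `cd_lb = 0` with a warning; larger violations
#' are an error.
#'
#' @param cd_original,cd_umb Cell densities in cells/mL (vectors recycle).
#' @param tolerance Fractional measurement tolerance (default 0.02).
#' @return `cd_original - cd_umb` in cells/mL, floored at 0 within tolerance.
#' @export
derive_lb_density <- function(cd_original, cd_umb, tolerance = 0.02) {
  if (any(cd_original < 0) || any(cd_umb < 0))
    stop("cell densities must be non-negative")
  excess <- cd_umb - cd_original
  bad <- excess > tolerance * pmax(cd_original, .Machine$double.eps)
  if (any(bad))
    stop("cd_umb exceeds cd_original beyond measurement tolerance: filtrate denser than original water")
  clamp <- excess > 0 & !bad
  if (any(clamp)) {
    warning(sprintf("%d measurement(s) with cd_umb marginally above cd_original clamped to cd_lb = 0",
                    sum(clamp)))
  }
  pmax(cd_original - cd_umb, 0)
}

#' Ultramicrobacteria proportion of total cell density
#'
#' `UMB% = (CD_UMB / CD_original) x 100`. Marginal violations
#' (`cd_umb` slightly above `cd_original`, within `tolerance`) are clamped to
#' 100% with a warning; see [derive_lb_density()].
#'
#' @inheritParams derive_lb_density
#' @return Percentage in `[0, 100]`.
#' @export
umb_proportion <- function(cd_original, cd_umb, tolerance = 0.02) {
  if (any(cd_original <= 0))
    stop("umb_proportion is undefined for cd_original = 0")
  if (any(cd_umb < 0)) stop("cell densities must be non-negative")
  bad <- cd_umb > cd_original * (1 + tolerance)
  if (any(bad))
    stop("cd_umb exceeds cd_original beyond measurement tolerance")
  p <- cd_umb / cd_original * 100
  clamp <- p > 100
  if (any(clamp))
    warning(sprintf("%d measurement(s) clamped to UMB%% = 100", sum(clamp)))
  pmin(p, 100)
}

#' Read and derive a flow-cytometry density table
#'
#' Reads a CSV with columns `batch`, `unit`, `cd_original`, `cd_umb`
#' (cells/mL) and attaches the derived large-bacteria density `cd_lb` and
#' ultramicrobacteria proportion `umb_pct`.
#'
#' @param path CSV path.
#' @param tolerance Measurement tolerance passed to [derive_lb_density()].
#' @return `data.frame` with columns `batch`, `unit`, `cd_original`,
#'   `cd_umb`, `cd_lb`, `umb_pct`.
#' @export
read_fcm <- function(path, tolerance = 0.02) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fcm_measurements(df, tolerance = tolerance)
}

#' @rdname read_fcm
#' @param df `data.frame` with columns `batch`, `unit`, `cd_original`, `cd_umb`.
#' @export
fcm_measurements <- function(df, tolerance = 0.02) {
  need <- c("batch", "unit", "cd_original", "cd_umb")
  if (!all(need %in% names(df)))
    stop("FCM table must have columns batch, unit, cd_original, cd_umb")
  df$cd_lb <- derive_lb_density(df$cd_original, df$cd_umb, tolerance)
  df$umb_pct <- umb_proportion(df$cd_original, df$cd_umb, tolerance)
  df
}

#' One-way ANOVA trend test across treatment units
#'
#' Tests whether a quantity differs across treatment units with a standard
#' one-way ANOVA F test, treating sampling batches as replicates. Densities
#' span orders of magnitude, so the test is run on log10 values by default.
#'
#' When all observations are identical the F statistic is degenerate (zero
#' between- and within-group variance); the convention here is `p = 1`.
#'
#' @param values Numeric vector of measurements.
#' @param units Grouping vector (treatment unit per measurement).
#' @param log10 Test on `log10(values)` (default `TRUE`); requires positive
#'   values.
#' @return The ANOVA p-value.
#' @export
trend_test <- function(values, units, log10 = TRUE) {
  keep <- !is.na(values) & !is.na(units)
  values <- values[keep]; units <- as.character(units[keep])
  empty <- setdiff(unique(units), units[!is.na(values)])
  if (length(empty) > 0)
    warning(sprintf("dropping unit(s) with no observations: %s",
                    paste(empty, collapse = ", ")))
  if (length(unique(units)) < 2 || length(values) < 3)
    stop("trend_test needs at least 2 units and 3 observations")
  if (log10) {
    if (any(values <= 0)) stop("log10 trend test requires positive values")
    values <- base::log10(values)
  }
  if (stats::var(values) == 0) return(1)
  fit <- stats::aov(values ~ factor(units))
  s <- summary(fit)[[1]]
  p <- s[["Pr(>F)"]][1]
  if (is.na(p)) 1 else p
}

#' Per-unit density summary with trend tests
#'
#' Summarises `cd_lb`, `cd_umb` and `umb_pct` per treatment unit (mean, min,
#' max across batches) and attaches the across-unit one-way ANOVA p-value
#' for each quantity ([trend_test()]; densities on the log10 scale, UMB% on
#' the raw scale).
#'
#' @param fcm Derived FCM table from [fcm_measurements()] or [read_fcm()].
#' @param units Unit ordering for the output (default the treatment-train
#'   order RW, FS, RSF, BAC, CW restricted to units present).
#' @return List with `per_unit` (`data.frame`) and `trend_p` (named vector
#'   over `cd_lb`, `cd_umb`, `umb_pct`).
#' @export
density_trends <- function(fcm, units = NULL) {
  if (is.null(units)) units <- intersect(UNITS_DEFAULT, unique(fcm$unit))
  fcm <- fcm[fcm$unit %in% units, , drop = FALSE]
  qty <- c("cd_lb", "cd_umb", "umb_pct")
  per_unit <- do.call(rbind, lapply(units, function(u) {
    sub <- fcm[fcm$unit == u, , drop = FALSE]
    out <- data.frame(unit = u, n = nrow(sub))
    for (q in qty) {
      out[[paste0(q, "_mean")]] <- mean(sub[[q]])
      out[[paste0(q, "_min")]] <- min(sub[[q]])
      out[[paste0(q, "_max")]] <- max(sub[[q]])
    }
    out
  }))
  trend_p <- c(cd_lb = trend_test(fcm$cd_lb, fcm$unit, log10 = TRUE),
               cd_umb = trend_test(fcm$cd_umb, fcm$unit, log10 = TRUE),
               umb_pct = trend_test(fcm$umb_pct, fcm$unit, log10 = FALSE))
  list(per_unit = per_unit, trend_p = trend_p)
}
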