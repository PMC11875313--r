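#' Classify a zeta potential measurement
#'
#' Maps a measured zeta potential (mV) to the four-level surface-charge
#' category used throughout the pipeline: `positive` (> 10 mV),
#' `negative` (< -10 mV), `neutral` (-10 mV to 10 mV inclusive), or
#' `not_determined` when the measurement is missing.
#'
#' @param zeta_mv Numeric vector of zeta potentials in mV; `NA` allowed.
#' @return Character vector of classes, same length as `zeta_mv`.
#' @examples
#' categorize_zeta(c(15, 10, -25, NA))
#' @export
categorize_zeta <- function(zeta_mv) {
  if (!is.numeric(zeta_mv) && !all(is.na(zeta_mv))) {
    bad <- which(!is.na(zeta_mv) & is.na(suppressWarnings(as.numeric(zeta_mv))))
    stop("non-numeric zeta potential at record(s): ", paste(bad, collapse = ", "))
  }
  z <- suppressWarnings(as.numeric(zeta_mv))
  out <- rep("not_determined", length(z))
  out[!is.na(z) & z > 10] <- "positive"
  out[!is.na(z) & z < -10] <- "negative"
  out[!is.na(z) & z >= -10 & z <= 10] <- "neutral"
  out
}

#' Binarize cell viability into a toxicity label
#'
#' Following the ISO 10993-5 convention, viability of at least 70% of the
#' untreated control is labelled safe (0); anything below is cytotoxic (1).
#'
#' @param viability_pct Numeric vector of percent viability (>= 0).
#' @return Integer vector of labels in \{0, 1\}.
#' @examples
#' binarize_viability(c(70, 69.9, 100))
#' @export
binarize_viability <- function(viability_pct) {
  v <- as.numeric(viability_pct)
  if (any(is.na(v))) stop("missing viability at record(s): ",
                          paste(which(is.na(v)), collapse = ", "))
  if (any(v < 0)) stop("negative viability at record(s): ",
                       paste(which(v < 0), collapse = ", "))
  as.integer(v < 70)
}

#' Impute missing categorical descriptors
#'
#' Missing surface coating is labelled `"Unmodified"` and missing shape
#' `"Sphere"`; all other categorical columns pass through unchanged. Empty
#' strings count as missing.
#'
#' @param records Data frame of nanoparticle records.
#' @return The data frame with `coating` and `shape` imputed.
#' @export
impute_missing_categoricals <- function(records) {
  fill <- function(x, value) {
    x <- as.character(x)
    x[is.na(x) | !nzchar(trimws(x))] <- value
    x
  }
  if ("coating" %in% names(records)) records$coating <- fill(records$coating, "Unmodified")
  if ("shape" %in% names(records)) records$shape <- fill(records$shape, "Sphere")
  records
}

#' Flag outliers by the 1.5 x IQR rule
#'
#' Values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are flagged. Quartiles use
#' the linear-interpolation convention (`stats::quantile` type 7). Flags are
#' advisory: removal is a separate, logged decision taken by [harmonize()].
#'
#' @param values Numeric vector with at least 4 finite values.
#' @return Logical vector, `TRUE` where a value falls outside the fences.
#' @export
flag_outliers_iqr <- function(values) {
  v <- as.numeric(values)
  if (sum(is.finite(v)) < 4) stop("need at least 4 finite values for IQR flagging")
  q <- quantile(v[is.finite(v)], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  is.finite(v) & (v < lo | v > hi)
}

#' Curate raw nanoparticle records
#'
#' Applies the full curation sequence to a raw table: categorical imputation,
#' zeta-potential classification, viability binarization, positivity checks on
#' size/concentration/time (log-undefined values are rejected), and 1.5 x IQR
#' outlier flagging on each continuous feature (computed on the log10 scale,
#' where these quantities are roughly symmetric). Flagged records are excluded
#' unless retained via `keep_ids`, mirroring a manual-inspection allowlist.
#'
#' @param records Data frame with columns `size_nm`, `conc_ug_per_ml`,
#'   `time_h`, `viability_pct`, `composition`, `coating`, `shape`, `species`,
#'   `organ`, `cell_class`, and either `zeta_mv` or `zeta_class`. An optional
#'   `row_id` column names records; row numbers are used otherwise.
#' @param keep_ids Row ids exempt from outlier exclusion (curator allowlist).
#' @param drop_outliers If `FALSE`, outliers are flagged in the log but kept.
#' @return Object of class `nanotox_records`: the curated data frame plus a
#'   `log` attribute describing every exclusion.
#' @export
harmonize <- function(records, keep_ids = character(), drop_outliers = TRUE) {
  stopifnot(is.data.frame(records))
  needed <- c("size_nm", "conc_ug_per_ml", "time_h", "viability_pct",
              "composition", "species", "organ", "cell_class")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))

  rec <- records
  if (!"row_id" %in% names(rec)) rec$row_id <- as.character(seq_len(nrow(rec)))
  rec$row_id <- as.character(rec$row_id)
  log <- character()

  rec <- impute_missing_categoricals(rec)
  if (!"zeta_class" %in% names(rec)) {
    if (!"zeta_mv" %in% names(rec)) rec$zeta_mv <- NA_real_
    rec$zeta_class <- categorize_zeta(rec$zeta_mv)
  } else if ("zeta_mv" %in% names(rec)) {
    # measured values take precedence over a pre-supplied class
    has_mv <- !is.na(rec$zeta_mv)
    rec$zeta_class[has_mv] <- categorize_zeta(rec$zeta_mv[has_mv])
  }

  cont <- c("size_nm", "conc_ug_per_ml", "time_h")
  for (f in cont) rec[[f]] <- as.numeric(rec[[f]])
  bad <- !stats::complete.cases(rec[cont]) |
    rec$size_nm <= 0 | rec$conc_ug_per_ml <= 0 | rec$time_h <= 0
  if (any(bad)) {
    log <- c(log, paste0("dropped (non-positive or missing continuous value): ",
                         paste(rec$row_id[bad], collapse = ", ")))
    rec <- rec[!bad, , drop = FALSE]
  }

  rec$label <- binarize_viability(rec$viability_pct)

  if (nrow(rec) >= 4) {
    flagged <- Reduce(`|`, lapply(cont, function(f) flag_outliers_iqr(log10(rec[[f]]))))
    flagged <- flagged & !(rec$row_id %in% keep_ids)
    if (any(flagged)) {
      log <- c(log, paste0(if (drop_outliers) "dropped" else "flagged",
                           " (1.5xIQR outlier on log10 scale): ",
                           paste(rec$row_id[flagged], collapse = ", ")))
      if (drop_outliers) rec <- rec[!flagged, , drop = FALSE]
    }
  }

  rownames(rec) <- NULL
  structure(rec, log = log, class = c("nanotox_records", "data.frame"))
}

#' @export
print.nanotox_records <- function(x, ...) {
  cat("Curated nanoparticle records: ", nrow(x), " rows, ",
      round(100 * mean(x$label), 1), "% toxic\n", sep = "")
  log <- attr(x, "log")
  if (length(log)) cat("Curation log:\n", paste(" -", log, collapse = "\n"), "\n")
  invisible(x)
}
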