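# Feature-table I/O. One detected species ("feature") carries the four
# extracted dimensions (m/z, retention time, CCS/mobility, intensity) plus
# signal-to-noise and an optional link to an MS2 spectrum.

.FEATURE_COLUMNS <- c("feature_id", "sample_id", "mz", "rt_min", "ccs_A2",
                      "mobility_1k0", "intensity", "snr", "ms2_ref")
.FEATURE_NUMERIC <- c("mz", "rt_min", "ccs_A2", "mobility_1k0",
                      "intensity", "snr")

#' Construct a feature table
#'
#' A feature table is a data.frame with one row per detected species and
#' columns `feature_id`, `sample_id`, `mz` (Da), `rt_min` (minutes),
#' `ccs_A2` (collisional cross section, A^2; NA when not measured),
#' `mobility_1k0` (1/k0, V s/cm^2; NA allowed), `intensity`, `snr`,
#' `ms2_ref` (spectrum id or NA).
#'
#' @param feature_id,sample_id character vectors.
#' @param mz,rt_min,intensity,snr numeric vectors.
#' @param ccs_A2,mobility_1k0 optional numeric vectors (NA = absent).
#' @param ms2_ref optional character vector (NA = no linked spectrum).
#' @return A validated `feature_table` data.frame.
#' @export
feature_table <- function(feature_id, sample_id, mz, rt_min,
                          ccs_A2 = NA_real_, mobility_1k0 = NA_real_,
                          intensity = 0, snr = 0, ms2_ref = NA_character_) {
  df <- data.frame(feature_id = as.character(feature_id),
                   sample_id = as.character(sample_id),
                   mz = as.numeric(mz), rt_min = as.numeric(rt_min),
                   ccs_A2 = as.numeric(ccs_A2),
                   mobility_1k0 = as.numeric(mobility_1k0),
                   intensity = as.numeric(intensity),
                   snr = as.numeric(snr),
                   ms2_ref = as.character(ms2_ref),
                   stringsAsFactors = FALSE)
  validate_feature_table(df)
}

#' Validate a feature table
#'
#' @param df a data.frame to validate.
#' @return The data.frame, invisibly classed as `feature_table`.
#' @export
validate_feature_table <- function(df) {
  missing_cols <- setdiff(.FEATURE_COLUMNS, names(df))
  if (length(missing_cols))
    stop("feature table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df)) {
    if (any(!is.finite(df$mz)) || any(df$mz <= 0))
      stop("feature table: mz must be finite and > 0")
    if (any(df$rt_min < 0, na.rm = TRUE))
      stop("feature table: rt_min must be >= 0")
    if (any(df$intensity < 0, na.rm = TRUE))
      stop("feature table: intensity must be >= 0")
    if (any(df$ccs_A2 <= 0, na.rm = TRUE))
      stop("feature table: ccs_A2 must be > 0 when present")
  }
  class(df) <- unique(c("feature_table", class(df)))
  df
}

#' Read a feature table from CSV
#'
#' The dialect is UTF-8 CSV with a mandatory header carrying exactly the
#' columns `feature_id,sample_id,mz,rt_min,ccs_A2,mobility_1k0,intensity,
#' snr,ms2_ref`; empty strings encode absent optional values.
#'
#' @param path file path.
#' @return A `feature_table` data.frame.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  missing_cols <- setdiff(.FEATURE_COLUMNS, names(df))
  if (length(missing_cols))
    stop("feature table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[, .FEATURE_COLUMNS]
  for (col in .FEATURE_NUMERIC) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(raw) & is.na(val))
    if (length(bad))
      stop("non-numeric value in column '", col, "' at data row ", bad[1],
           " of ", path)
    val[!nzchar(raw)] <- NA_real_
    df[[col]] <- val
  }
  df$ms2_ref[!nzchar(df$ms2_ref)] <- NA_character_
  validate_feature_table(df)
}

#' Write a feature table to CSV
#'
#' @param features a `feature_table`.
#' @param path destination file path.
#' @return The path, invisibly.
#' @export
write_feature_table <- function(features, path) {
  features <- validate_feature_table(as.data.frame(features))
  out <- features[, .FEATURE_COLUMNS]
  for (col in .FEATURE_NUMERIC)
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         format(out[[col]], digits = 15, trim = TRUE,
                                scientific = FALSE))
  out$ms2_ref[is.na(out$ms2_ref)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Detect in-source fragmentation artifacts among MS1 features
#'
#' During electrospray ionisation a molecule can fragment in the source,
#' producing an MS1 peak (e.g. `[M-H2O+H]+`) that mimics a distinct
#' compound. A (child, parent) pair is linked when the parent-minus-child
#' m/z difference matches a listed neutral loss within `mz_tol_ppm` (of the
#' parent m/z) and the two features co-elute within `rt_tol_min`. A child
#' may link to multiple co-eluting parents; downstream classification flags
#' such children as ambiguous rather than choosing one.
#'
#' @param features a `feature_table` from a single sample.
#' @param losses named numeric vector of neutral losses in Da
#'   (default `c(H2O = 18.0105646)`).
#' @param mz_tol_ppm mass tolerance in ppm (default 5).
#' @param rt_tol_min co-elution window in minutes (default 0.05).
#' @return data.frame with columns `child_id`, `parent_id`, `loss_name`,
#'   `neutral_loss` (Da), `rt_delta` (child minus parent, min), sorted by
#'   `abs(rt_delta)`. Zero rows when nothing links.
#' @export
detect_insource_artifacts <- function(features,
                                      losses = c(H2O = 18.0105646),
                                      mz_tol_ppm = 5, rt_tol_min = 0.05) {
  features <- validate_feature_table(as.data.frame(features))
  if (length(losses) == 0) stop("at least one neutral loss is required")
  if (is.null(names(losses)) || any(!nzchar(names(losses))))
    stop("losses must be a named numeric vector")
  n <- nrow(features)
  empty <- data.frame(child_id = character(), parent_id = character(),
                      loss_name = character(), neutral_loss = double(),
                      rt_delta = double(), stringsAsFactors = FALSE)
  if (n < 2) return(empty)

  rows <- list(); k <- 0L
  for (li in seq_along(losses)) {
    loss <- losses[[li]]
    dmz <- outer(features$mz, features$mz, "-")   # parent (row) - child (col)
    drt <- abs(outer(features$rt_min, features$rt_min, "-"))
    tol_da <- features$mz * mz_tol_ppm * 1e-6     # per-parent tolerance
    hit <- which(abs(dmz - loss) <= tol_da[row(dmz)] & drt <= rt_tol_min &
                   row(dmz) != col(dmz), arr.ind = TRUE)
    if (!nrow(hit)) next
    for (r in seq_len(nrow(hit))) {
      pi <- hit[r, 1]; ci <- hit[r, 2]
      if (features$mz[ci] >= features$mz[pi]) next
      k <- k + 1L
      rows[[k]] <- data.frame(
        child_id = features$feature_id[ci],
        parent_id = features$feature_id[pi],
        loss_name = names(losses)[li],
        neutral_loss = features$mz[pi] - features$mz[ci],
        rt_delta = features$rt_min[ci] - features$rt_min[pi],
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(abs(out$rt_delta), out$child_id, out$parent_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
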