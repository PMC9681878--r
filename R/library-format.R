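# MSP-like text format for the reference spectral library. Each entry is a
# block of KEY: value lines (NAME, ABBREV, FORMULA, ADDUCT, RT_MIN, CCS_A2,
# PROVENANCE) followed by "NUM PEAKS: n" and n "mz intensity" lines; blocks
# are separated by blank lines.

#' Construct a library entry
#'
#' @param name full compound name.
#' @param abbreviation short unique id (e.g. `"CBD"`).
#' @param neutral_formula neutral `elemental_formula` (or Hill string).
#' @param adduct `adduct_spec` or label (default `"[M+H]+"`).
#' @param rt retention time, minutes (> 0).
#' @param ccs collisional cross section, A^2 (> 0).
#' @param ms2 optional `ms2_spectrum` reference spectrum.
#' @param provenance free-text origin of the entry's values; entries whose
#'   RT/CCS/MS2 are not instrument-derived are flagged `"synthetic"`.
#' @return A list of class `library_entry`; the field `mz` holds the
#'   theoretical adduct ion m/z computed from the formula.
#' @export
library_entry <- function(name, abbreviation, neutral_formula,
                          adduct = "[M+H]+", rt, ccs, ms2 = NULL,
                          provenance = "") {
  stopifnot(rt > 0, ccs > 0)
  f <- as_formula_counts(neutral_formula)
  a <- adduct_spec(adduct)
  structure(list(name = name, abbreviation = abbreviation,
                 neutral_formula = f, adduct = a,
                 mz = ion_mz(f, a), rt = rt, ccs = ccs,
                 ms2 = ms2, provenance = provenance),
            class = "library_entry")
}

#' @export
print.library_entry <- function(x, ...) {
  cat(sprintf("<library_entry> %s (%s)  %s %s  m/z %.4f  RT %.2f  CCS %.1f\n",
              x$abbreviation, x$name, format_formula(x$neutral_formula),
              x$adduct$label, x$mz, x$rt, x$ccs))
  invisible(x)
}

#' Read a spectral library
#'
#' @param path path to an MSP-like library file.
#' @return Named list of `library_entry` (names = abbreviations).
#' @export
read_library <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  entries <- list()
  i <- 1L; n <- length(lines)
  known <- c("NAME", "ABBREV", "FORMULA", "ADDUCT", "RT_MIN", "CCS_A2",
             "PROVENANCE")
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    kv <- list(); extra <- character(); peaks <- NULL
    while (i <= n && nzchar(trimws(lines[i]))) {
      line <- trimws(lines[i])
      if (grepl("^NUM PEAKS:", line, ignore.case = TRUE)) {
        np <- as.integer(trimws(sub("^NUM PEAKS:", "", line,
                                    ignore.case = TRUE)))
        if (np > 0) {
          pk <- lines[(i + 1L):(i + np)]
          parts <- strsplit(trimws(pk), "[ \t]+")
          peaks <- data.frame(
            mz = vapply(parts, function(p) as.numeric(p[1]), 0),
            intensity = vapply(parts, function(p) as.numeric(p[2]), 0))
          i <- i + np
        } else peaks <- data.frame(mz = numeric(), intensity = numeric())
      } else if (grepl(":", line, fixed = TRUE)) {
        key <- toupper(trimws(sub(":.*$", "", line)))
        val <- trimws(sub("^[^:]*:", "", line))
        if (key %in% known) kv[[key]] <- val
        else {
          warning("unknown library key '", key, "' kept as provenance text")
          extra <- c(extra, line)
        }
      }
      i <- i + 1L
    }
    need <- c("NAME", "ABBREV", "FORMULA", "ADDUCT", "RT_MIN", "CCS_A2")
    miss <- setdiff(need, names(kv))
    if (length(miss))
      stop("library entry missing key(s): ", paste(miss, collapse = ", "))
    if (kv$ABBREV %in% names(entries))
      stop("duplicate library abbreviation: ", kv$ABBREV)
    prov <- kv$PROVENANCE
    if (is.null(prov)) prov <- ""
    if (length(extra)) prov <- paste(c(prov, extra), collapse = "; ")
    ms2 <- NULL
    if (!is.null(peaks) && nrow(peaks) > 0) {
      ms2 <- ms2_spectrum(kv$ABBREV,
                          ion_mz(parse_formula(kv$FORMULA),
                                 adduct_spec(kv$ADDUCT)),
                          peaks$mz, peaks$intensity)
    }
    entries[[kv$ABBREV]] <- library_entry(
      name = kv$NAME, abbreviation = kv$ABBREV,
      neutral_formula = parse_formula(kv$FORMULA),
      adduct = adduct_spec(kv$ADDUCT),
      rt = as.numeric(kv$RT_MIN), ccs = as.numeric(kv$CCS_A2),
      ms2 = ms2, provenance = prov)
  }
  entries
}

#' Write a spectral library
#'
#' @param entries list of `library_entry`.
#' @param path destination file path.
#' @return The path, invisibly.
#' @export
write_library <- function(entries, path) {
  abbr <- vapply(entries, function(e) e$abbreviation, character(1))
  if (anyDuplicated(abbr))
    stop("duplicate library abbreviation: ", abbr[duplicated(abbr)][1])
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (e in entries) {
    writeLines(c(paste0("NAME: ", e$name),
                 paste0("ABBREV: ", e$abbreviation),
                 paste0("FORMULA: ", format_formula(e$neutral_formula)),
                 paste0("ADDUCT: ", e$adduct$label),
                 sprintf("RT_MIN: %.4f", e$rt),
                 sprintf("CCS_A2: %.4f", e$ccs),
                 paste0("PROVENANCE: ", e$provenance)), con)
    if (is.null(e$ms2)) {
      writeLines("NUM PEAKS: 0", con)
    } else {
      writeLines(sprintf("NUM PEAKS: %d", nrow(e$ms2$peaks)), con)
      writeLines(sprintf("%.6f %.6f", e$ms2$peaks$mz, e$ms2$peaks$intensity),
                 con)
    }
    writeLines("", con)
  }
  invisible(path)
}
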