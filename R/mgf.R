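# Minimal MGF (Mascot Generic Format) reader/writer for MS2 spectra.
# Only the keys this pipeline uses are interpreted: TITLE (spectrum id),
# PEPMASS (precursor m/z), optional COLLISION_ENERGY; peak lines are
# "mz intensity". Values round-trip at 6 decimal places.

#' Construct an MS2 spectrum
#'
#' @param spectrum_id character id.
#' @param precursor_mz precursor m/z (Da, > 0).
#' @param mz,intensity numeric peak vectors (same length, >= 1 peak).
#' @param collision_energy optional character metadata (e.g. `"25-50 eV"`).
#' @return A list of class `ms2_spectrum` with fields `spectrum_id`,
#'   `precursor_mz`, `peaks` (data.frame `mz`, `intensity`, sorted by mz),
#'   `collision_energy`.
#' @export
ms2_spectrum <- function(spectrum_id, precursor_mz, mz, intensity,
                         collision_energy = NA_character_) {
  stopifnot(length(mz) == length(intensity), length(mz) >= 1,
            precursor_mz > 0, all(intensity >= 0))
  o <- order(mz)
  structure(list(spectrum_id = as.character(spectrum_id),
                 precursor_mz = as.numeric(precursor_mz),
                 peaks = data.frame(mz = as.numeric(mz[o]),
                                    intensity = as.numeric(intensity[o])),
                 collision_energy = as.character(collision_energy)),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum> %s  precursor %.4f  %d peak(s)\n",
              x$spectrum_id, x$precursor_mz, nrow(x$peaks)))
  invisible(x)
}

#' Read MS2 spectra from an MGF file
#'
#' @param path file path.
#' @return Named list of `ms2_spectrum` (names = spectrum ids).
#' @export
read_ms2_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  spectra <- list()
  i <- 1L; n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (line == "BEGIN IONS") {
      title <- NA_character_; pepmass <- NA_real_; ce <- NA_character_
      mzv <- c(); intv <- c()
      i <- i + 1L
      closed <- FALSE
      while (i <= n) {
        line <- trimws(lines[i])
        if (line == "END IONS") { closed <- TRUE; break }
        if (grepl("^TITLE=", line)) {
          title <- sub("^TITLE=", "", line)
        } else if (grepl("^PEPMASS=", line)) {
          pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", line),
                                         "[ \t]+")[[1]][1])
        } else if (grepl("^COLLISION_ENERGY=", line)) {
          ce <- sub("^COLLISION_ENERGY=", "", line)
        } else if (grepl("^[0-9]", line)) {
          parts <- strsplit(line, "[ \t]+")[[1]]
          mzv <- c(mzv, as.numeric(parts[1]))
          intv <- c(intv, as.numeric(parts[2]))
        }
        i <- i + 1L
      }
      if (!closed) stop("MGF block without END IONS in ", path)
      if (is.na(pepmass)) stop("MGF block without PEPMASS in ", path)
      if (is.na(title)) title <- paste0("spectrum_", length(spectra) + 1L)
      if (!length(mzv)) stop("MGF block '", title, "' has no peaks")
      spectra[[title]] <- ms2_spectrum(title, pepmass, mzv, intv, ce)
    }
    i <- i + 1L
  }
  spectra
}

#' Write MS2 spectra to an MGF file
#'
#' @param spectra list of `ms2_spectrum`.
#' @param path destination file path.
#' @return The path, invisibly.
#' @export
write_ms2_mgf <- function(spectra, path) {
  if (inherits(spectra, "ms2_spectrum")) spectra <- list(spectra)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in spectra) {
    stopifnot(inherits(s, "ms2_spectrum"))
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$spectrum_id), con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    if (!is.na(s$collision_energy))
      writeLines(paste0("COLLISION_ENERGY=", s$collision_energy), con)
    writeLines(sprintf("%.6f %.6f", s$peaks$mz, s$peaks$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}
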