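# The packaged 39-compound phytocannabinoid reference library.
#
# Retention times and CCS values printed in the study's identification
# tables are used where available; all other RT/CCS values and all MS2
# spectra without published fragments are synthetic placeholders and are
# flagged provenance = "synthetic ..." so tests and users can tell them
# apart from instrument-derived values.

.ROSTER <- local({
  r <- function(abbrev, name, formula, rt, ccs, prov)
    data.frame(abbrev = abbrev, name = name, formula = formula,
               rt = rt, ccs = ccs, provenance = prov,
               stringsAsFactors = FALSE)
  rbind(
    r("CBC",          "cannabichromene",                 "C21H30O2", 11.50, 187.5, "synthetic RT/CCS/MS2"),
    r("11-OH-D9-THC", "11-hydroxy-delta9-tetrahydrocannabinol", "C21H30O3", 2.90, 189.0, "synthetic RT/CCS/MS2"),
    r("CBCVA",        "cannabichromevarinic acid",       "C20H26O4", 7.40, 189.5, "synthetic RT/CCS/MS2"),
    r("7-OH-CBD",     "7-hydroxy-cannabidiol",           "C21H30O3", 2.03, 188.0, "table RT; synthetic CCS/MS2"),
    r("CBCO",         "cannabichromeorcin",              "C17H22O2", 5.60, 167.0, "synthetic RT/CCS/MS2"),
    r("CBDA",         "cannabidiolic acid",              "C22H30O4", 4.40, 191.0, "synthetic RT/CCS/MS2"),
    r("7-COOH-CBD",   "7-carboxy-cannabidiol",           "C21H28O4", 1.55, 190.0, "synthetic RT/CCS/MS2"),
    r("CBT",          "cannabicitran",                   "C21H30O2", 7.80, 184.0, "synthetic RT/CCS/MS2"),
    r("CBDB",         "cannabidibutol",                  "C20H28O2", 3.92, 180.5, "table RT; synthetic CCS/MS2"),
    r("CBCA",         "cannabichromenic acid",           "C22H30O4", 12.20, 192.5, "synthetic RT/CCS/MS2"),
    r("6a-OH-CBD",    "6-alpha-hydroxy-cannabidiol",     "C21H30O3", 1.84, 183.0, "table RT; synthetic CCS/MS2"),
    r("CBD",          "cannabidiol",                     "C21H30O2", 4.99, 185.3, "table RT; synthetic CCS; published base fragment"),
    r("CBDV",         "cannabidivarin",                  "C19H26O2", 3.20, 174.0, "table RT; synthetic CCS/MS2"),
    r("CBLA",         "cannabicyclolic acid",            "C22H30O4", 12.80, 193.5, "synthetic RT/CCS/MS2"),
    r("CBE",          "cannabielsoin",                   "C21H30O3", 4.17, 186.0, "table RT; published CCS and fragments"),
    r("THCVA",        "tetrahydrocannabivarinic acid",   "C20H26O4", 6.90, 188.0, "synthetic RT/CCS/MS2"),
    r("CBCQ",         "cannabichromenquinone",           "C21H28O3", 6.20, 186.5, "synthetic RT/CCS/MS2"),
    r("D9-THC",       "delta9-tetrahydrocannabinol",     "C21H30O2", 8.20, 184.5, "synthetic RT/CCS/MS2"),
    r("CBND",         "cannabinodiol",                   "C21H26O2", 7.00, 181.0, "synthetic RT/CCS/MS2"),
    r("THCV",         "tetrahydrocannabivarin",          "C19H26O2", 5.20, 172.5, "synthetic RT/CCS/MS2"),
    r("CBGQ",         "cannabigeroquinone",              "C21H30O3", 6.70, 191.5, "synthetic RT/CCS/MS2"),
    r("CBGA",         "cannabigerolic acid",             "C22H32O4", 9.40, 195.0, "synthetic RT/CCS/MS2"),
    r("THCA",         "delta9-tetrahydrocannabinolic acid A", "C22H30O4", 13.30, 194.0, "synthetic RT/CCS/MS2"),
    r("CBNA",         "cannabinolic acid",               "C22H26O4", 10.80, 190.5, "synthetic RT/CCS/MS2"),
    r("11-COOH-D9-THC", "11-nor-9-carboxy-delta9-tetrahydrocannabinol", "C21H28O4", 2.30, 189.5, "synthetic RT/CCS/MS2"),
    r("CBDP",         "cannabidiphorol",                 "C23H34O2", 8.95, 196.0, "table RT; synthetic CCS/MS2"),
    r("CBGVA",        "cannabigerovarinic acid",         "C20H28O4", 5.90, 186.0, "synthetic RT/CCS/MS2"),
    r("CBDVA",        "cannabidivarinic acid",           "C20H26O4", 2.60, 185.5, "synthetic RT/CCS/MS2"),
    r("HU-331",       "cannabidiol hydroxyquinone",      "C21H28O3", 9.92, 185.0, "table RT; synthetic CCS/MS2"),
    r("CBNM",         "cannabinol monomethyl ether",     "C22H28O2", 11.00, 186.0, "synthetic RT/CCS/MS2"),
    r("CBG",          "cannabigerol",                    "C21H32O2", 5.40, 188.5, "synthetic RT/CCS/MS2"),
    r("D8-THC",       "delta8-tetrahydrocannabinol",     "C21H30O2", 8.50, 184.8, "synthetic RT/CCS/MS2"),
    r("CBN",          "cannabinol",                      "C21H26O2", 6.40, 180.0, "synthetic RT/CCS/MS2"),
    r("CBCV",         "cannabichromevarin",              "C19H26O2", 9.10, 173.5, "synthetic RT/CCS/MS2"),
    r("CBL",          "cannabicyclol",                   "C21H30O2", 12.50, 183.0, "synthetic RT/CCS/MS2"),
    r("CBDH",         "cannabidihexol",                  "C22H32O2", 6.56, 190.5, "table RT; synthetic CCS/MS2"),
    r("CBDM",         "cannabidiol monomethyl ether",    "C22H32O2", 7.20, 189.8, "synthetic RT/CCS/MS2"),
    r("D9-THCH",      "delta9-tetrahydrocannabihexol",   "C22H32O2", 10.20, 189.2, "synthetic RT/CCS/MS2"),
    r("D3-D9-THC",    "delta9-tetrahydrocannabinol-D3 (internal standard)", "C21H27D3O2", 8.20, 184.5, "internal standard; synthetic RT/CCS/MS2")
  )
})

# Published diagnostic fragment ions (m/z as quoted) and synthetic
# placeholder fragments used for entries without printed MS2 data.
.MS2_TEMPLATES <- list(
  # CBD-type core: olivetol moiety ion (C12H17O2+)
  CBD      = data.frame(mz = c(193.1228, 259.1693, 135.1169),
                        intensity = c(100, 35, 25)),
  # CBE-type core
  CBE      = data.frame(mz = c(205.1224, 135.0442, 109.1042),
                        intensity = c(100, 60, 30)),
  # CBDH/CBDM/THCH family: homologated olivetol-type ion (C13H19O2+)
  CBDH     = data.frame(mz = c(207.1379, 193.1228),
                        intensity = c(100, 20))
)

.ms2_template_for <- function(abbrev, formula, adduct = "[M+H]+") {
  pre <- ion_mz(formula, adduct)
  if (abbrev %in% c("CBD", "CBDV", "CBDB", "CBDP", "6a-OH-CBD", "7-OH-CBD"))
    pk <- .MS2_TEMPLATES$CBD
  else if (abbrev == "CBE")
    pk <- .MS2_TEMPLATES$CBE
  else if (abbrev %in% c("CBDH", "CBDM", "D9-THCH"))
    pk <- .MS2_TEMPLATES$CBDH
  else {
    # synthetic placeholder: water loss plus a generic low-mass fragment
    pk <- data.frame(mz = c(pre - 18.0105646, 119.0855),
                     intensity = c(100, 40))
  }
  # hydroxylated standards fragment differently from the parent: shift the
  # secondary synthetic peaks so isomeric standards are distinguishable
  if (abbrev %in% c("6a-OH-CBD", "7-OH-CBD")) {
    pk <- rbind(pk, data.frame(mz = pre - 18.0105646,
                               intensity = if (abbrev == "6a-OH-CBD") 80 else 50))
  }
  ms2_spectrum(paste0("lib_", abbrev), pre, pk$mz, pk$intensity, "25-50 eV")
}

#' The packaged phytocannabinoid reference library
#'
#' Builds the 39-entry reference library: the 35 standards of the optimised
#' separation panel, the later additions cannabidihexol (CBDH), cannabidiol
#' monomethyl ether (CBDM) and delta9-tetrahydrocannabihexol (THCH), and the
#' deuterated internal standard D3-delta9-THC. Theoretical m/z values are
#' computed from each entry's neutral formula and adduct. Entries whose
#' RT/CCS/MS2 are not study-derived carry `provenance = "synthetic ..."`.
#'
#' @return Named list of 39 `library_entry` objects.
#' @export
default_library <- function() {
  entries <- lapply(seq_len(nrow(.ROSTER)), function(i) {
    row <- .ROSTER[i, ]
    library_entry(
      name = row$name, abbreviation = row$abbrev,
      neutral_formula = parse_formula(row$formula),
      adduct = "[M+H]+", rt = row$rt, ccs = row$ccs,
      ms2 = .ms2_template_for(row$abbrev, row$formula),
      provenance = row$provenance)
  })
  names(entries) <- .ROSTER$abbrev
  entries
}
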