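## Deconvoluted spectrum container and file formats: MGF dialect (neutral-mass
## peak lists), annotated MGF for training data, and the results table.

#' Construct a deconvoluted spectrum
#'
#' @param scan_id scan identifier string.
#' @param precursor_mass neutral, adduct-corrected precursor mass (Da).
#' @param precursor_charge observed precursor charge (>= 1).
#' @param rt retention time in minutes.
#' @param peaks data.frame with `neutral_mass`, `intensity`, optional `charge`.
#' @return a `spectrum` object; peaks are sorted by mass and given intensity
#'   ranks (1 = most intense).
#' @export
spectrum <- function(scan_id, precursor_mass, precursor_charge, rt, peaks) {
  stopifnot(precursor_charge >= 1)
  if (is.null(peaks$charge)) peaks$charge <- 1L
  peaks <- peaks[order(peaks$neutral_mass), , drop = FALSE]
  peaks$rank <- rank(-peaks$intensity, ties.method = "first")
  rownames(peaks) <- NULL
  structure(
    list(scan_id = as.character(scan_id), precursor_mass = precursor_mass,
         precursor_charge = as.integer(precursor_charge), rt = rt,
         peaks = peaks),
    class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum %s  precursor %.4f (%d+)  rt %.2f min  %d peaks>\n",
              x$scan_id, x$precursor_mass, x$precursor_charge, x$rt,
              nrow(x$peaks)))
  invisible(x)
}

#' Read spectra from an MGF file (neutral-mass dialect)
#'
#' Standard BEGIN IONS/END IONS framing. When a block carries the `CHARGE=0`
#' sentinel, PEPMASS is taken as the neutral precursor mass and the true
#' charge is read from `PRECURSOR_CHARGE=`; otherwise PEPMASS is m/z and is
#' converted with the stated charge. Peak lines are
#' `mass intensity [charge] [label]`; non-numeric peak lines are skipped and
#' counted in the `skipped_lines` attribute.
#'
#' @param path MGF file.
#' @return list of [spectrum()] objects (annotated spectra carry an
#'   `annotations` data.frame and `assignment` fields when labels present).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  i <- 1L
  n <- length(lines)
  skipped <- 0L
  while (i <= n) {
    if (trimws(lines[i]) != "BEGIN IONS") { i <- i + 1L; next }
    hdr <- list(TITLE = NA, PEPMASS = NA, CHARGE = NA, RTINSECONDS = NA,
                PRECURSOR_CHARGE = NA, GLYCOPEPTIDE = NA)
    pk_mass <- numeric(0); pk_int <- numeric(0); pk_z <- integer(0)
    pk_lab <- character(0)
    i <- i + 1L
    while (i <= n && trimws(lines[i]) != "END IONS") {
      ln <- trimws(lines[i])
      if (!nzchar(ln)) { i <- i + 1L; next }
      if (grepl("^[A-Z_]+=", ln)) {
        key <- sub("=.*$", "", ln)
        val <- sub("^[A-Z_]+=", "", ln)
        hdr[[key]] <- val
      } else {
        toks <- strsplit(ln, "[ \t]+")[[1]]
        m <- suppressWarnings(as.numeric(toks[1]))
        it <- suppressWarnings(as.numeric(toks[2]))
        if (is.na(m) || is.na(it)) {
          skipped <- skipped + 1L
        } else {
          z <- if (length(toks) >= 3L)
            suppressWarnings(as.integer(toks[3])) else NA_integer_
          lab <- if (length(toks) >= 4L) toks[4] else ""
          pk_mass <- c(pk_mass, m); pk_int <- c(pk_int, it)
          pk_z <- c(pk_z, ifelse(is.na(z), 1L, z))
          pk_lab <- c(pk_lab, lab)
        }
      }
      i <- i + 1L
    }
    if (i > n) stop("unterminated MGF block (scan ",
                    if (is.na(hdr$TITLE)) "?" else hdr$TITLE, ")")
    i <- i + 1L
    if (is.na(hdr$PEPMASS)) stop("MGF block missing PEPMASS (scan ",
                                 if (is.na(hdr$TITLE)) "?" else hdr$TITLE, ")")
    pepmass <- as.numeric(strsplit(hdr$PEPMASS, "[ \t]+")[[1]][1])
    chg_raw <- if (is.na(hdr$CHARGE)) 1L else
      as.integer(sub("\\+$", "", hdr$CHARGE))
    if (!is.na(chg_raw) && chg_raw == 0L) {
      ## neutral-mass sentinel dialect
      z <- if (!is.na(hdr$PRECURSOR_CHARGE))
        as.integer(hdr$PRECURSOR_CHARGE) else 1L
      neutral <- pepmass
    } else {
      z <- max(chg_raw, 1L)
      neutral <- pepmass * z - z * PROTON_MASS
    }
    rt <- if (!is.na(hdr$RTINSECONDS)) as.numeric(hdr$RTINSECONDS) / 60 else NA_real_
    sp <- spectrum(scan_id = if (is.na(hdr$TITLE)) sprintf("scan=%d", length(spectra) + 1L) else hdr$TITLE,
                   precursor_mass = neutral, precursor_charge = z, rt = rt,
                   peaks = data.frame(neutral_mass = pk_mass,
                                      intensity = pk_int, charge = pk_z,
                                      label = pk_lab,
                                      stringsAsFactors = FALSE))
    if (!is.na(hdr$GLYCOPEPTIDE)) {
      parts <- strsplit(hdr$GLYCOPEPTIDE, "\\|")[[1]]
      sp$assignment <- list(peptide = parts[1],
                            glycan = if (length(parts) > 1L) parts[2] else NA)
    }
    spectra[[length(spectra) + 1L]] <- sp
  }
  attr(spectra, "skipped_lines") <- skipped
  if (skipped > 0L)
    warning(sprintf("skipped %d non-numeric peak line(s)", skipped))
  spectra
}

format_peak_line <- function(mass, intensity, charge, label = "") {
  base <- sprintf("%.6f %.4f %d", mass, intensity, charge)
  if (nzchar(label)) paste(base, label) else base
}

#' Write spectra to the neutral-mass MGF dialect
#'
#' @param spectra list of [spectrum()] objects.
#' @param path output file.
#' @param annotated write per-peak fragment labels and the GLYCOPEPTIDE
#'   header (requires `assignment`/`annotations` on each spectrum).
#' @export
write_mgf <- function(spectra, path, annotated = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", sp$scan_id), con)
    if (!is.na(sp$rt)) writeLines(sprintf("RTINSECONDS=%.3f", sp$rt * 60), con)
    writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mass), con)
    writeLines("CHARGE=0", con)
    writeLines(sprintf("PRECURSOR_CHARGE=%d", sp$precursor_charge), con)
    if (annotated) {
      if (is.null(sp$assignment))
        stop("unresolved assignment for scan ", sp$scan_id)
      writeLines(sprintf("GLYCOPEPTIDE=%s|%s", sp$assignment$peptide,
                         sp$assignment$glycan), con)
    }
    labs <- if (annotated && !is.null(sp$peaks$label)) sp$peaks$label
      else rep("", nrow(sp$peaks))
    for (k in seq_len(nrow(sp$peaks))) {
      writeLines(format_peak_line(sp$peaks$neutral_mass[k],
                                  sp$peaks$intensity[k],
                                  sp$peaks$charge[k], labs[k]), con)
    }
    writeLines("END IONS", con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write annotated spectra (training format)
#'
#' Peak labels use the grammar `b4` / `y7` (backbone), `Y:{HexNAc:2; Hex:1}` /
#' `Y:0` (peptide+Y), `oxonium:NeuAc`; unannotated peaks carry no label.
#'
#' @param spectra list of annotated [spectrum()] objects.
#' @param path output file.
#' @export
write_annotated_mgf <- function(spectra, path) write_mgf(spectra, path, annotated = TRUE)

.RESULT_COLUMNS <- c(
  "scan_id", "peptide", "protein", "site", "glycan", "mass_shift",
  "is_decoy_peptide", "is_decoy_glycan", "score_peptide", "score_glycan",
  "score_total", "coverage_P", "coverage_G", "coverage_G_core",
  "fdr_peptide", "fdr_glycan", "fdr_joint", "glycan_fdr_defined",
  "rt", "rt_score", "u_g", "revised_from")

#' Write a GPSM results table
#'
#' Tab-delimited; scores serialized at 4 decimals. Missing columns are filled
#' with NA so that partial pipelines still round-trip.
#'
#' @param gpsms data.frame of scored identifications.
#' @param path output file.
#' @export
write_results <- function(gpsms, path) {
  if (is.null(gpsms) || nrow(gpsms) == 0L) {
    gpsms <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(.RESULT_COLUMNS)), .RESULT_COLUMNS))
  } else {
    for (cl in setdiff(.RESULT_COLUMNS, names(gpsms))) gpsms[[cl]] <- NA
    gpsms <- gpsms[, .RESULT_COLUMNS, drop = FALSE]
    num <- vapply(gpsms, is.numeric, logical(1)) &
      !(names(gpsms) %in% c("rt", "mass_shift"))
    gpsms[num] <- lapply(gpsms[num], function(x) round(x, 4))
  }
  utils::write.table(gpsms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GPSM results table written by [write_results()]
#' @param path results TSV.
#' @return data.frame.
#' @export
read_results <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
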