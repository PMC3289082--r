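#' Construct a single MS/MS spectrum
#'
#' A spectrum is a centroided peak list plus the precursor (parent) m/z.
#' Peaks are stored sorted strictly ascending in m/z: peaks sharing an
#' identical m/z are merged by summing their intensities, and zero-intensity
#' peaks are dropped, so that downstream pair-enumeration predicates can
#' assume distinct m/z values and non-degenerate intensity ratios.
#'
#' @param spectrum_id Opaque identifier string.
#' @param precursor_mz Precursor m/z in Thomson; must be positive.
#' @param mz Numeric vector of peak m/z values (Th); all positive.
#' @param intensity Numeric vector of non-negative peak intensities, same
#'   length as `mz`.
#' @param true_charge Optional known precursor charge (2 or 3) used only for
#'   evaluation; `NA` when unknown.
#'
#' @return An object of class `ms_spectrum` with fields `spectrum_id`,
#'   `precursor_mz`, `mz`, `intensity`, `true_charge`.
#' @examples
#' sp <- spectrum("s1", 500, c(200, 100), c(5, 10))
#' sp$mz  # sorted ascending
#' @export
spectrum <- function(spectrum_id, precursor_mz, mz, intensity, true_charge = NA_integer_) {
  stopifnot(
    is.character(spectrum_id), length(spectrum_id) == 1L,
    is.numeric(precursor_mz), length(precursor_mz) == 1L, precursor_mz > 0,
    length(mz) == length(intensity)
  )
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) > 0) {
    if (any(!is.finite(mz)) || any(!is.finite(intensity))) {
      stop("non-finite peak values in spectrum '", spectrum_id, "'")
    }
    if (any(mz <= 0) || any(intensity < 0)) {
      stop("peaks must have mz > 0 and intensity >= 0 in spectrum '", spectrum_id, "'")
    }
    keep <- intensity > 0
    mz <- mz[keep]
    intensity <- intensity[keep]
    if (length(mz) > 0) {
      o <- order(mz)
      mz <- mz[o]
      intensity <- intensity[o]
      if (anyDuplicated(mz)) {
        intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)), sum))
        mz <- unique(mz)
      }
    }
  }
  tc <- suppressWarnings(as.integer(true_charge))
  if (!is.na(tc) && !tc %in% c(2L, 3L)) tc <- NA_integer_
  structure(
    list(
      spectrum_id = spectrum_id,
      precursor_mz = as.numeric(precursor_mz),
      mz = mz,
      intensity = intensity,
      true_charge = tc
    ),
    class = "ms_spectrum"
  )
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf(
    "<ms_spectrum '%s'> precursor m/z %.4f, %d peaks%s\n",
    x$spectrum_id, x$precursor_mz, length(x$mz),
    if (is.na(x$true_charge)) "" else sprintf(", true charge %d+", x$true_charge)
  ))
  invisible(x)
}

#' Construct a collection of spectra
#'
#' @param spectra List of [spectrum()] objects. Duplicate `spectrum_id`s are
#'   made unique with a warning.
#' @param source_path Provenance string (file the collection came from, or a
#'   description of how it was generated).
#'
#' @return An object of class `ms_spectrum_collection`.
#' @export
spectrum_collection <- function(spectra, source_path = NA_character_) {
  stopifnot(is.list(spectra), all(vapply(spectra, inherits, logical(1), "ms_spectrum")))
  ids <- vapply(spectra, `[[`, character(1), "spectrum_id")
  if (anyDuplicated(ids)) {
    warning("duplicate spectrum_id values made unique")
    ids <- make.unique(ids)
    for (k in seq_along(spectra)) spectra[[k]]$spectrum_id <- ids[k]
  }
  structure(
    list(spectra = spectra, source_path = source_path),
    class = "ms_spectrum_collection"
  )
}

#' @export
print.ms_spectrum_collection <- function(x, ...) {
  nlab <- sum(!is.na(true_charges(x)))
  cat(sprintf(
    "<ms_spectrum_collection> %d spectra (%d with known charge), source: %s\n",
    length(x$spectra), nlab, x$source_path
  ))
  invisible(x)
}

#' @export
length.ms_spectrum_collection <- function(x) length(x$spectra)

#' Known precursor charges of a collection
#'
#' @param collection An `ms_spectrum_collection`.
#' @return Integer vector of true charges (`NA` where unknown), one per spectrum.
#' @export
true_charges <- function(collection) {
  vapply(collection$spectra, `[[`, integer(1), "true_charge")
}

#' Spectrum identifiers of a collection
#'
#' @param collection An `ms_spectrum_collection`.
#' @return Character vector of spectrum ids.
#' @export
spectrum_ids <- function(collection) {
  vapply(collection$spectra, `[[`, character(1), "spectrum_id")
}

#' Read a Mascot generic format (MGF) peak-list file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks. The first token of `PEPMASS`
#' becomes the precursor m/z; a `CHARGE` line is stored as the known charge
#' only when it reads `2+` or `3+` (other values are dropped, since the
#' classifier only separates these two states). Peaks are sorted ascending,
#' identical m/z merged, zero intensities removed (see [spectrum()]).
#'
#' @param path Path to an MGF file.
#' @return An [spectrum_collection()].
#' @examples
#' f <- tempfile(fileext = ".mgf")
#' writeLines(c("BEGIN IONS", "TITLE=a", "PEPMASS=500.0",
#'              "100 10", "200 5", "END IONS"), f)
#' read_mgf(f)
#' @export
read_mgf <- function(path) {
  stopifnot(file.exists(path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty MGF file: ", path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) == 0 || length(begins) != length(ends) || any(ends < begins)) {
    stop("malformed MGF (unbalanced BEGIN IONS/END IONS): ", path)
  }
  spectra <- vector("list", length(begins))
  for (b in seq_along(begins)) {
    block <- lines[(begins[b] + 1L):(ends[b] - 1L)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- block[is_kv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    if (!"PEPMASS" %in% keys) stop("MGF block ", b, ": missing PEPMASS")
    pepmass <- suppressWarnings(as.numeric(strsplit(trimws(vals[match("PEPMASS", keys)]),
                                                    "[ \t]+")[[1]][1]))
    if (!is.finite(pepmass)) stop("MGF block ", b, ": non-numeric PEPMASS")
    id <- if ("TITLE" %in% keys) trimws(vals[match("TITLE", keys)]) else sprintf("spectrum_%d", b)
    tc <- NA_integer_
    if ("CHARGE" %in% keys) {
      cs <- trimws(vals[match("CHARGE", keys)])
      if (grepl("^[23]\\+$", cs)) tc <- as.integer(substr(cs, 1, 1))
    }
    pk <- block[!is_kv]
    mzv <- numeric(0)
    inten <- numeric(0)
    if (length(pk) > 0) {
      toks <- strsplit(pk, "[ \t]+")
      bad <- vapply(toks, function(t) length(t) < 2, logical(1))
      if (any(bad)) stop("MGF block ", b, ": malformed peak line '", pk[which(bad)[1]], "'")
      mzv <- suppressWarnings(as.numeric(vapply(toks, `[`, character(1), 1L)))
      inten <- suppressWarnings(as.numeric(vapply(toks, `[`, character(1), 2L)))
      if (any(!is.finite(mzv)) || any(!is.finite(inten))) {
        stop("MGF block ", b, ": non-numeric peak line")
      }
    }
    spectra[[b]] <- spectrum(id, pepmass, mzv, inten, tc)
  }
  spectrum_collection(spectra, source_path = path)
}

#' Write a spectrum collection as MGF
#'
#' Emits one `BEGIN IONS` block per spectrum with `TITLE`, `PEPMASS`, a
#' `CHARGE` line only when the true charge is known, and fixed-precision
#' peak lines (m/z to 5 decimals, intensity to 4) so that repeated writes of
#' the same collection are byte-identical.
#'
#' @param collection An [spectrum_collection()]; must be non-empty.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_mgf <- function(collection, path) {
  stopifnot(inherits(collection, "ms_spectrum_collection"))
  if (length(collection$spectra) == 0) stop("refusing to write an empty collection")
  blocks <- vapply(collection$spectra, function(sp) {
    hdr <- c(
      "BEGIN IONS",
      paste0("TITLE=", sp$spectrum_id),
      sprintf("PEPMASS=%.5f", sp$precursor_mz),
      if (!is.na(sp$true_charge)) sprintf("CHARGE=%d+", sp$true_charge)
    )
    paste(c(hdr, sprintf("%.5f %.4f", sp$mz, sp$intensity), "END IONS"),
          collapse = "\n")
  }, character(1))
  con <- file(path, open = "wb")  # binary: fixed LF endings for byte-identity
  on.exit(close(con))
  writeLines(blocks, con, sep = "\n\n")
  invisible(path)
}

#' Write a per-spectrum prediction table
#'
#' Tab-separated table with one header line and columns `spectrum_id`,
#' `delta_cp`, `delta_rcp`, `i_dc`, `n_bs` (raw feature values),
#' `posterior_plus3` and `predicted_charge`. Numeric columns are written
#' with 6 decimals so the table is reproducible byte-for-byte.
#'
#' @param rows A data frame with (at least) those seven columns, e.g. the
#'   `predictions` element of a [charge_gmm()] fit.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(rows, path) {
  need <- c("spectrum_id", "delta_cp", "delta_rcp", "i_dc", "n_bs",
            "posterior_plus3", "predicted_charge")
  stopifnot(is.data.frame(rows), nrow(rows) > 0)
  missing_cols <- setdiff(need, names(rows))
  if (length(missing_cols) > 0) {
    stop("prediction table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    spectrum_id = as.character(rows$spectrum_id),
    delta_cp = sprintf("%.6f", rows$delta_cp),
    delta_rcp = sprintf("%.6f", rows$delta_rcp),
    i_dc = sprintf("%.6f", rows$i_dc),
    n_bs = sprintf("%.6f", rows$n_bs),
    posterior_plus3 = sprintf("%.6f", rows$posterior_plus3),
    predicted_charge = as.integer(rows$predicted_charge),
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(need, collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(out), sep = "\t")), con)
  invisible(path)
}
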