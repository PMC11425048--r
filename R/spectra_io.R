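#' m/z binning scheme
#'
#' Defines the discretization of fragment m/z values onto an integer bin grid
#' with half-open intervals `[offset + b*w, offset + (b+1)*w)`. The same
#' scheme must be used for experimental peaks and theoretical ions so that a
#' fragment match reduces to integer bin equality.
#'
#' @param bin_width Bin width w in Da, > 0.
#' @param offset Grid origin in Da (default 0).
#' @return An object of class `binning_scheme`.
#' @export
#' @examples
#' sc <- binning_scheme(0.02)
#' bin_mz(500.25, sc)
binning_scheme <- function(bin_width, offset = 0) {
  stopifnot(is.numeric(bin_width), length(bin_width) == 1L, bin_width > 0,
            is.numeric(offset), length(offset) == 1L)
  structure(list(bin_width = bin_width, offset = offset),
            class = "binning_scheme")
}

#' @export
print.binning_scheme <- function(x, ...) {
  cat(sprintf("m/z binning scheme: width %g Da, offset %g Da\n",
              x$bin_width, x$offset))
  invisible(x)
}

#' Discretize m/z values to integer bins
#'
#' `bin_mz` maps m/z to `floor((mz - offset) / bin_width)`; `bin_center`
#' inverts a bin index to the center of its half-open interval.
#'
#' @param mz Numeric vector of m/z values (Da), each > `offset`.
#' @param scheme A [binning_scheme()].
#' @return Integer-valued numeric vector of bin indices.
#' @export
bin_mz <- function(mz, scheme) {
  if (any(mz <= scheme$offset)) {
    stop("m/z values must exceed the binning offset")
  }
  floor((mz - scheme$offset) / scheme$bin_width)
}

#' @param bin Integer vector of bin indices.
#' @rdname bin_mz
#' @export
bin_center <- function(bin, scheme) {
  scheme$offset + (bin + 0.5) * scheme$bin_width
}

new_raw_spectrum <- function(spectrum_id, precursor_mz, precursor_charge,
                             retention_time, mz, intensity, title = NA_character_) {
  o <- order(mz)
  structure(list(
    spectrum_id = as.integer(spectrum_id),
    precursor_mz = precursor_mz,
    precursor_charge = as.integer(precursor_charge),
    precursor_neutral_mass = precursor_charge * (precursor_mz - PROTON_MASS),
    retention_time = retention_time,
    mz = mz[o],
    intensity = intensity[o],
    title = title
  ), class = "raw_spectrum")
}

#' @export
print.raw_spectrum <- function(x, ...) {
  cat(sprintf(
    "MS2 spectrum #%d: precursor %.4f m/z (%d+), neutral mass %.4f Da, RT %.1f s, %d peaks\n",
    x$spectrum_id, x$precursor_mz, x$precursor_charge,
    x$precursor_neutral_mass, x$retention_time, length(x$mz)))
  invisible(x)
}

#' Read DDA MS2 spectra from MGF or mzML
#'
#' One `raw_spectrum` per MS2 scan, ids assigned in file order starting at 0.
#' MS1 scans in mzML are skipped. Scans without precursor m/z are skipped with
#' a warning; scans without a charge are assumed 2+ with a warning.
#'
#' @param path Path to the input file.
#' @param format `"mgf"` or `"mzml"`; default guesses from the file extension.
#' @return List of `raw_spectrum` objects.
#' @export
read_spectra <- function(path, format = c("auto", "mgf", "mzml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "mgf"
  }
  if (!file.exists(path)) {
    stop("spectrum file not found: ", path)
  }
  switch(format, mgf = read_mgf(path), mzml = read_mzml(path))
}

parse_mgf_charge <- function(x) {
  # accepts "2+", "+2", "2"
  sign <- if (grepl("-", x, fixed = TRUE)) -1L else 1L
  z <- suppressWarnings(as.integer(gsub("[^0-9]", "", x)))
  if (is.na(z) || z < 1L) NA_integer_ else sign * z
}

read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  }
  out <- vector("list", length(begins))
  nid <- 0L
  for (i in seq_along(begins)) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    keys <- sub("=.*$", "", block[hdr])
    vals <- sub("^[^=]*=", "", block[hdr])
    names(vals) <- toupper(keys)
    if (!"PEPMASS" %in% names(vals)) {
      warning("MGF block ", i, " has no PEPMASS; scan skipped")
      next
    }
    pepmass <- as.numeric(strsplit(trimws(vals[["PEPMASS"]]), "\\s+")[[1L]][1L])
    charge <- if ("CHARGE" %in% names(vals)) parse_mgf_charge(vals[["CHARGE"]]) else NA_integer_
    if (is.na(charge)) {
      warning("MGF block ", i, " has no usable CHARGE; assuming 2+")
      charge <- 2L
    }
    rt <- if ("RTINSECONDS" %in% names(vals)) as.numeric(vals[["RTINSECONDS"]]) else NA_real_
    title <- if ("TITLE" %in% names(vals)) vals[["TITLE"]] else NA_character_
    pk <- block[!hdr]
    pk <- pk[nzchar(trimws(pk))]
    if (length(pk)) {
      m <- do.call(rbind, lapply(strsplit(trimws(pk), "\\s+"), function(p) {
        as.numeric(p[1:2])
      }))
      mz <- m[, 1L]; int <- m[, 2L]
    } else {
      warning("MGF block ", i, " has an empty peak list")
      mz <- numeric(0); int <- numeric(0)
    }
    out[[nid + 1L]] <- new_raw_spectrum(nid, pepmass, charge, rt, mz, int, title)
    nid <- nid + 1L
  }
  out[!vapply(out, is.null, logical(1L))]
}

read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package")
  }
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  out <- list()
  nid <- 0L
  for (i in seq_len(nrow(hd))) {
    if (hd$msLevel[i] < 2L) next
    if (is.na(hd$precursorMZ[i]) || hd$precursorMZ[i] <= 0) {
      warning("mzML scan ", hd$seqNum[i], " has no precursor m/z; scan skipped")
      next
    }
    z <- hd$precursorCharge[i]
    if (is.na(z) || z < 1L) {
      warning("mzML scan ", hd$seqNum[i], " has no precursor charge; assuming 2+")
      z <- 2L
    }
    pk <- mzR::peaks(fh, i)
    out[[length(out) + 1L]] <- new_raw_spectrum(
      nid, hd$precursorMZ[i], z, hd$retentionTime[i],
      pk[, 1L], pk[, 2L])
    nid <- nid + 1L
  }
  out
}

#' Write spectra to an MGF file
#'
#' Writes `PEPMASS`/`CHARGE`/`RTINSECONDS` headers and peak lines with six
#' decimal places; output bytes are a pure function of the input, so
#' identically generated runs round-trip identically.
#'
#' @param spectra List of `raw_spectrum` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wb")  # fixed newlines across platforms
  on.exit(close(con))
  for (sp in spectra) {
    title <- if (is.na(sp$title)) sprintf("spectrum_%d", sp$spectrum_id) else sp$title
    hdr <- c("BEGIN IONS",
             sprintf("TITLE=%s", title),
             sprintf("PEPMASS=%.6f", sp$precursor_mz),
             sprintf("CHARGE=%d+", sp$precursor_charge),
             sprintf("RTINSECONDS=%.4f", sp$retention_time))
    pk <- sprintf("%.6f %.6f", sp$mz, sp$intensity)
    writeLines(c(hdr, pk, "END IONS"), con, sep = "\n")
  }
  invisible(path)
}

#' Select the K most intense fragment peaks
#'
#' Ties on intensity are broken toward lower m/z; the retained peaks are
#' re-sorted ascending by m/z. Fewer than `k` peaks means all are retained.
#'
#' @param spectrum A `raw_spectrum`.
#' @param k Number of peaks to keep (default 150).
#' @return A `peak_selection`: list with `spectrum_id`, `mz`, `intensity`, `k`.
#' @export
select_top_k <- function(spectrum, k = 150L) {
  stopifnot(k >= 1L)
  n <- length(spectrum$mz)
  keep <- if (n > k) {
    sort(order(-spectrum$intensity, spectrum$mz)[seq_len(k)])
  } else {
    seq_len(n)
  }
  structure(list(
    spectrum_id = spectrum$spectrum_id,
    mz = spectrum$mz[keep],
    intensity = spectrum$intensity[keep],
    k = as.integer(k)
  ), class = "peak_selection")
}

#' Calibrate the bin width on a grid
#'
#' For each candidate width the total squared error of the binned
#' representation is accumulated over all peaks. Without `reference`, the
#' error of a peak is its offset from the center of its own bin (pure
#' discretization error). With `reference` (known true m/z values, e.g. from
#' calibrants or a synthetic run), a peak whose observed and true m/z share a
#' bin contributes `(reference - bin_center)^2`, while a peak whose
#' measurement error pushed it into a different bin is a lost match and
#' contributes its raw instrument error `(reference - observed)^2`. The
#' referenced form trades match loss (dominant at small widths) against
#' quantisation (dominant at large widths) and has a single interior minimum
#' near twice the instrument m/z standard deviation.
#'
#' @param selections A `peak_selection`, a list of them, or a numeric vector
#'   of observed m/z values.
#' @param widths Strictly increasing grid of candidate widths in Da. The
#'   default is log-spaced (25 points over 0.005-0.1 Da): bin-width choice
#'   is a multiplicative question, and a log grid keeps neighboring
#'   candidates far enough apart that the empirical curve is not dominated
#'   by the sampling jitter of individual bin re-assignments.
#' @param reference Optional numeric vector of true m/z values, parallel to
#'   the flattened observed peaks.
#' @param offset Bin grid origin (Da).
#' @return List with `best_width` (ties resolved toward the smaller width)
#'   and `curve`, a data.frame of `width` and `total_error`.
#' @export
optimal_bin_width <- function(selections,
                              widths = exp(seq(log(0.005), log(0.1),
                                               length.out = 25L)),
                              reference = NULL, offset = 0) {
  if (length(widths) == 0L) stop("empty width grid")
  if (any(diff(widths) <= 0)) stop("width grid must be strictly increasing")
  obs <- if (is.numeric(selections)) {
    selections
  } else if (inherits(selections, "peak_selection")) {
    selections$mz
  } else {
    unlist(lapply(selections, `[[`, "mz"), use.names = FALSE)
  }
  if (length(obs) == 0L) stop("no peaks to calibrate on")
  if (is.null(reference)) reference <- obs
  stopifnot(length(reference) == length(obs))
  total_error <- vapply(widths, function(w) {
    sc <- binning_scheme(w, offset)
    bo <- bin_mz(obs, sc)
    br <- bin_mz(reference, sc)
    hit <- bo == br
    e <- ifelse(hit, reference - bin_center(bo, sc), reference - obs)
    sum(e * e)
  }, numeric(1L))
  list(best_width = widths[which.min(total_error)],
       curve = data.frame(width = widths, total_error = total_error))
}
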