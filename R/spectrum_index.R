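#' Build the inverted spectrum index
#'
#' Maps every occupied integer m/z bin to the postings list of
#' `(spectrum_id, intensity)` pairs of the experimental spectra with a
#' selected peak in that bin. Two peaks of one spectrum falling into one bin
#' are merged by intensity summation. Postings are sorted by spectrum id, so
#' the index is a deterministic function of its inputs. Index size depends
#' only on the experimental side, never on the candidate peptide database.
#'
#' @param selections List of `peak_selection` objects (see [select_top_k()]).
#' @param scheme The [binning_scheme()] shared with theoretical ions.
#' @param spectra Optional list of the originating `raw_spectrum` objects,
#'   used to fill per-spectrum metadata (precursor mass, RT, charge).
#' @return A `spectrum_index` with CSR-layout postings: sorted `bins`,
#'   offsets `start` (length `n_bins + 1`), postings `sid` and `intensity`,
#'   plus `meta` (one row per spectrum) and the `scheme`.
#' @export
build_spectrum_index <- function(selections, scheme, spectra = NULL) {
  sids <- vapply(selections, `[[`, integer(1L), "spectrum_id")
  if (anyDuplicated(sids)) stop("duplicate spectrum ids")
  n_spectra <- length(selections)
  total_int <- vapply(selections, function(s) sum(s$intensity), numeric(1L))

  meta <- data.frame(
    spectrum_id = as.integer(sids),
    precursor_neutral_mass = rep(NA_real_, n_spectra),
    retention_time = rep(NA_real_, n_spectra),
    precursor_charge = rep(NA_integer_, n_spectra),
    total_intensity = total_int
  )
  if (!is.null(spectra)) {
    sp_ids <- vapply(spectra, `[[`, integer(1L), "spectrum_id")
    m <- match(sids, sp_ids)
    meta$precursor_neutral_mass <- vapply(spectra, `[[`, numeric(1L), "precursor_neutral_mass")[m]
    meta$retention_time <- vapply(spectra, `[[`, numeric(1L), "retention_time")[m]
    meta$precursor_charge <- vapply(spectra, `[[`, integer(1L), "precursor_charge")[m]
  }

  if (n_spectra == 0L || sum(lengths(lapply(selections, `[[`, "mz"))) == 0L) {
    return(structure(list(
      bins = integer(0), start = 0L, sid = integer(0), intensity = numeric(0),
      n_spectra = n_spectra, scheme = scheme, meta = meta
    ), class = "spectrum_index"))
  }

  binned <- lapply(selections, bin_spectrum, scheme = scheme)
  dt <- data.table::data.table(
    bin = unlist(lapply(binned, `[[`, "bins"), use.names = FALSE),
    sid = rep(sids, times = vapply(binned, function(b) length(b$bins), integer(1L))),
    intensity = unlist(lapply(binned, `[[`, "intensity"), use.names = FALSE)
  )
  data.table::setorderv(dt, c("bin", "sid"))
  rle_bins <- rle(dt$bin)
  structure(list(
    bins = rle_bins$values,
    start = c(0L, cumsum(rle_bins$lengths)),
    sid = dt$sid,
    intensity = dt$intensity,
    n_spectra = n_spectra,
    scheme = scheme,
    meta = meta
  ), class = "spectrum_index")
}

#' @export
print.spectrum_index <- function(x, ...) {
  s <- index_stats(x)
  cat(sprintf(
    "inverted spectrum index: %d spectra, %d occupied bins, %d postings (~%.1f KB)\n",
    s$n_spectra, s$n_bins, s$n_postings, s$estimated_bytes / 1024))
  invisible(x)
}

#' Query the postings of one bin
#'
#' @param index A `spectrum_index`.
#' @param bin Integer bin index.
#' @param neighbors If `TRUE`, also query bins `bin - 1` and `bin + 1` and
#'   merge the postings (intensity summed per spectrum). Off by default: a
#'   calibrated bin width already absorbs the instrument m/z error.
#' @return data.frame with `spectrum_id` and `intensity`, sorted by
#'   `spectrum_id`; empty if the bin is unoccupied.
#' @export
query_bin <- function(index, bin, neighbors = FALSE) {
  bins <- if (neighbors) (bin - 1L):(bin + 1L) else bin
  pos <- match(bins, index$bins)
  pos <- pos[!is.na(pos)]
  if (!length(pos)) {
    return(data.frame(spectrum_id = integer(0), intensity = numeric(0)))
  }
  idx <- unlist(lapply(pos, function(p) {
    (index$start[p] + 1L):index$start[p + 1L]
  }), use.names = FALSE)
  out <- data.frame(spectrum_id = index$sid[idx], intensity = index$intensity[idx])
  if (length(pos) > 1L) {
    agg <- rowsum(out$intensity, out$spectrum_id)
    out <- data.frame(spectrum_id = as.integer(rownames(agg)), intensity = agg[, 1L])
  }
  out[order(out$spectrum_id), , drop = FALSE]
}

#' Index size summary
#'
#' `estimated_bytes` is a deterministic function of the numbers of occupied
#' bins and postings only; it is therefore invariant under any change to the
#' peptide database searched against the index.
#'
#' @param index A `spectrum_index`.
#' @return List with `n_spectra`, `n_bins`, `n_postings`, `estimated_bytes`.
#' @export
index_stats <- function(index) {
  n_bins <- length(index$bins)
  n_postings <- length(index$sid)
  list(
    n_spectra = index$n_spectra,
    n_bins = n_bins,
    n_postings = n_postings,
    # 4-byte bin id + 4-byte offset per bin; 4-byte sid + 8-byte intensity
    # per posting; fixed 64-byte header
    estimated_bytes = 64 + 8 * n_bins + 12 * n_postings
  )
}

#' Serialize an index to a flat binary file
#'
#' Layout: magic `"PSMIDX"`, version (int32), bin width and offset (float64),
#' `n_spectra`, `n_bins`, `n_postings` (int32), then the bin table (int32),
#' CSR offsets (int32), posting spectrum ids (int32), posting intensities
#' (float64), and the per-spectrum metadata columns. Little-endian
#' throughout; bytes are a pure function of the index.
#'
#' @param index A `spectrum_index`.
#' @param path Output path.
#' @return `path` invisibly (`read_index` returns the index).
#' @export
write_index <- function(index, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw("PSMIDX"), con)
  writeBin(1L, con, size = 4L, endian = "little")
  writeBin(c(index$scheme$bin_width, index$scheme$offset), con,
           size = 8L, endian = "little")
  writeBin(as.integer(c(index$n_spectra, length(index$bins), length(index$sid))),
           con, size = 4L, endian = "little")
  writeBin(as.integer(index$bins), con, size = 4L, endian = "little")
  writeBin(as.integer(index$start), con, size = 4L, endian = "little")
  writeBin(as.integer(index$sid), con, size = 4L, endian = "little")
  writeBin(as.double(index$intensity), con, size = 8L, endian = "little")
  writeBin(as.integer(index$meta$spectrum_id), con, size = 4L, endian = "little")
  writeBin(as.double(index$meta$precursor_neutral_mass), con, size = 8L, endian = "little")
  writeBin(as.double(index$meta$retention_time), con, size = 8L, endian = "little")
  writeBin(as.integer(index$meta$precursor_charge), con, size = 4L, endian = "little")
  writeBin(as.double(index$meta$total_intensity), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 6L))
  if (magic != "PSMIDX") stop("not a spectrum index file: ", path)
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (version != 1L) stop("unsupported index version ", version)
  wo <- readBin(con, "double", 2L, size = 8L, endian = "little")
  dims <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  bins <- readBin(con, "integer", dims[2L], size = 4L, endian = "little")
  start <- readBin(con, "integer", dims[2L] + 1L, size = 4L, endian = "little")
  sid <- readBin(con, "integer", dims[3L], size = 4L, endian = "little")
  intensity <- readBin(con, "double", dims[3L], size = 8L, endian = "little")
  meta <- data.frame(
    spectrum_id = readBin(con, "integer", dims[1L], size = 4L, endian = "little"),
    precursor_neutral_mass = readBin(con, "double", dims[1L], size = 8L, endian = "little"),
    retention_time = readBin(con, "double", dims[1L], size = 8L, endian = "little"),
    precursor_charge = readBin(con, "integer", dims[1L], size = 4L, endian = "little"),
    total_intensity = readBin(con, "double", dims[1L], size = 8L, endian = "little")
  )
  structure(list(
    bins = bins, start = start, sid = sid, intensity = intensity,
    n_spectra = dims[1L], scheme = binning_scheme(wo[1L], wo[2L]), meta = meta
  ), class = "spectrum_index")
}
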