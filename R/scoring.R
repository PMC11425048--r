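#' Hyperscore
#'
#' X!Tandem-lineage match score: `H = ln(Nb! * Ny! * max(sum_Ib, 1) *
#' max(sum_Iy, 1))`, evaluated as a sum of log terms. The `max(., 1)` guard
#' keeps the log finite when a series has no matched intensity; a match with
#' no ions at all scores exactly 0. H is strictly increasing in each
#' argument (above the intensity guard).
#'
#' @param Nb,Ny Matched b- and y-ion counts (non-negative integers).
#' @param sum_Ib,sum_Iy Summed matched b- and y-ion intensities.
#' @return Hyperscore (vectorized).
#' @export
#' @examples
#' hyperscore(2, 1, 10, 5)  # ln(2 * 1 * 10 * 5)
hyperscore <- function(Nb, Ny, sum_Ib, sum_Iy) {
  stopifnot(all(Nb >= 0), all(Ny >= 0), all(sum_Ib >= 0), all(sum_Iy >= 0))
  lfactorial(Nb) + lfactorial(Ny) + log(pmax(sum_Ib, 1)) + log(pmax(sum_Iy, 1))
}

# canonical binned representation of a peak selection: merge peaks sharing a
# bin by intensity summation, ascending bin order. Shared by the index
# builder, the xcorr preprocessor and the reference (no-index) matcher so
# that all paths agree on the binned spectrum to the last bit.
bin_spectrum <- function(selection, scheme) {
  if (!length(selection$mz)) {
    return(list(bins = integer(0), intensity = numeric(0)))
  }
  b <- as.integer(bin_mz(selection$mz, scheme))
  ub <- sort(unique(b))
  ints <- vapply(ub, function(bb) sum(selection$intensity[b == bb]), numeric(1L))
  list(bins = ub, intensity = ints)
}

#' Preprocess a spectrum for fast cross-correlation
#'
#' Comet-style fast-xcorr preparation on the bin grid: peaks are merged into
#' bins (intensity summed), bin intensities are square-rooted, normalized to
#' a maximum of 50 within 10 equal m/z windows spanning the spectrum, and
#' the background term is set up so that the processed spectrum is
#' `y'[b] = y[b] - (1/151) * sum(y[b + tau], tau = -75..75)`. The result is
#' held sparsely (occupied bins, values, prefix sums); [xcorr_eval()]
#' evaluates `y'` at arbitrary bins and [xcorr_dense()] expands the full
#' vector.
#'
#' @param selection A `peak_selection` (see [select_top_k()]).
#' @param scheme A [binning_scheme()].
#' @return An `xcorr_spectrum`: list with `bins`, `values`, `prefix`
#'   (`c(0, cumsum(values))`) and the `scheme`.
#' @export
xcorr_preprocess <- function(selection, scheme) {
  xcorr_from_binned(bin_spectrum(selection, scheme), scheme)
}

# preprocessing from an already-binned spectrum (bins ascending, merged)
xcorr_from_binned <- function(bs, scheme) {
  v <- sqrt(bs$intensity)
  if (length(v)) {
    ctr <- bin_center(bs$bins, scheme = scheme)
    lo <- min(ctr); hi <- max(ctr)
    win <- if (hi > lo) pmin(9L, floor((ctr - lo) / ((hi - lo) / 10))) else rep(0L, length(ctr))
    for (w in unique(win)) {
      i <- win == w
      m <- max(v[i])
      if (m > 0) v[i] <- v[i] * (50 / m)
    }
  }
  structure(list(bins = bs$bins, values = v, prefix = c(0, cumsum(v)),
                 scheme = scheme),
            class = "xcorr_spectrum")
}

#' Evaluate the background-subtracted spectrum at given bins
#'
#' @param xs An `xcorr_spectrum` from [xcorr_preprocess()].
#' @param bins Integer bins to evaluate at.
#' @param half_window Background half-window in bins (default 75).
#' @return Numeric vector of `y'` values.
#' @export
xcorr_eval <- function(xs, bins, half_window = 75L) {
  vapply(bins, function(q) {
    lo <- findInterval(q - half_window - 0.5, xs$bins) + 1L
    hi <- findInterval(q + half_window + 0.5, xs$bins)
    s <- xs$prefix[hi + 1L] - xs$prefix[lo]
    p <- match(q, xs$bins)
    v <- if (is.na(p)) 0 else xs$values[p]
    v - s / 151
  }, numeric(1L))
}

#' @param from,to Bin range to expand (defaults cover all nonzero `y'`).
#' @rdname xcorr_eval
#' @export
xcorr_dense <- function(xs, from = NULL, to = NULL, half_window = 75L) {
  if (!length(xs$bins)) return(numeric(0))
  if (is.null(from)) from <- max(0L, min(xs$bins) - half_window)
  if (is.null(to)) to <- max(xs$bins) + half_window
  out <- xcorr_eval(xs, from:to, half_window)
  names(out) <- from:to
  out
}

#' Cross-correlation score of a fragment set against a spectrum
#'
#' The raw dot product between the processed spectrum and the unit
#' theoretical ion vector: the sum of `y'` over the bins of all theoretical
#' b and y ions (every generated charge state). Ions binned outside the
#' occupied range simply contribute their (zero) background.
#'
#' @param xs An `xcorr_spectrum`.
#' @param fragments A `fragment_set` from [fragment_ions()].
#' @param scheme The shared [binning_scheme()].
#' @return Xcorr score (scalar).
#' @export
xcorr_score <- function(xs, fragments, scheme) {
  ions <- c(unlist(fragments$b, use.names = FALSE),
            unlist(fragments$y, use.names = FALSE))
  sum(xcorr_eval(xs, as.integer(bin_mz(ions, scheme))))
}
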