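#' Search configuration
#'
#' One configuration object drives peak selection, binning, candidate
#' enumeration, scoring and FDR filtering. The three search modes differ
#' only in the precursor mass-difference gate: `"full"` keeps the whole
#' reporting window (default -6000..4500 Da, i.e. effectively unbounded),
#' `"open"` restricts to a few hundred Da (default -150..500), `"narrow"`
#' applies a ppm tolerance (default 20 ppm) as a candidate gate.
#'
#' @param mode `"full"`, `"open"` or `"narrow"`.
#' @param k Top fragment peaks retained per spectrum (default 150).
#' @param bin_width,offset m/z bin grid (Da); see [binning_scheme()].
#' @param min_matched Minimum matched ions (b + y) for a candidate-spectrum
#'   pair to be scored (default 4).
#' @param dm_window Precursor mass-difference reporting window in Da;
#'   `NULL` takes the mode default.
#' @param narrow_ppm Precursor tolerance in ppm (narrow mode only).
#' @param frag_charges Fragment charge states generated (default 1:2);
#'   2+ fragments are only counted for precursors of charge >= 2.
#' @param cap,open_k Variable-modification site cap and truncation order;
#'   see [count_modforms()].
#' @param missed_cleavages,length_range,enzyme Digestion settings.
#' @param decoy_prefix Decoy accession prefix.
#' @param fdr_threshold Reporting q-value threshold (default 0.01).
#' @param seed Seed for all stochastic steps of the validation stage.
#' @param chunk_size Candidate forms scored per C++ call.
#' @return A `search_config` list.
#' @export
search_config <- function(mode = c("full", "open", "narrow"),
                          k = 150L, bin_width = 0.02, offset = 0,
                          min_matched = 4L, dm_window = NULL,
                          narrow_ppm = 20, frag_charges = c(1L, 2L),
                          cap = 20L, open_k = 3L,
                          missed_cleavages = 2L, length_range = c(7L, 50L),
                          enzyme = "trypsin", decoy_prefix = "DECOY_",
                          fdr_threshold = 0.01, seed = 42L,
                          chunk_size = 4000L) {
  mode <- match.arg(mode)
  if (is.null(dm_window)) {
    dm_window <- switch(mode,
                        full = c(-6000, 4500),
                        open = c(-150, 500),
                        narrow = c(-6000, 4500))
  }
  stopifnot(min_matched >= 1L, all(is.finite(dm_window)), k >= 1L)
  if (mode == "narrow" && (is.null(narrow_ppm) || narrow_ppm <= 0)) {
    stop("narrow mode requires a positive ppm tolerance")
  }
  structure(list(
    mode = mode, k = as.integer(k),
    scheme = binning_scheme(bin_width, offset),
    min_matched = as.integer(min_matched), dm_window = dm_window,
    narrow_ppm = if (mode == "narrow") narrow_ppm else NULL,
    frag_charges = as.integer(frag_charges),
    cap = as.integer(cap), open_k = as.integer(open_k),
    missed_cleavages = as.integer(missed_cleavages),
    length_range = length_range, enzyme = enzyme,
    decoy_prefix = decoy_prefix, fdr_threshold = fdr_threshold,
    seed = as.integer(seed), chunk_size = as.integer(chunk_size)
  ), class = "search_config")
}

# stateful stream over all candidate modforms of a peptide table, in the
# canonical per-peptide order (subset size 0, 1, ...; lexicographic within
# a size). Each call yields one chunk (or NULL): parallel vectors of
# sequences, peptide-table rows, varmod counts, decoy flags, canonical
# keys, and the concatenated per-position delta masses with 0-based
# offsets. Chunks can split inside a peptide, so even a 20-site peptide
# (2^20 forms) is never materialized whole.
candidate_stream <- function(peptides, specs, cap, open_k, chunk_size) {
  i <- 0L                 # current peptide row
  n_pep <- nrow(peptides)
  lay <- NULL; n_sites <- 0L; max_size <- 0L
  size <- 0L; comb <- integer(0); active <- FALSE

  function() {
    if (!active && i >= n_pep) return(NULL)
    seqs <- character(chunk_size); rows <- integer(chunk_size)
    nvm <- integer(chunk_size); dl <- vector("list", chunk_size)
    k <- 0L
    while (k < chunk_size) {
      if (!active) {
        if (i >= n_pep) break
        i <<- i + 1L
        lay <<- mod_layout(peptides$peptide[i], specs)
        n_sites <<- length(lay$var_pos)
        max_size <<- if (n_sites <= cap) n_sites else open_k
        size <<- 0L; comb <<- integer(0); active <<- TRUE
      }
      # emit the current form
      k <- k + 1L
      d <- lay$base
      if (size > 0L) {
        d[lay$var_pos[comb]] <- d[lay$var_pos[comb]] + lay$var_delta[comb]
      }
      seqs[k] <- peptides$peptide[i]; rows[k] <- i; nvm[k] <- size
      dl[[k]] <- d
      # advance the subset enumerator
      nxt <- if (size == 0L) NULL else next_combination(comb, n_sites)
      if (is.null(nxt)) {
        size <<- size + 1L
        if (size > max_size) active <<- FALSE else comb <<- seq_len(size)
      } else {
        comb <<- nxt
      }
    }
    if (k == 0L) return(NULL)
    seqs <- seqs[seq_len(k)]; rows <- rows[seq_len(k)]
    nvm <- nvm[seq_len(k)]; dl <- dl[seq_len(k)]
    keys <- paste0(seqs, "|", vapply(dl, mod_annotation, character(1L)))
    list(seqs = seqs, pep_row = rows, n_varmods = nvm,
         is_decoy = as.integer(peptides$is_decoy[rows]),
         pepkey = keys,
         deltas = unlist(dl, use.names = FALSE),
         delta_start = c(0L, cumsum(nchar(seqs)))[seq_along(seqs)])
  }
}

# reconstruct per-spectrum binned spectra (ascending bins, merged
# intensities) from the inverted index postings
invert_index <- function(index, post_row) {
  n <- index$n_spectra
  bins <- rep(index$bins, diff(index$start))
  o <- order(post_row, method = "radix")  # stable: bins stay ascending per row
  row_sorted <- post_row[o]
  lens <- tabulate(row_sorted + 1L, nbins = n)
  stops <- cumsum(lens)
  starts <- stops - lens + 1L
  lapply(seq_len(n), function(r) {
    if (lens[r] == 0L) return(list(bins = integer(0), intensity = numeric(0)))
    idx <- o[starts[r]:stops[r]]
    list(bins = bins[idx], intensity = index$intensity[idx])
  })
}

#' Search all candidate peptides against all spectra
#'
#' The full-database matcher: every modification form of every peptide is
#' generated on the fly, its theoretical b/y ion bins are queried against
#' the inverted index, matched ion counts and intensities are accumulated
#' per spectrum, candidate-spectrum pairs with at least `min_matched` ions
#' inside the mass-difference gate are scored (hyperscore, then fast
#' xcorr), and the best PSM per spectrum is retained under the total order
#' max H, then max X, then lexicographically smallest peptide key, then
#' target over decoy. No precursor tolerance restricts the candidate set in
#' full mode.
#'
#' @param index A [build_spectrum_index()] result built with per-spectrum
#'   metadata (precursor masses are needed for the mass-difference gate).
#' @param peptides Peptide table from [build_peptide_db()].
#' @param specs Modification specs used to expand each peptide.
#' @param config A [search_config()]; its binning scheme must equal the
#'   index scheme.
#' @return A `psm_table` data.frame, at most one row per spectrum. The
#'   companion per-peptide stream (the best-matching spectrum of every
#'   candidate form that passed the gates anywhere — the granularity the
#'   validation stage trains on, where every decoy peptide contributes its
#'   best match) is attached as attribute `peptide_psms`.
#' @export
search_all <- function(index, peptides, specs = default_mods(),
                       config = search_config()) {
  if (!identical(unclass(config$scheme), unclass(index$scheme))) {
    stop("binning scheme mismatch between index and search configuration")
  }
  meta <- index$meta
  n <- index$n_spectra
  if (n == 0L) return(empty_psm_table())
  if (anyNA(meta$precursor_neutral_mass)) {
    stop("index lacks precursor metadata; build it with `spectra =`")
  }
  post_row <- match(index$sid, meta$spectrum_id) - 1L

  binned <- invert_index(index, post_row)
  xs <- lapply(binned, xcorr_from_binned, scheme = index$scheme)
  lens <- vapply(xs, function(x) length(x$bins), integer(1L))
  xc_start <- c(0L, cumsum(lens))
  xcp_start <- c(0L, cumsum(lens + 1L))
  xc_bins <- as.integer(unlist(lapply(xs, `[[`, "bins"), use.names = FALSE))
  xc_vals <- as.numeric(unlist(lapply(xs, `[[`, "values"), use.names = FALSE))
  xc_prefix <- as.numeric(unlist(lapply(xs, `[[`, "prefix"), use.names = FALSE))

  aa26 <- numeric(26)
  aa26[match(AA_LETTERS, LETTERS)] <- AA_MONO
  lfact <- lfactorial(0:2047)

  best <- list(
    H = rep(NA_real_, n), X = numeric(n), sIb = numeric(n), sIy = numeric(n),
    mass = numeric(n), dm = numeric(n), Nb = integer(n), Ny = integer(n),
    pep_row = integer(n), nvm = integer(n), decoy = integer(n),
    key = rep("", n)
  )

  stream <- candidate_stream(peptides, specs, config$cap, config$open_k,
                             config$chunk_size)
  pep_chunks <- list()
  repeat {
    ch <- stream()
    if (is.null(ch)) break
    cb <- search_chunk_cpp(
      as.integer(index$bins), as.integer(index$start), as.integer(post_row),
      as.numeric(index$intensity),
      as.numeric(meta$precursor_neutral_mass), as.integer(meta$precursor_charge),
      xc_start, xcp_start, xc_bins, xc_vals, xc_prefix,
      ch$seqs, ch$pep_row, ch$n_varmods, ch$is_decoy, ch$pepkey,
      as.numeric(ch$deltas), as.integer(ch$delta_start),
      aa26, index$scheme$bin_width, index$scheme$offset, PROTON_MASS, WATER_MASS,
      config$frag_charges, config$min_matched,
      config$dm_window[1L], config$dm_window[2L],
      if (is.null(config$narrow_ppm)) -1 else config$narrow_ppm,
      75L, lfact,
      best$H, best$X, best$sIb, best$sIy, best$mass, best$dm,
      best$Nb, best$Ny, best$pep_row, best$nvm, best$decoy, best$key
    )
    cs <- which(cb$spec_row >= 0L)
    if (length(cs)) {
      sr <- cb$spec_row[cs] + 1L
      pr <- ch$pep_row[cs]
      pep_chunks[[length(pep_chunks) + 1L]] <- data.frame(
        spectrum_id = meta$spectrum_id[sr],
        retention_time = meta$retention_time[sr],
        precursor_charge = meta$precursor_charge[sr],
        precursor_mass = meta$precursor_neutral_mass[sr],
        total_intensity = meta$total_intensity[sr],
        peptide = ch$seqs[cs],
        mod_string = sub("^[^|]*\\|", "", ch$pepkey[cs]),
        pepkey = ch$pepkey[cs],
        proteins = peptides$proteins[pr],
        missed_cleavages = peptides$missed_cleavages[pr],
        n_varmods = ch$n_varmods[cs],
        pep_mass = cb$mass[cs],
        delta_mass = cb$dm[cs],
        Nb = cb$Nb[cs], Ny = cb$Ny[cs],
        sum_Ib = cb$sIb[cs], sum_Iy = cb$sIy[cs],
        hyperscore = cb$H[cs], xcorr = cb$X[cs],
        is_decoy = as.logical(ch$is_decoy[cs]),
        shared = peptides$shared[pr]
      )
    }
  }
  peptide_psms <- if (length(pep_chunks)) {
    out <- data.table::setDF(data.table::rbindlist(pep_chunks))
    class(out) <- c("psm_table", "data.frame")
    out
  } else {
    empty_psm_table()
  }

  hit <- !is.na(best$H)
  if (!any(hit)) {
    out <- empty_psm_table()
    attr(out, "peptide_psms") <- peptide_psms
    return(out)
  }
  pr <- best$pep_row[hit]
  out <- data.frame(
    spectrum_id = meta$spectrum_id[hit],
    retention_time = meta$retention_time[hit],
    precursor_charge = meta$precursor_charge[hit],
    precursor_mass = meta$precursor_neutral_mass[hit],
    total_intensity = meta$total_intensity[hit],
    peptide = peptides$peptide[pr],
    mod_string = sub("^[^|]*\\|", "", best$key[hit]),
    pepkey = best$key[hit],
    proteins = peptides$proteins[pr],
    missed_cleavages = peptides$missed_cleavages[pr],
    n_varmods = best$nvm[hit],
    pep_mass = best$mass[hit],
    delta_mass = best$dm[hit],
    Nb = best$Nb[hit], Ny = best$Ny[hit],
    sum_Ib = best$sIb[hit], sum_Iy = best$sIy[hit],
    hyperscore = best$H[hit], xcorr = best$X[hit],
    is_decoy = as.logical(best$decoy[hit]),
    shared = peptides$shared[pr]
  )
  class(out) <- c("psm_table", "data.frame")
  attr(out, "peptide_psms") <- peptide_psms
  out
}

empty_psm_table <- function() {
  out <- data.frame(
    spectrum_id = integer(0), retention_time = numeric(0),
    precursor_charge = integer(0), precursor_mass = numeric(0),
    total_intensity = numeric(0), peptide = character(0),
    mod_string = character(0), pepkey = character(0), proteins = character(0),
    missed_cleavages = integer(0), n_varmods = integer(0),
    pep_mass = numeric(0), delta_mass = numeric(0),
    Nb = integer(0), Ny = integer(0), sum_Ib = numeric(0), sum_Iy = numeric(0),
    hyperscore = numeric(0), xcorr = numeric(0), is_decoy = logical(0),
    shared = logical(0)
  )
  class(out) <- c("psm_table", "data.frame")
  out
}

#' @export
print.psm_table <- function(x, ...) {
  cat(sprintf("PSM table: %d spectra matched (%d decoy best hits)\n",
              nrow(x), sum(x$is_decoy)))
  if (nrow(x)) {
    cat(sprintf("  hyperscore range %.2f .. %.2f\n",
                min(x$hyperscore), max(x$hyperscore)))
  }
  invisible(x)
}

#' Reference all-pairs matcher (no index)
#'
#' Scores every candidate against every spectrum by direct bin comparison,
#' without the inverted index. Slow, but an independent implementation of
#' the identical contract; used to cross-check [search_all()] bit for bit
#' on small problems.
#'
#' @param selections List of `peak_selection` objects.
#' @param spectra The originating `raw_spectrum` list (precursor metadata).
#' @param peptides,specs,config As in [search_all()].
#' @return A `psm_table` data.frame.
#' @export
search_all_naive <- function(selections, spectra, peptides,
                             specs = default_mods(), config = search_config()) {
  scheme <- config$scheme
  n <- length(selections)
  sp_ids <- vapply(selections, `[[`, integer(1L), "spectrum_id")
  raw_ids <- vapply(spectra, `[[`, integer(1L), "spectrum_id")
  m <- match(sp_ids, raw_ids)
  prec_mass <- vapply(spectra, `[[`, numeric(1L), "precursor_neutral_mass")[m]
  prec_charge <- vapply(spectra, `[[`, integer(1L), "precursor_charge")[m]
  rt <- vapply(spectra, `[[`, numeric(1L), "retention_time")[m]
  binned <- lapply(selections, bin_spectrum, scheme = scheme)
  xs <- lapply(selections, xcorr_preprocess, scheme = scheme)
  total_int <- vapply(selections, function(s) sum(s$intensity), numeric(1L))

  best <- lapply(seq_len(n), function(i) NULL)
  pep_best <- list()
  ppm <- if (is.null(config$narrow_ppm)) -1 else config$narrow_ppm

  stream <- candidate_stream(peptides, specs, config$cap, config$open_k,
                             config$chunk_size)
  repeat {
    ch <- stream()
    if (is.null(ch)) break
    for (c in seq_along(ch$seqs)) {
      cbest <- NULL
      sq <- ch$seqs[c]
      L <- nchar(sq)
      d0 <- ch$delta_start[c]
      dl <- ch$deltas[(d0 + 1L):(d0 + L)]
      fr <- fragment_ions(sq, dl, charges = config$frag_charges)
      cand_mass <- peptide_mass(sq, dl)
      ions <- c(unlist(fr$b, use.names = FALSE), unlist(fr$y, use.names = FALSE))
      nfrag <- L - 1L
      nz <- length(config$frag_charges)
      ion_z <- rep(rep(config$frag_charges, each = nfrag), 2L)
      ion_is_b <- rep(c(TRUE, FALSE), each = nfrag * nz)
      ion_bins <- as.integer(bin_mz(ions, scheme))
      for (s in seq_len(n)) {
        allowed <- ion_z == 1L | prec_charge[s] >= ion_z
        pos <- match(ion_bins, binned[[s]]$bins)
        matched <- allowed & !is.na(pos)
        Nb <- sum(matched & ion_is_b)
        Ny <- sum(matched & !ion_is_b)
        if (Nb + Ny < config$min_matched) next
        dm <- prec_mass[s] - cand_mass
        if (dm < config$dm_window[1L] || dm > config$dm_window[2L]) next
        if (ppm > 0 && abs(dm) / cand_mass * 1e6 > ppm) next
        sIb <- sum(binned[[s]]$intensity[pos[matched & ion_is_b]])
        sIy <- sum(binned[[s]]$intensity[pos[matched & !ion_is_b]])
        H <- hyperscore(Nb, Ny, sIb, sIy)
        X <- sum(xcorr_eval(xs[[s]], ion_bins[allowed]))
        cand <- list(H = H, X = X, Nb = Nb, Ny = Ny, sIb = sIb, sIy = sIy,
                     mass = cand_mass, dm = dm, pep_row = ch$pep_row[c],
                     nvm = ch$n_varmods[c], decoy = ch$is_decoy[c],
                     key = ch$pepkey[c])
        b <- best[[s]]
        better <- if (is.null(b)) TRUE
          else if (H != b$H) H > b$H
          else if (X != b$X) X > b$X
          else if (cand$key != b$key) cand$key < b$key
          else cand$decoy < b$decoy
        if (better) best[[s]] <- cand
        # per-candidate best spectrum: max H, then max X, then first
        # (spectra are scanned in ascending row order)
        cbetter <- if (is.null(cbest)) TRUE
          else if (H != cbest$H) H > cbest$H
          else if (X != cbest$X) X > cbest$X
          else FALSE
        if (cbetter) cbest <- c(cand, list(spec = s))
      }
      if (!is.null(cbest)) pep_best[[length(pep_best) + 1L]] <- cbest
    }
  }

  peptide_psms <- if (length(pep_best)) {
    ss <- vapply(pep_best, `[[`, integer(1L), "spec")
    pr <- vapply(pep_best, `[[`, integer(1L), "pep_row")
    out <- data.frame(
      spectrum_id = sp_ids[ss],
      retention_time = rt[ss],
      precursor_charge = prec_charge[ss],
      precursor_mass = prec_mass[ss],
      total_intensity = total_int[ss],
      peptide = peptides$peptide[pr],
      mod_string = sub("^[^|]*\\|", "",
                       vapply(pep_best, `[[`, character(1L), "key")),
      pepkey = vapply(pep_best, `[[`, character(1L), "key"),
      proteins = peptides$proteins[pr],
      missed_cleavages = peptides$missed_cleavages[pr],
      n_varmods = vapply(pep_best, `[[`, integer(1L), "nvm"),
      pep_mass = vapply(pep_best, `[[`, numeric(1L), "mass"),
      delta_mass = vapply(pep_best, `[[`, numeric(1L), "dm"),
      Nb = vapply(pep_best, `[[`, integer(1L), "Nb"),
      Ny = vapply(pep_best, `[[`, integer(1L), "Ny"),
      sum_Ib = vapply(pep_best, `[[`, numeric(1L), "sIb"),
      sum_Iy = vapply(pep_best, `[[`, numeric(1L), "sIy"),
      hyperscore = vapply(pep_best, `[[`, numeric(1L), "H"),
      xcorr = vapply(pep_best, `[[`, numeric(1L), "X"),
      is_decoy = as.logical(vapply(pep_best, `[[`, integer(1L), "decoy")),
      shared = peptides$shared[pr]
    )
    class(out) <- c("psm_table", "data.frame")
    out
  } else {
    empty_psm_table()
  }

  hit <- !vapply(best, is.null, logical(1L))
  if (!any(hit)) {
    out <- empty_psm_table()
    attr(out, "peptide_psms") <- peptide_psms
    return(out)
  }
  bb <- best[hit]
  pr <- vapply(bb, `[[`, integer(1L), "pep_row")
  out <- data.frame(
    spectrum_id = sp_ids[hit],
    retention_time = rt[hit],
    precursor_charge = prec_charge[hit],
    precursor_mass = prec_mass[hit],
    total_intensity = total_int[hit],
    peptide = peptides$peptide[pr],
    mod_string = sub("^[^|]*\\|", "", vapply(bb, `[[`, character(1L), "key")),
    pepkey = vapply(bb, `[[`, character(1L), "key"),
    proteins = peptides$proteins[pr],
    missed_cleavages = peptides$missed_cleavages[pr],
    n_varmods = vapply(bb, `[[`, integer(1L), "nvm"),
    pep_mass = vapply(bb, `[[`, numeric(1L), "mass"),
    delta_mass = vapply(bb, `[[`, numeric(1L), "dm"),
    Nb = vapply(bb, `[[`, integer(1L), "Nb"),
    Ny = vapply(bb, `[[`, integer(1L), "Ny"),
    sum_Ib = vapply(bb, `[[`, numeric(1L), "sIb"),
    sum_Iy = vapply(bb, `[[`, numeric(1L), "sIy"),
    hyperscore = vapply(bb, `[[`, numeric(1L), "H"),
    xcorr = vapply(bb, `[[`, numeric(1L), "X"),
    is_decoy = as.logical(vapply(bb, `[[`, integer(1L), "decoy")),
    shared = peptides$shared[pr]
  )
  class(out) <- c("psm_table", "data.frame")
  attr(out, "peptide_psms") <- peptide_psms
  out
}

#' Filter PSMs to a narrow precursor tolerance
#'
#' Retains PSMs with `|delta_mass| / peptide_mass * 1e6 <= tolerance_ppm`.
#' An infinite tolerance reproduces the input exactly.
#'
#' @param psms A `psm_table`.
#' @param tolerance_ppm Precursor tolerance in ppm (> 0).
#' @return The filtered `psm_table`.
#' @export
narrow_window_filter <- function(psms, tolerance_ppm) {
  stopifnot(tolerance_ppm > 0)
  keep <- abs(psms$delta_mass) / psms$pep_mass * 1e6 <= tolerance_ppm
  out <- psms[keep, , drop = FALSE]
  class(out) <- c("psm_table", "data.frame")
  out
}
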