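#' Specification of a synthetic DDA run
#'
#' Parameters of the ground-truthed generator used to exercise every stage
#' of the engine without external data. Defaults describe a modest
#' high-resolution run: uniform-composition proteins of 100-400 residues,
#' 1000 MS2 spectra of which 80% carry the b/y ladder of a real tryptic
#' peptide (the rest are pure noise), log-normal fragment intensities,
#' Gaussian fragment m/z error of 0.005 Da, 0.002 Da precursor mass error,
#' a Poisson(30) count of uniform background peaks per spectrum, and an
#' additive per-residue retention-time model with 30 s of chromatographic
#' noise.
#'
#' @param n_proteins Number of synthetic proteins.
#' @param protein_length Protein length range (uniform integer draw).
#' @param n_spectra Number of MS2 spectra to simulate.
#' @param fraction_true Fraction of spectra generated from a true peptide.
#' @param intensity_meanlog,intensity_sdlog Log-normal fragment intensity
#'   parameters.
#' @param mz_sd Fragment m/z error SD in Da.
#' @param precursor_mass_sd Precursor neutral-mass error SD in Da.
#' @param noise_peaks_lambda Poisson mean of background peaks per spectrum.
#' @param noise_mz_range m/z range of background peaks.
#' @param rt_sd Retention-time noise SD in seconds.
#' @param rt_coef_range Range of the per-residue RT coefficients (seconds),
#'   drawn once per run.
#' @param mod_occupancy Probability that an eligible variable-modification
#'   site is occupied.
#' @param specs Modification specs applied by the generator.
#' @param charges,charge_probs Precursor charge states and their
#'   probabilities.
#' @param length_range,missed_cleavages Tryptic peptide pool settings
#'   (missed cleavages in the pool are 0 by default: the generator emits
#'   fully cleaved peptides, a subset of any search space digested with
#'   more).
#' @return A `synthetic_run_spec` list.
#' @export
synthetic_run_spec <- function(n_proteins = 200L, protein_length = c(100L, 400L),
                               n_spectra = 1000L, fraction_true = 0.8,
                               intensity_meanlog = 0, intensity_sdlog = 0.5,
                               mz_sd = 0.005, precursor_mass_sd = 0.002,
                               noise_peaks_lambda = 30,
                               noise_mz_range = c(200, 1800),
                               rt_sd = 30, rt_coef_range = c(60, 420),
                               mod_occupancy = 0.2, specs = default_mods(),
                               charges = c(2L, 3L), charge_probs = c(0.7, 0.3),
                               length_range = c(7L, 50L),
                               missed_cleavages = 0L) {
  stopifnot(fraction_true >= 0, fraction_true <= 1,
            mod_occupancy >= 0, mod_occupancy <= 1,
            length(charges) == length(charge_probs))
  structure(as.list(environment()), class = "synthetic_run_spec")
}

random_protein <- function(len) {
  paste(sample(AA_LETTERS, len, replace = TRUE), collapse = "")
}

#' Generate a synthetic proteome
#'
#' Uniform-composition random proteins; every protein is guaranteed to
#' yield at least one fully tryptic peptide inside the configured length
#' window (rejected and redrawn otherwise). Byte-identical output for a
#' given spec and seed.
#'
#' @param spec A [synthetic_run_spec()].
#' @param seed RNG seed (mandatory; the generator owns its RNG state).
#' @param fasta_path Optional path; when given the proteome is also written
#'   as wrapped FASTA.
#' @return data.frame of target proteins (`accession`, `sequence`,
#'   `is_decoy`).
#' @export
make_proteome <- function(spec = synthetic_run_spec(), seed, fasta_path = NULL) {
  stopifnot(spec$n_proteins >= 1L)
  set.seed(seed)
  seqs <- character(spec$n_proteins)
  for (i in seq_len(spec$n_proteins)) {
    repeat {
      len <- sample(spec$protein_length[1L]:spec$protein_length[2L], 1L)
      s <- random_protein(len)
      d <- digest(s, missed_cleavages = 0L, length_range = spec$length_range)
      if (nrow(d) >= 1L) break
    }
    seqs[i] <- s
  }
  prot <- data.frame(
    accession = sprintf("SYNPROT%04d", seq_len(spec$n_proteins)),
    sequence = seqs, is_decoy = FALSE)
  if (!is.null(fasta_path)) write_fasta(prot, fasta_path)
  prot
}

#' Write proteins as wrapped FASTA
#'
#' @param proteins data.frame with `accession` and `sequence`.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(paste0(">", proteins$accession[i]), con, sep = "\n")
    s <- proteins$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Simulate a ground-truthed DDA run
#'
#' Each signal spectrum is built from a randomly drawn tryptic peptide of
#' the proteome: variable modifications are switched on per site with the
#' configured occupancy, the full b/y ladder (1+, plus 2+ for precursors of
#' charge >= 2) is emitted with Gaussian m/z error and log-normal
#' intensities, Poisson background peaks are added, the precursor mass
#' carries its own small error, and the retention time follows the run's
#' additive per-residue model plus noise. Noise spectra contain background
#' peaks only. The returned ground truth covers every spectrum.
#'
#' @param proteome Target proteins from [make_proteome()].
#' @param spec A [synthetic_run_spec()].
#' @param seed RNG seed (independent of the proteome seed).
#' @param mgf_path,truth_path Optional output paths (MGF and TSV).
#' @return List with `spectra` (list of `raw_spectrum`), `truth`
#'   (data.frame: `spectrum_id`, `peptide` — `"noise"` for noise spectra —
#'   `mod_string`, `proteins`, `charge`, `true_mass`, `rt_true`), and
#'   `rt_coefficients` (the named per-residue seconds used for RT).
#' @export
simulate_run <- function(proteome, spec = synthetic_run_spec(), seed,
                         mgf_path = NULL, truth_path = NULL) {
  stopifnot(nrow(proteome) >= 1L)
  set.seed(seed + 1L)
  rt_coef <- stats::runif(20L, spec$rt_coef_range[1L], spec$rt_coef_range[2L])
  names(rt_coef) <- AA_LETTERS

  pool <- data.table::rbindlist(lapply(seq_len(nrow(proteome)), function(i) {
    d <- digest(proteome$sequence[i], missed_cleavages = spec$missed_cleavages,
                length_range = spec$length_range)
    if (!nrow(d)) return(NULL)
    data.table::data.table(peptide = d$peptide,
                           accession = proteome$accession[i])
  }))
  pool <- pool[, list(proteins = paste(sort(unique(accession)), collapse = ";")),
               by = "peptide"]

  n <- spec$n_spectra
  spectra <- vector("list", n)
  truth <- vector("list", n)
  rt_window <- range(vapply(pool$peptide, function(p) {
    sum(rt_coef[strsplit(p, "", fixed = TRUE)[[1L]]])
  }, numeric(1L)))

  for (i in seq_len(n)) {
    id <- i - 1L
    is_signal <- stats::runif(1L) < spec$fraction_true
    if (is_signal) {
      row <- pool[sample(nrow(pool), 1L)]
      pep <- row$peptide
      lay <- mod_layout(pep, spec$specs)
      deltas <- lay$base
      if (length(lay$var_pos)) {
        on <- stats::runif(length(lay$var_pos)) < spec$mod_occupancy
        deltas[lay$var_pos[on]] <- deltas[lay$var_pos[on]] + lay$var_delta[on]
      }
      z <- sample(spec$charges, 1L, prob = spec$charge_probs)
      M <- peptide_mass(pep, deltas)
      frag_z <- if (z >= 2L) c(1L, 2L) else 1L
      fr <- fragment_ions(pep, deltas, charges = frag_z)
      ion_mz <- c(unlist(fr$b, use.names = FALSE), unlist(fr$y, use.names = FALSE))
      sig_mz <- ion_mz + stats::rnorm(length(ion_mz), 0, spec$mz_sd)
      sig_int <- stats::rlnorm(length(ion_mz), spec$intensity_meanlog,
                               spec$intensity_sdlog)
      n_noise <- stats::rpois(1L, spec$noise_peaks_lambda)
      noise_mz <- stats::runif(n_noise, spec$noise_mz_range[1L],
                               spec$noise_mz_range[2L])
      noise_int <- stats::rlnorm(n_noise, spec$intensity_meanlog,
                                 spec$intensity_sdlog)
      rt_true <- sum(rt_coef[strsplit(pep, "", fixed = TRUE)[[1L]]])
      rt_obs <- rt_true + stats::rnorm(1L, 0, spec$rt_sd)
      prec_mz <- (M + stats::rnorm(1L, 0, spec$precursor_mass_sd) +
                    z * PROTON_MASS) / z
      spectra[[i]] <- new_raw_spectrum(
        id, prec_mz, z, rt_obs,
        c(sig_mz, noise_mz), c(sig_int, noise_int),
        title = sprintf("synthetic_%d", id))
      truth[[i]] <- data.frame(
        spectrum_id = id, peptide = pep, mod_string = mod_annotation(deltas),
        proteins = row$proteins, charge = z, true_mass = M, rt_true = rt_true)
    } else {
      n_noise <- stats::rpois(1L, spec$noise_peaks_lambda)
      spectra[[i]] <- new_raw_spectrum(
        id, stats::runif(1L, 300, 1500), 2L,
        stats::runif(1L, rt_window[1L], rt_window[2L]),
        stats::runif(n_noise, spec$noise_mz_range[1L], spec$noise_mz_range[2L]),
        stats::rlnorm(n_noise, spec$intensity_meanlog, spec$intensity_sdlog),
        title = sprintf("synthetic_%d", id))
      truth[[i]] <- data.frame(
        spectrum_id = id, peptide = "noise", mod_string = "", proteins = "",
        charge = 2L, true_mass = NA_real_, rt_true = NA_real_)
    }
  }
  truth <- do.call(rbind, truth)
  if (!is.null(mgf_path)) write_mgf(spectra, mgf_path)
  if (!is.null(truth_path)) {
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(spectra = spectra, truth = truth, rt_coefficients = rt_coef)
}
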