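#' One-call database search
#'
#' Reads spectra, selects the top-K peaks, builds the inverted index,
#' digests and expands the FASTA database (targets plus reversed decoys),
#' and runs the full matcher. This is the R-facing form of the `search`
#' pipeline stage.
#'
#' @param spectra_path MGF or mzML file.
#' @param fasta_path Protein FASTA.
#' @param specs Modification specs.
#' @param config A [search_config()].
#' @return A `psm_table` (one best PSM per matched spectrum) with the
#'   `index` and `peptides` attached as attributes.
#' @export
psm_search <- function(spectra_path, fasta_path, specs = default_mods(),
                       config = search_config()) {
  spectra <- read_spectra(spectra_path)
  selections <- lapply(spectra, select_top_k, k = config$k)
  index <- build_spectrum_index(selections, config$scheme, spectra = spectra)
  proteins <- parse_fasta(fasta_path)
  peptides <- build_peptide_db(proteins, specs,
                               missed_cleavages = config$missed_cleavages,
                               length_range = config$length_range,
                               decoy_prefix = config$decoy_prefix)
  psms <- search_all(index, peptides, specs, config)
  attr(psms, "index") <- index
  attr(psms, "peptides") <- peptides
  psms
}

run_log_line <- function(path, stage, payload) {
  line <- jsonlite::toJSON(c(list(stage = stage, time = format(Sys.time())),
                             payload), auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = path, append = TRUE)
}

config_payload <- function(config) {
  cfg <- unclass(config)
  cfg$scheme <- unclass(cfg$scheme)
  cfg
}

#' Pipeline stages: simulate, search, validate
#'
#' File-in/file-out wrappers around the package functions, mirroring the
#' three stages of a run. Every stage appends machine-readable JSON lines
#' (configuration, seeds, counts) to `run_log.jsonl` in the output
#' directory, enough to reproduce the run.
#'
#' `cmd_simulate` writes `proteome.fasta`, `run.mgf` and `ground_truth.tsv`.
#' `cmd_search` writes `psm.tsv`. `cmd_validate` writes `peptides.tsv`,
#' `proteins.tsv`, `qvalue_curve.tsv` (discriminant score vs peptide
#' q-value) and `delta_mass_histogram.tsv`.
#'
#' @param out_dir Output directory (created if missing).
#' @param sim_spec A [synthetic_run_spec()].
#' @param seed Generator seed.
#' @param spectra_path,fasta_path Search inputs.
#' @param specs Modification specs.
#' @param config A [search_config()].
#' @param psms A `psm_table` or the path of a `psm.tsv` written by
#'   `cmd_search`.
#' @return Invisibly: `cmd_simulate` the file paths, `cmd_search` the
#'   `psm_table`, `cmd_validate` the `psm_validation`.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
cmd_simulate <- function(out_dir, sim_spec = synthetic_run_spec(), seed = 42L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(fasta = file.path(out_dir, "proteome.fasta"),
                mgf = file.path(out_dir, "run.mgf"),
                truth = file.path(out_dir, "ground_truth.tsv"))
  proteome <- make_proteome(sim_spec, seed, fasta_path = paths$fasta)
  run <- simulate_run(proteome, sim_spec, seed, mgf_path = paths$mgf,
                      truth_path = paths$truth)
  if (sim_spec$n_spectra == 0L) warning("simulated run has zero spectra")
  n_signal <- sum(run$truth$peptide != "noise")
  message(sprintf("simulated %d proteins, %d spectra (%d signal, %d noise)",
                  nrow(proteome), nrow(run$truth), n_signal,
                  nrow(run$truth) - n_signal))
  run_log_line(file.path(out_dir, "run_log.jsonl"), "simulate",
               list(seed = seed, n_proteins = sim_spec$n_proteins,
                    n_spectra = sim_spec$n_spectra, n_signal = n_signal))
  invisible(paths)
}

#' @rdname pipeline
#' @export
cmd_search <- function(spectra_path, fasta_path, out_dir,
                       specs = default_mods(), config = search_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  psms <- psm_search(spectra_path, fasta_path, specs, config)
  out <- file.path(out_dir, "psm.tsv")
  utils::write.table(as.data.frame(psms), out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pp <- attr(psms, "peptide_psms")
  if (!is.null(pp)) {
    utils::write.table(as.data.frame(pp), file.path(out_dir, "peptide_psm.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  idx <- attr(psms, "index")
  run_log_line(file.path(out_dir, "run_log.jsonl"), "search",
               list(config = config_payload(config),
                    spectra = spectra_path, fasta = fasta_path,
                    n_spectra = idx$n_spectra,
                    n_peptides = nrow(attr(psms, "peptides")),
                    n_psms = nrow(psms), n_decoy = sum(psms$is_decoy)))
  invisible(psms)
}

#' @rdname pipeline
#' @export
cmd_validate <- function(psms, out_dir, config = search_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(psms)) {
    path <- psms
    psms <- utils::read.delim(path, stringsAsFactors = FALSE)
    class(psms) <- c("psm_table", "data.frame")
    pp_path <- file.path(dirname(path), "peptide_psm.tsv")
    if (file.exists(pp_path)) {
      pp <- utils::read.delim(pp_path, stringsAsFactors = FALSE)
      class(pp) <- c("psm_table", "data.frame")
      attr(psms, "peptide_psms") <- pp
    }
  }
  val <- psm_validate(psms, config)
  utils::write.table(val$report$peptides, file.path(out_dir, "peptides.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(val$report$proteins, file.path(out_dir, "proteins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(val$peptide_q[, c("score", "q_value", "is_decoy")],
                     file.path(out_dir, "qvalue_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  h <- graphics::hist(val$psms$delta_mass, breaks = 200, plot = FALSE)
  utils::write.table(data.frame(delta_mass = h$mids, count = h$counts),
                     file.path(out_dir, "delta_mass_histogram.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  run_log_line(file.path(out_dir, "run_log.jsonl"), "validate",
               c(list(config = config_payload(config)), val$counts))
  invisible(val)
}

#' Read a plain-text run configuration
#'
#' `key = value` lines (``#`` comments allowed). Recognized keys mirror the
#' [search_config()] arguments (`mode`, `k`, `bin_width`, `min_matched`,
#' `narrow_ppm`, `missed_cleavages`, `length_min`/`length_max`,
#' `fdr_threshold`, `seed`) plus modification lists `fixed_mods` and
#' `variable_mods` as `name:targets:delta` entries separated by commas.
#' Values given as function arguments override the file (CLI > file >
#' defaults).
#'
#' @param path Configuration file.
#' @param ... Overrides passed straight to [search_config()].
#' @return List with `config` ([search_config()]) and `specs`.
#' @export
read_run_config <- function(path, ...) {
  kv <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
    for (ln in lines) {
      parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      kv[[trimws(parts[1L])]] <- trimws(paste(parts[-1L], collapse = "="))
    }
  }
  num <- function(key) if (!is.null(kv[[key]])) as.numeric(kv[[key]]) else NULL
  args <- list(
    mode = kv[["mode"]], k = num("k"), bin_width = num("bin_width"),
    min_matched = num("min_matched"), narrow_ppm = num("narrow_ppm"),
    missed_cleavages = num("missed_cleavages"),
    fdr_threshold = num("fdr_threshold"), seed = num("seed")
  )
  if (!is.null(num("length_min"))) {
    args$length_range <- c(num("length_min"), num("length_max") %||% 50)
  }
  args <- args[!vapply(args, is.null, logical(1L))]
  args <- utils::modifyList(args, list(...))
  config <- do.call(search_config, args)

  parse_mods <- function(txt, kind) {
    if (is.null(txt) || !nzchar(txt)) return(list())
    lapply(strsplit(txt, ",", fixed = TRUE)[[1L]], function(m) {
      f <- strsplit(trimws(m), ":", fixed = TRUE)[[1L]]
      modification_spec(f[1L], f[2L], as.numeric(f[3L]), kind)
    })
  }
  specs <- c(parse_mods(kv[["fixed_mods"]], "fixed"),
             parse_mods(kv[["variable_mods"]], "variable"))
  if (!length(specs)) specs <- default_mods()
  list(config = config, specs = specs)
}
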