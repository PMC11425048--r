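#' Parse a protein FASTA file
#'
#' The accession is the header token up to the first whitespace; wrapped
#' sequence lines are concatenated and uppercased. Sequences may contain
#' non-canonical letters (e.g. X); they are kept here, but peptides spanning
#' them are skipped (with a warning) at digestion time.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `accession`, `sequence`, `is_decoy`.
#' @export
parse_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("malformed FASTA (no leading header): ", path)
  grp <- cumsum(hdr)
  acc <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  if (anyDuplicated(acc)) {
    stop("duplicate FASTA accession(s): ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), function(x) {
    toupper(paste(x, collapse = ""))
  }, character(1L))
  data.frame(accession = acc, sequence = unname(seqs[as.character(seq_along(acc))]),
             is_decoy = FALSE)
}

#' Generate reversed-sequence decoy proteins
#'
#' One decoy per target protein by full sequence reversal, accession
#' prefixed. Reversal preserves length and residue composition, so decoy
#' peptides are score-matched negatives for target-decoy FDR estimation.
#'
#' @param proteins data.frame as returned by [parse_fasta()].
#' @param prefix Decoy accession prefix.
#' @return data.frame of decoy records (same columns, `is_decoy = TRUE`).
#' @export
generate_decoys <- function(proteins, prefix = "DECOY_") {
  rev_seq <- vapply(strsplit(proteins$sequence, "", fixed = TRUE), function(x) {
    paste(rev(x), collapse = "")
  }, character(1L))
  data.frame(accession = paste0(prefix, proteins$accession),
             sequence = rev_seq, is_decoy = TRUE)
}

#' In-silico enzymatic digestion
#'
#' Default enzyme is trypsin: cleave C-terminal of K/R except before P.
#' Peptides with up to `missed_cleavages` internal uncleaved sites are
#' produced, filtered to the configured length window. Peptides containing
#' non-canonical residues are dropped with a warning.
#'
#' @param sequence Protein sequence string.
#' @param enzyme Only `"trypsin"` is implemented.
#' @param missed_cleavages Maximum internal missed cleavage sites (default 2).
#' @param length_range Length window `c(min, max)`; `NULL` disables the
#'   filter.
#' @return data.frame with `peptide` and `missed_cleavages`.
#' @export
#' @examples
#' digest("MKWVTFISLLLLFSSAYSR", missed_cleavages = 0, length_range = NULL)
digest <- function(sequence, enzyme = "trypsin", missed_cleavages = 2L,
                   length_range = c(7L, 50L)) {
  if (enzyme != "trypsin") stop("unsupported enzyme: ", enzyme)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < L & aa[pmin(cut_after + 1L, L)] != "P"]
  bounds <- c(0L, cut_after, L)
  nb <- length(bounds)
  pep <- character(0); mc <- integer(0)
  for (i in seq_len(nb - 1L)) {
    jmax <- min(nb, i + 1L + missed_cleavages)
    for (j in (i + 1L):jmax) {
      pep <- c(pep, substr(sequence, bounds[i] + 1L, bounds[j]))
      mc <- c(mc, j - i - 1L)
    }
  }
  if (!is.null(length_range)) {
    keep <- nchar(pep) >= length_range[1L] & nchar(pep) <= length_range[2L]
    pep <- pep[keep]; mc <- mc[keep]
  }
  bad <- grepl(sprintf("[^%s]", paste(AA_LETTERS, collapse = "")), pep)
  if (any(bad)) {
    warning(sum(bad), " peptide(s) with non-canonical residues skipped")
    pep <- pep[!bad]; mc <- mc[!bad]
  }
  data.frame(peptide = pep, missed_cleavages = mc)
}

#' Modification specification
#'
#' @param name Short name (e.g. `"carbamidomethyl"`).
#' @param target String of residue letters the modification applies to
#'   (e.g. `"M"` or `"STY"`).
#' @param delta_mass Added monoisotopic mass in Da.
#' @param kind `"fixed"` (applied unconditionally) or `"variable"`
#'   (enumerated on/off per eligible site).
#' @return A `modification_spec` list.
#' @export
modification_spec <- function(name, target, delta_mass, kind = c("variable", "fixed")) {
  kind <- match.arg(kind)
  stopifnot(is.finite(delta_mass))
  structure(list(name = name, target = target, delta_mass = delta_mass,
                 kind = kind), class = "modification_spec")
}

#' Default modification set
#'
#' Fixed carbamidomethylation of cysteine and variable oxidation of
#' methionine; [phospho_mods()] adds variable phosphorylation of S/T/Y for
#' phosphoproteome searches.
#'
#' @return List of [modification_spec()] objects.
#' @export
default_mods <- function() {
  list(modification_spec("carbamidomethyl", "C", 57.021464, "fixed"),
       modification_spec("oxidation", "M", 15.994915, "variable"))
}

#' @rdname default_mods
#' @export
phospho_mods <- function() {
  c(default_mods(),
    list(modification_spec("phospho", "STY", 79.966331, "variable")))
}

# fixed-mod base deltas and eligible variable sites for one peptide.
# each position is eligible for at most one variable spec (first matching
# spec wins); conflicting *fixed* specs on one residue are an error.
mod_layout <- function(peptide, specs) {
  aa <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  L <- length(aa)
  base <- numeric(L)
  fixed_hit <- logical(L)
  var_pos <- integer(0)
  var_delta <- numeric(0)
  var_taken <- logical(L)
  for (sp in specs) {
    targets <- strsplit(sp$target, "", fixed = TRUE)[[1L]]
    at <- which(aa %in% targets)
    if (sp$kind == "fixed") {
      if (any(fixed_hit[at])) {
        stop("conflicting fixed modifications on one residue in ", peptide)
      }
      fixed_hit[at] <- TRUE
      base[at] <- base[at] + sp$delta_mass
    } else {
      at <- at[!var_taken[at]]
      var_taken[at] <- TRUE
      var_pos <- c(var_pos, at)
      var_delta <- c(var_delta, rep(sp$delta_mass, length(at)))
    }
  }
  o <- order(var_pos)
  list(base = base, var_pos = var_pos[o], var_delta = var_delta[o])
}

#' Count modified peptide forms under the 20-site rule
#'
#' A peptide with `n` eligible variable sites has `2^n` on/off combinations
#' when `n <= cap` (default cap 20, i.e. up to 1,048,576 forms). Beyond the
#' cap the enumeration is truncated to at most `open_k` simultaneous
#' modifications, giving `sum(choose(n, 0:open_k))` forms.
#'
#' @param n Number of eligible variable sites (>= 0).
#' @param cap Full-combination cap (default 20).
#' @param open_k Truncation order beyond the cap (default 3).
#' @return Number of modification forms, as a double.
#' @export
#' @examples
#' count_modforms(20)  # 2^20
#' count_modforms(22)  # 1 + 22 + 231 + 1540
count_modforms <- function(n, cap = 20L, open_k = 3L) {
  stopifnot(n >= 0)
  if (n <= cap) 2^n else sum(choose(n, 0:open_k))
}

# next size-k combination of 1..n in lexicographic order; NULL when done
next_combination <- function(comb, n) {
  k <- length(comb)
  if (k == 0L) return(NULL)
  i <- k
  while (i >= 1L && comb[i] == n - k + i) i <- i - 1L
  if (i < 1L) return(NULL)
  comb[i] <- comb[i] + 1L
  if (i < k) comb[(i + 1L):k] <- comb[i] + seq_len(k - i)
  comb
}

#' Stream the modification forms of a peptide
#'
#' Returns a stateful iterator over all modified forms: fixed modifications
#' are applied unconditionally, then variable-site subsets are emitted by
#' increasing subset size and, within a size, in lexicographic site order
#' (the unmodified variable state comes first). The total number of emitted
#' forms equals [count_modforms()] of the number of eligible sites; forms
#' are generated lazily so a 20-site peptide never materializes its million
#' forms at once.
#'
#' @param peptide Peptide sequence string.
#' @param specs List of [modification_spec()] objects.
#' @inheritParams count_modforms
#' @return A function: each call returns the next form as a list with
#'   `sequence`, `deltas` (per-position Da), `neutral_mass`, `n_varmods`,
#'   and `mod_string` (canonical `"pos:delta"` annotation), or `NULL` when
#'   exhausted.
#' @export
enumerate_modforms <- function(peptide, specs = default_mods(), cap = 20L,
                               open_k = 3L) {
  lay <- mod_layout(peptide, specs)
  n <- length(lay$var_pos)
  max_size <- if (n <= cap) n else open_k
  base_mass <- peptide_mass(peptide, lay$base)
  size <- 0L
  comb <- integer(0)
  done <- FALSE
  nxt <- function() {
    if (done) return(NULL)
    sel <- comb
    # build the current form
    deltas <- lay$base
    if (length(sel)) {
      deltas[lay$var_pos[sel]] <- deltas[lay$var_pos[sel]] + lay$var_delta[sel]
    }
    form <- list(
      sequence = peptide,
      deltas = deltas,
      neutral_mass = base_mass + sum(lay$var_delta[sel]),
      n_varmods = length(sel),
      mod_string = mod_annotation(deltas)
    )
    # advance
    nxt_comb <- if (size == 0L) NULL else next_combination(comb, n)
    if (is.null(nxt_comb)) {
      size <<- size + 1L
      if (size > max_size) done <<- TRUE else comb <<- seq_len(size)
    } else {
      comb <<- nxt_comb
    }
    form
  }
  nxt
}

# canonical "pos:delta;pos:delta" annotation of nonzero position deltas
mod_annotation <- function(deltas) {
  at <- which(deltas != 0)
  if (!length(at)) return("")
  paste(sprintf("%d:%.6f", at, deltas[at]), collapse = ";")
}

#' Theoretical b and y fragment ions
#'
#' For a peptide of length L, each charge state z yields L - 1 b ions and
#' L - 1 y ions: `b_i(z) = (sum of the first i residue masses and deltas +
#' z * proton) / z` and `y_j(z) = (sum of the last j residue masses and
#' deltas + water + z * proton) / z`. Singly charged b and y ions satisfy
#' `b_i + y_(L-i) = M + 2 * proton`.
#'
#' @param sequence Peptide string (length >= 2).
#' @param deltas Optional per-position mass deltas (Da).
#' @param charges Fragment charge states to generate (default 1:2).
#' @return A `fragment_set`: list with per-charge lists `b` and `y` of m/z
#'   vectors, plus the neutral `mass`.
#' @export
#' @examples
#' fragment_ions("PEPTIDE", charges = 1L)$b[["1"]][2]  # b2, 1+
fragment_ions <- function(sequence, deltas = NULL, charges = c(1L, 2L)) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(aa)
  if (L < 2L) stop("peptide too short to fragment: ", sequence)
  m <- unname(AA_MONO[aa])
  if (anyNA(m)) stop("non-canonical residue in peptide: ", sequence)
  if (!is.null(deltas)) m <- m + deltas
  bsum <- cumsum(m[-L])
  ysum <- cumsum(rev(m)[-L])
  b <- lapply(charges, function(z) (bsum + z * PROTON_MASS) / z)
  y <- lapply(charges, function(z) (ysum + WATER_MASS + z * PROTON_MASS) / z)
  names(b) <- names(y) <- as.character(charges)
  structure(list(b = b, y = y, mass = sum(m) + WATER_MASS,
                 charges = as.integer(charges)),
            class = "fragment_set")
}

#' Build the searchable peptide database
#'
#' Digests target proteins and their reversed decoys, deduplicates peptide
#' sequences across proteins (collecting all supporting accessions), and
#' records per peptide the number of eligible variable-modification sites.
#' A sequence occurring in both the target and decoy space (e.g. a
#' palindromic tryptic peptide) is kept once, flagged `shared`, and treated
#' as a target; such sequences are excluded from decoy training downstream.
#'
#' @param proteins Target protein data.frame from [parse_fasta()].
#' @param specs Modification specs (see [modification_spec()]).
#' @param decoy_prefix Accession prefix for generated decoys.
#' @inheritParams digest
#' @return data.frame with `peptide`, `is_decoy`, `shared`,
#'   `missed_cleavages` (minimum over origins), `proteins` (collapsed with
#'   `;`), and `n_var_sites`.
#' @export
build_peptide_db <- function(proteins, specs = default_mods(),
                             missed_cleavages = 2L, length_range = c(7L, 50L),
                             decoy_prefix = "DECOY_") {
  all_prot <- rbind(proteins, generate_decoys(proteins, decoy_prefix))
  digs <- lapply(seq_len(nrow(all_prot)), function(i) {
    d <- digest(all_prot$sequence[i], missed_cleavages = missed_cleavages,
                length_range = length_range)
    if (!nrow(d)) return(NULL)
    d$accession <- all_prot$accession[i]
    d$is_decoy <- all_prot$is_decoy[i]
    d
  })
  dt <- data.table::rbindlist(digs[!vapply(digs, is.null, logical(1L))])
  if (!nrow(dt)) stop("digestion produced no peptides")
  pep <- dt[, list(
    missed_cleavages = min(missed_cleavages),
    proteins = paste(sort(unique(accession)), collapse = ";"),
    any_target = any(!is_decoy),
    any_decoy = any(is_decoy)
  ), by = "peptide"]
  pep[, `:=`(shared = any_target & any_decoy, is_decoy = !any_target)]
  pep[, c("any_target", "any_decoy") := NULL]
  # eligible variable sites per peptide
  var_targets <- unique(unlist(lapply(
    Filter(function(s) s$kind == "variable", specs),
    function(s) strsplit(s$target, "", fixed = TRUE)[[1L]]
  )))
  pep[, n_var_sites := if (length(var_targets)) {
    vapply(strsplit(peptide, "", fixed = TRUE),
           function(a) sum(a %in% var_targets), integer(1L))
  } else 0L]
  data.table::setDF(pep)
  pep
}
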