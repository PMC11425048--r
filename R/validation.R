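#' Target-decoy q-values
#'
#' Records are sorted by score descending; at each rank the FDR estimate is
#' `#decoys / max(1, #targets)` among the records at or above that rank,
#' and the q-value is the running minimum of FDR from the bottom up. Tied
#' scores share the q-value of the lowest rank in the tie. With
#' `plus_one = TRUE` the conservative `(#decoys + 1)` numerator is used.
#'
#' @param score Numeric scores (higher = more confident).
#' @param is_decoy Logical decoy labels, parallel to `score`.
#' @param plus_one Use the +1-corrected decoy count (default `FALSE`).
#' @return Numeric q-values parallel to the input order, in `[0, 1]`.
#' @export
#' @examples
#' compute_qvalues(c(5, 4, 3, 2, 1), c(FALSE, FALSE, TRUE, FALSE, TRUE))
compute_qvalues <- function(score, is_decoy, plus_one = FALSE) {
  n <- length(score)
  if (n == 0L) return(numeric(0))
  stopifnot(length(is_decoy) == n)
  o <- order(score, decreasing = TRUE)
  dec <- cumsum(is_decoy[o])
  tgt <- cumsum(!is_decoy[o])
  # evaluate FDR only at complete tie groups (the lowest rank of each),
  # so that the arbitrary order within a tie cannot influence the estimate
  s_sorted <- score[o]
  grp <- cumsum(c(TRUE, s_sorted[-1L] != s_sorted[-n]))
  last <- cumsum(tabulate(grp))
  fdr <- (dec[last] + if (plus_one) 1 else 0) / pmax(1, tgt[last])
  fdr <- pmin(fdr, 1)
  q_group <- rev(cummin(rev(fdr)))
  out <- numeric(n)
  out[o] <- q_group[grp]
  out
}

#' Score-sorted q-value table at a given level
#'
#' Collapses PSM records to the requested level (best score per modified
#' peptide, or per protein accession with decoy accessions competing) and
#' attaches target-decoy q-values.
#'
#' @param psms A `psm_table`, with a `score` column (see
#'   [psm_validate()]); falls back to `hyperscore` when absent.
#' @param level `"psm"`, `"peptide"` or `"protein"`.
#' @param plus_one Passed to [compute_qvalues()].
#' @param picked At protein level, apply picked-pair competition: a target
#'   accession and its decoy mate keep only the better-scoring of the two.
#' @return data.frame sorted by score descending with `key`, `score`,
#'   `is_decoy`, `q_value` (plus level-specific columns).
#' @export
qvalue_table <- function(psms, level = c("psm", "peptide", "protein"),
                         plus_one = FALSE, picked = FALSE) {
  level <- match.arg(level)
  score <- if ("score" %in% names(psms)) psms$score else psms$hyperscore
  if (level == "psm") {
    tab <- data.frame(key = paste0("spec", psms$spectrum_id), score = score,
                      is_decoy = psms$is_decoy, peptide = psms$peptide,
                      pepkey = psms$pepkey, stringsAsFactors = FALSE)
  } else if (level == "peptide") {
    dt <- data.table::data.table(grp = psms$pepkey, score = score,
                                 is_decoy = psms$is_decoy,
                                 peptide = psms$peptide,
                                 proteins = psms$proteins)
    tab <- dt[, .SD[which.max(score)], by = "grp"]
    data.table::setDF(tab)
    names(tab)[names(tab) == "grp"] <- "key"
  } else {
    acc <- strsplit(psms$proteins, ";", fixed = TRUE)
    reps <- lengths(acc)
    dt <- data.table::data.table(
      grp = unlist(acc, use.names = FALSE),
      score = rep(score, reps),
      is_decoy = rep(psms$is_decoy, reps),
      peptide = rep(psms$peptide, reps)
    )
    tab <- dt[, list(score = max(score), is_decoy = is_decoy[1L],
                     peptides = paste(sort(unique(peptide)), collapse = ";")),
              by = "grp"]
    data.table::setDF(tab)
    names(tab)[names(tab) == "grp"] <- "key"
    if (picked) {
      root <- sub("^DECOY_", "", tab$key)
      keep <- unlist(lapply(split(seq_len(nrow(tab)), root), function(i) {
        i[which.max(tab$score[i])]
      }), use.names = FALSE)
      tab <- tab[sort(keep), , drop = FALSE]
    }
  }
  tab$q_value <- compute_qvalues(tab$score, tab$is_decoy, plus_one)
  tab <- tab[order(-tab$score), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Split scored PSMs into discriminant training classes
#'
#' Positives are the target precursors (best PSM per modified peptide and
#' charge) of the rank-1 stream that pass the hyperscore-ranked
#' target-decoy q-value threshold. Negatives are all decoy PSMs of
#' `decoy_pool` — normally the per-peptide stream, so that every decoy
#' peptide contributes its best match as a negative sample even when it
#' never wins a spectrum outright. Sequences shared between the target and
#' decoy space are excluded from the negatives.
#'
#' @param psms A `psm_table` (hyperscore-scored, best PSM per spectrum).
#' @param fdr_threshold Precursor-level q-value threshold (default 0.01).
#' @param decoy_pool `psm_table` whose decoy rows form the negative class;
#'   defaults to `psms` itself.
#' @return List with `positives` and `negatives` (both `psm_table` subsets)
#'   and the precursor table used for the cut.
#' @export
assemble_training_set <- function(psms, fdr_threshold = 0.01,
                                  decoy_pool = psms) {
  if (!any(!psms$is_decoy)) stop("no target PSMs; cannot assemble training set")
  dt <- data.table::as.data.table(psms)
  dt[, precursor := paste0(pepkey, "/", precursor_charge)]
  prec <- dt[, .SD[which.max(hyperscore)], by = "precursor"]
  prec[, q_value := compute_qvalues(hyperscore, is_decoy)]
  pos_keys <- prec[q_value <= fdr_threshold & !is_decoy, precursor]
  positives <- dt[precursor %in% pos_keys]
  positives <- positives[, .SD[which.max(hyperscore)], by = "precursor"]
  if (nrow(positives) == 0L) {
    stop("no confident target precursors at q <= ", fdr_threshold)
  }
  negatives <- data.table::as.data.table(decoy_pool)[is_decoy & !shared]
  if (nrow(negatives) == 0L) stop("no decoy PSMs to use as negatives")
  data.table::setDF(positives); data.table::setDF(negatives)
  pr <- data.table::setDF(prec)
  list(positives = positives, negatives = negatives, precursors = pr)
}

# feature block fed to the discriminant: scores, matched-ion summaries,
# peptide properties, charge one-hot, mass error and RT error
build_psm_features <- function(psms, rt_model = NULL) {
  rt_err <- rep(0, nrow(psms))
  if (!is.null(rt_model) && inherits(rt_model, "rt_model") &&
      rt_model$type != "disabled") {
    pred <- predict(rt_model, psms)
    rt_err <- psms$retention_time - pred
    rt_err[!is.finite(rt_err)] <- 0
  }
  z <- pmin(pmax(psms$precursor_charge, 1L), 4L)
  X <- cbind(
    hyperscore = psms$hyperscore,
    xcorr = psms$xcorr,
    ln_nb = log1p(psms$Nb),
    ln_ny = log1p(psms$Ny),
    matched_frac = ifelse(psms$total_intensity > 0,
                          (psms$sum_Ib + psms$sum_Iy) / psms$total_intensity, 0),
    length = nchar(psms$peptide),
    ln_mass = log(psms$pep_mass),
    z1 = as.numeric(z == 1L), z2 = as.numeric(z == 2L),
    z3 = as.numeric(z == 3L), z4 = as.numeric(z == 4L),
    delta_mass = psms$delta_mass,
    abs_delta_mass = abs(psms$delta_mass),
    n_varmods = psms$n_varmods,
    missed_cleavages = psms$missed_cleavages,
    rt_error = rt_err
  )
  X
}

#' Train the PSM discriminant network
#'
#' A three-layer fully connected binary classifier (32-16-1, ReLU, dropout)
#' over the PSM feature vector, trained from scratch per run with the
#' class imbalance handled by weighting negatives by
#' `n_positives / n_negatives`. The discriminant score d is the pre-sigmoid
#' output; higher d means greater match confidence.
#'
#' @param positives,negatives `psm_table` subsets from
#'   [assemble_training_set()].
#' @param rt_model The run's [train_rt_model()] result (used for the
#'   RT-error feature).
#' @param seed RNG seed.
#' @param epochs,batch,dropout,patience Optimizer settings.
#' @return A `discriminant_model` with a [predict][predict.discriminant_model]
#'   method returning d.
#' @export
train_discriminant <- function(positives, negatives, rt_model = NULL,
                               seed = 42L, epochs = 60L, batch = 512L,
                               dropout = 0.2, patience = 10L) {
  stopifnot(nrow(positives) > 0L, nrow(negatives) > 0L)
  X <- rbind(build_psm_features(positives, rt_model),
             build_psm_features(negatives, rt_model))
  y <- c(rep(1, nrow(positives)), rep(0, nrow(negatives)))
  ok <- apply(X, 1L, function(r) all(is.finite(r)))
  if (!all(ok)) {
    warning(sum(!ok), " PSM(s) with non-finite features excluded from training")
    X <- X[ok, , drop = FALSE]; y <- y[ok]
  }
  w <- ifelse(y == 1, 1, sum(y == 1) / sum(y == 0))
  x_center <- colMeans(X)
  x_scale <- apply(X, 2L, stats::sd)
  x_scale[x_scale < 1e-12] <- 1
  Xs <- scale(X, center = x_center, scale = x_scale)
  set.seed(seed + 1L)
  tr <- nn_mlp_train(Xs, y, w, sizes = c(32L, 16L), epochs = epochs,
                     batch = batch, dropout = dropout, patience = patience)
  structure(list(layers = tr$layers, history = tr$history,
                 best_epoch = tr$best_epoch, x_center = x_center,
                 x_scale = x_scale, rt_model = rt_model, seed = seed),
            class = "discriminant_model")
}

#' @param object A `discriminant_model`.
#' @param newdata A `psm_table`.
#' @param ... Unused.
#' @return Discriminant scores d (pre-sigmoid logits).
#' @rdname train_discriminant
#' @export
predict.discriminant_model <- function(object, newdata, ...) {
  X <- build_psm_features(newdata, object$rt_model)
  Xs <- scale(X, center = object$x_center, scale = object$x_scale)
  nn_mlp_predict(object$layers, Xs)
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf(
    "PSM discriminant (3-layer MLP), best epoch %d, validation loss %.4f\n",
    x$best_epoch, min(x$history$val_loss)))
  invisible(x)
}

#' FDR-filtered peptide and protein reports
#'
#' @param pep_q,prot_q Peptide- and protein-level tables from
#'   [qvalue_table()].
#' @param threshold Reporting q-value threshold (default 0.01).
#' @return List with `peptides` (target modified peptides at
#'   `q <= threshold`) and `proteins` (target accessions at
#'   `q <= threshold`, each with its supporting peptides and a
#'   `shared_only` flag for accessions supported exclusively by peptides
#'   mapping to several proteins). Decoys are excluded from both reports.
#' @export
final_report <- function(pep_q, prot_q, threshold = 0.01) {
  peptides <- pep_q[!pep_q$is_decoy & pep_q$q_value <= threshold, , drop = FALSE]
  rownames(peptides) <- NULL
  proteins <- prot_q[!prot_q$is_decoy & prot_q$q_value <= threshold, , drop = FALSE]
  if (nrow(proteins)) {
    multi <- vapply(strsplit(peptides$proteins %||% character(0), ";",
                             fixed = TRUE),
                    function(a) length(a) > 1L, logical(1L))
    shared_pep <- if (length(multi)) peptides$peptide[multi] else character(0)
    proteins$shared_only <- vapply(strsplit(proteins$peptides, ";", fixed = TRUE),
                                   function(p) all(p %in% shared_pep),
                                   logical(1L))
  }
  rownames(proteins) <- NULL
  list(peptides = peptides, proteins = proteins)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a PSM table with the learned per-run models
#'
#' The full validation stage: hyperscore-ranked precursor q-values over the
#' rank-1 PSMs define the positive class, an RT regressor is trained on
#' the confident target peptides, the three-layer discriminant is trained
#' against the best PSM of every decoy peptide, every rank-1 PSM is
#' rescored with the discriminant d, and q-values are computed at the PSM,
#' peptide and protein levels. If no confident positives (or no decoys)
#' exist the stage falls back to hyperscore ranking with a warning.
#'
#' @param psms A `psm_table` from [search_all()]. The per-peptide stream
#'   (attribute `peptide_psms`, best spectrum per candidate form) supplies
#'   the decoy negatives for training; when absent, `psms` itself stands
#'   in for it.
#' @param config A [search_config()] (seed and FDR threshold are used).
#' @param rt_epochs,disc_epochs Training lengths of the two networks.
#' @return A `psm_validation` object: the rescored PSM table (`psms`, with
#'   `score` and `q_value`), the rescored per-peptide stream
#'   (`peptide_psms`), the level tables (`psm_q`, `peptide_q`,
#'   `protein_q`), the filtered `report`, both models, and a `counts` log.
#' @export
psm_validate <- function(psms, config = search_config(), rt_epochs = 100L,
                         disc_epochs = 60L) {
  stopifnot(inherits(psms, "psm_table"), nrow(psms) > 0L)
  pep_psms <- attr(psms, "peptide_psms")
  if (is.null(pep_psms) || nrow(pep_psms) == 0L) pep_psms <- psms
  thr <- config$fdr_threshold
  counts <- list(n_psms = nrow(psms), n_peptide_psms = nrow(pep_psms),
                 n_decoy_peptide_psms = sum(pep_psms$is_decoy))
  fallback <- FALSE
  ts <- tryCatch(assemble_training_set(psms, thr, decoy_pool = pep_psms),
                 error = function(e) {
    warning("validation fallback to hyperscore ranking: ",
            conditionMessage(e))
    NULL
  })
  if (is.null(ts)) {
    fallback <- TRUE
    d <- psms$hyperscore
    dp <- pep_psms$hyperscore
    rt_model <- NULL; disc <- NULL
  } else {
    counts$n_positives <- nrow(ts$positives)
    counts$n_negatives <- nrow(ts$negatives)
    # RT training set: best PSM per confident target peptide, observed RT
    rt_train <- ts$positives[!duplicated(ts$positives$peptide) &
                               is.finite(ts$positives$retention_time), ,
                             drop = FALSE]
    rt_model <- train_rt_model(rt_train, seed = config$seed,
                               epochs = rt_epochs)
    counts$n_rt_train <- nrow(rt_train)
    disc <- train_discriminant(ts$positives, ts$negatives, rt_model,
                               seed = config$seed, epochs = disc_epochs)
    d <- predict(disc, psms)
    dp <- predict(disc, pep_psms)
  }
  psms$score <- d
  pep_psms$score <- dp
  psm_q <- qvalue_table(psms, "psm")
  pep_q <- qvalue_table(psms, "peptide")
  prot_q <- qvalue_table(psms, "protein")
  psms$q_value <- psm_q$q_value[match(paste0("spec", psms$spectrum_id),
                                      psm_q$key)]
  report <- final_report(pep_q, prot_q, thr)
  counts$n_peptides_reported <- nrow(report$peptides)
  counts$n_proteins_reported <- nrow(report$proteins)
  structure(list(psms = psms, peptide_psms = pep_psms,
                 psm_q = psm_q, peptide_q = pep_q,
                 protein_q = prot_q, report = report, rt_model = rt_model,
                 discriminant = disc, counts = counts,
                 fdr_threshold = thr, fallback = fallback),
            class = "psm_validation")
}

#' @export
print.psm_validation <- function(x, ...) {
  cat(sprintf("PSM validation (%s): %d PSMs in, %d peptides and %d proteins at q <= %g\n",
              if (x$fallback) "hyperscore fallback" else "learned discriminant",
              x$counts$n_psms, x$counts$n_peptides_reported,
              x$counts$n_proteins_reported, x$fdr_threshold))
  invisible(x)
}

#' @export
summary.psm_validation <- function(object, ...) {
  print(object)
  c <- object$counts
  if (!is.null(c$n_positives)) {
    cat(sprintf("  training classes: %d positives, %d negatives (%d RT peptides)\n",
                c$n_positives, c$n_negatives, c$n_rt_train))
  }
  d <- object$peptide_psms$score
  dec <- object$peptide_psms$is_decoy
  cat(sprintf("  discriminant d (peptide stream): targets %.2f, decoys %.2f (mean)\n",
              mean(d[!dec]), mean(d[dec])))
  invisible(object)
}
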