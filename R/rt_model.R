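#' Encode a peptide for retention-time prediction
#'
#' 63 features: 20 whole-sequence residue counts, 20 counts over the first
#' two residues, 20 counts over the last two residues, the C-terminal
#' residue index (0-19, alphabetical), the peptide length, and the neutral
#' mass in Da (including modification deltas). Composition counts ignore
#' modifications; only the mass feature changes with them.
#'
#' @param sequence Peptide string over the canonical residues.
#' @param deltas Optional per-position modification masses (Da).
#' @param mass Optional precomputed neutral mass; overrides `deltas`.
#' @return Named numeric vector of length 63.
#' @export
encode_rt_features <- function(sequence, deltas = NULL, mass = NULL) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(aa)
  if (L < 2L) stop("peptide too short to encode: ", sequence)
  if (!all(aa %in% AA_LETTERS)) {
    stop("non-canonical residue in peptide: ", sequence)
  }
  count20 <- function(x) {
    v <- table(factor(x, levels = AA_LETTERS))
    as.numeric(v)
  }
  if (is.null(mass)) mass <- peptide_mass(sequence, deltas)
  out <- c(count20(aa),
           count20(aa[1:2]),
           count20(aa[(L - 1L):L]),
           match(aa[L], AA_LETTERS) - 1L,
           L,
           mass)
  names(out) <- c(paste0("n_", AA_LETTERS), paste0("nt_", AA_LETTERS),
                  paste0("ct_", AA_LETTERS), "cterm_idx", "length", "mass")
  out
}

# vectorized encoder (same values as encode_rt_features, row per peptide)
rt_feature_matrix <- function(sequences, masses = NULL) {
  n <- length(sequences)
  if (is.null(masses)) masses <- rep(NA_real_, n)
  split_seqs <- strsplit(sequences, "", fixed = TRUE)
  X <- matrix(0, n, 63L)
  for (i in seq_len(n)) {
    idx <- match(split_seqs[[i]], AA_LETTERS)
    if (anyNA(idx)) stop("non-canonical residue in peptide: ", sequences[i])
    L <- length(idx)
    m <- masses[i]
    if (is.na(m)) m <- sum(AA_MONO[idx]) + WATER_MASS
    X[i, ] <- c(tabulate(idx, 20L), tabulate(idx[1:2], 20L),
                tabulate(idx[c(L - 1L, L)], 20L), idx[L] - 1L, L, m)
  }
  colnames(X) <- c(paste0("n_", AA_LETTERS), paste0("nt_", AA_LETTERS),
                   paste0("ct_", AA_LETTERS), "cterm_idx", "length", "mass")
  X
}

#' Train the retention-time regressor on a run's confident peptides
#'
#' Trains, from scratch on this run only, a four-branch network (parallel
#' dense stacks of depth 1, 2 and 3 with 64 ReLU units and dropout, plus a
#' linear shortcut, concatenated and reduced 256 -> 64 -> 1) on the
#' 63-dimensional sequence-composition encoding. Features are standardized
#' and RT is min-max scaled internally; a 90/10 train/validation split
#' drives early stopping and the per-epoch losses are kept in the returned
#' object. With fewer than `min_nn` confident peptides the model falls back
#' to linear regression on the same features; with fewer than `min_fit`
#' peptides RT prediction is disabled and downstream RT-error features are
#' zeroed.
#'
#' @param peptides data.frame with columns `peptide`, `retention_time`
#'   (seconds) and optionally `pep_mass`.
#' @param seed RNG seed; training is deterministic given data and seed.
#' @param epochs,batch,dropout,patience Optimizer settings.
#' @param min_nn,min_fit Sample-size thresholds for the network and for any
#'   fit at all.
#' @return An `rt_model` (types `"nn"`, `"lm"`, `"constant"` or
#'   `"disabled"`) with a [predict][predict.rt_model] method returning
#'   seconds.
#' @export
train_rt_model <- function(peptides, seed = 42L, epochs = 100L, batch = 64L,
                           dropout = 0.2, patience = 15L,
                           min_nn = 200L, min_fit = 20L) {
  n <- nrow(peptides)
  if (n < min_fit) {
    warning("only ", n, " confident peptides; RT prediction disabled")
    return(structure(list(type = "disabled", n_train = n), class = "rt_model"))
  }
  masses <- if ("pep_mass" %in% names(peptides)) peptides$pep_mass else NULL
  X <- rt_feature_matrix(peptides$peptide, masses)
  y <- peptides$retention_time
  rt_min <- min(y); rt_max <- max(y)
  if (rt_max - rt_min < 1e-9) {
    return(structure(list(type = "constant", value = rt_min, n_train = n),
                     class = "rt_model"))
  }
  x_center <- colMeans(X)
  x_scale <- apply(X, 2L, stats::sd)
  x_scale[x_scale < 1e-12] <- 1
  Xs <- scale(X, center = x_center, scale = x_scale)
  ys <- (y - rt_min) / (rt_max - rt_min)

  set.seed(seed)
  if (n < min_nn) {
    df <- data.frame(y = ys, Xs)
    fit <- stats::lm(y ~ ., data = df)
    mod <- structure(list(type = "lm", fit = fit, x_center = x_center,
                          x_scale = x_scale, rt_min = rt_min, rt_max = rt_max,
                          n_train = n, seed = seed), class = "rt_model")
    return(mod)
  }
  val_idx <- sample(n, max(1L, round(0.1 * n)))
  tr <- nn_branched_train(Xs, ys, val_idx, epochs = epochs, batch = batch,
                          dropout = dropout, patience = patience)
  structure(list(type = "nn", net = tr$net, history = tr$history,
                 best_epoch = tr$best_epoch, x_center = x_center,
                 x_scale = x_scale, rt_min = rt_min, rt_max = rt_max,
                 n_train = n, val_idx = val_idx, seed = seed),
            class = "rt_model")
}

#' Predict retention times (seconds)
#'
#' @param object An `rt_model` from [train_rt_model()].
#' @param newdata data.frame with `peptide` (and optionally `pep_mass`), or
#'   a character vector of peptides.
#' @param ... Unused.
#' @return Numeric vector of predicted retention times in seconds (`NA`
#'   when the model is disabled).
#' @export
predict.rt_model <- function(object, newdata, ...) {
  if (is.character(newdata)) newdata <- data.frame(peptide = newdata)
  n <- nrow(newdata)
  if (object$type == "disabled") return(rep(NA_real_, n))
  if (object$type == "constant") return(rep(object$value, n))
  masses <- if ("pep_mass" %in% names(newdata)) newdata$pep_mass else NULL
  X <- rt_feature_matrix(newdata$peptide, masses)
  Xs <- scale(X, center = object$x_center, scale = object$x_scale)
  ys <- if (object$type == "lm") {
    # the fixed 63-feature design is collinear (counts sum to length), so
    # the small-sample lm fallback is rank-deficient by construction
    suppressWarnings(stats::predict(object$fit, newdata = data.frame(Xs)))
  } else {
    drop(nn_branched_forward(object$net, Xs)$out)
  }
  as.numeric(ys) * (object$rt_max - object$rt_min) + object$rt_min
}

#' @export
print.rt_model <- function(x, ...) {
  cat(sprintf("retention-time model (%s), trained on %d peptides\n",
              x$type, x$n_train))
  if (x$type == "nn") {
    cat(sprintf("  best epoch %d, validation MSE %.5f (scaled units)\n",
                x$best_epoch, min(x$history$val_loss)))
  }
  invisible(x)
}
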