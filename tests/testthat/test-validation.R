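test_that("q-values reproduce the hand-computed target-decoy sequence", {
  # sorted labels T T D T D -> FDR 0/1, 0/2, 1/2, 1/3, 2/3 -> running min
  q <- compute_qvalues(c(5, 4, 3, 2, 1), c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(q, c(0, 0, 1/3, 1/3, 2/3))
  expect_equal(compute_qvalues(c(3, 2, 1), rep(FALSE, 3)), rep(0, 3))
  expect_equal(compute_qvalues(numeric(0), logical(0)), numeric(0))
  # +1 correction raises every estimate
  q1 <- compute_qvalues(c(5, 4, 3, 2, 1), c(FALSE, FALSE, TRUE, FALSE, TRUE),
                        plus_one = TRUE)
  expect_true(all(q1 >= q))
})

test_that("tied scores share the q of the lowest rank in the tie", {
  q <- compute_qvalues(c(5, 5, 5, 1), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(q[1], q[2])
  expect_equal(q[2], q[3])
  expect_equal(q[1], 1/2)  # worst rank of the tie: 1 decoy / 2 targets
})

test_that("q-values are monotone and match a set-based oracle", {
  set.seed(55)
  n <- 800L
  score <- round(rnorm(n), 2)  # rounding forces ties
  dec <- runif(n) < 0.4
  q <- compute_qvalues(score, dec)
  o <- order(score, decreasing = TRUE)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_true(all(q >= 0 & q <= 1))
  # oracle: FDR of the score set at or above s, then minimum over any
  # admissible threshold at or below s
  fdr_at <- function(s) sum(dec[score >= s]) / max(1, sum(!dec[score >= s]))
  for (s in sample(unique(score), 25L)) {
    oracle_q <- min(1, min(vapply(unique(score[score <= s]), fdr_at,
                                  numeric(1L))))
    expect_equal(unique(q[score == s]), oracle_q)
  }
})

test_that("training classes follow the hand-evaluated precursor q cut", {
  H <- c(100, 90, 80, 70, 60, 50, 40, 30, 20, 10)
  dec <- c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  psms <- data.frame(
    spectrum_id = 0:9, retention_time = 60, precursor_charge = 2L,
    precursor_mass = 1000, total_intensity = 1000,
    peptide = paste0("PEPTID", LETTERS[1:10], "K"),
    mod_string = "", pepkey = paste0("PEPTID", LETTERS[1:10], "K|"),
    proteins = "P1", missed_cleavages = 0L, n_varmods = 0L,
    pep_mass = 1000, delta_mass = 0, Nb = 5L, Ny = 5L,
    sum_Ib = 100, sum_Iy = 100, hyperscore = H, xcorr = 1,
    is_decoy = dec, shared = FALSE)
  class(psms) <- c("psm_table", "data.frame")
  ts <- assemble_training_set(psms, fdr_threshold = 0.01)
  # hand-computed: FDR stays 0 through the six targets, jumps at the decoys
  expect_setequal(ts$positives$peptide, psms$peptide[1:6])
  expect_equal(nrow(ts$negatives), 4L)

  all_dec <- psms; all_dec$is_decoy <- TRUE
  expect_error(assemble_training_set(all_dec), "no target")
})

test_that("the RT encoder emits the documented 63-dimensional layout", {
  v <- encode_rt_features("AAK")
  expect_length(v, 63L)
  expect_equal(unname(v["n_A"]), 2)
  expect_equal(unname(v["n_K"]), 1)
  expect_equal(sum(v[1:20]), 3)            # whole-sequence counts sum to length
  expect_equal(unname(v["nt_A"]), 2)       # first two residues: A, A
  expect_equal(sum(v[21:40]), 2)
  expect_equal(unname(v["ct_A"]), 1)       # last two residues: A, K
  expect_equal(unname(v["ct_K"]), 1)
  expect_equal(unname(v["cterm_idx"]), match("K", names(AA_MONO)) - 1)
  expect_equal(unname(v["length"]), 3)
  # modification deltas feed only the mass feature
  v2 <- encode_rt_features("ACDK", deltas = c(0, 57.021464, 0, 0))
  v0 <- encode_rt_features("ACDK")
  expect_equal(unname(v2["mass"] - v0["mass"]), 57.021464)
  expect_equal(v2[1:62], v0[1:62])
  expect_error(encode_rt_features("AXK"), "non-canonical")
  # vectorized encoder agrees with the scalar one
  set.seed(3)
  peps <- vapply(1:10, function(i) random_peptide(sample(7:20, 1L)), "")
  M <- psmsearch:::rt_feature_matrix(peps)
  for (i in seq_along(peps)) {
    expect_equal(unname(M[i, ]), unname(encode_rt_features(peps[i])))
  }
})

test_that("RT training is seeded-deterministic and handles degenerate data", {
  set.seed(9)
  peps <- vapply(1:250, function(i) random_peptide(sample(7:25, 1L)), "")
  coef <- runif(20, 60, 420); names(coef) <- names(AA_MONO)
  rt <- vapply(peps, function(p) {
    sum(coef[strsplit(p, "")[[1]]])
  }, numeric(1L)) + rnorm(250, 0, 30)
  df <- data.frame(peptide = peps, retention_time = rt)
  m1 <- train_rt_model(df, seed = 7, epochs = 30L)
  m2 <- train_rt_model(df, seed = 7, epochs = 30L)
  expect_equal(m1$type, "nn")
  expect_identical(predict(m1, df), predict(m2, df))

  # constant retention times give constant predictions
  dfc <- df; dfc$retention_time <- 1200
  mc <- train_rt_model(dfc, seed = 7)
  expect_equal(predict(mc, df[1:5, ]), rep(1200, 5), tolerance = 1)

  # below the fitting floor the model is disabled
  expect_warning(md <- train_rt_model(df[1:10, ], seed = 7), "disabled")
  expect_true(all(is.na(predict(md, df[1:3, ]))))

  # between the floors a linear fit on the same features is used
  ml <- train_rt_model(df[1:100, ], seed = 7)
  expect_equal(ml$type, "lm")
  expect_gt(cor(predict(ml, df[101:250, ]), rt[101:250]), 0.9)
})

test_that("discriminant separates separable classes and not permuted ones", {
  set.seed(13)
  n <- 300L
  base <- data.frame(
    spectrum_id = seq_len(2 * n) - 1L, retention_time = 60,
    precursor_charge = 2L, precursor_mass = 1000, total_intensity = 1000,
    peptide = "LVNEVTEFAK", mod_string = "", pepkey = "LVNEVTEFAK|",
    proteins = "P1", missed_cleavages = 0L, n_varmods = 0L, pep_mass = 1000,
    delta_mass = 0, Nb = 5L, Ny = 5L, sum_Ib = 100, sum_Iy = 100,
    hyperscore = 0, xcorr = 0, is_decoy = FALSE, shared = FALSE)
  pos <- base[1:n, ];  pos$hyperscore <- rnorm(n, 40, 3);  pos$xcorr <- rnorm(n, 5, 1)
  neg <- base[(n + 1):(2 * n), ]; neg$hyperscore <- rnorm(n, 8, 3); neg$xcorr <- rnorm(n, 0.5, 1)
  class(pos) <- class(neg) <- c("psm_table", "data.frame")
  disc <- train_discriminant(pos, neg, rt_model = NULL, seed = 1, epochs = 40L)
  acc <- mean(c(predict(disc, pos) > 0, predict(disc, neg) < 0))
  expect_gte(acc, 0.99)

  # label permutation destroys the signal: held-out accuracy near chance
  both <- rbind(pos, neg)
  set.seed(2)
  perm <- sample(2 * n)
  ppos <- both[perm[1:n], ]; pneg <- both[perm[(n + 1):(2 * n)], ]
  class(ppos) <- class(pneg) <- c("psm_table", "data.frame")
  disc2 <- train_discriminant(ppos[1:(n - 50), ], pneg[1:(n - 50), ],
                              rt_model = NULL, seed = 1, epochs = 40L)
  held_acc <- mean(c(predict(disc2, ppos[(n - 49):n, ]) > 0,
                     predict(disc2, pneg[(n - 49):n, ]) < 0))
  expect_gte(held_acc, 0.3)
  expect_lte(held_acc, 0.7)
})

test_that("level tables collapse correctly and reports respect thresholds", {
  psms <- data.frame(
    spectrum_id = 0:5, retention_time = 60, precursor_charge = 2L,
    precursor_mass = 1000, total_intensity = 1000,
    peptide = c("AAAAAAK", "AAAAAAK", "CCCCCCK", "DDDDDDK", "EEEEEEK", "FFFFFFK"),
    mod_string = "",
    pepkey = c("AAAAAAK|", "AAAAAAK|", "CCCCCCK|", "DDDDDDK|", "EEEEEEK|", "FFFFFFK|"),
    proteins = c("P1", "P1", "P1;P2", "DECOY_P1", "P1", "DECOY_P2"),
    missed_cleavages = 0L, n_varmods = 0L, pep_mass = 1000, delta_mass = 0,
    Nb = 5L, Ny = 5L, sum_Ib = 100, sum_Iy = 100,
    hyperscore = c(50, 60, 40, 30, 20, 10), xcorr = 1,
    is_decoy = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE), shared = FALSE)
  class(psms) <- c("psm_table", "data.frame")

  pq <- qvalue_table(psms, "peptide")
  expect_equal(nrow(pq), 5L)  # two spectra of AAAAAAK collapse to its best
  expect_equal(pq$score[pq$key == "AAAAAAK|"], 60)

  rq <- qvalue_table(psms, "protein")
  expect_setequal(rq$key, c("P1", "P2", "DECOY_P1", "DECOY_P2"))
  expect_equal(rq$score[rq$key == "P2"], 40)  # its best supporting peptide
  expect_equal(rq$score[rq$key == "P1"], 60)
  picked <- qvalue_table(psms, "protein", picked = TRUE)
  expect_equal(nrow(picked), 2L)  # each decoy loses its pairing

  rep0 <- final_report(pq, rq, threshold = 1)
  expect_setequal(rep0$peptides$peptide, c("AAAAAAK", "CCCCCCK", "EEEEEEK"))
  expect_false(any(rep0$proteins$key %in% c("DECOY_P1", "DECOY_P2")))
  # a protein supported only by shared peptides is flagged
  expect_true(rep0$proteins$shared_only[rep0$proteins$key == "P2"])
  expect_false(rep0$proteins$shared_only[rep0$proteins$key == "P1"])

  rep1 <- final_report(pq, rq, threshold = 0.01)
  expect_true(all(rep1$peptides$q_value <= 0.01))
})
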