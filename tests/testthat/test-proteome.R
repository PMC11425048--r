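test_that("FASTA parsing: accessions, wrapping, duplicates, odd residues", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">sp|P1|ALBU description here", "PEPTIDEK", "WWTR",
               ">P2", "AAAA", "KKKK", "RRRR"), f)
  p <- parse_fasta(f)
  expect_equal(nrow(p), 2L)
  expect_equal(p$accession, c("sp|P1|ALBU", "P2"))
  expect_equal(p$sequence[1], "PEPTIDEKWWTR")
  expect_equal(p$sequence[2], "AAAAKKKKRRRR")

  writeLines(c(">A", "PEPK", ">A", "WWWR"), f)
  expect_error(parse_fasta(f), "duplicate")
  writeLines(character(0), f)
  expect_error(parse_fasta(f), "empty")

  # X-containing proteins are retained; offending peptides drop at digestion
  expect_warning(d <- digest("AAAAAAKXXXPEPTIDEK", length_range = NULL),
                 "non-canonical")
  expect_true("AAAAAAK" %in% d$peptide)
  expect_false(any(grepl("X", d$peptide)))
})

test_that("tryptic digestion follows the K/R-not-before-P rule", {
  d <- digest("MKWVTFISLLLLFSSAYSR", missed_cleavages = 0L, length_range = NULL)
  expect_setequal(d$peptide, c("MK", "WVTFISLLLLFSSAYSR"))
  # K before P is protected; the terminal R ends the protein
  expect_equal(digest("AKPR", missed_cleavages = 0L, length_range = NULL)$peptide,
               "AKPR")
  # missed cleavages add the concatenated forms
  d2 <- digest("AAKGGGRSSSK", missed_cleavages = 1L, length_range = NULL)
  expect_true(all(c("AAK", "GGGR", "SSSK", "AAKGGGR", "GGGRSSSK") %in% d2$peptide))
  expect_equal(d2$missed_cleavages[d2$peptide == "AAKGGGR"], 1L)
})

test_that("digestion equals an exhaustive cleavage-subset oracle", {
  # oracle: enumerate every substring and keep those whose ends are valid
  # cleavage boundaries with at most mc internal uncleaved sites
  oracle_digest <- function(seq, mc) {
    aa <- strsplit(seq, "", fixed = TRUE)[[1L]]
    L <- length(aa)
    is_site <- function(i) i == 0L || i == L ||
      (aa[i] %in% c("K", "R") && aa[i + 1L] != "P")
    out <- character(0)
    for (i in 0:(L - 1L)) for (j in (i + 1L):L) {
      if (!is_site(i) || !is_site(j)) next
      internal <- sum(vapply(seq_len(L - 1L), function(k) {
        k > i && k < j && aa[k] %in% c("K", "R") && aa[k + 1L] != "P"
      }, logical(1L)))
      if (internal <= mc) out <- c(out, substr(seq, i + 1L, j))
    }
    sort(out)
  }
  set.seed(17)
  for (rep in 1:15) {
    seq <- random_peptide(sample(8:30, 1L))
    mc <- sample(0:2, 1L)
    expect_equal(sort(digest(seq, missed_cleavages = mc,
                             length_range = NULL)$peptide),
                 oracle_digest(seq, mc))
  }
})

test_that("decoys are full reversals, one per target", {
  p <- data.frame(accession = c("P1", "P2"),
                  sequence = c("PEPTIDEK", "AAWR"), is_decoy = FALSE)
  d <- generate_decoys(p)
  expect_equal(nrow(d), 2L)
  expect_equal(d$sequence, c("KEDITPEP", "RWAA"))
  expect_equal(d$accession, c("DECOY_P1", "DECOY_P2"))
  expect_true(all(d$is_decoy))
})

test_that("sequences shared by target and decoy space are flagged shared", {
  # a palindromic protein digests into peptides identical to its reversal
  p <- data.frame(accession = "PAL", sequence = "AADDKDDAAKWWYYTTR",
                  is_decoy = FALSE)
  db <- build_peptide_db(p, specs = list(), missed_cleavages = 0L,
                         length_range = c(4L, 50L))
  shared <- db$peptide[db$shared]
  expect_true("AADDK" %in% shared)  # reversal contains KDDAA -> AADDK again
  expect_true(all(!db$is_decoy[db$shared]))
})

test_that("modform counts: full combinatorics below the cap, truncation above", {
  expect_equal(count_modforms(3), 8)
  expect_equal(count_modforms(0), 1)
  expect_equal(count_modforms(20), 2^20)
  expect_equal(count_modforms(20), 1048576)
  expect_equal(count_modforms(22), 1 + 22 + 231 + 1540)
  expect_equal(count_modforms(21), 1 + 21 + 210 + 1330)
  # brute-force subset oracle above the cap
  n <- 23L
  brute <- sum(vapply(0:3, function(k) ncol(utils::combn(n, k)), numeric(1L)))
  expect_equal(count_modforms(n), brute)
})

test_that("streamed enumeration matches the closed-form count", {
  phos <- list(modification_spec("phospho", "STY", 79.966331, "variable"))
  for (n in c(0L, 1L, 3L, 6L, 8L)) {
    pep <- paste0(paste(rep("S", n), collapse = ""),
                  paste(rep("A", max(0, 6 - n)), collapse = ""), "K")
    it <- enumerate_modforms(pep, phos)
    cnt <- 0L
    while (!is.null(it())) cnt <- cnt + 1L
    expect_equal(cnt, count_modforms(n))
  }
  # above the cap the stream truncates to subsets of size <= 3
  pep21 <- paste0(paste(rep("S", 21), collapse = ""), "K")
  it <- enumerate_modforms(pep21, phos)
  cnt <- 0L
  while (!is.null(it())) cnt <- cnt + 1L
  expect_equal(cnt, 1562)
})

test_that("modform masses and annotations follow the site subsets", {
  specs <- default_mods()
  it <- enumerate_modforms("ACDK", specs)
  forms <- list()
  repeat { f <- it(); if (is.null(f)) break; forms[[length(forms) + 1L]] <- f }
  expect_length(forms, 1L)  # fixed carbamidomethyl only, no variable site
  expect_equal(forms[[1]]$neutral_mass,
               peptide_mass("ACDK") + 57.021464, tolerance = 1e-9)
  expect_equal(forms[[1]]$mod_string, "2:57.021464")

  it2 <- enumerate_modforms("AMMK", specs)  # two oxidation sites
  masses <- c(); nvm <- c()
  repeat {
    f <- it2(); if (is.null(f)) break
    masses <- c(masses, f$neutral_mass); nvm <- c(nvm, f$n_varmods)
  }
  expect_equal(nvm, c(0L, 1L, 1L, 2L))
  base <- peptide_mass("AMMK")
  expect_equal(sort(masses),
               sort(base + 15.994915 * c(0, 1, 1, 2)), tolerance = 1e-9)
  # conflicting fixed specs error out
  expect_error(enumerate_modforms("ACK", list(
    modification_spec("a", "C", 1, "fixed"),
    modification_spec("b", "C", 2, "fixed"))), "conflicting")
})

test_that("fragment masses match the monoisotopic summation oracle", {
  fr <- fragment_ions("PEPTIDE", charges = 1L)
  expect_equal(fr$b[["1"]][2], 97.05276385 + 129.04259309 + 1.007276466,
               tolerance = 1e-6)
  expect_equal(fr$b[["1"]][2], 227.10263, tolerance = 1e-5)
  expect_equal(fr$y[["1"]][1], 129.04259309 + 18.0105646 + 1.007276466,
               tolerance = 1e-6)
  expect_equal(fr$y[["1"]][1], 148.06043, tolerance = 1e-5)
  expect_length(fr$b[["1"]], 6L)
  expect_error(fragment_ions("A"), "too short")
})

test_that("b/y complementarity and peptide mass identities hold", {
  set.seed(23)
  for (rep in 1:25) {
    pep <- random_peptide(sample(7:30, 1L))
    deltas <- if (runif(1) < 0.5) NULL else {
      d <- numeric(nchar(pep)); d[sample(nchar(pep), 1L)] <- 79.966331; d
    }
    fr <- fragment_ions(pep, deltas, charges = 1L)
    M <- peptide_mass(pep, deltas)
    L <- nchar(pep)
    expect_equal(fr$b[["1"]] + rev(fr$y[["1"]]),
                 rep(M + 2 * PROTON_MASS, L - 1L), tolerance = 1e-6)
    # unmodified mass equals the residue-sum oracle
    aa <- strsplit(pep, "", fixed = TRUE)[[1L]]
    expect_equal(peptide_mass(pep), sum(AA_MONO[aa]) + 18.0105646,
                 tolerance = 1e-6)
  }
})
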