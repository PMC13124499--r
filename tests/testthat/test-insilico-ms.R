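TABLE1_PEPTIDES <- c("VATPVDWKNGDSVMVLPTIPEEEAK", "GDEEGVPAVVIHMSGLR",
                     "NISSDLDGHPVPK", "DPNGTFNPHALAQGPWWAR")

test_that("digestion applies the Trypsin/LysC rule", {
  expect_setequal(digest("AAAKCCCR", 0, 1, 30)$sequence, c("AAAK", "CCCR"))
  # K|P is cleaved (LysC), R|P is not
  expect_setequal(digest("AAKPGGR", 0, 1, 30)$sequence, c("AAK", "PGGR"))
  expect_setequal(digest("AARPGGK", 0, 1, 30)$sequence, c("AARPGGK"))
  # missed cleavages
  expect_setequal(digest("AAAKCCCRDDDK", 1, 1, 30)$sequence,
                  c("AAAK", "CCCR", "DDDK", "AAAKCCCR", "CCCRDDDK"))
  expect_error(digest("AAAK", 2, 10, 5), "min_len")
})

test_that("0-missed digests reconstruct the protein (100 random sequences)", {
  withr::with_seed(19, {
    for (k in 1:100) {
      prot <- random_protein(sample(20:200, 1))
      d <- digest(prot, max_missed = 0, min_len = 1, max_len = Inf)
      expect_equal(paste(d$sequence, collapse = ""), prot)
      expect_equal(d$start[1], 1)
      expect_equal(d$end[nrow(d)], nchar(prot))
    }
  })
})

test_that("fragment m/z matches an independently computed golden value", {
  # y6 of GDEEGVPAVVIHMSGLR, computed with a separate mass calculator
  expect_equal(fragment_mz("GDEEGVPAVVIHMSGLR", "y", 6), 700.3559006,
               tolerance = 1e-8)
  expect_equal(peptide_mass("GDEEGVPAVVIHMSGLR"), 1764.8828246,
               tolerance = 1e-8)
  # one cysteine carries exactly one fixed carbamidomethyl
  expect_equal(peptide_mass("ACK") - peptide_mass("AAK"),
               103.00919 - 71.03711 + 57.02146, tolerance = 1e-6)
  expect_error(fragment_mz("PEPTIDE", "b", 7), "outside")
})

test_that("b/y complementarity holds for all peptides of the printed sequences", {
  for (pep in TABLE1_PEPTIDES) {
    M <- peptide_mass(pep)
    n <- nchar(pep)
    for (i in seq_len(n - 1)) {
      expect_equal(fragment_mz(pep, "b", i) + fragment_mz(pep, "y", n - i),
                   M + 2 * 1.007276, tolerance = 1e-6)
    }
  }
})

test_that("complementarity is preserved under modifications (property)", {
  withr::with_seed(23, {
    for (k in 1:25) {
      pep <- random_protein(sample(6:25, 1))
      mpos <- which(strsplit(pep, "")[[1]] == "M")
      ox <- if (length(mpos) > 0) {
        mpos[sample.int(length(mpos), sample(0:length(mpos), 1))]
      } else integer(0)
      M <- peptide_mass(pep, ox)
      n <- nchar(pep)
      i <- sample(n - 1, 1)
      expect_equal(fragment_mz(pep, "b", i, ox = ox) +
                     fragment_mz(pep, "y", n - i, ox = ox),
                   M + 2 * 1.007276, tolerance = 1e-6)
    }
  })
})

test_that("heavy label shifts follow isotope arithmetic and C-terminal placement", {
  expect_equal(heavy_mass_shift(6, 4, "R"), 10.008269, tolerance = 1e-5)
  expect_equal(heavy_mass_shift(0, 0, "K"), 0)
  expect_error(heavy_mass_shift(7, 0, "K"), "exceeds")
  expect_error(heavy_mass_shift(6, 3, "K"), "exceeds")

  pep <- "GDEEGVPAVVIHMSGLR"
  d <- heavy_mass_shift(6, 4, "R")
  n <- nchar(pep)
  for (i in seq_len(n - 1)) {
    expect_equal(fragment_mz(pep, "y", i, cterm_shift = d) -
                   fragment_mz(pep, "y", i), d, tolerance = 1e-9)
    expect_equal(fragment_mz(pep, "b", i, cterm_shift = d),
                 fragment_mz(pep, "b", i))
  }
  expect_equal(peptide_mass(pep, cterm_shift = d) - peptide_mass(pep), d)
})

test_that("fragment matching respects the tolerance window", {
  pep <- "NISSDLDGHPVPK"
  sp <- theo_spectrum(pep)
  theo <- theoretical_fragments(pep)
  n <- nchar(pep)
  # noiseless self-spectrum: all 2(n-1) ions matched
  m <- match_fragments(theo, sp)
  expect_equal(nrow(m), 2 * (n - 1))
  expect_true(all(abs(m$error) <= 0.6))
  # empty spectrum
  empty <- proteomut:::new_spectrum("e", 500, 2, numeric(0), numeric(0))
  expect_equal(nrow(match_fragments(theo, empty)), 0)
  # jitter within bound: all matched; 1.0 Da shift: none
  withr::with_seed(31, {
    jit <- pmin(pmax(rnorm(length(sp$mz), 0, 0.1), -0.3), 0.3)
  })
  spj <- proteomut:::new_spectrum("j", sp$pepmass, 2, sp$mz + jit, sp$intensity)
  expect_equal(nrow(match_fragments(theo, spj)), 2 * (n - 1))
  sps <- proteomut:::new_spectrum("s", sp$pepmass, 2, sp$mz + 1.0, sp$intensity)
  expect_equal(nrow(match_fragments(theo, sps)), 0)
})

test_that("each observed peak is used at most once", {
  # two theoretical ions 0.5 Da apart, one peak between them
  theo <- data.frame(series = c("b", "b"), index = 1:2, charge = 1,
                     mz = c(100.0, 100.5), rel_intensity = 1)
  sp <- proteomut:::new_spectrum("x", 100, 1, 100.2, 10)
  m <- match_fragments(theo, sp)
  expect_equal(nrow(m), 1)
  expect_equal(m$index, 1) # nearer ion wins
})

test_that("scoring has the stated closed forms", {
  pep <- "GDEEGVPAVVIHMSGLR"
  n <- nchar(pep)
  sp <- theo_spectrum(pep)
  expect_equal(score_psm(pep, sp)$score, 2 * (n - 1) + 1, tolerance = 1e-9)
  empty <- proteomut:::new_spectrum("e", sp$pepmass, 2, numeric(0), numeric(0))
  expect_equal(score_psm(pep, empty)$score, 0)
  # half the fragments removed: matched count is exactly n-1
  keep <- seq(1, length(sp$mz), by = 2)
  half <- proteomut:::new_spectrum("h", sp$pepmass, 2, sp$mz[keep],
                                   sp$intensity[keep])
  expect_equal(nrow(score_psm(pep, half)$matched), length(keep))
  expect_equal(length(keep), n - 1)
})

test_that("search recovers planted peptides and honors precursor tolerance", {
  sim <- sim_config(seed = 41, n_proteins = 10)
  ref <- generate_reference_set(sim)
  db <- assemble_personalized_db(ref$proteins)
  idx <- index_database(db)
  withr::with_seed(43, {
    peps <- sample(idx$sequence[!idx$is_decoy & idx$ox == ""], 20)
  })
  spectra <- lapply(peps, function(p) theo_spectrum(p, charge = 2, id = p))
  psms <- search_spectra(spectra, idx)
  expect_equal(nrow(psms), 20)
  expect_equal(psms$peptide, peps)
  expect_false(any(psms$is_decoy))

  # precursor 50 ppm off => unidentified
  off <- theo_spectrum(peps[1], charge = 2, id = "off")
  off$pepmass <- off$pepmass * (1 + 50e-6)
  expect_equal(nrow(search_spectra(list(off), idx)), 0)
  # charge outside the admissible range => skipped
  z6 <- theo_spectrum(peps[1], charge = 2, id = "z6")
  z6$charge <- 6L
  expect_equal(nrow(search_spectra(list(z6), idx)), 0)
})

test_that("oxidized-methionine variants are searchable", {
  pep <- "NISSDLDGHMVPK"
  reference <- data.frame(accession = "P1", gene = "G1",
                          sequence = paste0("AAAK", pep, "GGGR"))
  db <- assemble_personalized_db(reference)
  sp <- theo_spectrum(pep, charge = 2, ox = 10, id = "oxspec")
  psms <- search_spectra(list(sp), db)
  expect_equal(nrow(psms), 1)
  expect_equal(psms$peptide, pep)
  expect_equal(psms$ox, "10")
})

test_that("q-values equal the hand-enumerated 12-PSM oracle", {
  scores <- c(12, 11, 10, 9, 8, 7, 6, 5, 4, 3, 2, 1)
  decoy <- c(F, F, T, F, F, T, F, T, F, F, T, F)
  psms <- data.frame(score = scores, is_decoy = decoy)
  q <- estimate_qvalues(psms)$q_value
  expect_equal(q, c(0, 0, 0.25, 0.25, 0.25, 0.4, 0.4, 3/7, 3/7, 3/7,
                    0.5, 0.5), tolerance = 1e-12)
  # independent brute-force oracle: q(s) = min over thresholds t <= s of FDR(t)
  brute <- vapply(scores, function(s) {
    thresholds <- sort(unique(scores[scores <= s]))
    min(vapply(thresholds, function(t)
      sum(decoy & scores >= t) / max(1, sum(!decoy & scores >= t)), 0))
  }, 0)
  expect_equal(q, brute, tolerance = 1e-12)
  # monotone non-decreasing as score decreases
  expect_true(all(diff(q[order(-scores)]) >= -1e-12))
})

test_that("separated targets get q = 0 and interleaved ties get q ~ 1", {
  sep <- data.frame(score = c(10, 9, 8, 3, 2, 1),
                    is_decoy = c(F, F, F, T, T, T))
  qs <- estimate_qvalues(sep)
  expect_equal(qs$q_value[!qs$is_decoy], rep(0, 3))
  tie <- data.frame(score = rep(5, 10), is_decoy = rep(c(TRUE, FALSE), 5))
  qt <- estimate_qvalues(tie)
  expect_equal(qt$q_value, rep(1, 10))
  e <- estimate_qvalues(data.frame(score = numeric(), is_decoy = logical()))
  expect_equal(nrow(e), 0)
})

test_that("site-determining ion sets match the boundary enumerations", {
  # mutation at offset 1: b ions only (y_n is not a valid fragment)
  s1 <- site_determining_ions(10, 1)
  expect_setequal(paste(s1$series, s1$index),
                  paste("b", 1:9))
  # mutation at the C-terminal residue: all y ions, no b
  sn <- site_determining_ions(10, 10)
  expect_setequal(paste(sn$series, sn$index), paste("y", 1:9))
  # printed case: n=17, m=12 -> b12..b16 and y6..y16; y6 is site-determining
  s <- site_determining_ions(17, 12)
  expect_setequal(paste(s$series, s$index),
                  c(paste("b", 12:16), paste("y", 6:16)))
  expect_true("y 6" %in% paste(s$series, s$index))
  expect_error(site_determining_ions(10, 0), "outside")
})

test_that("site support requires a matched site-determining ion", {
  pep <- "GDEEGVPAVVIHMSGLR" # treat offset 12 as the mutated residue
  n <- nchar(pep)
  sp <- theo_spectrum(pep)
  m_all <- match_fragments(theoretical_fragments(pep), sp)
  expect_true(site_supported(m_all, n, 12))
  expect_true(site_supported(m_all, n, 12, strict = TRUE))
  # keep only non-site ions: b1..b11 and y1..y5
  m_non <- m_all[(m_all$series == "b" & m_all$index <= 11) |
                   (m_all$series == "y" & m_all$index <= 5), ]
  expect_false(site_supported(m_non, n, 12))
  # one site ion but incomplete ladder: supported, but not in strict mode
  m_one <- m_all[(m_all$series == "y" & m_all$index == 6), ]
  expect_true(site_supported(m_one, n, 12))
  expect_false(site_supported(m_one, n, 12, strict = TRUE))
})

test_that("mutation-covering peptides match a brute-force span scan", {
  withr::with_seed(47, {
    for (k in 1:10) {
      prot <- random_protein(120)
      pos <- sample(30:90, 1)
      alt <- setdiff(c("A", "G"), substr(prot, pos, pos))[1]
      e <- build_missense_entry(prot, pos, alt)
      got <- enumerate_mutant_peptides(e, min_len = 1, max_len = 60)
      all_peps <- digest(e$sequence, max_missed = 2, min_len = 1,
                         max_len = 60)
      brute <- all_peps[all_peps$start <= e$mut_offset &
                          all_peps$end >= e$mut_offset, ]
      expect_setequal(got$sequence, brute$sequence)
      expect_true(all(got$start <= e$mut_offset & got$end >= e$mut_offset))
    }
  })
})

test_that("a K-destroying substitution yields a peptide starting at the mutated residue", {
  # reference ...K | KISSDLDGHPVPK...  with K -> N at the cleavage site:
  # the covering peptide begins with the substituted N
  ref_pep <- "KISSDLDGHPVPK"
  prot <- embed_peptide(ref_pep, 102, 200, seed = 53)
  e <- build_missense_entry(prot, 102, "N")
  peps <- enumerate_mutant_peptides(e, max_missed = 0)
  expect_true("NISSDLDGHPVPK" %in% peps$sequence)
  p <- peps[peps$sequence == "NISSDLDGHPVPK", ]
  expect_equal(p$mut_offset_in_peptide, 1)
  expect_equal(c(p$protein_start, p$protein_end), c(102, 114))
})

test_that("peptides shared with the reference are never mutant evidence", {
  prot <- random_protein(100, seed = 57)
  # duplicate the region elsewhere so the mutated peptide also exists in a
  # second reference protein
  pos <- 50
  alt <- setdiff(c("A", "G"), substr(prot, pos, pos))[1]
  e <- build_missense_entry(prot, pos, alt, accession = "P1", gene = "G1")
  mut_pep <- enumerate_mutant_peptides(e, min_len = 6, max_len = 30)
  reference <- data.frame(
    accession = c("P1", "P2"), gene = c("G1", "G2"),
    sequence = c(prot,
                 paste0("AAAK", mut_pep$sequence[1], "GGGR")))
  db <- assemble_personalized_db(reference, list(e))
  idx <- index_database(db)
  row <- idx[idx$sequence == mut_pep$sequence[1] & idx$ox == "", ]
  expect_false(any(row$is_mutant))
})

test_that("spectral similarity is a proper binned cosine", {
  pep <- "NISSDLDGHPVPK"
  a <- theo_spectrum(pep)
  expect_equal(spectral_similarity(a, a), 1.0, tolerance = 1e-12)
  b <- proteomut:::new_spectrum("b", 500, 2, a$mz + 50, a$intensity)
  expect_equal(spectral_similarity(a, b), 0.0)
  e <- proteomut:::new_spectrum("e", 500, 2, numeric(0), numeric(0))
  se <- spectral_similarity(a, e)
  expect_equal(as.numeric(se), 0)
  expect_true(attr(se, "empty"))
  # symmetry
  withr::with_seed(61, {
    c_ <- proteomut:::new_spectrum("c", 500, 2, a$mz + rnorm(length(a$mz), 0, 0.1),
                                   a$intensity * runif(length(a$mz), 0.5, 2))
  })
  expect_equal(spectral_similarity(a, c_), spectral_similarity(c_, a))
})

test_that("endogenous-vs-heavy similarity is shift-invariant", {
  pep <- "GDEEGVPAVVIHMSGLR"
  d <- heavy_mass_shift(6, 4, "R")
  light <- theo_spectrum(pep)
  heavy <- theo_spectrum(pep, cterm_shift = d)
  # shift the heavy spectrum's y ions back by the label delta
  theo_h <- theoretical_fragments(pep, cterm_shift = d)
  shifted_mz <- ifelse(theo_h$series == "y", theo_h$mz - d, theo_h$mz)
  heavy_shifted <- proteomut:::new_spectrum("hs", heavy$pepmass, 2,
                                            shifted_mz,
                                            1000 * theo_h$rel_intensity)
  expect_equal(spectral_similarity(light, heavy_shifted),
               spectral_similarity(light, light), tolerance = 1e-9)
})
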