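# codons used to build deterministic toy CDSs
.codon_of <- c(M = "ATG", A = "GCT", V = "GTT", L = "CTG", D = "GAT",
               T = "ACC", K = "AAA", G = "GGC", H = "CAC", E = "GAA",
               S = "TCT", R = "CGT", I = "ATT", P = "CCG", N = "AAC",
               Q = "CAG", W = "TGG", Y = "TAT", C = "TGC", F = "TTC")
toy_cds <- function(protein) {
  paste0(paste(.codon_of[strsplit(protein, "")[[1]]], collapse = ""), "TAA")
}

test_that("translate_cds follows the standard codon table", {
  expect_equal(as.vector(translate_cds("ATGGCTTAA")), "MA")
  expect_true(attr(translate_cds("ATGGCTTAA"), "has_stop"))
  expect_false(attr(translate_cds("ATGGCT"), "has_stop"))
  expect_equal(as.vector(translate_cds("atggcuuaa")), "MA") # case and RNA
  expect_error(translate_cds("ATGXCT"), "non-ACGT")
  expect_error(translate_cds("AT"), "shorter")
})

test_that("translate_cds agrees with Biostrings::translate on random CDS", {
  withr::with_seed(11, {
    for (k in 1:20) {
      n_codons <- sample(5:60, 1)
      cds <- paste(sample(c("A", "C", "G", "T"), 3 * n_codons,
                          replace = TRUE), collapse = "")
      ours <- as.vector(translate_cds(cds))
      oracle <- as.character(Biostrings::translate(
        Biostrings::DNAString(cds), no.init.codon = TRUE))
      oracle <- sub("\\*.*$", "", oracle) # stop-at-first-stop convention
      expect_equal(ours, oracle)
    }
  })
})

test_that("missense window invariants hold at every position of a toy protein", {
  prot <- random_protein(80, seed = 5)
  L <- nchar(prot)
  for (pos in seq_len(L)) {
    ref <- substr(prot, pos, pos)
    alt <- setdiff(c("A", "G", "V"), ref)[1]
    e <- build_missense_entry(prot, pos, alt)
    expect_equal(e$left_flank, min(25, pos - 1))
    expect_equal(e$right_flank, min(25, L - pos))
    expect_equal(e$mut_offset, e$left_flank + 1)
    expect_equal(nchar(e$sequence), e$left_flank + 1 + e$right_flank)
    expect_equal(e$start_in_protein, pos - e$left_flank)
    # exactly one mismatch vs the reference window, at mut_offset
    window <- substr(prot, e$start_in_protein,
                     e$start_in_protein + nchar(e$sequence) - 1)
    diffs <- which(strsplit(window, "")[[1]] != strsplit(e$sequence, "")[[1]])
    expect_equal(diffs, e$mut_offset)
    expect_equal(substr(e$sequence, e$mut_offset, e$mut_offset), alt)
  }
})

test_that("interior missense entries are 51 residues with the mutation at 26", {
  prot <- random_protein(200, seed = 6)
  pos <- 100
  alt <- setdiff(c("A", "G"), substr(prot, pos, pos))[1]
  e <- build_missense_entry(prot, pos, alt)
  expect_equal(nchar(e$sequence), 51)
  expect_equal(e$mut_offset, 26)
})

test_that("missense entry rejects synonymous, out-of-range and stop alleles", {
  prot <- random_protein(60, seed = 8)
  ref10 <- substr(prot, 10, 10)
  expect_error(build_missense_entry(prot, 10, ref10), "synonymous")
  expect_error(build_missense_entry(prot, 0, "A"), "outside")
  expect_error(build_missense_entry(prot, 61, "A"), "outside")
  expect_error(build_missense_entry(prot, 10, "*"), "canonical")
})

test_that("frameshift entry matches a hand-translated 90-nt golden case", {
  prot <- "MAVLDTKGHESRIPNQWYCFMAVLDTKGH" # 29 aa
  cds <- toy_cds(prot)
  expect_equal(nchar(cds), 90)
  expect_equal(as.vector(translate_cds(cds)), prot)
  # delete the first base of codon 26 (cds position 76)
  e <- build_frameshift_entry(cds, 76, ref_base = "A", alt_base = "")
  # hand translation: lead = residues 2..25, shifted frame reads PKAT and
  # runs off the transcript without a stop codon
  expect_equal(e$sequence, "AVLDTKGHESRIPNQWYCFMAVLDPKAT")
  expect_equal(e$mut_offset, 25)
  expect_equal(e$left_flank, 24)
  expect_equal(e$start_in_protein, 2)
  expect_equal(e$hgvs_p, "p.T26fs")
  expect_true(e$no_downstream_stop)
})

test_that("frameshift with an immediate stop yields the reference lead only", {
  prot <- paste0("MAVLDTKGHESRIPNQWYCFMAVLD", "YT", "GH")
  cds <- toy_cds(prot)
  # codon 26 is TAT (Y); deleting its third base makes the shifted codon TAA
  e <- build_frameshift_entry(cds, 78, ref_base = "T", alt_base = "")
  expect_equal(e$sequence, substr(prot, 2, 25))
  expect_equal(nchar(e$sequence), 24)
  expect_equal(e$mut_offset, 25) # first affected position, past the lead
  expect_false(e$no_downstream_stop)
})

test_that("frameshift leads match the reference and in-frame indels are rejected", {
  sim <- sim_config(seed = 13, n_proteins = 10, n_missense = 0,
                    n_frameshift = 5, n_negatives_per_clause = 0)
  ref <- generate_reference_set(sim)
  pv <- plant_variants(ref, sim)
  for (j in seq_len(nrow(pv$variants))) {
    v <- pv$variants[j, ]
    e <- entry_from_variant(v, ref)
    prot <- ref$proteins$sequence[ref$proteins$accession == v$accession]
    lead_len <- e$mut_offset - 1
    expect_equal(substr(e$sequence, 1, lead_len),
                 substr(prot, e$start_in_protein,
                        e$start_in_protein + lead_len - 1))
    expect_lte(lead_len, 24)
    expect_false(grepl("[*]", e$sequence))
  }
  cds <- toy_cds("MAVLDTKGHESRIPNQWYCFMAVLDTKGH")
  expect_error(build_frameshift_entry(cds, 10, ref_base = "",
                                      alt_base = "ACC"), "in-frame")
})

test_that("database assembly dedups, orders and decoys correctly", {
  prot <- random_protein(120, seed = 21)
  reference <- data.frame(accession = c("P1", "P2"), gene = c("G1", "G2"),
                          sequence = c(prot, random_protein(90, seed = 22)))
  alt <- setdiff(c("A", "G"), substr(prot, 60, 60))[1]
  e1 <- build_missense_entry(prot, 60, alt, accession = "P1", gene = "G1")
  e2 <- build_missense_entry(prot, 60, alt, accession = "P1", gene = "G1")
  e2$variant_id <- "VARB"
  e1$variant_id <- "VARA"
  alt2 <- setdiff(c("A", "G"), substr(prot, 10, 10))[1]
  e3 <- build_missense_entry(prot, 10, alt2, accession = "P1", gene = "G1")

  db <- assemble_personalized_db(reference, list(e1, e2, e3))
  expect_s3_class(db, "personalized_db")
  expect_equal(nrow(db$targets), 2 + 2) # duplicates collapsed
  expect_equal(nrow(db$decoys), nrow(db$targets))
  dup <- db$targets[db$targets$hgvs_p == e1$hgvs_p, ]
  expect_equal(dup$provenance, "VARA;VARB")
  expect_equal(dup$n_provenance, 2L)
  # mutant entries sorted by accession then start position
  muts <- db$targets[db$targets$is_mutant, ]
  expect_equal(muts$start_in_protein, sort(muts$start_in_protein))
  # decoys are reversals with reserved prefix
  expect_equal(db$decoys$sequence[1],
               paste(rev(strsplit(db$targets$sequence[1], "")[[1]]),
                     collapse = ""))
  expect_true(all(startsWith(db$decoys$id, "rev_")))
  # idempotent / deterministic
  db2 <- assemble_personalized_db(reference, list(e1, e2, e3))
  expect_identical(db$targets, db2$targets)

  # empty entry list => reference only
  db0 <- assemble_personalized_db(reference)
  expect_equal(nrow(db0$targets), 2)
  # unknown accession rejected
  e_bad <- e1
  e_bad$source_accession <- "NOPE"
  expect_error(assemble_personalized_db(reference, list(e_bad)), "unknown")
})

test_that("palindromic decoys are flagged", {
  reference <- data.frame(accession = "P1", gene = "G1",
                          sequence = "AKAKAKA") # palindrome
  db <- assemble_personalized_db(reference)
  expect_true(db$decoys$palindrome[1])
  expect_equal(db$decoys$sequence[1], db$targets$sequence[1])
  expect_false(db$decoys$id[1] == db$targets$id[1])
})

test_that("FASTA and manifest round-trip", {
  sim <- sim_config(seed = 17, n_proteins = 5, n_missense = 3,
                    n_frameshift = 1, n_negatives_per_clause = 0)
  ref <- generate_reference_set(sim)
  pv <- plant_variants(ref, sim)
  entries <- lapply(seq_len(nrow(pv$variants)), function(j)
    entry_from_variant(pv$variants[j, ], ref))
  db <- assemble_personalized_db(ref$proteins, entries)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_db(db, fa)
  back <- Biostrings::readAAStringSet(fa)
  expect_equal(length(back), nrow(db$targets) + nrow(db$decoys))
  expect_equal(unname(as.character(back))[seq_len(nrow(db$targets))],
               db$targets$sequence)
  # mutation offset recoverable from mutant headers
  mut_headers <- names(back)[grepl("^mut\\|", names(back))]
  expect_true(all(grepl("\\|start=\\d+$", mut_headers)))
  man <- db_manifest(db)
  expect_equal(nrow(man), sum(db$targets$is_mutant))
})
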