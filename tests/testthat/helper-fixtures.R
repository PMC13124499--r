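# Shared fixture builders. Everything is generated in code; no binary data.

# A noiseless simulation: spectra reduce to the theoretical b/y set and
# chromatograms to clean Gaussians.
noiseless_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, dropout = 0, n_noise_peaks = 0L, mz_jitter_sd = 0,
         intensity_sdlog = 0, baseline_sd = 0, transition_cv = 0),
    list(...))
  do.call(sim_config, args)
}

random_protein <- function(n, seed = NULL) {
  draw <- function() paste(sample(proteomut:::.AA_LETTERS, n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Minimal variant-table row(s) with sensible defaults.
make_variants <- function(n = 1, tumor_alt = 10, tumor_depth = 100,
                          normal_alt = 0, normal_depth = 100,
                          simple_repeat = FALSE, type = "missense",
                          protein_pos = 50) {
  df <- data.frame(
    variant_id = sprintf("V%03d", seq_len(max(n, 1))),
    accession = "SYN0001", gene = "GENE1", type = type,
    cds_pos = 3 * (protein_pos - 1) + 1, protein_pos = protein_pos,
    ref_aa = "A", alt_aa = "V", ref_base = "C", alt_base = "T",
    tumor_alt = tumor_alt, tumor_depth = tumor_depth,
    normal_alt = normal_alt, normal_depth = normal_depth,
    simple_repeat = simple_repeat, stringsAsFactors = FALSE)
  df[seq_len(n), , drop = FALSE]
}

# Independent clause-by-clause re-evaluation of the somatic filters
# (deliberately naive; the oracle for apply_somatic_filters).
oracle_filter <- function(v) {
  vapply(seq_len(nrow(v)), function(j) {
    vaf <- if (v$tumor_depth[j] == 0) 0 else v$tumor_alt[j] / v$tumor_depth[j]
    v$tumor_alt[j] > 3 && v$normal_alt[j] < 3 && vaf > 0.05 &&
      !v$simple_repeat[j]
  }, TRUE)
}

# Embed a peptide into a random protein so that its span is tryptic:
# residue before the span is K, residue after is not P.
embed_peptide <- function(peptide, span_start, total_length, seed = 42) {
  withr::with_seed(seed, {
    pool <- setdiff(proteomut:::.AA_LETTERS, c("K", "R", "P"))
    pre <- sample(pool, span_start - 1, replace = TRUE)
    pre[span_start - 1] <- "K"
    n_post <- total_length - (span_start + nchar(peptide) - 1)
    post <- sample(pool, n_post, replace = TRUE)
    paste(c(pre, strsplit(peptide, "")[[1]], post), collapse = "")
  })
}

# Noiseless spectrum directly from the theoretical fragment table.
theo_spectrum <- function(sequence, charge = 2, ox = integer(0),
                          cterm_shift = 0, id = sequence) {
  theo <- theoretical_fragments(sequence, ox = ox, charges = 1,
                                cterm_shift = cterm_shift)
  proteomut:::new_spectrum(
    id, (peptide_mass(sequence, ox, cterm_shift) +
           charge * proteomut:::PROTON_MASS) / charge,
    charge, theo$mz, 1000 * theo$rel_intensity)
}
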