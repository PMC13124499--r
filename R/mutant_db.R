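#' Translate a coding sequence with the standard codon table
#'
#' Translation proceeds codon by codon and stops at the first stop codon;
#' the translated prefix is returned. Incomplete trailing codons (as arise
#' after a frameshift) are ignored.
#'
#' @param cds nucleotide string (ACGT or ACGU, case-insensitive).
#' @return single string of amino acids, with attribute `has_stop` saying
#'   whether a stop codon terminated translation.
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1)
  cds <- chartr("U", "T", toupper(cds))
  if (nchar(cds) < 3) stop("CDS shorter than one codon")
  if (grepl("[^ACGT]", cds)) stop("CDS contains non-ACGT/U characters")
  n3 <- nchar(cds) %/% 3
  codons <- substring(cds, seq(1, by = 3, length.out = n3),
                      seq(3, by = 3, length.out = n3))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stop_at <- which(aa == "*")[1]
  if (is.na(stop_at)) {
    out <- paste(aa, collapse = "")
    has_stop <- FALSE
  } else {
    out <- paste(aa[seq_len(stop_at - 1)], collapse = "")
    has_stop <- TRUE
  }
  attr(out, "has_stop") <- has_stop
  out
}

new_mutant_entry <- function(entry_id, source_accession, gene, hgvs_p, kind,
                             sequence, mut_offset, left_flank, right_flank,
                             start_in_protein, no_downstream_stop = FALSE) {
  structure(list(
    entry_id = entry_id, source_accession = source_accession, gene = gene,
    hgvs_p = hgvs_p, kind = kind, sequence = sequence,
    mut_offset = mut_offset, left_flank = left_flank,
    right_flank = right_flank, start_in_protein = start_in_protein,
    no_downstream_stop = no_downstream_stop
  ), class = "mutant_entry")
}

#' @export
print.mutant_entry <- function(x, ...) {
  cat(sprintf("<mutant_entry> %s (%s), %d aa, mutation offset %d, starts at protein position %d\n",
              x$entry_id, x$kind, nchar(x$sequence), x$mut_offset,
              x$start_in_protein))
  invisible(x)
}

#' Build a missense mutant-database entry
#'
#' The entry is the mutated residue with up to `flank` reference residues on
#' each side (the window truncates at the protein termini; an interior
#' mutation yields a 51-residue entry with the mutation at offset 26).
#'
#' @param protein reference protein sequence (string).
#' @param protein_pos 1-based position of the substituted residue.
#' @param alt_aa substituting residue (single canonical letter; a stop is
#'   rejected).
#' @param accession,gene identifiers of the source protein.
#' @param flank maximum number of reference residues kept per side.
#' @return a `mutant_entry`.
#' @export
build_missense_entry <- function(protein, protein_pos, alt_aa,
                                 accession = "PROT", gene = "GENE",
                                 flank = 25) {
  L <- nchar(protein)
  if (protein_pos < 1 || protein_pos > L) {
    stop("protein_pos ", protein_pos, " outside 1..", L)
  }
  ref_aa <- substr(protein, protein_pos, protein_pos)
  if (!alt_aa %in% .AA_LETTERS) {
    stop("alternate residue '", alt_aa, "' outside the canonical alphabet")
  }
  if (identical(ref_aa, alt_aa)) {
    stop("synonymous call: reference residue already ", alt_aa,
         " at position ", protein_pos)
  }
  left <- min(flank, protein_pos - 1)
  right <- min(flank, L - protein_pos)
  start <- protein_pos - left
  window <- substr(protein, start, protein_pos + right)
  sequence <- window
  substr(sequence, left + 1, left + 1) <- alt_aa
  hgvs <- sprintf("p.%s%d%s", ref_aa, protein_pos, alt_aa)
  new_mutant_entry(
    entry_id = sprintf("mut|%s|%s_%s", accession, gene, hgvs),
    source_accession = accession, gene = gene, hgvs_p = hgvs,
    kind = "missense", sequence = sequence, mut_offset = left + 1,
    left_flank = left, right_flank = right, start_in_protein = start)
}

#' Build a frameshift mutant-database entry
#'
#' Applies a frame-disrupting indel to the coding sequence, translates, and
#' emits the last `lead` (default 24) unaffected reference residues followed
#' by the neo-frame residues up to but excluding the first stop codon. When
#' the shifted frame stops immediately, the entry is the reference lead
#' alone; when no downstream stop exists the entry runs to the transcript
#' end and is flagged.
#'
#' @param cds reference coding sequence (must end in a stop codon when
#'   complete, but only `length >= 3` is required here).
#' @param cds_pos 1-based position of the indel: for a deletion, the first
#'   deleted base; for an insertion, the base before which `alt_base` is
#'   inserted.
#' @param ref_base deleted bases (empty string for an insertion).
#' @param alt_base inserted bases (empty string for a deletion).
#' @param accession,gene identifiers of the source protein.
#' @param lead maximum number of reference residues kept before the shift.
#' @return a `mutant_entry` with `mut_offset` pointing at the first
#'   frame-affected residue position (`lead + 1` in the general case).
#' @export
build_frameshift_entry <- function(cds, cds_pos, ref_base = "", alt_base = "",
                                   accession = "PROT", gene = "GENE",
                                   lead = 24) {
  net <- nchar(alt_base) - nchar(ref_base)
  if (net %% 3 == 0) {
    stop("in-frame indel (net length change ", net,
         " is a multiple of 3); not a frameshift")
  }
  if (cds_pos < 1 || cds_pos > nchar(cds)) stop("cds_pos outside the CDS")
  if (nzchar(ref_base)) {
    found <- substr(cds, cds_pos, cds_pos + nchar(ref_base) - 1)
    if (!identical(found, ref_base)) {
      stop("reference bases at cds_pos are '", found, "', not '",
           ref_base, "'")
    }
    mutated <- paste0(substr(cds, 1, cds_pos - 1),
                      substring(cds, cds_pos + nchar(ref_base)))
  } else {
    mutated <- paste0(substr(cds, 1, cds_pos - 1), alt_base,
                      substring(cds, cds_pos))
  }
  c0 <- (cds_pos + 2L) %/% 3L # first affected codon
  ref_prot <- translate_cds(cds)
  mut_prot <- translate_cds(mutated)
  lead_start <- max(1L, c0 - lead)
  lead_seq <- substr(ref_prot, lead_start, c0 - 1L)
  neo <- if (nchar(mut_prot) >= c0) substring(mut_prot, c0) else ""
  ref_at <- substr(ref_prot, c0, c0)
  if (!nzchar(ref_at)) ref_at <- "X" # shift at/after the stop codon
  hgvs <- sprintf("p.%s%dfs", ref_at, c0)
  new_mutant_entry(
    entry_id = sprintf("mut|%s|%s_%s", accession, gene, hgvs),
    source_accession = accession, gene = gene, hgvs_p = hgvs,
    kind = "frameshift", sequence = paste0(lead_seq, neo),
    mut_offset = nchar(lead_seq) + 1L, left_flank = nchar(lead_seq),
    right_flank = nchar(neo), start_in_protein = lead_start,
    no_downstream_stop = !attr(mut_prot, "has_stop"))
}

#' Build a mutant entry from one filtered variant call
#'
#' Dispatches on the variant `type`. CDS-level missense calls are translated
#' and must agree with the stated alternate residue, otherwise the call is
#' rejected (this catches coordinate bookkeeping errors).
#'
#' @param variant one-row data.frame (a row of the variant table).
#' @param reference reference set: data.frame `proteins`
#'   (accession, gene, sequence) and named character `cds`.
#' @param flank,lead window parameters, see [build_missense_entry()] and
#'   [build_frameshift_entry()].
#' @return a `mutant_entry`.
#' @export
entry_from_variant <- function(variant, reference, flank = 25, lead = 24) {
  prot <- reference$proteins[reference$proteins$accession == variant$accession, ]
  if (nrow(prot) != 1) {
    stop("variant references unknown accession: ", variant$accession)
  }
  if (variant$type == "missense") {
    if (nzchar(variant$ref_base) && nzchar(variant$alt_base) &&
        variant$accession %in% names(reference$cds)) {
      cds <- reference$cds[[variant$accession]]
      mutated <- cds
      substr(mutated, variant$cds_pos, variant$cds_pos) <- variant$alt_base
      tr <- translate_cds(mutated)
      got <- as.vector(substr(tr, variant$protein_pos, variant$protein_pos))
      if (!isTRUE(got == variant$alt_aa)) {
        stop("CDS-level call translates to '", got, "', not stated alt '",
             variant$alt_aa, "' (", variant$accession, " cds_pos ",
             variant$cds_pos, ")")
      }
    }
    build_missense_entry(prot$sequence, variant$protein_pos, variant$alt_aa,
                         accession = variant$accession, gene = prot$gene,
                         flank = flank)
  } else if (variant$type == "frameshift") {
    build_frameshift_entry(reference$cds[[variant$accession]],
                           variant$cds_pos, ref_base = variant$ref_base,
                           alt_base = variant$alt_base,
                           accession = variant$accession, gene = prot$gene,
                           lead = lead)
  } else {
    stop("unknown variant type: ", variant$type)
  }
}

#' Assemble the personalized target+decoy database
#'
#' Combines the reference proteome with the mutant entries, collapsing
#' duplicate mutant sequences (all provenance kept), and appends one
#' full-sequence-reversed decoy per target. Ordering is deterministic:
#' reference order, then mutant entries sorted by accession and start
#' position.
#'
#' @param reference data.frame with columns accession, gene, sequence.
#' @param entries list of `mutant_entry` objects (possibly empty).
#' @param provenance optional list of metadata (patient id, filter settings)
#'   stored with the database.
#' @return a `personalized_db`: list with data.frames `targets` and `decoys`
#'   (columns id, accession, gene, sequence, kind, hgvs_p, mut_offset,
#'   start_in_protein, is_mutant, is_decoy, provenance) plus `provenance`.
#' @export
assemble_personalized_db <- function(reference, entries = list(),
                                     provenance = list()) {
  stopifnot(is.data.frame(reference),
            all(c("accession", "gene", "sequence") %in% names(reference)))
  if (length(entries) > 0) {
    accs <- vapply(entries, `[[`, "", "source_accession")
    unknown <- setdiff(accs, reference$accession)
    if (length(unknown) > 0) {
      stop("mutant entries reference unknown accession(s): ",
           paste(unique(unknown), collapse = ", "))
    }
    bad <- vapply(entries, function(e) grepl("[*]", e$sequence), FALSE)
    if (any(bad)) stop("entry contains a stop character: ",
                       paste(vapply(entries[bad], `[[`, "", "entry_id"),
                             collapse = ", "))
  }
  ref_df <- data.frame(
    id = sprintf("sp|%s|%s", reference$accession, reference$gene),
    accession = reference$accession, gene = reference$gene,
    sequence = reference$sequence, kind = "reference", hgvs_p = "",
    mut_offset = NA_integer_, start_in_protein = 1L,
    is_mutant = FALSE, is_decoy = FALSE, provenance = "reference",
    stringsAsFactors = FALSE)

  if (length(entries) > 0) {
    mut_df <- do.call(rbind, lapply(entries, function(e) data.frame(
      id = e$entry_id, accession = e$source_accession, gene = e$gene,
      sequence = e$sequence, kind = e$kind, hgvs_p = e$hgvs_p,
      mut_offset = as.integer(e$mut_offset),
      start_in_protein = as.integer(e$start_in_protein),
      is_mutant = TRUE, is_decoy = FALSE,
      provenance = e$variant_id %||% e$entry_id,
      stringsAsFactors = FALSE)))
    key <- paste(mut_df$id, mut_df$sequence)
    prov <- vapply(split(mut_df$provenance, key), function(p)
      paste(p, collapse = ";"), "")
    nrec <- vapply(split(key, key), length, 0L)
    mut_df <- mut_df[!duplicated(key), , drop = FALSE]
    mut_df$provenance <- unname(prov[paste(mut_df$id, mut_df$sequence)])
    mut_df$n_provenance <- unname(nrec[paste(mut_df$id, mut_df$sequence)])
    mut_df <- mut_df[order(mut_df$accession, mut_df$start_in_protein,
                           mut_df$hgvs_p), , drop = FALSE]
    ref_df$n_provenance <- 1L
    targets <- rbind(ref_df, mut_df)
  } else {
    ref_df$n_provenance <- 1L
    targets <- ref_df
  }
  if (anyDuplicated(targets$id)) {
    stop("duplicate entry ids after assembly: ",
         paste(unique(targets$id[duplicated(targets$id)]), collapse = ", "))
  }
  rownames(targets) <- NULL
  db <- structure(list(targets = targets, decoys = generate_decoys(targets),
                       provenance = provenance),
                  class = "personalized_db")
  db
}

#' Generate reversed decoy entries
#'
#' One full-sequence-reversed decoy per target, ids prefixed `rev_`.
#' Palindromic sequences (decoy identical to its target) are flagged in a
#' `palindrome` column but kept.
#'
#' @param targets target entry data.frame (see [assemble_personalized_db()]).
#' @return decoy data.frame of the same shape with `is_decoy = TRUE`.
#' @export
generate_decoys <- function(targets) {
  rev_seq <- vapply(strsplit(targets$sequence, ""), function(ch)
    paste(rev(ch), collapse = ""), "")
  decoys <- targets
  decoys$id <- paste0("rev_", targets$id)
  decoys$sequence <- rev_seq
  decoys$is_decoy <- TRUE
  decoys$is_mutant <- FALSE
  decoys$palindrome <- rev_seq == targets$sequence
  rownames(decoys) <- NULL
  decoys
}

#' @export
print.personalized_db <- function(x, ...) {
  cat(sprintf("<personalized_db> %d targets (%d mutant entries), %d decoys\n",
              nrow(x$targets), sum(x$targets$is_mutant), nrow(x$decoys)))
  invisible(x)
}

#' All database entries (targets and decoys) as one data.frame
#' @param db a `personalized_db`.
#' @return data.frame.
#' @export
db_entries <- function(db) {
  t <- db$targets
  d <- db$decoys
  t$palindrome <- FALSE
  rbind(t, d[, names(t), drop = FALSE])
}

#' Entry manifest of a personalized database
#'
#' @param db a `personalized_db`.
#' @return data.frame (entry_id, kind, hgvs_p, mut_offset, left/right flank
#'   information) for the mutant entries.
#' @export
db_manifest <- function(db) {
  m <- db$targets[db$targets$is_mutant, , drop = FALSE]
  data.frame(entry_id = m$id, kind = m$kind, hgvs_p = m$hgvs_p,
             mut_offset = m$mut_offset, start_in_protein = m$start_in_protein,
             length = nchar(m$sequence), stringsAsFactors = FALSE)
}
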