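#' Write protein sequences as FASTA
#'
#' @param db_or_proteins a `personalized_db`, or a data.frame with columns
#'   `id`/`accession` and `sequence`.
#' @param path output path.
#' @param split write targets and decoys to separate files
#'   (`<path>` and `<path>.decoy.fasta`); only meaningful for a database.
#' @return `path`, invisibly.
#' @export
write_fasta_db <- function(db_or_proteins, path, split = FALSE) {
  if (inherits(db_or_proteins, "personalized_db")) {
    db <- db_or_proteins
    headers <- function(df) {
      h <- df$id
      mut <- df$is_mutant
      h[mut] <- sprintf("%s|start=%d", df$id[mut], df$start_in_protein[mut])
      h
    }
    if (split) {
      t <- Biostrings::AAStringSet(stats::setNames(db$targets$sequence,
                                                   headers(db$targets)))
      d <- Biostrings::AAStringSet(stats::setNames(db$decoys$sequence,
                                                   db$decoys$id))
      Biostrings::writeXStringSet(t, path)
      Biostrings::writeXStringSet(d, paste0(path, ".decoy.fasta"))
    } else {
      all <- db_entries(db)
      h <- all$id
      mut <- all$is_mutant
      h[mut] <- sprintf("%s|start=%d", all$id[mut], all$start_in_protein[mut])
      Biostrings::writeXStringSet(
        Biostrings::AAStringSet(stats::setNames(all$sequence, h)), path)
    }
  } else {
    df <- db_or_proteins
    ids <- if ("id" %in% names(df)) df$id else
      sprintf("sp|%s|%s", df$accession, df$gene)
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(stats::setNames(df$sequence, ids)), path)
  }
  invisible(path)
}

#' Write/read a reference set (proteome + CDS FASTA pair)
#'
#' @param ref reference set (list `proteins`, `cds`).
#' @param protein_path,cds_path FASTA paths.
#' @return paths, invisibly.
#' @export
write_reference_set <- function(ref, protein_path, cds_path) {
  ids <- sprintf("%s %s", ref$proteins$accession, ref$proteins$gene)
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(stats::setNames(ref$proteins$sequence, ids)),
    protein_path)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(unname(ref$cds),
                                             names(ref$cds))), cds_path)
  invisible(c(protein_path, cds_path))
}

#' @rdname write_reference_set
#' @export
read_reference_set <- function(protein_path, cds_path) {
  aa <- Biostrings::readAAStringSet(protein_path)
  parts <- strsplit(names(aa), " +")
  acc <- vapply(parts, `[`, "", 1)
  gene <- vapply(parts, function(p) if (length(p) > 1) p[2] else p[1], "")
  nt <- Biostrings::readDNAStringSet(cds_path)
  list(proteins = data.frame(accession = acc, gene = gene,
                             sequence = as.character(aa),
                             stringsAsFactors = FALSE, row.names = NULL),
       cds = stats::setNames(as.character(nt),
                             vapply(strsplit(names(nt), " +"), `[`, "", 1)))
}

#' Write spectra to MGF
#'
#' Standard Mascot generic format: BEGIN/END IONS blocks with TITLE,
#' PEPMASS, CHARGE and one `m/z intensity` pair per line.
#'
#' @param spectra list of `spectrum` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", sp$id),
                 sprintf("PEPMASS=%.6f", sp$pepmass),
                 sprintf("CHARGE=%d+", sp$charge),
                 sprintf("%.6f %.4f", sp$mz, sp$intensity),
                 "END IONS", ""), con)
  }
  invisible(path)
}

#' Read spectra from MGF
#'
#' @param path MGF file path.
#' @return list of `spectrum` objects (TITLE as id, PEPMASS/CHARGE honored).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends)) stop("unbalanced BEGIN/END IONS in ", path)
  spectra <- vector("list", length(begins))
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1):(ends[k] - 1)]
    is_kv <- grepl("^[A-Z]+=", block)
    kv <- strsplit(block[is_kv], "=", fixed = TRUE)
    meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
    peaks <- block[!is_kv & nzchar(block)]
    pm <- do.call(rbind, lapply(strsplit(peaks, "[ \t]+"), as.numeric))
    if (is.null(pm)) pm <- matrix(numeric(0), ncol = 2)
    spectra[[k]] <- new_spectrum(
      id = unname(meta["TITLE"]),
      pepmass = as.numeric(strsplit(unname(meta["PEPMASS"]), " ")[[1]][1]),
      charge = as.integer(sub("[+-]$", "", unname(meta["CHARGE"]))),
      mz = pm[, 1], intensity = if (ncol(pm) > 1) pm[, 2] else
        rep(1, nrow(pm)))
  }
  spectra
}

#' Write chromatogram traces as CSV
#'
#' Long format with columns analyte, channel, transition, rt, intensity.
#'
#' @param traces list of `chrom_trace` objects (possibly nested lists).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_csv <- function(traces, path) {
  flat <- list()
  walk <- function(x) {
    if (inherits(x, "chrom_trace")) {
      flat[[length(flat) + 1]] <<- data.frame(
        analyte = x$analyte, channel = x$channel, transition = x$transition,
        rt = x$rt, intensity = x$intensity, stringsAsFactors = FALSE)
    } else if (is.list(x)) lapply(x, walk)
    invisible(NULL)
  }
  walk(traces)
  utils::write.csv(do.call(rbind, flat), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read chromatogram traces from CSV
#'
#' @param path CSV written by [write_chrom_csv()].
#' @return flat named list of `chrom_trace` (names
#'   `analyte/channel/transition`).
#' @export
read_chrom_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- paste(df$analyte, df$channel, df$transition, sep = "/")
  lapply(split(df, key), function(g) {
    g <- g[order(g$rt), ]
    new_chrom_trace(g$rt, g$intensity, analyte = g$analyte[1],
                    channel = g$channel[1], transition = g$transition[1])
  })
}

#' Write/read a planted truth set as JSON
#'
#' @param truth truth list from [plant_variants()] (optionally with
#'   `true_amounts`).
#' @param path JSON path.
#' @return `path` / truth list.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$labels <- as.data.frame(tr$labels, stringsAsFactors = FALSE)
  tr
}

#' Write PSMs as TSV
#'
#' @param psms PSM data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psm_tsv <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Text rendering of the b/y coverage matrix of one PSM
#'
#' One row per residue with markers for matched b and y ions (the style of a
#' sequence-coverage matrix in a search-engine report).
#'
#' @param peptide peptide sequence.
#' @param matched matched-fragment data.frame.
#' @param mut_offset optional mutation offset to flag with `*`.
#' @return character vector of report lines.
#' @export
coverage_matrix <- function(peptide, matched, mut_offset = NA) {
  n <- nchar(peptide)
  ch <- strsplit(peptide, "")[[1]]
  key <- paste(matched$series, matched$index)
  lines <- vapply(seq_len(n), function(i) {
    b <- if (i <= n - 1 && paste("b", i) %in% key) sprintf("b%-3d", i) else "    "
    y <- if (i >= 2 && paste("y", n - i + 1) %in% key)
      sprintf("y%-3d", n - i + 1) else "    "
    star <- if (!is.na(mut_offset) && i == mut_offset) "*" else " "
    sprintf("%3d %s%s %s %s", i, ch[i], star, b, y)
  }, "")
  c(sprintf("peptide %s (n=%d)", peptide, n), lines)
}
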