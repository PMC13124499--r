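#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Either file paths
#' (reference FASTA/CDS, variant table, MGF spectra, chromatogram CSV) or a
#' [sim_config()] must be supplied; with `sim`, all inputs are generated in
#' memory.
#'
#' @param reference_fasta,cds_fasta,variant_table,spectra_mgf,chrom_csv
#'   input paths (unused when `sim` is given).
#' @param variant_dialect `"tsv"` or `"vcf-min"`.
#' @param sim optional [sim_config()].
#' @param tumor_alt_min,normal_alt_max,vaf_min somatic filter thresholds
#'   (strict comparisons; defaults 3, 3, 0.05).
#' @param flank,lead database window parameters (25 missense / 24
#'   frameshift).
#' @param precursor_tol_ppm,frag_tol search tolerances (10 ppm, 0.6 Da).
#' @param charges precursor charges searched (2:5).
#' @param max_missed,min_len,max_len,max_ox digestion/modification limits.
#' @param fdr q-value threshold (0.01).
#' @param strict_site require full ladder coverage for site support.
#' @param label_k,label_r heavy-label compositions `c(n13C, n15N)`.
#' @param spike_amount PRM heavy spike, fmol.
#' @param rt_tol co-elution tolerance, minutes.
#' @param seed master seed for any simulation randomness.
#' @param out_dir optional run directory; when set, stage outputs and a
#'   JSON report are written there.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(reference_fasta = NULL, cds_fasta = NULL,
                            variant_table = NULL, spectra_mgf = NULL,
                            chrom_csv = NULL, variant_dialect = "tsv",
                            sim = NULL,
                            tumor_alt_min = 3, normal_alt_max = 3,
                            vaf_min = 0.05, flank = 25, lead = 24,
                            precursor_tol_ppm = 10, frag_tol = 0.6,
                            charges = 2:5, max_missed = 2, min_len = 6,
                            max_len = 30, max_ox = 4, fdr = 0.01,
                            strict_site = FALSE,
                            label_k = c(6, 2), label_r = c(6, 4),
                            spike_amount = 10, rt_tol = 0.2, seed = 1L,
                            out_dir = NULL) {
  cfg <- as.list(environment())
  if (fdr <= 0 || fdr >= 1) stop("FDR threshold must lie in (0, 1)")
  if (tumor_alt_min < 0 || normal_alt_max < 0 || vaf_min < 0) {
    stop("filter thresholds must be non-negative")
  }
  if (is.null(sim) && (is.null(reference_fasta) || is.null(variant_table))) {
    stop("either `sim` or input paths must be supplied")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `sim:` block
#' holds [sim_config()] arguments.
#'
#' @param path YAML file.
#' @param seed optional seed override.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(seed)) y$seed <- as.integer(seed)
  if (!is.null(y$sim)) {
    if (!is.null(seed)) y$sim$seed <- as.integer(seed)
    y$sim <- do.call(sim_config, y$sim)
  }
  do.call(pipeline_config, y)
}

log_stage <- function(log, stage, ...) {
  rec <- c(list(stage = stage), list(...))
  log[[length(log) + 1]] <- rec
  log
}

#' Run the proteogenomic pipeline end to end
#'
#' filter -> build-db -> digest/search -> FDR + site validation ->
#' detection report (and, when chromatograms are supplied or simulated,
#' PRM quantification). Deterministic given the configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @return a `sample_report`: list with `counts`, `filter_results`,
#'   `db_manifest`, `psms`, `accepted_psms`, `detected` (data.frame of
#'   detected mutations), `landscape`, `truth` (when simulated), `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()

  if (!is.null(config$sim)) {
    ref <- generate_reference_set(config$sim)
    planted <- plant_variants(ref, config$sim)
    variants <- planted$variants
    truth <- planted$truth
  } else {
    ref <- read_reference_set(config$reference_fasta, config$cds_fasta)
    variants <- read_variant_table(config$variant_table,
                                   config$variant_dialect)
    truth <- NULL
  }
  log <- log_stage(log, "inputs", n_proteins = nrow(ref$proteins),
                   n_variants = nrow(variants))

  fr <- if (nrow(variants) > 0) {
    apply_somatic_filters(variants,
                          thresholds = list(tumor_alt_min = config$tumor_alt_min,
                                            normal_alt_max = config$normal_alt_max,
                                            vaf_min = config$vaf_min))
  } else {
    cbind(variants, data.frame(vaf_tumor = numeric(0),
                               zero_depth = logical(0),
                               failed_clauses = character(0),
                               passed = logical(0)))
  }
  passing <- fr[fr$passed, , drop = FALSE]
  log <- log_stage(log, "filter", n_in = nrow(fr), n_pass = nrow(passing))

  entries <- lapply(seq_len(nrow(passing)), function(j) {
    e <- entry_from_variant(passing[j, ], ref, flank = config$flank,
                            lead = config$lead)
    if ("variant_id" %in% names(passing)) {
      e$variant_id <- passing$variant_id[j]
    }
    e
  })
  db <- assemble_personalized_db(ref$proteins, entries,
                                 provenance = list(seed = config$seed))
  log <- log_stage(log, "build-db", n_entries = length(entries),
                   n_targets = nrow(db$targets), n_decoys = nrow(db$decoys))

  spectra <- if (!is.null(config$sim)) {
    simulate_sample_spectra(ref, db, truth, passing, config)
  } else if (!is.null(config$spectra_mgf)) {
    read_mgf(config$spectra_mgf)
  } else {
    list()
  }
  log <- log_stage(log, "spectra", n_spectra = length(spectra))

  if (length(spectra) > 0) {
    psms <- search_spectra(spectra, db,
                           precursor_tol_ppm = config$precursor_tol_ppm,
                           frag_tol = config$frag_tol,
                           charges = config$charges,
                           max_missed = config$max_missed,
                           min_len = config$min_len,
                           max_len = config$max_len, max_ox = config$max_ox)
    psms <- estimate_qvalues(psms)
    accepted <- filter_psms(psms, q_max = config$fdr, targets_only = TRUE,
                            require_site = FALSE)
  } else {
    psms <- estimate_qvalues(search_empty_psms())
    accepted <- psms
  }
  log <- log_stage(log, "search", n_psms = nrow(psms),
                   n_accepted = nrow(accepted))

  # a mutant protein is detected when >= 1 accepted PSM is mutant evidence
  # AND supported at the mutation site
  mut_psms <- accepted[accepted$is_mutant & accepted$site_supported %in% TRUE,
                       , drop = FALSE]
  detected <- detected_mutations(mut_psms, db)
  log <- log_stage(log, "detect", n_mutant_psms = nrow(mut_psms),
                   n_detected = nrow(detected))

  counts <- list(
    n_variants = nrow(fr), n_passing = nrow(passing),
    n_db_entries = length(entries), n_spectra = length(spectra),
    n_psms = nrow(psms), n_accepted = nrow(accepted),
    n_mutant_psms = nrow(mut_psms), n_detected = nrow(detected))
  stopifnot(counts$n_mutant_psms <= counts$n_psms,
            counts$n_db_entries <= counts$n_passing)

  report <- structure(list(
    counts = counts, filter_results = fr, db_manifest = db_manifest(db),
    psms = psms, accepted_psms = accepted, detected = detected,
    truth = truth, log = log, config_seed = config$seed),
    class = "sample_report")

  if (!is.null(config$out_dir)) write_report(report, db, config)
  report
}

search_empty_psms <- function() {
  data.frame(spectrum_id = character(), peptide = character(),
             ox = character(), charge = integer(), score = numeric(),
             n_matched = integer(), is_decoy = logical(),
             is_mutant = logical(), mut_offset_in_peptide = integer(),
             entry_ids = character(), site_supported = logical())
}

detected_mutations <- function(mut_psms, db) {
  if (nrow(mut_psms) == 0) {
    return(data.frame(entry_id = character(), accession = character(),
                      gene = character(), hgvs_p = character(),
                      n_psms = integer(), variant_ids = character()))
  }
  ids <- unlist(strsplit(mut_psms$entry_ids, ";", fixed = TRUE))
  ids <- ids[!startsWith(ids, "rev_")]
  tgt <- db$targets
  mut_ids <- intersect(unique(ids), tgt$id[tgt$is_mutant])
  out <- do.call(rbind, lapply(mut_ids, function(id) {
    row <- tgt[tgt$id == id, ]
    n <- sum(vapply(strsplit(mut_psms$entry_ids, ";", fixed = TRUE),
                    function(v) id %in% v, TRUE))
    data.frame(entry_id = id, accession = row$accession, gene = row$gene,
               hgvs_p = row$hgvs_p, n_psms = n,
               variant_ids = row$provenance, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$accession, out$hgvs_p), , drop = FALSE]
}

# Simulate the MS/MS spectra of a synthetic sample: for each expressed
# mutation, spectra of its mutation-covering tryptic peptides; plus spectra
# of a deterministic sample of reference peptides (sequence context).
simulate_sample_spectra <- function(ref, db, truth, passing, config,
                                    n_reference_peptides = 40,
                                    per_peptide = 1) {
  sim <- config$sim
  spectra <- list()
  seed0 <- stream_seed(sim, "spectra")
  counter <- 0
  add_spectrum <- function(seq, tag) {
    counter <<- counter + 1
    spectra[[length(spectra) + 1]] <<- simulate_spectrum(
      seq, charge = 2, config = sim,
      seed = (seed0 + counter * 131) %% 2147483629,
      id = sprintf("scan%04d_%s", counter, tag))
  }
  expressed <- passing[passing$variant_id %in% truth$expressed, , drop = FALSE]
  for (j in seq_len(nrow(expressed))) {
    e <- entry_from_variant(expressed[j, ], ref, flank = config$flank,
                            lead = config$lead)
    peps <- enumerate_mutant_peptides(e, max_missed = config$max_missed,
                                      min_len = config$min_len,
                                      max_len = config$max_len)
    # prefer fully tryptic (0 missed) evidence peptides, as a real run would
    peps <- peps[order(peps$missed, -nchar(peps$sequence)), , drop = FALSE]
    take <- utils::head(seq_len(nrow(peps)), per_peptide)
    for (k in take) add_spectrum(peps$sequence[k], expressed$variant_id[j])
  }
  ref_peps <- do.call(rbind, lapply(seq_len(nrow(ref$proteins)), function(i)
    digest(ref$proteins$sequence[i], max_missed = 0,
           min_len = config$min_len, max_len = config$max_len)))
  ref_peps <- ref_peps[!duplicated(ref_peps$sequence), , drop = FALSE]
  take <- utils::head(seq_len(nrow(ref_peps)), n_reference_peptides)
  for (k in take) add_spectrum(ref_peps$sequence[k], "ref")
  spectra
}

write_report <- function(report, db, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  write_fasta_db(db, p("personalized_db.fasta"))
  utils::write.table(report$filter_results, p("filter_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_psm_tsv(report$psms, p("psms.tsv"))
  utils::write.table(report$detected, p("detected_mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(counts = report$counts, seed = report$config_seed,
         log = report$log),
    p("report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    lapply(report$log, function(x) x), p("log.jsonl.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}

#' @export
print.sample_report <- function(x, ...) {
  c <- x$counts
  cat(sprintf(paste0(
    "<sample_report>\n",
    "  variants: %d in, %d passing filters\n",
    "  database: %d mutant entries\n",
    "  spectra: %d searched, %d PSMs, %d accepted (q <= threshold)\n",
    "  mutant PSMs (site-supported): %d -> %d detected mutations\n"),
    c$n_variants, c$n_passing, c$n_db_entries, c$n_spectra, c$n_psms,
    c$n_accepted, c$n_mutant_psms, c$n_detected))
  invisible(x)
}

#' Map a peptide back to protein coordinates
#'
#' @param entry a `mutant_entry`.
#' @param peptide_start 1-based start offset of the peptide within the
#'   entry sequence.
#' @param peptide_length peptide length.
#' @return list(span = c(start, end) 1-based inclusive protein coordinates,
#'   mutation_position = protein position of the mutated residue).
#' @export
map_mutation_coordinates <- function(entry, peptide_start, peptide_length) {
  stopifnot(inherits(entry, "mutant_entry"))
  span_start <- entry$start_in_protein + peptide_start - 1L
  span_end <- span_start + peptide_length - 1L
  mut_pos <- entry$start_in_protein + entry$mut_offset - 1L
  if (mut_pos < span_start || mut_pos > span_end) {
    stop("peptide does not cover the mutation")
  }
  list(span = c(span_start, span_end), mutation_position = mut_pos)
}

#' Association between tumor VAF and protein-level detection
#'
#' Two-sided rank-sum (Wilcoxon) comparison of the tumor VAF between
#' variants whose mutant protein was detected and those where it was not.
#'
#' @param filter_results output of [apply_somatic_filters()] (needs
#'   `variant_id` and `vaf_tumor`), usually restricted upstream to passing
#'   variants.
#' @param detected_ids variant ids detected at the protein level.
#' @return list(p, statistic, n_detected, n_not_detected, computable).
#' @export
vaf_detection_association <- function(filter_results, detected_ids) {
  det <- filter_results$variant_id %in% detected_ids
  x <- filter_results$vaf_tumor[det]
  y <- filter_results$vaf_tumor[!det]
  if (length(x) < 2 || length(y) < 2) {
    return(list(p = NA_real_, statistic = NA_real_, n_detected = length(x),
                n_not_detected = length(y), computable = FALSE))
  }
  wt <- stats::wilcox.test(x, y, exact = FALSE)
  list(p = wt$p.value, statistic = unname(wt$statistic),
       n_detected = length(x), n_not_detected = length(y),
       computable = TRUE)
}

#' Mutant-protein detection landscape across samples and specimen types
#'
#' @param reports named list of `sample_report` objects; names are
#'   `"<sample>:<specimen>"` labels that become columns.
#' @return data.frame: one row per mutation (gene + hgvs_p), one logical
#'   column per report, TRUE where the mutation was detected (FDR- and
#'   site-support-passing evidence only).
#' @export
render_landscape <- function(reports) {
  stopifnot(length(reports) >= 1)
  if (is.null(names(reports)) || any(!nzchar(names(reports)))) {
    names(reports) <- sprintf("sample%d:unknown", seq_along(reports))
  }
  all_rows <- unique(do.call(rbind, lapply(reports, function(r)
    r$detected[, c("gene", "hgvs_p"), drop = FALSE])))
  if (is.null(all_rows) || nrow(all_rows) == 0) {
    out <- data.frame(mutation = character())
    for (nm in names(reports)) out[[nm]] <- logical(0)
    return(out)
  }
  all_rows <- all_rows[order(all_rows$gene, all_rows$hgvs_p), , drop = FALSE]
  out <- data.frame(mutation = paste0(all_rows$gene, "_", all_rows$hgvs_p),
                    stringsAsFactors = FALSE)
  for (nm in names(reports)) {
    det <- paste0(reports[[nm]]$detected$gene, "_",
                  reports[[nm]]$detected$hgvs_p)
    out[[nm]] <- out$mutation %in% det
  }
  rownames(out) <- NULL
  out
}

#' Write the landscape matrix as TSV (and optionally a PNG heatmap)
#'
#' @param landscape output of [render_landscape()].
#' @param path TSV output path.
#' @param png_path optional PNG path for a yes/no detection heatmap.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(landscape, path, png_path = NULL) {
  utils::write.table(landscape, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(png_path) && nrow(landscape) > 0) {
    m <- as.matrix(landscape[, -1, drop = FALSE]) * 1
    rownames(m) <- landscape$mutation
    grDevices::png(png_path, width = 200 + 80 * ncol(m),
                   height = 120 + 22 * nrow(m))
    graphics::par(mar = c(1, 10, 8, 1))
    graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                    col = c("grey90", "gold"), axes = FALSE)
    graphics::axis(3, at = seq(0, 1, length.out = ncol(m)),
                   labels = colnames(m), las = 2, tick = FALSE)
    graphics::axis(2, at = seq(0, 1, length.out = nrow(m)),
                   labels = rev(rownames(m)), las = 1, tick = FALSE)
    grDevices::dev.off()
  }
  invisible(path)
}

#' Plot longitudinal quantification (mean +/- SE per timepoint)
#'
#' @param summaries output of [summarize_timepoints()].
#' @param png_path output image path.
#' @return `png_path`, invisibly.
#' @export
plot_longitudinal <- function(summaries, png_path) {
  grDevices::png(png_path, width = 720, height = 360)
  on.exit(grDevices::dev.off())
  analytes <- unique(summaries$analyte)
  tps <- unique(summaries$timepoint)
  graphics::par(mfrow = c(1, length(analytes)), mar = c(6, 4, 2, 1))
  for (a in analytes) {
    s <- summaries[summaries$analyte == a, ]
    x <- seq_len(nrow(s))
    ylim <- c(0, max(s$mean_amount + ifelse(is.na(s$se), 0, s$se)) * 1.1)
    graphics::plot(x, s$mean_amount, type = "b", pch = 16, ylim = ylim,
                   xaxt = "n", xlab = "", ylab = "amount (fmol)", main = a)
    graphics::axis(1, at = x, labels = s$timepoint, las = 2)
    se <- ifelse(is.na(s$se), 0, s$se)
    graphics::arrows(x, s$mean_amount - se, x, s$mean_amount + se,
                     angle = 90, code = 3, length = 0.04)
  }
  invisible(png_path)
}
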