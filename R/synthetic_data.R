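#' Simulation configuration
#'
#' One object holds every knob of the synthetic-data generators. Random
#' number streams are partitioned per generator (sequences, variants,
#' spectra, chromatograms) so adding one stage does not perturb another;
#' with a fixed seed every generator is byte-reproducible.
#'
#' @param seed integer master seed.
#' @param n_proteins number of reference proteins.
#' @param len_min,len_max protein length bounds (uniform lengths).
#' @param n_missense,n_frameshift somatic variants to plant.
#' @param n_negatives_per_clause planted non-somatic variants per filter
#'   clause (four flavors: low tumor support, germline normal reads, low
#'   VAF, simple repeat).
#' @param vaf_min,vaf_max true somatic VAF range (uniform).
#' @param depth_mean mean sequencing depth (Poisson).
#' @param normal_error_rate per-read error rate in the normal sample for
#'   true somatics.
#' @param dropout per-fragment dropout probability of simulated spectra.
#' @param n_noise_peaks additive random noise peaks per spectrum.
#' @param mz_jitter_sd fragment m/z jitter SD in Da.
#' @param mz_jitter_bound hard bound on jitter (must stay within the 0.6 Da
#'   match tolerance).
#' @param intensity_sdlog lognormal sdlog of multiplicative intensity noise.
#' @param noise_intensity_max maximum intensity of noise peaks (base peak
#'   intensity is 1000).
#' @param rt_apex chromatographic apex retention time (minutes).
#' @param peak_sigma Gaussian peak width (minutes).
#' @param sample_interval chromatogram sampling interval (minutes; default
#'   `peak_sigma / 10`, at which trapezoidal integration of the peak is
#'   accurate to well under 0.1%).
#' @param chrom_halfwidth half-width of the sampled window (minutes).
#' @param baseline_sd chromatogram baseline noise SD (intensity units).
#' @param response_factor peak area per fmol of analyte.
#' @param n_transitions PRM transitions per analyte (default 3).
#' @param transition_cv lognormal coefficient of variation of
#'   transition-level amounts in longitudinal simulations.
#' @param spike_amount heavy-standard spike per injection (fmol).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_proteins = 25L, len_min = 60L, len_max = 400L,
                       n_missense = 10L, n_frameshift = 2L,
                       n_negatives_per_clause = 2L,
                       vaf_min = 0.15, vaf_max = 0.6,
                       depth_mean = 100, normal_error_rate = 0.001,
                       dropout = 0.1, n_noise_peaks = 5L,
                       mz_jitter_sd = 0.05, mz_jitter_bound = 0.3,
                       intensity_sdlog = 0.3, noise_intensity_max = 50,
                       rt_apex = 12, peak_sigma = 0.05,
                       sample_interval = peak_sigma / 10,
                       chrom_halfwidth = 10 * peak_sigma,
                       baseline_sd = 0, response_factor = 1e5,
                       n_transitions = 3L, transition_cv = 0.2,
                       spike_amount = 10) {
  cfg <- as.list(environment())
  probs <- c(dropout = dropout)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (len_min < 60) stop("protein length distribution must yield lengths >= 60")
  if (len_max < len_min) stop("len_max < len_min")
  if (n_proteins < 1) stop("n_proteins must be >= 1")
  if (vaf_min <= 0 || vaf_max > 1 || vaf_min > vaf_max) {
    stop("VAF range must satisfy 0 < vaf_min <= vaf_max <= 1")
  }
  if (sample_interval <= 0) stop("sampling interval must be positive")
  if (peak_sigma <= 0) stop("Gaussian peak width must be positive")
  if (mz_jitter_bound > 0.6) stop("jitter bound exceeds the match tolerance")
  if (transition_cv < 0) stop("transition CV must be >= 0")
  structure(cfg, class = "sim_config")
}

# Per-generator substream seeds; keeps streams independent and < 2^31.
stream_seed <- function(config, stream = c("sequence", "variants", "spectra",
                                           "chromatograms")) {
  stream <- match.arg(stream)
  k <- match(stream, c("sequence", "variants", "spectra", "chromatograms"))
  (as.numeric(config$seed) * 1009 + k * 99991) %% 2147483629
}

# Codons per residue, stop codons excluded.
.codon_table_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc)[gc != "*"], gc[gc != "*"])
}

#' Generate a synthetic reference proteome with paired coding sequences
#'
#' Protein lengths are uniform on `[len_min, len_max]`; residues are drawn
#' uniformly from the canonical alphabet; each CDS is assembled by sampling
#' a synonymous codon per residue and appending a stop codon, so translating
#' any CDS reproduces its paired protein exactly.
#'
#' @param config a [sim_config()].
#' @return list with `proteins` (data.frame accession, gene, sequence) and
#'   `cds` (named character vector).
#' @export
generate_reference_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(stream_seed(config, "sequence"), {
    by_aa <- .codon_table_by_aa()
    n <- config$n_proteins
    lens <- sample(config$len_min:config$len_max, n, replace = TRUE)
    proteins <- character(n)
    cds <- character(n)
    for (i in seq_len(n)) {
      aa <- sample(.AA_LETTERS, lens[i], replace = TRUE)
      proteins[i] <- paste(aa, collapse = "")
      codons <- vapply(aa, function(a) {
        pool <- by_aa[[a]]
        pool[sample.int(length(pool), 1)]
      }, "")
      cds[i] <- paste0(paste(codons, collapse = ""), "TAA")
    }
    acc <- sprintf("SYN%04d", seq_len(n))
    list(proteins = data.frame(accession = acc,
                               gene = sprintf("GENE%d", seq_len(n)),
                               sequence = proteins, stringsAsFactors = FALSE),
         cds = stats::setNames(cds, acc))
  })
}

# Single-base substitutions of a codon that change the residue without
# creating a stop; returns data.frame(base_off, ref_base, alt_base, alt_aa).
.missense_options <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  ref_aa <- unname(gc[codon])
  out <- list()
  for (off in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, off, off))) {
      alt <- codon
      substr(alt, off, off) <- b
      aa <- unname(gc[alt])
      if (aa != "*" && aa != ref_aa) {
        out[[length(out) + 1]] <- data.frame(
          base_off = off, ref_base = substr(codon, off, off), alt_base = b,
          alt_aa = aa, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

draw_depth <- function(n, mean_depth, min_depth = 30L) {
  pmax(min_depth, stats::rpois(n, mean_depth))
}

#' Plant somatic and non-somatic variants in a reference set
#'
#' True somatics get tumor alt reads drawn binomially at their true VAF and
#' near-zero normal support. Non-somatic negatives are planted in four
#' flavors, one per filter clause (low tumor support, germline-level normal
#' reads, sub-threshold VAF, simple repeat); draws that would contradict the
#' planted truth label are clamped to keep labels and read counts
#' consistent, so with the default (well-separated) parameters the filter
#' recovers the planted somatic set exactly. Somatic missense positions are
#' only accepted when the resulting mutant entry has at least one tryptic
#' peptide (within the search length bounds) covering the mutation, and all
#' planted somatics are flagged protein-expressed.
#'
#' @param ref reference set from [generate_reference_set()].
#' @param config a [sim_config()].
#' @return list `variants` (data.frame, the pipeline input) and `truth`
#'   (list: `labels` data.frame with variant_id, is_somatic, flavor;
#'   `expressed` character vector of expressed variant ids).
#' @export
plant_variants <- function(ref, config) {
  stopifnot(inherits(config, "sim_config"))
  n_needed <- config$n_missense + config$n_frameshift +
    4 * config$n_negatives_per_clause
  total_positions <- sum(nchar(ref$proteins$sequence))
  if (n_needed > total_positions) {
    stop("more variants requested than codon positions available")
  }
  withr::with_seed(stream_seed(config, "variants"), {
    rows <- list()
    labels <- list()
    used <- character(0)

    draw_missense <- function(require_detectable) {
      for (attempt in 1:200) {
        pi <- sample.int(nrow(ref$proteins), 1)
        prot <- ref$proteins$sequence[pi]
        L <- nchar(prot)
        pos <- sample.int(L, 1)
        key <- paste(ref$proteins$accession[pi], pos)
        if (key %in% used) next
        codon_start <- 3 * (pos - 1) + 1
        codon <- substr(ref$cds[[pi]], codon_start, codon_start + 2)
        opts <- .missense_options(codon)
        if (is.null(opts)) next
        o <- opts[sample.int(nrow(opts), 1), ]
        if (require_detectable) {
          e <- build_missense_entry(prot, pos, o$alt_aa,
                                    accession = ref$proteins$accession[pi],
                                    gene = ref$proteins$gene[pi])
          if (nrow(enumerate_mutant_peptides(e)) == 0) next
        }
        used <<- c(used, key)
        return(list(pi = pi, pos = pos, opt = o,
                    cds_pos = codon_start + o$base_off - 1))
      }
      stop("could not place a missense variant; reference set too small")
    }

    make_row <- function(id, pi, type, cds_pos, protein_pos, ref_aa, alt_aa,
                         ref_base, alt_base, tumor_alt, tumor_depth,
                         normal_alt, normal_depth, simple_repeat) {
      data.frame(variant_id = id, accession = ref$proteins$accession[pi],
                 gene = ref$proteins$gene[pi], type = type,
                 cds_pos = as.integer(cds_pos),
                 protein_pos = as.integer(protein_pos),
                 ref_aa = ref_aa, alt_aa = alt_aa,
                 ref_base = ref_base, alt_base = alt_base,
                 tumor_alt = as.integer(tumor_alt),
                 tumor_depth = as.integer(tumor_depth),
                 normal_alt = as.integer(normal_alt),
                 normal_depth = as.integer(normal_depth),
                 simple_repeat = simple_repeat, stringsAsFactors = FALSE)
    }

    somatic_counts <- function(vaf) {
      td <- draw_depth(1, config$depth_mean)
      ta <- stats::rbinom(1, td, vaf)
      # clamp: the planted label says this variant passes clauses i and iii
      ta <- max(ta, 4L, floor(0.05 * td) + 1L)
      nd <- draw_depth(1, config$depth_mean)
      na <- min(stats::rbinom(1, nd, config$normal_error_rate), 2L)
      list(ta = ta, td = td, na = na, nd = nd)
    }

    vid <- 0
    next_id <- function(prefix) {
      vid <<- vid + 1
      sprintf("%s%03d", prefix, vid)
    }

    for (k in seq_len(config$n_missense)) {
      d <- draw_missense(require_detectable = TRUE)
      vaf <- stats::runif(1, config$vaf_min, config$vaf_max)
      cc <- somatic_counts(vaf)
      id <- next_id("VAR")
      prot <- ref$proteins$sequence[d$pi]
      rows[[length(rows) + 1]] <- make_row(
        id, d$pi, "missense", d$cds_pos, d$pos,
        substr(prot, d$pos, d$pos), d$opt$alt_aa,
        d$opt$ref_base, d$opt$alt_base, cc$ta, cc$td, cc$na, cc$nd, FALSE)
      labels[[length(labels) + 1]] <- data.frame(
        variant_id = id, is_somatic = TRUE, flavor = "somatic",
        true_vaf = vaf, stringsAsFactors = FALSE)
    }

    for (k in seq_len(config$n_frameshift)) {
      for (attempt in 1:200) {
        pi <- sample.int(nrow(ref$proteins), 1)
        L <- nchar(ref$proteins$sequence[pi])
        pos <- sample.int(L - 30, 1) + 25 # keep room for lead and neo frame
        cds_pos <- 3 * (pos - 1) + 1
        key <- paste(ref$proteins$accession[pi], pos)
        if (key %in% used) next
        del <- substr(ref$cds[[pi]], cds_pos, cds_pos)
        used <- c(used, key)
        vaf <- stats::runif(1, config$vaf_min, config$vaf_max)
        cc <- somatic_counts(vaf)
        id <- next_id("VAR")
        rows[[length(rows) + 1]] <- make_row(
          id, pi, "frameshift", cds_pos, pos, "", "", del, "",
          cc$ta, cc$td, cc$na, cc$nd, FALSE)
        labels[[length(labels) + 1]] <- data.frame(
          variant_id = id, is_somatic = TRUE, flavor = "somatic",
          true_vaf = vaf, stringsAsFactors = FALSE)
        break
      }
    }

    for (flavor in c("fail_i", "fail_ii", "fail_iii", "fail_iv")) {
      for (k in seq_len(config$n_negatives_per_clause)) {
        d <- draw_missense(require_detectable = FALSE)
        id <- next_id("VAR")
        prot <- ref$proteins$sequence[d$pi]
        td <- draw_depth(1, config$depth_mean)
        nd <- draw_depth(1, config$depth_mean)
        na <- min(stats::rbinom(1, nd, config$normal_error_rate), 2L)
        srpt <- FALSE
        if (flavor == "fail_i") {
          ta <- min(stats::rbinom(1, td, 0.02), 3L)
        } else if (flavor == "fail_ii") {
          vaf <- stats::runif(1, config$vaf_min, config$vaf_max)
          ta <- max(stats::rbinom(1, td, vaf), 4L, floor(0.05 * td) + 1L)
          na <- max(stats::rbinom(1, nd, vaf), 3L) # germline support
        } else if (flavor == "fail_iii") {
          td <- max(td, 90L) # room for alt > 3 at VAF <= 0.05
          ta <- max(4L, min(stats::rbinom(1, td, 0.03), floor(0.05 * td)))
        } else {
          vaf <- stats::runif(1, config$vaf_min, config$vaf_max)
          ta <- max(stats::rbinom(1, td, vaf), 4L, floor(0.05 * td) + 1L)
          srpt <- TRUE
        }
        rows[[length(rows) + 1]] <- make_row(
          id, d$pi, "missense", d$cds_pos, d$pos,
          substr(prot, d$pos, d$pos), d$opt$alt_aa,
          d$opt$ref_base, d$opt$alt_base, ta, td, na, nd, srpt)
        labels[[length(labels) + 1]] <- data.frame(
          variant_id = id, is_somatic = FALSE, flavor = flavor,
          true_vaf = NA_real_, stringsAsFactors = FALSE)
      }
    }

    variants <- do.call(rbind, rows)
    labels <- do.call(rbind, labels)
    rownames(variants) <- rownames(labels) <- NULL
    # expressed = somatic variants whose mutant entry has at least one
    # mutation-covering tryptic peptide within the search length bounds
    # (missense placements already guarantee this; frameshifts may not)
    expressed <- vapply(seq_len(nrow(variants)), function(j) {
      if (!labels$is_somatic[j]) return(FALSE)
      e <- entry_from_variant(variants[j, ], ref)
      nrow(enumerate_mutant_peptides(e)) > 0
    }, TRUE)
    list(variants = variants,
         truth = list(labels = labels,
                      expressed = labels$variant_id[expressed]))
  })
}

new_spectrum <- function(id, pepmass, charge, mz, intensity) {
  ord <- order(mz)
  structure(list(id = id, pepmass = pepmass, charge = as.integer(charge),
                 mz = mz[ord], intensity = intensity[ord]),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s: precursor %.4f (%d+), %d peaks\n",
              x$id, x$pepmass, x$charge, length(x$mz)))
  invisible(x)
}

#' Simulate an MS/MS spectrum of a peptide
#'
#' Peaks are placed at the theoretical singly-charged b/y m/z values with
#' per-fragment dropout, multiplicative lognormal intensity noise around the
#' exponential-decay ladder, bounded m/z jitter, and additive random noise
#' peaks. The precursor m/z follows from the peptide mass and charge.
#'
#' @param sequence peptide string.
#' @param charge precursor charge (1..5).
#' @param config a [sim_config()].
#' @param seed optional substream seed; when NULL the current RNG stream is
#'   consumed.
#' @param ox oxidized methionine positions.
#' @param cterm_shift heavy-label C-terminal mass shift.
#' @param id spectrum id.
#' @return a `spectrum`.
#' @export
simulate_spectrum <- function(sequence, charge, config, seed = NULL,
                              ox = integer(0), cterm_shift = 0,
                              id = sequence) {
  if (charge < 1 || charge > 5) stop("charge must lie in 1..5")
  stopifnot(nchar(sequence) >= 2)
  body <- function() {
    theo <- theoretical_fragments(sequence, ox = ox, charges = 1,
                                  cterm_shift = cterm_shift)
    nf <- nrow(theo)
    keep <- stats::runif(nf) >= config$dropout
    base <- 1000 * theo$rel_intensity
    inten <- base * stats::rlnorm(nf, 0, config$intensity_sdlog)
    jit <- stats::rnorm(nf, 0, config$mz_jitter_sd)
    jit <- pmin(pmax(jit, -config$mz_jitter_bound), config$mz_jitter_bound)
    mz <- theo$mz + jit
    mz <- mz[keep]
    inten <- inten[keep]
    if (config$n_noise_peaks > 0) {
      nm <- stats::runif(config$n_noise_peaks, 100,
                         max(theo$mz) + 100)
      ni <- stats::runif(config$n_noise_peaks, 0, config$noise_intensity_max)
      mz <- c(mz, nm)
      inten <- c(inten, ni)
    }
    pep_mz <- (peptide_mass(sequence, ox, cterm_shift) +
                 charge * PROTON_MASS) / charge
    new_spectrum(id, pep_mz, charge, mz, inten)
  }
  if (is.null(seed)) body() else withr::with_seed(seed, body())
}

new_chrom_trace <- function(rt, intensity, analyte = "analyte",
                            channel = c("light", "heavy"),
                            transition = "y6") {
  channel <- match.arg(channel)
  if (is.unsorted(rt, strictly = TRUE)) stop("retention times must increase")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(rt = rt, intensity = intensity, analyte = analyte,
                 channel = channel, transition = transition),
            class = "chrom_trace")
}

#' @export
print.chrom_trace <- function(x, ...) {
  cat(sprintf("<chrom_trace> %s/%s/%s: %d samples, rt %.2f-%.2f min\n",
              x$analyte, x$channel, x$transition, length(x$rt),
              min(x$rt), max(x$rt)))
  invisible(x)
}

#' Simulate a paired light/heavy PRM chromatogram
#'
#' Each trace is a sampled Gaussian peak plus non-negative-clipped additive
#' baseline noise. True peak area is proportional to the amount through the
#' shared response factor, and the light and heavy apexes co-elute.
#'
#' @param analyte_amount endogenous (light) amount, fmol.
#' @param spike_amount heavy-standard amount, fmol.
#' @param config a [sim_config()].
#' @param seed optional substream seed.
#' @param analyte,transition trace labels.
#' @return list(light, heavy) of `chrom_trace`.
#' @export
simulate_chromatogram <- function(analyte_amount, spike_amount, config,
                                  seed = NULL, analyte = "analyte",
                                  transition = "y6") {
  if (analyte_amount < 0 || spike_amount < 0) stop("amounts must be >= 0")
  if (config$sample_interval <= 0) stop("sampling interval must be positive")
  body <- function() {
    rt <- seq(config$rt_apex - config$chrom_halfwidth,
              config$rt_apex + config$chrom_halfwidth,
              by = config$sample_interval)
    shape <- exp(-(rt - config$rt_apex)^2 / (2 * config$peak_sigma^2)) /
      (config$peak_sigma * sqrt(2 * pi))
    one <- function(amount, channel) {
      signal <- amount * config$response_factor * shape
      if (config$baseline_sd > 0) {
        signal <- signal + stats::rnorm(length(rt), 0, config$baseline_sd)
      }
      new_chrom_trace(rt, pmax(signal, 0), analyte = analyte,
                      channel = channel, transition = transition)
    }
    list(light = one(analyte_amount, "light"),
         heavy = one(spike_amount, "heavy"))
  }
  if (is.null(seed)) body() else withr::with_seed(seed, body())
}

#' Simulate a longitudinal pre/post-surgery PRM series
#'
#' The true amount is `pre_amount` at the first (presurgical) timepoint and
#' `pre_amount * post_fold_change` thereafter; transition-level amounts get
#' multiplicative lognormal noise at the configured CV (mean preserved) and
#' are rendered as light/heavy chromatogram pairs.
#'
#' @param pre_amount presurgical amount, fmol.
#' @param post_fold_change postsurgical fold change (e.g. 0.05).
#' @param timepoints character vector of timepoint labels (first one is the
#'   presurgical point); must be non-empty.
#' @param config a [sim_config()].
#' @param seed optional substream seed.
#' @param analyte analyte label.
#' @return list `traces` (traces[[timepoint]][[transition]] = list(light,
#'   heavy)) and `amounts` (data.frame analyte, timepoint, transition,
#'   true_amount, spike).
#' @export
simulate_longitudinal <- function(pre_amount, post_fold_change, timepoints,
                                  config, seed = NULL, analyte = "analyte") {
  if (length(timepoints) == 0) stop("timepoint list must be non-empty")
  if (config$n_transitions < 1) stop("need at least one transition")
  body <- function() {
    sdlog <- if (config$transition_cv > 0) {
      sqrt(log(1 + config$transition_cv^2))
    } else 0
    traces <- list()
    amounts <- list()
    for (ti in seq_along(timepoints)) {
      base <- if (ti == 1) pre_amount else pre_amount * post_fold_change
      tp <- as.character(timepoints[ti])
      traces[[tp]] <- list()
      for (tr in seq_len(config$n_transitions)) {
        noise <- if (sdlog > 0) stats::rlnorm(1, -sdlog^2 / 2, sdlog) else 1
        amt <- base * noise
        trans <- sprintf("y%d", tr + 3)
        traces[[tp]][[trans]] <- simulate_chromatogram(
          amt, config$spike_amount, config,
          analyte = sprintf("%s@%s", analyte, tp), transition = trans)
        amounts[[length(amounts) + 1]] <- data.frame(
          analyte = analyte, timepoint = tp, transition = trans,
          true_amount = amt, spike = config$spike_amount,
          stringsAsFactors = FALSE)
      }
    }
    list(traces = traces, amounts = do.call(rbind, amounts))
  }
  if (is.null(seed)) body() else withr::with_seed(seed, body())
}
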