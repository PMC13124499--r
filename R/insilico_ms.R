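#' In-silico tryptic digestion
#'
#' Cleaves after every K (the LysC component of a Trypsin/LysC mix cleaves
#' K-P) and after every R not followed by P, emitting all peptides with up to
#' `max_missed` missed cleavages within the length bounds.
#'
#' @param sequence protein/entry amino-acid string.
#' @param max_missed maximum missed cleavages (default 2).
#' @param min_len,max_len peptide length bounds (defaults 6 and 30).
#' @return data.frame with columns `sequence`, `start`, `end` (1-based,
#'   inclusive, within the input), `missed`.
#' @export
digest <- function(sequence, max_missed = 2, min_len = 6, max_len = 30) {
  if (min_len > max_len) stop("min_len > max_len")
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) > 0)
  ch <- strsplit(sequence, "")[[1]]
  if (!all(ch %in% .AA_LETTERS)) {
    stop("sequence contains non-canonical residues")
  }
  n <- length(ch)
  nxt <- c(ch[-1], "")
  sites <- which((ch == "K" | (ch == "R" & nxt != "P")) & seq_len(n) < n)
  starts <- c(1L, sites + 1L)
  ends <- c(sites, n)
  k <- length(starts)
  out <- vector("list", k * (max_missed + 1))
  idx <- 0L
  for (i in seq_len(k)) {
    for (m in 0:max_missed) {
      if (i + m > k) break
      s <- starts[i]; e <- ends[i + m]
      len <- e - s + 1L
      if (len < min_len || len > max_len) next
      idx <- idx + 1L
      out[[idx]] <- list(sequence = substr(sequence, s, e),
                         start = s, end = e, missed = m)
    }
  }
  if (idx == 0L) {
    return(data.frame(sequence = character(), start = integer(),
                      end = integer(), missed = integer()))
  }
  out <- out[seq_len(idx)]
  data.frame(sequence = vapply(out, `[[`, "", "sequence"),
             start = vapply(out, `[[`, 0L, "start"),
             end = vapply(out, `[[`, 0L, "end"),
             missed = vapply(out, `[[`, 0L, "missed"),
             stringsAsFactors = FALSE)
}

#' Enumerate mutation-covering peptides of a mutant entry
#'
#' Digest products are mutant evidence only when their span includes the
#' mutated residue (missense) or reaches the frame-affected region
#' (frameshift). Protein-level coordinates are attached.
#'
#' @param entry a `mutant_entry`.
#' @param max_missed,min_len,max_len digestion parameters, see [digest()].
#' @return data.frame of peptides with `mut_offset_in_peptide` and
#'   protein-coordinate columns `protein_start`, `protein_end`.
#' @export
enumerate_mutant_peptides <- function(entry, max_missed = 2, min_len = 6,
                                      max_len = 30) {
  stopifnot(inherits(entry, "mutant_entry"))
  peps <- digest(entry$sequence, max_missed = max_missed,
                 min_len = min_len, max_len = max_len)
  m <- entry$mut_offset
  covers <- if (entry$kind == "missense") {
    peps$start <= m & peps$end >= m
  } else {
    peps$end >= m
  }
  peps <- peps[covers, , drop = FALSE]
  if (nrow(peps) > 0) {
    peps$mut_offset_in_peptide <- pmax(1L, m - peps$start + 1L)
    peps$protein_start <- entry$start_in_protein + peps$start - 1L
    peps$protein_end <- entry$start_in_protein + peps$end - 1L
  }
  rownames(peps) <- NULL
  peps
}

ox_mass <- function(sequence, ox) {
  if (length(ox) == 0) return(0)
  chars <- strsplit(sequence, "")[[1]]
  if (any(ox < 1 | ox > length(chars)) || any(chars[ox] != "M")) {
    stop("oxidation positions must index methionines")
  }
  MOD_OXIDATION * length(ox)
}

#' Neutral monoisotopic peptide mass
#'
#' Carbamidomethylation of every cysteine is applied as a fixed
#' modification; methionine oxidation positions are supplied via `ox`.
#'
#' @param sequence peptide string.
#' @param ox integer positions of oxidized methionines (may be empty).
#' @param cterm_shift extra mass on the C-terminal residue (heavy label).
#' @return neutral monoisotopic mass in Da.
#' @export
peptide_mass <- function(sequence, ox = integer(0), cterm_shift = 0) {
  chars <- strsplit(sequence, "")[[1]]
  if (!all(chars %in% .AA_LETTERS)) stop("non-canonical residue in peptide")
  sum(.AA_MONO[chars]) + WATER_MONO +
    MOD_CARBAMIDOMETHYL * sum(chars == "C") +
    ox_mass(sequence, ox) + cterm_shift
}

#' Fragment-ion m/z
#'
#' b-ion neutral mass is the sum of the first `index` residue masses (plus
#' modifications therein); y-ion neutral mass is the sum of the last `index`
#' residue masses plus water (plus modifications therein, and the C-terminal
#' heavy-label shift, which y ions carry and b ions do not). m/z is
#' `(neutral + z * proton) / z`.
#'
#' @param sequence peptide string.
#' @param series `"b"` or `"y"`.
#' @param index fragment index, 1..length-1.
#' @param charge fragment charge, >= 1.
#' @inheritParams peptide_mass
#' @return m/z value.
#' @export
fragment_mz <- function(sequence, series = c("b", "y"), index, charge = 1,
                        ox = integer(0), cterm_shift = 0) {
  series <- match.arg(series)
  n <- nchar(sequence)
  if (index < 1 || index > n - 1) {
    stop("fragment index ", index, " outside 1..", n - 1)
  }
  if (charge < 1) stop("fragment charge must be >= 1")
  chars <- strsplit(sequence, "")[[1]]
  if (series == "b") {
    span <- seq_len(index)
    neutral <- sum(.AA_MONO[chars[span]]) +
      MOD_CARBAMIDOMETHYL * sum(chars[span] == "C") +
      MOD_OXIDATION * sum(ox %in% span)
  } else {
    span <- seq.int(n - index + 1L, n)
    neutral <- sum(.AA_MONO[chars[span]]) + WATER_MONO +
      MOD_CARBAMIDOMETHYL * sum(chars[span] == "C") +
      MOD_OXIDATION * sum(ox %in% span) + cterm_shift
  }
  (neutral + charge * PROTON_MASS) / charge
}

#' Full theoretical b/y fragment table
#'
#' @inheritParams fragment_mz
#' @param charges fragment charge states to generate (default 1).
#' @param decay exponential-decay constant of the relative-intensity ladder.
#' @return data.frame (series, index, charge, mz, rel_intensity).
#' @export
theoretical_fragments <- function(sequence, ox = integer(0), charges = 1,
                                  cterm_shift = 0,
                                  decay = FRAGMENT_LADDER_DECAY) {
  n <- nchar(sequence)
  grid <- expand.grid(index = seq_len(n - 1), series = c("b", "y"),
                      charge = charges, stringsAsFactors = FALSE)
  grid$mz <- mapply(function(s, i, z)
    fragment_mz(sequence, s, i, z, ox = ox, cterm_shift = cterm_shift),
    grid$series, grid$index, grid$charge)
  grid$rel_intensity <- exp(-decay * (grid$index - 1))
  grid[, c("series", "index", "charge", "mz", "rel_intensity")]
}

#' Mass shift of a stable-isotope-labeled C-terminal residue
#'
#' @param n13c number of 13C substitutions.
#' @param n15n number of 15N substitutions.
#' @param residue labeled residue, `"K"` or `"R"`; counts are validated
#'   against the residue's atom content (C6/N2 for Lys, C6/N4 for Arg).
#' @return mass delta in Da.
#' @export
heavy_mass_shift <- function(n13c, n15n, residue = c("K", "R")) {
  residue <- match.arg(residue)
  lim <- .LABEL_ATOM_LIMITS[[residue]]
  if (n13c < 0 || n15n < 0 || n13c > lim["C"] || n15n > lim["N"]) {
    stop("label composition 13C", n13c, " 15N", n15n,
         " exceeds atom content of ", residue,
         " (C", lim["C"], " N", lim["N"], ")")
  }
  n13c * C13_SHIFT + n15n * N15_SHIFT
}

#' Match theoretical fragments to spectrum peaks
#'
#' Greedy nearest-peak matching within the fragment tolerance; each observed
#' peak is used at most once; ties break toward smaller absolute error, then
#' larger peak intensity.
#'
#' @param theoretical data.frame from [theoretical_fragments()].
#' @param spectrum a `spectrum` (list with sorted `mz` and `intensity`).
#' @param tol fragment tolerance in Da (default 0.6).
#' @return data.frame: theoretical columns plus `observed_mz`,
#'   `observed_intensity`, `error` (observed - theoretical).
#' @export
match_fragments <- function(theoretical, spectrum, tol = 0.6) {
  empty <- cbind(theoretical[0, , drop = FALSE],
                 data.frame(observed_mz = numeric(),
                            observed_intensity = numeric(),
                            error = numeric()))
  if (length(spectrum$mz) == 0 || nrow(theoretical) == 0) return(empty)
  cand <- list()
  for (ti in seq_len(nrow(theoretical))) {
    lo <- findInterval(theoretical$mz[ti] - tol, spectrum$mz) + 1L
    hi <- findInterval(theoretical$mz[ti] + tol, spectrum$mz)
    if (hi >= lo) {
      cand[[length(cand) + 1L]] <- data.frame(
        ti = ti, pi = lo:hi,
        err = spectrum$mz[lo:hi] - theoretical$mz[ti],
        intensity = spectrum$intensity[lo:hi])
    }
  }
  if (length(cand) == 0) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(abs(cand$err), -cand$intensity), , drop = FALSE]
  used_t <- logical(nrow(theoretical))
  used_p <- logical(length(spectrum$mz))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used_t[cand$ti[k]] && !used_p[cand$pi[k]]) {
      keep[k] <- TRUE
      used_t[cand$ti[k]] <- TRUE
      used_p[cand$pi[k]] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- theoretical[cand$ti, , drop = FALSE]
  out$observed_mz <- spectrum$mz[cand$pi]
  out$observed_intensity <- spectrum$intensity[cand$pi]
  out$error <- cand$err
  out <- out[order(out$series, out$index, out$charge), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score one peptide against one spectrum
#'
#' Hybrid score: number of matched fragment ions plus the cosine similarity
#' between the square-root-transformed theoretical intensity ladder and the
#' observed intensities over the matched ions. A noiseless self-spectrum of
#' a length-n peptide scores `2(n-1) + 1`.
#'
#' @inheritParams fragment_mz
#' @param spectrum a `spectrum`.
#' @param frag_tol fragment tolerance in Da.
#' @param frag_charges theoretical fragment charge states.
#' @return list(score, matched) where `matched` is the matched-fragment
#'   data.frame.
#' @export
score_psm <- function(sequence, spectrum, ox = integer(0), frag_tol = 0.6,
                      frag_charges = 1, cterm_shift = 0) {
  theo <- theoretical_fragments(sequence, ox = ox, charges = frag_charges,
                                cterm_shift = cterm_shift)
  matched <- match_fragments(theo, spectrum, tol = frag_tol)
  if (nrow(matched) == 0) return(list(score = 0, matched = matched))
  a <- sqrt(matched$rel_intensity)
  b <- sqrt(matched$observed_intensity)
  cosine <- if (sum(b) == 0) 0 else sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  list(score = nrow(matched) + cosine, matched = matched)
}

enumerate_ox_variants <- function(sequence, max_ox = 4) {
  mpos <- which(strsplit(sequence, "")[[1]] == "M")
  variants <- list(integer(0))
  if (length(mpos) > 0) {
    for (k in seq_len(min(max_ox, length(mpos)))) {
      # combn over indices: combn(x, k) misbehaves for length-1 numeric x
      combos <- utils::combn(seq_along(mpos), k, simplify = FALSE)
      variants <- c(variants, lapply(combos, function(i) mpos[i]))
    }
  }
  variants
}

#' Build the searchable peptide index of a database
#'
#' Digests every target and decoy entry, aggregates peptides shared between
#' entries, determines mutant-evidence status (a peptide is mutant evidence
#' only if it covers the mutation in a mutant entry and is not also a
#' peptide of any reference entry), and enumerates methionine-oxidation
#' variants (up to `max_ox` per peptide).
#'
#' @param db a `personalized_db`.
#' @param max_missed,min_len,max_len digestion parameters.
#' @param max_ox maximum variable modifications per peptide.
#' @return data.frame sorted by neutral mass with columns `sequence`, `ox`
#'   (comma-joined positions), `mass`, `is_decoy`, `is_mutant`,
#'   `mut_offset_in_peptide`, `entry_ids`.
#' @export
index_database <- function(db, max_missed = 2, min_len = 6, max_len = 30,
                           max_ox = 4) {
  entries <- db_entries(db)
  recs <- vector("list", nrow(entries))
  for (j in seq_len(nrow(entries))) {
    e <- entries[j, ]
    peps <- digest(e$sequence, max_missed = max_missed, min_len = min_len,
                   max_len = max_len)
    if (nrow(peps) == 0) next
    covers <- if (e$is_mutant && !is.na(e$mut_offset)) {
      if (e$kind == "missense") {
        peps$start <= e$mut_offset & peps$end >= e$mut_offset
      } else {
        peps$end >= e$mut_offset
      }
    } else rep(FALSE, nrow(peps))
    recs[[j]] <- data.frame(
      sequence = peps$sequence, entry_id = e$id, is_decoy = e$is_decoy,
      is_reference = !e$is_mutant && !e$is_decoy,
      covers = covers,
      mut_off = ifelse(covers, pmax(1L, e$mut_offset - peps$start + 1L),
                       NA_integer_),
      stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, recs)
  if (is.null(recs) || nrow(recs) == 0) {
    stop("database digestion produced no peptides within the length bounds")
  }
  agg <- split(recs, recs$sequence)
  base <- do.call(rbind, lapply(agg, function(g) {
    is_decoy <- all(g$is_decoy)
    is_mut <- any(g$covers) && !any(g$is_reference)
    mo <- if (is_mut) g$mut_off[which(g$covers)[1]] else NA_integer_
    data.frame(sequence = g$sequence[1], is_decoy = is_decoy,
               is_mutant = is_mut, mut_offset_in_peptide = mo,
               entry_ids = paste(sort(unique(g$entry_id)), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(base) <- NULL
  rows <- vector("list", nrow(base))
  for (j in seq_len(nrow(base))) {
    vars <- enumerate_ox_variants(base$sequence[j], max_ox = max_ox)
    rows[[j]] <- data.frame(
      sequence = base$sequence[j],
      ox = vapply(vars, paste, "", collapse = ","),
      mass = vapply(vars, function(v) peptide_mass(base$sequence[j], v), 0),
      is_decoy = base$is_decoy[j], is_mutant = base$is_mutant[j],
      mut_offset_in_peptide = base$mut_offset_in_peptide[j],
      entry_ids = base$entry_ids[j], stringsAsFactors = FALSE)
  }
  idx <- do.call(rbind, rows)
  idx <- idx[order(idx$mass, idx$sequence, idx$ox), , drop = FALSE]
  rownames(idx) <- NULL
  idx
}

parse_ox <- function(ox_string) {
  if (is.na(ox_string) || ox_string == "") return(integer(0))
  as.integer(strsplit(ox_string, ",", fixed = TRUE)[[1]])
}

#' Search spectra against a personalized database
#'
#' For each spectrum, all indexed peptides whose theoretical precursor m/z
#' at the spectrum's charge lies within the ppm tolerance are scored, and
#' the best-scoring candidate is retained (top-1). Ties break toward
#' targets, then fewer modifications, then lexicographic sequence.
#'
#' @param spectra list of `spectrum` objects (precursor charge required,
#'   charges outside `charges` are skipped as unidentified).
#' @param db a `personalized_db`, or a prebuilt index from
#'   [index_database()].
#' @param precursor_tol_ppm precursor tolerance (default 10 ppm).
#' @param frag_tol fragment tolerance in Da (default 0.6).
#' @param charges admissible precursor charges (default 2:5).
#' @param frag_charges theoretical fragment charges (default 1).
#' @param ... digestion/indexing parameters passed to [index_database()].
#' @return data.frame of PSMs: spectrum_id, peptide, ox, charge, score,
#'   n_matched, is_decoy, is_mutant, mut_offset_in_peptide, entry_ids,
#'   site_supported.
#' @export
search_spectra <- function(spectra, db, precursor_tol_ppm = 10,
                           frag_tol = 0.6, charges = 2:5, frag_charges = 1,
                           ...) {
  idx <- if (is.data.frame(db)) db else index_database(db, ...)
  psms <- vector("list", length(spectra))
  for (si in seq_along(spectra)) {
    sp <- spectra[[si]]
    z <- sp$charge
    if (is.null(z) || !z %in% charges) next
    obs_mz <- sp$pepmass
    cand_mz <- (idx$mass + z * PROTON_MASS) / z
    lo <- findInterval(obs_mz * (1 - 2 * precursor_tol_ppm * 1e-6),
                       cand_mz) + 1L
    hi <- findInterval(obs_mz * (1 + 2 * precursor_tol_ppm * 1e-6), cand_mz)
    if (hi < lo) next
    sel <- lo:hi
    sel <- sel[abs(obs_mz - cand_mz[sel]) / cand_mz[sel] * 1e6 <=
                 precursor_tol_ppm]
    if (length(sel) == 0) next
    # deterministic preference on score ties: target < decoy, fewer mods,
    # then lexicographic sequence
    rank_key <- function(ci, score) {
      list(score = score, decoy = idx$is_decoy[ci],
           nox = length(parse_ox(idx$ox[ci])), seq = idx$sequence[ci])
    }
    beats <- function(a, b) {
      if (a$score != b$score) return(a$score > b$score)
      if (a$decoy != b$decoy) return(!a$decoy)
      if (a$nox != b$nox) return(a$nox < b$nox)
      a$seq < b$seq
    }
    best <- NULL
    best_key <- NULL
    for (ci in sel) {
      ox <- parse_ox(idx$ox[ci])
      sc <- score_psm(idx$sequence[ci], sp, ox = ox, frag_tol = frag_tol,
                      frag_charges = frag_charges)
      key <- rank_key(ci, sc$score)
      if (is.null(best) || beats(key, best_key)) {
        best <- list(ci = ci, score = sc$score, matched = sc$matched)
        best_key <- key
      }
    }
    ci <- best$ci
    n <- nchar(idx$sequence[ci])
    supported <- if (idx$is_mutant[ci]) {
      site_supported(best$matched, n, idx$mut_offset_in_peptide[ci])
    } else NA
    psms[[si]] <- data.frame(
      spectrum_id = sp$id %||% as.character(si),
      peptide = idx$sequence[ci], ox = idx$ox[ci], charge = z,
      score = best$score, n_matched = nrow(best$matched),
      is_decoy = idx$is_decoy[ci], is_mutant = idx$is_mutant[ci],
      mut_offset_in_peptide = idx$mut_offset_in_peptide[ci],
      entry_ids = idx$entry_ids[ci], site_supported = supported,
      stringsAsFactors = FALSE)
  }
  psms <- psms[!vapply(psms, is.null, TRUE)]
  if (length(psms) == 0) {
    return(data.frame(spectrum_id = character(), peptide = character(),
                      ox = character(), charge = integer(), score = numeric(),
                      n_matched = integer(), is_decoy = logical(),
                      is_mutant = logical(),
                      mut_offset_in_peptide = integer(),
                      entry_ids = character(), site_supported = logical(),
                      q_value = numeric()))
  }
  do.call(rbind, psms)
}

#' Target-decoy q-values
#'
#' FDR at score threshold s is `#decoys(score >= s) / max(1, #targets(score
#' >= s))`; the q-value of a PSM is the running minimum of FDR over all
#' thresholds at or below its score (so q is monotone non-decreasing as
#' score decreases).
#'
#' @param psms PSM data.frame with `score` and `is_decoy`.
#' @return the PSMs with a `q_value` column appended (input order kept).
#' @export
estimate_qvalues <- function(psms) {
  if (nrow(psms) == 0) {
    psms$q_value <- numeric(0)
    return(psms)
  }
  s_levels <- sort(unique(psms$score), decreasing = TRUE)
  d_cum <- cumsum(vapply(s_levels, function(s)
    sum(psms$is_decoy & psms$score == s), 0))
  t_cum <- cumsum(vapply(s_levels, function(s)
    sum(!psms$is_decoy & psms$score == s), 0))
  fdr <- d_cum / pmax(1, t_cum)
  q_at_level <- rev(cummin(rev(fdr)))
  psms$q_value <- q_at_level[match(psms$score, s_levels)]
  psms
}

#' Filter PSMs at a q-value threshold
#'
#' @param psms PSMs with `q_value` (see [estimate_qvalues()]).
#' @param q_max q-value threshold (default 0.01).
#' @param targets_only drop decoy PSMs (default TRUE).
#' @param require_site keep mutant PSMs only when site-supported.
#' @return filtered PSM data.frame.
#' @export
filter_psms <- function(psms, q_max = 0.01, targets_only = TRUE,
                        require_site = FALSE) {
  keep <- psms$q_value <= q_max
  if (targets_only) keep <- keep & !psms$is_decoy
  if (require_site) {
    keep <- keep & (!psms$is_mutant | psms$site_supported %in% TRUE)
  }
  psms[keep, , drop = FALSE]
}

#' Site-determining fragment ions of a mutant peptide
#'
#' Fragment ions whose mass depends on the mutated residue: b ions with
#' index >= the mutation offset and y ions covering it from the C-terminal
#' side, both capped at the maximal fragment index n-1.
#'
#' @param n peptide length.
#' @param mut_offset 1-based mutation offset within the peptide.
#' @return data.frame (series, index).
#' @export
site_determining_ions <- function(n, mut_offset) {
  if (is.na(mut_offset) || mut_offset < 1 || mut_offset > n) {
    stop("mutation offset outside the peptide")
  }
  b_idx <- if (mut_offset <= n - 1L) seq.int(mut_offset, n - 1L) else integer(0)
  y_lo <- n - mut_offset + 1L
  y_idx <- if (y_lo <= n - 1L) seq.int(y_lo, n - 1L) else integer(0)
  rbind(
    if (length(b_idx)) data.frame(series = "b", index = b_idx) else NULL,
    if (length(y_idx)) data.frame(series = "y", index = y_idx) else NULL)
}

#' Is a mutant PSM supported at the mutation site?
#'
#' Default mode: at least one matched fragment is site-determining. Strict
#' mode additionally requires the matched b/y ladder to cover every backbone
#' junction of the peptide (full sequence coverage).
#'
#' @param matched matched-fragment data.frame (series, index columns).
#' @param n peptide length.
#' @param mut_offset mutation offset within the peptide.
#' @param strict require full ladder coverage as well.
#' @return logical.
#' @export
site_supported <- function(matched, n, mut_offset, strict = FALSE) {
  sdi <- site_determining_ions(n, mut_offset)
  key <- paste(matched$series, matched$index)
  hit <- any(paste(sdi$series, sdi$index) %in% key)
  if (!strict) return(hit)
  junctions <- vapply(seq_len(n - 1L), function(i) {
    paste("b", i) %in% key || paste("y", n - i) %in% key
  }, TRUE)
  hit && all(junctions)
}

#' Binned cosine similarity of two spectra
#'
#' Intensities are square-root transformed, peaks are binned at the fragment
#' tolerance, and the normalized dot product is returned. Symmetric in its
#' arguments. An empty spectrum yields 0 with attribute `empty = TRUE`.
#'
#' @param spec_a,spec_b `spectrum` objects.
#' @param bin bin width in Da (default 0.6, the fragment tolerance).
#' @return cosine in `[0, 1]`.
#' @export
spectral_similarity <- function(spec_a, spec_b, bin = 0.6) {
  if (length(spec_a$mz) == 0 || length(spec_b$mz) == 0) {
    out <- 0
    attr(out, "empty") <- TRUE
    return(out)
  }
  key_a <- floor(spec_a$mz / bin)
  key_b <- floor(spec_b$mz / bin)
  va <- tapply(sqrt(spec_a$intensity), key_a, sum)
  vb <- tapply(sqrt(spec_b$intensity), key_b, sum)
  keys <- union(names(va), names(vb))
  a <- ifelse(keys %in% names(va), va[keys], 0)
  b <- ifelse(keys %in% names(vb), vb[keys], 0)
  denom <- sqrt(sum(a^2) * sum(b^2))
  if (denom == 0) return(0)
  max(0, min(1, sum(a * b) / denom))
}
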