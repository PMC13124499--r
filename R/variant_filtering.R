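#' Somatic variant filtering
#'
#' Applies the four somatic-mutation filter criteria to a tumor/normal
#' variant table: (i) variant reads in tumor > 3, (ii) variant reads in
#' normal < 3, (iii) tumor variant allele frequency > 0.05, and (iv) the
#' variant does not fall in a simple repeat. All four comparisons are strict;
#' boundary values (tumor_alt = 3, normal_alt = 3, VAF = 0.05) fail.
#'
#' @param variants data.frame of variant calls, one row per variant, with at
#'   least columns `tumor_alt`, `tumor_depth`, `normal_alt`, `normal_depth`,
#'   `simple_repeat` (logical). Extra columns are carried through.
#' @param thresholds named list overriding the defaults
#'   `list(tumor_alt_min = 3, normal_alt_max = 3, vaf_min = 0.05)`; the
#'   comparisons remain strict (`>` / `<` / `>`).
#' @return The input data.frame with columns appended: `vaf_tumor` (tumor
#'   alt reads / tumor depth, 0 when depth is 0), `zero_depth` (logical flag
#'   for tumor depth 0), `failed_clauses` (comma-separated subset of
#'   `"i","ii","iii","iv"`, empty string when passing) and `passed`.
#'   Row order is preserved and every input row appears exactly once.
#' @export
apply_somatic_filters <- function(variants,
                                  thresholds = list(tumor_alt_min = 3,
                                                    normal_alt_max = 3,
                                                    vaf_min = 0.05)) {
  stopifnot(is.data.frame(variants))
  req <- c("tumor_alt", "tumor_depth", "normal_alt", "normal_depth",
           "simple_repeat")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols) > 0) {
    stop("variant table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  validate_variant_counts(variants)

  n <- nrow(variants)
  zero_depth <- variants$tumor_depth == 0
  vaf <- ifelse(zero_depth, 0, variants$tumor_alt / pmax(1L, variants$tumor_depth))
  vaf[!zero_depth] <- variants$tumor_alt[!zero_depth] /
    variants$tumor_depth[!zero_depth]

  fail_i <- !(variants$tumor_alt > thresholds$tumor_alt_min)
  fail_ii <- !(variants$normal_alt < thresholds$normal_alt_max)
  fail_iii <- !(vaf > thresholds$vaf_min) # zero depth => vaf 0 => fails
  fail_iv <- as.logical(variants$simple_repeat)

  failed <- character(n)
  for (j in seq_len(n)) {
    cl <- c("i", "ii", "iii", "iv")[c(fail_i[j], fail_ii[j], fail_iii[j],
                                      fail_iv[j])]
    failed[j] <- paste(cl, collapse = ",")
  }

  out <- variants
  out$vaf_tumor <- vaf
  out$zero_depth <- zero_depth
  out$failed_clauses <- failed
  out$passed <- failed == ""
  out
}

validate_variant_counts <- function(variants) {
  bad <- which(variants$tumor_alt > variants$tumor_depth |
                 variants$normal_alt > variants$normal_depth |
                 variants$tumor_alt < 0 | variants$normal_alt < 0)
  if (length(bad) > 0) {
    stop("alt reads exceed total reads (or are negative) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(TRUE)
}

.VARIANT_TSV_COLS <- c("accession", "gene", "type", "cds_pos", "protein_pos",
                       "ref_aa", "alt_aa", "ref_base", "alt_base",
                       "tumor_alt", "tumor_depth", "normal_alt",
                       "normal_depth", "simple_repeat")

#' Read a somatic variant table
#'
#' Two dialects are supported: the package's TSV layout (columns listed in
#' the simulator docs; `.` encodes an empty allele string for indels) and a
#' minimal VCF in which INFO carries the protein-level annotation
#' (`ACC,GENE,TYPE,CDSPOS,PPOS,RAA,AAA,SRPT`) and the TUMOR/NORMAL sample
#' columns carry `AD` ref,alt allelic depths.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"vcf-min"`.
#' @return data.frame of variant calls (one row per record).
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf-min")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  v <- if (dialect == "tsv") read_variant_tsv(path) else read_variant_vcf(path)
  if (nrow(v) > 0) validate_variant_counts(v)
  v
}

read_variant_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = list(ref_aa = "character",
                                            alt_aa = "character",
                                            ref_base = "character",
                                            alt_base = "character"))
  missing_cols <- setdiff(.VARIANT_TSV_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("variant TSV missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("ref_aa", "alt_aa", "ref_base", "alt_base")) {
    df[[col]][is.na(df[[col]]) | df[[col]] == "."] <- ""
  }
  df$simple_repeat <- as.logical(df$simple_repeat)
  df
}

#' Write a somatic variant table as TSV
#'
#' @param variants data.frame of variant calls.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  df <- variants[, intersect(c(.VARIANT_TSV_COLS, "variant_id"),
                             names(variants)), drop = FALSE]
  for (col in c("ref_aa", "alt_aa", "ref_base", "alt_base")) {
    df[[col]][df[[col]] == ""] <- "."
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write variants as a minimal VCF
#'
#' Protein-level annotation travels in INFO; tumor and normal allelic depths
#' travel as `AD` in the TUMOR and NORMAL sample columns. Genomic
#' coordinates are not modeled: CHROM is the accession and POS the CDS
#' position.
#'
#' @param variants data.frame of variant calls.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ACC,Number=1,Type=String,Description=\"Protein accession\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"missense|frameshift\">",
    "##INFO=<ID=CDSPOS,Number=1,Type=Integer,Description=\"1-based CDS position\">",
    "##INFO=<ID=PPOS,Number=1,Type=Integer,Description=\"1-based protein position\">",
    "##INFO=<ID=RAA,Number=1,Type=String,Description=\"Reference residue\">",
    "##INFO=<ID=AAA,Number=1,Type=String,Description=\"Alternate residue\">",
    "##INFO=<ID=SRPT,Number=0,Type=Flag,Description=\"Simple repeat\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR\tNORMAL"
  ), con)
  for (j in seq_len(nrow(variants))) {
    v <- variants[j, ]
    ref <- if (nzchar(v$ref_base)) v$ref_base else "N"
    alt <- if (nzchar(v$alt_base)) v$alt_base else "N"
    info <- sprintf("ACC=%s;GENE=%s;TYPE=%s;CDSPOS=%d;PPOS=%d;RAA=%s;AAA=%s",
                    v$accession, v$gene, v$type, v$cds_pos, v$protein_pos,
                    ifelse(nzchar(v$ref_aa), v$ref_aa, "."),
                    ifelse(nzchar(v$alt_aa), v$alt_aa, "."))
    if (isTRUE(v$simple_repeat)) info <- paste0(info, ";SRPT")
    writeLines(sprintf(
      "%s\t%d\t.\t%s\t%s\t.\t.\t%s\tAD\t%d,%d\t%d,%d",
      v$accession, v$cds_pos, ref, alt, info,
      v$tumor_depth - v$tumor_alt, v$tumor_alt,
      v$normal_depth - v$normal_alt, v$normal_alt), con)
  }
  invisible(path)
}

read_variant_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    return(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(.VARIANT_TSV_COLS))),
      .VARIANT_TSV_COLS))
  }
  parse_info <- function(info) {
    kv <- strsplit(strsplit(info, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    out <- list(SRPT = FALSE)
    for (p in kv) {
      if (length(p) == 2) out[[p[1]]] <- p[2] else out[[p[1]]] <- TRUE
    }
    out
  }
  rows <- lapply(seq_along(body), function(k) {
    f <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) stop("malformed minimal-VCF record at data line ", k)
    info <- parse_info(f[8])
    ad_t <- as.integer(strsplit(f[10], ",", fixed = TRUE)[[1]])
    ad_n <- as.integer(strsplit(f[11], ",", fixed = TRUE)[[1]])
    dot <- function(x) if (is.null(x) || identical(x, ".")) "" else x
    data.frame(
      accession = info$ACC, gene = info$GENE, type = info$TYPE,
      cds_pos = as.integer(info$CDSPOS), protein_pos = as.integer(info$PPOS),
      ref_aa = dot(info$RAA), alt_aa = dot(info$AAA),
      ref_base = if (f[4] == "N") "" else f[4],
      alt_base = if (f[5] == "N") "" else f[5],
      tumor_alt = ad_t[2], tumor_depth = sum(ad_t),
      normal_alt = ad_n[2], normal_depth = sum(ad_n),
      simple_repeat = isTRUE(info$SRPT),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
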