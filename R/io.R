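## Readers and writers for the tabular interchange formats.
##
## All coordinates are 1-based inclusive throughout the package (the
## array-CGH / cytogenomic convention). Missing population annotations
## (gnomAD MAF, homozygote count, DGV frequency) are a distinct "absent"
## state, never imputed as zero: the filtering rules treat "not annotated"
## as a pass.

emptyCnvTable <- function() {
  data.frame(patient_id = character(), chrom = character(),
             start = integer(), end = integer(), copy_state = character(),
             copy_number = integer(), inheritance = character(),
             prior_class = character(), dgv_frequency = numeric(),
             band_start = character(), band_end = character(),
             size_bp = integer(), stringsAsFactors = FALSE)
}

emptyGeneTable <- function() {
  data.frame(symbol = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), sfari_member = logical(),
             sfari_score = character(), function_tags = character(),
             family_name = character(), brain_expression_pct = numeric(),
             haploinsufficient = logical(), triplosensitive = logical(),
             stringsAsFactors = FALSE)
}

emptyArrayQcTable <- function() {
  data.frame(patient_id = character(), sd = numeric(),
             dlr_spread = numeric(), stringsAsFactors = FALSE)
}

#' Read a 6-column PED pedigree
#'
#' Standard whitespace-delimited pedigree: family id, individual id, father
#' id, mother id, sex (1 male / 2 female / 0 unknown), phenotype
#' (2 affected / 1 unaffected / 0 or -9 unknown). `0` parent ids become
#' missing. A `trio_complete` flag is computed per member: both parents
#' present as rows of the same family. Affected members with incomplete
#' trios draw a warning, since triage is trio-based.
#'
#' @param path PED file.
#' @return data.frame with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex`, `affected`, `trio_complete`.
#' @examples
#' ped <- file.path(tempdir(), "ex.ped")
#' writeLines("F1 P1 D1 M1 1 2\nF1 D1 0 0 1 1\nF1 M1 0 0 2 1", ped)
#' readPedigree(ped)
#' @export
readPedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(family_id = character(), individual_id = character(),
                      father_id = character(), mother_id = character(),
                      sex = character(), affected = character(),
                      trio_complete = logical(), stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) != 6L)
  if (length(bad))
    stop(sprintf("malformed pedigree row at line %d of '%s': expected 6 columns, found %d",
                 bad[1L], path, lengths(fields)[bad[1L]]), call. = FALSE)
  m <- do.call(rbind, fields)
  ped <- data.frame(family_id = m[, 1L], individual_id = m[, 2L],
                    father_id = ifelse(m[, 3L] == "0", NA_character_, m[, 3L]),
                    mother_id = ifelse(m[, 4L] == "0", NA_character_, m[, 4L]),
                    sex = c("1" = "male", "2" = "female")[m[, 5L]],
                    affected = c("2" = "affected", "1" = "unaffected")[m[, 6L]],
                    stringsAsFactors = FALSE)
  ped$sex[is.na(ped$sex)] <- "unknown"
  ped$affected[is.na(ped$affected)] <- "unknown"
  key <- paste(ped$family_id, ped$individual_id)
  if (anyDuplicated(key))
    stop("duplicate individual_id within family: ",
         key[duplicated(key)][1L], call. = FALSE)
  ped$trio_complete <- vapply(seq_len(nrow(ped)), function(i) {
    fam <- ped$individual_id[ped$family_id == ped$family_id[i]]
    !is.na(ped$father_id[i]) && !is.na(ped$mother_id[i]) &&
      ped$father_id[i] %in% fam && ped$mother_id[i] %in% fam
  }, logical(1))
  incomplete <- ped$affected == "affected" & !ped$trio_complete
  if (any(incomplete))
    warning("affected member(s) without a complete trio: ",
            paste(ped$individual_id[incomplete], collapse = ", "),
            call. = FALSE)
  ped
}

VARIANT_COLUMNS <- c("patient_id", "family_id", "gene", "hgvs_c", "chrom",
                     "pos", "ref", "alt", "consequence", "zygosity",
                     "inheritance", "cadd", "acmg", "gnomad_maf",
                     "gnomad_hom", "coverage", "gq")

#' Read an annotated sequence-variant table
#'
#' Tab-separated with a header row; expected columns are documented under
#' External formats in the package vignette (`patient_id`, `family_id`,
#' `gene`, `hgvs_c`, `chrom`, `pos`, `ref`, `alt`, `consequence`,
#' `zygosity`, `inheritance`, `cadd`, `acmg`, `gnomad_maf`, `gnomad_hom`,
#' `coverage`, `gq`). Empty gnomAD fields are parsed as absent (`NA`), not
#' zero. Unknown enum tokens and non-numeric scores raise located errors.
#'
#' @param path TSV file.
#' @return validated data.frame, one row per variant call.
#' @export
readVariantTable <- function(path) {
  if (!file.exists(path)) stop("variant table not found: ", path)
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(VARIANT_COLUMNS, names(df))
  if (length(miss))
    stop("variant table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  validateVariantTable(df, path)
}

validateVariantTable <- function(df, file = "<in-memory>") {
  out <- data.frame(patient_id = df$patient_id, family_id = df$family_id,
                    gene = df$gene, hgvs_c = df$hgvs_c, chrom = df$chrom,
                    stringsAsFactors = FALSE)
  out$pos <- as.integer(parseNum(df$pos, file, "pos"))
  out$ref <- blankToNA(df$ref)
  out$alt <- blankToNA(df$alt)
  out$consequence <- parseEnum(df$consequence, CONSEQUENCES, file, "consequence")
  out$zygosity <- parseEnum(df$zygosity, ZYGOSITIES, file, "zygosity")
  out$inheritance <- parseEnum(df$inheritance, INHERITANCES, file, "inheritance")
  out$cadd <- parseNum(df$cadd, file, "cadd")
  if (anyNA(out$cadd))
    stopAt(file, which(is.na(out$cadd))[1L], "cadd", "cadd is required")
  if (any(!is.finite(out$cadd) | out$cadd < 0))
    stopAt(file, which(!is.finite(out$cadd) | out$cadd < 0)[1L], "cadd",
           "cadd must be finite and non-negative")
  out$acmg <- parseEnum(df$acmg, ACMG_CLASSES, file, "acmg")
  if (anyNA(out$acmg))
    stopAt(file, which(is.na(out$acmg))[1L], "acmg", "acmg is required")
  out$gnomad_maf <- parseNum(df$gnomad_maf, file, "gnomad_maf")
  if (any(!is.na(out$gnomad_maf) & (out$gnomad_maf < 0 | out$gnomad_maf > 1)))
    stopAt(file, which(out$gnomad_maf < 0 | out$gnomad_maf > 1)[1L],
           "gnomad_maf", "gnomad_maf must lie in [0, 1]")
  out$gnomad_hom <- as.integer(parseNum(df$gnomad_hom, file, "gnomad_hom"))
  if (any(!is.na(out$gnomad_hom) & out$gnomad_hom < 0))
    stopAt(file, which(out$gnomad_hom < 0)[1L], "gnomad_hom",
           "gnomad_hom must be >= 0")
  out$coverage <- as.integer(parseNum(df$coverage, file, "coverage"))
  out$gq <- as.integer(parseNum(df$gq, file, "gq"))
  out
}

CNV_COLUMNS <- c("patient_id", "chrom", "start", "end", "copy_state",
                 "copy_number", "inheritance", "prior_class",
                 "dgv_frequency", "band_start", "band_end")

#' Read an array-CGH CNV call table
#'
#' Tab-separated; coordinates 1-based inclusive. `size_bp` is recomputed as
#' `end - start + 1` and checked against any provided `size_bp` column.
#' Empty `dgv_frequency` parses as absent.
#'
#' @param path TSV file.
#' @return validated data.frame, one row per CNV call, with `size_bp`.
#' @export
readCnvTable <- function(path) {
  if (!file.exists(path)) stop("CNV table not found: ", path)
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(CNV_COLUMNS, names(df))
  if (length(miss))
    stop("CNV table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  validateCnvTable(df, path)
}

validateCnvTable <- function(df, file = "<in-memory>") {
  out <- data.frame(patient_id = df$patient_id, chrom = df$chrom,
                    stringsAsFactors = FALSE)
  out$start <- as.integer(parseNum(df$start, file, "start"))
  out$end <- as.integer(parseNum(df$end, file, "end"))
  bad <- which(out$start > out$end)
  if (length(bad))
    stopAt(file, bad[1L], "start", "CNV start exceeds end")
  out$copy_state <- parseEnum(df$copy_state, COPY_STATES, file, "copy_state")
  out$copy_number <- as.integer(parseNum(df$copy_number, file, "copy_number"))
  out$inheritance <- parseEnum(df$inheritance,
                               c("de_novo", "maternal", "paternal", "unknown"),
                               file, "inheritance")
  out$prior_class <- parseEnum(df$prior_class, ACMG_CLASSES, file, "prior_class")
  out$dgv_frequency <- parseNum(df$dgv_frequency, file, "dgv_frequency")
  out$band_start <- blankToNA(df$band_start)
  out$band_end <- blankToNA(df$band_end)
  out$size_bp <- out$end - out$start + 1L
  if ("size_bp" %in% names(df)) {
    given <- as.integer(parseNum(df$size_bp, file, "size_bp"))
    bad <- which(!is.na(given) & given != out$size_bp)
    if (length(bad))
      stopAt(file, bad[1L], "size_bp",
             sprintf("declared size %d disagrees with end - start + 1 = %d",
                     given[bad[1L]], out$size_bp[bad[1L]]))
  }
  out
}

GENE_COLUMNS <- c("symbol", "chrom", "start", "end", "strand", "sfari_member",
                  "sfari_score", "function_tags", "family_name",
                  "brain_expression_pct", "haploinsufficient",
                  "triplosensitive")

#' Read a gene-metadata table
#'
#' One row per gene symbol; `function_tags` is a semicolon-separated tag
#' set; `sfari_score` one of 1, 2, 2B, 3, S or none (2B ranks as tier 2).
#' Duplicate symbols are an error. Genes queried downstream but absent
#' from the table are treated as non-SFARI with empty tags (with a logged
#' message), per the documented fallback.
#'
#' @param path TSV file.
#' @return validated data.frame keyed by `symbol`.
#' @export
readGeneTable <- function(path) {
  if (!file.exists(path)) stop("gene table not found: ", path)
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(GENE_COLUMNS, names(df))
  if (length(miss))
    stop("gene table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  validateGeneTable(df, path)
}

parseLogical <- function(x, file, col) {
  x <- tolower(blankToNA(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stopAt(file, bad[1L], col, sprintf("unknown logical token '%s'", x[bad[1L]]))
  out
}

validateGeneTable <- function(df, file = "<in-memory>") {
  if (anyDuplicated(df$symbol))
    stopAt(file, which(duplicated(df$symbol))[1L], "symbol",
           sprintf("duplicate gene symbol '%s'",
                   df$symbol[duplicated(df$symbol)][1L]))
  out <- data.frame(symbol = df$symbol, chrom = df$chrom,
                    stringsAsFactors = FALSE)
  out$start <- as.integer(parseNum(df$start, file, "start"))
  out$end <- as.integer(parseNum(df$end, file, "end"))
  bad <- which(out$start > out$end)
  if (length(bad)) stopAt(file, bad[1L], "start", "gene start exceeds end")
  out$strand <- parseEnum(df$strand, c("+", "-", "unknown"), file, "strand")
  out$sfari_member <- parseLogical(df$sfari_member, file, "sfari_member")
  out$sfari_score <- parseEnum(df$sfari_score, SFARI_SCORES, file, "sfari_score")
  bad <- which(out$sfari_score != "none" & !out$sfari_member)
  if (length(bad))
    stopAt(file, bad[1L], "sfari_score",
           "sfari_score set on a gene not flagged sfari_member")
  out$function_tags <- blankToNA(df$function_tags)
  out$function_tags[is.na(out$function_tags)] <- ""
  out$family_name <- blankToNA(df$family_name)
  out$brain_expression_pct <- parseNum(df$brain_expression_pct, file,
                                       "brain_expression_pct")
  out$haploinsufficient <- parseLogical(df$haploinsufficient, file,
                                        "haploinsufficient")
  out$triplosensitive <- parseLogical(df$triplosensitive, file,
                                      "triplosensitive")
  out
}

#' Read per-patient array QC metrics
#'
#' Columns `patient_id`, `sd`, `dlr_spread` (both finite, non-negative).
#'
#' @param path TSV file.
#' @return validated data.frame.
#' @export
readArrayQc <- function(path) {
  if (!file.exists(path)) stop("array QC table not found: ", path)
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("patient_id", "sd", "dlr_spread"), names(df))
  if (length(miss))
    stop("array QC table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- data.frame(patient_id = df$patient_id, stringsAsFactors = FALSE)
  out$sd <- parseNum(df$sd, file = path, col = "sd")
  out$dlr_spread <- parseNum(df$dlr_spread, file = path, col = "dlr_spread")
  if (any(!is.finite(out$sd) | !is.finite(out$dlr_spread)))
    stop("array QC metrics must be finite", call. = FALSE)
  out
}

#' Read a full cohort from a directory
#'
#' Convenience loader for the file set written by [writeCohort()]:
#' `trios.ped`, `variants.tsv`, `cnvs.tsv`, `genes.tsv`, `arrayqc.tsv`.
#' Missing optional files (`cnvs.tsv`, `genes.tsv`, `arrayqc.tsv`) yield
#' empty tables. Cross-table checks (hemizygous calls in female probands,
#' variant patients absent from the pedigree) are run on assembly.
#'
#' @param dir directory holding the cohort files.
#' @return a [TrioCohort-class].
#' @export
readCohort <- function(dir) {
  ped <- readPedigree(file.path(dir, "trios.ped"))
  v <- readVariantTable(file.path(dir, "variants.tsv"))
  cn <- if (file.exists(file.path(dir, "cnvs.tsv")))
    readCnvTable(file.path(dir, "cnvs.tsv")) else emptyCnvTable()
  g <- if (file.exists(file.path(dir, "genes.tsv")))
    readGeneTable(file.path(dir, "genes.tsv")) else emptyGeneTable()
  qc <- if (file.exists(file.path(dir, "arrayqc.tsv")))
    readArrayQc(file.path(dir, "arrayqc.tsv")) else emptyArrayQcTable()
  assembleCohort(ped, v, cn, g, qc)
}

assembleCohort <- function(ped, variants, cnvs, genes, qc) {
  sex <- ped$sex[match(variants$patient_id, ped$individual_id)]
  femHemi <- variants$zygosity == "hemizygous" & !is.na(sex) & sex == "female"
  if (any(femHemi))
    warning("hemizygous call(s) in female proband(s): ",
            paste(unique(variants$patient_id[femHemi]), collapse = ", "),
            call. = FALSE)
  TrioCohort(pedigree = ped, variants = variants, cnvs = cnvs,
             genes = genes, arrayQc = qc)
}

## deterministic row order for outputs
sortVariantRows <- function(df) {
  df[order(df$patient_id, df$gene, df$hgvs_c), , drop = FALSE]
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
}

#' Write a cohort to a directory
#'
#' Emits `trios.ped`, `variants.tsv`, `cnvs.tsv`, `genes.tsv` and
#' `arrayqc.tsv` in the dialects the readers accept; re-reading with
#' [readCohort()] reproduces the tables. Row order is deterministic.
#'
#' @param cohort a [TrioCohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- pedigree(cohort)
  pedOut <- data.frame(ped$family_id, ped$individual_id,
                       ifelse(is.na(ped$father_id), "0", ped$father_id),
                       ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                       c(male = "1", female = "2", unknown = "0")[ped$sex],
                       c(affected = "2", unaffected = "1", unknown = "0")[ped$affected])
  utils::write.table(pedOut, file.path(dir, "trios.ped"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeTsv(sortVariantRows(variantCalls(cohort)), file.path(dir, "variants.tsv"))
  cn <- cnvCalls(cohort)
  writeTsv(cn[order(cn$patient_id, cn$chrom, cn$start), , drop = FALSE],
           file.path(dir, "cnvs.tsv"))
  g <- geneMeta(cohort)
  writeTsv(g[order(g$symbol), , drop = FALSE], file.path(dir, "genes.tsv"))
  writeTsv(arrayQc(cohort), file.path(dir, "arrayqc.tsv"))
  invisible(dir)
}

#' Write triage results
#'
#' Writes `classified_variants.tsv`, `compound_pairs.tsv`,
#' `cnv_results.tsv`, `gene_overlaps.tsv`, `patient_findings.tsv` and
#' `summary.tsv` under `dir`. Column order is fixed and rows are sorted
#' (`patient_id`, `gene`, `hgvs_c`), so identical inputs give
#' byte-identical outputs. Rule traces are serialised as semicolon-joined
#' rule identifiers.
#'
#' @param result a [TriageResult-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeResults <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeTsv(sortVariantRows(classifiedVariants(result)),
           file.path(dir, "classified_variants.tsv"))
  pr <- compoundHetPairs(result)
  writeTsv(pr[order(pr$patient_id, pr$gene, pr$key_a, pr$key_b), , drop = FALSE],
           file.path(dir, "compound_pairs.tsv"))
  cn <- cnvResults(result)
  writeTsv(cn[order(cn$patient_id, cn$chrom, cn$start), , drop = FALSE],
           file.path(dir, "cnv_results.tsv"))
  ov <- geneOverlaps(result)
  writeTsv(ov[order(ov$patient_id, ov$cnv_key, ov$gene), , drop = FALSE],
           file.path(dir, "gene_overlaps.tsv"))
  fd <- patientFindings(result)
  writeTsv(fd[order(fd$patient_id), , drop = FALSE],
           file.path(dir, "patient_findings.tsv"))
  s <- cohortSummary(result)
  summaryDf <- data.frame(
    category = c(names(s@categoryCounts), "overall_detection_rate"),
    count = c(unname(s@categoryCounts), NA_integer_),
    rate_pct = c(unname(s@categoryRates), s@overallDetectionRate),
    stringsAsFactors = FALSE)
  writeTsv(summaryDf, file.path(dir, "summary.tsv"))
  invisible(dir)
}
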