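# shared fixtures, built in code

# one validated variant row with overridable fields
mkVariant <- function(patient_id = "A001", family_id = "F001",
                      gene = "GENE1", hgvs_c = "c.100G>A", chrom = "2",
                      pos = 100L, consequence = "missense",
                      zygosity = "heterozygous", inheritance = "de_novo",
                      cadd = 25, acmg = "VOUS", gnomad_maf = NA_real_,
                      gnomad_hom = NA_integer_, coverage = 60L, gq = 90L) {
  data.frame(patient_id = patient_id, family_id = family_id, gene = gene,
             hgvs_c = hgvs_c, chrom = chrom, pos = pos, ref = "G",
             alt = "A", consequence = consequence, zygosity = zygosity,
             inheritance = inheritance, cadd = cadd, acmg = acmg,
             gnomad_maf = gnomad_maf, gnomad_hom = as.integer(gnomad_hom),
             coverage = coverage, gq = gq, stringsAsFactors = FALSE)
}

mkGene <- function(symbol = "GENE1", chrom = "2", start = 1000L,
                   end = 5000L, strand = "+", sfari_member = TRUE,
                   sfari_score = "2",
                   function_tags = "neurodevelopment",
                   family_name = NA_character_,
                   brain_expression_pct = 80,
                   haploinsufficient = NA, triplosensitive = NA) {
  if (!sfari_member) sfari_score <- "none"
  data.frame(symbol = symbol, chrom = chrom, start = start, end = end,
             strand = strand, sfari_member = sfari_member,
             sfari_score = sfari_score, function_tags = function_tags,
             family_name = family_name,
             brain_expression_pct = brain_expression_pct,
             haploinsufficient = haploinsufficient,
             triplosensitive = triplosensitive, stringsAsFactors = FALSE)
}

mkCnv <- function(patient_id = "A001", chrom = "5", start = 1000L,
                  end = 2000L, copy_state = "loss",
                  copy_number = if (copy_state == "loss") 1L else 3L,
                  inheritance = "maternal", prior_class = "VOUS",
                  dgv_frequency = NA_real_, band_start = "5q11.1",
                  band_end = band_start) {
  data.frame(patient_id = patient_id, chrom = chrom, start = start,
             end = end, copy_state = copy_state, copy_number = copy_number,
             inheritance = inheritance, prior_class = prior_class,
             dgv_frequency = dgv_frequency, band_start = band_start,
             band_end = band_end, size_bp = end - start + 1L,
             stringsAsFactors = FALSE)
}

mkPed <- function(patient_ids, sex = "male", family_ids = NULL) {
  sex <- rep_len(sex, length(patient_ids))
  if (is.null(family_ids)) family_ids <- paste0("F", seq_along(patient_ids))
  rows <- lapply(seq_along(patient_ids), function(i) {
    p <- patient_ids[i]
    data.frame(family_id = family_ids[i],
               individual_id = c(paste0(p, "F"), paste0(p, "M"), p),
               father_id = c(NA, NA, paste0(p, "F")),
               mother_id = c(NA, NA, paste0(p, "M")),
               sex = c("male", "female", sex[i]),
               affected = c("unaffected", "unaffected", "affected"),
               trio_complete = c(FALSE, FALSE, TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# independent decision-table oracle for the classifier (restated from the
# published rule text, kept separate from the implementation path)
oracleClassify <- function(sfari, cadd, acmg, hom, tag) {
  absent <- is.na(hom)
  if (sfari) {
    if (cadd >= 20 && acmg %in% c("P", "LP") && (absent || hom <= 1))
      return("P")
    if (!absent && hom >= 2 && hom <= 10 && cadd >= 20 &&
        acmg %in% c("P", "LP", "VOUS") && tag)
      return("LP")
    if (cadd < 15 && acmg == "LB") return("LB")
    return("VOUS")
  }
  if (cadd >= 20 && acmg %in% c("P", "LP") && tag) return("LP")
  if (cadd < 15 && acmg %in% c("B", "LB", "VOUS")) return("LB")
  "VOUS"
}

# the full 720-cell discrete feature grid
classifierGrid <- function() {
  expand.grid(acmg = c("P", "LP", "VOUS", "LB", "B"),
              sfari = c(TRUE, FALSE), tag = c(TRUE, FALSE),
              hom = c(NA, 0L, 1L, 2L, 10L, 11L),
              cadd = c(10, 14.9, 15, 19.9, 20, 35),
              stringsAsFactors = FALSE)
}

# default 122-trio run, computed once per test session
defaultRunCache <- new.env(parent = emptyenv())
defaultRun <- function() {
  if (is.null(defaultRunCache$res)) {
    defaultRunCache$cohort <- simulateCohort(seed = 20240)
    defaultRunCache$res <- runTriage(defaultRunCache$cohort)
  }
  list(cohort = defaultRunCache$cohort, res = defaultRunCache$res)
}
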