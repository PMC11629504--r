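## Deterministic synthetic trio-cohort generator with planted truth.
##
## The generator emits a full input set (pedigree, variants, CNV calls,
## gene metadata, array QC) plus ground-truth tables stating, for every
## planted record, whether the pipeline must retain it, which class it
## must receive, and which tier each patient must reach. Because the rule
## engine is deterministic, the pipeline must recover 100% of the truth on
## any feasible plan; a mismatch is a pipeline bug.
##
## The default plan reproduces the composition of a 122-trio essential-ASD
## study cohort: tier strata {P: 4, LP: 34 (24 sequence / 8 CNV / 2 both),
## VOUS: 70 (54 / 3 / 13), none: 14}; 104 males / 18 females with 30 / 5
## array-positive; 46 retained CNVs (1 P, 11 LP, 34 VOUS; 16 losses, 30
## gains, 11 intragenic) in 35 patients; a private-variant set of 95 keys
## distributed {P: 2, LP: 24, VOUS: 61, LB: 8}; and noise records that
## must fall to each documented drop reason.

PLAN_ROLES <- c("pP_denovo", "pP_upgrade", "pP_sharedHemi",
                "pLP_seq_single", "pLP_seq_chet", "pLP_seq_nonsfari",
                "pLP_cnv", "pLP_both",
                "pVOUS_seq_single", "pVOUS_seq_sib3", "pVOUS_seq_rec2",
                "pVOUS_seq_rec3", "pVOUS_cnv", "pVOUS_both",
                "pNone_lb", "pNone_empty")

basePlanCounts <- function() {
  c(pP_denovo = 1L, pP_upgrade = 1L, pP_sharedHemi = 2L,
    pLP_seq_single = 20L, pLP_seq_chet = 2L, pLP_seq_nonsfari = 2L,
    pLP_cnv = 8L, pLP_both = 2L,
    pVOUS_seq_single = 46L, pVOUS_seq_sib3 = 3L, pVOUS_seq_rec2 = 2L,
    pVOUS_seq_rec3 = 3L, pVOUS_cnv = 3L, pVOUS_both = 13L,
    pNone_lb = 5L, pNone_empty = 9L)
}

#' Default cohort simulation plan
#'
#' Describes the per-patient branch composition the generator plants. At
#' the default `nPatients = 122` the plan encodes the study composition
#' documented in the package vignette; smaller cohorts are scaled
#' proportionally while keeping structured roles (sibling triples, shared
#' keys) intact. The plan also fixes the noise-record counts (each noise
#' branch violates exactly one retention predicate) and the CNV placement
#' extras.
#'
#' @param nPatients number of probands (>= 8).
#' @return a list with elements `counts` (named patient-role counts),
#'   `nFemales`, `noise` (named noise-record counts) and `extras` (CNV
#'   placement counts); pass to [simulateCohort()].
#' @export
defaultCohortPlan <- function(nPatients = 122L) {
  nPatients <- as.integer(nPatients)
  if (nPatients < 8L) stop("plan needs at least 8 probands", call. = FALSE)
  base <- basePlanCounts()
  if (nPatients == 122L) {
    counts <- base
  } else {
    f <- nPatients / 122
    counts <- as.integer(floor(base * f))
    names(counts) <- names(base)
    ## structured roles come in fixed block sizes
    counts["pP_sharedHemi"] <- if (counts["pP_sharedHemi"] >= 1L) 2L else 0L
    counts["pLP_both"] <- if (counts["pLP_both"] >= 1L) 2L else 0L
    counts["pVOUS_seq_sib3"] <- if (counts["pVOUS_seq_sib3"] >= 1L) 3L else 0L
    counts["pVOUS_seq_rec2"] <- if (counts["pVOUS_seq_rec2"] >= 1L) 2L else 0L
    counts["pVOUS_seq_rec3"] <- if (counts["pVOUS_seq_rec3"] >= 1L) 3L else 0L
    counts["pP_denovo"] <- max(1L, counts["pP_denovo"])
    diff <- nPatients - sum(counts)
    for (slot in c("pVOUS_seq_single", "pNone_empty", "pLP_seq_single")) {
      move <- if (diff >= 0L) diff else max(diff, -counts[slot])
      counts[slot] <- counts[slot] + move
      diff <- diff - move
      if (diff == 0L) break
    }
    if (diff != 0L)
      stop("infeasible branch plan for nPatients = ", nPatients,
           call. = FALSE)
  }
  f <- nPatients / 122
  noise <- c(synonymous = 40L, inherited_het = 40L, qc_coverage = 5L,
             qc_gq = 5L, qc_maf = 5L, hom_gt_max = 8L,
             gene_filter = 15L, cnv_lb = 6L, cnv_b = 2L, cnv_dgv = 4L)
  if (nPatients != 122L)
    noise[] <- pmax(1L, as.integer(round(noise * f)))
  extras <- c(vousCnvCoOccur = min(4L, counts[["pLP_cnv"]]),
              vousCnvOnLpSeq = min(7L, counts[["pLP_seq_single"]]),
              vousCnvSecond = min(7L, counts[["pVOUS_both"]]))
  nFemales <- min(as.integer(round(18 * f)),
                  counts[["pVOUS_both"]] + counts[["pVOUS_seq_single"]] +
                    counts[["pNone_lb"]] + counts[["pNone_empty"]])
  list(nPatients = nPatients, counts = counts, nFemales = nFemales,
       noise = noise, extras = extras)
}

validatePlan <- function(plan) {
  counts <- plan$counts
  if (!all(PLAN_ROLES %in% names(counts)))
    stop("branch plan lacks role(s): ",
         paste(setdiff(PLAN_ROLES, names(counts)), collapse = ", "),
         call. = FALSE)
  if (any(counts < 0L) || any(plan$noise < 0L))
    stop("infeasible branch plan: negative count", call. = FALSE)
  if (sum(counts) != plan$nPatients)
    stop("infeasible branch plan: role counts sum to ", sum(counts),
         ", not nPatients = ", plan$nPatients, call. = FALSE)
  if (counts[["pP_sharedHemi"]] %in% c(0L, 2L) == FALSE)
    stop("pP_sharedHemi must be 0 or 2", call. = FALSE)
  if (counts[["pVOUS_seq_sib3"]] %in% c(0L, 3L) == FALSE)
    stop("pVOUS_seq_sib3 must be 0 or 3", call. = FALSE)
  if (plan$extras[["vousCnvCoOccur"]] > counts[["pLP_cnv"]] ||
      plan$extras[["vousCnvOnLpSeq"]] > counts[["pLP_seq_single"]] ||
      plan$extras[["vousCnvSecond"]] > counts[["pVOUS_both"]])
    stop("infeasible branch plan: CNV extras exceed hosting roles",
         call. = FALSE)
  invisible(plan)
}

## annotation recipe forcing a member class under the default thresholds
memberRecipe <- function(class) {
  switch(class,
         P = list(cadd = round(stats::runif(1, 20, 45), 1),
                  acmg = sample(c("P", "LP"), 1),
                  hom = sample(c(NA_integer_, 0L, 1L), 1)),
         LP = list(cadd = round(stats::runif(1, 20, 45), 1),
                   acmg = sample(c("VOUS", "LP"), 1),
                   hom = sample(2:10, 1)),
         VOUS = list(cadd = round(stats::runif(1, 15.5, 19.5), 1),
                     acmg = "VOUS",
                     hom = sample(0:5, 1)),
         LB = list(cadd = round(stats::runif(1, 1, 14.5), 1),
                   acmg = "LB",
                   hom = sample(0:5, 1)),
         stop("no generator recipe reaches member class ", class,
              call. = FALSE))
}

#' Plant a compound-heterozygote pair
#'
#' Emits two heterozygous variant rows in the same gene with distinct
#' parental origins and annotations forcing the requested member classes,
#' plus the expected pair-level class under the default combination
#' matrix. Refuses identical origins (trio phasing cannot place two
#' same-parent variants in trans) and member classes no recipe reaches
#' (`B` is excluded before pairing).
#'
#' @param patient_id,family_id proband identifiers.
#' @param gene gene symbol (must be SFARI with a criterion-4 tag in the
#'   metadata for the recipes to classify as planted).
#' @param chrom,basePos placement of the two variants (`basePos` and
#'   `basePos + 60`).
#' @param class_pair length-2 character: intended member classes.
#' @param origins length-2 character: distinct origins among
#'   maternal / paternal / de_novo.
#' @return list with `variants` (two validated rows) and `pair_class`.
#' @export
plantCompoundHet <- function(patient_id, family_id, gene, chrom = "2",
                             basePos = 1000L,
                             class_pair = c("LP", "VOUS"),
                             origins = c("maternal", "paternal")) {
  if (length(origins) != 2L || origins[1] == origins[2])
    stop("compound-het members need two distinct parental origins",
         call. = FALSE)
  if (!all(origins %in% c("maternal", "paternal", "de_novo")))
    stop("origins must be maternal, paternal or de_novo", call. = FALSE)
  rows <- lapply(1:2, function(i) {
    r <- memberRecipe(class_pair[i])
    pos <- basePos + (i - 1L) * 60L
    data.frame(patient_id = patient_id, family_id = family_id, gene = gene,
               hgvs_c = sprintf("c.%dG>A", pos), chrom = chrom, pos = pos,
               ref = "G", alt = "A", consequence = "missense",
               zygosity = "heterozygous", inheritance = origins[i],
               cadd = r$cadd, acmg = r$acmg, gnomad_maf = NA_real_,
               gnomad_hom = r$hom,
               coverage = sample(30:120, 1), gq = sample(50:99, 1),
               stringsAsFactors = FALSE)
  })
  list(variants = do.call(rbind, rows),
       pair_class = combineCompoundHet(class_pair[1], class_pair[2],
                                       triageConfig()))
}

#' Generate a synthetic trio cohort with planted truth
#'
#' Deterministically materialises the branch plan into a fully valid
#' cohort: one trio per proband (one family hosts the sibling triple),
#' annotated variants spanning every classification and drop branch,
#' CNV calls spanning the retention and rearrangement-type cases,
#' synthesized gene metadata (SFARI flags, criterion-4 tags, families,
#' coordinates) and passing array QC. The same seed gives identical
#' output; different seeds change identifiers and drawn values but not
#' branch counts.
#'
#' @param seed integer seed for every random draw.
#' @param plan a plan from [defaultCohortPlan()].
#' @return a [SimulatedTrioCohort-class]; truth via [truthTables()].
#' @examples
#' cohort <- simulateCohort(seed = 7, plan = defaultCohortPlan(20))
#' cohort
#' @export
simulateCohort <- function(seed = 1L, plan = defaultCohortPlan()) {
  validatePlan(plan)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))

  counts <- plan$counts
  n <- plan$nPatients
  pid <- sprintf("A%03d", seq_len(n))
  role <- rep(names(counts), counts)

  ## --- sex assignment: females go to roles without hemizygous recipes,
  ## array-positive females come from the VOUS-both role
  sex <- rep("male", n)
  quota <- plan$nFemales
  carrierFem <- min(quota, min(5L, counts[["pVOUS_both"]]))
  take <- function(roleName, k) {
    idx <- which(role == roleName & sex == "male")
    utils::head(idx, k)
  }
  fem <- take("pVOUS_both", carrierFem)
  pool <- c(take("pVOUS_seq_single", quota), take("pNone_lb", quota),
            take("pNone_empty", quota))
  fem <- c(fem, utils::head(pool, quota - length(fem)))
  sex[fem] <- "female"

  ## --- pedigree: one family per proband; sibling triple shares one
  fam <- sprintf("F%03d", seq_len(n))
  sibs <- which(role == "pVOUS_seq_sib3")
  if (length(sibs)) fam[sibs] <- fam[sibs[1L]]

  pedRows <- list()
  for (f in unique(fam)) {
    kids <- which(fam == f)
    father <- paste0(pid[kids[1L]], "F")
    mother <- paste0(pid[kids[1L]], "M")
    pedRows[[f]] <- data.frame(
      family_id = f,
      individual_id = c(father, mother, pid[kids]),
      father_id = c(NA, NA, rep(father, length(kids))),
      mother_id = c(NA, NA, rep(mother, length(kids))),
      sex = c("male", "female", sex[kids]),
      affected = c("unaffected", "unaffected", rep("affected", length(kids))),
      stringsAsFactors = FALSE)
  }
  ped <- do.call(rbind, c(pedRows, list(make.row.names = FALSE)))
  ped$trio_complete <- !is.na(ped$father_id)

  ## --- registries
  genes <- list(); variants <- list(); truthV <- list()
  cnvs <- list(); truthC <- list()
  geneN <- 0L; cnvN <- 0L; posN <- 0L

  addGene <- function(prefix, chrom = "2", sfari = TRUE, score = "3",
                      tags = "", family = NA_character_,
                      start = NULL, end = NULL, strand = "+",
                      brain = round(stats::runif(1, 10, 99), 1),
                      hi = NA, ts = NA) {
    geneN <<- geneN + 1L
    sym <- sprintf("%s%03d", prefix, geneN)
    if (is.null(start)) {
      start <- 200000L + geneN * 60000L
      end <- start + 40000L
    }
    genes[[sym]] <<- data.frame(
      symbol = sym, chrom = chrom, start = as.integer(start),
      end = as.integer(end), strand = strand, sfari_member = sfari,
      sfari_score = if (sfari) score else "none",
      function_tags = tags, family_name = family,
      brain_expression_pct = brain, haploinsufficient = hi,
      triplosensitive = ts, stringsAsFactors = FALSE)
    sym
  }

  addVariant <- function(i, gene, branch, consequence = "missense",
                         zygosity, inheritance, cadd, acmg,
                         maf = NA_real_, hom = NA_integer_,
                         coverage = NULL, gq = NULL, chrom = "2",
                         hgvs = NULL, expect_retained, expect_class,
                         expect_combined = NA_character_,
                         expect_drop = NA_character_) {
    posN <<- posN + 1L
    pos <- 5000L + posN * 137L
    if (is.null(hgvs)) hgvs <- sprintf("c.%dG>A", pos)
    if (is.null(coverage)) coverage <- sample(30:120, 1)
    if (is.null(gq)) gq <- sample(50:99, 1)
    variants[[length(variants) + 1L]] <<- data.frame(
      patient_id = pid[i], family_id = fam[i], gene = gene, hgvs_c = hgvs,
      chrom = chrom, pos = pos, ref = "G", alt = "A",
      consequence = consequence, zygosity = zygosity,
      inheritance = inheritance, cadd = cadd, acmg = acmg,
      gnomad_maf = maf, gnomad_hom = as.integer(hom),
      coverage = as.integer(coverage), gq = as.integer(gq),
      stringsAsFactors = FALSE)
    truthV[[length(truthV) + 1L]] <<- data.frame(
      patient_id = pid[i], key = variantKey(gene, hgvs), branch = branch,
      expect_retained = expect_retained, expect_class = expect_class,
      expect_combined = expect_combined, expect_drop_reason = expect_drop,
      stringsAsFactors = FALSE)
    invisible(hgvs)
  }

  C4 <- "neurodevelopment;synaptic_transmission"

  ## CNV windows never collide with SNV gene coordinates (< 50 Mb)
  addCnv <- function(i, prior, state, geometry = "full",
                     inheritance = "maternal", dgv = NA_real_,
                     branch, expect_retained = TRUE, multi = FALSE) {
    cnvN <<- cnvN + 1L
    chrom <- as.character((cnvN %% 20L) + 1L)
    w <- 100e6 + cnvN * 2e6
    if (geometry == "intragenic") {
      g <- addGene("CG", chrom, sfari = sample(c(TRUE, FALSE), 1),
                   score = sample(c("1", "2", "3"), 1), tags = C4,
                   start = w + 1000, end = w + 600000,
                   hi = state == "loss", ts = state == "gain")
      st <- w + 200000; en <- w + 320000
    } else {
      g <- addGene("CG", chrom, sfari = TRUE,
                   score = sample(c("1", "2", "2B"), 1), tags = C4,
                   start = w + 200000, end = w + 280000,
                   hi = state == "loss", ts = state == "gain")
      if (multi)
        addGene("CG", chrom, sfari = FALSE, tags = "",
                start = w + 350000, end = w + 480000)
      st <- w + 100000; en <- w + 400000
    }
    band <- sprintf("%sq%d.%d", chrom, 11L + (cnvN %% 15L), 1L + (cnvN %% 3L))
    cnvs[[length(cnvs) + 1L]] <<- data.frame(
      patient_id = pid[i], chrom = chrom, start = as.integer(st),
      end = as.integer(en), copy_state = state,
      copy_number = if (state == "loss") 1L else 3L,
      inheritance = inheritance, prior_class = prior,
      dgv_frequency = dgv, band_start = band, band_end = band,
      size_bp = as.integer(en - st + 1), stringsAsFactors = FALSE)
    truthC[[length(truthC) + 1L]] <<- data.frame(
      patient_id = pid[i], key = paste(pid[i], chrom, st, en, sep = ":"),
      branch = branch, expect_retained = expect_retained,
      stringsAsFactors = FALSE)
  }

  tier <- rep("none", n); src <- rep("none", n)

  ## ---- shared-key annotations drawn once, reused per carrier
  sharedHemi <- memberRecipe("P")
  sharedLP <- list(cadd = round(stats::runif(1, 20, 45), 1), acmg = "LP",
                   hom = sample(2:10, 1))
  sib3r <- list(cadd = round(stats::runif(1, 5, 14), 1), acmg = "VOUS")
  rec2r <- memberRecipe("VOUS"); rec3r <- memberRecipe("VOUS")
  compr <- list(cadd = round(stats::runif(1, 15.5, 19.5), 1), acmg = "VOUS",
                hom = sample(0:5, 1))

  gSharedHemi <- if (counts[["pP_sharedHemi"]])
    addGene("SF", "X", score = "2B", tags = C4) else NA
  gSharedLP <- if (counts[["pLP_both"]]) addGene("SF", tags = C4) else NA
  gSib3 <- if (counts[["pVOUS_seq_sib3"]]) addGene("SF", "X", tags = "") else NA
  gRec2 <- if (counts[["pVOUS_seq_rec2"]]) addGene("SF", tags = "") else NA
  gRec3 <- if (counts[["pVOUS_seq_rec3"]]) addGene("SF", tags = "") else NA
  gCompanion <- addGene("SF", tags = "", family = "SynapticAnchor")
  sharedPos <- list()  # branch -> hgvs, so carriers share the key

  shared <- function(branch, i, gene, recipe, zygosity, inheritance,
                     chrom, expect_class) {
    if (is.null(sharedPos[[branch]])) {
      sharedPos[[branch]] <<- addVariant(
        i, gene, branch, zygosity = zygosity, inheritance = inheritance,
        cadd = recipe$cadd, acmg = recipe$acmg, hom = recipe$hom,
        chrom = chrom, expect_retained = TRUE, expect_class = expect_class)
    } else {
      addVariant(i, gene, branch, zygosity = zygosity,
                 inheritance = inheritance, cadd = recipe$cadd,
                 acmg = recipe$acmg, hom = recipe$hom, chrom = chrom,
                 hgvs = sharedPos[[branch]], expect_retained = TRUE,
                 expect_class = expect_class)
    }
  }

  nSingleLP <- 0L; nVousSingle <- 0L; nLpCnv <- 0L; nVousBoth <- 0L
  nLpSeqCnv <- 0L; sibSeen <- 0L; rec2Seen <- 0L; rec3Seen <- 0L
  lpBothSeen <- 0L; sharedHemiSeen <- 0L
  famGenes <- character()

  for (i in seq_len(n)) {
    r <- role[i]
    if (r == "pP_denovo") {
      g <- addGene("SF", score = "1", tags = C4)
      rec <- memberRecipe("P")
      addVariant(i, g, r, zygosity = "heterozygous", inheritance = "de_novo",
                 cadd = rec$cadd, acmg = rec$acmg, hom = rec$hom,
                 expect_retained = TRUE, expect_class = "P")
      tier[i] <- "P"; src[i] <- "sequence"
    } else if (r == "pP_upgrade") {
      g <- addGene("SF", "X", score = "2B", tags = C4)
      addVariant(i, g, r, consequence = "splicing", zygosity = "hemizygous",
                 inheritance = "maternal", chrom = "X",
                 cadd = round(stats::runif(1, 20, 45), 1), acmg = "VOUS",
                 hom = sample(2:10, 1),
                 expect_retained = TRUE, expect_class = "P")
      tier[i] <- "P"; src[i] <- "sequence"
    } else if (r == "pP_sharedHemi") {
      sharedHemiSeen <- sharedHemiSeen + 1L
      shared("sharedHemiP", i, gSharedHemi, sharedHemi, "hemizygous",
             "maternal", "X", "P")
      if (sharedHemiSeen == 1L) {
        ## first carrier also holds an LP CNV (tier still P via sequence)
        addCnv(i, "LP", "loss", "intragenic", "maternal",
               branch = "cnv_LP_on_P_patient")
        tier[i] <- "P"; src[i] <- "sequence"
      } else {
        ## second carrier holds the single pathogenic de novo CNV
        addCnv(i, "P", "loss", "intragenic", "de_novo", branch = "cnv_P")
        tier[i] <- "P"; src[i] <- "both"
      }
    } else if (r == "pLP_seq_single") {
      nSingleLP <- nSingleLP + 1L
      zyg <- if (nSingleLP %% 7L == 0L) "homozygous"
        else if (nSingleLP %% 11L == 0L) "hemizygous" else "heterozygous"
      if (zyg == "hemizygous" && sex[i] == "female") zyg <- "heterozygous"
      inh <- switch(zyg, heterozygous = "de_novo",
                    homozygous = "biparental", hemizygous = "maternal")
      chrom <- if (zyg == "hemizygous") "X" else "2"
      g <- addGene("SF", chrom = chrom, score = sample(c("1", "2", "3", "S"), 1),
                   tags = C4)
      rec <- memberRecipe("LP")
      addVariant(i, g, r, zygosity = zyg, inheritance = inh,
                 cadd = rec$cadd, acmg = rec$acmg, hom = rec$hom,
                 chrom = chrom, expect_retained = TRUE, expect_class = "LP")
      ## recurrent companion blocks the sole-candidate upgrade
      shared("companionVOUS", i, gCompanion, compr, "homozygous",
             "biparental", "2", "VOUS")
      if (nLpSeqCnv < plan$extras[["vousCnvOnLpSeq"]]) {
        nLpSeqCnv <- nLpSeqCnv + 1L
        addCnv(i, "VOUS", "gain", "full", "paternal", branch = "cnv_VOUS")
      }
      tier[i] <- "LP"; src[i] <- "sequence"
    } else if (r == "pLP_seq_chet") {
      g <- addGene("SF", tags = C4)
      ch <- plantCompoundHet(pid[i], fam[i], g, chrom = "2",
                             basePos = 900000L + i * 500L,
                             class_pair = c("LP", "VOUS"))
      ## one pair carries a high homozygote count on the VOUS member to
      ## exercise the "regardless of homozygote count" exception
      if (sum(role[seq_len(i)] == r) == 1L)
        ch$variants$gnomad_hom[2L] <- 50L
      for (k in 1:2) {
        v <- ch$variants[k, ]
        variants[[length(variants) + 1L]] <- v
        truthV[[length(truthV) + 1L]] <- data.frame(
          patient_id = pid[i], key = variantKey(v$gene, v$hgvs_c),
          branch = r, expect_retained = TRUE,
          expect_class = c("LP", "VOUS")[k],
          expect_combined = ch$pair_class,
          expect_drop_reason = NA_character_, stringsAsFactors = FALSE)
      }
      tier[i] <- "LP"; src[i] <- "sequence"
    } else if (r == "pLP_seq_nonsfari") {
      g <- addGene("NS", sfari = FALSE, tags = C4)
      rec <- list(cadd = round(stats::runif(1, 20, 45), 1),
                  acmg = sample(c("P", "LP"), 1), hom = NA_integer_)
      addVariant(i, g, r, consequence = "frameshift",
                 zygosity = "heterozygous", inheritance = "de_novo",
                 cadd = rec$cadd, acmg = rec$acmg, hom = rec$hom,
                 maf = round(stats::runif(1, 0, 0.005), 5),
                 expect_retained = TRUE, expect_class = "LP")
      shared("companionVOUS", i, gCompanion, compr, "homozygous",
             "biparental", "2", "VOUS")
      tier[i] <- "LP"; src[i] <- "sequence"
    } else if (r == "pLP_cnv") {
      nLpCnv <- nLpCnv + 1L
      state <- if (nLpCnv <= 7L) "loss" else "gain"
      geometry <- if (state == "loss" && nLpCnv <= 3L) "intragenic" else "full"
      addCnv(i, "LP", state, geometry,
             if (nLpCnv %% 2L) "maternal" else "paternal",
             branch = "cnv_LP", multi = geometry == "full" && nLpCnv == 5L)
      if (nLpCnv <= plan$extras[["vousCnvCoOccur"]])
        addCnv(i, "VOUS", "gain", "full", "maternal", branch = "cnv_VOUS")
      tier[i] <- "LP"; src[i] <- "cnv"
    } else if (r == "pLP_both") {
      lpBothSeen <- lpBothSeen + 1L
      shared("sharedLPseq", i, gSharedLP, sharedLP, "heterozygous",
             "de_novo", "2", "LP")
      addCnv(i, "LP", "gain", "full",
             if (lpBothSeen == 1L) "maternal" else "paternal",
             branch = "cnv_LP", multi = lpBothSeen == 1L)
      tier[i] <- "LP"; src[i] <- "both"
    } else if (r == "pVOUS_seq_single") {
      nVousSingle <- nVousSingle + 1L
      g <- addGene("SF", tags = if (nVousSingle %% 2L) C4 else "",
                   family = if (nVousSingle <= 4L) "SynapticAnchor"
                   else NA_character_)
      famGenes <- c(famGenes, g)
      if (nVousSingle %% 5L == 0L) {
        ## criterion-1 pass but homozygote count below the LP window:
        ## falls through to VOUS under the literal 2-10 reading
        addVariant(i, g, r, zygosity = "heterozygous",
                   inheritance = "de_novo",
                   cadd = round(stats::runif(1, 20, 40), 1), acmg = "VOUS",
                   hom = sample(0:1, 1),
                   expect_retained = TRUE, expect_class = "VOUS")
      } else {
        rec <- memberRecipe("VOUS")
        addVariant(i, g, r, zygosity = "heterozygous",
                   inheritance = "de_novo", cadd = rec$cadd,
                   acmg = rec$acmg, hom = rec$hom,
                   expect_retained = TRUE, expect_class = "VOUS")
      }
      tier[i] <- "VOUS"; src[i] <- "sequence"
    } else if (r == "pVOUS_seq_sib3") {
      sibSeen <- sibSeen + 1L
      shared("sib3hemiVOUS", i, gSib3, c(sib3r, list(hom = 3L)),
             "hemizygous", "maternal", "X", "VOUS")
      tier[i] <- "VOUS"; src[i] <- "sequence"
    } else if (r == "pVOUS_seq_rec2") {
      shared("rec2VOUS", i, gRec2, rec2r, "heterozygous", "de_novo", "2",
             "VOUS")
      tier[i] <- "VOUS"; src[i] <- "sequence"
    } else if (r == "pVOUS_seq_rec3") {
      shared("rec3VOUS", i, gRec3, rec3r, "heterozygous", "de_novo", "2",
             "VOUS")
      tier[i] <- "VOUS"; src[i] <- "sequence"
    } else if (r == "pVOUS_cnv") {
      addCnv(i, "VOUS", "loss", "intragenic", "maternal", branch = "cnv_VOUS")
      g <- addGene("SF", tags = "")
      rec <- memberRecipe("LB")
      addVariant(i, g, "private_LB", zygosity = "heterozygous",
                 inheritance = "de_novo", cadd = rec$cadd, acmg = rec$acmg,
                 hom = rec$hom, expect_retained = TRUE, expect_class = "LB")
      tier[i] <- "VOUS"; src[i] <- "cnv"
    } else if (r == "pVOUS_both") {
      nVousBoth <- nVousBoth + 1L
      g <- addGene("SF", tags = "")
      rec <- memberRecipe("VOUS")
      addVariant(i, g, r, zygosity = "heterozygous", inheritance = "de_novo",
                 cadd = rec$cadd, acmg = rec$acmg, hom = rec$hom,
                 expect_retained = TRUE, expect_class = "VOUS")
      state <- if (nVousBoth <= 4L) "loss" else "gain"
      geometry <- if (state == "gain" && nVousBoth <= 7L) "intragenic"
        else "full"
      addCnv(i, "VOUS", state, geometry,
             if (nVousBoth %% 2L) "maternal" else "paternal",
             branch = "cnv_VOUS")
      if (nVousBoth <= plan$extras[["vousCnvSecond"]])
        addCnv(i, "VOUS", "gain", "full", "paternal", branch = "cnv_VOUS")
      tier[i] <- "VOUS"; src[i] <- "both"
    } else if (r == "pNone_lb") {
      g <- addGene("SF", tags = "")
      rec <- memberRecipe("LB")
      addVariant(i, g, "private_LB", zygosity = "heterozygous",
                 inheritance = "de_novo", cadd = rec$cadd, acmg = rec$acmg,
                 hom = rec$hom, expect_retained = TRUE, expect_class = "LB")
      tier[i] <- "none"; src[i] <- "none"
    }
    ## pNone_empty: no planted signal
  }

  ## ---- noise records: each violates exactly one predicate
  noisePatient <- function(k) 1L + ((k * 7L) %% n)
  nz <- plan$noise
  for (k in seq_len(nz[["synonymous"]])) {
    i <- noisePatient(k)
    g <- addGene("SN", tags = "")
    addVariant(i, g, "noise_synonymous", consequence = "synonymous",
               zygosity = "heterozygous", inheritance = "de_novo",
               cadd = round(stats::runif(1, 0, 10), 1), acmg = "LB",
               expect_retained = FALSE, expect_class = NA_character_,
               expect_drop = "synonymous")
  }
  for (k in seq_len(nz[["inherited_het"]])) {
    i <- noisePatient(k + 50L)
    g <- addGene("SN", tags = "")
    addVariant(i, g, "noise_inherited_het", zygosity = "heterozygous",
               inheritance = if (k %% 2L) "maternal" else "paternal",
               cadd = round(stats::runif(1, 10, 30), 1), acmg = "VOUS",
               hom = sample(0:5, 1),
               expect_retained = FALSE, expect_class = NA_character_,
               expect_drop = "inherited_het")
  }
  qcRecipe <- list(qc_coverage = list(coverage = sample(0:9, 1), gq = 80L,
                                      maf = NA_real_),
                   qc_gq = list(coverage = 60L, gq = sample(0:14, 1),
                                maf = NA_real_),
                   qc_maf = list(coverage = 60L, gq = 80L,
                                 maf = round(stats::runif(1, 0.05, 0.4), 3)))
  for (b in names(qcRecipe)) {
    for (k in seq_len(nz[[b]])) {
      i <- noisePatient(k + 100L)
      g <- addGene("SN", tags = "")
      qr <- qcRecipe[[b]]
      addVariant(i, g, paste0("noise_", b), zygosity = "heterozygous",
                 inheritance = "de_novo",
                 cadd = round(stats::runif(1, 10, 30), 1), acmg = "VOUS",
                 maf = qr$maf, coverage = qr$coverage, gq = qr$gq,
                 expect_retained = FALSE, expect_class = NA_character_,
                 expect_drop = b)
    }
  }
  for (k in seq_len(nz[["hom_gt_max"]])) {
    i <- noisePatient(k + 150L)
    g <- addGene("SN", tags = "")
    addVariant(i, g, "noise_hom_gt_max", zygosity = "heterozygous",
               inheritance = "de_novo",
               cadd = round(stats::runif(1, 10, 30), 1), acmg = "VOUS",
               hom = sample(11:500, 1),
               expect_retained = FALSE, expect_class = NA_character_,
               expect_drop = "hom_gt_max")
  }
  for (k in seq_len(nz[["gene_filter"]])) {
    i <- noisePatient(k + 200L)
    g <- addGene("NN", sfari = FALSE, tags = "")
    addVariant(i, g, "noise_non_sfari_inherited", zygosity = "heterozygous",
               inheritance = if (k %% 2L) "maternal" else "paternal",
               cadd = round(stats::runif(1, 10, 30), 1), acmg = "VOUS",
               maf = round(stats::runif(1, 0, 0.005), 5),
               expect_retained = FALSE, expect_class = NA_character_,
               expect_drop = "gene_filter")
  }
  nonePatients <- which(role == "pNone_empty")
  if (!length(nonePatients)) nonePatients <- which(role == "pNone_lb")
  if (!length(nonePatients)) nonePatients <- seq_len(n)
  noiseCnv <- function(k, prior, dgv, branch) {
    i <- nonePatients[1L + ((k - 1L) %% length(nonePatients))]
    addCnv(i, prior, if (k %% 2L) "loss" else "gain", "full", "maternal",
           dgv = dgv, branch = branch, expect_retained = FALSE)
  }
  for (k in seq_len(nz[["cnv_lb"]])) noiseCnv(k, "LB", NA_real_, "noise_cnv_lb")
  for (k in seq_len(nz[["cnv_b"]])) noiseCnv(k, "B", NA_real_, "noise_cnv_b")
  for (k in seq_len(nz[["cnv_dgv"]]))
    noiseCnv(k, "VOUS", round(stats::runif(1, 0.011, 0.05), 3),
             "noise_cnv_dgv")

  qc <- data.frame(patient_id = pid,
                   sd = round(stats::runif(n, 0.2, 0.6), 2),
                   dlr_spread = round(stats::runif(n, 0.1, 0.25), 2),
                   stringsAsFactors = FALSE)

  geneDf <- do.call(rbind, c(genes, list(make.row.names = FALSE)))
  variantDf <- do.call(rbind, c(variants, list(make.row.names = FALSE)))
  cnvDf <- if (length(cnvs))
    do.call(rbind, c(cnvs, list(make.row.names = FALSE))) else emptyCnvTable()
  truthVDf <- do.call(rbind, c(truthV, list(make.row.names = FALSE)))
  truthCDf <- if (length(truthC))
    do.call(rbind, c(truthC, list(make.row.names = FALSE)))
  else data.frame(patient_id = character(), key = character(),
                  branch = character(), expect_retained = logical(),
                  stringsAsFactors = FALSE)
  truthP <- data.frame(patient_id = pid, expect_tier = tier,
                       expect_source = src, stringsAsFactors = FALSE)

  new("SimulatedTrioCohort",
      pedigree = ped, variants = variantDf, cnvs = cnvDf, genes = geneDf,
      arrayQc = qc, truthVariants = truthVDf, truthCnvs = truthCDf,
      truthPatients = truthP, seed = as.integer(seed))
}
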