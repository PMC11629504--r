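cfg <- triageConfig()

test_that("half-away-from-zero rounding matches reported precision", {
  expect_equal(roundHalfAway(11.475, 1), 11.5)
  expect_equal(roundHalfAway(28.846, 1), 28.8)
  expect_equal(roundHalfAway(100 * 1 / 122, 2), 0.82)
  expect_equal(roundHalfAway(-2.25, 1), -2.3)
  expect_equal(roundHalfAway(23.91, 0), 24)
})

test_that("best findings pick the most severe retained finding and its
           platform", {
  ped <- mkPed(c("A001", "A002", "A003"))
  cl <- rbind(mkVariant("A001"), mkVariant("A003"))
  cl$assigned_class <- c("LP", "LB")
  cl$combined_class <- NA_character_
  cl$retained <- TRUE
  cn <- rbind(mkCnv("A001", prior_class = "VOUS"),
              mkCnv("A002", prior_class = "P"))
  cn$retained <- TRUE
  fd <- bestFindings(cl, cn, ped)
  expect_equal(fd$best_class, c("LP", "P", "none"))
  expect_equal(fd$source, c("sequence", "cnv", "none"))

  ## both platforms at the same tier -> both
  cn$prior_class <- c("LP", "P")
  fd2 <- bestFindings(cl, cn, ped)
  expect_equal(fd2$best_class[1], "LP")
  expect_equal(fd2$source[1], "both")

  ## compound-het members count at their pair-level class
  cl$combined_class <- c("P", NA)
  fd3 <- bestFindings(cl, cn, ped)
  expect_equal(fd3$best_class[1], "P")
})

test_that("detection-rate arithmetic reproduces the published tier rates", {
  comp <- c(P = 4L, LP = 34L, VOUS = 70L, none = 14L)
  src <- c(rep("sequence", 4),
           rep("sequence", 24), rep("cnv", 8), rep("both", 2),
           rep("sequence", 54), rep("cnv", 3), rep("both", 13),
           rep("none", 14))
  findings <- data.frame(
    patient_id = sprintf("A%03d", 1:122),
    best_class = rep(names(comp), comp),
    source = src, contributing_keys = "", stringsAsFactors = FALSE)
  ped <- mkPed(findings$patient_id,
               sex = rep(c("male", "female"), c(104, 18)))
  s <- detectionRates(findings, ped, cfg)
  expect_equal(unname(s@categoryRates),
               c(3.3, 27.9, 57.4, 11.5))
  expect_equal(s@maleFemaleRatio, 5.8)
  lp <- s@strata[s@strata$tier == "LP", ]
  expect_equal(lp$count[lp$source == "sequence"], 24L)
  expect_equal(lp$rate_pct[lp$source == "sequence"], 19.7)
  expect_equal(lp$rate_pct[lp$source == "cnv"], 6.6)
  expect_equal(lp$rate_pct[lp$source == "both"], 1.6)
  ## partition: tier counts sum to the cohort
  expect_equal(sum(s@categoryCounts), 122L)
  ## platform strata within a tier sum to the tier count
  agg <- tapply(s@strata$count, s@strata$tier, sum)
  expect_equal(as.vector(agg[c("P", "LP", "VOUS")]),
               unname(s@categoryCounts[c("P", "LP", "VOUS")]))
  expect_error(detectionRates(findings[0, ], ped, cfg), "no probands")
})

test_that("CNV composition percentages match the published shares", {
  cn <- rbind(
    do.call(rbind, replicate(16, mkCnv(copy_state = "loss"), FALSE)),
    do.call(rbind, replicate(30, mkCnv(copy_state = "gain"), FALSE)))
  cn$retained <- TRUE
  cn$intragenic <- rep(c(TRUE, FALSE), c(11, 35))
  comp <- cnvComposition(cn)
  expect_equal(comp$deletions_pct, 34.8)
  expect_equal(comp$duplications_pct, 65.2)
  expect_equal(comp$intragenic_pct, 24)
  expect_equal(cnvComposition(cn[0, ]), list(n = 0L))
})

test_that("private and recurrent keys partition the retained set", {
  ## three affected siblings sharing a key make it recurrent, not private
  cl <- rbind(mkVariant("A057", gene = "G1", hgvs_c = "c.181G>A"),
              mkVariant("A058", gene = "G1", hgvs_c = "c.181G>A"),
              mkVariant("A059", gene = "G1", hgvs_c = "c.181G>A"),
              mkVariant("A060", gene = "G2", hgvs_c = "c.5G>A"))
  cl$assigned_class <- c("VOUS", "VOUS", "VOUS", "LP")
  cl$retained <- TRUE
  rp <- recurrenceAndPrivate(cl, cfg)
  expect_equal(rp$recurrenceTable$key, "G1:c.181G>A")
  expect_equal(rp$recurrenceTable$n_probands, 3L)
  expect_equal(rp$privateTable$key, "G2:c.5G>A")
  nKeys <- length(unique(paste(cl$gene, cl$hgvs_c, sep = ":")))
  expect_equal(nrow(rp$recurrenceTable) + nrow(rp$privateTable), nKeys)

  ## the published private-set distribution
  classes <- rep(c("P", "LP", "VOUS", "LB"), c(2, 24, 61, 8))
  big <- do.call(rbind, lapply(seq_along(classes), function(i)
    mkVariant(sprintf("A%03d", i), gene = sprintf("G%03d", i))))
  big$assigned_class <- classes
  big$retained <- TRUE
  rates <- recurrenceAndPrivate(big, cfg)$privateClassRates
  expect_equal(unname(rates), c(2.1, 25.3, 64.2, 8.4))
})

test_that("sex-stratified positivity uses retained calls per sex", {
  ids <- sprintf("A%03d", 1:122)
  ped <- mkPed(ids, sex = rep(c("male", "female"), c(104, 18)))
  findings <- data.frame(patient_id = ids, best_class = "none",
                         source = "none", contributing_keys = "",
                         stringsAsFactors = FALSE)
  carriers <- c(ids[1:30], ids[105:109])   # 30 males, 5 females
  cn <- do.call(rbind, lapply(carriers, function(p) mkCnv(p)))
  cn$retained <- TRUE
  pos <- sexStratifiedPositivity(cn, ped, findings, cfg)
  expect_equal(unname(pos["female"]), 27.8)
  expect_equal(unname(pos["male"]), 28.8)
  expect_equal(unname(attr(pos, "positives")), c(30L, 5L))
})

test_that("gene families group observed genes with carriers", {
  genes <- rbind(mkGene("ANK3", family_name = "Ankyrin"),
                 mkGene("ANK2", family_name = "Ankyrin"),
                 mkGene("LONER"))
  cl <- rbind(mkVariant("A052", gene = "ANK2"),
              mkVariant("A116", gene = "ANK3"),
              mkVariant("A001", gene = "LONER"))
  cl$assigned_class <- "VOUS"; cl$retained <- TRUE
  fam <- geneFamilySummary(c("ANK2", "ANK3", "LONER"), cl, genes,
                           minFamilySize = 2L)
  expect_equal(nrow(fam), 2L)
  expect_setequal(fam$gene, c("ANK2", "ANK3"))
  expect_equal(fam$patients[fam$gene == "ANK2"], "A052")
  ## a threshold above every family empties the table
  expect_equal(nrow(geneFamilySummary(c("ANK2", "ANK3"), cl, genes,
                                      minFamilySize = 10L)), 0L)
})

test_that("cohort summary rates are permutation-invariant and partition", {
  run <- defaultRun()
  s <- cohortSummary(run$res)
  expect_equal(sum(s@categoryCounts), s@nPatients)
  within <- tapply(s@strata$count, s@strata$tier, sum)
  expect_equal(as.vector(within[c("P", "LP", "VOUS")]),
               unname(s@categoryCounts[c("P", "LP", "VOUS")]))
  ## rates recompute from counts under the configured rounding
  for (t in names(s@categoryCounts))
    expect_equal(s@categoryRates[[t]],
                 roundHalfAway(100 * s@categoryCounts[[t]] / s@nPatients, 1))
  ## private + recurrent keys partition the observed key set
  cl <- classifiedVariants(run$res)
  ret <- cl[cl$retained, ]
  nKeys <- length(unique(paste(ret$gene, ret$hgvs_c)))
  expect_equal(nrow(s@privateTable) + nrow(s@recurrenceTable), nKeys)
})
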