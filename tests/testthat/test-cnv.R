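cfg <- triageConfig()

test_that("array QC gate is strict on both metrics", {
  qc <- data.frame(patient_id = c("A", "B", "C"),
                   sd = c(0.5, 1.0, 0.5), dlr_spread = c(0.2, 0.2, 0.3))
  expect_equal(arrayQcCheck(qc, cfg), c(TRUE, FALSE, FALSE))
})

test_that("CNV retention drops benign classes and common DGV calls", {
  cn <- rbind(mkCnv(prior_class = "LB", dgv_frequency = 0.001),
              mkCnv(prior_class = "VOUS", dgv_frequency = 0.015),
              mkCnv(prior_class = "VOUS", dgv_frequency = 0.01),
              mkCnv(prior_class = "B"),
              mkCnv(prior_class = "P"))
  out <- cnvRetentionFilter(cn, cfg)
  expect_equal(out$retained, c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(out$drop_reason[c(1, 2, 4)],
               c("class_benign", "dgv_common", "class_benign"))
})

test_that("rearrangement typing is exhaustive, exclusive and strand-aware", {
  expect_equal(rearrangementType(100, 200, "gain", 120, 180, "+"),
               "DUPLICATED")
  expect_equal(rearrangementType(100, 200, "loss", 120, 180, "+"), "DELETED")
  expect_equal(rearrangementType(130, 160, "loss", 100, 200, "+"),
               "INTRAGENIC")
  expect_equal(rearrangementType(150, 300, "loss", 100, 200, "+"), "INT_END")
  expect_equal(rearrangementType(150, 300, "loss", 100, 200, "-"),
               "INT_START")
  expect_equal(rearrangementType(50, 150, "loss", 100, 200, "+"),
               "INT_START")
  expect_error(rearrangementType(10, 20, "loss", 100, 200, "+"), "disjoint")

  ## exactly one label per overlapping geometry, incl. single-base overlap
  expect_equal(rearrangementType(200, 300, "loss", 100, 200, "+"), "INT_END")
})

test_that("gene overlap uses closed 1-based intervals", {
  cn <- mkCnv(chrom = "7", start = 100L, end = 200L)
  genes <- rbind(mkGene("IN", chrom = "7", start = 120L, end = 180L),
                 mkGene("EDGE", chrom = "7", start = 200L, end = 400L),
                 mkGene("OUT", chrom = "7", start = 201L, end = 400L),
                 mkGene("OTHER", chrom = "8", start = 100L, end = 200L))
  ov <- overlapCnvGenes(cn, genes)
  expect_setequal(ov$gene, c("IN", "EDGE"))
  expect_equal(ov$rearrangement[ov$gene == "IN"], "DELETED")
  expect_equal(ov$rearrangement[ov$gene == "EDGE"], "INT_START")
})

test_that("genes-of-interest ranking is total and deterministic", {
  single <- mkGene("AUTS2", sfari_score = "1")
  expect_equal(genesOfInterest(single, "loss", cfg), "AUTS2")

  two <- rbind(mkGene("TOP", sfari_score = "1"),
               mkGene("OTHER", sfari_member = FALSE, function_tags = ""))
  expect_equal(genesOfInterest(two, "loss", cfg)[1], "TOP")

  ## all attributes tied: alphabetical
  tied <- rbind(mkGene("BBB"), mkGene("AAA"))
  tied$brain_expression_pct <- 50
  expect_equal(genesOfInterest(tied, "loss", cfg), c("AAA", "BBB"))

  ## permutation-stable
  three <- rbind(mkGene("G1", sfari_score = "3"),
                 mkGene("G2", sfari_score = "2B"),
                 mkGene("G3", sfari_member = FALSE, function_tags = ""))
  r1 <- genesOfInterest(three, "gain", cfg)
  r2 <- genesOfInterest(three[c(3, 1, 2), ], "gain", cfg)
  expect_equal(r1, r2)
  expect_equal(r1[1], "G2")  # 2B ranks as tier 2, ahead of 3 and none

  expect_warning(out <- genesOfInterest(mkGene()[0, ], "loss", cfg),
                 "no annotated gene")
  expect_length(out, 0L)
})

test_that("ISCN-style labels follow the band/coordinate/copy format", {
  a <- mkCnv(chrom = "14", start = 79388339L, end = 79657573L,
             copy_number = 1L, inheritance = "de_novo",
             band_start = "14q31.1")
  expect_equal(formatIscn(a), "14q31.1(79388339_79657573)x1 de novo")
  b <- mkCnv(chrom = "13", start = 47240527L, end = 48096722L,
             copy_number = 1L, inheritance = "paternal",
             band_start = "13q14.13", band_end = "13q14.2")
  expect_equal(formatIscn(b), "13q14.13q14.2(47240527_48096722)x1 pat")
  c3 <- mkCnv(inheritance = "maternal", band_start = "5q11.1")
  expect_match(formatIscn(c3), "x1 mat$")
  noBand <- mkCnv(band_start = NA_character_, band_end = NA_character_,
                  inheritance = "unknown")
  expect_warning(lab <- formatIscn(noBand), "cytoband")
  expect_equal(lab, "(1000_2000)x1")
})

test_that("CNV triage retains order-independently and flags intragenic
           calls", {
  run <- defaultRun()
  cohort <- run$cohort
  out <- triageCnvs(cnvCalls(cohort), geneMeta(cohort), arrayQc(cohort), cfg)
  cn <- out$cnvResults
  ## idempotence on the retained subset
  again <- triageCnvs(cn[cn$retained, names(cnvCalls(cohort))],
                      geneMeta(cohort), arrayQc(cohort), cfg)
  expect_true(all(again$cnvResults$retained))
  ## order invariance
  set.seed(7)
  shuf <- cnvCalls(cohort)[sample(nrow(cnvCalls(cohort))), ]
  out2 <- triageCnvs(shuf, geneMeta(cohort), arrayQc(cohort), cfg)
  expect_equal(out2$cnvResults, cn)
  ## a failing array drops that patient's calls
  qcBad <- arrayQc(cohort)
  pidWithCnv <- cn$patient_id[cn$retained][1]
  qcBad$sd[qcBad$patient_id == pidWithCnv] <- 1.5
  out3 <- triageCnvs(cnvCalls(cohort), geneMeta(cohort), qcBad, cfg)
  dropped <- out3$cnvResults[out3$cnvResults$patient_id == pidWithCnv, ]
  expect_true(all(!dropped$retained))
  expect_true(all(dropped$drop_reason == "array_qc"))
})
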