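test_that("same seed gives identical cohorts; seeds change values, not
           branch counts", {
  a <- simulateCohort(seed = 7, plan = defaultCohortPlan(30))
  b <- simulateCohort(seed = 7, plan = defaultCohortPlan(30))
  expect_equal(variantCalls(a), variantCalls(b))
  expect_equal(cnvCalls(a), cnvCalls(b))
  expect_equal(geneMeta(a), geneMeta(b))
  expect_equal(truthTables(a), truthTables(b))

  c3 <- simulateCohort(seed = 8, plan = defaultCohortPlan(30))
  expect_false(identical(variantCalls(a)$cadd, variantCalls(c3)$cadd))
  expect_equal(table(truthTables(a)$variants$branch),
               table(truthTables(c3)$variants$branch))
  expect_equal(table(truthTables(a)$patients$expect_tier),
               table(truthTables(c3)$patients$expect_tier))
})

test_that("generated files pass validation with no unplanned warnings", {
  co <- simulateCohort(seed = 11, plan = defaultCohortPlan(25))
  dir <- file.path(tempdir(), "simvalid")
  writeCohort(co, dir)
  expect_warning(back <- suppressMessages(readCohort(dir)), NA)
  expect_s4_class(back, "TrioCohort")
  v <- variantCalls(back)
  expect_true(all(v$consequence %in%
                    c("missense", "synonymous", "frameshift",
                      "inframe_indel", "splicing", "start_lost",
                      "stop_gained", "stop_lost", "other")))
  ped <- pedigree(back)
  expect_true(all(ped$trio_complete[ped$affected == "affected"]))
})

test_that("planted compound-het pairs honour the pairing contract", {
  ch <- plantCompoundHet("A001", "F001", "GENE1",
                         class_pair = c("LP", "VOUS"))
  expect_equal(nrow(ch$variants), 2L)
  expect_equal(ch$pair_class, "LP")
  expect_setequal(ch$variants$inheritance, c("maternal", "paternal"))

  lb <- plantCompoundHet("A001", "F001", "GENE1",
                         class_pair = c("LB", "LB"))
  expect_equal(lb$pair_class, "LB")

  expect_error(plantCompoundHet("A001", "F001", "GENE1",
                                origins = c("maternal", "maternal")),
               "distinct parental origins")
  expect_error(plantCompoundHet("A001", "F001", "GENE1",
                                class_pair = c("B", "LP")),
               "no generator recipe")
})

test_that("infeasible plans are rejected before generation", {
  plan <- defaultCohortPlan(20)
  plan$counts["pNone_empty"] <- plan$counts["pNone_empty"] + 1L
  expect_error(simulateCohort(seed = 1, plan = plan), "infeasible")
  plan2 <- defaultCohortPlan(20)
  plan2$extras["vousCnvCoOccur"] <- 99L
  expect_error(simulateCohort(seed = 1, plan = plan2), "infeasible")
  expect_error(defaultCohortPlan(3), "at least 8")
})

test_that("the default plan encodes the study composition", {
  plan <- defaultCohortPlan()
  expect_equal(plan$nPatients, 122L)
  expect_equal(sum(plan$counts), 122L)
  expect_equal(plan$nFemales, 18L)
  tiers <- c(P = 4L, LP = 34L, VOUS = 70L, none = 14L)
  got <- c(
    P = sum(plan$counts[c("pP_denovo", "pP_upgrade", "pP_sharedHemi")]),
    LP = sum(plan$counts[c("pLP_seq_single", "pLP_seq_chet",
                           "pLP_seq_nonsfari", "pLP_cnv", "pLP_both")]),
    VOUS = sum(plan$counts[c("pVOUS_seq_single", "pVOUS_seq_sib3",
                             "pVOUS_seq_rec2", "pVOUS_seq_rec3",
                             "pVOUS_cnv", "pVOUS_both")]),
    none = sum(plan$counts[c("pNone_lb", "pNone_empty")]))
  expect_equal(got, tiers)
})
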