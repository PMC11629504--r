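cfg <- triageConfig()

test_that("the classifier reproduces the canonical rule outcomes", {
  cc <- function(...) classifyVariant(...)$class
  expect_equal(cc(TRUE, 29.3, "LP", 0L, TRUE, cfg), "P")
  expect_equal(cc(TRUE, 24.6, "VOUS", 4L, TRUE, cfg), "LP")
  expect_equal(cc(TRUE, 12.0, "LB", NA_integer_, TRUE, cfg), "LB")
  ## non-SFARI genes are conservatively capped at LP
  expect_equal(cc(FALSE, 34.0, "P", 0L, TRUE, cfg), "LP")
  expect_equal(cc(TRUE, 18.0, "VOUS", 0L, TRUE, cfg), "VOUS")
  ## literal 2-10 homozygote window: low counts fall through to VOUS
  expect_equal(cc(TRUE, 25, "VOUS", 0L, TRUE, cfg), "VOUS")
  lenient <- triageConfig(lpAllowLowHom = TRUE)
  expect_equal(cc(TRUE, 25, "VOUS", 0L, TRUE, lenient), "LP")
  ## missing annotations are an error, not a silent VOUS
  expect_error(classifyVariant(TRUE, NA, "LP", 0L, TRUE, cfg), "cadd")
})

test_that("classifier agrees with the brute-force decision table on the
           full 720-cell grid", {
  grid <- classifierGrid()
  expect_equal(nrow(grid), 720L)
  got <- character(nrow(grid))
  want <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got[i] <- classifyVariant(g$sfari, g$cadd, g$acmg, g$hom, g$tag, cfg)$class
    want[i] <- oracleClassify(g$sfari, g$cadd, g$acmg, g$hom, g$tag)
  }
  expect_identical(got, want)
  ## non-SFARI cells never classify P under the default config
  expect_false(any(got[!grid$sfari] == "P"))
})

test_that("class severity is monotone in CADD", {
  set.seed(41)
  sev <- function(cl) classSeverity(cl)
  for (k in 1:200) {
    sfari <- sample(c(TRUE, FALSE), 1)
    acmg <- sample(c("P", "LP", "VOUS", "LB", "B"), 1)
    hom <- sample(c(NA, 0L, 1L, 5L, 11L), 1)
    tag <- sample(c(TRUE, FALSE), 1)
    cadds <- sort(stats::runif(2, 0, 45))
    lo <- classifyVariant(sfari, cadds[1], acmg, hom, tag, cfg)$class
    hi <- classifyVariant(sfari, cadds[2], acmg, hom, tag, cfg)$class
    expect_gte(sev(hi), sev(lo))
  }
})

test_that("compound-het combination matches the published pair table and
           commutes", {
  expect_equal(combineCompoundHet("P", "P"), "P")
  expect_equal(combineCompoundHet("P", "LP"), "P")
  expect_equal(combineCompoundHet("LP", "LP"), "LP")
  expect_equal(combineCompoundHet("VOUS", "LP"), "LP")
  expect_equal(combineCompoundHet("VOUS", "VOUS"), "VOUS")
  expect_equal(combineCompoundHet("LB", "VOUS"), "VOUS")
  expect_equal(combineCompoundHet("LB", "P"), "VOUS")
  expect_equal(combineCompoundHet("LB", "LP"), "VOUS")
  expect_equal(combineCompoundHet("LB", "LB"), "LB")
  ## the pair the published table leaves out resolves between its
  ## neighbouring rows
  expect_equal(combineCompoundHet("P", "VOUS"), "LP")
  ## commutativity over all 10 unordered pairs
  cls <- c("P", "LP", "VOUS", "LB")
  for (a in cls) for (b in cls)
    expect_equal(combineCompoundHet(a, b), combineCompoundHet(b, a))
  expect_error(combineCompoundHet("B", "LP"), "benign")
})

test_that("sole LP candidates in SFARI genes are upgraded to P", {
  genes <- rbind(mkGene("SF1"), mkGene("NS1", sfari_member = FALSE))
  one <- mkVariant(gene = "SF1")
  one$assigned_class <- "LP"
  one$rule_trace <- "sfari_LP"
  one$retained <- TRUE
  up <- upgradeUniqueCandidate(one, character(), genes, cfg)
  expect_equal(up$assigned_class, "P")
  expect_match(up$rule_trace, "unique_candidate_upgrade")

  ## a retained CNV on the same patient vetoes the upgrade
  noUp <- upgradeUniqueCandidate(one, "A001:5:100:200", genes, cfg)
  expect_equal(noUp$assigned_class, "LP")

  ## two retained candidates: no upgrade
  two <- rbind(one, one)
  two$hgvs_c[2] <- "c.200G>A"
  expect_equal(upgradeUniqueCandidate(two, character(), genes, cfg)$assigned_class,
               c("LP", "LP"))

  ## non-SFARI gene: no upgrade
  ns <- one; ns$gene <- "NS1"
  expect_equal(upgradeUniqueCandidate(ns, character(), genes, cfg)$assigned_class,
               "LP")

  ## switch off: identity
  off <- triageConfig(uniqueCandidateUpgrade = FALSE)
  expect_identical(upgradeUniqueCandidate(one, character(), genes, off), one)
})

test_that("configuration validity guards hold", {
  expect_error(triageConfig(caddBenignMax = 25), "caddBenignMax")
  expect_error(triageConfig(homLpMin = 1L), "homLpMin")
  expect_error(triageConfig(combinationMatrix = c("P|P" = "P")),
               "combinationMatrix")
  yml <- file.path(tempdir(), "cfg.yaml")
  writeLines(c("caddPathMin: 25", "rateDigits: 2"), yml)
  c2 <- readTriageConfig(yml)
  expect_equal(c2@caddPathMin, 25)
  expect_equal(c2@rateDigits, 2L)
  writeLines("nope: 1", yml)
  expect_error(readTriageConfig(yml), "unknown configuration key")
})
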