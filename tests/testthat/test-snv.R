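cfg <- triageConfig()

test_that("quality filter applies strict coverage/GQ/MAF exclusions", {
  v <- rbind(mkVariant(hgvs_c = "c.1G>A", coverage = 9L, gq = 50L),
             mkVariant(hgvs_c = "c.2G>A", coverage = 10L, gq = 15L,
                       gnomad_maf = 0.049),
             mkVariant(hgvs_c = "c.3G>A", gnomad_maf = 0.06),
             mkVariant(hgvs_c = "c.4G>A", gq = 14L))
  out <- qcFilter(v, cfg)
  expect_equal(out$qc_pass, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$drop_reason,
               c("qc_coverage", NA, "qc_maf", "qc_gq"))
})

test_that("trio inheritance is resolved from genotypes", {
  expect_equal(assignInheritance("0/1", "0/0", "0/0")$inheritance, "de_novo")
  expect_equal(assignInheritance("1", "0", "0/1", "male", "X")$inheritance,
               "maternal")
  r <- assignInheritance("1/1", "0/0", "0/1")
  expect_equal(r$inheritance, "unknown")
  expect_false(r$mendelian_ok)
  expect_equal(assignInheritance("0/1", "0/1", "0/0")$inheritance, "paternal")
  expect_equal(assignInheritance("0/1", "0/1", "0/1")$inheritance,
               "biparental")
  expect_equal(assignInheritance("0/1", NA, "0/0")$inheritance, "unknown")
})

test_that("compound-het pairing requires distinct parental origins", {
  base <- function(h, inh) mkVariant(hgvs_c = h, inheritance = inh)
  p <- detectCompoundHet(rbind(base("c.1G>A", "maternal"),
                               base("c.2G>A", "paternal")))
  expect_equal(nrow(p), 1L)
  expect_setequal(c(p$origin_a, p$origin_b), c("maternal", "paternal"))

  expect_equal(nrow(detectCompoundHet(rbind(base("c.1G>A", "maternal"),
                                            base("c.2G>A", "maternal")))),
               0L)
  expect_equal(nrow(detectCompoundHet(rbind(base("c.1G>A", "maternal"),
                                            base("c.2G>A", "de_novo")))),
               1L)
  ## three origins give all three couples
  p3 <- detectCompoundHet(rbind(base("c.1G>A", "maternal"),
                                base("c.2G>A", "paternal"),
                                base("c.3G>A", "de_novo")))
  expect_equal(nrow(p3), 3L)
  ## symmetric: keys sorted within the pair
  expect_true(all(p3$key_a < p3$key_b))
})

test_that("gene filter passes SFARI genes and gates non-SFARI categories", {
  genes <- rbind(mkGene("SF1"), mkGene("NS1", sfari_member = FALSE))
  noPairs <- detectCompoundHet(mkVariant()[0, ])
  sfariInh <- mkVariant(gene = "SF1", inheritance = "maternal")
  expect_true(geneFilter(sfariInh, genes, noPairs, cfg))
  fs <- mkVariant(gene = "NS1", consequence = "frameshift",
                  inheritance = "maternal", gnomad_maf = 0.005)
  expect_true(geneFilter(fs, genes, noPairs, cfg))
  fsCommon <- mkVariant(gene = "NS1", consequence = "frameshift",
                        inheritance = "maternal", gnomad_maf = 0.02)
  expect_false(geneFilter(fsCommon, genes, noPairs, cfg))
  ms <- mkVariant(gene = "NS1", inheritance = "maternal",
                  gnomad_maf = 0.005)
  expect_false(geneFilter(ms, genes, noPairs, cfg))
  ## unknown gene follows the non-SFARI branch
  unknown <- mkVariant(gene = "NOPE", inheritance = "maternal")
  expect_false(geneFilter(unknown, genes, noPairs, cfg))
  expect_true(geneFilter(mkVariant(gene = "NOPE"), genes, noPairs, cfg))
})

test_that("retention drops synonymous, unpaired inherited hets and common
           homozygote counts, with the paired LP exception", {
  v <- rbind(mkVariant(hgvs_c = "c.1G>A", consequence = "synonymous"),
             mkVariant(hgvs_c = "c.2G>A", zygosity = "homozygous",
                       inheritance = "biparental", gnomad_hom = 11L),
             mkVariant(hgvs_c = "c.3G>A", inheritance = "maternal"),
             mkVariant(hgvs_c = "c.4G>A", zygosity = "hemizygous",
                       inheritance = "maternal", gnomad_hom = 10L))
  v$assigned_class <- "VOUS"
  noPairs <- detectCompoundHet(v[0, ])
  out <- retentionFilter(v, noPairs, cfg)
  expect_equal(out$retained, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(out$drop_reason[1:3],
               c("synonymous", "hom_gt_max", "inherited_het"))

  ## paired (LP, VOUS) members survive any homozygote count
  pv <- rbind(mkVariant(hgvs_c = "c.10G>A", inheritance = "maternal",
                        gnomad_hom = 50L),
              mkVariant(hgvs_c = "c.20G>A", inheritance = "paternal",
                        gnomad_hom = 3L))
  pv$assigned_class <- c("VOUS", "LP")
  pairs <- detectCompoundHet(pv)
  out2 <- retentionFilter(pv, pairs, cfg)
  expect_true(all(out2$retained))
})

test_that("the cascade is idempotent and order-invariant with one primary
           drop reason per dropped variant", {
  run <- defaultRun()
  cohort <- run$cohort
  genes <- geneMeta(cohort)
  first <- triageSnvs(variantCalls(cohort), genes, cfg)
  cl <- first$classified

  ## exactly one primary reason per dropped variant, none for retained
  expect_true(all(is.na(cl$drop_reason[cl$retained])))
  expect_true(all(!is.na(cl$drop_reason[!cl$retained])))

  ## no retained synonymous; no retained unpaired inherited het
  expect_false(any(cl$consequence[cl$retained] == "synonymous"))
  inhHet <- cl$retained & cl$zygosity == "heterozygous" &
    cl$inheritance %in% c("maternal", "paternal", "biparental")
  expect_true(all(!is.na(cl$compound_partner[inhHet])))

  ## idempotence: re-running on the retained rows keeps them all
  keep <- cl[cl$retained, names(variantCalls(cohort))]
  second <- triageSnvs(keep, genes, cfg)
  expect_true(all(second$classified$retained))
  m <- match(paste(second$classified$patient_id, second$classified$hgvs_c),
             paste(cl$patient_id, cl$hgvs_c))
  expect_equal(second$classified$assigned_class, cl$assigned_class[m])

  ## order invariance: a permutation changes nothing
  set.seed(99)
  shuffled <- variantCalls(cohort)[sample(nrow(variantCalls(cohort))), ]
  third <- triageSnvs(shuffled, genes, cfg)
  expect_equal(third$classified, first$classified)
  expect_equal(third$pairs, first$pairs)
})
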