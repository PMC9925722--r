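make_loci <- function(df) lociGRanges(df)

test_that("tandem chaining joins loci within the gap threshold", {
  df <- data.frame(
    gene_id = c("a", "b", "c"),
    chromosome = "chr1",
    start = c(1000, 12000, 25000),
    end = c(10000, 20000, 33000),
    strand = "+", family_label = "CPO", duplicated_group = TRUE)
  cl <- detectTandemArrays(make_loci(df), maxGap = 10000)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n, 3L)
  expect_equal(cl$members, "a,b,c")
  expect_equal(cl$span, 33000 - 1000 + 1)

  # different chromosomes never chain
  df2 <- df[1:2, ]; df2$chromosome <- c("chr1", "chr2")
  expect_equal(nrow(detectTandemArrays(make_loci(df2), maxGap = 1e6)), 0L)

  # five close same-family loci form one cluster of 5
  df3 <- data.frame(
    gene_id = paste0("g", 1:5), chromosome = "chrX",
    start = seq(1e6, by = 2e4, length.out = 5),
    end = seq(1e6, by = 2e4, length.out = 5) + 1e4,
    strand = "+", family_label = "CPO", duplicated_group = TRUE)
  cl3 <- detectTandemArrays(make_loci(df3), maxGap = 25000)
  expect_equal(cl3$n, 5L)
})

test_that("family labels gate chaining only when asked", {
  df <- data.frame(
    gene_id = c("a", "b"), chromosome = "chr1",
    start = c(1000, 12000), end = c(10000, 20000),
    strand = "+", family_label = c("CPO", "CPA1"),
    duplicated_group = TRUE)
  loci <- make_loci(df)
  expect_equal(nrow(detectTandemArrays(loci, maxGap = 10000,
                                       sameFamily = TRUE)), 0L)
  expect_equal(detectTandemArrays(loci, maxGap = 10000,
                                  sameFamily = FALSE)$n, 2L)
})

test_that("cluster detection is order-invariant", {
  loci <- makeLocusCohort(seed = 21, nDuplicated = 30, nOther = 30,
                          tandemSizes = c(3L, 4L))
  ref <- detectTandemArrays(loci)
  set.seed(99)
  for (k in 1:5) {
    shuf <- loci[sample(length(loci))]
    expect_equal(detectTandemArrays(shuf), ref)
  }
})

test_that("planted tandem clusters are recovered exactly", {
  loci <- makeLocusCohort(seed = 33, nDuplicated = 40, nOther = 20,
                          tandemSizes = c(3L, 5L))
  cl <- detectTandemArrays(loci)
  expect_equal(sort(cl$n), c(3L, 5L))
  expect_true(all(cl$family_label == "CPO"))
})

test_that("gene-size comparison runs Welch t and Kruskal-Wallis", {
  loci <- makeLocusCohort(seed = 3)
  sc <- compareGeneSizes(loci)
  expect_lt(sc@tP, 1e-6)
  expect_lt(sc@mean1, sc@mean2)
  expect_lt(sc@kwP, 1e-6)
})

test_that("degenerate size comparisons are handled", {
  # identical constant sizes in both groups: reported as no difference
  df <- data.frame(
    gene_id = paste0("g", 1:6), chromosome = "chr1",
    start = seq(1, by = 1e6, length.out = 6),
    end = seq(1, by = 1e6, length.out = 6) + 999,
    strand = "+", family_label = "CPO",
    duplicated_group = rep(c(TRUE, FALSE), 3))
  sc <- compareGeneSizes(make_loci(df))
  expect_equal(sc@mean1, sc@mean2)
  expect_equal(sc@tP, 1)

  # a one-member group: descriptives only
  df$duplicated_group <- c(TRUE, rep(FALSE, 5))
  sc2 <- compareGeneSizes(make_loci(df))
  expect_true(is.na(sc2@tP))
  expect_equal(sc2@n1, 1L)

  # an empty group is an error
  df$duplicated_group <- FALSE
  expect_error(compareGeneSizes(make_loci(df)), "non-empty")
})

test_that("cohort tables count and fraction correctly", {
  calls <- data.frame(
    family = rep(c("CPO", "CPA1"), c(6, 4)),
    label = c(rep("ACTIVE", 5), "PSEUDOGENE", rep("ACTIVE", 4)),
    substrate_class = c(rep("ACIDIC_SUBSTRATE", 6),
                        rep("HYDROPHOBIC_SUBSTRATE", 4)))
  tabs <- tabulateCohort(calls)
  fbf <- tabs$functionalByFamily
  expect_equal(sum(fbf$count), 10L)
  cpo_active <- fbf$fraction[fbf$group == "CPO" & fbf$category == "ACTIVE"]
  expect_equal(cpo_active, 5 / 6)
  # fractions sum to 1 per family
  expect_equal(as.numeric(tapply(fbf$fraction, fbf$group, sum)), c(1, 1))
  # group split pools non-focal families
  fbg <- tabs$functionalByGroup
  expect_setequal(unique(fbg$group), c("CPO", "OTHER"))

  # all-active cohort
  calls2 <- data.frame(family = "CPO", label = rep("ACTIVE", 10),
                       substrate_class = "ACIDIC_SUBSTRATE")
  t2 <- tabulateCohort(calls2)
  expect_equal(
    t2$functionalByFamily$fraction[t2$functionalByFamily$category ==
                                     "ACTIVE"], 1)

  # empty input gives empty tables, no error
  t3 <- tabulateCohort(calls[0, ])
  expect_equal(nrow(t3$functionalByFamily), 0L)
})

test_that("cohort fractions are invariant under whole-cohort duplication", {
  co <- makeSyntheticCohort(nParalogs = 20, seed = 6)
  calls <- as.data.frame(cohortTruth(co))
  calls$label <- calls$label
  calls$substrate_class <- calls$specificity_class
  t1 <- tabulateCohort(calls)
  t2 <- tabulateCohort(rbind(calls, calls))
  expect_equal(t1$functionalByFamily$fraction,
               t2$functionalByFamily$fraction)
  expect_equal(t1$specificityByGroup$fraction,
               t2$specificityByGroup$fraction)
})

test_that("the pipeline runs from a config and is deterministic", {
  dir1 <- tempfile("demo1"); dir2 <- tempfile("demo2")
  cfg1 <- makeDemoInputs(dir1, seed = 5, nParalogs = 12)
  res <- runPipeline(cfg1)
  out1 <- file.path(dir1, "out")
  produced <- list.files(out1)
  expect_true(all(c("triage.tsv", "selection.tsv", "tandem_clusters.tsv",
                    "size_comparison.tsv", "run_log.txt") %in% produced))
  expect_false(is.null(res$triage))

  # rerun with the same seed: byte-identical numeric outputs
  cfg2 <- makeDemoInputs(dir2, seed = 5, nParalogs = 12)
  runPipeline(cfg2)
  for (f in c("triage.tsv", "selection.tsv", "tandem_clusters.tsv",
              "size_comparison.tsv"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(dir2, "out", f)), label = f)

  # configuration without a scheme fails before any compute
  expect_error(runPipeline(list(cds_fasta = "x.fa")), "configuration")
})
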