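test_that("per-codon site counts match the stated degeneracies", {
  expect_equal(countSites("TTT"), c(s = 1 / 3, n = 8 / 3))
  # Trp: all sense single-nucleotide mutants are nonsynonymous; two of the
  # nine mutants are stops and drop out of the denominators
  expect_equal(countSites("TGG"), c(s = 0, n = 3))
  # fourfold-degenerate third position
  expect_equal(countSites("GGG"), c(s = 1, n = 2))
  expect_error(countSites("TAA"), "stop")
  expect_error(countSites("ANT"), "ambiguous")
})

test_that("between-codon differences average over minimal pathways", {
  expect_equal(countDifferences("AAA", "AAA"), c(sd = 0, nd = 0))
  expect_equal(countDifferences("TTT", "TTA"), c(sd = 0, nd = 1))
  expect_equal(countDifferences("TTT", "GTA"), c(sd = 0.5, nd = 1.5))
  expect_error(countDifferences("TTT", "TGA"), "stop")
})

test_that("site counts match the 9-mutant enumeration oracle for all 61 sense codons", {
  for (variant in c("exclude", "count")) {
    for (cod in sense_codons()) {
      expect_equal(
        countSites(cod, stopHandling = variant),
        oracle_count_sites(cod, exclude_stops = variant == "exclude"),
        tolerance = 1e-12, info = paste(variant, cod))
    }
  }
})

test_that("differences match the pathway enumeration oracle for all 61x61 pairs", {
  codons <- sense_codons()
  impl <- sapply(codons, function(a)
    sapply(codons, function(b) countDifferences(a, b)[["sd"]]))
  oracle <- sapply(codons, function(a)
    sapply(codons, function(b) oracle_count_differences(a, b)[["sd"]]))
  expect_equal(impl, oracle, tolerance = 1e-12)
  impl_nd <- sapply(codons, function(a)
    sapply(codons, function(b) countDifferences(a, b)[["nd"]]))
  oracle_nd <- sapply(codons, function(a)
    sapply(codons, function(b) oracle_count_differences(a, b)[["nd"]]))
  expect_equal(impl_nd, oracle_nd, tolerance = 1e-12)
})

test_that("sd + nd equals the nucleotide Hamming distance per codon pair", {
  codons <- sense_codons()
  set.seed(5)
  for (k in 1:200) {
    a <- sample(codons, 1); b <- sample(codons, 1)
    d <- countDifferences(a, b)
    hamming <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(unname(d["sd"] + d["nd"]), hamming)
  }
})

# a moderately diverged partner: copy with a fraction of codons replaced
mutate_codons <- function(a, frac = 0.1) {
  codons <- sense_codons()
  b <- a
  at <- sample(length(a), max(1, round(frac * length(a))))
  b[at] <- sample(codons, length(at), replace = TRUE)
  b
}

test_that("S + N = 3 x codons under the stop-exclusion convention", {
  set.seed(9)
  codons <- sense_codons()
  for (k in 1:10) {
    n <- sample(20:100, 1)
    a <- sample(codons, n, replace = TRUE)
    b <- mutate_codons(a)
    r <- neiGojobori(a, b)
    expect_equal(r@S + r@N, 3 * r@codonsUsed, tolerance = 1e-9)
  }
})

test_that("Jukes-Cantor correction inflates and is monotone", {
  p <- seq(0, 0.7, by = 0.05)
  d <- jukesCantor(p)
  expect_true(all(d >= p))
  expect_true(all(diff(d) > 0))
  expect_equal(jukesCantor(1e-9), 1e-9, tolerance = 1e-6)
  expect_error(jukesCantor(0.75), "undefined")
})

test_that("identical sequences give a null selection result", {
  a <- c("ATG", "AAA", "CGA", "TTT", "GGG")
  r <- neiGojobori(a, a)
  expect_equal(r@dS, 0)
  expect_equal(r@dN, 0)
  expect_equal(r@statistic, 0)
  expect_equal(r@Z, 0)
  expect_equal(r@p, 0.5)
})

test_that("purely synonymous divergence gives dN = 0 and p < 0.5", {
  # a few third-position synonymous differences only
  a <- rep("GGG", 30)
  b <- c(rep("GGA", 5), rep("GGG", 25))
  r <- neiGojobori(a, b)
  expect_equal(r@dN, 0)
  expect_gt(r@dS, 0)
  expect_lt(r@p, 0.5)
})

test_that("selection results are symmetric in the two sequences", {
  set.seed(13)
  codons <- sense_codons()
  for (k in 1:5) {
    a <- sample(codons, 50, replace = TRUE)
    b <- mutate_codons(a, 0.15)
    r1 <- neiGojobori(a, b); r2 <- neiGojobori(b, a)
    for (sl in c("S", "N", "Sd", "Nd", "pS", "pN", "dS", "dN",
                 "varDS", "varDN", "statistic", "Z", "p"))
      expect_equal(slot(r1, sl), slot(r2, sl), info = sl)
  }
})

test_that("gapped, ambiguous and stop codons are excluded pairwise", {
  a <- c("ATG", "---", "CGA", "TAA", "GGN", "TTT")
  b <- c("ATG", "AAA", "---", "CGA", "GGG", "TTT")
  r <- neiGojobori(a, b)
  expect_equal(r@codonsUsed, 2L)
  expect_equal(r@excludedCodons, 4L)
  expect_error(neiGojobori(c("---"), c("AAA")), "no comparable")
})

test_that("the correction fails loudly when proportions reach 3/4", {
  # maximally synonymous-divergent pair: every codon pair differs at all
  # synonymous sites is impossible, so force pN instead via many
  # nonsynonymous differences on few codons
  a <- rep("TGG", 3)   # Trp: zero synonymous sites
  b <- rep("CAA", 3)
  expect_error(neiGojobori(a, b), "undefined|proportion")
})

test_that("omega-contrasted pair cohorts separate in the group t-test", {
  sel <- makeSelectionCohort(scheme = toyScheme(), nFocal = 8, nOther = 8,
                             omegaFocal = 0.2, omegaOther = 1.0,
                             lengthCodons = 200, seed = 4)
  tab <- pairwiseSelectionTable(sel$cds, sel$manifest)
  expect_equal(nrow(tab), 16L)
  expect_true(all(tab$note == ""))
  gt <- attr(tab, "groupTest")
  expect_true(gt$computable)
  expect_gt(gt$mean_focal, gt$mean_other)
  expect_lt(gt$p, 0.05)
  fs <- attr(tab, "familySummary")
  expect_setequal(fs$family, c("CPO", "CPA1"))
})

test_that("degenerate pair tables are handled not fatal", {
  cds <- Biostrings::DNAStringSet(c(x1 = "ATGAAACGATTT",
                                    x2 = "ATGAAACGATTT",
                                    y1 = "ATGAAACGATTT",
                                    y2 = "ATGAAACGATTT"))
  man <- data.frame(id_a = c("x1", "y1"), id_b = c("x2", "y2"),
                    family = c("CPO", "CPA1"))
  tab <- pairwiseSelectionTable(cds, man)
  expect_equal(tab$statistic, c(0, 0))
  gt <- attr(tab, "groupTest")
  expect_false(gt$computable)  # single pair per group: t-test not computable

  # a failing pair is flagged, not fatal
  man2 <- rbind(man, data.frame(id_a = "zz", id_b = "x1", family = "CPO"))
  tab2 <- pairwiseSelectionTable(cds, man2)
  expect_equal(nrow(tab2), 3L)
  expect_match(tab2$note[3], "missing")
  expect_true(all(is.na(tab2$statistic[3])))
})

test_that("strict-NG86 stop handling is available and differs where it should", {
  # TGG site counts differ between the conventions
  expect_equal(countSites("TGG", stopHandling = "count"), c(s = 0, n = 3))
  expect_gt(countSites("TAT", stopHandling = "exclude")[["s"]],
            countSites("TAT", stopHandling = "count")[["s"]])
})
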