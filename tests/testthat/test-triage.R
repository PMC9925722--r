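scheme <- syntheticScheme()
ref_prot <- as.character(schemeReference(scheme))

sub_at <- function(prot, pos, res) {
  substr(prot, pos, pos) <- res
  prot
}

test_that("the four rule-forced functional calls come out as forced", {
  map <- mapToScheme(ref_prot, scheme)

  # all scheme residues present
  expect_equal(functionalLabel(classifyFunction(ref_prot, map, scheme)),
               "ACTIVE")

  # single catalytic substitution E270 -> A
  p <- sub_at(ref_prot, 270, "A")
  fc <- classifyFunction(p, mapToScheme(p, scheme), scheme)
  expect_equal(functionalLabel(fc), "PSEUDOENZYME")
  expect_equal(catalyticSubstitutions(fc)$position, 270L)
  expect_equal(catalyticSubstitutions(fc)$observed, "A")

  # truncation before position 196 excludes key segments
  p <- substr(ref_prot, 1, 195)
  fc <- classifyFunction(p, mapToScheme(p, scheme), scheme)
  expect_equal(functionalLabel(fc), "PSEUDOGENE")
  expect_true(isFragment(fc))

  # three structural substitutions with catalytic intact
  pos <- as.integer(names(structuralPositions(scheme)))[1:3]
  p <- ref_prot
  for (q in pos) {
    new <- setdiff(c("A", "G", "W"), substr(p, q, q))[1]
    p <- sub_at(p, q, new)
  }
  fc <- classifyFunction(p, mapToScheme(p, scheme), scheme)
  expect_equal(functionalLabel(fc), "PSEUDOGENE")
  expect_equal(nrow(structuralSubstitutions(fc)), 3L)
  expect_false(isFragment(fc))
})

test_that("internal stops force pseudogene only upstream of catalysis", {
  # stop upstream of the last catalytic position (270)
  p <- sub_at(ref_prot, 100, "*")
  fc <- classifyFunction(p, mapToScheme(p, scheme), scheme)
  expect_equal(functionalLabel(fc), "PSEUDOGENE")
  expect_true(hasInternalStop(fc))

  # stop downstream of all catalytic positions: recorded, not forcing
  p <- sub_at(ref_prot, 300, "*")
  fc <- classifyFunction(p, mapToScheme(p, scheme), scheme)
  expect_true(hasInternalStop(fc))
  expect_equal(functionalLabel(fc), "ACTIVE")
})

test_that("residue-255 classes follow the carboxypeptidase convention", {
  map <- mapToScheme(ref_prot, scheme)
  cases <- list(R = "ACIDIC_SUBSTRATE",   # CPO-like Arg255
                K = "ACIDIC_SUBSTRATE",
                D = "BASIC_SUBSTRATE",    # CPB-like Asp255
                L = "HYDROPHOBIC_SUBSTRATE",  # CPA-like Leu255
                V = "HYDROPHOBIC_SUBSTRATE",
                Q = "POLAR_UNKNOWN",      # polar 255, uncharted specificity
                G = "POLAR_UNKNOWN")
  for (res in names(cases)) {
    p <- sub_at(ref_prot, 255, res)
    sc <- classifySpecificity(p, mapToScheme(p, scheme), scheme)
    expect_equal(substrateClass(sc), cases[[res]], info = res)
    expect_equal(specificityResidue(sc), res)
  }

  # absent position 255 (fragment) -> UNDETERMINED
  p <- substr(ref_prot, 1, 200)
  sc <- classifySpecificity(p, mapToScheme(p, scheme), scheme)
  expect_true(is.na(specificityResidue(sc)))
  expect_equal(substrateClass(sc), "UNDETERMINED")

  # residue outside the table -> UNDETERMINED with a warning
  p <- sub_at(ref_prot, 255, "X")
  expect_warning(
    sc <- classifySpecificity(p, mapToScheme(p, scheme), scheme),
    "class table")
  expect_equal(substrateClass(sc), "UNDETERMINED")
})

test_that("pocket reports show the pocket positions plus 255", {
  map <- mapToScheme(ref_prot, scheme)
  prof <- pocketReport(ref_prot, map, scheme)
  expect_equal(names(prof),
               as.character(sort(c(pocketPositions(scheme), 255L))))
  expect_equal(unname(prof["255"]), "R")

  # S243 -> F shows up in the profile
  p <- sub_at(ref_prot, 243, "F")
  prof <- pocketReport(p, mapToScheme(p, scheme), scheme)
  expect_equal(unname(prof["243"]), "F")

  # fragment missing the C-terminal half: absent at 253, 255, 268
  p <- substr(ref_prot, 1, 250)
  prof <- pocketReport(p, mapToScheme(p, scheme), scheme)
  expect_true(all(is.na(prof[c("253", "255", "268")])))
  expect_false(is.na(prof["203"]))
})

test_that("every protein receives exactly one label and labels partition", {
  co <- makeSyntheticCohort(nParalogs = 30, seed = 8)
  calls <- triageCohort(cohortProteins(co), scheme)
  expect_equal(nrow(calls), 30L)
  expect_true(all(calls$label %in%
                    c("ACTIVE", "PSEUDOENZYME", "PSEUDOGENE")))
  expect_equal(sum(table(calls$label)), 30L)
})

test_that("adding a catalytic substitution to an active protein never stays active", {
  set.seed(31)
  for (k in 1:8) {
    pos <- sample(as.integer(names(catalyticPositions(scheme))), 1)
    expected <- catalyticPositions(scheme)[[as.character(pos)]]
    new <- sample(setdiff(c("A", "G", "S", "T", "V"), expected), 1)
    p <- sub_at(ref_prot, pos, new)
    fc <- classifyFunction(p, mapToScheme(p, scheme), scheme)
    expect_false(functionalLabel(fc) == "ACTIVE")
  }
})

test_that("triage recovers constructive truth labels on a synthetic cohort", {
  co <- makeSyntheticCohort(nParalogs = 60, seed = 19)
  calls <- triageCohort(cohortProteins(co), scheme)
  truth <- cohortTruth(co)
  expect_equal(calls$label, truth$label)
  expect_equal(calls$substrate_class, truth$specificity_class)
  # realized mixture equals the requested mixture exactly
  expect_equal(unname(table(calls$label)[c("ACTIVE", "PSEUDOENZYME",
                                           "PSEUDOGENE")]),
               unname(table(c(rep("ACTIVE", 50), rep("PSEUDOENZYME", 5),
                              rep("PSEUDOGENE", 5)))[c("ACTIVE",
                                                       "PSEUDOENZYME",
                                                       "PSEUDOGENE")]))
})

test_that("structural threshold is configurable and re-tabulates calls", {
  pos <- as.integer(names(structuralPositions(scheme)))[1:2]
  p <- ref_prot
  for (q in pos) p <- sub_at(p, q, setdiff(c("A", "W"), substr(p, q, q))[1])
  map <- mapToScheme(p, scheme)
  expect_equal(functionalLabel(classifyFunction(p, map, scheme)),
               "PSEUDOGENE")
  expect_equal(functionalLabel(
    classifyFunction(p, map, scheme, structuralThreshold = 3L)), "ACTIVE")
})
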