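#' Accessors for scheme, map, call and result objects
#'
#' Slot access for the package's S4 classes goes through these accessors.
#'
#' @param x An object of the documented class.
#' @return The slot value (see each accessor's name).
#' @name accessors
NULL

#' @rdname accessors
#' @export
schemeReference <- function(x) {
  stopifnot(is(x, "FunctionalScheme"))
  x@reference
}

#' @rdname accessors
#' @export
schemeOffset <- function(x) {
  stopifnot(is(x, "FunctionalScheme"))
  x@offset
}

#' @rdname accessors
#' @export
catalyticPositions <- function(x) {
  stopifnot(is(x, "FunctionalScheme"))
  x@catalytic
}

#' @rdname accessors
#' @export
structuralPositions <- function(x) {
  stopifnot(is(x, "FunctionalScheme"))
  x@structural
}

#' @rdname accessors
#' @export
specificityPosition <- function(x) {
  stopifnot(is(x, "FunctionalScheme"))
  x@specificityPosition
}

#' @rdname accessors
#' @export
pocketPositions <- function(x) {
  stopifnot(is(x, "FunctionalScheme"))
  x@pocketPositions
}

#' @rdname accessors
#' @export
mapCoverage <- function(x) {
  stopifnot(is(x, "NumberingMap"))
  x@coverage
}

#' @rdname accessors
#' @export
functionalLabel <- function(x) {
  stopifnot(is(x, "FunctionalCall"))
  x@label
}

#' @rdname accessors
#' @export
catalyticSubstitutions <- function(x) {
  stopifnot(is(x, "FunctionalCall"))
  x@catalyticSubstitutions
}

#' @rdname accessors
#' @export
structuralSubstitutions <- function(x) {
  stopifnot(is(x, "FunctionalCall"))
  x@structuralSubstitutions
}

#' @rdname accessors
#' @export
isFragment <- function(x) {
  stopifnot(is(x, "FunctionalCall"))
  x@fragment
}

#' @rdname accessors
#' @export
hasInternalStop <- function(x) {
  stopifnot(is(x, "FunctionalCall"))
  x@internalStop
}

#' @rdname accessors
#' @export
substrateClass <- function(x) {
  stopifnot(is(x, "SpecificityCall"))
  x@substrateClass
}

#' @rdname accessors
#' @export
specificityResidue <- function(x) {
  stopifnot(is(x, "SpecificityCall"))
  x@residue255
}

#' @rdname accessors
#' @export
pocketProfile <- function(x) {
  stopifnot(is(x, "SpecificityCall"))
  x@pocketProfile
}

#' @rdname accessors
#' @export
cohortCDS <- function(x) {
  stopifnot(is(x, "SyntheticCohort"))
  x@cds
}

#' @rdname accessors
#' @export
cohortProteins <- function(x) {
  stopifnot(is(x, "SyntheticCohort"))
  x@proteins
}

#' @rdname accessors
#' @export
cohortTruth <- function(x) {
  stopifnot(is(x, "SyntheticCohort"))
  x@truth
}

#' @rdname accessors
#' @export
cohortLoci <- function(x) {
  stopifnot(is(x, "SyntheticCohort"))
  x@loci
}

#' Turn a SelectionResult into a one-row data.frame
#'
#' @param x A [SelectionResult-class] object.
#' @param row.names,optional,... Passed for S3 compatibility; ignored.
#' @return A one-row `data.frame` with the standard output columns.
#' @export
as.data.frame.SelectionResult <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(
    S = x@S, N = x@N, Sd = x@Sd, Nd = x@Nd,
    pS = x@pS, pN = x@pN, dS = x@dS, dN = x@dN,
    var_dS = x@varDS, var_dN = x@varDN,
    statistic = x@statistic, Z = x@Z, p = x@p,
    codons_used = x@codonsUsed, excluded_codons = x@excludedCodons
  )
}

setMethod("show", "FunctionalScheme", function(object) {
  cat("FunctionalScheme\n")
  cat("  reference length:", length(object@reference),
      "(numbering", object@offset, "..",
      object@offset + length(object@reference) - 1L, ")\n")
  cat("  catalytic positions:",
      paste(names(object@catalytic), collapse = ", "), "\n")
  cat("  structural positions:", length(object@structural), "\n")
  cat("  specificity position:", object@specificityPosition, "\n")
  cat("  pocket positions:",
      paste(object@pocketPositions, collapse = ", "), "\n")
})

setMethod("show", "NumberingMap", function(object) {
  cat("NumberingMap:", length(object@queryPos), "of", object@queryLength,
      "query residues mapped; coverage",
      sprintf("%.3f", object@coverage), "\n")
})

setMethod("show", "FunctionalCall", function(object) {
  cat("FunctionalCall:", object@label, "\n")
  cat("  catalytic substitutions:", nrow(object@catalyticSubstitutions),
      " structural substitutions:", nrow(object@structuralSubstitutions), "\n")
  cat("  fragment:", object@fragment,
      " internal stop:", object@internalStop, "\n")
})

setMethod("show", "SpecificityCall", function(object) {
  cat("SpecificityCall:", object@substrateClass,
      "(residue:", ifelse(is.na(object@residue255), "absent",
                          object@residue255), ")\n")
})

setMethod("show", "SelectionResult", function(object) {
  cat("Nei-Gojobori codon-based test of purifying selection (dN < dS)\n")
  cat(sprintf("  S = %.2f  N = %.2f  (codons used: %d, excluded: %d)\n",
              object@S, object@N, object@codonsUsed, object@excludedCodons))
  cat(sprintf("  Sd = %.2f  Nd = %.2f  pS = %.4f  pN = %.4f\n",
              object@Sd, object@Nd, object@pS, object@pN))
  cat(sprintf("  dS = %.4f  dN = %.4f  dS - dN = %.4f\n",
              object@dS, object@dN, object@statistic))
  cat(sprintf("  Z = %.3f  one-tailed p = %.4g\n", object@Z, object@p))
})

setMethod("show", "SizeComparison", function(object) {
  cat("Gene-size comparison (duplicated vs other genes)\n")
  cat(sprintf("  n = %d / %d;  mean = %.0f / %.0f bp;  median = %.0f / %.0f bp\n",
              object@n1, object@n2, object@mean1, object@mean2,
              object@median1, object@median2))
  if (!is.na(object@tP))
    cat(sprintf("  Welch t = %.3f, p = %.4g;  Kruskal-Wallis chi-sq = %.3f, p = %.4g\n",
                object@tStatistic, object@tP, object@kwStatistic, object@kwP))
  else
    cat("  tests omitted (a group has fewer than 2 members)\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", length(object@cds), "paralogs;",
      length(object@loci), "loci; seed", object@config$seed, "\n")
})
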