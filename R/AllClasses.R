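#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
NULL

#' FunctionalScheme: the reference-numbered residue inventory
#'
#' A `FunctionalScheme` bundles a numbered reference carboxypeptidase protein
#' with the positions that drive functional triage: the catalytic positions
#' (zinc coordination, substrate carboxylate binding and acid-base catalysis),
#' a structural-conservation inventory, the substrate-specificity position at
#' the base of the S1' pocket (bovine CPA1 position 255 by convention), and
#' the additional pocket-shaping positions.
#'
#' All positions are expressed in the reference's own numbering, which starts
#' at `offset` (the mature-enzyme convention puts position 1 at the first
#' mature residue, so a reference that still carries a prodomain can keep its
#' conventional numbering by setting `offset` accordingly, including to
#' negative or large values).
#'
#' @slot reference An [Biostrings::AAString] with the reference protein.
#' @slot offset Integer scalar; the reference number of the first residue.
#' @slot catalytic Named list; names are positions (as characters), values are
#'   character vectors of residues accepted at that position.
#' @slot structural Named list with the same shape as `catalytic`.
#' @slot specificityPosition Integer scalar, default 255.
#' @slot pocketPositions Integer vector of pocket-shaping positions.
#' @name FunctionalScheme-class
#' @aliases FunctionalScheme-class
#' @exportClass FunctionalScheme
setClass("FunctionalScheme",
  representation(
    reference = "ANY",
    offset = "integer",
    catalytic = "list",
    structural = "list",
    specificityPosition = "integer",
    pocketPositions = "integer"
  )
)

setValidity("FunctionalScheme", function(object) {
  msg <- character(0)
  if (length(object@offset) != 1L) msg <- c(msg, "offset must be a scalar")
  cat_pos <- as.integer(names(object@catalytic))
  str_pos <- as.integer(names(object@structural))
  if (anyNA(cat_pos) || anyNA(str_pos))
    msg <- c(msg, "position names must be integers")
  if (length(intersect(cat_pos, str_pos)) > 0L)
    msg <- c(msg, "catalytic and structural position sets must be disjoint")
  if (object@specificityPosition %in% cat_pos)
    msg <- c(msg, "specificity position must not be catalytic")
  rng <- object@offset + c(0L, length(object@reference) - 1L)
  all_pos <- c(cat_pos, str_pos, object@specificityPosition,
               object@pocketPositions)
  if (length(all_pos) && (min(all_pos) < rng[1] || max(all_pos) > rng[2]))
    msg <- c(msg, "scheme positions must lie within the reference numbering range")
  if (length(msg)) msg else TRUE
})

#' NumberingMap: query-to-reference residue correspondence
#'
#' Produced by [buildNumberingMap()] from a global alignment of a query
#' protein to a scheme's numbered reference. Maps 1-based query residue
#' indices to reference position numbers; both coordinates are strictly
#' increasing. `coverage` is the fraction of reference positions that
#' received a query residue.
#'
#' @slot queryPos Integer vector of 1-based query residue indices.
#' @slot refPos Integer vector of matching reference position numbers.
#' @slot coverage Numeric scalar in [0, 1].
#' @slot queryLength Integer; length of the (ungapped) query.
#' @slot refOffset Integer; reference number of the first reference residue.
#' @slot refLength Integer; length of the reference.
#' @name NumberingMap-class
#' @exportClass NumberingMap
setClass("NumberingMap",
  representation(
    queryPos = "integer",
    refPos = "integer",
    coverage = "numeric",
    queryLength = "integer",
    refOffset = "integer",
    refLength = "integer"
  )
)

setValidity("NumberingMap", function(object) {
  msg <- character(0)
  if (length(object@queryPos) != length(object@refPos))
    msg <- c(msg, "queryPos and refPos must have equal length")
  if (is.unsorted(object@queryPos, strictly = TRUE) ||
      is.unsorted(object@refPos, strictly = TRUE))
    msg <- c(msg, "mapping must be strictly increasing in both coordinates")
  if (object@coverage < 0 || object@coverage > 1)
    msg <- c(msg, "coverage must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' FunctionalCall: per-paralog functional classification
#'
#' The outcome of [classifyFunction()]: one of `"ACTIVE"`, `"PSEUDOENZYME"`
#' or `"PSEUDOGENE"`, with the substitution evidence that produced the call.
#'
#' @slot label Character scalar.
#' @slot catalyticSubstitutions A [S4Vectors::DataFrame] with columns
#'   `position`, `expected`, `observed`.
#' @slot structuralSubstitutions Same shape.
#' @slot fragment Logical; TRUE when one or more catalytic positions are not
#'   covered by the query (truncated/fragmentary protein).
#' @slot internalStop Logical; TRUE when a stop codon occurs upstream of the
#'   last catalytic position.
#' @name FunctionalCall-class
#' @exportClass FunctionalCall
setClass("FunctionalCall",
  representation(
    label = "character",
    catalyticSubstitutions = "ANY",
    structuralSubstitutions = "ANY",
    fragment = "logical",
    internalStop = "logical"
  )
)

setValidity("FunctionalCall", function(object) {
  ok_labels <- c("ACTIVE", "PSEUDOENZYME", "PSEUDOGENE")
  msg <- character(0)
  if (!object@label %in% ok_labels)
    msg <- c(msg, "label must be ACTIVE, PSEUDOENZYME or PSEUDOGENE")
  if (object@label == "ACTIVE" &&
      (nrow(object@catalyticSubstitutions) > 0L || object@fragment))
    msg <- c(msg, "ACTIVE implies no catalytic substitutions and fragment = FALSE")
  if (length(msg)) msg else TRUE
})

#' SpecificityCall: predicted substrate-specificity class
#'
#' The outcome of [classifySpecificity()]: the residue observed at the
#' scheme's specificity position (CPA1 255 equivalent), its substrate class
#' under the configured residue-to-class table, and the residues observed at
#' the pocket-shaping positions.
#'
#' @slot residue255 Character scalar (one amino-acid letter) or `NA` when the
#'   position is absent from the query.
#' @slot substrateClass One of `"HYDROPHOBIC_SUBSTRATE"`, `"BASIC_SUBSTRATE"`,
#'   `"ACIDIC_SUBSTRATE"`, `"POLAR_UNKNOWN"`, `"UNDETERMINED"`.
#' @slot pocketProfile Named character vector: residue (or `NA`) at each
#'   pocket position plus the specificity position.
#' @name SpecificityCall-class
#' @exportClass SpecificityCall
setClass("SpecificityCall",
  representation(
    residue255 = "character",
    substrateClass = "character",
    pocketProfile = "character"
  )
)

setValidity("SpecificityCall", function(object) {
  ok <- c("HYDROPHOBIC_SUBSTRATE", "BASIC_SUBSTRATE", "ACIDIC_SUBSTRATE",
          "POLAR_UNKNOWN", "UNDETERMINED")
  msg <- character(0)
  if (!object@substrateClass %in% ok)
    msg <- c(msg, "unknown substrate class")
  if (is.na(object@residue255) && object@substrateClass != "UNDETERMINED")
    msg <- c(msg, "absent residue implies UNDETERMINED")
  if (length(msg)) msg else TRUE
})

#' SelectionResult: the full Nei-Gojobori record for one pair
#'
#' Returned by [neiGojobori()]. Holds expected synonymous/nonsynonymous site
#' counts (S, N; averaged over the two sequences), observed synonymous and
#' nonsynonymous differences (Sd, Nd; averaged over minimal mutational
#' pathways), the proportions pS and pN, Jukes-Cantor corrected distances dS
#' and dN with their analytical (delta-method) variances, the test statistic
#' dS - dN, the Z score and the one-tailed p value for the alternative
#' dN < dS (purifying selection).
#'
#' @slot S,N,Sd,Nd,pS,pN,dS,dN,varDS,varDN,statistic,Z,p Numeric scalars.
#' @slot codonsUsed,excludedCodons Integer scalars.
#' @name SelectionResult-class
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(
    S = "numeric", N = "numeric", Sd = "numeric", Nd = "numeric",
    pS = "numeric", pN = "numeric", dS = "numeric", dN = "numeric",
    varDS = "numeric", varDN = "numeric",
    statistic = "numeric", Z = "numeric", p = "numeric",
    codonsUsed = "integer", excludedCodons = "integer"
  )
)

setValidity("SelectionResult", function(object) {
  msg <- character(0)
  if (object@p < 0 || object@p > 1) msg <- c(msg, "p must lie in [0, 1]")
  if (object@dS < object@pS - 1e-9 || object@dN < object@pN - 1e-9)
    msg <- c(msg, "Jukes-Cantor correction must not shrink a proportion")
  if (length(msg)) msg else TRUE
})

#' SizeComparison: two-group gene-size comparison
#'
#' Returned by [compareGeneSizes()]. Descriptive statistics for the
#' frequently-duplicated and other gene groups, a Welch two-sample t-test and
#' a Kruskal-Wallis test on gene size (exon-span, bp). Test fields are `NA`
#' when either group has fewer than two members.
#'
#' @slot n1,n2 Integer group sizes (duplicated group first).
#' @slot mean1,mean2,median1,median2 Numeric descriptives (bp).
#' @slot tStatistic,tP,kwStatistic,kwP Numeric test results.
#' @name SizeComparison-class
#' @exportClass SizeComparison
setClass("SizeComparison",
  representation(
    n1 = "integer", n2 = "integer",
    mean1 = "numeric", mean2 = "numeric",
    median1 = "numeric", median2 = "numeric",
    tStatistic = "numeric", tP = "numeric",
    kwStatistic = "numeric", kwP = "numeric"
  )
)

#' SyntheticCohort: generated sequences, loci and truth labels
#'
#' Produced by [makeSyntheticCohort()]. Contains everything the analysis
#' pipeline consumes, plus the constructive truth labels the generator
#' actually applied, so classifier recovery can be checked exactly.
#'
#' @slot cds A [Biostrings::DNAStringSet] of paralog coding sequences.
#' @slot proteins An [Biostrings::AAStringSet] of their translations.
#' @slot truth A [S4Vectors::DataFrame]: id, family, functional label,
#'   specificity class, residue installed at the specificity position.
#' @slot loci A [GenomicRanges::GRanges] of gene loci (may be empty).
#' @slot config The generator configuration list (seed included).
#' @name SyntheticCohort-class
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
  representation(
    cds = "ANY",
    proteins = "ANY",
    truth = "ANY",
    loci = "ANY",
    config = "list"
  )
)
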