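#' @importFrom Biostrings pairwiseAlignment pattern subject score
NULL

# Biostrings ships BLOSUM62 as a dataset, not an exported object.
.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Affine-gap scoring scheme for global protein alignment
#'
#' A gap of length L is penalised `gapOpen + L * gapExtend` (both negative),
#' i.e. a single-residue gap under the defaults (-11, -1) costs -12, the
#' usual BLOSUM62 convention for divergent protein pairs. The substitution
#' matrix must be symmetric; the default is BLOSUM62 (which covers `X` and
#' `*`, so internal stop codons in conceptual translations align cleanly).
#'
#' @param substitutionMatrix Symmetric numeric matrix with amino-acid row and
#'   column names, or `NULL` for BLOSUM62.
#' @param gapOpen,gapExtend Negative integers, `gapOpen <= gapExtend < 0`.
#' @return A list with class `"ScoringScheme"`.
#' @export
scoringScheme <- function(substitutionMatrix = NULL, gapOpen = -11L,
                          gapExtend = -1L) {
  if (is.null(substitutionMatrix)) substitutionMatrix <- .blosum62()
  if (!isTRUE(all.equal(substitutionMatrix, t(substitutionMatrix))))
    stop("substitution matrix must be symmetric")
  if (!(gapOpen <= gapExtend && gapExtend < 0))
    stop("require gapOpen <= gapExtend < 0")
  structure(list(matrix = substitutionMatrix,
                 gapOpen = as.integer(gapOpen),
                 gapExtend = as.integer(gapExtend)),
            class = "ScoringScheme")
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-delimited matrix format used by NCBI/EMBOSS (lines
#' starting with `#` are comments; the first non-comment row names the
#' columns).
#'
#' @param path Path to the matrix file.
#' @return A symmetric numeric matrix.
#' @export
readScoringMatrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- strsplit(trimws(lines[-1]), "\\s+")
  m <- matrix(0, length(body), length(cols),
              dimnames = list(vapply(body, `[`, "", 1L), cols))
  for (i in seq_along(body))
    m[i, ] <- as.numeric(body[[i]][-1])
  m
}

#' Global pairwise protein alignment
#'
#' Optimal Needleman-Wunsch global alignment under affine-gap scoring,
#' computed with [Biostrings::pairwiseAlignment()] (`type = "global"`, end
#' gaps penalised). The traceback is deterministic, so repeated calls give
#' identical alignments.
#'
#' @param a,b Proteins: [Biostrings::AAString], single-element `AAStringSet`,
#'   or character strings. Both must be non-empty.
#' @param scheme A [scoringScheme()].
#' @return A list with class `"ProteinAlignment"`: elements `alignedA`,
#'   `alignedB` (equal-length gapped strings) and `score`.
#' @export
#' @examples
#' globalAlign("MKRW", "MKW")
globalAlign <- function(a, b, scheme = scoringScheme()) {
  sa <- toupper(as.character(a)); sb <- toupper(as.character(b))
  if (nchar(sa) == 0L || nchar(sb) == 0L)
    stop("cannot align an empty protein")
  aln <- pairwiseAlignment(
    AAString(sa), AAString(sb),
    substitutionMatrix = scheme$matrix,
    gapOpening = -scheme$gapOpen,
    gapExtension = -scheme$gapExtend,
    type = "global"
  )
  out <- list(alignedA = as.character(Biostrings::alignedPattern(aln)),
              alignedB = as.character(Biostrings::alignedSubject(aln)),
              score = score(aln))
  stopifnot(nchar(out$alignedA) == nchar(out$alignedB),
            gsub("-", "", out$alignedA) == sa,
            gsub("-", "", out$alignedB) == sb)
  class(out) <- "ProteinAlignment"
  out
}

#' Write a pairwise alignment as aligned FASTA
#'
#' @param alignment A `"ProteinAlignment"` from [globalAlign()].
#' @param path Output path.
#' @param ids Character vector of two record ids.
#' @return `path`, invisibly.
#' @export
writeAlignedFasta <- function(alignment, path, ids = c("a", "b")) {
  writeLines(c(paste0(">", ids[1]), alignment$alignedA,
               paste0(">", ids[2]), alignment$alignedB), path)
  invisible(path)
}

#' Build a reference-numbering map for a query protein
#'
#' Globally aligns the query to the numbered reference and records, for each
#' alignment column where both rows carry a residue, the correspondence from
#' the 1-based query index to the reference position number. Reference
#' numbering starts at `offset` (bovine CPA1 mature-enzyme convention:
#' position 1 is the first mature residue), so schemes whose reference still
#' carries a prodomain stay correctly numbered. Coverage is the fraction of
#' reference positions that received a query residue.
#'
#' @param query,reference Proteins (strings, `AAString`, or single-element
#'   `AAStringSet`).
#' @param scheme A [scoringScheme()].
#' @param offset Integer; reference number of the reference's first residue.
#' @return A [NumberingMap-class] object.
#' @export
buildNumberingMap <- function(query, reference, scheme = scoringScheme(),
                              offset = 1L) {
  aln <- globalAlign(query, reference, scheme)
  qa <- strsplit(aln$alignedA, "")[[1]]
  ra <- strsplit(aln$alignedB, "")[[1]]
  qi <- cumsum(qa != "-")
  ri <- cumsum(ra != "-")
  both <- qa != "-" & ra != "-"
  new("NumberingMap",
      queryPos = as.integer(qi[both]),
      refPos = as.integer(ri[both] + offset - 1L),
      coverage = sum(both) / sum(ra != "-"),
      queryLength = as.integer(sum(qa != "-")),
      refOffset = as.integer(offset),
      refLength = as.integer(sum(ra != "-")))
}

#' Query residue at a reference position
#'
#' Returns the query residue aligned to the given reference position, or
#' `NA` when that column is a query gap or lies outside query coverage
#' (the position is then reported as absent).
#'
#' @param map A [NumberingMap-class].
#' @param query The (ungapped) query protein the map was built from.
#' @param refPosition Integer reference position, within the reference
#'   numbering range.
#' @return Single character (amino-acid letter or `*`), or `NA_character_`.
#' @export
residueAt <- function(map, query, refPosition) {
  lo <- map@refOffset
  hi <- map@refOffset + map@refLength - 1L
  if (refPosition < lo || refPosition > hi)
    stop("reference position ", refPosition,
         " outside reference numbering range [", lo, ", ", hi, "]")
  i <- match(as.integer(refPosition), map@refPos)
  if (is.na(i)) return(NA_character_)
  substr(toupper(as.character(query)), map@queryPos[i], map@queryPos[i])
}

#' CodonAlignment: codon rows threaded onto a protein alignment
#'
#' Two equal-length codon vectors with gaps in whole-codon (`"---"`) units;
#' each ungapped codon translates to the residue in the matching
#' protein-alignment column.
#'
#' @slot codonsA,codonsB Character vectors of codons or `"---"`.
#' @name CodonAlignment-class
#' @exportClass CodonAlignment
setClass("CodonAlignment",
  representation(codonsA = "character", codonsB = "character"))

setValidity("CodonAlignment", function(object) {
  if (length(object@codonsA) != length(object@codonsB))
    return("codon rows must have equal length")
  TRUE
})

setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment:", length(object@codonsA), "codon columns\n")
})

#' Thread coding sequences onto a protein alignment
#'
#' Expands each protein-alignment gap to a codon-triplet gap and verifies,
#' column by column, that every ungapped codon translates to the residue in
#' the corresponding protein-alignment row. Trailing stop codons are trimmed
#' before threading.
#'
#' @param alignment A `"ProteinAlignment"` of the two translated proteins.
#' @param cdsA,cdsB The coding sequences (strings or `DNAString`), in frame.
#' @param code Genetic code as [Biostrings::GENETIC_CODE].
#' @return A [CodonAlignment-class] object.
#' @export
threadCodons <- function(alignment, cdsA, cdsB,
                         code = Biostrings::GENETIC_CODE) {
  thread_one <- function(row, cds, which) {
    cod <- codonSplit(trimTrailingStop(cds, code))
    chars <- strsplit(row, "")[[1]]
    n_res <- sum(chars != "-")
    if (length(cod) != n_res)
      stop("coding sequence ", which, " has ", length(cod),
           " codons but its protein-alignment row has ", n_res, " residues")
    out <- rep("---", length(chars))
    out[chars != "-"] <- cod
    # translation consistency per column
    idx <- which(chars != "-")
    aa <- vapply(cod, function(cc) {
      if (grepl("N", cc)) "X" else unname(code[cc])
    }, "")
    bad <- which(aa != chars[idx])
    if (length(bad))
      stop("translation mismatch in sequence ", which,
           " at alignment column ", idx[bad[1]],
           ": codon ", cod[bad[1]], " vs residue ", chars[idx[bad[1]]])
    out
  }
  new("CodonAlignment",
      codonsA = thread_one(alignment$alignedA, cdsA, "A"),
      codonsB = thread_one(alignment$alignedB, cdsB, "B"))
}

#' Align two coding sequences at the codon level
#'
#' Convenience wrapper: translate both CDS (after trimming trailing stops),
#' globally align the proteins, then thread the codons back on.
#'
#' @param cdsA,cdsB Coding sequences.
#' @param scheme A [scoringScheme()].
#' @param code Genetic code.
#' @return A [CodonAlignment-class].
#' @export
alignCodingPair <- function(cdsA, cdsB, scheme = scoringScheme(),
                            code = Biostrings::GENETIC_CODE) {
  pa <- as.character(translateCDS(trimTrailingStop(cdsA, code), code))
  pb <- as.character(translateCDS(trimTrailingStop(cdsB, code), code))
  aln <- globalAlign(pa, pb, scheme)
  threadCodons(aln, cdsA, cdsB, code)
}
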