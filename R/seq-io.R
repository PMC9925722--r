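#' @importFrom Biostrings DNAStringSet AAStringSet DNAString AAString
#'   readDNAStringSet readAAStringSet writeXStringSet translate GENETIC_CODE
#'   subseq
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

.check_fasta_ids <- function(x, path) {
  if (length(x) == 0L)
    stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(x))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  ids
}

#' Read coding sequences from a FASTA file
#'
#' Reads a multi-record nucleotide FASTA. Record ids are the first
#' whitespace-delimited token of each header (the remainder is kept as the
#' description); sequences are upper-cased. Duplicate ids and empty files are
#' hard errors. Ambiguous `N` bases are accepted; downstream codon analysis
#' excludes N-containing codons pairwise.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record id, with a
#'   `description` metadata column.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "atg", ">b", "TTT"), fa)
#' readCodingSequences(fa)
readCodingSequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readDNAStringSet(path)
  ids <- .check_fasta_ids(x, path)
  desc <- sub("^\\S+\\s*", "", names(x))
  x <- DNAStringSet(toupper(as.character(x)))
  names(x) <- ids
  mcols(x)$description <- desc
  x
}

#' Read protein sequences from a FASTA file
#'
#' As [readCodingSequences()] but for amino-acid records; `*` (stop) and `X`
#' (unknown) letters are retained.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::AAStringSet] named by record id.
#' @export
readProteins <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readAAStringSet(path)
  ids <- .check_fasta_ids(x, path)
  desc <- sub("^\\S+\\s*", "", names(x))
  x <- AAStringSet(toupper(as.character(x)))
  names(x) <- ids
  mcols(x)$description <- desc
  x
}

#' Trim a trailing stop codon from a coding sequence
#'
#' Removes one terminal stop codon (TAA/TAG/TGA) when the sequence is a whole
#' number of codons; internal stops are untouched (they are evidence for the
#' triage stage, not noise).
#'
#' @param cds A [Biostrings::DNAString] or single character string.
#' @param code Genetic code, a named character vector as
#'   [Biostrings::GENETIC_CODE].
#' @return A character string without the trailing stop.
#' @export
trimTrailingStop <- function(cds, code = Biostrings::GENETIC_CODE) {
  s <- toupper(as.character(cds))
  n <- nchar(s)
  if (n >= 3L && n %% 3L == 0L) {
    last <- substr(s, n - 2L, n)
    if (!is.na(code[last]) && code[last] == "*")
      s <- substr(s, 1L, n - 3L)
  }
  s
}

#' Translate a coding sequence
#'
#' Codon-by-codon translation under a supplied genetic code. Internal stop
#' codons are retained as `*`; codons containing `N` translate to `X`. A
#' length not divisible by three is a frame error.
#'
#' @param cds A [Biostrings::DNAString], a single-element
#'   [Biostrings::DNAStringSet], or a character string.
#' @param code Genetic code, a named character vector as
#'   [Biostrings::GENETIC_CODE].
#' @return A [Biostrings::AAString] of length `nchar(cds)/3`.
#' @export
#' @examples
#' translateCDS("ATGAAACGATAA")  # MKR*
#' translateCDS("ATGNNT")        # MX
translateCDS <- function(cds, code = Biostrings::GENETIC_CODE) {
  s <- toupper(as.character(cds))
  if (length(s) != 1L) stop("translateCDS() expects a single sequence")
  if (nchar(s) %% 3L != 0L)
    stop("frame-broken coding sequence: length ", nchar(s),
         " is not divisible by 3")
  if (nchar(s) == 0L) return(AAString(""))
  translate(DNAString(s), genetic.code = code, if.fuzzy.codon = "X",
            no.init.codon = TRUE)
}

#' Split a coding sequence into codons
#'
#' @param cds A coding sequence (string or `DNAString`), length divisible
#'   by 3.
#' @return Character vector of codons.
#' @export
codonSplit <- function(cds) {
  s <- toupper(as.character(cds))
  if (nchar(s) %% 3L != 0L)
    stop("frame-broken coding sequence: length ", nchar(s))
  if (nchar(s) == 0L) return(character(0))
  substring(s, seq(1L, nchar(s), by = 3L), seq(3L, nchar(s), by = 3L))
}

#' Read a gene-locus table
#'
#' Parses a tab-separated table with a header row and columns `gene_id`,
#' `chromosome`, `start`, `end`, `strand`, `family_label`,
#' `duplicated_group`. Coordinates are 1-based inclusive (the Ensembl
#' gene-table convention); gene size is the exon span `end - start + 1`
#' (first-exon start to last-exon end), not summed exon length. Rows with
#' `start >= end` are rejected with their line number.
#'
#' @param path Path to the TSV file.
#' @return A [GenomicRanges::GRanges], sorted by chromosome then start, with
#'   metadata columns `gene_id`, `family_label`, `duplicated_group` and
#'   `gene_size`.
#' @export
readLocusTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "chromosome", "start", "end", "strand",
            "family_label", "duplicated_group")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("locus table lacks column(s): ", paste(missing_cols, collapse = ", "))
  bad <- which(tab$start >= tab$end)
  if (length(bad))
    stop("invalid locus row(s) with start >= end at line(s) ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header row
  lociGRanges(tab)
}

#' Build a GRanges of gene loci from a data.frame
#'
#' @param tab A data.frame with the locus-table columns (see
#'   [readLocusTable()]).
#' @return A sorted [GenomicRanges::GRanges] with `gene_size = width`.
#' @export
lociGRanges <- function(tab) {
  stopifnot(all(tab$start < tab$end))
  gr <- GRanges(
    seqnames = as.character(tab$chromosome),
    ranges = IRanges(start = as.integer(tab$start), end = as.integer(tab$end)),
    strand = as.character(tab$strand)
  )
  mcols(gr)$gene_id <- as.character(tab$gene_id)
  mcols(gr)$family_label <- as.character(tab$family_label)
  mcols(gr)$duplicated_group <- as.logical(tab$duplicated_group)
  mcols(gr)$gene_size <- GenomicRanges::width(gr)
  gr[order(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr))]
}

#' Write a gene-locus GRanges back to the TSV dialect
#'
#' @param loci A [GenomicRanges::GRanges] as produced by [readLocusTable()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeLocusTable <- function(loci, path) {
  tab <- data.frame(
    gene_id = mcols(loci)$gene_id,
    chromosome = as.character(GenomicRanges::seqnames(loci)),
    start = GenomicRanges::start(loci),
    end = GenomicRanges::end(loci),
    strand = as.character(GenomicRanges::strand(loci)),
    family_label = mcols(loci)$family_label,
    duplicated_group = mcols(loci)$duplicated_group
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
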