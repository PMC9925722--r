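#' Construct a FunctionalScheme
#'
#' The scheme is the residue inventory that drives functional triage of
#' carboxypeptidase paralogs. The default catalytic inventory is the CPA/B
#' one, in bovine CPA1 numbering: H69, E72 and H196 coordinate the catalytic
#' zinc ion; R127, N144 and R145 bind the C-terminal carboxylate of the
#' substrate; E270 performs acid-base catalysis. The default specificity
#' position is 255 (base of the S1' pocket) and the default pocket-shaping
#' set is 203, 207, 243, 247, 253 and 268. The structural-conservation
#' inventory (residues invariant across the subfamily and required for fold
#' integrity) is not universal and must be supplied per scheme; see
#' [syntheticScheme()] for the packaged synthetic fixture.
#'
#' @param reference Reference protein (string, `AAString`, or single-element
#'   `AAStringSet`) carrying the scheme's numbering.
#' @param offset Integer; reference number of the first residue of
#'   `reference`.
#' @param catalytic Named list: position -> character vector of accepted
#'   residues.
#' @param structural Named list with the same shape.
#' @param specificityPosition Integer.
#' @param pocketPositions Integer vector.
#' @return A [FunctionalScheme-class] object.
#' @export
functionalScheme <- function(reference,
                             offset = 1L,
                             catalytic = list(
                               "69" = "H", "72" = "E", "127" = "R",
                               "144" = "N", "145" = "R", "196" = "H",
                               "270" = "E"),
                             structural = list(),
                             specificityPosition = 255L,
                             pocketPositions = c(203L, 207L, 243L, 247L,
                                                 253L, 268L)) {
  new("FunctionalScheme",
      reference = AAString(toupper(as.character(reference))),
      offset = as.integer(offset),
      catalytic = lapply(catalytic, as.character),
      structural = lapply(structural, as.character),
      specificityPosition = as.integer(specificityPosition),
      pocketPositions = as.integer(pocketPositions))
}

#' Residue-255 substrate-specificity class table
#'
#' Maps the residue at the specificity position to a predicted C-terminal
#' substrate class, following the classical carboxypeptidase convention: a
#' hydrophobic residue 255 gives specificity for aliphatic/aromatic
#' (hydrophobic) C-terminal residues; an acidic residue 255 (as in CPB,
#' Asp255) gives specificity for basic residues; a basic residue 255 (as in
#' CPO, Arg255) gives specificity for acidic residues; polar residues give
#' an experimentally uncharted class reported as `POLAR_UNKNOWN`.
#'
#' Two assignments are conventions of this package rather than settled
#' biochemistry, and are therefore override-friendly: glycine is grouped
#' with the polar/unknown class (a Gly255 paralog has shown
#' hydrophobic-substrate activity, so users may prefer to regroup it), and
#' histidine is grouped with the basic residues on standard physicochemical
#' grounds.
#'
#' @return Named character vector: names are amino-acid letters, values are
#'   substrate classes.
#' @export
defaultClassTable <- function() {
  c(A = "HYDROPHOBIC_SUBSTRATE", V = "HYDROPHOBIC_SUBSTRATE",
    L = "HYDROPHOBIC_SUBSTRATE", I = "HYDROPHOBIC_SUBSTRATE",
    M = "HYDROPHOBIC_SUBSTRATE", F = "HYDROPHOBIC_SUBSTRATE",
    W = "HYDROPHOBIC_SUBSTRATE", P = "HYDROPHOBIC_SUBSTRATE",
    D = "BASIC_SUBSTRATE", E = "BASIC_SUBSTRATE",
    R = "ACIDIC_SUBSTRATE", K = "ACIDIC_SUBSTRATE", H = "ACIDIC_SUBSTRATE",
    S = "POLAR_UNKNOWN", T = "POLAR_UNKNOWN", N = "POLAR_UNKNOWN",
    Q = "POLAR_UNKNOWN", C = "POLAR_UNKNOWN", Y = "POLAR_UNKNOWN",
    G = "POLAR_UNKNOWN")
}

#' Build the numbering map of a query against a scheme's reference
#'
#' @param query Query protein.
#' @param scheme A [FunctionalScheme-class].
#' @param scoring A [scoringScheme()].
#' @return A [NumberingMap-class].
#' @export
mapToScheme <- function(query, scheme, scoring = scoringScheme()) {
  buildNumberingMap(query, scheme@reference, scoring,
                    offset = scheme@offset)
}

.observed_at <- function(positions, protein, map) {
  vapply(positions, function(p) residueAt(map, protein, p), "")
}

.substitution_frame <- function(inventory, protein, map) {
  pos <- as.integer(names(inventory))
  obs <- .observed_at(pos, protein, map)
  ok <- mapply(function(o, exp) !is.na(o) && o %in% exp, obs, inventory)
  keep <- !is.na(obs) & !ok
  DataFrame(position = pos[keep],
            expected = vapply(inventory[keep], paste, "", collapse = "/"),
            observed = unname(obs[keep]))
}

#' Classify a paralog protein as active enzyme, pseudoenzyme or pseudogene
#'
#' Applies the triage decision rule, in order:
#' 1. if any catalytic position is not covered by the query (fragmentary
#'    protein missing key segments), or an internal stop occurs upstream of
#'    the last catalytic position, the gene is called `PSEUDOGENE` with
#'    fragment / internal-stop evidence;
#' 2. else if at least `structuralThreshold` structurally conserved
#'    positions carry substitutions ("multiple conserved residues
#'    substituted"), `PSEUDOGENE`;
#' 3. else if at least one catalytic position is substituted,
#'    `PSEUDOENZYME`;
#' 4. else `ACTIVE`.
#'
#' Internal stops downstream of the last catalytic position are recorded in
#' the call but do not force a pseudogene label (they may only truncate a
#' C-terminal anchor region).
#'
#' @param protein Query protein (may contain `*` for internal stops).
#' @param map Its [NumberingMap-class] against the scheme reference.
#' @param scheme A [FunctionalScheme-class].
#' @param structuralThreshold Integer; substitution count at structural
#'   positions that forces a pseudogene call (default 2).
#' @return A [FunctionalCall-class].
#' @export
classifyFunction <- function(protein, map, scheme, structuralThreshold = 2L) {
  if (map@refLength != length(scheme@reference) ||
      map@refOffset != scheme@offset)
    stop("numbering map was not built against this scheme's reference")
  prot <- toupper(as.character(protein))
  cat_pos <- as.integer(names(scheme@catalytic))
  cat_obs <- .observed_at(cat_pos, prot, map)
  fragment <- anyNA(cat_obs)

  # reference-equivalent position of each internal stop: the stop's own
  # mapped position, or the last mapped position preceding it
  stars <- which(strsplit(prot, "")[[1]] == "*")
  stars <- stars[stars < nchar(prot)]  # a terminal * is not an internal stop
  stop_before_last_cat <- FALSE
  if (length(stars)) {
    ref_equiv <- vapply(stars, function(q) {
      i <- which(map@queryPos <= q)
      if (length(i)) max(map@refPos[i]) else scheme@offset - 1L
    }, integer(1))
    stop_before_last_cat <- any(ref_equiv <= max(cat_pos))
  }

  cat_subs <- .substitution_frame(scheme@catalytic, prot, map)
  str_subs <- .substitution_frame(scheme@structural, prot, map)

  label <- if (fragment || stop_before_last_cat) "PSEUDOGENE"
    else if (nrow(str_subs) >= structuralThreshold) "PSEUDOGENE"
    else if (nrow(cat_subs) >= 1L) "PSEUDOENZYME"
    else "ACTIVE"

  new("FunctionalCall",
      label = label,
      catalyticSubstitutions = cat_subs,
      structuralSubstitutions = str_subs,
      fragment = fragment,
      internalStop = length(stars) > 0L)
}

#' Predict substrate-specificity class from the residue-255 equivalent
#'
#' Looks up the query residue aligned to the scheme's specificity position
#' (the CPA1 residue-255 equivalent at the base of the S1' pocket) and maps
#' it through the residue-to-class table. An absent position (query gap or
#' fragment) gives `UNDETERMINED`; a residue letter outside the table (e.g.
#' `X` or `*`) gives `UNDETERMINED` with a warning.
#'
#' @param protein Query protein.
#' @param map Its [NumberingMap-class].
#' @param scheme A [FunctionalScheme-class].
#' @param classTable Named character vector as [defaultClassTable()].
#' @return A [SpecificityCall-class].
#' @export
classifySpecificity <- function(protein, map, scheme,
                                classTable = defaultClassTable()) {
  res <- residueAt(map, protein, scheme@specificityPosition)
  cls <- if (is.na(res)) {
    "UNDETERMINED"
  } else if (!res %in% names(classTable)) {
    warning("residue '", res, "' at the specificity position is not in the ",
            "class table; reporting UNDETERMINED")
    "UNDETERMINED"
  } else {
    unname(classTable[res])
  }
  new("SpecificityCall",
      residue255 = res,
      substrateClass = cls,
      pocketProfile = pocketReport(protein, map, scheme))
}

#' Report residues at the pocket-shaping positions
#'
#' Ordered residues (or `NA` for absent) observed at the scheme's pocket
#' positions plus the specificity position, for tabular output. These
#' positions shape the S1' substrate pocket and fine-tune specificity beyond
#' residue 255 itself.
#'
#' @inheritParams classifySpecificity
#' @return Named character vector (names are reference positions).
#' @export
pocketReport <- function(protein, map, scheme) {
  pos <- sort(unique(c(scheme@pocketPositions, scheme@specificityPosition)))
  out <- .observed_at(pos, toupper(as.character(protein)), map)
  names(out) <- pos
  out
}

#' Triage a whole cohort of paralog proteins
#'
#' Runs [mapToScheme()], [classifyFunction()] and [classifySpecificity()] on
#' every protein and tabulates one row per paralog.
#'
#' @param proteins A named [Biostrings::AAStringSet] (or named character
#'   vector) of predicted paralog proteins.
#' @param scheme A [FunctionalScheme-class].
#' @param scoring A [scoringScheme()].
#' @param classTable Residue-to-class table.
#' @param structuralThreshold Passed to [classifyFunction()].
#' @param family Optional character vector of family labels (recycled name
#'   lookup by id when named).
#' @return A [S4Vectors::DataFrame] with columns `id`, `family`, `label`,
#'   `residue_255`, `substrate_class`, `n_catalytic_subs`,
#'   `n_structural_subs`, `fragment`, `internal_stop`, `coverage`.
#' @export
triageCohort <- function(proteins, scheme, scoring = scoringScheme(),
                         classTable = defaultClassTable(),
                         structuralThreshold = 2L, family = NULL) {
  ids <- names(proteins)
  if (is.null(ids)) ids <- paste0("seq", seq_along(proteins))
  rows <- lapply(seq_along(proteins), function(i) {
    prot <- as.character(proteins[[i]])
    map <- mapToScheme(prot, scheme, scoring)
    fc <- classifyFunction(prot, map, scheme, structuralThreshold)
    sc <- suppressWarnings(
      classifySpecificity(prot, map, scheme, classTable))
    DataFrame(id = ids[i],
              label = fc@label,
              residue_255 = sc@residue255,
              substrate_class = sc@substrateClass,
              n_catalytic_subs = nrow(fc@catalyticSubstitutions),
              n_structural_subs = nrow(fc@structuralSubstitutions),
              fragment = fc@fragment,
              internal_stop = fc@internalStop,
              coverage = map@coverage)
  })
  out <- do.call(rbind, rows)
  fam <- if (is.null(family)) NA_character_
         else if (!is.null(names(family))) unname(family[out$id])
         else family
  out$family <- fam
  out[, c("id", "family", setdiff(colnames(out), c("id", "family")))]
}

#' Write a triage table as TSV
#'
#' @param calls Output of [triageCohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTriageTable <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
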