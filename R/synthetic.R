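.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.codons_for_aa <- function(aa, code = Biostrings::GENETIC_CODE) {
  names(code)[code == aa]
}

.derive_seed <- function(seed, i) {
  (as.integer(seed) %% 1000003L) + 104729L * (i %% 10007L)
}

#' Packaged synthetic CPA1-style functional scheme
#'
#' A deterministic, randomly generated 310-residue reference protein carrying
#' the CPA/B catalytic inventory (H69, E72, R127, N144, R145, H196, E270),
#' Arg at the specificity position 255 (CPO-like), the pocket positions 203,
#' 207, 243, 247, 253, 268, and a 20-position structural-conservation
#' inventory drawn from the reference itself. This is a SYNTHETIC stand-in
#' for a curated subfamily pan-alignment inventory: positions follow the
#' bovine CPA1 numbering convention, but the sequence is not a natural
#' carboxypeptidase, so real analyses must supply their own scheme.
#'
#' @param seed Integer; the generation seed (part of the fixture identity —
#'   changing it changes the scheme).
#' @return A [FunctionalScheme-class].
#' @export
syntheticScheme <- function(seed = 101L) {
  set.seed(seed)
  len <- 310L
  res <- sample(.AA20, len, replace = TRUE)
  catalytic <- list("69" = "H", "72" = "E", "127" = "R", "144" = "N",
                    "145" = "R", "196" = "H", "270" = "E")
  for (p in names(catalytic)) res[as.integer(p)] <- catalytic[[p]]
  res[255L] <- "R"
  pocket <- c(203L, 207L, 243L, 247L, 253L, 268L)
  reserved <- c(as.integer(names(catalytic)), 255L, pocket)
  candidates <- setdiff(seq_len(len), reserved)
  str_pos <- sort(sample(candidates, 20L))
  structural <- as.list(res[str_pos])
  names(structural) <- str_pos
  functionalScheme(paste(res, collapse = ""),
                   offset = 1L,
                   catalytic = catalytic,
                   structural = structural,
                   specificityPosition = 255L,
                   pocketPositions = pocket)
}

#' Small fixture scheme for fast tests
#'
#' A 40-residue reference with three catalytic positions (10 H, 20 E, 30 H),
#' five structural positions and specificity position 25; pocket positions
#' 22 and 28. Same shape as the full scheme, a fraction of the alignment
#' cost.
#'
#' @return A [FunctionalScheme-class].
#' @export
toyScheme <- function() {
  ref <- "MKTAYIAKQRHQISVEAFERMLGDWTAKWRLNDVPGAFSK"
  # positions:      10 H      20 E   25 W  30 R -> set catalytic to actual
  res <- strsplit(ref, "")[[1]]
  res[10] <- "H"; res[20] <- "E"; res[30] <- "H"; res[25] <- "R"
  functionalScheme(paste(res, collapse = ""),
                   offset = 1L,
                   catalytic = list("10" = "H", "20" = "E", "30" = "H"),
                   structural = list("5" = res[5], "13" = res[13],
                                     "17" = res[17], "33" = res[33],
                                     "37" = res[37]),
                   specificityPosition = 25L,
                   pocketPositions = c(22L, 28L))
}

#' Generate a scheme-compliant ancestral coding sequence
#'
#' Back-translates the scheme's reference protein with uniformly random
#' synonymous codon choices, optionally substituting a fraction of
#' non-scheme positions to random residues (so different family ancestors
#' diverge from the reference while staying trivially alignable to it), and
#' optionally extending with random C-terminal residues when `lengthCodons`
#' exceeds the reference length. The translation carries the scheme's
#' expected residues at all catalytic, structural and specificity positions
#' and contains no stop codon, so triage on the ancestor is ACTIVE by
#' construction.
#'
#' @param scheme A [FunctionalScheme-class].
#' @param lengthCodons Integer; must cover the largest scheme position.
#' @param seed Integer seed (deterministic output).
#' @param nonSchemeDivergence Fraction of non-scheme positions substituted
#'   to a random different residue (default 0).
#' @param code Genetic code.
#' @return A character string of `3 * lengthCodons` nucleotides.
#' @export
makeAncestor <- function(scheme, lengthCodons = NULL, seed = 1L,
                         nonSchemeDivergence = 0,
                         code = Biostrings::GENETIC_CODE) {
  ref <- strsplit(as.character(scheme@reference), "")[[1]]
  if (is.null(lengthCodons)) lengthCodons <- length(ref)
  lengthCodons <- as.integer(lengthCodons)
  scheme_pos <- c(as.integer(names(scheme@catalytic)),
                  as.integer(names(scheme@structural)),
                  scheme@specificityPosition, scheme@pocketPositions)
  scheme_idx <- scheme_pos - scheme@offset + 1L
  if (lengthCodons < max(scheme_idx))
    stop("length ", lengthCodons, " codons is too short to host all scheme ",
         "positions (need >= ", max(scheme_idx), ")")
  set.seed(seed)
  res <- if (lengthCodons <= length(ref)) ref[seq_len(lengthCodons)]
         else c(ref, sample(.AA20, lengthCodons - length(ref), replace = TRUE))
  if (nonSchemeDivergence > 0) {
    free <- setdiff(seq_len(lengthCodons), scheme_idx)
    n_mut <- round(nonSchemeDivergence * length(free))
    if (n_mut > 0) {
      at <- sample(free, n_mut)
      res[at] <- vapply(res[at], function(a)
        sample(setdiff(.AA20, a), 1L), "")
    }
  }
  codons <- vapply(res, function(a) {
    opts <- .codons_for_aa(a, code)
    opts[sample.int(length(opts), 1L)]
  }, "")
  paste(codons, collapse = "")
}

.replace_codon <- function(cds, idx, codon) {
  paste0(substr(cds, 1L, (idx - 1L) * 3L), codon,
         substr(cds, idx * 3L + 1L, nchar(cds)))
}

.codon_at <- function(cds, idx) substr(cds, (idx - 1L) * 3L + 1L, idx * 3L)

#' Install a residue at the scheme's specificity position
#'
#' Replaces the codon at the residue-255 equivalent with a random codon for
#' the target residue.
#'
#' @param cds Ancestor coding sequence (string).
#' @param scheme A [FunctionalScheme-class].
#' @param residue Single amino-acid letter.
#' @param seed Integer seed.
#' @param code Genetic code.
#' @return The edited coding sequence.
#' @export
applySpecificityEdit <- function(cds, scheme, residue, seed = 1L,
                                 code = Biostrings::GENETIC_CODE) {
  set.seed(seed)
  idx <- scheme@specificityPosition - scheme@offset + 1L
  opts <- .codons_for_aa(residue, code)
  .replace_codon(cds, idx, opts[sample.int(length(opts), 1L)])
}

#' Apply a constructive functional-class edit to an ancestor
#'
#' Produces a coding sequence whose triage label is forced by construction:
#' * `ACTIVE` — synonymous edits at random codons plus a couple of
#'   nonsynonymous edits at non-scheme positions;
#' * `PSEUDOENZYME` — one randomly chosen catalytic position substituted to
#'   a non-expected residue via a single-nucleotide codon edit;
#' * `PSEUDOGENE` — one of three modes chosen by the seed: at least two
#'   structural substitutions, an internal stop codon upstream of the last
#'   catalytic position, or truncation removing at least one catalytic
#'   position.
#'
#' @param cds Ancestor coding sequence (ACTIVE under the scheme).
#' @param scheme A [FunctionalScheme-class].
#' @param targetLabel `"ACTIVE"`, `"PSEUDOENZYME"` or `"PSEUDOGENE"`.
#' @param seed Integer seed.
#' @param code Genetic code.
#' @return A list: `cds` (edited sequence), `label`, `mode` (edit mode) and
#'   `detail` (positions touched).
#' @export
applyClassEdit <- function(cds, scheme, targetLabel, seed = 1L,
                           code = Biostrings::GENETIC_CODE) {
  set.seed(seed)
  cds <- toupper(as.character(cds))
  n_cod <- nchar(cds) %/% 3L
  cat_pos <- as.integer(names(scheme@catalytic))
  str_pos <- as.integer(names(scheme@structural))
  scheme_idx <- c(cat_pos, str_pos, scheme@specificityPosition,
                  scheme@pocketPositions) - scheme@offset + 1L

  if (targetLabel == "ACTIVE") {
    at <- sample(n_cod, min(10L, n_cod))
    for (i in at) {
      aa <- unname(code[.codon_at(cds, i)])
      opts <- setdiff(.codons_for_aa(aa, code), .codon_at(cds, i))
      if (length(opts))
        cds <- .replace_codon(cds, i, opts[sample.int(length(opts), 1L)])
    }
    free <- setdiff(seq_len(n_cod), scheme_idx)
    at2 <- sample(free, 2L)
    for (i in at2) {
      aa <- unname(code[.codon_at(cds, i)])
      new_aa <- sample(setdiff(.AA20, aa), 1L)
      opts <- .codons_for_aa(new_aa, code)
      cds <- .replace_codon(cds, i, opts[sample.int(length(opts), 1L)])
    }
    return(list(cds = cds, label = "ACTIVE", mode = "synonymous",
                detail = sort(c(at, at2))))
  }

  if (targetLabel == "PSEUDOENZYME") {
    pos <- sample(cat_pos, 1L)
    idx <- pos - scheme@offset + 1L
    cod <- strsplit(.codon_at(cds, idx), "")[[1]]
    expected <- scheme@catalytic[[as.character(pos)]]
    muts <- character(0)
    for (p in 1:3) for (nt in setdiff(.NUC, cod[p])) {
      m <- cod; m[p] <- nt; muts <- c(muts, paste(m, collapse = ""))
    }
    aa0 <- unname(code[paste(cod, collapse = "")])
    ok <- muts[code[muts] != "*" & code[muts] != aa0 &
               !(code[muts] %in% expected)]
    if (!length(ok))  # fall back to any codon of a non-expected residue
      ok <- unlist(lapply(setdiff(.AA20, c(aa0, expected)), .codons_for_aa,
                          code = code))
    cds <- .replace_codon(cds, idx, ok[sample.int(length(ok), 1L)])
    return(list(cds = cds, label = "PSEUDOENZYME", mode = "catalytic",
                detail = pos))
  }

  if (targetLabel == "PSEUDOGENE") {
    mode <- sample(c("structural", "stop", "truncation"), 1L)
    if (mode == "structural") {
      picks <- sample(str_pos, 2L)
      for (pos in picks) {
        idx <- pos - scheme@offset + 1L
        expected <- scheme@structural[[as.character(pos)]]
        aa0 <- unname(code[.codon_at(cds, idx)])
        new_aa <- sample(setdiff(.AA20, c(aa0, expected)), 1L)
        opts <- .codons_for_aa(new_aa, code)
        cds <- .replace_codon(cds, idx, opts[sample.int(length(opts), 1L)])
      }
      return(list(cds = cds, label = "PSEUDOGENE", mode = mode,
                  detail = sort(picks)))
    }
    if (mode == "stop") {
      last_cat_idx <- max(cat_pos) - scheme@offset + 1L
      free <- setdiff(seq(2L, last_cat_idx - 1L), scheme_idx)
      idx <- free[sample.int(length(free), 1L)]
      cds <- .replace_codon(cds, idx, "TAA")
      return(list(cds = cds, label = "PSEUDOGENE", mode = mode,
                  detail = idx + scheme@offset - 1L))
    }
    # truncation: cut immediately before a randomly chosen catalytic position
    pos <- sample(cat_pos, 1L)
    keep <- pos - scheme@offset  # residues strictly before `pos`
    cds <- substr(cds, 1L, keep * 3L)
    return(list(cds = cds, label = "PSEUDOGENE", mode = "truncation",
                detail = pos))
  }
  stop("unknown target label: ", targetLabel)
}

#' Evolve a divergent coding-sequence pair under an omega regime
#'
#' Starting from a common ancestor, two lineages independently accumulate
#' accepted point substitutions (star topology, no back-mutation
#' bookkeeping): proposals pick a uniform random site and a uniform random
#' alternative nucleotide; proposals creating a stop codon are rejected;
#' synonymous proposals are accepted with probability 1 and nonsynonymous
#' proposals with probability `min(1, omega)`. Each lineage stops after
#' `round(lengthCodons * targetDivergence / 2)` accepted substitutions, so
#' the pair's total divergence is close to `targetDivergence` substitutions
#' per codon. Realized synonymous/nonsynonymous acceptance counts are the
#' truth channel.
#'
#' @param ancestor Ancestral coding sequence (no internal stops).
#' @param omega Nonsynonymous acceptance probability (dN/dS regime), > 0
#'   allowed to be 0 for a purely synonymous regime.
#' @param targetDivergence Substitutions per codon for the pair.
#' @param seed Integer seed.
#' @param code Genetic code.
#' @return A list: `cdsA`, `cdsB`, and `realized`, a matrix with rows A/B
#'   and columns `synonymous`, `nonsynonymous`.
#' @export
evolvePair <- function(ancestor, omega, targetDivergence, seed = 1L,
                       code = Biostrings::GENETIC_CODE) {
  set.seed(seed)
  anc <- strsplit(toupper(as.character(ancestor)), "")[[1]]
  n_cod <- length(anc) %/% 3L
  n_target <- round(n_cod * targetDivergence / 2)
  evolve_one <- function(nt) {
    syn <- 0L; nonsyn <- 0L
    while (syn + nonsyn < n_target) {
      site <- sample.int(length(nt), 1L)
      alt <- sample(setdiff(.NUC, nt[site]), 1L)
      ci <- (site - 1L) %/% 3L
      old_cod <- paste(nt[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
      new <- nt; new[site] <- alt
      new_cod <- paste(new[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
      if (code[new_cod] == "*") next
      if (code[new_cod] == code[old_cod]) {
        nt <- new; syn <- syn + 1L
      } else if (stats::runif(1) < omega) {
        nt <- new; nonsyn <- nonsyn + 1L
      }
    }
    list(nt = nt, syn = syn, nonsyn = nonsyn)
  }
  a <- evolve_one(anc)
  b <- evolve_one(anc)
  realized <- matrix(c(a$syn, a$nonsyn, b$syn, b$nonsyn), 2, 2, byrow = TRUE,
                     dimnames = list(c("A", "B"),
                                     c("synonymous", "nonsynonymous")))
  list(cdsA = paste(a$nt, collapse = ""),
       cdsB = paste(b$nt, collapse = ""),
       realized = realized)
}

#' Expected dN/dS of the acceptance simulator on a given ancestor
#'
#' The simulator proposes uniform random single-nucleotide changes and
#' rejects those creating stops, so positions whose mutant spectrum includes
#' stops substitute more slowly than unconstrained positions, while the
#' Nei-Gojobori inventory still counts them as full sites. The expected
#' NG-measured dN/dS under the acceptance mechanism is therefore not
#' exactly `omega` but `omega * (m_non * S) / (m_syn * N)`, where `m_syn`
#' and `m_non` count the ancestor's synonymous and nonsynonymous (non-stop)
#' single-nucleotide mutation opportunities and S, N are its NG site
#' counts. For natural coding sequences the correction factor is close to 1
#' (about 1.03 for typical compositions).
#'
#' @param ancestor Ancestral coding sequence.
#' @param omega Nonsynonymous acceptance probability.
#' @param code Genetic code.
#' @param stopHandling Site-counting convention, as [countSites()].
#' @return The expected dN/dS (numeric scalar).
#' @export
acceptanceExpectation <- function(ancestor, omega,
                                  code = Biostrings::GENETIC_CODE,
                                  stopHandling = "exclude") {
  cod <- codonSplit(trimTrailingStop(ancestor, code))
  m_syn <- 0; m_non <- 0; S <- 0
  for (cc in cod) {
    aa <- unname(code[cc])
    cv <- strsplit(cc, "")[[1]]
    S <- S + countSites(cc, code, stopHandling)[["s"]]
    for (p in 1:3) for (nt in setdiff(.NUC, cv[p])) {
      mv <- cv; mv[p] <- nt
      maa <- unname(code[paste(mv, collapse = "")])
      if (maa == "*") next
      if (maa == aa) m_syn <- m_syn + 1 else m_non <- m_non + 1
    }
  }
  N <- 3 * length(cod) - S
  omega * (m_non * S) / (m_syn * N)
}

.allocate_counts <- function(n, mixture) {
  # largest-remainder allocation so the realized mixture is exact
  raw <- n * mixture / sum(mixture)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(mixture))
}

#' Generate a truth-labelled synthetic paralog cohort
#'
#' Emulates the shape of a curated duplicated-gene cohort: families of
#' paralogs derived from scheme-compliant ancestors, functional labels
#' allocated exactly to the requested mixture via constructive edits
#' ([applyClassEdit()]), specificity residues sampled from the requested
#' residue mixture ([applySpecificityEdit()]), and a locus table with tandem
#' and dispersed layouts. Truth labels reflect the edits actually applied
#' (a truncation that removes the specificity position makes that paralog's
#' truth specificity `UNDETERMINED`).
#'
#' @param scheme A [FunctionalScheme-class].
#' @param nParalogs Integer cohort size.
#' @param labelMixture Named fractions over ACTIVE/PSEUDOENZYME/PSEUDOGENE
#'   (default 0.83/0.08/0.09, the rounded composition reported for
#'   duplicated CPO cohorts).
#' @param specificityMixture Named fractions over residue-255 choices
#'   (default dominated by Arg with polar minorities, CPO-like).
#' @param familyMixture Named fractions over family labels.
#' @param seed Integer seed; the cohort is bit-reproducible from
#'   `(arguments, seed)`.
#' @param classTable Residue-to-class table used to record truth classes.
#' @param code Genetic code.
#' @return A [SyntheticCohort-class].
#' @export
makeSyntheticCohort <- function(scheme = syntheticScheme(),
                                nParalogs = 60L,
                                labelMixture = c(ACTIVE = 0.83,
                                                 PSEUDOENZYME = 0.08,
                                                 PSEUDOGENE = 0.09),
                                specificityMixture = c(R = 0.70, Q = 0.10,
                                                       G = 0.06, C = 0.04,
                                                       L = 0.04, V = 0.03,
                                                       D = 0.03),
                                familyMixture = c(CPO = 0.6, CPA1 = 0.2,
                                                  CPB1 = 0.2),
                                seed = 1L,
                                classTable = defaultClassTable(),
                                code = Biostrings::GENETIC_CODE) {
  set.seed(seed)
  labels <- rep(names(labelMixture), .allocate_counts(nParalogs, labelMixture))
  labels <- sample(labels)
  fams <- rep(names(familyMixture), .allocate_counts(nParalogs, familyMixture))
  fams <- sample(fams)
  residues <- sample(names(specificityMixture), nParalogs, replace = TRUE,
                     prob = specificityMixture)

  anc <- lapply(stats::setNames(nm = names(familyMixture)), function(f)
    makeAncestor(scheme, seed = .derive_seed(seed, match(f, names(familyMixture))),
                 nonSchemeDivergence = 0.03, code = code))

  spec_idx <- scheme@specificityPosition - scheme@offset + 1L
  cds <- character(nParalogs)
  truth_res <- character(nParalogs)
  truth_class <- character(nParalogs)
  modes <- character(nParalogs)
  for (i in seq_len(nParalogs)) {
    s <- applySpecificityEdit(anc[[fams[i]]], scheme, residues[i],
                              seed = .derive_seed(seed, 100L + i), code = code)
    edit <- applyClassEdit(s, scheme, labels[i],
                           seed = .derive_seed(seed, 10000L + i), code = code)
    cds[i] <- edit$cds
    modes[i] <- edit$mode
    lost_255 <- edit$mode == "truncation" &&
      nchar(edit$cds) %/% 3L < spec_idx
    truth_res[i] <- if (lost_255) NA_character_ else residues[i]
    truth_class[i] <- if (lost_255) "UNDETERMINED"
                      else unname(classTable[residues[i]])
  }
  ids <- paste0(tolower(fams), ".", seq_len(nParalogs))
  cds_set <- DNAStringSet(cds)
  names(cds_set) <- ids
  prot <- AAStringSet(vapply(cds, function(s)
    as.character(translateCDS(s, code)), ""))
  names(prot) <- ids
  truth <- DataFrame(id = ids, family = fams, label = labels,
                     residue_255 = truth_res,
                     specificity_class = truth_class,
                     edit_mode = modes)
  loci <- makeLocusCohort(seed = .derive_seed(seed, 424243L),
                          nDuplicated = nParalogs, nOther = nParalogs)
  new("SyntheticCohort", cds = cds_set, proteins = prot, truth = truth,
      loci = loci,
      config = list(seed = seed, nParalogs = nParalogs,
                    labelMixture = labelMixture,
                    specificityMixture = specificityMixture,
                    familyMixture = familyMixture))
}

#' Generate coding-sequence pairs for selection-test cohorts
#'
#' Builds a focal-family group of pairs evolved under `omegaFocal` and an
#' other-families group under `omegaOther`, all at the same length and
#' divergence, returning the sequence set and pairing manifest that
#' [pairwiseSelectionTable()] consumes.
#'
#' @param scheme A [FunctionalScheme-class] (its reference seeds the
#'   ancestors).
#' @param nFocal,nOther Pair counts per group.
#' @param omegaFocal,omegaOther Acceptance omegas per group.
#' @param targetDivergence Substitutions per codon per pair.
#' @param lengthCodons Sequence length.
#' @param seed Integer seed.
#' @param focalFamily,otherFamily Family labels.
#' @param code Genetic code.
#' @return A list: `cds` ([Biostrings::DNAStringSet]) and `manifest`
#'   (data.frame `id_a`, `id_b`, `family`, `omega`).
#' @export
makeSelectionCohort <- function(scheme = syntheticScheme(),
                                nFocal = 20L, nOther = 20L,
                                omegaFocal = 0.2, omegaOther = 1.0,
                                targetDivergence = 0.3,
                                lengthCodons = 310L, seed = 1L,
                                focalFamily = "CPO", otherFamily = "CPA1",
                                code = Biostrings::GENETIC_CODE) {
  n <- nFocal + nOther
  fam <- c(rep(focalFamily, nFocal), rep(otherFamily, nOther))
  omega <- c(rep(omegaFocal, nFocal), rep(omegaOther, nOther))
  seqs <- character(2L * n)
  ids <- character(2L * n)
  for (i in seq_len(n)) {
    anc <- makeAncestor(scheme, lengthCodons = lengthCodons,
                        seed = .derive_seed(seed, 3000L + i),
                        nonSchemeDivergence = 0.05, code = code)
    pair <- evolvePair(anc, omega[i], targetDivergence,
                       seed = .derive_seed(seed, 5000L + i), code = code)
    seqs[2L * i - 1L] <- pair$cdsA
    seqs[2L * i] <- pair$cdsB
    ids[2L * i - 1L] <- paste0(tolower(fam[i]), ".", i, "a")
    ids[2L * i] <- paste0(tolower(fam[i]), ".", i, "b")
  }
  cds <- DNAStringSet(seqs)
  names(cds) <- ids
  manifest <- data.frame(id_a = ids[seq(1L, 2L * n, 2L)],
                         id_b = ids[seq(2L, 2L * n, 2L)],
                         family = fam, omega = omega)
  list(cds = cds, manifest = manifest)
}

#' Generate a synthetic gene-locus cohort
#'
#' Gene sizes are lognormal per group; defaults are calibrated so the
#' frequently-duplicated group has mean size about 15.2 kb and the other
#' group about 83.2 kb (the two vertebrate MCP gene-group means), with a
#' common log-scale spread of 0.8. Layout: the first duplicated genes are
#' placed as tandem clusters (same chromosome, inter-gene gaps below
#' `withinGap`), remaining genes dispersed with gaps of `dispersedGap`.
#'
#' @param seed Integer seed.
#' @param nDuplicated,nOther Group sizes.
#' @param meanDup,meanOther Target mean gene sizes (bp).
#' @param sdlog Common lognormal sdlog.
#' @param tandemSizes Integer vector; sizes of planted tandem clusters
#'   (drawn from the duplicated group; must sum to at most `nDuplicated`).
#' @param withinGap Max inter-gene gap inside a cluster (bp).
#' @param dispersedGap Gap between dispersed genes (bp); keep it above the
#'   tandem-detection threshold.
#' @return A [GenomicRanges::GRanges] as from [readLocusTable()].
#' @export
makeLocusCohort <- function(seed = 1L, nDuplicated = 100L, nOther = 100L,
                            meanDup = 15214, meanOther = 83159,
                            sdlog = 0.8,
                            tandemSizes = c(3L, 5L),
                            withinGap = 10000L,
                            dispersedGap = 1000000L) {
  set.seed(seed)
  if (sum(tandemSizes) > nDuplicated)
    stop("tandem clusters need more genes than nDuplicated provides")
  size_dup <- round(stats::rlnorm(nDuplicated,
                                  meanlog = log(meanDup) - sdlog^2 / 2,
                                  sdlog = sdlog))
  size_oth <- round(stats::rlnorm(nOther,
                                  meanlog = log(meanOther) - sdlog^2 / 2,
                                  sdlog = sdlog))
  size_dup <- pmax(size_dup, 200); size_oth <- pmax(size_oth, 200)

  rows <- list()
  gi <- 0L
  di <- 0L
  chr_i <- 0L
  for (k in seq_along(tandemSizes)) {
    chr_i <- chr_i + 1L
    pos <- 1000000L
    for (j in seq_len(tandemSizes[k])) {
      di <- di + 1L; gi <- gi + 1L
      rows[[gi]] <- data.frame(
        gene_id = sprintf("cpo.t%d.%d", k, j),
        chromosome = paste0("chr", chr_i),
        start = pos, end = pos + size_dup[di] - 1L,
        strand = sample(c("+", "-"), 1L),
        family_label = "CPO", duplicated_group = TRUE)
      pos <- pos + size_dup[di] + sample(1000:withinGap, 1L)
    }
  }
  # dispersed remainder, round-robin over fresh chromosomes
  disp <- data.frame(
    size = c(size_dup[seq_len(nDuplicated - di) + di], size_oth),
    dup = rep(c(TRUE, FALSE), c(nDuplicated - di, nOther)))
  fam_dup <- c("CPO", "AEBP1", "CPXM1", "CPZ")
  fam_oth <- c("CPA1", "CPA2", "CPB1", "CPD", "CPE", "CPXM2")
  pos <- 5000000L
  chr_i <- chr_i + 1L
  for (j in seq_len(nrow(disp))) {
    gi <- gi + 1L
    rows[[gi]] <- data.frame(
      gene_id = sprintf("g%03d", gi),
      chromosome = paste0("chr", chr_i),
      start = pos, end = pos + disp$size[j] - 1L,
      strand = sample(c("+", "-"), 1L),
      family_label = if (disp$dup[j]) sample(fam_dup, 1L)
                     else sample(fam_oth, 1L),
      duplicated_group = disp$dup[j])
    pos <- pos + disp$size[j] + dispersedGap
  }
  lociGRanges(do.call(rbind, rows))
}
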