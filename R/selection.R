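#' @importFrom stats pnorm p.adjust t.test kruskal.test median setNames
NULL

.NUC <- c("A", "C", "G", "T")

.all_codons <- function() {
  g <- expand.grid(p3 = .NUC, p2 = .NUC, p1 = .NUC,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

# permutations of differing-position orderings, by number of differences
.PERMS <- list(
  `1` = matrix(1L, 1, 1),
  `2` = rbind(c(1L, 2L), c(2L, 1L)),
  `3` = rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
              c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# cache of per-code lookup tables (site counts + difference matrices)
.ng_cache <- new.env(parent = emptyenv())

.ng_tables <- function(code, stopHandling) {
  key <- paste0(stopHandling, ":", paste(code, collapse = ""))
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  codons <- .all_codons()
  aa <- unname(code[codons])
  is_stop <- aa == "*"

  s_sites <- vapply(seq_along(codons), function(i) {
    if (is_stop[i]) return(NA_real_)
    cod <- strsplit(codons[i], "")[[1]]
    s <- 0
    for (p in 1:3) {
      alt <- setdiff(.NUC, cod[p])
      mut <- vapply(alt, function(nt) {
        m <- cod; m[p] <- nt; paste(m, collapse = "")
      }, "")
      maa <- unname(code[mut])
      if (stopHandling == "exclude") {
        keep <- maa != "*"
        if (any(keep)) s <- s + sum(maa[keep] == aa[i]) / sum(keep)
      } else {
        s <- s + sum(maa == aa[i]) / 3
      }
    }
    s
  }, numeric(1))

  pair_diffs <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    which(ca != cb)
  }
  path_counts <- function(a, b, order, code) {
    # walk a -> b changing positions in `order`; return c(sd, nd, hits_stop)
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    cur <- ca; sd <- 0; nd <- 0; hit <- FALSE
    for (p in order) {
      nxt <- cur; nxt[p] <- cb[p]
      from <- unname(code[paste(cur, collapse = "")])
      to <- unname(code[paste(nxt, collapse = "")])
      if (to == "*" && paste(nxt, collapse = "") != b) hit <- TRUE
      if (from == to) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, as.numeric(hit))
  }

  sd_mat <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  nd_mat <- sd_mat
  for (i in seq_along(codons)) {
    if (is_stop[i]) next
    for (j in seq_along(codons)) {
      if (is_stop[j]) next
      if (i == j) { sd_mat[i, j] <- 0; nd_mat[i, j] <- 0; next }
      if (j < i) { sd_mat[i, j] <- sd_mat[j, i]; nd_mat[i, j] <- nd_mat[j, i]; next }
      d <- pair_diffs(codons[i], codons[j])
      perms <- .PERMS[[as.character(length(d))]]
      res <- t(apply(perms, 1, function(ord)
        path_counts(codons[i], codons[j], d[ord], code)))
      use <- if (stopHandling == "exclude" && any(res[, 3] == 0))
        res[res[, 3] == 0, , drop = FALSE] else res
      sd_mat[i, j] <- mean(use[, 1]); nd_mat[i, j] <- mean(use[, 2])
    }
  }
  tabs <- list(codons = codons, aa = aa, is_stop = is_stop,
               s_sites = s_sites, sd = sd_mat, nd = nd_mat)
  .ng_cache[[key]] <- tabs
  tabs
}

#' Expected synonymous and nonsynonymous sites of one codon
#'
#' For each of the three codon positions, the synonymous fraction is the
#' number of single-nucleotide changes at that position that preserve the
#' encoded amino acid, divided by the number of such changes considered. Under
#' the default (MEGA-style) `stopHandling = "exclude"`, changes that create a
#' stop codon are excluded and the position denominator is renormalised;
#' under the strict-NG86 `"count"` variant they are counted as nonsynonymous
#' over a denominator of 3. The codon's synonymous site count `s` is the sum
#' of the three fractions and `n = 3 - s`.
#'
#' @param codon A 3-letter sense codon (no `N`, not a stop).
#' @param code Genetic code as [Biostrings::GENETIC_CODE].
#' @param stopHandling `"exclude"` (default) or `"count"`.
#' @return Named numeric vector `c(s = , n = )`.
#' @export
#' @examples
#' countSites("TTT")  # s = 1/3
#' countSites("GGG")  # s = 1 (fourfold-degenerate third position)
countSites <- function(codon, code = Biostrings::GENETIC_CODE,
                       stopHandling = c("exclude", "count")) {
  stopHandling <- match.arg(stopHandling)
  codon <- toupper(codon)
  if (grepl("[^ACGT]", codon) || nchar(codon) != 3L)
    stop("ambiguous or malformed codon: ", codon)
  if (code[codon] == "*")
    stop("stop codon has no site counts: ", codon)
  tabs <- .ng_tables(code, stopHandling)
  s <- tabs$s_sites[match(codon, tabs$codons)]
  c(s = unname(s), n = 3 - unname(s))
}

#' Synonymous and nonsynonymous differences between two codons
#'
#' Differences are averaged over all minimal mutational pathways between the
#' two codons (1, 2 or 6 orderings for 1, 2 or 3 differing positions). Under
#' the default `stopHandling = "exclude"`, pathways passing through a stop
#' codon are discarded before averaging; if every pathway passes through a
#' stop, all pathways are used (stop-passing steps counted nonsynonymous).
#' Under `"count"`, all pathways are always used.
#'
#' @param codonA,codonB Sense codons.
#' @inheritParams countSites
#' @return Named numeric vector `c(sd = , nd = )`; `sd + nd` equals the
#'   number of differing nucleotide positions.
#' @export
#' @examples
#' countDifferences("TTT", "TTA")  # one nonsynonymous difference (Phe -> Leu)
#' countDifferences("TTT", "GTA")  # (0.5, 1.5) over the two 2-step pathways
countDifferences <- function(codonA, codonB,
                             code = Biostrings::GENETIC_CODE,
                             stopHandling = c("exclude", "count")) {
  stopHandling <- match.arg(stopHandling)
  codonA <- toupper(codonA); codonB <- toupper(codonB)
  for (cod in c(codonA, codonB)) {
    if (grepl("[^ACGT]", cod) || nchar(cod) != 3L)
      stop("ambiguous or malformed codon: ", cod)
    if (code[cod] == "*")
      stop("stop codon not comparable: ", cod)
  }
  tabs <- .ng_tables(code, stopHandling)
  i <- match(codonA, tabs$codons); j <- match(codonB, tabs$codons)
  c(sd = tabs$sd[i, j], nd = tabs$nd[i, j])
}

#' Jukes-Cantor multiple-hit correction
#'
#' `d = -(3/4) log(1 - (4/3) p)`; defined for `p < 3/4`, with `d >= p` and
#' `d -> p` as `p -> 0`.
#'
#' @param p Observed proportion of differences per site, in `[0, 3/4)`.
#' @return Corrected distance.
#' @export
jukesCantor <- function(p) {
  if (any(p >= 0.75))
    stop("Jukes-Cantor correction undefined for proportion ", max(p),
         " (>= 3/4)")
  -0.75 * log(1 - 4 * p / 3)
}

.jc_var <- function(p, m) {
  # delta-method variance of the Jukes-Cantor distance on binomial p
  if (m <= 0) return(0)
  9 * p * (1 - p) / ((3 - 4 * p)^2 * m)
}

.codon_ok <- function(codons, tabs) {
  i <- match(codons, tabs$codons)
  !is.na(i) & !tabs$is_stop[ifelse(is.na(i), 1L, i)]
}

#' Nei-Gojobori estimate and codon-based test of purifying selection
#'
#' Implements the Nei-Gojobori (1986) counting method on an aligned codon
#' pair: expected synonymous (S) and nonsynonymous (N) site counts averaged
#' over the two sequences, observed synonymous (Sd) and nonsynonymous (Nd)
#' differences averaged over minimal mutational pathways, proportions
#' `pS = Sd/S` and `pN = Nd/N`, Jukes-Cantor corrected distances dS and dN,
#' analytical (delta-method) variances, and the one-tailed Z-test of the
#' null dN = dS against the purifying-selection alternative dN < dS with
#' `Z = (dS - dN) / sqrt(var(dS) + var(dN))` (the covariance of dS and dN is
#' taken as zero). Codon pairs containing alignment gaps, ambiguous bases or
#' stop codons are excluded pairwise and reported in `excludedCodons`.
#'
#' When both variances are zero and the statistic is zero (e.g. identical
#' sequences), Z is defined as 0 and p as 0.5.
#'
#' @param x A [CodonAlignment-class], or a character vector of codons for
#'   sequence A (then `y` must be the codons of sequence B).
#' @param y Codons of sequence B when `x` is a codon vector.
#' @param code Genetic code.
#' @param stopHandling Site/pathway stop-codon convention; see
#'   [countSites()].
#' @return A [SelectionResult-class].
#' @export
#' @examples
#' a <- c("ATG", "AAA", "CGA", "TTT")
#' neiGojobori(a, a)  # identical: statistic 0, p = 0.5
neiGojobori <- function(x, y = NULL, code = Biostrings::GENETIC_CODE,
                        stopHandling = c("exclude", "count")) {
  stopHandling <- match.arg(stopHandling)
  if (is(x, "CodonAlignment")) {
    ca <- x@codonsA; cb <- x@codonsB
  } else {
    ca <- toupper(x); cb <- toupper(y)
    if (length(ca) != length(cb))
      stop("codon vectors must have equal length")
  }
  tabs <- .ng_tables(code, stopHandling)
  ok <- .codon_ok(ca, tabs) & .codon_ok(cb, tabs)
  used <- sum(ok)
  if (used == 0L)
    stop("no comparable codon pairs after exclusions")
  ia <- match(ca[ok], tabs$codons); ib <- match(cb[ok], tabs$codons)

  S <- (sum(tabs$s_sites[ia]) + sum(tabs$s_sites[ib])) / 2
  N <- 3 * used - S
  Sd <- sum(tabs$sd[cbind(ia, ib)])
  Nd <- sum(tabs$nd[cbind(ia, ib)])

  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  dS <- jukesCantor(pS)
  dN <- jukesCantor(pN)
  varDS <- .jc_var(pS, S)
  varDN <- .jc_var(pN, N)
  stat <- dS - dN
  se <- sqrt(varDS + varDN)
  Z <- if (se > 0) stat / se else if (stat == 0) 0 else sign(stat) * Inf
  p <- pnorm(Z, lower.tail = FALSE)

  new("SelectionResult",
      S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
      dS = dS, dN = dN, varDS = varDS, varDN = varDN,
      statistic = stat, Z = Z, p = p,
      codonsUsed = as.integer(used),
      excludedCodons = as.integer(length(ca) - used))
}

#' Selection test over a table of paralog pairs
#'
#' Aligns each coding-sequence pair at the codon level, runs [neiGojobori()]
#' on it, and tabulates one row per pair. Per-family mean `dS - dN` summaries
#' and a Welch two-sample t-test comparing the focal family (default
#' `"CPO"`) against all other pairs on `dS - dN` are attached. A
#' Benjamini-Hochberg adjusted column (`p_BH`) is emitted as a clearly
#' labelled extension; the primary per-pair probabilities are unadjusted.
#' Pairs that fail (e.g. unalignable) are flagged in the `note` column, not
#' fatal.
#'
#' @param cds A named [Biostrings::DNAStringSet] (or named character vector)
#'   of coding sequences.
#' @param manifest A data.frame with columns `id_a`, `id_b` and optionally
#'   `family`.
#' @param scoring A [scoringScheme()] for the protein-level alignment.
#' @param code Genetic code.
#' @param stopHandling See [countSites()].
#' @param focalFamily Family label contrasted against all others (default
#'   `"CPO"`).
#' @return A data.frame (one row per pair) with attributes
#'   `familySummary` (per-family n and mean statistic) and `groupTest`
#'   (Welch t-test of focal family vs others, or `NA`s when not computable).
#' @export
pairwiseSelectionTable <- function(cds, manifest,
                                   scoring = scoringScheme(),
                                   code = Biostrings::GENETIC_CODE,
                                   stopHandling = c("exclude", "count"),
                                   focalFamily = "CPO") {
  stopHandling <- match.arg(stopHandling)
  if (!all(c("id_a", "id_b") %in% names(manifest)))
    stop("manifest needs columns id_a and id_b")
  fam <- if ("family" %in% names(manifest)) as.character(manifest$family)
         else rep(NA_character_, nrow(manifest))
  rows <- lapply(seq_len(nrow(manifest)), function(k) {
    ida <- manifest$id_a[k]; idb <- manifest$id_b[k]
    base <- data.frame(id_a = ida, id_b = idb, family = fam[k])
    res <- tryCatch({
      if (!ida %in% names(cds) || !idb %in% names(cds))
        stop("pair member missing from the sequence set")
      caln <- alignCodingPair(cds[[ida]], cds[[idb]], scoring, code)
      sr <- neiGojobori(caln, code = code, stopHandling = stopHandling)
      cbind(base, as.data.frame(sr), note = "")
    }, error = function(e) {
      empty <- as.data.frame(
        setNames(as.list(rep(NA_real_, 15)),
                 c("S", "N", "Sd", "Nd", "pS", "pN", "dS", "dN",
                   "var_dS", "var_dN", "statistic", "Z", "p",
                   "codons_used", "excluded_codons")))
      cbind(base, empty, note = conditionMessage(e))
    })
    res
  })
  tab <- do.call(rbind, rows)
  tab$p_BH <- p.adjust(tab$p, method = "BH")  # extension, not in the primary test

  ok <- !is.na(tab$statistic)
  fam_summary <- if (any(ok)) {
    agg <- aggregate(statistic ~ family, data = tab[ok, , drop = FALSE],
                     FUN = mean, na.action = stats::na.omit)
    agg$n <- as.integer(table(tab$family[ok])[agg$family])
    agg[, c("family", "n", "statistic")]
  } else data.frame(family = character(0), n = integer(0),
                    statistic = numeric(0))

  in_focal <- ok & !is.na(tab$family) & tab$family == focalFamily
  in_other <- ok & !(!is.na(tab$family) & tab$family == focalFamily)
  group_test <- if (sum(in_focal) >= 2 && sum(in_other) >= 2) {
    tt <- t.test(tab$statistic[in_focal], tab$statistic[in_other])
    list(computable = TRUE, t = unname(tt$statistic), p = tt$p.value,
         mean_focal = mean(tab$statistic[in_focal]),
         mean_other = mean(tab$statistic[in_other]))
  } else {
    list(computable = FALSE, t = NA_real_, p = NA_real_,
         mean_focal = NA_real_, mean_other = NA_real_)
  }
  attr(tab, "familySummary") <- fam_summary
  attr(tab, "groupTest") <- group_test
  tab
}

#' Write a selection table as TSV
#'
#' @param tab Output of [pairwiseSelectionTable()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSelectionTable <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
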