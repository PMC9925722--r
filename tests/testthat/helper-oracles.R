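# Independent oracles used to cross-check the implementation.

# Brute-force global alignment: enumerate every alignment of a and b
# (no gap-gap columns) and score under affine gaps (gap of length L costs
# gapOpen + L * gapExtend, both negative). Returns the optimal score.
brute_force_align_score <- function(a, b, mat, gapOpen, gapExtend) {
  best <- -Inf
  score_alignment <- function(colsA, colsB) {
    s <- 0
    in_gap_a <- FALSE; in_gap_b <- FALSE
    for (k in seq_along(colsA)) {
      ca <- colsA[k]; cb <- colsB[k]
      if (ca == "-") {
        s <- s + gapExtend + if (in_gap_a) 0 else gapOpen
        in_gap_a <- TRUE; in_gap_b <- FALSE
      } else if (cb == "-") {
        s <- s + gapExtend + if (in_gap_b) 0 else gapOpen
        in_gap_b <- TRUE; in_gap_a <- FALSE
      } else {
        s <- s + mat[ca, cb]
        in_gap_a <- FALSE; in_gap_b <- FALSE
      }
    }
    s
  }
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  recurse <- function(i, j, colsA, colsB) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score_alignment(colsA, colsB))
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv))
      recurse(i + 1, j + 1, c(colsA, av[i]), c(colsB, bv[j]))
    if (i <= length(av))
      recurse(i + 1, j, c(colsA, av[i]), c(colsB, "-"))
    if (j <= length(bv))
      recurse(i, j + 1, c(colsA, "-"), c(colsB, bv[j]))
  }
  recurse(1L, 1L, character(0), character(0))
  best
}

# Enumeration oracle for per-codon site counts: all 9 single-nucleotide
# mutants, synonymous fraction per position over non-stop (or all) mutants.
oracle_count_sites <- function(codon, code = Biostrings::GENETIC_CODE,
                               exclude_stops = TRUE) {
  nuc <- c("A", "C", "G", "T")
  cod <- strsplit(codon, "")[[1]]
  aa <- unname(code[codon])
  s <- 0
  for (p in 1:3) {
    syn <- 0; denom <- 0
    for (nt in setdiff(nuc, cod[p])) {
      m <- cod; m[p] <- nt
      maa <- unname(code[paste(m, collapse = "")])
      if (exclude_stops && maa == "*") next
      denom <- denom + 1
      if (maa == aa) syn <- syn + 1
    }
    if (!exclude_stops) denom <- 3
    if (denom > 0) s <- s + syn / denom
  }
  c(s = s, n = 3 - s)
}

# Recursive minimal-pathway oracle for between-codon differences: walk every
# ordering of the differing positions, drop stop-passing paths (with the
# include-all fallback), average synonymous/nonsynonymous step counts.
oracle_count_differences <- function(a, b, code = Biostrings::GENETIC_CODE,
                                     exclude_stops = TRUE) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  paths <- list()
  walk <- function(cur, remaining, sd, nd, hit_stop) {
    if (!length(remaining)) {
      paths[[length(paths) + 1L]] <<- c(sd = sd, nd = nd, hit = hit_stop)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur; nxt[p] <- bv[p]
      from_aa <- unname(code[paste(cur, collapse = "")])
      to_aa <- unname(code[paste(nxt, collapse = "")])
      is_stop <- to_aa == "*" && !identical(nxt, bv)
      walk(nxt, setdiff(remaining, p),
           sd + as.numeric(from_aa == to_aa),
           nd + as.numeric(from_aa != to_aa),
           hit_stop || is_stop)
    }
  }
  walk(av, which(av != bv), 0, 0, FALSE)
  m <- do.call(rbind, paths)
  if (is.null(m)) return(c(sd = 0, nd = 0))
  use <- if (exclude_stops && any(m[, "hit"] == 0))
    m[m[, "hit"] == 0, , drop = FALSE] else m
  c(sd = mean(use[, "sd"]), nd = mean(use[, "nd"]))
}

sense_codons <- function(code = Biostrings::GENETIC_CODE) {
  names(code)[code != "*"]
}

random_protein <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               n, replace = TRUE), collapse = "")
}

write_temp_fasta <- function(records) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(mapply(function(id, seq) c(paste0(">", id), seq),
                           names(records), records, SIMPLIFY = FALSE)),
             path)
  path
}
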