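#' @importFrom stats aggregate rlnorm runif
NULL

#' Detect tandem gene arrays in a locus table
#'
#' Single-linkage chaining along each chromosome: two loci join the same
#' cluster when they lie on the same chromosome, the gap between their gene
#' spans is at most `maxGap`, and (when `sameFamily`) they share a family
#' label. Clusters of size >= 2 are reported, sorted by chromosome and
#' start. Detection is order-invariant: shuffled input yields identical
#' clusters.
#'
#' The default `maxGap` of 250 kb is a pragmatic synteny-scale threshold for
#' "close chromosomal proximity"; it is prominent in the pipeline
#' configuration and echoed in the run log.
#'
#' @param loci A [GenomicRanges::GRanges] as from [readLocusTable()].
#' @param maxGap Maximum gap (bp) between consecutive gene spans.
#' @param sameFamily Require shared `family_label` within a cluster.
#' @return A data.frame with one row per cluster: `chromosome`,
#'   `family_label`, `n`, `start`, `end`, `span`, and `members`
#'   (comma-separated gene ids in start order).
#' @export
detectTandemArrays <- function(loci, maxGap = 250000L, sameFamily = TRUE) {
  if (length(loci) == 0L)
    return(data.frame(chromosome = character(0), family_label = character(0),
                      n = integer(0), start = integer(0), end = integer(0),
                      span = integer(0), members = character(0)))
  df <- data.frame(
    chromosome = as.character(GenomicRanges::seqnames(loci)),
    start = GenomicRanges::start(loci),
    end = GenomicRanges::end(loci),
    gene_id = mcols(loci)$gene_id,
    family_label = mcols(loci)$family_label)
  key <- if (sameFamily) paste(df$chromosome, df$family_label, sep = "\r")
         else df$chromosome
  out <- lapply(split(df, key), function(g) {
    g <- g[order(g$start, g$gene_id), , drop = FALSE]
    gap <- g$start[-1] - g$end[-nrow(g)] - 1L
    cl <- cumsum(c(1L, as.integer(gap > maxGap)))
    do.call(rbind, lapply(split(g, cl), function(m) {
      if (nrow(m) < 2L) return(NULL)
      data.frame(chromosome = m$chromosome[1],
                 family_label = if (sameFamily) m$family_label[1]
                                else NA_character_,
                 n = nrow(m),
                 start = min(m$start), end = max(m$end),
                 span = max(m$end) - min(m$start) + 1L,
                 members = paste(m$gene_id, collapse = ","))
    }))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(detectTandemArrays(loci[0], maxGap, sameFamily))
  out <- out[order(out$chromosome, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare gene sizes between duplicated and other genes
#'
#' Gene size is the exon span (`end - start + 1`). The frequently-duplicated
#' group (`duplicated_group == TRUE`) is compared with all other genes by a
#' Welch two-sample t-test (unequal variances; gene-size variances differ
#' wildly between groups) and by the non-parametric Kruskal-Wallis test.
#' With fewer than two members in either group only descriptives are
#' reported. Two groups of identical constant size are reported as
#' no-difference (t = 0, p = 1).
#'
#' @param loci A [GenomicRanges::GRanges] with `duplicated_group` and
#'   `gene_size` metadata columns.
#' @return A [SizeComparison-class].
#' @export
compareGeneSizes <- function(loci) {
  dup <- mcols(loci)$duplicated_group
  if (is.null(dup)) stop("loci lack the duplicated_group column")
  size <- mcols(loci)$gene_size
  if (is.null(size)) size <- GenomicRanges::width(loci)
  g1 <- size[dup]; g2 <- size[!dup]
  if (length(g1) == 0L || length(g2) == 0L)
    stop("both gene groups must be non-empty")
  res <- new("SizeComparison",
             n1 = length(g1), n2 = length(g2),
             mean1 = mean(g1), mean2 = mean(g2),
             median1 = median(g1), median2 = median(g2),
             tStatistic = NA_real_, tP = NA_real_,
             kwStatistic = NA_real_, kwP = NA_real_)
  if (length(g1) < 2L || length(g2) < 2L) return(res)
  tt <- tryCatch(t.test(g1, g2), error = function(e) NULL)
  if (is.null(tt)) {
    # zero variance in both groups: identical constants mean no difference
    if (isTRUE(all.equal(mean(g1), mean(g2)))) {
      res@tStatistic <- 0; res@tP <- 1
    }
  } else {
    res@tStatistic <- unname(tt$statistic); res@tP <- tt$p.value
  }
  kw <- tryCatch(kruskal.test(list(g1, g2)), error = function(e) NULL)
  if (!is.null(kw) && is.finite(kw$statistic)) {
    res@kwStatistic <- unname(kw$statistic); res@kwP <- kw$p.value
  } else {
    res@kwStatistic <- 0; res@kwP <- 1
  }
  res
}

.frac_table <- function(group, category, levels) {
  if (length(group) == 0L)
    return(data.frame(group = character(0), category = character(0),
                      count = integer(0), fraction = numeric(0)))
  tab <- table(factor(group), factor(category, levels = levels))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("group", "category", "count")
  tot <- stats::ave(out$count, out$group, FUN = sum)
  out$fraction <- ifelse(tot > 0, out$count / tot, NA_real_)
  out[order(out$group, out$category), , drop = FALSE]
}

#' Tabulate functional and specificity classes over a cohort
#'
#' Counts and fractions of functional labels (active / pseudoenzyme /
#' pseudogene) and substrate classes, per family and for the focal-family
#' versus pooled-others split.
#'
#' @param calls A table from [triageCohort()] (columns `family`, `label`,
#'   `substrate_class`).
#' @param focalFamily Family pooled against all others (default `"CPO"`).
#' @return A list of four data.frames (`group`, `category`, `count`,
#'   `fraction`): `functionalByFamily`, `functionalByGroup`,
#'   `specificityByFamily`, `specificityByGroup`. Empty input gives empty
#'   tables.
#' @export
tabulateCohort <- function(calls, focalFamily = "CPO") {
  calls <- as.data.frame(calls)
  fun_lev <- c("ACTIVE", "PSEUDOENZYME", "PSEUDOGENE")
  spec_lev <- c("HYDROPHOBIC_SUBSTRATE", "BASIC_SUBSTRATE",
                "ACIDIC_SUBSTRATE", "POLAR_UNKNOWN", "UNDETERMINED")
  fam <- if (nrow(calls)) as.character(calls$family) else character(0)
  grp <- ifelse(!is.na(fam) & fam == focalFamily, focalFamily, "OTHER")
  list(
    functionalByFamily = .frac_table(fam, calls$label, fun_lev),
    functionalByGroup = .frac_table(grp, calls$label, fun_lev),
    specificityByFamily = .frac_table(fam, calls$substrate_class, spec_lev),
    specificityByGroup = .frac_table(grp, calls$substrate_class, spec_lev))
}

.pipeline_log <- function(lines, path) {
  cat(paste0(lines, "\n"), file = path, append = TRUE, sep = "")
}

.scheme_from_config <- function(cfg) {
  if (is.character(cfg)) {
    return(switch(cfg,
                  synthetic = syntheticScheme(),
                  toy = toyScheme(),
                  stop("unknown scheme name: ", cfg)))
  }
  ref <- if (!is.null(cfg$reference_fasta))
    as.character(readProteins(cfg$reference_fasta)[[1]])
  else cfg$reference
  functionalScheme(
    reference = ref,
    offset = if (is.null(cfg$offset)) 1L else cfg$offset,
    catalytic = cfg$catalytic,
    structural = if (is.null(cfg$structural)) list() else cfg$structural,
    specificityPosition = if (is.null(cfg$specificity_position)) 255L
                          else cfg$specificity_position,
    pocketPositions = if (is.null(cfg$pocket_positions))
      c(203L, 207L, 243L, 247L, 253L, 268L)
    else unlist(cfg$pocket_positions))
}

#' Run the full triage / selection / cohort pipeline from a config
#'
#' The configuration (a YAML file or an equivalent list) names the inputs
#' and parameters:
#' \preformatted{
#' scheme: synthetic          # or toy, or a mapping defining a scheme
#' cds_fasta: cohort.fa       # paralog coding sequences (triage + selection)
#' pairs_tsv: pairs.tsv       # manifest id_a / id_b / family (selection)
#' loci_tsv: loci.tsv         # gene loci (tandem detection + size stats)
#' output_dir: out
#' seed: 1
#' params:
#'   max_gap: 250000
#'   structural_threshold: 2
#'   focal_family: CPO
#'   stop_handling: exclude
#' }
#' Stages run in order triage -> selection -> cohort; each failing stage is
#' logged with context and the remaining stages still run, so partial
#' outputs are preserved. Numeric outputs are deterministic given the same
#' inputs and seed.
#'
#' @param config Path to a YAML file, or a list with the fields above.
#' @return Invisibly, a list with the per-stage results and output paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$scheme))
    stop("configuration error: no scheme specified")
  scheme <- .scheme_from_config(config$scheme)
  out_dir <- if (is.null(config$output_dir)) "." else config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- config$params
  max_gap <- if (is.null(params$max_gap)) 250000L else params$max_gap
  sthr <- if (is.null(params$structural_threshold)) 2L
          else params$structural_threshold
  focal <- if (is.null(params$focal_family)) "CPO" else params$focal_family
  stop_handling <- if (is.null(params$stop_handling)) "exclude"
                   else params$stop_handling

  log_path <- file.path(out_dir, "run_log.txt")
  unlink(log_path)
  .pipeline_log(c(
    paste0("MCPtriage pipeline, package version ",
           as.character(utils::packageVersion("MCPtriage"))),
    paste0("seed: ", if (is.null(config$seed)) "none" else config$seed),
    paste0("params: max_gap=", max_gap, " structural_threshold=", sthr,
           " focal_family=", focal, " stop_handling=", stop_handling)),
    log_path)

  results <- list(log = log_path)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .pipeline_log(paste0("ERROR in stage ", name, ": ",
                           conditionMessage(e)), log_path)
      NULL
    })
  }

  cds <- NULL
  if (!is.null(config$cds_fasta))
    cds <- run_stage("read-cds", readCodingSequences(config$cds_fasta))

  if (!is.null(cds)) {
    results$triage <- run_stage("triage", {
      prot <- AAStringSet(vapply(seq_along(cds), function(i)
        as.character(translateCDS(trimTrailingStop(cds[[i]]))), ""))
      names(prot) <- names(cds)
      calls <- triageCohort(prot, scheme, structuralThreshold = sthr)
      writeTriageTable(calls, file.path(out_dir, "triage.tsv"))
      .pipeline_log(paste0("triage: ", nrow(calls), " paralogs classified"),
                    log_path)
      calls
    })
    if (!is.null(results$triage)) {
      results$cohortTables <- run_stage("cohort-tables", {
        calls <- results$triage
        fam <- sub("\\..*$", "", calls$id)
        calls$family <- toupper(fam)
        tabs <- tabulateCohort(calls, focalFamily = focal)
        utils::write.table(tabs$functionalByFamily,
                           file.path(out_dir, "cohort_functional.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(tabs$specificityByFamily,
                           file.path(out_dir, "cohort_specificity.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        tabs
      })
    }
  }

  if (!is.null(config$pairs_tsv) && !is.null(cds)) {
    results$selection <- run_stage("selection", {
      manifest <- utils::read.delim(config$pairs_tsv,
                                    stringsAsFactors = FALSE)
      tab <- pairwiseSelectionTable(cds, manifest,
                                    stopHandling = stop_handling,
                                    focalFamily = focal)
      writeSelectionTable(tab, file.path(out_dir, "selection.tsv"))
      gt <- attr(tab, "groupTest")
      .pipeline_log(paste0("selection: ", nrow(tab), " pairs; ",
                           "focal-vs-others t-test ",
                           if (gt$computable)
                             sprintf("t=%.3f p=%.4g", gt$t, gt$p)
                           else "not computable"),
                    log_path)
      tab
    })
  }

  if (!is.null(config$loci_tsv)) {
    results$cohort <- run_stage("cohort", {
      loci <- readLocusTable(config$loci_tsv)
      clusters <- detectTandemArrays(loci, maxGap = max_gap)
      utils::write.table(clusters,
                         file.path(out_dir, "tandem_clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sizes <- compareGeneSizes(loci)
      size_df <- data.frame(
        n_duplicated = sizes@n1, n_other = sizes@n2,
        mean_duplicated = sizes@mean1, mean_other = sizes@mean2,
        median_duplicated = sizes@median1, median_other = sizes@median2,
        t_statistic = sizes@tStatistic, t_p = sizes@tP,
        kw_statistic = sizes@kwStatistic, kw_p = sizes@kwP)
      utils::write.table(size_df,
                         file.path(out_dir, "size_comparison.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      .pipeline_log(paste0("cohort: ", nrow(clusters), " tandem clusters; ",
                           "size t_p=", format(sizes@tP)), log_path)
      list(clusters = clusters, sizes = sizes)
    })
  }

  .pipeline_log("done", log_path)
  invisible(results)
}

#' Write a self-contained synthetic demo input set
#'
#' Generates a synthetic cohort, selection pairs and locus table under
#' `dir`, plus a ready-to-run pipeline `config.yaml`, and returns the config
#' path. Used by the examples and the packaged smoke tests.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param nParalogs Cohort size.
#' @return Path to the written config file.
#' @export
makeDemoInputs <- function(dir, seed = 1L, nParalogs = 30L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- makeSyntheticCohort(nParalogs = nParalogs, seed = seed)
  sel <- makeSelectionCohort(nFocal = 4L, nOther = 4L,
                             lengthCodons = 310L, seed = seed)
  cds <- c(cohort@cds, sel$cds)
  writeXStringSet(cds, file.path(dir, "cohort.fa"))
  utils::write.table(sel$manifest, file.path(dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLocusTable(cohort@loci, file.path(dir, "loci.tsv"))
  utils::write.table(as.data.frame(cohort@truth),
                     file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- list(scheme = "synthetic",
              cds_fasta = file.path(dir, "cohort.fa"),
              pairs_tsv = file.path(dir, "pairs.tsv"),
              loci_tsv = file.path(dir, "loci.tsv"),
              output_dir = file.path(dir, "out"),
              seed = seed,
              params = list(max_gap = 250000L, structural_threshold = 2L,
                            focal_family = "CPO",
                            stop_handling = "exclude"))
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_path
}
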