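#' Configuration for a full analysis run
#'
#' Validates paths and thresholds for [runPipeline()]. Every threshold echoes
#' the default of the module that owns it.
#'
#' @param fasta path to the 3'-UTR FASTA file (required).
#' @param expr,samples paths to the expression matrix and its sample
#'   annotation TSV (optional; enables the kinetic classification stage).
#' @param enrichment path to a RIP enrichment TSV (optional; enables target
#'   calling).
#' @param outdir output directory.
#' @param positional,pasWindow,requirePAS positional-CPE options
#'   (see [classifyCPEPositional()]).
#' @param persistenceCutoff peak-normalized 9 h threshold (default 0.5).
#' @param lateNum,lateDen late-ratio timepoints in hours (defaults 9, 6).
#' @param minReads transcriptome input-read threshold (default 10).
#' @param seed integer seed recorded in the run log.
#' @param verbose log progress messages (default `TRUE`).
#' @return a validated list of class `runConfig`.
#' @export
runConfig <- function(fasta, expr = NULL, samples = NULL, enrichment = NULL,
                      outdir = "arecpe_out", positional = FALSE,
                      pasWindow = 100L, requirePAS = TRUE,
                      persistenceCutoff = 0.5, lateNum = 9, lateDen = 6,
                      minReads = 10L, seed = 1L, verbose = TRUE) {
    stopifnot(is.character(fasta), length(fasta) == 1L)
    if (xor(is.null(expr), is.null(samples)))
        stop("'expr' and 'samples' must be given together")
    stopifnot(pasWindow > 0, persistenceCutoff > 0, persistenceCutoff < 1)
    structure(list(fasta = fasta, expr = expr, samples = samples,
                   enrichment = enrichment, outdir = outdir,
                   positional = positional, pasWindow = as.integer(pasWindow),
                   requirePAS = requirePAS,
                   persistenceCutoff = persistenceCutoff,
                   lateNum = lateNum, lateDen = lateDen,
                   minReads = as.integer(minReads), seed = as.integer(seed),
                   verbose = verbose),
              class = "runConfig")
}

#' Run the full 3'-UTR motif analysis pipeline
#'
#' Stages: scan the UTRs (longest isoform per gene) for ARE/CPE content;
#' build the ARE:CPE score table; if expression data are given, average
#' replicates, peak-normalize, classify persistence at 9 h and compare the
#' persistence of ARE- vs CPE-dominant genes (Mann-Whitney); if an enrichment
#' table is given, call targets. Per-stage TSVs and a run log (package
#' version, seed, thresholds) are written to `config$outdir`.
#'
#' @param config a [runConfig()] object.
#' @return invisibly, a list with the in-memory stage results (`counts`,
#'   `scores`, `classes`, `targets`, `comparison`) and `paths` of all files
#'   written.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "runConfig"))
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    log <- file.path(config$outdir, "run.log")
    logLines <- c(sprintf("arecpe %s", as.character(utils::packageVersion("arecpe"))),
                  sprintf("seed=%d", config$seed),
                  sprintf("positional=%s pasWindow=%d requirePAS=%s",
                          config$positional, config$pasWindow,
                          config$requirePAS),
                  sprintf("persistenceCutoff=%g lateNum=%g lateDen=%g minReads=%d",
                          config$persistenceCutoff, config$lateNum,
                          config$lateDen, config$minReads))
    paths <- character(0)

    .msg(config$verbose, "stage 1/4: motif scan")
    utrs <- readUTRFasta(config$fasta)
    if (length(utrs) == 0L)
        stop("no UTR records in ", config$fasta)
    counts <- scanUTRs(utrs, positional = config$positional,
                       pasWindow = config$pasWindow,
                       requirePAS = config$requirePAS)
    paths["counts"] <- writeTsv(counts, file.path(config$outdir, "counts.tsv"))

    .msg(config$verbose, "stage 2/4: ARE:CPE scores")
    scores <- buildScoreTable(counts, verbose = config$verbose)
    paths["scores"] <- writeTsv(scores, file.path(config$outdir, "scores.tsv"))
    logLines <- c(logLines,
                  sprintf("genes scanned=%d scored=%d dropped=%d",
                          nrow(counts), nrow(scores),
                          sum(attr(scores, "dropped"))))

    classes <- NULL; comparison <- NULL
    if (!is.null(config$expr)) {
        .msg(config$verbose, "stage 3/4: kinetic classification")
        tce <- readExpressionMatrix(config$expr, config$samples)
        avg <- averageReplicates(tce)
        pk <- peakNormalize(avg)
        lateCol <- as.character(config$lateNum)
        if (!lateCol %in% colnames(pk))
            stop("timepoint ", config$lateNum, " h not present in expression data")
        late <- pk[, lateCol]
        persist <- classifyPersistence(late)
        classes <- DataFrame(gene_id = rownames(pk),
                             peak_norm_late = late,
                             persistence = persist,
                             late_ratio = lateRatio(avg, tNum = config$lateNum,
                                                    tDen = config$lateDen))
        common <- intersect(classes$gene_id, scores$gene_id)
        classes$dominance <- scores$dominance[match(classes$gene_id,
                                                    scores$gene_id)]
        classes <- classes[classes$gene_id %in% common, , drop = FALSE]
        paths["classes"] <- writeTsv(classes,
                                     file.path(config$outdir, "classes.tsv"))
        areD <- classes$peak_norm_late[classes$dominance == "ARE_DOMINANT"]
        cpeD <- classes$peak_norm_late[classes$dominance == "CPE_DOMINANT"]
        if (length(areD) && length(cpeD)) {
            comparison <- compareGroups(areD, cpeD)
            logLines <- c(logLines, sprintf(
                "persistence ARE-d (n=%d) vs CPE-d (n=%d): U=%g, p=%.4g",
                length(areD), length(cpeD), comparison$statistic,
                comparison$p.value))
        }
        logLines <- c(logLines, sprintf(
            "persistence: %d sustained / %d downregulated of %d",
            sum(persist == "SUSTAINED"), sum(persist == "DOWNREGULATED"),
            length(persist)))
    }

    targets <- NULL
    if (!is.null(config$enrichment)) {
        .msg(config$verbose, "stage 4/4: target calling")
        enr <- readEnrichmentTable(config$enrichment)
        targets <- callTargets(enr, minReads = config$minReads)
        paths["targets"] <- writeGeneSet(targetGenes(targets),
                                         file.path(config$outdir,
                                                   "targets.txt"))
        logLines <- c(logLines, sprintf(
            "targets called=%d of universe=%d", length(targetGenes(targets)),
            length(universe(targets))))
    }

    writeLines(logLines, log)
    paths["log"] <- log
    invisible(list(counts = counts, scores = scores, classes = classes,
                   targets = targets, comparison = comparison,
                   paths = paths))
}
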