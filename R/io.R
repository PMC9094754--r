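# Single tabular dialect used everywhere: tab-separated, header row, "."
# for missing optional values, sorted output for diff-stability.

#' Read a typed TSV table
#'
#' Reads a tab-separated table with a header row, checks that all required
#' columns are present (extra columns are preserved), converts `"."` to `NA`,
#' and coerces declared numeric columns with an error naming the offending
#' cell on failure.
#'
#' @param path file path.
#' @param required character vector of required column names.
#' @param numeric character vector of columns that must parse as numbers.
#' @return a data.frame.
#' @export
readTsv <- function(path, required = character(0), numeric = character(0)) {
    if (!file.exists(path))
        stop("file not found: ", path)
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE,
                            colClasses = "character")
    miss <- setdiff(required, colnames(df))
    if (length(miss))
        stop("missing required column(s) in ", basename(path), ": ",
             paste(miss, collapse = ", "))
    df[df == "."] <- NA
    for (col in intersect(numeric, colnames(df))) {
        v <- suppressWarnings(as.numeric(df[[col]]))
        bad <- which(is.na(v) & !is.na(df[[col]]))
        if (length(bad))
            stop(sprintf("cannot parse '%s' as a number (row %d, column '%s') in %s",
                         df[[col]][bad[1L]], bad[1L], col, basename(path)))
        df[[col]] <- v
    }
    df
}

#' Write a TSV table
#'
#' Writes tab-separated output with a header, `NA` rendered as `"."`, no
#' quoting, rows sorted by the first column for deterministic diffs.
#'
#' @param x data.frame or DataFrame.
#' @param path output file path.
#' @param sort sort rows by the first column (default `TRUE`).
#' @return `path`, invisibly.
#' @export
writeTsv <- function(x, path, sort = TRUE) {
    x <- as.data.frame(x)
    if (sort && nrow(x))
        x <- x[order(x[[1L]]), , drop = FALSE]
    utils::write.table(x, path, sep = "\t", quote = FALSE, na = ".",
                       row.names = FALSE)
    invisible(path)
}

#' Read a per-UTR enrichment table
#'
#' Expects columns `gene_id`, `input_reads`, `log2_rpkm_fc`, `pv`, `pv_by`
#' and optionally `region_id` and `max_score` (missing peak scores become 0).
#'
#' @param path TSV file path.
#' @return a data.frame ready for [callTargets()].
#' @export
readEnrichmentTable <- function(path) {
    df <- readTsv(path,
                  required = c("gene_id", "input_reads", "log2_rpkm_fc",
                               "pv", "pv_by"),
                  numeric = c("input_reads", "log2_rpkm_fc", "pv", "pv_by",
                              "max_score"))
    if (!"max_score" %in% colnames(df))
        df$max_score <- 0
    df$max_score[is.na(df$max_score)] <- 0
    df
}

#' Read an expression matrix with sample annotations
#'
#' The expression TSV has `gene_id` as its first column and one column per
#' sample; the companion samples TSV maps `sample` to `timepoint` (hours) and
#' optional `replicate` and `genotype`.
#'
#' @param exprPath expression TSV path.
#' @param samplesPath sample-annotation TSV path.
#' @return a [TimeCourseExperiment].
#' @export
readExpressionMatrix <- function(exprPath, samplesPath) {
    expr <- readTsv(exprPath, required = "gene_id")
    samples <- readTsv(samplesPath, required = c("sample", "timepoint"),
                       numeric = "timepoint")
    sampleCols <- setdiff(colnames(expr), "gene_id")
    miss <- setdiff(sampleCols, samples$sample)
    if (length(miss))
        stop("sample(s) missing from annotation: ",
             paste(miss, collapse = ", "))
    if (anyDuplicated(expr$gene_id))
        stop("duplicated gene_id in ", basename(exprPath))
    m <- as.matrix(as.data.frame(lapply(expr[sampleCols], as.numeric)))
    colnames(m) <- sampleCols   # guard against make.names mangling
    if (anyNA(m))
        stop("non-numeric expression value in ", basename(exprPath))
    rownames(m) <- expr$gene_id
    ann <- samples[match(sampleCols, samples$sample), ]
    TimeCourseExperiment(m, timepoint = ann$timepoint,
                         replicate = if ("replicate" %in% colnames(ann))
                             ann$replicate else NULL,
                         genotype = if ("genotype" %in% colnames(ann))
                             ann$genotype else NULL)
}

#' Read/write a gene-set file (one gene id per line)
#'
#' @param path file path.
#' @return character vector of gene ids.
#' @export
readGeneSet <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    x <- readLines(path)
    x <- trimws(x)
    unique(x[nzchar(x)])
}

#' @rdname readGeneSet
#' @param genes character vector of gene ids to write.
#' @export
writeGeneSet <- function(genes, path) {
    writeLines(sort(unique(as.character(genes))), path)
    invisible(path)
}

#' Write a synthetic study bundle to disk
#'
#' Writes `utrs.fa`, `expression.tsv`, `samples.tsv`, `enrichment.tsv`,
#' `truth.tsv` and a key-value `manifest.txt` recording the generating
#' parameters and seed.
#'
#' @param study a bundle from [generateStudy()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
writeStudy <- function(study, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeUTRFasta(study$utrs, file.path(outdir, "utrs.fa"))
    a <- SummarizedExperiment::assay(study$expression)
    writeTsv(data.frame(gene_id = rownames(a), a, check.names = FALSE),
             file.path(outdir, "expression.tsv"))
    cd <- SummarizedExperiment::colData(study$expression)
    writeTsv(data.frame(sample = rownames(cd), timepoint = cd$timepoint,
                        replicate = cd$replicate, genotype = cd$genotype),
             file.path(outdir, "samples.tsv"), sort = FALSE)
    writeTsv(study$enrichment, file.path(outdir, "enrichment.tsv"))
    writeTsv(study$truth, file.path(outdir, "truth.tsv"))
    sp <- study$spec
    flat <- c(nGenes = sp$nGenes, areLambda = sp$areLambda,
              areMax = sp$areMax, cpeLambda = sp$cpeLambda,
              cpeMax = sp$cpeMax,
              utrLengthMin = sp$utrLengthRange[1L],
              utrLengthMax = sp$utrLengthRange[2L],
              withPAS = sp$withPAS, replicates = sp$replicates,
              seed = sp$seed,
              unlist(sp$kinetic), unlist(sp$enrichment))
    writeLines(paste0(names(flat), "=", unname(flat)),
               file.path(outdir, "manifest.txt"))
    invisible(outdir)
}
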