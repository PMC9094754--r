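#' Parameters of the synthetic kinetic model
#'
#' The generator's decay law is a deliberately simple stand-in for the
#' motif-dependent late-phase destabilization the analysis is designed to
#' detect: after an induced pulse peaking at a drawn peak time, abundance
#' decays as `exp(-k * dt)` with a per-gene rate linear in motif counts,
#' `k = max(0, k0 + alphaAre * nAre - alphaCpe * nCpe)` (per hour). It exists
#' to make recovery tests meaningful and is fully parameterized, not a claim
#' about real decay chemistry.
#'
#' @param k0 baseline late decay rate per hour (default 0.05).
#' @param alphaAre decay increment per ARE (default 0.04/h).
#' @param alphaCpe decay decrement per CPE (default 0.05/h).
#' @param peakTimes candidate peak times in hours, drawn uniformly per gene
#'   (default 1, 3, 6).
#' @param noiseSigma sdlog of the multiplicative lognormal noise
#'   (default 0.1).
#' @param baselineMeanLog,baselineSdLog lognormal law of the unstimulated
#'   baseline abundance (defaults `log(50)`, 0.5).
#' @param foldMeanLog,foldSdLog lognormal law of the induction fold change at
#'   the peak (defaults `log(8)`, 0.3).
#' @param times measurement timepoints in hours post LPS
#'   (default 0, 1, 3, 6, 9).
#' @return a validated list of class `kineticParams`.
#' @export
kineticParams <- function(k0 = 0.05, alphaAre = 0.04, alphaCpe = 0.05,
                          peakTimes = c(1, 3, 6), noiseSigma = 0.1,
                          baselineMeanLog = log(50), baselineSdLog = 0.5,
                          foldMeanLog = log(8), foldSdLog = 0.3,
                          times = c(0, 1, 3, 6, 9)) {
    stopifnot(k0 >= 0, alphaAre >= 0, alphaCpe >= 0, noiseSigma >= 0,
              all(peakTimes > 0), all(diff(times) > 0),
              all(peakTimes %in% times))
    structure(list(k0 = k0, alphaAre = alphaAre, alphaCpe = alphaCpe,
                   peakTimes = peakTimes, noiseSigma = noiseSigma,
                   baselineMeanLog = baselineMeanLog,
                   baselineSdLog = baselineSdLog,
                   foldMeanLog = foldMeanLog, foldSdLog = foldSdLog,
                   times = times),
              class = "kineticParams")
}

#' Parameters of the synthetic RIP enrichment model
#'
#' True targets draw a positive log2 IP/input fold change and a very small
#' raw enrichment p-value, as genuinely bound UTRs do in RIP-seq; non-targets
#' draw a null fold change and a uniform p-value. Benjamini-Yekutieli
#' adjusted p-values are computed over the whole table, so the table
#' exercises all three target-calling criteria.
#'
#' @param fracTargets fraction of genes that are true targets (default 0.1).
#' @param fcMean,fcSd normal law of the target log2 fold change
#'   (defaults 1.5, 0.4).
#' @param nullFcSd sd of the null fold change, mean 0 (default 0.3).
#' @param targetPvMax true-target raw p-values are Uniform(0, `targetPvMax`)
#'   (default 5e-6, small enough that BY adjustment over the table keeps bound
#'   UTRs significant, as in a real enrichment analysis).
#' @param meanReads,dispersion negative-binomial law of input read counts
#'   (defaults mean 200, dispersion 0.5, i.e. `size = 2`).
#' @return a validated list of class `enrichmentParams`.
#' @export
enrichmentParams <- function(fracTargets = 0.1, fcMean = 1.5, fcSd = 0.4,
                             nullFcSd = 0.3, targetPvMax = 5e-6,
                             meanReads = 200, dispersion = 0.5) {
    stopifnot(fracTargets >= 0, fracTargets <= 1, fcSd > 0, nullFcSd > 0,
              targetPvMax > 0, targetPvMax <= 1, meanReads > 0,
              dispersion > 0)
    structure(list(fracTargets = fracTargets, fcMean = fcMean, fcSd = fcSd,
                   nullFcSd = nullFcSd, targetPvMax = targetPvMax,
                   meanReads = meanReads, dispersion = dispersion),
              class = "enrichmentParams")
}

#' Specification of a complete synthetic study
#'
#' Bundles every generator parameter plus the per-gene motif-count laws
#' (truncated Poisson) and UTR length law (uniform integers).
#'
#' @param nGenes number of genes (default 200).
#' @param areLambda,areMax Poisson mean and cap of per-gene ARE counts
#'   (defaults 3, 12).
#' @param cpeLambda,cpeMax Poisson mean and cap of per-gene CPE counts
#'   (defaults 2, 8).
#' @param utrLengthRange UTR length range in nt (default 200-2000).
#' @param withPAS plant one AATAAA near the 3' end of each UTR
#'   (default `TRUE`).
#' @param replicates expression replicates per timepoint (default 4).
#' @param kinetic a [kineticParams()] object.
#' @param enrichment an [enrichmentParams()] object.
#' @param seed master seed; all sub-generators derive their own seeds from it.
#' @return a validated list of class `syntheticSpec`.
#' @export
syntheticSpec <- function(nGenes = 200L, areLambda = 3, areMax = 12L,
                          cpeLambda = 2, cpeMax = 8L,
                          utrLengthRange = c(200L, 2000L), withPAS = TRUE,
                          replicates = 4L, kinetic = kineticParams(),
                          enrichment = enrichmentParams(), seed = 1L) {
    stopifnot(nGenes >= 1, areLambda >= 0, cpeLambda >= 0,
              length(utrLengthRange) == 2, utrLengthRange[1] > 0,
              diff(utrLengthRange) >= 0, replicates >= 1,
              inherits(kinetic, "kineticParams"),
              inherits(enrichment, "enrichmentParams"))
    structure(list(nGenes = as.integer(nGenes), areLambda = areLambda,
                   areMax = as.integer(areMax), cpeLambda = cpeLambda,
                   cpeMax = as.integer(cpeMax),
                   utrLengthRange = as.integer(utrLengthRange),
                   withPAS = withPAS, replicates = as.integer(replicates),
                   kinetic = kinetic, enrichment = enrichment,
                   seed = as.integer(seed)),
              class = "syntheticSpec")
}

# Lightweight motif-hit scanner for the generator's hot loop: matrix of
# (start, end), 1-based closed, no DataFrame overhead.
.scanHits <- function(s, vocab) {
    subj <- Biostrings::DNAString(s)
    out <- lapply(vocab, function(m) {
        r <- Biostrings::matchPattern(m, subj)
        if (length(r)) cbind(IRanges::start(r), IRanges::end(r))
    })
    hits <- do.call(rbind, out)
    if (is.null(hits)) matrix(0L, 0L, 2L) else hits
}

# A stretch of background sequence free of ARE/CPE/PAS motifs: uniform ACGT
# with resampling of any window that happens to spell a motif.
.cleanBackground <- function(n, maxRounds = 200L) {
    if (n == 0L) return("")
    v <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    vocab <- c(areMotif(), cpeMotifs(), pasMotifs())
    for (round in seq_len(maxRounds)) {
        hits <- .scanHits(paste(v, collapse = ""), vocab)
        if (!nrow(hits)) return(paste(v, collapse = ""))
        for (j in seq_len(nrow(hits)))
            v[hits[j, 1L]:hits[j, 2L]] <-
                sample(c("A", "C", "G", "T"), hits[j, 2L] - hits[j, 1L] + 1L,
                       replace = TRUE)
    }
    stop("could not generate motif-free background")
}

#' Generate a 3'-UTR with exactly the requested motif content
#'
#' Plants `nAre` ARE pentamers and `nCpe` CPE motifs (cycling through the CPE
#' vocabulary) in motif-free background sequence, optionally with one `AATAAA`
#' polyadenylation signal near the 3' end. The built sequence is re-scanned
#' with [countARE()]/[countCPE()] and rebuilt until the planted counts are
#' reproduced exactly, so the generator is its own round-trip check.
#' Deterministic given `seed`.
#'
#' @param nAre,nCpe planted motif counts, `>= 0`.
#' @param length total UTR length in nt.
#' @param seed integer seed.
#' @param withPAS plant a PAS ~10 nt from the 3' end (default `FALSE`).
#' @param maxTries rebuild budget before declaring the packing infeasible.
#' @return a character string of exactly `length` nt.
#' @examples
#' u <- generateUTR(5, 3, 500, seed = 1)
#' c(countARE(u), countCPE(u))   # 5 3
#' @export
generateUTR <- function(nAre, nCpe, length, seed = 1L, withPAS = FALSE,
                        maxTries = 40L) {
    stopifnot(nAre >= 0, nCpe >= 0, length > 0)
    cpePick <- rep_len(cpeMotifs(), max(nCpe, 1L))[seq_len(nCpe)]
    # guard C on both sides of each planted motif
    blocks <- c(rep(paste0("C", areMotif(), "C"), nAre),
                if (nCpe) paste0("C", cpePick, "C"))
    tailBlock <- if (withPAS) paste0("C", pasMotifs()[1L], "C") else NULL
    fixed <- sum(nchar(blocks)) + sum(nchar(tailBlock)) +
        if (withPAS) 8L else 0L   # reserve a short 3' tail after the PAS
    if (fixed > length)
        stop("cannot fit ", nAre, " ARE + ", nCpe, " CPE motifs",
             if (withPAS) " + PAS", " in ", length, " nt")
    for (try in seq_len(maxTries)) {
        s <- .withSeed(.subSeed(seed, try), {
            blk <- if (length(blocks)) sample(blocks) else character(0)
            spare <- length - fixed
            # split one clean background stretch across the gaps around the
            # blocks (substrings of a motif-free string stay motif-free)
            nGap <- length(blk) + 1L
            cuts <- if (spare > 0)
                tabulate(sample.int(nGap, spare, replace = TRUE), nGap)
            else rep(0L, nGap)
            bg <- .cleanBackground(spare + if (withPAS) 8L else 0L)
            ends <- cumsum(cuts)
            starts <- c(1L, utils::head(ends, -1L) + 1L)
            parts <- character(0)
            for (i in seq_len(nGap)) {
                parts <- c(parts,
                           if (cuts[i] > 0) substr(bg, starts[i], ends[i])
                           else "")
                if (i <= length(blk)) parts <- c(parts, blk[i])
            }
            if (withPAS)
                parts <- c(parts, tailBlock,
                           substr(bg, spare + 1L, spare + 8L))
            paste(parts, collapse = "")
        })
        okPas <- !withPAS || nrow(findPAS(s)) == 1L
        if (countARE(s) == nAre && countCPE(s) == nCpe && okPas &&
            nchar(s) == length)
            return(s)
    }
    stop("could not build a UTR with the requested motif content in ",
         maxTries, " attempts")
}

# Noise-free pulse curves for vectors of motif counts; one row per gene.
.baseCourses <- function(nAre, nCpe, params) {
    n <- max(length(nAre), length(nCpe))
    nAre <- rep_len(nAre, n); nCpe <- rep_len(nCpe, n)
    k <- pmax(0, params$k0 + params$alphaAre * nAre - params$alphaCpe * nCpe)
    b <- stats::rlnorm(n, params$baselineMeanLog, params$baselineSdLog)
    fold <- stats::rlnorm(n, params$foldMeanLog, params$foldSdLog)
    peak <- sample(params$peakTimes, n, replace = TRUE)
    tt <- params$times
    m <- matrix(0, n, length(tt), dimnames = list(NULL, as.character(tt)))
    for (j in seq_along(tt)) {
        t <- tt[j]
        rising <- t <= peak
        # geometric rise baseline -> peak, then exponential decay
        m[, j] <- ifelse(rising, b * fold^(t / peak),
                         b * fold * exp(-k * (t - peak)))
    }
    list(values = m, k = k, peak = peak)
}

#' Generate LPS-response expression time courses
#'
#' Simulates abundances at the measurement timepoints: a lognormal baseline,
#' an induced pulse peaking at a drawn peak time, post-peak exponential decay
#' at a rate linear in the planted motif counts (see [kineticParams()]), and
#' multiplicative lognormal noise. Vectorized over genes; deterministic given
#' `seed`.
#'
#' @param nAre,nCpe integer vectors of motif counts (recycled).
#' @param params a [kineticParams()] object.
#' @param seed integer seed.
#' @return numeric matrix, genes x timepoints (column names = hours), with
#'   the per-gene decay rate in attribute `"decayRate"` and the drawn peak
#'   time in `"peakTime"`.
#' @examples
#' tc <- generateTimeCourse(5, 2, kineticParams(noiseSigma = 0), seed = 1)
#' tc[, "9"] / max(tc)   # below 1: ARE-dominant decay
#' @export
generateTimeCourse <- function(nAre, nCpe, params = kineticParams(),
                               seed = 1L) {
    stopifnot(inherits(params, "kineticParams"))
    .withSeed(seed, {
        base <- .baseCourses(nAre, nCpe, params)
        v <- base$values
        if (params$noiseSigma > 0)
            v <- v * matrix(stats::rlnorm(length(v), 0, params$noiseSigma),
                            nrow(v))
        attr(v, "decayRate") <- base$k
        attr(v, "peakTime") <- base$peak
        v
    })
}

#' Generate a synthetic RIP enrichment table with known truth
#'
#' @param nGenes number of genes.
#' @param params an [enrichmentParams()] object.
#' @param seed integer seed.
#' @param geneIds optional gene ids (default `gene0001`, ...).
#' @return list with `table` (columns `region_id`, `gene_id`, `input_reads`,
#'   `log2_rpkm_fc`, `pv`, `pv_by`, `max_score`) and `truth` (data.frame of
#'   `gene_id`, `is_target`).
#' @examples
#' g <- generateEnrichmentTable(100, seed = 7)
#' sum(g$truth$is_target)
#' @export
generateEnrichmentTable <- function(nGenes, params = enrichmentParams(),
                                    seed = 1L, geneIds = NULL) {
    stopifnot(inherits(params, "enrichmentParams"), nGenes >= 1)
    if (is.null(geneIds))
        geneIds <- sprintf("gene%04d", seq_len(nGenes))
    stopifnot(length(geneIds) == nGenes, !anyDuplicated(geneIds))
    .withSeed(seed, {
        isTarget <- stats::runif(nGenes) < params$fracTargets
        fc <- ifelse(isTarget,
                     stats::rnorm(nGenes, params$fcMean, params$fcSd),
                     stats::rnorm(nGenes, 0, params$nullFcSd))
        pv <- ifelse(isTarget,
                     stats::runif(nGenes, 0, params$targetPvMax),
                     stats::runif(nGenes))
        pv <- pmax(pv, .Machine$double.xmin)   # keep p in (0, 1]
        reads <- stats::rnbinom(nGenes, size = 1 / params$dispersion,
                                mu = params$meanReads)
        tbl <- data.frame(region_id = paste0(geneIds, "_utr"),
                          gene_id = geneIds,
                          input_reads = as.integer(reads),
                          log2_rpkm_fc = fc,
                          pv = pv,
                          pv_by = stats::p.adjust(pv, method = "BY"),
                          max_score = 0,
                          stringsAsFactors = FALSE)
        list(table = tbl,
             truth = data.frame(gene_id = geneIds, is_target = isTarget,
                                stringsAsFactors = FALSE))
    })
}

#' Generate a complete synthetic study
#'
#' Produces, for one master seed, a cross-referenced bundle: planted-motif
#' UTR sequences, an LPS expression time course whose late decay is driven by
#' each gene's planted motif counts, a RIP enrichment table with a known
#' target truth set, and the per-gene truth table. Optionally writes the
#' bundle to disk (FASTA + TSVs + a plain-text manifest).
#'
#' @param spec a [syntheticSpec()] object.
#' @param outdir if non-`NULL`, directory to write `utrs.fa`,
#'   `expression.tsv`, `samples.tsv`, `enrichment.tsv`, `truth.tsv`, and
#'   `manifest.txt` into (created if needed).
#' @param verbose report progress (default `FALSE`).
#' @return list with `utrs` ([UTRSet]), `expression`
#'   ([TimeCourseExperiment]), `enrichment` (data.frame), `truth`
#'   (data.frame: `gene_id`, `n_are`, `n_cpe`, `utr_length`, `decay_rate`,
#'   `peak_time`, `is_target`), and `spec`.
#' @examples
#' study <- generateStudy(syntheticSpec(nGenes = 5, seed = 1))
#' study$truth
#' @export
generateStudy <- function(spec, outdir = NULL, verbose = FALSE) {
    stopifnot(inherits(spec, "syntheticSpec"))
    draws <- .withSeed(.subSeed(spec$seed, 1L), {
        list(nAre = pmin(stats::rpois(spec$nGenes, spec$areLambda),
                         spec$areMax),
             nCpe = pmin(stats::rpois(spec$nGenes, spec$cpeLambda),
                         spec$cpeMax),
             len = sample(spec$utrLengthRange[1L]:spec$utrLengthRange[2L],
                          spec$nGenes, replace = TRUE))
    })
    genes <- sprintf("gene%04d", seq_len(spec$nGenes))
    .msg(verbose, "generating ", spec$nGenes, " UTR sequences")
    seqs <- vapply(seq_len(spec$nGenes), function(i)
        generateUTR(draws$nAre[i], draws$nCpe[i], draws$len[i],
                    seed = .subSeed(spec$seed, 100L + i),
                    withPAS = spec$withPAS),
        character(1L))
    utrs <- UTRSet(seqs, txIds = paste0(genes, ".1"), geneIds = genes)

    .msg(verbose, "generating expression time courses")
    kp <- spec$kinetic
    base <- .withSeed(.subSeed(spec$seed, 2L),
                      .baseCourses(draws$nAre, draws$nCpe, kp))
    reps <- lapply(seq_len(spec$replicates), function(r) .withSeed(
        .subSeed(spec$seed, 200L + r),
        base$values * matrix(stats::rlnorm(length(base$values), 0,
                                           kp$noiseSigma),
                             nrow(base$values))))
    counts <- do.call(cbind, reps)
    rownames(counts) <- genes
    tp <- rep(kp$times, times = spec$replicates)
    repl <- rep(seq_len(spec$replicates), each = length(kp$times))
    colnames(counts) <- sprintf("t%g_r%d", tp, repl)
    expr <- TimeCourseExperiment(counts, timepoint = tp, replicate = repl)

    .msg(verbose, "generating enrichment table")
    enr <- generateEnrichmentTable(spec$nGenes, spec$enrichment,
                                   seed = .subSeed(spec$seed, 3L),
                                   geneIds = genes)
    truth <- data.frame(gene_id = genes,
                        n_are = draws$nAre, n_cpe = draws$nCpe,
                        utr_length = draws$len,
                        decay_rate = base$k, peak_time = base$peak,
                        is_target = enr$truth$is_target,
                        stringsAsFactors = FALSE)
    study <- list(utrs = utrs, expression = expr, enrichment = enr$table,
                  truth = truth, spec = spec)
    if (!is.null(outdir))
        writeStudy(study, outdir)
    study
}
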