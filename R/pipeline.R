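#' @include AllClasses.R enumerate.R zwitter.R binding.R weighting.R pcps.R
NULL

#' Find the source proteins of a set of peptides
#'
#' For every peptide, every protein of the proteome that can generate it:
#' as a contiguous (non-spliced) fragment and/or through a cis-splicing
#' decomposition within the config's constraints.  Used to map zwitter
#' peptides to the human antigens (genes) they derive from.
#'
#' @param peps character vector of peptides.
#' @param proteome a [Proteome-class].
#' @param config an [enumerationConfig()].
#' @return data.frame with columns `peptide`, `protein_id`, `gene`,
#'   `category` (`"nonspliced"` or `"cis"`), deduplicated.
#' @export
annotateSources <- function(peps, proteome, config = enumerationConfig()) {
    peps <- unique(as.character(peps))
    gmap <- geneIds(proteome)
    seqs <- proteinSequences(proteome)
    rows <- list()
    for (p in peps) {
        hit_non <- names(seqs)[vapply(seqs, function(s)
            grepl(p, s, fixed = TRUE), logical(1))]
        if (length(hit_non))
            rows[[length(rows) + 1L]] <- data.frame(
                peptide = p, protein_id = hit_non, category = "nonspliced",
                stringsAsFactors = FALSE)
        dec <- findCisDecompositions(p, proteome, config)
        if (nrow(dec))
            rows[[length(rows) + 1L]] <- data.frame(
                peptide = p, protein_id = unique(dec$protein_id),
                category = "cis", stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(data.frame(peptide = character(), protein_id = character(),
                          gene = character(), category = character()))
    out <- unique(do.call(rbind, rows))
    out$gene <- unname(gmap[out$protein_id])
    rownames(out) <- NULL
    out[, c("peptide", "protein_id", "gene", "category")]
}

# per-virus binder-restricted report columns
.binderReport <- function(vNb, vCb, hNb, hCb) {
    hits <- findZwitter(vNb, vCb, hNb, hCb)
    tab <- hits$table
    cis_rows <- tab$viral_category == "cis" | tab$human_category == "cis"
    b_non <- length(vNb); b_cis <- length(vCb)
    b_all <- length(union(peptides(vNb), peptides(vCb)))
    data.frame(
        zb_i = hits$counts[["z_i"]],
        zb_cis = length(unique(tab$peptide[cis_rows])),
        zb_all = hits$counts[["z_all"]],
        b_v_non = b_non, b_v_cis = b_cis, b_v_all = b_all,
        B_v_non = if (b_non > 0) 100 * hits$counts[["z_i"]] / b_non else NA_real_,
        B_v_cis = if (b_cis > 0)
            100 * length(unique(tab$peptide[cis_rows])) / b_cis else NA_real_,
        B_v_all = if (b_all > 0)
            100 * hits$counts[["z_all"]] / b_all else NA_real_)
}

#' Run the baseline zwitter pipeline
#'
#' Enumerate the human and per-virus peptide universes, intersect them,
#' filter by predicted HLA binding at the cutoff, and compute the
#' per-virus frequency statistics plus the group comparisons
#' (Kolmogorov-Smirnov across category frequency distributions, per-virus
#' zwitter/binder odds ratios, proteome-size correlation).
#'
#' @param human a [Proteome-class] (self side).
#' @param viruses named list of [Proteome-class] objects, or a manifest
#'   path/data.frame for [readVirusProteomes()].
#' @param config an [enumerationConfig()].
#' @param predictor optional, anything [asPredictor()] accepts; when
#'   `NULL`, binder-restricted columns are omitted.
#' @param cutoff_nM binder cutoff in nM (default 500).
#' @param outDir optional output directory; written files are
#'   deterministic given identical inputs.
#' @return list with `report` (one row per virus), `peptides` (zwitter
#'   peptide table with per-pair category columns and IC50 when a
#'   predictor is given), `groupStats`, `params`, and `humanUniverses`
#'   (reused by downstream stages).
#' @export
runBaseline <- function(human, viruses, config = enumerationConfig(),
                        predictor = NULL, cutoff_nM = 500, outDir = NULL) {
    if (is.character(viruses) || is.data.frame(viruses))
        viruses <- readVirusProteomes(viruses)
    if (!length(viruses)) stop("no viruses")
    if (is.null(names(viruses)))
        names(viruses) <- vapply(viruses, proteomeName, character(1))
    fn <- if (!is.null(predictor)) asPredictor(predictor) else NULL

    hN <- peptideUniverse(human, "nonspliced", config)
    hC <- peptideUniverse(human, "cis", config)
    hNb <- if (!is.null(fn)) filterBinders(hN, fn, cutoff_nM) else NULL
    hCb <- if (!is.null(fn)) filterBinders(hC, fn, cutoff_nM) else NULL

    report <- list(); pep_tabs <- list()
    for (v in names(viruses)) {
        vN <- peptideUniverse(viruses[[v]], "nonspliced", config)
        vC <- peptideUniverse(viruses[[v]], "cis", config)
        row <- zwitterReport(v, vN, vC, hN, hC)
        tab <- attr(row, "table")
        if (nrow(tab)) tab <- data.frame(virus = v, tab)
        if (!is.null(fn)) {
            vNb <- filterBinders(vN, fn, cutoff_nM)
            vCb <- filterBinders(vC, fn, cutoff_nM)
            row <- cbind(row, .binderReport(vNb, vCb, hNb, hCb))
            if (nrow(tab)) {
                tab$ic50_nM <- unname(fn(tab$peptide))
                tab$binder <- tab$ic50_nM <= cutoff_nM
            }
        }
        attr(row, "table") <- NULL
        report[[v]] <- row
        if (nrow(tab)) pep_tabs[[v]] <- tab
    }
    report <- do.call(rbind, report)
    rownames(report) <- NULL
    pep_table <- if (length(pep_tabs)) do.call(rbind, pep_tabs) else
        data.frame(virus = character(), peptide = character(),
                   viral_category = character(), human_category = character())
    rownames(pep_table) <- NULL

    groupStats <- list()
    if (nrow(report) >= 1L &&
        sum(!is.na(report$F_v_non)) >= 1L && sum(!is.na(report$F_v_cis)) >= 1L)
        groupStats$ks_non_vs_cis <- ksCompare(
            report$F_v_non[!is.na(report$F_v_non)],
            report$F_v_cis[!is.na(report$F_v_cis)])
    if (!is.null(fn)) {
        groupStats$binder_enrichment <- lapply(names(viruses), function(v) {
            vN <- peptideUniverse(viruses[[v]], "nonspliced", config)
            vC <- peptideUniverse(viruses[[v]], "cis", config)
            all_pep <- union(peptides(vN), peptides(vC))
            zw <- unique(pep_table$peptide[pep_table$virus == v])
            bind <- all_pep[fn(all_pep) <= cutoff_nM]
            a <- sum(zw %in% bind); b <- length(zw) - a
            c_ <- sum(!all_pep %in% zw & all_pep %in% bind)
            d <- length(all_pep) - length(zw) - c_
            c(list(virus = v), binderEnrichment(rbind(c(a, b), c(c_, d))))
        })
    }
    residues <- vapply(viruses, totalResidues, numeric(1))
    if (length(viruses) >= 3L && stats::sd(residues) > 0 &&
        stats::sd(report$z_all) > 0)
        groupStats$length_correlation <-
            lengthCorrelation(residues, report$z_all)
    groupStats$summary <- list(
        F_v_non = summarizeFrequencies(report$F_v_non),
        F_v_cis = summarizeFrequencies(report$F_v_cis),
        F_v_all = summarizeFrequencies(report$F_v_all),
        F_v_non_nonzero = summarizeFrequencies(report$F_v_non,
                                               excludeZero = TRUE),
        F_v_cis_nonzero = summarizeFrequencies(report$F_v_cis,
                                               excludeZero = TRUE))

    params <- list(peptideLength = config@peptideLength,
                   maxIntervening = config@maxIntervening,
                   minGapNormal = config@minGapNormal,
                   minGapReverse = config@minGapReverse,
                   minReactantLength = config@minReactantLength,
                   excludeNonstandard = config@excludeNonstandard,
                   cutoff_nM = if (!is.null(fn)) cutoff_nM else NA,
                   nViruses = length(viruses))
    out <- list(report = report, peptides = pep_table,
                groupStats = groupStats, params = params,
                humanUniverses = list(non = hN, cis = hC,
                                      non_b = hNb, cis_b = hCb))
    if (!is.null(outDir)) .writeBaselineOutputs(out, outDir)
    out
}

.writeBaselineOutputs <- function(res, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv <- function(df, name)
        write.table(.format_num(df), file.path(outDir, name), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    .write_tsv(res$report, "baseline_report.tsv")
    .write_tsv(res$peptides, "zwitter_peptides.tsv")
    jsonlite::write_json(res$params, file.path(outDir, "params.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    jsonlite::write_json(res$groupStats, file.path(outDir, "group_stats.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         na = "null")
    invisible(NULL)
}

# full-precision numeric formatting so identical results give identical bytes
.format_num <- function(df) {
    for (j in seq_along(df))
        if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
    df
}

#' Run the presentation-weighted pipeline
#'
#' [runBaseline()] plus the mTEC stage: per-gene expression values are
#' turned into presentation weights, every zwitter peptide is mapped to
#' its human source genes, and the zwitter pool is re-sampled with those
#' weights ([weightedZwitterSampling()]) to estimate `M_v` (all zwitter
#' candidates, denominator `p_v_all`) and, when a predictor is given,
#' `MB_v` (binder-restricted pool, denominator `b_v_all`).
#'
#' @inheritParams runBaseline
#' @param expression microarray long table or scrna count matrix (see
#'   [microarrayExpression()] / [scrnaLognormalize()]).
#' @param platform `"microarray"` or `"scrna"`.
#' @param sampling a [samplingConfig()].
#' @param geneMap optional data.frame (`gene_id`, `protein_id`) overriding
#'   the proteome's own gene annotation.
#' @return the baseline list plus `weighted`: `weights`, `sourceMap`,
#'   `M` (and `MB`), per-repeat counts.
#' @export
runWeighted <- function(human, viruses, expression,
                        platform = c("microarray", "scrna"),
                        config = enumerationConfig(), predictor = NULL,
                        cutoff_nM = 500, sampling = samplingConfig(),
                        geneMap = NULL, outDir = NULL) {
    platform <- match.arg(platform)
    base <- runBaseline(human, viruses, config, predictor, cutoff_nM,
                        outDir = outDir)
    E <- if (platform == "microarray") microarrayExpression(expression)
         else scrnaLognormalize(expression)$E
    weights <- computeWeights(E)

    pool <- base$peptides
    if (!nrow(pool))
        stop("no zwitter peptides to sample")
    src <- annotateSources(unique(pool$peptide), human, config)
    if (!is.null(geneMap)) {
        geneMap <- as.data.frame(geneMap)
        src$gene <- geneMap$gene_id[match(src$protein_id, geneMap$protein_id)]
    }
    if (all(is.na(src$gene)) || !nrow(src))
        stop("no zwitter source protein could be mapped to a gene")
    pw <- peptideWeights(data.frame(peptide = src$peptide, gene = src$gene),
                         weights)
    denom_all <- setNames(base$report$p_v_all, base$report$virus)
    samp <- weightedZwitterSampling(pool[, c("peptide", "virus")], pw,
                                    sampling, denom_all)
    weighted <- list(weights = weights, sourceMap = src,
                     peptideWeights = pw, M = samp$M,
                     perRepeat = samp$perRepeat)
    if (!is.null(predictor) && "binder" %in% names(pool)) {
        bpool <- pool[pool$binder, , drop = FALSE]
        denom_b <- setNames(base$report$b_v_all, base$report$virus)
        cfg_b <- samplingConfig(sampling@repeats, sampling@sizeFraction,
                                sampling@replacement, sampling@seed + 1L)
        sampb <- weightedZwitterSampling(bpool[, c("peptide", "virus")], pw,
                                         cfg_b, denom_b)
        weighted$MB <- sampb$M
        weighted$perRepeatB <- sampb$perRepeat
    }
    out <- c(base, list(weighted = weighted))
    if (!is.null(outDir)) {
        m_df <- data.frame(virus = names(samp$M), M_v = unname(samp$M))
        if (!is.null(weighted$MB))
            m_df$MB_v <- unname(weighted$MB[m_df$virus])
        write.table(.format_num(m_df), file.path(outDir, "weighted_report.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out
}

#' Run the PCPS-frequency pipeline
#'
#' [pcpsSweep()] over a grid of immunopeptidome cis-spliced percentages,
#' with `fNon` either given directly or estimated from a digestion
#' dataset via [estimateFnon()].
#'
#' @inheritParams runBaseline
#' @param fValues grid of cis percentages (default `seq(1, 35, by = 2)`).
#' @param fNon produced non-spliced fraction; overrides `digestion`.
#' @param digestion a [digestionDataset()] used when `fNon` is missing.
#' @param gamma theoretical cis/non ratio (default 398).
#' @param repeats subsampling repeats per f (default 600).
#' @param seed master seed.
#' @return the [pcpsSweep()] result plus `fNon` and `params`.
#' @export
runPcps <- function(human, viruses, config = enumerationConfig(),
                    predictor = NULL, cutoff_nM = 500,
                    fValues = seq(1, 35, by = 2), fNon = NULL,
                    digestion = NULL, gamma = 398, repeats = 600,
                    seed = 1, outDir = NULL) {
    if (is.character(viruses) || is.data.frame(viruses))
        viruses <- readVirusProteomes(viruses)
    if (!length(viruses)) stop("no viruses")
    if (is.null(fNon)) {
        if (is.null(digestion))
            stop("either 'fNon' or 'digestion' must be given")
        fNon <- estimateFnon(digestion, config@peptideLength)
    }
    hN <- peptideUniverse(human, "nonspliced", config)
    hC <- peptideUniverse(human, "cis", config)
    vu <- lapply(viruses, function(p)
        list(non = peptideUniverse(p, "nonspliced", config),
             cis = peptideUniverse(p, "cis", config)))
    sweep <- pcpsSweep(vu, hN, hC, fValues = fValues, fNon = fNon,
                       gamma = gamma, repeats = repeats,
                       predictor = predictor, cutoff_nM = cutoff_nM,
                       seed = seed)
    out <- c(sweep, list(fNon = fNon,
                         params = list(fValues = fValues, gamma = gamma,
                                       repeats = repeats, seed = seed,
                                       cutoff_nM = cutoff_nM)))
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        write.table(.format_num(sweep$draws),
                    file.path(outDir, "pcps_draws.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(.format_num(sweep$summary),
                    file.path(outDir, "pcps_summary.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out
}

#' Run the complete pipeline end to end
#'
#' Baseline, presentation-weighted and PCPS-frequency stages from one
#' configuration list, writing deterministic TSV/JSON outputs: identical
#' config and seed give byte-identical files.
#'
#' @param params list with elements `human` (Proteome or FASTA path),
#'   `viruses` (named Proteome list or manifest path), optional
#'   `predictor` (matrix object or file path), `cutoff_nM`, `config`
#'   (an [enumerationConfig()]), `expression` + `platform` (+ optional
#'   `geneMap`), `sampling` (a [samplingConfig()]), `pcps` (list:
#'   `fValues`, `fNon` or `digestion`, `gamma`, `repeats`) and `seed`.
#' @param outDir output directory.
#' @return list with the three stage results (invisibly).
#' @export
runAll <- function(params, outDir) {
    human <- params$human
    if (is.character(human)) human <- readProteome(human, name = "human")
    viruses <- params$viruses
    if (is.character(viruses) || is.data.frame(viruses))
        viruses <- readVirusProteomes(viruses)
    predictor <- params$predictor
    if (is.character(predictor)) predictor <- readScoringMatrix(predictor)
    config <- if (is.null(params$config)) enumerationConfig() else params$config
    cutoff <- if (is.null(params$cutoff_nM)) 500 else params$cutoff_nM
    seed <- if (is.null(params$seed)) 1L else as.integer(params$seed)

    if (!is.null(params$expression)) {
        sampling <- if (is.null(params$sampling))
            samplingConfig(seed = seed) else params$sampling
        stage12 <- runWeighted(human, viruses, params$expression,
                               platform = params$platform, config = config,
                               predictor = predictor, cutoff_nM = cutoff,
                               sampling = sampling, geneMap = params$geneMap,
                               outDir = outDir)
    } else {
        stage12 <- runBaseline(human, viruses, config, predictor, cutoff,
                               outDir = outDir)
    }
    pcps <- NULL
    if (!is.null(params$pcps)) {
        pp <- params$pcps
        pcps <- runPcps(human, viruses, config = config,
                        predictor = predictor, cutoff_nM = cutoff,
                        fValues = if (is.null(pp$fValues))
                            seq(1, 35, by = 2) else pp$fValues,
                        fNon = pp$fNon, digestion = pp$digestion,
                        gamma = if (is.null(pp$gamma)) 398 else pp$gamma,
                        repeats = if (is.null(pp$repeats)) 600 else pp$repeats,
                        seed = seed, outDir = outDir)
    }
    invisible(list(baseline = stage12, pcps = pcps))
}
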