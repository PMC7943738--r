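#' @include AllClasses.R enumerate.R zwitter.R
NULL

#' Generate a random proteome
#'
#' I.i.d. sequences over the 20 standard amino acids, reproducible from
#' the seed.  Defaults emulate a compact self proteome (200 proteins of
#' 300 residues); viral fixtures use smaller values.
#'
#' @param nProteins number of proteins.
#' @param lengths protein length(s); a scalar is recycled, a vector of
#'   length `nProteins` is used as-is.
#' @param aaFreq named amino-acid frequency vector over the 20 standard
#'   letters summing to 1 (tolerance 1e-9); default uniform.
#' @param seed integer seed.
#' @param name proteome label (also used as the id prefix).
#' @return a [Proteome-class]; gene ids are `<name>_G<i>`.
#' @export
generateProteome <- function(nProteins = 200, lengths = 300, aaFreq = NULL,
                             seed = 1, name = "synthetic") {
    if (is.null(aaFreq))
        aaFreq <- setNames(rep(1 / 20, 20), STANDARD_AA)
    if (!setequal(names(aaFreq), STANDARD_AA) ||
        abs(sum(aaFreq) - 1) > 1e-9 || any(aaFreq < 0))
        stop("'aaFreq' must be nonnegative frequencies over the 20 ",
             "standard letters summing to 1")
    lengths <- rep_len(as.integer(lengths), nProteins)
    set.seed(as.integer(seed))
    seqs <- vapply(lengths, function(L)
        paste(sample(STANDARD_AA, L, replace = TRUE,
                     prob = aaFreq[STANDARD_AA]), collapse = ""),
        character(1))
    names(seqs) <- sprintf("%s_P%03d", name, seq_len(nProteins))
    Proteome(seqs, name = name,
             geneIds = sprintf("%s_G%03d", name, seq_len(nProteins)))
}

# one random peptide for planting; drawn from the standard alphabet minus
# the side-specific flanking letters, so a flank residue can never extend
# a planted fragment into a sequence that is also pure peptide on the
# other side (see .writePlant)
.randomPeptide <- function(k) {
    alphabet <- setdiff(STANDARD_AA, c(.VIRAL_FLANKS, .HUMAN_FLANKS))
    paste(sample(alphabet, k, replace = TRUE), collapse = "")
}

# validate an explicit cis geometry against the enumeration config
.checkGeometry <- function(len1, gap, order, config) {
    k <- config@peptideLength
    gmin <- if (order == "normal") config@minGapNormal else config@minGapReverse
    if (len1 < config@minReactantLength ||
        k - len1 < config@minReactantLength ||
        gap > config@maxIntervening || gap < gmin)
        stop("geometry violates config (len1 = ", len1, ", gap = ", gap,
             ", order = ", order, ")")
    invisible(TRUE)
}

# write a peptide into one sequence of `seqs` as a contiguous stretch
# (category "nonspliced") or as two splice-reactants (category "cis"),
# avoiding previously used intervals. Returns list(seqs, used, truth-row).
#
# The residues immediately flanking every written fragment are overwritten
# with letters from `flankSet` (side-specific, disjoint between the human
# and viral sides of a fixture): a cis product that extends a planted
# fragment by a boundary residue then carries a side-specific letter at
# that product position, so the same extended sequence cannot arise on
# the other side through its own boundary residues.  Without this, two
# sides sharing a planted 9mer acquire identical extension products with
# probability ~1/20 per boundary, which defeats exact ground-truth
# verification.
.writePlant <- function(seqs, used, peptide, category, config,
                        geometry = NULL, margin = NULL, tries = 200L,
                        flankSet = NULL) {
    k <- nchar(peptide)
    if (is.null(margin)) margin <- k
    if (category == "cis") {
        if (is.null(geometry) || is.null(geometry$len1)) {
            splits <- setdiff(config@minReactantLength:
                              (k - config@minReactantLength),
                              if (is.null(geometry)) integer()
                              else geometry$avoidLen1)
            len1 <- splits[sample.int(length(splits), 1L)]
            order <- sample(c("normal", "reverse"), 1L)
            gmin <- if (order == "normal") config@minGapNormal else
                config@minGapReverse
            gap <- sample(gmin:min(config@maxIntervening, gmin + 12L), 1L)
        } else {
            len1 <- geometry$len1; gap <- geometry$gap; order <- geometry$order
        }
        .checkGeometry(len1, gap, order, config)
        span <- k + gap
    } else {
        span <- k
    }
    for (t in seq_len(tries)) {
        i <- sample(length(seqs), 1L)
        L <- nchar(seqs[[i]])
        if (L < span) next
        start <- sample(L - span + 1L, 1L)
        iv <- used[[i]]
        clash <- !is.null(iv) &&
            any(start <= iv$end + margin & start + span - 1L >= iv$start - margin)
        if (clash) next
        s <- seqs[[i]]
        L <- nchar(s)
        write_flanks <- function(s, ...) {
            if (is.null(flankSet)) return(s)
            for (pos in c(...)) {
                if (pos < 1L || pos > L) next
                substr(s, pos, pos) <-
                    flankSet[sample.int(length(flankSet), 1L)]
            }
            s
        }
        if (category == "nonspliced") {
            substr(s, start, start + k - 1L) <- peptide
            s <- write_flanks(s, start - 1L, start + k)
            scheme <- NA_character_
        } else {
            len2 <- k - len1
            frag1 <- substr(peptide, 1L, len1)
            frag2 <- substr(peptide, len1 + 1L, k)
            if (order == "normal") {
                s1 <- start; e1 <- s1 + len1 - 1L
                s2 <- e1 + gap + 1L; e2 <- s2 + len2 - 1L
            } else {
                s2 <- start; e2 <- s2 + len2 - 1L
                s1 <- e2 + gap + 1L; e1 <- s1 + len1 - 1L
            }
            substr(s, s1, e1) <- frag1
            substr(s, s2, e2) <- frag2
            fl <- c(s1 - 1L, e1 + 1L, s2 - 1L, e2 + 1L)
            fl <- fl[!(fl >= s1 & fl <= e1) & !(fl >= s2 & fl <= e2)]
            s <- do.call(write_flanks, c(list(s), as.list(unique(fl))))
            scheme <- formatSchemeNotation(names(seqs)[i], s1, e1, s2, e2)
        }
        seqs[[i]] <- s
        used[[i]] <- rbind(iv, data.frame(start = start,
                                          end = start + span - 1L))
        return(list(seqs = seqs, used = used,
                    protein = names(seqs)[i], start = start,
                    scheme = scheme,
                    len1 = if (category == "cis") len1 else NA_integer_))
    }
    stop("could not place a ", category, " plant after ", tries, " tries; ",
         "proteome too small for the requested plants")
}

# disjoint flanking alphabets for the two sides (see .writePlant)
.VIRAL_FLANKS <- c("G", "P")
.HUMAN_FLANKS <- c("K", "R")

# plant one batch of pairs into (human, viral) sequence vectors; no
# verification here. plants: data.frame(pair, len1?, gap?, order?)
.plantPairs <- function(humanSeqs, viralSeqs, usedH, usedV, plants, config) {
    truth <- NULL
    for (r in seq_len(nrow(plants))) {
        pair <- plants$pair[r]
        parts <- strsplit(pair, "_", fixed = TRUE)[[1L]]
        vcat <- if (parts[1L] == "cis") "cis" else "nonspliced"
        hcat <- if (parts[2L] == "cis") "cis" else "nonspliced"
        geometry <- NULL
        if (!is.null(plants$gap) && !is.na(plants$gap[r]))
            geometry <- list(len1 = plants$len1[r], gap = plants$gap[r],
                             order = plants$order[r])
        repeat {
            pep <- .randomPeptide(config@peptideLength)
            if (is.null(truth) || !pep %in% truth$peptide) break
        }
        pv <- .writePlant(viralSeqs, usedV, pep, vcat, config,
                          geometry = if (vcat == "cis") geometry else NULL,
                          flankSet = .VIRAL_FLANKS)
        viralSeqs <- pv$seqs; usedV <- pv$used
        # for cis x cis pairs, force a different split point on the human
        # side: the same split would plant the shared reverse/normal
        # recombination product of the two reactants on both sides
        hgeom <- if (hcat != "cis") NULL
                 else if (!is.null(geometry)) geometry
                 else if (vcat == "cis") list(avoidLen1 = pv$len1)
                 else NULL
        ph <- .writePlant(humanSeqs, usedH, pep, hcat, config,
                          geometry = hgeom, flankSet = .HUMAN_FLANKS)
        humanSeqs <- ph$seqs; usedH <- ph$used
        truth <- rbind(truth, data.frame(
            peptide = pep, pair = pair,
            viral_protein = pv$protein, viral_scheme = pv$scheme,
            human_protein = ph$protein, human_scheme = ph$scheme,
            stringsAsFactors = FALSE))
    }
    list(humanSeqs = humanSeqs, viralSeqs = viralSeqs,
         usedH = usedH, usedV = usedV, truth = truth)
}

# expand a (pair, count) spec table into one row per plant
.expandSpecs <- function(specs) {
    specs <- as.data.frame(specs)
    valid <- c("non_non", "cis_cis", "non_cis", "cis_non")
    if (!all(specs$pair %in% valid))
        stop("'pair' must be one of ", paste(valid, collapse = ", "))
    if (any(specs$count < 0)) stop("'count' must be >= 0")
    idx <- rep(seq_len(nrow(specs)), specs$count)
    out <- specs[idx, , drop = FALSE]
    rownames(out) <- NULL
    out
}

# category-pair counts observed by a full enumeration + intersection run
.observedPairCounts <- function(human, viral, config) {
    hN <- peptideUniverse(human, "nonspliced", config)
    hC <- peptideUniverse(human, "cis", config)
    vN <- peptideUniverse(viral, "nonspliced", config)
    vC <- peptideUniverse(viral, "cis", config)
    hits <- findZwitter(vN, vC, hN, hC)
    list(counts = hits$counts, table = hits$table)
}

#' Plant zwitter pairs of known category into two proteomes
#'
#' For each requested pair, a random 9mer is written into one viral and
#' one human protein: verbatim for a non-spliced side, as two
#' splice-reactants realizing a (given or randomized) gap/order geometry
#' for a cis side, so that enumeration reconstructs the peptide.  After
#' planting, a full enumeration + intersection run verifies that the
#' observed zwitter counts per category pair equal exactly the planted
#' counts and that the matched peptides are exactly the planted ones;
#' otherwise peptides and positions are re-drawn (bounded retries) before
#' failing loudly with a diagnostic of the unplanned matches.
#'
#' @param human,viral [Proteome-class] objects (the viral proteome is one
#'   virus).
#' @param specs data.frame with columns `pair` (one of `"non_non"`,
#'   `"cis_cis"`, `"non_cis"`, `"cis_non"`, viral category first) and
#'   `count`; optional columns `len1`, `gap`, `order` pin the cis
#'   geometry (validated against `config`).
#' @param config an [enumerationConfig()].  The default differs from the
#'   analysis default (`minReactantLength = 4`, `minGapReverse = 1`):
#'   with short reactants or adjacent reverse ligation allowed, a peptide
#'   planted on both sides *necessarily* induces additional shared cis
#'   products (any common short splice partner near a shared substring
#'   reconstructs the same sequence on both sides), so exact ground-truth
#'   recovery is identifiable only under these bounds; see the methods
#'   vignette.
#' @param seed integer seed.
#' @param maxRetries bounded number of re-draws (default 10).
#' @return list with `human`, `viral` (modified proteomes), `groundTruth`
#'   (data.frame: peptide, pair, host proteins, cis schemes) and
#'   `attempts`.
#' @export
plantZwitter <- function(human, viral, specs,
                         config = enumerationConfig(minReactantLength = 4,
                                                    minGapReverse = 1),
                         seed = 1, maxRetries = 10) {
    plants <- .expandSpecs(specs)
    for (attempt in seq_len(maxRetries)) {
        set.seed(as.integer(seed) + attempt - 1L)
        res <- .plantPairs(proteinSequences(human), proteinSequences(viral),
                           vector("list", length(human)),
                           vector("list", length(viral)), plants, config)
        humanMod <- Proteome(res$humanSeqs, name = proteomeName(human),
                             geneIds = human@geneIds)
        viralMod <- Proteome(res$viralSeqs, name = proteomeName(viral),
                             geneIds = viral@geneIds)
        obs <- .observedPairCounts(humanMod, viralMod, config)
        if (.truthMatches(obs, res$truth)) {
            return(list(human = humanMod, viral = viralMod,
                        groundTruth = res$truth, attempts = attempt))
        }
    }
    stop("plantZwitter: retries exhausted; unplanned matches persist ",
         "(observed ", paste(names(obs$counts), obs$counts,
                             sep = "=", collapse = ", "),
         " vs planted ", nrow(plants), " pairs). ",
         "Accidental peptides: ",
         paste(utils::head(setdiff(obs$table$peptide,
                            if (nrow(plants)) res$truth$peptide else character()),
                    5L), collapse = ", "))
}

# observed counts/table match the planted truth exactly, per category pair
.truthMatches <- function(obs, truth) {
    key <- c(non_non = "z_i", cis_cis = "z_j", non_cis = "z_k",
             cis_non = "z_l")
    pair_of <- function(vc, hc)
        paste(ifelse(vc == "cis", "cis", "non"),
              ifelse(hc == "cis", "cis", "non"), sep = "_")
    obs_pairs <- pair_of(obs$table$viral_category, obs$table$human_category)
    for (p in names(key)) {
        want <- if (is.null(truth)) character() else
            sort(truth$peptide[truth$pair == p])
        got <- sort(obs$table$peptide[obs_pairs == p])
        if (!identical(want, got)) return(FALSE)
    }
    TRUE
}

#' Generate a multi-virus fixture with planted zwitter pairs
#'
#' Builds a synthetic human proteome and `nViruses` viral proteomes,
#' distributes `kPerCategory` planted pairs of each category pair across
#' the viruses round-robin, and verifies the complete fixture end-to-end
#' (every virus against the final human proteome); the whole fixture is
#' regenerated on verification failure (bounded retries).
#'
#' @param kPerCategory planted pairs per category pair (scalar, or named
#'   vector over `non_non`, `cis_cis`, `non_cis`, `cis_non`).
#' @param nHumanProteins,humanLength,nViruses,proteinsPerVirus,viralLength
#'   fixture dimensions.
#' @param config an [enumerationConfig()]; the default is the
#'   ground-truth-identifiable geometry of [plantZwitter()].
#' @param seed integer seed.
#' @param maxRetries bounded regeneration attempts (default 10).
#' @return list with `human`, `viruses` (named list of proteomes),
#'   `groundTruth` (with a `virus` column), `config` and `attempts`.
#' @export
zwitterFixture <- function(kPerCategory = 3, nHumanProteins = 30,
                           humanLength = 100, nViruses = 3,
                           proteinsPerVirus = 2, viralLength = 80,
                           config = enumerationConfig(minReactantLength = 4,
                                                      minGapReverse = 1),
                           seed = 1, maxRetries = 10) {
    cats <- c("non_non", "cis_cis", "non_cis", "cis_non")
    k <- if (length(kPerCategory) == 1L)
        setNames(rep(kPerCategory, 4L), cats)
    else kPerCategory[cats]
    plants <- data.frame(pair = rep(cats, times = k),
                         stringsAsFactors = FALSE)
    for (attempt in seq_len(maxRetries)) {
        s <- as.integer(seed) + 1000L * (attempt - 1L)
        human <- generateProteome(nHumanProteins, humanLength,
                                  seed = s, name = "synthuman")
        viruses <- lapply(seq_len(nViruses), function(v)
            generateProteome(proteinsPerVirus, viralLength, seed = s + v,
                             name = sprintf("virus%02d", v)))
        names(viruses) <- vapply(viruses, proteomeName, character(1))
        humanSeqs <- proteinSequences(human)
        usedH <- vector("list", length(human))
        truth <- NULL
        set.seed(s + 500L)
        virus_of_plant <- if (nrow(plants))
            rep_len(seq_len(nViruses), nrow(plants)) else integer()
        ok <- TRUE
        for (v in seq_len(nViruses)) {
            sel <- plants[virus_of_plant == v, , drop = FALSE]
            if (!nrow(sel)) next
            res <- tryCatch(
                .plantPairs(humanSeqs, proteinSequences(viruses[[v]]),
                            usedH, vector("list", length(viruses[[v]])),
                            sel, config),
                error = function(e) NULL)
            if (is.null(res)) { ok <- FALSE; break }
            humanSeqs <- res$humanSeqs
            usedH <- res$usedH
            viruses[[v]] <- Proteome(res$viralSeqs,
                                     name = proteomeName(viruses[[v]]),
                                     geneIds = viruses[[v]]@geneIds)
            res$truth$virus <- proteomeName(viruses[[v]])
            truth <- rbind(truth, res$truth)
        }
        if (!ok) next
        human <- Proteome(humanSeqs, name = proteomeName(human),
                          geneIds = human@geneIds)
        # global end-to-end verification, virus by virus
        verified <- all(vapply(seq_len(nViruses), function(v) {
            obs <- .observedPairCounts(human, viruses[[v]], config)
            vt <- if (is.null(truth)) NULL else
                truth[truth$virus == proteomeName(viruses[[v]]), ,
                      drop = FALSE]
            .truthMatches(obs, if (!is.null(vt) && nrow(vt)) vt else NULL)
        }, logical(1)))
        if (verified)
            return(list(human = human, viruses = viruses,
                        groundTruth = truth, config = config,
                        attempts = attempt))
    }
    stop("zwitterFixture: retries exhausted; accidental cross-matches ",
         "persist at this fixture scale")
}

#' Generate a synthetic mTEC expression table
#'
#' Microarray mode: a long table of per-subset replicate log2 intensities
#' with configurable between-gene spread.  Single-cell mode: a gene x
#' cell UMI count matrix with multinomial cells of fixed library size.
#' Both are pure functions of their seed and parameters.
#'
#' @param genes character vector of gene ids.
#' @param platform `"microarray"` or `"scrna"`.
#' @param seed integer seed.
#' @param nSubsets,nReplicates microarray design (defaults 3 subsets x 2
#'   technical replicates).
#' @param meanLog2,sdLog2,noiseSd microarray signal: per-gene means drawn
#'   from N(meanLog2, sdLog2), replicate noise N(0, noiseSd).
#' @param nCells,librarySize single-cell design (defaults 50 cells of 1e4
#'   UMIs); per-gene propensities are Gamma-distributed.
#' @return microarray: data.frame (`gene`, `subset`, `value`); scrna:
#'   integer matrix genes x cells.
#' @export
generateExpression <- function(genes, platform = c("microarray", "scrna"),
                               seed = 1, nSubsets = 3, nReplicates = 2,
                               meanLog2 = 8, sdLog2 = 2, noiseSd = 0.25,
                               nCells = 50, librarySize = 1e4) {
    platform <- match.arg(platform)
    if (!length(genes)) stop("gene list is empty")
    set.seed(as.integer(seed))
    n <- length(genes)
    if (platform == "microarray") {
        gene_mean <- rnorm(n, meanLog2, sdLog2)
        out <- expand.grid(gene = genes, subset = paste0("mTEC_subset", seq_len(nSubsets)),
                           replicate = seq_len(nReplicates),
                           stringsAsFactors = FALSE)
        subset_shift <- rnorm(n * nSubsets, 0, 0.5)
        gi <- match(out$gene, genes)
        si <- match(out$subset, unique(out$subset))
        out$value <- gene_mean[gi] + subset_shift[(si - 1L) * n + gi] +
            rnorm(nrow(out), 0, noiseSd)
        out[, c("gene", "subset", "value")]
    } else {
        prop <- rgamma(n, shape = 0.8, rate = 1)
        prop <- prop / sum(prop)
        counts <- rmultinom(nCells, size = librarySize, prob = prop)
        dimnames(counts) <- list(genes, sprintf("cell%03d", seq_len(nCells)))
        counts
    }
}

#' Generate a synthetic in-vitro digestion dataset
#'
#' Random substrate polypeptides; each theoretical window of
#' `peptideLength` residues is included as an observed non-spliced product
#' independently with probability `targetFnon`, so [estimateFnon()]
#' recovers `targetFnon` up to binomial noise.  A few random cis-spliced
#' products per substrate are added (type `"spliced"`; ignored by
#' [estimateFnon()]).
#'
#' @param nSubstrates number of substrates (default 47).
#' @param substrateLength substrate length(s), recycled.
#' @param targetFnon inclusion probability per window, in \[0, 1\].
#' @param seed integer seed.
#' @param peptideLength product length (default 9).
#' @param splicedPerSubstrate spliced products per substrate (default 3).
#' @return a [digestionDataset()].
#' @export
generateDigestionDataset <- function(nSubstrates = 47, substrateLength = 100,
                                     targetFnon = 0.27, seed = 1,
                                     peptideLength = 9,
                                     splicedPerSubstrate = 3) {
    if (targetFnon < 0 || targetFnon > 1)
        stop("targetFnon must be in [0, 1]")
    set.seed(as.integer(seed))
    lens <- rep_len(as.integer(substrateLength), nSubstrates)
    ids <- sprintf("SUB%03d", seq_len(nSubstrates))
    seqs <- vapply(lens, function(L)
        paste(sample(STANDARD_AA, L, replace = TRUE), collapse = ""),
        character(1))
    prods <- list()
    cfg <- enumerationConfig(peptideLength = peptideLength)
    for (i in seq_len(nSubstrates)) {
        nw <- lens[i] - peptideLength + 1L
        keep <- which(runif(nw) < targetFnon)
        if (length(keep))
            prods[[length(prods) + 1L]] <- data.frame(
                substrate_id = ids[i],
                peptide = substring(seqs[i], keep, keep + peptideLength - 1L),
                type = "nonspliced", stringsAsFactors = FALSE)
        if (splicedPerSubstrate > 0) {
            sch <- enumerateCisSpliced(seqs[i], cfg)
            if (nrow(sch)) {
                j <- sample(nrow(sch), min(splicedPerSubstrate, nrow(sch)))
                prods[[length(prods) + 1L]] <- data.frame(
                    substrate_id = ids[i], peptide = sch$peptide[j],
                    type = "spliced", stringsAsFactors = FALSE)
            }
        }
    }
    products <- if (length(prods)) do.call(rbind, prods) else
        data.frame(substrate_id = character(), peptide = character(),
                   type = character())
    digestionDataset(data.frame(id = ids, sequence = seqs,
                                stringsAsFactors = FALSE), products)
}

#' Generate a calibrated toy binding matrix
#'
#' Random position scores with the intercept calibrated by the empirical
#' quantile of the summed scores over `nCalibration` random peptides, so
#' that the expected binder rate at `cutoff_nM` matches
#' `targetBinderRate` (within about 1%).
#'
#' @param peptideLength matrix length (default 9).
#' @param targetBinderRate desired fraction of random peptides with
#'   IC50 <= cutoff, in (0, 1).
#' @param cutoff_nM calibration cutoff (default 500).
#' @param seed integer seed.
#' @param sd per-position score spread on the log10 scale (default 0.3).
#' @param nCalibration random peptides used for calibration (default 1e5).
#' @return a [PositionScoringMatrix-class].
#' @export
generateBindingMatrix <- function(peptideLength = 9, targetBinderRate = 0.3,
                                  cutoff_nM = 500, seed = 1, sd = 0.3,
                                  nCalibration = 1e5) {
    if (targetBinderRate <= 0 || targetBinderRate >= 1)
        stop("targetBinderRate must be in (0, 1)")
    set.seed(as.integer(seed))
    scores <- matrix(rnorm(peptideLength * 20, 0, sd), peptideLength, 20,
                     dimnames = list(NULL, STANDARD_AA))
    # summed scores of random peptides, accumulated position by position
    s <- numeric(nCalibration)
    for (pos in seq_len(peptideLength))
        s <- s + scores[pos, sample.int(20, nCalibration, replace = TRUE)]
    intercept <- log10(cutoff_nM) - quantile(s, targetBinderRate,
                                             names = FALSE)
    positionScoringMatrix(scores, intercept, allele = "toy-HLA-A*02:01")
}

#' Binder-neutral scoring matrix
#'
#' All-zero scores with intercept `log10(ic50_nM)`: every peptide gets the
#' same predicted IC50, so binder filtering at any cutoff at or above
#' `ic50_nM` keeps everything (the cutoff comparison is inclusive).
#'
#' @param peptideLength matrix length (default 9).
#' @param ic50_nM the constant prediction (default 50, neutral at both
#'   the 500 nM and 50 nM cutoffs).
#' @return a [PositionScoringMatrix-class].
#' @export
neutralBindingMatrix <- function(peptideLength = 9, ic50_nM = 50) {
    positionScoringMatrix(
        matrix(0, peptideLength, 20, dimnames = list(NULL, STANDARD_AA)),
        intercept = log10(ic50_nM), allele = "neutral")
}
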