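#' @include AllClasses.R
NULL

#' In-vitro proteasome digestion dataset
#'
#' Substrate polypeptides and the non-spliced / spliced peptide products
#' identified in their digestions.  Every product must reference a listed
#' substrate, and every non-spliced product must occur as a substring of
#' its substrate (checked at construction, naming the first offender).
#'
#' @param substrates data.frame with columns `id`, `sequence`.
#' @param products data.frame with columns `substrate_id`, `peptide`,
#'   `type` (`"nonspliced"` or `"spliced"`).
#' @return a validated list of class `DigestionDataset`.
#' @export
digestionDataset <- function(substrates, products) {
    substrates <- as.data.frame(substrates)
    products <- as.data.frame(products)
    if (!all(c("id", "sequence") %in% names(substrates)))
        stop("'substrates' needs columns id, sequence")
    if (!all(c("substrate_id", "peptide", "type") %in% names(products)))
        stop("'products' needs columns substrate_id, peptide, type")
    if (anyDuplicated(substrates$id))
        stop("duplicate substrate id ",
             substrates$id[duplicated(substrates$id)][1L])
    substrates$sequence <- toupper(substrates$sequence)
    products$peptide <- toupper(products$peptide)
    bad <- !products$substrate_id %in% substrates$id
    if (any(bad))
        stop("product references unknown substrate ",
             products$substrate_id[bad][1L])
    if (!all(products$type %in% c("nonspliced", "spliced")))
        stop("product type must be 'nonspliced' or 'spliced'")
    ns <- products[products$type == "nonspliced", , drop = FALSE]
    if (nrow(ns)) {
        seqs <- setNames(substrates$sequence, substrates$id)
        inside <- mapply(function(p, s) grepl(p, s, fixed = TRUE),
                         ns$peptide, seqs[ns$substrate_id])
        if (!all(inside))
            stop("non-spliced product not a substring of its substrate: ",
                 ns$peptide[!inside][1L])
    }
    structure(list(substrates = substrates, products = products),
              class = "DigestionDataset")
}

#' Read/write digestion datasets
#'
#' Two TSV files: substrates (`id`, `sequence`) and products
#' (`substrate_id`, `peptide`, `type`).
#'
#' @param dataset a [digestionDataset()].
#' @param substratesPath,productsPath file paths.
#' @return `writeDigestionDataset()`: invisibly `NULL`;
#'   `readDigestionDataset()`: the dataset.
#' @export
writeDigestionDataset <- function(dataset, substratesPath, productsPath) {
    write.table(dataset$substrates, substratesPath, sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(dataset$products, productsPath, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(NULL)
}

#' @rdname writeDigestionDataset
#' @export
readDigestionDataset <- function(substratesPath, productsPath) {
    digestionDataset(
        read.delim(substratesPath, stringsAsFactors = FALSE,
                   colClasses = "character"),
        read.delim(productsPath, stringsAsFactors = FALSE,
                   colClasses = "character"))
}

#' Estimate the produced fraction of non-spliced peptides
#'
#' Per substrate: the number of unique observed non-spliced products of
#' the target length divided by the number of theoretically possible
#' windows (`L - length + 1`); the estimate is the median across
#' substrates.  In-vitro digestion databases put this around 0.27 for
#' 9mers.
#'
#' @param dataset a [digestionDataset()].
#' @param peptideLength product length considered (default 9).
#' @return the median fraction, a number in \[0, 1\].
#' @export
estimateFnon <- function(dataset, peptideLength = 9) {
    if (!inherits(dataset, "DigestionDataset"))
        stop("'dataset' must be a DigestionDataset")
    subs <- dataset$substrates
    subs <- subs[nchar(subs$sequence) >= peptideLength, , drop = FALSE]
    if (!nrow(subs)) stop("no substrate of length >= ", peptideLength)
    prod <- dataset$products
    prod <- prod[prod$type == "nonspliced" &
                 nchar(prod$peptide) == peptideLength, , drop = FALSE]
    fractions <- vapply(seq_len(nrow(subs)), function(i) {
        theo <- nchar(subs$sequence[i]) - peptideLength + 1L
        obs <- unique(prod$peptide[prod$substrate_id == subs$id[i]])
        length(obs) / theo
    }, numeric(1))
    stats::median(fractions)
}

#' Presented-fraction arithmetic for cis-spliced peptides
#'
#' With `f` the percentage of cis-spliced peptides among peptides detected
#' in HLA-I immunopeptidomes, `f_non` the produced fraction of non-spliced
#' peptides and `gamma` the ratio of theoretical cis-spliced to
#' non-spliced peptides (398 for proteins of >= 500 residues):
#' `fCisFrom()` returns `f * f_non / (gamma * (100 - f))`, the fraction of
#' theoretical cis-spliced peptides that is presented, and `nCisFrom()`
#' returns `f * N_non * f_non / (100 - f)`, the presented cis-spliced
#' count given `N_non` theoretical non-spliced peptides.
#'
#' @param f cis-spliced percentage of the immunopeptidome, `0 <= f < 100`
#'   (vectorized).
#' @param fNon produced fraction of non-spliced peptides.
#' @param gamma theoretical cis/non-spliced ratio (default 398).
#' @param Nnon number of theoretical non-spliced peptides.
#' @return numeric vector.
#' @examples
#' fCisFrom(15, 0.27, 398)  # 1.197e-4
#' @export
fCisFrom <- function(f, fNon, gamma = 398) {
    if (any(f < 0 | f >= 100)) stop("f must satisfy 0 <= f < 100")
    if (gamma <= 0) stop("gamma must be > 0")
    f * fNon / (gamma * (100 - f))
}

#' @rdname fCisFrom
#' @export
nCisFrom <- function(f, Nnon, fNon) {
    if (any(f < 0 | f >= 100)) stop("f must satisfy 0 <= f < 100")
    f * Nnon * fNon / (100 - f)
}

#' Uniform subsample of a peptide universe
#'
#' Draws `round(fraction * n)` unique peptides without replacement
#' (round-half-even, R's default rounding), reproducibly from the seed.
#'
#' @param universe a [PeptideUniverse-class].
#' @param fraction sampling fraction in \[0, 1\].
#' @param seed integer seed.
#' @return the subsampled [PeptideUniverse-class].
#' @export
subsampleUniverse <- function(universe, fraction, seed) {
    if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
    n <- round(fraction * length(universe))
    if (n == length(universe)) return(universe)
    set.seed(as.integer(seed))
    .replacePeptides(universe, sample(peptides(universe), n))
}

# seed ladder: master seed -> per-f stream -> per-repeat substream, so
# extending the f grid never perturbs existing repeats; kept below 2^31.
.ladderSeed <- function(master, f, repeat_i, stage = 0L) {
    (as.double(master) * 7L + round(f * 1000) * 1009 +
     repeat_i * 7919 + stage * 104729) %% 2147483647
}

#' Sweep the zwitter analysis over cis-spliced presentation frequencies
#'
#' For each assumed immunopeptidome cis-spliced percentage `f` and each
#' repeat: subsample the human and every viral non-spliced universe at
#' rate `fNon` and all cis universes at `fCisFrom(f, fNon, gamma)`
#' (independently, without replacement), rerun the zwitter intersection on
#' the samples and, when a predictor is supplied, count the
#' binder-restricted candidates as well.  A zwitter pair survives only if
#' its sequence survives the sampling on both sides.
#'
#' @param viralUniverses named list (one entry per virus) of lists with
#'   elements `non` and `cis` ([PeptideUniverse-class] objects).
#' @param humanNon,humanCis human universes.
#' @param fValues numeric vector of immunopeptidome cis percentages
#'   (default `seq(1, 35, by = 2)`).
#' @param fNon produced fraction of non-spliced peptides (e.g. from
#'   [estimateFnon()]).
#' @param gamma theoretical cis/non ratio (default 398).
#' @param repeats subsampling repeats per f (default 600).
#' @param predictor optional, anything [asPredictor()] accepts.
#' @param cutoff_nM binder cutoff (default 500).
#' @param seed master seed for the whole sweep.
#' @return list with `draws` (long data.frame: `f`, `repeat_i`, `virus`,
#'   surviving counts `nonspliced`, `cis`, `combined` and, with a
#'   predictor, `nonspliced_b`, `cis_b`, `combined_b`) and `summary` (per
#'   f: per-virus mean counts and the mean number of viruses with at
#'   least one surviving zwitter per iteration).
#' @export
pcpsSweep <- function(viralUniverses, humanNon, humanCis,
                      fValues = seq(1, 35, by = 2), fNon, gamma = 398,
                      repeats = 600, predictor = NULL, cutoff_nM = 500,
                      seed = 1) {
    if (!length(viralUniverses)) stop("no viruses")
    viruses <- names(viralUniverses)
    fn <- if (!is.null(predictor)) asPredictor(predictor) else NULL
    # binder status resolved once on the full universes (binding is a
    # property of the sequence; applied after sampling)
    binder_set <- NULL
    if (!is.null(fn)) {
        all_pep <- unique(c(peptides(humanNon), peptides(humanCis),
                            unlist(lapply(viralUniverses, function(u)
                                c(peptides(u$non), peptides(u$cis))))))
        ic50 <- fn(all_pep)
        binder_set <- all_pep[ic50 <= cutoff_nM]
    }
    count_hits <- function(vN, vC, hN, hC) {
        non <- intersect(vN, hN)
        cis <- unique(c(intersect(vC, hC), intersect(vN, hC),
                        intersect(vC, hN)))
        comb <- intersect(union(vN, vC), union(hN, hC))
        c(nonspliced = length(non), cis = length(cis),
          combined = length(comb))
    }
    rows <- vector("list", length(fValues) * repeats)
    ri <- 0L
    for (f in fValues) {
        fCis <- min(1, fCisFrom(f, fNon, gamma))
        for (m in seq_len(repeats)) {
            hN <- peptides(subsampleUniverse(humanNon, fNon,
                                             .ladderSeed(seed, f, m, 1L)))
            hC <- peptides(subsampleUniverse(humanCis, fCis,
                                             .ladderSeed(seed, f, m, 2L)))
            per_virus <- lapply(seq_along(viruses), function(vi) {
                u <- viralUniverses[[vi]]
                vN <- peptides(subsampleUniverse(u$non, fNon,
                        .ladderSeed(seed, f, m, 10L + 2L * vi)))
                vC <- peptides(subsampleUniverse(u$cis, fCis,
                        .ladderSeed(seed, f, m, 11L + 2L * vi)))
                base <- count_hits(vN, vC, hN, hC)
                if (!is.null(binder_set)) {
                    b <- count_hits(intersect(vN, binder_set),
                                    intersect(vC, binder_set),
                                    intersect(hN, binder_set),
                                    intersect(hC, binder_set))
                    names(b) <- paste0(names(b), "_b")
                    base <- c(base, b)
                }
                base
            })
            ri <- ri + 1L
            rows[[ri]] <- data.frame(f = f, repeat_i = m, virus = viruses,
                                     do.call(rbind, per_virus),
                                     stringsAsFactors = FALSE)
        }
    }
    draws <- do.call(rbind, rows)
    rownames(draws) <- NULL
    count_cols <- setdiff(names(draws), c("f", "repeat_i", "virus"))
    per_f <- lapply(split(draws, draws$f), function(d) {
        means <- colMeans(d[count_cols])
        atleast1 <- vapply(count_cols, function(cc) {
            # per repeat: number of viruses with >= 1 surviving zwitter
            mean(tapply(d[[cc]] >= 1, d$repeat_i, sum))
        }, numeric(1))
        data.frame(f = d$f[1L], statistic = c(rep("mean_count", length(means)),
                                              rep("viruses_ge1", length(atleast1))),
                   category = c(names(means), names(atleast1)),
                   value = c(unname(means), unname(atleast1)),
                   stringsAsFactors = FALSE)
    })
    summary <- do.call(rbind, per_f)
    rownames(summary) <- NULL
    list(draws = draws, summary = summary)
}
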