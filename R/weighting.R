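#' @include AllClasses.R
NULL

#' Summarize microarray mTEC expression per gene
#'
#' For each gene: the mean log2 intensity over the technical replicates of
#' each cell subset, then the maximum of those subset means.  Genes
#' without a single finite value are excluded (their number is reported
#' via a message).
#'
#' @param table long-format data.frame with columns `gene`, `subset`,
#'   `value` (one row per replicate measurement, log2 intensities).
#' @return named numeric vector of per-gene expression values `E_i`.
#' @examples
#' tab <- data.frame(gene = "g1", subset = c("A", "A", "B"),
#'                   value = c(2, 4, 5))
#' microarrayExpression(tab)  # max(mean(2,4), 5) = 5
#' @export
microarrayExpression <- function(table) {
    table <- as.data.frame(table)
    if (!all(c("gene", "subset", "value") %in% names(table)))
        stop("'table' needs columns gene, subset, value")
    ok <- is.finite(table$value)
    dropped <- setdiff(unique(table$gene), unique(table$gene[ok]))
    if (length(dropped))
        message(length(dropped), " gene(s) without finite values excluded")
    table <- table[ok, , drop = FALSE]
    if (!nrow(table)) stop("no finite expression values")
    subset_means <- tapply(table$value,
                           list(table$gene, table$subset), mean)
    E <- apply(subset_means, 1L, max, na.rm = TRUE)
    E[sort(names(E))]
}

#' Log-normalize single-cell UMI counts
#'
#' Per cell j and gene i: `x_ij = log(scaleFactor * UMI_ij / total_j + 1)`
#' (natural log by default; the per-cell total is the library size).  The
#' per-gene expression value is the mean of `x_ij` over cells.
#'
#' @param counts nonnegative integer matrix, genes x cells, with row and
#'   column names.
#' @param scaleFactor library-size scale (default 1e5).
#' @param base logarithm base (default `exp(1)`).
#' @return list with `x` (the normalized gene x cell matrix) and `E`
#'   (named per-gene means).
#' @examples
#' m <- matrix(c(10, 990), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
#' scrnaLognormalize(m)$x["g1", "c1"]  # log(1001) ~ 6.9088
#' @export
scrnaLognormalize <- function(counts, scaleFactor = 1e5, base = exp(1)) {
    counts <- as.matrix(counts)
    if (any(counts < 0) || any(counts != round(counts)))
        stop("UMI counts must be nonnegative integers")
    totals <- colSums(counts)
    if (any(totals == 0)) {
        bad <- colnames(counts)[totals == 0][1L]
        stop("cell with zero total UMI count: ",
             if (is.null(bad) || is.na(bad)) which(totals == 0)[1L] else bad)
    }
    x <- log(sweep(counts, 2L, totals, "/") * scaleFactor + 1, base = base)
    list(x = x, E = rowMeans(x))
}

#' Presentation weights from gene expression
#'
#' Min-max scales the per-gene expression values and normalizes to sum 1:
#' `w_i = (E_i - min E) / (max E - min E)`, divided by the sum over genes.
#' Genes at the minimum get weight 0.  A constant expression vector is
#' degenerate; uniform weights `1/n` are returned with a warning.
#'
#' @param E named numeric vector of per-gene expression values (>= 2
#'   genes).
#' @return named numeric weight vector summing to 1.
#' @examples
#' computeWeights(c(a = 1, b = 2, c = 3))  # 0, 1/3, 2/3
#' @export
computeWeights <- function(E) {
    if (length(E) < 2L) stop("need >= 2 genes")
    if (any(!is.finite(E))) stop("non-finite expression values")
    rng <- max(E) - min(E)
    if (rng == 0) {
        warning("constant expression: falling back to uniform weights")
        return(setNames(rep(1 / length(E), length(E)), names(E)))
    }
    s <- (E - min(E)) / rng
    s / sum(s)
}

#' Aggregate gene weights into peptide weights
#'
#' A zwitter peptide's presentation weight is the sum of the weights of
#' every human source gene that can generate it (presentation chances add
#' over independent sources).  Genes absent from the weight vector
#' contribute 0; their count is reported via a message.
#'
#' @param sourceMap data.frame with columns `peptide` and `gene` (one row
#'   per peptide-source pair; duplicates are collapsed).
#' @param weights named gene weight vector (see [computeWeights()]).
#' @return named numeric vector, peptide -> weight.
#' @export
peptideWeights <- function(sourceMap, weights) {
    sourceMap <- unique(as.data.frame(sourceMap)[, c("peptide", "gene")])
    w <- weights[match(sourceMap$gene, names(weights))]
    missing <- is.na(w)
    if (any(missing))
        message(length(unique(sourceMap$gene[missing])),
                " source gene(s) absent from the expression table (weight 0)")
    w[missing] <- 0
    out <- tapply(w, sourceMap$peptide, sum)
    setNames(as.numeric(out), names(out))
}

#' Weighted sampling of the zwitter pool
#'
#' Emulates presentation odds in mTECs: per repeat, `round(sizeFraction *
#' n_pool)` draws with replacement from the zwitter peptide pool with
#' probability proportional to peptide weight; a peptide counts as sampled
#' in a repeat when drawn at least once.  `z_mv` is the number of distinct
#' virus-v zwitter peptides sampled in repeat m, and
#' `M_v = 100 * mean_m(z_mv) / p_v`.
#'
#' @param zwitterTable data.frame with columns `peptide` and `virus` (a
#'   peptide may belong to several viruses).
#' @param weights named numeric vector covering every pool peptide (see
#'   [peptideWeights()]); must not be all zero.
#' @param config a [samplingConfig()]; sampling is fully reproducible
#'   from its seed.
#' @param denominators named per-virus denominator vector `p_v` (or `b_v`
#'   for the binder-restricted pool).
#' @return list with `perRepeat` (repeats x viruses integer matrix of
#'   `z_mv`), `M` (named `M_v` percentages, `NA` where the denominator is
#'   0) and `drawsPerRepeat`.
#' @export
weightedZwitterSampling <- function(zwitterTable, weights, config,
                                    denominators) {
    zwitterTable <- unique(as.data.frame(zwitterTable)[, c("peptide", "virus")])
    viruses <- names(denominators)
    pool <- sort(unique(zwitterTable$peptide))
    reps <- config@repeats
    if (!length(pool)) {
        per <- matrix(0L, reps, length(viruses),
                      dimnames = list(NULL, viruses))
        return(list(perRepeat = per,
                    M = setNames(ifelse(denominators > 0, 0, NA_real_),
                                 viruses),
                    drawsPerRepeat = 0L))
    }
    w <- weights[match(pool, names(weights))]
    if (anyNA(w)) stop("missing weight for peptide ", pool[is.na(w)][1L])
    if (all(w == 0)) stop("all peptide weights are zero")
    n <- round(config@sizeFraction * length(pool))
    per <- matrix(0L, reps, length(viruses), dimnames = list(NULL, viruses))
    by_virus <- split(zwitterTable$peptide, zwitterTable$virus)
    set.seed(config@seed)
    for (m in seq_len(reps)) {
        drawn <- if (n > 0)
            unique(sample(pool, n, replace = config@replacement, prob = w))
        else character()
        for (v in viruses) {
            pv <- by_virus[[v]]
            per[m, v] <- if (is.null(pv)) 0L else sum(pv %in% drawn)
        }
    }
    M <- 100 * colMeans(per) / denominators
    M[denominators == 0] <- NA_real_
    list(perRepeat = per, M = M, drawsPerRepeat = n)
}
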