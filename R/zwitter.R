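#' @include AllClasses.R
NULL

#' Intersect viral and human peptide universes
#'
#' A zwitter peptide is a sequence present in at least one viral and one
#' human universe.  Matching is exact string equality on uppercase
#' sequences (no I/L equivalence).  The four category pairs are counted
#' separately: `z_i` viral-non x human-non, `z_j` viral-cis x human-cis,
#' `z_k` viral-non x human-cis, `z_l` viral-cis x human-non; `z_all` is
#' the size of the unique union, counting each peptide once even when it
#' satisfies several pairs.
#'
#' @param viralNon,viralCis,humanNon,humanCis [PeptideUniverse-class]
#'   objects of a common peptide length.
#' @return list with `table` (data.frame `peptide`, `viral_category`,
#'   `human_category`; one row per category pair a peptide satisfies) and
#'   `counts` (named numeric `z_i`, `z_j`, `z_k`, `z_l`, `z_all`).
#' @examples
#' vn <- uniquePeptides("QLAEVVQKV", "virus", "nonspliced")
#' hn <- uniquePeptides("QLAEVVQKV", "human", "nonspliced")
#' empty <- uniquePeptides(character(), "x", "cis", peptideLength = 9)
#' findZwitter(vn, empty, hn, empty)$counts
#' @export
findZwitter <- function(viralNon, viralCis, humanNon, humanCis) {
    us <- list(viralNon, viralCis, humanNon, humanCis)
    len <- unique(vapply(us, function(u) u@peptideLength, integer(1)))
    if (length(len) != 1L)
        stop("peptide length mismatch across universes")
    pair <- function(v, h, vc, hc) {
        p <- intersect(peptides(v), peptides(h))
        if (!length(p))
            return(data.frame(peptide = character(),
                              viral_category = character(),
                              human_category = character()))
        data.frame(peptide = p, viral_category = vc, human_category = hc,
                   stringsAsFactors = FALSE)
    }
    tab <- rbind(pair(viralNon, humanNon, "nonspliced", "nonspliced"),
                 pair(viralCis, humanCis, "cis", "cis"),
                 pair(viralNon, humanCis, "nonspliced", "cis"),
                 pair(viralCis, humanNon, "cis", "nonspliced"))
    tab <- tab[order(tab$peptide, tab$viral_category, tab$human_category), ,
               drop = FALSE]
    rownames(tab) <- NULL
    z_all <- length(intersect(union(peptides(viralNon), peptides(viralCis)),
                              union(peptides(humanNon), peptides(humanCis))))
    counts <- c(
        z_i = sum(tab$viral_category == "nonspliced" &
                  tab$human_category == "nonspliced"),
        z_j = sum(tab$viral_category == "cis" & tab$human_category == "cis"),
        z_k = sum(tab$viral_category == "nonspliced" &
                  tab$human_category == "cis"),
        z_l = sum(tab$viral_category == "cis" &
                  tab$human_category == "nonspliced"),
        z_all = z_all)
    list(table = tab, counts = counts)
}

#' Relative zwitter frequency
#'
#' `F_v = 100 * z_v / p_v`: the percentage of a virus's unique peptides
#' that are zwitter peptides.
#'
#' @param z zwitter count(s).
#' @param p denominator: size of the cognate viral peptide universe.
#' @return percentage(s) in \[0, 100\].
#' @export
zwitterFrequency <- function(z, p) {
    if (any(p == 0)) stop("empty peptide universe")
    100 * z / p
}

#' Per-virus zwitter report
#'
#' Computes all zwitter counts, denominators and relative frequencies for
#' one virus against the human universes: `F_v_non` (non-spliced pairs
#' over the viral non-spliced universe), `F_v_cis` (unique peptides of the
#' three cis-involving pairs over the viral cis universe) and `F_v_all`
#' (unique union over the union universe).
#'
#' @param virus virus label.
#' @inheritParams findZwitter
#' @return one-row data.frame with counts (`z_i`, `z_j`, `z_k`, `z_l`,
#'   `z_cis`, `z_all`), denominators (`p_v_non`, `p_v_cis`, `p_v_all`) and
#'   frequencies (`F_v_non`, `F_v_cis`, `F_v_all`, `NA` when the cognate
#'   universe is empty), plus the hit table as attribute `"table"`.
#' @export
zwitterReport <- function(virus, viralNon, viralCis, humanNon, humanCis) {
    hits <- findZwitter(viralNon, viralCis, humanNon, humanCis)
    tab <- hits$table
    cis_rows <- tab$viral_category == "cis" | tab$human_category == "cis"
    z_cis <- length(unique(tab$peptide[cis_rows]))
    p_non <- length(viralNon)
    p_cis <- length(viralCis)
    p_all <- length(union(peptides(viralNon), peptides(viralCis)))
    freq_or_na <- function(z, p) if (p > 0) zwitterFrequency(z, p) else NA_real_
    out <- data.frame(
        virus = virus,
        z_i = hits$counts[["z_i"]], z_j = hits$counts[["z_j"]],
        z_k = hits$counts[["z_k"]], z_l = hits$counts[["z_l"]],
        z_cis = z_cis, z_all = hits$counts[["z_all"]],
        p_v_non = p_non, p_v_cis = p_cis, p_v_all = p_all,
        F_v_non = freq_or_na(hits$counts[["z_i"]], p_non),
        F_v_cis = freq_or_na(z_cis, p_cis),
        F_v_all = freq_or_na(hits$counts[["z_all"]], p_all),
        stringsAsFactors = FALSE)
    attr(out, "table") <- tab
    out
}

#' Kolmogorov-Smirnov comparison of per-virus frequency distributions
#'
#' Two-sided two-sample KS test; a difference is flagged significant at
#' p < 0.05.
#'
#' @param x,y numeric samples (each of size >= 1).
#' @return list with `D`, `p_value`, `significant`.
#' @examples
#' ksCompare(c(1, 2), c(1, 3))$D  # 0.5
#' @export
ksCompare <- function(x, y) {
    if (!length(x) || !length(y)) stop("empty sample")
    kt <- suppressWarnings(stats::ks.test(x, y, alternative = "two.sided"))
    list(D = unname(kt$statistic), p_value = kt$p.value,
         significant = kt$p.value < 0.05)
}

#' Zwitter/binder enrichment on a 2x2 contingency table
#'
#' Odds ratio `(a*d)/(b*c)` on the table
#' `rbind(c(a, b), c(c, d))` (rows: zwitter / non-zwitter; columns:
#' binder / non-binder), with a two-sided Fisher exact test when the total
#' count is at most `fisherMax`, else a chi-square test with continuity
#' correction.  A zero margin (or a zero in the odds-ratio denominator)
#' yields a missing odds ratio with an explicit reason, never a silent
#' infinity.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @param fisherMax total-count switchover from Fisher to chi-square
#'   (default 10000).
#' @return list with `odds_ratio` (sample OR, `NA` when undefined),
#'   `reason` (`NA` or why the OR is missing), `p_value`, `test`.
#' @examples
#' binderEnrichment(rbind(c(10, 90), c(5, 95)))$odds_ratio  # 2.111...
#' @export
binderEnrichment <- function(tab, fisherMax = 10000) {
    tab <- as.matrix(tab)
    if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) ||
        any(tab != round(tab)))
        stop("'tab' must be a 2x2 matrix of nonnegative integers")
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    or <- NA_real_; reason <- NA_character_
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        reason <- "zero margin"
    } else if (b * c == 0) {
        reason <- "zero cell in denominator"
    } else {
        or <- (a * d) / (b * c)
    }
    n <- sum(tab)
    if (n <= fisherMax) {
        p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
        test <- "fisher"
    } else {
        p <- suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value)
        test <- "chisq"
    }
    list(odds_ratio = or, reason = reason, p_value = p, test = test)
}

#' Correlation between proteome size and zwitter count
#'
#' Pearson product-moment correlation of per-virus proteome residue counts
#' against per-virus zwitter counts.
#'
#' @param residues numeric vector of per-virus proteome sizes.
#' @param counts numeric vector of per-virus zwitter counts.
#' @return list with `r` and `p_value`.
#' @export
lengthCorrelation <- function(residues, counts) {
    if (length(residues) != length(counts) || length(residues) < 3L)
        stop("need >= 3 paired (residues, count) observations")
    if (stats::sd(residues) == 0 || stats::sd(counts) == 0)
        stop("zero variance in residues or counts")
    ct <- stats::cor.test(residues, counts, method = "pearson")
    list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Distribution summary across viruses
#'
#' Median, 25-75 and 5-95 percentiles (linear interpolation) and mean, the
#' summary layout used for per-virus frequency distributions.  `NA` values
#' (viruses with an empty cognate universe) are dropped.
#'
#' @param values numeric vector of per-virus values.
#' @param excludeZero also drop exact zeros (the "viruses with at least one
#'   zwitter peptide" display mode); default FALSE.
#' @return named numeric: `median`, `q25`, `q75`, `q5`, `q95`, `mean`, `n`.
#' @export
summarizeFrequencies <- function(values, excludeZero = FALSE) {
    v <- values[!is.na(values)]
    if (excludeZero) v <- v[v != 0]
    if (!length(v))
        return(c(median = NA_real_, q25 = NA_real_, q75 = NA_real_,
                 q5 = NA_real_, q95 = NA_real_, mean = NA_real_, n = 0))
    q <- stats::quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    c(median = q[3], q25 = q[2], q75 = q[4], q5 = q[1], q95 = q[5],
      mean = mean(v), n = length(v))
}
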