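# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the cis enumerator below is a plain filter over
# every coordinate quadruple, the Fisher oracle is a direct hypergeometric
# enumeration, and the scoring oracle re-sums matrix entries one letter at
# a time.

STD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(L, letters = STD_AA) {
    paste(sample(letters, L, replace = TRUE), collapse = "")
}

# brute-force cis-splicing enumeration: every (s1, e1, s2, e2) quadruple,
# filtered by the stated convention.  Returns a character vector of
# canonical scheme keys "s1:e1:s2:e2:order:peptide".
brute_cis_keys <- function(seq, config) {
    L <- nchar(seq)
    k <- config@peptideLength
    if (L < 2L) return(character())
    idx <- seq_len(L)
    g <- expand.grid(s1 = idx, e1 = idx, s2 = idx, e2 = idx,
                     KEEP.OUT.ATTRS = FALSE)
    len1 <- g$e1 - g$s1 + 1L
    len2 <- g$e2 - g$s2 + 1L
    keep <- len1 >= config@minReactantLength &
        len2 >= config@minReactantLength & (len1 + len2) == k
    g <- g[keep, , drop = FALSE]
    gap_n <- g$s2 - g$e1 - 1L          # frag1 before frag2 in substrate
    gap_r <- g$s1 - g$e2 - 1L          # frag2 before frag1 in substrate
    ok_n <- gap_n >= config@minGapNormal & gap_n <= config@maxIntervening
    ok_r <- gap_r >= config@minGapReverse & gap_r <= config@maxIntervening
    g <- g[ok_n | ok_r, , drop = FALSE]
    ord <- ifelse((g$s2 - g$e1 - 1L) >= config@minGapNormal &
                  (g$s2 - g$e1 - 1L) <= config@maxIntervening,
                  "normal", "reverse")
    pep <- paste0(substring(seq, g$s1, g$e1), substring(seq, g$s2, g$e2))
    if (config@excludeNonstandard) {
        good <- !grepl(sprintf("[^%s]", paste(STD_AA, collapse = "")), pep)
        g <- g[good, , drop = FALSE]
        ord <- ord[good]
        pep <- pep[good]
    }
    paste(g$s1, g$e1, g$s2, g$e2, ord, pep, sep = ":")
}

# canonical keys for the package enumerator's output
scheme_keys <- function(df) {
    paste(df$s1, df$e1, df$s2, df$e2, df$order, df$peptide, sep = ":")
}

# two-sided Fisher exact p by exhaustive hypergeometric enumeration over
# all tables with the observed margins (sum of probabilities not exceeding
# the observed table's, with the conventional relative tolerance)
fisher_oracle_p <- function(a, b, c_, d) {
    m <- a + b
    n <- c_ + d
    kcol <- a + c_
    x <- max(0L, kcol - n):min(kcol, m)
    pr <- dhyper(x, m, n, kcol)
    p_obs <- dhyper(a, m, n, kcol)
    sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# mean and variance of the number of distinct items after `draws` uniform
# draws with replacement from n items (closed form)
distinct_draw_moments <- function(n, draws) {
    p1 <- (1 - 1 / n)^draws
    p2 <- (1 - 2 / n)^draws
    mu <- n * (1 - p1)
    v <- n * p1 + n * (n - 1) * p2 - n^2 * p1^2
    list(mean = mu, var = v)
}

# independent IC50 re-summation: per peptide, walk the letters and add the
# matrix entries, then exponentiate
resum_ic50 <- function(peptides, scores, intercept) {
    vapply(peptides, function(p) {
        letters <- strsplit(p, "")[[1]]
        s <- intercept
        for (i in seq_along(letters)) s <- s + scores[i, letters[i]]
        10^s
    }, numeric(1))
}

# small helper: a PeptideUniverse from raw peptides with less typing
pu <- function(peps, source = "x", category = "nonspliced", len = 9L) {
    uniquePeptides(peps, source, category, peptideLength = len)
}
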