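#' @include AllClasses.R
NULL

# resolve a protein argument (Proteome record, named character, AAString)
# to a single uppercase string
.one_sequence <- function(protein) {
    if (is(protein, "Proteome")) {
        if (length(protein) != 1L)
            stop("expected a single protein; got a proteome of ",
                 length(protein))
        return(proteinSequences(protein)[[1L]])
    }
    toupper(as.character(protein)[1L])
}

#' Enumerate non-spliced peptides of a protein
#'
#' Yields every contiguous window of `peptideLength` residues, left to
#' right.  Windows containing non-standard residues are omitted when
#' `excludeNonstandard` is set in the config.
#'
#' @param protein a sequence string (or single-record [Proteome-class]).
#' @param config an [enumerationConfig()].
#' @return data.frame with columns `peptide` and `start` (1-based);
#'   zero rows when the protein is shorter than the peptide length.
#' @examples
#' enumerateNonspliced("ACDEFGHIKL")
#' @export
enumerateNonspliced <- function(protein, config = enumerationConfig()) {
    seq <- .one_sequence(protein)
    k <- config@peptideLength
    L <- nchar(seq)
    if (L < k)
        return(data.frame(peptide = character(), start = integer()))
    starts <- seq_len(L - k + 1L)
    pep <- substring(seq, starts, starts + k - 1L)
    if (config@excludeNonstandard) {
        keep <- !grepl(sprintf("[^%s]", paste(STANDARD_AA, collapse = "")), pep)
        starts <- starts[keep]
        pep <- pep[keep]
    }
    data.frame(peptide = pep, start = starts, stringsAsFactors = FALSE)
}

#' Enumerate cis-splicing schemes of a protein
#'
#' Every way of ligating two disjoint fragments of the same substrate into
#' a peptide of `peptideLength` residues, in normal order (fragment 1
#' N-terminal in both substrate and product) or reverse order (fragment
#' order in the substrate inverted), with the intervening sequence length
#' bounded by the config.  Coordinates are 1-based inclusive; `s1`/`e1`
#' always delimit the N-terminal fragment of the product.
#'
#' @inheritParams enumerateNonspliced
#' @return data.frame with columns `s1`, `e1`, `s2`, `e2`, `order`,
#'   `intervening`, `peptide`, in a deterministic order.
#' @examples
#' nrow(enumerateCisSpliced("ACDEFGHIKL"))  # 32 schemes
#' @export
enumerateCisSpliced <- function(protein, config = enumerationConfig()) {
    seq <- .one_sequence(protein)
    .cpp_enumerate_cis(seq, config@peptideLength, config@maxIntervening,
                       config@minGapNormal, config@minGapReverse,
                       config@minReactantLength, config@excludeNonstandard)
}

#' Closed-form peptide and scheme counts
#'
#' `countNonspliced()` returns the number of contiguous windows,
#' `max(L - peptideLength + 1, 0)`.  `countCisSchemes()` returns the exact
#' number of cis-splicing schemes [enumerateCisSpliced()] yields for an
#' all-standard protein of length `L`, computed by summation over fragment
#' split and intervening length rather than enumeration.  Neither corrects
#' for non-standard residues.
#'
#' @param L protein length(s) in residues (vectorized).
#' @param config an [enumerationConfig()].
#' @return integer-valued numeric vector of counts.
#' @examples
#' countCisSchemes(500)                    # 195536
#' countCisSchemes(500) / countNonspliced(500)  # ~397.4
#' @export
countNonspliced <- function(L, config = enumerationConfig()) {
    pmax(L - config@peptideLength + 1, 0)
}

#' @rdname countNonspliced
#' @export
countCisSchemes <- function(L, config = enumerationConfig()) {
    k <- config@peptideLength
    nsplit <- max(k - 2L * config@minReactantLength + 1L, 0L)
    one_order <- function(L1, gmin) {
        # placements for gap g: L - k + 1 - g (when positive)
        gmax <- min(config@maxIntervening, L1 - k)
        if (gmax < gmin) return(0)
        g <- gmin:gmax
        sum(pmax(L1 - k + 1 - g, 0))
    }
    vapply(L, function(L1) {
        if (L1 < k) return(0)
        nsplit * (one_order(L1, config@minGapNormal) +
                  one_order(L1, config@minGapReverse))
    }, numeric(1))
}

#' Build the peptide universe of a proteome
#'
#' Enumerates either all non-spliced windows or all cis-spliced products of
#' every protein and returns the deduplicated, sorted peptide set.  The cis
#' path streams schemes one at a time into a hash set and never
#' materializes the scheme table.
#'
#' @param proteome a [Proteome-class].
#' @param category `"nonspliced"` or `"cis"`.
#' @param config an [enumerationConfig()].
#' @return a [PeptideUniverse-class].
#' @examples
#' p <- Proteome(c(P1 = "ACDEFGHIKLMNPQRSTVWY"), name = "toy")
#' peptideUniverse(p, "nonspliced")
#' @export
peptideUniverse <- function(proteome, category = c("nonspliced", "cis"),
                            config = enumerationConfig()) {
    category <- match.arg(category)
    seqs <- unname(proteinSequences(proteome))
    pep <- if (category == "nonspliced") {
        .cpp_nonspliced_unique(seqs, config@peptideLength,
                               config@excludeNonstandard)
    } else {
        .cpp_cis_unique(seqs, config@peptideLength, config@maxIntervening,
                        config@minGapNormal, config@minGapReverse,
                        config@minReactantLength, config@excludeNonstandard)
    }
    new("PeptideUniverse", source = proteomeName(proteome),
        category = category, peptideLength = config@peptideLength,
        peptides = pep)
}

#' Find cis-splicing decompositions of a peptide in a proteome
#'
#' Searches every protein for pairs of disjoint fragments whose ligation
#' (normal or reverse order) reproduces `peptide`, optionally without the
#' intervening-length cap (`maxIntervening = Inf` searches any theoretical
#' cis decomposition).  Occurrence search uses overlapping exact matching.
#'
#' @param peptide a single peptide string.
#' @param proteome a [Proteome-class].
#' @param config an [enumerationConfig()]; its `maxIntervening` is
#'   overridden by the `maxIntervening` argument when given.
#' @param maxIntervening optional cap on the intervening length; `Inf`
#'   removes the cap.
#' @param first stop after the first decomposition found (default FALSE).
#' @return data.frame with columns `protein_id`, `s1`, `e1`, `s2`, `e2`,
#'   `order`, `intervening`, `scheme` (printed notation); zero rows when
#'   none exists.
#' @export
findCisDecompositions <- function(peptide, proteome,
                                  config = enumerationConfig(),
                                  maxIntervening = NULL, first = FALSE) {
    peptide <- toupper(as.character(peptide)[1L])
    k <- nchar(peptide)
    if (k != config@peptideLength)
        stop("peptide length ", k, " does not match config peptideLength ",
             config@peptideLength)
    maxI <- if (is.null(maxIntervening)) config@maxIntervening else maxIntervening
    seqs <- proteinSequences(proteome)
    res <- list()
    for (pid in names(seqs)) {
        subject <- Biostrings::AAString(seqs[[pid]])
        for (len1 in config@minReactantLength:(k - config@minReactantLength)) {
            len2 <- k - len1
            left <- substr(peptide, 1L, len1)
            right <- substr(peptide, len1 + 1L, k)
            posL <- Biostrings::start(Biostrings::matchPattern(left, subject))
            posR <- Biostrings::start(Biostrings::matchPattern(right, subject))
            if (!length(posL) || !length(posR)) next
            grid <- expand.grid(s1 = posL, s2 = posR)
            e1 <- grid$s1 + len1 - 1L
            e2 <- grid$s2 + len2 - 1L
            gap_n <- grid$s2 - e1 - 1L                 # normal: frag1 first
            gap_r <- grid$s1 - e2 - 1L                 # reverse: frag2 first
            ok_n <- gap_n >= config@minGapNormal & gap_n <= maxI
            ok_r <- gap_r >= config@minGapReverse & gap_r <= maxI
            keep <- ok_n | ok_r
            if (!any(keep)) next
            d <- data.frame(protein_id = pid, s1 = grid$s1[keep],
                            e1 = e1[keep], s2 = grid$s2[keep], e2 = e2[keep],
                            order = ifelse(ok_n[keep], "normal", "reverse"),
                            intervening = ifelse(ok_n[keep], gap_n[keep],
                                                 gap_r[keep]),
                            stringsAsFactors = FALSE)
            res[[length(res) + 1L]] <- d
            if (first) break
        }
        if (first && length(res)) break
    }
    if (!length(res))
        return(data.frame(protein_id = character(), s1 = integer(),
                          e1 = integer(), s2 = integer(), e2 = integer(),
                          order = character(), intervening = integer(),
                          scheme = character()))
    out <- do.call(rbind, res)
    out <- out[order(out$protein_id, out$s1, out$s2), , drop = FALSE]
    rownames(out) <- NULL
    out$scheme <- formatSchemeNotation(out$protein_id, out$s1, out$e1,
                                       out$s2, out$e2)
    out
}
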