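#' @include zwitterscan-package.R
NULL

## ---------------------------------------------------------------------------
## Proteome
## ---------------------------------------------------------------------------

#' Proteome: a named set of protein sequences
#'
#' Thin wrapper around a [Biostrings::AAStringSet] carrying a proteome label
#' and optional per-protein gene identifiers.  Sequences are stored
#' uppercase; residues outside the 20 standard amino-acid letters are
#' allowed on input but flagged (see [nonstandardFlags()]) and skipped by
#' the enumerators by default.
#'
#' @slot name single character label for the proteome.
#' @slot sequences an `AAStringSet`; `names()` are the protein accessions.
#' @slot geneIds character vector parallel to `sequences` (or length zero)
#'   mapping each protein to a gene identifier.
#' @slot descriptions full FASTA headers, parallel to `sequences` (or
#'   length zero).
#' @exportClass Proteome
setClass("Proteome",
    slots = c(name = "character",
              sequences = "AAStringSet",
              geneIds = "character",
              descriptions = "character"))

setValidity("Proteome", function(object) {
    msg <- character()
    if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
        msg <- c(msg, "'name' must be a single non-empty string")
    ids <- names(object@sequences)
    if (length(object@sequences) > 0L) {
        if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
            msg <- c(msg, "every record must have a non-empty id")
        else if (anyDuplicated(ids))
            msg <- c(msg, sprintf("duplicate id %s",
                                  ids[duplicated(ids)][1L]))
        if (any(Biostrings::width(object@sequences) < 1L))
            msg <- c(msg, "every sequence must have length >= 1")
    }
    for (sl in c("geneIds", "descriptions")) {
        v <- slot(object, sl)
        if (length(v) != 0L && length(v) != length(object@sequences))
            msg <- c(msg, sprintf("'%s' must be empty or parallel to 'sequences'", sl))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a Proteome
#'
#' @param sequences named character vector or `AAStringSet` of protein
#'   sequences (names are the protein ids). Lowercase input is uppercased.
#' @param name proteome label.
#' @param geneIds optional character vector of gene identifiers, parallel
#'   to `sequences`.
#' @param descriptions optional full headers, parallel to `sequences`.
#' @return A [Proteome-class] object.
#' @examples
#' p <- Proteome(c(P1 = "ACDEFGHIKL", P2 = "MNPQRSTVWY"), name = "toy")
#' totalResidues(p)
#' @export
Proteome <- function(sequences, name = "proteome", geneIds = character(),
                     descriptions = character()) {
    if (is.character(sequences))
        sequences <- Biostrings::AAStringSet(toupper(sequences))
    else if (is(sequences, "AAStringSet"))
        sequences <- Biostrings::AAStringSet(toupper(as.character(sequences)))
    else
        stop("'sequences' must be a character vector or an AAStringSet")
    new("Proteome", name = name, sequences = sequences,
        geneIds = as.character(geneIds),
        descriptions = as.character(descriptions))
}

#' @describeIn Proteome number of protein records.
#' @param x a `Proteome`.
#' @export
setMethod("length", "Proteome", function(x) length(x@sequences))

#' @describeIn Proteome protein accessions.
#' @export
setMethod("names", "Proteome", function(x) names(x@sequences))

setMethod("show", "Proteome", function(object) {
    cat(sprintf("Proteome '%s': %d proteins, %d residues",
                object@name, length(object), totalResidues(object)))
    n_flag <- sum(nonstandardFlags(object))
    if (n_flag > 0L)
        cat(sprintf(" (%d with non-standard residues)", n_flag))
    cat("\n")
})

#' Proteome accessors
#'
#' `proteomeName()` returns the label, `totalResidues()` the summed protein
#' lengths, `proteinSequences()` the sequences as a plain named character
#' vector, `geneIds()` the per-protein gene identifiers (protein ids when
#' none were supplied), and `nonstandardFlags()` a named logical marking
#' records containing residues outside the 20 standard letters.
#'
#' @param x a [Proteome-class].
#' @return See description; `totalResidues()` is an integer.
#' @name proteome-accessors
NULL

#' @rdname proteome-accessors
#' @export
proteomeName <- function(x) x@name

#' @rdname proteome-accessors
#' @export
totalResidues <- function(x) sum(Biostrings::width(x@sequences))

#' @rdname proteome-accessors
#' @export
proteinSequences <- function(x) {
    out <- as.character(x@sequences)
    names(out) <- names(x@sequences)
    out
}

#' @rdname proteome-accessors
#' @export
geneIds <- function(x) {
    if (length(x@geneIds)) setNames(x@geneIds, names(x))
    else setNames(names(x), names(x))
}

#' @rdname proteome-accessors
#' @export
nonstandardFlags <- function(x) {
    seqs <- proteinSequences(x)
    setNames(grepl(sprintf("[^%s]", paste(STANDARD_AA, collapse = "")), seqs),
             names(seqs))
}

## ---------------------------------------------------------------------------
## EnumerationConfig
## ---------------------------------------------------------------------------

#' Enumeration parameters for non-spliced and cis-spliced peptides
#'
#' @slot peptideLength product peptide length (residues, default 9: the
#'   dominant length in HLA-I immunopeptidomes).
#' @slot maxIntervening maximal number of substrate residues between the
#'   two splice-reactants (default 25).
#' @slot minGapNormal minimal intervening length for normal-order splicing
#'   (default 1: gap 0 would reproduce the contiguous sequence).
#' @slot minGapReverse minimal intervening length for reverse-order
#'   splicing (default 0: adjacent fragments ligated in reverse order form
#'   a genuinely new sequence).
#' @slot minReactantLength minimal splice-reactant length (default 1).
#' @slot excludeNonstandard drop peptides containing non-standard residues
#'   (default TRUE).
#' @exportClass EnumerationConfig
setClass("EnumerationConfig",
    slots = c(peptideLength = "integer", maxIntervening = "integer",
              minGapNormal = "integer", minGapReverse = "integer",
              minReactantLength = "integer", excludeNonstandard = "logical"))

setValidity("EnumerationConfig", function(object) {
    msg <- character()
    if (object@peptideLength < 2L)
        msg <- c(msg, "peptideLength must be >= 2")
    if (object@maxIntervening < 0L)
        msg <- c(msg, "maxIntervening must be >= 0")
    if (object@minReactantLength < 1L)
        msg <- c(msg, "minReactantLength must be >= 1")
    if (object@minGapNormal < 1L)
        msg <- c(msg, "minGapNormal must be >= 1")
    if (object@minGapReverse < 0L)
        msg <- c(msg, "minGapReverse must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @rdname EnumerationConfig-class
#' @param peptideLength,maxIntervening,minGapNormal,minGapReverse,minReactantLength,excludeNonstandard
#'   see the class slots.
#' @return an `EnumerationConfig`.
#' @examples
#' enumerationConfig()
#' @export
enumerationConfig <- function(peptideLength = 9, maxIntervening = 25,
                              minGapNormal = 1, minGapReverse = 0,
                              minReactantLength = 1,
                              excludeNonstandard = TRUE) {
    new("EnumerationConfig",
        peptideLength = as.integer(peptideLength),
        maxIntervening = as.integer(maxIntervening),
        minGapNormal = as.integer(minGapNormal),
        minGapReverse = as.integer(minGapReverse),
        minReactantLength = as.integer(minReactantLength),
        excludeNonstandard = isTRUE(excludeNonstandard))
}

setMethod("show", "EnumerationConfig", function(object) {
    cat(sprintf(paste0("EnumerationConfig: %dmers, intervening %d..%d",
                       " (normal) / %d..%d (reverse), reactants >= %d%s\n"),
                object@peptideLength, object@minGapNormal,
                object@maxIntervening, object@minGapReverse,
                object@maxIntervening, object@minReactantLength,
                if (object@excludeNonstandard)
                    ", non-standard residues excluded" else ""))
})

## ---------------------------------------------------------------------------
## PeptideUniverse
## ---------------------------------------------------------------------------

#' PeptideUniverse: the deduplicated peptides of one proteome and category
#'
#' @slot source proteome label the peptides derive from.
#' @slot category `"nonspliced"` or `"cis"`.
#' @slot peptideLength common peptide length.
#' @slot peptides sorted unique peptide sequences.
#' @exportClass PeptideUniverse
setClass("PeptideUniverse",
    slots = c(source = "character", category = "character",
              peptideLength = "integer", peptides = "character"))

setValidity("PeptideUniverse", function(object) {
    msg <- character()
    if (!object@category %in% c("nonspliced", "cis"))
        msg <- c(msg, "category must be 'nonspliced' or 'cis'")
    if (length(object@peptides)) {
        if (anyDuplicated(object@peptides))
            msg <- c(msg, "peptides must be unique")
        if (any(nchar(object@peptides) != object@peptideLength))
            msg <- c(msg, "all peptides must have length 'peptideLength'")
    }
    if (length(msg)) msg else TRUE
})

#' Build a PeptideUniverse from raw peptides
#'
#' Deduplicates and sorts, so the result is stable across input order.
#'
#' @param peptides character vector of peptides (all the same length).
#' @param source proteome label.
#' @param category `"nonspliced"` or `"cis"`.
#' @param peptideLength peptide length; inferred from the data when omitted
#'   (required for an empty universe).
#' @return a [PeptideUniverse-class].
#' @examples
#' uniquePeptides(c("ACDEFGHIK", "ACDEFGHIK", "CDEFGHIKL"), "toy", "nonspliced")
#' @export
uniquePeptides <- function(peptides, source, category, peptideLength = NULL) {
    peptides <- sort(unique(as.character(peptides)))
    if (is.null(peptideLength)) {
        if (!length(peptides))
            stop("peptideLength must be given for an empty universe")
        peptideLength <- nchar(peptides[1L])
    }
    new("PeptideUniverse", source = source, category = category,
        peptideLength = as.integer(peptideLength), peptides = peptides)
}

#' @describeIn PeptideUniverse number of unique peptides.
#' @param x a `PeptideUniverse`.
#' @export
setMethod("length", "PeptideUniverse", function(x) length(x@peptides))

setMethod("show", "PeptideUniverse", function(object) {
    cat(sprintf("PeptideUniverse: %d unique %s %dmers from '%s'\n",
                length(object), object@category, object@peptideLength,
                object@source))
})

#' @rdname PeptideUniverse-class
#' @export
peptides <- function(x) x@peptides

#' @rdname PeptideUniverse-class
#' @export
universeCategory <- function(x) x@category

#' @rdname PeptideUniverse-class
#' @export
universeSource <- function(x) x@source

# internal: replace the peptide set, keeping metadata
.replacePeptides <- function(universe, pep) {
    new("PeptideUniverse", source = universe@source,
        category = universe@category,
        peptideLength = universe@peptideLength,
        peptides = sort(unique(as.character(pep))))
}

## ---------------------------------------------------------------------------
## PositionScoringMatrix
## ---------------------------------------------------------------------------

#' Position scoring matrix for peptide-HLA binding prediction
#'
#' Log-additive predictor on the log10 IC50 (nM) scale:
#' `ic50 = 10 ^ (intercept + sum over positions of scores[pos, aa])`, the
#' scoring contract of stabilized-matrix-method style predictors.
#'
#' @slot allele HLA allele label (e.g. `"HLA-A*02:01"`).
#' @slot scores numeric matrix, `peptideLength` rows by 20 columns (the
#'   standard amino acids), finite values.
#' @slot intercept scalar intercept on the log10 nM scale.
#' @exportClass PositionScoringMatrix
setClass("PositionScoringMatrix",
    slots = c(allele = "character", scores = "matrix", intercept = "numeric"))

setValidity("PositionScoringMatrix", function(object) {
    msg <- character()
    sc <- object@scores
    if (!is.numeric(sc) || is.null(colnames(sc)) ||
        !setequal(colnames(sc), STANDARD_AA))
        msg <- c(msg, "scores must be numeric with the 20 standard amino acids as columns")
    else if (any(!is.finite(sc)))
        msg <- c(msg, "scores must be finite")
    if (length(object@intercept) != 1L || !is.finite(object@intercept))
        msg <- c(msg, "intercept must be a single finite number")
    if (length(msg)) msg else TRUE
})

#' @rdname PositionScoringMatrix-class
#' @param scores,intercept,allele see the class slots.
#' @return a `PositionScoringMatrix`.
#' @export
positionScoringMatrix <- function(scores, intercept, allele = "HLA-A*02:01") {
    scores <- as.matrix(scores)
    scores <- scores[, STANDARD_AA, drop = FALSE]
    new("PositionScoringMatrix", allele = allele, scores = scores,
        intercept = as.numeric(intercept))
}

setMethod("show", "PositionScoringMatrix", function(object) {
    cat(sprintf("PositionScoringMatrix for %s: %dmer, intercept %.4f (log10 nM)\n",
                object@allele, nrow(object@scores), object@intercept))
})

## ---------------------------------------------------------------------------
## SamplingConfig
## ---------------------------------------------------------------------------

#' Configuration for weighted presentation sampling
#'
#' @slot repeats number of sampling repeats (default 60).
#' @slot sizeFraction sample size as a fraction of the peptide pool
#'   (default 1 = 100%); values above 1 are allowed and approach exhaustive
#'   inclusion.
#' @slot replacement sample with replacement (default TRUE).
#' @slot seed integer seed.
#' @exportClass SamplingConfig
setClass("SamplingConfig",
    slots = c(repeats = "integer", sizeFraction = "numeric",
              replacement = "logical", seed = "integer"))

setValidity("SamplingConfig", function(object) {
    msg <- character()
    if (object@repeats < 1L) msg <- c(msg, "repeats must be >= 1")
    if (object@sizeFraction <= 0) msg <- c(msg, "sizeFraction must be > 0")
    if (length(msg)) msg else TRUE
})

#' @rdname SamplingConfig-class
#' @param repeats,sizeFraction,replacement,seed see the class slots.
#' @return a `SamplingConfig`.
#' @export
samplingConfig <- function(repeats = 60, sizeFraction = 1,
                           replacement = TRUE, seed = 1) {
    new("SamplingConfig", repeats = as.integer(repeats),
        sizeFraction = as.numeric(sizeFraction),
        replacement = isTRUE(replacement), seed = as.integer(seed))
}
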