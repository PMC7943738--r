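#' @include AllClasses.R
NULL

#' Predict IC50 from a position scoring matrix
#'
#' Log-additive scoring: `ic50 = 10 ^ (intercept + sum_pos scores[pos, aa])`
#' in nM.  Deterministic and pure; errors on length mismatch or
#' non-standard letters.
#'
#' @param peptides character vector of peptides, all of the matrix's
#'   length, standard letters only.
#' @param psm a [PositionScoringMatrix-class].
#' @return named numeric vector of IC50 values (nM).
#' @examples
#' psm <- positionScoringMatrix(
#'   matrix(0, 9, 20, dimnames = list(NULL, zwitterscan:::STANDARD_AA)),
#'   intercept = log10(500))
#' predictIC50("QLAEVVQKV", psm)  # 500
#' @export
predictIC50 <- function(peptides, psm) {
    peptides <- as.character(peptides)
    L <- nrow(psm@scores)
    if (any(nchar(peptides) != L))
        stop("peptide length mismatch: matrix expects ", L, "mers")
    if (!length(peptides)) return(setNames(numeric(), character()))
    aa <- matrix(unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE),
                 nrow = L)
    col <- match(aa, colnames(psm@scores))
    if (anyNA(col))
        stop("non-standard letter in peptide: ",
             peptides[ceiling(which(is.na(col))[1L] / L)])
    idx <- matrix(c(rep(seq_len(L), ncol(aa)), col), ncol = 2L)
    s <- colSums(matrix(psm@scores[idx], nrow = L))
    setNames(10 ^ (psm@intercept + s), peptides)
}

#' Read and write position scoring matrices
#'
#' TSV format: comment header lines `#allele<TAB>label` and
#' `#intercept<TAB>value`, then a header row `pos` plus the 20 amino-acid
#' letters and one row per position.
#'
#' @param psm a [PositionScoringMatrix-class].
#' @param path file path.
#' @return `writeScoringMatrix()`: `path`, invisibly;
#'   `readScoringMatrix()`: the matrix object.
#' @export
writeScoringMatrix <- function(psm, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste0("#allele\t", psm@allele),
                 paste0("#intercept\t", sprintf("%.17g", psm@intercept)),
                 paste(c("pos", colnames(psm@scores)), collapse = "\t")), con)
    for (i in seq_len(nrow(psm@scores)))
        writeLines(paste(c(i, sprintf("%.17g", psm@scores[i, ])),
                         collapse = "\t"), con)
    invisible(path)
}

#' @rdname writeScoringMatrix
#' @export
readScoringMatrix <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    meta <- lines[startsWith(lines, "#")]
    body <- lines[!startsWith(lines, "#")]
    pick <- function(key, default = NA_character_) {
        hit <- meta[startsWith(meta, paste0("#", key, "\t"))]
        if (length(hit)) sub("^#[^\t]*\t", "", hit[1L]) else default
    }
    intercept <- as.numeric(pick("intercept"))
    if (is.na(intercept)) stop("scoring matrix file lacks an #intercept line")
    allele <- pick("allele", "HLA-A*02:01")
    header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
    rows <- do.call(rbind, strsplit(body[-1L], "\t", fixed = TRUE))
    scores <- matrix(as.numeric(rows[, -1L, drop = FALSE]),
                     nrow = nrow(rows),
                     dimnames = list(NULL, header[-1L]))
    positionScoringMatrix(scores, intercept, allele)
}

#' Load externally produced IC50 predictions
#'
#' Adapter for predictions produced by an external peptide-MHC binding
#' tool: a two-column TSV (`peptide`, `ic50_nM`).  The resulting lookup
#' table is usable wherever a scoring matrix is (see [asPredictor()]).
#' Duplicate rows with conflicting values are an error; at query time a
#' missing peptide is an error naming it.
#'
#' @param path predictions TSV.
#' @return named numeric vector, peptide -> IC50 (nM).
#' @export
loadExternalPredictions <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.delim(path, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    if (!all(c("peptide", "ic50_nm") %in% names(df)))
        stop("predictions file needs columns 'peptide' and 'ic50_nM'")
    pep <- as.character(df$peptide)
    val <- as.numeric(df$ic50_nm)
    dup <- duplicated(pep)
    if (any(dup)) {
        conflict <- tapply(val, pep, function(v) length(unique(v)) > 1L)
        if (any(conflict))
            stop("duplicate peptide with conflicting values: ",
                 names(conflict)[conflict][1L])
        keep <- !dup
        pep <- pep[keep]; val <- val[keep]
    }
    setNames(val, pep)
}

#' @rdname loadExternalPredictions
#' @param predictions named numeric vector, peptide -> IC50.
#' @export
writeExternalPredictions <- function(predictions, path) {
    write.table(data.frame(peptide = names(predictions),
                           ic50_nM = sprintf("%.17g", predictions)),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Normalize a predictor argument
#'
#' Accepts a [PositionScoringMatrix-class], a named numeric lookup table
#' (peptide -> IC50), or a function, and returns a function
#' `f(peptides) -> named IC50 vector`.  Lookup predictors error, listing
#' the first offender, when queried for a peptide they do not cover.
#'
#' @param predictor matrix, lookup table or function.
#' @return a prediction function.
#' @export
asPredictor <- function(predictor) {
    if (is(predictor, "PositionScoringMatrix"))
        return(function(peptides) predictIC50(peptides, predictor))
    if (is.numeric(predictor) && !is.null(names(predictor))) {
        table <- predictor
        return(function(peptides) {
            hit <- match(peptides, names(table))
            if (anyNA(hit))
                stop("no prediction for ", peptides[is.na(hit)][1L])
            setNames(unname(table[hit]), peptides)
        })
    }
    if (is.function(predictor)) return(predictor)
    stop("'predictor' must be a PositionScoringMatrix, a named numeric ",
         "lookup table or a function")
}

#' Filter a peptide universe to predicted HLA binders
#'
#' Keeps peptides with predicted IC50 at or below the cutoff (inclusive,
#' so the conventional 500 nM binder definition keeps a peptide at exactly
#' 500 nM).
#'
#' @param universe a [PeptideUniverse-class].
#' @param predictor anything [asPredictor()] accepts.
#' @param cutoff_nM IC50 cutoff in nM (default 500; 50 for the stringent
#'   strong-binder analysis).
#' @return the filtered [PeptideUniverse-class]; the per-peptide IC50
#'   values of the kept peptides are attached as attribute `"ic50"`.
#' @export
filterBinders <- function(universe, predictor, cutoff_nM = 500) {
    fn <- asPredictor(predictor)
    if (!length(universe)) {
        out <- universe
        attr(out, "ic50") <- setNames(numeric(), character())
        return(out)
    }
    ic50 <- fn(peptides(universe))
    keep <- ic50 <= cutoff_nM
    out <- .replacePeptides(universe, peptides(universe)[keep])
    attr(out, "ic50") <- ic50[keep][peptides(out)]
    out
}
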