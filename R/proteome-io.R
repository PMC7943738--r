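#' @include AllClasses.R
NULL

#' Read a proteome from a FASTA file
#'
#' The header token up to the first whitespace becomes the protein id; the
#' full header is kept as the record description.  Sequences are
#' uppercased.  Records containing letters outside the 20 standard amino
#' acids are retained but flagged (see [nonstandardFlags()]).
#'
#' @param path FASTA file (wrapped or unwrapped, multi-record).
#' @param name proteome label (default: file name without extension).
#' @return a [Proteome-class].
#' @seealso [writeProteome()]
#' @export
readProteome <- function(path, name = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(name))
        name <- sub("\\.[^.]*$", "", basename(path))
    seqs <- Biostrings::readAAStringSet(path)
    if (length(seqs) == 0L)
        stop("empty FASTA file: ", path)
    headers <- names(seqs)
    ids <- sub("\\s.*$", "", headers)
    if (anyDuplicated(ids))
        stop("duplicate id ", ids[duplicated(ids)][1L])
    names(seqs) <- ids
    Proteome(seqs, name = name, descriptions = headers)
}

#' Write a proteome to FASTA
#'
#' @param proteome a [Proteome-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeProteome <- function(proteome, path) {
    Biostrings::writeXStringSet(proteome@sequences, filepath = path)
    invisible(path)
}

#' Parse and format cis-splicing scheme notation
#'
#' Splicing schemes are printed as `<protein-id>.<s1>-<e1>/<s2>-<e2>` with
#' 1-based inclusive substrate coordinates, fragment 1 being the N-terminal
#' fragment of the product.  The order is `normal` when fragment 1 precedes
#' fragment 2 in the substrate (`e1 < s2`) and `reverse` when fragment 2
#' precedes fragment 1 (`e2 < s1`); the intervening length is `s2 - e1 - 1`
#' (normal) or `s1 - e2 - 1` (reverse).
#'
#' @param text character vector of scheme strings; whitespace around the
#'   coordinate block is tolerated.
#' @return `parseSchemeNotation()`: a data.frame with columns `protein_id`,
#'   `s1`, `e1`, `s2`, `e2`, `order`, `intervening`.
#' @examples
#' parseSchemeNotation("Q14764|MVP_HUMAN.786-790/762-765")
#' @export
parseSchemeNotation <- function(text) {
    text <- as.character(text)
    rx <- "^(.+)\\.\\s*(\\d+)-(\\d+)/(\\d+)-(\\d+)\\s*$"
    bad <- !grepl(rx, text)
    if (any(bad))
        stop("malformed scheme notation: ", text[bad][1L])
    m <- regmatches(text, regexec(rx, text))
    pid <- vapply(m, `[`, character(1), 2L)
    co <- vapply(m, function(x) as.integer(x[3:6]), integer(4))
    s1 <- co[1L, ]; e1 <- co[2L, ]; s2 <- co[3L, ]; e2 <- co[4L, ]
    if (any(e1 < s1) || any(e2 < s2))
        stop("fragment end before start in: ",
             text[which(e1 < s1 | e2 < s2)][1L])
    is_normal <- e1 < s2
    is_reverse <- e2 < s1
    if (any(!is_normal & !is_reverse))
        stop("overlapping fragments in: ", text[which(!is_normal & !is_reverse)][1L])
    data.frame(protein_id = pid, s1 = s1, e1 = e1, s2 = s2, e2 = e2,
               order = ifelse(is_normal, "normal", "reverse"),
               intervening = ifelse(is_normal, s2 - e1 - 1L, s1 - e2 - 1L),
               stringsAsFactors = FALSE)
}

#' @rdname parseSchemeNotation
#' @param protein_id,s1,e1,s2,e2 scheme components (vectors recycle).
#' @return `formatSchemeNotation()`: character vector of scheme strings.
#' @export
formatSchemeNotation <- function(protein_id, s1, e1, s2, e2) {
    sprintf("%s.%d-%d/%d-%d", protein_id, as.integer(s1), as.integer(e1),
            as.integer(s2), as.integer(e2))
}

#' Read and write peptide tables
#'
#' Tab-separated peptide tables with columns `peptide`, `source`,
#' `category`, `scheme` (empty for non-spliced records) and optionally
#' `ic50_nM`.  Writing then reading is lossless, including full numeric
#' precision for `ic50_nM`.
#'
#' @param records data.frame with the columns above (`scheme` and
#'   `ic50_nM` optional; missing `scheme` entries may be `NA`).
#' @param path file path.
#' @return `writePeptideTable()` returns `path` invisibly;
#'   `readPeptideTable()` returns the data.frame.
#' @export
writePeptideTable <- function(records, path) {
    records <- as.data.frame(records)
    for (col in c("peptide", "source", "category"))
        if (is.null(records[[col]]))
            stop("peptide table needs column '", col, "'")
    if (is.null(records$scheme))
        records$scheme <- rep(NA_character_, nrow(records))
    scheme <- as.character(records$scheme)
    scheme[is.na(scheme)] <- ""
    out <- data.frame(peptide = as.character(records$peptide),
                      source = as.character(records$source),
                      category = as.character(records$category),
                      scheme = scheme,
                      stringsAsFactors = FALSE)
    if (!is.null(records$ic50_nM))
        out$ic50_nM <- sprintf("%.17g", records$ic50_nM)
    ok <- tryCatch({
        write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
        TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("cannot write peptide table to ", path)
    invisible(path)
}

#' @rdname writePeptideTable
#' @export
readPeptideTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = "character")
    df$scheme[!nzchar(df$scheme)] <- NA_character_
    if (!is.null(df$ic50_nM)) df$ic50_nM <- as.numeric(df$ic50_nM)
    df
}

#' Virus manifests
#'
#' A virus manifest is a two-column TSV (`virus`, `path`) listing one FASTA
#' file per virus.  `readVirusProteomes()` loads every listed proteome.
#'
#' @param path manifest file.
#' @param manifest data.frame with columns `virus` and `path`.
#' @param baseDir directory FASTA paths are resolved against (default: the
#'   manifest's directory).
#' @return `readVirusManifest()`: the manifest data.frame;
#'   `readVirusProteomes()`: named list of [Proteome-class] objects.
#' @export
readVirusManifest <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = "character")
    if (!all(c("virus", "path") %in% names(df)))
        stop("manifest needs columns 'virus' and 'path'")
    if (anyDuplicated(df$virus))
        stop("duplicate virus name ", df$virus[duplicated(df$virus)][1L])
    df
}

#' @rdname readVirusManifest
#' @export
writeVirusManifest <- function(manifest, path) {
    write.table(manifest[, c("virus", "path")], path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname readVirusManifest
#' @export
readVirusProteomes <- function(manifest, baseDir = NULL) {
    if (is.character(manifest)) {
        if (is.null(baseDir)) baseDir <- dirname(manifest)
        manifest <- readVirusManifest(manifest)
    }
    if (is.null(baseDir)) baseDir <- "."
    out <- lapply(seq_len(nrow(manifest)), function(i) {
        p <- manifest$path[i]
        if (!file.exists(p)) p <- file.path(baseDir, manifest$path[i])
        readProteome(p, name = manifest$virus[i])
    })
    names(out) <- manifest$virus
    out
}

#' Curated HIV-derived non-immunogenic 9mer peptide pool
#'
#' A fixed pool of 20 HIV-derived, HLA-A*02:01-restricted 9mer peptides
#' (predicted IC50 <= 500 nM) reported non-immunogenic across published
#' T-cell activation assays, together with, where one exists, a human
#' cis-splicing scheme generating the same sequence: one scheme with
#' intervening length <= 25 residues and/or one without length restriction.
#' Shipped as a plain-text fixture in `inst/extdata`.
#'
#' @return data.frame with columns `peptide`, `ic50_nM`, `rank`,
#'   `scheme_cis25` and `scheme_any` (NA when no scheme is annotated).
#' @examples
#' pool <- hivNonimmunogenicPeptides()
#' subset(pool, !is.na(scheme_cis25))
#' @export
hivNonimmunogenicPeptides <- function() {
    path <- system.file("extdata", "hiv_nonimmunogenic_9mers.tsv",
                        package = "zwitterscan", mustWork = TRUE)
    df <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = "character")
    df$ic50_nM <- as.numeric(df$ic50_nM)
    df$rank <- as.numeric(df$rank)
    df$scheme_cis25[!nzchar(df$scheme_cis25)] <- NA_character_
    df$scheme_any[!nzchar(df$scheme_any)] <- NA_character_
    df
}
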