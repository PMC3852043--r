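#' @importFrom Biostrings readBStringSet width
#' @importFrom utils read.delim write.table
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

.normalizeSeqs <- function(x) {
    s <- chartr("U", "T", toupper(as.character(x)))
    names(s) <- names(x)
    s
}

#' Construct a TranscriptSet from character vectors
#'
#' @param orf named character vector of ORF sequences (required).
#' @param utr5,utr3 named character vectors; missing genes get "".
#' @param pars optional named list of numeric PARS profiles.
#' @param mode "strict" rejects invalid records; "permissive" truncates ORFs
#'   that are not multiples of 3 from the 3' end and only warns about
#'   start/stop violations.
#' @return a \code{TranscriptSet}; rejected gene ids and reasons are attached
#'   as \code{attr(x, "rejected")} (a data.frame).
#' @export
TranscriptSet <- function(orf, utr5 = NULL, utr3 = NULL, pars = NULL,
                          mode = c("strict", "permissive")) {
    mode <- match.arg(mode)
    ids <- names(orf)
    if (is.null(ids) || anyDuplicated(ids))
        stop("ORF sequences must have unique names")
    orf <- .normalizeSeqs(orf)
    fill <- function(x) {
        out <- setNames(rep("", length(ids)), ids)
        if (!is.null(x)) {
            x <- .normalizeSeqs(x)
            keep <- intersect(names(x), ids)
            out[keep] <- x[keep]
        }
        out
    }
    utr5 <- fill(utr5); utr3 <- fill(utr3)

    reasons <- character(0); rej <- character(0)
    keep <- rep(TRUE, length(ids))
    for (i in seq_along(ids)) {
        reason <- NULL
        o <- orf[i]
        if (grepl("[^ACGT]", o) || grepl("[^ACGT]", utr5[i]) ||
            grepl("[^ACGT]", utr3[i])) {
            reason <- "non-ACGT characters"
        } else if (nchar(o) == 0) {
            reason <- "empty ORF"
        } else if (nchar(o) %% 3 != 0) {
            if (mode == "permissive") {
                orf[i] <- substr(o, 1, nchar(o) - nchar(o) %% 3)
                warning("ORF of ", ids[i], " truncated to a multiple of 3",
                        call. = FALSE)
                o <- orf[i]
                if (nchar(o) == 0) reason <- "empty ORF after truncation"
            } else reason <- "ORF length not divisible by 3"
        }
        if (is.null(reason) && nchar(orf[i]) >= 3) {
            startOk <- substr(orf[i], 1, 3) == "ATG"
            stopOk <- substr(orf[i], nchar(orf[i]) - 2, nchar(orf[i])) %in% STOP_CODONS
            if (!startOk || !stopOk) {
                msg <- paste0(ids[i], ": ",
                              if (!startOk) "ORF does not start with ATG" else
                                  "ORF does not end with a stop codon")
                if (mode == "permissive") warning(msg, call. = FALSE)
                else reason <- msg
            }
        }
        if (!is.null(reason)) { keep[i] <- FALSE; rej <- c(rej, ids[i]);
                                reasons <- c(reasons, reason) }
    }
    ids2 <- ids[keep]
    parsList <- list()
    if (!is.null(pars)) {
        parsList <- setNames(vector("list", length(ids2)), ids2)
        for (g in intersect(names(pars), ids2)) parsList[[g]] <- as.numeric(pars[[g]])
        tot <- nchar(utr5[ids2]) + nchar(orf[ids2]) + nchar(utr3[ids2])
        for (j in seq_along(ids2)) {
            p <- parsList[[j]]
            if (!is.null(p) && length(p) != tot[j]) {
                rej <- c(rej, ids2[j])
                reasons <- c(reasons, "PARS length mismatch")
            }
        }
        bad <- ids2 %in% rej
        ids2 <- ids2[!bad]
        parsList <- parsList[!bad]
    }
    if (length(rej))
        message(length(rej), " record(s) rejected: ",
                paste(rej, reasons, sep = " - ", collapse = "; "))
    obj <- new("TranscriptSet",
               utr5 = DNAStringSet(utr5[ids2]),
               orf = DNAStringSet(orf[ids2]),
               utr3 = DNAStringSet(utr3[ids2]),
               pars = parsList)
    attr(obj, "rejected") <- data.frame(gene_id = rej, reason = reasons,
                                        stringsAsFactors = FALSE)
    obj
}

#' Read transcript segments (and optional PARS profiles) from files
#'
#' The ORF FASTA defines the gene universe; genes absent from a UTR FASTA get
#' an empty string for that segment. U is mapped to T and sequences are
#' uppercased. PARS is a TSV (gene_id, pos, score) with 1-based positions
#' over the concatenated utr5+orf+utr3 transcript.
#'
#' @param orfPath,utr5Path,utr3Path FASTA paths (the UTR paths may be NULL).
#' @param parsPath optional PARS TSV path.
#' @param mode see \code{\link{TranscriptSet}}.
#' @return a \code{TranscriptSet}.
#' @export
readTranscripts <- function(orfPath, utr5Path = NULL, utr3Path = NULL,
                            parsPath = NULL, mode = c("strict", "permissive")) {
    rd <- function(p) {
        if (is.null(p)) return(NULL)
        x <- as.character(readBStringSet(p))
        names(x) <- sub("\\s.*$", "", names(x))
        x
    }
    orf <- rd(orfPath)
    pars <- NULL
    if (!is.null(parsPath)) {
        tab <- read.delim(parsPath, header = TRUE, stringsAsFactors = FALSE)
        stopifnot(all(c("gene_id", "pos", "score") %in% names(tab)))
        pars <- lapply(split(tab, tab$gene_id), function(d) {
            v <- numeric(max(d$pos))
            v[d$pos] <- d$score
            v
        })
    }
    TranscriptSet(orf, utr5 = rd(utr5Path), utr3 = rd(utr3Path),
                  pars = pars, mode = mode)
}

#' Read per-gene expression measurements
#'
#' TSV with columns gene_id, mrna, pa, rd (missing values as NA). PPR and RL
#' are never read from file; call \code{\link{deriveTargets}}.
#' @param path TSV path
#' @return data.frame with columns gene_id, mrna, pa, rd
#' @export
readExpression <- function(path) {
    tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    stopifnot(all(c("gene_id", "mrna", "pa", "rd") %in% names(tab)))
    tab[c("gene_id", "mrna", "pa", "rd")]
}

#' Derive PPR and RL from the measured expression columns
#'
#' PPR (proteins per mRNA) = PA / mRNA. RL (ribosomal load) defaults to
#' RD x mRNA; the alternative "total_ribosomes" definition additionally
#' multiplies by the ORF length in codons (pass \code{orfCodons}).
#'
#' @param table data.frame with gene_id, mrna, pa, rd
#' @param rlDefinition "density_times_mrna" (default) or "total_ribosomes"
#' @param orfCodons named numeric (gene_id -> ORF codon count), required for
#'   the "total_ribosomes" definition
#' @return the table with ppr and rl columns (re)computed
#' @export
deriveTargets <- function(table,
                          rlDefinition = c("density_times_mrna", "total_ribosomes"),
                          orfCodons = NULL) {
    rlDefinition <- match.arg(rlDefinition)
    mrna <- table$mrna
    badm <- !is.na(mrna) & mrna <= 0
    if (any(badm)) {
        warning(sum(badm), " gene(s) with non-positive mRNA; PPR/RL set to NA")
        mrna[badm] <- NA
    }
    table$ppr <- table$pa / mrna
    rl <- table$rd * mrna
    if (rlDefinition == "total_ribosomes") {
        if (is.null(orfCodons)) stop("orfCodons required for total_ribosomes")
        rl <- rl * as.numeric(orfCodons[table$gene_id])
    }
    table$rl <- rl
    table
}

#' Write / read a feature table as TSV
#'
#' Genes as rows, first column gene_id, header of feature names; NaN/NA cells
#' serialised as "NA". Round-trips losslessly to 12 significant digits.
#' @param x FeatureSet or numeric matrix with dimnames
#' @param path output path
#' @export
writeFeatureTable <- function(x, path) {
    m <- if (is(x, "FeatureSet")) featureMatrix(x) else x
    if (anyDuplicated(colnames(m))) stop("duplicate feature names")
    df <- data.frame(gene_id = rownames(m),
                     signif(m, 12), check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    invisible(path)
}

#' @rdname writeFeatureTable
#' @return \code{readFeatureTable}: a \code{FeatureSet} (catalogue
#'   reconstructed from the feature names).
#' @export
readFeatureTable <- function(path) {
    df <- read.delim(path, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    cn <- names(df)[-1]
    dup <- cn[duplicated(cn)]
    if (length(dup)) stop("duplicate feature column(s): ",
                          paste(unique(dup), collapse = ", "))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$gene_id
    new("FeatureSet", values = m, catalogue = .catalogueFromNames(cn),
        scheme = "A", cache = list())
}

# minimal catalogue rebuilt from "<scope>.<family>.<detail>" names
.catalogueFromNames <- function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)
    data.frame(name = nm,
               scope = vapply(parts, `[`, "", 1),
               family = vapply(parts, `[`, "", 2),
               default = 0,
               tunable = FALSE,
               stringsAsFactors = FALSE)
}

#' Join a feature set and an expression table on gene id
#'
#' Genes present on one side only are dropped, with counts reported.
#' @param features FeatureSet
#' @param expression data.frame with gene_id column
#' @return list(features = matrix, expression = data.frame) on common genes
#' @export
joinFeaturesExpression <- function(features, expression) {
    fg <- geneIds(features)
    common <- intersect(fg, expression$gene_id)
    dropF <- length(fg) - length(common)
    dropE <- nrow(expression) - length(common)
    if (dropF || dropE)
        message("dropped ", dropF, " feature-only and ", dropE,
                " expression-only gene(s)")
    list(features = featureMatrix(features)[common, , drop = FALSE],
         expression = expression[match(common, expression$gene_id), ,
                                 drop = FALSE])
}
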