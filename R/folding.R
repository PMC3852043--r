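#' Folding engine configuration
#'
#' The default backend is a self-contained weighted base-pair maximisation
#' (Nussinov-style dynamic program) with a minimum hairpin loop constraint;
#' scores are reported as -(total pair weight) so that more structure is
#' more negative, matching the folding-energy sign convention. An external
#' thermodynamic minimum-free-energy provider can be plugged in as a
#' function(seq) -> list(score, n_bp).
#'
#' @param backend "basepair_max" or "external_thermodynamic"
#' @param minLoop minimum unpaired nucleotides in a hairpin loop (default 3)
#' @param weights pair weights for GC, AU and GU pairs
#' @param fold provider function for the external backend
#' @return a folding engine list
#' @export
foldingEngine <- function(backend = c("basepair_max", "external_thermodynamic"),
                          minLoop = 3L, weights = c(GC = 3, AU = 2, GU = 1),
                          fold = NULL) {
    backend <- match.arg(backend)
    if (backend == "external_thermodynamic" && !is.function(fold))
        stop("external backend requires a fold(seq) provider function")
    list(backend = backend, minLoop = as.integer(minLoop),
         weights = weights, fold = fold)
}

.encodeSeq <- function(s) {
    m <- c(A = 0L, C = 1L, G = 2L, T = 3L, U = 3L)
    unname(m[strsplit(toupper(s), "")[[1]]])
}

#' Folding strength of a sequence
#'
#' @param seq a character sequence (DNA alphabet; U mapped to T)
#' @param engine a \code{\link{foldingEngine}}
#' @return list(score, n_bp): score = -(maximum total pair weight); n_bp =
#'   base pairs in one optimal structure
#' @export
foldScore <- function(seq, engine = foldingEngine()) {
    if (nchar(seq) < 1) stop("foldScore needs a non-empty sequence")
    if (engine$backend == "external_thermodynamic") return(engine$fold(seq))
    r <- .nussinov_cpp(.encodeSeq(seq), engine$minLoop,
                       engine$weights[["GC"]], engine$weights[["AU"]],
                       engine$weights[["GU"]])
    list(score = -r$weight, n_bp = r$n_bp)
}

#' Default folding/PARS windows
#'
#' Last 40 nt of the 5'UTR, first 90 nt of the ORF (30 codons), last 90 nt
#' of the ORF, first 40 nt of the 3'UTR, plus (for folding) sliding 40-nt
#' windows at step 10 over the first 300 nt of the ORF. Windows are clipped
#' to the segment length; empty windows emit the catalogue defaults.
#' @param sliding include the sliding ORF windows
#' @return data.frame of window specs (name, segment, anchor, offset, length)
#' @export
defaultWindows <- function(sliding = TRUE) {
    w <- data.frame(
        name = c("UTR5.last40", "ORF.first90", "ORF.last90", "UTR3.first40"),
        segment = c("UTR5", "ORF", "ORF", "UTR3"),
        anchor = c("segment_end", "segment_start", "segment_end",
                   "segment_start"),
        offset = c(0L, 0L, 0L, 0L),
        length = c(40L, 90L, 90L, 40L),
        stringsAsFactors = FALSE)
    if (sliding) {
        starts <- seq(1L, 261L, by = 10L)
        w <- rbind(w, data.frame(
            name = sprintf("ORF.w%03d_40", starts), segment = "ORF",
            anchor = "segment_start", offset = starts - 1L, length = 40L,
            stringsAsFactors = FALSE))
    }
    w
}

# extract one window from a segment string; "" when the window is empty
.windowSeq <- function(segSeq, anchor, offset, len) {
    n <- nchar(segSeq)
    if (anchor == "segment_start") {
        from <- offset + 1L
        to <- min(n, offset + len)
    } else {
        to <- n - offset
        from <- max(1L, to - len + 1L)
    }
    if (from > to || to < 1L) return("")
    substr(segSeq, from, to)
}

#' Windowed folding features
#'
#' For each window: folding score, number of base pairs, and score per
#' nucleotide; zero defaults for empty windows.
#' @param ts TranscriptSet
#' @param windows window data.frame (see \code{\link{defaultWindows}})
#' @param engine a \code{\link{foldingEngine}}
#' @return numeric matrix, genes x (3 per window)
#' @export
windowedFoldingFeatures <- function(ts, windows = defaultWindows(),
                                    engine = foldingEngine()) {
    segs <- list(UTR5 = as.character(utr5(ts)), ORF = as.character(orf(ts)),
                 UTR3 = as.character(utr3(ts)))
    n <- length(ts)
    cols <- as.vector(t(outer(windows$name, c("score", "n_bp", "score_per_nt"),
                              function(a, b) sprintf("%s.fold.%s",
                                  sub("\\..*$", "", a),
                                  paste(sub("^[^.]*\\.", "", a), b, sep = ".")))))
    m <- matrix(0, n, nrow(windows) * 3,
                dimnames = list(geneIds(ts), cols))
    for (wi in seq_len(nrow(windows))) {
        seg <- segs[[windows$segment[wi]]]
        for (g in seq_len(n)) {
            s <- .windowSeq(seg[g], windows$anchor[wi], windows$offset[wi],
                            windows$length[wi])
            if (nchar(s) == 0) next
            r <- foldScore(s, engine)
            j <- (wi - 1L) * 3L
            m[g, j + 1L] <- r$score
            m[g, j + 2L] <- r$n_bp
            m[g, j + 3L] <- r$score / nchar(s)
        }
    }
    m
}

#' PARS structure features
#'
#' Per window: mean PARS, max PARS, and mean expPARS (expPARS_i =
#' exp(pars_i), exponentiated per nucleotide then averaged). Genes without a
#' PARS profile emit the defaults (0, 0, 1 -> stored defaults are 0/0/1).
#' @param ts TranscriptSet
#' @param windows window data.frame (the four fixed windows by default)
#' @return numeric matrix, genes x (3 per window)
#' @export
parsFeatures <- function(ts, windows = defaultWindows(sliding = FALSE)) {
    n <- length(ts)
    w5 <- Biostrings::width(utr5(ts)); wo <- Biostrings::width(orf(ts))
    w3 <- Biostrings::width(utr3(ts))
    segStart <- cbind(UTR5 = rep(1L, n), ORF = w5 + 1L, UTR3 = w5 + wo + 1L)
    segLen <- cbind(UTR5 = w5, ORF = wo, UTR3 = w3)
    cols <- as.vector(t(outer(windows$name, c("mean", "max", "mean_exp"),
                              function(a, b) sprintf("%s.pars.%s",
                                  sub("\\..*$", "", a),
                                  paste(sub("^[^.]*\\.", "", a), b, sep = ".")))))
    m <- matrix(0, n, nrow(windows) * 3, dimnames = list(geneIds(ts), cols))
    m[, grep("mean_exp$", cols)] <- 1  # exp(0) default
    pars <- parsScores(ts)
    if (!length(pars)) return(m)
    for (g in seq_len(n)) {
        p <- pars[[g]]
        if (is.null(p)) next
        for (wi in seq_len(nrow(windows))) {
            seg <- windows$segment[wi]
            sl <- segLen[g, seg]
            if (sl == 0) next
            if (windows$anchor[wi] == "segment_start") {
                from <- windows$offset[wi] + 1L
                to <- min(sl, windows$offset[wi] + windows$length[wi])
            } else {
                to <- sl - windows$offset[wi]
                from <- max(1L, to - windows$length[wi] + 1L)
            }
            if (from > to) next
            v <- p[segStart[g, seg] + (from:to) - 1L]
            j <- (wi - 1L) * 3L
            m[g, j + 1L] <- mean(v)
            m[g, j + 2L] <- max(v)
            m[g, j + 3L] <- mean(exp(v))
        }
    }
    m
}
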