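#' Random tercile splits for the jackknife
#'
#' Each replicate is an independent uniform random partition of the gene ids
#' into train/test/validation terciles whose sizes differ by at most one
#' (the remainder goes to train first, then test). Reproducible per
#' (seed, replicate).
#' @param geneIds character vector, n >= 9
#' @param nReplicates number of replicates (default 100)
#' @param seed root seed
#' @return list of replicates, each list(train, test, validation)
#' @export
makeSplits <- function(geneIds, nReplicates = 100L, seed = 1L) {
    n <- length(geneIds)
    if (n < 9) stop("need at least 9 genes for tercile splits")
    base <- n %/% 3L; r <- n %% 3L
    sizes <- c(train = base + (r >= 1L), test = base + (r >= 2L),
               validation = base)
    lapply(seq_len(nReplicates), function(rep) {
        perm <- .withSeed(.deriveSeed(seed, rep), sample(geneIds))
        list(train = perm[seq_len(sizes[1])],
             test = perm[sizes[1] + seq_len(sizes[2])],
             validation = perm[sizes[1] + sizes[2] + seq_len(sizes[3])],
             replicate = rep)
    })
}

#' Ordinary least squares with minimum-norm fallback
#'
#' Fits y ~ intercept + X by OLS; rank-deficient designs are resolved by the
#' minimum-norm (pseudoinverse) solution with a warning.
#' @param X numeric matrix (already standardized by the caller)
#' @param y numeric response
#' @return model list(kind, intercept, coef)
#' @export
fitLinearModel <- function(X, y) {
    if (!all(is.finite(X)) || !all(is.finite(y)))
        stop("non-finite values in the design or response")
    X <- as.matrix(X)
    if (ncol(X) == 0)
        return(list(kind = "linear", intercept = mean(y), coef = numeric(0)))
    sv <- svd(cbind(1, X))
    pos <- sv$d > max(sv$d) * 1e-10
    if (sum(pos) < length(sv$d))
        warning("rank-deficient design; minimum-norm solution used")
    beta <- sv$v[, pos, drop = FALSE] %*%
        ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    list(kind = "linear", intercept = beta[1],
         coef = setNames(beta[-1], colnames(X)))
}

.hinge <- function(x, knot, sign) pmax(0, sign * (x - knot))

.marsBasis <- function(X, terms) {
    B <- matrix(1, nrow(X), 1 + length(terms))
    for (k in seq_along(terms)) {
        tm <- terms[[k]]
        b <- rep(1, nrow(X))
        for (j in seq_len(nrow(tm)))
            b <- b * .hinge(X[, tm$var[j]], tm$knot[j], tm$sign[j])
        B[, k + 1] <- b
    }
    B
}

.rss <- function(B, y) {
    fit <- tryCatch(stats::lm.fit(B, y), error = function(e) NULL)
    if (is.null(fit)) return(list(rss = Inf, coef = NULL))
    r <- fit$residuals
    list(rss = sum(r * r), coef = fit$coefficients)
}

#' Multivariate adaptive regression splines
#'
#' Forward pass adding mirrored hinge pairs max(0, x-t) / max(0, t-x) at
#' observed-quantile knots by greedy residual reduction (interaction degree
#' up to 2 via products with an existing hinge term), then backward pruning
#' by generalized cross-validation GCV = RSS/n / (1 - C/n)^2 with
#' C = m + penalty (m-1)/2.
#' @param X numeric matrix (columns standardized by the caller)
#' @param y numeric response
#' @param maxTerms maximum basis terms including the intercept (default 15)
#' @param gcvPenalty GCV cost per knot (default 3)
#' @param degree maximum interaction degree (default 2)
#' @param nKnots candidate knots per variable (quantiles; default 10)
#' @return model list(kind, terms, coef)
#' @export
fitMars <- function(X, y, maxTerms = 15L, gcvPenalty = 3, degree = 2L,
                    nKnots = 10L) {
    if (maxTerms < 1) stop("maxTerms must be >= 1")
    X <- as.matrix(X)
    n <- nrow(X)
    # the p=0 knot makes max(0, x - min(x)) exactly linear on the train
    # range, so linear truths are representable without extrapolation blow-up
    knots <- lapply(seq_len(ncol(X)), function(j) {
        unique(stats::quantile(X[, j],
                               probs = c(0, seq(0.05, 0.95,
                                                length.out = max(1, nKnots - 1))),
                               names = FALSE, type = 1)) })
    sst <- sum((y - mean(y))^2)
    terms <- list()
    B <- matrix(1, n, 1)
    cur <- .rss(B, y)
    repeat {
        if (1 + length(terms) + 2 > maxTerms) break
        if (cur$rss <= 1e-10 * max(sst, 1e-10)) break
        best <- NULL; bestRss <- cur$rss - max(1e-8 * sst, 1e-12)
        parents <- c(0, seq_along(terms))  # 0 = intercept parent
        for (p in parents) {
            pdeg <- if (p == 0) 0L else nrow(terms[[p]])
            if (pdeg >= degree) next
            pvars <- if (p == 0) integer(0) else terms[[p]]$var
            pb <- if (p == 0) rep(1, n) else B[, p + 1]
            for (v in seq_len(ncol(X))) {
                if (v %in% pvars) next
                for (t in knots[[v]]) {
                    b1 <- pb * .hinge(X[, v], t, 1)
                    b2 <- pb * .hinge(X[, v], t, -1)
                    r <- .rss(cbind(B, b1, b2), y)
                    if (r$rss < bestRss) {
                        bestRss <- r$rss
                        best <- list(p = p, v = v, t = t)
                    }
                }
            }
        }
        if (is.null(best)) break
        parent <- if (best$p == 0)
            data.frame(var = integer(0), knot = numeric(0), sign = numeric(0))
        else terms[[best$p]]
        terms <- c(terms,
                   list(rbind(parent, data.frame(var = best$v, knot = best$t,
                                                 sign = 1))),
                   list(rbind(parent, data.frame(var = best$v, knot = best$t,
                                                 sign = -1))))
        B <- .marsBasis(X, terms)
        cur <- .rss(B, y)
    }
    # backward pruning by GCV; the penalty counts the distinct hinge knots
    # actually present (terms need not stay mirrored after pruning)
    gcv <- function(rss, keep) {
        m <- 1 + length(keep)
        kn <- if (length(keep))
            nrow(unique(do.call(rbind, lapply(terms[keep],
                                              function(t) t[c("var", "knot")]))))
        else 0
        C <- m + gcvPenalty * kn
        if (C >= n) return(Inf)
        (rss / n) / (1 - C / n)^2
    }
    keep <- seq_along(terms)
    bestKeep <- keep
    bestGcv <- gcv(cur$rss, keep)
    while (length(keep) > 0) {
        rssDrop <- vapply(seq_along(keep), function(i) {
            .rss(.marsBasis(X, terms[keep[-i]]), y)$rss
        }, 0)
        i <- which.min(rssDrop)
        keep <- keep[-i]
        g <- gcv(rssDrop[i], keep)
        if (g < bestGcv) { bestGcv <- g; bestKeep <- keep }
    }
    terms <- terms[bestKeep]
    fit <- .rss(.marsBasis(X, terms), y)
    co <- fit$coef
    co[is.na(co)] <- 0
    list(kind = "mars", terms = terms, coef = co,
         vars = colnames(X))
}

#' Predict from a fitted greedy model
#'
#' @param model output of the fitting routines, wrapped with the
#'   standardization statistics by \code{\link{greedySelect}}
#' @param X raw feature matrix containing the model's features
#' @return numeric predictions
#' @export
predictModel <- function(model, X) {
    Z <- .applyScale(X[, model$features, drop = FALSE], model$center,
                     model$scale)
    if (model$fit$kind == "linear") {
        if (length(model$fit$coef) == 0)
            return(rep(model$fit$intercept, nrow(Z)))
        as.numeric(model$fit$intercept + Z %*% model$fit$coef)
    } else {
        B <- .marsBasis(Z, model$fit$terms)
        as.numeric(B %*% model$fit$coef)
    }
}

.applyScale <- function(X, center, scale) {
    Z <- sweep(as.matrix(X), 2, center, "-")
    sweep(Z, 2, ifelse(scale > 0, scale, 1), "/")
}

#' Correlation score between predictions and a target
#'
#' Pairwise-complete Pearson (default) or Spearman correlation; NA with a
#' warning when fewer than 3 complete pairs remain or the predictions are
#' constant.
#' @param pred,y numeric vectors
#' @param method "pearson" or "spearman"
#' @return correlation or NA
#' @export
scoreCorrelation <- function(pred, y, method = c("pearson", "spearman")) {
    method <- match.arg(method)
    ok <- is.finite(pred) & is.finite(y)
    if (sum(ok) < 3) { warning("fewer than 3 complete pairs"); return(NA_real_) }
    if (sd(pred[ok]) == 0 || sd(y[ok]) == 0) {
        warning("constant predictions or target; correlation undefined")
        return(NA_real_)
    }
    cor(pred[ok], y[ok], method = method)
}

#' Control parameters for greedy selection and family building
#'
#' @param maxFeatures cap on selected features (default 30)
#' @param eps required test-correlation improvement to continue (default 0:
#'   any non-improvement on the test tercile stops the greedy growth)
#' @param selectBy "train" (default) or "test": which tercile's correlation
#'   picks the next feature (the test tercile always governs stopping)
#' @param scoreMethod "pearson" (on log targets) or "spearman"
#' @param logTarget log-transform the target before fitting/scoring
#' @param marsMaxTerms,marsPenalty,marsKnots MARS hyperparameters
#' @param screenTop for MARS selection only: pre-screen candidates by
#'   residual correlation and fit MARS for the top k (Inf = no screening)
#' @param schemeBOptimizeCai also retune CAI per-codon weights under scheme B
#' @param schemeBMaxSweeps coordinate-ascent sweep cap under scheme B
#' @param schemeBTasep re-simulate the TASEP feature per scheme-B replicate
#' @return control list
#' @export
familyControl <- function(maxFeatures = 30L, eps = 0, selectBy = "train",
                          scoreMethod = "pearson", logTarget = TRUE,
                          marsMaxTerms = 15L, marsPenalty = 3,
                          marsKnots = 10L, screenTop = 25L,
                          schemeBOptimizeCai = TRUE, schemeBMaxSweeps = 25L,
                          schemeBTasep = FALSE) {
    list(maxFeatures = maxFeatures, eps = eps, selectBy = selectBy,
         scoreMethod = scoreMethod, logTarget = logTarget,
         marsMaxTerms = marsMaxTerms, marsPenalty = marsPenalty,
         marsKnots = marsKnots, screenTop = screenTop,
         schemeBOptimizeCai = schemeBOptimizeCai,
         schemeBMaxSweeps = schemeBMaxSweeps, schemeBTasep = schemeBTasep)
}

.fitOn <- function(Z, y, features, modelKind, control) {
    if (modelKind == "linear")
        fitLinearModel(Z[, features, drop = FALSE], y)
    else
        fitMars(Z[, features, drop = FALSE], y,
                maxTerms = control$marsMaxTerms,
                gcvPenalty = control$marsPenalty, nKnots = control$marsKnots)
}

.predictOnZ <- function(fit, Z, features) {
    if (fit$kind == "linear") {
        if (length(fit$coef) == 0) return(rep(fit$intercept, nrow(Z)))
        as.numeric(fit$intercept + Z[, features, drop = FALSE] %*% fit$coef)
    } else {
        as.numeric(.marsBasis(Z[, features, drop = FALSE], fit$terms) %*%
                   fit$coef)
    }
}

#' Greedy forward feature selection on one tercile split
#'
#' In each iteration every remaining candidate is added to the growing
#' regressor, the model is fitted on the train tercile and the feature
#' giving the highest train correlation is selected; growth stops when the
#' test-tercile correlation of the grown model fails to exceed the previous
#' test correlation by eps, or at maxFeatures. The final model is refit on
#' train and additionally reported on the validation tercile.
#'
#' @param X raw feature matrix (all genes x candidate features)
#' @param y named numeric target (same genes; already log-transformed when
#'   the caller asked for it)
#' @param split one element of \code{\link{makeSplits}}
#' @param modelKind "linear" or "mars"
#' @param control see \code{\link{familyControl}}
#' @return a \code{Predictor}
#' @export
greedySelect <- function(X, y, split, modelKind = c("linear", "mars"),
                         control = familyControl()) {
    modelKind <- match.arg(modelKind)
    tr <- split$train; te <- split$test; va <- split$validation
    stopifnot(length(intersect(tr, te)) == 0, length(intersect(tr, va)) == 0,
              length(intersect(te, va)) == 0)
    okY <- names(y)[is.finite(y)]
    tr <- intersect(tr, okY); te <- intersect(te, okY); va <- intersect(va, okY)
    Xtr <- X[tr, , drop = FALSE]
    center <- colMeans(Xtr)
    scale <- apply(Xtr, 2, sd)
    Z <- .applyScale(X, center, scale)
    ytr <- y[tr]; yte <- y[te]
    alive <- colnames(X)[scale > 0]
    selected <- character(0)
    prevTest <- -Inf
    finalFit <- NULL

    while (length(selected) < control$maxFeatures && length(alive) > 0) {
        # residual correlation of each candidate given the selected design
        qrS <- qr(cbind(1, Z[tr, selected, drop = FALSE]))
        ry <- qr.resid(qrS, ytr)
        RC <- qr.resid(qrS, Z[tr, alive, drop = FALSE])
        num <- as.numeric(crossprod(RC, ry))
        den <- sqrt(colSums(RC^2) * sum(ry^2))
        pc <- ifelse(den > 1e-12, abs(num) / den, -Inf)
        if (modelKind == "linear") {
            best <- max(pc)
            if (!is.finite(best)) break
            # ties (incl. floating-point-identical duplicates): catalogue order
            cand <- alive[which(pc >= best - 1e-10)[1]]
            fit <- .fitOn(Z[tr, , drop = FALSE], ytr, c(selected, cand),
                          modelKind, control)
        } else {
            pool <- alive[order(-pc)]
            if (is.finite(control$screenTop))
                pool <- pool[seq_len(min(length(pool), control$screenTop))]
            bestCor <- -Inf; cand <- NULL; fit <- NULL
            for (f in pool) {
                ft <- .fitOn(Z[tr, , drop = FALSE], ytr, c(selected, f),
                             modelKind, control)
                tc <- suppressWarnings(
                    scoreCorrelation(.predictOnZ(ft, Z[tr, , drop = FALSE],
                                                 c(selected, f)),
                                     ytr, control$scoreMethod))
                if (is.finite(tc) && tc > bestCor + 1e-10) {
                    bestCor <- tc; cand <- f; fit <- ft
                }
            }
            if (is.null(cand)) break
        }
        testCor <- suppressWarnings(
            scoreCorrelation(.predictOnZ(fit, Z[te, , drop = FALSE],
                                         c(selected, cand)),
                             yte, control$scoreMethod))
        if (length(selected) >= 1 &&
            (!is.finite(testCor) || testCor <= prevTest + control$eps)) break
        selected <- c(selected, cand)
        alive <- setdiff(alive, cand)
        prevTest <- if (is.finite(testCor)) testCor else prevTest
        finalFit <- fit
    }
    if (length(selected) == 0) {       # degenerate: keep the single best
        selected <- alive[1]
        finalFit <- .fitOn(Z[tr, , drop = FALSE], ytr, selected, modelKind,
                           control)
    }
    model <- list(features = selected, fit = finalFit,
                  center = center[selected], scale = scale[selected])
    # re-anchor standardization to the selected columns only
    model$fit <- .fitOn(Z[tr, , drop = FALSE], ytr, selected, modelKind,
                        control)
    corrs <- vapply(list(train = tr, test = te, validation = va),
                    function(idx) suppressWarnings(scoreCorrelation(
                        .predictOnZ(model$fit, Z[idx, , drop = FALSE],
                                    selected),
                        y[idx], control$scoreMethod)), 0)
    new("Predictor", target = "", scope = "", scheme = "",
        modelKind = modelKind, features = selected,
        model = model, correlations = corrs,
        replicate = as.integer(split$replicate %||% NA_integer_))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a jackknife family of predictors
#'
#' Runs \code{\link{greedySelect}} on each random tercile split. Under
#' scheme B the adaptation weights and START-context PSSM are re-inferred
#' inside every replicate from that replicate's train tercile only (the
#' optimizer is handed train-set rows exclusively), and the tunable feature
#' columns are recomputed before selection. The median predictor is the
#' family member with the median validation correlation; prevalence counts,
#' per feature, in how many members it was selected.
#'
#' @param features FeatureSet (scheme A extraction; its cache drives the
#'   scheme-B recomputation)
#' @param expression data.frame with gene_id and the target columns
#' @param target one of "mrna", "pa", "rd", "ppr", "rl"
#' @param scope "UTR5", "ORF", "UTR3" or "TRANSCRIPT" (= all features)
#' @param scheme "A" or "B"
#' @param modelKind "linear" or "mars"
#' @param nReplicates family size (default 100)
#' @param seed root seed for the splits
#' @param control see \code{\link{familyControl}}
#' @return a \code{PredictorFamily}
#' @export
buildFamily <- function(features, expression, target = "pa",
                        scope = "TRANSCRIPT", scheme = c("A", "B"),
                        modelKind = c("linear", "mars"), nReplicates = 100L,
                        seed = 1L, control = familyControl()) {
    scheme <- match.arg(scheme); modelKind <- match.arg(modelKind)
    j <- joinFeaturesExpression(features, expression)
    expr <- j$expression
    yraw <- expr[[target]]
    y <- if (control$logTarget) {
        v <- ifelse(!is.na(yraw) & yraw > 0, log(yraw), NA)
        if (any(!is.na(yraw) & yraw <= 0))
            warning("non-positive ", target, " values set to NA before log")
        v
    } else yraw
    names(y) <- expr$gene_id
    cat <- catalogue(features)
    keep <- if (scope == "TRANSCRIPT") cat$name
            else cat$name[cat$scope == scope]
    if (!length(keep)) stop("no features in scope ", scope)
    splits <- makeSplits(expr$gene_id, nReplicates, seed)
    fsWork <- features
    preds <- vector("list", nReplicates)
    for (r in seq_len(nReplicates)) {
        sp <- splits[[r]]
        Xr <- j$features
        if (scheme == "B") {
            fsB <- tryCatch(
                .schemeBReplicate(features, expr, sp$train, control),
                error = function(e) stop("scheme-B replicate ", r,
                                         " failed: ", conditionMessage(e)))
            Xr <- featureMatrix(fsB)[rownames(Xr), , drop = FALSE]
        }
        preds[[r]] <- tryCatch(
            greedySelect(Xr[, keep, drop = FALSE], y, sp, modelKind, control),
            error = function(e) stop("replicate ", r, " failed: ",
                                     conditionMessage(e)))
        preds[[r]]@target <- target; preds[[r]]@scope <- scope
        preds[[r]]@scheme <- scheme
    }
    sel <- lapply(preds, selectedFeatures)
    prev <- table(unlist(sel))
    prevalence <- setNames(as.integer(prev), names(prev))
    val <- vapply(preds, function(p) p@correlations[["validation"]], 0)
    ordv <- order(ifelse(is.finite(val), val, -Inf), seq_along(val))
    medianIndex <- ordv[floor((length(val) + 1) / 2)]
    new("PredictorFamily", predictors = preds, target = target,
        scope = scope, scheme = scheme, modelKind = modelKind,
        prevalence = prevalence, medianIndex = as.integer(medianIndex),
        seed = as.integer(seed))
}

# scheme-B parameter inference from one replicate's train tercile
.schemeBReplicate <- function(features, expr, trainIds, control) {
    cache <- features@cache
    stopifnot(length(cache) > 0)
    # leakage guard: the optimizer only ever sees train-set rows
    trainIds <- intersect(trainIds, rownames(featureMatrix(features)))
    mrna <- setNames(expr$mrna, expr$gene_id)[trainIds]
    ok <- is.finite(mrna) & mrna > 0
    trainIds <- trainIds[ok]; mrna <- mrna[ok]
    cnt <- cache$codonCounts[trainIds, , drop = FALSE]
    taiB <- schemeBOptimize(cache$taiA, cnt, mrna, cache$trnaCopies,
                            maxSweeps = control$schemeBMaxSweeps)
    caiW <- caiWeights(cache$orfs[trainIds[order(-mrna, trainIds)][
        seq_len(max(10, round(cache$config$topFraction * length(trainIds))))]])
    if (control$schemeBOptimizeCai)
        caiW <- schemeBOptimize(caiW, cnt, mrna,
                                maxSweeps = min(3L, control$schemeBMaxSweeps))
    top <- trainIds[order(-mrna, trainIds)]
    top <- top[seq_len(max(10, round(cache$config$topFraction * length(top))))]
    tsIds <- names(cache$orfs)
    pssm <- .pssmFromCache(cache, top)
    updateTunableFeatures(features, taiB, caiW, pssm,
                          retuneTasep = control$schemeBTasep)
}

# rebuild the context PSSM from cached windows (training subset only)
.pssmFromCache <- function(cache, trainingIds, pseudocount = 1) {
    up <- cache$config$contextUp; down <- cache$config$contextDown
    npos <- up + down
    counts <- matrix(pseudocount, npos, 4,
                     dimnames = list(NULL, c("A", "C", "G", "T")))
    for (g in trainingIds) {
        ch <- cache$contextCache[[g]]$main
        for (p in seq_len(npos))
            if (!is.na(ch[p])) counts[p, ch[p]] <- counts[p, ch[p]] + 1
    }
    freq <- counts / rowSums(counts)
    bg <- colSums(counts); bg <- bg / sum(bg)
    list(logodds = log(sweep(freq, 2, bg, "/")), freq = freq,
         background = bg, up = up, down = down)
}

#' Score a fitted predictor on new data
#'
#' @param predictor a \code{Predictor}
#' @param X raw feature matrix
#' @param y target values (log-transform beforehand if the predictor was
#'   fitted on the log scale)
#' @param method correlation type
#' @return correlation (NA with a warning for degenerate cases)
#' @export
scorePredictor <- function(predictor, X, y, method = c("pearson", "spearman")) {
    scoreCorrelation(predictModel(predictor@model, X), y, match.arg(method))
}
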