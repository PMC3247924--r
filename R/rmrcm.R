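## Core method: per-column elastic-net multinomial regression over the
## indicator expansion of all other columns, and projection of the
## coefficient paths onto a symmetric link matrix.

#' Multinomial log-likelihood in the symmetric (softmax) parameterization
#'
#' Computes `sum_obs [ eta_y - log sum_c exp(eta_c) ]` with
#' `eta_c = intercept_c + x . beta_c`. The value is invariant to adding a
#' constant to all class linear predictors.
#'
#' @param y integer responses in `1..nrow(beta)`.
#' @param X predictor matrix (dense or sparse), observations in rows.
#' @param beta coefficient matrix, one row per class.
#' @param intercepts one intercept per class.
#' @return The log-likelihood (scalar).
#' @examples
#' X <- matrix(0, 5, 2)
#' multinomialLogLik(rep(1L, 5), X, matrix(0, 21, 2), rep(0, 21))
#' 5 * log(1 / 21)
#' @export
multinomialLogLik <- function(y, X, beta, intercepts) {
  if (!all(is.finite(as.matrix(beta))) || !all(is.finite(intercepts)))
    stop("non-finite coefficients")
  nclass <- nrow(beta)
  stopifnot(length(intercepts) == nclass, all(y >= 1L), all(y <= nclass))
  eta <- as.matrix(X %*% Matrix::t(beta))
  eta <- sweep(eta, 2L, intercepts, "+")
  mx <- apply(eta, 1L, max)
  lse <- mx + log(rowSums(exp(eta - mx)))
  sum(eta[cbind(seq_along(y), y)] - lse)
}

#' Elastic-net penalty of a coefficient table
#'
#' `sum_j (1 - alpha) * beta_j^2 / 2 + alpha * |beta_j|` over all
#' non-intercept coefficients: the lasso penalty at `alpha = 1`, the ridge
#' penalty at `alpha = 0`.
#'
#' @param beta numeric vector or matrix of coefficients.
#' @param alpha mixing parameter in `[0, 1]`.
#' @return The penalty value (scalar).
#' @examples
#' elasticNetPenalty(c(1, -2), 1)   # 3
#' @export
elasticNetPenalty <- function(beta, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  b <- as.numeric(as.matrix(beta))
  sum((1 - alpha) * 0.5 * b^2 + alpha * abs(b))
}

# default smallest-lambda ratio: 1% of lambda_max. Alignments put far more
# indicator predictors than sequences into each fit, where 0.01 is also the
# path solver's own default; extending the path to 1e-4 in the rare n > p
# toy cases only adds saturated, poorly determined fits whose coefficient
# sums destabilize path-based link scores.
.lambdaMinRatio <- function(config, n, p) {
  if (!is.na(config@lambdaMinRatio)) return(config@lambdaMinRatio)
  0.01
}

#' Fit the elastic-net multinomial path for one response column
#'
#' The response column (integer codes 1..21) is regressed on the supplied
#' indicator predictors along a log-spaced path of `nLambda` penalty values
#' from `lambda_max` (the smallest penalty with an all-zero solution)
#' downward. Intercepts are never penalized. Classes absent from the
#' response carry no parameters. A constant response yields a degenerate
#' all-zero path flagged in the result. The path is solved by coordinate
#' descent (glmnet) under the objective
#' `(1/n) * negative log-likelihood + lambda * P_alpha(beta)`.
#'
#' Response classes seen fewer than twice cannot be fitted by the
#' coordinate-descent solver; their observations are excluded from the fit
#' (and from the path's log-likelihood), and such classes carry zero
#' coefficients like any class absent from the response.
#'
#' @param y integer response vector with values in 1..21.
#' @param X sparse indicator predictor matrix (the response column's own
#'   indicators, and any masked columns, must already be excluded).
#' @param config a [FitConfig-class].
#' @param responseColumn index of the response column (bookkeeping).
#' @param predictorColumns original column index of each column of `X`.
#' @return A [CoefficientPath-class].
#' @export
fitColumnPath <- function(y, X, config = fitConfig(),
                          responseColumn = NA_integer_,
                          predictorColumns = integer()) {
  stopifnot(length(y) == nrow(X))
  if (!length(predictorColumns)) predictorColumns <- rep(NA_integer_, ncol(X))
  y <- as.integer(y)
  cnt <- tabulate(y, .NSTATE)
  keepRows <- cnt[y] >= 2L
  y <- y[keepRows]
  X <- X[keepRows, , drop = FALSE]
  obs <- sort(unique(y))
  n <- length(y)
  if (length(obs) <= 1L) {
    return(new("CoefficientPath", responseColumn = as.integer(responseColumn),
               lambdas = Inf, beta = list(), intercepts = matrix(0, 1L, 1L),
               obsClasses = obs, loglik = 0, nNonzero = 0L,
               predictorColumns = as.integer(predictorColumns),
               nObs = n, degenerate = TRUE))
  }
  yf <- factor(y, levels = obs)
  fit <- withCallingHandlers(
    glmnet::glmnet(X, yf, family = "multinomial",
                   alpha = config@alpha,
                   nlambda = config@nLambda,
                   lambda.min.ratio = .lambdaMinRatio(config, n, ncol(X)),
                   standardize = config@standardize,
                   type.multinomial = "ungrouped"),
    warning = function(w) {
      if (grepl("fewer than 8\\s+observations", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  nl <- length(fit$lambda)
  a0 <- fit$a0
  if (is.null(dim(a0))) a0 <- matrix(a0, nrow = length(obs))
  beta <- unname(fit$beta)
  nNonzero <- Reduce(`+`, lapply(beta, function(b) Matrix::colSums(b != 0)))
  # log-likelihood at each path entry, over the observed class space
  yIdx <- match(as.integer(y), obs)
  etaC <- lapply(beta, function(b) as.matrix(X %*% b))
  loglik <- vapply(seq_len(nl), function(l) {
    eta <- vapply(seq_along(obs), function(c) etaC[[c]][, l] + a0[c, l],
                  numeric(n))
    mx <- eta[cbind(seq_len(n), max.col(eta, ties.method = "first"))]
    lse <- mx + log(rowSums(exp(eta - mx)))
    sum(eta[cbind(seq_len(n), yIdx)] - lse)
  }, numeric(1))
  new("CoefficientPath", responseColumn = as.integer(responseColumn),
      lambdas = fit$lambda, beta = beta, intercepts = a0,
      obsClasses = obs, loglik = loglik,
      nNonzero = as.integer(nNonzero),
      predictorColumns = as.integer(predictorColumns),
      nObs = n, degenerate = FALSE)
}

#' Expand one path entry to the full 21-row coefficient table
#'
#' @param path a [CoefficientPath-class].
#' @param index position on the lambda path.
#' @return Sparse 21 x nPredictor coefficient matrix (rows of classes not
#'   observed in the response are zero).
#' @export
pathCoefficients <- function(path, index) {
  p <- length(path@predictorColumns)
  out <- Matrix::Matrix(0, .NSTATE, p, sparse = TRUE)
  if (path@degenerate) return(out)
  stopifnot(index >= 1L, index <= length(path@lambdas))
  for (c in seq_along(path@obsClasses))
    out[path@obsClasses[c], ] <- path@beta[[c]][, index]
  out
}

#' Select the minimum-BIC entry of a coefficient path
#'
#' `BIC = -2 * loglik + k * ln(n)` where `k` counts nonzero non-intercept
#' coefficients and `n` is the number of sequences. Ties are broken toward
#' the larger lambda (sparser model).
#'
#' @param path a [CoefficientPath-class].
#' @param n number of observations; defaults to the fit's own.
#' @return List with `index`, `lambda`, `bic` (full vector),
#'   `coefficients` (21 x nPredictor, zeros for unobserved classes),
#'   `intercepts` (length 21, zeros for unobserved classes) and
#'   `obsClasses`.
#' @export
bicSelect <- function(path, n = path@nObs) {
  stopifnot(is(path, "CoefficientPath"))
  bic <- -2 * path@loglik + path@nNonzero * log(n)
  idx <- which.min(bic)   # lambdas decrease, so the first minimum is sparsest
  ints <- numeric(.NSTATE)
  if (!path@degenerate)
    ints[path@obsClasses] <- path@intercepts[, idx]
  list(index = idx,
       lambda = path@lambdas[idx],
       bic = bic,
       coefficients = pathCoefficients(path, idx),
       intercepts = ints,
       obsClasses = path@obsClasses)
}

# per-lambda link scores grouped by original predictor column:
# entry [j, l] = sum over classes and over column j's indicators of |beta|
.groupScores <- function(path) {
  absSum <- Reduce(`+`, lapply(path@beta, abs))
  g <- rowsum(as.matrix(absSum), group = path@predictorColumns)
  rownames(g) <- rownames(g)  # original column indices as names
  g
}

#' Project a coefficient path onto per-column link scores
#'
#' For every predictor column `j`, the link score towards `j` aggregates
#' the absolute coefficients of `j`'s 21 indicators over all response
#' classes: at the BIC-selected path entry (`mode = "bic"`), summed over
#' the whole path (`"path_sum"`), or as the number of path entries in which
#' `j` carries any nonzero coefficient (`"model_count"`).
#'
#' @param path a [CoefficientPath-class].
#' @param mode `"bic"`, `"path_sum"` or `"model_count"`.
#' @return Named numeric vector of nonnegative scores, one entry per
#'   distinct predictor column.
#' @export
projectLinks <- function(path, mode = c("path_sum", "bic", "model_count")) {
  mode <- match.arg(mode)
  cols <- sort(unique(path@predictorColumns))
  if (path@degenerate)
    return(setNames(numeric(length(cols)), cols))
  g <- .groupScores(path)
  out <- switch(mode,
    bic = g[, bicSelect(path)$index],
    path_sum = rowSums(g),
    model_count = rowSums(g > 0)
  )
  setNames(as.numeric(out), rownames(g))
}

#' Correlated-mutation link matrix by regularized multinomial regression
#'
#' Every alignment column in turn is used as the response and regressed on
#' the indicator expansion of all other columns (or, with
#' `maskMode = "intermolecular"` in `config`, only the partner molecule's
#' columns); the per-column scores from [projectLinks()] are assembled into
#' an asymmetric table which is then symmetrized by averaging the two
#' directions, with a zero diagonal. Fully conserved response columns are
#' skipped and contribute zero outgoing scores. The alignment should be
#' gap-filtered first (see [filterGapColumns()]).
#'
#' @param aln a [ProteinMSA-class] with at least 2 columns.
#' @param config a [FitConfig-class].
#' @param mode link scoring mode, see [projectLinks()].
#' @param verbose print per-column progress to stderr.
#' @return A [LinkMatrix-class].
#' @examples
#' m <- buildPotentials(generateNetwork(6, 0.5, seed = 1), 0.3, 0.3, seed = 2)
#' aln <- gibbsSample(m, 2000, 10, 100, seed = 3)
#' rmrcm(aln, fitConfig(nLambda = 20))
#' @export
rmrcm <- function(aln, config = fitConfig(),
                  mode = c("path_sum", "bic", "model_count"),
                  verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is(aln, "ProteinMSA"))
  p <- ncol(aln@chars)
  if (p < 2L) stop("need at least 2 columns")
  if (config@maskMode == "intermolecular" && !length(aln@moleculeLabels))
    stop("maskMode 'intermolecular' requires moleculeLabels")
  enc <- encodeAlignment(aln)
  S <- matrix(0, p, p)
  for (i in seq_len(p)) {
    predCols <- if (config@maskMode == "intermolecular")
      which(aln@moleculeLabels != aln@moleculeLabels[i])
    else setdiff(seq_len(p), i)
    if (!length(predCols)) next
    t0 <- proc.time()[["elapsed"]]
    xIdx <- unlist(enc@columnMap[predCols])
    path <- fitColumnPath(enc@A[, i], enc@M[, xIdx, drop = FALSE], config,
                          responseColumn = i,
                          predictorColumns = rep(predCols, each = .NSTATE))
    s <- projectLinks(path, mode)
    S[i, as.integer(names(s))] <- s
    if (verbose)
      message(sprintf("column %d/%d: %s in %.2fs", i, p,
                      if (path@degenerate) "conserved, skipped" else
                        sprintf("%d lambdas", length(path@lambdas)),
                      proc.time()[["elapsed"]] - t0))
  }
  sym <- (S + t(S)) / 2
  diag(sym) <- 0
  new("LinkMatrix", scores = sym, scoringMode = mode,
      columnLabels = enc@columnLabels)
}

#' Write a link matrix as a sorted TSV table
#'
#' @param links a [LinkMatrix-class].
#' @param path output path; columns `col_i`, `col_j` (original 1-based
#'   numbers), `score`, `scoring_mode`, sorted by descending score.
#' @return `path`, invisibly.
#' @export
writeLinkTSV <- function(links, path) {
  s <- links@scores
  ut <- which(upper.tri(s), arr.ind = TRUE)
  d <- data.frame(col_i = links@columnLabels[ut[, 1L]],
                  col_j = links@columnLabels[ut[, 2L]],
                  score = s[ut],
                  scoring_mode = links@scoringMode)
  d <- d[order(-d$score, d$col_i, d$col_j), ]
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a link table written by [writeLinkTSV()]
#'
#' @param path TSV path.
#' @return A [LinkMatrix-class].
#' @export
readLinkTSV <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t")
  labs <- sort(unique(c(d$col_i, d$col_j)))
  p <- length(labs)
  s <- matrix(0, p, p)
  i <- match(d$col_i, labs); j <- match(d$col_j, labs)
  s[cbind(i, j)] <- d$score
  s[cbind(j, i)] <- d$score
  new("LinkMatrix", scores = s,
      scoringMode = as.character(d$scoring_mode[1L]),
      columnLabels = as.integer(labs))
}
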