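## Interaction scoring: per-column BIC-selected models applied to candidate
## molecule-pair sequences (PDZ-peptide style cross-species prediction).

#' Fit an interaction model on a two-molecule alignment
#'
#' Each (gap-filtered) column's elastic-net path is fitted with the
#' predictor mask implied by `maskMode` and the minimum-BIC entry is
#' stored. `"intermolecular_only"` restricts a column's predictors to the
#' partner molecule; `"inter_and_intra"` uses every other column.
#'
#' @param aln a [ProteinMSA-class] with `moleculeLabels` set.
#' @param config a [FitConfig-class]; its own `maskMode` is ignored in
#'   favor of `maskMode`.
#' @param maskMode `"inter_and_intra"` (default) or `"intermolecular_only"`.
#' @param pseudocount additive class-probability floor used when scoring
#'   (default 1/210); probabilities are renormalized after adding it.
#' @param verbose print per-column progress.
#' @return An [InteractionModel-class].
#' @export
fitInteractionModel <- function(aln, config = fitConfig(),
                                maskMode = c("inter_and_intra",
                                             "intermolecular_only"),
                                pseudocount = 1 / 210, verbose = FALSE) {
  maskMode <- match.arg(maskMode)
  stopifnot(is(aln, "ProteinMSA"))
  if (!length(aln@moleculeLabels))
    stop("interaction models need moleculeLabels on the alignment")
  enc <- encodeAlignment(aln)
  p <- ncol(enc@A)
  mol <- aln@moleculeLabels
  fits <- vector("list", p)
  for (i in seq_len(p)) {
    predCols <- if (maskMode == "intermolecular_only")
      which(mol != mol[i]) else setdiff(seq_len(p), i)
    if (!length(predCols)) {
      fits[[i]] <- list(degenerate = TRUE)
      next
    }
    xIdx <- unlist(enc@columnMap[predCols])
    path <- fitColumnPath(enc@A[, i], enc@M[, xIdx, drop = FALSE], config,
                          responseColumn = i,
                          predictorColumns = rep(predCols, each = .NSTATE))
    if (path@degenerate) {
      fits[[i]] <- list(degenerate = TRUE,
                        obsClasses = path@obsClasses)
      next
    }
    sel <- bicSelect(path)
    obs <- path@obsClasses
    betaObs <- do.call(rbind, lapply(seq_along(obs), function(c)
      path@beta[[c]][, sel$index]))
    fits[[i]] <- list(degenerate = FALSE,
                      beta = Matrix::Matrix(betaObs, sparse = TRUE),
                      intercepts = path@intercepts[, sel$index],
                      obsClasses = obs,
                      predictorIndicators = xIdx,
                      lambda = sel$lambda,
                      bic = sel$bic[sel$index])
    if (verbose)
      message(sprintf("column %d/%d: lambda %.4g, %d classes", i, p,
                      sel$lambda, length(obs)))
  }
  new("InteractionModel", fits = fits, maskMode = maskMode,
      aaOrder = enc@aaOrder, columnLabels = enc@columnLabels,
      moleculeLabels = mol, pseudocount = pseudocount)
}

# one-hot indicator vector (length 21 * nCol) for a single aligned sequence
.encodeCandidate <- function(chars, aaOrder) {
  code <- match(toupper(chars), aaOrder)
  code[is.na(code)] <- .GAP
  x <- numeric(.NSTATE * length(code))
  x[code + (seq_along(code) - 1L) * .NSTATE] <- 1
  list(code = code, x = x)
}

#' Log-likelihood score of an aligned candidate sequence pair
#'
#' Sums over columns the log of the model probability of the observed
#' character given the candidate's other columns. Class probabilities come
#' from the stored BIC-selected multinomial fit (softmax over the classes
#' observed in training; unobserved classes have probability 0), then each
#' of the 21 class probabilities receives the additive pseudocount and the
#' vector is renormalized, which keeps every score finite.
#'
#' @param model an [InteractionModel-class].
#' @param pairedSeq a character vector of single characters, or a single
#'   string, aligned to the model's columns (both molecules concatenated).
#' @return Summed log-likelihood (scalar).
#' @export
loglikScore <- function(model, pairedSeq) {
  stopifnot(is(model, "InteractionModel"))
  if (length(pairedSeq) == 1L && nchar(pairedSeq) > 1L)
    pairedSeq <- strsplit(pairedSeq, "")[[1L]]
  p <- length(model@fits)
  if (length(pairedSeq) != p)
    stop("candidate has ", length(pairedSeq), " columns; model expects ", p)
  encd <- .encodeCandidate(pairedSeq, model@aaOrder)
  pc <- model@pseudocount
  norm <- 1 + .NSTATE * pc
  total <- 0
  for (i in seq_len(p)) {
    f <- model@fits[[i]]
    prob21 <- numeric(.NSTATE)
    if (isTRUE(f$degenerate)) {
      if (!is.null(f$obsClasses)) prob21[f$obsClasses] <- 1
      else prob21[] <- 1 / .NSTATE
    } else {
      eta <- as.numeric(f$beta %*% encd$x[f$predictorIndicators]) +
        f$intercepts
      eta <- eta - max(eta)
      prob21[f$obsClasses] <- exp(eta) / sum(exp(eta))
    }
    total <- total + log((prob21[encd$code[i]] + pc) / norm)
  }
  total
}

#' Rank candidate pairs by model log-likelihood
#'
#' @param model an [InteractionModel-class].
#' @param candidates list (or character vector) of aligned candidate
#'   sequences; names become candidate ids.
#' @param labels optional binary vector (1 = interacting); when given, the
#'   ranking AUC is computed with the same rank-sum convention as
#'   [aucLinks()].
#' @return Data frame sorted by descending score with columns `id`,
#'   `score`, `rank` (and `label`); the AUC, when computed, is attached as
#'   attribute `"auc"`.
#' @export
rankInteractions <- function(model, candidates, labels = NULL) {
  if (is.character(candidates)) candidates <- as.list(candidates)
  stopifnot(length(candidates) >= 1L)
  ids <- names(candidates)
  if (is.null(ids)) ids <- paste0("cand", seq_along(candidates))
  sc <- vapply(candidates, function(s) loglikScore(model, s), numeric(1))
  ord <- order(-sc)   # ties keep input order (stable)
  out <- data.frame(id = ids[ord], score = sc[ord],
                    rank = seq_along(ord))
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(candidates))
    out$label <- labels[ord]
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    if (n1 > 0 && n0 > 0) {
      r <- rank(sc)
      attr(out, "auc") <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) /
        (n1 * n0)
    }
  }
  out
}

#' Serialize an interaction model to a portable JSON archive
#'
#' @param model an [InteractionModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeInteractionModel <- function(model, path) {
  fits <- lapply(model@fits, function(f) {
    if (isTRUE(f$degenerate))
      return(list(degenerate = TRUE,
                  obsClasses = as.integer(f$obsClasses)))
    nz <- which(f$beta != 0, arr.ind = TRUE)
    list(degenerate = FALSE,
         obsClasses = as.integer(f$obsClasses),
         intercepts = as.numeric(f$intercepts),
         predictorIndicators = as.integer(f$predictorIndicators),
         lambda = f$lambda, bic = f$bic,
         betaRow = as.integer(nz[, 1L]), betaCol = as.integer(nz[, 2L]),
         betaVal = as.numeric(f$beta[nz]))
  })
  obj <- list(maskMode = model@maskMode, aaOrder = model@aaOrder,
              columnLabels = model@columnLabels,
              moleculeLabels = model@moleculeLabels,
              pseudocount = model@pseudocount, fits = fits)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an interaction model written by [writeInteractionModel()]
#'
#' @param path JSON path.
#' @return An [InteractionModel-class].
#' @export
readInteractionModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  int <- function(x) as.integer(unlist(x))
  fits <- lapply(obj$fits, function(f) {
    if (isTRUE(f$degenerate)) {
      out <- list(degenerate = TRUE)
      if (!is.null(f$obsClasses)) out$obsClasses <- int(f$obsClasses)
      return(out)
    }
    obs <- int(f$obsClasses)
    predIdx <- int(f$predictorIndicators)
    beta <- Matrix::sparseMatrix(i = int(f$betaRow), j = int(f$betaCol),
                                 x = num(f$betaVal),
                                 dims = c(length(obs), length(predIdx)))
    list(degenerate = FALSE, beta = beta, intercepts = num(f$intercepts),
         obsClasses = obs, predictorIndicators = predIdx,
         lambda = num(f$lambda), bic = num(f$bic))
  })
  new("InteractionModel", fits = fits, maskMode = obj$maskMode,
      aaOrder = unlist(obj$aaOrder),
      columnLabels = int(obj$columnLabels),
      moleculeLabels = int(obj$moleculeLabels),
      pseudocount = as.numeric(obj$pseudocount))
}
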