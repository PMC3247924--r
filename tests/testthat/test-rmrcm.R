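# small hand-built CoefficientPath for the projection / BIC unit tests:
# 2 predictor columns (42 indicator cols), 2 lambdas, 2 observed classes
miniPath <- function(b1, b2, loglik = c(-10, -8), nObs = 20L) {
  beta <- list(Matrix::Matrix(b1, sparse = TRUE),
               Matrix::Matrix(b2, sparse = TRUE))
  nnz <- as.integer(Matrix::colSums(beta[[1]] != 0) +
                      Matrix::colSums(beta[[2]] != 0))
  new("CoefficientPath", responseColumn = 3L,
      lambdas = c(0.5, 0.1), beta = beta,
      intercepts = matrix(0, 2L, 2L), obsClasses = c(2L, 5L),
      loglik = loglik, nNonzero = nnz,
      predictorColumns = rep(c(1L, 2L), each = 21L),
      nObs = as.integer(nObs), degenerate = FALSE)
}

test_that("multinomial log-likelihood matches its definition", {
  set.seed(11)
  X <- matrix(rbinom(5 * 4, 1, 0.5), 5, 4)
  # all-zero model: uniform softmax over 21 classes
  expect_equal(multinomialLogLik(rep(3L, 5), X, matrix(0, 21, 4), rep(0, 21)),
               5 * log(1 / 21))
  set.seed(1)
  beta <- matrix(rnorm(21 * 4, sd = 0.5), 21, 4)
  ints <- rnorm(21)
  y <- sample.int(21, 5, replace = TRUE)
  got <- multinomialLogLik(y, X, beta, ints)
  # shift invariance of the symmetric parameterization
  expect_equal(multinomialLogLik(y, X, beta, ints + 3.7), got)
  # direct per-observation recomputation
  ref <- sum(vapply(seq_len(5), function(s) {
    eta <- ints + as.numeric(beta %*% X[s, ])
    eta[y[s]] - log(sum(exp(eta)))
  }, numeric(1)))
  expect_equal(got, ref)
  expect_error(multinomialLogLik(y, X, beta * NA, ints), "non-finite")
})

test_that("elastic-net penalty evaluates the mixed L1/L2 form", {
  expect_equal(elasticNetPenalty(c(1, -2), 1), 3)
  expect_equal(elasticNetPenalty(c(2), 0), 2)
  expect_equal(elasticNetPenalty(c(1), 0.99), 0.99 + 0.01 * 0.5)
})

test_that("path starts all-zero at lambda_max and flags constant responses", {
  aln <- randomMSA(60, 4, seed = 101)
  enc <- encodeAlignment(aln)
  xIdx <- unlist(enc@columnMap[2:4])
  path <- fitColumnPath(enc@A[, 1L], enc@M[, xIdx], fitConfig(nLambda = 20),
                        responseColumn = 1L,
                        predictorColumns = rep(2:4, each = 21L))
  expect_false(path@degenerate)
  expect_equal(path@nNonzero[1L], 0L)
  expect_true(all(diff(path@lambdas) < 0))
  expect_equal(Matrix::nnzero(pathCoefficients(path, 1L)), 0L)
  # objective at every lambda is never worse than the intercept-only model
  n <- path@nObs
  for (l in c(1L, length(path@lambdas))) {
    obj <- -path@loglik[l] / n + path@lambdas[l] *
      elasticNetPenalty(pathCoefficients(path, l), 0.99)
    yk <- enc@A[, 1L]
    keep <- tabulate(yk, 21)[yk] >= 2
    y0 <- yk[keep]
    cnt <- table(y0)
    ll0 <- sum(cnt * log(cnt / sum(cnt)))  # intercept-only max likelihood
    expect_lte(obj, -ll0 / n + 1e-8)
  }
  const <- fitColumnPath(rep(4L, 60), enc@M[, xIdx], fitConfig(),
                         responseColumn = 1L,
                         predictorColumns = rep(2:4, each = 21L))
  expect_true(const@degenerate)
  expect_equal(projectLinks(const, "path_sum"),
               setNames(c(0, 0, 0), 2:4))
})

test_that("coordinate-descent fits match the proximal-gradient oracle", {
  set.seed(202)
  aln <- randomMSA(50, 5, seed = 202)
  # couple columns 1 and 2 so the fit has real signal
  aln@chars[, 2L] <- aln@chars[, 1L]
  flip <- sample.int(50, 15)
  aln@chars[flip, 2L] <- aaAlphabet()[sample.int(20, 15, replace = TRUE)]
  enc <- encodeAlignment(aln)
  xIdx <- unlist(enc@columnMap[2:5])
  X <- enc@M[, xIdx]
  y <- enc@A[, 1L]
  cfg <- fitConfig(nLambda = 12)
  path <- fitColumnPath(y, X, cfg, 1L, rep(2:5, each = 21L))
  keep <- tabulate(y, 21)[y] >= 2
  yk <- y[keep]; Xk <- X[keep, , drop = FALSE]
  yMap <- match(yk, path@obsClasses)
  for (l in c(3L, 7L, length(path@lambdas))) {
    lam <- path@lambdas[l]
    co <- pathCoefficients(path, l)[path@obsClasses, , drop = FALSE]
    ints <- path@intercepts[, l]
    objFit <- penalizedObjective(yMap, Xk, as.matrix(co), ints, lam, 0.99)
    oracle <- istaMultinomial(yMap, Xk, lam, 0.99,
                              nClass = length(path@obsClasses))
    expect_lt(abs(objFit - oracle$objective), 1e-3)
  }
})

test_that("BIC selection applies the formula and prefers sparser ties", {
  # loglik = -10, k = 3, n = e^2 -> BIC = 20 + 6 = 26
  b1 <- matrix(0, 42, 2); b1[3L, 1L] <- 1; b1[25L, 1L] <- -1
  b2 <- matrix(0, 42, 2); b2[10L, 1L] <- 2
  p <- miniPath(b1, b2, loglik = c(-10, -8), nObs = round(exp(2)))
  expect_equal((-2) * p@loglik[1L] + p@nNonzero[1L] * log(exp(2)), 26)
  sel <- bicSelect(p, n = exp(2))
  expect_equal(sel$bic[1L], 26)
  # k = 0, loglik = 0 -> BIC = 0
  z <- miniPath(matrix(0, 42, 2), matrix(0, 42, 2), loglik = c(0, 0))
  expect_equal(bicSelect(z, n = 50)$bic, c(0, 0))
  # equal BIC -> the larger-lambda (sparser, earlier) entry wins
  expect_equal(bicSelect(z, n = 50)$index, 1L)
})

test_that("link projection aggregates |beta| per predictor column", {
  zero <- miniPath(matrix(0, 42, 2), matrix(0, 42, 2))
  expect_equal(projectLinks(zero, "path_sum"), setNames(c(0, 0), 1:2))
  # single nonzero beta = -0.4 in column 2's block at lambda 1
  b1 <- matrix(0, 42, 2); b1[30L, 1L] <- -0.4
  p <- miniPath(b1, matrix(0, 42, 2), loglik = c(-5, -8))
  expect_equal(bicSelect(p, n = 20)$index, 1L)
  expect_equal(projectLinks(p, "bic"), setNames(c(0, 0.4), 1:2))
  # path_sum equals the sum of per-lambda projections
  b1[5L, 2L] <- 1.5; b2 <- matrix(0, 42, 2); b2[44L - 21L, 1L] <- 2
  p2 <- miniPath(b1, b2)
  perLambda <- sapply(1:2, function(l) {
    co <- pathCoefficients(p2, l)
    g <- rowsum(Matrix::colSums(abs(co)), rep(1:2, each = 21))
    as.numeric(g)
  })
  expect_equal(unname(projectLinks(p2, "path_sum")), rowSums(perLambda))
  expect_equal(unname(projectLinks(p2, "model_count")),
               rowSums(perLambda > 0))
})

test_that("rmrcm finds coupled columns and returns a symmetric map", {
  set.seed(301)
  aa <- aaAlphabet()
  base <- sample.int(4L, 200, replace = TRUE)     # 4-state driver
  # two-column alignment, col2 a deterministic relabeling of col1:
  # path-sum links them
  two <- ProteinMSA(cbind(aa[base], aa[base + 4L]))
  s2 <- scores(suppressWarnings(rmrcm(two, fitConfig(nLambda = 20))))
  expect_gt(s2[1L, 2L], 0)
  # with independent noise columns added, the BIC-selected map keeps the
  # coupled pair and drops the noise (path-sum magnitudes in this tiny
  # n >> p toy are dominated by the saturated small-lambda tail, so the
  # sparser BIC projection is the discriminating one here)
  chars <- cbind(aa[base], aa[base + 4L],
                 aa[sample.int(20, 200, TRUE)],
                 aa[sample.int(20, 200, TRUE)])
  aln <- ProteinMSA(chars)
  links <- suppressWarnings(rmrcm(aln, fitConfig(nLambda = 20), mode = "bic"))
  s <- scores(links)
  expect_equal(unname(s), unname(t(s)))
  expect_equal(unname(diag(s)), rep(0, 4))
  expect_gt(s[1L, 2L], 0)
  expect_gt(s[1L, 2L], max(s[1L, 3L], s[1L, 4L], s[3L, 4L]))
})

test_that("row permutation leaves links unchanged; column permutation permutes them", {
  aln <- randomMSA(80, 5, seed = 401)
  # correlate columns 3 and 5 without making them identical (exactly
  # duplicated predictor blocks leave the lasso split between them
  # underdetermined at the solver tolerance)
  set.seed(402)
  aln@chars[, 3L] <- aln@chars[, 5L]
  flip <- sample.int(80, 20)
  aln@chars[flip, 3L] <- aaAlphabet()[sample.int(20, 20, replace = TRUE)]
  cfg <- fitConfig(nLambda = 15)
  base <- scores(suppressWarnings(rmrcm(aln, cfg)))
  perm <- sample(seq_len(80))
  alnR <- ProteinMSA(aln@chars[perm, ])
  expect_equal(scores(suppressWarnings(rmrcm(alnR, cfg))), base,
               tolerance = 1e-6)
  cperm <- c(2L, 5L, 1L, 4L, 3L)
  alnC <- ProteinMSA(aln@chars[, cperm])
  got <- scores(suppressWarnings(rmrcm(alnC, cfg)))
  # each one-hot block sums to the intercept column, so every fit has a
  # near-flat penalty valley (ridge weight only (1-alpha) * lambda) along
  # which coordinate descent stops at a predictor-order-dependent point;
  # scores are equivariant up to that solver wobble, and the pair ranking
  # is preserved exactly here
  expect_equal(unname(got), unname(base[cperm, cperm]), tolerance = 0.1)
  utP <- upper.tri(got)
  expect_equal(which.max(got[utP]), which.max(base[cperm, cperm][utP]))
  expect_gt(cor(got[utP], base[cperm, cperm][utP]), 0.99)
})

test_that("uniform independent columns give zero median link under BIC", {
  aln <- randomMSA(150, 6, seed = 501)
  links <- suppressWarnings(rmrcm(aln, fitConfig(nLambda = 20), mode = "bic"))
  ut <- scores(links)[upper.tri(scores(links))]
  expect_equal(median(ut), 0)
})

test_that("link tables round-trip through the sorted TSV format", {
  aln <- randomMSA(40, 4, seed = 601)
  links <- miMatrix(aln)
  p <- tempfile(fileext = ".tsv")
  writeLinkTSV(links, p)
  d <- read.table(p, header = TRUE, sep = "\t")
  expect_equal(nrow(d), 6L)
  expect_true(all(diff(d$score) <= 0))
  back <- readLinkTSV(p)
  expect_equal(scores(back), scores(links), tolerance = 1e-12)
})
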