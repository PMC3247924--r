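## End-to-end simulation benchmark driver.

#' Derive a task seed from a master seed
#'
#' Deterministic counter scheme keeping every derived seed inside the
#' 32-bit integer range: task `k` of master seed `s` gets
#' `((s mod 100000) * 20011 + k * 7919) mod 2147483629 + 1`.
#'
#' @param master master seed (integer).
#' @param k task counter (nonnegative integer).
#' @return An integer seed.
#' @export
deriveSeed <- function(master, k) {
  as.integer((((as.double(master) %% 100000) * 20011 + k * 7919) %%
                2147483629) + 1)
}

#' Run the simulation benchmark factorial
#'
#' For every combination of density, node potential and edge potential,
#' and for each replicate: generate a network, build MRF potentials,
#' Gibbs-sample an alignment, and score it with each requested method
#' (corrected MI and/or the regression method), reporting AUC against the
#' true edge set. `scaleFactor` shrinks the experiment for quick runs:
#' nodes scale linearly, while sequences and the lambda grid are floored
#' at 60% and 40% of their full values so that the scaled fits retain
#' enough observations per predictor (`scaleFactor = 0.25` gives 50
#' nodes, 300 sequences and a 40-value lambda path).
#'
#' @param seed master seed; every task seed derives from it via
#'   [deriveSeed()].
#' @param nNodes nodes per network (columns per alignment).
#' @param densities vector of edge densities.
#' @param pPrefNode,pPrefEdge vectors of preference weights.
#' @param nSeq sequences per alignment.
#' @param thinning sweeps between recorded samples.
#' @param nIterations total Gibbs sweeps.
#' @param nLambda lambda path length for the regression method.
#' @param alpha elastic-net mixing parameter.
#' @param replicates replicate networks per condition.
#' @param methods subset of `c("mi", "rmrcm")`.
#' @param mode link scoring mode for the regression method.
#' @param scaleFactor proportional shrink of the experiment (see above).
#' @param verbose print progress.
#' @return Data frame with one row per (condition, replicate, method):
#'   the condition parameters, `auc` and `seconds`.
#' @examples
#' runBenchmark(seed = 1, nNodes = 12, nSeq = 60, nIterations = 2000,
#'              thinning = 10, nLambda = 10, replicates = 1,
#'              methods = "mi")
#' @export
runBenchmark <- function(seed, nNodes = 200L, densities = 0.25,
                         pPrefNode = 0.1, pPrefEdge = 0.3, nSeq = 500L,
                         thinning = 50L, nIterations = 100000L,
                         nLambda = 100L, alpha = 0.99, replicates = 3L,
                         methods = c("mi", "rmrcm"),
                         mode = "path_sum", scaleFactor = 1,
                         verbose = FALSE) {
  stopifnot(scaleFactor > 0, scaleFactor <= 1)
  methods <- match.arg(methods, c("mi", "rmrcm"), several.ok = TRUE)
  if (scaleFactor < 1) {
    nNodes <- max(10L, round(nNodes * scaleFactor))
    nSeq <- round(nSeq * max(scaleFactor, 0.6))
    nLambda <- max(10L, round(nLambda * max(scaleFactor, 0.4)))
  }
  grid <- expand.grid(density = densities, pPrefNode = pPrefNode,
                      pPrefEdge = pPrefEdge, replicate = seq_len(replicates))
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    density <- grid$density[g]
    pn <- grid$pPrefNode[g]; pe <- grid$pPrefEdge[g]
    rep_ <- grid$replicate[g]
    net <- generateNetwork(nNodes, density, seed = deriveSeed(seed, 3L * g))
    model <- buildPotentials(net, pn, pe, seed = deriveSeed(seed, 3L * g + 1L))
    aln <- gibbsSample(model, nIterations = nIterations, thinning = thinning,
                       nSamples = nSeq, seed = deriveSeed(seed, 3L * g + 2L))
    for (method in methods) {
      t0 <- proc.time()[["elapsed"]]
      links <- if (method == "mi") miMatrix(aln)
        else rmrcm(aln, fitConfig(alpha = alpha, nLambda = nLambda),
                   mode = mode)
      auc <- aucLinks(links, net)
      secs <- proc.time()[["elapsed"]] - t0
      if (verbose)
        message(sprintf(
          "density %.2f pn %.2f pe %.2f rep %d %s: AUC %.3f (%.1fs)",
          density, pn, pe, rep_, method, auc, secs))
      rows[[length(rows) + 1L]] <- data.frame(
        nNodes = nNodes, density = density, pPrefNode = pn, pPrefEdge = pe,
        nSeq = nSeq, thinning = thinning, replicate = rep_,
        method = method, auc = auc, seconds = secs)
    }
  }
  do.call(rbind, rows)
}
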