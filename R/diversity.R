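#' @include mockEval.R
NULL

.asCountMatrix <- function(x) {
  if (methods::is(x, "MilkExperiment")) counts(x) else as.matrix(x)
}

#' Per-sample relative abundances
#'
#' @param x count matrix (OTUs x samples) or
#'   [MilkExperiment][MilkExperiment-class].
#' @return matrix of proportions; columns sum to 1.
#' @export
relativeAbundance <- function(x) {
  m <- .asCountMatrix(x)
  tot <- colSums(m)
  if (any(tot == 0))
    stop("sample(s) with zero total count: ",
         paste(colnames(m)[tot == 0], collapse = ", "))
  sweep(m, 2, tot, "/")
}

#' Shannon-Weaver diversity index
#'
#' `H = -sum(p_i * log(p_i))` over taxa with positive counts, natural
#' logarithm, `p_i = count_i / total`. Invariant under rescaling of the
#' count vector by a positive constant; 0 for a single-taxon sample;
#' `log(k)` for a uniform community of `k` taxa.
#'
#' @param x non-negative count vector with at least one positive entry,
#'   or a count matrix / [MilkExperiment][MilkExperiment-class] (OTUs x
#'   samples) for per-sample values.
#' @return numeric scalar, or named vector (one value per sample).
#' @examples
#' shannonIndex(c(5, 3, 2))
#' @export
shannonIndex <- function(x) {
  if (is.matrix(x) || methods::is(x, "MilkExperiment")) {
    m <- .asCountMatrix(x)
    return(vapply(stats::setNames(colnames(m), colnames(m)),
                  function(s) shannonIndex(m[, s]), numeric(1)))
  }
  if (any(x < 0)) stop("counts must be non-negative")
  if (sum(x) == 0) stop("all-zero count vector")
  unname(vegan::diversity(x, index = "shannon"))
}

#' Bray-Curtis dissimilarity
#'
#' `BC(x, y) = sum(|x - y|) / sum(x + y)` on non-negative abundance
#' vectors: 0 for identical profiles, 1 for disjoint supports, symmetric
#' and bounded in \[0, 1\].
#'
#' @param x,y non-negative numeric vectors of equal length, not both
#'   all-zero.
#' @return dissimilarity in \[0, 1\].
#' @examples
#' brayCurtis(c(6, 2), c(2, 2))
#' @export
brayCurtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  if (sum(x) == 0 && sum(y) == 0) stop("both vectors are all-zero")
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

#' Bray-Curtis dissimilarity matrix across samples
#'
#' @param x count matrix (OTUs x samples) or
#'   [MilkExperiment][MilkExperiment-class].
#' @param relative compute on per-sample proportions (default `TRUE`),
#'   so unequal sequencing depths do not masquerade as composition
#'   differences.
#' @return a `dist` object labelled by sample id.
#' @export
brayCurtisMatrix <- function(x, relative = TRUE) {
  m <- .asCountMatrix(x)
  if (relative) m <- relativeAbundance(m)
  vegan::vegdist(t(m), method = "bray")
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering in which the distance between two clusters is
#' the maximum pairwise distance between their members, so merge heights
#' are non-decreasing along any root path. Input is validated as a proper
#' dissimilarity (symmetric, zero diagonal, non-negative).
#'
#' @param d a `dist` object or symmetric dissimilarity matrix, n >= 2.
#' @return an `hclust` object; write it as Newick with [writeNewick()].
#' @export
hclustComplete <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 2) stop("need at least 2 samples")
  if (any(abs(m - t(m)) > 1e-12)) stop("dissimilarity not symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("diagonal must be zero")
  if (any(m < 0)) stop("dissimilarities must be non-negative")
  stats::hclust(stats::as.dist(m), method = "complete")
}

#' Rarefy a count vector to fixed depth
#'
#' Subsampling without replacement (multivariate hypergeometric): the
#' output sums exactly to `depth` and each taxon's expectation is
#' `depth * count_i / total`.
#'
#' @param counts non-negative integer vector.
#' @param depth target depth, `<= sum(counts)`; samples shallower than
#'   the target cannot be rarefied and must be dropped upstream.
#' @param seed optional integer seed.
#' @return integer vector summing to `depth`.
#' @export
rarefyCounts <- function(counts, depth, seed = NULL) {
  if (any(counts < 0)) stop("counts must be non-negative")
  depth <- as.integer(depth)
  if (depth > sum(counts))
    stop("depth (", depth, ") exceeds sample total (", sum(counts), ")")
  .withSeed(seed, {
    # vegan warns when the smallest nonzero count exceeds 1 (a heuristic
    # for non-count data); irrelevant here, where inputs are validated
    out <- withCallingHandlers(
      as.integer(vegan::rrarefy(as.integer(counts), depth)),
      warning = function(w) {
        if (grepl("smallest count", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    names(out) <- names(counts)
    out
  })
}

#' Alpha-rarefaction curve of Shannon diversity
#'
#' Mean Shannon index over repeated rarefactions at each depth of an
#' ascending grid; samples shallower than a depth are excluded at that
#' depth. The depth at which the curve plateaus indicates the sequencing
#' effort beyond which no further diversity is discovered.
#'
#' @param x count matrix (OTUs x samples), vector, or
#'   [MilkExperiment][MilkExperiment-class].
#' @param depths ascending integer grid of rarefaction depths.
#' @param reps rarefaction replicates per depth (default 10).
#' @param seed optional integer seed.
#' @return `data.frame` with `depth`, `mean_shannon` and `n_samples`
#'   (samples deep enough to contribute).
#' @export
alphaRarefactionCurve <- function(x, depths, reps = 10, seed = NULL) {
  if (is.unsorted(depths)) stop("depths must be ascending")
  m <- if (is.matrix(x) || methods::is(x, "MilkExperiment"))
    .asCountMatrix(x) else matrix(x, ncol = 1,
                                  dimnames = list(names(x), "sample"))
  .withSeed(seed, {
    rows <- lapply(depths, function(d) {
      ok <- colSums(m) >= d
      if (!any(ok))
        return(data.frame(depth = d, mean_shannon = NA_real_,
                          n_samples = 0L))
      h <- vapply(which(ok), function(j) {
        mean(vapply(seq_len(reps), function(r)
          shannonIndex(rarefyCounts(m[, j], d)), numeric(1)))
      }, numeric(1))
      data.frame(depth = d, mean_shannon = mean(h),
                 n_samples = sum(ok))
    })
    do.call(rbind, rows)
  })
}

#' Compositional log-ratio biplot coordinates
#'
#' Rank-2 biplot of a count table treated as compositional data. Taxa
#' below an overall relative-abundance floor are dropped; zero counts are
#' handled by a Bayesian-multiplicative adjustment (Dirichlet posterior
#' expected proportions under a uniform prior of `priorStrength`
#' pseudo-counts per taxon, which shrinks nonzero proportions
#' proportionally); each sample is then centered log-ratio (clr)
#' transformed, the clr matrix is column-centered, and a singular value
#' decomposition supplies rank-2 sample coordinates (form biplot:
#' `U_2 D_2`) and taxon loadings (`V_2`). Lambda-scaling rescales the two
#' point sets so their total spreads are equal; the scalar is returned.
#'
#' @param x count matrix (OTUs x samples) or
#'   [MilkExperiment][MilkExperiment-class]; >= 2 samples.
#' @param priorStrength uniform Dirichlet prior pseudo-count per taxon
#'   (default 0.5, Jeffreys-like).
#' @param lambdaScale equalize sample/taxon spread (default `TRUE`).
#' @param minAbundance overall relative-abundance floor in percent
#'   (default 0.5); at least 2 taxa must survive.
#' @return a list with `samples` (n x 2), `taxa` (p x 2), `d` (singular
#'   values), `lambda`, and `retained` (taxon ids kept).
#' @export
logratioBiplot <- function(x, priorStrength = 0.5, lambdaScale = TRUE,
                           minAbundance = 0.5) {
  m <- .asCountMatrix(x)
  if (ncol(m) < 2) stop("need at least 2 samples")
  overall <- rowSums(m) / sum(m) * 100
  keep <- overall > minAbundance
  if (sum(keep) < 2)
    stop("fewer than 2 taxa retained at the ", minAbundance,
         "% abundance floor")
  m <- m[keep, , drop = FALSE]
  if (any(colSums(m > 0) < 2))
    stop("sample(s) left with fewer than 2 observed taxa after ",
         "filtering")
  K <- nrow(m)
  tot <- colSums(m)
  p <- sweep(m + priorStrength, 2, tot + priorStrength * K, "/")
  lp <- log(p)
  clr <- t(sweep(lp, 2, colMeans(lp), "-"))  # samples x taxa
  z <- sweep(clr, 2, colMeans(clr), "-")
  sv <- svd(z)
  F2 <- sv$u[, 1:2, drop = FALSE] %*% diag(sv$d[1:2], 2)
  G2 <- sv$v[, 1:2, drop = FALSE]
  lambda <- 1
  if (lambdaScale) {
    sprF <- sum(F2^2)
    sprG <- sum(G2^2)
    if (sprF > 0 && sprG > 0) lambda <- (sprG / sprF)^(1 / 4)
  }
  F2 <- F2 * lambda
  G2 <- G2 / lambda
  dimnames(F2) <- list(rownames(z), c("axis1", "axis2"))
  dimnames(G2) <- list(colnames(z), c("axis1", "axis2"))
  list(samples = F2, taxa = G2, d = sv$d, lambda = lambda,
       retained = rownames(m))
}
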