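#' @include decontam.R
NULL

#' Spike dominance from qPCR copy numbers
#'
#' Quantifies how completely a mock-community spike dominates the
#' endogenous background of a spiked sample, from median log10 16S
#' copy numbers: the log10 difference between spiked and un-spiked
#' medians, and the fraction of total 16S DNA contributed by the spike,
#' `1 - 10^(unspiked - spiked)`. A difference of 3 log10 corresponds to a
#' spike fraction of exactly 0.999; at 3.8 log10 the spike accounts for
#' more than 99.9% of the DNA and the endogenous contribution to the
#' spiked profile is negligible.
#'
#' @param spikedLog10 median log10 copies/uL of the spiked samples.
#' @param unspikedLog10 median log10 copies/uL of the un-spiked samples.
#' @return a list with `log10Difference` and `spikeFraction` (in
#'   \[0, 1\]). If `spikedLog10 < unspikedLog10` the fraction is clamped
#'   to 0 with a warning.
#' @examples
#' spikeDominance(5.7, 1.9)
#' @export
spikeDominance <- function(spikedLog10, unspikedLog10) {
  if (!is.finite(spikedLog10) || !is.finite(unspikedLog10))
    stop("log10 copy numbers must be finite")
  diff <- spikedLog10 - unspikedLog10
  frac <- 1 - 10^(-diff)
  if (diff < 0) {
    warning("spiked median below un-spiked median; spike fraction ",
            "clamped to 0")
    frac <- 0
  }
  list(log10Difference = diff, spikeFraction = frac)
}

#' Collapse OTU counts onto the mock community's taxa
#'
#' Sums OTU counts into the mock community's declared taxa by matching
#' each OTU's genus (then family) label against the mock taxon labels;
#' everything unmatched lands in an `"other"` bucket. Output is
#' normalized to percent per sample.
#'
#' @param x a [MilkExperiment][MilkExperiment-class] with lineage
#'   annotation, or a count matrix (then `taxonomy` is required).
#' @param mock a [MockProfile][MockProfile-class].
#' @param taxonomy named character vector of lineage strings for bare
#'   matrices.
#' @return numeric matrix, rows = mock taxa plus `"other"`, columns =
#'   samples, values in percent (columns sum to 100).
#' @export
collapseToMockTaxa <- function(x, mock = defaultMockProfile(),
                               taxonomy = NULL) {
  if (methods::is(x, "MilkExperiment")) {
    m <- counts(x)
    taxonomy <- otuLineage(x)
  } else {
    m <- as.matrix(x)
    if (is.null(taxonomy))
      stop("taxonomy is required when x is a bare matrix")
  }
  zero <- colSums(m) == 0
  if (any(zero))
    stop("sample(s) with zero total count: ",
         paste(colnames(m)[zero], collapse = ", "))
  active <- rownames(m)[rowSums(m) > 0]
  lin <- taxonomy[active]
  if (any(is.na(lin)))
    stop("taxonomy does not cover all OTUs with nonzero counts: ",
         paste(utils::head(active[is.na(lin)], 5), collapse = ", "))
  genus <- lineageRank(lin, "genus")
  family <- lineageRank(lin, "family")
  taxa <- mockTaxa(mock)
  bucket <- ifelse(genus %in% taxa, genus,
            ifelse(family %in% taxa, family, "other"))
  out <- matrix(0, nrow = length(taxa) + 1L, ncol = ncol(m),
                dimnames = list(c(taxa, "other"), colnames(m)))
  for (b in unique(bucket)) {
    rows <- active[bucket == b]
    out[b, ] <- colSums(m[rows, , drop = FALSE])
  }
  sweep(out, 2, colSums(out), "/") * 100
}

#' Concordance of observed profiles with the mock community
#'
#' For each sample of a collapsed profile matrix, computes the
#' Bray-Curtis dissimilarity between the observed and the theoretical
#' mock composition, per-taxon signed deviations (observed - expected,
#' percentage points) and an over/under/concordant call at a threshold.
#' A lower Bray-Curtis value means the extraction recovered a composition
#' closer to the declared standard.
#'
#' By default the `"other"` mass is dropped and the observed profile
#' renormalized over the mock taxa before comparison, so that the score
#' reflects recovered mock-community *structure*; set
#' `includeOther = TRUE` to penalize non-mock mass instead.
#'
#' @param observed percent matrix from [collapseToMockTaxa()] (mock taxa
#'   plus `"other"` as rows).
#' @param mock a [MockProfile][MockProfile-class].
#' @param meta optional metadata `data.frame` (adds `kit`, `milk`,
#'   `replicate` columns to the output).
#' @param callThreshold percentage points beyond which a taxon is called
#'   over-/under-represented (default 3).
#' @param includeOther keep the `"other"` bucket in the comparison
#'   (expected 0%).
#' @return a list with `summary` (one row per sample: `sample_id`,
#'   optional design columns, `bray_curtis`) and `deviations` (long
#'   `data.frame`: `sample_id`, `taxon`, `observed`, `expected`,
#'   `deviation`, `call`).
#' @export
mockConcordance <- function(observed, mock = defaultMockProfile(),
                            meta = NULL, callThreshold = 3,
                            includeOther = FALSE) {
  taxa <- mockTaxa(mock)
  expPct <- unname(mockAbundance(mock)) / sum(mockAbundance(mock)) * 100
  if (includeOther) {
    taxa <- c(taxa, "other")
    expPct <- c(expPct, 0)
  }
  summary <- list(); deviations <- list()
  for (s in colnames(observed)) {
    obs <- observed[taxa[taxa %in% rownames(observed)], s]
    obs <- obs[taxa]
    names(obs) <- taxa
    obs[is.na(obs)] <- 0
    if (!includeOther) {
      tot <- sum(obs)
      if (tot == 0) stop("sample ", s, " has no mock-taxon mass")
      obs <- obs / tot * 100
    }
    bc <- sum(abs(obs - expPct)) / sum(obs + expPct)
    dev <- obs - expPct
    call <- ifelse(dev > callThreshold, "over",
            ifelse(dev < -callThreshold, "under", "concordant"))
    summary[[s]] <- data.frame(sample_id = s, bray_curtis = bc)
    deviations[[s]] <- data.frame(sample_id = s, taxon = taxa,
                                  observed = unname(obs),
                                  expected = expPct,
                                  deviation = unname(dev),
                                  call = unname(call))
  }
  summary <- do.call(rbind, summary)
  deviations <- do.call(rbind, deviations)
  rownames(summary) <- rownames(deviations) <- NULL
  if (!is.null(meta)) {
    idx <- match(summary$sample_id, meta$sample_id)
    for (col in intersect(c("kit", "milk", "replicate"), colnames(meta)))
      summary[[col]] <- meta[[col]][idx]
    idx2 <- match(deviations$sample_id, meta$sample_id)
    for (col in intersect(c("kit", "milk"), colnames(meta)))
      deviations[[col]] <- meta[[col]][idx2]
  }
  list(summary = summary, deviations = deviations)
}

#' Gram-stratified extraction bias
#'
#' Averages the per-taxon deviations of a concordance report within the
#' Gram-negative and Gram-positive members of the mock community, per kit
#' (and milk type when available). A kit whose Gram-negative mean
#' deviation falls below `-threshold` percentage points is flagged as
#' under-representing Gram-negative organisms — the signature of
#' incomplete lysis chemistry differences between kits.
#'
#' @param concordance result of [mockConcordance()] run with `meta` so
#'   that deviations carry `kit` (and optionally `milk`).
#' @param mock a [MockProfile][MockProfile-class] with Gram flags.
#' @param threshold flag threshold in percentage points (default 3).
#' @return `data.frame` with one row per kit (x milk): mean signed
#'   deviation over Gram-negative and Gram-positive taxa and a logical
#'   `gram_negative_under` flag.
#' @export
gramBias <- function(concordance, mock = defaultMockProfile(),
                     threshold = 3) {
  dev <- concordance$deviations
  if (!"kit" %in% colnames(dev))
    stop("concordance deviations lack a kit column; pass meta to ",
         "mockConcordance()")
  g <- gramFlags(mock)
  if (all(is.na(g))) stop("mock profile has no gram flags")
  dev <- dev[dev$taxon %in% names(g)[!is.na(g)], ]
  dev$gram <- g[dev$taxon]
  keys <- intersect(c("kit", "milk"), colnames(dev))
  split_by <- interaction(dev[keys], drop = TRUE)
  rows <- lapply(split(dev, split_by), function(d) {
    out <- d[1, keys, drop = FALSE]
    out$gram_negative_mean <- mean(d$deviation[d$gram == "negative"])
    out$gram_positive_mean <- mean(d$deviation[d$gram == "positive"])
    out$gram_negative_under <- out$gram_negative_mean < -threshold
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
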