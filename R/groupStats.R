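#' @include diversity.R
NULL

.checkFactors <- function(groups, n) {
  if (is.factor(groups) || is.character(groups))
    groups <- list(group = groups)
  groups <- as.data.frame(groups, stringsAsFactors = TRUE)
  if (nrow(groups) != n)
    stop("groups must have one entry per observation")
  for (nm in colnames(groups)) {
    f <- factor(groups[[nm]])
    if (nlevels(f) < 2)
      stop("factor '", nm, "' has fewer than 2 levels")
    if (any(table(f) < 2))
      stop("factor '", nm, "' has level(s) with fewer than 2 ",
           "observations")
    groups[[nm]] <- f
  }
  groups
}

#' Type II analysis of variance
#'
#' Tests each factor of an additive layout (e.g. `yield ~ kit + milk`)
#' with Type II sums of squares: each factor is assessed after the other
#' main effects, which coincides with the sequential (Type I) analysis
#' when the design is balanced.
#'
#' @param values numeric response (one per observation), e.g. DNA yield,
#'   purity ratio, or Shannon diversity.
#' @param groups factor, or `data.frame`/list of factors (additive
#'   layout). Every level needs at least 2 observations.
#' @return `data.frame` with one row per factor: `factor`, `df`,
#'   `statistic` (F) and `p_value`.
#' @examples
#' anovaTypeII(rnorm(16), data.frame(kit = rep(c("A", "B"), 8),
#'                                   milk = rep(c("WM", "SM"), each = 8)))
#' @export
anovaTypeII <- function(values, groups) {
  values <- as.numeric(values)
  groups <- .checkFactors(groups, length(values))
  dat <- cbind(data.frame(.y = values), groups)
  fit <- stats::lm(.y ~ ., data = dat)
  a <- car::Anova(fit, type = "II")
  keep <- rownames(a) != "Residuals"
  data.frame(factor = rownames(a)[keep], df = a$Df[keep],
             statistic = a$`F value`[keep], p_value = a$`Pr(>F)`[keep],
             row.names = NULL)
}

#' Tukey honest significant differences
#'
#' Single-step multiple comparison of group means with simultaneous
#' (family-wise) confidence intervals from the studentized range
#' distribution.
#'
#' @param values numeric response.
#' @param groups a single grouping factor (>= 2 levels, >= 2 obs each).
#' @param familyConfidence family-wise confidence level (default 0.95).
#' @return `data.frame` with `comparison`, `diff`, `lwr`, `upr`,
#'   `p_adj`.
#' @export
tukeyHsd <- function(values, groups, familyConfidence = 0.95) {
  values <- as.numeric(values)
  groups <- .checkFactors(groups, length(values))
  if (ncol(groups) != 1) stop("tukeyHsd takes a single factor")
  dat <- data.frame(.y = values, .g = groups[[1]])
  hsd <- stats::TukeyHSD(stats::aov(.y ~ .g, data = dat),
                         conf.level = familyConfidence)$.g
  data.frame(comparison = rownames(hsd), diff = hsd[, "diff"],
             lwr = hsd[, "lwr"], upr = hsd[, "upr"],
             p_adj = hsd[, "p adj"], row.names = NULL)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment: `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1.
#' Adjusted values never fall below the raw p-values and preserve their
#' ordering.
#'
#' @param p vector of p-values in \[0, 1\] (`NA` allowed, passed
#'   through).
#' @return vector of adjusted q-values.
#' @examples
#' benjaminiHochberg(c(0.01, 0.02, 0.03))
#' @export
benjaminiHochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Collapse OTU counts to a taxonomy rank
#'
#' @param x count matrix (OTUs x samples) or
#'   [MilkExperiment][MilkExperiment-class] with lineage annotation.
#' @param rank taxonomy rank (see [lineageRank()]).
#' @param taxonomy named lineage vector for bare matrices.
#' @return count matrix, rows = labels at `rank` (OTUs without a label
#'   pooled under `"unassigned"`).
#' @export
collapseByRank <- function(x, rank = "genus", taxonomy = NULL) {
  if (methods::is(x, "MilkExperiment")) {
    m <- counts(x)
    taxonomy <- otuLineage(x)
  } else {
    m <- as.matrix(x)
    if (is.null(taxonomy))
      stop("taxonomy is required when x is a bare matrix")
  }
  lab <- lineageRank(taxonomy[rownames(m)], rank)
  lab[is.na(lab)] <- "unassigned"
  out <- rowsum(m, lab)
  out[order(rownames(out)), , drop = FALSE]
}

#' Per-taxon differential abundance across kits and milk types
#'
#' Fits an overdispersed count GLM per taxon,
#' `count ~ kit + milk + offset(log(librarySize))`, and tests each factor:
#' with `model = "quasi_poisson"` by an F test on the quasi-likelihood
#' fit, with `model = "negative_binomial"` by a likelihood-ratio test on
#' a [MASS::glm.nb()] fit. Raw p-values are Benjamini-Hochberg adjusted
#' across taxa separately per factor (the family is one taxonomy level x
#' one factor). Taxa observed in fewer than `prevalenceFloor` of the
#' samples are not tested — overdispersed GLMs are unstable on
#' near-all-zero taxa — and non-convergent fits are reported but excluded
#' from the adjustment family.
#'
#' @param x [MilkExperiment][MilkExperiment-class]; only
#'   `role = "sample"` columns are used when roles are present.
#' @param level taxonomy rank at which counts are collapsed.
#' @param model `"quasi_poisson"` (default) or `"negative_binomial"`;
#'   both absorb overdispersion, and the choice is recorded in the
#'   output.
#' @param prevalenceFloor minimum fraction of samples with a nonzero
#'   count (default 0.25).
#' @param factors design columns tested (default `c("kit", "milk")`).
#' @return `data.frame`, one row per taxon x factor: `taxon`, `level`,
#'   `model`, `factor`, `statistic`, `p_value`, `q_value`, `converged`,
#'   plus mean relative abundance (percent) per group level
#'   (`mean_<level>` columns).
#' @export
diffAbundance <- function(x, level = "genus",
                          model = c("quasi_poisson",
                                    "negative_binomial"),
                          prevalenceFloor = 0.25,
                          factors = c("kit", "milk")) {
  model <- match.arg(model)
  meta <- sampleMeta(x)
  if ("role" %in% colnames(meta)) {
    keep <- meta$role == "sample"
    meta <- meta[keep, ]
  }
  m <- collapseByRank(counts(x)[, meta$sample_id, drop = FALSE],
                      rank = level, taxonomy = otuLineage(x))
  miss <- setdiff(factors, colnames(meta))
  if (length(miss))
    stop("metadata lacks factor(s): ", paste(miss, collapse = ", "))
  design <- meta[factors]
  design[] <- lapply(design, factor)
  libSize <- colSums(m)
  prev <- rowMeans(m > 0)
  tested <- rownames(m)[prev >= prevalenceFloor]
  if (!length(tested)) stop("no taxon passes the prevalence floor")
  rel <- relativeAbundance(m) * 100

  fitOne <- function(taxon) {
    dat <- cbind(data.frame(.count = m[taxon, ], .off = log(libSize)),
                 design)
    form <- stats::as.formula(paste(
      ".count ~", paste(factors, collapse = " + "), "+ offset(.off)"))
    res <- lapply(factors, function(f)
      data.frame(taxon = taxon, level = level, model = model,
                 factor = f, statistic = NA_real_, p_value = NA_real_,
                 converged = FALSE))
    names(res) <- factors
    ok <- TRUE
    fit <- tryCatch({
      if (model == "quasi_poisson")
        stats::glm(form, family = stats::quasipoisson(), data = dat)
      else
        MASS::glm.nb(stats::as.formula(paste(
          ".count ~", paste(factors, collapse = " + "),
          "+ offset(.off)")), data = dat)
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || !isTRUE(fit$converged)) ok <- FALSE
    if (ok) {
      dr <- tryCatch(
        stats::drop1(fit, test = if (model == "quasi_poisson") "F"
                                 else "LRT"),
        error = function(e) NULL)
      if (is.null(dr)) ok <- FALSE
      else for (f in factors) {
        if (model == "quasi_poisson") {
          stat <- dr[f, "F value"]
          p <- dr[f, "Pr(>F)"]
          devChange <- dr[f, "Deviance"] - dr["<none>", "Deviance"]
          if (!is.finite(p) && isTRUE(abs(devChange) < 1e-10)) {
            # a saturated-dispersion-free fit: no evidence of any effect
            stat <- 0; p <- 1
          }
        } else {
          stat <- dr[f, "LRT"]
          p <- dr[f, "Pr(>Chi)"]
        }
        res[[f]]$statistic <- stat
        res[[f]]$p_value <- p
        res[[f]]$converged <- is.finite(p)
      }
    }
    do.call(rbind, res)
  }

  out <- do.call(rbind, lapply(tested, fitOne))
  out$q_value <- NA_real_
  for (f in factors) {
    idx <- out$factor == f & out$converged
    out$q_value[idx] <- benjaminiHochberg(out$p_value[idx])
  }
  for (f in factors) for (lev in levels(design[[f]])) {
    cols <- meta$sample_id[design[[f]] == lev]
    out[[paste0("mean_", lev)]] <-
      rowMeans(rel[out$taxon, cols, drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Repeatability of duplicate extractions
#'
#' `repeatabilityR2()` is the squared Pearson correlation between the
#' per-OTU read totals of two duplicate extraction days — the proportion
#' of variance reproduced by replication. It is symmetric in its
#' arguments and invariant to affine rescaling of either vector.
#' `repeatabilityTable()` computes it for every kit x milk cell of a
#' study, pairing replicate days 1 and 2 over the union of OTUs (absent
#' = 0 counts).
#'
#' @param day1,day2 paired numeric vectors of per-OTU read totals.
#' @return `repeatabilityR2()`: scalar in \[0, 1\].
#'   `repeatabilityTable()`: `data.frame` with `kit`, `milk`, `r2`,
#'   `n_otus` (OTUs observed in the pair).
#' @examples
#' repeatabilityR2(c(1, 2, 3), c(1, 3, 2))
#' @export
repeatabilityR2 <- function(day1, day2) {
  if (length(day1) != length(day2))
    stop("day1 and day2 must have equal length")
  if (length(day1) < 3) stop("need at least 3 OTUs")
  if (stats::var(day1) == 0 || stats::var(day2) == 0)
    stop("zero variance in a replicate vector")
  unname(stats::cor(day1, day2)^2)
}

#' @rdname repeatabilityR2
#' @param x [MilkExperiment][MilkExperiment-class] with `role`,
#'   `kit`, `milk` and `replicate` metadata.
#' @export
repeatabilityTable <- function(x) {
  meta <- sampleMeta(x)
  meta <- meta[meta$role == "sample", ]
  m <- counts(x)
  cells <- unique(meta[, c("kit", "milk")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    k <- cells$kit[i]; mi <- cells$milk[i]
    s1 <- meta$sample_id[meta$kit == k & meta$milk == mi &
                           meta$replicate == 1]
    s2 <- meta$sample_id[meta$kit == k & meta$milk == mi &
                           meta$replicate == 2]
    if (!length(s1) || !length(s2)) return(NULL)
    d1 <- rowSums(m[, s1, drop = FALSE])
    d2 <- rowSums(m[, s2, drop = FALSE])
    data.frame(kit = k, milk = mi, r2 = repeatabilityR2(d1, d2),
               n_otus = sum(d1 + d2 > 0))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
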