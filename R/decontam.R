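#' @include simulate.R
NULL

#' Partition spiked negative controls into spike and contaminant reads
#'
#' The first step of spike-anchored decontamination: in the
#' cyanobacteria-spiked negative extraction controls (NTCs), remove every
#' OTU whose taxonomy matches the spike label at the given rank. What
#' remains with a nonzero read count in any NTC is, by construction,
#' reagent contamination.
#'
#' @param x a [MilkExperiment][MilkExperiment-class] containing (at least)
#'   the `role = "ntc"` columns with lineage annotation, or a numeric
#'   count matrix of NTC columns (then `taxonomy` is required).
#' @param spikeLabel taxonomy label identifying the spike (default
#'   `"Cyanobacteria"`; use `"Arthrospira"` with `rank = "genus"` for a
#'   genus-level match).
#' @param rank taxonomic rank at which `spikeLabel` is matched.
#' @param taxonomy named character vector of lineage strings (only needed
#'   when `x` is a bare matrix).
#' @return a list with `spikeOtus` (character vector of spike OTU ids),
#'   `residual` (NTC count matrix restricted to contaminant-candidate
#'   OTUs: spike rows dropped, rows with all-zero NTC counts dropped) and
#'   `ntcIds`. If no spike OTU carries reads in the NTCs a warning is
#'   emitted (possible mislabeled spike) and the residual equals the
#'   input.
#' @seealso [buildContaminantProfile()], [decontaminate()]
#' @export
identifySpike <- function(x, spikeLabel = "Cyanobacteria",
                          rank = "phylum", taxonomy = NULL) {
  if (methods::is(x, "MilkExperiment")) {
    meta <- sampleMeta(x)
    if (!"role" %in% colnames(meta) || !any(meta$role == "ntc"))
      stop("no role=ntc columns present")
    ntc <- counts(x)[, meta$sample_id[meta$role == "ntc"], drop = FALSE]
    taxonomy <- otuLineage(x)
  } else {
    ntc <- as.matrix(x)
    if (is.null(taxonomy))
      stop("taxonomy is required when x is a bare matrix")
  }
  labels <- lineageRank(taxonomy[rownames(ntc)], rank)
  isSpike <- !is.na(labels) & labels == spikeLabel
  spikeOtus <- rownames(ntc)[isSpike]
  if (!length(spikeOtus) || sum(ntc[spikeOtus, , drop = FALSE]) == 0)
    warning("spike label '", spikeLabel, "' matches no reads in the ",
            "NTCs; spike may be mislabeled")
  residual <- ntc[!isSpike, , drop = FALSE]
  residual <- residual[rowSums(residual) > 0, , drop = FALSE]
  list(spikeOtus = spikeOtus, residual = residual, ntcIds = colnames(ntc))
}

#' Estimate mean contaminant read counts from spiked controls
#'
#' For each contaminant OTU left in the NTCs after spike removal, computes
#' its mean read count across NTCs — per extraction kit
#' (`scope = "per_kit"`) or across all NTCs (`scope = "pooled"`). Zero
#' counts enter the mean's denominator: an NTC where a contaminant was not
#' observed still counts. The profile is keyed by the OTU's representative
#' sequence so it can be matched into any sample table at 100% identity.
#'
#' `scope = "auto"` resolves to `per_kit` when every kit present in the
#' metadata has at least one NTC, else to `pooled`; the resolved scope is
#' recorded in the returned object.
#'
#' @param residual contaminant-candidate NTC count matrix
#'   (`identifySpike()$residual`).
#' @param meta sample metadata `data.frame` covering the NTC columns
#'   (`sample_id`, `kit`, `role`).
#' @param seqs named character vector or
#'   [Biostrings::DNAStringSet-class] of representative sequences; every
#'   OTU in `residual` must be present.
#' @param scope `"auto"`, `"per_kit"` or `"pooled"`.
#' @return a [ContaminantProfile][ContaminantProfile-class].
#' @export
buildContaminantProfile <- function(residual, meta, seqs,
                                    scope = c("auto", "per_kit",
                                              "pooled")) {
  scope <- match.arg(scope)
  seqs <- .normalizeSeq(as.character(seqs) |>
                          stats::setNames(names(seqs)))
  meta <- as.data.frame(meta)
  ntcMeta <- meta[meta$role == "ntc" &
                    meta$sample_id %in% colnames(residual), ]
  if (nrow(residual)) {
    missing <- setdiff(rownames(residual), names(seqs))
    if (length(missing))
      stop("contaminant OTU(s) missing a representative sequence: ",
           paste(missing, collapse = ", "))
  }
  studyKits <- unique(stats::na.omit(meta$kit))
  if (scope == "auto")
    scope <- if (length(studyKits) &&
                 all(studyKits %in% ntcMeta$kit)) "per_kit" else "pooled"
  meanBySeq <- function(cols) {
    if (!nrow(residual) || !length(cols)) return(numeric(0))
    mu <- rowMeans(residual[, cols, drop = FALSE])
    mu <- mu[mu > 0]
    if (!length(mu)) return(numeric(0))
    # several OTUs may share one sequence: their means add
    tapply(mu, seqs[names(mu)], sum) |> c()
  }
  if (scope == "per_kit") {
    kits <- sort(unique(ntcMeta$kit))
    means <- lapply(kits, function(k)
      meanBySeq(ntcMeta$sample_id[ntcMeta$kit == k]))
    names(means) <- kits
  } else {
    means <- list(all = meanBySeq(ntcMeta$sample_id))
  }
  ContaminantProfile(scope, means, ntcIds = ntcMeta$sample_id)
}

.truncSeq <- function(s, truncateTo) {
  if (is.null(truncateTo)) s else substr(s, 1L, truncateTo)
}

#' Match contaminant sequences into a sample table at 100% identity
#'
#' A sample OTU matches a contaminant sequence iff the two sequences are
#' exactly equal after both are truncated to a common length (default 250
#' bp, the truncation length of quality-filtered V4 amplicons). Several
#' sample OTUs may match the same contaminant sequence.
#'
#' @param sampleSeqs named character vector or
#'   [Biostrings::DNAStringSet-class] of the sample table's representative
#'   sequences.
#' @param profile a [ContaminantProfile][ContaminantProfile-class].
#' @param truncateTo common truncation length in bp (`NULL` = no
#'   truncation).
#' @return named list: contaminant sequence -> character vector of
#'   matching sample OTU ids (empty vector where nothing matches).
#' @export
matchContaminants <- function(sampleSeqs, profile, truncateTo = 250L) {
  sampleSeqs <- .normalizeSeq(as.character(sampleSeqs) |>
                                stats::setNames(names(sampleSeqs)))
  contamSeqs <- unique(unlist(lapply(profile@means, names),
                              use.names = FALSE))
  sTrunc <- .truncSeq(sampleSeqs, truncateTo)
  out <- lapply(contamSeqs, function(cs)
    names(sampleSeqs)[sTrunc == .truncSeq(cs, truncateTo)])
  names(out) <- contamSeqs
  out
}

#' Subtract mean NTC contaminant reads from samples
#'
#' The subtraction step of spike-anchored decontamination: for every
#' sample column and every sample OTU matched to a contaminant sequence,
#' the contaminant's mean NTC read count (for the sample's kit, under
#' per-kit scope) is subtracted from the observed count and the result
#' clamped at zero. Unmatched OTUs are untouched; the output is flagged
#' as decontaminated (real-valued counts permitted). Optionally the spike
#' OTUs themselves are zeroed in sample columns — the spike is exogenous
#' by construction.
#'
#' @param x a [MilkExperiment][MilkExperiment-class]; all columns whose
#'   role is not `"ntc"` are decontaminated (NTC columns pass through
#'   unchanged).
#' @param profile a [ContaminantProfile][ContaminantProfile-class].
#' @param matches match list from [matchContaminants()]; computed from
#'   `x`'s own sequences when `NULL`.
#' @param spikeOtus OTU ids to zero out in non-NTC columns (default
#'   none).
#' @param truncateTo truncation length used when `matches` is computed
#'   here.
#' @param integerize round the decontaminated counts half away from zero
#'   (default `FALSE`: real-valued counts are kept, since downstream
#'   relative abundances do not require integers and rounding hides small
#'   removals).
#' @return a list with `experiment` (decontaminated `MilkExperiment`) and
#'   `report` (a `data.frame` of reads removed per sample x OTU, spike
#'   removals included with `source = "spike"`).
#' @export
subtractContaminants <- function(x, profile, matches = NULL,
                                 spikeOtus = character(),
                                 truncateTo = 250L, integerize = FALSE) {
  stopifnot(methods::is(x, "MilkExperiment"))
  m <- counts(x)
  storage.mode(m) <- "double"
  meta <- sampleMeta(x)
  target <- if ("role" %in% colnames(meta))
    meta$sample_id[is.na(meta$role) | meta$role != "ntc"]
  else colnames(m)
  if (is.null(matches))
    matches <- matchContaminants(otuSequences(x), profile, truncateTo)
  perKit <- profileScope(profile) == "per_kit"
  if (perKit) {
    kits <- stats::setNames(meta$kit, meta$sample_id)
    missing <- target[is.na(kits[target])]
    if (length(missing))
      stop("per_kit profile but no kit metadata for sample(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    noProfile <- setdiff(unique(kits[target]), names(profile@means))
    if (length(noProfile))
      stop("per_kit profile lacks kit(s): ",
           paste(noProfile, collapse = ", "))
  }
  report <- list()
  for (s in target) {
    mu <- if (perKit) profileMeans(profile, kits[[s]])
          else profileMeans(profile)
    for (cs in names(matches)) {
      if (!cs %in% names(mu)) next
      for (o in matches[[cs]]) {
        removed <- min(m[o, s], mu[[cs]])
        if (removed > 0) {
          m[o, s] <- m[o, s] - removed
          report[[length(report) + 1L]] <-
            data.frame(sample_id = s, otu_id = o, removed = removed,
                       source = "contaminant")
        }
      }
    }
    for (o in intersect(spikeOtus, rownames(m))) {
      if (m[o, s] > 0) {
        report[[length(report) + 1L]] <-
          data.frame(sample_id = s, otu_id = o, removed = m[o, s],
                     source = "spike")
        m[o, s] <- 0
      }
    }
  }
  if (integerize) m <- sign(m) * floor(abs(m) + 0.5)
  report <- if (length(report)) do.call(rbind, report)
            else data.frame(sample_id = character(), otu_id = character(),
                            removed = numeric(), source = character())
  out <- MilkExperiment(m, meta,
                        sequences = {
                          s <- otuSequences(x)
                          if (length(s)) s else NULL
                        },
                        taxonomy = {
                          l <- otuLineage(x)
                          if (length(l)) l else NULL
                        },
                        decontaminated = TRUE)
  list(experiment = out, report = report)
}

#' Spike-anchored in-silico decontamination, end to end
#'
#' Runs the full procedure on one study object: identify the spike reads
#' in the cyanobacteria-spiked negative extraction controls, estimate mean
#' contaminant read counts (per kit when every kit has an NTC), match
#' contaminant sequences into the sample OTUs at 100% identity on
#' truncated amplicons, subtract the means (clamped at zero), and zero the
#' spike OTUs out of the sample columns.
#'
#' @inheritParams identifySpike
#' @inheritParams buildContaminantProfile
#' @inheritParams subtractContaminants
#' @param removeSpikeFromSamples also zero the spike OTU(s) in non-NTC
#'   columns (default `TRUE`).
#' @return a list with `experiment` (decontaminated
#'   [MilkExperiment][MilkExperiment-class]), `profile`
#'   ([ContaminantProfile][ContaminantProfile-class]), `matches`,
#'   `spikeOtus` and `report`.
#' @examples
#' sim <- simulateStudy(studyDesign(nDonors = 2), seed = 1)
#' dec <- decontaminate(sim$experiment)
#' dec$profile
#' @export
decontaminate <- function(x, spikeLabel = "Cyanobacteria",
                          rank = "phylum",
                          scope = c("auto", "per_kit", "pooled"),
                          truncateTo = 250L, integerize = FALSE,
                          removeSpikeFromSamples = TRUE) {
  scope <- match.arg(scope)
  spike <- identifySpike(x, spikeLabel, rank)
  profile <- buildContaminantProfile(spike$residual, sampleMeta(x),
                                     otuSequences(x), scope)
  matches <- matchContaminants(otuSequences(x), profile, truncateTo)
  sub <- subtractContaminants(
    x, profile, matches,
    spikeOtus = if (removeSpikeFromSamples) spike$spikeOtus
                else character(),
    truncateTo = truncateTo, integerize = integerize)
  list(experiment = sub$experiment, profile = profile, matches = matches,
       spikeOtus = spike$spikeOtus, report = sub$report)
}
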