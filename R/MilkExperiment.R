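#' @include AllClasses.R AllGenerics.R
NULL

.normalizeSeq <- function(x) {
  nms <- names(x)
  x <- toupper(as.character(x))
  x <- chartr("U", "T", x)  # chartr drops names
  names(x) <- nms
  bad <- grepl("[^ACGTN]", x)
  if (any(bad))
    stop("sequence(s) contain characters outside {A,C,G,T,N,U}: ",
         paste(utils::head(names(x)[bad], 3), collapse = ", "))
  if (any(!nzchar(x))) stop("empty sequence(s) present")
  x
}

.checkMeta <- function(meta) {
  req <- c("sample_id", "donor", "kit", "milk", "replicate", "role")
  missing <- setdiff(req, colnames(meta))
  if (length(missing))
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  meta <- as.data.frame(meta)[, req]
  meta$sample_id <- as.character(meta$sample_id)
  meta$donor <- as.character(meta$donor)
  meta$donor[!is.na(meta$donor) & meta$donor == ""] <- NA_character_
  meta$kit <- as.character(meta$kit)
  meta$milk <- as.character(meta$milk)
  meta$replicate <- suppressWarnings(as.integer(meta$replicate))
  meta$role <- as.character(meta$role)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  badRole <- !is.na(meta$role) & !(meta$role %in% .VALID_ROLES)
  if (any(badRole))
    stop("unknown role value(s): ",
         paste(unique(meta$role[badRole]), collapse = ", "))
  badKit <- !is.na(meta$kit) & !(meta$kit %in% .VALID_KITS)
  if (any(badKit))
    stop("unknown kit value(s): ",
         paste(unique(meta$kit[badKit]), collapse = ", "))
  badMilk <- !is.na(meta$milk) & !(meta$milk %in% .VALID_MILKS)
  if (any(badMilk))
    stop("unknown milk value(s): ",
         paste(unique(meta$milk[badMilk]), collapse = ", "))
  badRep <- !is.na(meta$replicate) & !(meta$replicate %in% c(1L, 2L))
  if (any(badRep))
    stop("replicate must be 1 or 2")
  ntcDonor <- meta$role == "ntc" & !is.na(meta$donor)
  if (any(ntcDonor)) {
    warning("role=ntc rows with non-empty donor; donor set to NA for: ",
            paste(meta$sample_id[ntcDonor], collapse = ", "))
    meta$donor[ntcDonor] <- NA_character_
  }
  meta
}

#' @rdname MilkExperiment-class
#' @export
MilkExperiment <- function(counts, meta = NULL, sequences = NULL,
                           taxonomy = NULL, decontaminated = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have OTU row names and sample column names")
  storage.mode(counts) <- "double"
  if (!decontaminated && all(counts == floor(counts)))
    storage.mode(counts) <- "integer"
  rd <- S4Vectors::DataFrame(row.names = rownames(counts))
  if (!is.null(sequences)) {
    sequences <- .normalizeSeq(sequences)
    extra <- setdiff(names(sequences), rownames(counts))
    missing <- setdiff(rownames(counts), names(sequences))
    if (length(extra))
      message(length(extra),
              " sequence id(s) absent from the count table (kept aside)")
    if (length(missing))
      message(length(missing), " OTU(s) have no representative sequence")
    rd$sequence <- unname(sequences[rownames(counts)])
  }
  if (!is.null(taxonomy))
    rd$lineage <- unname(as.character(taxonomy)[match(rownames(counts),
                                                      names(taxonomy))])
  if (!is.null(meta)) {
    meta <- .checkMeta(meta)
    missing <- setdiff(colnames(counts), meta$sample_id)
    if (length(missing))
      stop("sample(s) missing from metadata: ",
           paste(missing, collapse = ", "))
    meta <- meta[match(colnames(counts), meta$sample_id), ]
    cd <- S4Vectors::DataFrame(meta[, -1], row.names = meta$sample_id)
  } else {
    cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd, colData = cd,
    metadata = list(decontaminated = isTRUE(decontaminated)))
  methods::new("MilkExperiment", se)
}

#' @rdname MilkExperiment-class
#' @export
setMethod("counts", "MilkExperiment", function(object)
  SummarizedExperiment::assay(object, "counts"))

#' @rdname MilkExperiment-class
#' @export
setMethod("otuIds", "MilkExperiment", function(x) rownames(x))

#' @rdname MilkExperiment-class
#' @export
setMethod("sampleIds", "MilkExperiment", function(x) colnames(x))

#' @rdname MilkExperiment-class
#' @export
setMethod("sampleMeta", "MilkExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  out <- as.data.frame(cd)
  out <- cbind(sample_id = rownames(out), out)
  rownames(out) <- NULL
  out
})

#' @rdname MilkExperiment-class
#' @export
setMethod("otuSequences", "MilkExperiment", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (!"sequence" %in% colnames(rd))
    return(Biostrings::DNAStringSet())
  s <- rd$sequence
  keep <- !is.na(s)
  out <- Biostrings::DNAStringSet(s[keep])
  names(out) <- rownames(x)[keep]
  out
})

#' @rdname MilkExperiment-class
#' @export
setMethod("otuLineage", "MilkExperiment", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (!"lineage" %in% colnames(rd))
    return(stats::setNames(character(0), character(0)))
  stats::setNames(rd$lineage, rownames(x))
})

#' @rdname MilkExperiment-class
#' @export
setMethod("isDecontaminated", "MilkExperiment", function(x)
  isTRUE(S4Vectors::metadata(x)$decontaminated))

setMethod("show", "MilkExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  roles <- if ("role" %in% colnames(cd)) table(cd$role) else NULL
  cat(sprintf("MilkExperiment: %d OTUs x %d samples%s\n",
              nrow(object), ncol(object),
              if (isDecontaminated(object)) " (decontaminated)" else ""))
  if (!is.null(roles))
    cat("  roles:", paste(sprintf("%s=%d", names(roles), roles),
                          collapse = ", "), "\n")
  rd <- SummarizedExperiment::rowData(object)
  cat("  rowData:",
      if (ncol(rd)) paste(colnames(rd), collapse = ", ") else "(none)",
      "\n")
})

#' @rdname MockProfile-class
#' @export
MockProfile <- function(taxa, abundance, gram = rep(NA_character_,
                                                    length(taxa))) {
  methods::new("MockProfile", taxa = as.character(taxa),
               abundance = as.numeric(abundance),
               gram = as.character(gram))
}

#' @rdname MockProfile-class
#' @export
setMethod("mockTaxa", "MockProfile", function(x) x@taxa)

#' @rdname MockProfile-class
#' @export
setMethod("mockAbundance", "MockProfile", function(x)
  stats::setNames(x@abundance, x@taxa))

#' @rdname MockProfile-class
#' @export
setMethod("gramFlags", "MockProfile", function(x)
  stats::setNames(x@gram, x@taxa))

setMethod("show", "MockProfile", function(object) {
  cat(sprintf("MockProfile: %d taxa, total %.1f%%\n",
              length(object@taxa), sum(object@abundance)))
  for (i in seq_along(object@taxa))
    cat(sprintf("  %-22s %5.1f%%  gram %s\n", object@taxa[i],
                object@abundance[i],
                ifelse(is.na(object@gram[i]), "?", object@gram[i])))
})

#' @rdname ContaminantProfile-class
#' @export
ContaminantProfile <- function(scope, means, ntcIds = character()) {
  methods::new("ContaminantProfile", scope = scope, means = means,
               ntcIds = as.character(ntcIds))
}

#' @rdname ContaminantProfile-class
#' @export
setMethod("profileScope", "ContaminantProfile", function(x) x@scope)

#' @rdname ContaminantProfile-class
#' @export
setMethod("profileMeans", "ContaminantProfile", function(x, kit) {
  if (x@scope == "pooled")
    return(if (length(x@means)) x@means[["all"]] else numeric(0))
  if (missing(kit)) stop("per_kit profile: a kit must be given")
  if (!kit %in% names(x@means))
    stop("no contaminant profile for kit ", kit)
  x@means[[kit]]
})

#' @rdname ContaminantProfile-class
#' @export
setMethod("profileNtcIds", "ContaminantProfile", function(x) x@ntcIds)

setMethod("show", "ContaminantProfile", function(object) {
  nseq <- length(unique(unlist(lapply(object@means, names))))
  cat(sprintf("ContaminantProfile (%s): %d contaminant sequence(s), %d NTC(s)\n",
              object@scope, nseq, length(object@ntcIds)))
})

#' @rdname StudyDesign-class
#' @export
studyDesign <- function(nDonors = 10L, kits = c("A", "B", "C", "D"),
                        milks = c("WM", "SM"), replicates = 2L,
                        depthMean = 2000, donorEffectConcentration = 30,
                        nNtcPerKit = 1L) {
  methods::new("StudyDesign", nDonors = as.integer(nDonors),
               kits = as.character(kits), milks = as.character(milks),
               replicates = as.integer(replicates),
               depthMean = as.numeric(depthMean),
               donorEffectConcentration = as.numeric(donorEffectConcentration),
               nNtcPerKit = as.integer(nNtcPerKit))
}

setMethod("show", "StudyDesign", function(object) {
  cat(sprintf(
    "StudyDesign: %d donors x %d kits x %d milks x %d replicates (%d samples)\n",
    object@nDonors, length(object@kits), length(object@milks),
    object@replicates,
    object@nDonors * length(object@kits) * length(object@milks) *
      object@replicates))
  cat(sprintf("  depthMean %.0f, donor concentration %.2f, %d NTC(s)/kit\n",
              object@depthMean, object@donorEffectConcentration,
              object@nNtcPerKit))
})
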