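#' Container for a low-biomass 16S amplicon study
#'
#' `MilkExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment-class] and holds everything
#' the pipeline consumes for one study: an OTU-by-sample count matrix
#' (assay `"counts"`), per-sample metadata (`colData`: `donor`, `kit`,
#' `milk`, `replicate`, `role`), and per-OTU annotation (`rowData`:
#' representative `sequence`, taxonomic `lineage`). Counts are integer on
#' ingest; after mean-subtraction decontamination they may be real-valued,
#' in which case the object carries `metadata(x)$decontaminated = TRUE`.
#'
#' Sample roles distinguish the three column types of a spike-anchored
#' study design: `"sample"` (a milk extract), `"ntc"` (a
#' cyanobacteria-spiked negative extraction control; `donor` must be `NA`),
#' and `"mock_spiked"` (milk spiked with the mock community standard).
#'
#' @param counts numeric matrix, OTUs as rows, samples as columns, with
#'   unique row and column names. All entries must be non-negative;
#'   non-integer entries are only accepted when `decontaminated = TRUE`.
#' @param meta `data.frame` of sample metadata with columns `sample_id`,
#'   `donor`, `kit`, `milk`, `replicate`, `role`, one row per column of
#'   `counts` (any order; matched by `sample_id`). May be `NULL` when no
#'   metadata is available.
#' @param sequences named character vector or
#'   [Biostrings::DNAStringSet-class] of representative sequences, named by
#'   OTU id. Sequences are normalized to uppercase T-form. Optional.
#' @param taxonomy named character vector of lineage strings (e.g.
#'   `"k__Bacteria; p__Firmicutes; ...; g__Staphylococcus"`), named by OTU
#'   id. Optional.
#' @param decontaminated logical flag; marks the table as the output of
#'   [subtractContaminants()] and licenses real-valued counts.
#' @param x a `MilkExperiment` (accessors).
#'
#' @return `MilkExperiment()` returns a validated `MilkExperiment`.
#'   `otuIds()`/`sampleIds()` return character vectors; `sampleMeta()` a
#'   `data.frame` keyed by `sample_id`; `otuSequences()` a `DNAStringSet`
#'   (zero-length if none supplied); `otuLineage()` a named character
#'   vector; `isDecontaminated()` a logical scalar.
#'
#' @examples
#' m <- matrix(c(3L, 1L, 0L, 2L), nrow = 2,
#'             dimnames = list(c("otu1", "otu2"), c("S1", "S2")))
#' meta <- data.frame(sample_id = c("S1", "S2"), donor = c("D1", "D1"),
#'                    kit = c("B", "B"), milk = c("WM", "SM"),
#'                    replicate = c(1L, 1L), role = "sample")
#' me <- MilkExperiment(m, meta)
#' sampleIds(me)
#' @aliases MilkExperiment
#' @export
setClass("MilkExperiment", contains = "SummarizedExperiment")

.VALID_ROLES <- c("sample", "ntc", "mock_spiked")
.VALID_KITS  <- c("A", "B", "C", "D")
.VALID_MILKS <- c("WM", "SM")

setValidity("MilkExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (!is.numeric(m)) msg <- c(msg, "counts must be numeric")
    else if (any(!is.finite(m)) || any(m < 0))
      msg <- c(msg, "counts must be finite and non-negative")
    dec <- isTRUE(S4Vectors::metadata(object)$decontaminated)
    if (is.numeric(m) && !dec && any(m != floor(m)))
      msg <- c(msg, "non-integer counts require the decontaminated flag")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate OTU ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  cd <- SummarizedExperiment::colData(object)
  if ("role" %in% colnames(cd)) {
    bad <- setdiff(unique(as.character(cd$role)), c(.VALID_ROLES, NA))
    if (length(bad))
      msg <- c(msg, paste0("unknown role(s): ", paste(bad, collapse = ", ")))
    if ("donor" %in% colnames(cd)) {
      ntc <- !is.na(cd$role) & cd$role == "ntc"
      if (any(ntc & !is.na(cd$donor)))
        msg <- c(msg, "role=ntc entries must have donor NA")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Theoretical composition of a mock microbial community
#'
#' A `MockProfile` records the declared relative abundances (in percent) of
#' the taxa in a commercial mock community standard, together with an
#' optional Gram-stain flag per taxon used for Gram-stratified bias calls.
#' Abundances must be non-negative and sum to 100 within manufacturer
#' rounding tolerance (\[99, 101\]).
#'
#' @param taxa character vector of taxon labels (genus- or family-level).
#' @param abundance numeric vector of expected relative abundances, percent.
#' @param gram character vector of `"positive"`/`"negative"` (or `NA`) per
#'   taxon.
#' @param x a `MockProfile` (accessors).
#'
#' @return `MockProfile()` returns a validated object. `mockTaxa()`,
#'   `mockAbundance()` (named, percent) and `gramFlags()` (named) extract
#'   the slots.
#'
#' @seealso [defaultMockProfile()] for the packaged ZymoBIOMICS standard.
#' @examples
#' MockProfile(c("X", "Y"), c(40, 60), c("positive", "negative"))
#' @aliases MockProfile
#' @export
setClass("MockProfile",
  representation(taxa = "character", abundance = "numeric",
                 gram = "character"))

setValidity("MockProfile", function(object) {
  msg <- character()
  n <- length(object@taxa)
  if (length(object@abundance) != n || length(object@gram) != n)
    msg <- c(msg, "taxa, abundance and gram must have equal length")
  if (anyDuplicated(object@taxa)) msg <- c(msg, "duplicate taxon labels")
  if (any(object@abundance < 0)) msg <- c(msg, "abundances must be >= 0")
  s <- sum(object@abundance)
  if (n > 0 && (s < 99 || s > 101))
    msg <- c(msg, sprintf("abundances sum to %.3f, outside [99, 101]", s))
  bad <- setdiff(unique(object@gram), c("positive", "negative", NA))
  if (length(bad)) msg <- c(msg, "gram flags must be positive/negative/NA")
  if (length(msg)) msg else TRUE
})

#' Per-kit reagent-contaminant profile estimated from spiked controls
#'
#' A `ContaminantProfile` maps each contaminant sequence to its mean read
#' count across negative extraction controls (NTCs), either per extraction
#' kit (`scope = "per_kit"`) or pooled over all NTCs
#' (`scope = "pooled"`). The profile is keyed by sequence, not OTU id, so
#' it can be matched into any sample table whose representative sequences
#' are known. The ids of the NTCs that produced the profile are kept as
#' provenance.
#'
#' @param scope `"per_kit"` or `"pooled"`.
#' @param means named list: one element per kit (or a single element
#'   `"all"` when pooled), each a named numeric vector of mean NTC read
#'   counts keyed by contaminant sequence.
#' @param ntcIds character vector of the NTC sample ids used.
#' @param x a `ContaminantProfile`.
#' @param kit kit label to extract (`profileMeans`); omit for pooled scope.
#'
#' @return `ContaminantProfile()` returns a validated object.
#'   `profileScope()` returns the scope string, `profileMeans()` the named
#'   numeric vector for one kit, `profileNtcIds()` the provenance ids.
#'
#' @seealso [buildContaminantProfile()]
#' @aliases ContaminantProfile
#' @export
setClass("ContaminantProfile",
  representation(scope = "character", means = "list", ntcIds = "character"))

setValidity("ContaminantProfile", function(object) {
  msg <- character()
  if (!identical(object@scope, "per_kit") &&
      !identical(object@scope, "pooled"))
    msg <- c(msg, "scope must be 'per_kit' or 'pooled'")
  if (identical(object@scope, "pooled") &&
      length(object@means) && !identical(names(object@means), "all"))
    msg <- c(msg, "pooled scope must have a single element named 'all'")
  for (k in names(object@means)) {
    v <- object@means[[k]]
    if (length(v) && (is.null(names(v)) || any(!nzchar(names(v)))))
      msg <- c(msg, sprintf("means[['%s']] must be named by sequence", k))
    if (any(v < 0))
      msg <- c(msg, sprintf("means[['%s']] has negative entries", k))
  }
  if (length(msg)) msg else TRUE
})

#' Design of a synthetic spike-anchored extraction study
#'
#' Describes the factorial layout a synthetic study is generated under:
#' number of milk donors, extraction kits, milk preparations (whole vs
#' skim), duplicate extraction days, mean sequencing depth, and the
#' Dirichlet concentration that controls how distinct donor baseline
#' compositions are (smaller = donors further apart). The default layout
#' (10 donors x 4 kits x 2 milk types x 2 replicate days) yields 160
#' milk-sample columns, the shape of a full kit-comparison study.
#'
#' @param nDonors positive integer, number of donors.
#' @param kits subset of `c("A","B","C","D")`.
#' @param milks subset of `c("WM","SM")` (whole / skim milk).
#' @param replicates integer >= 1, duplicate extraction days per
#'   donor-kit-milk cell.
#' @param depthMean positive number, mean reads per sample.
#' @param donorEffectConcentration positive number; total concentration of
#'   the Dirichlet prior for donor baseline compositions.
#' @param nNtcPerKit integer >= 1, spiked negative extraction controls per
#'   kit.
#'
#' @return a validated `StudyDesign` object.
#' @seealso [simulateStudy()]
#' @examples
#' studyDesign(nDonors = 10)
#' @aliases StudyDesign
#' @export
setClass("StudyDesign",
  representation(nDonors = "integer", kits = "character",
                 milks = "character", replicates = "integer",
                 depthMean = "numeric",
                 donorEffectConcentration = "numeric",
                 nNtcPerKit = "integer"))

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (object@nDonors < 1L) msg <- c(msg, "nDonors must be >= 1")
  if (!length(object@kits) || !all(object@kits %in% .VALID_KITS))
    msg <- c(msg, "kits must be a non-empty subset of A,B,C,D")
  if (!length(object@milks) || !all(object@milks %in% .VALID_MILKS))
    msg <- c(msg, "milks must be a non-empty subset of WM,SM")
  if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
  if (object@depthMean <= 0) msg <- c(msg, "depthMean must be > 0")
  if (object@donorEffectConcentration <= 0)
    msg <- c(msg, "donorEffectConcentration must be > 0")
  if (object@nNtcPerKit < 1L) msg <- c(msg, "nNtcPerKit must be >= 1")
  if (length(msg)) msg else TRUE
})
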