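#' @include MilkExperiment.R
NULL

#' Read and write OTU count tables
#'
#' Count tables travel in two on-disk forms: a tab-delimited table whose
#' first column holds OTU ids and whose header row holds sample ids, and a
#' BIOM-style JSON document (minimal dense variant). Integer parsing is
#' strict on ingest; real-valued counts are accepted only when the file is
#' flagged as decontaminated (a leading `#decontaminated=true` comment line
#' in tsv; a top-level `"decontaminated": true` key in JSON), the form the
#' mean-subtraction step produces. Reader/writer pairs round-trip exactly.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom_json"`.
#' @param x a [MilkExperiment][MilkExperiment-class] or a numeric matrix
#'   with OTU row names and sample column names.
#'
#' @return `readCountTable()` returns a `MilkExperiment` (counts only, no
#'   sample metadata). `writeCountTable()` returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(c(3L, 1L, 0L, 2L), nrow = 2,
#'             dimnames = list(c("otu1", "otu2"), c("S1", "S2")))
#' writeCountTable(m, tf)
#' counts(readCountTable(tf))
#' @export
readCountTable <- function(path, format = c("tsv", "biom_json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") .readCountTsv(path) else .readCountBiom(path)
}

.parseCounts <- function(m, decontaminated, where) {
  if (any(is.na(m)))
    stop("non-numeric cell(s) in ", where, ": e.g. row '",
         rownames(m)[which(is.na(m), arr.ind = TRUE)[1, 1]], "', column '",
         colnames(m)[which(is.na(m), arr.ind = TRUE)[1, 2]], "'")
  if (any(m < 0)) {
    ij <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative count in ", where, ": row '", rownames(m)[ij[1]],
         "', column '", colnames(m)[ij[2]], "'")
  }
  if (!decontaminated && any(m != floor(m))) {
    ij <- which(m != floor(m), arr.ind = TRUE)[1, ]
    stop("non-integer count in ", where, " (row '", rownames(m)[ij[1]],
         "', column '", colnames(m)[ij[2]],
         "') in a table not flagged as decontaminated")
  }
  m
}

.readCountTsv <- function(path) {
  lines <- readLines(path)
  dec <- FALSE
  if (length(lines) && grepl("^#decontaminated=true", lines[1])) {
    dec <- TRUE
    lines <- lines[-1]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("no data rows in ", path)
  con <- textConnection(lines)
  on.exit(close(con))
  df <- utils::read.delim(con, header = TRUE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("no sample columns in ", path)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate OTU id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(colnames(df)[-1]))
    stop("duplicate sample id(s) in header")
  m <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df))))
  m <- matrix(m, nrow = nrow(df),
              dimnames = list(ids, colnames(df)[-1]))
  m <- .parseCounts(m, dec, path)
  MilkExperiment(m, decontaminated = dec)
}

.readCountBiom <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  need <- c("rows", "columns", "data", "shape")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    stop("biom_json missing field(s): ", paste(miss, collapse = ", "))
  if (!is.null(doc$matrix_type) && doc$matrix_type != "dense")
    stop("only the dense biom_json variant is supported")
  dec <- isTRUE(doc$decontaminated)
  rid <- vapply(doc$rows, function(r) as.character(r$id), character(1))
  cid <- vapply(doc$columns, function(r) as.character(r$id), character(1))
  if (anyDuplicated(rid)) stop("duplicate OTU id(s) in biom_json")
  if (anyDuplicated(cid)) stop("duplicate sample id(s) in biom_json")
  if (!length(rid)) stop("no data rows in ", path)
  m <- do.call(rbind, lapply(doc$data, function(r)
    suppressWarnings(as.numeric(unlist(r)))))
  if (nrow(m) != length(rid) || ncol(m) != length(cid))
    stop("biom_json data does not match shape")
  dimnames(m) <- list(rid, cid)
  m <- .parseCounts(m, dec, path)
  MilkExperiment(m, decontaminated = dec)
}

#' @rdname readCountTable
#' @export
writeCountTable <- function(x, path, format = c("tsv", "biom_json")) {
  format <- match.arg(format)
  if (methods::is(x, "MilkExperiment")) {
    m <- counts(x)
    dec <- isDecontaminated(x)
  } else {
    m <- as.matrix(x)
    dec <- any(m != floor(m))
  }
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    if (dec) writeLines("#decontaminated=true", con)
    writeLines(paste(c("otu_id", colnames(m)), collapse = "\t"), con)
    body <- apply(m, 1, function(r)
      paste(format(r, scientific = FALSE, trim = TRUE), collapse = "\t"))
    writeLines(paste(rownames(m), body, sep = "\t"), con)
  } else {
    doc <- list(
      id = NULL,
      format = "Biological Observation Matrix 1.0.0",
      format_url = "http://biom-format.org",
      type = "OTU table",
      generated_by = paste0("lowmassqc ",
                            as.character(utils::packageVersion("lowmassqc"))),
      date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      matrix_type = "dense",
      matrix_element_type = if (dec) "float" else "int",
      shape = dim(m),
      decontaminated = dec,
      rows = lapply(rownames(m), function(i)
        list(id = i, metadata = NULL)),
      columns = lapply(colnames(m), function(i)
        list(id = i, metadata = NULL)),
      data = unname(lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' Read and write representative sequences (FASTA)
#'
#' The token before the first whitespace in each header is taken as the
#' OTU id. Sequences are normalized to uppercase T-form (`U -> T`);
#' characters outside `{A,C,G,T,N,U}` and duplicate ids are errors.
#'
#' @param path file path.
#' @param seqs named character vector or
#'   [Biostrings::DNAStringSet-class], names = OTU ids.
#' @return `readFasta()` returns a named `DNAStringSet`; `writeFasta()`
#'   returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeFasta(c(otu1 = "ACGT"), tf)
#' readFasta(tf)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(raw), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate OTU id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  s <- stats::setNames(as.character(raw), ids)
  s <- .normalizeSeq(s)
  out <- Biostrings::DNAStringSet(s)
  names(out) <- ids
  out
}

#' @rdname readFasta
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) {
    seqs <- Biostrings::DNAStringSet(.normalizeSeq(seqs))
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named by OTU id")
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read and write sample metadata
#'
#' Tab-delimited with header columns `sample_id`, `donor`, `kit`, `milk`,
#' `replicate`, `role`. Enumerations are validated (`kit` in A-D, `milk`
#' in WM/SM, `replicate` in 1/2, `role` in sample/ntc/mock_spiked); an NTC
#' row carrying a donor id is coerced to `NA` with a warning (a negative
#' extraction control has no donor).
#'
#' @param path file path.
#' @param meta metadata `data.frame` as returned by `readMetadata()` or
#'   [sampleMeta()].
#' @return `readMetadata()` returns a validated `data.frame`;
#'   `writeMetadata()` returns `path` invisibly.
#' @export
readMetadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          na.strings = c("NA", ""))
  .checkMeta(df)
}

#' @rdname readMetadata
#' @export
writeMetadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a 16S qPCR copy-number table
#'
#' Tab-delimited with header columns `sample_id` and `copies`
#' (16S gene copies per microlitre, positive). A `log10_copies` convenience
#' column is added, the scale on which spike dominance is assessed.
#'
#' @param path file path.
#' @return `data.frame` with columns `sample_id`, `copies`, `log10_copies`.
#' @seealso [spikeDominance()]
#' @export
readQpcr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE)
  miss <- setdiff(c("sample_id", "copies"), colnames(df))
  if (length(miss))
    stop("qPCR table missing column(s): ", paste(miss, collapse = ", "))
  df$copies <- as.numeric(df$copies)
  if (any(!is.finite(df$copies)) || any(df$copies <= 0))
    stop("qPCR copy numbers must be positive")
  df$log10_copies <- log10(df$copies)
  df[, c("sample_id", "copies", "log10_copies")]
}

#' @rdname readQpcr
#' @param qpcr `data.frame` with `sample_id` and `copies` columns.
#' @export
writeQpcr <- function(qpcr, path) {
  utils::write.table(qpcr[, c("sample_id", "copies")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy assignment table
#'
#' Tab-delimited with header columns `otu_id` and `lineage`, where the
#' lineage is a semicolon-separated string with rank prefixes
#' (`k__; p__; c__; o__; f__; g__`), the form classifier output tables
#' usually take.
#'
#' @param path file path.
#' @return named character vector of lineage strings, names = OTU ids.
#' @export
readTaxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  miss <- setdiff(c("otu_id", "lineage"), colnames(df))
  if (length(miss))
    stop("taxonomy table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$otu_id)) stop("duplicate otu_id in taxonomy table")
  stats::setNames(df$lineage, df$otu_id)
}

#' @rdname readTaxonomy
#' @param taxonomy named character vector of lineage strings.
#' @export
writeTaxonomy <- function(taxonomy, path) {
  utils::write.table(
    data.frame(otu_id = names(taxonomy), lineage = unname(taxonomy)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.RANK_PREFIX <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
                  family = "f", genus = "g", species = "s")

#' Extract one rank from lineage strings
#'
#' @param lineage character vector of semicolon-separated lineage strings
#'   with `k__/p__/.../g__` rank prefixes.
#' @param rank one of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @return character vector of labels at that rank (`NA` where absent).
#' @examples
#' lineageRank("k__Bacteria; p__Firmicutes; g__Staphylococcus", "genus")
#' @export
lineageRank <- function(lineage, rank = names(.RANK_PREFIX)) {
  rank <- match.arg(rank)
  pre <- paste0(.RANK_PREFIX[[rank]], "__")
  vapply(strsplit(as.character(lineage), ";"), function(parts) {
    parts <- trimws(parts)
    hit <- parts[startsWith(parts, pre)]
    if (!length(hit)) return(NA_character_)
    lab <- sub(pre, "", hit[1], fixed = TRUE)
    if (nzchar(lab)) lab else NA_character_
  }, character(1))
}

#' Read and write mock-community profiles (YAML)
#'
#' The YAML layout is a list of records with `taxon`, `abundance`
#' (percent) and optional `gram` fields. The packaged
#' `extdata/zmcs.yaml` carries the ZymoBIOMICS Microbial Community
#' Standard's declared 16S relative abundances.
#'
#' @param path YAML file path.
#' @param profile a [MockProfile][MockProfile-class].
#' @return `readMockProfile()` returns a `MockProfile`;
#'   `writeMockProfile()` returns `path` invisibly.
#' @seealso [defaultMockProfile()]
#' @export
readMockProfile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (!length(doc)) stop("empty mock profile: ", path)
  MockProfile(
    taxa = vapply(doc, function(r) as.character(r$taxon), character(1)),
    abundance = vapply(doc, function(r) as.numeric(r$abundance),
                       numeric(1)),
    gram = vapply(doc, function(r)
      if (is.null(r$gram)) NA_character_ else as.character(r$gram),
      character(1)))
}

#' @rdname readMockProfile
#' @export
writeMockProfile <- function(profile, path) {
  recs <- lapply(seq_along(mockTaxa(profile)), function(i) {
    r <- list(taxon = mockTaxa(profile)[i],
              abundance = unname(mockAbundance(profile))[i])
    g <- unname(gramFlags(profile))[i]
    if (!is.na(g)) r$gram <- g
    r
  })
  yaml::write_yaml(recs, path)
  invisible(path)
}

#' Write a dendrogram in Newick format
#'
#' @param hc an `hclust` object, e.g. from [hclustComplete()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
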