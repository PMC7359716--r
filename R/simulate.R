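#' @include io.R
NULL

# Run code under a fixed seed without disturbing the caller's RNG stream.
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv(), inherits = FALSE) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  code
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s == 0) {
    # numerically degenerate draw at very small concentrations:
    # all mass on one component, chosen proportionally to alpha
    g[sample.int(length(alpha), 1L, prob = alpha / sum(alpha))] <- 1
    s <- 1
  }
  g / s
}

#' The ZymoBIOMICS mock community standard 16S profile
#'
#' Returns the declared theoretical 16S relative abundances of the eight
#' bacterial taxa in the ZymoBIOMICS Microbial Community Standard (ZMCS),
#' with Gram-stain flags: three Gram-negative taxa (Pseudomonas and the
#' two Enterobacteriaceae members) and five Gram-positive (Listeria,
#' Staphylococcus, Lactobacillus, Enterococcus, Bacillus). The values are
#' read from the packaged `extdata/zmcs.yaml`.
#'
#' @return a [MockProfile][MockProfile-class] whose abundances sum to 100.
#' @examples
#' defaultMockProfile()
#' @export
defaultMockProfile <- function() {
  readMockProfile(system.file("extdata", "zmcs.yaml",
                              package = "lowmassqc", mustWork = TRUE))
}

#' Draw one sequenced community composition
#'
#' Generates a count vector for one sample under a Dirichlet-multinomial
#' model: the realized composition is drawn from a Dirichlet centered on
#' `profile` with total concentration `overdispersion`, and reads are then
#' a multinomial draw of size `depth`. `overdispersion = Inf` gives the
#' plain multinomial limit; smaller values give more between-replicate
#' spread, the overdispersion that quasi-Poisson/negative-binomial count
#' models downstream are built to absorb.
#'
#' @param profile named numeric vector of expected fractions, summing to 1
#'   (within 1e-9), all non-negative.
#' @param depth integer >= 1, total reads to draw.
#' @param overdispersion positive Dirichlet concentration (`Inf` =
#'   multinomial).
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return named integer vector of counts summing exactly to `depth`.
#' @examples
#' simulateComposition(c(a = 0.5, b = 0.5), depth = 100, seed = 1)
#' @export
simulateComposition <- function(profile, depth, overdispersion = 200,
                                seed = NULL) {
  if (any(profile < 0)) stop("profile fractions must be >= 0")
  if (abs(sum(profile) - 1) > 1e-9)
    stop("profile fractions must sum to 1 (got ", sum(profile), ")")
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1")
  if (overdispersion <= 0) stop("overdispersion must be > 0")
  .withSeed(seed, {
    p <- if (is.infinite(overdispersion)) profile
         else .rdirichlet(overdispersion * profile)
    stats::setNames(as.integer(stats::rmultinom(1L, depth, p)),
                    names(profile))
  })
}

#' Kit-specific multiplicative lysis bias
#'
#' `kitBiasModel()` assembles a bias model: per kit, a named vector of
#' multiplicative lysis efficiencies per taxon (taxa not listed default to
#' 1). `applyKitBias()` applies one kit's efficiencies to a composition and
#' renormalizes: `f_i' = f_i * e_i / sum_j f_j * e_j`. This is the
#' mechanism by which, e.g., a kit with a mild lysis protocol
#' under-represents Gram-negative organisms relative to a mock standard.
#' `kitBiasFromGram()` is a shortcut building such a Gram-stratified model
#' for one kit from a mock profile's Gram flags.
#'
#' @param ... for `kitBiasModel()`: named arguments, one per kit, each a
#'   named numeric vector of efficiencies (> 0).
#' @param profile named numeric composition summing to 1
#'   (`applyKitBias`), or a [MockProfile][MockProfile-class]
#'   (`kitBiasFromGram`).
#' @param bias a kit bias model as returned by `kitBiasModel()`, or
#'   `NULL` for no bias.
#' @param kit kit label.
#' @param negEfficiency,posEfficiency efficiencies applied to
#'   Gram-negative / Gram-positive taxa in `kitBiasFromGram()`.
#' @return `kitBiasModel()` a validated named list; `applyKitBias()` the
#'   renormalized composition; `kitBiasFromGram()` a bias model for `kit`.
#' @examples
#' applyKitBias(c(x = 0.5, y = 0.5), kitBiasModel(A = c(y = 3)), "A")
#' @export
kitBiasModel <- function(...) {
  bias <- list(...)
  if (length(bias)) {
    if (is.null(names(bias)) || any(!nzchar(names(bias))))
      stop("kit bias entries must be named by kit")
    for (k in names(bias)) {
      e <- bias[[k]]
      if (!is.numeric(e) || is.null(names(e)) || any(e <= 0))
        stop("efficiencies for kit ", k,
             " must be a named numeric vector with all values > 0")
    }
  }
  bias
}

#' @rdname kitBiasModel
#' @export
applyKitBias <- function(profile, bias, kit) {
  if (any(profile < 0)) stop("profile fractions must be >= 0")
  if (is.null(bias) || !length(bias)) return(profile / sum(profile))
  if (!kit %in% names(bias)) {
    warning("kit ", kit, " absent from bias model; composition unchanged")
    return(profile / sum(profile))
  }
  e <- rep(1, length(profile))
  names(e) <- names(profile)
  hit <- intersect(names(bias[[kit]]), names(profile))
  e[hit] <- bias[[kit]][hit]
  out <- profile * e
  out / sum(out)
}

#' @rdname kitBiasModel
#' @export
kitBiasFromGram <- function(profile, kit, negEfficiency = 0.05,
                            posEfficiency = 1) {
  g <- gramFlags(profile)
  e <- ifelse(g == "negative", negEfficiency, posEfficiency)
  e <- e[!is.na(g)]
  args <- list(e)
  names(args) <- kit
  do.call(kitBiasModel, args)
}

#' Kit-specific reagent contamination model
#'
#' Reagent ("kitome") contaminants are modelled as negative-binomial read
#' counts around kit-specific per-OTU means: every extract processed with
#' a kit — milk sample, mock-spiked sample or negative control alike —
#' receives an independent draw per contaminant OTU. Summarizing NTCs by a
#' mean and subtracting it from samples is exactly the estimator this
#' generative model calls for.
#'
#' `defaultContaminantModel()` assigns each kit a distinct subset of
#' common reagent-contaminant genera (Ralstonia, Bradyrhizobium,
#' Sphingomonas, Methylobacterium, Burkholderia, Delftia, Pelomonas,
#' Cutibacterium) with means between 8 and 60 reads.
#'
#' @param means named list: kit -> named numeric vector of expected NTC
#'   read counts per contaminant OTU id (>= 0).
#' @param dispersion negative-binomial size parameter for count noise.
#' @param kits kit labels to populate in `defaultContaminantModel()`.
#' @return a list with elements `means` and `dispersion`.
#' @export
contaminantModel <- function(means, dispersion = 5) {
  if (!is.list(means)) stop("means must be a list keyed by kit")
  for (k in names(means)) {
    v <- means[[k]]
    if (length(v) && (any(v < 0) || is.null(names(v))))
      stop("contaminant means for kit ", k,
           " must be a named non-negative vector")
  }
  if (dispersion <= 0) stop("dispersion must be > 0")
  list(means = means, dispersion = dispersion)
}

.CONTAM_TAXA <- data.frame(
  otu_id = paste0("OTU_contam_", 1:8),
  genus = c("Ralstonia", "Bradyrhizobium", "Sphingomonas",
            "Methylobacterium", "Burkholderia", "Delftia", "Pelomonas",
            "Cutibacterium"),
  family = c("Burkholderiaceae", "Nitrobacteraceae", "Sphingomonadaceae",
             "Methylobacteriaceae", "Burkholderiaceae", "Comamonadaceae",
             "Comamonadaceae", "Propionibacteriaceae"),
  phylum = c(rep("Proteobacteria", 7), "Actinobacteria"),
  stringsAsFactors = FALSE)

#' @rdname contaminantModel
#' @export
defaultContaminantModel <- function(kits = c("A", "B", "C", "D"),
                                    dispersion = 5) {
  base <- c(60, 35, 25, 18, 12, 10, 9, 8)
  names(base) <- .CONTAM_TAXA$otu_id
  means <- lapply(seq_along(kits), function(i) {
    # each kit carries 4 contaminants, overlapping but not identical sets
    idx <- ((seq_len(4) + (i - 1)) - 1L) %% 8L + 1L
    base[idx]
  })
  names(means) <- kits
  contaminantModel(means, dispersion)
}

.MILK_TEMPLATE <- data.frame(
  otu_id = sprintf("OTU_%02d", 1:24),
  genus = c("Staphylococcus", "Streptococcus", "Lactobacillus", "Gemella",
            "Veillonella", "Enterococcus", "Bacillus", "Clostridium",
            "Acinetobacter", "Escherichia", "Klebsiella", "Pseudomonas",
            "Haemophilus", "Enhydrobacter", "Serratia", "Moraxella",
            "Neisseria", "Corynebacterium", "Rothia", "Bifidobacterium",
            "Micrococcus", "Actinomyces", "Prevotella", "Porphyromonas"),
  family = c("Staphylococcaceae", "Streptococcaceae", "Lactobacillaceae",
             "Bacillales_XI", "Veillonellaceae", "Enterococcaceae",
             "Bacillaceae", "Clostridiaceae", "Moraxellaceae",
             "Enterobacteriaceae", "Enterobacteriaceae",
             "Pseudomonadaceae", "Pasteurellaceae", "Moraxellaceae",
             "Yersiniaceae", "Moraxellaceae", "Neisseriaceae",
             "Corynebacteriaceae", "Micrococcaceae", "Bifidobacteriaceae",
             "Micrococcaceae", "Actinomycetaceae", "Prevotellaceae",
             "Porphyromonadaceae"),
  phylum = c(rep("Firmicutes", 8), rep("Proteobacteria", 9),
             rep("Actinobacteria", 5), rep("Bacteroidetes", 2)),
  fraction = c(0.22, 0.16, 0.08, 0.04, 0.03, 0.01, 0.005, 0.01,
               0.09, 0.05, 0.03, 0.04, 0.03, 0.03, 0.01, 0.01, 0.01,
               0.03, 0.02, 0.02, 0.01, 0.005, 0.02, 0.005),
  stringsAsFactors = FALSE)
.MILK_TEMPLATE$fraction <- .MILK_TEMPLATE$fraction /
  sum(.MILK_TEMPLATE$fraction)

.SPIKE_OTU <- data.frame(
  otu_id = "OTU_spike", genus = "Arthrospira", family = "Microcoleaceae",
  phylum = "Cyanobacteria", stringsAsFactors = FALSE)

.mockOtuTable <- function(mock) {
  data.frame(
    otu_id = paste0("OTU_mock_", seq_along(mockTaxa(mock))),
    genus = mockTaxa(mock),
    family = ifelse(grepl("^Enterobacteriaceae", mockTaxa(mock)),
                    "Enterobacteriaceae", paste0(mockTaxa(mock), "aceae")),
    phylum = ifelse(gramFlags(mock) == "negative", "Proteobacteria",
                    "Firmicutes"),
    stringsAsFactors = FALSE)
}

.randomSeqs <- function(ids, length = 250L) {
  stats::setNames(vapply(ids, function(i)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = ""), character(1)), ids)
}

.lineage <- function(tab) {
  stats::setNames(sprintf("k__Bacteria; p__%s; f__%s; g__%s",
                          tab$phylum, tab$family, tab$genus), tab$otu_id)
}

#' Simulate a complete spike-anchored extraction study
#'
#' Generates every artefact of a kit-comparison study of low-biomass milk
#' samples, with the latent truth retained for parameter-recovery tests:
#'
#' * donor samples (`role = "sample"`): each donor gets a baseline
#'   composition drawn once from a Dirichlet centered on a
#'   Firmicutes/Proteobacteria-dominated milk template; per extract the
#'   composition is kit-biased ([applyKitBias()]), sequenced under the
#'   Dirichlet-multinomial of [simulateComposition()] at a Poisson depth
#'   around `depthMean`, and then receives kit-specific reagent
#'   contaminant reads;
#' * negative extraction controls (`role = "ntc"`, `nNtcPerKit` per kit):
#'   a dedicated cyanobacteria spike OTU at sample-like read count plus
#'   the kit's contaminant reads;
#' * mock-spiked samples (`role = "mock_spiked"`, per kit x milk in
#'   duplicate): the mock profile, kit-biased, with a trace endogenous
#'   admixture weighted by the ratio of endogenous to spike 16S copies;
#' * a qPCR table: endogenous copies lognormal around
#'   `10^endogenousLog10Mean`; mock-spiked samples add `spikeCopies`.
#'
#' @param design a [StudyDesign][StudyDesign-class].
#' @param bias kit bias model from [kitBiasModel()], or `NULL` (none).
#' @param contam contamination model from [contaminantModel()].
#' @param mock a [MockProfile][MockProfile-class] for the spiked samples.
#' @param spikeCopies 16S copies/uL contributed by the mock spike
#'   (default `10^5.7`).
#' @param endogenousLog10Mean,endogenousLog10Sd lognormal parameters of
#'   endogenous 16S copies/uL (defaults 1.9 and 0.3).
#' @param overdispersion Dirichlet-multinomial concentration for read
#'   sampling (between-replicate technical spread).
#' @param seed integer seed; the full output is reproducible bit-exactly.
#'
#' @return a list with elements
#' \describe{
#'   \item{experiment}{a [MilkExperiment][MilkExperiment-class] holding
#'     counts, sample metadata, representative 250-bp sequences and
#'     lineage strings for all columns (samples, NTCs, mock-spiked);}
#'   \item{qpcr}{`data.frame` with `sample_id`, `copies`,
#'     `log10_copies`;}
#'   \item{truth}{latent quantities: `donorComposition` (donor x OTU),
#'     `sampleComposition` (OTU x sample expected contaminant-free
#'     relative abundances), `contaminantMeans`, `bias`, `spikeOtu`,
#'     `mockExpected` (per-kit biased mock fractions).}
#' }
#' @examples
#' sim <- simulateStudy(studyDesign(nDonors = 2), seed = 1)
#' sim$experiment
#' @export
simulateStudy <- function(design = studyDesign(), bias = NULL,
                          contam = defaultContaminantModel(design@kits),
                          mock = defaultMockProfile(),
                          spikeCopies = 10^5.7,
                          endogenousLog10Mean = 1.9,
                          endogenousLog10Sd = 0.3,
                          overdispersion = 200, seed = 17) {
  methods::validObject(design)
  missingKits <- setdiff(design@kits, names(contam$means))
  if (length(missingKits))
    stop("contaminant model lacks kit(s): ",
         paste(missingKits, collapse = ", "))
  .withSeed(seed, {
    endo <- .MILK_TEMPLATE
    mockTab <- .mockOtuTable(mock)
    allTab <- rbind(endo[, c("otu_id", "genus", "family", "phylum")],
                    mockTab, .CONTAM_TAXA, .SPIKE_OTU)
    otus <- allTab$otu_id
    seqs <- .randomSeqs(otus)
    lineage <- .lineage(allTab)

    donors <- sprintf("D%02d", seq_len(design@nDonors))
    alpha <- design@donorEffectConcentration * endo$fraction
    donorComp <- t(vapply(donors, function(d) .rdirichlet(alpha),
                          numeric(nrow(endo))))
    colnames(donorComp) <- endo$otu_id

    biasOrIdentity <- function(comp, b, k) {
      if (!is.null(b) && k %in% names(b)) applyKitBias(comp, b, k)
      else comp / sum(comp)
    }
    drawContam <- function(kit) {
      mu <- contam$means[[kit]]
      if (!length(mu)) return(numeric(0))
      stats::setNames(stats::rnbinom(length(mu), mu = mu,
                                     size = contam$dispersion), names(mu))
    }
    newColumn <- function(base) {
      v <- numeric(length(otus))
      names(v) <- otus
      v[names(base)] <- base
      v
    }

    cols <- list(); meta <- list(); truthComp <- list()
    for (d in donors) for (k in design@kits) for (m in design@milks)
      for (r in seq_len(design@replicates)) {
        id <- sprintf("S_%s_%s_%s_%d", d, k, m, r)
        comp <- biasOrIdentity(donorComp[d, ], bias, k)
        depth <- max(50L, stats::rpois(1L, design@depthMean))
        reads <- simulateComposition(comp, depth, overdispersion)
        col <- newColumn(reads)
        cc <- drawContam(k)
        col[names(cc)] <- col[names(cc)] + cc
        cols[[id]] <- col
        meta[[id]] <- data.frame(sample_id = id, donor = d, kit = k,
                                 milk = m, replicate = r, role = "sample")
        truthComp[[id]] <- newColumn(comp)
      }

    for (k in design@kits) for (i in seq_len(design@nNtcPerKit)) {
      id <- sprintf("NTC_%s_%d", k, i)
      col <- newColumn(numeric(0))
      col[.SPIKE_OTU$otu_id] <- stats::rnbinom(1L, mu = design@depthMean,
                                               size = 20)
      cc <- drawContam(k)
      col[names(cc)] <- col[names(cc)] + cc
      cols[[id]] <- col
      meta[[id]] <- data.frame(sample_id = id, donor = NA_character_,
                               kit = k, milk = NA_character_,
                               replicate = NA_integer_, role = "ntc")
      truthComp[[id]] <- newColumn(numeric(0))
    }

    mockFrac <- unname(mockAbundance(mock)) / sum(mockAbundance(mock))
    names(mockFrac) <- mockTab$otu_id
    wEndo <- 10^endogenousLog10Mean / (10^endogenousLog10Mean + spikeCopies)
    mockExpected <- list()
    for (k in design@kits) for (m in design@milks) for (r in 1:2) {
      id <- sprintf("MOCK_%s_%s_%d", k, m, r)
      biasedMock <- biasOrIdentity(mockFrac,
                                   .translateBiasToOtus(bias, mock,
                                                        mockTab), k)
      mockExpected[[k]] <- biasedMock
      endoComp <- biasOrIdentity(donorComp[donors[1], ], bias, k)
      comp <- c(biasedMock * (1 - wEndo), endoComp * wEndo)
      depth <- max(50L, stats::rpois(1L, design@depthMean))
      reads <- simulateComposition(comp / sum(comp), depth, overdispersion)
      col <- newColumn(reads)
      cc <- drawContam(k)
      col[names(cc)] <- col[names(cc)] + cc
      cols[[id]] <- col
      meta[[id]] <- data.frame(sample_id = id, donor = donors[1], kit = k,
                               milk = m, replicate = r,
                               role = "mock_spiked")
      truthComp[[id]] <- newColumn(comp / sum(comp))
    }

    countMat <- do.call(cbind, cols)
    metaDf <- do.call(rbind, meta)
    rownames(metaDf) <- NULL

    endoCopies <- 10^stats::rnorm(nrow(metaDf), endogenousLog10Mean,
                                  endogenousLog10Sd)
    copies <- ifelse(metaDf$role == "mock_spiked",
                     endoCopies + spikeCopies,
              ifelse(metaDf$role == "ntc",
                     10^stats::rnorm(nrow(metaDf), endogenousLog10Mean,
                                     0.1),
                     endoCopies))
    qpcr <- data.frame(sample_id = metaDf$sample_id, copies = copies,
                       log10_copies = log10(copies))

    experiment <- MilkExperiment(countMat, metaDf, sequences = seqs,
                                 taxonomy = lineage)
    truth <- list(donorComposition = donorComp,
                  sampleComposition = do.call(cbind, truthComp),
                  contaminantMeans = contam$means,
                  bias = bias,
                  spikeOtu = .SPIKE_OTU$otu_id,
                  mockExpected = mockExpected)
    list(experiment = experiment, qpcr = qpcr, truth = truth)
  })
}

# A bias model is keyed by taxon label (mock taxa / genus); mock OTU ids
# differ, so remap efficiencies onto the mock OTU ids for sampling.
.translateBiasToOtus <- function(bias, mock, mockTab) {
  if (is.null(bias) || !length(bias)) return(bias)
  lapply(bias, function(e) {
    hit <- intersect(names(e), mockTab$genus)
    out <- e[hit]
    names(out) <- mockTab$otu_id[match(hit, mockTab$genus)]
    out
  })
}
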