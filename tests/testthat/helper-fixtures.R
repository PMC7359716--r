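# Small in-code fixtures shared across test files.

tinyCounts <- function() {
  matrix(c(3L, 1L, 0L, 2L), nrow = 2,
         dimnames = list(c("otu1", "otu2"), c("S1", "S2")))
}

tinyMeta <- function() {
  data.frame(sample_id = c("S1", "S2"), donor = c("D1", "D1"),
             kit = c("B", "B"), milk = c("WM", "SM"),
             replicate = c(1L, 1L), role = "sample",
             stringsAsFactors = FALSE)
}

randomSeq <- function(n = 250) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A MilkExperiment with fabricated single-OTU-per-genus lineages, for
# differential-abundance simulations: counts has taxa as rows.
taxonExperiment <- function(counts, kit, milk) {
  ids <- paste0("S", seq_len(ncol(counts)))
  colnames(counts) <- ids
  rownames(counts) <- paste0("t", seq_len(nrow(counts)))
  lin <- setNames(sprintf("k__Bacteria; p__P; f__F; g__taxon%02d",
                          seq_len(nrow(counts))), rownames(counts))
  meta <- data.frame(sample_id = ids, donor = NA_character_, kit = kit,
                     milk = milk, replicate = 1L, role = "sample")
  MilkExperiment(counts, meta, taxonomy = lin)
}

# Dirichlet-multinomial count table under a kit x milk layout; `boost`
# multiplies the named taxa's fractions in kit-A samples (an injected
# compositional effect).
dmTable <- function(nTaxa = 40, perCell = 6, depth = 1e4, conc = 300,
                    boost = NULL, boostFactor = 8) {
  base <- (1 / seq_len(nTaxa))
  base <- base / sum(base)
  grid <- expand.grid(rep = seq_len(perCell), kit = c("A", "B", "C", "D"),
                      milk = c("WM", "SM"), stringsAsFactors = FALSE)
  kit <- grid$kit
  milk <- grid$milk
  n <- nrow(grid)
  counts <- sapply(seq_len(n), function(j) {
    f <- base
    if (!is.null(boost) && kit[j] == "A") {
      f[boost] <- f[boost] * boostFactor
      f <- f / sum(f)
    }
    simulateComposition(setNames(f, paste0("t", seq_len(nTaxa))),
                        depth, overdispersion = conc)
  })
  taxonExperiment(counts, kit, milk)
}
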