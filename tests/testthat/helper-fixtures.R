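# Shared builders for small in-code fixtures.

# A minimal replicate-level atlas: `tissues` named list of per-tissue signal
# matrices (probes x replicates) or vectors recycled per replicate.
toy_atlas <- function(signal_by_tissue, gene_symbol = NULL, calls = NULL,
                      life_stage = NULL) {
  tissues <- names(signal_by_tissue)
  mats <- lapply(signal_by_tissue, as.matrix)
  np <- nrow(mats[[1]])
  sig <- do.call(cbind, mats)
  ids <- sprintf("p%02d", seq_len(np))
  if (is.null(gene_symbol)) gene_symbol <- ids
  reps <- vapply(mats, ncol, integer(1))
  samples <- data.frame(
    sample_id = unlist(lapply(tissues, function(t)
      paste0(t, "_r", seq_len(ncol(mats[[t]]))))),
    tissue = rep(tissues, reps),
    life_stage = if (is.null(life_stage)) rep("adult", sum(reps))
                 else rep(life_stage, reps),
    replicate = unlist(lapply(reps, seq_len)),
    stringsAsFactors = FALSE
  )
  colnames(sig) <- samples$sample_id
  atlas_matrix(sig,
               probes = data.frame(probe_id = ids, gene_symbol = gene_symbol,
                                   stringsAsFactors = FALSE),
               samples = samples, calls = calls)
}

# Random enrichment table over `nt` tissues, optional missingness.
random_enrichment <- function(ng, nt, na_frac = 0, ref = "ref") {
  tissues <- paste0("t", seq_len(nt))
  fc <- matrix(2^runif(ng * nt, -3, 6), ng, nt,
               dimnames = list(sprintf("g%03d", seq_len(ng)), tissues))
  if (na_frac > 0)
    fc[sample(length(fc), round(na_frac * length(fc)))] <- NA
  enrichment_table(fc,
                   probes = data.frame(probe_id = rownames(fc),
                                       gene_symbol = rownames(fc),
                                       stringsAsFactors = FALSE),
                   reference_tissue = ref, floor = 1)
}

# Cognate pairs of the default simulated panel, one row per pair.
default_cognate_pairs <- function() {
  panel <- default_tissue_panel()
  paired <- panel[!is.na(panel$cognate_pair), ]
  do.call(rbind, lapply(split(paired$tissue, paired$cognate_pair), sort))
}

epithelial_set <- function() {
  panel <- default_tissue_panel()
  panel$tissue[panel$epithelial]
}
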