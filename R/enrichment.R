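#' Aggregate replicate samples into tissue-level profiles
#'
#' For every probe and tissue, averages the non-missing replicate signals
#' (arithmetic mean on the raw signal scale) and, when the atlas carries
#' detection calls, records the fraction of non-missing replicates called
#' present.  A cell whose replicates are all missing stays missing.  When each
#' tissue has a single replicate (tissue-level input, as with the transcribed
#' published tables) aggregation is the identity.
#'
#' @param atlas an [atlas_matrix()].
#' @param config an [analysis_config()]; only `aggregation` is consulted.
#' @return a [tissue_profile()].
#' @export
aggregate_replicates <- function(atlas, config = analysis_config()) {
  stopifnot(inherits(atlas, "atlas_matrix"))
  tissues <- atlas_tissues(atlas)
  np <- nrow(atlas$signal)
  mean_signal <- matrix(NA_real_, np, length(tissues),
                        dimnames = list(rownames(atlas$signal), tissues))
  n_replicates <- matrix(0L, np, length(tissues), dimnames = dimnames(mean_signal))
  present_fraction <- if (is.null(atlas$calls)) NULL else mean_signal
  for (t in tissues) {
    idx <- which(atlas$samples$tissue == t)
    if (!length(idx)) stop("tissue with zero samples: ", t)
    sub <- atlas$signal[, idx, drop = FALSE]
    n_ok <- rowSums(!is.na(sub))
    n_replicates[, t] <- as.integer(n_ok)
    mean_signal[, t] <- ifelse(n_ok > 0, rowMeans(sub, na.rm = TRUE), NA_real_)
    if (!is.null(present_fraction)) {
      cl <- atlas$calls[, idx, drop = FALSE]
      present_fraction[, t] <- ifelse(
        n_ok > 0, rowSums(cl == "P", na.rm = TRUE) / n_ok, NA_real_)
    }
  }
  tissue_profile(mean_signal, probes = atlas$probes,
                 present_fraction = present_fraction,
                 n_replicates = n_replicates)
}

#' Fold-change enrichment over a reference tissue
#'
#' The workflow's core statistic: for every probe and tissue,
#' `FC = max(signal, floor) / max(reference_signal, floor)`.  The floor
#' (default 1 signal unit) bounds the ratio when either operand is at or near
#' zero — atlases of this kind contain exact zeros — and keeps the statistic
#' symmetric between numerator and denominator.  Cells missing in either
#' operand are undefined (`NA`); the reference tissue's own column is exactly 1
#' wherever the reference signal is defined.
#'
#' @param profile a [tissue_profile()] containing the reference tissue.
#' @param config an [analysis_config()]; uses `reference_tissue` and `floor`.
#' @return an [enrichment_table()] over all profile tissues.
#' @export
fold_change <- function(profile, config = analysis_config()) {
  stopifnot(inherits(profile, "tissue_profile"))
  ref <- config$reference_tissue
  if (!ref %in% profile$tissues)
    stop("reference tissue not in profile: ", ref)
  if (config$floor <= 0) stop("floor must be > 0")
  denom <- pmax(profile$mean_signal[, ref], config$floor)
  fc <- pmax(profile$mean_signal, config$floor) / denom
  fc[, ref][!is.na(profile$mean_signal[, ref])] <- 1  # exact, no fp residue
  enrichment_table(fc, probes = profile$probes, reference_tissue = ref,
                   floor = config$floor)
}

.resolve_probe_rows <- function(enrichment, gene) {
  rows <- which(enrichment$probes$probe_id == gene)
  if (!length(rows)) rows <- which(enrichment$probes$gene_symbol == gene)
  if (!length(rows)) stop("gene not found: ", gene)
  rows
}

.extreme_enrichment <- function(enrichment, gene, tissues, which_fun) {
  stopifnot(inherits(enrichment, "enrichment_table"))
  missing_t <- setdiff(tissues, colnames(enrichment$fold_change))
  if (length(missing_t))
    stop("tissues not in table: ", paste(missing_t, collapse = ", "))
  rows <- .resolve_probe_rows(enrichment, gene)
  vals <- enrichment$fold_change[rows, tissues, drop = FALSE]
  # per-gene summary over a symbol's probes: per-tissue maximum
  v <- apply(vals, 2, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  if (all(is.na(v))) stop("all cells undefined for gene: ", gene)
  target <- which_fun(v, na.rm = TRUE)
  hit <- tissues[which(!is.na(v) & v == target)][1]  # ties: first in given order
  list(tissue = hit, fold_change = unname(target))
}

#' Maximum enrichment of a gene over a tissue set
#'
#' Returns the largest defined fold change of `gene` (a probe id or gene
#' symbol; a symbol spanning several probes is summarized by the per-tissue
#' maximum) over `tissues`, with its argmax tissue.  Ties break by the order
#' of `tissues`.
#'
#' @param enrichment an [enrichment_table()].
#' @param gene probe id or gene symbol.
#' @param tissues tissue subset to scan.
#' @return list with elements `tissue` and `fold_change`.
#' @export
max_enrichment <- function(enrichment, gene, tissues)
  .extreme_enrichment(enrichment, gene, tissues, max)

#' Minimum enrichment of a gene over a tissue set
#'
#' As [max_enrichment()] with the minimum — the evidence behind the consensus
#' criterion ("enriched in every epithelium" means the minimum clears the
#' threshold).
#'
#' @inheritParams max_enrichment
#' @return list with elements `tissue` and `fold_change`.
#' @export
min_enrichment <- function(enrichment, gene, tissues)
  .extreme_enrichment(enrichment, gene, tissues, min)
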