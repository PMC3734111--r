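#' Default tissue panel for simulated atlases
#'
#' Eleven tissues mirroring a multi-tissue atlas design: four cognate
#' adult/larval epithelial pairs (salivary gland, midgut, Malpighian tubule,
#' hindgut), two non-epithelial out-group tissues, and a whole-organism
#' reference.
#'
#' @return data frame with columns `tissue`, `life_stage`, `cognate_pair`
#'   (shared label within an adult/larval pair, `NA` otherwise) and logical
#'   `epithelial`.
#' @export
default_tissue_panel <- function() {
  data.frame(
    tissue = c("adult_salivary_gland", "adult_midgut", "adult_tubule",
               "adult_hindgut", "larval_salivary_gland", "larval_midgut",
               "larval_tubule", "larval_hindgut", "adult_brain",
               "adult_testis", "whole_fly"),
    life_stage = c(rep("adult", 4), rep("larval", 4), "adult", "adult",
                   "whole"),
    cognate_pair = c("salivary_gland", "midgut", "tubule", "hindgut",
                     "salivary_gland", "midgut", "tubule", "hindgut",
                     NA, NA, NA),
    epithelial = c(rep(TRUE, 8), FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for synthetic atlases
#'
#' Defines the generative model of [generate_atlas()].  Baseline per-gene
#' expression is log-normal (strictly positive, heavily right-skewed, spanning
#' roughly 0 to 14,000 signal units at the defaults, as in Affymetrix-style
#' atlases).  Four planted gene classes: `housekeeping` (high expression in
#' every tissue), `core` (enriched by a planted fold change in all epithelial
#' tissues), `specific` (enriched in a single target tissue), and
#' `background`.  Background genes carry correlated tissue effects so that
#' cognate adult/larval tissues share transcriptome structure; replicate
#' signals are the tissue mean times multiplicative log-normal noise of the
#' stated coefficient of variation; a present call is emitted when a signal
#' exceeds the detection threshold.
#'
#' @param n_genes number of simulated genes (default 2000).
#' @param tissues tissue panel as from [default_tissue_panel()].
#' @param reference_tissue whole-organism reference column.
#' @param n_replicates biological replicates per tissue (default 4).
#' @param class_proportions named proportions for housekeeping, core,
#'   specific and background genes; must sum to 1 (defaults plant 50 core
#'   genes among 2000).
#' @param baseline_log2_mean,baseline_log2_sd log2-scale baseline expression
#'   distribution (defaults 5 and 2).
#' @param housekeeping_log2_mean,housekeeping_log2_sd baseline distribution of
#'   the housekeeping class (defaults 11 and 1).
#' @param core_fc_range planted core fold-change range (default `c(3, 10)`).
#' @param specific_fc_range planted tissue-specific fold-change range
#'   (default `c(10, 100)`).
#' @param tissue_effect_log2_sd log2 sd of background-gene tissue effects for
#'   tissues in a cognate pair (default 0.5).
#' @param unpaired_effect_log2_sd log2 sd of the background-gene tissue
#'   effect of unpaired non-reference tissues (default 1).  Out-group
#'   tissues (neuronal, germline) are more distinct from the epithelia than
#'   the epithelia are from each other.  The whole-organism reference
#'   receives no tissue effect: it represents the organism-wide average
#'   expression that every planted fold change is defined against.
#' @param cognate_strength fraction of tissue-effect variance shared within a
#'   cognate pair, in `[0, 1]` (default 0.8).
#' @param cv replicate coefficient of variation (default 0.2).
#' @param detection_threshold signal above which a replicate is called present
#'   (default 50).
#' @param rng_seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       tissues = default_tissue_panel(),
                       reference_tissue = "whole_fly",
                       n_replicates = 4L,
                       class_proportions = c(housekeeping = 0.10,
                                             core = 0.025,
                                             specific = 0.10,
                                             background = 0.775),
                       baseline_log2_mean = 5, baseline_log2_sd = 2,
                       housekeeping_log2_mean = 11, housekeeping_log2_sd = 1,
                       core_fc_range = c(3, 10),
                       specific_fc_range = c(10, 100),
                       tissue_effect_log2_sd = 0.5,
                       unpaired_effect_log2_sd = 1,
                       cognate_strength = 0.8,
                       cv = 0.2,
                       detection_threshold = 50,
                       rng_seed = 1L) {
  req <- c("housekeeping", "core", "specific", "background")
  if (!setequal(names(class_proportions), req))
    stop("class_proportions must name housekeeping, core, specific, background")
  class_proportions <- class_proportions[req]
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stop("class proportions must sum to 1")
  if (any(class_proportions < 0)) stop("class proportions must be >= 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (any(core_fc_range <= 0) || any(specific_fc_range <= 0))
    stop("planted fold-change ranges must be positive")
  if (cv < 0) stop("cv must be >= 0")
  if (cognate_strength < 0 || cognate_strength > 1)
    stop("cognate_strength must lie in [0, 1]")
  if (!reference_tissue %in% tissues$tissue)
    stop("reference_tissue must be in the tissue panel")
  structure(
    list(n_genes = as.integer(n_genes), tissues = tissues,
         reference_tissue = reference_tissue,
         n_replicates = as.integer(n_replicates),
         class_proportions = class_proportions,
         baseline_log2_mean = baseline_log2_mean,
         baseline_log2_sd = baseline_log2_sd,
         housekeeping_log2_mean = housekeeping_log2_mean,
         housekeeping_log2_sd = housekeeping_log2_sd,
         core_fc_range = core_fc_range,
         specific_fc_range = specific_fc_range,
         tissue_effect_log2_sd = tissue_effect_log2_sd,
         unpaired_effect_log2_sd = unpaired_effect_log2_sd,
         cognate_strength = cognate_strength, cv = cv,
         detection_threshold = detection_threshold,
         rng_seed = as.integer(rng_seed)),
    class = "sim_config"
  )
}

#' Generate a synthetic expression atlas with planted ground truth
#'
#' Draws an atlas from the model described in [sim_config()]:
#' \itemize{
#'   \item baseline expression per gene is log-normal (class-specific for
#'     housekeeping genes);
#'   \item core genes are multiplied by one planted fold change in every
#'     epithelial tissue, tissue-specific genes by theirs in one target tissue
#'     (targets cycle over the non-reference tissues);
#'   \item background genes receive per-tissue log-normal effects in which
#'     cognate adult/larval tissues share `cognate_strength` of the variance,
#'     the remainder being stage-specific perturbation;
#'   \item replicate signals are the tissue mean times multiplicative
#'     log-normal noise with coefficient of variation `cv` (mean 1, so the
#'     noise-free limit `cv = 0` reproduces the tissue means exactly);
#'   \item the detection call is present iff the signal exceeds
#'     `detection_threshold`, otherwise absent.
#' }
#' The planted-class construction is deliberately exact: with `cv = 0` the
#' pipeline fold change of a core gene equals its planted fold change in every
#' epithelial tissue, so the generator is its own oracle.
#'
#' @param config a [sim_config()].
#' @return list with elements `atlas` (an [atlas_matrix()] with detection
#'   calls) and `truth` (data frame `probe_id`, `gene_symbol`, `class`,
#'   `planted_fc` — 1 for non-enriched classes — and `target_tissue`).
#' @export
generate_atlas <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  n <- config$n_genes
  panel <- config$tissues
  tissues <- panel$tissue
  epithelia <- panel$tissue[panel$epithelial]
  non_ref <- setdiff(tissues, config$reference_tissue)

  counts <- round(config$class_proportions * n)
  counts["background"] <- n - sum(counts[c("housekeeping", "core", "specific")])
  if (counts["background"] < 0) stop("class proportions leave no background")
  cls <- rep(names(counts), counts)

  gene_id <- sprintf("gene%04d", seq_len(n))
  base_log2 <- ifelse(
    cls == "housekeeping",
    rnorm(n, config$housekeeping_log2_mean, config$housekeeping_log2_sd),
    rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd))
  baseline <- 2^base_log2

  planted_fc <- rep(1, n)
  target <- rep(NA_character_, n)
  is_core <- cls == "core"
  is_spec <- cls == "specific"
  planted_fc[is_core] <- runif(sum(is_core), config$core_fc_range[1],
                               config$core_fc_range[2])
  planted_fc[is_spec] <- runif(sum(is_spec), config$specific_fc_range[1],
                               config$specific_fc_range[2])
  target[is_spec] <- rep_len(non_ref, sum(is_spec))

  # tissue means
  m <- matrix(baseline, n, length(tissues), dimnames = list(gene_id, tissues))
  for (t in epithelia) m[is_core, t] <- m[is_core, t] * planted_fc[is_core]
  for (t in non_ref) {
    sel <- is_spec & target == t
    m[sel, t] <- m[sel, t] * planted_fc[sel]
  }
  # correlated tissue/composition effects on background genes only, so
  # planted fold changes of the other classes stay exact by construction
  is_bg <- cls == "background"
  if (any(is_bg)) {
    s <- config$cognate_strength
    pair_z <- list()
    for (t in non_ref) {
      p <- panel$cognate_pair[panel$tissue == t]
      if (!is.na(p)) {
        if (config$tissue_effect_log2_sd <= 0) next
        if (is.null(pair_z[[p]])) pair_z[[p]] <- rnorm(sum(is_bg))
        z <- sqrt(s) * pair_z[[p]] + sqrt(1 - s) * rnorm(sum(is_bg))
        m[is_bg, t] <- m[is_bg, t] * 2^(config$tissue_effect_log2_sd * z)
      } else {
        if (config$unpaired_effect_log2_sd <= 0) next
        m[is_bg, t] <- m[is_bg, t] *
          2^(config$unpaired_effect_log2_sd * rnorm(sum(is_bg)))
      }
    }
  }

  # replicate-level signals with multiplicative log-normal noise, mean 1
  nr <- config$n_replicates
  samples <- data.frame(
    sample_id = paste0(rep(tissues, each = nr), "_r", rep(seq_len(nr),
                                                          length(tissues))),
    tissue = rep(tissues, each = nr),
    life_stage = rep(panel$life_stage, each = nr),
    replicate = rep(seq_len(nr), length(tissues)),
    stringsAsFactors = FALSE
  )
  signal <- matrix(NA_real_, n, nrow(samples),
                   dimnames = list(gene_id, samples$sample_id))
  if (config$cv > 0) {
    sdlog <- sqrt(log(1 + config$cv^2))
    for (j in seq_len(nrow(samples))) {
      noise <- exp(rnorm(n, -sdlog^2 / 2, sdlog))
      signal[, j] <- m[, samples$tissue[j]] * noise
    }
  } else {
    for (j in seq_len(nrow(samples))) signal[, j] <- m[, samples$tissue[j]]
  }
  calls <- ifelse(signal > config$detection_threshold, "P", "A")

  atlas <- atlas_matrix(
    signal = signal,
    probes = data.frame(probe_id = gene_id, gene_symbol = gene_id,
                        stringsAsFactors = FALSE),
    samples = samples, calls = calls
  )
  truth <- data.frame(probe_id = gene_id, gene_symbol = gene_id, class = cls,
                      planted_fc = planted_fc, target_tissue = target,
                      stringsAsFactors = FALSE)
  list(atlas = atlas, truth = truth)
}

#' Precision and recall of a detected signature against planted truth
#'
#' Compares the passing genes of a [signature_result()] (or a plain character
#' vector of probe ids) with the planted members of one truth class.
#'
#' @param detected a `signature_result` or character vector of detected probe
#'   ids.
#' @param truth truth table from [generate_atlas()].
#' @param target_class truth class counted as positive (e.g. `"core"`).
#' @return list with `precision` (0 with `no_detections = TRUE` when nothing
#'   was detected), `recall`, and confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
evaluate_recovery <- function(detected, truth, target_class = "core") {
  if (!target_class %in% truth$class)
    stop("unknown target_class: ", target_class)
  det <- if (inherits(detected, "signature_result")) {
    if (!all(truth$probe_id %in% detected$table$probe_id))
      stop("detected result does not cover the truth gene universe")
    passing_genes(detected)
  } else {
    as.character(detected)
  }
  pos <- truth$probe_id[truth$class == target_class]
  tp <- length(intersect(det, pos))
  fp <- length(setdiff(det, pos))
  fn <- length(setdiff(pos, det))
  tn <- nrow(truth) - tp - fp - fn
  no_det <- (tp + fp) == 0
  list(precision = if (no_det) 0 else tp / (tp + fp),
       recall = if (length(pos)) tp / (tp + fn) else 0,
       tp = tp, fp = fp, fn = fn, tn = tn, no_detections = no_det)
}
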