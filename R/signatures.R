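#' Construct a signature result
#'
#' Container for the outcome of a signature procedure: the detection mode, a
#' per-gene evidence table with per-tissue pass flags, and a snapshot of the
#' criterion that produced it.  Usually built by [core_signature()],
#' [strict_call_signature()] or [tissue_specific_top_n()].
#'
#' @param mode one of `"consensus_fc"`, `"strict_calls"`, `"tissue_specific"`.
#' @param table data frame with columns `probe_id`, `gene_symbol`, one or more
#'   `evidence.<tissue>` columns, optional `pass.<tissue>` flags and a logical
#'   `overall_pass`.
#' @param criterion named list snapshotting the thresholds used.
#' @return object of class `signature_result`.
#' @export
signature_result <- function(mode, table, criterion) {
  mode <- match.arg(mode, c("consensus_fc", "strict_calls", "tissue_specific"))
  stopifnot(is.data.frame(table),
            all(c("probe_id", "gene_symbol", "overall_pass") %in% names(table)))
  pass_cols <- grep("^pass\\.", names(table), value = TRUE)
  if (length(pass_cols) && nrow(table)) {
    agreed <- apply(as.matrix(table[pass_cols]), 1, all)
    if (!identical(unname(agreed), unname(table$overall_pass)))
      stop("overall_pass must equal the conjunction of the per-tissue flags")
  }
  structure(list(mode = mode, table = table, criterion = criterion),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("signature_result [%s]: %d genes, %d passing\n",
              x$mode, nrow(x$table), sum(x$table$overall_pass)))
  invisible(x)
}

#' Genes passing a signature criterion
#' @param result a [signature_result()].
#' @return character vector of passing probe ids, in result order.
#' @export
passing_genes <- function(result) {
  stopifnot(inherits(result, "signature_result"))
  result$table$probe_id[result$table$overall_pass]
}

.criterion_snapshot <- function(config, extra = list()) {
  c(list(epithelial_tissues = config$epithelial_tissues,
         reference_tissue = config$reference_tissue,
         tau = config$tau, top_n = config$top_n, floor = config$floor),
    extra)
}

#' Consensus core signature across a tissue set
#'
#' The hypothesis-free detector: a gene belongs to the core signature iff its
#' fold change over the reference is defined and at least `tau` in *every*
#' tissue of `config$epithelial_tissues`.  Missing cells fail the gene —
#' consistent enrichment cannot be asserted on missing evidence.  All genes
#' (passing and failing) are retained with per-tissue flags so the criterion
#' can be audited; rows are ordered by descending minimum fold change, ties by
#' gene symbol then probe id.
#'
#' @param enrichment an [enrichment_table()] covering the epithelial tissues.
#' @param config an [analysis_config()]; uses `epithelial_tissues` and `tau`.
#' @return a [signature_result()] in `consensus_fc` mode.
#' @export
core_signature <- function(enrichment, config = analysis_config()) {
  stopifnot(inherits(enrichment, "enrichment_table"))
  tissues <- config$epithelial_tissues
  if (!length(tissues)) stop("epithelial tissue set is empty")
  missing_t <- setdiff(tissues, colnames(enrichment$fold_change))
  if (length(missing_t))
    stop("tissues not in enrichment table: ", paste(missing_t, collapse = ", "))
  fc <- enrichment$fold_change[, tissues, drop = FALSE]
  pass <- !is.na(fc) & fc >= config$tau
  overall <- rowSums(pass) == length(tissues)
  min_fc <- apply(fc, 1, function(x)
    if (all(is.na(x))) -Inf else min(x, na.rm = TRUE))
  tab <- data.frame(probe_id = enrichment$probes$probe_id,
                    gene_symbol = enrichment$probes$gene_symbol,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (t in tissues) tab[[paste0("evidence.", t)]] <- fc[, t]
  for (t in tissues) tab[[paste0("pass.", t)]] <- pass[, t]
  tab$overall_pass <- unname(overall)
  ord <- order(-min_fc, tab$gene_symbol, tab$probe_id)
  signature_result("consensus_fc", tab[ord, , drop = FALSE],
                   .criterion_snapshot(config, list(mode = "consensus_fc")))
}

#' Audit a consensus signature against its own threshold
#'
#' Lists every evidence cell below `tau` (or undefined) for the audited genes.
#' Published consensus tables can contain printed values below their stated
#' threshold — rounding of replicate-level ratios is the usual cause — and
#' this audit documents such discrepancies instead of guessing intent.
#'
#' @param result a [signature_result()] in `consensus_fc` mode.
#' @param config optional [analysis_config()] overriding the audited `tau`;
#'   defaults to the threshold recorded in `result`.
#' @param published optional character vector of probe ids or gene symbols to
#'   restrict the audit to (e.g. a published gene set); default: all genes.
#' @return data frame `(probe_id, gene_symbol, tissue, value)`, one row per
#'   violating cell, in result row order then tissue order.  Empty iff every
#'   audited gene's `overall_pass` is true at the audited `tau`.
#' @export
criterion_audit <- function(result, config = NULL, published = NULL) {
  stopifnot(inherits(result, "signature_result"))
  if (result$mode != "consensus_fc")
    stop("criterion_audit requires a consensus_fc result")
  tau <- if (is.null(config)) result$criterion$tau else config$tau
  tab <- result$table
  if (!is.null(published))
    tab <- tab[tab$probe_id %in% published | tab$gene_symbol %in% published, ,
               drop = FALSE]
  ev_cols <- grep("^evidence\\.", names(tab), value = TRUE)
  tissues <- sub("^evidence\\.", "", ev_cols)
  out <- list()
  for (i in seq_len(nrow(tab))) {
    vals <- as.numeric(tab[i, ev_cols])
    bad <- is.na(vals) | vals < tau
    if (any(bad))
      out[[length(out) + 1L]] <- data.frame(
        probe_id = tab$probe_id[i], gene_symbol = tab$gene_symbol[i],
        tissue = tissues[bad], value = vals[bad],
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(probe_id = character(), gene_symbol = character(),
                      tissue = character(), value = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Strict detection-call signature
#'
#' The stringent alternative criterion: a gene passes iff its present-call
#' fraction is at least `present_min` in every `inside` tissue and at most
#' `absent_max` in every `outside` tissue.  With the defaults this is
#' "present in all inside tissues and absent in all outside tissues" — a
#' criterion so strict that on real atlases it typically identifies no genes,
#' which motivates the fold-change consensus of [core_signature()].
#'
#' @param profile a [tissue_profile()] carrying present fractions.
#' @param config an [analysis_config()] (snapshotted into the result).
#' @param inside,outside disjoint tissue sets.
#' @param present_min minimum present fraction required inside (default 1).
#' @param absent_max maximum present fraction tolerated outside (default 0).
#' @return a [signature_result()] in `strict_calls` mode.
#' @export
strict_call_signature <- function(profile, config = analysis_config(),
                                  inside, outside,
                                  present_min = 1.0, absent_max = 0.0) {
  stopifnot(inherits(profile, "tissue_profile"))
  if (is.null(profile$present_fraction))
    stop("profile carries no detection calls")
  if (length(intersect(inside, outside)))
    stop("inside and outside tissue sets must be disjoint")
  missing_t <- setdiff(c(inside, outside), profile$tissues)
  if (length(missing_t))
    stop("tissues not in profile: ", paste(missing_t, collapse = ", "))
  pf <- profile$present_fraction
  tab <- data.frame(probe_id = profile$probes$probe_id,
                    gene_symbol = profile$probes$gene_symbol,
                    stringsAsFactors = FALSE, check.names = FALSE)
  pass <- matrix(TRUE, nrow(pf), 0)
  for (t in inside) {
    ok <- !is.na(pf[, t]) & pf[, t] >= present_min
    tab[[paste0("evidence.", t)]] <- pf[, t]
    tab[[paste0("pass.", t)]] <- ok
    pass <- cbind(pass, ok)
  }
  for (t in outside) {
    ok <- !is.na(pf[, t]) & pf[, t] <= absent_max
    tab[[paste0("evidence.", t)]] <- pf[, t]
    tab[[paste0("pass.", t)]] <- ok
    pass <- cbind(pass, ok)
  }
  tab$overall_pass <- unname(rowSums(pass) == ncol(pass))
  ord <- order(!tab$overall_pass, tab$gene_symbol, tab$probe_id)
  signature_result("strict_calls", tab[ord, , drop = FALSE],
                   .criterion_snapshot(config, list(
                     mode = "strict_calls", inside = inside, outside = outside,
                     present_min = present_min, absent_max = absent_max)))
}

#' Top-N tissue-specific genes
#'
#' Ranks genes by descending fold-change enrichment in one tissue (or, for a
#' merged adult/larval view, by the per-gene maximum over a cognate tissue
#' pair) and keeps the `config$top_n` best.  Undefined cells are excluded;
#' ties break by gene symbol then probe id.
#'
#' @param enrichment an [enrichment_table()].
#' @param tissue a tissue identifier, or a character vector of tissues whose
#'   per-gene maximum is the ranking evidence.
#' @param config an [analysis_config()]; uses `top_n`.
#' @param exclusive if `TRUE`, drop genes whose fold change in some other
#'   non-reference tissue exceeds their ranking evidence (strictly
#'   tissue-exclusive view; default off).
#' @return a [signature_result()] in `tissue_specific` mode; the ranking value
#'   is the `evidence.best` column, non-increasing down the table.
#' @export
tissue_specific_top_n <- function(enrichment, tissue,
                                  config = analysis_config(),
                                  exclusive = FALSE) {
  stopifnot(inherits(enrichment, "enrichment_table"))
  missing_t <- setdiff(tissue, colnames(enrichment$fold_change))
  if (length(missing_t))
    stop("unknown tissue: ", paste(missing_t, collapse = ", "))
  fc <- enrichment$fold_change[, tissue, drop = FALSE]
  best <- apply(fc, 1, function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  keep <- !is.na(best)
  if (exclusive) {
    others <- setdiff(colnames(enrichment$fold_change),
                      c(tissue, enrichment$reference_tissue))
    if (length(others)) {
      other_max <- apply(enrichment$fold_change[, others, drop = FALSE], 1,
                         function(x) if (all(is.na(x))) -Inf else max(x, na.rm = TRUE))
      keep <- keep & other_max <= best
    }
  }
  tab <- data.frame(probe_id = enrichment$probes$probe_id,
                    gene_symbol = enrichment$probes$gene_symbol,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (t in tissue) tab[[paste0("evidence.", t)]] <- fc[, t]
  tab$evidence.best <- unname(best)
  tab <- tab[keep, , drop = FALSE]
  ord <- order(-tab$evidence.best, tab$gene_symbol, tab$probe_id)
  tab <- tab[ord, , drop = FALSE]
  tab <- head(tab, config$top_n)
  tab$overall_pass <- rep(TRUE, nrow(tab))
  signature_result("tissue_specific", tab,
                   .criterion_snapshot(config, list(
                     mode = "tissue_specific", tissue = tissue,
                     exclusive = exclusive)))
}

#' Profile a curated gene list across tissues
#'
#' The hypothesis-led entry point: maps each curated gene onto the atlas and
#' reports its per-tissue mean signal, keeping the gene-list order and class
#' grouping.  A symbol matched by several probe sets yields one row per probe;
#' symbols absent from the atlas are flagged, not dropped.
#'
#' @param profile a [tissue_profile()].
#' @param genes a [gene_list()].
#' @param config an [analysis_config()] (unused fields tolerated).
#' @return data frame with `gene_symbol`, `class_label`, `family_label`,
#'   `probe_id`, logical `in_atlas`, then one signal column per tissue.
#' @export
profile_gene_list <- function(profile, genes, config = analysis_config()) {
  stopifnot(inherits(profile, "tissue_profile"), inherits(genes, "gene_list"))
  if (!nrow(genes)) stop("gene list is empty")
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    sym <- genes$gene_symbol[i]
    hit <- which(profile$probes$gene_symbol == sym)
    base <- genes[i, c("gene_symbol", "class_label", "family_label"),
                  drop = FALSE]
    if (!length(hit)) {
      row <- cbind(base, data.frame(probe_id = NA_character_, in_atlas = FALSE,
                                    stringsAsFactors = FALSE))
      for (t in profile$tissues) row[[t]] <- NA_real_
      rows[[length(rows) + 1L]] <- row
    } else {
      for (h in hit) {
        row <- cbind(base,
                     data.frame(probe_id = profile$probes$probe_id[h],
                                in_atlas = TRUE, stringsAsFactors = FALSE))
        for (t in profile$tissues) row[[t]] <- profile$mean_signal[h, t]
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.gene_level_signal <- function(profile, symbols, tissue) {
  # per-tissue maximum across a symbol's probes (duplicate probe sets)
  vapply(symbols, function(sym) {
    hit <- which(profile$probes$gene_symbol == sym)
    if (!length(hit)) return(NA_real_)
    v <- profile$mean_signal[hit, tissue]
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  }, numeric(1))
}

#' Dominant isoform of a gene family in one tissue
#'
#' Within a paralog family (e.g. the subunit genes of a multi-gene enzyme
#' complex), returns the member with the highest mean signal in `tissue`, its
#' signal, and the ratio of the dominant to the second-highest signal (with
#' `floor` applied to both, so a zero runner-up yields a finite ratio).  Ties
#' resolve to the lexicographically smallest symbol and are flagged ambiguous.
#'
#' @param profile a [tissue_profile()].
#' @param family character vector of gene symbols; at least one must be in the
#'   atlas.
#' @param tissue tissue identifier.
#' @param floor positive signal floor for the runner-up ratio (default 1).
#' @return list `(gene_symbol, signal, runner_up_ratio, ambiguous)`;
#'   `runner_up_ratio` is `NA` for a singleton family.
#' @export
dominant_isoform <- function(profile, family, tissue, floor = 1.0) {
  stopifnot(inherits(profile, "tissue_profile"))
  if (!tissue %in% profile$tissues) stop("unknown tissue: ", tissue)
  family <- sort(unique(as.character(family)))
  sig <- .gene_level_signal(profile, family, tissue)
  if (all(is.na(sig)))
    stop("no family member with defined signal in the atlas")
  defined <- which(!is.na(sig))
  top <- max(sig[defined])
  winners <- family[defined][sig[defined] == top]
  dominant <- winners[1]  # family already sorted lexicographically
  rest <- sig[defined][family[defined] != dominant]
  ratio <- if (!length(rest)) NA_real_
           else max(top, floor) / max(max(rest), floor)
  list(gene_symbol = dominant, signal = unname(top),
       runner_up_ratio = unname(ratio), ambiguous = length(winners) > 1)
}

#' Dominant-isoform profile of every family in a gene list
#'
#' Applies [dominant_isoform()] to each `family_label` group of a gene list in
#' each requested tissue — the check that a single paralog is favoured per
#' family across a tissue set.
#'
#' @param profile a [tissue_profile()].
#' @param genes a [gene_list()] with family labels.
#' @param tissues tissues to scan (default: all profile tissues).
#' @param floor positive signal floor for runner-up ratios.
#' @return data frame `(family_label, tissue, dominant_symbol,
#'   dominant_signal, runner_up_ratio, ambiguous)`.
#' @export
family_profile <- function(profile, genes, tissues = profile$tissues,
                           floor = 1.0) {
  stopifnot(inherits(genes, "gene_list"))
  fams <- unique(genes$family_label[!is.na(genes$family_label)])
  out <- list()
  for (fam in fams) {
    members <- genes$gene_symbol[!is.na(genes$family_label) &
                                   genes$family_label == fam]
    for (t in tissues) {
      d <- dominant_isoform(profile, members, t, floor = floor)
      out[[length(out) + 1L]] <- data.frame(
        family_label = fam, tissue = t, dominant_symbol = d$gene_symbol,
        dominant_signal = d$signal, runner_up_ratio = d$runner_up_ratio,
        ambiguous = d$ambiguous, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
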