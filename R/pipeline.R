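#' Validate a pipeline configuration
#'
#' The pipeline is driven by a single JSON document (or equivalent named
#' list).  Recognised fields:
#' \describe{
#'   \item{`seed`}{integer; seeds the simulation when the atlas is simulated.}
#'   \item{`out_dir`}{output directory; created if absent.}
#'   \item{`atlas`}{either `{"source": "simulate", "sim": {...}}` with
#'     [sim_config()] overrides, or `{"source": "files", "signal": path,
#'     "meta": path, "calls": path}` (calls optional).}
#'   \item{`analysis`}{[analysis_config()] overrides
#'     (`epithelial_tissues`, `reference_tissue`, `tau`, `top_n`, `floor`).}
#'   \item{`gene_list`}{optional path to a curated gene-list TSV.}
#'   \item{`specific_tissues`}{tissues to rank top-N lists for; default the
#'     epithelial set.}
#' }
#' A machine-readable description ships in
#' `system.file("schema", "pipeline-config.json", package = "atlasmine")`.
#'
#' @param config named list or path to a JSON file.
#' @return the validated config as a named list, with defaults filled in.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  if (!is.list(config)) stop("config must be a named list or a JSON path")
  if (is.null(config$seed)) config$seed <- 1L
  if (!is.numeric(config$seed)) stop("config field 'seed' must be an integer")
  if (is.null(config$out_dir)) stop("config field 'out_dir' is required")
  if (is.null(config$atlas) || is.null(config$atlas$source))
    stop("config field 'atlas.source' is required")
  if (!config$atlas$source %in% c("simulate", "files"))
    stop("atlas.source must be 'simulate' or 'files'")
  if (config$atlas$source == "files") {
    for (f in c("signal", "meta"))
      if (is.null(config$atlas[[f]]))
        stop("atlas.source 'files' requires atlas.", f)
  }
  if (is.null(config$analysis)) config$analysis <- list()
  known <- c("epithelial_tissues", "reference_tissue", "tau", "top_n", "floor")
  bad <- setdiff(names(config$analysis), known)
  if (length(bad))
    stop("unknown analysis fields: ", paste(bad, collapse = ", "))
  config
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full atlas-mining pipeline
#'
#' Executes both analysis branches on one atlas: the hypothesis-free branch
#' (replicate aggregation, fold-change enrichment, consensus core signature,
#' top-N tissue-specific rankings, clustering/PCA) and, when a curated gene
#' list is configured, the hypothesis-led branch (gene-list profiling).  All
#' stage outputs are written under `out_dir` and recorded, with MD5 digests,
#' in a run manifest (`manifest.json`).  Identical config and seed reproduce
#' identical output digests.
#'
#' @param config named list or JSON path; see [validate_pipeline_config()].
#' @return the run manifest, invisibly: config snapshot, seed, package
#'   version, input digests, per-stage output paths and digests, gene counts
#'   in/out of each filter, and timestamps.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

  cfg_args <- config$analysis
  acfg <- do.call(analysis_config, c(cfg_args, list(rng_seed = config$seed)))

  inputs <- list()
  truth <- NULL
  if (config$atlas$source == "simulate") {
    sim_args <- config$atlas$sim
    if (is.null(sim_args)) sim_args <- list()
    sim_args$rng_seed <- config$seed
    scfg <- .stage("simulate", do.call(sim_config, sim_args))
    gen <- .stage("simulate", generate_atlas(scfg))
    atlas <- gen$atlas
    truth <- gen$truth
  } else {
    inputs <- list(signal = unname(tools::md5sum(config$atlas$signal)),
                   meta = unname(tools::md5sum(config$atlas$meta)))
    atlas <- .stage("ingest", read_atlas(config$atlas$signal,
                                         config$atlas$meta,
                                         config$atlas$calls))
  }

  outputs <- list()
  counts <- list(genes = nrow(atlas$signal),
                 tissues = length(atlas_tissues(atlas)))
  emit <- function(name, path) {
    outputs[[name]] <<- list(path = path,
                             md5 = unname(tools::md5sum(path)))
  }

  profile <- .stage("aggregate", aggregate_replicates(atlas, acfg))
  p <- file.path(out_dir, "tissue_profile.tsv")
  write_table(profile, p); emit("tissue_profile", p)

  enr <- .stage("enrich", fold_change(profile, acfg))
  p <- file.path(out_dir, "enrichment.tsv")
  write_table(enr, p); emit("enrichment", p)

  core <- .stage("core", core_signature(enr, acfg))
  counts$core_pass <- sum(core$table$overall_pass)
  p <- file.path(out_dir, "core_signature.tsv")
  write_table(core, p); emit("core_signature", p)
  p <- file.path(out_dir, "core_report.tsv")
  render_report(core, style = "consensus", path = p); emit("core_report", p)

  spec_tissues <- config$specific_tissues
  if (is.null(spec_tissues)) spec_tissues <- acfg$epithelial_tissues
  specific <- list()
  for (t in spec_tissues) {
    s <- .stage("specific", tissue_specific_top_n(enr, t, acfg))
    specific[[t]] <- s
    counts[[paste0("specific_", t)]] <- nrow(s$table)
    p <- file.path(out_dir, paste0("specific_", t, ".tsv"))
    write_table(s, p); emit(paste0("specific_", t), p)
  }
  p <- file.path(out_dir, "topn_report.tsv")
  render_report(specific, style = "topn", path = p); emit("topn_report", p)

  if (!is.null(config$gene_list)) {
    inputs$gene_list <- unname(tools::md5sum(config$gene_list))
    gl <- .stage("profile", read_gene_list(config$gene_list))
    gp <- .stage("profile", profile_gene_list(profile, gl, acfg))
    counts$gene_list_found <- sum(gp$in_atlas)
    counts$gene_list_missing <- sum(!gp$in_atlas)
    p <- file.path(out_dir, "gene_list_profile.tsv")
    render_report(gp, style = "genelist", path = p); emit("gene_list_profile", p)
  }

  # cluster tissues only: the whole-organism reference is a mixture, not a
  # tissue, and is excluded from transcriptome comparisons
  clus_prof <- subset_tissues(profile,
                              setdiff(profile$tissues, acfg$reference_tissue))
  hc <- .stage("cluster", hcluster_tissues(clus_prof))
  p <- file.path(out_dir, "dendrogram.nwk")
  dendrogram_newick(hc, p); emit("dendrogram", p)
  k <- min(2L, length(clus_prof$tissues) - 1L)
  pca <- .stage("cluster", pca_tissues(clus_prof, k = k))
  p <- file.path(out_dir, "pca_scores.tsv")
  sc <- data.frame(tissue = rownames(pca$scores), pca$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(sc, p); emit("pca_scores", p)

  if (!is.null(truth)) {
    rec <- evaluate_recovery(core, truth, "core")
    counts$core_recovery <- rec[c("precision", "recall", "tp", "fp", "fn")]
    p <- file.path(out_dir, "truth.tsv")
    .write_tsv(truth, p); emit("truth", p)
  }

  manifest <- list(
    tool = "atlasmine",
    version = as.character(utils::packageVersion("atlasmine")),
    seed = config$seed,
    config = config,
    inputs = inputs,
    counts = counts,
    outputs = outputs,
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest: atlasmine %s, seed %d, %d outputs in %s\n",
              x$version, x$seed, length(x$outputs), x$config$out_dir))
  invisible(x)
}

#' Render a result as a publication-style table
#'
#' Three layouts: `"consensus"` renders a consensus [signature_result()] as gene,
#' per-epithelium fold changes, a description column and a pass flag (all
#' audited rows are kept, so the pass column documents the criterion);
#' `"genelist"` renders a [profile_gene_list()] matrix grouped by class label;
#' `"topn"` renders one or more tissue-specific results as ranked rows per
#' tissue.
#'
#' @param results a `signature_result` (consensus), a gene-list profile data
#'   frame (genelist), or a (list of) `tissue_specific` results (topn).
#' @param style one of `"genelist"`, `"consensus"`, `"topn"`.
#' @param descriptions optional named character vector (by probe id) filling
#'   the description column of consensus style.
#' @param path optional TSV output path.
#' @return the report as a data frame; written to `path` when given.
#' @export
render_report <- function(results, style = c("consensus", "genelist", "topn"),
                          descriptions = NULL, path = NULL) {
  style <- match.arg(style)
  rep_df <- switch(style,
    consensus = {
      stopifnot(inherits(results, "signature_result"))
      tab <- results$table
      ev <- grep("^evidence\\.", names(tab), value = TRUE)
      out <- data.frame(gene_symbol = tab$gene_symbol,
                        stringsAsFactors = FALSE, check.names = FALSE)
      for (col in ev) out[[sub("^evidence\\.", "", col)]] <- tab[[col]]
      out$description <- if (is.null(descriptions)) rep("", nrow(tab))
                         else unname(descriptions[tab$probe_id])
      out$pass <- ifelse(tab$overall_pass, "pass", "fail")
      out
    },
    genelist = {
      stopifnot(is.data.frame(results), "class_label" %in% names(results))
      results[order(match(results$class_label,
                          unique(results$class_label))), , drop = FALSE]
    },
    topn = {
      if (inherits(results, "signature_result")) results <- list(results)
      if (is.null(names(results)))
        names(results) <- vapply(results, function(r)
          paste(r$criterion$tissue, collapse = "+"), character(1))
      rows <- lapply(names(results), function(nm) {
        tab <- results[[nm]]$table
        if (!nrow(tab)) return(NULL)
        data.frame(tissue = nm, rank = seq_len(nrow(tab)),
                   probe_id = tab$probe_id, gene_symbol = tab$gene_symbol,
                   fold_change = tab$evidence.best,
                   stringsAsFactors = FALSE)
      })
      nulls <- vapply(rows, is.null, logical(1))
      if (all(nulls))
        data.frame(tissue = character(), rank = integer(),
                   probe_id = character(), gene_symbol = character(),
                   fold_change = numeric(), stringsAsFactors = FALSE)
      else do.call(rbind, rows[!nulls])
    }
  )
  rownames(rep_df) <- NULL
  if (!is.null(path)) .write_tsv(rep_df, path)
  rep_df
}
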