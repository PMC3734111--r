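#' @importFrom stats cor prcomp runif rnorm setNames sd
#' @importFrom utils read.delim write.table head
NULL

# Canonical detection-call codes. Input files use P/M/A; blank cells are missing.
.CALL_LEVELS <- c("P", "M", "A")

#' Construct a replicate-level atlas matrix
#'
#' An `atlas_matrix` is the raw input of every analysis stage: a probes x
#' samples signal matrix (arbitrary non-negative fluorescence units, `NA` for
#' missing cells), optional per-cell detection calls (`"P"`/`"M"`/`"A"`, `NA`
#' missing), a probe table and a sample table.  Probe identifiers must be
#' unique; gene symbols may repeat, because several probe sets can interrogate
#' the same gene.
#'
#' @param signal numeric matrix, probes x samples; rownames are probe ids,
#'   colnames are sample ids. Values must be `>= 0` or `NA` (missing).
#' @param probes data frame with columns `probe_id`, `gene_symbol`, one row per
#'   signal row.
#' @param samples data frame with columns `sample_id`, `tissue`, `life_stage`
#'   (one of `"adult"`, `"larval"`, `"whole"`, `"other"`), `replicate`
#'   (positive integer); one row per signal column.  `(tissue, replicate)`
#'   pairs must be unique.
#' @param calls optional character matrix of detection calls, same shape and
#'   dimnames as `signal`.
#' @return an object of class `atlas_matrix`.
#' @export
atlas_matrix <- function(signal, probes, samples, calls = NULL) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  stopifnot(
    all(c("probe_id", "gene_symbol") %in% names(probes)),
    all(c("sample_id", "tissue", "life_stage", "replicate") %in% names(samples)),
    nrow(probes) == nrow(signal),
    nrow(samples) == ncol(signal)
  )
  if (anyDuplicated(probes$probe_id))
    stop("duplicate probe_id: ", paste(unique(probes$probe_id[duplicated(probes$probe_id)]), collapse = ", "))
  if (any(signal < 0, na.rm = TRUE))
    stop("negative signal values are not allowed")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in metadata")
  if (anyDuplicated(samples[, c("tissue", "replicate")]))
    stop("(tissue, replicate) pairs must be unique")
  if (!all(samples$life_stage %in% c("adult", "larval", "whole", "other")))
    stop("life_stage must be one of adult, larval, whole, other")
  if (any(samples$replicate < 1))
    stop("replicate indices must be positive")
  rownames(signal) <- probes$probe_id
  colnames(signal) <- samples$sample_id
  if (!is.null(calls)) {
    calls <- as.matrix(calls)
    stopifnot(all(dim(calls) == dim(signal)))
    bad <- !(calls %in% .CALL_LEVELS) & !is.na(calls)
    if (any(bad))
      stop("detection calls must be P, M, A or missing")
    dimnames(calls) <- dimnames(signal)
  }
  structure(
    list(signal = signal, calls = calls, probes = probes, samples = samples),
    class = "atlas_matrix"
  )
}

#' @export
print.atlas_matrix <- function(x, ...) {
  cat(sprintf(
    "atlas_matrix: %d probes x %d samples (%d tissues)%s\n",
    nrow(x$signal), ncol(x$signal), length(unique(x$samples$tissue)),
    if (is.null(x$calls)) "" else ", with detection calls"
  ))
  invisible(x)
}

#' Tissues present in an atlas
#' @param atlas an `atlas_matrix`.
#' @return character vector of unique tissue identifiers, in sample order.
#' @export
atlas_tissues <- function(atlas) unique(atlas$samples$tissue)

#' Read an atlas from TSV files
#'
#' The signal file must have `probe_id` and `gene_symbol` columns followed by
#' one numeric column per sample; the metadata file has one row per sample
#' (`sample_id`, `tissue`, `life_stage`, `replicate`).  An optional calls file
#' has the same shape as the signal file with values P/M/A.  Blank cells in
#' either matrix become missing (`NA`), never zero.
#'
#' @param signal_path path to the signal TSV.
#' @param meta_path path to the sample metadata TSV.
#' @param calls_path optional path to the detection-call TSV.
#' @return an [atlas_matrix()].
#' @export
read_atlas <- function(signal_path, meta_path, calls_path = NULL) {
  sig <- read.delim(signal_path, check.names = FALSE, colClasses = "character",
                    na.strings = "")
  if (!all(c("probe_id", "gene_symbol") %in% names(sig)))
    stop("signal file must have probe_id and gene_symbol columns")
  meta <- read.delim(meta_path, check.names = FALSE, stringsAsFactors = FALSE)
  sample_cols <- setdiff(names(sig), c("probe_id", "gene_symbol"))
  if (!setequal(sample_cols, meta$sample_id))
    stop("sample columns and metadata sample_id do not match")
  mat <- vapply(sig[meta$sample_id], function(col) as.numeric(col),
                numeric(nrow(sig)))
  mat <- matrix(mat, nrow = nrow(sig),
                dimnames = list(sig$probe_id, meta$sample_id))
  calls <- NULL
  if (!is.null(calls_path)) {
    cl <- read.delim(calls_path, check.names = FALSE, colClasses = "character",
                     na.strings = "")
    if (!setequal(setdiff(names(cl), c("probe_id", "gene_symbol")), meta$sample_id) ||
        nrow(cl) != nrow(sig) || !all(cl$probe_id == sig$probe_id))
      stop("calls file does not match the signal file")
    calls <- as.matrix(cl[meta$sample_id])
    dimnames(calls) <- dimnames(mat)
  }
  atlas_matrix(
    signal = mat,
    probes = data.frame(probe_id = sig$probe_id, gene_symbol = sig$gene_symbol,
                        stringsAsFactors = FALSE),
    samples = meta,
    calls = calls
  )
}

#' Read a curated gene list
#'
#' A gene list is the hypothesis-led entry point: curated symbols grouped under
#' functional class labels (e.g. "V-ATPase subunits"), optionally with a
#' within-class family label used for dominant-isoform selection.
#'
#' @param path TSV with columns `gene_symbol`, `class_label` and optionally
#'   `family_label`.
#' @return a data frame of class `gene_list`.
#' @export
read_gene_list <- function(path) {
  gl <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = "")
  if (!all(c("gene_symbol", "class_label") %in% names(gl)))
    stop("gene list must have gene_symbol and class_label columns")
  if (!"family_label" %in% names(gl)) gl$family_label <- NA_character_
  gene_list(gl$gene_symbol, gl$class_label, gl$family_label)
}

#' @rdname read_gene_list
#' @param gene_symbol,class_label,family_label vectors of equal length;
#'   `class_label` must be non-empty for every entry.
#' @export
gene_list <- function(gene_symbol, class_label, family_label = NA_character_) {
  if (any(is.na(class_label) | !nzchar(class_label)))
    stop("class_label must be non-empty for every entry")
  gl <- data.frame(gene_symbol = as.character(gene_symbol),
                   class_label = as.character(class_label),
                   family_label = as.character(family_label),
                   stringsAsFactors = FALSE)
  class(gl) <- c("gene_list", "data.frame")
  gl
}

#' Analysis configuration
#'
#' Bundles the tunable constants of the workflow.  Defaults mirror the
#' FlyAtlas epithelial study design: eight transporting epithelia (adult and
#' larval salivary gland, midgut, Malpighian tubule and hindgut), fold change
#' measured against the adult whole organism, a consensus enrichment threshold
#' `tau = 2.5`, top-N specificity lists of 50 genes, and a signal floor of 1
#' unit applied to both sides of every ratio.
#'
#' @param epithelial_tissues ordered character vector of the tissue set over
#'   which consensus enrichment is required.
#' @param reference_tissue tissue used as the fold-change denominator; must not
#'   be one of `epithelial_tissues`.
#' @param tau positive consensus enrichment threshold.
#' @param top_n positive integer, size of tissue-specific rankings.
#' @param floor positive signal floor (same units as the signal matrix).
#' @param aggregation replicate aggregation statistic; only `"mean"`.
#' @param rng_seed integer seed recorded with results.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(epithelial_tissues = c(
                              "adult_salivary_gland", "adult_midgut",
                              "adult_tubule", "adult_hindgut",
                              "larval_salivary_gland", "larval_midgut",
                              "larval_tubule", "larval_hindgut"),
                            reference_tissue = "whole_fly",
                            tau = 2.5, top_n = 50L, floor = 1.0,
                            aggregation = "mean", rng_seed = 1L) {
  stopifnot(is.numeric(tau), length(tau) == 1, is.numeric(top_n),
            is.numeric(floor), length(floor) == 1)
  if (tau <= 0) stop("tau must be > 0")
  if (top_n < 1) stop("top_n must be >= 1")
  if (floor <= 0) stop("floor must be > 0")
  aggregation <- match.arg(aggregation, "mean")
  if (reference_tissue %in% epithelial_tissues)
    stop("reference_tissue must not be one of epithelial_tissues")
  structure(
    list(epithelial_tissues = epithelial_tissues,
         reference_tissue = reference_tissue,
         tau = tau, top_n = as.integer(top_n), floor = floor,
         aggregation = aggregation, rng_seed = as.integer(rng_seed)),
    class = "analysis_config"
  )
}

# ---- tissue_profile ---------------------------------------------------------

#' Construct a tissue profile
#'
#' Per probe x tissue aggregates: mean signal over non-missing replicates, the
#' fraction of non-missing replicates called present, and the replicate count
#' behind each cell.  Usually produced by [aggregate_replicates()].
#'
#' @param mean_signal numeric matrix probes x tissues (`NA` = all replicates
#'   missing).
#' @param probes probe table as in [atlas_matrix()].
#' @param present_fraction optional matrix in `[0, 1]`, same shape.
#' @param n_replicates integer matrix of contributing replicate counts.
#' @return object of class `tissue_profile`.
#' @export
tissue_profile <- function(mean_signal, probes, present_fraction = NULL,
                           n_replicates = NULL) {
  mean_signal <- as.matrix(mean_signal)
  if (any(mean_signal < 0, na.rm = TRUE)) stop("mean signals must be >= 0")
  if (!is.null(present_fraction)) {
    present_fraction <- as.matrix(present_fraction)
    if (any(present_fraction < 0 | present_fraction > 1, na.rm = TRUE))
      stop("present_fraction must lie in [0, 1]")
  }
  if (is.null(n_replicates)) {
    n_replicates <- matrix(1L, nrow(mean_signal), ncol(mean_signal),
                           dimnames = dimnames(mean_signal))
    n_replicates[is.na(mean_signal)] <- 0L
  }
  if (any(n_replicates[!is.na(mean_signal)] < 1))
    stop("n_replicates must be >= 1 for every non-missing cell")
  rownames(mean_signal) <- probes$probe_id
  structure(
    list(mean_signal = mean_signal, present_fraction = present_fraction,
         n_replicates = n_replicates, probes = probes,
         tissues = colnames(mean_signal)),
    class = "tissue_profile"
  )
}

#' Restrict a tissue profile to a tissue subset
#'
#' Used e.g. to cluster tissue transcriptomes without the whole-organism
#' reference column, which is a mixture rather than a tissue.
#'
#' @param profile a [tissue_profile()].
#' @param tissues tissues to keep, in the requested order.
#' @return a [tissue_profile()] over `tissues`.
#' @export
subset_tissues <- function(profile, tissues) {
  stopifnot(inherits(profile, "tissue_profile"))
  missing_t <- setdiff(tissues, profile$tissues)
  if (length(missing_t))
    stop("tissues not in profile: ", paste(missing_t, collapse = ", "))
  tissue_profile(
    profile$mean_signal[, tissues, drop = FALSE],
    probes = profile$probes,
    present_fraction = if (is.null(profile$present_fraction)) NULL
                       else profile$present_fraction[, tissues, drop = FALSE],
    n_replicates = profile$n_replicates[, tissues, drop = FALSE]
  )
}

#' @export
print.tissue_profile <- function(x, ...) {
  cat(sprintf("tissue_profile: %d probes x %d tissues%s\n",
              nrow(x$mean_signal), length(x$tissues),
              if (is.null(x$present_fraction)) "" else ", with present fractions"))
  invisible(x)
}

# ---- enrichment_table -------------------------------------------------------

#' Construct a fold-change enrichment table
#'
#' Per probe x tissue fold change over a reference tissue.  Defined cells are
#' strictly positive; `NA` marks cells where either operand was missing.  If
#' the reference tissue is among the columns its fold change is exactly 1.
#'
#' @param fold_change numeric matrix probes x tissues.
#' @param probes probe table.
#' @param reference_tissue denominator tissue identifier.
#' @param floor positive signal floor that was applied to both operands.
#' @return object of class `enrichment_table`.
#' @export
enrichment_table <- function(fold_change, probes, reference_tissue, floor) {
  fold_change <- as.matrix(fold_change)
  storage.mode(fold_change) <- "double"
  if (any(fold_change <= 0, na.rm = TRUE))
    stop("fold changes must be positive wherever defined")
  if (floor <= 0) stop("floor must be > 0")
  if (reference_tissue %in% colnames(fold_change)) {
    ref <- fold_change[, reference_tissue]
    if (any(ref[!is.na(ref)] != 1))
      stop("fold change of the reference tissue against itself must be 1")
  }
  rownames(fold_change) <- probes$probe_id
  structure(
    list(fold_change = fold_change, probes = probes,
         reference_tissue = reference_tissue, floor = floor),
    class = "enrichment_table"
  )
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("enrichment_table: %d probes x %d tissues, reference '%s', floor %g\n",
              nrow(x$fold_change), ncol(x$fold_change), x$reference_tissue,
              x$floor))
  invisible(x)
}

#' Load the transcribed published fold-change table
#'
#' Returns the bundled 25-gene, 8-epithelium fold-change fixture (fold change
#' over the adult whole organism) as an [enrichment_table()], with the printed
#' gene descriptions attached as `attr(x, "descriptions")`.
#'
#' @return an `enrichment_table` over the eight epithelial tissues.
#' @export
load_published_enrichment <- function() {
  path <- system.file("extdata", "flyatlas_epithelial_foldchange.tsv",
                      package = "atlasmine", mustWork = TRUE)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  tissue_cols <- setdiff(names(df), c("probe_id", "gene_symbol", "description"))
  fc <- as.matrix(df[tissue_cols])
  rownames(fc) <- df$probe_id
  et <- enrichment_table(
    fc, probes = df[, c("probe_id", "gene_symbol")],
    reference_tissue = "whole_fly", floor = 1.0
  )
  attr(et, "descriptions") <- setNames(df$description, df$probe_id)
  et
}

#' Load the transcribed published signal matrix
#'
#' Returns the bundled 102-probe, 11-tissue signal fixture as an
#' [atlas_matrix()] (tissue-level values; each tissue modeled as a single
#' replicate), together with its curated gene list.
#'
#' @return a list with elements `atlas` and `gene_list`.
#' @export
load_published_signals <- function() {
  ext <- function(f) system.file("extdata", f, package = "atlasmine",
                                 mustWork = TRUE)
  list(
    atlas = read_atlas(ext("flyatlas_signals.tsv"),
                       ext("flyatlas_samples.tsv")),
    gene_list = read_gene_list(ext("flyatlas_genelist.tsv"))
  )
}

# ---- writers / readers ------------------------------------------------------

.fmt_num <- function(x) {
  out <- ifelse(is.na(x), "", formatC(signif(x, 6), format = "g", digits = 6))
  out
}

.write_tsv <- function(df, path, meta = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(paste0("#", jsonlite::toJSON(meta, auto_unbox = TRUE)), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE, na = "")
  invisible(path)
}

.read_tsv_meta <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- NULL
  skip <- 0L
  if (startsWith(first, "#")) {
    meta <- jsonlite::fromJSON(sub("^#", "", first))
    skip <- 1L
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   skip = skip, na.strings = "")
  list(meta = meta, df = df)
}

#' Write a result table to TSV
#'
#' Serializes a [tissue_profile()], [enrichment_table()] or
#' [signature_result()] to a tab-separated file with a deterministic column
#' order (`probe_id`, `gene_symbol`, then tissues in table order).  Numeric
#' values are written at 6 significant digits and structural metadata
#' (reference tissue, floor, criterion snapshot) goes into a single leading
#' `#`-prefixed JSON line, so the matching reader reproduces the object.
#'
#' @param result the object to serialize.
#' @param path output path.
#' @param ... unused.
#' @return `path`, invisibly.
#' @export
write_table <- function(result, path, ...) UseMethod("write_table")

#' @export
write_table.tissue_profile <- function(result, path, ...) {
  df <- data.frame(probe_id = result$probes$probe_id,
                   gene_symbol = result$probes$gene_symbol,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (t in result$tissues) {
    df[[t]] <- .fmt_num(result$mean_signal[, t])
    if (!is.null(result$present_fraction))
      df[[paste0(t, ".present_fraction")]] <- .fmt_num(result$present_fraction[, t])
    df[[paste0(t, ".n")]] <- result$n_replicates[, t]
  }
  .write_tsv(df, path, meta = list(kind = "tissue_profile",
                                   has_calls = !is.null(result$present_fraction)))
}

#' @export
write_table.enrichment_table <- function(result, path, ...) {
  df <- data.frame(probe_id = result$probes$probe_id,
                   gene_symbol = result$probes$gene_symbol,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (t in colnames(result$fold_change))
    df[[t]] <- .fmt_num(result$fold_change[, t])
  .write_tsv(df, path, meta = list(kind = "enrichment_table",
                                   reference_tissue = result$reference_tissue,
                                   floor = result$floor))
}

#' @export
write_table.signature_result <- function(result, path, ...) {
  tab <- result$table
  df <- tab[, c("probe_id", "gene_symbol"), drop = FALSE]
  ev <- grep("^evidence\\.", names(tab), value = TRUE)
  for (col in ev) df[[col]] <- .fmt_num(tab[[col]])
  for (col in grep("^pass\\.", names(tab), value = TRUE))
    df[[col]] <- ifelse(tab[[col]], "pass", "fail")
  df$overall_pass <- ifelse(tab$overall_pass, "pass", "fail")
  .write_tsv(df, path, meta = list(kind = "signature_result",
                                   mode = result$mode,
                                   criterion = result$criterion))
}

#' Read back a result table written by [write_table()]
#'
#' Dispatches on the `kind` recorded in the file's metadata line.
#'
#' @param path a TSV produced by [write_table()].
#' @return the reconstructed object.
#' @export
read_table <- function(path) {
  parsed <- .read_tsv_meta(path)
  meta <- parsed$meta
  df <- parsed$df
  if (is.null(meta) || is.null(meta$kind))
    stop("file does not carry atlasmine table metadata")
  probes <- data.frame(probe_id = as.character(df$probe_id),
                       gene_symbol = as.character(df$gene_symbol),
                       stringsAsFactors = FALSE)
  n <- nrow(df)
  num_mat <- function(cols, names_out = cols) {
    m <- matrix(NA_real_, n, length(cols),
                dimnames = list(probes$probe_id, names_out))
    for (i in seq_along(cols)) m[, i] <- as.numeric(df[[cols[i]]])
    m
  }
  switch(meta$kind,
    tissue_profile = {
      cols <- setdiff(names(df), c("probe_id", "gene_symbol"))
      tissues <- cols[!grepl("\\.(present_fraction|n)$", cols)]
      pf <- NULL
      if (isTRUE(meta$has_calls))
        pf <- num_mat(paste0(tissues, ".present_fraction"), tissues)
      nr <- num_mat(paste0(tissues, ".n"), tissues)
      storage.mode(nr) <- "integer"
      nr[is.na(nr)] <- 0L
      tissue_profile(num_mat(tissues), probes, present_fraction = pf,
                     n_replicates = nr)
    },
    enrichment_table = {
      tissues <- setdiff(names(df), c("probe_id", "gene_symbol"))
      enrichment_table(num_mat(tissues), probes,
                       reference_tissue = meta$reference_tissue,
                       floor = meta$floor)
    },
    signature_result = {
      tab <- probes
      for (col in grep("^evidence\\.", names(df), value = TRUE))
        tab[[col]] <- as.numeric(df[[col]])
      for (col in grep("^pass\\.", names(df), value = TRUE))
        tab[[col]] <- df[[col]] == "pass"
      tab$overall_pass <- if (n) df$overall_pass == "pass" else logical(0)
      signature_result(mode = meta$mode, table = tab, criterion = meta$criterion)
    },
    stop("unknown table kind: ", meta$kind)
  )
}
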