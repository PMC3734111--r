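.log_profile <- function(profile, tissues = profile$tissues) {
  log2(profile$mean_signal[, tissues, drop = FALSE] + 1)
}

#' Correlation distance between tissue transcriptomes
#'
#' `1 - Pearson(r)` computed on `log2(signal + 1)` over the genes defined in
#' both tissues — the standard scale-free transcriptome distance; values lie
#' in `[0, 2]`.  With `t1`/`t2` given, returns that single distance; without
#' them, the full symmetric distance matrix over all profile tissues.
#'
#' @param profile a [tissue_profile()].
#' @param t1,t2 optional tissue identifiers.
#' @param transform signal transform; only `"log2p1"`.
#' @return a number, or a symmetric matrix with zero diagonal.
#' @export
tissue_distance <- function(profile, t1 = NULL, t2 = NULL,
                            transform = "log2p1") {
  stopifnot(inherits(profile, "tissue_profile"))
  transform <- match.arg(transform, "log2p1")
  lg <- .log_profile(profile)
  pair_dist <- function(a, b) {
    ok <- !is.na(lg[, a]) & !is.na(lg[, b])
    if (sum(ok) < 3)
      stop("fewer than 3 genes defined in both tissues: ", a, ", ", b)
    1 - cor(lg[ok, a], lg[ok, b])
  }
  if (!is.null(t1) || !is.null(t2)) {
    if (is.null(t1) || is.null(t2)) stop("give both tissues or neither")
    if (!all(c(t1, t2) %in% profile$tissues))
      stop("unknown tissue")
    return(pair_dist(t1, t2))
  }
  tissues <- profile$tissues
  d <- matrix(0, length(tissues), length(tissues),
              dimnames = list(tissues, tissues))
  for (i in seq_along(tissues))
    for (j in seq_len(i - 1L)) {
      d[i, j] <- d[j, i] <- pair_dist(tissues[i], tissues[j])
    }
  d
}

#' Hierarchical clustering of tissue transcriptomes
#'
#' Agglomerative clustering of tissues on the [tissue_distance()] matrix.
#' Average linkage (the default) yields an ultrametric tree: merge heights are
#' non-decreasing from leaves to root.  Tissues are processed in name order so
#' the result is reproducible regardless of input column order.
#'
#' @param profile a [tissue_profile()] with at least 2 tissues.
#' @param linkage agglomeration method; only `"average"`.
#' @return an object of class `hclust` over the tissue leaves.
#' @export
hcluster_tissues <- function(profile, linkage = "average") {
  stopifnot(inherits(profile, "tissue_profile"))
  linkage <- match.arg(linkage, "average")
  if (length(profile$tissues) < 2) stop("need at least 2 tissues to cluster")
  d <- tissue_distance(profile)
  ord <- order(colnames(d))
  d <- d[ord, ord]
  stats::hclust(stats::as.dist(d), method = linkage)
}

#' Newick serialization of a tissue dendrogram
#'
#' Branch lengths are merge-height differences, so leaf-to-root path lengths
#' reproduce the merge heights.
#'
#' @param hc an `hclust` from [hcluster_tissues()].
#' @param path optional file to write; otherwise the string is returned.
#' @return the Newick string, invisibly when written to `path`.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# Leaf sets of every internal node of an hclust tree.
.clade_sets <- function(hc) {
  n <- nrow(hc$merge)
  sets <- vector("list", n)
  for (i in seq_len(n)) {
    kids <- hc$merge[i, ]
    get <- function(k) if (k < 0) hc$labels[-k] else sets[[k]]
    sets[[i]] <- sort(c(get(kids[1]), get(kids[2])))
  }
  sets
}

#' Does a tissue group form a clade?
#'
#' `TRUE` iff some node of the dendrogram has exactly `group` as its leaf set
#' (the whole tissue set is trivially a clade).
#'
#' @param hc an `hclust` over tissues.
#' @param group character vector of tissue labels.
#' @return logical scalar.
#' @export
is_clade <- function(hc, group) {
  group <- sort(unique(group))
  if (setequal(group, hc$labels)) return(TRUE)
  any(vapply(.clade_sets(hc), function(s) identical(s, group), logical(1)))
}

#' Sibling status of cognate tissue pairs
#'
#' For each adult/larval cognate pair, reports whether the two tissues are
#' siblings — i.e. form a two-leaf clade — in the dendrogram.  This is the
#' qualitative structure expected of tissue atlases: cognate adult and larval
#' transcriptomes cluster together despite metamorphic remodelling.
#'
#' @param hc an `hclust` over tissues.
#' @param pairs two-column matrix or data frame of cognate tissue labels.
#' @return logical vector, one element per pair, named `adult|larval`.
#' @export
cognate_siblings <- function(hc, pairs) {
  pairs <- as.matrix(pairs)
  out <- logical(nrow(pairs))
  names(out) <- paste(pairs[, 1], pairs[, 2], sep = "|")
  for (i in seq_len(nrow(pairs)))
    out[i] <- is_clade(hc, pairs[i, ])
  out
}

#' PCA of tissue transcriptome profiles
#'
#' Principal component analysis of centered `log2(signal + 1)` tissue
#' vectors (tissues as observations, genes as variables; genes with any
#' missing value are dropped).  Component signs are fixed by making each
#' component's largest-magnitude gene loading positive, so results are
#' bit-reproducible.
#'
#' @param profile a [tissue_profile()].
#' @param k number of components, at most `n_tissues - 1`.
#' @return object of class `pca_result`: `scores` (tissues x k),
#'   `loadings`, `explained_variance` (fractions over all components, first
#'   `k` reported), `center`.
#' @export
pca_tissues <- function(profile, k = 2L) {
  stopifnot(inherits(profile, "tissue_profile"))
  nt <- length(profile$tissues)
  if (k < 1 || k > nt - 1) stop("k must be between 1 and n_tissues - 1")
  lg <- .log_profile(profile)
  keep <- rowSums(is.na(lg)) == 0
  x <- t(lg[keep, , drop = FALSE])  # tissues x genes
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  ncomp <- min(k, ncol(p$rotation))
  scores <- p$x[, seq_len(ncomp), drop = FALSE]
  loadings <- p$rotation[, seq_len(ncomp), drop = FALSE]
  for (j in seq_len(ncomp)) {
    flip <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (flip < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev[seq_len(ncomp)],
                 explained_variance_all = ev, center = p$center,
                 full_scores = p$x, full_loadings = p$rotation),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d tissues, %d components (%.1f%% variance)\n",
              nrow(x$scores), ncol(x$scores),
              100 * sum(x$explained_variance)))
  invisible(x)
}

# Mean silhouette of `group` against the rest, Euclidean, direct formula.
.mean_silhouette <- function(scores, group) {
  labels <- rownames(scores)
  in_g <- labels %in% group
  d <- as.matrix(stats::dist(scores))
  s <- vapply(which(in_g), function(i) {
    a <- mean(d[i, in_g & seq_along(labels) != i])
    b <- mean(d[i, !in_g])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Cohesion of a tissue group in ordination and tree space
#'
#' Reports (a) the mean silhouette of `group` versus all other tissues in PCA
#' score space (positive means the group is more compact than its separation
#' from the rest) and (b) whether the group forms a connected subtree (clade)
#' of the dendrogram.
#'
#' @param pca a `pca_result` from [pca_tissues()], or `NULL` to skip the
#'   silhouette.
#' @param hc an `hclust` from [hcluster_tissues()], or `NULL` to skip the
#'   clade check.
#' @param group tissue set of size at least 2.
#' @return list with `silhouette` (or `NA`) and `is_subtree` (or `NA`).
#' @export
group_cohesion <- function(pca = NULL, hc = NULL, group) {
  if (length(group) < 2) stop("group must contain at least 2 tissues")
  sil <- NA_real_
  if (!is.null(pca)) {
    stopifnot(inherits(pca, "pca_result"))
    if (!all(group %in% rownames(pca$scores))) stop("group not in PCA scores")
    if (all(rownames(pca$scores) %in% group)) {
      sil <- NA_real_  # no out-group to compare against
    } else {
      sil <- .mean_silhouette(pca$scores, group)
    }
  }
  subtree <- NA
  if (!is.null(hc)) {
    if (!all(group %in% hc$labels)) stop("group not in dendrogram")
    subtree <- is_clade(hc, group)
  }
  list(silhouette = sil, is_subtree = subtree)
}
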