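## Expression analytics: correlation, hierarchical clustering, PCA and
## classical MDS over any expression table. Conventions: expression
## matrices are features x samples; PCA/MDS treat samples as observations
## (the sample-QC orientation) — transpose explicitly for gene-axis views.

.expr_values <- function(expr) {
  if (is(expr, "ExpressionTable")) expr$values else as.matrix(expr)
}

#' Pairwise correlation matrix over genes or samples
#'
#' `axis = "gene"` correlates feature rows across samples (co-expression);
#' `axis = "sample"` correlates sample columns across features (sample
#' similarity / outlier detection). Constant vectors have no defined
#' correlation: their entries are `NA` and reported with a warning. The
#' returned row order is the leaf order of average-linkage clustering on
#' `1 - correlation`, ready for a heatmap.
#'
#' @param expr `ExpressionTable` or features x samples matrix.
#' @param axis `"gene"` or `"sample"`.
#' @param method `"pearson"`, `"spearman"` or `"kendall"` (tau-b).
#' @return A `CorrelationResult`: `matrix`, `axis`, `method`, `row_order`.
#' @export
correlation_matrix <- function(expr, axis = c("gene", "sample"),
                               method = c("pearson", "spearman",
                                          "kendall")) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  m <- .expr_values(expr)
  vecs <- if (axis == "gene") t(m) else m     # vectors in columns for cor()
  if (ncol(vecs) < 2L)
    stop("correlation needs at least 2 ", axis, " vectors")
  if (nrow(vecs) < 3L)
    stop("correlation needs vectors of length >= 3")
  constant <- apply(vecs, 2, function(x) var(x) == 0)
  cm <- suppressWarnings(cor(vecs, method = method))
  if (any(constant)) {
    warning(sum(constant), " constant vector(s) have undefined ",
            "correlation (reported as NA)")
    cm[constant, ] <- NA_real_
    cm[, constant] <- NA_real_
  }
  diag(cm)[!constant] <- 1
  row_order <- if (anyNA(cm)) seq_len(nrow(cm))
  else hclust(as.dist(1 - cm), method = "average")$order
  structure(list(matrix = cm, axis = axis, method = method,
                 row_order = row_order),
            class = "CorrelationResult")
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat(sprintf("CorrelationResult (%s-wise, %s): %d x %d\n", x$axis,
              x$method, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

.distance_matrix <- function(m, distance) {
  switch(distance,
    euclidean = dist(m),
    manhattan = dist(m, method = "manhattan"),
    one_minus_corr = as.dist(1 - suppressWarnings(
      cor(t(m), method = "pearson"))),
    stop("unknown distance: '", distance, "'"))
}

#' Agglomerative hierarchical clustering
#'
#' Standard agglomerative clustering of the rows of a matrix (or of a
#' precomputed distance). Ward linkage implements the squared-increment
#' (ward.D2) criterion and is only meaningful on euclidean distances, so it
#' is rejected for the others. Leaf order and merge history come from
#' `stats::hclust` and are deterministic for a given input order.
#'
#' @param x Items x variables matrix (items are clustered), or a `dist`.
#' @param distance `"euclidean"`, `"one_minus_corr"` or `"manhattan"`
#'   (ignored when `x` is a `dist`).
#' @param linkage `"average"`, `"single"`, `"complete"` or `"ward"`.
#' @return A `Dendrogram`: the `hclust` fit plus the settings used.
#' @export
hierarchical_cluster <- function(x,
                                 distance = c("euclidean", "one_minus_corr",
                                              "manhattan"),
                                 linkage = c("average", "single",
                                             "complete", "ward")) {
  linkage <- match.arg(linkage)
  if (inherits(x, "dist")) {
    d <- x
    distance <- "precomputed"
  } else {
    distance <- match.arg(distance)
    m <- .expr_values(x)
    if (nrow(m) < 2L) stop("clustering needs at least 2 items")
    d <- .distance_matrix(m, distance)
  }
  if (any(!is.finite(d)))
    stop("non-finite distances; check for constant or missing rows")
  if (linkage == "ward" && !(distance %in% c("euclidean", "precomputed")))
    stop("ward linkage requires euclidean distances")
  hc <- hclust(d, method = if (linkage == "ward") "ward.D2" else linkage)
  structure(list(hclust = hc, merge = hc$merge, heights = hc$height,
                 leaf_order = hc$order, labels = hc$labels,
                 distance = distance, linkage = linkage),
            class = "Dendrogram")
}

#' @export
print.Dendrogram <- function(x, ...) {
  cat(sprintf("Dendrogram: %d leaves (%s distance, %s linkage)\n",
              length(x$leaf_order), x$distance, x$linkage))
  invisible(x)
}

#' Export a dendrogram in Newick format
#'
#' @param dend A `Dendrogram`.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to file).
#' @export
dendrogram_newick <- function(dend, path = NULL) {
  stopifnot(is(dend, "Dendrogram"))
  phy <- ape::as.phylo(dend$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Principal component analysis of samples
#'
#' Samples are the observations, features the variables (transpose the
#' input for a gene-axis view). Zero-variance features are dropped with a
#' warning when `scale = TRUE` (they cannot be standardized). Explained
#' fractions cover all components and sum to one. Biplot data put scores
#' and scaled loadings in one frame.
#'
#' @param expr `ExpressionTable` or features x samples matrix.
#' @param center Center features? (default `TRUE`)
#' @param scale Standardize features to unit variance? (default `FALSE`)
#' @return A `PcaResult`: `scores` (samples x k), `loadings`
#'   (features x k), `explained`, `biplot`, and the settings.
#' @export
pca <- function(expr, center = TRUE, scale = FALSE) {
  m <- .expr_values(expr)
  if (ncol(m) < 2L || nrow(m) < 2L)
    stop("pca needs at least 2 samples and 2 features")
  obs <- t(m)                                   # samples as observations
  if (scale) {
    v <- apply(obs, 2, var)
    if (any(v == 0)) {
      warning(sum(v == 0), " zero-variance feature(s) dropped for scaling")
      obs <- obs[, v > 0, drop = FALSE]
    }
  }
  fit <- prcomp(obs, center = center, scale. = scale)
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  lam <- fit$sdev * sqrt(max(nrow(obs) - 1L, 1L))
  biplot <- list(scores = sweep(fit$x, 2, lam, "/"),
                 loadings = sweep(fit$rotation, 2, lam, "*"))
  structure(list(scores = fit$x, loadings = fit$rotation,
                 explained = explained, centered = center, scaled = scale,
                 biplot = biplot),
            class = "PcaResult")
}

#' @export
print.PcaResult <- function(x, ...) {
  cat(sprintf("PcaResult: %d observation(s); PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), 100 * x$explained[1],
              if (length(x$explained) > 1) 100 * x$explained[2] else 0))
  invisible(x)
}

#' Classical multidimensional scaling (principal coordinates)
#'
#' Double-centering of squared distances followed by eigendecomposition.
#' For euclidean distances of a centered configuration with full `k` the
#' embedding reproduces the configuration up to rotation/reflection.
#' Negative eigenvalues (non-euclidean input) are truncated with a warning.
#'
#' @param distances A `dist`, or a symmetric non-negative matrix with zero
#'   diagonal (asymmetry beyond 1e-9 is an error).
#' @param k Number of coordinates (less than the number of points).
#' @return An `MdsResult`: `coordinates` (points x k) and `eigenvalues`.
#' @export
mds_classic <- function(distances, k = 2L) {
  if (!inherits(distances, "dist")) {
    dm <- as.matrix(distances)
    if (nrow(dm) != ncol(dm) || max(abs(dm - t(dm))) > 1e-9)
      stop("distance matrix must be symmetric (tolerance 1e-9)")
    if (any(diag(dm) != 0)) stop("distance matrix must have zero diagonal")
    if (any(dm < 0)) stop("distances must be non-negative")
    distances <- as.dist(dm)
  }
  n <- attr(distances, "Size")
  if (k >= n) stop("k must be smaller than the number of points")
  fit <- cmdscale(distances, k = k, eig = TRUE)
  if (any(fit$eig < -1e-8 * max(abs(fit$eig), 1)))
    warning("negative eigenvalues truncated (non-euclidean distances)")
  coords <- fit$points
  if (ncol(coords) < k) {        # degenerate input (e.g. all-zero distances)
    coords <- cbind(coords, matrix(0, n, k - ncol(coords)))
  }
  structure(list(coordinates = coords, eigenvalues = fit$eig),
            class = "MdsResult")
}

#' @export
print.MdsResult <- function(x, ...) {
  cat(sprintf("MdsResult: %d point(s) in %d coordinate(s)\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  invisible(x)
}

#' Procrustes residual between two configurations
#'
#' Least-squares superimposition (translation, rotation/reflection and
#' scale) of `x` onto `target`; returns the root-mean-square residual.
#' Used to verify that an MDS embedding reproduces a known configuration.
#'
#' @param x,target Points x dims matrices of matching shape.
#' @return RMS residual after superimposition.
#' @export
procrustes_residual <- function(x, target) {
  x <- as.matrix(x); target <- as.matrix(target)
  stopifnot(all(dim(x) == dim(target)))
  xc <- scale(x, scale = FALSE)
  tc <- scale(target, scale = FALSE)
  s <- svd(crossprod(tc, xc))
  rot <- s$v %*% t(s$u)
  scale_f <- sum(s$d) / sum(xc^2)
  fitted <- scale_f * xc %*% rot
  sqrt(mean((fitted - tc)^2))
}
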