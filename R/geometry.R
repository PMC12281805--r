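#' Construct a feature matrix
#'
#' Wraps an `n x d` numeric matrix of molecular representation features
#' (rows = molecules) together with row identifiers and a representation
#' label. Binary fingerprint matrices must contain only 0/1 entries.
#'
#' @param values numeric matrix (or data.frame coercible to one), rows =
#'   molecules, columns = representation features.
#' @param row_ids character vector of molecule identifiers; defaults to the
#'   rownames of `values` or `m1..mn`.
#' @param representation_id short label for the representation.
#' @param representation_kind one of `"binary_fingerprint"`, `"descriptor"`,
#'   `"embedding"`, or `"auto"` (binary matrices are tagged as fingerprints).
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, row_ids = NULL,
                           representation_id = "rep",
                           representation_kind = c("auto", "binary_fingerprint",
                                                   "descriptor", "embedding")) {
  representation_kind <- match.arg(representation_kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("feature matrix must have at least one row and one column")
  if (anyNA(values))
    stop("feature matrix contains missing values")
  is_binary <- all(values %in% c(0, 1))
  if (representation_kind == "auto")
    representation_kind <- if (is_binary) "binary_fingerprint" else "embedding"
  if (representation_kind == "binary_fingerprint" && !is_binary)
    stop("representation_kind is 'binary_fingerprint' but entries are not all 0/1")
  if (is.null(row_ids)) {
    row_ids <- rownames(values)
    if (is.null(row_ids)) row_ids <- paste0("m", seq_len(nrow(values)))
  }
  if (length(row_ids) != nrow(values))
    stop("row_ids length does not match the number of rows")
  structure(list(values = values, row_ids = as.character(row_ids),
                 representation_id = representation_id,
                 representation_kind = representation_kind),
            class = "feature_matrix")
}

as_feature_matrix <- function(X) {
  if (inherits(X, "feature_matrix")) return(X)
  feature_matrix(X)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d x %d (%s, '%s')\n",
              nrow(x$values), ncol(x$values), x$representation_kind,
              x$representation_id))
  invisible(x)
}

#' Pairwise distance matrix
#'
#' Computes the full symmetric distance matrix of a feature matrix under one
#' of the supported metrics. The default metric is Jaccard for binary
#' fingerprints and Euclidean otherwise; Tanimoto similarity relates to the
#' Jaccard distance as `sim = 1 - d`.
#'
#' Pairs of all-zero bit rows have an undefined Jaccard distance; they are
#' defined here as distance 0 (identical empty sets) with a warning.
#'
#' @param X a [feature_matrix()] or plain numeric matrix.
#' @param metric_name one of `"euclidean"`, `"manhattan"`, `"cosine"`,
#'   `"jaccard"`, or `NULL` for the representation-dependent default.
#' @return an object of class `dist_matrix`: list with `values` (n x n
#'   matrix) and `metric_name`.
#' @export
pairwise_distances <- function(X, metric_name = NULL) {
  X <- as_feature_matrix(X)
  v <- X$values
  if (is.null(metric_name))
    metric_name <- if (X$representation_kind == "binary_fingerprint")
      "jaccard" else "euclidean"
  metric_name <- match.arg(metric_name,
                           c("euclidean", "manhattan", "cosine", "jaccard"))
  D <- switch(metric_name,
    euclidean = as.matrix(dist(v, method = "euclidean")),
    manhattan = as.matrix(dist(v, method = "manhattan")),
    cosine = {
      nrm <- sqrt(rowSums(v^2))
      S <- tcrossprod(v) / outer(nrm, nrm)
      zero <- nrm == 0
      if (any(zero)) {
        warning("zero-norm rows under cosine distance; pairs involving them ",
                "set to distance 1 (0 for two zero rows)")
        S[zero, ] <- 0
        S[, zero] <- 0
        S[zero, zero] <- 1
      }
      D <- 1 - S
      D[D < 0] <- 0
      D
    },
    jaccard = {
      if (!all(v %in% c(0, 1)))
        stop("jaccard distance requires a binary feature matrix ",
             "(metric/representation mismatch)")
      D <- as.matrix(dist(v, method = "binary"))
      if (sum(rowSums(v) == 0) >= 2)
        warning("pairs of all-zero bit rows under jaccard set to distance 0 ",
                "(identical empty sets)")
      D[is.na(D)] <- 0  # all-zero pairs, when the dist backend yields NaN
      D
    })
  diag(D) <- 0
  D <- (D + t(D)) / 2  # remove floating-point asymmetry
  dimnames(D) <- list(X$row_ids, X$row_ids)
  structure(list(values = D, metric_name = metric_name), class = "dist_matrix")
}

as_dist_matrix <- function(D, metric_name = "unknown") {
  if (inherits(D, "dist_matrix")) return(D)
  if (inherits(D, "dist")) return(structure(list(values = as.matrix(D),
                                                 metric_name = metric_name),
                                            class = "dist_matrix"))
  D <- as.matrix(D)
  structure(list(values = D, metric_name = metric_name), class = "dist_matrix")
}

validate_dist_matrix <- function(D) {
  v <- D$values
  if (nrow(v) != ncol(v)) stop("distance matrix must be square")
  if (any(abs(v - t(v)) > 1e-8)) stop("distance matrix must be symmetric")
  if (any(diag(v) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(v < 0)) stop("distances must be nonnegative")
  invisible(D)
}

new_persistence_diagram <- function(intervals, n_points, metric_name,
                                    threshold) {
  structure(intervals, class = c("persistence_diagram", "data.frame"),
            n_points = n_points, metric_name = metric_name,
            threshold = threshold)
}

#' Vietoris-Rips persistent homology
#'
#' Computes the finite persistence intervals of the Vietoris-Rips filtration
#' of a distance matrix for homological dimensions 0 and (optionally) 1.
#' Dimension 0 is computed with a union-find minimum-spanning-forest pass
#' (deaths are the forest edge weights in merge order); dimension 1 by mod-2
#' column reduction of the triangle boundary block of the clique complex
#' restricted to simplices of dimension at most 2.
#'
#' Infinite intervals (including the single `[0, Inf]` dimension-0 class of
#' the full filtration) are removed, and zero-length intervals are dropped.
#' With `threshold = NULL` (full filtration) a point set with no duplicated
#' points therefore yields exactly `n - 1` dimension-0 intervals.
#'
#' @param D a `dist_matrix` (or square symmetric matrix).
#' @param max_hom_dim 0 or 1.
#' @param threshold filtration cutoff, or `NULL` for the full filtration.
#' @return a `persistence_diagram`: data.frame with columns `hom_dim`,
#'   `birth`, `death` and attributes `n_points`, `metric_name`, `threshold`.
#' @export
vr_persistence <- function(D, max_hom_dim = 1, threshold = NULL) {
  D <- as_dist_matrix(D)
  validate_dist_matrix(D)
  if (!max_hom_dim %in% c(0, 1)) stop("max_hom_dim must be 0 or 1")
  n <- nrow(D$values)
  thr <- if (is.null(threshold)) Inf else as.numeric(threshold)
  if (n < 2) {
    warning("fewer than 2 points: empty persistence diagram")
    return(new_persistence_diagram(
      data.frame(hom_dim = integer(), birth = numeric(), death = numeric()),
      n, D$metric_name, threshold))
  }
  res <- vr_persistence_cpp(D$values, as.integer(max_hom_dim), thr)
  d0 <- res$h0_deaths
  d0 <- d0[d0 > 0]
  out <- data.frame(
    hom_dim = c(rep(0L, length(d0)), rep(1L, length(res$h1_births))),
    birth = c(rep(0, length(d0)), res$h1_births),
    death = c(d0, res$h1_deaths))
  new_persistence_diagram(out, n, D$metric_name, threshold)
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("<persistence_diagram> n_points=%d metric=%s: %d H0, %d H1 intervals\n",
              attr(x, "n_points"), attr(x, "metric_name"),
              sum(x$hom_dim == 0), sum(x$hom_dim == 1)))
  invisible(x)
}

#' Minimum-spanning-forest edge weights
#'
#' The ascending weights of a minimum spanning forest of the complete graph
#' on the points; this multiset equals the dimension-0 death times of the
#' Vietoris-Rips filtration (including zero-length ones from duplicated
#' points, which a finalized diagram drops).
#'
#' @param D a `dist_matrix` (or square symmetric matrix).
#' @return ascending numeric vector of length `n - 1`.
#' @export
mst_deaths <- function(D) {
  D <- as_dist_matrix(D)
  validate_dist_matrix(D)
  if (nrow(D$values) < 2) stop("mst_deaths requires at least 2 points")
  sort(vr_persistence_cpp(D$values, 0L, Inf)$h0_deaths)
}
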