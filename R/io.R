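#' Read a feature, label or group table from CSV
#'
#' All tables share the same layout: a header row and molecule identifiers
#' in the first column. `kind = "features"` returns a [feature_matrix()]
#' (all remaining columns numeric), `"labels"` a named numeric vector,
#' `"groups"` a named character vector. Row order is preserved.
#'
#' @param path CSV file path.
#' @param kind `"features"`, `"labels"` or `"groups"`.
#' @param ... passed to [feature_matrix()] for `kind = "features"`.
#' @return the typed object described above.
#' @export
read_tabular <- function(path, kind = c("features", "labels", "groups"),
                         ...) {
  kind <- match.arg(kind)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected an id column plus at least one value column")
  ids <- as.character(df[[1]])
  if (kind == "features") {
    vals <- df[, -1, drop = FALSE]
    for (cn in names(vals)) {
      v <- suppressWarnings(as.numeric(vals[[cn]]))
      if (anyNA(v) && !anyNA(vals[[cn]])) {
        bad <- which(is.na(v))[1]
        stop("non-numeric cell at row ", bad, ", column '", cn, "'")
      }
      vals[[cn]] <- v
    }
    m <- as.matrix(vals)
    rownames(m) <- ids
    feature_matrix(m, row_ids = ids, ...)
  } else if (kind == "labels") {
    v <- suppressWarnings(as.numeric(df[[2]]))
    if (anyNA(v)) stop("non-numeric label at row ", which(is.na(v))[1])
    stats::setNames(v, ids)
  } else {
    stats::setNames(as.character(df[[2]]), ids)
  }
}

#' Assemble a labelled dataset from typed tables
#'
#' Cross-checks the identifier sets of features and labels (and optional
#' groups): a mismatch raises an error listing the offending ids. Labels
#' and groups are reordered to the feature row order.
#'
#' @param features a [feature_matrix()].
#' @param labels named numeric vector (names = molecule ids).
#' @param groups optional named character vector.
#' @param dataset_id dataset label.
#' @return a [labeled_dataset()].
#' @export
bind_dataset <- function(features, labels, groups = NULL,
                         dataset_id = "dataset") {
  stopifnot(inherits(features, "feature_matrix"))
  check_ids <- function(ids, what) {
    extra <- setdiff(ids, features$row_ids)
    miss <- setdiff(features$row_ids, ids)
    if (length(extra) || length(miss))
      stop("id mismatch between features and ", what, ": ",
           if (length(miss)) paste0("missing [",
             paste(head(miss, 5), collapse = ", "), "] ") else "",
           if (length(extra)) paste0("extra [",
             paste(head(extra, 5), collapse = ", "), "]") else "")
  }
  check_ids(names(labels), "labels")
  labels <- labels[features$row_ids]
  if (!is.null(groups)) {
    check_ids(names(groups), "groups")
    groups <- groups[features$row_ids]
  }
  labeled_dataset(features, labels, dataset_id, groups)
}

#' Write / read a persistence diagram as CSV
#'
#' Finalized diagrams contain only finite intervals, so the CSV never holds
#' an `inf` death. The point count, metric and threshold travel as
#' commented header lines and are restored on read.
#'
#' @param diag a `persistence_diagram`.
#' @param path CSV file path.
#' @return `write_diagram` returns `path` invisibly; `read_diagram` the
#'   diagram.
#' @export
write_diagram <- function(diag, path) {
  stopifnot(inherits(diag, "persistence_diagram"))
  thr <- attr(diag, "threshold")
  hdr <- sprintf("# n_points=%d metric=%s threshold=%s",
                 attr(diag, "n_points"), attr(diag, "metric_name"),
                 if (is.null(thr)) "none" else format(thr, digits = 17))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(as.data.frame(diag)[, c("hom_dim", "birth", "death")], con,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_diagram
#' @export
read_diagram <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec(
    "# n_points=(\\d+) metric=(\\S+) threshold=(\\S+)", hdr))[[1]]
  if (length(m) != 4) stop("not a diagram CSV: missing header comment")
  df <- read.csv(path, comment.char = "#")
  thr <- if (m[4] == "none") NULL else as.numeric(m[4])
  new_persistence_diagram(
    data.frame(hom_dim = as.integer(df$hom_dim), birth = df$birth,
               death = df$death),
    as.integer(m[2]), m[3], thr)
}

#' Write / read descriptor tables as CSV
#'
#' Plain CSV round-trip for descriptor rows (17 significant digits, lossless
#' to double precision).
#'
#' @param descriptors data.frame of descriptor rows.
#' @param path CSV file path.
#' @return `write_descriptors` returns `path` invisibly;
#'   `read_descriptors` the data.frame.
#' @export
write_descriptors <- function(descriptors, path) {
  df <- as.data.frame(descriptors)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 17))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
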