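#' Construct a labeled 2D embedding
#'
#' The unit of comparison throughout the package: `n` points with 2D
#' coordinates and one class label each. Point identity is positional (row
#' index); no point-ID column exists because the class-based metrics never use
#' point correspondence across embeddings. Labels are case-sensitive exact
#' strings.
#'
#' @param x,y Numeric coordinate vectors of equal length (arbitrary embedding
#'   units, e.g. UMAP axes). Must be finite.
#' @param labels Character vector of class labels, same length as `x`. Every
#'   label must be a non-empty string.
#' @param name Identifier used in printed output and comparison results.
#' @return An object of class `labeled_embedding`: a list with elements
#'   `coords` (an `n x 2` numeric matrix with columns `x`, `y`), `labels`
#'   (character) and `name`.
#' @examples
#' emb <- labeled_embedding(c(0, 1, 0), c(0, 0, 1), c("a", "a", "b"))
#' emb
#' @export
labeled_embedding <- function(x, y, labels, name = "embedding") {
  x <- as.numeric(x)
  y <- as.numeric(y)
  labels <- as.character(labels)
  emb <- structure(
    list(coords = cbind(x = x, y = y), labels = labels, name = as.character(name)[1]),
    class = "labeled_embedding"
  )
  validate_embedding(emb)
}

#' @rdname labeled_embedding
#' @param emb A `labeled_embedding` to validate.
#' @export
validate_embedding <- function(emb) {
  stopifnot(is.list(emb), is.matrix(emb$coords), ncol(emb$coords) == 2)
  n <- nrow(emb$coords)
  if (length(emb$labels) != n) {
    stop("embedding has ", n, " points but ", length(emb$labels), " labels", call. = FALSE)
  }
  if (n < 3L) {
    stop("an embedding needs at least 3 points, got ", n, call. = FALSE)
  }
  bad <- which(!is.finite(emb$coords[, 1]) | !is.finite(emb$coords[, 2]))
  if (length(bad)) {
    stop("non-finite coordinate at row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  badlab <- which(is.na(emb$labels) | !nzchar(emb$labels))
  if (length(badlab)) {
    stop("empty or missing label at row(s): ", paste(utils::head(badlab, 5), collapse = ", "),
         call. = FALSE)
  }
  emb
}

#' @export
print.labeled_embedding <- function(x, ...) {
  cat("<labeled_embedding> '", x$name, "': ", nrow(x$coords), " points, ",
      length(unique(x$labels)), " classes\n", sep = "")
  invisible(x)
}

#' Number of points in an embedding
#' @param emb A `labeled_embedding`.
#' @return Integer point count.
#' @export
n_points <- function(emb) nrow(emb$coords)

# Sniff comma vs tab from the header line of a delimited text file.
sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a labeled embedding from a delimited text file
#'
#' Reads a CSV or TSV file (delimiter sniffed from the header line) with one
#' row per point, preserving row order so that point index equals row index.
#' Duplicate coordinates are allowed here; exactly coincident points are
#' resolved by seeded jitter when the Delaunay graph is built (see
#' [build_graph()]).
#'
#' @param path Path to a delimited file with a header row.
#' @param x_col,y_col,label_col Column names holding the coordinates and the
#'   class label. Defaults `"x"`, `"y"`, `"label"`.
#' @param name Embedding identifier; defaults to the file name.
#' @return A [labeled_embedding()].
#' @seealso [write_embedding()], [load_hierarchy()]
#' @export
load_embedding <- function(path, x_col = "x", y_col = "y", label_col = "label",
                           name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- sniff_sep(path)
  header <- gsub('"', "", strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]])
  missing_cols <- setdiff(c(x_col, y_col, label_col), header)
  if (length(missing_cols)) {
    stop("missing column(s) in ", path, ": ", paste(missing_cols, collapse = ", "),
         " (found: ", paste(header, collapse = ", "), ")", call. = FALSE)
  }
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = list(character = label_col),
                          data.table = FALSE, showProgress = FALSE)
  labeled_embedding(dt[[x_col]], dt[[y_col]], dt[[label_col]], name = name)
}

#' Write a labeled embedding to CSV
#'
#' Writes columns `x`, `y`, `label` with a header. Coordinates are written at
#' full double precision (via [format()] with 17 significant digits) so that a
#' write/load round trip reproduces them exactly.
#'
#' @param emb A `labeled_embedding`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(emb, path) {
  df <- data.frame(
    x = format(emb$coords[, 1], digits = 17, trim = TRUE, scientific = FALSE),
    y = format(emb$coords[, 2], digits = 17, trim = TRUE, scientific = FALSE),
    label = emb$labels,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a label hierarchy (child -> parent map)
#'
#' The hierarchy file is a two-column CSV/TSV with header `child,parent`;
#' every child maps to exactly one parent. Applying the map to a label set can
#' only keep or reduce the number of distinct classes, so comparisons can be
#' repeated at coarser levels of a cell-population (or any other) hierarchy.
#'
#' @param path Path to the two-column file.
#' @return A named character vector: `names()` are child labels, values are
#'   parent labels. Class `hierarchy_map`.
#' @export
load_hierarchy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = sniff_sep(path), header = TRUE,
                          colClasses = "character", data.table = FALSE,
                          showProgress = FALSE)
  if (ncol(dt) < 2L) stop("hierarchy file needs two columns (child,parent)", call. = FALSE)
  hierarchy_map(stats::setNames(dt[[2]], dt[[1]]))
}

#' @rdname load_hierarchy
#' @param mapping Named character vector, child label -> parent label.
#' @export
hierarchy_map <- function(mapping) {
  mapping <- unlist(mapping)
  if (is.null(names(mapping)) || any(!nzchar(names(mapping)))) {
    stop("hierarchy mapping must have child labels as names", call. = FALSE)
  }
  if (anyDuplicated(names(mapping))) {
    dup <- unique(names(mapping)[duplicated(names(mapping))])
    stop("child label(s) mapped more than once: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(mapping) | !nzchar(mapping))) {
    stop("every child must map to a non-empty parent label", call. = FALSE)
  }
  structure(mapping, class = "hierarchy_map")
}

#' Roll labels up a hierarchy
#'
#' Replaces each point's label by its parent label, leaving coordinates and
#' point order untouched, so the same layout can be analyzed and compared at a
#' coarser class granularity. The class count can only shrink or stay equal.
#'
#' @param emb A `labeled_embedding`.
#' @param hier A `hierarchy_map` (see [load_hierarchy()]). Every label present
#'   in `emb` must appear as a child.
#' @return A `labeled_embedding` with the same coordinates and parent labels.
#' @examples
#' emb <- labeled_embedding(1:3, c(0, 0, 0) + 1:3, c("A1", "A2", "B1"))
#' rollup_labels(emb, hierarchy_map(c(A1 = "A", A2 = "A", B1 = "B")))
#' @export
rollup_labels <- function(emb, hier) {
  validate_embedding(emb)
  if (!inherits(hier, "hierarchy_map")) hier <- hierarchy_map(hier)
  unmapped <- setdiff(unique(emb$labels), names(hier))
  if (length(unmapped)) {
    stop("label(s) absent from hierarchy: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  labeled_embedding(emb$coords[, 1], emb$coords[, 2],
                    unname(hier[emb$labels]),
                    name = emb$name)
}
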