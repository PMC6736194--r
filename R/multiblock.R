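#' Linked multi-block data
#'
#' Bundle a numeric matrix of I observation units by J variables together
#' with a block map assigning each column to one of K blocks. Blocks are
#' groups of variables (questionnaire scales, gene expression, ...) measured
#' on the same units; columns of each block occupy a contiguous range.
#'
#' @param values numeric matrix, rows = units, columns = variables. All
#'   entries must be finite; missing values are rejected.
#' @param block_sizes integer vector of K column counts, summing to
#'   `ncol(values)`. Each block must have at least one column.
#' @param block_names optional character vector of K block names; defaults
#'   to `"block1"`, `"block2"`, ...
#' @param unit_ids optional character vector of row labels.
#' @param variable_names optional character vector of column labels;
#'   defaults to existing colnames.
#'
#' @return An object of class `"multiblock"`: a list with elements
#'   `values` (the I x J matrix), `blocks` (data frame with columns
#'   `name`, `start`, `end`, `size`), and the dimensions `I`, `J`, `K`.
#' @examples
#' x <- multiblock(matrix(rnorm(40), 10, 4), block_sizes = c(3, 1))
#' x
#' @export
multiblock <- function(values, block_sizes, block_names = NULL,
                       unit_ids = NULL, variable_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L)
    stop("multi-block data needs at least 2 observation units")
  if (!all(is.finite(values)))
    stop("non-finite or missing entries are not accepted")
  block_sizes <- as.integer(block_sizes)
  if (length(block_sizes) < 1L || any(block_sizes < 1L))
    stop("every block must contain at least one variable")
  if (sum(block_sizes) != ncol(values))
    stop("block sizes must sum to the number of columns (",
         sum(block_sizes), " vs ", ncol(values), ")")
  K <- length(block_sizes)
  if (is.null(block_names)) block_names <- paste0("block", seq_len(K))
  if (length(block_names) != K) stop("need one name per block")
  ends <- cumsum(block_sizes)
  starts <- ends - block_sizes + 1L
  if (!is.null(variable_names)) {
    stopifnot(length(variable_names) == ncol(values))
    colnames(values) <- variable_names
  }
  if (is.null(colnames(values)))
    colnames(values) <- paste0("V", seq_len(ncol(values)))
  if (!is.null(unit_ids)) {
    stopifnot(length(unit_ids) == nrow(values))
    rownames(values) <- unit_ids
  }
  structure(list(
    values = values,
    blocks = data.frame(name = block_names, start = starts, end = ends,
                        size = block_sizes, stringsAsFactors = FALSE),
    I = nrow(values), J = ncol(values), K = K
  ), class = "multiblock")
}

#' @export
print.multiblock <- function(x, ...) {
  cat("Multi-block data: ", x$I, " units x ", x$J, " variables in ",
      x$K, " block", if (x$K > 1) "s", "\n", sep = "")
  for (k in seq_len(x$K))
    cat(sprintf("  %s: columns %d-%d (%d variables)\n",
                x$blocks$name[k], x$blocks$start[k], x$blocks$end[k],
                x$blocks$size[k]))
  invisible(x)
}

#' @export
as.matrix.multiblock <- function(x, ...) x$values

#' @export
dim.multiblock <- function(x) dim(x$values)

## Accept either a multiblock or a bare matrix (single block) everywhere.
as_multiblock <- function(x) {
  if (inherits(x, "multiblock")) return(x)
  x <- as.matrix(x)
  multiblock(x, block_sizes = ncol(x))
}

#' Columns belonging to each block
#'
#' @param data a [multiblock] object.
#' @return list of K integer vectors of column indices.
#' @export
block_columns <- function(data) {
  data <- as_multiblock(data)
  lapply(seq_len(data$K),
         function(k) seq.int(data$blocks$start[k], data$blocks$end[k]))
}

#' Read linked data blocks from delimited files
#'
#' Each file holds one block as a delimited numeric matrix with the same
#' number of rows (row i of every file is the same unit; alignment is
#' positional). A header row and a leading row-label column are
#' auto-detected unless forced by the flags.
#'
#' @param paths character vector of file paths, one per block.
#' @param block_names optional block names; defaults to file base names.
#' @param sep field separator; `NULL` (default) auto-detects among
#'   comma, tab, and semicolon.
#' @param header `NULL` to auto-detect, otherwise logical.
#' @param row_labels `NULL` to auto-detect a non-numeric first column,
#'   otherwise logical.
#' @return a [multiblock] object with columns concatenated in block order.
#' @export
read_blocks <- function(paths, block_names = NULL, sep = NULL,
                        header = NULL, row_labels = NULL) {
  if (length(paths) < 1L) stop("need at least one file")
  if (is.null(block_names))
    block_names <- sub("\\.[^.]*$", "", basename(paths))
  parts <- lapply(paths, read_numeric_matrix, sep = sep, header = header,
                  row_labels = row_labels)
  nr <- vapply(parts, nrow, 1L)
  if (length(unique(nr)) != 1L)
    stop("row-count mismatch across files: ", paste(nr, collapse = ", "))
  sizes <- vapply(parts, ncol, 1L)
  if (any(sizes == 0L)) stop("empty block: ", paths[which(sizes == 0L)[1L]])
  values <- do.call(cbind, parts)
  ids <- rownames(parts[[1L]])
  multiblock(values, block_sizes = sizes, block_names = block_names,
             unit_ids = ids)
}

read_numeric_matrix <- function(path, sep = NULL, header = NULL,
                                row_labels = NULL) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path)
  if (is.null(sep)) {
    counts <- vapply(c(",", "\t", ";"),
                     function(s) lengths(regmatches(first, gregexpr(s, first, fixed = TRUE))),
                     1L)
    sep <- c(",", "\t", ";")[which.max(counts)]
    if (max(counts) == 0L) sep <- ","
  }
  tokens <- strsplit(first, sep, fixed = TRUE)[[1L]]
  num1 <- suppressWarnings(as.numeric(tokens))
  if (is.null(header)) header <- anyNA(num1[-1L]) || (length(tokens) > 1L && all(is.na(num1)))
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(row_labels)) row_labels <- !is.numeric(df[[1L]])
  ids <- NULL
  if (row_labels) {
    ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  bad <- !vapply(df, is.numeric, TRUE)
  if (any(bad))
    stop("non-numeric cells in ", path, " (column ",
         paste(names(df)[bad], collapse = ", "), ")")
  m <- as.matrix(df)
  if (!all(is.finite(m))) stop("missing or non-finite values in ", path)
  if (!is.null(ids)) rownames(m) <- ids
  m
}

#' Write a multi-block dataset to delimited files
#'
#' One CSV per block, values at full double precision, so that
#' [read_blocks()] round-trips the data.
#'
#' @param data a [multiblock] object.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_blocks <- function(data, dir) {
  data <- as_multiblock(data)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cols <- block_columns(data)
  paths <- character(data$K)
  for (k in seq_len(data$K)) {
    paths[k] <- file.path(dir, paste0(data$blocks$name[k], ".csv"))
    utils::write.csv(format_full(data$values[, cols[[k]], drop = FALSE]),
                     paths[k], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

format_full <- function(m) {
  out <- apply(m, 2L, function(col) sprintf("%.17g", col))
  out <- matrix(out, nrow = nrow(m), dimnames = dimnames(m))
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Standardize every variable
#'
#' Centers each column to mean zero and scales it to variance one, the
#' usual pre-processing before a simultaneous component analysis so that
#' every variable gets equal weight.
#'
#' @param data a [multiblock] object or numeric matrix.
#' @param denominator `"I-1"` (sample variance, the default) or `"I"`.
#' @return a [multiblock] object with standardized columns; the block map
#'   is unchanged. An attribute-free transformation: apply the same
#'   centering/scaling to new data via [preprocess_params()].
#' @export
center_scale <- function(data, denominator = c("I-1", "I")) {
  data <- as_multiblock(data)
  denominator <- match.arg(denominator)
  p <- preprocess_params(data, denominator)
  apply_preprocess(data, p)
}

#' Estimate standardization parameters
#'
#' Column means and scales that [apply_preprocess()] uses; estimating them
#' on training rows only keeps cross-validation leakage-free.
#'
#' @inheritParams center_scale
#' @return list with `center`, `scale`, and the denominator used.
#' @export
preprocess_params <- function(data, denominator = c("I-1", "I")) {
  data <- as_multiblock(data)
  denominator <- match.arg(denominator)
  x <- data$values
  n <- nrow(x)
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  ss <- colSums(xc^2)
  div <- if (denominator == "I-1") n - 1 else n
  v <- ss / div
  if (any(v <= .Machine$double.eps)) {
    bad <- colnames(x)[which(v <= .Machine$double.eps)[1L]]
    stop("constant column cannot be standardized: ", bad)
  }
  list(center = ctr, scale = sqrt(v), denominator = denominator)
}

#' Apply standardization parameters to (new) data
#'
#' @param data a [multiblock] object or matrix with the same columns.
#' @param params output of [preprocess_params()].
#' @return a standardized [multiblock] object.
#' @export
apply_preprocess <- function(data, params) {
  data <- as_multiblock(data)
  x <- sweep(sweep(data$values, 2L, params$center), 2L, params$scale, "/")
  out <- data
  out$values <- x
  out
}

#' Scale blocks to equal total sum of squares
#'
#' Divides every column of block k by the square root of the number of
#' variables in that block. After standardization each variable has the
#' same sum of squares, so this weighting makes each block contribute the
#' same total sum of squares regardless of size: a large omics block no
#' longer dominates a small questionnaire block.
#'
#' @param data a [multiblock] object (recommended: already standardized).
#' @return the block-scaled [multiblock] object.
#' @export
block_scale <- function(data) {
  data <- as_multiblock(data)
  x <- data$values
  cols <- block_columns(data)
  for (k in seq_len(data$K)) {
    jk <- data$blocks$size[k]
    if (jk > 1L) x[, cols[[k]]] <- x[, cols[[k]]] / sqrt(jk)
  }
  out <- data
  out$values <- x
  out
}
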