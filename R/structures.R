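#' Common/distinctive component structures
#'
#' A structure template assigns each of the Q components a nonempty subset
#' of the K blocks: components on all K blocks are *common*, components on
#' a proper subset are *distinctive* for those blocks. A template expands
#' into a J x Q binary constraint mask: weights of variables outside a
#' component's blocks are constrained to zero.
#'
#' Templates are unordered collections (component order is not identified),
#' so they are kept in a canonical form: block subsets sorted by
#' (subset size, then block indices), smallest first.
#'
#' @param components list of integer vectors, each a nonempty subset of
#'   `1:K`, one per component.
#' @param K number of blocks.
#' @return an object of class `"scads_structure"`.
#' @examples
#' structure_template(list(1, 2, 1:2), K = 2)      # "D1 D2 C"
#' parse_structure("D1 D2 C", K = 2)
#' @export
structure_template <- function(components, K) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  comps <- lapply(components, function(s) {
    s <- sort(unique(as.integer(s)))
    if (length(s) == 0L) stop("every component needs a nonempty block subset")
    if (any(s < 1L | s > K)) stop("unknown block index (K = ", K, ")")
    s
  })
  structure(canonicalize_components(comps), class = "scads_structure", K = K)
}

## sort subsets by (size, lexicographic indices); fixed total order makes
## templates comparable and enumeration duplicate-free
canonicalize_components <- function(comps) {
  keys <- vapply(comps, subset_key, "")
  comps[order(keys)]
}

subset_key <- function(s)
  paste0(sprintf("%02d", length(s)), ":",
         paste(sprintf("%03d", s), collapse = ","))

#' @export
format.scads_structure <- function(x, ...) structure_label(x)

#' @export
print.scads_structure <- function(x, ...) {
  cat("Structure (K = ", attr(x, "K"), "): ", structure_label(x), "\n",
      sep = "")
  invisible(x)
}

#' @export
length.scads_structure <- function(x) length(unclass(x))

#' Human-readable label of a structure
#'
#' A component on every block is written `C`; a component on block k alone
#' is `Dk`; a component on a proper multi-block subset is `D{k,k'}`.
#'
#' @param template a [structure_template] object.
#' @return a single string such as `"D1 D2 C"`.
#' @export
structure_label <- function(template) {
  K <- attr(template, "K")
  lab <- vapply(unclass(template), function(s) {
    if (length(s) == K) "C"
    else if (length(s) == 1L) paste0("D", s)
    else paste0("D{", paste(s, collapse = ","), "}")
  }, "")
  paste(lab, collapse = " ")
}

#' Parse a structure label
#'
#' Accepts the `"D1 D2 C"` shorthand and the explicit subset form
#' `"{1},{2},{1,2}"`.
#'
#' @param spec a single string.
#' @param K number of blocks.
#' @return a [structure_template] object.
#' @export
parse_structure <- function(spec, K) {
  spec <- trimws(spec)
  if (grepl("[DdCc]", spec)) {
    parts <- strsplit(spec, "\\s+")[[1L]]
    parts <- parts[nzchar(parts)]
    comps <- lapply(parts, function(p) {
      if (toupper(p) == "C") seq_len(K)
      else if (grepl("^[Dd][0-9]+$", p)) as.integer(sub("^[Dd]", "", p))
      else if (grepl("^[Dd]\\{[0-9, ]+\\}$", p))
        as.integer(strsplit(gsub("[Dd{}]", "", p), ",")[[1L]])
      else stop("cannot parse component label: ", p)
    })
  } else {
    parts <- regmatches(spec, gregexpr("\\{[^}]*\\}", spec))[[1L]]
    if (length(parts) == 0L) stop("cannot parse structure: ", spec)
    comps <- lapply(parts, function(p)
      as.integer(strsplit(gsub("[{}]", "", p), ",")[[1L]]))
  }
  structure_template(comps, K)
}

#' Count all common/distinctive structures
#'
#' The number of distinct structures with Q components over K blocks is the
#' number of multisets of size Q drawn from the 2^K - 1 nonempty block
#' subsets: choose(2^K - 1 + Q - 1, Q).
#'
#' @param K number of blocks (>= 1).
#' @param Q number of components (>= 1).
#' @return an integer count.
#' @examples
#' count_structures(3, 6)  # 924
#' count_structures(2, 3)  # 10
#' @export
count_structures <- function(K, Q) {
  K <- as.integer(K); Q <- as.integer(Q)
  if (K < 1L || Q < 1L) stop("K and Q must be >= 1")
  n_types <- 2^K - 1
  n <- choose(n_types + Q - 1, Q)
  if (n <= .Machine$integer.max) as.integer(round(n)) else n
}

#' Enumerate all common/distinctive structures
#'
#' Generates every multiset of size Q over the nonempty block subsets, each
#' in canonical form, without duplicates. The list length equals
#' [count_structures()].
#'
#' @inheritParams count_structures
#' @param warn_above warn when the number of candidates exceeds this cap.
#' @return list of [structure_template] objects.
#' @export
enumerate_structures <- function(K, Q, warn_above = 10000) {
  n <- count_structures(K, Q)  # validates K, Q
  if (n > warn_above)
    warning(n, " candidate structures; consider an explicit candidate list")
  subsets <- all_nonempty_subsets(K)
  m <- length(subsets)
  out <- vector("list", n)
  idx <- rep(1L, Q)
  pos <- 0L
  repeat {
    pos <- pos + 1L
    out[[pos]] <- structure(subsets[idx], class = "scads_structure", K = K)
    j <- Q
    while (j >= 1L && idx[j] == m) j <- j - 1L
    if (j < 1L) break
    idx[j:Q] <- idx[j] + 1L
  }
  stopifnot(pos == n)
  out
}

## nonempty subsets of 1:K in canonical (size, lexicographic) order
all_nonempty_subsets <- function(K) {
  subsets <- list()
  for (size in seq_len(K))
    subsets <- c(subsets,
                 utils::combn(K, size, simplify = FALSE))
  subsets
}

#' Expand a structure into a weight constraint mask
#'
#' @param template a [structure_template] (or label string).
#' @param data a [multiblock] object, or an integer vector of block sizes.
#' @return a J x Q binary matrix; 1 marks a free weight, 0 a weight
#'   constrained to zero. Column q is 1 exactly on the variables of the
#'   blocks in component q's subset.
#' @examples
#' tpl <- parse_structure("D1 D2 C", K = 2)
#' structure_mask(tpl, c(2, 2))
#' @export
structure_mask <- function(template, data) {
  sizes <- if (inherits(data, "multiblock")) data$blocks$size
           else as.integer(data)
  K <- length(sizes)
  if (is.character(template)) template <- parse_structure(template, K)
  if (attr(template, "K") != K)
    stop("template defined for K = ", attr(template, "K"),
         " blocks but data has K = ", K)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  J <- sum(sizes)
  Q <- length(template)
  mask <- matrix(0, J, Q)
  for (q in seq_len(Q))
    for (k in unclass(template)[[q]])
      mask[starts[k]:ends[k], q] <- 1
  mask
}

## complexity of a template = number of zero-constrained weight cells
## (more zeroes = simpler model)
structure_zero_count <- function(template, sizes) {
  sizes <- as.integer(sizes)
  J <- sum(sizes)
  sum(vapply(unclass(template),
             function(s) J - sum(sizes[s]), 0))
}
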