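#' Read a rooted phylogenetic tree from Newick text or a file
#'
#' Thin wrapper around [ape::read.tree()] that additionally validates the
#' properties the downstream distance machinery relies on: the tree must be
#' rooted, tip labels must be unique, and every edge must carry a
#' non-negative branch length.  Missing branch lengths are set to 0 with a
#' warning (a zero-length branch contributes nothing to UniFrac).  Unlabeled
#' internal nodes are auto-named `N<node number>` deterministically so that
#' every branch (identified by its child node) has a stable id.
#'
#' @param x a Newick string, or the path of a file containing one.
#' @return an object of class `phylo` (see [ape::read.tree()]).
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  txt <- if (file.exists(x) && !grepl("\\(", x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else x
  txt <- trimws(txt)
  check_newick_syntax(txt)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree))
    stop("failed to parse Newick input")
  if (!ape::is.rooted(tree))
    stop("tree is unrooted (trifurcating root); please root the tree ",
         "(e.g. with ape::root) before use")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; all set to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  label_internal_nodes(tree)
}

# Balanced-parenthesis / terminator pre-check giving a character position in
# parse errors, which ape::read.tree does not report.
check_newick_syntax <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("Newick parse error at character %d: unmatched ')'", i))
    }
  }
  if (depth != 0L)
    stop(sprintf("Newick parse error at character %d: %d unclosed '('",
                 length(chars), depth))
  if (!grepl(";\\s*$", txt))
    stop(sprintf("Newick parse error at character %d: missing terminal ';'",
                 nchar(txt)))
  invisible(TRUE)
}

# Fill in missing/blank internal node labels deterministically.
label_internal_nodes <- function(tree) {
  ntip <- length(tree$tip.label)
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", tree$Nnode)
  blank <- is.na(lab) | lab == ""
  lab[blank] <- paste0("N", which(blank) + ntip)
  if (anyDuplicated(c(tree$tip.label, lab)))
    lab <- make.unique(c(tree$tip.label, lab))[-seq_len(ntip)]
  tree$node.label <- lab
  tree
}

#' Write a tree in Newick format
#'
#' @param tree a `phylo` object.
#' @param path optional file path; if `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(ape::write.tree(tree))
}

#' Read an OTU count/abundance table from a tab-separated file
#'
#' The file must have a header row of feature ids and ids in the first
#' column.  By default rows are samples and columns OTUs; set
#' `otus_in_rows = TRUE` for the transposed orientation, which is normalized
#' internally so that tables are always samples x OTUs.
#'
#' @param path TSV file path.
#' @param otus_in_rows logical; `TRUE` when the file stores OTUs as rows.
#' @return numeric matrix, samples in rows, OTUs in columns.
#' @export
read_otu_table <- function(path, otus_in_rows = FALSE) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (otus_in_rows) m <- t(m)
  validate_otu_table(m)
  m
}

validate_otu_table <- function(m) {
  if (anyDuplicated(rownames(m)))
    stop("duplicate sample ids in OTU table")
  if (anyDuplicated(colnames(m)))
    stop("duplicate OTU ids in OTU table")
  if (anyNA(m)) stop("OTU table contains missing values")
  if (any(m < 0)) stop("OTU table contains negative entries")
  invisible(m)
}

#' Write an OTU (or any samples-by-features) matrix as TSV
#' @param m numeric matrix with row and column names.
#' @param path output file path.
#' @export
write_otu_table <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (labels and optional numeric covariates)
#'
#' The TSV must have sample ids in the first column and a `label` column
#' with values in \{0, 1\}; any further numeric columns are treated as
#' covariates.
#'
#' @param path TSV file path.
#' @return data.frame with rownames = sample ids, a `label` column and any
#'   covariate columns.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  rownames(df) <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  if (!"label" %in% colnames(df))
    stop("metadata must contain a 'label' column")
  if (!all(df$label %in% c(0, 1)))
    stop("metadata labels must be 0 or 1")
  df
}

#' Convert counts to relative abundances
#'
#' Divides each sample row by its total count.  Rows with zero total stay
#' all-zero and trigger a warning.
#'
#' @param tab numeric samples x OTUs matrix of non-negative values.
#' @return matrix of the same shape whose non-zero rows sum to 1.
#' @export
to_relative_abundance <- function(tab) {
  validate_otu_table(tab)
  tot <- rowSums(tab)
  if (any(tot == 0))
    warning(sum(tot == 0), " sample(s) with zero total count left all-zero")
  out <- tab / ifelse(tot == 0, 1, tot)
  out
}

#' Restrict a tree and an abundance table to their shared OTUs
#'
#' The tree is pruned to the OTUs present in the table (collapsing
#' unbranched internal nodes and summing their branch lengths); table
#' columns absent from the tree are dropped and rows re-normalized so the
#' relative-abundance invariant is preserved.  The number of ids dropped
#' from each side is reported via `message()`.
#'
#' @param tree a `phylo` object.
#' @param rel samples x OTUs matrix of relative abundances.
#' @return list with elements `tree` and `rel`.
#' @export
align_tree_and_table <- function(tree, rel) {
  shared <- intersect(tree$tip.label, colnames(rel))
  if (length(shared) == 0)
    stop("tree tips and table OTU ids have empty intersection")
  drop_tree <- length(tree$tip.label) - length(shared)
  drop_tab <- ncol(rel) - length(shared)
  if (drop_tree > 0 || drop_tab > 0)
    message(sprintf("align: dropped %d tree tip(s), %d table OTU(s)",
                    drop_tree, drop_tab))
  if (drop_tree > 0)
    tree <- label_internal_nodes(ape::keep.tip(tree, shared))
  if (drop_tab > 0) {
    rel <- rel[, shared, drop = FALSE]
    tot <- rowSums(rel)
    rel <- rel / ifelse(tot == 0, 1, tot)
  }
  list(tree = tree, rel = rel)
}

#' Per-sample branch abundance profiles
#'
#' For each branch (edge, identified by its child node) of a rooted tree,
#' the profile of a sample is the summed relative abundance of the leaves
#' descending from that branch, computed by one post-order accumulation per
#' sample.  Leaf branches therefore reproduce the leaf abundances and a
#' parent's profile is always at least each child's.
#'
#' @param tree rooted `phylo` whose tip labels match `colnames(rel)`.
#' @param rel samples x OTUs relative-abundance matrix.
#' @return object of class `branch_profiles`: list with `profiles`
#'   (samples x branches matrix), `branch_length` (named vector aligned to
#'   the profile columns) and `tree`.
#' @export
branch_profiles <- function(tree, rel) {
  stopifnot(inherits(tree, "phylo"))
  if (!setequal(tree$tip.label, colnames(rel)))
    stop("tree tips and table OTU ids differ; run align_tree_and_table first")
  tree <- label_internal_nodes(tree)
  ntip <- length(tree$tip.label)
  n <- nrow(rel)
  prof <- matrix(0, n, ntip + tree$Nnode)
  prof[, seq_len(ntip)] <- rel[, tree$tip.label, drop = FALSE]
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]
    prof[, par] <- prof[, par] + prof[, po$edge[e, 2L]]
  }
  node_labels <- c(tree$tip.label, tree$node.label)
  child <- tree$edge[, 2L]
  out <- prof[, child, drop = FALSE]
  colnames(out) <- node_labels[child]
  rownames(out) <- rownames(rel)
  bl <- tree$edge.length
  names(bl) <- node_labels[child]
  structure(list(profiles = out, branch_length = bl, tree = tree),
            class = "branch_profiles")
}

#' @export
print.branch_profiles <- function(x, ...) {
  cat(sprintf("branch profiles: %d sample(s) x %d branch(es)\n",
              nrow(x$profiles), ncol(x$profiles)))
  invisible(x)
}

# Subset a branch_profiles object by sample rows.
bp_subset <- function(bp, idx) {
  bp$profiles <- bp$profiles[idx, , drop = FALSE]
  bp
}

#' Write / read a square distance matrix as TSV
#' @param d symmetric matrix with sample ids as dimnames.
#' @param path file path.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}
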