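#' Read a phylogeny from a Newick file
#'
#' Reads a Newick tree with branch lengths (bootstrap values in node labels
#' are tolerated and preserved). Unrooted trees (basal multifurcation) are
#' rooted deterministically at the midpoint of the first edge descending from
#' the basal node, so that condition allocation always operates on a rooted
#' tree.
#'
#' @param path path to a Newick file, or a Newick string.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tr <- if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
  if (is.null(tr)) stop("could not parse Newick input: ", path, call. = FALSE)
  validate_tree(tr)
}

#' @keywords internal
validate_tree <- function(tr) {
  if (anyDuplicated(tr$tip.label)) {
    dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
    stop("duplicate tip names: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(tr$edge.length) || anyNA(tr$edge.length)) {
    stop("tree must have branch lengths on every edge", call. = FALSE)
  }
  if (any(tr$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  if (!ape::is.rooted(tr)) {
    basal <- ape::Ntip(tr) + 1L
    child <- tr$edge[tr$edge[, 1] == basal, 2][1]
    len <- tr$edge.length[tr$edge[, 1] == basal & tr$edge[, 2] == child][1]
    tr <- phytools::reroot(tr, node.number = child, position = len / 2)
  }
  tr
}

#' Read a taxon-to-phenotype table
#'
#' A two-column tab-separated file (taxon, phenotype label), no header by
#' default.
#'
#' @param path file path.
#' @param header logical; does the file have a header row?
#' @return named character vector: `phenotype[taxon]`.
#' @export
read_phenotypes <- function(path, header = FALSE) {
  d <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("phenotype table needs two columns", call. = FALSE)
  stats::setNames(as.character(d[[2]]), as.character(d[[1]]))
}

#' Allocate every branch of a phylogeny to a selective condition
#'
#' Implements the two branch-partition schemes used by the differential
#' selection models. Maximal phenotype-pure clades (monophyletic groups whose
#' tips all carry one phenotype and that are not nested in a larger such
#' group) are identified for each phenotype; each clade's branches *plus its
#' basal (subtending) branch* are assigned to that phenotype's condition.
#'
#' * `scheme = "ds3"` (K = 3): condition 0 = remaining interior (ancestral)
#'   branches, condition 1 = maximal pure clades of the `ancestral` phenotype
#'   (e.g. C3), condition 2 = maximal pure clades of the `derived` phenotype
#'   (e.g. C4).
#' * `scheme = "ds2"` (K = 2): condition 1 = maximal pure clades of the
#'   `derived` phenotype (with basal branches); condition 0 = everything
#'   else, labelled with the ancestral phenotype. This amounts to a
#'   parsimony-style reconstruction under irreversible ancestral-to-derived
#'   transitions.
#'
#' @param tree a rooted [ape::phylo] tree (see [read_newick()]).
#' @param phenotypes named character vector mapping every tip to a phenotype
#'   label (see [read_phenotypes()]).
#' @param scheme `"ds3"` or `"ds2"`.
#' @param derived,ancestral the two phenotype labels; by default the derived
#'   label is `"C4"` and the ancestral one `"C3"`.
#' @return a `conditioned_tree`: list with elements `tree` (phylo),
#'   `condition` (integer per edge, in `0:(K-1)`, ordered as `tree$edge`),
#'   `K`, and `condition_labels` (names for conditions `0:(K-1)`).
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' ph <- c(A = "C3", B = "C3", C = "C4", D = "C4")
#' ct <- allocate_conditions(tr, ph, "ds3")
#' branch_condition_census(ct)
allocate_conditions <- function(tree, phenotypes,
                                scheme = c("ds3", "ds2"),
                                derived = "C4", ancestral = "C3") {
  scheme <- match.arg(scheme)
  tree <- validate_tree(tree)
  miss <- setdiff(tree$tip.label, names(phenotypes))
  if (length(miss)) {
    stop("tips without phenotype label: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lab <- unname(phenotypes[tree$tip.label])
  bad <- setdiff(unique(lab), c(derived, ancestral))
  if (length(bad)) {
    stop("unknown phenotype labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  edge <- tree$edge
  # phenotype purity per node (NA = mixed), computed tips-up
  purity <- rep(NA_character_, nnode)
  purity[seq_len(ntip)] <- lab
  po <- ape::reorder.phylo(tree, "postorder")
  children <- split(edge[, 2], edge[, 1])
  order_nodes <- unique(po$edge[, 1]) # parents in postorder: children first
  for (v in order_nodes) {
    kids <- children[[as.character(v)]]
    labs <- unique(purity[kids])
    purity[v] <- if (length(labs) == 1L && !anyNA(labs)) labs else NA_character_
  }

  root <- ntip + 1L
  parent_of <- integer(nnode); parent_of[] <- NA_integer_
  parent_of[edge[, 2]] <- edge[, 1]
  # maximal pure nodes: pure, and parent not pure (root counts as maximal)
  is_max <- !is.na(purity) &
    (seq_len(nnode) == root | is.na(purity[ifelse(is.na(parent_of), root, parent_of)]))

  cond_of_label <- if (scheme == "ds3") {
    stats::setNames(c(1L, 2L), c(ancestral, derived))
  } else {
    stats::setNames(c(NA_integer_, 1L), c(ancestral, derived))
  }

  condition <- rep(0L, nrow(edge))
  for (v in which(is_max)) {
    k <- cond_of_label[[purity[v]]]
    if (is.na(k)) next
    # edges of the subtree rooted at v, plus v's own (basal) parent edge
    desc <- subtree_edges(edge, v, ntip)
    condition[desc] <- k
    pe <- which(edge[, 2] == v)
    if (length(pe)) condition[pe] <- k
  }

  labels <- if (scheme == "ds3") {
    stats::setNames(c("ancestral", ancestral, derived), 0:2)
  } else {
    stats::setNames(c(ancestral, derived), 0:1)
  }
  structure(
    list(tree = tree, condition = condition,
         K = if (scheme == "ds3") 3L else 2L,
         condition_labels = labels, scheme = scheme),
    class = "conditioned_tree"
  )
}

# indices of all edges within the clade rooted at node v
subtree_edges <- function(edge, v, ntip) {
  out <- integer(0)
  stack <- v
  while (length(stack)) {
    node <- stack[length(stack)]; stack <- stack[-length(stack)]
    es <- which(edge[, 1] == node)
    out <- c(out, es)
    stack <- c(stack, edge[es, 2][edge[es, 2] > ntip])
  }
  out
}

#' Construct a conditioned tree with explicit per-edge conditions
#'
#' Lower-level constructor used by the simulator and in tests, when the
#' condition of each branch is chosen directly rather than derived from tip
#' phenotypes.
#'
#' @param tree a rooted [ape::phylo].
#' @param condition integer vector (one entry per edge, ordered as
#'   `tree$edge`) with values in `0:(K-1)`.
#' @param K number of conditions.
#' @param condition_labels optional names for the conditions.
#' @return a `conditioned_tree`.
#' @export
conditioned_tree <- function(tree, condition, K = max(condition) + 1L,
                             condition_labels = NULL) {
  tree <- validate_tree(tree)
  condition <- as.integer(condition)
  if (length(condition) != nrow(tree$edge)) {
    stop("`condition` must have one entry per edge", call. = FALSE)
  }
  if (any(condition < 0L) || any(condition >= K)) {
    stop("conditions must lie in 0:(K-1)", call. = FALSE)
  }
  if (is.null(condition_labels)) {
    condition_labels <- stats::setNames(paste0("cond", 0:(K - 1)), 0:(K - 1))
  }
  structure(list(tree = tree, condition = condition, K = as.integer(K),
                 condition_labels = condition_labels, scheme = "manual"),
            class = "conditioned_tree")
}

#' Per-condition branch counts of a conditioned tree
#'
#' @param ct a `conditioned_tree`.
#' @return a tibble with columns `condition`, `label`, `n_branches`; counts
#'   sum to the number of edges of the tree.
#' @export
branch_condition_census <- function(ct) {
  stopifnot(inherits(ct, "conditioned_tree"))
  k <- 0:(ct$K - 1L)
  tibble::tibble(
    condition = k,
    label = unname(ct$condition_labels[as.character(k)]),
    n_branches = vapply(k, function(x) sum(ct$condition == x), integer(1))
  )
}

#' @export
print.conditioned_tree <- function(x, ...) {
  cat("Conditioned tree:", ape::Ntip(x$tree), "tips,",
      nrow(x$tree$edge), "branches, K =", x$K,
      sprintf("(%s)\n", x$scheme))
  cen <- branch_condition_census(x)
  for (i in seq_len(nrow(cen))) {
    cat(sprintf("  condition %d (%s): %d branches\n",
                cen$condition[i], cen$label[i], cen$n_branches[i]))
  }
  invisible(x)
}
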