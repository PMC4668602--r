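#' Parse Newick text into phylogenetic trees
#'
#' Thin wrapper around [ape::read.tree] returning `phylo` objects with
#' normalized tip labels (runs of whitespace/underscores collapsed). Multiple
#' trees (one per line or semicolon-separated) yield a `multiPhylo` list.
#'
#' @param text Newick string(s).
#' @param file optional path to a Newick file (one or more trees).
#' @return a `phylo` or `multiPhylo`.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  tr <- if (!is.null(file)) ape::read.tree(file) else ape::read.tree(text = text)
  if (is.null(tr)) stopf("could not parse Newick input")
  fix <- function(t) {
    t$tip.label <- normalize_label(t$tip.label)
    if (anyDuplicated(t$tip.label))
      stopf("duplicate leaf label '%s'", t$tip.label[duplicated(t$tip.label)][1])
    t
  }
  if (inherits(tr, "multiPhylo")) {
    out <- lapply(tr, fix)
    class(out) <- "multiPhylo"
    out
  } else fix(tr)
}

#' Write trees as Newick text
#'
#' @param tree a `phylo`, `multiPhylo`, or list of `phylo`.
#' @param file optional output path.
#' @param annotations optional named numeric/character vector or per-tree list
#'   of internal-node labels (e.g. support values) serialized as node labels.
#' @return the Newick text, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL, annotations = NULL) {
  if (inherits(tree, "phylo")) tree <- list(tree)
  txt <- vapply(tree, function(t) {
    if (!is.null(annotations)) t$node.label <- as.character(annotations)
    ape::write.tree(t)
  }, "")
  out <- paste(txt, collapse = "\n")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

# tip sets below every edge of a phylo; returns list indexed by edge row
edge_tip_sets <- function(tree) {
  nt <- length(tree$tip.label)
  edge <- tree$edge
  nn <- max(edge)
  below <- vector("list", nn)
  for (i in seq_len(nt)) below[[i]] <- tree$tip.label[i]
  for (i in ape::postorder(tree)) {
    p <- edge[i, 1]; v <- edge[i, 2]
    if (is.null(below[[p]])) below[[p]] <- character(0)
    below[[p]] <- c(below[[p]], below[[v]])
  }
  lapply(seq_len(nrow(edge)), function(i) below[[edge[i, 2]]])
}

# canonical key of a bipartition: the block NOT containing the reference
# taxon (lexicographically first overall), as a sorted, pipe-joined string
split_key <- function(block, taxa, reference = NULL) {
  reference <- reference %||% min(taxa)
  if (reference %in% block) block <- setdiff(taxa, block)
  paste(sort(block), collapse = "|")
}

#' Nontrivial bipartitions of a tree
#'
#' One canonical bipartition per internal edge, encoded by the block not
#' containing the reference taxon (the lexicographically first label). Trees
#' with polytomies yield fewer bipartitions; rooting does not change the set.
#'
#' @param tree a `phylo`.
#' @param reference reference taxon for canonicalization (default: first
#'   label in sort order).
#' @return character vector of bipartition keys (sorted); the corresponding
#'   taxon blocks are available in `attr(, "blocks")`.
#' @export
bipartitions <- function(tree, reference = NULL) {
  taxa <- tree$tip.label
  reference <- reference %||% min(taxa)
  sets <- edge_tip_sets(tree)
  keys <- character(0)
  blocks <- list()
  for (s in sets) {
    if (length(s) <= 1 || length(s) >= length(taxa) - 1) next
    k <- split_key(s, taxa, reference)
    if (!k %in% keys) {
      keys <- c(keys, k)
      blocks[[k]] <- sort(if (reference %in% s) setdiff(taxa, s) else s)
    }
  }
  o <- order(keys)
  structure(keys[o], blocks = blocks[keys[o]], taxa = sort(taxa),
            reference = reference)
}

# are two bipartitions (as taxon blocks over the same taxon set) compatible?
splits_compatible <- function(a, b, taxa) {
  !all(lengths(list(intersect(a, b), setdiff(a, b), setdiff(b, a),
                    setdiff(taxa, union(a, b)))) > 0)
}

#' Root a tree on a monophyletic outgroup
#'
#' Fails with an explicit error naming the conflicting split when the
#' outgroup does not form one block of a bipartition of the unrooted tree.
#' Parsimony length is invariant under rooting.
#'
#' @param tree a `phylo` (rooted or unrooted).
#' @param outgroup character vector of taxon labels (normalized before
#'   matching).
#' @return a rooted `phylo` whose root separates the outgroup from the rest.
#' @export
root_at_outgroup <- function(tree, outgroup) {
  outgroup <- normalize_label(outgroup)
  taxa <- tree$tip.label
  missing <- setdiff(outgroup, taxa)
  if (length(missing) > 0)
    stopf("outgroup taxa not in tree: %s", paste(missing, collapse = ", "))
  if (length(outgroup) > 1 && length(outgroup) < length(taxa) - 1) {
    sets <- edge_tip_sets(tree)
    og <- sort(outgroup)
    ok <- any(vapply(sets, function(s)
      identical(sort(s), og) || identical(sort(setdiff(taxa, s)), og), TRUE))
    if (!ok)
      stopf("outgroup {%s} is not monophyletic in the tree",
            paste(og, collapse = ", "))
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

# topology identity for trees over the same leaf set (split-set equality)
same_topology <- function(a, b) {
  setequal(as.character(bipartitions(a)), as.character(bipartitions(b)))
}

# canonical topology id usable for deduplication
topology_id <- function(tree) {
  paste(sort(as.character(bipartitions(tree))), collapse = ";")
}
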