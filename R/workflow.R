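#' Complete parsimony analysis workflow
#'
#' Runs the full pipeline on a character matrix: heuristic search (RAS +
#' TBR), collapse rule, strict consensus and agreement subtree of the MPTs,
#' ensemble fit indices, optional rooting on an outgroup, optional jackknife
#' and Bremer support on the strict consensus, and synapomorphy mapping.
#'
#' @param m a [char_matrix], or a file path / file text parseable by
#'   [read_char_matrix].
#' @param outgroup optional taxon labels; the consensus and synapomorphy
#'   mapping are reported on trees rooted at this (monophyly is enforced in
#'   the rooting step, not the search).
#' @param config a [search_config].
#' @param constraint optional [monophyly_constraint] for the search.
#' @param jackknife logical or a list of arguments to [jackknife_support]
#'   (e.g. `list(n_replicates = 1000, p_del = 0.36)`).
#' @param bremer logical; compute Bremer supports on the consensus groups.
#' @param map_synapomorphies logical; map unambiguous changes across MPTs.
#' @return an object of class `mp_analysis`: list with `matrix`, `search`
#'   (tree_buffer), `mpts`, `consensus`, `agreement`, `score`
#'   ([ensemble_indices] result), and (when requested) `jackknife`,
#'   `bremer`, `synapomorphies`.
#' @export
run_full_analysis <- function(m, outgroup = NULL, config = search_config(),
                              constraint = NULL, jackknife = FALSE,
                              bremer = FALSE, map_synapomorphies = TRUE) {
  if (is.character(m))
    m <- if (length(m) == 1 && file.exists(m)) read_char_matrix(file = m)
         else read_char_matrix(text = m)
  stopifnot(inherits(m, "char_matrix"))

  search <- mp_search(m, config, constraint)
  mpts <- search$collapsed_trees %||% search$trees
  cons <- strict_consensus(mpts)
  agree <- agreement_subtree(mpts)
  score <- ensemble_indices(search$trees, m)

  rooted_mpts <- mpts
  rooted_cons <- cons
  if (!is.null(outgroup)) {
    rooted_mpts <- lapply(mpts, root_at_outgroup, outgroup = outgroup)
    class(rooted_mpts) <- "multiPhylo"
    rooted_cons <- root_at_outgroup(cons, outgroup)
  }

  out <- list(matrix = m, search = search, mpts = rooted_mpts,
              consensus = rooted_cons, agreement = agree, score = score,
              outgroup = outgroup)

  if (!isFALSE(jackknife)) {
    jk_args <- if (is.list(jackknife)) jackknife else list()
    out$jackknife <- do.call(jackknife_support,
                             c(list(m = m, reference = cons), jk_args))
  }
  if (isTRUE(bremer))
    out$bremer <- bremer_support(m, cons, search$best_length)
  if (isTRUE(map_synapomorphies))
    out$synapomorphies <- synapomorphies(rooted_mpts, m)

  class(out) <- "mp_analysis"
  out
}

#' @export
print.mp_analysis <- function(x, ...) {
  d <- dim(x$matrix)
  cat(sprintf("maximum-parsimony analysis: %d taxa x %d characters\n",
              d[1], d[2]))
  cat(sprintf("  best length: %g\n", x$search$best_length))
  cat(sprintf("  most-parsimonious trees: %d\n", length(x$mpts)))
  cat(sprintf("  CI: %.3f  RI: %.3f\n", x$score$ci, x$score$ri))
  nb <- length(as.character(bipartitions(x$consensus)))
  cat(sprintf("  strict consensus: %d internal group(s)\n", nb))
  cat(sprintf("  agreement subtree: %d of %d taxa\n",
              length(x$agreement$tip.label), d[1]))
  if (!is.null(x$jackknife))
    cat(sprintf("  jackknife GC: %s\n",
                paste(round(sort(x$jackknife$gc, decreasing = TRUE)),
                      collapse = " ")))
  if (!is.null(x$bremer))
    cat(sprintf("  Bremer: %s\n",
                paste(sort(x$bremer$bremer, decreasing = TRUE),
                      collapse = " ")))
  if (!is.null(x$synapomorphies))
    cat(sprintf("  unambiguous synapomorphies: %d (%d unique)\n",
                nrow(x$synapomorphies), sum(x$synapomorphies$unique)))
  invisible(x)
}
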