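#' Jackknife resampling support with GC frequencies
#'
#' Characters are deleted independently with probability `p_del`; each
#' pseudoreplicate is analyzed by a reduced heuristic search and its
#' most-parsimonious trees summarized by strict consensus. Support for each
#' group of the reference tree is reported as GC (group present minus most
#' frequent contradictory group): the percentage of replicates whose
#' consensus contains the group, minus the percentage containing the most
#' frequent rival group that conflicts with it. GC lies in [-100, 100]; an
#' uncontradicted group recovered everywhere scores 100.
#'
#' @param m a [char_matrix].
#' @param reference a reference tree (e.g. the strict consensus of the MPTs)
#'   whose internal groups are annotated.
#' @param n_replicates number of pseudoreplicates.
#' @param p_del independent per-character deletion probability.
#' @param seed integer seed; the whole run is deterministic given the seed.
#' @param search_reps,search_hold effort of the per-replicate search.
#' @return data.frame with one row per internal group of `reference`:
#'   `group` (taxon block, collapsed label), `freq_in` (% recovered),
#'   `freq_rival` (% of best rival), `gc`.
#' @export
jackknife_support <- function(m, reference, n_replicates = 100, p_del = 0.36,
                              seed = NULL, search_reps = 10, search_hold = 2) {
  if (!is.null(seed)) set.seed(seed)
  taxa <- sort(reference$tip.label)
  ref_bp <- bipartitions(reference)
  ref_keys <- as.character(ref_bp)
  ref_blocks <- attr(ref_bp, "blocks")
  n_in <- setNames(numeric(length(ref_keys)), ref_keys)
  rival_counts <- list()  # key -> named numeric of contradicting split counts

  cols_all <- which(m$active_chars)
  for (r in seq_len(n_replicates)) {
    keep <- cols_all[stats::runif(length(cols_all)) >= p_del]
    if (length(keep) == 0) next
    mr <- m
    mr$active_chars <- rep(FALSE, length(mr$active_chars))
    mr$active_chars[keep] <- TRUE
    buf <- mp_search(mr, search_config(n_replicates = search_reps,
                                       hold_per_replicate = search_hold,
                                       collapse = "min_length_zero"))
    cons <- strict_consensus(buf$collapsed_trees)
    bp <- bipartitions(cons)
    keys <- as.character(bp)
    blocks <- attr(bp, "blocks")
    hit <- ref_keys %in% keys
    n_in[hit] <- n_in[hit] + 1
    # tally contradicting groups for the reference splits missing here
    for (k in ref_keys[!hit]) {
      rb <- ref_blocks[[k]]
      for (j in seq_along(keys)) {
        if (!splits_compatible(rb, blocks[[j]], taxa)) {
          kk <- keys[j]
          cur <- rival_counts[[k]] %||% numeric(0)
          cur[kk] <- (if (kk %in% names(cur)) cur[[kk]] else 0) + 1
          rival_counts[[k]] <- cur
        }
      }
    }
  }
  freq_in <- 100 * n_in / n_replicates
  freq_rival <- vapply(ref_keys, function(k) {
    rc <- rival_counts[[k]]
    if (is.null(rc) || length(rc) == 0) 0 else 100 * max(rc) / n_replicates
  }, 0)
  data.frame(group = vapply(ref_blocks[ref_keys], paste, "", collapse = "+"),
             freq_in = unname(freq_in), freq_rival = unname(freq_rival),
             gc = unname(freq_in - freq_rival), row.names = NULL)
}

#' Bremer (decay) support
#'
#' For each internal group of the reference tree, the extra length required
#' by the best tree NOT containing the group, found by a converse-constraint
#' heuristic search. Nonnegative for groups present in all MPTs.
#'
#' @param m a [char_matrix].
#' @param reference tree whose internal groups are annotated (e.g. the
#'   strict consensus of the MPTs).
#' @param best_length length of the unconstrained most-parsimonious trees.
#' @param config [search_config] for the per-group converse searches.
#' @return data.frame with `group`, `constrained_length`, `bremer`.
#' @export
bremer_support <- function(m, reference, best_length,
                           config = search_config(n_replicates = 20,
                                                  hold_per_replicate = 3)) {
  bp <- bipartitions(reference)
  blocks <- attr(bp, "blocks")
  out <- lapply(names(blocks), function(k) {
    g <- blocks[[k]]
    cons <- monophyly_constraint(g, converse = TRUE)
    buf <- constrained_search(m, config, cons)
    data.frame(group = paste(g, collapse = "+"),
               constrained_length = buf$best_length,
               bremer = buf$best_length - best_length)
  })
  do.call(rbind, out)
}
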