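# brute-force MPR oracle: enumerate every full state assignment (tips
# restricted to their allowed sets, internal nodes free over the alphabet),
# keep the minimum-cost ones, and collect per-node state sets and per-edge
# (parent, child) pairs
oracle_mpr <- function(tree, m, char) {
  idx <- match(tree$tip.label, m$taxa)
  nt <- length(tree$tip.label)
  nn <- max(tree$edge)
  sets <- lapply(seq_len(nn), function(v) {
    if (v <= nt) {
      mk <- m$masks[idx[v], char]
      s <- which(bitwAnd(bitwShiftR(as.integer(mk), 0:9), 1L) == 1L) - 1L
      if (length(s) == 0) 0L else s
    } else NULL
  })
  alphabet <- sort(unique(unlist(sets)))
  for (v in (nt + 1):nn) sets[[v]] <- alphabet
  grid <- do.call(expand.grid, sets)
  cost <- apply(grid, 1, function(st)
    sum(st[tree$edge[, 1]] != st[tree$edge[, 2]]))
  L <- min(cost)
  opt <- grid[cost == L, , drop = FALSE]
  node_sets <- lapply(seq_len(nn), function(v) sort(unique(opt[[v]])))
  edge_pairs <- lapply(seq_len(nrow(tree$edge)), function(i)
    unique(data.frame(from = opt[[tree$edge[i, 1]]],
                      to = opt[[tree$edge[i, 2]]])))
  list(L = L, node_sets = node_sets, edge_pairs = edge_pairs)
}

test_that("MPR node sets and edge pairs match exhaustive enumeration", {
  set.seed(51)
  for (rep in 1:6) {
    m <- rand_matrix(6, 4, n_states = 2, p_missing = 0.15, p_inapp = 0.05,
                     p_poly = 0.1)
    tr <- root_at_outgroup(fitchsearch:::random_topology(m$taxa), "t1")
    sets <- mpr_sets(tr, m)
    for (j in seq_len(4)) {
      oc <- oracle_mpr(tr, m, j)
      expect_equal(attr(sets, "lengths")[j], oc$L,
                   info = sprintf("rep %d char %d length", rep, j))
      for (v in seq_along(oc$node_sets))
        expect_equal(sort(sets[[j]][[v]]), oc$node_sets[[v]],
                     info = sprintf("rep %d char %d node %d", rep, j, v))
    }
  }
})

test_that("MPR lengths equal Fitch steps (conservation)", {
  set.seed(52)
  m <- rand_matrix(9, 12, n_states = 3)
  tr <- root_at_outgroup(fitchsearch:::random_topology(m$taxa), "t1")
  sets <- mpr_sets(tr, m)
  expect_equal(attr(sets, "lengths"), as.numeric(fitch_steps(tr, m)))
})

test_that("unambiguous changes match the oracle's edge pairs", {
  set.seed(53)
  for (rep in 1:4) {
    m <- rand_matrix(6, 3, n_states = 2, p_missing = 0.1, p_poly = 0)
    tr <- root_at_outgroup(fitchsearch:::random_topology(m$taxa), "t1")
    uc <- unambiguous_changes(tr, m)
    for (j in 1:3) {
      oc <- oracle_mpr(tr, m, j)
      for (i in seq_along(oc$edge_pairs)) {
        pr <- oc$edge_pairs[[i]]
        chg <- pr[pr$from != pr$to, , drop = FALSE]
        ours <- uc[uc$edge == i & uc$char == j, , drop = FALSE]
        expect_equal(nrow(ours), nrow(chg),
                     info = sprintf("rep %d char %d edge %d", rep, j, i))
        if (nrow(chg) > 0) {
          expect_setequal(paste(ours$from, ours$to), paste(chg$from, chg$to))
          expect_equal(unique(ours$unambiguous), nrow(pr) == 1)
        }
      }
    }
  }
})

test_that("clean ladder: every derived state is a unique synapomorphy", {
  m <- make_fixture("clean6")
  tr <- root_at_outgroup(exhaustive_search(m)$trees[[1]], "A")
  syn <- synapomorphies(tr, m)
  # char 1 (A vs rest) is ambiguous at the root when rooted at A; chars 2-5
  # map unambiguously to the nested clades
  expect_setequal(syn$char, 2:5)
  expect_true(all(syn$from == 0 & syn$to == 1))
  expect_true(all(syn$unique))
  expect_true("E+F" %in% syn$clade)
})

test_that("parallel origins are not unique synapomorphies", {
  # char 1: state 1 arises independently on the terminal branches of B and
  # E (each surrounded by 0-state neighbors, so both gains are forced);
  # char 2: a single unambiguous gain below (E,F)
  cells <- matrix(c("0", "1", "0", "0", "1", "0",
                    "0", "0", "0", "0", "1", "1"), nrow = 6,
                  dimnames = list(LETTERS[1:6], NULL))
  m <- char_matrix(cells)
  tr <- root_at_outgroup(parse_newick("((A,B),(C,(D,(E,F))));"), "C")
  syn <- synapomorphies(tr, m)
  ch1 <- syn[syn$char == 1, ]
  expect_equal(nrow(ch1), 2)         # two separate origins mapped
  expect_setequal(ch1$clade, c("B", "E"))
  expect_true(all(!ch1$unique))      # neither is unique
  ch2 <- syn[syn$char == 2, ]
  expect_equal(nrow(ch2), 1)
  expect_true(ch2$unique)
})

test_that("synapomorphies across multiple MPTs keep only shared mappings", {
  m <- make_fixture("rogue6")
  ex <- exhaustive_search(m)
  trees <- lapply(ex$trees, root_at_outgroup, outgroup = "A")
  syn_all <- synapomorphies(trees, m)
  syn_one <- synapomorphies(trees[[1]], m)
  expect_true(all(paste(syn_all$clade, syn_all$char) %in%
                  paste(syn_one$clade, syn_one$char)))
})

test_that("trace_character is self-consistent", {
  m <- make_fixture("clean6")
  tr <- root_at_outgroup(exhaustive_search(m)$trees[[1]], "A")
  tc <- trace_character(tr, m, char = 3)
  expect_equal(tc$steps, fitch_steps(tr, m)[3])
  expect_length(tc$states, max(tr$edge))
  expect_true(all(tc$changes$char == 3))
})
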