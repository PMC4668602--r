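test_that("strict consensus bipartitions = intersection of input sets", {
  set.seed(31)
  for (rep in 1:6) {
    trees <- lapply(1:4, function(i) fitchsearch:::random_topology(paste0("t", 1:8)))
    cons <- strict_consensus(trees)
    shared <- Reduce(intersect, lapply(trees, function(t)
      as.character(bipartitions(t))))
    expect_setequal(as.character(bipartitions(cons)), shared)
  }
})

test_that("strict consensus agrees with ape::consensus", {
  set.seed(32)
  for (rep in 1:5) {
    trees <- lapply(1:3, function(i) fitchsearch:::random_topology(paste0("t", 1:9)))
    class(trees) <- "multiPhylo"
    ours <- strict_consensus(trees)
    theirs <- ape::consensus(trees, p = 1)
    expect_setequal(as.character(bipartitions(ours)),
                    as.character(bipartitions(theirs)))
  }
})

test_that("strict consensus of one binary tree reproduces it exactly", {
  set.seed(30)
  for (rep in 1:5) {
    tr <- fitchsearch:::random_topology(paste0("t", 1:10))
    cons <- strict_consensus(list(tr))
    expect_true(fitchsearch:::same_topology(cons, tr))
  }
  # nested ladder (the worst case for nested-block insertion)
  lad <- parse_newick("(A,(B,(C,(D,(E,(F,(G,H)))))));")
  expect_true(fitchsearch:::same_topology(strict_consensus(list(lad)), lad))
})

test_that("strict consensus is idempotent and order-independent", {
  set.seed(33)
  trees <- lapply(1:4, function(i) fitchsearch:::random_topology(paste0("t", 1:7)))
  cons <- strict_consensus(trees)
  expect_true(fitchsearch:::same_topology(cons, strict_consensus(list(cons))))
  expect_true(fitchsearch:::same_topology(cons, strict_consensus(rev(trees))))
  expect_true(fitchsearch:::same_topology(cons,
                strict_consensus(c(trees, list(cons)))))
})

test_that("consensus of identical trees is that tree; of wildly different, a star", {
  tr <- parse_newick("((A,B),(C,(D,E)));")
  expect_true(fitchsearch:::same_topology(strict_consensus(list(tr, tr)), tr))
  a <- parse_newick("((A,B),(C,(D,E)));")
  b <- parse_newick("((A,C),(E,(D,B)));")
  c_ <- parse_newick("((A,D),(B,(C,E)));")
  cons <- strict_consensus(list(a, b, c_))
  expect_equal(length(bipartitions(cons)), 0)
})

test_that("mismatched taxon sets are rejected", {
  a <- parse_newick("((A,B),(C,D));")
  b <- parse_newick("((A,B),(C,E));")
  expect_error(strict_consensus(list(a, b)), "same taxa")
})

test_that("agreement subtree: identical trees keep everything", {
  tr <- parse_newick("((A,B),(C,(D,E)));")
  ag <- agreement_subtree(list(tr, tr))
  expect_setequal(ag$tip.label, tr$tip.label)
  expect_length(attr(ag, "dropped"), 0)
})

test_that("agreement subtree drops a rogue taxon and verifies agreement", {
  m <- make_fixture("rogue6")
  ex <- exhaustive_search(m)
  ag <- agreement_subtree(ex$trees)
  expect_equal(attr(ag, "dropped"), "R")
  # verification law: all trees restricted to the kept taxa are identical
  keep <- ag$tip.label
  ids <- vapply(ex$trees, function(t)
    fitchsearch:::topology_id(ape::keep.tip(t, keep)), "")
  expect_equal(length(unique(ids)), 1)
  expect_true(fitchsearch:::same_topology(ag, ape::keep.tip(ex$trees[[1]], keep)))
})

test_that("agreement subtree result always satisfies the agreement law", {
  set.seed(34)
  for (rep in 1:5) {
    trees <- lapply(1:3, function(i) fitchsearch:::random_topology(paste0("t", 1:8)))
    ag <- agreement_subtree(trees)
    keep <- ag$tip.label
    expect_gte(length(keep), 3)
    if (length(keep) > 3) {
      ids <- vapply(trees, function(t)
        fitchsearch:::topology_id(ape::keep.tip(t, keep)), "")
      expect_equal(length(unique(ids)), 1)
    }
  }
})
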