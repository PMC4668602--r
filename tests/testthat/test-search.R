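test_that("all_topologies counts follow the double factorial", {
  expect_equal(length(all_topologies(letters[1:4])), 3)
  expect_equal(length(all_topologies(letters[1:5])), 15)
  expect_equal(length(all_topologies(letters[1:6])), 105)
  # all distinct
  tt <- all_topologies(letters[1:6])
  expect_equal(length(unique(vapply(tt, fitchsearch:::topology_id, ""))), 105)
  expect_error(all_topologies(letters[1:10]), "refusing")
})

test_that("stepwise addition is deterministic given order; optimal on clean data", {
  m <- make_fixture("clean6")
  tr1 <- stepwise_addition(m, order = m$taxa)
  tr2 <- stepwise_addition(m, order = m$taxa)
  expect_true(fitchsearch:::same_topology(tr1, tr2))
  # clean ladder data: sequential addition in ladder order hits the optimum
  expect_equal(tree_length(tr1, m), 5)
})

test_that("TBR from a poor start reaches the known optimum", {
  m <- make_fixture("clean6")
  worst <- NULL
  for (t in all_topologies(m$taxa))
    if (is.null(worst) || tree_length(t, m) > tree_length(worst, m)) worst <- t
  buf <- tbr_search(worst, m, hold = 5)
  expect_equal(buf$best_length, 5)
  # every returned tree attains the reported length
  for (t in buf$trees) expect_equal(tree_length(t, m), buf$best_length)
})

test_that("heuristic equals exhaustive optimum on random instances", {
  set.seed(21)
  for (rep in 1:8) {
    m <- rand_matrix(7, 12, n_states = 2)
    ex <- exhaustive_search(m)
    buf <- mp_search(m, search_config(n_replicates = 5, seed = rep))
    expect_equal(buf$best_length, ex$best_length, info = sprintf("rep %d", rep))
    # the binary MPT sets agree too
    expect_setequal(vapply(buf$trees, fitchsearch:::topology_id, ""),
                    vapply(ex$trees, fitchsearch:::topology_id, ""))
  }
})

test_that("seeded searches are reproducible; different seeds may differ", {
  set.seed(99)  # outer state must not leak into the seeded run
  m <- rand_matrix(10, 15, n_states = 2)
  a <- mp_search(m, search_config(n_replicates = 5, seed = 1))
  b <- mp_search(m, search_config(n_replicates = 5, seed = 1))
  expect_equal(a$best_length, b$best_length)
  expect_identical(vapply(a$trees, fitchsearch:::topology_id, ""),
                   vapply(b$trees, fitchsearch:::topology_id, ""))
  expect_identical(a$replicate_best, b$replicate_best)
})

test_that("positive constraints are honored and cost extra steps", {
  m <- make_fixture("clean6")
  # force a group conflicting with the clean ladder
  con <- monophyly_constraint(c("A", "F"))
  buf <- constrained_search(m, search_config(n_replicates = 10, seed = 2), con)
  expect_true(all(vapply(buf$trees, satisfies_constraint, TRUE, constraint = con)))
  ex <- exhaustive_search(m, constraint = con)
  expect_equal(buf$best_length, ex$best_length)
  expect_gt(buf$best_length, 5)  # constrained optimum must be worse
})

test_that("converse constraints exclude the forbidden clade", {
  m <- make_fixture("clean6")
  con <- monophyly_constraint(c("E", "F"), converse = TRUE)
  buf <- constrained_search(m, search_config(n_replicates = 10, seed = 3), con)
  expect_true(all(vapply(buf$trees, satisfies_constraint, TRUE, constraint = con)))
  ex <- exhaustive_search(m, constraint = con)
  expect_equal(buf$best_length, ex$best_length)
  expect_gt(buf$best_length, 5)
})

test_that("scoped constraints let out-of-scope taxa float", {
  tr <- parse_newick("((A,C),(B,(D,E)));")
  # {A,B} monophyletic relative to scope {A,B,D,E}: C may intrude
  con_scoped <- monophyly_constraint(c("A", "B"), scope = c("A", "B", "D", "E"))
  con_full <- monophyly_constraint(c("A", "B"))
  expect_true(satisfies_constraint(tr, con_scoped))
  expect_false(satisfies_constraint(tr, con_full))
})

test_that("sister-group forcing via nested groups", {
  # X sister of {Y1,Y2}: both {Y1,Y2} and {X,Y1,Y2} monophyletic
  con <- monophyly_constraint(list(c("Y1", "Y2"), c("X", "Y1", "Y2")))
  good <- parse_newick("((X,(Y1,Y2)),(A,B));")
  bad <- parse_newick("((Y1,(X,Y2)),(A,B));")
  expect_true(satisfies_constraint(good, con))
  expect_false(satisfies_constraint(bad, con))
})

test_that("collapse rule merges equal-length resolutions of plateaus", {
  m <- make_fixture("rogue6")
  ex <- exhaustive_search(m)
  expect_gt(length(ex$trees), length(ex$collapsed_trees) - 1)
  buf <- mp_search(m, search_config(n_replicates = 10, seed = 4))
  expect_equal(buf$best_length, ex$best_length)
  expect_setequal(
    vapply(buf$collapsed_trees, fitchsearch:::topology_id, ""),
    vapply(ex$collapsed_trees, fitchsearch:::topology_id, ""))
  # no_collapse keeps binary trees
  buf2 <- mp_search(m, search_config(n_replicates = 10, seed = 4,
                                     collapse = "no_collapse"))
  expect_true(all(vapply(buf2$collapsed_trees,
                         function(t) nrow(t$edge) ==
                           2 * length(t$tip.label) - 3, TRUE)))
})

test_that("vacuous and malformed constraints", {
  m <- make_fixture("clean6")
  con <- monophyly_constraint("A")       # single-taxon group is vacuous
  buf <- mp_search(m, search_config(n_replicates = 2, seed = 1), con)
  expect_equal(buf$best_length, 5)
  expect_error(
    mp_search(m, search_config(n_replicates = 1, seed = 1),
              monophyly_constraint(c("A", "ZZZ"))),
    "not found")
})
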