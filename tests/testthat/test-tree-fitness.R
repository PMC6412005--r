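quartet <- function() ape::read.tree(text = "((L1,L2),(L3,L4));")

test_that("parsimony matches the exhaustive-labelling oracle on toy cases", {
  tr <- quartet()
  same <- c(L1 = "a", L2 = "a", L3 = "a", L4 = "a")
  expect_equal(parsimony_score(tr, same), 0)
  congr <- c(L1 = "a", L2 = "a", L3 = "b", L4 = "b")
  expect_equal(parsimony_score(tr, congr), 1)
  expect_equal(brute_force_parsimony(tr, congr), 1)
  incongr <- c(L1 = "a", L2 = "b", L3 = "a", L4 = "b")
  expect_equal(parsimony_score(tr, incongr), 2)
  expect_equal(brute_force_parsimony(tr, incongr), 2)

  # all-distinct alleles need m - 1 changes
  for (m in 3:6) {
    tr_m <- random_tree(m)
    a <- setNames(paste0("s", 1:m), tr_m$tip.label)
    expect_equal(parsimony_score(tr_m, a), m - 1)
    expect_equal(brute_force_parsimony(tr_m, a), m - 1)
  }
})

test_that("parsimony equals brute force on random trees and assignments", {
  set.seed(99)
  for (i in 1:25) {
    m <- sample(3:6, 1)
    tr <- random_tree(m)
    a <- setNames(sample(letters[1:4], m, replace = TRUE), tr$tip.label)
    expect_equal(parsimony_score(tr, a), brute_force_parsimony(tr, a),
                 info = paste("case", i))
  }
})

test_that("parsimony agrees with an independent phylogenetics library", {
  skip_if_not_installed("phangorn")
  set.seed(123)
  for (i in 1:10) {
    m <- sample(4:8, 1)
    tr <- random_tree(m)
    states <- sample(c("a", "c", "g", "t"), m, replace = TRUE)
    a <- setNames(states, tr$tip.label)
    dat <- phangorn::phyDat(matrix(states, ncol = 1,
                                   dimnames = list(tr$tip.label, NULL)),
                            type = "USER", levels = c("a", "c", "g", "t"))
    expect_equal(parsimony_score(tr, a),
                 as.numeric(phangorn::parsimony(tr, dat, method = "sankoff")))
  }
})

test_that("unassigned leaves are pruned before scoring", {
  tr <- ape::read.tree(text = "(((L1,L2),(L3,L4)),(L5,L6));")
  a <- c(L1 = "a", L2 = "a", L5 = "b", L6 = "b")
  expect_equal(parsimony_score(tr, a), 1)
  expect_equal(tree_fitness(tr, a), 4 - 1 - 1 - sqrt(2))
  # assignments mentioning unknown cells are rejected
  expect_error(parsimony_score(tr, c(L1 = "a", zz = "b")), "not in tree")
  expect_error(parsimony_score(tr, setNames(character(0), character(0))),
               "nonempty")
})

test_that("allele diversity follows the root-sum-square of excess counts", {
  expect_equal(allele_diversity(setNames(rep("a", 5), paste0("c", 1:5))), 4)
  expect_equal(allele_diversity(setNames(letters[1:5], paste0("c", 1:5))), 0)
  expect_equal(allele_diversity(setNames(c("a", "a", "b", "b"),
                                         paste0("c", 1:4))),
               sqrt(2), tolerance = 1e-9)
  expect_equal(allele_diversity(setNames(c(10, 10, 10, 12), paste0("c", 1:4))),
               2)
})

test_that("tree fitness is zero for uninformative loci, signed otherwise", {
  tr <- quartet()
  expect_equal(tree_fitness(tr, c(L1 = "a", L2 = "a", L3 = "a", L4 = "a")), 0)
  expect_equal(tree_fitness(tr, c(L1 = "a", L2 = "b", L3 = "c", L4 = "d")), 0)
  f_congr <- tree_fitness(tr, c(L1 = "a", L2 = "a", L3 = "b", L4 = "b"))
  expect_equal(f_congr, 3 - 1 - sqrt(2), tolerance = 1e-9)   # ~0.58579
  expect_gt(f_congr, 0)
  f_incon <- tree_fitness(tr, c(L1 = "a", L2 = "b", L3 = "a", L4 = "b"))
  expect_equal(f_incon, 3 - 2 - sqrt(2), tolerance = 1e-9)   # ~-0.41421
  expect_lt(f_incon, 0)

  # calibration points hold on arbitrary topologies
  set.seed(17)
  for (i in 1:10) {
    m <- sample(3:7, 1)
    tr_m <- random_tree(m)
    one <- setNames(rep("x", m), tr_m$tip.label)
    dis <- setNames(paste0("s", 1:m), tr_m$tip.label)
    expect_equal(tree_fitness(tr_m, one), 0)
    expect_equal(tree_fitness(tr_m, dis), 0)
  }
})

test_that("fitness is invariant to allele relabelling", {
  set.seed(41)
  for (i in 1:10) {
    m <- sample(4:7, 1)
    tr <- random_tree(m)
    a <- setNames(sample(letters[1:3], m, replace = TRUE), tr$tip.label)
    perm <- setNames(sample(LETTERS[1:3]), letters[1:3])
    b <- setNames(perm[a], names(a))
    expect_equal(tree_fitness(tr, a), tree_fitness(tr, b))
  }
})

test_that("stepwise mutation cost weighs changes by repeat difference", {
  tr <- quartet()
  a <- c(L1 = 20, L2 = 20, L3 = 23, L4 = 23)
  expect_equal(parsimony_score(tr, a, cost = "unordered"), 1)
  expect_equal(parsimony_score(tr, a, cost = "stepwise"), 3)
})

test_that("batch scoring filters by confidence and skips thin loci", {
  tr <- quartet()
  calls <- rbind(
    data.frame(locus_id = "good", cell = paste0("L", 1:4),
               allele1 = c(10L, 10L, 12L, 12L), status = "called",
               percentile = c(0, 10, 20, 30), stringsAsFactors = FALSE),
    data.frame(locus_id = "thin", cell = "L1", allele1 = 10L,
               status = "called", percentile = 0, stringsAsFactors = FALSE),
    data.frame(locus_id = "shaky", cell = paste0("L", 1:4),
               allele1 = c(10L, 11L, 10L, 11L), status = "called",
               percentile = c(0, 90, 90, 90), stringsAsFactors = FALSE))
  res <- batch_tree_fitness(tr, calls, max_percentile = 50)
  tab <- res$table
  expect_equal(tab$status[tab$locus_id == "good"], "scored")
  expect_equal(tab$fitness[tab$locus_id == "good"], 3 - 1 - sqrt(2),
               tolerance = 1e-9)
  expect_equal(tab$status[tab$locus_id == "thin"], "too_few_cells")
  # "shaky" loses 3 of 4 cells to the confidence filter
  expect_equal(tab$status[tab$locus_id == "shaky"], "too_few_cells")
  expect_equal(res$summary$n_scored, 1)

  # tightening the threshold never scores more loci
  res_loose <- batch_tree_fitness(tr, calls, max_percentile = 100)
  expect_gte(res_loose$summary$n_scored, res$summary$n_scored)
  res_none <- batch_tree_fitness(tr, calls, max_percentile = -1)
  expect_equal(nrow(res_none$table[res_none$table$status == "scored", ]), 0)
})
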