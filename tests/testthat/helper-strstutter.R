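# Shared fixtures and independent oracles for the test suite.

# canonical dinucleotide-scale parameters used across tests
ac_params <- function() default_stutter_params("AC")

# random histogram with positive total, for property-style tests
random_histogram <- function(n_bins = 5, max_repeat = 40) {
  reps <- sort(sample.int(max_repeat, n_bins))
  repeat_histogram(runif(n_bins, 0.5, 10), repeats = reps)
}

# total-variation distance between two histograms on their union support
tv_distance <- function(h1, h2) {
  s <- sort(unique(c(h1$repeats, h2$repeats)))
  v1 <- numeric(length(s)); v2 <- v1
  v1[match(h1$repeats, s)] <- h1$counts / sum(h1$counts)
  v2[match(h2$repeats, s)] <- h2$counts / sum(h2$counts)
  0.5 * sum(abs(v1 - v2))
}

# brute-force small-parsimony oracle: minimum over every labelling of the
# internal nodes of the total number of state changes along edges
brute_force_parsimony <- function(tree, assignment) {
  if (length(assignment) < length(tree$tip.label))
    tree <- ape::keep.tip(tree, names(assignment))
  states <- sort(unique(unname(assignment)))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tipstate <- match(assignment[tree$tip.label], states)
  combos <- expand.grid(rep(list(seq_along(states)), nnode))
  best <- Inf
  for (i in seq_len(nrow(combos))) {
    lab <- c(tipstate, as.integer(combos[i, ]))
    changes <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# random rooted tree with labelled tips
random_tree <- function(n_tips) {
  tr <- ape::rtree(n_tips, rooted = TRUE)
  tr$tip.label <- paste0("c", seq_len(n_tips))
  tr
}
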