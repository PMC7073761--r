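as_dm <- function(D) structure(list(ids = rownames(D), d = D,
                                    var = 0 * D, n = 0 * D, model = "K2P"),
                               class = "dist_matrix")

test_that("three-taxon NJ solves the closed-form branch lengths", {
  D <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(as_dm(D))
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2L]])
  expect_equal(bl[["A"]], (0.3 + 0.5 - 0.6) / 2)
  expect_equal(bl[["B"]], (0.3 + 0.6 - 0.5) / 2)
  expect_equal(bl[["C"]], (0.5 + 0.6 - 0.3) / 2)
  expect_error(neighbor_joining(as_dm(D[1:2, 1:2])), "at least 3")
  D[1, 2] <- D[2, 1] <- NA
  expect_error(neighbor_joining(as_dm(D)), "non-finite")
})

test_that("NJ recovers additive 4-taxon trees exactly", {
  set.seed(17)
  for (rep in 1:20) {
    gen <- random_additive_matrix(4L)
    tr <- neighbor_joining(as_dm(gen$D))
    # topology and branch lengths against the generating tree
    expect_equal(split_set(tr), split_set(gen$tree))
    expect_equal(sort(cophenetic(tr)[rownames(gen$D), colnames(gen$D)]),
                 sort(gen$D), tolerance = 1e-10)
    # and against the exhaustive least-squares oracle
    orc <- ls_tree_oracle(gen$D)
    expect_lt(orc$rss, 1e-16)
    expect_equal(split_set(tr), split_set(orc$tree))
  }
})

test_that("NJ matches the exhaustive LS oracle on 5-taxon additive trees", {
  set.seed(29)
  hits <- 0L
  for (rep in 1:100) {
    gen <- random_additive_matrix(5L)
    tr <- neighbor_joining(as_dm(gen$D))
    orc <- ls_tree_oracle(gen$D)
    if (identical(split_set(tr), split_set(orc$tree))) hits <- hits + 1L
    expect_equal(sort(cophenetic(tr)[rownames(gen$D), colnames(gen$D)]),
                 sort(gen$D), tolerance = 1e-10)
  }
  expect_equal(hits, 100L)
})

test_that("NJ agrees with an independent implementation on noisy matrices", {
  skip_if_not_installed("phangorn")
  set.seed(31)
  for (rep in 1:10) {
    gen <- random_additive_matrix(7L)
    D <- gen$D + matrix(runif(49, 0, 0.01), 7, 7)
    D <- (D + t(D)) / 2; diag(D) <- 0
    ours <- neighbor_joining(as_dm(D))
    theirs <- ape::nj(as.dist(D))
    expect_equal(phangorn::RF.dist(ours, theirs), 0)
  }
})

test_that("NJ is invariant to taxon order up to relabeling", {
  set.seed(41)
  gen <- random_additive_matrix(6L)
  perm <- sample(rownames(gen$D))
  tr1 <- neighbor_joining(as_dm(gen$D))
  tr2 <- neighbor_joining(as_dm(gen$D[perm, perm]))
  expect_equal(split_set(tr1), split_set(tr2))
})

test_that("negative branches are clamped and logged, never emitted", {
  # a non-additive matrix known to drive a negative NJ branch
  D <- matrix(c(0, 0.1, 0.4, 0.45,
                0.1, 0, 0.42, 0.4,
                0.4, 0.42, 0, 0.05,
                0.45, 0.4, 0.05, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- D["b", "a"] <- 0.5   # stress towards negativity
  tr <- neighbor_joining(as_dm(D))
  expect_true(all(tr$edge.length >= 0))
  expect_true(is.numeric(attr(tr, "n_clamped")))
})

test_that("bootstrap gives full support to an unambiguous cherry", {
  # A and B nearly identical, far from C and D: the (A,B) split should be
  # in every replicate
  ev <- data.frame(id = c("r", "s1", "s2"), time = c(10, 0.1, 9),
                   target = c("ancestor", "AB", "CD"),
                   left = c("AB", "A", "C"), right = c("CD", "B", "D"))
  sc <- duplication_scenario("cherry", ev, rate = 0.002,
                             seq_length = 10000L)
  aln <- evolve_sequences(build_event_tree(sc), 0.002, 2, 10000L, seed = 4L)
  bs <- bootstrap_support(aln, n_reps = 100L, seed = 9L)
  ab <- bs$report$bootstrap_support[bs$report$split %in%
                                      c("A|B", "C|D")]
  expect_equal(ab, 1.0)
  expect_equal(bs$n_dropped, 0L)

  # determinism and the n_reps = 1 degenerate case
  bs2 <- bootstrap_support(aln, n_reps = 100L, seed = 9L)
  expect_identical(bs$report, bs2$report)
  bs1 <- bootstrap_support(aln, n_reps = 1L, seed = 2L)
  expect_true(all(bs1$report$bootstrap_support %in% c(0, 1)))
})

test_that("interior-branch test is confident where resampling cannot vary", {
  # every column carries the identical split pattern, so each bootstrap
  # replicate reproduces the same tree: SE = 0, positive length, CP = 1
  aln <- new_alignment(c("A", "B", "C", "D"),
                       c(strrep("A", 200L), strrep("A", 200L),
                         strrep("G", 200L), strrep("G", 200L)))
  ibt <- interior_branch_test(aln, model = "p", n_reps = 20L, seed = 1L)
  row <- ibt[ibt$split %in% c("A|B", "C|D"), ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$branch_se, 0)
  expect_equal(row$confidence_probability, 1)
})

test_that("interior-branch confidence collapses on star-like data", {
  # all internal signal removed: four lineages radiating from one point
  ev <- data.frame(id = c("r", "s1", "s2"), time = c(8, 8 - 1e-9, 8 - 2e-9),
                   target = c("ancestor", "AB", "CD"),
                   left = c("AB", "A", "C"), right = c("CD", "B", "D"))
  sc <- duplication_scenario("star", ev, rate = 0.001, seq_length = 5000L)
  tree <- build_event_tree(sc)
  cps <- vapply(1:15, function(i) {
    aln <- evolve_sequences(tree, 0.001, 2, 5000L, seed = 300L + i)
    ibt <- interior_branch_test(aln, n_reps = 50L, seed = 77L)
    mean(ibt$confidence_probability)
  }, numeric(1L))
  # individual CPs hover around 1/2; far below the confident regime
  expect_lt(median(cps), 0.95)
  expect_gt(median(cps), 0.3)
  # strong-signal contrast: a real interior branch is called confidently
  ev2 <- data.frame(id = c("r", "s1", "s2"), time = c(10, 2, 2),
                    target = c("ancestor", "AB", "CD"),
                    left = c("AB", "A", "C"), right = c("CD", "B", "D"))
  sc2 <- duplication_scenario("deep", ev2, rate = 0.002, seq_length = 5000L)
  aln <- evolve_sequences(build_event_tree(sc2), 0.002, 2, 5000L, seed = 6L)
  ibt <- interior_branch_test(aln, n_reps = 50L, seed = 78L)
  expect_gt(max(ibt$confidence_probability), 0.99)
  # reproducibility for a fixed seed
  ibt2 <- interior_branch_test(aln, n_reps = 50L, seed = 78L)
  expect_identical(ibt, ibt2)
})
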