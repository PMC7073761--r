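test_that("complete deletion removes exactly the gap/N columns", {
  aln <- new_alignment(c("s1", "s2", "s3"),
                       c("ACGTACGTAC",
                         "ACG-ACGTAC",
                         "ACGTACGTAC"))
  out <- complete_deletion(aln)
  expect_equal(alignment_length(out), 9L)
  expect_equal(rownames(out), c("s1", "s2", "s3"))

  clean <- new_alignment(c("a", "b"), c("ACGT", "ACGA"))
  expect_identical(unclass(complete_deletion(clean)), unclass(clean))

  withN <- new_alignment(c("a", "b"), c("ACNT", "ACGA"))
  expect_equal(alignment_length(complete_deletion(withN)), 3L)

  allgap <- new_alignment(c("a", "b"), c("----", "ACGT"))
  expect_error(complete_deletion(allgap), "no sites remain")
})

test_that("site-pattern counting separates transitions from transversions", {
  expect_equal(count_patterns("ACGT", "ACGT"), list(n = 4L, ts = 0L, tv = 0L))
  expect_equal(count_patterns("AAAA", "GAAA"), list(n = 4L, ts = 1L, tv = 0L))
  expect_equal(count_patterns("AAAA", "CAAA"), list(n = 4L, ts = 0L, tv = 1L))
  # C<->T is a transition; gap/N sites are excluded from n
  expect_equal(count_patterns("CCT-A", "CTTGN"), list(n = 3L, ts = 1L, tv = 0L))
  expect_error(count_patterns("AC", "ACG"), "unequal")
  expect_error(count_patterns("--", "AC"), "no comparable sites")
})

test_that("JC distance matches direct likelihood maximization", {
  ident <- jc_distance(list(n = 100L, ts = 0L, tv = 0L))
  expect_equal(ident$d, 0)
  expect_equal(ident$var, 0)

  d <- jc_distance(list(n = 1000L, ts = 60L, tv = 40L))
  expect_equal(d$d, jc_ml_oracle(0.10, 1000L), tolerance = 1e-6)

  expect_error(jc_distance(list(n = 100L, ts = 40L, tv = 35L)),
               class = "potevol_saturation_error")

  # closed form equals the ML oracle across a p grid
  for (p in seq(0.02, 0.6, by = 0.06)) {
    est <- jc_distance(list(n = 1000L, ts = round(600 * p),
                            tv = 1000 * p - round(600 * p)))
    expect_equal(est$d, jc_ml_oracle(p, 1000L), tolerance = 1e-6)
  }
})

test_that("K2P distance matches 2-parameter likelihood maximization", {
  z <- k2p_distance(list(n = 500L, ts = 0L, tv = 0L))
  expect_equal(z$d, 0)
  expect_equal(z$var, 0)

  est <- k2p_distance(list(n = 1000L, ts = 100L, tv = 50L))
  expect_equal(est$d, k2p_ml_oracle(0.10, 0.05, 1000L), tolerance = 1e-6)

  # grid over (P, Q)
  for (P in c(0.05, 0.12, 0.2)) {
    for (Q in c(0.02, 0.08, 0.16)) {
      est <- k2p_distance(list(n = 2000L, ts = P * 2000, tv = Q * 2000))
      expect_equal(est$d, k2p_ml_oracle(P, Q, 2000L), tolerance = 1e-6)
    }
  }

  expect_error(k2p_distance(list(n = 100L, ts = 48L, tv = 10L)),
               class = "potevol_saturation_error")
  expect_error(k2p_distance(list(n = 100L, ts = 5L, tv = 50L)),
               class = "potevol_saturation_error")
})

test_that("K2P reduces to JC when substitutions follow the 1:2 split", {
  # simulate a cherry under equal transition/transversion rates per target
  # (kappa = 1 gives the JC expectation ts:tv = 1:2)
  tree <- three_taxon_clock_tree(6, 16)
  aln <- evolve_sequences(tree, rate = 0.001, kappa = 1, L = 100000L,
                          seed = 99L)
  cts <- count_patterns(unclass(aln)["a", ], unclass(aln)["b", ])
  expect_equal(k2p_distance(cts)$d, jc_distance(cts)$d, tolerance = 1e-3)
})

test_that("distances increase monotonically and variances shrink with n", {
  p_grid <- seq(0.01, 0.7, by = 0.01)
  d_jc <- vapply(p_grid, function(p) {
    jc_distance(list(n = 1000L, ts = 500 * p, tv = 500 * p))$d
  }, numeric(1L))
  expect_true(all(diff(d_jc) > 0))

  P_grid <- seq(0.01, 0.35, by = 0.01)
  d_k2p <- vapply(P_grid, function(P) {
    k2p_distance(list(n = 1000L, ts = 1000 * P, tv = 100L))$d
  }, numeric(1L))
  expect_true(all(diff(d_k2p) > 0))

  v_small <- k2p_distance(list(n = 1e3, ts = 0.1 * 1e3, tv = 0.05 * 1e3))$var
  v_big <- k2p_distance(list(n = 1e6, ts = 0.1 * 1e6, tv = 0.05 * 1e6))$var
  expect_lt(v_big, v_small)
})

test_that("K2P estimation is unbiased under its own generating process", {
  tree <- three_taxon_clock_tree(5, 16)   # cherry separated by 10 Myr of path
  d0 <- 2 * 0.001 * 5
  ests <- ses <- numeric(200L)
  for (i in seq_len(200L)) {
    aln <- evolve_sequences(tree, rate = 0.001, kappa = 2, L = 10000L,
                            seed = 5000L + i)
    est <- k2p_distance(count_patterns(unclass(aln)["a", ],
                                       unclass(aln)["b", ]))
    ests[i] <- est$d
    ses[i] <- sqrt(est$var)
  }
  # mean estimate within 3 Monte-Carlo SEs of truth
  expect_lt(abs(mean(ests) - d0), 3 * sd(ests) / sqrt(length(ests)))
  # analytic SE agrees with the sampling spread to ~10%
  expect_equal(mean(ses), sd(ests), tolerance = 0.1)
})

test_that("distance matrices are symmetric with zero diagonal", {
  expect_error(distance_matrix(new_alignment("a", "ACGT")), "at least 2")

  twin <- new_alignment(c("a", "b"), c("ACGTACGT", "ACGTACGT"))
  dm <- distance_matrix(twin)
  expect_equal(dm$d, matrix(0, 2, 2, dimnames = list(c("a", "b"),
                                                     c("a", "b"))))
  set.seed(21)
  for (rep in 1:5) {
    tr <- three_taxon_clock_tree(4, 12)
    aln <- evolve_sequences(tr, 0.002, 2, 2000L, seed = rep)
    dm <- distance_matrix(aln, model = sample(c("JC", "K2P", "p"), 1L))
    expect_identical(dm$d, t(dm$d))
    expect_true(all(diag(dm$d) == 0))
  }
})

test_that("complete and pairwise deletion differ exactly on gap columns", {
  aln <- new_alignment(c("a", "b", "c"),
                       c("AAAAAAAAAG",
                         "AAAAAAAAAG",
                         "AAAA-AAAAA"))
  comp <- distance_matrix(aln, model = "p", deletion = "complete")
  pair <- distance_matrix(aln, model = "p", deletion = "pairwise")
  # a-b pair has no gaps: complete deletion shrinks its denominator
  expect_equal(pair$n["a", "b"], 10)
  expect_equal(comp$n["a", "b"], 9)
  expect_equal(comp$d["a", "c"], pair$d["a", "c"])

  gapless <- new_alignment(c("a", "b"), c("ACGTACGTAC", "ACGAACGTAC"))
  expect_equal(distance_matrix(gapless, deletion = "complete")$d,
               distance_matrix(gapless, deletion = "pairwise")$d)
})

test_that("saturated pairs raise a listing error rather than NaN", {
  sat <- new_alignment(c("a", "b", "c"),
                       c(strrep("A", 40L), strrep("G", 40L),
                         strrep("A", 40L)))
  err <- tryCatch(distance_matrix(sat, model = "K2P"),
                  potevol_saturation_error = function(e) e)
  expect_s3_class(err, "potevol_saturation_error")
  expect_match(conditionMessage(err), "a-b")
})

test_that("distance matrices serialize to PHYLIP and TSV", {
  tr <- three_taxon_clock_tree(4, 12)
  aln <- evolve_sequences(tr, 0.002, 2, 2000L, seed = 8L)
  dm <- distance_matrix(aln)
  fp <- tempfile(); ft <- tempfile(fileext = ".tsv")
  write_phylip(dm, fp)
  expect_equal(as.integer(trimws(readLines(fp)[1L])), 3L)
  write_dist_tsv(dm, ft)
  tab <- read.delim(ft)
  expect_equal(nrow(tab), 3L)
  expect_equal(sort(tab$d), sort(dm$d[upper.tri(dm$d)]))
})
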