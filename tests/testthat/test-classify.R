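mk_sig <- function(invasion = FALSE, l1m5 = FALSE, cluster = character(),
                   dup = FALSE, gene = "g") {
  structure(list(gene_id = gene, l1pa_invasion = invasion,
                 l1m5_intron1 = l1m5, intron9_cluster = cluster,
                 exon6_9_dup = dup), class = "line_signature")
}

test_that("gene models validate exons and derive canonical introns", {
  m <- canonical_gene_model("g1")
  expect_equal(nrow(m$exons), 11L)
  iv1 <- intron_interval(m, 1L)
  expect_equal(iv1, c(151L, 3150L))
  expect_error(gene_model("bad", data.frame(start = c(1, 50), end = c(100, 80),
                                            label = c("1", "2"))),
               "overlapping")
  dup <- canonical_gene_model("g2", dup_6_9 = TRUE)
  expect_equal(nrow(dup$exons), 15L)
  expect_true(all(paste0(6:9, "'") %in% dup$exons$label))
  # extra exons do not renumber the canonical introns
  expect_equal(intron_interval(dup, 1L), iv1)
})

test_that("LINE signatures are read off tracks against the gene model", {
  m <- canonical_gene_model("g1")
  iv1 <- intron_interval(m, 1L)
  iv9 <- intron_interval(m, 9L)
  hit <- function(name, start, len = 600L, class = "LINE/L1") {
    data.frame(start = start, end = start + len - 1L, strand = "+",
               repeat_name = name, repeat_class = class, score = 1000)
  }
  tr <- repeat_track("g1", rbind(hit("L1M5", iv1[1L] + 10L),
                                 hit("L1M5", iv9[1L] + 10L),
                                 hit("AluY", iv9[1L] + 700L, 300L,
                                     "SINE/Alu"),
                                 hit("L1PA15", iv9[1L] + 1100L),
                                 hit("L1M5", iv9[1L] + 1800L)))
  sig <- extract_line_signature(tr, m)
  expect_true(sig$l1m5_intron1)
  # interleaved non-LINE hits are ignored in the ordered cluster
  expect_equal(sig$intron9_cluster, c("L1M5", "L1PA15", "L1M5"))
  expect_false(sig$l1pa_invasion)
  expect_false(sig$exon6_9_dup)

  empty <- extract_line_signature(repeat_track("g1", NULL), m)
  expect_false(empty$l1m5_intron1)
  expect_false(empty$l1pa_invasion)
  expect_equal(empty$intron9_cluster, character())

  # invasion threshold on total L1PA bp
  inv <- repeat_track("g1", rbind(hit("L1PA2", intron_interval(m, 2L)[1L],
                                      2500L),
                                  hit("L1PA3", intron_interval(m, 3L)[1L],
                                      2500L),
                                  hit("L1PA4", intron_interval(m, 4L)[1L],
                                      2500L)))
  expect_true(extract_line_signature(inv, m)$l1pa_invasion)
  expect_false(extract_line_signature(inv, m,
                                      invasion_threshold = 0.5)$l1pa_invasion)

  beyond <- repeat_track("g1", hit("L1M5", m$locus_length + 100L))
  expect_error(extract_line_signature(beyond, m), "coordinate frame")
})

test_that("the group rules fire as a truth table with recorded traces", {
  g2c <- c("L1M5", "L1PA15", "L1M5")
  g4c <- c("L1ME3G", "L1PA15", "L1ME3G")

  a <- assign_group(mk_sig(invasion = TRUE, l1m5 = TRUE, cluster = g4c))
  expect_equal(a$group, "I")
  expect_equal(a$fired_rules, "R1")

  a <- assign_group(mk_sig(l1m5 = TRUE, cluster = g2c))
  expect_equal(a$group, "II")
  expect_equal(a$fired_rules, "R2")

  a <- assign_group(mk_sig(cluster = g4c, dup = TRUE))
  expect_equal(a$group, "III")
  expect_equal(a$fired_rules, "R3")

  a <- assign_group(mk_sig(cluster = g4c))
  expect_equal(a$group, "IV")
  expect_equal(a$fired_rules, "R4")

  # conflicting rules -> ambiguous with the conflict recorded
  a <- assign_group(mk_sig(invasion = TRUE, l1m5 = TRUE, cluster = g2c))
  expect_equal(a$group, "ambiguous")
  expect_equal(sort(a$conflicts), c("I", "II"))

  # no rule fires -> ambiguous, no conflicts
  a <- assign_group(mk_sig(l1m5 = TRUE, cluster = g4c))
  expect_equal(a$group, "ambiguous")
  expect_equal(a$fired_rules, character())

  # purity: identical signatures give identical assignments
  s <- mk_sig(cluster = g4c, dup = TRUE)
  expect_identical(assign_group(s), assign_group(s))
})

test_that("inverted-repeat detection matches the brute-force oracle", {
  set.seed(61)
  # inert flanks: the designed 300-bp arms are provably the best hit
  pal <- make_palindrome(300L, 400L, inert_flanks = TRUE)
  call <- find_inverted_repeat(pal$seq)
  orc <- perfect_arm_oracle(pal$seq)
  expect_equal(orc$len, 300L)
  expect_equal(call$arm1, orc$arm1)
  expect_equal(call$arm2, orc$arm2)
  expect_equal(call$arm1, pal$arm1)
  expect_equal(call$arm2, pal$arm2)
  expect_equal(call$arm_identity, 1.0)
  expect_equal(call$arm_length, 300L)
  expect_equal(call$status, "half")   # 300 bp arm: above 200, below 500
  expect_equal(call$loop_length, 400L)

  # random flanks: arms may score-extend (with gaps where they pay), so
  # the call dominates the gapless oracle and contains the designed arms
  pal2 <- make_palindrome(300L, 400L)
  call2 <- find_inverted_repeat(pal2$seq)
  orc2 <- score_arm_oracle(pal2$seq)
  expect_gte(call2$score, orc2$score)
  expect_lte(call2$arm1[1L], pal2$arm1[1L])
  expect_gte(call2$arm2[2L], pal2$arm2[2L])

  long <- make_palindrome(600L, 300L, inert_flanks = TRUE)
  expect_equal(find_inverted_repeat(long$seq)$status, "full")

  expect_error(find_inverted_repeat(random_dna(100L)), "min_arm")
})

test_that("random sequences do not produce spurious LIR calls", {
  set.seed(71)
  statuses <- vapply(1:30, function(i) {
    find_inverted_repeat(random_dna(2000L))$status
  }, character(1L))
  expect_true(all(statuses == "none"))
})

test_that("feature tables join computed and provided columns", {
  ext <- pote_feature_table()
  asg <- data.frame(gene_id = ext$gene_id, group = ext$group_reported)
  lir <- data.frame(gene_id = ext$gene_id, lir = ext$lir_reported)
  tab <- build_feature_table(asg, lir, ext)
  expect_equal(nrow(tab), 14L)
  expect_equal(sum(tab$lir == "full"), 8L)
  expect_equal(sum(tab$lir == "half"), 6L)
  expect_true(all(c("group", "lir", "ankyrin_repeats") %in% names(tab)))

  only_computed <- build_feature_table(asg)
  expect_equal(names(only_computed), c("gene_id", "group"))

  dup <- rbind(ext, ext[1L, ])
  expect_error(build_feature_table(asg, lir, dup), "duplicate")

  extra <- rbind(asg, data.frame(gene_id = "NOVEL", group = "I"))
  expect_warning(build_feature_table(extra, external = ext), "NOVEL")
})

test_that("synthetic families are classified back to their true group", {
  for (gp in c("I", "II", "III", "IV")) {
    ev <- data.frame(id = "s", time = 2, target = "ancestor",
                     left = "geneA", right = "geneB")
    sc <- duplication_scenario(paste0("fam", gp), ev, seq_length = 100L,
                               group = gp)
    fam <- simulate_family(sc, seed = 5L)
    for (g in names(fam$tracks)) {
      sig <- extract_line_signature(fam$tracks[[g]], fam$models[[g]])
      expect_equal(assign_group(sig)$group, gp)
    }
  }
})
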