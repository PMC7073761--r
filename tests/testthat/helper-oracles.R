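# Independent oracles used across test files. These deliberately avoid the
# package's closed-form/algorithmic code paths: distances are checked by
# direct likelihood maximization, NJ by exhaustive least-squares topology
# search, and the inverted-repeat scanner by a gapless diagonal run scan.

BASES <- c("A", "C", "G", "T")

revcomp_str <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

# --- Maximum-likelihood distance oracles ------------------------------------

# JC: maximize the binomial likelihood of x differing sites out of n over
# the distance d, where the expected difference proportion is
# (3/4)(1 - exp(-4d/3)).
jc_ml_oracle <- function(p, n) {
  x <- p * n
  nll <- function(d) {
    pd <- 3 / 4 * (1 - exp(-4 * d / 3))
    -(x * log(pd) + (n - x) * log(1 - pd))
  }
  optimize(nll, c(1e-8, 5), tol = 1e-12)$minimum
}

# K2P: maximize the trinomial likelihood of (ts, tv) counts over distance d
# and transition/transversion ratio kappa, by nested golden-section
# profiles (d inner, log-kappa outer).
k2p_ml_oracle <- function(P, Q, n) {
  ts <- P * n; tv <- Q * n
  nll <- function(d, kappa) {
    b <- d / (kappa + 2); a <- kappa * b
    p_ts <- 0.25 + 0.25 * exp(-4 * b) - 0.5 * exp(-2 * (a + b))
    p_tv <- 0.5 - 0.5 * exp(-4 * b)
    p_same <- 1 - p_ts - p_tv
    if (p_ts <= 0 || p_tv <= 0 || p_same <= 0) return(1e12)
    -(ts * log(p_ts) + tv * log(p_tv) + (n - ts - tv) * log(p_same))
  }
  profile_d <- function(log_kappa) {
    optimize(nll, c(1e-9, 5), kappa = exp(log_kappa), tol = 1e-13)
  }
  outer <- optimize(function(lk) profile_d(lk)$objective,
                    log(c(1e-3, 1e3)), tol = 1e-11)
  profile_d(outer$minimum)$minimum
}

# --- Exhaustive least-squares tree oracle -----------------------------------

# Design matrix: rows = unordered tip pairs, cols = edges; entry 1 when the
# edge lies on the path between the pair.
path_design_matrix <- function(tree) {
  n <- length(tree$tip.label)
  prs <- t(combn(n, 2L))
  A <- matrix(0, nrow(prs), nrow(tree$edge))
  for (r in seq_len(nrow(prs))) {
    nodes <- ape::nodepath(tree, prs[r, 1L], prs[r, 2L])
    for (s in seq_len(length(nodes) - 1L)) {
      e <- which((tree$edge[, 1L] == nodes[s] & tree$edge[, 2L] == nodes[s + 1L]) |
                 (tree$edge[, 1L] == nodes[s + 1L] & tree$edge[, 2L] == nodes[s]))
      A[r, e] <- 1
    }
  }
  A
}

# Fit branch lengths of every unrooted topology on the taxa by least
# squares; return the best topology with fitted lengths and its RSS.
ls_tree_oracle <- function(D) {
  ids <- rownames(D)
  n <- length(ids)
  tops <- phangorn::allTrees(n, rooted = FALSE, tip.label = ids)
  prs <- t(combn(n, 2L))
  y <- D[prs]
  best <- NULL
  for (k in seq_along(tops)) {
    tp <- tops[[k]]   # [[ restores tip labels from the multiPhylo store
    A <- path_design_matrix(tp)
    fit <- lsfit(A, y, intercept = FALSE)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss) {
      tp$edge.length <- unname(fit$coefficients)
      best <- list(tree = tp, rss = rss)
    }
  }
  best
}

random_additive_matrix <- function(n, min_bl = 0.01, max_bl = 0.3) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- runif(nrow(tr$edge), min_bl, max_bl)
  list(tree = tr, D = cophenetic(tr))
}

split_set <- function(tree) sort(unname(tree_bipartitions(tree)))

# --- Gapless inverted-arm oracle --------------------------------------------

# Best perfect (ungapped, mismatch-free) pair of reverse-complementary arms
# by scanning every diagonal of S against revcomp(S), restricted to
# non-overlapping arms. Quadratic; for fixtures of a couple of kb.
perfect_arm_oracle <- function(seq) {
  s <- strsplit(toupper(seq), "")[[1L]]
  n <- length(s)
  t <- strsplit(revcomp_str(paste(s, collapse = "")), "")[[1L]]
  best <- list(len = 0L)
  for (dg in (-(n - 1L)):(n - 1L)) {
    # cells (i, j = i + dg); constraint i + j <= n
    i_max <- floor((n - dg) / 2)
    i_min <- max(1L, 1L - dg)
    if (i_max < i_min) next
    i_seq <- i_min:i_max
    m <- s[i_seq] == t[i_seq + dg]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    for (k in which(r$values & r$lengths > best$len)) {
      len <- r$lengths[k]
      i0 <- i_seq[ends[k] - len + 1L]
      best <- list(len = len, arm1 = c(i0, i0 + len - 1L),
                   arm2 = c(n + 1L - (i0 + dg + len - 1L),
                            n + 1L - (i0 + dg)))
    }
  }
  best
}

# Best-scoring gapless inverted-arm segment (match +1, mismatch -1) by a
# Kadane scan over every diagonal of S vs revcomp(S), restricted to
# non-overlapping arms. Shares the scanner's objective (gap-free paths;
# a gap never pays on these fixtures) but none of its code. Ties resolved
# like the DP: the first best-scoring end cell in row-major (i, j) order.
score_arm_oracle <- function(seq, match = 1L, mismatch = -1L) {
  s <- strsplit(toupper(seq), "")[[1L]]
  n <- length(s)
  t <- strsplit(revcomp_str(paste(s, collapse = "")), "")[[1L]]
  best <- list(score = 0L)
  cand <- list()
  for (dg in (-(n - 1L)):(n - 1L)) {
    i_max <- floor((n - dg) / 2)
    i_min <- max(1L, 1L - dg)
    if (i_max < i_min) next
    run <- 0L; start <- i_min
    for (i in i_min:i_max) {
      sc <- if (s[i] == t[i + dg] && s[i] != "N") match else mismatch
      if (run <= 0L) { run <- 0L; start <- i }
      run <- run + sc
      if (run > best$score) {
        best <- list(score = run)
        cand <- list()
      }
      if (run == best$score && best$score > 0L) {
        cand[[length(cand) + 1L]] <- c(i = i, j = i + dg, i0 = start)
      }
    }
  }
  if (best$score == 0L) return(list(score = 0L))
  ends <- do.call(rbind, cand)
  pick <- ends[order(ends[, "i"], ends[, "j"])[1L], ]
  i0 <- pick[["i0"]]; i1 <- pick[["i"]]; dg <- pick[["j"]] - pick[["i"]]
  list(score = best$score,
       arm1 = c(i0, i1),
       arm2 = c(n + 1L - (i1 + dg), n + 1L - (i0 + dg)))
}

# --- Misc -------------------------------------------------------------------

make_palindrome <- function(arm_len = 300L, loop_len = 400L,
                            pad = 200L, inert_flanks = FALSE) {
  # inert_flanks: loop and pads of poly-A, which can never pair with their
  # own complement, so the designed arms are exactly the best ones
  filler <- function(k) {
    if (inert_flanks) strrep("A", k) else random_dna(k)
  }
  arm <- random_dna(arm_len)
  seq <- paste0(filler(pad), arm, filler(loop_len),
                revcomp_str(arm), filler(pad))
  list(seq = seq, arm1 = c(pad + 1L, pad + arm_len),
       arm2 = c(pad + arm_len + loop_len + 1L,
                pad + arm_len + loop_len + arm_len))
}

write_fasta_text <- function(records, path) {
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}

three_taxon_clock_tree <- function(split_ab = 6, split_out = 16) {
  ev <- data.frame(id = c("s_out", "s_ab"), time = c(split_out, split_ab),
                   target = c("ancestor", "ab"),
                   left = c("out", "a"), right = c("ab", "b"))
  build_event_tree(duplication_scenario("three", ev))
}
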