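# Neighbor-joining with bootstrap and interior-branch support.

fmt_bl <- function(x) sprintf("%.17g", x)

subset_columns <- function(aln, idx) {
  out <- unclass(aln)[, idx, drop = FALSE]
  class(out) <- c("dna_alignment", class(out))
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomerative algorithm: repeatedly join the pair (i, j)
#' minimizing `Q(i,j) = (r-2) D(i,j) - sum_k D(i,k) - sum_k D(j,k)`, with
#' branch lengths from the standard two-point formulas. Ties in Q are
#' broken by the lowest (i, j) index pair in the current node ordering, so
#' the result is deterministic for a given input. Negative branch lengths
#' are clamped to zero with the deficit moved to the adjacent branch of
#' the join (total path length preserved); the number of clamped branches
#' is recorded in attribute `n_clamped`.
#'
#' @param dm a `dist_matrix` (or plain symmetric matrix with dimnames)
#'   over at least 3 taxa with finite entries.
#' @return An unrooted [ape::phylo] tree (trifurcating root) with branch
#'   lengths; attribute `n_clamped` counts zero-clamped branches.
#' @export
neighbor_joining <- function(dm) {
  D <- if (inherits(dm, "dist_matrix")) dm$d else as.matrix(dm)
  ids <- rownames(D)
  r <- nrow(D)
  if (r < 3L) stop("neighbor-joining needs at least 3 taxa")
  if (any(!is.finite(D))) stop("non-finite entry in distance matrix")
  labels <- ids            # newick fragment per active node
  n_clamped <- 0L

  clamp2 <- function(bi, bj) {
    # clamp one negative member of a cherry, moving the deficit across
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    if (bi < 0) bi <- 0   # both negative: floor at zero
    c(bi, bj)
  }

  while (r > 3L) {
    rs <- rowSums(D)
    Q <- (r - 2L) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    # lowest (i, j) among minima, scanning i then j, i < j
    best <- NULL
    qmin <- min(Q[upper.tri(Q)])
    for (i in seq_len(r - 1L)) {
      j_hit <- which(Q[i, seq(i + 1L, r)] <= qmin + 0)
      if (length(j_hit)) { best <- c(i, i + j_hit[1L]); break }
    }
    i <- best[1L]; j <- best[2L]
    bi <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2L))
    bj <- D[i, j] - bi
    if (bi < 0 || bj < 0) n_clamped <- n_clamped + 1L
    b <- clamp2(bi, bj)
    new_lab <- paste0("(", labels[i], ":", fmt_bl(b[1L]), ",",
                      labels[j], ":", fmt_bl(b[2L]), ")")
    dn <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dn[keep]),
               c(dn[keep], 0))
    labels <- c(labels[keep], new_lab)
    r <- r - 1L
  }
  a <- (D[1L, 2L] + D[1L, 3L] - D[2L, 3L]) / 2
  b <- (D[1L, 2L] + D[2L, 3L] - D[1L, 3L]) / 2
  cc <- (D[1L, 3L] + D[2L, 3L] - D[1L, 2L]) / 2
  if (any(c(a, b, cc) < 0)) n_clamped <- n_clamped + 1L
  a <- max(a, 0); b <- max(b, 0); cc <- max(cc, 0)
  nwk <- paste0("(", labels[1L], ":", fmt_bl(a), ",",
                labels[2L], ":", fmt_bl(b), ",",
                labels[3L], ":", fmt_bl(cc), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "n_clamped") <- n_clamped
  tree
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each interior edge of an unrooted tree defines a split of the leaf set.
#' Splits are canonicalized as the sorted leaf subset on the side *not*
#' containing the alphabetically first leaf, pasted with "|", so splits
#' from trees with permuted taxon orders compare equal.
#'
#' @param tree an [ape::phylo] tree.
#' @return A named character vector of split keys; names are the internal
#'   node numbers the edges lead to.
#' @export
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  ref <- sort(tips)[1L]
  pp <- ape::prop.part(tree)
  out <- character()
  nodes <- integer()
  for (k in seq_along(pp)) {
    nd <- n + k
    if (nd == n + 1L) next   # root: trivial split
    clade <- tips[pp[[k]]]
    side <- if (ref %in% clade) setdiff(tips, clade) else clade
    if (length(side) < 2L || length(side) > n - 2L) next
    out <- c(out, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, nd)
  }
  names(out) <- nodes
  out
}

split_edge_lengths <- function(tree, keys) {
  # length of the interior edge realizing each split key; 0 when absent
  sp <- tree_bipartitions(tree)
  out <- setNames(numeric(length(keys)), keys)
  hit <- match(keys, sp)
  for (k in seq_along(keys)) {
    if (!is.na(hit[k])) {
      nd <- as.integer(names(sp)[hit[k]])
      out[k] <- tree$edge.length[tree$edge[, 2L] == nd]
    }
  }
  out
}

nj_bootstrap_worker <- function(aln, model, n_reps, seed,
                                tree = NULL) {
  aln <- complete_deletion(aln)
  dm <- distance_matrix(aln, model = model)
  if (is.null(tree)) tree <- neighbor_joining(dm)
  keys <- tree_bipartitions(tree)
  L <- ncol(aln)
  set.seed(seed)
  pres <- matrix(NA, nrow = n_reps, ncol = length(keys))
  lens <- matrix(NA_real_, nrow = n_reps, ncol = length(keys))
  colnames(pres) <- colnames(lens) <- keys
  dropped <- 0L
  for (rep in seq_len(n_reps)) {
    idx <- sample.int(L, L, replace = TRUE)
    rdm <- tryCatch(distance_matrix(subset_columns(aln, idx), model = model),
                    potevol_saturation_error = function(e) NULL)
    if (is.null(rdm)) { dropped <- dropped + 1L; next }
    rtree <- neighbor_joining(rdm)
    rl <- split_edge_lengths(rtree, keys)
    pres[rep, ] <- rl > 0 | keys %in% tree_bipartitions(rtree)
    lens[rep, ] <- rl
  }
  if (dropped > 0.2 * n_reps) {
    stop("more than 20% of bootstrap replicates dropped (saturated pairs): ",
         dropped, " of ", n_reps)
  }
  ok <- !is.na(pres[, 1L, drop = TRUE]) | ncol(pres) == 0L
  if (ncol(pres) == 0L) ok <- rep(TRUE, n_reps)  # star tree: nothing to score
  list(tree = tree, keys = keys, presence = pres[ok, , drop = FALSE],
       lengths = lens[ok, , drop = FALSE], n_dropped = dropped,
       n_used = sum(ok))
}

#' Bootstrap support for neighbor-joining splits
#'
#' Alignment columns (after complete deletion) are resampled with
#' replacement; an NJ tree is rebuilt per replicate; the support of each
#' interior edge of the original tree is the fraction of replicates whose
#' tree contains the same bipartition. Replicates with saturated pairs are
#' dropped and counted; more than 20% dropped is an error. Reproducible
#' for a fixed seed. Support is reported on [0, 1].
#'
#' @param aln a `dna_alignment`.
#' @param model substitution model for distances (`"K2P"`, `"JC"`, `"p"`).
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer RNG seed.
#' @return A list: `tree` (original NJ tree with `node.label` holding the
#'   support of the edge leading to each internal node), `report` (data
#'   frame with split key, edge node, bootstrap support), and `n_dropped`.
#' @export
bootstrap_support <- function(aln, model = "K2P", n_reps = 500L,
                              seed = 1L) {
  stopifnot(n_reps >= 1L)
  w <- nj_bootstrap_worker(aln, model, n_reps, seed)
  supp <- if (length(w$keys)) colMeans(w$presence) else numeric()
  tree <- w$tree
  nlab <- rep("", tree$Nnode)
  if (length(w$keys)) {
    nd <- as.integer(names(w$keys))
    nlab[nd - length(tree$tip.label)] <- format(supp, digits = 4L)
  }
  tree$node.label <- nlab
  report <- data.frame(split = unname(w$keys),
                       node = as.integer(names(w$keys)),
                       bootstrap_support = unname(supp))
  list(tree = tree, report = report, n_dropped = w$n_dropped)
}

#' Interior-branch test of phylogeny
#'
#' For each interior edge of the (NJ) tree, alignment-column bootstrap
#' replicates yield a distribution of that edge's length (zero where the
#' bipartition is absent from a replicate tree). `branch_se` is the
#' standard deviation of those lengths and the confidence probability is
#' the one-sided normal probability that the true length exceeds zero,
#' `pnorm(length / branch_se)`. A zero-length edge with zero SE gets
#' confidence probability 0.5 by convention; a positive-length edge with
#' zero SE gets 1.
#'
#' @param aln a `dna_alignment`.
#' @param tree optional [ape::phylo] to test; defaults to the NJ tree of
#'   `aln` under `model`.
#' @param model substitution model for distances.
#' @param n_reps number of bootstrap replicates.
#' @param seed integer RNG seed.
#' @return A data frame with one row per interior edge: split key, node,
#'   branch length, `branch_se`, `bootstrap_support` and
#'   `confidence_probability`.
#' @export
interior_branch_test <- function(aln, tree = NULL, model = "K2P",
                                 n_reps = 500L, seed = 1L) {
  w <- nj_bootstrap_worker(aln, model, n_reps, seed, tree = tree)
  if (!length(w$keys)) {
    return(data.frame(split = character(), node = integer(),
                      branch_length = numeric(), branch_se = numeric(),
                      bootstrap_support = numeric(),
                      confidence_probability = numeric()))
  }
  orig_len <- split_edge_lengths(w$tree, w$keys)
  se <- apply(w$lengths, 2L, sd)
  cp <- vapply(seq_along(w$keys), function(k) {
    if (se[k] == 0) {
      if (orig_len[k] > 0) 1 else 0.5
    } else {
      pnorm(orig_len[k] / se[k])
    }
  }, numeric(1L))
  data.frame(split = unname(w$keys), node = as.integer(names(w$keys)),
             branch_length = unname(orig_len), branch_se = unname(se),
             bootstrap_support = unname(colMeans(w$presence)),
             confidence_probability = cp)
}
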