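# Pairwise model-corrected distances: the K of T = K/2R.

GAPLIKE <- c("-", "N")

saturation_error <- function(msg) {
  stop(structure(class = c("potevol_saturation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}

#' Remove every alignment column containing a gap or N in any sequence
#'
#' The "complete deletion" site filter: a column is kept only if every
#' sequence carries an unambiguous base (A/C/G/T) there. Applied once,
#' globally, before any pairwise comparison. `N` is treated like a gap.
#'
#' @param aln a `dna_alignment`.
#' @return A `dna_alignment` with the filtered columns; row order preserved.
#' @export
complete_deletion <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  m <- unclass(aln)
  keep <- colSums(matrix(m %in% GAPLIKE, nrow = nrow(m))) == 0L
  if (!any(keep)) stop("no sites remain after complete deletion")
  out <- m[, keep, drop = FALSE]
  class(out) <- c("dna_alignment", class(out))
  out
}

is_transition <- function(x, y) {
  (x == "A" & y == "G") | (x == "G" & y == "A") |
  (x == "C" & y == "T") | (x == "T" & y == "C")
}

#' Count transition and transversion site differences between two sequences
#'
#' Sites where either sequence carries a gap or N are excluded from the
#' comparison. Transitions are A<->G and C<->T; every other difference is
#' a transversion.
#'
#' @param a,b character vectors of single bases (rows of a `dna_alignment`)
#'   or single strings; must have equal length.
#' @return A list with `n` (sites compared), `ts` (transitions) and `tv`
#'   (transversions).
#' @export
count_patterns <- function(a, b) {
  if (length(a) == 1L && nchar(a[1L]) > 1L) a <- strsplit(a, "")[[1L]]
  if (length(b) == 1L && nchar(b[1L]) > 1L) b <- strsplit(b, "")[[1L]]
  a <- toupper(a); b <- toupper(b)
  if (length(a) != length(b)) stop("sequences have unequal lengths")
  ok <- !(a %in% GAPLIKE | b %in% GAPLIKE)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0L) stop("no comparable sites (all gapped or ambiguous)")
  diff <- a != b
  ts <- sum(diff & is_transition(a, b))
  tv <- sum(diff) - ts
  list(n = n, ts = ts, tv = tv)
}

#' Jukes-Cantor corrected distance with analytic variance
#'
#' For proportion of differing sites p, the JC distance is
#' `d = -(3/4) log(1 - 4p/3)` with large-sample variance
#' `var = p(1-p) / (n (1 - 4p/3)^2)`.
#'
#' @param counts site-pattern counts from [count_patterns()].
#' @return A list with `d`, `var`, and `model = "JC"`.
#' @export
jc_distance <- function(counts) {
  n <- counts$n; p <- (counts$ts + counts$tv) / n
  if (p >= 3 / 4) {
    saturation_error(sprintf(
      "Jukes-Cantor distance saturated: p = %.4f >= 0.75 (n = %d)", p, n))
  }
  w <- 1 - 4 * p / 3
  list(d = -3 / 4 * log(w), var = p * (1 - p) / (n * w^2), model = "JC")
}

#' Kimura 2-parameter distance with analytic variance
#'
#' With transition proportion `P = ts/n` and transversion proportion
#' `Q = tv/n`, the K2P distance is
#' `d = -(1/2) log((1 - 2P - Q) sqrt(1 - 2Q))` and its variance
#' `var = (c1^2 P + c3^2 Q - (c1 P + c3 Q)^2) / n` with
#' `c1 = 1/(1-2P-Q)`, `c2 = 1/(1-2Q)`, `c3 = (c1 + c2)/2`.
#'
#' @param counts site-pattern counts from [count_patterns()].
#' @return A list with `d`, `var`, and `model = "K2P"`.
#' @export
k2p_distance <- function(counts) {
  n <- counts$n
  P <- counts$ts / n
  Q <- counts$tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    saturation_error(sprintf(
      "K2P distance saturated: P = %.4f, Q = %.4f (n = %d)", P, Q, n))
  }
  d <- -0.5 * log(w1 * sqrt(w2))
  c1 <- 1 / w1
  c2 <- 1 / w2
  c3 <- (c1 + c2) / 2
  v <- (c1^2 * P + c3^2 * Q - (c1 * P + c3 * Q)^2) / n
  list(d = d, var = v, model = "K2P")
}

#' Uncorrected p-distance (debugging model)
#' @param counts site-pattern counts from [count_patterns()].
#' @return A list with `d`, `var`, and `model = "p"`.
#' @export
p_distance <- function(counts) {
  n <- counts$n; p <- (counts$ts + counts$tv) / n
  list(d = p, var = p * (1 - p) / n, model = "p")
}

#' Pairwise distance matrix under a substitution model
#'
#' Computes all pairwise model-corrected distances and their variances.
#' With `deletion = "complete"` the gap/N filter is applied once across the
#' whole alignment before the pair loop; with `"pairwise"` each pair drops
#' only its own gapped sites. Saturated pairs are an error listing the
#' offending pairs (a silent NaN would corrupt neighbor-joining).
#'
#' @param aln a `dna_alignment` of at least 2 sequences.
#' @param model `"K2P"`, `"JC"` or `"p"`.
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @return An object of class `dist_matrix`: list with `ids`, symmetric
#'   numeric matrices `d` and `var` (zero diagonal), `n` (sites used per
#'   pair), and `model`.
#' @export
distance_matrix <- function(aln, model = c("K2P", "JC", "p"),
                            deletion = c("complete", "pairwise")) {
  stopifnot(inherits(aln, "dna_alignment"))
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  if (nrow(aln) < 2L) stop("need at least 2 sequences")
  if (deletion == "complete") aln <- complete_deletion(aln)
  fn <- switch(model, K2P = k2p_distance, JC = jc_distance, p = p_distance)
  ids <- rownames(aln)
  k <- length(ids)
  D <- V <- N <- matrix(0, k, k, dimnames = list(ids, ids))
  saturated <- character()
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      cts <- count_patterns(unclass(aln)[i, ], unclass(aln)[j, ])
      est <- tryCatch(fn(cts), potevol_saturation_error = function(e) e)
      if (inherits(est, "condition")) {
        saturated <- c(saturated, paste0(ids[i], "-", ids[j]))
        next
      }
      D[i, j] <- D[j, i] <- est$d
      V[i, j] <- V[j, i] <- est$var
      N[i, j] <- N[j, i] <- cts$n
    }
  }
  if (length(saturated)) {
    saturation_error(paste0("saturated pairs: ",
                            paste(saturated, collapse = ", ")))
  }
  structure(list(ids = ids, d = D, var = V, n = N, model = model),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(x$model, "distance matrix over", length(x$ids), "taxa\n")
  print(round(x$d, 5L))
  invisible(x)
}

#' Write a distance matrix as a PHYLIP square matrix
#' @param dm a `dist_matrix`.
#' @param path output path.
#' @export
write_phylip <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", length(dm$ids)), con)
  for (i in seq_along(dm$ids)) {
    writeLines(paste0(formatC(dm$ids[i], width = -10L), " ",
                      paste(sprintf("%.8f", dm$d[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Write a distance matrix as long-format TSV
#' @param dm a `dist_matrix`.
#' @param path output path.
#' @export
write_dist_tsv <- function(dm, path) {
  k <- length(dm$ids)
  idx <- which(upper.tri(dm$d), arr.ind = TRUE)
  tab <- data.frame(taxon_a = dm$ids[idx[, 1L]], taxon_b = dm$ids[idx[, 2L]],
                    d = dm$d[idx], var = dm$var[idx], n_sites = dm$n[idx],
                    model = dm$model)
  tab <- tab[order(tab$taxon_a, tab$taxon_b), ]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
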