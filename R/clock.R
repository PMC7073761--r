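# Rate-constancy testing and calibrated molecular-clock dating.

#' Tajima's relative rate test
#'
#' Tests clocklike evolution of two ingroup sequences against an outgroup
#' by comparing the counts of lineage-unique substitutions: `m1` is the
#' number of sites where only sequence `a` differs (b equals the
#' outgroup), `m2` where only `b` differs. Under rate constancy
#' `E(m1) = E(m2)` and `chi2 = (m1 - m2)^2 / (m1 + m2)` has approximately
#' a chi-square distribution with 1 df. Sites with a gap or N in any of
#' the three sequences are excluded. `m1 + m2 = 0` yields `chi2 = 0`,
#' `p = 1`.
#'
#' @param a,b ingroup sequences (rows of a `dna_alignment`, or strings).
#' @param outgroup outgroup sequence, same length.
#' @return A list with `m1`, `m2`, `chi2`, `p_value`.
#' @export
tajima_relative_rate <- function(a, b, outgroup) {
  as_chars <- function(x) {
    if (length(x) == 1L && nchar(x[1L]) > 1L) strsplit(toupper(x), "")[[1L]]
    else toupper(x)
  }
  a <- as_chars(a); b <- as_chars(b); o <- as_chars(outgroup)
  if (length(a) != length(b) || length(a) != length(o)) {
    stop("sequences have unequal lengths")
  }
  ok <- !(a %in% GAPLIKE | b %in% GAPLIKE | o %in% GAPLIKE)
  a <- a[ok]; b <- b[ok]; o <- o[ok]
  m1 <- sum(a != b & b == o)
  m2 <- sum(b != a & a == o)
  if (m1 + m2 == 0L) {
    chi2 <- 0; p <- 1
  } else {
    chi2 <- (m1 - m2)^2 / (m1 + m2)
    p <- pchisq(chi2, df = 1L, lower.tail = FALSE)
  }
  list(m1 = m1, m2 = m2, chi2 = chi2, p_value = p)
}

#' Read a calibration table
#'
#' TSV with columns `taxon_a`, `taxon_b`, `split_time_myr`, one row per
#' calibration pair (e.g. human-chimpanzee at 6 Myr, human-orangutan at
#' 16 Myr).
#'
#' @param path path to a TSV file.
#' @return A data frame of calibration points.
#' @export
read_calibrations <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("taxon_a", "taxon_b", "split_time_myr")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("calibration table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(tab$split_time_myr <= 0)) stop("split_time_myr must be positive")
  tab[need]
}

#' Per-lineage substitution rate from calibration pairs
#'
#' Each calibration pair (taxa split `T_i` Myr ago) yields
#' `R_i = K_i / (2 T_i)` where `K_i` is the model-corrected distance
#' between the pair. The combined rate is the unweighted mean of the
#' per-calibration rates. Its standard error combines the delta-method
#' propagation of each `Var(K_i)` with the between-calibration spread:
#' `se^2 = sum(Var(K_i)/(2 T_i)^2)/k^2 + var(R_i)/k`.
#'
#' @param dm a `dist_matrix` containing every calibration pair.
#' @param cals data frame with columns `taxon_a`, `taxon_b`,
#'   `split_time_myr` (see [read_calibrations()]).
#' @return A list of class `lineage_rate`: `R` (subs/site/Myr per
#'   lineage), `se`, and `source` (per-calibration data frame with each
#'   `K_i`, `T_i` and `R_i`).
#' @export
calibrate_rate <- function(dm, cals) {
  stopifnot(inherits(dm, "dist_matrix"))
  k <- nrow(cals)
  if (k == 0L) stop("no calibration points supplied")
  Ki <- vi <- Ri <- numeric(k)
  for (i in seq_len(k)) {
    ta <- cals$taxon_a[i]; tb <- cals$taxon_b[i]
    if (!ta %in% dm$ids || !tb %in% dm$ids) {
      stop("calibration pair ", ta, "-", tb, " not present in distance matrix")
    }
    Ki[i] <- dm$d[ta, tb]
    vi[i] <- dm$var[ta, tb]
    if (Ki[i] == 0) stop("zero calibration distance for pair ", ta, "-", tb)
    Ri[i] <- Ki[i] / (2 * cals$split_time_myr[i])
  }
  R <- mean(Ri)
  delta_var <- sum(vi / (2 * cals$split_time_myr)^2) / k^2
  spread_var <- if (k > 1L) var(Ri) / k else 0
  structure(list(R = R, se = sqrt(delta_var + spread_var),
                 source = data.frame(taxon_a = cals$taxon_a,
                                     taxon_b = cals$taxon_b,
                                     split_time_myr = cals$split_time_myr,
                                     K = Ki, var_K = vi, R = Ri)),
            class = "lineage_rate")
}

#' @export
print.lineage_rate <- function(x, ...) {
  cat(sprintf("per-lineage rate R = %.6g +- %.2g subs/site/Myr (%d calibration%s)\n",
              x$R, x$se, nrow(x$source), if (nrow(x$source) > 1L) "s" else ""))
  invisible(x)
}

#' Date a duplication event from a pairwise distance
#'
#' The molecular-clock estimate `T = K / (2R)`: `K` is the corrected
#' distance between the two duplicates, `R` the per-lineage substitution
#' rate. The default standard error propagates only the distance
#' variance, `se_T = sqrt(Var(K)) / (2R)`; the component due to rate
#' uncertainty, `K * se_R / (2 R^2)`, is reported separately
#' (`se_T_rate`) and in quadrature (`se_T_total`).
#'
#' @param K distance estimate: a list with `d` and `var` (as returned by
#'   [k2p_distance()]), or a bare number (then `var = 0`).
#' @param rate a `lineage_rate`.
#' @return A list with `K`, `T` (Myr), `se_T`, `se_T_rate`, `se_T_total`,
#'   and `rate_used`.
#' @export
date_duplication <- function(K, rate) {
  stopifnot(inherits(rate, "lineage_rate"), rate$R > 0)
  if (is.numeric(K)) K <- list(d = K, var = 0)
  if (!is.finite(K$d)) stop("cannot date a saturated distance")
  T_hat <- K$d / (2 * rate$R)
  se_T <- sqrt(K$var) / (2 * rate$R)
  se_rate <- K$d * rate$se / (2 * rate$R^2)
  list(K = K$d, T = T_hat, se_T = se_T, se_T_rate = se_rate,
       se_T_total = sqrt(se_T^2 + se_rate^2), rate_used = rate)
}

#' Date a set of duplication events within an aligned gene family
#'
#' End-to-end dating: complete deletion, model-corrected distance matrix,
#' per-event distance `K` (the pair distance, or the arithmetic mean over
#' the pairs spanning one duplication node), rate calibration, and
#' `T = K/2R` per event. Tajima's relative rate test against the named
#' outgroup is run for every dated pair and attached to the report.
#'
#' @param aln a `dna_alignment` containing all named taxa.
#' @param events named list: each element is a character matrix or vector
#'   of taxon pairs spanning one duplication event. A vector of length 2
#'   is one pair; a 2-column matrix holds several spanning pairs.
#' @param cals calibration data frame (see [calibrate_rate()]).
#' @param outgroup taxon id used for the relative rate tests; must be
#'   named explicitly.
#' @param model substitution model (default `"K2P"`).
#' @return A data frame of class `dating_report`, one row per event, with
#'   columns `event`, `K`, `var_K`, `R`, `T_myr`, `se_T_myr`,
#'   `se_T_total_myr`, `tajima_chi2`, `tajima_p` (worst, i.e. smallest, p
#'   over the event's pairs). The calibrated rate is in attribute `rate`.
#' @export
date_family <- function(aln, events, cals, outgroup, model = "K2P") {
  stopifnot(inherits(aln, "dna_alignment"))
  if (length(events) == 0L) {
    return(structure(data.frame(event = character(), K = numeric(),
                                var_K = numeric(), R = numeric(),
                                T_myr = numeric(), se_T_myr = numeric(),
                                se_T_total_myr = numeric(),
                                tajima_chi2 = numeric(),
                                tajima_p = numeric()),
                     class = c("dating_report", "data.frame")))
  }
  if (!outgroup %in% rownames(aln)) stop("outgroup '", outgroup,
                                         "' not in alignment")
  aln <- complete_deletion(aln)
  dm <- distance_matrix(aln, model = model, deletion = "pairwise")
  rate <- calibrate_rate(dm, cals)
  rows <- lapply(names(events), function(ev) {
    prs <- events[[ev]]
    if (is.null(dim(prs))) prs <- matrix(prs, ncol = 2L, byrow = TRUE)
    miss <- setdiff(unique(as.vector(prs)), dm$ids)
    if (length(miss)) stop("event ", ev, " names unknown taxa: ",
                           paste(miss, collapse = ", "))
    np <- nrow(prs)
    Ks <- vapply(seq_len(np), function(i) dm$d[prs[i, 1L], prs[i, 2L]],
                 numeric(1L))
    vs <- vapply(seq_len(np), function(i) dm$var[prs[i, 1L], prs[i, 2L]],
                 numeric(1L))
    # mean of spanning pair distances; variance of the mean under an
    # independence approximation
    K <- list(d = mean(Ks), var = mean(vs) / np)
    dt <- date_duplication(K, rate)
    taj <- lapply(seq_len(np), function(i) {
      tajima_relative_rate(unclass(aln)[prs[i, 1L], ],
                           unclass(aln)[prs[i, 2L], ],
                           unclass(aln)[outgroup, ])
    })
    worst <- which.min(vapply(taj, `[[`, numeric(1L), "p_value"))
    data.frame(event = ev, K = dt$K, var_K = K$var, R = rate$R,
               T_myr = dt$T, se_T_myr = dt$se_T,
               se_T_total_myr = dt$se_T_total,
               tajima_chi2 = taj[[worst]]$chi2,
               tajima_p = taj[[worst]]$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "rate") <- rate
  class(out) <- c("dating_report", class(out))
  out
}
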