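# LINE-signature classification of POTE paralogs and LIR detection.
#
# The four groups are recognizable from transposable-element signatures:
# group I is massively invaded by L1PA elements and (like group II)
# carries an L1M5 element in intron 1; group II shows the cluster
# L1M5-L1PA15-L1M5 in intron 9, which in the other groups reads
# L1ME3G-L1PA15-L1ME3G; group III carries a duplicated exon 6-9 block
# that groups IV lacks.

#' Construct a gene model (exon/intron structure) for one locus
#'
#' Exons are locus-relative, 1-based inclusive, sorted and
#' non-overlapping. Introns are derived as the gaps between consecutive
#' *canonical* exons (labels `"1"` to `"11"`); paralog-specific extra
#' exons (e.g. the duplicated 6'-9' block, or 9a-9c) are carried as
#' annotations with their own labels and do not renumber the canonical
#' scheme.
#'
#' @param gene_id locus identifier.
#' @param exons data frame with columns `start`, `end`, `label`
#'   (character; canonical exons labelled `"1"`..`"11"`).
#' @param dup_6_9 logical: does the model carry an annotated duplicated
#'   exon 6-9 block?
#' @return A list of class `gene_model` with `gene_id`, `exons`,
#'   `dup_6_9`, and `locus_length` (the span end of the last exon).
#' @export
gene_model <- function(gene_id, exons, dup_6_9 = FALSE) {
  need <- c("start", "end", "label")
  miss <- setdiff(need, names(exons))
  if (length(miss)) stop("gene model missing columns: ",
                         paste(miss, collapse = ", "))
  exons <- exons[order(exons$start), need, drop = FALSE]
  exons$label <- as.character(exons$label)
  if (any(exons$start > exons$end) || any(exons$start < 1L)) {
    stop("invalid exon interval in model for ", gene_id)
  }
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    stop("overlapping exons in model for ", gene_id)
  }
  rownames(exons) <- NULL
  structure(list(gene_id = gene_id, exons = exons,
                 dup_6_9 = isTRUE(dup_6_9),
                 locus_length = max(exons$end)),
            class = "gene_model")
}

#' Interval of the k-th canonical intron
#'
#' Intron `k` spans from just after canonical exon `k` to just before
#' canonical exon `k+1` (any paralog-specific exons lying between them
#' are inside the intron for repeat-overlap purposes).
#'
#' @param model a `gene_model`.
#' @param k intron number (1 to 10).
#' @return Integer vector `c(start, end)`, or `NULL` if the flanking
#'   exons abut.
#' @export
intron_interval <- function(model, k) {
  ex <- model$exons
  a <- ex[ex$label == as.character(k), , drop = FALSE]
  b <- ex[ex$label == as.character(k + 1L), , drop = FALSE]
  if (nrow(a) != 1L || nrow(b) != 1L) {
    stop("canonical exons ", k, "/", k + 1L, " not found in model for ",
         model$gene_id)
  }
  s <- a$end + 1L
  e <- b$start - 1L
  if (s > e) return(NULL)
  c(s, e)
}

hits_overlapping <- function(track, iv) {
  if (is.null(iv) || nrow(track) == 0L) {
    return(track[integer(), , drop = FALSE])
  }
  track[track$start <= iv[2L] & track$end >= iv[1L], , drop = FALSE]
}

#' Extract the LINE-content signature of one gene locus
#'
#' Computes the four classification characters from a repeat track and a
#' gene model sharing the same locus-relative coordinate frame:
#' * `l1m5_intron1`: an L1M5 element overlaps intron 1;
#' * `intron9_cluster`: the ordered LINE element names overlapping intron
#'   9 (interleaved non-LINE hits are ignored, since RepeatMasker
#'   fragments elements);
#' * `l1pa_invasion`: total bp covered by `L1PA*` hits exceeds
#'   `invasion_threshold` of the locus length;
#' * `exon6_9_dup`: the model has more than 11 exons with an annotated
#'   duplicated exon 6-9 block.
#'
#' @param track a `repeat_track`.
#' @param model a `gene_model` with the same `gene_id`.
#' @param invasion_threshold fraction of locus bp covered by L1PA
#'   elements that counts as "massive invasion" (default 0.20).
#' @return A list of class `line_signature`.
#' @export
extract_line_signature <- function(track, model, invasion_threshold = 0.20) {
  stopifnot(inherits(model, "gene_model"))
  tid <- attr(track, "gene_id")
  if (!is.null(tid) && tid != model$gene_id) {
    stop("track gene_id '", tid, "' does not match model '",
         model$gene_id, "'")
  }
  if (nrow(track) && any(track$end > model$locus_length)) {
    stop("coordinate frame mismatch: repeat hit beyond locus end for ",
         model$gene_id)
  }
  iv1 <- intron_interval(model, 1L)
  iv9 <- intron_interval(model, 9L)
  in1 <- hits_overlapping(track, iv1)
  in9 <- hits_overlapping(track, iv9)
  line9 <- in9[startsWith(in9$repeat_class, "LINE"), , drop = FALSE]
  l1pa <- track[grepl("^L1PA", track$repeat_name), , drop = FALSE]
  l1pa_bp <- if (nrow(l1pa)) sum(l1pa$end - l1pa$start + 1L) else 0L
  structure(list(
    gene_id = model$gene_id,
    l1pa_invasion = l1pa_bp / model$locus_length >= invasion_threshold,
    l1m5_intron1 = any(in1$repeat_name == "L1M5"),
    intron9_cluster = as.character(line9$repeat_name),
    exon6_9_dup = nrow(model$exons) > 11L && model$dup_6_9
  ), class = "line_signature")
}

GROUP_II_CLUSTER <- c("L1M5", "L1PA15", "L1M5")
GROUP_IV_CLUSTER <- c("L1ME3G", "L1PA15", "L1ME3G")

#' Assign a paralog to a POTE group from its LINE signature
#'
#' Pure rule-based classification; the rules fire independently and each
#' appends to the trace:
#' * R1: L1PA invasion and L1M5 in intron 1 -> group I;
#' * R2: L1M5 in intron 1 and intron-9 cluster L1M5-L1PA15-L1M5 -> group II;
#' * R3: no intron-1 L1M5 and duplicated exon 6-9 block -> group III;
#' * R4: no intron-1 L1M5, no duplication, intron-9 cluster
#'   L1ME3G-L1PA15-L1ME3G -> group IV.
#'
#' If no rule or more than one rule fires the gene is `"ambiguous"` (a
#' value, not an error), with the conflicting groups listed — the
#' behaviour the family's POTEKP shows between groups III and IV.
#'
#' @param sig a `line_signature`.
#' @return A list of class `group_assignment` with `gene_id`, `group`
#'   (one of `"I"`, `"II"`, `"III"`, `"IV"`, `"ambiguous"`),
#'   `fired_rules`, and `conflicts`.
#' @export
assign_group <- function(sig) {
  stopifnot(inherits(sig, "line_signature"))
  fired <- character()
  groups <- character()
  if (sig$l1pa_invasion && sig$l1m5_intron1) {
    fired <- c(fired, "R1"); groups <- c(groups, "I")
  }
  if (sig$l1m5_intron1 && identical(sig$intron9_cluster, GROUP_II_CLUSTER)) {
    fired <- c(fired, "R2"); groups <- c(groups, "II")
  }
  if (!sig$l1m5_intron1 && sig$exon6_9_dup) {
    fired <- c(fired, "R3"); groups <- c(groups, "III")
  }
  if (!sig$l1m5_intron1 && !sig$exon6_9_dup &&
      identical(sig$intron9_cluster, GROUP_IV_CLUSTER)) {
    fired <- c(fired, "R4"); groups <- c(groups, "IV")
  }
  if (length(groups) == 1L) {
    group <- groups
    conflicts <- character()
  } else {
    group <- "ambiguous"
    conflicts <- groups
  }
  structure(list(gene_id = sig$gene_id, group = group,
                 fired_rules = fired, conflicts = conflicts),
            class = "group_assignment")
}

#' Locate the best long inverted repeat (stem-loop arms) in a sequence
#'
#' Finds the highest-scoring pair of reverse-complementary arms by local
#' alignment of the sequence against its own reverse complement (match
#' +1, mismatch -1, gap -2), constrained so the two arms cannot overlap
#' (which excludes the trivial self-diagonal). Status is `"full"` when
#' the shorter arm reaches `full_arm` bp, `"half"` when it reaches
#' `min_arm`, else `"none"`; a call below `min_identity` is `"none"`.
#'
#' @param seq DNA string (A/C/G/T/N); length must be at least
#'   `2 * min_arm` and at most 10000 (the scan keeps an O(n^2) traceback
#'   matrix).
#' @param min_arm minimum arm length in bp for a "half" call (default 200).
#' @param min_identity minimum arm identity (matches / alignment columns,
#'   default 0.8).
#' @param full_arm arm length for a "full" call (default 500).
#' @return A list of class `lir_call`: `status`, `arm_length` (shorter
#'   arm, bp), `arm_identity`, `loop_length` (bp between the arms),
#'   `arm1`, `arm2` (1-based inclusive `c(start, end)`), `location`
#'   (span from arm1 start to arm2 end), `score`.
#' @export
find_inverted_repeat <- function(seq, min_arm = 200L, min_identity = 0.8,
                                 full_arm = 500L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 2L * min_arm) stop("sequence shorter than 2 * min_arm")
  if (n > 10000L) stop("sequence longer than 10 kb: scan window it first")
  hit <- sw_inverted_arm(seq, 1L, -1L, -2L)
  none <- structure(list(status = "none", arm_length = 0L,
                         arm_identity = NA_real_, loop_length = NA_integer_,
                         arm1 = NULL, arm2 = NULL, location = NULL,
                         score = 0L), class = "lir_call")
  if (hit$score <= 0L) return(none)
  arm1 <- c(hit$s_start, hit$s_end)
  arm2 <- c(n + 1L - hit$t_end, n + 1L - hit$t_start)
  arm_len <- min(arm1[2L] - arm1[1L] + 1L, arm2[2L] - arm2[1L] + 1L)
  identity <- hit$matches / hit$columns
  loop <- arm2[1L] - arm1[2L] - 1L
  status <- if (identity < min_identity || arm_len < min_arm) {
    "none"
  } else if (arm_len >= full_arm) "full" else "half"
  structure(list(status = status, arm_length = arm_len,
                 arm_identity = identity, loop_length = loop,
                 arm1 = arm1, arm2 = arm2,
                 location = c(arm1[1L], arm2[2L]), score = hit$score),
            class = "lir_call")
}

#' Join computed and externally provided gene features into one table
#'
#' Builds a per-gene feature table combining the computed group
#' assignment and LIR status with externally provided columns the
#' pipeline does not compute (exon counts, beta-actin retrogene status,
#' cysteine/ankyrin/coil counts — outputs of protein-domain tools,
#' consumed as data). Genes present in only one source get missing-value
#' markers and a warning.
#'
#' @param assignments data frame with columns `gene_id`, `group` (e.g.
#'   built from [assign_group()] results).
#' @param lir_calls data frame with columns `gene_id`, `lir` (status) —
#'   or NULL.
#' @param external data frame with a `gene_id` column plus any provided
#'   feature columns — or NULL. Duplicate `gene_id` is an error.
#' @return A data frame, one row per gene, computed columns first.
#' @export
build_feature_table <- function(assignments, lir_calls = NULL,
                                external = NULL) {
  stopifnot(is.data.frame(assignments), "gene_id" %in% names(assignments))
  tab <- assignments
  if (!is.null(lir_calls)) {
    tab <- merge(tab, lir_calls, by = "gene_id", all = TRUE)
  }
  if (!is.null(external)) {
    if (!"gene_id" %in% names(external)) {
      stop("external feature table lacks a gene_id column")
    }
    if (anyDuplicated(external$gene_id)) {
      stop("duplicate gene_id in external feature table: ",
           external$gene_id[duplicated(external$gene_id)][1L])
    }
    only_ext <- setdiff(external$gene_id, tab$gene_id)
    only_cmp <- setdiff(tab$gene_id, external$gene_id)
    if (length(only_ext) || length(only_cmp)) {
      warning("genes present in only one source: ",
              paste(c(only_ext, only_cmp), collapse = ", "))
    }
    tab <- merge(tab, external, by = "gene_id", all = TRUE)
  }
  tab[order(tab$gene_id), , drop = FALSE]
}
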