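# Synthetic gene families with known duplication times, substitution
# process and repeat-insertion histories. The generator is the test bed
# for the whole pipeline: sequences evolve under the same K2P process the
# distance estimators assume, and repeat tracks are written in the same
# RepeatMasker dialect the parser reads.

#' Construct a duplication scenario
#'
#' A scenario is a bifurcation history (speciation splits and duplication
#' events, times in Myr before present) plus the generating substitution
#' process. Events are rows `(id, time, target, left, right)`: at `time`,
#' the lineage named `target` splits into `left` and `right`. The oldest
#' event must target the lineage `"ancestor"`; every other event must
#' target a lineage created by an earlier (older) event.
#'
#' @param name scenario name.
#' @param events data frame with columns `id`, `time`, `target`, `left`,
#'   `right`.
#' @param rate per-lineage substitution rate R0 in subs/site/Myr
#'   (default 0.001, a typical neutral primate rate: it reproduces ~1.2%
#'   human-chimp divergence at a 6-Myr split).
#' @param kappa transition/transversion rate ratio (default 2.0, typical
#'   mammalian transition bias).
#' @param seq_length alignment length in sites (default 10000).
#' @param calibrations optional calibration data frame (`taxon_a`,
#'   `taxon_b`, `split_time_myr`) consistent with the events.
#' @param event_pairs optional named list of taxon pairs spanning each
#'   dated duplication node (the `events` argument of [date_family()]).
#' @param outgroup optional outgroup taxon id for rate tests.
#' @param group optional POTE group label (`"I"` to `"IV"`) switching on
#'   signature repeat-track simulation.
#' @return A list of class `duplication_scenario`.
#' @export
duplication_scenario <- function(name, events, rate = 0.001, kappa = 2.0,
                                 seq_length = 10000L, calibrations = NULL,
                                 event_pairs = NULL, outgroup = NULL,
                                 group = NA_character_) {
  need <- c("id", "time", "target", "left", "right")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("events missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(events$time <= 0)) stop("event times must be positive")
  if (seq_length < 1L) stop("seq_length must be >= 1")
  if (kappa < 0) stop("kappa must be >= 0")
  events <- events[order(-events$time), , drop = FALSE]
  rownames(events) <- NULL
  alive <- "ancestor"
  for (i in seq_len(nrow(events))) {
    tg <- events$target[i]
    if (!tg %in% alive) {
      stop("event ", events$id[i], " targets unknown or already-split ",
           "lineage '", tg, "' (child older than parent?)")
    }
    alive <- c(setdiff(alive, tg), events$left[i], events$right[i])
  }
  structure(list(name = name, events = events, rate = rate, kappa = kappa,
                 seq_length = as.integer(seq_length),
                 calibrations = calibrations, event_pairs = event_pairs,
                 outgroup = outgroup, group = group, leaves = alive),
            class = "duplication_scenario")
}

#' Build the time-tree of a duplication scenario
#'
#' Each split/duplication node sits at its stated time; branch lengths
#' are in Myr; all leaves are at time 0, so the tree is ultrametric.
#' Internal nodes are labelled with the name of the lineage that split,
#' which lets downstream code resolve "all descendants of lineage X".
#'
#' @param sc a `duplication_scenario`.
#' @return A rooted [ape::phylo] tree with branch lengths in Myr.
#' @export
build_event_tree <- function(sc) {
  stopifnot(inherits(sc, "duplication_scenario"))
  ev <- sc$events
  split_time <- setNames(ev$time, ev$target)
  children <- setNames(lapply(seq_len(nrow(ev)),
                              function(i) c(ev$left[i], ev$right[i])),
                       ev$target)
  build <- function(name, parent_time) {
    if (name %in% names(children)) {
      t0 <- split_time[[name]]
      if (t0 > parent_time) {
        stop("event at lineage '", name, "' (", t0, " Myr) is older than ",
             "its parent node (", parent_time, " Myr)")
      }
      kids <- children[[name]]
      paste0("(", build(kids[1L], t0), ",", build(kids[2L], t0), ")",
             name, ":", fmt_bl(parent_time - t0))
    } else {
      paste0(name, ":", fmt_bl(parent_time))
    }
  }
  root_time <- ev$time[1L]
  kids <- children[["ancestor"]]
  nwk <- paste0("(", build(kids[1L], root_time), ",",
                build(kids[2L], root_time), ")ancestor;")
  ape::read.tree(text = nwk)
}

k2p_site_probs <- function(d, kappa) {
  # 4x4 transition matrix over bases A,C,G,T for total branch divergence d
  bp <- d / (kappa + 2)
  ap <- kappa * bp
  e1 <- exp(-4 * bp)
  e2 <- exp(-2 * (ap + bp))
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1        # each of the two transversion targets
  p_same <- 1 - p_ts - 2 * p_tv
  #        A       C      G      T
  m <- rbind(c(p_same, p_tv, p_ts, p_tv),    # from A
             c(p_tv, p_same, p_tv, p_ts),    # from C
             c(p_ts, p_tv, p_same, p_tv),    # from G
             c(p_tv, p_ts, p_tv, p_same))    # from T
  m
}

#' Evolve sequences along a time-tree under the K2P process
#'
#' The root sequence is uniform over A/C/G/T; along each branch of `t`
#' Myr every site substitutes according to the Kimura 2-parameter
#' transition probabilities for a total expected divergence `d = R * t`
#' substitutions/site (per lineage), with transition/transversion rate
#' ratio `kappa`. Sequences are generated gap-free; `gap_columns`
#' optionally converts that many random columns to gaps in one random
#' sequence each, solely to exercise deletion logic downstream.
#'
#' @param tree a rooted [ape::phylo] with branch lengths in Myr.
#' @param rate per-lineage substitution rate (subs/site/Myr).
#' @param kappa transition/transversion rate ratio.
#' @param L number of sites (>= 1).
#' @param seed integer RNG seed; same seed, same alignment.
#' @param gap_columns number of columns to gap (default 0).
#' @return A `dna_alignment` over the tree's leaves.
#' @export
evolve_sequences <- function(tree, rate, kappa, L, seed,
                             gap_columns = 0L) {
  if (L < 1L) stop("L must be >= 1")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  seqs <- vector("list", nnode)
  root <- ntip + 1L
  seqs[[root]] <- sample.int(4L, L, replace = TRUE)
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  eln <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1L]; chl <- edges[e, 2L]
    d <- rate * eln[e]
    pseq <- seqs[[par]]
    if (d == 0) {
      seqs[[chl]] <- pseq
      next
    }
    pm <- k2p_site_probs(d, kappa)
    cseq <- integer(L)
    for (b in 1:4) {
      idx <- which(pseq == b)
      if (length(idx)) {
        cseq[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                prob = pm[b, ])
      }
    }
    seqs[[chl]] <- cseq
  }
  m <- matrix("", nrow = ntip, ncol = L,
              dimnames = list(tree$tip.label, NULL))
  for (i in seq_len(ntip)) m[i, ] <- bases[seqs[[i]]]
  if (gap_columns > 0L) {
    cols <- sample.int(L, min(gap_columns, L))
    for (cc in cols) m[sample.int(ntip, 1L), cc] <- "-"
  }
  class(m) <- c("dna_alignment", class(m))
  m
}

#' Canonical 11-exon gene-model template
#'
#' A synthetic POTE-like locus: 11 canonical exons of 150 bp separated by
#' 3000-bp introns (locus span 31,650 bp, in the size range of the real
#' genes). With `dup_6_9 = TRUE`, four extra exons labelled `"6'"`-`"9'"`
#' (the duplicated exon 6-9 block) are annotated inside intron 9.
#'
#' @param gene_id locus identifier.
#' @param dup_6_9 annotate a duplicated exon 6-9 block?
#' @return A `gene_model`.
#' @export
canonical_gene_model <- function(gene_id, dup_6_9 = FALSE) {
  starts <- (0:10) * 3150L + 1L
  ex <- data.frame(start = starts, end = starts + 149L,
                   label = as.character(1:11))
  if (dup_6_9) {
    i9 <- ex$end[ex$label == "9"] + 1L
    ds <- i9 + 1699L + (0:3) * 300L
    ex <- rbind(ex, data.frame(start = ds, end = ds + 149L,
                               label = paste0(6:9, "'")))
  }
  gene_model(gene_id, ex, dup_6_9 = dup_6_9)
}

line_class <- function(name) {
  if (grepl("^L1", name)) "LINE/L1" else "Unknown"
}

#' Simulate branch-specific repeat insertions as annotation tracks
#'
#' Each insertion `(lineage, repeat_name, intron, length)` places one
#' element in the named canonical intron of every leaf descended from
#' `lineage` (a leaf name or an internal lineage name from the scenario)
#' and in no other leaf — the presence/absence logic by which LINE
#' insertions date duplications. Tracks are annotation-level: sequence
#' content is untouched. Elements inserted into the same intron of the
#' same gene are laid out left to right in input order at deterministic
#' offsets.
#'
#' @param family a simulated family (list with `tree` and `alignment`,
#'   see [simulate_family()]).
#' @param insertions data frame with columns `lineage`, `repeat_name`,
#'   `intron` (1-10), and optionally `length` (bp, default 600).
#' @param dup_6_9 logical (scalar or named by leaf): use the duplicated
#'   exon 6-9 template for these leaves' gene models.
#' @return The family with `tracks` (named list of `repeat_track`) and
#'   `models` (named list of `gene_model`) filled in.
#' @export
insert_repeats <- function(family, insertions, dup_6_9 = FALSE) {
  tree <- family$tree
  tips <- tree$tip.label
  if (is.null(insertions$length)) insertions$length <- 600L
  tips_below <- function(node) {
    if (node <= length(tips)) return(tips[node])
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    unlist(lapply(kids, tips_below))
  }
  desc_of <- function(lineage) {
    if (lineage %in% tips) return(lineage)
    hit <- which(tree$node.label == lineage)
    if (length(hit) != 1L) stop("unknown lineage: ", lineage)
    tips_below(length(tips) + hit)
  }
  dup <- if (length(dup_6_9) == 1L) setNames(rep(isTRUE(dup_6_9),
                                                 length(tips)), tips)
         else dup_6_9
  models <- lapply(tips, function(tp) {
    canonical_gene_model(tp, dup_6_9 = isTRUE(dup[[tp]]))
  })
  names(models) <- tips
  tracks <- list()
  for (tp in tips) {
    slot <- integer(10L)   # next free slot per intron
    rows <- list()
    for (i in seq_len(nrow(insertions))) {
      if (!tp %in% desc_of(insertions$lineage[i])) next
      k <- insertions$intron[i]
      iv <- intron_interval(models[[tp]], k)
      len <- insertions$length[i]
      st <- iv[1L] + 99L + slot[k] * (len + 100L)
      slot[k] <- slot[k] + 1L
      if (st + len - 1L > iv[2L]) {
        stop("intron ", k, " of ", tp, " cannot hold insertion ",
             insertions$repeat_name[i])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        start = st, end = st + len - 1L, strand = "+",
        repeat_name = insertions$repeat_name[i],
        repeat_class = line_class(insertions$repeat_name[i]),
        score = 1000)
    }
    tracks[[tp]] <- repeat_track(tp, if (length(rows)) do.call(rbind, rows)
                                     else NULL)
  }
  family$tracks <- tracks
  family$models <- models
  family
}

#' Group-defining repeat-insertion presets
#'
#' The insertion lists that reproduce the four LINE-content signatures on
#' a whole family (applied at the root lineage `"ancestor"`): group I,
#' L1M5 in intron 1 plus a massive L1PA load (four 2-kb L1PA2/L1PA3
#' elements, >20% of the locus); group II, intron-1 L1M5 plus the
#' intron-9 cluster L1M5-L1PA15-L1M5; groups III and IV, the intron-9
#' cluster L1ME3G-L1PA15-L1ME3G without intron-1 L1M5 (group III is then
#' separated by its duplicated exon 6-9 block).
#'
#' @param group `"I"`, `"II"`, `"III"` or `"IV"`.
#' @param lineage lineage carrying the insertions (default `"ancestor"`).
#' @return Insertion data frame for [insert_repeats()].
#' @export
group_signature_insertions <- function(group, lineage = "ancestor") {
  ins <- function(name, intron, length = 600L) {
    data.frame(lineage = lineage, repeat_name = name, intron = intron,
               length = length)
  }
  cluster <- function(a) rbind(ins(a, 9L), ins("L1PA15", 9L), ins(a, 9L))
  switch(group,
    I = rbind(ins("L1M5", 1L),
              ins("L1PA2", 2L, 2000L), ins("L1PA2", 3L, 2000L),
              ins("L1PA3", 4L, 2000L), ins("L1PA3", 5L, 2000L),
              cluster("L1ME3G")),
    II = rbind(ins("L1M5", 1L), cluster("L1M5")),
    III = cluster("L1ME3G"),
    IV = cluster("L1ME3G"),
    stop("unknown group: ", group))
}

#' Simulate a complete gene family from a scenario
#'
#' Builds the event tree, evolves sequences under the scenario's K2P
#' process, and (when the scenario names a POTE group) generates the
#' group's signature repeat tracks. The returned family carries the
#' ground truth every pipeline stage is checked against.
#'
#' @param sc a `duplication_scenario`.
#' @param seed integer RNG seed.
#' @param gap_columns columns to gap (see [evolve_sequences()]).
#' @return A list of class `simulated_family`: `alignment`, `tree`,
#'   `scenario`, `truth` (event times, rate, kappa, group), and — when a
#'   group is set — `tracks` and `models`.
#' @export
simulate_family <- function(sc, seed = 1L, gap_columns = 0L) {
  stopifnot(inherits(sc, "duplication_scenario"))
  tree <- build_event_tree(sc)
  aln <- evolve_sequences(tree, sc$rate, sc$kappa, sc$seq_length, seed,
                          gap_columns = gap_columns)
  fam <- structure(list(alignment = aln, tree = tree, scenario = sc,
                        truth = list(times = as.list(setNames(sc$events$time,
                                                              sc$events$id)),
                                     rate = sc$rate, kappa = sc$kappa,
                                     group = sc$group, seed = seed)),
                   class = "simulated_family")
  if (!is.na(sc$group)) {
    fam <- insert_repeats(fam, group_signature_insertions(sc$group),
                          dup_6_9 = identical(sc$group, "III"))
  }
  fam
}

two_step_scenario <- function(name, genes, t1, t2, group,
                              anc_name, ...) {
  # 16-Myr orangutan split, 6-Myr chimp split, duplication at t1 giving
  # genes[1] and an ancestor that splits again at t2 into genes[2:3]
  ev <- data.frame(
    id = c("split_orang", "split_chimp", paste0(name, "_dup1"),
           paste0(name, "_dup2")),
    time = c(16, 6, t1, t2),
    target = c("ancestor", "hc_ancestor", "human_lineage", anc_name),
    left = c("orangutan", "chimpanzee", genes[1L], genes[2L]),
    right = c("hc_ancestor", "human_lineage", anc_name, genes[3L]))
  duplication_scenario(
    name, ev,
    calibrations = data.frame(taxon_a = genes[1L],
                              taxon_b = c("chimpanzee", "orangutan"),
                              split_time_myr = c(6, 16)),
    event_pairs = setNames(list(
      rbind(c(genes[1L], genes[2L]), c(genes[1L], genes[3L])),
      rbind(c(genes[2L], genes[3L]))),
      paste0(name, c("_dup1", "_dup2"))),
    outgroup = "orangutan", group = group, ...)
}

one_step_scenario <- function(name, genes, t1, group, ...) {
  ev <- data.frame(
    id = c("split_orang", "split_chimp", paste0(name, "_dup")),
    time = c(16, 6, t1),
    target = c("ancestor", "hc_ancestor", "human_lineage"),
    left = c("orangutan", "chimpanzee", genes[1L]),
    right = c("hc_ancestor", "human_lineage", genes[2L]))
  duplication_scenario(
    name, ev,
    calibrations = data.frame(taxon_a = genes[1L],
                              taxon_b = c("chimpanzee", "orangutan"),
                              split_time_myr = c(6, 16)),
    event_pairs = setNames(list(rbind(genes)), paste0(name, "_dup")),
    outgroup = "orangutan", group = group, ...)
}

#' The six human-specific duplication scenario presets
#'
#' One preset per dated human-specific POTE duplication, with the
#' family's truth times: group II duplications at 1.07 and 0.55 Myr
#' (POTEB3, then POTEB/POTEB2), group III duplicative transpositions at
#' 1.90 Myr (POTEE/POTEF) and 1.57 Myr (POTEI/POTEJ), and group IV
#' duplications at 1.06 and 0.44 Myr (POTEH, then POTEG/POTEM). All
#' presets carry the 6-Myr human-chimpanzee and 16-Myr human-orangutan
#' calibration splits, rate 0.001 subs/site/Myr, kappa 2, and 10,000
#' sites. Each preset's `target_event`/`truth_time` name the dated event.
#'
#' @return A named list of six `duplication_scenario` objects
#'   (`groupII_first`, `groupII_second`, `groupIII_EF`, `groupIII_IJ`,
#'   `groupIV_first`, `groupIV_second`), each with `target_event` and
#'   `truth_time` fields set.
#' @export
scenario_presets <- function() {
  g2 <- two_step_scenario("groupII", c("POTEB3", "POTEB", "POTEB2"),
                          1.07, 0.55, "II", "B_ancestor")
  g4 <- two_step_scenario("groupIV", c("POTEH", "POTEG", "POTEM"),
                          1.06, 0.44, "IV", "GM_ancestor")
  g3ef <- one_step_scenario("groupIII_EF", c("POTEE", "POTEF"), 1.90, "III")
  g3ij <- one_step_scenario("groupIII_IJ", c("POTEI", "POTEJ"), 1.57, "III")
  set_target <- function(sc, ev, t) {
    sc$target_event <- ev; sc$truth_time <- t; sc
  }
  list(
    groupII_first = set_target(g2, "groupII_dup1", 1.07),
    groupII_second = set_target(g2, "groupII_dup2", 0.55),
    groupIII_EF = set_target(g3ef, "groupIII_EF_dup", 1.90),
    groupIII_IJ = set_target(g3ij, "groupIII_IJ_dup", 1.57),
    groupIV_first = set_target(g4, "groupIV_dup1", 1.06),
    groupIV_second = set_target(g4, "groupIV_dup2", 0.44))
}

#' Write a simulated family as the pipeline's input formats
#'
#' Emits aligned FASTA, RepeatMasker-style `.out` (when tracks exist),
#' the calibration TSV and a truth JSON into a directory, so that
#' fixtures exercise the same I/O paths as real data.
#'
#' @param family a `simulated_family`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_family <- function(family, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(alignment = file.path(dir, "alignment.fasta"))
  write_fasta_alignment(family$alignment, paths[["alignment"]])
  if (!is.null(family$tracks)) {
    paths[["repeats"]] <- file.path(dir, "repeats.out")
    write_repeatmasker(family$tracks, paths[["repeats"]])
  }
  if (!is.null(family$scenario$calibrations)) {
    paths[["calibrations"]] <- file.path(dir, "calibrations.tsv")
    write.table(family$scenario$calibrations, paths[["calibrations"]],
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths[["truth"]] <- file.path(dir, "truth.json")
  jsonlite::write_json(family$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
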