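# Configuration-driven orchestration of the dating/classification stages.

#' Read a BED-like gene-model table
#'
#' TSV with columns `gene_id`, `start`, `end`, `label` (1-based inclusive
#' exon coordinates, one row per exon) and optionally `dup_6_9` (logical,
#' constant within gene).
#'
#' @param path path to a TSV file.
#' @return A named list of `gene_model` objects.
#' @export
read_gene_models <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "start", "end", "label")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("gene model table missing columns: ",
                         paste(miss, collapse = ", "))
  out <- lapply(split(tab, tab$gene_id), function(d) {
    gene_model(d$gene_id[1L], d[c("start", "end", "label")],
               dup_6_9 = isTRUE(as.logical(d$dup_6_9[1L])))
  })
  out[unique(tab$gene_id)]
}

#' Write gene models as a BED-like TSV
#'
#' Inverse of [read_gene_models()].
#'
#' @param models named list of `gene_model` objects.
#' @param path output path.
#' @export
write_gene_models <- function(models, path) {
  rows <- lapply(models, function(m) {
    data.frame(gene_id = m$gene_id, start = m$exons$start,
               end = m$exons$end, label = m$exons$label,
               dup_6_9 = m$dup_6_9)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Build a validated run configuration
#'
#' All stage inputs and tuning knobs in one flat object. Required paths
#' are validated up front for the selected stages, so a missing
#' calibration file fails before any compute. All randomness downstream
#' flows from `seed` via fixed substream offsets (bootstrap: `seed + 1`).
#'
#' @param alignment path to the aligned multi-FASTA.
#' @param calibrations path to the calibration TSV (required when dating).
#' @param repeats path to RepeatMasker `.out` (required when classifying).
#' @param gene_models path to the gene-model TSV (required when
#'   classifying).
#' @param external_features optional TSV of externally provided feature
#'   columns.
#' @param events named list of taxon pairs per duplication event (see
#'   [date_family()]).
#' @param outgroup outgroup taxon id for rate tests (required when
#'   dating).
#' @param model substitution model, `"K2P"` or `"JC"`.
#' @param deletion `"complete"` or `"pairwise"`.
#' @param n_bootstrap bootstrap replicates for tree support (default 500).
#' @param seed integer master seed.
#' @param invasion_threshold,min_arm,min_identity,full_arm classifier
#'   thresholds (see [extract_line_signature()], [find_inverted_repeat()]).
#' @param stages character vector out of `"tree"`, `"date"`,
#'   `"classify"`, or `"all"`.
#' @param out_dir output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(alignment, calibrations = NULL, repeats = NULL,
                       gene_models = NULL, external_features = NULL,
                       events = list(), outgroup = NULL,
                       model = c("K2P", "JC"),
                       deletion = c("complete", "pairwise"),
                       n_bootstrap = 500L, seed = 1L,
                       invasion_threshold = 0.20, min_arm = 200L,
                       min_identity = 0.8, full_arm = 500L,
                       stages = "all", out_dir = "potevol_run") {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  if (identical(stages, "all")) stages <- c("tree", "date", "classify")
  cfg <- list(alignment = alignment, calibrations = calibrations,
              repeats = repeats, gene_models = gene_models,
              external_features = external_features, events = events,
              outgroup = outgroup, model = model, deletion = deletion,
              n_bootstrap = as.integer(n_bootstrap), seed = as.integer(seed),
              invasion_threshold = invasion_threshold,
              min_arm = as.integer(min_arm), min_identity = min_identity,
              full_arm = as.integer(full_arm), stages = stages,
              out_dir = out_dir)
  if (!file.exists(alignment)) stop("alignment file not found: ", alignment)
  if ("date" %in% stages && length(events)) {
    if (is.null(calibrations)) {
      stop("dating requested but no calibration file configured")
    }
    if (!file.exists(calibrations)) {
      stop("calibration file not found: ", calibrations)
    }
    if (is.null(outgroup)) {
      stop("dating requested but no outgroup named (no automatic selection)")
    }
  }
  if ("classify" %in% stages && !is.null(repeats)) {
    if (!file.exists(repeats)) stop("repeat file not found: ", repeats)
    if (is.null(gene_models)) {
      stop("classification requested but no gene-model table configured")
    }
    if (!file.exists(gene_models)) {
      stop("gene model file not found: ", gene_models)
    }
  }
  structure(cfg, class = "run_config")
}

#' Read a flat `key = value` run-configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values are
#' coerced to numbers where possible. Duplication events are given as
#' `event.<name> = taxonA|taxonB` (several spanning pairs separated by
#' `;`); `stages` as a comma-separated list.
#'
#' @param path path to the config file.
#' @param ... overrides passed on to [run_config()] (flags beat file).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  keys <- trimws(vapply(kv, `[`, character(1L), 2L))
  vals <- trimws(vapply(kv, `[`, character(1L), 3L))
  args <- list()
  events <- list()
  for (i in seq_along(keys)) {
    if (startsWith(keys[i], "event.")) {
      prs <- strsplit(strsplit(vals[i], ";", fixed = TRUE)[[1L]], "|",
                      fixed = TRUE)
      events[[sub("^event\\.", "", keys[i])]] <-
        do.call(rbind, lapply(prs, trimws))
    } else if (keys[i] == "stages") {
      args$stages <- trimws(strsplit(vals[i], ",", fixed = TRUE)[[1L]])
    } else {
      num <- suppressWarnings(as.numeric(vals[i]))
      args[[keys[i]]] <- if (!is.na(num)) num else vals[i]
    }
  }
  if (length(events)) args$events <- events
  over <- list(...)
  args[names(over)] <- over
  do.call(run_config, args)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(unclass(cfg)[order(names(cfg))], file = tmp)
  unname(tools::md5sum(tmp))
}

#' Run the dating/classification pipeline
#'
#' Stages, in order: load inputs, site filtering + distance matrix,
#' NJ tree with interior-branch support, calibrated dating with Tajima
#' rate tests (stage `"date"`), LINE-signature classification (stage
#' `"classify"`). Deterministic for a fixed config: all randomness
#' derives from `cfg$seed`. Output tables are TSV with JSON mirrors; the
#' run report embeds the config hash, seed, and a checksum of every file
#' written. A stage failure halts with the stage name; files already
#' written are retained.
#'
#' @param cfg a `run_config`.
#' @return A list of class `run_report`: `stages` (status per stage),
#'   `warnings`, `outputs` (files + md5), `dating`, `groups`, `tree`,
#'   `support`, `config_hash`, `seed`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(stages = character(), warnings = character(),
                 outputs = data.frame(file = character(), md5 = character()),
                 config_hash = config_hash(cfg), seed = cfg$seed)
  emit <- function(path) {
    report$outputs <<- rbind(report$outputs,
                             data.frame(file = path,
                                        md5 = unname(tools::md5sum(path))))
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    report$stages[name] <<- "ok"
    res
  }

  aln <- stage("load", read_fasta_alignment(cfg$alignment))

  dm <- stage("distances",
              distance_matrix(aln, model = cfg$model,
                              deletion = cfg$deletion))
  dist_path <- file.path(cfg$out_dir, "distances.tsv")
  write_dist_tsv(dm, dist_path); emit(dist_path)

  if ("tree" %in% cfg$stages && length(dm$ids) >= 3L) {
    ibt <- stage("tree", {
      interior_branch_test(aln, model = cfg$model,
                           n_reps = cfg$n_bootstrap,
                           seed = cfg$seed + 1L)
    })
    tree <- neighbor_joining(dm)
    if (attr(tree, "n_clamped") > 0L) {
      report$warnings <- c(report$warnings,
                           paste0(attr(tree, "n_clamped"),
                                  " negative NJ branch(es) clamped to 0"))
    }
    tree_path <- file.path(cfg$out_dir, "nj_tree.nwk")
    sup_tree <- tree
    sup_tree$node.label <- rep("", tree$Nnode)
    hit <- match(tree_bipartitions(tree), ibt$split)
    lab_nodes <- as.integer(names(tree_bipartitions(tree)))
    ok <- !is.na(hit)
    sup_tree$node.label[lab_nodes[ok] - length(tree$tip.label)] <-
      format(ibt$bootstrap_support[hit[ok]], digits = 4L)
    write_newick(sup_tree, tree_path); emit(tree_path)
    sup_path <- file.path(cfg$out_dir, "support.tsv")
    write.table(ibt, sup_path, sep = "\t", quote = FALSE,
                row.names = FALSE); emit(sup_path)
    report$tree <- sup_tree
    report$support <- ibt
  }

  if ("date" %in% cfg$stages && length(cfg$events)) {
    dating <- stage("date", {
      cals <- read_calibrations(cfg$calibrations)
      date_family(aln, cfg$events, cals, outgroup = cfg$outgroup,
                  model = cfg$model)
    })
    dpath <- file.path(cfg$out_dir, "dating.tsv")
    write.table(dating, dpath, sep = "\t", quote = FALSE,
                row.names = FALSE); emit(dpath)
    jpath <- file.path(cfg$out_dir, "dating.json")
    jsonlite::write_json(dating, jpath, auto_unbox = TRUE, digits = NA)
    emit(jpath)
    report$dating <- dating
  }

  if ("classify" %in% cfg$stages && !is.null(cfg$repeats)) {
    groups <- stage("classify", {
      tracks <- read_repeatmasker(cfg$repeats)
      models <- read_gene_models(cfg$gene_models)
      rows <- lapply(names(tracks), function(g) {
        if (!g %in% names(models)) {
          stop("no gene model for locus ", g)
        }
        sig <- extract_line_signature(tracks[[g]], models[[g]],
                                      invasion_threshold =
                                        cfg$invasion_threshold)
        asg <- assign_group(sig)
        data.frame(gene_id = g, group = asg$group,
                   fired_rules = paste(asg$fired_rules, collapse = ","),
                   conflicts = paste(asg$conflicts, collapse = ","))
      })
      do.call(rbind, rows)
    })
    ext <- if (!is.null(cfg$external_features)) {
      read.delim(cfg$external_features, stringsAsFactors = FALSE)
    } else NULL
    groups <- build_feature_table(groups, external = ext)
    gpath <- file.path(cfg$out_dir, "groups.tsv")
    write.table(groups, gpath, sep = "\t", quote = FALSE,
                row.names = FALSE); emit(gpath)
    report$groups <- groups
  }

  rpath <- file.path(cfg$out_dir, "run_report.json")
  jsonlite::write_json(
    list(seed = report$seed, config_hash = report$config_hash,
         stages = as.list(report$stages), warnings = report$warnings,
         outputs = report$outputs),
    rpath, auto_unbox = TRUE, digits = NA)
  report$outputs <- rbind(report$outputs,
                          data.frame(file = rpath,
                                     md5 = unname(tools::md5sum(rpath))))
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("potevol run (seed ", x$seed, ", config ", x$config_hash, ")\n",
      sep = "")
  cat("stages:", paste(names(x$stages), x$stages, sep = "=",
                       collapse = ", "), "\n")
  if (!is.null(x$dating)) {
    cat("dating:\n"); print(x$dating)
  }
  if (!is.null(x$groups)) {
    cat("groups:\n"); print(x$groups[c("gene_id", "group")])
  }
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "),
                              "\n")
  invisible(x)
}
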