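#' @useDynLib potevol, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd var pnorm pchisq setNames
#' @importFrom utils read.delim write.table
NULL

# ---- Alignment container ---------------------------------------------------

#' Construct an alignment from id'd sequences
#'
#' An alignment is stored as a character matrix of single upper-case
#' characters over \{A, C, G, T, N, -\}, one row per sequence, with row
#' names holding the sequence identifiers. All rows must have the same
#' number of columns.
#'
#' @param ids character vector of unique, non-empty sequence identifiers.
#' @param seqs character vector of sequences (strings), same length as `ids`.
#' @return An object of class `dna_alignment` (a character matrix).
#' @export
new_alignment <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs))
  if (length(ids) == 0L) stop("no records")
  if (any(!nzchar(ids))) stop("empty sequence id")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  }
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs))) stop("empty sequence for id ", ids[!nzchar(seqs)][1L])
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1L])[1L]
    stop("alignment length mismatch: '", ids[bad], "' has ", lens[bad],
         " columns, expected ", lens[1L])
  }
  chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  bad_char <- setdiff(unique(chars), c("A", "C", "G", "T", "N", "-"))
  if (length(bad_char)) {
    stop("invalid characters in alignment: ", paste(bad_char, collapse = ", "))
  }
  m <- matrix(chars, nrow = length(ids), ncol = lens[1L], byrow = TRUE,
              dimnames = list(ids, NULL))
  class(m) <- c("dna_alignment", class(m))
  m
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("DNA alignment: ", nrow(x), " sequences x ", ncol(x), " columns\n",
      sep = "")
  cat("ids:", paste(utils::head(rownames(x), 8L), collapse = ", "),
      if (nrow(x) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Number of columns in an alignment
#' @param aln a `dna_alignment`.
#' @return Integer number of columns.
#' @export
alignment_length <- function(aln) ncol(aln)

#' Read an aligned (gapped) multi-FASTA file
#'
#' Records are returned in file order; sequence lengths are validated to be
#' identical. Identifiers are the FASTA header up to the first whitespace.
#'
#' @param path path to a FASTA file.
#' @return A `dna_alignment`.
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  new_alignment(ids, as.character(set))
}

#' Write an alignment as wrapped FASTA
#'
#' Sequence lines are wrapped at 60 columns.
#'
#' @param aln a `dna_alignment`.
#' @param path output path.
#' @export
write_fasta_alignment <- function(aln, path) {
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- rownames(aln)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

# ---- Genomic intervals -----------------------------------------------------

#' Construct a 1-based, inclusive genomic interval
#'
#' The whole package uses 1-based coordinates with inclusive ends, the
#' convention of UCSC-style printed positions: an interval chr16:10-12
#' covers three bases.
#'
#' @param chrom chromosome / locus name.
#' @param start,end 1-based inclusive coordinates, `start <= end`, `start >= 1`.
#' @return A list of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end)) stop("non-integer interval bounds")
  if (start < 1L) stop("start must be >= 1 (1-based coordinates)")
  if (start > end) stop("start > end in interval ", chrom, ":", start, "-", end)
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "genomic_interval")
}

#' Length of a genomic interval in base pairs
#'
#' Under the 1-based inclusive convention the length is `end - start + 1`.
#'
#' @param iv a `genomic_interval`.
#' @return Integer width in bp.
#' @export
interval_length <- function(iv) {
  stopifnot(inherits(iv, "genomic_interval"))
  iv$end - iv$start + 1L
}

#' Parse a "chrN:start-end" coordinate string into an interval
#' @param s coordinate string such as `"chr16:10145382-10145806"`.
#' @return A `genomic_interval`.
#' @export
parse_interval <- function(s) {
  m <- regmatches(s, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", s))[[1L]]
  if (length(m) != 4L) stop("cannot parse interval string: ", s)
  genomic_interval(m[2L],
                   as.integer(gsub(",", "", m[3L], fixed = TRUE)),
                   as.integer(gsub(",", "", m[4L], fixed = TRUE)))
}

# ---- RepeatMasker tracks ---------------------------------------------------

#' Construct a repeat track for one gene locus
#'
#' A repeat track is a data frame of repeat hits on a single locus in
#' locus-relative 1-based inclusive coordinates, sorted by start.
#'
#' @param gene_id locus identifier shared by all hits.
#' @param hits data frame with columns `start`, `end`, `strand` (`"+"` or
#'   `"C"`), `repeat_name`, `repeat_class`, `score`.
#' @return A data frame of class `repeat_track` with attribute `gene_id`.
#' @export
repeat_track <- function(gene_id, hits) {
  need <- c("start", "end", "strand", "repeat_name", "repeat_class", "score")
  if (is.null(hits) || nrow(hits) == 0L) {
    hits <- data.frame(start = integer(), end = integer(),
                       strand = character(), repeat_name = character(),
                       repeat_class = character(), score = numeric())
  }
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("repeat track missing columns: ",
                         paste(miss, collapse = ", "))
  hits <- hits[need]
  if (nrow(hits)) {
    if (any(!nzchar(hits$repeat_name))) stop("empty repeat_name in track")
    if (any(hits$start < 1L | hits$start > hits$end)) {
      stop("invalid hit interval in track for ", gene_id)
    }
    if (any(!hits$strand %in% c("+", "C"))) {
      stop("strand must be '+' or 'C'")
    }
    hits <- hits[order(hits$start, hits$end), , drop = FALSE]
    rownames(hits) <- NULL
  }
  attr(hits, "gene_id") <- gene_id
  class(hits) <- c("repeat_track", class(hits))
  hits
}

#' Read RepeatMasker ".out" annotation
#'
#' Parses the standard RepeatMasker output layout (3 header lines, then
#' whitespace-separated columns: SW score, divergence, deletion, insertion,
#' query, query begin/end/left, strand, repeat name, repeat class/family,
#' repeat begin/end/left, id). The `"C"` strand marker for reverse-strand
#' hits is preserved as written.
#'
#' @param path path to a RepeatMasker `.out` file.
#' @return A named list of `repeat_track` objects, one per distinct query,
#'   each with hits sorted by start.
#' @export
read_repeatmasker <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  body <- lines[-seq_len(min(3L, length(lines)))]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) return(list())
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1L]]
    if (length(f) < 14L || length(f) > 16L) {
      stop("malformed RepeatMasker row at line ", i + 3L, ": expected ",
           "14-16 columns, got ", length(f))
    }
    st <- suppressWarnings(as.integer(f[6L]))
    en <- suppressWarnings(as.integer(f[7L]))
    sc <- suppressWarnings(as.numeric(f[1L]))
    if (is.na(st) || is.na(en) || is.na(sc)) {
      stop("malformed RepeatMasker row at line ", i + 3L,
           ": non-numeric coordinate or score")
    }
    data.frame(query = f[5L], start = st, end = en, strand = f[9L],
               repeat_name = f[10L], repeat_class = f[11L], score = sc)
  })
  tab <- do.call(rbind, rows)
  out <- lapply(split(tab, tab$query), function(d) {
    repeat_track(d$query[1L], d[setdiff(names(d), "query")])
  })
  out[unique(tab$query)]
}

#' Write repeat tracks in RepeatMasker ".out" layout
#'
#' Emits the 3-line header and one row per hit so that files written here
#' round-trip through [read_repeatmasker()]. Fields the package does not
#' model (divergence, left counts, repeat-relative coordinates) are written
#' as zeros.
#'
#' @param tracks a list of `repeat_track` objects.
#' @param path output path.
#' @export
write_repeatmasker <- function(tracks, path) {
  hdr <- c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    "")
  rows <- unlist(lapply(tracks, function(tr) {
    gid <- attr(tr, "gene_id")
    if (nrow(tr) == 0L) return(character())
    vapply(seq_len(nrow(tr)), function(i) {
      sprintf("%5d  0.0  0.0  0.0  %s %8d %8d (0) %s %-14s %-18s 0 0 (0) %d",
              as.integer(tr$score[i]), gid, tr$start[i], tr$end[i],
              tr$strand[i], tr$repeat_name[i], tr$repeat_class[i], i)
    }, character(1L))
  }), use.names = FALSE)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# ---- Newick ----------------------------------------------------------------

sanitize_newick_label <- function(x) {
  x <- gsub("[[:space:]]+", "_", x)
  bad <- grepl("[][();:,']", x)
  if (any(bad)) {
    stop("leaf label contains Newick metacharacters: ", x[bad][1L])
  }
  x
}

#' Write a phylogenetic tree in Newick format
#'
#' Branch lengths are always written; internal-node support values, when
#' present as `node.label`, are written as internal node labels.
#' Whitespace in leaf labels is replaced by underscores; other Newick
#' metacharacters raise an error.
#'
#' @param tree an [ape::phylo] tree with at least 2 leaves.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) stop("tree must have >= 2 leaves")
  tree$tip.label <- sanitize_newick_label(tree$tip.label)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path path to a Newick file.
#' @return An [ape::phylo] tree; internal node labels (support values, if
#'   any) are retained in `node.label`.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("cannot parse Newick file: ", path)
  tr
}
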