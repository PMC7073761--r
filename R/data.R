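# Accessors for the bundled reference tables (printed study inputs).

potevol_extdata <- function(name) {
  path <- system.file("extdata", name, package = "potevol")
  if (!nzchar(path)) stop("bundled file not found: ", name)
  path
}

#' The 14 human POTE genes with genomic localizations
#'
#' Symbol, Ensembl id, cytogenetic localization, gene size and transcript
#' count for each human POTE paralog.
#'
#' @return A data frame with one row per gene.
#' @export
pote_gene_table <- function() {
  read.delim(potevol_extdata("pote_gene_table.tsv"),
             stringsAsFactors = FALSE)
}

#' Externally provided POTE gene features
#'
#' Per-gene features the pipeline consumes but does not compute: exon
#' counts, reported LIR status, beta-actin retrogene status, and
#' protein-domain counts (cysteine/ankyrin repeats, coiled coils) from
#' domain-prediction tools, plus the reported group assignment.
#'
#' @return A data frame keyed by `gene_id` (Ensembl id).
#' @export
pote_feature_table <- function() {
  read.delim(potevol_extdata("pote_features.tsv"),
             stringsAsFactors = FALSE)
}

#' Marmoset screening probe coordinates
#'
#' The two BAC-screening probes (STS1, STS2) with their printed UCSC-style
#' coordinates and reported lengths; the coordinate arithmetic on these
#' probes pins the package's 1-based inclusive convention.
#'
#' @return A data frame with columns `probe`, `coordinates`,
#'   `reported_length_bp`.
#' @export
pote_probe_table <- function() {
  read.delim(potevol_extdata("probes.tsv"), stringsAsFactors = FALSE)
}

#' Number of distinct chromosomes carrying POTE genes
#'
#' Parses the cytogenetic localizations of [pote_gene_table()] (e.g.
#' `"8p11.1"`, `"15q11.2"`) and counts distinct chromosomes.
#'
#' @return Integer count of distinct chromosomes.
#' @export
pote_chromosome_count <- function() {
  loc <- pote_gene_table()$localization
  chrom <- sub("^([0-9XY]+)[pq].*$", "\\1", loc)
  length(unique(chrom))
}

#' Path to the bundled human/great-ape calibration table
#' @return File path to a calibration TSV (6-Myr human-chimpanzee,
#'   16-Myr human-orangutan).
#' @export
ape_calibration_file <- function() {
  potevol_extdata("calibrations_human_apes.tsv")
}
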