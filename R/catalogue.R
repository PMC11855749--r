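#' Repeat expansion disease locus catalogue
#'
#' The package ships a catalogue of 26 short tandem repeat (STR) loci known to
#' cause repeat expansion diseases (REDs), covering coding, intronic and UTR
#' repeats. Each locus carries its repeat motif, the pathogenicity cutoff in
#' repeat units and in base pairs, a genomic region class, optional known
#' interruption motifs (e.g. CAT units inside the ATXN1 CAG tract), a zygosity
#' requirement (GLS is pathogenic only when biallelic) and a motif-change flag
#' for loci where the pathogenic motif differs from the reference motif (the
#' RFC1 AAGGG expansion).
#'
#' Catalogue coordinates shipped with the package are synthetic placeholders
#' (consistent per-locus chrom/start/end, with interval length equal to a
#' typical normal tract) sufficient for depth aggregation; users with real
#' GRCh38 coordinates supply their own `chrom`/`start`/`end` columns.
#' Coordinates are 0-based half-open internally; VCF output converts to
#' 1-based.
#'
#' Three loci (PHOX2B, NIPA1, PABN1) are catalogued with "NA" cutoffs: they are
#' loaded and reported but excluded from expansion calling. The ATXN7 row's
#' disease description is catalogued as printed in the source table even though
#' it duplicates the ATXN8OS entry.
#'
#' @name red_catalogue
#' @keywords internal
NULL

CATALOGUE_COLUMNS <- c("gene", "disease", "motif", "cutoff_units", "cutoff_bp",
                       "region_class", "chrom", "start", "end",
                       "interruption_motifs", "zygosity", "motif_change")
REQUIRED_COLUMNS <- c("gene", "motif", "cutoff_units", "cutoff_bp", "region_class")

REGION_CLASS_MAP <- c(
  "coding" = "coding", "exon" = "coding", "intron" = "intron",
  "5'utr" = "utr5", "5utr" = "utr5", "utr5" = "utr5",
  "3'utr" = "utr3", "3utr" = "utr3", "utr3" = "utr3"
)

#' Load a RED locus catalogue from TSV
#'
#' Reads a tab-delimited locus catalogue and validates it. The region class
#' column accepts the conventional printed labels ("Coding"/"Exon" -> `coding`,
#' "Intron" -> `intron`, "5'UTR" -> `utr5`, "3'UTR" -> `utr3`) as well as the
#' internal labels. Rows must satisfy `cutoff_bp == cutoff_units * nchar(motif)`
#' unless flagged `motif_change` (whitelisted; the shipped RFC1 AAGGG row keeps
#' its catalogued bp value verbatim). Absent cutoffs are the literal "NA".
#'
#' @param path Path to a tab-delimited catalogue file with a header row naming
#'   at least `gene`, `motif`, `cutoff_units`, `cutoff_bp`, `region_class`.
#'   Optional columns: `disease`, `chrom`, `start`, `end`,
#'   `interruption_motifs` (comma-joined), `zygosity`
#'   (`monoallelic`/`biallelic`), `motif_change` (logical).
#' @return A tibble with one row per locus and columns
#'   `gene`, `disease`, `motif`, `cutoff_units`, `cutoff_bp`, `region_class`,
#'   `chrom`, `start`, `end`, `interruption_motifs` (list of character
#'   vectors), `zygosity`, `motif_change`.
#' @examples
#' cat_path <- system.file("extdata", "red_catalogue.tsv", package = "exrepeat")
#' catalogue <- load_catalogue(cat_path)
#' table(catalogue$region_class)
#' @export
load_catalogue <- function(path) {
  if (!file.exists(path)) {
    stop("catalogue file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  missing <- setdiff(REQUIRED_COLUMNS, names(raw))
  if (length(missing) > 0) {
    stop("catalogue format error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  cat <- tibble::tibble(
    gene = raw$gene,
    disease = if ("disease" %in% names(raw)) raw$disease else NA_character_,
    motif = toupper(raw$motif),
    cutoff_units = suppressWarnings(as.integer(ifelse(raw$cutoff_units == "NA", NA, raw$cutoff_units))),
    cutoff_bp = suppressWarnings(as.integer(ifelse(raw$cutoff_bp == "NA", NA, raw$cutoff_bp))),
    region_class = map_region_class(raw$region_class),
    chrom = if ("chrom" %in% names(raw)) raw$chrom else paste0("chrS", seq_len(nrow(raw))),
    start = if ("start" %in% names(raw)) as.integer(raw$start) else 1000000L * seq_len(nrow(raw)),
    end = if ("end" %in% names(raw)) as.integer(raw$end) else NA_integer_,
    interruption_motifs = parse_interruption_motifs(
      if ("interruption_motifs" %in% names(raw)) raw$interruption_motifs else rep("", nrow(raw))),
    zygosity = if ("zygosity" %in% names(raw)) raw$zygosity else rep("monoallelic", nrow(raw)),
    motif_change = if ("motif_change" %in% names(raw)) {
      toupper(raw$motif_change) %in% c("TRUE", "T", "1")
    } else rep(FALSE, nrow(raw))
  )
  # default interval length: typical normal tract unknown -> 20 units
  cat$end <- ifelse(is.na(cat$end), cat$start + 20L * nchar(cat$motif), cat$end)

  if (nrow(cat) == 0) return(cat)
  validate_catalogue(cat)
  cat
}

map_region_class <- function(x) {
  key <- tolower(trimws(x))
  # tolerate typographic prime characters in UTR labels
  key <- gsub("′", "'", key)
  mapped <- unname(REGION_CLASS_MAP[key])
  if (anyNA(mapped)) {
    bad <- unique(x[is.na(mapped)])
    stop("catalogue validation error: unknown region_class value(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  mapped
}

parse_interruption_motifs <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) character(0)
    else toupper(trimws(strsplit(s, ",", fixed = TRUE)[[1]]))
  })
}

validate_catalogue <- function(cat) {
  dup <- cat$gene[duplicated(cat$gene)]
  if (length(dup) > 0) {
    stop("catalogue validation error: duplicate gene(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  # motifs: 1-12 bp, uppercase nucleotides; IUPAC N tolerated for the
  # degenerate GCN loci that carry no cutoff
  bad_motif <- !grepl("^[ACGTN]{1,12}$", cat$motif)
  if (any(bad_motif)) {
    stop("catalogue validation error: invalid motif for ",
         paste(cat$gene[bad_motif], collapse = ", "), call. = FALSE)
  }
  if (any(cat$start >= cat$end)) {
    bad <- cat$gene[cat$start >= cat$end]
    stop("catalogue validation error: start >= end for ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  both <- !is.na(cat$cutoff_units) & !is.na(cat$cutoff_bp) & !cat$motif_change
  inconsistent <- both & cat$cutoff_bp != cat$cutoff_units * nchar(cat$motif)
  if (any(inconsistent)) {
    i <- which(inconsistent)[1]
    stop(sprintf(
      "catalogue validation error: %s has cutoff_bp %d but cutoff_units %d x %d-bp motif = %d (not motif_change-whitelisted)",
      cat$gene[i], cat$cutoff_bp[i], cat$cutoff_units[i], nchar(cat$motif[i]),
      cat$cutoff_units[i] * nchar(cat$motif[i])), call. = FALSE)
  }
  one_bad_zyg <- !cat$zygosity %in% c("monoallelic", "biallelic")
  if (any(one_bad_zyg)) {
    stop("catalogue validation error: zygosity must be monoallelic/biallelic (",
         paste(cat$gene[one_bad_zyg], collapse = ", "), ")", call. = FALSE)
  }
  invisible(cat)
}

#' Load the catalogue shipped with the package
#'
#' @return A 26-locus catalogue tibble (see [load_catalogue()]).
#' @export
default_catalogue <- function() {
  load_catalogue(system.file("extdata", "red_catalogue.tsv", package = "exrepeat"))
}

locus_row <- function(catalogue, gene) {
  i <- match(gene, catalogue$gene)
  if (is.na(i)) stop("unknown locus: ", gene, call. = FALSE)
  catalogue[i, ]
}

#' Pathogenicity cutoff of a locus in base pairs
#'
#' For ordinary loci this is `cutoff_units * nchar(motif)`. For motif-change
#' loci (pathogenic motif differs from the reference motif, e.g. the RFC1
#' AAGGG expansion catalogued as 0 units / 5 bp) the catalogued `cutoff_bp` is
#' returned verbatim. Loci catalogued without a cutoff signal "no threshold"
#' by raising an error of class `exrepeat_no_threshold`.
#'
#' @param locus A single catalogue row (tibble with one row).
#' @return Integer cutoff in bp.
#' @export
cutoff_bp_of <- function(locus) {
  stopifnot(nrow(locus) == 1)
  if (is.na(locus$cutoff_units)) {
    no_threshold_error(locus$gene)
  }
  if (isTRUE(locus$motif_change)) {
    return(as.integer(locus$cutoff_bp))
  }
  as.integer(locus$cutoff_units * nchar(locus$motif))
}

no_threshold_error <- function(gene) {
  cnd <- structure(
    class = c("exrepeat_no_threshold", "error", "condition"),
    list(message = paste0("locus ", gene,
                          " has no pathogenicity cutoff (catalogued NA); excluded from expansion calling"),
         call = NULL))
  stop(cnd)
}

#' Classify an allele length as normal or expanded
#'
#' An allele is expanded when its repeat-unit count reaches the locus cutoff
#' (`allele_units >= cutoff_units`; cutoffs are treated as the minimal abnormal
#' size). For motif-change loci any allele carrying the pathogenic motif
#' (>= 1 unit) is expanded. Loci with no cutoff raise a no-threshold error.
#'
#' @param locus A single catalogue row.
#' @param allele_units Non-negative integer repeat-unit count (vectorised).
#' @return Character vector, `"normal"` or `"expanded"`.
#' @examples
#' catalogue <- default_catalogue()
#' htt <- catalogue[catalogue$gene == "HTT", ]
#' classify_allele(htt, c(29, 53))
#' @export
classify_allele <- function(locus, allele_units) {
  stopifnot(nrow(locus) == 1, all(allele_units >= 0))
  if (is.na(locus$cutoff_units)) no_threshold_error(locus$gene)
  threshold <- if (isTRUE(locus$motif_change) && locus$cutoff_units == 0) 1L else locus$cutoff_units
  ifelse(allele_units >= threshold, "expanded", "normal")
}

#' Can a read length resolve expanded from normal alleles at a locus?
#'
#' A locus is `spanning_resolvable` at a given read length when a read can
#' span an allele at the pathogenic cutoff with `min_flank` anchoring bases on
#' both sides: `cutoff_bp + 2 * min_flank <= read_length`. Otherwise only a
#' lower bound on the long allele can be produced (`lower_bound_only`), and
#' normal alleles cannot be distinguished from expanded ones by spanning
#' evidence.
#'
#' @param locus A single catalogue row.
#' @param read_length Read length in bp (> 0).
#' @param min_flank Minimum anchoring flank per side in bp (>= 0).
#' @return `"spanning_resolvable"` or `"lower_bound_only"`.
#' @export
detectability <- function(locus, read_length, min_flank = 10L) {
  if (length(read_length) != 1 || is.na(read_length) || read_length <= 0) {
    stop("read_length must be a single positive number", call. = FALSE)
  }
  if (min_flank < 0) stop("min_flank must be >= 0", call. = FALSE)
  cb <- cutoff_bp_of(locus)  # raises no-threshold for NA loci
  if (cb + 2 * min_flank <= read_length) "spanning_resolvable" else "lower_bound_only"
}
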