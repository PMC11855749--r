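#' File formats
#'
#' All tabular artefacts are plain TSV with stable column order; read evidence
#' is JSON-lines (one object per sample x locus); calls can additionally be
#' written as a minimal VCF 4.2 with symbolic `<STR>` ALT records. Every
#' writer/reader pair round-trips exactly.
#'
#' @name exrepeat_io
#' @keywords internal
NULL

#' @rdname exrepeat_io
#' @param manifest,path See individual functions.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(manifest, path, progress = FALSE)
  invisible(path)
}

#' @rdname exrepeat_io
#' @export
read_manifest <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), kit = readr::col_character(),
    read_length = readr::col_integer()), progress = FALSE)
}

#' @rdname exrepeat_io
#' @param truth Truth-table tibble from [simulate_cohort()].
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path, progress = FALSE)
  invisible(path)
}

#' @rdname exrepeat_io
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), gene = readr::col_character(),
    allele1_units = readr::col_integer(), allele2_units = readr::col_integer(),
    interrupted = readr::col_logical(), interruption_unit = readr::col_integer()),
    progress = FALSE)
}

#' Write read evidence as JSON-lines
#'
#' One JSON object per sample x locus, with the reads as an array.
#'
#' @param evidence Cohort read-evidence tibble.
#' @param path Output file.
#' @export
write_evidence_jsonl <- function(evidence, path) {
  key <- paste(evidence$sample_id, evidence$gene, sep = "\r")
  groups <- split(seq_len(nrow(evidence)), factor(key, levels = unique(key)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (ix in groups) {
    rec <- list(
      sample_id = evidence$sample_id[ix[1]],
      gene = evidence$gene[ix[1]],
      read_length = evidence$read_length[ix[1]],
      reads = evidence[ix, c("read_class", "start_offset", "implied_units",
                             "implied_min_units", "in_tract_sequence",
                             "base_quality_ok")])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null",
                                digits = NA), con)
  }
  invisible(path)
}

#' Read JSON-lines read evidence
#'
#' @param path Evidence file written by [write_evidence_jsonl()].
#' @return A cohort read-evidence tibble.
#' @export
read_evidence_jsonl <- function(path) {
  if (!file.exists(path)) stop("evidence not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0) return(empty_evidence())
  recs <- lapply(lines, jsonlite::fromJSON)
  dplyr::bind_rows(lapply(recs, function(r) {
    reads <- tibble::as_tibble(r$reads)
    reads$implied_units <- suppressWarnings(as.integer(reads$implied_units))
    tibble::tibble(sample_id = r$sample_id, gene = r$gene,
                   read_class = reads$read_class,
                   start_offset = as.integer(reads$start_offset),
                   read_length = as.integer(r$read_length),
                   implied_units = reads$implied_units,
                   implied_min_units = as.integer(reads$implied_min_units),
                   in_tract_sequence = reads$in_tract_sequence,
                   base_quality_ok = reads$base_quality_ok)
  }))
}

#' Write calls as VCF-like TSV
#'
#' @param calls Calls tibble (see [call_cohort()]).
#' @param path Output file.
#' @export
write_calls_tsv <- function(calls, path) {
  out <- calls
  out$genotype <- render_genotype(calls)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), gene = readr::col_character(),
    allele_short = readr::col_integer(), allele_long = readr::col_integer(),
    long_is_lower_bound = readr::col_logical(),
    n_spanning_short = readr::col_integer(), n_spanning_long = readr::col_integer(),
    n_flanking = readr::col_integer(), n_in_repeat = readr::col_integer(),
    caller_lc = readr::col_double(), filter = readr::col_character(),
    genotype = readr::col_character()), progress = FALSE)
  out[, setdiff(names(out), "genotype")]
}

#' Write calls as a minimal VCF
#'
#' Emits VCF 4.2 with one `<STR>` record per locus, `INFO` keys `REPID` (gene)
#' and `RU` (repeat unit), and per-sample `FORMAT` fields `GT` (placeholder
#' `./.`), `REPCN` (rendered repeat genotype, e.g. `23/>81`), `LC` (caller
#' locus coverage) and `FT` (per-call filter). Positions are converted from
#' the internal 0-based half-open intervals to 1-based VCF coordinates.
#'
#' @param calls Calls tibble.
#' @param catalogue Locus catalogue (supplies coordinates and motifs).
#' @param path Output file.
#' @param samples Optional sample ordering; default: order of appearance.
#' @export
write_calls_vcf <- function(calls, catalogue, path, samples = NULL) {
  if (is.null(samples)) samples <- unique(calls$sample_id)
  genes <- intersect(catalogue$gene, unique(calls$gene))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=exrepeat",
    "##ALT=<ID=STR,Description=\"Short tandem repeat\">",
    "##INFO=<ID=REPID,Number=1,Type=String,Description=\"Repeat locus identifier\">",
    "##INFO=<ID=RU,Number=1,Type=String,Description=\"Repeat unit\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of repeat interval\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=REPCN,Number=1,Type=String,Description=\"Repeat genotype in units, > marks a lower bound\">",
    "##FORMAT=<ID=LC,Number=1,Type=Float,Description=\"Caller locus coverage\">",
    "##FORMAT=<ID=FT,Number=1,Type=String,Description=\"Call filter\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  gt <- render_genotype(calls)
  lc <- formatC(calls$caller_lc, format = "g", digits = 10)
  cell_key <- paste(calls$sample_id, calls$gene, sep = "\r")
  cells <- paste0("./.:", gt, ":", lc, ":", calls$filter)
  names(cells) <- cell_key
  body <- vapply(genes, function(g) {
    loc <- locus_row(catalogue, g)
    wanted <- paste(samples, g, sep = "\r")
    scells <- ifelse(wanted %in% cell_key, cells[wanted], "./.:./.:0:NoCall")
    paste(c(loc$chrom, loc$start + 1L, g, "N", "<STR>", ".", ".",
            sprintf("REPID=%s;RU=%s;END=%d", g, loc$motif, loc$end),
            "GT:REPCN:LC:FT", scells), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a minimal VCF of repeat calls
#'
#' @param path VCF written by [write_calls_vcf()].
#' @return Calls tibble with `sample_id`, `gene`, allele fields parsed from
#'   `REPCN`, `caller_lc` from `LC`, and `filter` from `FT`.
#' @export
read_calls_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  genes <- unname(vcfR::extract.info(v, "REPID"))
  repcn <- vcfR::extract.gt(v, element = "REPCN")
  lc <- vcfR::extract.gt(v, element = "LC", as.numeric = TRUE)
  ft <- vcfR::extract.gt(v, element = "FT")
  samples <- colnames(repcn)
  out <- tibble::tibble(
    sample_id = rep(samples, each = length(genes)),
    gene = rep(genes, times = length(samples)),
    repcn = as.vector(repcn), caller_lc = as.vector(lc),
    filter = as.vector(ft))
  parsed <- parse_genotype(out$repcn)
  out$allele_short <- parsed$allele_short
  out$allele_long <- parsed$allele_long
  out$long_is_lower_bound <- parsed$long_is_lower_bound
  out[out$filter != "NoCall",
      c("sample_id", "gene", "allele_short", "allele_long",
        "long_is_lower_bound", "caller_lc", "filter")]
}

#' @rdname exrepeat_io
#' @param verdicts Verdicts tibble from [triage_cohort()].
#' @export
write_verdicts <- function(verdicts, path) {
  readr::write_tsv(verdicts, path, progress = FALSE)
  invisible(path)
}

#' @rdname exrepeat_io
#' @export
read_verdicts <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), gene = readr::col_character(),
    category = readr::col_character(), n_hq_support = readr::col_integer(),
    n_max_reads = readr::col_integer(),
    read_len_exceeds_cutoff = readr::col_logical(),
    interruption_found = readr::col_logical(),
    zygosity_flag = readr::col_character()), progress = FALSE)
}

PIPELINE_CONFIG_KEYS <- c("paths", "simulation", "caller", "triage", "report", "seed")

#' Read and validate a pipeline configuration
#'
#' A single YAML document with blocks `paths` (catalogue, manifest, evidence,
#' output dir), `simulation` (arguments of [simulation_config()]), `caller`
#' (`min_flank`, `lowdepth_threshold`), `triage`, `report` and a top-level
#' `seed`. Unknown top-level keys are rejected.
#'
#' @param path YAML file.
#' @return Named list with validated blocks.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), PIPELINE_CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop("config validation error: unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(cfg$simulation)) {
    cfg$simulation <- do.call(simulation_config, cfg$simulation)
  }
  cfg
}
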