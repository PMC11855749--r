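#' Cohort-level expansion-call summary
#'
#' Tabulates triage verdicts per locus (pass/borderline/fail/discard counts)
#' with a totals row and the fail percentage (percent of all predicted
#' expanded calls classified fail, one decimal). Loci are ordered by region
#' class (coding, intron, UTR) then gene; catalogued loci without any
#' predicted expansion appear with zero counts.
#'
#' @param verdicts Verdicts tibble (see [triage_cohort()]); may be empty.
#' @param catalogue Locus catalogue.
#' @return Tibble with columns `gene`, `region_class`, `n_pass`,
#'   `n_borderline`, `n_fail`, `n_discard_interruption`, `n_total`,
#'   `fail_percent`; the last row is the totals row (`gene == "TOTAL"`).
#' @export
expansion_summary <- function(verdicts, catalogue) {
  counts <- tibble::tibble(
    gene = catalogue$gene,
    region_class = factor(catalogue$region_class,
                          levels = c("coding", "intron", "utr5", "utr3")))
  cats <- c("pass", "borderline", "fail", "discard_interruption")
  for (cc in cats) {
    tab <- table(factor(verdicts$gene[verdicts$category == cc],
                        levels = catalogue$gene))
    counts[[paste0("n_", cc)]] <- as.integer(tab[counts$gene])
  }
  counts <- dplyr::arrange(counts, .data$region_class, .data$gene)
  counts$region_class <- as.character(counts$region_class)
  counts$n_total <- counts$n_pass + counts$n_borderline + counts$n_fail +
    counts$n_discard_interruption
  counts$fail_percent <- ifelse(counts$n_total > 0,
                                round(100 * counts$n_fail / counts$n_total, 1), NA_real_)
  total <- tibble::tibble(
    gene = "TOTAL", region_class = NA_character_,
    n_pass = sum(counts$n_pass), n_borderline = sum(counts$n_borderline),
    n_fail = sum(counts$n_fail),
    n_discard_interruption = sum(counts$n_discard_interruption))
  total$n_total <- total$n_pass + total$n_borderline + total$n_fail +
    total$n_discard_interruption
  total$fail_percent <- ifelse(total$n_total > 0,
                               round(100 * total$n_fail / total$n_total, 1), NA_real_)
  dplyr::bind_rows(counts, total)
}

#' Summarise PCR-validation outcomes and diagnostic yield
#'
#' Validation records carry the triage category each call held when the sample
#' was dispatched for repeat-primed PCR; only `pass` and `borderline` calls
#' are eligible for PCR dispatch, so records in other categories are a
#' validation error. Diagnostic yield is the percentage of PCR-confirmed
#' expansions that resolved a diagnosis, rounded to the nearest integer
#' (`NA` when nothing was confirmed).
#'
#' @param records Tibble with columns `sample_id`, `gene`, `category`
#'   (`pass`/`borderline`), `pcr_result` (`confirmed`/`not_confirmed`),
#'   `diagnostic` (`yes`/`no`/`unknown`).
#' @return List `n_tested`, `n_confirmed`, `n_confirmed_by_category` (named
#'   integer vector), `diagnostic_yield_percent`.
#' @export
validation_summary <- function(records) {
  bad <- !records$category %in% c("pass", "borderline")
  if (any(bad)) {
    stop("validation error: only pass/borderline calls are eligible for PCR (",
         paste(unique(records$category[bad]), collapse = ", "), ")",
         call. = FALSE)
  }
  confirmed <- records$pcr_result == "confirmed"
  n_conf_by_cat <- vapply(c(pass = "pass", borderline = "borderline"),
                          function(cc) sum(confirmed & records$category == cc),
                          integer(1))
  n_confirmed <- sum(confirmed)
  n_diag <- sum(confirmed & records$diagnostic == "yes")
  yield <- if (n_confirmed > 0) as.integer(round(100 * n_diag / n_confirmed)) else NA_integer_
  list(n_tested = nrow(records),
       n_confirmed = n_confirmed,
       n_confirmed_by_category = n_conf_by_cat,
       diagnostic_yield_percent = yield)
}

#' Genotyping rate and coverage per locus x kit x read length
#'
#' The genotyping rate of a locus under a kit is the percentage of that kit's
#' samples whose call carries the caller's `PASS` filter. Loci with no call
#' under a kit have rate 0. Mean pileup LC and mean caller LC are averaged
#' over all of the kit's samples (missing pairs count as depth 0).
#'
#' @param calls Cohort calls tibble (see [call_cohort()]).
#' @param manifest Sample manifest (`sample_id`, `kit`, `read_length`).
#' @param catalogue Locus catalogue.
#' @param kits Optional kit profiles (see [default_kits()]) supplying
#'   `target_status`; omitted -> `NA`.
#' @param pileup Optional pileup LC table (see [pileup_lc_table()]).
#' @return Tibble of per locus x kit x read-length rows: `gene`,
#'   `region_class`, `kit`, `read_length`, `n_samples`, `n_pass_filter`,
#'   `genotyping_rate`, `mean_pileup_lc`, `mean_caller_lc`, `target_status`,
#'   ordered by kit, read length, region class, gene.
#' @export
genotyping_rate_table <- function(calls, manifest, catalogue, kits = NULL,
                                  pileup = NULL) {
  orphan <- setdiff(unique(calls$sample_id), manifest$sample_id)
  orphan <- orphan[!is.na(orphan)]
  if (length(orphan) > 0) {
    stop("sample id(s) missing from manifest: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  grid <- tidyr::crossing(manifest, gene = catalogue$gene)
  grid <- dplyr::left_join(grid, calls[, c("sample_id", "gene", "filter", "caller_lc")],
                           by = c("sample_id", "gene"))
  grid$filter[is.na(grid$filter)] <- "NoCall"
  grid$caller_lc[is.na(grid$caller_lc)] <- 0
  if (!is.null(pileup)) {
    grid <- dplyr::left_join(grid, pileup, by = c("sample_id", "gene"))
    grid$pileup_lc[is.na(grid$pileup_lc)] <- 0
  } else {
    grid$pileup_lc <- NA_real_
  }
  out <- dplyr::summarise(
    dplyr::group_by(grid, .data$gene, .data$kit, .data$read_length),
    n_samples = dplyr::n(),
    n_pass_filter = sum(.data$filter == "PASS"),
    genotyping_rate = round(100 * sum(.data$filter == "PASS") / dplyr::n(), 1),
    mean_pileup_lc = mean(.data$pileup_lc),
    mean_caller_lc = mean(.data$caller_lc),
    .groups = "drop")
  out$region_class <- catalogue$region_class[match(out$gene, catalogue$gene)]
  if (!is.null(kits)) {
    out <- dplyr::left_join(out, kits$targets, by = c("kit", "gene"))
  } else {
    out$target_status <- NA_character_
  }
  out$region_class <- factor(out$region_class,
                             levels = c("coding", "intron", "utr5", "utr3"))
  out <- dplyr::arrange(out, .data$kit, .data$read_length,
                        .data$region_class, .data$gene)
  out$region_class <- as.character(out$region_class)
  out[, c("gene", "region_class", "kit", "read_length", "n_samples",
          "n_pass_filter", "genotyping_rate", "mean_pileup_lc",
          "mean_caller_lc", "target_status")]
}

#' Compare caller-reported and pileup locus coverage
#'
#' Averages pileup LC and caller LC per locus x kit over matched sample sets
#' and reports the caller/pileup ratio. Because the caller works on a subset
#' of the pileup reads, the ratio is expected in `[0, 1]`; rows above 1 are
#' flagged. Loci without coverage yield an `NA` ratio.
#'
#' @param pileup_lcs Tibble `sample_id`, `gene`, `pileup_lc`.
#' @param caller_lcs Tibble `sample_id`, `gene`, `caller_lc` (e.g. the calls
#'   table).
#' @param manifest Sample manifest.
#' @param catalogue Locus catalogue.
#' @return Tibble `gene`, `kit`, `mean_pileup_lc`, `mean_caller_lc`, `ratio`,
#'   `flag_ratio_gt_1`.
#' @export
coverage_comparison <- function(pileup_lcs, caller_lcs, manifest, catalogue) {
  key_p <- paste(pileup_lcs$sample_id, pileup_lcs$gene)
  key_c <- paste(caller_lcs$sample_id, caller_lcs$gene)
  if (!setequal(key_p, key_c)) {
    stop("mismatched sample x locus key sets between pileup and caller LC tables",
         call. = FALSE)
  }
  joined <- dplyr::inner_join(pileup_lcs[, c("sample_id", "gene", "pileup_lc")],
                              caller_lcs[, c("sample_id", "gene", "caller_lc")],
                              by = c("sample_id", "gene"))
  joined <- dplyr::left_join(joined, manifest[, c("sample_id", "kit")],
                             by = "sample_id")
  out <- dplyr::summarise(dplyr::group_by(joined, .data$gene, .data$kit),
                          mean_pileup_lc = mean(.data$pileup_lc),
                          mean_caller_lc = mean(.data$caller_lc),
                          .groups = "drop")
  out$ratio <- ifelse(out$mean_pileup_lc > 0,
                      out$mean_caller_lc / out$mean_pileup_lc, NA_real_)
  out$flag_ratio_gt_1 <- !is.na(out$ratio) & out$ratio > 1
  out
}

#' Genotyping rate by read length within genomic region classes
#'
#' Averages the genotyping rate per (region class, read length) stratum and
#' reports, per class, whether the mean rate is non-decreasing in read length
#' (the expected trend: longer reads place more bases over each locus and
#' resolve larger alleles). UTR subclasses are pooled into a single `utr`
#' class.
#'
#' @param summaries Output of [genotyping_rate_table()].
#' @return List `series` (tibble `region_class`, `read_length`, `mean_rate`),
#'   `monotone_by_class` (named logical), `verdict` (TRUE iff every class is
#'   non-decreasing).
#' @export
readlength_trend <- function(summaries) {
  if (length(unique(summaries$read_length)) < 2) {
    stop("readlength_trend requires at least two read-length strata",
         call. = FALSE)
  }
  s <- summaries
  s$region_class <- ifelse(s$region_class %in% c("utr5", "utr3"), "utr",
                           s$region_class)
  series <- dplyr::summarise(
    dplyr::group_by(s, .data$region_class, .data$read_length),
    mean_rate = mean(.data$genotyping_rate), .groups = "drop")
  series <- dplyr::arrange(series, .data$region_class, .data$read_length)
  mono <- vapply(split(series, series$region_class), function(d) {
    all(diff(d$mean_rate[order(d$read_length)]) >= 0)
  }, logical(1))
  list(series = series, monotone_by_class = mono, verdict = all(mono))
}
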