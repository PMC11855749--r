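#' Triage of predicted repeat expansions
#'
#' Automates the visual-inspection classification of predicted expanded calls
#' into `pass`, `borderline` or `fail`, plus an interruption-based
#' `discard_interruption` outcome, as a deterministic, stateless rule engine.
#'
#' Let `L` be TRUE when the exome's read length strictly exceeds the locus's
#' pathogenic cutoff in bp. With `n_hq` the number of high-quality reads
#' supporting the expanded genotype and `n_max` the number of in-repeat reads
#' at the maximum observable expansion (full read length of pure or
#' catalogue-interrupted motif):
#'
#' * `pass`:       `L` and (`n_hq >= 2` or `n_max > 10`)
#' * `borderline`: (`L` and `n_hq == 1`) or (not `L` and `n_hq >= 2`)
#' * `fail`:       anything else
#' * `discard_interruption`: a catalogued interruption motif is present on a
#'   read supporting the expanded allele (takes precedence over all counts)
#'
#' "Longer than" is read strictly: read length equal to the cutoff falls into
#' the short-read branch. "A large number (>10)" is strictly greater than 10.
#'
#' @name triage
#' @keywords internal
NULL

# threshold in units a read must imply to support the expanded genotype;
# motif-change loci (cutoff 0) require at least one pathogenic-motif unit
support_threshold <- function(locus) {
  max(locus$cutoff_units, 1L)
}

supports_expansion <- function(evidence, threshold) {
  implied <- ifelse(evidence$read_class == "spanning",
                    evidence$implied_units, evidence$implied_min_units)
  !is.na(implied) & implied >= threshold
}

# TRUE for reads whose frame-aligned in-tract sequence is a clean tiling of
# the motif, allowing catalogued interruption units
pure_motif_content <- function(seqs, motif, allowed_interruptions) {
  m <- nchar(motif)
  n_units <- nchar(seqs) %/% m
  pure <- seqs == strrep(motif, n_units) & nchar(seqs) %% m == 0
  if (length(allowed_interruptions) > 0 && any(!pure)) {
    units_ok <- vapply(which(!pure), function(i) {
      if (nchar(seqs[i]) %% m != 0) return(FALSE)
      units <- substring(seqs[i], seq(1, nchar(seqs[i]), by = m),
                         seq(m, nchar(seqs[i]), by = m))
      all(units %in% c(motif, allowed_interruptions))
    }, logical(1))
    pure[!pure] <- units_ok
  }
  pure
}

#' Count reads supporting a predicted expanded genotype
#'
#' `n_hq_support` counts quality-passing reads whose implied unit count
#' (spanning reads) or implied minimum (flanking/in-repeat reads) reaches the
#' locus cutoff; `n_max_reads` counts in-repeat reads — reads at the maximum
#' expansion observable at the read length — whose content is the pure motif
#' (catalogued interruption units allowed).
#'
#' @param call A one-row calls tibble with an expanded allele.
#' @param evidence Read evidence for the same sample x locus.
#' @param locus A single catalogue row.
#' @return Named list `n_hq_support`, `n_max_reads`.
#' @export
count_support <- function(call, evidence, locus) {
  stopifnot(nrow(locus) == 1)
  assert_expanded(call, locus)
  thr <- support_threshold(locus)
  sup <- supports_expansion(evidence, thr)
  n_hq <- sum(sup & evidence$base_quality_ok)
  inrep <- evidence$read_class == "in_repeat"
  n_max <- if (any(inrep)) {
    sum(pure_motif_content(evidence$in_tract_sequence[inrep], locus$motif,
                           locus$interruption_motifs[[1]]))
  } else 0L
  list(n_hq_support = as.integer(n_hq), n_max_reads = as.integer(n_max))
}

assert_expanded <- function(call, locus) {
  if (is.na(call$allele_long) ||
      classify_allele(locus, call$allele_long) != "expanded") {
    stop("triage applies only to predicted expansions; call at ", locus$gene,
         " is not expanded", call. = FALSE)
  }
  invisible(TRUE)
}

#' Detect catalogued repeat interruptions in read evidence
#'
#' Scans each read's frame-aligned in-tract sequence unit by unit and reports
#' units matching a catalogued interruption motif (e.g. CAT inside the ATXN1
#' CAG tract). Loci with an empty interruption list never report
#' interruptions, even if off-motif units are present.
#'
#' @param evidence Read evidence for one sample x locus.
#' @param locus A single catalogue row.
#' @return List `found` (logical) and `positions` (0-based unit indices within
#'   the tract, deduplicated; read-local indices are offset by the read's
#'   in-tract start unit).
#' @export
detect_interruptions <- function(evidence, locus) {
  stopifnot(nrow(locus) == 1)
  ints <- locus$interruption_motifs[[1]]
  if (length(ints) == 0 || nrow(evidence) == 0) {
    return(list(found = FALSE, positions = integer(0)))
  }
  m <- nchar(locus$motif)
  pos <- interruption_positions(evidence, m, locus$motif, ints)
  list(found = length(pos) > 0, positions = sort(unique(pos)))
}

# 0-based tract unit indices of interruption units seen on any read
interruption_positions <- function(evidence, m, motif, ints) {
  seqs <- evidence$in_tract_sequence
  n_units <- nchar(seqs) %/% m
  candidate <- which(nchar(seqs) > 0 & seqs != strrep(motif, n_units))
  out <- integer(0)
  for (i in candidate) {
    units <- substring(seqs[i], seq(1, n_units[i] * m, by = m),
                       seq(m, n_units[i] * m, by = m))
    local <- which(units %in% ints) - 1L
    if (length(local)) {
      # in-tract sequences are clipped up to the next unit boundary
      start_unit <- if (evidence$start_offset[i] > 0) {
        as.integer(ceiling(evidence$start_offset[i] / m))
      } else 0L
      out <- c(out, start_unit + local)
    }
  }
  out
}

#' Triage one predicted expanded call
#'
#' Applies the pass/borderline/fail rules (see [triage]) with interruption
#' precedence: if a catalogued interruption motif is found on a read that
#' supports the expanded allele, the call is `discard_interruption` regardless
#' of support counts. Interruptions on non-supporting (normal-allele) reads
#' are reported via [detect_interruptions()] but do not discard.
#'
#' @param call A one-row calls tibble with an expanded allele.
#' @param evidence Read evidence for the same sample x locus.
#' @param locus A single catalogue row (must have a cutoff).
#' @param read_length Read length in bp of the sample's exome.
#' @return A one-row verdict tibble: `sample_id`, `gene`, `category`,
#'   `n_hq_support`, `n_max_reads`, `read_len_exceeds_cutoff`,
#'   `interruption_found`.
#' @export
triage_call <- function(call, evidence, locus, read_length) {
  stopifnot(nrow(locus) == 1)
  assert_expanded(call, locus)
  cb <- cutoff_bp_of(locus)  # no-threshold loci cannot be triaged
  sup <- count_support(call, evidence, locus)
  L <- read_length > cb

  ints <- locus$interruption_motifs[[1]]
  interruption_on_support <- FALSE
  if (length(ints) > 0 && nrow(evidence) > 0) {
    supporting <- supports_expansion(evidence, support_threshold(locus))
    if (any(supporting)) {
      pos <- interruption_positions(evidence[supporting, ],
                                    nchar(locus$motif), locus$motif, ints)
      interruption_on_support <- length(pos) > 0
    }
  }

  category <- triage_category(L, sup$n_hq_support, sup$n_max_reads,
                              interruption_on_support)
  tibble::tibble(
    sample_id = call$sample_id, gene = locus$gene, category = category,
    n_hq_support = sup$n_hq_support, n_max_reads = sup$n_max_reads,
    read_len_exceeds_cutoff = L,
    interruption_found = interruption_on_support)
}

# the pure rule engine; vectorised over parallel inputs
triage_category <- function(L, n_hq, n_max, interruption = FALSE) {
  dplyr::case_when(
    interruption ~ "discard_interruption",
    L & (n_hq >= 2 | n_max > 10) ~ "pass",
    (L & n_hq == 1) | (!L & n_hq >= 2) ~ "borderline",
    TRUE ~ "fail")
}

#' Triage every predicted expanded call in a cohort
#'
#' Selects calls whose long allele reaches the locus cutoff (loci without a
#' cutoff are skipped) and applies [triage_call()] to each, attaching a
#' zygosity flag: at loci that are pathogenic only when biallelic (GLS), a
#' call whose short allele is not expanded is flagged
#' `monoallelic_at_biallelic_locus` for follow-up rather than being
#' reclassified.
#'
#' @param calls Cohort calls tibble (see [call_cohort()]).
#' @param evidence Cohort read-evidence tibble.
#' @param catalogue Locus catalogue.
#' @param manifest Sample manifest supplying each sample's read length.
#' @return Verdicts tibble: one row per predicted expanded call with the
#'   columns of [triage_call()] plus `zygosity_flag`.
#' @export
triage_cohort <- function(calls, evidence, catalogue, manifest) {
  thresholded <- catalogue[!is.na(catalogue$cutoff_units), ]
  thr <- ifelse(thresholded$motif_change & thresholded$cutoff_units == 0,
                1L, thresholded$cutoff_units)
  cal <- dplyr::inner_join(
    calls,
    tibble::tibble(gene = thresholded$gene, .thr = thr),
    by = "gene")
  cal <- cal[!is.na(cal$allele_long) & cal$allele_long >= cal$.thr, ]
  if (nrow(cal) == 0) {
    return(tibble::tibble(sample_id = character(), gene = character(),
                          category = character(), n_hq_support = integer(),
                          n_max_reads = integer(),
                          read_len_exceeds_cutoff = logical(),
                          interruption_found = logical(),
                          zygosity_flag = character()))
  }
  rl <- manifest$read_length[match(cal$sample_id, manifest$sample_id)]
  ev_split <- split(seq_len(nrow(evidence)),
                    paste(evidence$sample_id, evidence$gene, sep = "\r"))
  verdicts <- vector("list", nrow(cal))
  for (i in seq_len(nrow(cal))) {
    locus <- locus_row(catalogue, cal$gene[i])
    ix <- ev_split[[paste(cal$sample_id[i], cal$gene[i], sep = "\r")]]
    ev_i <- if (is.null(ix)) evidence[0, ] else evidence[ix, ]
    verdicts[[i]] <- triage_call(cal[i, ], ev_i, locus, rl[i])
  }
  out <- dplyr::bind_rows(verdicts)
  zyg <- catalogue$zygosity[match(out$gene, catalogue$gene)]
  short_expanded <- !is.na(cal$allele_short) & cal$allele_short >= cal$.thr
  out$zygosity_flag <- ifelse(zyg == "biallelic" & !short_expanded,
                              "monoallelic_at_biallelic_locus", "none")
  out
}
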