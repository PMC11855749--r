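#' Evidence-based repeat genotyping
#'
#' A simplified short-read repeat genotyper in the style of graph-realignment
#' callers: spanning reads yield exact allele sizes, flanking and in-repeat
#' reads yield lower bounds rendered as ">N". The caller reports locus
#' coverage (LC) over the catalogued reference interval and a filter status
#' (`PASS`, `LowDepth`, `NoCall`).
#'
#' @name repeat_caller
#' @keywords internal
NULL

# resolve spanning-read clusters for one sample x locus.
# Stutter surrogate: a unit value is absorbed into an adjacent (+/- 1 unit)
# value only when that neighbour holds at least 4x its read count; a symmetric
# merge would collapse genuine adjacent-allele heterozygotes.
resolve_spanning_alleles <- function(units, counts) {
  ord <- order(units)
  u <- units[ord]; n <- counts[ord]
  k <- length(u)
  if (k > 1) {
    target <- rep(NA_integer_, k)
    for (i in seq_len(k)) {
      cand <- integer(0)
      if (i > 1 && u[i] - u[i - 1] == 1 && n[i - 1] >= 4 * n[i]) cand <- c(cand, i - 1L)
      if (i < k && u[i + 1] - u[i] == 1 && n[i + 1] >= 4 * n[i]) cand <- c(cand, i + 1L)
      if (length(cand)) target[i] <- cand[which.max(n[cand])]
    }
    absorbed <- !is.na(target)
    if (any(absorbed)) {
      for (i in which(absorbed)) n[target[i]] <- n[target[i]] + n[i]
      u <- u[!absorbed]; n <- n[!absorbed]
    }
  }
  # two largest clusters; ties broken towards smaller unit counts
  pick <- order(-n, u)[seq_len(min(2L, length(u)))]
  list(units = u[pick], counts = n[pick])
}

#' Genotype every sample x locus in a cohort
#'
#' Vectorised driver applying the evidence-based genotyper to a whole evidence
#' table. Spanning reads are clustered by implied unit count (with single-unit
#' stutter absorption); the two largest clusters give the exact alleles. If
#' flanking or in-repeat reads imply a minimum allele exceeding the largest
#' spanning allele, the long allele becomes that minimum with a lower-bound
#' flag: in-repeat reads imply `floor(read_length / motif_length)` units,
#' flanking reads imply the minimum allele they witness (their full in-tract
#' units, plus one when the read was truncated mid-unit inside the tract).
#'
#' @param evidence Read-evidence tibble (see [simulate_cohort()]).
#' @param catalogue Locus catalogue.
#' @param manifest Optional sample manifest; when given, every sample x locus
#'   pair is reported, with `NoCall` rows for pairs without reads.
#' @param min_flank Minimum anchoring flank in bp (recorded; classification is
#'   carried on the evidence).
#' @param lowdepth_threshold Calls with caller LC below this are `LowDepth`
#'   (default 10; genotyping-rate metrics count `PASS` only).
#' @param quality_filter When `TRUE` the caller works only on quality-passing
#'   reads (its realistic working set); pileup LC is computed on all reads, so
#'   caller LC <= pileup LC.
#' @return A calls tibble: `sample_id`, `gene`, `allele_short`, `allele_long`,
#'   `long_is_lower_bound`, `n_spanning_short`, `n_spanning_long`,
#'   `n_flanking`, `n_in_repeat`, `caller_lc`, `filter`.
#' @export
call_cohort <- function(evidence, catalogue, manifest = NULL,
                        min_flank = 10L, lowdepth_threshold = 10,
                        quality_filter = FALSE) {
  ev <- evidence
  if (quality_filter) ev <- ev[ev$base_quality_ok, ]
  catx <- tibble::tibble(gene = catalogue$gene,
                         motif_len = nchar(catalogue$motif),
                         interval_len = catalogue$end - catalogue$start)
  ev <- dplyr::inner_join(ev, catx, by = "gene")

  if (nrow(ev) > 0) {
    ev$ref_overlap <- pmax(0, pmin(ev$start_offset + ev$read_length, ev$interval_len) -
                              pmax(ev$start_offset, 0))
    grp <- dplyr::group_by(ev, .data$sample_id, .data$gene)
    agg <- dplyr::summarise(
      grp,
      caller_lc = sum(.data$ref_overlap) / .data$interval_len[1],
      n_flanking = sum(.data$read_class == "flanking"),
      n_in_repeat = sum(.data$read_class == "in_repeat"),
      lb_inrep = if (any(.data$read_class == "in_repeat")) {
        max((.data$read_length %/% .data$motif_len)[.data$read_class == "in_repeat"])
      } else NA_integer_,
      lb_flank = if (any(.data$read_class == "flanking")) {
        max(.data$implied_min_units[.data$read_class == "flanking"])
      } else NA_integer_,
      .groups = "drop")

    sp <- ev[ev$read_class == "spanning", c("sample_id", "gene", "implied_units")]
    if (nrow(sp) > 0) {
      spc <- dplyr::count(sp, .data$sample_id, .data$gene, .data$implied_units)
      key <- paste(spc$sample_id, spc$gene, sep = "\r")
      groups <- split(seq_len(nrow(spc)), key)
      res <- lapply(groups, function(ix) {
        r <- resolve_spanning_alleles(spc$implied_units[ix], spc$n[ix])
        u <- sort(r$units)
        cn <- r$counts[order(r$units)]
        c(short = u[1], long = u[length(u)],
          n_short = cn[1], n_long = if (length(u) > 1) cn[2] else 0L)
      })
      span_tbl <- tibble::tibble(
        sample_id = sub("\r.*", "", names(groups)),
        gene = sub(".*\r", "", names(groups)),
        span_short = vapply(res, `[[`, 0, "short"),
        span_long = vapply(res, `[[`, 0, "long"),
        n_spanning_short = as.integer(vapply(res, `[[`, 0, "n_short")),
        n_spanning_long = as.integer(vapply(res, `[[`, 0, "n_long")))
      agg <- dplyr::left_join(agg, span_tbl, by = c("sample_id", "gene"))
    } else {
      agg$span_short <- NA_real_; agg$span_long <- NA_real_
      agg$n_spanning_short <- 0L; agg$n_spanning_long <- 0L
    }
    agg$n_spanning_short[is.na(agg$n_spanning_short)] <- 0L
    agg$n_spanning_long[is.na(agg$n_spanning_long)] <- 0L

    lb <- pmax(agg$lb_inrep, agg$lb_flank, na.rm = TRUE)
    lb[is.na(agg$lb_inrep) & is.na(agg$lb_flank)] <- NA_integer_
    has_span <- !is.na(agg$span_short)
    hom <- has_span & agg$span_short == agg$span_long

    allele_short <- ifelse(has_span, agg$span_short, NA_integer_)
    allele_long <- ifelse(has_span, agg$span_long, lb)
    bound <- !has_span & !is.na(lb)
    override <- has_span & !is.na(lb) & lb > agg$span_long
    allele_long[override] <- lb[override]
    bound[override] <- TRUE
    # a lower bound replacing the long allele has no spanning support
    n_long <- agg$n_spanning_long
    n_long[override & hom] <- 0L
    n_long[override & !hom] <- 0L
    n_long[hom & !override] <- agg$n_spanning_short[hom & !override]

    calls <- tibble::tibble(
      sample_id = agg$sample_id, gene = agg$gene,
      allele_short = as.integer(allele_short),
      allele_long = as.integer(allele_long),
      long_is_lower_bound = bound,
      n_spanning_short = agg$n_spanning_short,
      n_spanning_long = n_long,
      n_flanking = as.integer(agg$n_flanking),
      n_in_repeat = as.integer(agg$n_in_repeat),
      caller_lc = agg$caller_lc,
      filter = ifelse(agg$caller_lc < lowdepth_threshold, "LowDepth", "PASS"))
  } else {
    calls <- tibble::tibble(sample_id = character(), gene = character(),
                            allele_short = integer(), allele_long = integer(),
                            long_is_lower_bound = logical(),
                            n_spanning_short = integer(), n_spanning_long = integer(),
                            n_flanking = integer(), n_in_repeat = integer(),
                            caller_lc = double(), filter = character())
  }

  if (!is.null(manifest)) {
    grid <- tidyr::crossing(sample_id = manifest$sample_id, gene = catalogue$gene)
    calls <- dplyr::left_join(grid, calls, by = c("sample_id", "gene"))
    miss <- is.na(calls$filter)
    calls$filter[miss] <- "NoCall"
    calls$long_is_lower_bound[miss] <- FALSE
    calls$n_spanning_short[miss] <- 0L
    calls$n_spanning_long[miss] <- 0L
    calls$n_flanking[miss] <- 0L
    calls$n_in_repeat[miss] <- 0L
    calls$caller_lc[miss] <- 0
  }
  calls
}

#' Genotype a single sample x locus from its read evidence
#'
#' @param evidence Read-evidence tibble for one sample at one locus.
#' @param locus A single catalogue row.
#' @param min_flank Minimum anchoring flank in bp.
#' @param lowdepth_threshold LC threshold below which the call is `LowDepth`.
#' @return A one-row calls tibble (see [call_cohort()]); zero reads give a
#'   `NoCall` row with absent alleles.
#' @export
genotype_locus <- function(evidence, locus, min_flank = 10L,
                           lowdepth_threshold = 10) {
  stopifnot(nrow(locus) == 1)
  if (nrow(evidence) > 0 && !all(evidence$gene == locus$gene)) {
    stop("evidence does not belong to locus ", locus$gene, call. = FALSE)
  }
  sid <- if (nrow(evidence) > 0) evidence$sample_id[1] else NA_character_
  manifest <- tibble::tibble(sample_id = sid, kit = NA_character_,
                             read_length = NA_integer_)
  call_cohort(evidence, locus, manifest = manifest, min_flank = min_flank,
              lowdepth_threshold = lowdepth_threshold)
}

#' Pileup locus coverage (LC)
#'
#' Mean per-base read depth over the catalogued locus interval implied by the
#' read placements (the depth-aggregation analogue of running `samtools depth`
#' over the locus): each read contributes the number of its bases falling
#' inside the interval, and the total is divided by the interval length.
#'
#' @param evidence Read-evidence tibble for one sample at one locus.
#' @param locus A single catalogue row.
#' @return Mean depth in reads; 0 for empty evidence.
#' @export
pileup_lc <- function(evidence, locus) {
  stopifnot(nrow(locus) == 1)
  if (nrow(evidence) == 0) return(0)
  len <- locus$end - locus$start
  ov <- pmax(0, pmin(evidence$start_offset + evidence$read_length, len) -
                pmax(evidence$start_offset, 0))
  sum(ov) / len
}

#' Pileup LC for every sample x locus pair
#'
#' @param evidence Cohort read-evidence tibble.
#' @param catalogue Locus catalogue.
#' @param manifest Optional manifest; when given, pairs without reads are
#'   reported with LC 0.
#' @return Tibble `sample_id`, `gene`, `pileup_lc`.
#' @export
pileup_lc_table <- function(evidence, catalogue, manifest = NULL) {
  catx <- tibble::tibble(gene = catalogue$gene,
                         interval_len = catalogue$end - catalogue$start)
  ev <- dplyr::inner_join(evidence, catx, by = "gene")
  if (nrow(ev) > 0) {
    ev$ref_overlap <- pmax(0, pmin(ev$start_offset + ev$read_length, ev$interval_len) -
                              pmax(ev$start_offset, 0))
    out <- dplyr::summarise(dplyr::group_by(ev, .data$sample_id, .data$gene),
                            pileup_lc = sum(.data$ref_overlap) / .data$interval_len[1],
                            .groups = "drop")
  } else {
    out <- tibble::tibble(sample_id = character(), gene = character(),
                          pileup_lc = double())
  }
  if (!is.null(manifest)) {
    grid <- tidyr::crossing(sample_id = manifest$sample_id, gene = catalogue$gene)
    out <- dplyr::left_join(grid, out, by = c("sample_id", "gene"))
    out$pileup_lc[is.na(out$pileup_lc)] <- 0
  }
  out
}

#' Render a repeat genotype as a string
#'
#' Follows the conventional short/long rendering: `"29/53"` for two exact
#' alleles, `"23/>81"` when the long allele is a lower bound, `"a/a"` for
#' homozygotes, `"./."` for `NoCall`, and `"."` for an unresolved short allele
#' (lower-bound-only evidence).
#'
#' @param call A calls tibble (one or more rows).
#' @return Character vector of genotype strings.
#' @export
render_genotype <- function(call) {
  short <- ifelse(is.na(call$allele_short), ".", as.character(call$allele_short))
  long <- ifelse(is.na(call$allele_long), ".",
                 paste0(ifelse(call$long_is_lower_bound, ">", ""), call$allele_long))
  ifelse(call$filter == "NoCall", "./.", paste0(short, "/", long))
}

#' Parse a rendered repeat genotype
#'
#' Inverse of [render_genotype()]: `"23/>81"` becomes short 23, long 81 with
#' the lower-bound flag set; `"./."` is a no-call.
#'
#' @param gt Character vector of genotype strings.
#' @return Tibble `allele_short`, `allele_long`, `long_is_lower_bound`,
#'   `nocall`.
#' @export
parse_genotype <- function(gt) {
  ok <- grepl("^(\\.|\\d+)/(\\.|>?\\d+)$", gt)
  if (!all(ok)) {
    stop("malformed genotype string(s): ", paste(gt[!ok], collapse = ", "),
         call. = FALSE)
  }
  parts <- stringr::str_split_fixed(gt, stringr::fixed("/"), 2)
  short <- suppressWarnings(as.integer(parts[, 1]))
  bound <- startsWith(parts[, 2], ">")
  long <- suppressWarnings(as.integer(sub("^>", "", parts[, 2])))
  tibble::tibble(allele_short = short, allele_long = long,
                 long_is_lower_bound = bound,
                 nocall = gt == "./.")
}
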