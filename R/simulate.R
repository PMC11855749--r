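#' Default exome capture-kit profiles
#'
#' Returns a preset of four capture kits mirroring the kits most commonly used
#' in diagnostic exome sequencing (SureSelect V6, SureSelect V4, TruSeq Exome,
#' Nextera DNA Focused), each with a read length, mean on/off-target depth and
#' a per-locus target map. The target maps are illustrative, not vendor BED
#' files: coding RED loci are broadly targeted with known problem loci
#' (ATXN2, HTT, CACNA1A) untargeted on some kits; most intronic repeats are
#' untargeted except NOP56 and CSTB; the Nextera profile carries zero
#' off-target depth and misses the FXN intron entirely.
#'
#' @param catalogue A locus catalogue tibble; target maps are built over its
#'   genes.
#' @return A list with elements `kits` (tibble: `kit`, `read_length`,
#'   `mean_on_target_depth`, `mean_off_target_depth`) and `targets`
#'   (tibble: `kit`, `gene`, `target_status` in `target`/`not_target`).
#' @export
default_kits <- function(catalogue = default_catalogue()) {
  kits <- tibble::tibble(
    kit = c("SureSelectV6", "SureSelectV4", "TruSeq", "Nextera"),
    read_length = c(150L, 125L, 100L, 75L),
    mean_on_target_depth = 60,
    mean_off_target_depth = c(3, 3, 3, 0)
  )
  not_target <- list(
    SureSelectV6 = c("ATXN2", "CACNA1A", "ATXN10", "C9orf72", "CNBP", "RFC1"),
    SureSelectV4 = c("ATXN2", "HTT", "CACNA1A", "ATXN10", "C9orf72", "CNBP", "RFC1"),
    TruSeq       = c("HTT", "CACNA1A", "ATXN10", "C9orf72", "CNBP", "RFC1"),
    Nextera      = c("ATXN2", "HTT", "CACNA1A", "ATXN10", "C9orf72", "CNBP", "RFC1", "FXN")
  )
  targets <- tidyr::crossing(kit = kits$kit, gene = catalogue$gene)
  targets$target_status <- ifelse(
    mapply(function(k, g) g %in% not_target[[k]], targets$kit, targets$gene,
           USE.NAMES = FALSE),
    "not_target", "target")
  list(kits = kits, targets = targets)
}

#' Simulation configuration for a synthetic exome cohort
#'
#' Bundles and validates the knobs of the synthetic-cohort generator. All
#' randomness in [simulate_cohort()] flows from `seed`.
#'
#' @param n_samples_per_kit Samples simulated per capture kit (default 250).
#' @param normal_sd_units SD (repeat units) of the discretised normal-allele
#'   distribution around each locus's reference tract length.
#' @param expansion_prob Per-allele, per-locus probability that an allele is
#'   drawn from the expanded range. Either a single number or a named vector
#'   with a `.default` entry plus per-gene overrides.
#' @param expanded_max_mult Expanded allele sizes are uniform on
#'   `[cutoff_units, expanded_max_mult * cutoff_units]` (truncation keeps
#'   simulated tract strings small).
#' @param motif_change_expanded_range Unit range (length-2 integer) for
#'   expanded alleles at motif-change loci, whose catalogued cutoff (0 units)
#'   cannot anchor a size distribution.
#' @param interruption_prob Probability that an expanded allele at a locus with
#'   catalogued interruption motifs carries one interior interruption unit.
#' @param read_error_rate Per-read probability of failing the base-quality
#'   check (reads are flagged, not mutated).
#' @param min_flank Minimum anchoring flank (bp) per side for a read to count
#'   as spanning.
#' @param seed Integer seed fixing the full output.
#' @return A validated list of class `exrepeat_sim_config`.
#' @export
simulation_config <- function(n_samples_per_kit = 250L,
                              normal_sd_units = 3,
                              expansion_prob = c(.default = 0.005, ATXN1 = 0.02,
                                                 DMPK = 0.02, HTT = 0.02, GLS = 0.02),
                              expanded_max_mult = 10,
                              motif_change_expanded_range = c(100L, 400L),
                              interruption_prob = 0.25,
                              read_error_rate = 0.02,
                              min_flank = 10L,
                              seed = 1L) {
  cfg <- list(n_samples_per_kit = as.integer(n_samples_per_kit),
              normal_sd_units = normal_sd_units,
              expansion_prob = expansion_prob,
              expanded_max_mult = expanded_max_mult,
              motif_change_expanded_range = as.integer(motif_change_expanded_range),
              interruption_prob = interruption_prob,
              read_error_rate = read_error_rate,
              min_flank = as.integer(min_flank),
              seed = as.integer(seed))
  if (cfg$n_samples_per_kit < 0) stop("config validation error: n_samples_per_kit must be >= 0", call. = FALSE)
  probs <- c(unname(cfg$expansion_prob), cfg$interruption_prob, cfg$read_error_rate)
  if (any(probs < 0 | probs > 1)) stop("config validation error: probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$normal_sd_units < 0) stop("config validation error: normal_sd_units must be >= 0", call. = FALSE)
  if (cfg$expanded_max_mult < 1) stop("config validation error: expanded_max_mult must be >= 1", call. = FALSE)
  if (cfg$min_flank < 0) stop("config validation error: min_flank must be >= 0", call. = FALSE)
  structure(cfg, class = "exrepeat_sim_config")
}

expansion_prob_for <- function(cfg, genes) {
  p <- cfg$expansion_prob
  if (length(p) == 1 && is.null(names(p))) return(rep(unname(p), length(genes)))
  default <- if (".default" %in% names(p)) p[[".default"]] else 0
  out <- rep(default, length(genes))
  hit <- match(genes, names(p))
  out[!is.na(hit)] <- unname(p[hit[!is.na(hit)]])
  out
}

#' Replace one repeat unit of a tract with an interruption motif
#'
#' @param tract_sequence Repeat tract string (a whole number of motif units).
#' @param motif The canonical repeat unit.
#' @param interruption Replacement unit; must have the same length as `motif`.
#' @param position 0-based unit index to replace.
#' @return The tract with the unit at `position` replaced; length unchanged.
#' @examples
#' insert_interruption(strrep("CAG", 10), "CAG", "CAT", 4)
#' @export
insert_interruption <- function(tract_sequence, motif, interruption, position) {
  m <- nchar(motif)
  if (nchar(interruption) != m) {
    stop("interruption length must equal motif length", call. = FALSE)
  }
  n_units <- nchar(tract_sequence) %/% m
  if (position < 0 || position >= n_units) {
    stop("interruption position ", position, " out of range for a ",
         n_units, "-unit tract", call. = FALSE)
  }
  substr(tract_sequence, position * m + 1, (position + 1) * m) <- interruption
  tract_sequence
}

# vectorised over parallel vectors; positions 0-based, NA position = no change
insert_interruption_vec <- function(tracts, motif_len, interruptions, positions) {
  idx <- which(!is.na(positions))
  for (i in idx) {
    substr(tracts[i], positions[i] * motif_len[i] + 1,
           (positions[i] + 1) * motif_len[i]) <- interruptions[i]
  }
  tracts
}

#' Simulate a synthetic exome cohort with repeat read evidence
#'
#' Generates a seeded cohort: a sample manifest (kit, read length), a truth
#' table of diploid repeat genotypes, and per-sample, per-locus read evidence.
#' For each sample x locus the read count is Poisson with mean given by the
#' kit's on/off-target depth at that locus. Each read is placed uniformly over
#' the window `[-read_length, tract_bp)` relative to the (randomly chosen)
#' haplotype's tract and classified as spanning (covers the whole tract with
#' `min_flank` anchoring bases on both sides), in-repeat (entirely inside the
#' tract) or flanking. In-tract sequence is reported frame-aligned to motif
#' boundaries, as a graph-realigning caller would report it. Expanded alleles
#' at loci with catalogued interruption motifs carry, with probability
#' `interruption_prob`, one interior interruption unit which propagates into
#' every read covering it.
#'
#' @param config An [simulation_config()] object.
#' @param catalogue A locus catalogue (see [load_catalogue()]).
#' @param kits Kit profiles as returned by [default_kits()].
#' @return A list with tibbles `manifest` (`sample_id`, `kit`, `read_length`),
#'   `truth` (`sample_id`, `gene`, `allele1_units`, `allele2_units`,
#'   `interrupted`, `interruption_unit`), and `evidence` (one row per read:
#'   `sample_id`, `gene`, `read_class`, `start_offset`, `read_length`,
#'   `implied_units`, `implied_min_units`, `in_tract_sequence`,
#'   `base_quality_ok`).
#' @export
simulate_cohort <- function(config = simulation_config(),
                            catalogue = default_catalogue(),
                            kits = default_kits(catalogue)) {
  stopifnot(inherits(config, "exrepeat_sim_config"))
  if (nrow(catalogue) == 0) stop("catalogue must be non-empty", call. = FALSE)
  if (nrow(kits$kits) == 0) stop("at least one kit profile required", call. = FALSE)
  if (any(kits$kits$mean_on_target_depth < 0 | kits$kits$mean_off_target_depth < 0)) {
    stop("config validation error: kit depths must be >= 0", call. = FALSE)
  }

  set.seed(config$seed)

  n_per_kit <- config$n_samples_per_kit
  n_samples <- n_per_kit * nrow(kits$kits)
  manifest <- tibble::tibble(
    sample_id = sprintf("S%05d", seq_len(n_samples)),
    kit = rep(kits$kits$kit, each = n_per_kit),
    read_length = rep(kits$kits$read_length, each = n_per_kit)
  )
  if (n_samples == 0) {
    return(list(manifest = manifest,
                truth = empty_truth(),
                evidence = empty_evidence()))
  }

  loci <- catalogue[, c("gene", "motif", "cutoff_units", "motif_change",
                        "interruption_motifs", "start", "end")]
  loci$motif_len <- nchar(loci$motif)
  loci$interval_len <- loci$end - loci$start
  loci$has_interruption <- lengths(loci$interruption_motifs) > 0
  loci$interruption_motif <- vapply(loci$interruption_motifs,
                                    function(x) if (length(x)) x[[1]] else NA_character_, "")
  loci$normal_mean_units <- ifelse(loci$motif_change, 0, loci$interval_len / loci$motif_len)
  loci$exp_prob <- expansion_prob_for(config, loci$gene)
  # no-threshold loci never draw expanded alleles
  loci$exp_prob[is.na(loci$cutoff_units)] <- 0

  pairs <- tidyr::crossing(manifest, loci[, c("gene", "motif", "motif_len",
                                              "interval_len", "cutoff_units",
                                              "motif_change", "has_interruption",
                                              "interruption_motif",
                                              "normal_mean_units", "exp_prob")])
  pairs <- dplyr::left_join(pairs, kits$targets, by = c("kit", "gene"))
  kd <- kits$kits[, c("kit", "mean_on_target_depth", "mean_off_target_depth")]
  pairs <- dplyr::left_join(pairs, kd, by = "kit")
  pairs$depth_mean <- ifelse(pairs$target_status == "target",
                             pairs$mean_on_target_depth, pairs$mean_off_target_depth)
  np <- nrow(pairs)

  # --- diploid genotypes -----------------------------------------------------
  sample_alleles <- function() {
    expanded <- stats::rbinom(np, 1, pairs$exp_prob) == 1
    normal <- pmax(1L, round(stats::rnorm(np, pairs$normal_mean_units,
                                          config$normal_sd_units)))
    cap <- ifelse(is.na(pairs$cutoff_units), Inf,
                  pmax(1, pairs$cutoff_units - 1))
    normal <- as.integer(pmin(normal, cap))
    normal[pairs$motif_change] <- 0L  # reference motif absent at motif-change loci
    lo <- ifelse(pairs$motif_change, config$motif_change_expanded_range[1],
                 pairs$cutoff_units)
    hi <- ifelse(pairs$motif_change, config$motif_change_expanded_range[2],
                 pairs$cutoff_units * config$expanded_max_mult)
    lo[is.na(lo)] <- 1; hi[is.na(hi)] <- 1  # never drawn: exp_prob is 0 there
    exp_units <- as.integer(floor(stats::runif(np, lo, hi + 1)))
    ifelse(expanded, exp_units, normal)
  }
  a1 <- sample_alleles()
  a2 <- sample_alleles()
  expanded1 <- !is.na(pairs$cutoff_units) &
    a1 >= pmax(pairs$cutoff_units, ifelse(pairs$motif_change, 1L, pairs$cutoff_units))
  expanded2 <- !is.na(pairs$cutoff_units) &
    a2 >= pmax(pairs$cutoff_units, ifelse(pairs$motif_change, 1L, pairs$cutoff_units))
  expanded1[pairs$motif_change] <- a1[pairs$motif_change] >= 1
  expanded2[pairs$motif_change] <- a2[pairs$motif_change] >= 1

  # interior interruption unit on expanded alleles at interruption-prone loci
  draw_interruption <- function(a_units, is_exp) {
    eligible <- pairs$has_interruption & is_exp & a_units >= 3
    hit <- eligible & stats::runif(np) < config$interruption_prob
    pos <- rep(NA_integer_, np)
    # interior unit, 0-based: 1 .. units-2
    pos[hit] <- 1L + as.integer(floor(stats::runif(sum(hit)) * (a_units[hit] - 2L)))
    pos
  }
  int_pos1 <- draw_interruption(a1, expanded1)
  int_pos2 <- draw_interruption(a2, expanded2)

  truth <- tibble::tibble(
    sample_id = pairs$sample_id, gene = pairs$gene,
    allele1_units = a1, allele2_units = a2,
    interrupted = !is.na(int_pos1) | !is.na(int_pos2),
    interruption_unit = dplyr::coalesce(int_pos1, int_pos2)
  )

  # --- haplotype tract sequences --------------------------------------------
  tract1 <- strrep(pairs$motif, a1)
  tract2 <- strrep(pairs$motif, a2)
  tract1 <- insert_interruption_vec(tract1, pairs$motif_len,
                                    pairs$interruption_motif, int_pos1)
  tract2 <- insert_interruption_vec(tract2, pairs$motif_len,
                                    pairs$interruption_motif, int_pos2)

  # --- reads -----------------------------------------------------------------
  # depth_mean is per-base coverage: each haplotype contributes reads whose
  # count scales with its tract + read footprint (T + L - 1 start positions),
  # so per-base depth over the tract is depth_mean/2 per haplotype. A
  # zero-length tract (motif-change normal allele) contributes no reads.
  t1_bp <- a1 * pairs$motif_len
  t2_bp <- a2 * pairs$motif_len
  Lp <- pairs$read_length
  n1 <- stats::rpois(np, ifelse(t1_bp > 0, pairs$depth_mean / 2 * (t1_bp + Lp - 1) / Lp, 0))
  n2 <- stats::rpois(np, ifelse(t2_bp > 0, pairs$depth_mean / 2 * (t2_bp + Lp - 1) / Lp, 0))
  ri <- c(rep.int(seq_len(np), n1), rep.int(seq_len(np), n2))
  hap <- rep.int(c(1L, 2L), c(sum(n1), sum(n2)))
  nr <- length(ri)
  if (nr == 0) {
    return(list(manifest = manifest, truth = truth, evidence = empty_evidence()))
  }
  ord <- order(ri)  # interleave haplotypes per pair
  ri <- ri[ord]; hap <- hap[ord]
  t_units <- ifelse(hap == 1L, a1[ri], a2[ri])
  m <- pairs$motif_len[ri]
  t_bp <- t_units * m
  L <- pairs$read_length[ri]
  mf <- config$min_flank
  # uniform start over the T + L - 1 placements overlapping the tract
  s <- floor(stats::runif(nr, -L + 1, t_bp))

  spanning <- (s <= -mf) & (s + L >= t_bp + mf)
  in_repeat <- !spanning & (s >= 0) & (s + L <= t_bp)
  read_class <- ifelse(spanning, "spanning", ifelse(in_repeat, "in_repeat", "flanking"))

  a_bp <- pmax(s, 0)                       # in-tract bp window [a_bp, b_bp)
  b_bp <- pmin(s + L, t_bp)
  unit_from <- ceiling(a_bp / m)           # 0-based, frame-aligned
  unit_to <- floor(b_bp / m)
  n_units_obs <- pmax(0L, as.integer(unit_to - unit_from))
  tract <- ifelse(hap == 1L, tract1[ri], tract2[ri])
  seqs <- substring(tract, unit_from * m + 1, unit_to * m)
  seqs[n_units_obs == 0] <- ""

  # The minimum allele a read witnesses: its full in-tract units, plus one
  # when a read edge lying strictly inside the tract cuts a repeat unit
  # mid-motif (the partial unit proves at least one more unit exists). Edges
  # coinciding with a tract boundary prove nothing extra, so reads covering
  # the whole tract with thin (< min_flank) anchoring never over-call.
  left_edge_in <- s > 0
  right_edge_in <- s + L < t_bp
  partial <- (left_edge_in & (s %% m != 0)) |
             (right_edge_in & ((s + L) %% m != 0))
  implied_min <- n_units_obs + ifelse(!spanning & partial, 1L, 0L)

  evidence <- tibble::tibble(
    sample_id = pairs$sample_id[ri],
    gene = pairs$gene[ri],
    read_class = read_class,
    start_offset = as.integer(s),
    read_length = as.integer(L),
    implied_units = ifelse(spanning, t_units, NA_integer_),
    implied_min_units = as.integer(implied_min),
    in_tract_sequence = seqs,
    base_quality_ok = stats::runif(nr) >= config$read_error_rate
  )

  list(manifest = manifest, truth = truth, evidence = evidence)
}

empty_evidence <- function() {
  tibble::tibble(sample_id = character(), gene = character(),
                 read_class = character(), start_offset = integer(),
                 read_length = integer(), implied_units = integer(),
                 implied_min_units = integer(), in_tract_sequence = character(),
                 base_quality_ok = logical())
}

empty_truth <- function() {
  tibble::tibble(sample_id = character(), gene = character(),
                 allele1_units = integer(), allele2_units = integer(),
                 interrupted = logical(), interruption_unit = integer())
}
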