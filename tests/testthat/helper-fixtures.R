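# shared fixtures, built in code

make_locus <- function(gene = "LOC1", motif = "CAG", cutoff_units = 35L,
                       normal_units = 20L, region_class = "coding",
                       interruptions = character(0),
                       zygosity = "monoallelic", motif_change = FALSE,
                       cutoff_bp = NULL) {
  if (is.null(cutoff_bp)) {
    cutoff_bp <- if (is.na(cutoff_units)) NA_integer_ else cutoff_units * nchar(motif)
  }
  tibble::tibble(
    gene = gene, disease = "synthetic test locus", motif = motif,
    cutoff_units = as.integer(cutoff_units), cutoff_bp = as.integer(cutoff_bp),
    region_class = region_class, chrom = "chrT", start = 1000L,
    end = 1000L + as.integer(normal_units) * nchar(motif),
    interruption_motifs = list(interruptions), zygosity = zygosity,
    motif_change = motif_change)
}

make_reads <- function(read_class, n = 1L, start_offset = 0L,
                       read_length = 150L, implied_units = NA_integer_,
                       implied_min_units = 0L, seq = "", qual = TRUE,
                       sample_id = "S1", gene = "LOC1") {
  tibble::tibble(
    sample_id = sample_id, gene = gene,
    read_class = rep(read_class, length.out = n),
    start_offset = as.integer(rep(start_offset, length.out = n)),
    read_length = as.integer(rep(read_length, length.out = n)),
    implied_units = as.integer(rep(implied_units, length.out = n)),
    implied_min_units = as.integer(rep(implied_min_units, length.out = n)),
    in_tract_sequence = rep(seq, length.out = n),
    base_quality_ok = rep(qual, length.out = n))
}

# the reference synthetic cohort (study-scale: 4 kits x 250 samples, 26 loci),
# simulated once per test run and shared by the heavier tests
.exrepeat_fixtures <- new.env(parent = emptyenv())

cohort_fixture <- function() {
  if (is.null(.exrepeat_fixtures$cohort)) {
    catalogue <- exrepeat::default_catalogue()
    kits <- exrepeat::default_kits(catalogue)
    config <- exrepeat::simulation_config(seed = 101L)
    sim <- exrepeat::simulate_cohort(config, catalogue, kits)
    calls <- exrepeat::call_cohort(sim$evidence, catalogue,
                                   manifest = sim$manifest,
                                   quality_filter = TRUE)
    verdicts <- exrepeat::triage_cohort(calls, sim$evidence, catalogue,
                                        sim$manifest)
    .exrepeat_fixtures$cohort <- list(
      catalogue = catalogue, kits = kits, config = config, sim = sim,
      calls = calls, verdicts = verdicts)
  }
  .exrepeat_fixtures$cohort
}

# truth table joined with kit metadata and per-locus thresholds
cohort_truth_annotated <- function(fx) {
  cat_ <- fx$catalogue
  thr <- ifelse(cat_$motif_change & cat_$cutoff_units == 0, 1L, cat_$cutoff_units)
  catx <- tibble::tibble(
    gene = cat_$gene, thr = thr, motif_len = nchar(cat_$motif),
    cutoff_bp = ifelse(cat_$motif_change, cat_$cutoff_bp,
                       cat_$cutoff_units * nchar(cat_$motif)))
  tru <- dplyr::left_join(fx$sim$truth, fx$sim$manifest, by = "sample_id")
  tru <- dplyr::left_join(tru, catx, by = "gene")
  tru <- dplyr::left_join(tru, fx$kits$targets, by = c("kit", "gene"))
  tru$expanded <- !is.na(tru$thr) &
    (tru$allele1_units >= tru$thr | tru$allele2_units >= tru$thr)
  tru$resolvable <- !is.na(tru$cutoff_bp) &
    tru$cutoff_bp + 2 * fx$config$min_flank <= tru$read_length
  tru
}
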