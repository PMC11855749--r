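expanded_call <- function(gene = "HTT", allele_long = 53L, allele_short = 29L,
                          bound = FALSE) {
  tibble::tibble(sample_id = "S1", gene = gene,
                 allele_short = allele_short, allele_long = allele_long,
                 long_is_lower_bound = bound, n_spanning_short = 5L,
                 n_spanning_long = 2L, n_flanking = 0L, n_in_repeat = 0L,
                 caller_lc = 30, filter = "PASS")
}

test_that("support counting separates high-quality expanded evidence from the rest", {
  htt <- make_locus(gene = "HTT", motif = "CAG", cutoff_units = 35L,
                    normal_units = 17L)
  call <- expanded_call()
  ev <- dplyr::bind_rows(
    make_reads("spanning", n = 2, implied_units = 53L, implied_min_units = 53L,
               gene = "HTT"),
    make_reads("spanning", n = 6, implied_units = 29L, implied_min_units = 29L,
               gene = "HTT"))  # normal-allele reads never support the expansion
  sup <- count_support(call, ev, htt)
  expect_equal(sup$n_hq_support, 2L)
  expect_equal(sup$n_max_reads, 0L)

  # low-quality in-repeat reads still count towards the maximum-expansion tally
  ev2 <- make_reads("in_repeat", n = 11, start_offset = 60L,
                    implied_min_units = 50L, seq = strrep("CAG", 50),
                    qual = FALSE, gene = "HTT")
  sup2 <- count_support(expanded_call(bound = TRUE, allele_long = 50L), ev2, htt)
  expect_equal(sup2$n_hq_support, 0L)
  expect_equal(sup2$n_max_reads, 11L)

  ev3 <- make_reads("spanning", n = 3, implied_units = 53L,
                    implied_min_units = 53L, qual = FALSE, gene = "HTT")
  sup3 <- count_support(call, ev3, htt)
  expect_equal(sup3$n_hq_support, 0L)
  expect_equal(sup3$n_max_reads, 0L)

  not_expanded <- expanded_call(allele_long = 30L)
  expect_error(count_support(not_expanded, ev, htt), "not expanded")
})

test_that("interruption detection is frame-aware and scoped to catalogued motifs", {
  atxn1 <- make_locus(gene = "ATXN1", motif = "CAG", cutoff_units = 39L,
                      normal_units = 29L, interruptions = "CAT")
  tract <- insert_interruption(strrep("CAG", 10), "CAG", "CAT", 4)
  ev <- make_reads("spanning", implied_units = 10L, implied_min_units = 10L,
                   start_offset = -20L, seq = tract, gene = "ATXN1")
  hit <- detect_interruptions(ev, atxn1)
  expect_true(hit$found)
  expect_equal(hit$positions, 4L)

  pure <- make_reads("spanning", implied_units = 10L, implied_min_units = 10L,
                     seq = strrep("CAG", 10), gene = "ATXN1")
  expect_false(detect_interruptions(pure, atxn1)$found)

  # read starting mid-tract: positions are reported in tract units
  ev_mid <- make_reads("in_repeat", start_offset = 9L, implied_min_units = 10L,
                       seq = insert_interruption(strrep("CAG", 10), "CAG", "CAT", 1),
                       gene = "ATXN1")
  expect_equal(detect_interruptions(ev_mid, atxn1)$positions, 4L)  # unit 3 + offset

  no_list <- make_locus(gene = "LOC1", interruptions = character(0))
  ev2 <- make_reads("spanning", implied_units = 10L, implied_min_units = 10L,
                    seq = tract, gene = "LOC1")
  expect_false(detect_interruptions(ev2, no_list)$found)
})

test_that("triage applies the read-length and support rules with strict boundaries", {
  htt <- make_locus(gene = "HTT", motif = "CAG", cutoff_units = 35L,
                    normal_units = 17L)  # cutoff 105 bp
  dmpk <- make_locus(gene = "DMPK", motif = "CTG", cutoff_units = 36L,
                     normal_units = 12L, region_class = "utr3")  # 108 bp
  call_htt <- expanded_call()
  hq2 <- make_reads("spanning", n = 2, implied_units = 53L,
                    implied_min_units = 53L, gene = "HTT")
  expect_equal(triage_call(call_htt, hq2, htt, 150)$category, "pass")

  call_dmpk <- expanded_call(gene = "DMPK", allele_long = 60L, allele_short = 12L)
  hq2_dmpk <- make_reads("spanning", n = 2, implied_units = 60L,
                         implied_min_units = 60L, read_length = 100L,
                         gene = "DMPK")
  expect_equal(triage_call(call_dmpk, hq2_dmpk, dmpk, 100)$category, "borderline")

  # >10 maximum-expansion reads rescue a call with no HQ support; 10 do not
  maxed <- function(n) make_reads("in_repeat", n = n, start_offset = 60L,
                                  implied_min_units = 50L,
                                  seq = strrep("CAG", 50), qual = FALSE,
                                  gene = "HTT")
  call_b <- expanded_call(bound = TRUE, allele_long = 50L)
  expect_equal(triage_call(call_b, maxed(11), htt, 150)$category, "pass")
  expect_equal(triage_call(call_b, maxed(10), htt, 150)$category, "fail")

  # read length equal to the cutoff is NOT "longer than"
  hq2_105 <- make_reads("spanning", n = 2, implied_units = 53L,
                        implied_min_units = 53L, read_length = 105L,
                        gene = "HTT")
  expect_equal(triage_call(call_htt, hq2_105, htt, 105)$category, "borderline")
  hq1_106 <- make_reads("spanning", n = 1, implied_units = 53L,
                        implied_min_units = 53L, gene = "HTT")
  expect_equal(triage_call(call_htt, hq1_106, htt, 106)$category, "borderline")
  expect_equal(triage_call(call_htt, hq1_106[0, ], htt, 150)$category, "fail")

  nocut <- make_locus(gene = "PABN1", motif = "GCN", cutoff_units = NA)
  expect_error(triage_call(expanded_call(gene = "PABN1"), hq2, nocut, 150),
               class = "exrepeat_no_threshold")
})

test_that("interruptions on supporting reads discard the call; on normal-allele reads they do not", {
  atxn1 <- make_locus(gene = "ATXN1", motif = "CAG", cutoff_units = 39L,
                      normal_units = 29L, interruptions = "CAT")
  call <- expanded_call(gene = "ATXN1", allele_long = 45L, allele_short = 29L)
  interrupted_tract <- insert_interruption(strrep("CAG", 45), "CAG", "CAT", 20)
  sup <- dplyr::bind_rows(
    make_reads("spanning", n = 5, implied_units = 45L, implied_min_units = 45L,
               start_offset = -10L, seq = interrupted_tract, gene = "ATXN1"),
    make_reads("spanning", n = 5, implied_units = 29L, implied_min_units = 29L,
               seq = strrep("CAG", 29), gene = "ATXN1"))
  v <- triage_call(call, sup, atxn1, 150)
  expect_equal(v$category, "discard_interruption")
  expect_true(v$interruption_found)

  # interruption only on the normal allele: reported, not discarding
  normal_int <- dplyr::bind_rows(
    make_reads("spanning", n = 5, implied_units = 45L, implied_min_units = 45L,
               seq = strrep("CAG", 45), gene = "ATXN1"),
    make_reads("spanning", n = 5, implied_units = 29L, implied_min_units = 29L,
               seq = insert_interruption(strrep("CAG", 29), "CAG", "CAT", 10),
               gene = "ATXN1"))
  v2 <- triage_call(call, normal_int, atxn1, 150)
  expect_equal(v2$category, "pass")
  expect_true(detect_interruptions(normal_int, atxn1)$found)
})

test_that("increasing high-quality support never demotes the category", {
  rank <- c(fail = 1, borderline = 2, pass = 3)
  for (L in c(TRUE, FALSE)) {
    for (n_max in c(0L, 5L, 11L)) {
      cats <- exrepeat:::triage_category(L, 0:5, n_max)
      expect_false(is.unsorted(rank[cats]),
                   label = sprintf("L=%s n_max=%d: %s", L, n_max,
                                   paste(cats, collapse = ",")))
    }
  }
  # interruption precedence over any support level
  expect_equal(exrepeat:::triage_category(TRUE, 5L, 20L, interruption = TRUE),
               "discard_interruption")
})

test_that("cohort triage flags monoallelic expansions at biallelic-requirement loci", {
  gls <- make_locus(gene = "GLS", motif = "GCA", cutoff_units = 30L,
                    normal_units = 14L, region_class = "utr5",
                    zygosity = "biallelic")
  manifest <- tibble::tibble(sample_id = c("S1", "S2"), kit = "K",
                             read_length = 150L)
  calls <- dplyr::bind_rows(
    expanded_call(gene = "GLS", allele_short = 14L, allele_long = 40L),
    expanded_call(gene = "GLS", allele_short = 35L, allele_long = 40L))
  calls$sample_id <- c("S1", "S2")
  ev <- dplyr::bind_rows(
    make_reads("spanning", n = 3, implied_units = 40L, implied_min_units = 40L,
               sample_id = "S1", gene = "GLS"),
    make_reads("spanning", n = 3, implied_units = 40L, implied_min_units = 40L,
               sample_id = "S2", gene = "GLS"))
  v <- triage_cohort(calls, ev, gls, manifest)
  expect_equal(v$zygosity_flag[v$sample_id == "S1"],
               "monoallelic_at_biallelic_locus")
  expect_equal(v$zygosity_flag[v$sample_id == "S2"], "none")
  expect_equal(unique(v$category), "pass")
})
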