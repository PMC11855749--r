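test_that("spanning plus in-repeat evidence yields an exact short allele and a lower-bound long allele", {
  dmpk <- make_locus(gene = "DMPK", motif = "CTG", cutoff_units = 36L,
                     normal_units = 12L, region_class = "utr3")
  ev <- dplyr::bind_rows(
    make_reads("spanning", n = 12, start_offset = -30L, implied_units = 12L,
               implied_min_units = 12L, seq = strrep("CTG", 12), gene = "DMPK"),
    make_reads("in_repeat", n = 8, start_offset = 300L, implied_min_units = 50L,
               seq = strrep("CTG", 50), gene = "DMPK"))
  call <- genotype_locus(ev, dmpk)
  expect_equal(call$allele_short, 12L)
  expect_equal(call$allele_long, 50L)  # floor(150 / 3) from in-repeat reads
  expect_true(call$long_is_lower_bound)
  expect_equal(call$n_spanning_short, 12L)
  expect_equal(call$n_in_repeat, 8L)
  expect_equal(render_genotype(call), "12/>50")
})

test_that("two spanning clusters give an exact heterozygous genotype", {
  loc <- make_locus(gene = "ATXN2", motif = "CAG", cutoff_units = 32L,
                    normal_units = 22L)
  ev <- dplyr::bind_rows(
    make_reads("spanning", n = 10, start_offset = -40L, implied_units = 23L,
               gene = "ATXN2"),
    make_reads("spanning", n = 4, start_offset = -30L, implied_units = 38L,
               gene = "ATXN2"))
  call <- genotype_locus(ev, loc)
  expect_equal(call$allele_short, 23L)
  expect_equal(call$allele_long, 38L)
  expect_false(call$long_is_lower_bound)
  expect_equal(call$n_spanning_short, 10L)
  expect_equal(call$n_spanning_long, 4L)
  expect_equal(render_genotype(call), "23/38")
})

test_that("zero reads produce a NoCall with absent alleles", {
  loc <- make_locus()
  call <- genotype_locus(make_reads("spanning", n = 0), loc)
  expect_equal(call$filter, "NoCall")
  expect_true(is.na(call$allele_short))
  expect_true(is.na(call$allele_long))
  expect_equal(render_genotype(call), "./.")
})

test_that("stutter absorption collapses minor adjacent values but keeps balanced heterozygotes", {
  loc <- make_locus(normal_units = 20L)
  stutter <- dplyr::bind_rows(
    make_reads("spanning", n = 12, start_offset = -40L, implied_units = 20L),
    make_reads("spanning", n = 2, start_offset = -40L, implied_units = 21L))
  call <- genotype_locus(stutter, loc)
  expect_equal(render_genotype(call), "20/20")
  expect_equal(call$n_spanning_short, 14L)  # absorbed reads counted with the major cluster

  het <- dplyr::bind_rows(
    make_reads("spanning", n = 6, start_offset = -40L, implied_units = 20L),
    make_reads("spanning", n = 6, start_offset = -40L, implied_units = 21L))
  expect_equal(render_genotype(genotype_locus(het, loc)), "20/21")
})

test_that("pileup LC equals the brute-force per-base average", {
  loc <- make_locus(normal_units = 10L)  # 30 bp interval
  full <- make_reads("spanning", n = 10, start_offset = -10L)
  expect_equal(pileup_lc(full, loc), 10)
  expect_equal(pileup_lc(make_reads("spanning", n = 0), loc), 0)

  set.seed(99)
  mixed <- make_reads("flanking", n = 25,
                      start_offset = sample(-140:100, 25, replace = TRUE),
                      read_length = sample(c(100L, 150L), 25, replace = TRUE))
  len <- loc$end - loc$start
  brute <- mean(vapply(seq_len(len) - 1L, function(x) {
    sum(mixed$start_offset <= x & mixed$start_offset + mixed$read_length > x)
  }, numeric(1)))
  expect_equal(pileup_lc(mixed, loc), brute)
})

test_that("genotype rendering and parsing round-trip", {
  parsed <- parse_genotype(c("23/>81", "29/53", "./."))
  expect_equal(parsed$allele_short, c(23L, 29L, NA))
  expect_equal(parsed$allele_long, c(81L, 53L, NA))
  expect_equal(parsed$long_is_lower_bound, c(TRUE, FALSE, FALSE))
  expect_equal(parsed$nocall, c(FALSE, FALSE, TRUE))
  expect_error(parse_genotype("12|13"), "malformed")

  calls <- tibble::tibble(
    allele_short = c(8L, 12L, 23L, NA), allele_long = c(60L, 150L, 23L, 44L),
    long_is_lower_bound = c(FALSE, TRUE, FALSE, TRUE),
    filter = c("PASS", "PASS", "LowDepth", "PASS"))
  gt <- render_genotype(calls)
  expect_equal(gt, c("8/60", "12/>150", "23/23", "./>44"))
  back <- parse_genotype(gt)
  expect_equal(back$allele_short, calls$allele_short)
  expect_equal(back$allele_long, calls$allele_long)
  expect_equal(back$long_is_lower_bound, calls$long_is_lower_bound)
})

test_that("calls never contradict the simulated truth", {
  fx <- cohort_fixture()
  tru <- cohort_truth_annotated(fx)
  joined <- dplyr::inner_join(
    fx$calls[fx$calls$filter != "NoCall", ],
    tru[, c("sample_id", "gene", "allele1_units", "allele2_units")],
    by = c("sample_id", "gene"))
  amin <- pmin(joined$allele1_units, joined$allele2_units)
  amax <- pmax(joined$allele1_units, joined$allele2_units)
  # exact alleles are always true alleles (no stutter is simulated)
  has_short <- !is.na(joined$allele_short)
  expect_true(all(joined$allele_short[has_short] == amin[has_short] |
                    joined$allele_short[has_short] == amax[has_short]))
  exact_long <- !joined$long_is_lower_bound & !is.na(joined$allele_long)
  expect_true(all(joined$allele_long[exact_long] == amin[exact_long] |
                    joined$allele_long[exact_long] == amax[exact_long]))
  # lower bounds never overshoot the longest true allele
  lb <- joined$long_is_lower_bound
  expect_true(all(joined$allele_long[lb] <= amax[lb]))
})

test_that("diploid genotypes are recovered exactly when both alleles have spanning support", {
  fx <- cohort_fixture()
  tru <- cohort_truth_annotated(fx)
  mf <- fx$config$min_flank
  both <- tru[tru$target_status == "target" & !tru$interrupted &
                pmax(tru$allele1_units, tru$allele2_units) * tru$motif_len +
                  2 * mf <= tru$read_length, ]
  sp <- dplyr::count(
    fx$sim$evidence[fx$sim$evidence$read_class == "spanning", ],
    .data$sample_id, .data$gene, .data$implied_units)
  both <- dplyr::left_join(both, sp,
    by = c("sample_id", "gene", "allele1_units" = "implied_units"))
  both <- dplyr::rename(both, nsp1 = n)
  both <- dplyr::left_join(both, sp,
    by = c("sample_id", "gene", "allele2_units" = "implied_units"))
  both <- dplyr::rename(both, nsp2 = n)
  both$nsp1[is.na(both$nsp1)] <- 0L
  both$nsp2[is.na(both$nsp2)] <- 0L
  supported <- both[both$nsp1 >= 2 & both$nsp2 >= 2, ]
  supported <- dplyr::inner_join(supported, fx$calls,
                                 by = c("sample_id", "gene"))
  exact <- !supported$long_is_lower_bound &
    supported$allele_short == pmin(supported$allele1_units, supported$allele2_units) &
    supported$allele_long == pmax(supported$allele1_units, supported$allele2_units)
  expect_gt(nrow(supported), 10000)
  expect_gte(mean(exact), 0.99)
})
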