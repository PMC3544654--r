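test_that("variant density respects the half-open boundary convention", {
  iv <- tibble::tibble(seqid = "s", start = 0L, end = 100L,
                       class = "mature", mirna_id = "m", strand = "+")
  v_in <- tibble::tibble(seqid = "s", pos = 99L, type = "snp", id = "a")   # end-1: inside
  v_out <- tibble::tibble(seqid = "s", pos = 100L, type = "snp", id = "b") # end: outside
  expect_equal(variant_density(iv, v_in)$n_variants, 1L)
  expect_equal(variant_density(iv, v_out)$n_variants, 0L)
  expect_equal(variant_density(iv, v_in)$density, 0.01)
})

test_that("variant density counts per class and is additive over partitions", {
  iv <- tibble::tibble(
    seqid = "s", start = c(0L, 100L), end = c(100L, 200L),
    class = "mature", mirna_id = "m", strand = "+"
  )
  vars <- tibble::tibble(seqid = "s", pos = c(10L, 150L), type = "snp",
                         id = c("a", "b"))
  whole <- variant_density(iv, vars)
  expect_equal(whole$density, 2 / 200)
  # same class split into disjoint sub-intervals: hits+bp both add
  split_iv <- tibble::tibble(
    seqid = "s", start = c(0L, 50L, 100L, 150L), end = c(50L, 100L, 150L, 200L),
    class = "mature", mirna_id = "m", strand = "+"
  )
  expect_equal(variant_density(split_iv, vars)$density, whole$density)
  # empty input yields zero, absent class is absent (not zero)
  none <- variant_density(iv, vars[0, ])
  expect_equal(none$density, 0)
  expect_false("flank" %in% variant_density(iv, vars)$class)
})

test_that("fraction of miRNAs with a variant is a simple per-miRNA indicator", {
  iv <- tibble::tibble(
    seqid = rep(c("m1", "m2", "m3"), each = 1),
    start = 0L, end = 100L, class = "mature",
    mirna_id = c("m1", "m2", "m3"), strand = "+"
  )
  vars <- tibble::tibble(seqid = c("m1", "m2"), pos = 5L, type = "snp",
                         id = c("a", "b"))
  expect_equal(fraction_with_variant(iv, vars)$fraction, 2 / 3)
  expect_equal(fraction_with_variant(iv, vars[0, ])$fraction, 0)
  all_hit <- tibble::tibble(seqid = c("m1", "m2", "m3"), pos = 1L,
                            type = "snp", id = letters[1:3])
  expect_equal(fraction_with_variant(iv, all_hit)$fraction, 1)
})

test_that("K80 distance matches the closed formula and flags saturation", {
  expect_equal(k80_distance("ACGTACGT", "ACGTACGT"), 0)
  # construct exact P = 0.1, Q = 0.05 on 20 sites: 2 transitions, 1 transversion
  a <- strrep("A", 20)
  b <- paste0("GG", "C", strrep("A", 17))   # A->G transitions x2, A->C transversion
  d <- k80_distance(a, b)
  expect_equal(d, -0.5 * log(1 - 2 * 0.1 - 0.05) - 0.25 * log(1 - 2 * 0.05),
               tolerance = 1e-12)
  # saturation: P = 0.5, Q = 0 -> non-estimable
  a2 <- strrep("AG", 10)
  b2 <- strrep("GA", 10)
  expect_true(is.na(k80_distance(a2, b2)))
  # gapped/N columns are excluded (complete deletion)
  expect_equal(k80_distance("AC-GN", "ACTGA"), 0)
  expect_error(k80_distance("ACG", "AC"), "equal length")
  expect_error(k80_distance("---", "AAA"), "no comparable")
})

test_that("K80 estimator is unbiased on simulated divergence", {
  withr::local_seed(55)
  b <- 0.3
  ests <- vapply(1:20, function(i) {
    anc <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
    x <- k80_evolve(anc, b / 2, kappa = 2)
    y <- k80_evolve(anc, b / 2, kappa = 2)
    k80_distance(x, y)
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - b), 3 * se)
})

test_that("clock rate reduces to d/2 over divergence time for two taxa", {
  tr <- default_species_tree()
  # two sequences at K80 distance ~0.02
  a <- strrep("A", 1000)
  bchars <- strsplit(a, "")[[1]]
  bchars[1:10] <- "G"          # 10 transitions -> P = 0.01
  bchars[11:20] <- "C"         # 10 transversions -> Q = 0.01
  b <- paste(bchars, collapse = "")
  d <- k80_distance(a, b)
  blocks <- tibble::tibble(
    block_id = "blk", species = c("human", "chimp"), seq = c(a, b)
  )
  cr <- clock_rate(blocks, tr)
  expect_equal(cr$rate, (d / 2) / 6, tolerance = 1e-12)
  # zero-distance alignment: rate 0
  z <- tibble::tibble(block_id = "blk", species = c("human", "chimp"), seq = c(a, a))
  expect_equal(clock_rate(z, tr)$rate, 0)
  # single species: non-estimable
  expect_true(is.na(clock_rate(blocks[1, ], tr)$rate))
})

test_that("clock rate is invariant to block concatenation order", {
  withr::local_seed(9)
  tr <- default_species_tree()
  blocks <- purrr::map_dfr(1:4, function(b) {
    anc <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    tibble::tibble(
      block_id = paste0("b", b),
      species = c("human", "chimp", "mouse"),
      seq = c(k80_evolve(anc, 0.01), k80_evolve(anc, 0.01), k80_evolve(anc, 0.15))
    )
  })
  r1 <- clock_rate(blocks, tr)
  r2 <- clock_rate(blocks[sample(nrow(blocks)), ], tr)
  expect_equal(r1$rate, r2$rate)
  expect_equal(r1$n_sites, 1200)
})

test_that("simulated age-group alignments show the young > old rate contrast", {
  cfg <- sim_config(seed = 21)
  fam <- simulate_families(cfg, n_families = 350, ages_from = "census")
  aln <- simulate_alignments(cfg, fam, max_families = 150)
  tr <- cfg$tree
  rates <- clock_rates_by_group(aln$blocks, tr) %>%
    dplyr::filter(class == "flank", !is.na(rate))
  young <- mean(rates$rate[rates$age_label %in% c("t1", "t2", "t3")])
  old <- mean(rates$rate[rates$age_label %in% c("t6", "t7")])
  expect_gt(young, old)
  # generator contract: the configured young:old ratio is 3
  expect_equal(young / old, 3, tolerance = 0.35)
})
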