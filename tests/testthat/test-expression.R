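test_that("normalization divides by library totals and drops empty libraries", {
  at <- normalize_atlas(toy_atlas())
  expect_equal(unname(at$counts[, "lib1"]), c(0.2, 0.3, 0.5))
  expect_true(all(abs(colSums(at$counts) - 1) < 1e-12))
  # zero-total library dropped with warning
  raw <- toy_atlas()
  raw$counts[, "lib4"] <- 0
  expect_warning(at2 <- normalize_atlas(raw), "zero-total")
  expect_false("lib4" %in% colnames(at2$counts))
  # random atlases: columns always sum to 1
  withr::local_seed(12)
  for (i in 1:5) {
    counts <- matrix(rpois(60, 3), 6, 10,
                     dimnames = list(paste0("m", 1:6), paste0("L", 1:10)))
    counts[, 1] <- counts[, 1] + 1  # ensure at least one positive library
    libs <- tibble::tibble(library = paste0("L", 1:10),
                           tissue = rep(c("a", "b"), 5),
                           state = rep(c("normal", "malignant"), 5))
    suppressWarnings(nat <- normalize_atlas(expression_atlas(counts, libs)))
    expect_true(all(abs(colSums(nat$counts) - 1) < 1e-12))
  }
})

test_that("max abundance reports the library maximum, subsets bounded by global", {
  at <- normalize_atlas(toy_atlas())
  ma <- max_abundance(at)
  expect_equal(ma$max_abundance[ma$mirna == "mirA"], 0.5)
  for (sub in c("normal", "malignant")) {
    ms <- max_abundance(at, sub)
    expect_true(all(ms$max_abundance <= ma$max_abundance + 1e-15))
  }
  # all-zero row has zero abundance
  raw <- toy_atlas(); raw$counts["mirB", ] <- 0
  nat <- normalize_atlas(raw)
  expect_equal(max_abundance(nat)$max_abundance[2], 0)
})

test_that("specificity score spans [0, log2 n] with the documented extremes", {
  for (n in 2:32) {
    expect_equal(specificity_score(rep(1 / n, n)), 0, tolerance = 1e-12)
    expect_equal(specificity_score(c(1, rep(0, n - 1))), log2(n), tolerance = 1e-12)
  }
  # hand-evaluated case: p = (1/2, 1/2, 0, 0), n = 4 -> 1 bit
  expect_equal(specificity_score(c(0.5, 0.5, 0, 0)), 1)
  # all mass in 1 of 16 tissues -> 4 bits
  expect_equal(specificity_score(c(1, rep(0, 15))), 4)
  # renormalization is automatic
  expect_equal(specificity_score(c(5, 5, 0, 0)), 1)
  expect_error(specificity_score(rep(0, 4)), "all-zero")
  expect_error(specificity_score(c(-1, 2)), ">= 0")
})

test_that("tissue pooling averages within tissue then renormalizes", {
  at <- normalize_atlas(toy_atlas())
  pooled <- tissue_pool(at)
  sums <- tapply(pooled$frequency, pooled$mirna, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # brain has two libraries: pooled brain freq is their mean before renorm
  a_brain <- mean(at$counts["mirA", c("lib1", "lib2")])
  a_all <- c(a_brain, at$counts["mirA", "lib3"], at$counts["mirA", "lib4"])
  expect_equal(pooled$frequency[pooled$mirna == "mirA" & pooled$tissue == "brain"],
               a_brain / sum(a_all))
  # duplicating a library's tissue assignment leaves the pooled vector unchanged
  raw <- toy_atlas()
  dup_counts <- cbind(raw$counts, lib5 = raw$counts[, "lib3"])
  dup_libs <- dplyr::bind_rows(raw$libraries,
                               tibble::tibble(library = "lib5", tissue = "liver",
                                              state = "normal"))
  pooled2 <- tissue_pool(normalize_atlas(expression_atlas(dup_counts, dup_libs)))
  expect_equal(pooled2$frequency, pooled$frequency)
})

test_that("hypergeometric enrichment equals exhaustive enumeration", {
  # direct spot check: N=6, K=3, n=2, k=2 -> C(3,2)/C(6,2) = 0.2
  counts <- matrix(0L, 1, 6, dimnames = list("m", paste0("L", 1:6)))
  counts[1, c("L1", "L2")] <- 5L
  libs <- tibble::tibble(library = paste0("L", 1:6),
                         tissue = "t",
                         state = c("malignant", "malignant", "malignant",
                                   "normal", "normal", "normal"))
  res <- malignancy_enrichment(expression_atlas(counts, libs))
  expect_equal(res$p_value, 0.2)
  # expressed everywhere -> P = 1; expressed nowhere -> missing
  counts2 <- rbind(m2 = rep(1L, 6), m3 = rep(0L, 6))
  colnames(counts2) <- paste0("L", 1:6)
  res2 <- malignancy_enrichment(expression_atlas(counts2, libs))
  expect_equal(res2$p_value[1], 1)
  expect_true(is.na(res2$p_value[2]))
  # property: matches enumeration for all N <= 12 over a grid
  for (N in c(5, 8, 12)) {
    for (K in c(2, floor(N / 2))) {
      for (n in c(1, 3, N)) {
        for (k in 0:min(K, n)) {
          expect_equal(
            phyper(k - 1, K, N - K, n, lower.tail = FALSE),
            brute_hyper_upper(N, K, n, k),
            tolerance = 1e-12,
            info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k)
          )
        }
      }
    }
  }
})

test_that("group contrasts report medians and rank-sum p-values", {
  df <- tibble::tibble(
    value = c(1, 2, 3, 4, 1, 2, 3, 4),
    group = rep(c("a", "b"), each = 4)
  )
  gc <- group_contrasts(df, "value", "group")
  expect_equal(gc$medians$median, c(2.5, 2.5))
  expect_gt(gc$tests$p_value, 0.9)   # identical samples: no evidence
  # a clear location shift is detected at n = 80 per group
  withr::local_seed(77)
  df2 <- tibble::tibble(
    value = c(rnorm(80), rnorm(80, mean = 1)),
    group = rep(c("a", "b"), each = 80)
  )
  gc2 <- group_contrasts(df2, "value", "group")
  expect_lt(gc2$tests$p_value, 0.01)
  # medians invariant under within-group permutation
  df3 <- df2 %>% dplyr::group_by(group) %>%
    dplyr::mutate(value = sample(value)) %>% dplyr::ungroup()
  expect_equal(group_contrasts(df3, "value", "group")$medians, gc2$medians)
  expect_error(group_contrasts(df[1, ], "value", "group"), "at least 2")
})

test_that("NMFE stats return group means and unbiased variances", {
  rec <- tibble::tibble(
    mirna = paste0("m", 1:5),
    age_label = c("t0", "t0", "t0", "t1", "t1"),
    mfe = c(-50, -40, -60, -45, -45),
    length = 100
  )
  st <- nmfe_group_stats(rec)
  expect_equal(st$mean_nmfe, c(-0.5, -0.45))
  expect_equal(st$var_nmfe[1], var(c(-0.5, -0.4, -0.6)))
  expect_equal(st$var_nmfe[2], 0)
  # single-member group: variance missing
  st2 <- nmfe_group_stats(rec[c(1, 4:5), ])
  expect_true(is.na(st2$var_nmfe[st2$age_label == "t0"]))
  expect_error(nmfe_group_stats(dplyr::mutate(rec, length = 0)), "> 0")
})

test_that("generator variance ratio is recovered from NMFE group stats", {
  cfg <- sim_config(seed = 13)
  # 90 families per extreme group
  fam <- list(truth = tibble::tibble(
    family = paste0("f", 1:180),
    birth_myr = 1,
    age_index = rep(c(0L, 7L), each = 90),
    age_label = rep(c("t0", "t7"), each = 90)
  ))
  nm <- simulate_nmfe(cfg, fam)
  st <- nmfe_group_stats(nm)
  ratio <- st$var_nmfe[st$age_label == "t0"] / st$var_nmfe[st$age_label == "t7"]
  expect_lt(abs(ratio - 6) / 6, 0.25)
})
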