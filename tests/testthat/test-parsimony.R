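quartet <- function() species_tree(ape::read.tree(text = "((H:1,C:1):1,(M:1,R:1):1);"), "H")

test_that("min_changes handles the canonical small cases", {
  tr <- quartet()
  all_present <- setNames(rep("present", 4), c("H", "C", "M", "R"))
  res <- min_changes(tr, all_present)
  expect_equal(res$change_count, 0)
  expect_true(all(res$ancestral_states$present))
  expect_false(any(res$ancestral_states$absent))

  focal_only <- setNames(c("present", "absent", "absent", "absent"), c("H", "C", "M", "R"))
  expect_equal(min_changes(tr, focal_only)$change_count, 1)

  # H and M present on ((H,C),(M,R)): two independent gains (or presence at
  # the root with two losses) - 2 changes either way
  hm <- setNames(c("present", "absent", "present", "absent"), c("H", "C", "M", "R"))
  res <- min_changes(tr, hm)
  expect_equal(res$change_count, 2)
  expect_equal(res$change_count, brute_min_changes(tr$phylo, hm))

  expect_error(min_changes(tr, hm[-1]), "missing tip")
})

test_that("parsimony equals brute-force enumeration on random small trees", {
  withr::local_seed(101)
  for (i in 1:60) {
    n <- sample(3:6, 1)
    tr <- random_test_tree(n)
    prof <- random_profile(tr)
    expect_equal(
      min_changes(tr, prof)$change_count,
      brute_min_changes(tr$phylo, prof),
      info = paste0("case ", i, ": ", paste(prof, collapse = ","))
    )
  }
})

test_that("unknown tips are free: they never increase the change count", {
  withr::local_seed(7)
  for (i in 1:20) {
    tr <- random_test_tree(5)
    prof <- random_profile(tr, p_unknown = 0)
    base <- min_changes(tr, prof)$change_count
    relaxed <- prof
    relaxed[sample(5, 2)] <- "unknown"
    expect_lte(min_changes(tr, relaxed)$change_count, base)
  }
})

test_that("assign_age dates origins on the default vertebrate tree", {
  tr <- default_species_tree()
  tips <- tr$phylo$tip.label
  mk <- function(present) {
    p <- setNames(rep("absent", length(tips)), tips)
    p[present] <- "present"
    p
  }
  expect_equal(assign_age(tr, mk(tips))$age_label, "t7")         # constant character
  expect_equal(assign_age(tr, mk("human"))$age_label, "t0")
  a <- assign_age(tr, mk(c("human", "chimp", "orangutan", "rhesus")))
  expect_equal(a$age_label, "t3")
  expect_equal(a$change_count, 1)
  expect_false(a$ambiguous)
  # focal tip must be present
  expect_error(assign_age(tr, mk("chimp")), "must be present")
})

test_that("origin ties at the root are flagged and resolved by tie_break", {
  tr <- default_species_tree()
  tips <- tr$phylo$tip.label
  p <- setNames(rep("present", length(tips)), tips)
  p["zebrafish"] <- "absent"   # gain below root vs gain at root + one loss
  oldest <- assign_age(tr, p, tie_break = "oldest")
  youngest <- assign_age(tr, p, tie_break = "youngest")
  expect_true(oldest$ambiguous)
  expect_true(youngest$ambiguous)
  expect_equal(oldest$age_label, "t7")
  expect_equal(youngest$age_label, "t6")
  expect_equal(oldest$change_count, youngest$change_count)
})

test_that("assign_age is monotone in the depth of the shared ancestor", {
  tr <- default_species_tree()
  tips <- tr$phylo$tip.label
  p <- setNames(rep("absent", length(tips)), tips)
  p["human"] <- "present"
  # progressively add species that deepen the MRCA with human
  deepening <- c("chimp", "orangutan", "rhesus", "mouse", "dog", "chicken", "zebrafish")
  last <- assign_age(tr, p)$age_index
  for (sp in deepening) {
    p[sp] <- "present"
    cur <- assign_age(tr, p)$age_index
    expect_gte(cur, last)
    last <- cur
  }
  expect_equal(last, 7L)
})

test_that("Dollo mode dates the origin at the MRCA of present tips", {
  tr <- default_species_tree()
  tips <- tr$phylo$tip.label
  p <- setNames(rep("absent", length(tips)), tips)
  p[c("human", "mouse")] <- "present"
  d <- assign_age(tr, p, method = "dollo")
  expect_equal(d$age_label, "t4")          # human-rodent ancestor
  # one gain plus losses of chimp, orangutan, rhesus and rat
  expect_equal(d$change_count, 1 + 4)
  # all-unknown clades are free under Dollo
  p[c("chimp", "orangutan", "rhesus", "rat")] <- "unknown"
  expect_equal(assign_age(tr, p, method = "dollo")$change_count, 1)
})

test_that("bin_groups validates the partition and conserves counts", {
  ages <- tibble::tibble(family = paste0("f", 1:8), age_index = 0:7)
  merged <- bin_groups(ages, default_merge_map())
  expect_equal(as.integer(table(merged$group)[c("young", "middle", "old")]),
               c(4L, 2L, 2L))
  ident <- bin_groups(ages, as.list(setNames(0:7, paste0("g", 0:7))))
  expect_equal(ident$group, paste0("g", 0:7))
  expect_error(bin_groups(ages, list(a = 0:4, b = 4:7)), "overlap")
  expect_error(bin_groups(ages, list(a = 0:2, b = 5:7)), "partition")
})
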