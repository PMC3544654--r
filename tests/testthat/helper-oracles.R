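# Independent oracles and small fixture builders used across the suite.

# Brute-force parsimony: enumerate every ancestral labeling and take the
# minimum change count. Unknown tips are free (cheapest state chosen per
# labeling). Only usable on small trees.
brute_min_changes <- function(phy, states) {
  ntip <- length(phy$tip.label)
  nn <- phy$Nnode
  st <- states[phy$tip.label]
  best <- Inf
  for (code in 0:(2^nn - 1)) {
    lab <- as.integer(intToBits(code))[1:nn]  # 0 = absent, 1 = present
    cost <- 0
    for (e in seq_len(nrow(phy$edge))) {
      p <- phy$edge[e, 1] - ntip
      ch <- phy$edge[e, 2]
      ps <- lab[p]
      if (ch <= ntip) {
        s <- st[ch]
        if (s == "unknown") next
        cost <- cost + as.integer((s == "present") != (ps == 1))
      } else {
        cost <- cost + as.integer(lab[ch - ntip] != ps)
      }
    }
    best <- min(best, cost)
  }
  best
}

# random rooted binary tree with branch lengths, labelled t1..tn
random_test_tree <- function(n, focal = NULL) {
  phy <- ape::rtree(n)
  phy$tip.label <- paste0("sp", seq_len(n))
  species_tree(phy, focal %||% "sp1")
}

random_profile <- function(tree, p_unknown = 0.15) {
  tips <- tree$phylo$tip.label
  st <- sample(c("present", "absent"), length(tips), replace = TRUE)
  unk <- runif(length(tips)) < p_unknown
  st[unk] <- "unknown"
  setNames(st, tips)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive hypergeometric upper tail: enumerate all choose(N, n) draws of
# libraries and count those with >= k malignant among them.
brute_hyper_upper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mal <- seq_len(K)  # first K libraries malignant
  hits <- apply(draws, 2, function(d) sum(d %in% mal) >= k)
  mean(hits)
}

# Trapezoid integration oracle for the expected cumulative count
trapezoid_cumulative <- function(t, params, n_grid = 20001) {
  s <- seq(0, t, length.out = n_grid)
  y <- bd_survival(s, params)
  params$v * sum((y[-1] + y[-n_grid]) / 2) * (s[2] - s[1])
}

# small toy atlas used by several expression tests
toy_atlas <- function() {
  counts <- matrix(
    c(2, 0, 5, 1,
      3, 1, 0, 0,
      5, 9, 5, 3),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("mirA", "mirB", "mirC"),
                    c("lib1", "lib2", "lib3", "lib4"))
  )
  libs <- tibble::tibble(
    library = paste0("lib", 1:4),
    tissue = c("brain", "brain", "liver", "heart"),
    state = c("normal", "malignant", "normal", "malignant")
  )
  expression_atlas(counts, libs)
}
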