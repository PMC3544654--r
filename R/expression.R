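#' Expression analysis: normalization, specificity, abundance, enrichment
#'
#' Clone counts are normalised to per-library frequencies; expression level is
#' the maximum frequency over libraries; tissue specificity is the
#' information-content score `log2(n) + sum(p_i * log2(p_i))` over the `n`
#' major tissues (0 bits for uniform expression, `log2(n)` for single-tissue
#' expression); malignancy association is the hypergeometric upper tail of the
#' number of malignant libraries among those expressing the miRNA.
#'
#' @name expression_profiles
NULL

#' Per-library frequency normalization
#'
#' Each library's clone counts are divided by the library total, so columns
#' sum to 1. Libraries with zero total are dropped with a warning.
#'
#' @param atlas an [expression_atlas()].
#' @return an `expression_atlas` whose `counts` hold frequencies; gains a
#'   logical attribute marking it normalised.
#' @export
normalize_atlas <- function(atlas) {
  tot <- colSums(atlas$counts)
  if (any(tot == 0)) {
    drop <- colnames(atlas$counts)[tot == 0]
    warn(paste0("dropping zero-total library(ies): ", paste(drop, collapse = ", ")))
    atlas$counts <- atlas$counts[, tot > 0, drop = FALSE]
    atlas$libraries <- filter(atlas$libraries, .data$library %in% colnames(atlas$counts))
    tot <- tot[tot > 0]
  }
  atlas$counts <- sweep(atlas$counts, 2, tot, "/")
  attr(atlas, "normalized") <- TRUE
  atlas
}

assert_normalized <- function(atlas) {
  if (!isTRUE(attr(atlas, "normalized"))) abort("atlas must be normalized first")
  atlas
}

#' Maximal expression level per miRNA
#'
#' The maximum normalised frequency over all libraries, or over the normal /
#' malignant subset.
#'
#' @param atlas a normalised [expression_atlas()].
#' @param subset `"all"`, `"normal"` or `"malignant"`.
#' @return a tibble: `mirna`, `max_abundance`.
#' @export
max_abundance <- function(atlas, subset = c("all", "normal", "malignant")) {
  subset <- match.arg(subset)
  assert_normalized(atlas)
  keep <- if (subset == "all") atlas$libraries$library else
    atlas$libraries$library[atlas$libraries$state == subset]
  if (!length(keep)) abort(paste0("no ", subset, " libraries in atlas"))
  m <- atlas$counts[, keep, drop = FALSE]
  tibble(mirna = rownames(m), max_abundance = unname(apply(m, 1, max)))
}

#' Information-content tissue-specificity score
#'
#' `S = log2(n) + sum(p_i * log2(p_i))` with `0 * log2(0) = 0`; the vector is
#' renormalised to sum to 1. `S` ranges from 0 (uniform over tissues) to
#' `log2(n)` (all mass in one tissue).
#'
#' @param p non-negative tissue frequency vector.
#' @return the score in bits.
#' @export
specificity_score <- function(p) {
  if (any(p < 0)) abort("tissue frequencies must be >= 0")
  s <- sum(p)
  if (s == 0) abort("all-zero tissue vector has no specificity score")
  p <- p / s
  n <- length(p)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  log2(n) + sum(plogp)
}

#' Pool library frequencies into per-tissue vectors
#'
#' Per tissue, library frequencies are averaged over that tissue's libraries;
#' the per-miRNA vector over tissues is then renormalised to sum to 1.
#'
#' @param atlas a normalised [expression_atlas()].
#' @param subset `"all"`, `"normal"` or `"malignant"` libraries.
#' @return a tibble: `mirna`, `tissue`, `frequency` (per-miRNA rows sum to 1;
#'   miRNAs with no expression in the subset are dropped).
#' @export
tissue_pool <- function(atlas, subset = c("all", "normal", "malignant")) {
  subset <- match.arg(subset)
  assert_normalized(atlas)
  libs <- atlas$libraries
  if (subset != "all") libs <- filter(libs, .data$state == subset)
  if (!nrow(libs)) abort(paste0("no ", subset, " libraries in atlas"))
  tissues <- unique(libs$tissue)
  pooled <- vapply(tissues, function(ts) {
    cols <- libs$library[libs$tissue == ts]
    rowMeans(atlas$counts[, cols, drop = FALSE])
  }, numeric(nrow(atlas$counts)))
  pooled <- matrix(pooled, nrow = nrow(atlas$counts),
                   dimnames = list(rownames(atlas$counts), tissues))
  tot <- rowSums(pooled)
  pooled <- pooled[tot > 0, , drop = FALSE] / tot[tot > 0]
  as_tibble(as.data.frame(pooled, check.names = FALSE)) %>%
    mutate(mirna = rownames(pooled)) %>%
    tidyr::pivot_longer(-"mirna", names_to = "tissue", values_to = "frequency")
}

#' Tissue specificity per miRNA
#'
#' Convenience wrapper: [tissue_pool()] then [specificity_score()] per miRNA.
#'
#' @inheritParams tissue_pool
#' @return a tibble: `mirna`, `n_tissues`, `specificity`.
#' @export
tissue_specificity <- function(atlas, subset = c("all", "normal", "malignant")) {
  pooled <- tissue_pool(atlas, subset)
  pooled %>%
    group_by(.data$mirna) %>%
    summarise(n_tissues = dplyr::n(),
              specificity = specificity_score(.data$frequency),
              .groups = "drop")
}

#' Hypergeometric malignancy enrichment
#'
#' With `N` libraries of which `K` are malignant, and a miRNA expressed
#' (count > `threshold`) in `n` libraries of which `k` are malignant, returns
#' the upper-tail probability `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)` — the chance of drawing at least `k`
#' malignant libraries among `n` at random.
#'
#' @param atlas an [expression_atlas()] (raw counts).
#' @param threshold presence cutoff on the clone count (default 0: any count
#'   above zero counts as expressed).
#' @return a tibble: `mirna`, `n_expressed`, `k_malignant`, `p_value`
#'   (`NA` for miRNAs expressed in no library).
#' @export
malignancy_enrichment <- function(atlas, threshold = 0) {
  mal <- atlas$libraries$library[atlas$libraries$state == "malignant"]
  N <- ncol(atlas$counts)
  K <- length(mal)
  expressed <- atlas$counts > threshold
  purrr::map_dfr(rownames(atlas$counts), function(m) {
    idx <- expressed[m, ]
    n <- sum(idx)
    k <- sum(idx[mal])
    p <- if (n == 0) NA_real_ else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(mirna = m, n_expressed = n, k_malignant = k, p_value = p)
  })
}

#' Group medians and pairwise rank-sum contrasts
#'
#' Medians per group and two-sided Wilcoxon rank-sum p-values for each listed
#' pair (exact for small samples without ties, normal approximation with
#' continuity correction otherwise, the `stats::wilcox.test` defaults).
#'
#' @param df data frame with the value and group columns.
#' @param value,group column names (strings).
#' @param pairs list of 2-vectors of group labels to contrast; default all
#'   pairs in order of appearance.
#' @return a list with `medians` (tibble: group, n, median) and `tests`
#'   (tibble: group1, group2, p_value).
#' @export
group_contrasts <- function(df, value, group, pairs = NULL) {
  v <- df[[value]]; g <- as.character(df[[group]])
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]; g <- g[ok]
  labs <- unique(g)
  sizes <- table(g)
  if (any(sizes < 2) || length(labs) < 2) {
    abort("need at least 2 groups with at least 2 values each")
  }
  medians <- tibble(
    group = labs,
    n = as.integer(sizes[labs]),
    median = unname(vapply(labs, function(l) median(v[g == l]), numeric(1)))
  )
  if (is.null(pairs)) {
    pairs <- utils::combn(labs, 2, simplify = FALSE)
  }
  tests <- purrr::map_dfr(pairs, function(pr) {
    if (!all(pr %in% labs)) abort(paste0("unknown group in pair: ", paste(pr, collapse = ", ")))
    p <- suppressWarnings(wilcox.test(v[g == pr[1]], v[g == pr[2]])$p.value)
    tibble(group1 = pr[1], group2 = pr[2], p_value = p)
  })
  list(medians = medians, tests = tests)
}

#' NMFE per-group mean and variance
#'
#' NMFE is the minimum free energy of the precursor secondary structure
#' divided by precursor length (kcal/mol/nt, negative for stable hairpins).
#'
#' @param records tibble with `mfe`, `length` and a grouping column.
#' @param group grouping column name (default `"age_label"`).
#' @return a tibble: group, `n`, `mean_nmfe`, `var_nmfe` (unbiased variance;
#'   `NA` for groups of size < 2).
#' @export
nmfe_group_stats <- function(records, group = "age_label") {
  if (!all(c("mfe", "length") %in% names(records))) {
    abort("records need 'mfe' and 'length' columns")
  }
  if (any(records$length <= 0)) abort("precursor length must be > 0")
  records$nmfe <- records$mfe / records$length
  records %>%
    group_by(dplyr::across(dplyr::all_of(group))) %>%
    summarise(
      n = dplyr::n(),
      mean_nmfe = mean(.data$nmfe),
      var_nmfe = ifelse(dplyr::n() >= 2, var(.data$nmfe), NA_real_),
      .groups = "drop"
    )
}
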