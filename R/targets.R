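#' Target-set overlap and host-gene age analysis
#'
#' Cross-age overlap and multiplicity of miRNA target sets, and the
#' cross-tabulation of genic miRNA ages against host-gene ages (host genes may
#' use a coarser interval scheme than miRNAs, e.g. six intervals when some
#' primate annotations are missing).
#'
#' @name targets_hosts
NULL

# join target pairs to age labels; drop (with a message) miRNAs without an age
aged_targets <- function(target_map, ages) {
  for (cn in c("mirna", "gene")) {
    if (!cn %in% names(target_map)) abort(paste0("target map needs column '", cn, "'"))
  }
  tm <- distinct(target_map, .data$mirna, .data$gene)
  tm <- left_join(tm, select(ages, "mirna", "age_label"), by = "mirna")
  n_drop <- sum(is.na(tm$age_label))
  if (n_drop > 0) {
    warn(paste0(n_drop, " target pair(s) excluded: miRNA without age label"))
    tm <- filter(tm, !is.na(.data$age_label))
  }
  tm
}

ages_table <- function(ages) {
  # accept either a `family` or `mirna` id column
  if ("mirna" %in% names(ages)) return(ages)
  if ("family" %in% names(ages)) return(rename(ages, mirna = "family"))
  abort("ages need a 'mirna' (or 'family') column")
}

#' Target-set overlap between age groups
#'
#' Cell (i, j) is the number of distinct genes targeted by both group i and
#' group j; the diagonal is each group's target-set size.
#'
#' @param target_map tibble of `(mirna, gene)` pairs (duplicates ignored).
#' @param ages tibble with `mirna` (or `family`) and `age_label`.
#' @return a named square matrix of overlap counts.
#' @export
overlap_matrix <- function(target_map, ages) {
  if (!nrow(target_map)) abort("target map is empty")
  tm <- aged_targets(target_map, ages_table(ages))
  groups <- sort(unique(tm$age_label))
  sets <- lapply(groups, function(g) unique(tm$gene[tm$age_label == g]))
  names(sets) <- groups
  m <- matrix(0L, length(groups), length(groups), dimnames = list(groups, groups))
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  m
}

#' Multiplicity of targeting across age groups
#'
#' For each gene, the number of distinct age groups with at least one miRNA
#' targeting it; returned as a histogram over that count.
#'
#' @inheritParams overlap_matrix
#' @return a tibble: `n_groups`, `n_genes`.
#' @export
multiplicity_profile <- function(target_map, ages) {
  tm <- aged_targets(target_map, ages_table(ages))
  per_gene <- tm %>%
    group_by(.data$gene) %>%
    summarise(n_groups = dplyr::n_distinct(.data$age_label), .groups = "drop")
  per_gene %>%
    count(.data$n_groups, name = "n_genes") %>%
    arrange(.data$n_groups)
}

#' Mean target count by age group with a trend statistic
#'
#' Mean number of distinct targets per miRNA within each age group, plus the
#' Spearman rank correlation between group rank (young to old) and group mean
#' as a trend summary (`NA` with fewer than 2 groups).
#'
#' @inheritParams overlap_matrix
#' @return a list with `means` (tibble: age_label, n_mirnas, mean_targets) and
#'   `trend` (Spearman rho across groups ordered by label).
#' @export
mean_targets_by_age <- function(target_map, ages) {
  tm <- aged_targets(target_map, ages_table(ages))
  per_mirna <- tm %>%
    group_by(.data$mirna, .data$age_label) %>%
    summarise(n_targets = dplyr::n_distinct(.data$gene), .groups = "drop")
  means <- per_mirna %>%
    group_by(.data$age_label) %>%
    summarise(n_mirnas = dplyr::n(), mean_targets = mean(.data$n_targets),
              .groups = "drop") %>%
    arrange(.data$age_label)
  trend <- if (nrow(means) < 2) NA_real_ else
    suppressWarnings(cor(seq_len(nrow(means)), means$mean_targets, method = "spearman"))
  list(means = means, trend = trend)
}

#' Cross-tabulation of miRNA age against host-gene age
#'
#' Only miRNAs with a host gene enter; every host must carry an age label.
#' Host ages may use a different (typically coarser) interval scheme, so the
#' matrix need not be square. Ages are compared on their numeric interval
#' index (the digits in labels like `t3` / `h5`), with larger = older.
#'
#' @param hosts tibble with `mirna`, `host_gene`, `host_age` (and optionally
#'   `intronic`, `strand_relation`); rows with `host_gene = NA` are dropped.
#' @param ages tibble with `mirna` (or `family`) and `age_label`.
#' @return a list with `crosstab` (miRNA age x host age counts), and the
#'   summary fractions `same_interval`, `mirna_younger` and `oldest_host`
#'   (fraction of genic miRNAs whose host is in the oldest host-age class).
#' @export
host_age_crosstab <- function(hosts, ages) {
  genic <- filter(hosts, !is.na(.data$host_gene))
  if (!nrow(genic)) abort("no genic miRNAs in input")
  if (anyNA(genic$host_age)) abort("host gene(s) without age label")
  genic <- left_join(genic, select(ages_table(ages), "mirna", "age_label"), by = "mirna")
  genic <- filter(genic, !is.na(.data$age_label))
  if (!nrow(genic)) abort("no genic miRNA has an age label")
  m_labs <- sort(unique(genic$age_label))
  h_labs <- sort(unique(genic$host_age))
  tab <- table(factor(genic$age_label, m_labs), factor(genic$host_age, h_labs))
  crosstab <- matrix(as.integer(tab), nrow = length(m_labs),
                     dimnames = list(mirna_age = m_labs, host_age = h_labs))
  m_idx <- age_rank(genic$age_label)
  h_idx <- age_rank(genic$host_age)
  list(
    crosstab = crosstab,
    n_genic = nrow(genic),
    same_interval = mean(m_idx == h_idx),
    mirna_younger = mean(m_idx < h_idx),
    oldest_host = mean(h_idx == max(age_rank(h_labs)))
  )
}

age_rank <- function(labels) as.integer(gsub("[^0-9]", "", labels))

#' Intronic fraction by age group
#'
#' @param hosts tibble with `mirna` and a logical `intronic` column.
#' @param ages tibble with `mirna` (or `family`) and `age_label`.
#' @return a list with `by_age` (tibble: age_label, n, fraction_intronic; age
#'   groups with no annotated miRNA are absent) and `overall`.
#' @export
intronic_fraction <- function(hosts, ages) {
  if (!"intronic" %in% names(hosts)) abort("hosts need an 'intronic' column")
  joined <- left_join(select(hosts, "mirna", "intronic"),
                      select(ages_table(ages), "mirna", "age_label"), by = "mirna")
  joined <- filter(joined, !is.na(.data$age_label) & !is.na(.data$intronic))
  by_age <- joined %>%
    group_by(.data$age_label) %>%
    summarise(n = dplyr::n(), fraction_intronic = mean(.data$intronic),
              .groups = "drop")
  list(by_age = by_age, overall = mean(joined$intronic))
}
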