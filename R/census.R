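#' Published census of human miRNA age groups
#'
#' Summary counts from a published eight-group age classification of human
#' miRBase v15 miRNAs: group sizes and, per group, the number of miRNAs whose
#' mature (respectively seed) sequence occurs in no other age group. These
#' are consumed as inputs for arithmetic checks and the headline
#' age-composition summary; the package does not recompute them from the raw
#' miRBase data.
#'
#' @return a tibble: `age_label`, `n_mirnas`, `mature_unique`, `seed_unique`.
#' @export
published_age_census <- function() {
  path <- system.file("extdata", "hsa_age_group_census.tsv", package = "mirage")
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}

#' Fraction of miRNAs in the youngest age groups
#'
#' The share of all families whose origin falls in age groups `t0..t(young_max)`
#' (default `t0..t3`, the post primate-rodent-split groups), as a rounded
#' percentage.
#'
#' @param census tibble with `age_label` and `n_mirnas` (default the packaged
#'   published census).
#' @param young_max highest age index counted as young (default 3).
#' @return a one-row tibble: `n_young`, `n_total`, `percent`.
#' @export
young_fraction <- function(census = published_age_census(), young_max = 3) {
  idx <- age_rank(census$age_label)
  n_young <- sum(census$n_mirnas[idx <= young_max])
  n_total <- sum(census$n_mirnas)
  tibble(
    n_young = n_young,
    n_total = n_total,
    percent = round(100 * n_young / n_total)
  )
}
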