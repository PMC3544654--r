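#' Sequence variation: SNP/indel density and K80 substitution rates
#'
#' Densities contrast the mature arm, the rest of the precursor and flanking
#' background; substitution rates come from Kimura two-parameter distances on
#' concatenated per-age-group alignments under a molecular clock.
#'
#' @name variation
NULL

#' Variant density per region class
#'
#' Density is the number of variant records falling in the class's intervals
#' divided by the total bp of those intervals (0-based half-open, so a variant
#' at `end - 1` is inside and one at `end` is not). A variant overlapping
#' several intervals of one class counts once for that class.
#'
#' @param intervals tibble from [read_intervals()]/[validate_intervals()].
#' @param variants tibble from [read_variants()].
#' @param types variant types to count (default both `snp` and `indel`).
#' @return a tibble: `class`, `n_variants`, `total_bp`, `density`. Classes
#'   with no intervals are absent from the output (density undefined, not 0).
#' @export
variant_density <- function(intervals, variants, types = c("snp", "indel")) {
  variants <- filter(variants, .data$type %in% types)
  classes <- unique(intervals$class)
  purrr::map_dfr(classes, function(cl) {
    iv <- filter(intervals, .data$class == cl)
    hits <- variant_hits(iv, variants)
    tibble(
      class = cl,
      n_variants = length(unique(hits)),
      total_bp = sum(iv$end - iv$start),
      density = length(unique(hits)) / sum(iv$end - iv$start)
    )
  })
}

# ids (row indices into `variants`) of variants inside any interval of `iv`
variant_hits <- function(iv, variants) {
  if (nrow(variants) == 0 || nrow(iv) == 0) return(integer(0))
  hit <- logical(nrow(variants))
  for (i in seq_len(nrow(iv))) {
    hit <- hit | (variants$seqid == iv$seqid[i] &
                    variants$pos >= iv$start[i] &
                    variants$pos < iv$end[i])
  }
  which(hit)
}

#' Fraction of miRNAs carrying at least one variant
#'
#' @param intervals tibble of intervals carrying a `mirna_id` column (grouped
#'   per miRNA; typically the precursor intervals).
#' @param variants tibble of variants.
#' @param types variant types to count.
#' @return a one-row tibble: `n_mirnas`, `n_hit`, `fraction`.
#' @export
fraction_with_variant <- function(intervals, variants, types = c("snp", "indel")) {
  if (!"mirna_id" %in% names(intervals)) abort("intervals need a 'mirna_id' column")
  variants <- filter(variants, .data$type %in% types)
  ids <- unique(intervals$mirna_id)
  hit <- vapply(ids, function(m) {
    iv <- filter(intervals, .data$mirna_id == m)
    length(variant_hits(iv, variants)) > 0
  }, logical(1))
  tibble(n_mirnas = length(ids), n_hit = sum(hit), fraction = mean(hit))
}

#' Kimura two-parameter distance
#'
#' Columns containing a gap or N in either sequence are removed
#' (complete-deletion); with transition fraction `P` and transversion fraction
#' `Q` over the remaining sites,
#' `d = -(1/2) log(1 - 2P - Q) - (1/4) log(1 - 2Q)`.
#'
#' @param a,b equal-length (gapped) sequences, DNA or RNA alphabet.
#' @return the distance in substitutions per site, or `NA_real_` when the
#'   distance is saturated (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`).
#' @export
k80_distance <- function(a, b) {
  pq <- k80_pq(a, b)
  if (pq$n == 0) abort("no comparable (ungapped) sites")
  w1 <- 1 - 2 * pq$P - pq$Q
  w2 <- 1 - 2 * pq$Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1) - 0.25 * log(w2)
}

k80_pq <- function(a, b) {
  x <- strsplit(chartr("Uu", "Tt", toupper(a)), "")[[1]]
  y <- strsplit(chartr("Uu", "Tt", toupper(b)), "")[[1]]
  if (length(x) != length(y)) abort("sequences must be aligned to equal length")
  keep <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n == 0) return(list(P = NA_real_, Q = NA_real_, n = 0L))
  diff <- x != y
  purine <- c("A", "G")
  transition <- diff & ((x %in% purine) == (y %in% purine))
  list(P = sum(transition) / n, Q = sum(diff & !transition) / n, n = n)
}

#' Clock substitution rate from concatenated alignment blocks
#'
#' Blocks (same age group and region class) are concatenated per species;
#' pairwise K80 distances are computed, an ultrametric clock tree is built by
#' average linkage (UPGMA) on those distances, and the rate is the tree height
#' (root-to-tip, substitutions per site) divided by the root age (Myr), taken
#' from the species tree as the deepest divergence among the species present.
#' With exactly two species this reduces to `(d/2) / divergence_time`.
#'
#' Species pairs with saturated distances are dropped; if fewer than two
#' species remain the rate is non-estimable (`NA`).
#'
#' @param blocks tibble with `block_id`, `species`, `seq` (one alignment row
#'   per species per block); all blocks are concatenated.
#' @param tree a [species_tree()] supplying divergence times.
#' @return a one-row tibble: `n_species`, `n_sites`, `tree_height`,
#'   `root_age_myr`, `rate` (substitutions/site/Myr).
#' @export
clock_rate <- function(blocks, tree) {
  concat <- blocks %>%
    group_by(.data$species) %>%
    summarise(seq = paste(.data$seq[order(.data$block_id)], collapse = ""),
              .groups = "drop")
  sp <- concat$species
  if (length(sp) < 2) return(clock_na(length(sp), 0))
  d <- matrix(NA_real_, length(sp), length(sp), dimnames = list(sp, sp))
  for (i in seq_along(sp)) {
    d[i, i] <- 0
    for (j in seq_len(i - 1)) {
      d[i, j] <- d[j, i] <- k80_distance(concat$seq[i], concat$seq[j])
    }
  }
  # drop species involved in saturated pairs until none remain
  while (any(is.na(d)) && nrow(d) > 2) {
    worst <- which.max(rowSums(is.na(d)))
    d <- d[-worst, -worst, drop = FALSE]
  }
  if (any(is.na(d)) || nrow(d) < 2) return(clock_na(nrow(d), nchar(concat$seq[1])))
  sp <- rownames(d)
  height <- if (nrow(d) == 2) {
    d[1, 2] / 2
  } else {
    max(hclust(as.dist(d), method = "average")$height) / 2
  }
  dt <- divergence_times(tree)
  root_age <- max(dt[sp, sp])
  tibble(
    n_species = length(sp),
    n_sites = nchar(concat$seq[1]),
    tree_height = height,
    root_age_myr = root_age,
    rate = height / root_age
  )
}

clock_na <- function(n_species, n_sites) {
  tibble(n_species = n_species, n_sites = n_sites,
         tree_height = NA_real_, root_age_myr = NA_real_, rate = NA_real_)
}

#' Clock rates for every (age group, region class) stratum
#'
#' @param blocks tibble of alignment rows with `age_label` and `class` columns
#'   (as from [read_alignments()] or [simulate_alignments()]).
#' @param tree a [species_tree()].
#' @return a tibble with one row per stratum and the [clock_rate()] columns.
#' @export
clock_rates_by_group <- function(blocks, tree) {
  blocks %>%
    group_by(.data$age_label, .data$class) %>%
    dplyr::group_modify(~ clock_rate(.x, tree)) %>%
    ungroup()
}

#' @importFrom dplyr %>%
#' @export
dplyr::`%>%`
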