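#' Cross-group sharing of mature and seed sequences
#'
#' Counts, for each pair of age groups, how many miRNAs in one group carry a
#' functional sequence (full mature arm or 7-mer seed) identical to that of at
#' least one miRNA in the other group. The diagonal counts miRNAs whose
#' sequence is found in no other group, and the trailing Unique(%) column is
#' `round(100 * diagonal / group size)`.
#'
#' Identity is exact string equality after uppercasing and U/T normalisation.
#'
#' @param records tibble of miRNA records with `age_label` and the functional
#'   sequence columns from [add_functional_sequences()] (`mature`, `seed`).
#' @param key `"mature"` or `"seed"`.
#' @param groups optional character vector fixing group order; defaults to the
#'   sorted labels present.
#' @return a `sharing_matrix`: list with `matrix` (group x group counts),
#'   `sizes`, `unique_pct` and `key`.
#' @export
sharing_matrix <- function(records, key = c("mature", "seed"), groups = NULL) {
  key <- match.arg(key)
  if (!"age_label" %in% names(records) || anyNA(records$age_label)) {
    abort("every record needs an age label for sharing analysis")
  }
  if (!key %in% names(records)) {
    abort(paste0("records lack a '", key, "' column; run add_functional_sequences()"))
  }
  seqs <- chartr("Uu", "Tt", toupper(records[[key]]))
  grp <- as.character(records$age_label)
  groups <- groups %||% sort(unique(grp))
  ng <- length(groups)
  m <- matrix(0L, ng, ng, dimnames = list(groups, groups))
  seq_by_group <- split(seqs, factor(grp, levels = groups))
  for (i in seq_len(ng)) {
    si <- seq_by_group[[i]]
    others <- unique(unlist(seq_by_group[-i], use.names = FALSE))
    m[i, i] <- sum(!si %in% others)
    for (j in seq_len(ng)) {
      if (i == j) next
      m[i, j] <- sum(si %in% seq_by_group[[j]])
    }
  }
  sizes <- vapply(seq_by_group, length, 0L)
  structure(
    list(
      matrix = m,
      sizes = sizes,
      unique_pct = unique_percent(diag(m), sizes),
      key = key
    ),
    class = "sharing_matrix"
  )
}

#' Unique(%) column arithmetic
#'
#' @param diagonal within-group unique counts.
#' @param sizes group sizes.
#' @return `round(100 * diagonal / sizes)` as integers.
#' @export
unique_percent <- function(diagonal, sizes) {
  if (any(sizes <= 0)) abort("group size must be positive")
  as.integer(round(100 * diagonal / sizes))
}

#' @export
print.sharing_matrix <- function(x, ...) {
  cat("Sharing matrix (", x$key, " sequences), ", nrow(x$matrix), " groups\n", sep = "")
  print(x$matrix)
  cat("Unique(%): ", paste(x$unique_pct, collapse = " "), "\n")
  invisible(x)
}

#' @export
as_tibble.sharing_matrix <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$matrix, check.names = FALSE))
  dplyr::bind_cols(
    tibble(group = rownames(x$matrix)),
    out,
    tibble(size = unname(x$sizes), unique_pct = x$unique_pct)
  )
}

#' @rdname sharing_matrix
#' @param x a `sharing_matrix`.
#' @param path output path (tab-delimited, Table-1-style layout).
#' @export
write_sharing_matrix <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}
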