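#' Readers and writers for pipeline inputs
#'
#' All tabular formats are tab-delimited with a header row. Interval
#' coordinates are 0-based half-open throughout; a `one_based` flag on the
#' interval/variant readers converts 1-based inclusive input on the way in.
#'
#' @name io_formats
NULL

presence_states <- c("0", "1", "?")

#' Read a presence/absence matrix of miRNA families x species
#'
#' Cells are `1` (present), `0` (absent) or `?` (unknown; treated by age
#' inference as a free tip). The species columns must match the tree's tip set
#' exactly.
#'
#' @param path tab-delimited file; first column `family`, remaining columns one
#'   per species.
#' @param tree a [species_tree()]; used to validate the species set.
#' @return a tibble with columns `family` and one character column per species,
#'   values in `c("present", "absent", "unknown")`.
#' @export
read_presence_matrix <- function(path, tree) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"family" %in% names(raw)) abort("presence matrix must have a 'family' column")
  species <- setdiff(names(raw), "family")
  validate_presence(raw, species, tree)
}

#' Build presence profiles from a data frame
#'
#' @param df data frame with a `family` column and one column per species,
#'   cells in `0/1/?` or `absent/present/unknown`.
#' @param tree a [species_tree()].
#' @return validated tibble of profiles (see [read_presence_matrix()]).
#' @export
presence_profiles <- function(df, tree) {
  species <- setdiff(names(df), "family")
  validate_presence(df, species, tree)
}

validate_presence <- function(df, species, tree) {
  tips <- tree$phylo$tip.label
  missing <- setdiff(tips, species)
  extra <- setdiff(species, tips)
  if (length(missing)) {
    abort(paste0("presence matrix missing tree tip(s): ", paste(missing, collapse = ", ")))
  }
  if (length(extra)) {
    abort(paste0("presence matrix has unknown species column(s): ", paste(extra, collapse = ", ")))
  }
  out <- as_tibble(df)
  decode <- c("0" = "absent", "1" = "present", "?" = "unknown",
              absent = "absent", present = "present", unknown = "unknown")
  for (sp in species) {
    v <- as.character(out[[sp]])
    bad <- !v %in% names(decode)
    if (any(bad)) {
      abort(paste0("invalid presence cell(s) for species '", sp, "': ",
                   paste(unique(v[bad]), collapse = ", "),
                   " (allowed: 0, 1, ?)"))
    }
    out[[sp]] <- unname(decode[v])
  }
  if (anyDuplicated(out$family)) {
    abort(paste0("duplicate family id(s): ",
                 paste(unique(out$family[duplicated(out$family)]), collapse = ", ")))
  }
  out[, c("family", tips)]
}

#' @rdname read_presence_matrix
#' @param profiles tibble of profiles as returned by [read_presence_matrix()].
#' @export
write_presence_matrix <- function(profiles, path) {
  encode <- c(absent = "0", present = "1", unknown = "?")
  out <- profiles
  for (sp in setdiff(names(out), "family")) out[[sp]] <- unname(encode[out[[sp]]])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read miRNA records (precursor FASTA + coordinate table)
#'
#' Precursor sequences come from a FASTA file; the sidecar table supplies the
#' mature-arm interval within each precursor (0-based half-open) and optional
#' genomic locus, host gene and age label.
#'
#' @param fasta_path FASTA of precursor sequences (RNA or DNA alphabet).
#' @param table_path tab-delimited sidecar with columns `id`, `mature_start`,
#'   `mature_end` and optionally `chrom`, `start`, `end`, `strand`,
#'   `host_gene`, `age_label`.
#' @return a tibble of miRNA records with a `precursor` sequence column.
#' @export
read_mirna_records <- function(fasta_path, table_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  tab <- readr::read_tsv(table_path, col_types = readr::cols(), progress = FALSE)
  for (cn in c("id", "mature_start", "mature_end")) {
    if (!cn %in% names(tab)) abort(paste0("mirna table missing column '", cn, "'"))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(tab$id, ids)
  if (length(missing)) {
    abort(paste0("precursor sequence(s) missing from FASTA: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  tab$precursor <- unname(toupper(as.character(seqs[match(tab$id, ids)])))
  validate_mirna_records(as_tibble(tab))
}

validate_mirna_records <- function(rec) {
  bad_alpha <- grepl("[^ACGUTN]", rec$precursor)
  if (any(bad_alpha)) {
    abort(paste0("precursor sequence with invalid alphabet: ",
                 paste(rec$id[bad_alpha][1:min(3, sum(bad_alpha))], collapse = ", ")))
  }
  len <- nchar(rec$precursor)
  ok <- rec$mature_start >= 0 & rec$mature_end <= len & rec$mature_start < rec$mature_end
  if (any(!ok)) {
    abort(paste0("mature interval outside precursor for: ",
                 paste(rec$id[!ok], collapse = ", ")))
  }
  if (any(rec$mature_end - rec$mature_start < 8)) {
    short <- rec$id[rec$mature_end - rec$mature_start < 8]
    abort(paste0("mature arm shorter than 8 nt (no seed) for: ",
                 paste(short, collapse = ", ")))
  }
  rec
}

#' @rdname read_mirna_records
#' @param records tibble of miRNA records.
#' @export
write_mirna_records <- function(records, fasta_path, table_path) {
  seqs <- Biostrings::BStringSet(setNames(records$precursor, records$id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  readr::write_tsv(select(records, -"precursor"), table_path, progress = FALSE)
  invisible(c(fasta_path, table_path))
}

#' Extract the mature and seed sequences from miRNA records
#'
#' The seed is mature positions 2-8 (1-based within the mature arm), the
#' community convention for 7-mer seeds. Sequences are uppercased with U
#' normalised to T so that identity comparisons ignore the RNA/DNA alphabet.
#'
#' @param records tibble with `precursor`, `mature_start`, `mature_end`.
#' @return the records with `mature` and `seed` columns added.
#' @export
add_functional_sequences <- function(records) {
  mature <- substr(records$precursor, records$mature_start + 1, records$mature_end)
  norm <- function(x) chartr("Uu", "Tt", toupper(x))
  records$mature <- norm(mature)
  records$seed <- substr(records$mature, 2, 8)
  records
}

interval_classes <- c("mature", "precursor_nonmature", "flank")

#' Read a BED-like interval table
#'
#' Six columns: `seqid`, `start`, `end`, `class` (one of `mature`,
#' `precursor_nonmature`, `flank`), `mirna_id`, `strand`. Coordinates are
#' 0-based half-open natively; set `one_based = TRUE` for 1-based inclusive
#' input.
#'
#' @param path tab-delimited interval file with header.
#' @param one_based convert 1-based inclusive coordinates on input.
#' @return a tibble of intervals.
#' @export
read_intervals <- function(path, one_based = FALSE) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  validate_intervals(as_tibble(df), one_based = one_based)
}

#' @rdname read_intervals
#' @param df data frame of intervals.
#' @export
validate_intervals <- function(df, one_based = FALSE) {
  for (cn in c("seqid", "start", "end", "class")) {
    if (!cn %in% names(df)) abort(paste0("interval table missing column '", cn, "'"))
  }
  if (one_based) df$start <- df$start - 1
  bad <- df$start >= df$end
  if (any(bad)) {
    abort(paste0("interval with start >= end on ", paste(unique(df$seqid[bad]), collapse = ", ")))
  }
  if (any(df$start < 0)) abort("negative interval start")
  badc <- !df$class %in% interval_classes
  if (any(badc)) {
    abort(paste0("unknown interval class: ", paste(unique(df$class[badc]), collapse = ", ")))
  }
  as_tibble(df)
}

#' @rdname read_intervals
#' @param intervals tibble of intervals.
#' @export
write_intervals <- function(intervals, path) {
  readr::write_tsv(intervals, path, progress = FALSE)
  invisible(path)
}

#' Read a variant table (SNPs and indels)
#'
#' BED-like 4 columns: `seqid`, `pos` (0-based), `type` (`snp` or `indel`),
#' `id`. Each record counts once toward density regardless of indel length.
#'
#' @param path tab-delimited variant file with header.
#' @param one_based convert 1-based positions on input.
#' @return a tibble of variants.
#' @export
read_variants <- function(path, one_based = FALSE) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  for (cn in c("seqid", "pos", "type")) {
    if (!cn %in% names(df)) abort(paste0("variant table missing column '", cn, "'"))
  }
  if (one_based) df$pos <- df$pos - 1
  bad <- !df$type %in% c("snp", "indel")
  if (any(bad)) abort(paste0("unknown variant type: ", paste(unique(df$type[bad]), collapse = ", ")))
  if (any(df$pos < 0)) abort("negative variant position")
  as_tibble(df)
}

#' @rdname read_variants
#' @param variants tibble of variants.
#' @export
write_variants <- function(variants, path) {
  readr::write_tsv(variants, path, progress = FALSE)
  invisible(path)
}

#' Read an expression atlas (clone counts + library metadata)
#'
#' @param counts_path tab-delimited miRNA x library clone counts; first column
#'   `mirna`, remaining columns one per library, non-negative integers.
#' @param metadata_path tab-delimited library metadata with columns `library`,
#'   `tissue`, `state` (`normal` or `malignant`).
#' @return an `expression_atlas`: list with a counts matrix (`counts`) and a
#'   library metadata tibble (`libraries`).
#' @export
read_expression_atlas <- function(counts_path, metadata_path) {
  counts <- readr::read_tsv(counts_path, col_types = readr::cols(), progress = FALSE)
  meta <- readr::read_tsv(metadata_path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  if (!"mirna" %in% names(counts)) abort("counts must have a 'mirna' column")
  m <- as.matrix(counts[, -1, drop = FALSE])
  rownames(m) <- counts$mirna
  expression_atlas(m, meta)
}

#' @rdname read_expression_atlas
#' @param counts numeric matrix, miRNAs in rows, libraries in columns.
#' @param libraries data frame with `library`, `tissue`, `state`.
#' @export
expression_atlas <- function(counts, libraries) {
  libraries <- as_tibble(libraries)
  for (cn in c("library", "tissue", "state")) {
    if (!cn %in% names(libraries)) abort(paste0("library metadata missing column '", cn, "'"))
  }
  if (any(counts < 0)) abort("negative clone count in atlas")
  bad_state <- !libraries$state %in% c("normal", "malignant")
  if (any(bad_state)) {
    abort(paste0("library state must be normal/malignant, got: ",
                 paste(unique(libraries$state[bad_state]), collapse = ", ")))
  }
  libs <- colnames(counts)
  unmet <- setdiff(libs, libraries$library)
  if (length(unmet)) {
    abort(paste0("library without metadata: ", paste(unmet, collapse = ", ")))
  }
  extra <- setdiff(libraries$library, libs)
  if (length(extra)) {
    warn(paste0("metadata for ", length(extra),
                " library(ies) not in counts; ignored: ", paste(extra, collapse = ", ")))
    libraries <- filter(libraries, .data$library %in% libs)
  }
  if (all(colSums(counts) == 0)) abort("atlas has no library with positive total count")
  libraries <- libraries[match(libs, libraries$library), ]
  structure(list(counts = counts, libraries = libraries), class = "expression_atlas")
}

#' @export
print.expression_atlas <- function(x, ...) {
  cat("Expression atlas: ", nrow(x$counts), " miRNAs x ", ncol(x$counts),
      " libraries (", sum(x$libraries$state == "malignant"), " malignant)\n", sep = "")
  invisible(x)
}

#' @rdname read_expression_atlas
#' @param atlas an `expression_atlas`.
#' @export
write_expression_atlas <- function(atlas, counts_path, metadata_path) {
  df <- bind_cols_counts(atlas$counts)
  readr::write_tsv(df, counts_path, progress = FALSE)
  readr::write_tsv(atlas$libraries, metadata_path, progress = FALSE)
  invisible(c(counts_path, metadata_path))
}

bind_cols_counts <- function(m) {
  out <- as_tibble(as.data.frame(m, check.names = FALSE))
  dplyr::bind_cols(tibble(mirna = rownames(m)), out)
}

#' Read a pipeline configuration file
#'
#' YAML file naming the tree file, focal tip, optional age-interval labels and
#' the group-merge map used to collapse age groups.
#'
#' @param path YAML config file.
#' @return a named list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$merge_map)) cfg$merge_map <- lapply(cfg$merge_map, as.integer)
  cfg
}

#' Read an alignment block set (multi-FASTA + sidecar table)
#'
#' Each block is a species-indexed gapped alignment; FASTA headers are
#' `block_id|species`. The sidecar maps block id to age group and region class.
#'
#' @param fasta_path multi-FASTA of aligned sequences.
#' @param table_path tab-delimited sidecar with `block_id`, `age_label`, `class`.
#' @return a tibble with one row per (block, species) and the sidecar columns
#'   joined on.
#' @export
read_alignments <- function(fasta_path, table_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  hdr <- strsplit(names(seqs), "|", fixed = TRUE)
  blocks <- tibble(
    block_id = vapply(hdr, `[`, "", 1),
    species = vapply(hdr, `[`, "", 2),
    seq = unname(toupper(as.character(seqs)))
  )
  side <- readr::read_tsv(table_path, col_types = readr::cols(), progress = FALSE)
  out <- left_join(blocks, side, by = "block_id")
  validate_alignments(out)
}

validate_alignments <- function(blocks) {
  bad <- grepl("[^ACGTUN-]", blocks$seq)
  if (any(bad)) abort("alignment with invalid alphabet")
  lens <- tapply(nchar(blocks$seq), blocks$block_id, function(x) length(unique(x)))
  if (any(lens > 1)) {
    abort(paste0("unequal row lengths in block(s): ",
                 paste(names(lens)[lens > 1], collapse = ", ")))
  }
  as_tibble(blocks)
}

#' @rdname read_alignments
#' @param blocks tibble of alignment rows.
#' @export
write_alignments <- function(blocks, fasta_path, table_path) {
  seqs <- Biostrings::BStringSet(setNames(blocks$seq, paste(blocks$block_id, blocks$species, sep = "|")))
  Biostrings::writeXStringSet(seqs, fasta_path)
  side <- distinct(blocks, .data$block_id, .data$age_label, .data$class)
  readr::write_tsv(side, table_path, progress = FALSE)
  invisible(c(fasta_path, table_path))
}
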