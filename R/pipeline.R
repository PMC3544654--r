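#' Pipeline stage runners and reporting
#'
#' File-in/file-out wrappers chaining the analysis stages, each writing
#' tab-delimited outputs plus a run manifest (input digests, seed, package
#' version) so identical inputs reproduce identical outputs.
#'
#' @name cli_report
NULL

file_digest <- function(path) {
  # cheap content fingerprint: size + sum of byte values (no external digest dep)
  b <- readBin(path, "raw", file.info(path)$size)
  sprintf("%d:%s", length(b), format(sum(as.integer(b)), scientific = FALSE))
}

write_manifest <- function(out_dir, inputs, outputs, extra = list()) {
  man <- list(
    package = "mirage",
    version = as.character(utils::packageVersion("mirage")),
    inputs = lapply(inputs, file_digest),
    outputs = outputs,
    extra = extra
  )
  yaml::write_yaml(man, file.path(out_dir, "manifest.yaml"))
  invisible(man)
}

#' Run age inference: presence matrix -> age table + sharing matrices
#'
#' @param tree_path Newick species tree.
#' @param presence_path presence/absence matrix.
#' @param out_dir output directory.
#' @param focal focal tip name.
#' @param records optional miRNA records tibble (with `age_label`s joined from
#'   the inferred ages) enabling the mature/seed sharing matrices.
#' @param tie_break passed to [assign_ages()].
#' @return invisibly, the age assignment tibble.
#' @export
run_ages <- function(tree_path, presence_path, out_dir, focal = "human",
                     records = NULL, tie_break = "oldest") {
  tree <- read_species_tree(tree_path, focal)
  profiles <- read_presence_matrix(presence_path, tree)
  ages <- assign_ages(tree, profiles, tie_break = tie_break)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(ages, file.path(out_dir, "ages.tsv"), progress = FALSE)
  outputs <- "ages.tsv"
  if (!is.null(records)) {
    rec <- add_functional_sequences(records)
    rec <- left_join(select(rec, -dplyr::any_of("age_label")),
                     select(ages, mirna = "family", "age_label"),
                     by = c(id = "mirna"))
    for (key in c("mature", "seed")) {
      sm <- sharing_matrix(filter(rec, !is.na(.data$age_label)), key = key)
      write_sharing_matrix(sm, file.path(out_dir, paste0("sharing_", key, ".tsv")))
      outputs <- c(outputs, paste0("sharing_", key, ".tsv"))
    }
  }
  write_manifest(out_dir, list(tree = tree_path, presence = presence_path), outputs)
  invisible(ages)
}

#' Run the birth-death fit: age table -> fit report
#'
#' @param ages_path age table written by [run_ages()] (or any table with an
#'   `age_index` column).
#' @param tree_path Newick species tree.
#' @param out_dir output directory.
#' @param focal focal tip name.
#' @param horizon horizon (Myr) for derived rates.
#' @return invisibly, the `bd_fit`.
#' @export
run_fit_bd <- function(ages_path, tree_path, out_dir, focal = "human", horizon = 100) {
  tree <- read_species_tree(tree_path, focal)
  ages <- readr::read_tsv(ages_path, col_types = readr::cols(), progress = FALSE)
  obs <- observed_cumulative(ages, tree)
  populated <- sum(tabulate(ages$age_index + 1L, nbins = nrow(tree$path) + 1L) > 0)
  if (populated < 4) {
    abort(paste0("only ", populated, " age interval(s) populated; need >= 4 to fit"))
  }
  fit <- bd_fit(obs)
  if (!fit$converged) warn("birth-death fit did not converge; estimates are unreliable")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_bd_report(fit, file.path(out_dir, "bd_fit.tsv"), horizon = horizon)
  write_manifest(out_dir, list(ages = ages_path, tree = tree_path), "bd_fit.tsv",
                 extra = list(horizon = horizon))
  invisible(fit)
}

#' Assemble a combined report from stage outputs
#'
#' Concatenates the Table-1-style sharing matrices, the birth-death fit
#' summary, the Table-3-style expression contrasts, the host-age crosstab and
#' the variant densities into one tab-delimited report with section headers.
#' Missing stage outputs abort unless `allow_partial = TRUE`, in which case
#' the section is marked missing.
#'
#' @param stage_paths named list of stage output files; recognised names:
#'   `ages`, `sharing_mature`, `sharing_seed`, `bd_fit`, `expression`,
#'   `crosstab`, `densities`.
#' @param out_path report file to write.
#' @param allow_partial mark missing sections instead of failing.
#' @return invisibly, `out_path`.
#' @export
run_report <- function(stage_paths, out_path, allow_partial = FALSE) {
  sections <- c("ages", "sharing_mature", "sharing_seed", "bd_fit",
                "expression", "crosstab", "densities")
  con <- character(0)
  missing <- character(0)
  for (s in sections) {
    pth <- stage_paths[[s]]
    con <- c(con, paste0("## section: ", s))
    if (is.null(pth) || !file.exists(pth)) {
      missing <- c(missing, s)
      con <- c(con, "# MISSING")
      next
    }
    con <- c(con, readLines(pth))
  }
  if (length(missing) && !allow_partial) {
    abort(paste0("missing stage output(s): ", paste(missing, collapse = ", "),
                 " (use allow_partial = TRUE for a partial report)"))
  }
  writeLines(con, out_path)
  invisible(out_path)
}
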