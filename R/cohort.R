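#' Read a longitudinal cohort from a manifest
#'
#' The manifest is a tab-delimited table with columns `subject_id`,
#' `baseline_path`, `followup_path`, `d_vabs`, `d_eow`, `cgi_i` (an optional
#' `metadata_path` column may point to a per-subject node table). Matrix paths
#' are resolved relative to the manifest's directory; when no `metadata_path`
#' column is present a shared `nodes.tsv` next to the manifest is used. All
#' networks are validated to share the same node ids in the same order.
#'
#' Behavioral conventions: `d_vabs` and `d_eow` are follow-up minus baseline
#' scores (higher = more improvement); `cgi_i` is the follow-up
#' clinical-improvement rating itself (lower = more improvement).
#'
#' @param manifest_path Path to the manifest file.
#' @return A cohort tibble with columns `subject_id`, `baseline`, `followup`
#'   (list-columns of [brain_network()]s), `d_vabs`, `d_eow`, `cgi_i`.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  root <- dirname(manifest_path)
  man <- readr::read_tsv(manifest_path, col_types = readr::cols(),
                         progress = FALSE)
  required <- c("subject_id", "baseline_path", "followup_path",
                "d_vabs", "d_eow", "cgi_i")
  missing_cols <- setdiff(required, names(man))
  if (length(missing_cols) > 0) {
    stop("manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (m in c("d_vabs", "d_eow", "cgi_i")) {
    if (anyNA(man[[m]])) {
      stop("missing behavioral score '", m, "' for subject '",
           man$subject_id[which(is.na(man[[m]]))[1]], "'", call. = FALSE)
    }
  }
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(root, p))
  meta_paths <- if ("metadata_path" %in% names(man)) {
    resolve(man$metadata_path)
  } else {
    rep(file.path(root, "nodes.tsv"), nrow(man))
  }
  cohort <- tibble::tibble(
    subject_id = as.character(man$subject_id),
    baseline = purrr::map2(resolve(man$baseline_path), meta_paths,
                           read_network),
    followup = purrr::map2(resolve(man$followup_path), meta_paths,
                           read_network),
    d_vabs = as.numeric(man$d_vabs),
    d_eow = as.numeric(man$d_eow),
    cgi_i = as.numeric(man$cgi_i)
  )
  validate_cohort(cohort)
  cohort
}

#' Write a cohort (and optional ground truth) to disk
#'
#' Writes one matrix file per subject and timepoint, a shared `nodes.tsv`
#' metadata table, and a `manifest.tsv` consumable by [read_cohort()]. When a
#' ground-truth object from [generate_cohort()] is supplied, the planted
#' edges and per-subject latent improvements are written alongside as
#' `truth_planted_edges.tsv` and `truth_subjects.tsv`.
#'
#' @param cohort A cohort tibble.
#' @param dir Output directory, created if needed.
#' @param truth Optional ground truth list from [generate_cohort()].
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, truth = NULL) {
  validate_cohort(cohort)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$baseline[[1]]$nodes, file.path(dir, "nodes.tsv"),
                   progress = FALSE)
  man <- tibble::tibble(
    subject_id = cohort$subject_id,
    baseline_path = paste0(cohort$subject_id, "_baseline.txt"),
    followup_path = paste0(cohort$subject_id, "_followup.txt"),
    d_vabs = cohort$d_vabs,
    d_eow = cohort$d_eow,
    cgi_i = cohort$cgi_i
  )
  for (s in seq_len(nrow(cohort))) {
    write_network(cohort$baseline[[s]], file.path(dir, man$baseline_path[s]))
    write_network(cohort$followup[[s]], file.path(dir, man$followup_path[s]))
  }
  manifest_path <- file.path(dir, "manifest.tsv")
  readr::write_tsv(man, manifest_path, progress = FALSE)
  if (!is.null(truth)) {
    readr::write_tsv(truth$planted_edges,
                     file.path(dir, "truth_planted_edges.tsv"),
                     progress = FALSE)
    subj <- tibble::tibble(subject_id = cohort$subject_id,
                           latent_improvement = truth$latent_improvement)
    readr::write_tsv(subj, file.path(dir, "truth_subjects.tsv"),
                     progress = FALSE)
  }
  invisible(manifest_path)
}
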