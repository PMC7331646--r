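#' Within-subject curvature change ratios
#'
#' The longitudinal change of a unit (edge or node) is the ratio of its
#' curvature at follow-up over its curvature at baseline. A ratio is used
#' rather than a difference because curvature is unitless; the ratio reads
#' directly as relative change in robustness. A unit's ratio is undefined —
#' and the unit flagged, not silently dropped — when the baseline curvature is
#' within `epsilon` of zero or the unit is absent at either timepoint.
#' Curvature may legitimately be negative, so ratios may be negative; they are
#' retained as-is.
#'
#' @param before,after [ricci_curvature()] results computed on networks with
#'   identical node sets in identical order.
#' @param mode `"edges"` or `"nodes"`.
#' @param epsilon Baseline magnitude below which the ratio is undefined.
#' @return A tibble with unit identifiers (`node_a`, `node_b` for edges;
#'   `node` for nodes), `before`, `after`, `ratio` and logical `defined`
#'   (ratio is `NA` where `defined` is `FALSE`).
#' @export
curvature_change <- function(before, after, mode = c("edges", "nodes"),
                             epsilon = 1e-12) {
  stopifnot(inherits(before, "ricci_curvature"),
            inherits(after, "ricci_curvature"))
  mode <- match.arg(mode)
  if (!identical(before$nodes$node, after$nodes$node)) {
    stop("baseline and follow-up results have different node orderings",
         call. = FALSE)
  }
  if (mode == "edges") {
    tb <- dplyr::select(before$edges, "node_a", "node_b",
                        before = "curvature")
    ta <- dplyr::select(after$edges, "node_a", "node_b", after = "curvature")
    out <- dplyr::full_join(tb, ta, by = c("node_a", "node_b"))
  } else {
    tb <- dplyr::select(before$nodes, "node", before = "scalar_curvature")
    ta <- dplyr::select(after$nodes, "node", after = "scalar_curvature")
    out <- dplyr::full_join(tb, ta, by = "node")
  }
  out$defined <- !is.na(out$before) & !is.na(out$after) &
    abs(out$before) >= epsilon
  out$ratio <- ifelse(out$defined, out$after / out$before, NA_real_)
  out
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Ranks use average ranks for ties; the two-sided p-value uses the
#' t-distribution approximation on `n - 2` degrees of freedom, appropriate at
#' the cohort sizes this pipeline targets. Pairs with a missing value in
#' either vector are removed first.
#'
#' @param x,y Numeric vectors of equal length; at least 4 complete pairs.
#' @return A tibble with `r`, `p` and `n` (complete pairs used).
#' @examples
#' spearman_test(1:6, c(2, 3, 5, 7, 11, 13))   # r = 1
#' @export
spearman_test <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 4) {
    stop("need at least 4 complete pairs, got ", n, call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: an input vector is constant", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = n)
}

## Spearman r and t-approximation p for every row of a units x subjects
## matrix against one behavior vector. Rows are ranked independently;
## rows with zero variance get NA. Verified against cor.test in the tests.
spearman_rows <- function(ratio_matrix, behavior) {
  n <- ncol(ratio_matrix)
  rx <- t(apply(ratio_matrix, 1, rank))
  ry <- rank(behavior)
  sx <- apply(rx, 1, stats::sd)
  r <- rep(NA_real_, nrow(ratio_matrix))
  ok <- sx > 0 & stats::sd(ry) > 0
  if (any(ok)) {
    r[ok] <- as.vector(stats::cor(t(rx[ok, , drop = FALSE]), ry))
  }
  tsq <- pmax(0, 1 - r^2)
  tstat <- ifelse(tsq == 0, Inf, abs(r) * sqrt((n - 2) / tsq))
  p <- 2 * stats::pt(-tstat, df = n - 2)
  list(r = r, p = p)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Standard step-up procedure: adjusted values (q-values) are monotone
#' non-decreasing in sorted p order, invariant to input order, and a unit is
#' rejected when `q < alpha`.
#'
#' @param p Vector of p-values in `[0, 1]` (`NA` allowed, passed through).
#' @param alpha FDR level.
#' @return A tibble with `p`, `q` and logical `reject`, in input order.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
#' @export
benjamini_hochberg <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  q <- stats::p.adjust(p, method = "BH")
  tibble::tibble(p = p, q = q, reject = !is.na(q) & q < alpha)
}

#' Analysis configuration
#'
#' Collects the tunable parameters of the longitudinal pipeline. Defaults
#' follow the study conventions: hop ground metric, cross-hemisphere edges
#' removed (brainstem edges kept), significance threshold 0.05 on two or more
#' of the three behavioral measures, FDR level 0.05.
#'
#' @param metric_kind Ground metric for curvature, `"hop"` or `"weighted"`.
#' @param remove_cross_hemisphere Zero out left-right edges before curvature?
#' @param keep_brainstem Keep edges touching hemisphere-`none` nodes when
#'   removing cross-hemisphere edges?
#' @param epsilon Baseline-curvature magnitude below which a change ratio is
#'   undefined.
#' @param min_valid Minimum number of subjects with a defined ratio for a
#'   unit to enter the analysis; `NULL` means all subjects.
#' @param alpha FDR level for the Benjamini-Hochberg correction.
#' @param selection_threshold Per-measure p-value threshold for selection.
#' @param selection_min_measures Number of behavioral measures that must pass
#'   the threshold for a unit to be selected (1, 2 or 3).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(metric_kind = c("hop", "weighted"),
                            remove_cross_hemisphere = TRUE,
                            keep_brainstem = TRUE,
                            epsilon = 1e-12,
                            min_valid = NULL,
                            alpha = 0.05,
                            selection_threshold = 0.05,
                            selection_min_measures = 2L) {
  metric_kind <- match.arg(metric_kind)
  stopifnot(alpha > 0, alpha < 1,
            selection_threshold > 0, selection_threshold < 1,
            selection_min_measures %in% 1:3)
  structure(
    list(metric_kind = metric_kind,
         remove_cross_hemisphere = remove_cross_hemisphere,
         keep_brainstem = keep_brainstem,
         epsilon = epsilon,
         min_valid = min_valid,
         alpha = alpha,
         selection_threshold = selection_threshold,
         selection_min_measures = as.integer(selection_min_measures)),
    class = "analysis_config"
  )
}

behavior_measures <- c("d_vabs", "d_eow", "cgi_i")

#' Run the longitudinal curvature-behavior analysis
#'
#' The full pipeline: per subject, optionally remove cross-hemisphere edges,
#' compute Ollivier-Ricci curvature of baseline and follow-up networks, and
#' form the follow-up/baseline curvature ratio per edge and per node. Each
#' unit retained across enough subjects is then correlated (Spearman) with
#' the three behavioral change scores — change in Vineland socialization
#' (`d_vabs`), change in expressive vocabulary (`d_eow`), and the
#' clinical-improvement rating (`cgi_i`, lower = more improvement). A unit is
#' *selected* when its correlation is significant at `selection_threshold` on
#' at least `selection_min_measures` of the three measures.
#' Benjamini-Hochberg q-values are computed within each mode-by-measure
#' family (all edges for one measure form one family, separately from nodes);
#' a selected unit `survives_fdr` when at least `selection_min_measures`
#' measures have `q < alpha`.
#'
#' @param cohort A cohort tibble from [read_cohort()] or [generate_cohort()]:
#'   columns `subject_id`, `baseline`, `followup` (list-columns of
#'   [brain_network()]s), `d_vabs`, `d_eow`, `cgi_i`.
#' @param config An [analysis_config()].
#' @return A tibble of class `curvature_correlation`, one row per retained
#'   unit: `unit_type` (`"edge"`/`"node"`), `node_a`, `node_b` (`NA` for
#'   nodes), `r_*`, `p_*`, `q_*` for each measure, `mean_ratio`, `sd_ratio`,
#'   `n_valid`, `selected`, `survives_fdr`. The configuration and per-stage
#'   unit counts are attached as attributes `config` and `log`.
#' @export
run_analysis <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  validate_cohort(cohort)
  ns <- nrow(cohort)
  if (ns < 4) {
    stop("need at least 4 subjects, got ", ns, call. = FALSE)
  }
  min_valid <- if (is.null(config$min_valid)) ns else config$min_valid

  changes <- purrr::map(seq_len(ns), function(s) {
    before_net <- cohort$baseline[[s]]
    after_net <- cohort$followup[[s]]
    if (config$remove_cross_hemisphere) {
      before_net <- remove_cross_hemisphere_edges(before_net,
                                                  config$keep_brainstem)
      after_net <- remove_cross_hemisphere_edges(after_net,
                                                 config$keep_brainstem)
    }
    rc_before <- ricci_curvature(before_net, config$metric_kind)
    rc_after <- ricci_curvature(after_net, config$metric_kind)
    list(
      edges = curvature_change(rc_before, rc_after, "edges", config$epsilon),
      nodes = curvature_change(rc_before, rc_after, "nodes", config$epsilon)
    )
  })

  behavior <- as.data.frame(cohort[behavior_measures])
  out <- dplyr::bind_rows(
    analyze_mode(changes, "edges", behavior, min_valid, config),
    analyze_mode(changes, "nodes", behavior, min_valid, config)
  )
  attr(out, "config") <- config
  attr(out, "log") <- list(
    n_subjects = ns,
    min_valid = min_valid,
    n_edge_units = sum(out$unit_type == "edge"),
    n_node_units = sum(out$unit_type == "node"),
    n_selected = sum(out$selected),
    n_survive_fdr = sum(out$survives_fdr)
  )
  class(out) <- c("curvature_correlation", class(out))
  out
}

## Correlation table for one mode (edges or nodes) across the cohort.
analyze_mode <- function(changes, mode, behavior, min_valid, config) {
  tabs <- purrr::imap(changes, function(ch, s) {
    tab <- ch[[mode]]
    tab$subject <- s
    tab
  })
  long <- dplyr::bind_rows(tabs)
  if (mode == "edges") {
    long$unit <- paste(long$node_a, long$node_b, sep = "\r")
  } else {
    long$unit <- long$node
  }
  ns <- length(changes)
  wide <- tidyr::pivot_wider(
    dplyr::select(long, "unit", "subject", "ratio"),
    names_from = "subject", values_from = "ratio"
  )
  ratio_mat <- as.matrix(wide[, -1, drop = FALSE])
  n_valid <- rowSums(!is.na(ratio_mat))
  keep <- n_valid >= max(min_valid, 4)
  wide <- wide[keep, , drop = FALSE]
  ratio_mat <- ratio_mat[keep, , drop = FALSE]
  n_valid <- n_valid[keep]
  if (nrow(wide) == 0) {
    return(empty_correlation_table())
  }

  stats_by_measure <- purrr::map(behavior, function(bvec) {
    complete <- !apply(ratio_mat, 1, anyNA)
    r <- rep(NA_real_, nrow(ratio_mat))
    p <- rep(NA_real_, nrow(ratio_mat))
    if (any(complete)) {
      res <- spearman_rows(ratio_mat[complete, , drop = FALSE], bvec)
      r[complete] <- res$r
      p[complete] <- res$p
    }
    for (i in which(!complete)) {
      ok <- !is.na(ratio_mat[i, ])
      st <- tryCatch(spearman_test(ratio_mat[i, ok], bvec[ok]),
                     error = function(e) NULL)
      if (!is.null(st)) {
        r[i] <- st$r
        p[i] <- st$p
      }
    }
    list(r = r, p = p)
  })

  pmat <- do.call(cbind, purrr::map(stats_by_measure, "p"))
  qmat <- apply(pmat, 2, function(p) stats::p.adjust(p, method = "BH"))
  qmat <- matrix(qmat, nrow = nrow(pmat))
  n_sig <- rowSums(pmat < config$selection_threshold, na.rm = TRUE)
  n_sig_q <- rowSums(qmat < config$alpha, na.rm = TRUE)
  selected <- n_sig >= config$selection_min_measures
  survives <- selected & n_sig_q >= config$selection_min_measures

  if (mode == "edges") {
    parts <- strsplit(wide$unit, "\r", fixed = TRUE)
    node_a <- purrr::map_chr(parts, 1)
    node_b <- purrr::map_chr(parts, 2)
  } else {
    node_a <- wide$unit
    node_b <- NA_character_
  }
  tibble::tibble(
    unit_type = if (mode == "edges") "edge" else "node",
    node_a = node_a,
    node_b = node_b,
    r_vabs = stats_by_measure$d_vabs$r,
    p_vabs = stats_by_measure$d_vabs$p,
    q_vabs = qmat[, 1],
    r_eow = stats_by_measure$d_eow$r,
    p_eow = stats_by_measure$d_eow$p,
    q_eow = qmat[, 2],
    r_cgi = stats_by_measure$cgi_i$r,
    p_cgi = stats_by_measure$cgi_i$p,
    q_cgi = qmat[, 3],
    mean_ratio = rowMeans(ratio_mat, na.rm = TRUE),
    sd_ratio = apply(ratio_mat, 1, stats::sd, na.rm = TRUE),
    n_valid = as.integer(n_valid),
    selected = selected,
    survives_fdr = survives
  )
}

empty_correlation_table <- function() {
  tibble::tibble(
    unit_type = character(), node_a = character(), node_b = character(),
    r_vabs = numeric(), p_vabs = numeric(), q_vabs = numeric(),
    r_eow = numeric(), p_eow = numeric(), q_eow = numeric(),
    r_cgi = numeric(), p_cgi = numeric(), q_cgi = numeric(),
    mean_ratio = numeric(), sd_ratio = numeric(), n_valid = integer(),
    selected = logical(), survives_fdr = logical()
  )
}

validate_cohort <- function(cohort) {
  required <- c("subject_id", "baseline", "followup", behavior_measures)
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (m in behavior_measures) {
    if (anyNA(cohort[[m]])) {
      stop("missing behavioral score in '", m, "' for subject '",
           cohort$subject_id[which(is.na(cohort[[m]]))[1]], "'",
           call. = FALSE)
    }
  }
  ref <- cohort$baseline[[1]]$nodes$id
  for (s in seq_len(nrow(cohort))) {
    for (tp in c("baseline", "followup")) {
      ids <- cohort[[tp]][[s]]$nodes$id
      if (!identical(ids, ref)) {
        stop("node-set mismatch: subject '", cohort$subject_id[s], "' ", tp,
             " network does not match the cohort node ordering",
             call. = FALSE)
      }
    }
  }
  invisible(cohort)
}

#' @rdname run_analysis
#' @param x A `curvature_correlation` table.
#' @param ... Unused.
#' @method glance curvature_correlation
#' @export
glance.curvature_correlation <- function(x, ...) {
  lg <- attr(x, "log")
  tibble::tibble(
    n_subjects = lg$n_subjects,
    n_edge_units = lg$n_edge_units,
    n_node_units = lg$n_node_units,
    n_selected = lg$n_selected,
    n_survive_fdr = lg$n_survive_fdr
  )
}

#' Plot correlation results
#'
#' Correlation strength against significance for every unit and measure;
#' selected units are highlighted.
#'
#' @param object A `curvature_correlation` table from [run_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot curvature_correlation
#' @export
autoplot.curvature_correlation <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "unit_type", "node_a", "node_b",
                  "selected", dplyr::starts_with("r_"),
                  dplyr::starts_with("p_")),
    cols = c(dplyr::starts_with("r_"), dplyr::starts_with("p_")),
    names_to = c(".value", "measure"), names_sep = "_"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$r, y = -log10(.data$p),
                                     color = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::facet_grid(ggplot2::vars(.data$unit_type),
                        ggplot2::vars(.data$measure)) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Spearman r", y = "-log10(p)") +
    ggplot2::theme_minimal()
}

#' Write an analysis results table
#'
#' Tab-delimited, one row per unit, deterministic order (as returned by
#' [run_analysis()]).
#'
#' @param results A `curvature_correlation` table.
#' @param path Output path.
#' @return `results`, invisibly.
#' @export
write_results <- function(results, path) {
  readr::write_tsv(tibble::as_tibble(results), path, progress = FALSE)
  invisible(results)
}
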