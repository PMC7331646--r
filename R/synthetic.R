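#' Configuration for the synthetic-cohort generator
#'
#' The generator emulates the structure of a small longitudinal DTI cohort:
#' by default 19 subjects and 83 regions (41 per hemisphere plus one
#' brainstem region), symmetric non-negative weights drawn log-normally (the
#' heavy-tailed, strictly positive shape of streamline volumes after
#' normalization by white-matter volume), within-subject weight changes, and
#' three behavioral change scores coupled to a per-subject latent improvement
#' variable. `cgi_i` is inverted — lower values mean more improvement — so
#' its expected correlation with improvement-coupled connectivity change is
#' negative.
#'
#' All subjects share one intra-hemisphere edge topology (regions come from a
#' common atlas); weights are drawn independently per subject. Effects are
#' planted on *edge weights*, not directly on curvature, so recovering them
#' through the curvature pipeline is a genuine end-to-end exercise of the
#' method: for each planted pathway (an intra-hemisphere edge chosen in a
#' triangle-rich position), the flanking edges to every shared neighbor are
#' multiplied by `exp(effect_size * L)` at follow-up, where `L` is the
#' subject's latent improvement. Strengthening a pathway's triangle support
#' concentrates both endpoint walk measures on common neighbors, which
#' monotonically raises the pathway's Ollivier-Ricci curvature — the
#' feedback-through-triangles mechanism by which denser local connectivity
#' confers robustness — so improvement couples positively to the planted
#' pathway's curvature-change ratio, as observed clinically.
#'
#' Behavioral scores are anchored to the observed cohort summary statistics
#' (change in Vineland socialization 3.37 +/- 6.71, change in expressive
#' vocabulary 4.95 +/- 6.34, clinical-improvement rating 2.79 +/- 1.82):
#' each score is `mean + sd * (±L + noise_sd * e) / sqrt(1 + noise_sd^2)`
#' with `e` standard normal, giving the stated mean and standard deviation
#' while `noise_sd` sets the noise-to-signal ratio of the coupling.
#'
#' @param n_subjects Number of subjects.
#' @param n_nodes Total regions; `n_nodes - 1` must be even (split equally
#'   between hemispheres, one brainstem region).
#' @param edge_density Fraction of intra-hemisphere pairs connected.
#' @param weight_meanlog,weight_sdlog Log-normal parameters of baseline
#'   weights.
#' @param n_planted Number of planted intra-hemisphere edges (ignored when
#'   `planted_edges` is given).
#' @param planted_edges Optional two-column matrix/data frame of node ids.
#' @param effect_size Coupling between latent improvement and planted weight
#'   change (log-scale multiplier per unit of latent improvement).
#' @param noise_sd Behavioral noise-to-signal ratio (0 = noiseless coupling).
#' @param weight_noise_sd Log-scale SD of the multiplicative test-retest
#'   noise applied to every edge weight at follow-up.
#' @param behavior_anchors Named list of `c(mean, sd)` pairs for `d_vabs`,
#'   `d_eow`, `cgi_i`.
#' @param seed Integer seed; the whole cohort is a pure function of the
#'   configuration including the seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 19,
                             n_nodes = 83,
                             edge_density = 0.45,
                             weight_meanlog = -6,
                             weight_sdlog = 0.6,
                             n_planted = 3,
                             planted_edges = NULL,
                             effect_size = 0.5,
                             noise_sd = 0.5,
                             weight_noise_sd = 0.05,
                             behavior_anchors = list(
                               d_vabs = c(mean = 3.37, sd = 6.71),
                               d_eow = c(mean = 4.95, sd = 6.34),
                               cgi_i = c(mean = 2.79, sd = 1.82)
                             ),
                             seed = 1L) {
  stopifnot(n_subjects >= 1, n_nodes >= 5, (n_nodes - 1) %% 2 == 0,
            edge_density > 0, edge_density <= 1,
            effect_size >= 0, noise_sd >= 0, weight_noise_sd >= 0)
  structure(
    list(n_subjects = as.integer(n_subjects), n_nodes = as.integer(n_nodes),
         edge_density = edge_density, weight_meanlog = weight_meanlog,
         weight_sdlog = weight_sdlog, n_planted = as.integer(n_planted),
         planted_edges = planted_edges, effect_size = effect_size,
         noise_sd = noise_sd, weight_noise_sd = weight_noise_sd,
         behavior_anchors = behavior_anchors, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

synthetic_nodes <- function(n_nodes) {
  per_hemi <- (n_nodes - 1) %/% 2
  tibble::tibble(
    id = c(sprintf("L%02d", seq_len(per_hemi)),
           sprintf("R%02d", seq_len(per_hemi)), "BS"),
    name = c(sprintf("left_region_%02d", seq_len(per_hemi)),
             sprintf("right_region_%02d", seq_len(per_hemi)), "brainstem"),
    hemisphere = c(rep("left", per_hemi), rep("right", per_hemi), "none")
  )
}

## Connected Erdos-Renyi-style edge set over `nodes` (indices) at `density`,
## retried until connected. Returns a two-column index matrix.
sample_connected_edges <- function(nodes, density, max_tries = 100) {
  pairs <- t(utils::combn(nodes, 2))
  for (try in seq_len(max_tries)) {
    keep <- stats::runif(nrow(pairs)) < density
    sub <- pairs[keep, , drop = FALSE]
    if (is_connected_on(nodes, sub)) return(sub)
  }
  stop("edge density ", density, " too low to connect ", length(nodes),
       " nodes after ", max_tries, " attempts", call. = FALSE)
}

is_connected_on <- function(nodes, edges) {
  if (length(nodes) == 1) return(TRUE)
  if (nrow(edges) < length(nodes) - 1) return(FALSE)
  g <- igraph::graph_from_edgelist(
    matrix(match(edges, nodes), ncol = 2), directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0, length(nodes) - igraph::vcount(g)))
  igraph::is_connected(g)
}

## Shared cohort topology: connected graph within each hemisphere, brainstem
## attached to a few nodes of each hemisphere.
synthetic_topology <- function(config) {
  nodes <- synthetic_nodes(config$n_nodes)
  per_hemi <- (config$n_nodes - 1) %/% 2
  left <- seq_len(per_hemi)
  right <- per_hemi + seq_len(per_hemi)
  bs <- config$n_nodes
  edges <- rbind(
    sample_connected_edges(left, config$edge_density),
    sample_connected_edges(right, config$edge_density)
  )
  n_bs <- max(1L, round(config$edge_density * per_hemi / 2))
  bs_targets <- c(sample(left, n_bs), sample(right, n_bs))
  edges <- rbind(edges, cbind(bs_targets, bs))
  list(nodes = nodes, edges = edges)
}

weights_from_edges <- function(config, topology) {
  w <- matrix(0, config$n_nodes, config$n_nodes)
  vals <- stats::rlnorm(nrow(topology$edges),
                        meanlog = config$weight_meanlog,
                        sdlog = config$weight_sdlog)
  w[topology$edges] <- vals
  w[topology$edges[, c(2, 1), drop = FALSE]] <- vals
  w
}

#' Generate one synthetic baseline network
#'
#' Draws the shared topology and one subject's baseline weights under the
#' configuration's seed. Deterministic: identical calls return identical
#' networks.
#'
#' @param config A [synthetic_config()].
#' @return A [brain_network()].
#' @export
generate_baseline <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    topology <- synthetic_topology(config)
    brain_network(weights_from_edges(config, topology), topology$nodes)
  })
}

#' Generate a synthetic longitudinal cohort with known ground truth
#'
#' See [synthetic_config()] for the generative model. Per subject: a baseline
#' network on the shared topology; a latent improvement `L ~ N(0, 1)`; a
#' network equal to the baseline with the flanking edges of every planted
#' pathway (to each shared neighbor) multiplied by `exp(effect_size * L)`
#' and every edge weight additionally
#' multiplied by log-normal test-retest noise; three behavioral scores
#' coupled to `L` (the clinical-improvement rating negatively).
#'
#' @param config A [synthetic_config()].
#' @return A list with `cohort` (tibble as consumed by [run_analysis()]) and
#'   `truth`: `planted_edges` (tibble `node_a`, `node_b`),
#'   `latent_improvement` (per subject), and `weight_multipliers` (subjects x
#'   planted-edges matrix of realized follow-up multipliers).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  topology <- synthetic_topology(config)
  nodes <- topology$nodes

  planted <- resolve_planted(config, topology)
  np <- nrow(planted)
  flanks <- planted_flanks(planted, topology)

  latent <- stats::rnorm(config$n_subjects)
  multipliers <- matrix(1, config$n_subjects, np)

  baseline <- vector("list", config$n_subjects)
  followup <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    wb <- weights_from_edges(config, topology)
    wf <- wb
    if (np > 0 && config$effect_size > 0) {
      ## Improvement raises the robustness (curvature) of the planted
      ## pathway by strengthening its triangle support: multiplying the
      ## flanking edges to every shared neighbor concentrates both endpoint
      ## walk measures on common nodes, monotonically lowering the
      ## transport cost and raising k toward 1 — the triangle-feedback
      ## mechanism by which denser local connectivity confers robustness.
      mult <- exp(config$effect_size * latent[s])
      for (e in seq_len(np)) {
        fl <- flanks[[e]]
        wf[fl] <- wf[fl] * mult
        wf[fl[, c(2, 1), drop = FALSE]] <- wf[fl]
        multipliers[s, e] <- mult
      }
    }
    if (config$weight_noise_sd > 0) {
      noise <- stats::rlnorm(nrow(topology$edges), 0, config$weight_noise_sd)
      wf[topology$edges] <- wf[topology$edges] * noise
      wf[topology$edges[, c(2, 1), drop = FALSE]] <- wf[topology$edges]
    }
    baseline[[s]] <- brain_network(wb, nodes)
    followup[[s]] <- brain_network(wf, nodes)
  }

  behavior <- purrr::imap(config$behavior_anchors, function(anchor, nm) {
    sign <- if (nm == "cgi_i") -1 else 1
    e <- stats::rnorm(config$n_subjects)
    anchor[["mean"]] + anchor[["sd"]] * (sign * latent + config$noise_sd * e) /
      sqrt(1 + config$noise_sd^2)
  })

  cohort <- tibble::tibble(
    subject_id = sprintf("sub%02d", seq_len(config$n_subjects)),
    baseline = baseline,
    followup = followup,
    d_vabs = behavior$d_vabs,
    d_eow = behavior$d_eow,
    cgi_i = behavior$cgi_i
  )
  truth <- list(
    planted_edges = tibble::tibble(node_a = nodes$id[planted$i],
                                   node_b = nodes$id[planted$j]),
    latent_improvement = latent,
    weight_multipliers = multipliers
  )
  list(cohort = cohort, truth = truth)
}

resolve_planted <- function(config, topology) {
  nodes <- topology$nodes
  if (!is.null(config$planted_edges)) {
    pe <- as.data.frame(config$planted_edges)
    i <- match(as.character(pe[[1]]), nodes$id)
    j <- match(as.character(pe[[2]]), nodes$id)
    if (anyNA(i) || anyNA(j)) {
      stop("planted edge names unknown to the node set", call. = FALSE)
    }
  } else {
    intra <- topology$edges[
      nodes$hemisphere[topology$edges[, 1]] ==
        nodes$hemisphere[topology$edges[, 2]], , drop = FALSE]
    ## plant inside triangle-rich neighborhoods: edges with several shared
    ## neighbors have robustly positive baseline curvature, so the change
    ## ratio is well defined and comparable across subjects (a pendant
    ## edge, by contrast, has curvature exactly 0 at any weights)
    n_shared <- vapply(seq_len(nrow(intra)), function(e) {
      length(shared_neighbors(intra[e, 1], intra[e, 2], topology))
    }, integer(1))
    need <- sort(n_shared, decreasing = TRUE)[
      min(2L * config$n_planted, length(n_shared))]
    eligible <- which(n_shared >= max(need, 1L))
    if (length(eligible) < config$n_planted) eligible <- seq_len(nrow(intra))
    pick <- sample(eligible, min(config$n_planted, length(eligible)))
    i <- intra[pick, 1]
    j <- intra[pick, 2]
  }
  swap <- i > j
  tmp <- i[swap]
  i[swap] <- j[swap]
  j[swap] <- tmp
  hi <- nodes$hemisphere[i]
  hj <- nodes$hemisphere[j]
  if (any(hi != hj)) {
    stop("planted edges must be intra-hemisphere pairs", call. = FALSE)
  }
  ord <- order(i, j)
  tibble::tibble(i = i[ord], j = j[ord])
}

shared_neighbors <- function(i, j, topology) {
  nb <- function(v) {
    e <- topology$edges
    c(e[e[, 1] == v, 2], e[e[, 2] == v, 1])
  }
  setdiff(intersect(nb(i), nb(j)), c(i, j))
}

## For each planted edge, the flanking edges (i,z) and (j,z) to every shared
## neighbor z, as index matrices into the weight matrix.
planted_flanks <- function(planted, topology) {
  purrr::map(seq_len(nrow(planted)), function(e) {
    i <- planted$i[e]
    j <- planted$j[e]
    z <- shared_neighbors(i, j, topology)
    if (length(z) == 0) {
      return(matrix(integer(0), 0, 2))
    }
    rbind(cbind(i, z), cbind(j, z))
  })
}

#' Sensitivity and false positives of a recovery run
#'
#' Compares the units selected by [run_analysis()] on a synthetic cohort with
#' the edges the generator actually planted.
#'
#' @param truth Ground truth from [generate_cohort()].
#' @param results A `curvature_correlation` table from [run_analysis()].
#' @return A one-row tibble: `n_planted`, `n_selected_edges`,
#'   `true_positives`, `false_positives` (selected units, edges and nodes,
#'   that are not planted edges), `sensitivity`.
#' @export
recovery_report <- function(truth, results) {
  planted_key <- paste(truth$planted_edges$node_a,
                       truth$planted_edges$node_b, sep = "\r")
  edges <- results[results$unit_type == "edge", , drop = FALSE]
  missing_units <- setdiff(
    planted_key, paste(edges$node_a, edges$node_b, sep = "\r"))
  if (length(missing_units) > 0 && nrow(edges) > 0) {
    warning(length(missing_units),
            " planted edge(s) absent from the analyzed unit set",
            call. = FALSE)
  }
  sel_edges <- edges[edges$selected, , drop = FALSE]
  sel_key <- paste(sel_edges$node_a, sel_edges$node_b, sep = "\r")
  tp <- sum(planted_key %in% sel_key)
  n_selected_total <- sum(results$selected)
  tibble::tibble(
    n_planted = length(planted_key),
    n_selected_edges = nrow(sel_edges),
    true_positives = tp,
    false_positives = n_selected_total - tp,
    sensitivity = if (length(planted_key) > 0) tp / length(planted_key)
                  else NA_real_
  )
}
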