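#' Hierarchical K-means convergence clubs
#'
#' Groups countries into `k` clusters on the nine-indicator panel:
#' (1) z-score standardise each indicator column; (2) agglomerative
#' clustering with Euclidean distance and average linkage, cut at `k`;
#' (3) Lloyd K-means refinement initialised at the centroids of that cut,
#' run to label convergence (at most `max_iter` sweeps). The procedure is
#' deterministic given the input row order. Cluster ids are relabelled by
#' descending centroid life expectancy at birth, so cluster 1 is always the
#' highest-longevity club.
#'
#' @param panel An [indicator_panel()] for one period and sex.
#' @param k Number of clusters (>= 2, < number of distinct rows).
#' @param standardize Standardise columns before distances (default TRUE;
#'   without it the Euclidean metric is dominated by the age-scaled
#'   indicators).
#' @param max_iter Maximum Lloyd sweeps.
#' @return An object of class `cluster_solution`: list with `labels`
#'   (tibble country/code/cluster/dist_to_centroid), `centroids`
#'   (standardised), `centroids_raw`, `representative` (per-cluster country
#'   closest to its centroid), `sizes`, `summary` (per-cluster min/centroid/
#'   max of each indicator, raw units), `scaling` (per-indicator mean, sd),
#'   `wss_trace` (within-cluster SS per Lloyd iteration), `k`,
#'   `period_start`, `sex`.
#' @export
hkmeans_clubs <- function(panel, k, standardize = TRUE, max_iter = 100L) {
  x_raw <- as.matrix(panel[, indicator_names])
  rownames(x_raw) <- panel$country
  n_distinct <- nrow(unique(x_raw))
  if (k < 2 || k > n_distinct) {
    stop(errorCondition(
      sprintf("k = %d out of range (need 2 <= k <= %d distinct rows)", k, n_distinct),
      class = c("mortclubs_domain_error", "error")))
  }
  ctr <- colMeans(x_raw)
  scl <- apply(x_raw, 2, stats::sd)
  scl[scl == 0] <- 1
  x <- if (standardize) scale(x_raw, center = ctr, scale = scl) else x_raw

  hc <- stats::hclust(stats::dist(x, method = "euclidean"), method = "average")
  init_labels <- stats::cutree(hc, k = k)
  centers <- centroid_matrix(x, init_labels, k)

  ll <- lloyd_refine(x, centers, max_iter)
  labels <- ll$labels
  centers <- ll$centers

  # stable ids: order clusters by descending centroid e0 (raw units)
  raw_centers <- centroid_matrix(x_raw, labels, k)
  ord <- order(-raw_centers[, "e0"])
  relabel <- match(seq_len(k), ord)
  labels <- relabel[labels]
  centers <- centers[ord, , drop = FALSE]
  raw_centers <- raw_centers[ord, , drop = FALSE]
  rownames(centers) <- rownames(raw_centers) <- seq_len(k)

  dist_to_centroid <- sqrt(rowSums((x - centers[labels, , drop = FALSE])^2))
  representative <- vapply(seq_len(k), function(cl) {
    members <- which(labels == cl)
    panel$country[members[which.min(dist_to_centroid[members])]]
  }, character(1))

  summary_tbl <- purrr::map(seq_len(k), function(cl) {
    xm <- x_raw[labels == cl, , drop = FALSE]
    tibble::tibble(
      cluster = cl, indicator = indicator_names,
      min = apply(xm, 2, min), centroid = raw_centers[cl, ],
      max = apply(xm, 2, max)
    )
  }) |> purrr::list_rbind()

  structure(list(
    labels = tibble::tibble(country = panel$country, code = panel$code,
                            cluster = labels,
                            dist_to_centroid = dist_to_centroid),
    centroids = centers, centroids_raw = raw_centers,
    representative = stats::setNames(representative, seq_len(k)),
    sizes = tabulate(labels, k),
    summary = summary_tbl,
    scaling = list(center = ctr, scale = if (standardize) scl else rep(1, length(scl))),
    wss_trace = ll$wss_trace, k = k,
    period_start = panel$period_start[1], sex = panel$sex[1]
  ), class = "cluster_solution")
}

centroid_matrix <- function(x, labels, k) {
  out <- matrix(NA_real_, k, ncol(x), dimnames = list(NULL, colnames(x)))
  for (cl in seq_len(k)) {
    out[cl, ] <- colMeans(x[labels == cl, , drop = FALSE])
  }
  out
}

# Lloyd's algorithm with a per-iteration within-SS trace. Empty clusters are
# re-seeded with the point farthest from its assigned centroid.
lloyd_refine <- function(x, centers, max_iter) {
  k <- nrow(centers)
  labels <- integer(nrow(x))
  wss_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(centers) +
      outer(rep(1, nrow(x)), rowSums(centers^2))
    new_labels <- max.col(-d2, ties.method = "first")
    for (cl in which(tabulate(new_labels, k) == 0)) {
      far <- which.max(d2[cbind(seq_len(nrow(x)), new_labels)])
      new_labels[far] <- cl
      d2[far, ] <- Inf
      d2[far, cl] <- 0
    }
    converged <- identical(new_labels, labels)
    labels <- new_labels
    centers <- centroid_matrix(x, labels, k)
    wss_trace <- c(wss_trace,
                   sum((x - centers[labels, , drop = FALSE])^2))
    if (converged) break
  }
  list(labels = labels, centers = centers, wss_trace = wss_trace)
}

within_ss <- function(x, labels) {
  k <- max(labels)
  centers <- centroid_matrix(x, labels, k)
  sum((x - centers[labels, , drop = FALSE])^2)
}

#' Select the number of convergence clubs
#'
#' Runs [hkmeans_clubs()] for each candidate `k` and scores the solutions
#' with a battery of five indices: average silhouette width (maximise),
#' Calinski-Harabasz (maximise), Davies-Bouldin (minimise), the Hartigan
#' rule (smallest k with H(k) <= 10, where
#' `H(k) = (W_k / W_{k+1} - 1)(n - k - 1)`), and an elbow criterion on the
#' within-dispersion curve (largest second difference of `W_k`). Each index
#' casts one vote for its best k; the majority wins, ties going to the
#' smaller k. An index that is undefined for the panel abstains.
#'
#' @param panel An [indicator_panel()] for one period and sex.
#' @param k_range Candidate cluster counts (default 2:8).
#' @param standardize Passed to [hkmeans_clubs()].
#' @return An object of class `k_selection`: list with `best_k`, `votes`
#'   (per-index best k), `scores` (per-k per-index values), `weak_structure`
#'   (TRUE when the winning silhouette is below 0.3), `solutions`.
#' @export
select_k <- function(panel, k_range = 2:8, standardize = TRUE) {
  x <- as.matrix(panel[, indicator_names])
  if (standardize) x <- scale_safe(x)
  n <- nrow(x)
  k_range <- sort(unique(k_range))
  if (max(k_range) >= n) {
    stop(errorCondition("largest candidate k must be below the number of countries",
                        class = c("mortclubs_domain_error", "error")))
  }
  d <- stats::dist(x)
  sols <- purrr::map(k_range, \(k) hkmeans_clubs(panel, k, standardize = standardize))
  names(sols) <- k_range

  wss <- purrr::map_dbl(sols, \(s) within_ss(x, s$labels$cluster))
  sil <- purrr::map_dbl(sols, function(s) {
    mean(cluster::silhouette(s$labels$cluster, d)[, "sil_width"])
  })
  ch <- purrr::map_dbl(seq_along(k_range), function(i) {
    k <- k_range[i]
    tss <- sum(scale(x, scale = FALSE)^2)
    ((tss - wss[i]) / (k - 1)) / (wss[i] / (n - k))
  })
  db <- purrr::map_dbl(sols, \(s) davies_bouldin(x, s$labels$cluster))

  # Hartigan: smallest k in range with H(k) <= 10 (needs W at k+1)
  hart <- rep(NA_real_, length(k_range))
  for (i in seq_along(k_range)) {
    if (i < length(k_range) && k_range[i + 1] == k_range[i] + 1) {
      hart[i] <- (wss[i] / wss[i + 1] - 1) * (n - k_range[i] - 1)
    }
  }
  hart_ok <- which(!is.na(hart) & hart <= 10)
  hart_best <- if (length(hart_ok) > 0) {
    k_range[hart_ok[1]]
  } else if (any(!is.na(hart))) {
    k_range[which.min(hart)]
  } else NA_integer_

  # elbow on W_k: largest drop deceleration (second difference)
  elbow_best <- NA_integer_
  if (length(k_range) >= 3) {
    d2w <- diff(diff(wss))
    elbow_best <- k_range[which.max(d2w) + 1L]
  }

  votes <- c(
    silhouette = k_range[which.max(sil)],
    calinski_harabasz = k_range[which.max(ch)],
    davies_bouldin = k_range[which.min(db)],
    hartigan = hart_best,
    elbow = elbow_best
  )
  cast <- votes[!is.na(votes)]
  tab <- table(cast)
  winners <- as.integer(names(tab)[tab == max(tab)])
  best_k <- min(winners)

  structure(list(
    best_k = best_k, votes = votes,
    scores = tibble::tibble(k = k_range, wss = wss, silhouette = sil,
                            calinski_harabasz = ch, davies_bouldin = db,
                            hartigan = hart),
    weak_structure = sil[match(best_k, k_range)] < 0.3,
    solutions = sols
  ), class = "k_selection")
}

scale_safe <- function(x) {
  s <- apply(x, 2, stats::sd)
  s[s == 0] <- 1
  scale(x, scale = s)
}

davies_bouldin <- function(x, labels) {
  k <- max(labels)
  centers <- centroid_matrix(x, labels, k)
  spread <- vapply(seq_len(k), function(cl) {
    xm <- x[labels == cl, , drop = FALSE]
    mean(sqrt(rowSums((xm - matrix(centers[cl, ], nrow(xm), ncol(x), byrow = TRUE))^2)))
  }, numeric(1))
  mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      (spread[i] + spread[j]) / sqrt(sum((centers[i, ] - centers[j, ])^2))
    }, numeric(1)))
  }, numeric(1)))
}

#' Cluster transitions between two periods
#'
#' Cross-tabulates cluster membership of the countries shared by two cluster
#' solutions (same sex, different periods) and aligns the target clusters to
#' the source clusters by greedy maximal overlap — the alignment is used only
#' for display labelling.
#'
#' @param a,b `cluster_solution` objects for the source and target period.
#' @return An object of class `transition_table`: list with `counts`
#'   (a source x target contingency matrix), `alignment` (named integer:
#'   target id -> source id), `flows` (tidy tibble), periods and sex.
#' @export
cluster_transitions <- function(a, b) {
  if (!identical(a$sex, b$sex)) {
    stop(errorCondition("transition requires matching sex",
                        class = c("mortclubs_domain_error", "error")))
  }
  shared <- intersect(a$labels$country, b$labels$country)
  if (length(shared) == 0) {
    stop(errorCondition("no shared countries", class = c("mortclubs_domain_error", "error")))
  }
  la <- a$labels$cluster[match(shared, a$labels$country)]
  lb <- b$labels$cluster[match(shared, b$labels$country)]
  counts <- table(factor(la, levels = seq_len(a$k)),
                  factor(lb, levels = seq_len(b$k)))
  counts <- matrix(counts, a$k, b$k,
                   dimnames = list(source = seq_len(a$k), target = seq_len(b$k)))

  # greedy alignment: repeatedly match the largest remaining overlap
  alignment <- stats::setNames(rep(NA_integer_, b$k), seq_len(b$k))
  m <- counts
  for (step in seq_len(min(a$k, b$k))) {
    ij <- arrayInd(which.max(m), dim(m))
    if (m[ij] == 0 && step > 1) break
    alignment[ij[2]] <- ij[1]
    m[ij[1], ] <- -1
    m[, ij[2]] <- -1
  }
  flows <- as.data.frame(as.table(counts)) |>
    tibble::as_tibble() |>
    dplyr::rename(source = 1, target = 2, n = 3) |>
    dplyr::mutate(source = as.integer(as.character(.data$source)),
                  target = as.integer(as.character(.data$target))) |>
    dplyr::filter(.data$n > 0)

  structure(list(counts = counts, alignment = alignment, flows = flows,
                 source_period = a$period_start, target_period = b$period_start,
                 sex = a$sex),
            class = "transition_table")
}

#' Project a nine-indicator panel onto its first two principal components
#'
#' PCA of the standardised country x indicator matrix, used to visualise
#' between-country proximity. Sign convention: within each of the first two
#' components, the loading with the largest magnitude is made positive, so
#' projections are reproducible across platforms.
#'
#' @param panel An [indicator_panel()] for one period and sex.
#' @return An object of class `pca_projection`: list with `scores` (tibble
#'   country/code/PC1/PC2), `loadings` (9 x 2), `var_explained` (length-2
#'   fractions), `period_start`, `sex`.
#' @export
project_pca <- function(panel) {
  if (nrow(panel) < 3) {
    stop(errorCondition("PCA projection needs at least 3 countries",
                        class = c("mortclubs_domain_error", "error")))
  }
  x <- scale_safe(as.matrix(panel[, indicator_names]))
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- x %*% rot
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = tibble::tibble(country = panel$country, code = panel$code,
                            PC1 = scores[, 1], PC2 = scores[, 2]),
    loadings = rot, var_explained = ve[1:2],
    period_start = panel$period_start[1], sex = panel$sex[1]
  ), class = "pca_projection")
}

#' Cluster every period/sex panel with a shared k
#'
#' @param panels A stacked [indicator_panels()] tibble covering several
#'   periods and/or sexes.
#' @param k Number of clusters shared across all panels.
#' @param standardize Passed to [hkmeans_clubs()].
#' @return A list with `solutions` (named `<period>_<sex>`) and
#'   `transitions` (between consecutive analysed periods within each sex).
#' @export
cluster_all <- function(panels, k, standardize = TRUE) {
  combos <- dplyr::distinct(panels, .data$period_start, .data$sex) |>
    dplyr::arrange(.data$sex, .data$period_start)
  solutions <- purrr::pmap(combos, function(period_start, sex) {
    sub <- panels[panels$period_start == period_start & panels$sex == sex, ]
    hkmeans_clubs(sub, k, standardize = standardize)
  })
  names(solutions) <- sprintf("%d_%s", combos$period_start, combos$sex)
  transitions <- list()
  for (sx in unique(combos$sex)) {
    ps <- sort(combos$period_start[combos$sex == sx])
    for (i in seq_len(length(ps) - 1)) {
      nm <- sprintf("%d_to_%d_%s", ps[i], ps[i + 1], sx)
      transitions[[nm]] <- cluster_transitions(
        solutions[[sprintf("%d_%s", ps[i], sx)]],
        solutions[[sprintf("%d_%s", ps[i + 1], sx)]]
      )
    }
  }
  list(solutions = solutions, transitions = transitions)
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("Convergence clubs: period %s, %s, k = %d\n",
              x$period_start, x$sex, x$k))
  for (cl in seq_len(x$k)) {
    cat(sprintf("  club %d: %d countries, e0 centroid %.1f, representative %s\n",
                cl, x$sizes[cl], x$centroids_raw[cl, "e0"], x$representative[cl]))
  }
  invisible(x)
}

#' Tidy a cluster solution
#'
#' @param x A `cluster_solution`.
#' @param ... Unused.
#' @return The per-country label tibble with period and sex attached.
#' @export
tidy.cluster_solution <- function(x, ...) {
  dplyr::mutate(x$labels, period_start = x$period_start, sex = x$sex,
                .before = 1)
}

#' Glance at a cluster solution
#'
#' @inheritParams tidy.cluster_solution
#' @return One-row tibble: k, sizes, total within-SS, iterations.
#' @export
glance.cluster_solution <- function(x, ...) {
  tibble::tibble(
    period_start = x$period_start, sex = x$sex, k = x$k,
    n = sum(x$sizes), min_size = min(x$sizes), max_size = max(x$sizes),
    wss = x$wss_trace[length(x$wss_trace)],
    iterations = length(x$wss_trace)
  )
}

#' Plot convergence clubs on the first two principal components
#'
#' @param object A `cluster_solution`.
#' @param panel The [indicator_panel()] the solution was fitted on.
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2 coloured by club.
#' @export
autoplot.cluster_solution <- function(object, panel, ...) {
  proj <- project_pca(panel)
  df <- dplyr::left_join(proj$scores, object$labels, by = c("country", "code"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = factor(.data$cluster))) +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = sprintf("Convergence clubs, %s %s", object$period_start, object$sex),
      x = sprintf("PC1 (%.0f%%)", 100 * proj$var_explained[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * proj$var_explained[2]),
      colour = "club"
    )
}
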