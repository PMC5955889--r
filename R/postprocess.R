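#' Greedy neighbour-count clustering of an ensemble
#'
#' The cluster-discrimination stage groups conformations the way FFT-docking
#' servers do before submission: two conformations are neighbours when their
#' pairwise distance (typically placement RMSD) is strictly below
#' `threshold`; repeatedly, the remaining conformation with the most
#' remaining neighbours (ties: lower index) becomes a *cluster center* and,
#' together with its neighbours, forms a cluster and is removed. Clustering
#' stops after `max_clusters` clusters or when the best remaining candidate
#' would have fewer than `min_size` members. Self-pairs are excluded from
#' neighbour counts; cluster size counts the center.
#'
#' @param D Symmetric distance matrix (e.g. from [ensemble_rmsd_matrix()]).
#' @param threshold Neighbour distance threshold (default 9, the standard
#'   iRMSD cut in Angstrom).
#' @param max_clusters Maximum number of clusters (default 30).
#' @param min_size Minimum cluster size (default 10).
#' @return A tibble with one row per cluster: `cluster` (1-based id in
#'   formation order), `center` (row index in `D`), `size`, and `members`
#'   (list-column of row indices, center first).
#' @export
greedy_cluster <- function(D, threshold = 9, max_clusters = 30, min_size = 10) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || n < 1) stop_ssdu("`D` must be a square distance matrix")
  nb <- D < threshold
  diag(nb) <- FALSE
  alive <- rep(TRUE, n)
  out <- list()
  while (length(out) < max_clusters) {
    counts <- colSums(nb & alive) * alive  # neighbours among remaining points
    counts[!alive] <- -1L
    best <- which.max(counts)              # ties: lowest index
    if (counts[best] + 1 < min_size) break
    members <- c(best, which(nb[, best] & alive & seq_len(n) != best))
    alive[members] <- FALSE
    out[[length(out) + 1]] <- tibble::tibble(
      cluster = length(out) + 1L, center = as.integer(best),
      size = length(members), members = list(as.integer(members)))
    if (!any(alive)) break
  }
  if (length(out) == 0) {
    return(tibble::tibble(cluster = integer(), center = integer(),
                          size = integer(), members = list()))
  }
  dplyr::bind_rows(out)
}

#' Nine per-cluster features for ranking
#'
#' In the stated order: (1-4) mean energy of the lowest-energy 25%, 50%, 75%
#' and 100% of members; (5) cluster size; (6-9) mean distance to the cluster
#' center over the nearest 25%, 50%, 75% and 100% of members (members ranked
#' by increasing distance from the center). Fraction counts use
#' `ceiling(p * size)`, so every quantile set is non-empty.
#'
#' @param energies Member energies.
#' @param dist_to_center Member distances to the cluster center (same
#'   length; the center itself contributes 0).
#' @return A named numeric vector of length 9
#'   (`e25 e50 e75 e100 size d25 d50 d75 d100`).
#' @examples
#' cluster_features(c(1, 2, 3, 4), c(0, 1, 2, 3))
#' @export
cluster_features <- function(energies, dist_to_center) {
  n <- length(energies)
  if (n < 1 || length(dist_to_center) != n)
    stop_ssdu("energies and distances must be non-empty and matching")
  top_mean <- function(v, p) mean(sort(v)[seq_len(ceiling(p * n))])
  c(e25 = top_mean(energies, .25), e50 = top_mean(energies, .5),
    e75 = top_mean(energies, .75), e100 = mean(energies),
    size = n,
    d25 = top_mean(dist_to_center, .25), d50 = top_mean(dist_to_center, .5),
    d75 = top_mean(dist_to_center, .75), d100 = mean(dist_to_center))
}

#' Quality tiers of conformations against a reference
#'
#' A surrogate for interface-RMSD-based quality bands: each conformation's
#' placed ligand is compared with the reference placement by [rmsd()] (no
#' superposition) and binned as `High` (< 1 A), `Medium` (< 5 A),
#' `Acceptable` (< 10 A) or `Incorrect`. Thresholds are configurable.
#'
#' @param ensemble A conformation tibble.
#' @param truth Reference conformation (one-row tibble or 6-vector).
#' @param ligand A centroid-relative [rigid_body()] used for placement.
#' @param thresholds Named vector with `acceptable`, `medium`, `high` cuts.
#' @return An ordered factor (`Incorrect < Acceptable < Medium < High`).
#' @export
quality_classify <- function(ensemble, truth, ligand,
                             thresholds = c(acceptable = 10, medium = 5, high = 1)) {
  ref <- place_ligand(ligand, truth)
  d <- vapply(seq_len(nrow(ensemble)), function(i)
    rmsd(place_ligand(ligand, ensemble[i, ]), ref), 0)
  quality_from_distance(d, thresholds)
}

quality_from_distance <- function(d, thresholds = c(acceptable = 10, medium = 5, high = 1)) {
  lev <- c("Incorrect", "Acceptable", "Medium", "High")
  q <- ifelse(d < thresholds[["high"]], "High",
              ifelse(d < thresholds[["medium"]], "Medium",
                     ifelse(d < thresholds[["acceptable"]], "Acceptable",
                            "Incorrect")))
  factor(q, levels = lev, ordered = TRUE)
}

#' Label clusters by the quality of their centers
#'
#' A cluster is positive (+1) when its center is of Acceptable quality or
#' better, negative (-1) otherwise.
#'
#' @param clusters A [greedy_cluster()] tibble.
#' @param quality Per-conformation quality (ordered factor from
#'   [quality_classify()]), indexed by the `center` column.
#' @return The tibble with added `quality` and `label` (+1/-1) columns.
#' @export
label_clusters <- function(clusters, quality) {
  q <- quality[clusters$center]
  dplyr::mutate(clusters, quality = q,
                label = ifelse(q >= "Acceptable", 1L, -1L))
}

#' Train a random-forest cluster ranker
#'
#' Repeats a grouped 60/40 split (all clusters of a complex stay on one
#' side), oversamples positive clusters in the training split to parity,
#' fits a random forest on the 9 features, and scores the held-out clusters
#' with the forest's positive-class probability. Reports the mean
#' out-of-sample AUC over the repeats and the forest refitted on all data
#' (used by [rank_and_enrich()] via its out-of-bag probabilities).
#'
#' @param features A data frame with a `complex` grouping column, feature
#'   columns, and a `label` column (+1/-1 or factor).
#' @param split_frac Fraction of complexes assigned to training (default
#'   0.6).
#' @param n_repeats Number of random splits (default 15).
#' @param seed Integer seed.
#' @param n_trees Trees per forest.
#' @return An object of class `ssdu_ranker`: list with `model` (a
#'   [randomForest::randomForest] fit on all data), `auc` (mean test AUC),
#'   `auc_runs` (per-repeat), `feature_names`.
#' @export
train_ranker <- function(features, split_frac = 0.6, n_repeats = 15,
                         seed = 1, n_trees = 500) {
  if (!"label" %in% names(features) || !"complex" %in% names(features))
    stop_ssdu("`features` needs `complex` and `label` columns")
  fn <- setdiff(names(features), c("complex", "label", "cluster", "center",
                                   "members", "quality", "probability"))
  X <- as.data.frame(features[fn])
  y <- factor(ifelse(as.numeric(as.character(features$label)) > 0, "pos", "neg"),
              levels = c("neg", "pos"))
  if (nlevels(droplevels(y)) < 2) stop_ssdu("both classes must be present")
  groups <- unique(features$complex)
  set.seed(as.integer(seed))
  aucs <- numeric(n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    ok <- FALSE
    for (try_i in 1:20) {
      tr_groups <- sample(groups, max(1, round(split_frac * length(groups))))
      tr <- features$complex %in% tr_groups
      if (nlevels(droplevels(y[tr])) == 2 && nlevels(droplevels(y[!tr])) == 2) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop_ssdu("could not find a split with both classes on both sides")
    idx <- which(tr)
    pos <- idx[y[idx] == "pos"]; neg <- idx[y[idx] == "neg"]
    # oversample the minority class (positives) to parity, training side only
    if (length(pos) < length(neg))
      idx <- c(idx, sample(pos, length(neg) - length(pos), replace = TRUE))
    fit <- randomForest::randomForest(X[idx, , drop = FALSE], y[idx],
                                      ntree = n_trees)
    prob <- predict(fit, X[!tr, , drop = FALSE], type = "prob")[, "pos"]
    aucs[rep_i] <- as.numeric(pROC::auc(response = y[!tr], predictor = prob,
                                        levels = c("neg", "pos"),
                                        direction = "<", quiet = TRUE))
  }
  full <- randomForest::randomForest(X, y, ntree = n_trees)
  structure(list(model = full, auc = mean(aucs), auc_runs = aucs,
                 feature_names = fn),
            class = "ssdu_ranker")
}

#' @export
print.ssdu_ranker <- function(x, ...) {
  cat("<ssdu_ranker> random forest on", length(x$feature_names),
      "features; mean out-of-sample AUC", round(x$auc, 3), "\n")
  invisible(x)
}

#' One-row summary of a trained ranker
#'
#' @param x An `ssdu_ranker`.
#' @param ... Unused.
#' @return A one-row tibble with the mean, sd, and range of the
#'   out-of-sample AUCs.
#' @export
#' @method glance ssdu_ranker
glance.ssdu_ranker <- function(x, ...) {
  tibble::tibble(mean_auc = x$auc, sd_auc = sd(x$auc_runs),
                 min_auc = min(x$auc_runs), max_auc = max(x$auc_runs),
                 n_repeats = length(x$auc_runs))
}

#' Rank clusters and count quality solutions among the top k
#'
#' Sorts clusters by decreasing positive-class probability (`method =
#' "probability"`) or by decreasing size (`method = "size"`, the baseline
#' used by docking servers that submit the largest clusters), then counts
#' the clusters of each quality tier or better among the top `k`.
#'
#' @param clusters A labeled cluster tibble with a `quality` column and,
#'   for the probability method, a `probability` column.
#' @param k Integer vector of list depths (default `c(3, 5, 10)`).
#' @param method `"probability"` or `"size"`.
#' @return A tibble with `k`, `tier` (`Acceptable`/`Medium`/`High`, meaning
#'   "or better"), and `count`.
#' @export
rank_and_enrich <- function(clusters, k = c(3, 5, 10), method = c("probability", "size")) {
  method <- match.arg(method)
  if (nrow(clusters) == 0) {
    return(tidyr::expand_grid(k = as.integer(k),
                              tier = factor(c("Acceptable", "Medium", "High"),
                                            levels = c("Acceptable", "Medium", "High"))) |>
             dplyr::mutate(count = 0L))
  }
  keyv <- if (method == "probability") clusters$probability else clusters$size
  if (is.null(keyv)) stop_ssdu("ranking key `", method, "` is missing")
  ord <- order(-keyv, clusters$cluster)
  q <- clusters$quality[ord]
  purrr::map_dfr(as.integer(k), function(kk) {
    top <- q[seq_len(min(kk, length(q)))]
    tibble::tibble(
      k = kk,
      tier = factor(c("Acceptable", "Medium", "High"),
                    levels = c("Acceptable", "Medium", "High")),
      count = c(sum(top >= "Acceptable"), sum(top >= "Medium"),
                sum(top >= "High")))
  })
}

#' Cluster a refined ensemble and build its ranking report
#'
#' Convenience wrapper for the whole post-processing stage of one complex:
#' greedy clustering of placement RMSDs, feature extraction, quality
#' labeling against a reference, and (optionally) probability scoring with a
#' trained ranker.
#'
#' @param ensemble A conformation tibble with energies.
#' @param ligand A centroid-relative [rigid_body()].
#' @param truth Reference conformation for quality labels (optional).
#' @param ranker An optional `ssdu_ranker`; adds out-of-bag/`predict`
#'   probabilities.
#' @param threshold,max_clusters,min_size Greedy clustering parameters.
#' @param thresholds Quality thresholds, see [quality_classify()].
#' @return A cluster tibble with features (and `quality`, `label`,
#'   `probability` when available).
#' @export
postprocess_ensemble <- function(ensemble, ligand, truth = NULL, ranker = NULL,
                                 threshold = 9, max_clusters = 30, min_size = 10,
                                 thresholds = c(acceptable = 10, medium = 5, high = 1)) {
  validate_ensemble(ensemble, require_energy = TRUE)
  D <- ensemble_rmsd_matrix(ensemble, ligand)
  cl <- greedy_cluster(D, threshold, max_clusters, min_size)
  if (nrow(cl) == 0) return(cl)
  feats <- purrr::map_dfr(seq_len(nrow(cl)), function(i) {
    mem <- cl$members[[i]]
    fv <- cluster_features(ensemble$energy[mem], D[mem, cl$center[i]])
    tibble::as_tibble(as.list(fv))
  })
  # the cluster table's `size` column already is feature 5
  out <- dplyr::bind_cols(cl, feats[setdiff(names(feats), "size")])
  if (!is.null(truth)) {
    qual <- quality_classify(ensemble[out$center, ], truth, ligand, thresholds)
    out <- dplyr::mutate(out, quality = qual,
                         label = ifelse(qual >= "Acceptable", 1L, -1L))
  }
  if (!is.null(ranker)) {
    X <- as.data.frame(out[ranker$feature_names])
    out$probability <- predict(ranker$model, X, type = "prob")[, "pos"]
  }
  out
}
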