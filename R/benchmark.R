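#' Synthetic ligand point cloud
#'
#' A deterministic centroid-relative point set standing in for ligand atoms
#' in synthetic experiments (placement RMSDs and quality tiers need atoms to
#' place). The cloud is an isotropic Gaussian of the given radius; it is a
#' synthetic object, not a protein structure.
#'
#' @param n_atoms Number of points.
#' @param radius Cloud scale in Angstrom.
#' @param seed Integer seed.
#' @return A [rigid_body()].
#' @export
synthetic_ligand <- function(n_atoms = 30, radius = 5, seed = 1) {
  set.seed(as.integer(seed))
  xyz <- matrix(rnorm(3 * n_atoms, 0, radius), n_atoms, 3)
  rigid_body(sweep(xyz, 2, colMeans(xyz)))
}

#' Specify a desk-scale refinement experiment
#'
#' Bundles everything [run_experiment()] needs: the landscape, ensemble
#' size and temperature, refinement parameters, quality thresholds, and the
#' replicate seeds.
#'
#' @param funnels A [funnel()] or list of funnels.
#' @param n_ensemble Decoy ensemble size per replicate.
#' @param temperature Decoy sampling temperature.
#' @param params An [ssdu_params()] object.
#' @param ruggedness,omega,outlier_fraction Landscape options, see
#'   [funnel_landscape()].
#' @param thresholds Quality-tier cuts, see [quality_classify()].
#' @param seeds Integer vector of replicate seeds (>= 1 replicate).
#' @param ligand Optional [rigid_body()]; default [synthetic_ligand()].
#' @return A list of class `ssdu_experiment`.
#' @export
experiment_spec <- function(funnels, n_ensemble = 300, temperature = 1,
                            params = ssdu_params(n_min = 30),
                            ruggedness = 0.3, omega = 3, outlier_fraction = 0.05,
                            thresholds = c(acceptable = 10, medium = 5, high = 1),
                            seeds = 1:3, ligand = NULL) {
  if (length(seeds) < 1) stop_ssdu("at least one replicate seed is required")
  stopifnot(inherits(params, "ssdu_params"))
  structure(list(funnels = funnels, n_ensemble = n_ensemble,
                 temperature = temperature, params = params,
                 ruggedness = ruggedness, omega = omega,
                 outlier_fraction = outlier_fraction,
                 thresholds = thresholds, seeds = as.integer(seeds),
                 ligand = ligand %||% synthetic_ligand()),
            class = "ssdu_experiment")
}

#' Run a refinement experiment and compare input vs refined quality
#'
#' For each replicate seed: build the landscape, simulate a decoy ensemble,
#' refine it, classify every input and refined conformation against the
#' landscape's ground truth, and count Acceptable-or-better, Medium-or-better
#' and High conformations before and after refinement. Improvement
#' percentages are aggregated both per-replicate-averaged and pooled (see
#' [compare_average_vs_total()]). Fully deterministic given the spec.
#'
#' @param spec An [experiment_spec()].
#' @return An object of class `ssdu_report`: list with `counts` (tibble:
#'   replicate, tier, before, after), `improvement` (tibble: tier, average
#'   and total percentages), `spec`.
#' @export
run_experiment <- function(spec) {
  stopifnot(inherits(spec, "ssdu_experiment"))
  tiers <- c("Acceptable", "Medium", "High")
  counts <- purrr::map_dfr(spec$seeds, function(sd_i) {
    model <- funnel_landscape(spec$funnels, ruggedness = spec$ruggedness,
                              omega = spec$omega,
                              outlier_fraction = spec$outlier_fraction,
                              seed = sd_i)
    gt <- ground_truth(model)
    dec <- simulate_decoys(model, spec$n_ensemble, spec$temperature, seed = sd_i)
    prm <- spec$params
    prm$seed <- child_seed(prm$seed, stream = sd_i)
    ref <- ssdu_refine(dec, model, prm)
    q_in <- quality_classify(dec, gt$psi, spec$ligand, spec$thresholds)
    q_out <- quality_classify(ref$ensemble, gt$psi, spec$ligand, spec$thresholds)
    tibble::tibble(
      replicate = sd_i,
      tier = factor(tiers, levels = tiers),
      before = vapply(tiers, function(t) sum(q_in >= t), 0L),
      after = vapply(tiers, function(t) sum(q_out >= t), 0L))
  })
  improvement <- counts |>
    dplyr::group_by(.data$tier) |>
    dplyr::group_modify(function(df, key) {
      # tiers with no solutions on either side stay in the report as NA
      tryCatch(compare_average_vs_total(df), error = function(e)
        tibble::tibble(average_pct = NA_real_, total_pct = NA_real_,
                       n_cases = 0L))
    }) |>
    dplyr::ungroup()
  structure(list(counts = counts, improvement = improvement, spec = spec),
            class = "ssdu_report")
}

#' @export
print.ssdu_report <- function(x, ...) {
  cat("<ssdu_report>", length(unique(x$counts$replicate)), "replicate(s)\n")
  print(as.data.frame(x$improvement))
  invisible(x)
}

#' Average vs pooled improvement percentages
#'
#' Two conventions for summarizing before/after counts over cases: the
#' *average* improvement is the mean over cases of the per-case percentage
#' change, while the *total* improvement is the percentage change of the
#' pooled counts. Cases with zero counts on both sides are removed; cases
#' with a zero "before" but nonzero "after" have an undefined ratio and are
#' excluded from the average, yet still contribute to the total.
#'
#' @param counts A data frame with `before` and `after` columns (one row per
#'   case).
#' @return A one-row tibble with `average_pct`, `total_pct`, `n_cases`
#'   (cases kept for the pooled figure).
#' @examples
#' compare_average_vs_total(data.frame(before = c(10, 20), after = c(15, 22)))
#' @export
compare_average_vs_total <- function(counts) {
  keep <- !(counts$before == 0 & counts$after == 0)
  b <- counts$before[keep]; a <- counts$after[keep]
  if (length(b) == 0) stop_ssdu("all cases have zero counts on both sides")
  avg <- mean(100 * (a[b > 0] - b[b > 0]) / b[b > 0])
  tot <- 100 * (sum(a) - sum(b)) / sum(b)
  tibble::tibble(average_pct = avg, total_pct = tot, n_cases = length(b))
}

#' Tidy an experiment report
#'
#' @param x An `ssdu_report`.
#' @param ... Unused.
#' @return The per-replicate counts tibble.
#' @export
#' @method tidy ssdu_report
tidy.ssdu_report <- function(x, ...) x$counts

#' One-row-per-tier summary of an experiment report
#'
#' @param x An `ssdu_report`.
#' @param ... Unused.
#' @return The improvement tibble (tier, average and pooled percentages).
#' @export
#' @method glance ssdu_report
glance.ssdu_report <- function(x, ...) x$improvement
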