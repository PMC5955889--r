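# Plain-text interchange: ensemble tables (TSV), run configuration and
# funnel specifications (YAML). Floats are serialized with 17 significant
# digits, the shortest representation that round-trips doubles exactly, so
# write-then-read is bit-identical.

#' Read and write ensemble tables
#'
#' The interchange format for conformational ensembles is a tab-separated
#' table with the exact header `r a b y1 y2 y3 energy`, one conformation per
#' row, C-locale floats. `write_ensemble()` uses round-trip-exact precision;
#' `read_ensemble(write_ensemble(x))` recovers `x` bit-for-bit.
#'
#' @param path File path.
#' @param ensemble A conformation tibble.
#' @return `read_ensemble()`: a validated conformation tibble.
#'   `write_ensemble()`: the input, invisibly.
#' @export
read_ensemble <- function(path) {
  if (!file.exists(path)) stop_ssdu("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 1) stop_ssdu("empty ensemble file: ", path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (!identical(header, ens_cols))
    stop_ssdu("bad header in ", path, ": expected 'r a b y1 y2 y3 energy', got '",
              paste(header, collapse = " "), "'")
  if (length(lines) == 1) stop_ssdu("no conformations in ", path)
  rows <- lapply(seq.int(2, length(lines)), function(i) {
    v <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(v) != 7)
      stop_ssdu("line ", i, " of ", path, ": expected 7 fields, found ", length(v))
    num <- suppressWarnings(as.double(v))
    bad <- which(is.na(num) & !(v %in% c("NA", "nan", "NaN")))
    if (length(bad) > 0)
      stop_ssdu("line ", i, " of ", path, ": non-numeric value '", v[bad[1]], "'")
    num
  })
  m <- do.call(rbind, rows)
  conformations(r = m[, 1], a = m[, 2], b = m[, 3], y1 = m[, 4],
                y2 = m[, 5], y3 = m[, 6], energy = m[, 7])
}

#' @rdname read_ensemble
#' @export
write_ensemble <- function(ensemble, path) {
  validate_ensemble(ensemble)
  m <- as.matrix(ensemble[ens_cols])
  body <- apply(m, 1, function(row)
    paste(ifelse(is.na(row), "NA", sprintf("%.17g", row)), collapse = "\t"))
  writeLines(c(paste(ens_cols, collapse = "\t"), body), path)
  invisible(ensemble)
}

config_defaults <- function() {
  list(K = 1000, eps = 1.0, n_min = 100, eta = 0.3, beta = 2, k_bar = NULL,
       max_iter = 3, degree = 4, permissive_dim = 3, temperature = 1,
       threshold = 9.0, max_clusters = 30, min_size = 10, seed = 1)
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills unset keys with the documented defaults
#' (the published protocol values where the protocol states them: `K = 1000`,
#' `eps = 1.0`, `n_min = 100`, `eta = 0.3`, `max_iter = 3`; clustering
#' `threshold = 9`, `max_clusters = 30`, `min_size = 10`), rejects unknown
#' keys, and validates every value against the module invariants. An empty
#' file yields all defaults.
#'
#' @param path Path to a YAML file.
#' @return A named list of class `ssdu_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_ssdu("no such file: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defs <- config_defaults()
  unknown <- setdiff(names(raw), names(defs))
  if (length(unknown) > 0)
    stop_ssdu("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defs, raw, keep.null = TRUE)
  validate_config(cfg)
  structure(cfg, class = "ssdu_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, key, msg) if (!ok) stop_ssdu("config `", key, "`: ", msg)
  chk(cfg$K >= 1, "K", "must be >= 1")
  chk(cfg$eps > 0, "eps", "must be positive")
  chk(cfg$n_min >= 1 && cfg$n_min <= cfg$K, "n_min", "must be in 1..K")
  chk(cfg$eta > 0 && cfg$eta <= 1, "eta", "must be in (0, 1]")
  chk(cfg$beta >= 0, "beta", "must be >= 0")
  chk(is.null(cfg$k_bar) || cfg$k_bar >= 1, "k_bar", "must be >= 1")
  chk(cfg$max_iter >= 1, "max_iter", "must be >= 1")
  chk(cfg$degree %in% c(2, 4, 6), "degree", "must be 2, 4 or 6")
  chk(cfg$permissive_dim %in% c(2, 3), "permissive_dim", "must be 2 or 3")
  chk(cfg$temperature > 0, "temperature", "must be positive")
  chk(cfg$threshold > 0, "threshold", "must be positive")
  chk(cfg$max_clusters >= 1, "max_clusters", "must be >= 1")
  chk(cfg$min_size >= 1, "min_size", "must be >= 1")
  invisible(cfg)
}

#' @rdname load_config
#' @param config A configuration list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 17)
  invisible(config)
}

#' Read and write funnel-landscape specifications
#'
#' Serializes the full synthetic-landscape specification (funnels with
#' centers, depths, eigenvalues, rotations; ruggedness, frequencies, outlier
#' fraction, seed) to YAML, so that a landscape can be rebuilt exactly.
#'
#' @param path File path.
#' @param model A [funnel_landscape()].
#' @return `read_funnel_landscape()`: a rebuilt [funnel_landscape()];
#'   `write_funnel_landscape()`: the model, invisibly.
#' @export
write_funnel_landscape <- function(model, path) {
  stopifnot(inherits(model, "funnel_landscape"))
  lst <- list(
    ruggedness = model$ruggedness, omega = as.list(model$omega),
    outlier_fraction = model$outlier_fraction, seed = model$seed,
    funnels = lapply(model$funnels, function(f) list(
      center = as.list(f$center), r0 = f$r0, depth = f$depth,
      lambda = as.list(f$lambda), k_r = f$k_r,
      rotation = as.list(as.vector(f$rotation)))))
  yaml::write_yaml(lst, path, precision = 17)
  invisible(model)
}

#' @rdname write_funnel_landscape
#' @export
read_funnel_landscape <- function(path) {
  if (!file.exists(path)) stop_ssdu("no such file: ", path)
  lst <- yaml::read_yaml(path)
  need <- c("ruggedness", "omega", "outlier_fraction", "seed", "funnels")
  miss <- setdiff(need, names(lst))
  if (length(miss) > 0)
    stop_ssdu("funnel spec is missing key(s): ", paste(miss, collapse = ", "))
  funnels <- lapply(lst$funnels, function(f) {
    lam <- unlist(f$lambda)
    funnel(center = unlist(f$center), r0 = f$r0, depth = f$depth,
           lambda_permissive = lam[1:3], lambda_restrictive = lam[4:5],
           k_r = f$k_r, rotation = matrix(unlist(f$rotation), 5, 5))
  })
  funnel_landscape(funnels, ruggedness = lst$ruggedness,
                   omega = unlist(lst$omega),
                   outlier_fraction = lst$outlier_fraction, seed = lst$seed)
}
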