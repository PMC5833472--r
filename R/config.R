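#' Default study configuration
#'
#' Thresholds and tuning constants for the whole pipeline. The filtering
#' defaults encode the standard QC-based cleaning rules for pooled-QC
#' untargeted studies: a feature must be detected in at least half of the
#' QC injections (`qc_presence_min_frac = 0.50`), its QC coefficient of
#' variation must not exceed 30% (`qc_cv_max = 0.30`), and it must be
#' present in at least 90% of the members of at least one study group
#' (`group_presence_min_frac = 0.90`). All hypothesis tests and gates run
#' at `alpha = 0.05`; feature selection uses Benjamini-Hochberg FDR at
#' `fdr_alpha = 0.05`.
#'
#' @return A list of class `study_config` with elements
#'   `qc_presence_min_frac`, `qc_cv_max`, `group_presence_min_frac`,
#'   `alpha`, `fdr_alpha`, `n_components` (PLS-DA predictive components),
#'   `n_orthogonal` (OPLS-DA orthogonal components), `folds`,
#'   `n_permutations`, `svm_cost`, `svm_gamma` (`NULL` = 1/n_features on
#'   standardized data), `seed`.
#' @export
default_config <- function() {
  structure(list(
    qc_presence_min_frac = 0.50,
    qc_cv_max = 0.30,
    group_presence_min_frac = 0.90,
    alpha = 0.05,
    fdr_alpha = 0.05,
    n_components = 2L,
    n_orthogonal = 1L,
    folds = 7L,
    n_permutations = 200L,
    svm_cost = 1,
    svm_gamma = NULL,
    seed = 1L
  ), class = "study_config")
}

validate_config <- function(config) {
  fr <- c("qc_presence_min_frac", "qc_cv_max", "group_presence_min_frac")
  for (f in fr) {
    v <- config[[f]]
    if (!is.numeric(v) || v <= 0 || v > 1)
      stop(f, " must lie in (0, 1]; got ", v)
  }
  for (f in c("alpha", "fdr_alpha")) {
    v <- config[[f]]
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop(f, " must lie in (0, 1); got ", v)
  }
  for (f in c("n_components", "folds"))
    if (config[[f]] < 1) stop(f, " must be >= 1")
  if (config$n_orthogonal < 0) stop("n_orthogonal must be >= 0")
  invisible(config)
}

#' Read or write a study configuration
#'
#' Configurations are stored as YAML; any subset of the fields of
#' [default_config()] may appear and overrides the default. Unknown keys
#' are rejected so typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return `read_config()` a validated `study_config`;
#'   `write_config()` the path, invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- default_config()
  unknown <- setdiff(names(vals), names(cfg))
  if (length(unknown)) stop("unknown config key: ", unknown[1])
  for (k in names(vals)) cfg[[k]] <- vals[[k]]
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @param config A `study_config`.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
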