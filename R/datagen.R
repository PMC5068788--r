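#' Describe a synthetic two-group LC-MS study design
#'
#' Collects the parameters of the synthetic feature-table generator into a
#' validated design object. The defaults emulate a small amniocentesis-style
#' case-control study: two groups of about a dozen subjects, 1400 log-normal
#' intensity features, a handful of class-discriminant markers, and a block of
#' features driven by a continuous metadata covariate that may itself be
#' associated with the class (a confounder).
#'
#' @param n_per_group samples per class; either a single count or a length-2
#'   vector `c(n_case, n_control)` for unbalanced designs.
#' @param n_features number of RT_mz features.
#' @param n_markers features carrying a pure class effect.
#' @param n_confounded features carrying a pure covariate effect.
#' @param n_both features carrying both effects.
#' @param marker_effect standardized between-class mean shift, in units of
#'   `noise_sd`, applied on the log-intensity scale.
#' @param confounder_effect slope of log-intensity on the standardized
#'   confounding covariate.
#' @param noise_sd residual SD of log intensities (natural-log scale).
#' @param confounder_class_assoc target correlation in `[0, 1)` between the
#'   continuous confounding covariate and class membership.
#' @param censor_quantile optional left-censoring switch: intensities below
#'   this quantile are floored at it (0 disables; default off).
#' @param seed integer seed making generation reproducible.
#' @return an object of class `"simulation_design"` (a validated list).
#' @seealso [simulate_dataset()]
#' @export
simulation_design <- function(n_per_group = 12, n_features = 1400,
                              n_markers = 20, n_confounded = 30, n_both = 0,
                              marker_effect = 1, confounder_effect = 1,
                              noise_sd = 0.5, confounder_class_assoc = 0,
                              censor_quantile = 0, seed = 1L) {
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 2L)
  counts <- c(n_per_group = min(n_per_group), n_features = n_features,
              n_markers = n_markers, n_confounded = n_confounded,
              n_both = n_both)
  for (nm in names(counts)) {
    if (length(counts[[nm]]) != 1L || is.na(counts[[nm]]) || counts[[nm]] < 0)
      stop("invalid design: '", nm, "' must be a nonnegative count")
  }
  if (any(n_per_group < 1)) stop("invalid design: 'n_per_group' must be >= 1")
  if (n_markers + n_confounded + n_both > n_features)
    stop("invalid design: 'n_markers' + 'n_confounded' + 'n_both' exceeds 'n_features'")
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("invalid design: 'noise_sd' must be > 0")
  if (!is.finite(confounder_class_assoc) ||
      confounder_class_assoc < 0 || confounder_class_assoc >= 1)
    stop("invalid design: 'confounder_class_assoc' must be in [0, 1)")
  if (censor_quantile < 0 || censor_quantile >= 1)
    stop("invalid design: 'censor_quantile' must be in [0, 1)")
  structure(list(n_per_group = as.integer(n_per_group),
                 n_features = as.integer(n_features),
                 n_markers = as.integer(n_markers),
                 n_confounded = as.integer(n_confounded),
                 n_both = as.integer(n_both),
                 marker_effect = marker_effect,
                 confounder_effect = confounder_effect,
                 noise_sd = noise_sd,
                 confounder_class_assoc = confounder_class_assoc,
                 censor_quantile = censor_quantile,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat("Synthetic LC-MS study design\n")
  cat(sprintf("  samples: %d + %d; features: %d (markers %d, confounded %d, both %d)\n",
              x$n_per_group[1], x$n_per_group[2], x$n_features,
              x$n_markers, x$n_confounded, x$n_both))
  cat(sprintf("  marker effect %.2f sd, confounder slope %.2f, noise sd %.2f, covariate-class r %.2f\n",
              x$marker_effect, x$confounder_effect, x$noise_sd,
              x$confounder_class_assoc))
  invisible(x)
}

# RT_mz feature names, e.g. "5.06_197.0808"
.feature_ids <- function(p) {
  rt <- sprintf("%.2f", stats::runif(p, 0.5, 10))
  mz <- sprintf("%.4f", stats::runif(p, 80, 800))
  ids <- paste0(rt, "_", mz)
  # collisions are vanishingly rare but must not produce duplicate ids
  while (anyDuplicated(ids)) {
    d <- which(duplicated(ids))
    ids[d] <- paste0(sprintf("%.2f", stats::runif(length(d), 0.5, 10)), "_",
                     sprintf("%.4f", stats::runif(length(d), 80, 800)))
  }
  ids
}

#' Simulate a two-group LC-MS feature table with metadata
#'
#' Draws a samples-by-features intensity table (strictly positive, log-normal),
#' a metadata table mirroring a typical amniocentesis study (maternal age, BMI,
#' previous miscarriages, four therapy flags, gestational age at amniocentesis,
#' newborn sex), and the ground truth of which features carry class and/or
#' covariate effects. Maternal age acts as the designated continuous
#' confounder: it is drawn with the requested correlation to class membership,
#' and confounded features regress on its standardized value.
#'
#' @param design a [simulation_design()] object.
#' @return a list with components `features` (numeric matrix, samples x
#'   features, RT_mz column names, sample ids as row names), `metadata`
#'   (data.frame with `sample_id`, `class` and covariates), and `truth` (list
#'   with `marker_ids`, `confounded_ids`, `both_ids`, `covariate_values`).
#' @examples
#' d <- simulation_design(n_per_group = 6, n_features = 50, n_markers = 5,
#'                        n_confounded = 5, seed = 7)
#' sim <- simulate_dataset(d)
#' dim(sim$features)
#' table(sim$metadata$class)
#' @export
simulate_dataset <- function(design) {
  if (!inherits(design, "simulation_design"))
    design <- do.call(simulation_design, design)
  set.seed(design$seed)
  n1 <- design$n_per_group[1]; n2 <- design$n_per_group[2]
  n <- n1 + n2; p <- design$n_features
  cls <- factor(rep(c("case", "control"), c(n1, n2)),
                levels = c("case", "control"))
  cls01 <- as.numeric(cls == "case")

  # designated confounder (maternal age): correlated with the class dummy
  rho <- design$confounder_class_assoc
  z_cls <- as.numeric(scale(cls01))
  conf_std <- rho * z_cls + sqrt(1 - rho^2) * stats::rnorm(n)
  age <- round(30 + 4 * conf_std, 1)

  meta <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    class = cls,
    maternal_age = age,
    bmi = round(stats::rnorm(n, 22.5, 2.5), 1),
    previous_miscarriages = stats::rpois(n, 0.35),
    nifedipine = stats::rbinom(n, 1, 0.10),
    betamethasone = stats::rbinom(n, 1, 0.65),
    atosiban = stats::rbinom(n, 1, 0.40),
    progesterone = stats::rbinom(n, 1, 0.15),
    gestational_age = sample(21:28, n, replace = TRUE),
    male = stats::rbinom(n, 1, 0.5),
    stringsAsFactors = FALSE
  )

  ids <- .feature_ids(p)
  idx_marker <- seq_len(design$n_markers)
  idx_conf <- seq_len(design$n_confounded) + design$n_markers
  idx_both <- seq_len(design$n_both) + design$n_markers + design$n_confounded

  baseline <- stats::rnorm(p, 7, 1.5)
  logX <- matrix(stats::rnorm(n * p, 0, design$noise_sd), n, p)
  logX <- sweep(logX, 2, baseline, "+")
  shift <- design$marker_effect * design$noise_sd
  for (j in c(idx_marker, idx_both))
    logX[, j] <- logX[, j] + shift * cls01
  for (j in c(idx_conf, idx_both))
    logX[, j] <- logX[, j] + design$confounder_effect * conf_std

  X <- exp(logX)
  if (design$censor_quantile > 0) {
    floor_val <- stats::quantile(X, design$censor_quantile)
    X[X < floor_val] <- floor_val
  }
  dimnames(X) <- list(meta$sample_id, ids)

  truth <- list(marker_ids = ids[idx_marker],
                confounded_ids = ids[idx_conf],
                both_ids = ids[idx_both],
                covariate_values = stats::setNames(
                  list(conf_std), "maternal_age_std"))
  list(features = X, metadata = meta, truth = truth)
}

#' Add an independent binary factor to a metadata table
#'
#' Appends one binary column drawn independently of class at a fixed
#' prevalence, e.g. to model an external clinical condition (such as
#' chorioamnionitis) whose correlation with the fitted predictive score is to
#' be checked afterwards.
#'
#' @param meta metadata data.frame as produced by [simulate_dataset()].
#' @param prevalence probability of a 1, strictly inside (0, 1).
#' @param seed integer seed.
#' @param name column name to add (default `"external_factor"`).
#' @return the metadata with one extra 0/1 column.
#' @export
inject_binary_factor <- function(meta, prevalence, seed = 1L,
                                 name = "external_factor") {
  if (!is.finite(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop("'prevalence' must be strictly inside (0, 1)")
  set.seed(as.integer(seed))
  meta[[name]] <- stats::rbinom(nrow(meta), 1, prevalence)
  meta
}
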