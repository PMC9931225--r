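#' Stratify a per-state statistic by time to death or discharge
#'
#' Groups states by outcome and by hours remaining until the terminal event
#' and averages a statistic over each stratum. The statistic is computed
#' from the state only — outcome and time to event are used solely for
#' grouping, never as model input.
#'
#' @param dataset a `transition_dataset`.
#' @param statistic_fn function taking a state matrix and returning one
#'   numeric value per row (e.g. the state value, an entropy, an
#'   uncertainty).
#' @param max_hours largest offset retained (1-hour bins up to 48 by
#'   default).
#' @return data frame `outcome`, `hours_to_event`, `mean`, `n`; empty strata
#'   are omitted.
#' @export
stratify_by_time_to_event <- function(dataset, statistic_fn, max_hours = 48) {
  keep <- dataset$time_to_event <= max_hours &
    dataset$outcome %in% c("survivor", "nonsurvivor")
  if (!any(keep)) return(data.frame(outcome = character(),
                                    hours_to_event = integer(),
                                    mean = numeric(), n = integer()))
  S <- dataset$states[keep, , drop = FALSE]
  val <- statistic_fn(S)
  stopifnot(length(val) == nrow(S))
  df <- data.frame(outcome = dataset$outcome[keep],
                   hours_to_event = dataset$time_to_event[keep], val = val)
  agg <- stats::aggregate(val ~ outcome + hours_to_event, df,
                          function(x) c(mean = mean(x), n = length(x)))
  out <- data.frame(outcome = agg$outcome, hours_to_event = agg$hours_to_event,
                    mean = agg$val[, "mean"], n = as.integer(agg$val[, "n"]))
  out[order(out$outcome, out$hours_to_event), ]
}

#' Feature-permutation importance of the Q function
#'
#' Permutes one feature column across states (a single seeded shuffle,
#' optionally repeated) and scores the feature by the mean absolute change
#' of the expected values across states and actions. Constant columns and
#' identity permutations score zero by construction.
#'
#' @param agent a `c51_agent` (anything with a [predict()] method returning
#'   `$Q`), or a plain function mapping a state matrix to a Q matrix.
#' @param states scaled state matrix (>= 2 rows).
#' @param feature_index column to permute, or `NULL` for all columns.
#' @param n_repeats permutation repetitions to average.
#' @param seed RNG seed for the shuffles.
#' @return named numeric vector of importance scores (one per requested
#'   feature).
#' @export
permutation_importance <- function(agent, states, feature_index = NULL,
                                   n_repeats = 1, seed = 1) {
  if (is.null(dim(states)) || nrow(states) < 2)
    stop("permutation_importance: need at least 2 states")
  cols <- feature_index %||% seq_len(ncol(states))
  if (any(cols < 1 | cols > ncol(states)))
    stop("permutation_importance: feature index out of range")
  qfun <- if (is.function(agent)) agent else function(S) predict(agent, S)$Q
  Q0 <- qfun(states)
  out <- with_seed(seed, vapply(cols, function(j) {
    mean(vapply(seq_len(n_repeats), function(r) {
      Sp <- states
      Sp[, j] <- Sp[sample.int(nrow(Sp)), j]
      mean(abs(qfun(Sp) - Q0))
    }, numeric(1)))
  }, numeric(1)))
  names(out) <- if (!is.null(colnames(states))) colnames(states)[cols]
                else paste0("f", cols)
  out
}

#' Mean uncertainty of low-density states under a Gaussian mixture
#'
#' Fits a Gaussian mixture model to the states and reports, for each
#' requested percentile `p`, the mean uncertainty over states whose
#' likelihood falls below the p-th percentile — rising uncertainty at low
#' density indicates the ensemble is unsure away from the data.
#'
#' @param states state matrix.
#' @param uncertainties per-state uncertainty (e.g. mean of
#'   [model_uncertainty()] across actions).
#' @param n_components mixture components.
#' @param percentiles likelihood percentiles to report.
#' @param seed RNG seed for the mixture initialization.
#' @return data frame `percentile`, `mean_u`, `n`.
#' @export
density_vs_uncertainty <- function(states, uncertainties, n_components = 10,
                                   percentiles = c(1, 5, 10, 25, 50, 100),
                                   seed = 1) {
  stopifnot(n_components >= 1, nrow(states) == length(uncertainties))
  dens <- with_seed(seed, {
    fit <- tryCatch(
      mclust::densityMclust(states, G = n_components, modelNames = "VVV",
                            verbose = FALSE, plot = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) {
      ## singular covariance: retry on a regularized (jittered) copy
      fit <- mclust::densityMclust(
        states + matrix(stats::rnorm(length(states), 0, 1e-3), nrow(states)),
        G = n_components, modelNames = "VVV", verbose = FALSE, plot = FALSE)
      message("density_vs_uncertainty: singular covariance; regularized retry")
    }
    fit$density
  })
  do.call(rbind, lapply(percentiles, function(p) {
    thr <- stats::quantile(dens, p / 100)
    sel <- dens <= thr
    data.frame(percentile = p, mean_u = mean(uncertainties[sel]),
               n = sum(sel))
  }))
}

#' Compare vasopressor prescription across policies
#'
#' For each time-to-death bin, reports the percentage of non-survivor
#' states at which each policy selects a vasopressor-containing action, and
#' binned vasopressor percentages against the identifiable cardiovascular
#' state `SV*R`, mean pressure and SOFA over all states. Policies are
#' functions mapping a state matrix to 0-based action indices; the
#' clinician column uses the actions actually taken.
#'
#' @param dataset a `transition_dataset`.
#' @param policies named list of `function(states) -> action` policies.
#' @param max_hours largest time-to-death offset.
#' @param n_bins bins for the physiological axes.
#' @return list of data frames: `vs_time_to_death`, `vs_feature` (long
#'   format over `sv_times_r`, `map`, `sofa`).
#' @export
policy_comparison_report <- function(dataset, policies, max_hours = 48,
                                     n_bins = 8) {
  stopifnot(length(policies) > 0, !is.null(names(policies)))
  S <- dataset$states
  acts <- lapply(policies, function(f) f(S))
  acts$clinician <- dataset$action
  vaso <- lapply(acts, action_has_vaso)

  ns <- dataset$outcome == "nonsurvivor" & dataset$time_to_event <= max_hours
  t2d <- dataset$time_to_event[ns]
  vs_time <- do.call(rbind, lapply(names(vaso), function(nm)
    data.frame(policy = nm, hours_to_death = sort(unique(t2d)),
               pct_vaso = 100 * tapply(vaso[[nm]][ns], t2d, mean),
               n = as.integer(table(t2d)))))

  ## physiological axes from the (unscaled) feature values
  mu <- dataset$scaling$mu; sd_ <- dataset$scaling$sd
  raw <- sweep(sweep(S, 2, sd_, "*"), 2, mu, "+")
  fx <- list(sv_times_r = raw[, "cv_SV"] * raw[, "cv_R"],
             map = raw[, "map"],
             sofa = raw[, "sofa"])
  vs_feature <- do.call(rbind, lapply(names(fx), function(feat) {
    br <- unique(stats::quantile(fx[[feat]], seq(0, 1, length.out = n_bins + 1)))
    bin <- cut(fx[[feat]], br, include.lowest = TRUE)
    do.call(rbind, lapply(names(vaso), function(nm)
      data.frame(feature = feat, policy = nm,
                 bin_mid = tapply(fx[[feat]], bin, mean),
                 pct_vaso = 100 * tapply(vaso[[nm]], bin, mean),
                 n = as.integer(table(bin)))))
  }))
  rownames(vs_time) <- rownames(vs_feature) <- NULL
  list(vs_time_to_death = vs_time, vs_feature = vs_feature)
}
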