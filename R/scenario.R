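#' Dietary transition scenario accounting
#'
#' Quantifies what happens when the whole adult population adopts the diet
#' of a target cluster: the percentage change in each daily environmental
#' impact relative to the sample average, the national annual impact delta
#' for a given adult population size, and the per-capita annual change in
#' food-group intakes.
#'
#' @name scenario
NULL

#' @describeIn scenario percentage change of a cluster mean relative to the
#'   sample mean: \code{100 * (cluster_mean - sample_mean) / sample_mean}.
#'   Scale-invariant in the common unit of the two means.
#' @param cluster_mean,sample_mean mean daily impact (same unit), sample
#'   mean strictly positive.
#' @export
percent_change <- function(cluster_mean, sample_mean) {
  if (any(sample_mean <= 0)) stop("sample_mean must be > 0")
  100 * (cluster_mean - sample_mean) / sample_mean
}

#' @describeIn scenario national annual extrapolation of a per-capita daily
#'   delta: \code{annual_delta = daily_delta * population * 365}, optionally
#'   expressed as a share of a national annual baseline in the same unit.
#' @param daily_delta_per_capita change in daily impact per person (unit U/day).
#' @param population number of persons (> 0).
#' @param national_baseline optional national annual total (same unit U/year)
#'   used to compute the share; non-positive baselines omit the share.
#' @param unit_scale factor converting person-days of U into the baseline's
#'   unit (e.g. \code{1e-9} from kg to Mt); default 1.
#' @export
national_extrapolation <- function(daily_delta_per_capita, population,
                                   national_baseline = NULL, unit_scale = 1) {
  if (population <= 0) stop("population must be > 0")
  annual <- daily_delta_per_capita * population * 365 * unit_scale
  share <- NULL
  if (!is.null(national_baseline)) {
    if (national_baseline > 0) share <- 100 * annual / national_baseline
  }
  list(annual_delta = annual, share_percent = share)
}

#' @describeIn scenario per-capita annual food-intake change in
#'   kg/capita/year from daily g/day means:
#'   \code{(cluster - sample) * 365 / 1000}.
#' @param cluster_g_day,sample_g_day named vectors of food-group mean intakes
#'   (g/day) with matching names.
#' @export
per_capita_food_change <- function(cluster_g_day, sample_g_day) {
  if (!identical(sort(names(cluster_g_day)), sort(names(sample_g_day))))
    stop("food-group vocabularies must match")
  sample_g_day <- sample_g_day[names(cluster_g_day)]
  (cluster_g_day - sample_g_day) * 365 / 1000
}

#' Full scenario report for a target cluster
#'
#' @param impacts per-person impact table (from \code{\link{person_impacts}},
#'   typically energy-adjusted means are supplied via \code{impact_means}
#'   instead).
#' @param labels cluster labels per person.
#' @param weights survey weights.
#' @param target target cluster label.
#' @param population adult population size for the national extrapolation.
#' @param national_baselines optional named list of annual national totals
#'   per impact (same units as \code{unit_scales} implies).
#' @param unit_scales named vector converting person-days of each impact to
#'   the baseline unit; defaults to kg -> Mt for \code{gwp} and identity
#'   otherwise.
#' @param food_group_means optional data.frame with columns
#'   \code{food_group}, \code{sample}, \code{cluster} (g/day) for the
#'   per-capita annual intake change table.
#' @return Object of class \code{"scenario_report"}: per-impact data.frame
#'   (sample and cluster means, percent change, annual delta, baseline
#'   share) and optional \code{food_changes}.
#' @export
scenario_report <- function(impacts, labels, weights = NULL, target,
                            population, national_baselines = NULL,
                            unit_scales = c(gwp = 1e-9, land_use = 1,
                                            marine_eutroph = 1,
                                            freshwater_eutroph = 1),
                            food_group_means = NULL) {
  imp_cols <- setdiff(names(impacts), "person_id")
  n <- nrow(impacts)
  w <- check_weights(weights, n)
  if (!target %in% labels) stop("target cluster not present in labels")
  sel <- labels == target
  rows <- lapply(imp_cols, function(cl) {
    sm <- wtd_mean(impacts[[cl]], w)
    cm <- wtd_mean(impacts[[cl]][sel], w[sel])
    ne <- national_extrapolation(cm - sm, population,
                                 national_baselines[[cl]],
                                 unit_scales[[cl]] %||% 1)
    data.frame(impact = cl, sample_mean = sm, cluster_mean = cm,
               percent_change = percent_change(cm, sm),
               annual_delta = ne$annual_delta,
               baseline_share_percent = ne$share_percent %||% NA_real_)
  })
  out <- list(target = target, population = population,
              impacts = do.call(rbind, rows))
  if (!is.null(food_group_means)) {
    ch <- per_capita_food_change(
      stats::setNames(food_group_means$cluster, food_group_means$food_group),
      stats::setNames(food_group_means$sample, food_group_means$food_group))
    out$food_changes <- data.frame(food_group = names(ch),
                                   kg_per_capita_year = unname(ch))
  }
  class(out) <- "scenario_report"
  out
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("Dietary transition scenario: population adopts cluster", x$target,
      "diet\n")
  df <- x$impacts
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-18s %8.3f -> %8.3f /day (%+.2f%%)",
                df$impact[i], df$sample_mean[i], df$cluster_mean[i],
                df$percent_change[i]))
    if (!is.na(df$baseline_share_percent[i]))
      cat(sprintf("  [%+.2f%% of national baseline]", df$baseline_share_percent[i]))
    cat("\n")
  }
  invisible(x)
}
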