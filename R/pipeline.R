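#' Run the full diet-cluster pipeline from one configuration
#'
#' Executes the stages in order: generate (or load) inputs, adapt impact
#' factors, compute per-person footprints, score diet quality, energy-adjust
#' and standardise, fit the weighted MFA, cluster the factor scores,
#' characterise the clusters, and quantify the transition scenario. The run
#' is deterministic given the seed; per-stage randomness derives from
#' \code{seed} through a fixed counter so a stage's draws do not depend on
#' how earlier stages consumed the stream.
#'
#' @param config a list or path to a YAML file. Recognised entries:
#'   \describe{
#'     \item{synthetic}{list passed to \code{\link{population_spec}} (e.g.
#'       \code{n_persons}); mutually exclusive with \code{inputs}.}
#'     \item{inputs}{list of file paths: \code{intakes}, \code{nutrients},
#'       \code{persons}, \code{factors}, \code{foods}.}
#'     \item{adapt}{optional list with \code{rules} (an
#'       \code{\link{adaptation_rules}} or YAML-able equivalent) — synthetic
#'       runs generate their own trade records.}
#'     \item{mfa}{list, e.g. \code{ndim} (default 5).}
#'     \item{clustering}{list: \code{k} (NULL = use suggestion),
#'       \code{k_range}.}
#'     \item{scenario}{list: \code{target} (NULL = cluster with highest mean
#'       diet-quality score), \code{population} (default 4.4e6),
#'       \code{national_baselines}.}
#'     \item{seed}{integer master seed (default 1).}
#'     \item{output_dir}{optional directory for stage CSVs and the JSON run
#'       manifest.}
#'   }
#' @return A list with every stage's output: \code{data}, \code{factors},
#'   \code{impacts}, \code{contributions}, \code{mbsds}, \code{mfa},
#'   \code{clusters}, \code{characterization}, \code{scenario},
#'   \code{manifest}.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config$synthetic) && !is.null(config$inputs))
    stop("config error: supply either 'synthetic' or 'inputs', not both")
  seed <- as.integer(config$seed %||% 1L)
  manifest <- list(seed = seed, started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = character(0), warnings = character(0))

  note <- function(stage) manifest$stages <<- c(manifest$stages, stage)

  # --- generate / load ------------------------------------------------------
  if (is.null(config$inputs)) {
    syn <- config$synthetic %||% list()
    syn$seed <- seed
    spec <- do.call(population_spec, syn)
    data <- generate_population(spec)
    registry <- spec$foods
    factors <- generate_impact_factors(spec)
    trade <- generate_trade_records(spec)
    note("generate")
  } else {
    inp <- config$inputs
    data <- list(intakes = read_intake_table(inp$intakes),
                 nutrients = read_nutrient_table(inp$nutrients),
                 persons = read_person_table(inp$persons))
    registry <- read_food_registry(inp$foods)
    factors <- read_impact_factor_table(inp$factors,
                                        per_kg = isTRUE(inp$factors_per_kg))
    trade <- if (!is.null(inp$trade)) read_delim_auto(inp$trade)
    spec <- NULL
    note("load")
  }
  chk <- join_consistency_check(data$intakes, data$persons, factors, registry)
  if (!chk$ok) stop("stage load: input tables are inconsistent; see join_consistency_check()")

  # --- adapt ----------------------------------------------------------------
  if (!is.null(config$adapt)) {
    rules <- config$adapt$rules
    if (!inherits(rules, "adaptation_rules"))
      rules <- adaptation_rules(
        electricity_intensity = as.data.frame(rules$electricity_intensity),
        electricity_share = rules$electricity_share %||% 0,
        feed_factor = unlist(rules$feed_factor %||%
                               c(gwp = 1, land_use = 1, marine_eutroph = 1,
                                 freshwater_eutroph = 1)),
        livestock_foods = rules$livestock_foods %||% character(0))
    factors <- apply_adaptation(factors, trade, rules, default_origin = "domestic")
    note("adapt")
  }

  persons <- data$persons[match(data$intakes$person_id, data$persons$person_id), ]
  w <- persons$survey_weight

  # --- footprint ------------------------------------------------------------
  impacts <- person_impacts(data$intakes, factors)
  note("footprint")

  # --- diet quality ---------------------------------------------------------
  mbsds <- compute_mbsds(data$intakes, data$nutrients, persons, registry,
                         config$bsds %||% bsds_config())
  note("score")

  # --- preprocess -----------------------------------------------------------
  energy <- data$nutrients$energy_kj
  nut_cols <- setdiff(names(data$nutrients), c("person_id", "energy_kj"))
  imp_cols <- c("gwp", "land_use", "marine_eutroph", "freshwater_eutroph")
  food_cols <- setdiff(names(data$intakes), "person_id")
  raw <- cbind(as.matrix(data$nutrients[, nut_cols]),
               as.matrix(impacts[, imp_cols]),
               as.matrix(data$intakes[, food_cols]))
  adj <- energy_adjust_residual(raw, energy, w)
  std <- scale_to_sd(adj, w)
  note("preprocess")

  # --- mfa ------------------------------------------------------------------
  ndim <- config$mfa$ndim %||% 5
  fit <- mfa(std[, c(nut_cols, imp_cols)],
             groups = list(nutrients = nut_cols, impacts = imp_cols),
             weights = w, ndim = ndim)
  sup_quant <- cbind(std[, food_cols, drop = FALSE],
                     mbsds = mbsds$mbsds, energy = energy,
                     plant_animal_ratio = data$nutrients$plant_protein_g /
                       pmax(data$nutrients$animal_protein_g, 1e-9),
                     age = persons$age, bmi = persons$bmi, waist = persons$waist)
  sup_cat <- persons[, intersect(c("sex", "education", "income", "municipality",
                                   "smoking", "physical_activity"),
                                 names(persons))]
  sup <- project_supplementary(fit, sup_quant, sup_cat)
  note("mfa")

  # --- clustering -----------------------------------------------------------
  sol <- diet_clusters(fit$scores, weights = w,
                       k = config$clustering$k %||% NULL,
                       k_range = config$clustering$k_range %||% 2:8)
  labels <- sol$labels
  note("cluster")

  # --- characterize ---------------------------------------------------------
  char_vars <- cbind(mbsds = mbsds$mbsds, impacts[, imp_cols])
  characterization <- list(
    vtests = lapply(as.data.frame(char_vars), vtest_quant, labels = labels,
                    weights = w),
    posthoc = lapply(as.data.frame(char_vars), kruskal_dunn, labels = labels),
    diagnostics = lapply(as.data.frame(char_vars), variance_normality_diag,
                         labels = labels),
    categorical = if ("municipality" %in% names(persons))
      chisq_pairwise_props(persons$municipality, labels)
  )
  note("characterize")

  # --- contributions & scenario --------------------------------------------
  contributions <- group_contributions(data$intakes, factors, registry,
                                       labels = labels, weights = w)
  target <- config$scenario$target %||% {
    ms <- vapply(seq_len(sol$k), function(k)
      wtd_mean(mbsds$mbsds[labels == k], w[labels == k]), numeric(1))
    which.max(ms)
  }
  scen <- scenario_report(
    impacts, labels, weights = w, target = target,
    population = config$scenario$population %||% 4.4e6,
    national_baselines = config$scenario$national_baselines)
  note("scenario")

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  manifest$n_persons <- nrow(data$intakes)
  manifest$k <- sol$k
  manifest$config_hash <- config_hash(config)

  out <- list(data = data, registry = registry, factors = factors,
              trade = trade, impacts = impacts, contributions = contributions,
              mbsds = mbsds, adjusted = std, mfa = fit, supplementary = sup,
              clusters = sol, characterization = characterization,
              scenario = scen, manifest = manifest)

  if (!is.null(config$output_dir)) write_run_outputs(out, config$output_dir)
  out
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  # drop environments/objects that do not serialise to YAML
  safe <- rapply(config, function(x) if (is.atomic(x)) x else NULL,
                 how = "replace")
  yaml::write_yaml(safe, f)
  unname(tools::md5sum(f))
}

write_run_outputs <- function(out, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_table(out$impacts, file.path(dir, "impacts.csv"))
  write_table(out$contributions, file.path(dir, "contributions.csv"))
  write_table(out$mbsds, file.path(dir, "mbsds.csv"))
  write_table(out$mfa$eigenvalues, file.path(dir, "eigenvalues.csv"))
  write_table(data.frame(person_id = out$data$intakes$person_id,
                         out$mfa$scores, cluster = out$clusters$labels,
                         check.names = FALSE),
              file.path(dir, "scores_labels.csv"))
  write_table(out$scenario$impacts, file.path(dir, "scenario.csv"))
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
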