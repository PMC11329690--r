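#' Synthetic study population with planted diet-cluster structure
#'
#' \code{population_spec()} builds the full parametric description of a
#' synthetic food-frequency study population: ingredient-level foods organised
#' into food groups, per-cluster log-normal intake distributions, a food x
#' nutrient composition matrix, energy densities, per-group impact-factor
#' ranges, a sociodemographic model and a non-response weight model. The
#' defaults emulate a national adult diet survey: 25 food groups over 81
#' ingredient-level foods, 46 nutrient variables, five latent diet clusters
#' with unequal shares (16/38/18/24/4 percent) ranging from a low-impact,
#' plant-leaning pattern to a high-impact, meat-heavy pattern, log-normally
#' distributed intakes (non-negative and right-skewed, as FFQ-derived intakes
#' are), energy correlated with total intake, and survey weights from a
#' non-response propensity model in age and sex, normalised to mean one.
#'
#' @param n_persons number of persons to generate.
#' @param cluster_proportions simplex vector of latent cluster shares.
#' @param sigma_log common log-scale intake SD (default 0.5).
#' @param separation multiplier applied to the log-scale deviations of each
#'   cluster's signature food groups from the overall mean; \code{1} keeps the
#'   survey-like overlapping clusters, larger values create well-separated
#'   benchmark populations (e.g. \code{separation = 3} guarantees pairwise
#'   log-mean separation of at least \code{3 * sigma_log} on five or more
#'   foods for every cluster pair).
#' @param nutrient_noise_sd log-scale SD of the multiplicative noise applied
#'   to generated nutrient intakes (energy is exact, see
#'   \code{\link{generate_population}}).
#' @param seed integer seed stored in the spec; all generators derive their
#'   randomness from it.
#' @return An object of class \code{"population_spec"}.
#' @seealso \code{\link{generate_population}},
#'   \code{\link{generate_impact_factors}}, \code{\link{generate_trade_records}}
#' @export
population_spec <- function(n_persons = 1000,
                            cluster_proportions = c(0.16, 0.38, 0.18, 0.24, 0.04),
                            sigma_log = 0.5,
                            separation = 1,
                            nutrient_noise_sd = 0.05,
                            seed = 1L) {
  if (abs(sum(cluster_proportions) - 1) > 1e-9)
    stop("cluster_proportions must sum to 1")
  if (any(cluster_proportions < 0)) stop("cluster_proportions must be non-negative")
  if (sigma_log < 0) stop("sigma_log must be >= 0")
  K <- length(cluster_proportions)

  groups <- food_group_vocabulary()
  foods <- build_food_registry(groups)
  F <- nrow(foods)

  # group-level mean daily intakes (g/day) for the whole sample, split evenly
  # across the foods of a group
  gmean <- group_mean_intakes()[foods$food_group]
  food_mean <- gmean / as.vector(table(foods$food_group)[foods$food_group])

  if (separation == 1) {
    mult <- cluster_group_multipliers(K)         # K x 25, survey-like overlap
  } else {
    # benchmark mode: orthogonal +/- signature design from a Sylvester
    # Hadamard matrix. Each cluster raises half the food groups by
    # exp(+separation * sigma_log / 2) and lowers the other half by the
    # inverse; any two clusters then differ in log-mean by exactly
    # separation * sigma_log on about half of all groups (far more than
    # five foods), while total intake stays roughly balanced.
    H <- matrix(1, 1, 1)
    while (nrow(H) < K + 1) H <- rbind(cbind(H, H), cbind(H, -H))
    S <- H[2:(K + 1), rep_len(seq_len(ncol(H)), length(groups)), drop = FALSE]
    mult <- exp(separation * sigma_log * S / 2)
    dimnames(mult) <- list(NULL, groups)
  }
  mult_f <- mult[, foods$food_group, drop = FALSE]  # K x F

  if (separation != 1) {
    # equalize expected total energy across clusters so the planted
    # structure is purely compositional: the energy-adjustment step then
    # preserves the between-cluster signal instead of absorbing it
    dens <- energy_densities()[foods$food_group]
    E_k <- as.vector(mult_f %*% (food_mean * dens))
    mult_f <- mult_f * (mean(E_k) / E_k)
  }

  # log-normal parameters: median of cluster k's intake of food f is
  # food_mean[f] * mult_f[k, f]
  log_mu <- log(outer(rep(1, K), food_mean) * mult_f)
  log_sigma <- matrix(sigma_log, K, F)

  spec <- list(
    n_persons = n_persons,
    cluster_proportions = cluster_proportions,
    K = K,
    foods = foods,
    log_mu = log_mu,
    log_sigma = log_sigma,
    energy_density = energy_densities()[foods$food_group],
    nutrient_composition = build_nutrient_composition(foods),
    impact_ranges = impact_factor_ranges(),
    socio = sociodemographic_model(K),
    weight_model = list(intercept = 0.4, age = -0.55, female = -0.5),
    nutrient_noise_sd = nutrient_noise_sd,
    separation = separation,
    seed = as.integer(seed)
  )
  if (nrow(spec$log_mu) != K)
    stop("cluster count inconsistent between proportions and intake parameters")
  class(spec) <- "population_spec"
  spec
}

#' @export
print.population_spec <- function(x, ...) {
  cat("Synthetic population spec:", x$n_persons, "persons,",
      x$K, "clusters (shares", paste(round(100 * x$cluster_proportions), collapse = "/"),
      "%),\n ", nrow(x$foods), "foods in", length(unique(x$foods$food_group)),
      "groups,", ncol(x$nutrient_composition), "nutrients, seed", x$seed, "\n")
  invisible(x)
}

food_group_vocabulary <- function() {
  c("Fruit and vegetables", "Berries", "Legumes", "Nuts and seeds", "Potatoes",
    "Grains", "Pork", "Beef", "Processed meat", "Poultry", "Game", "Offal",
    "Fish", "Eggs", "Liquid dairy", "Solid dairy", "Vegetable fat",
    "Animal fat", "Sweets", "Juices", "Coffee and tea", "Alcoholic beverages",
    "Non-alcoholic beverages", "Condiments", "Other")
}

build_food_registry <- function(groups) {
  # 25 groups x 3 foods = 75, plus one extra food in the first six groups = 81
  n_per <- rep(3L, length(groups))
  n_per[1:6] <- 4L
  food_group <- rep(groups, n_per)
  idx <- unlist(lapply(n_per, seq_len))
  slug <- gsub("[^a-z]+", "_", tolower(food_group))
  data.frame(
    food_id = sprintf("%s_%02d", slug, idx),
    name = sprintf("%s item %d", food_group, idx),
    food_group = food_group,
    stringsAsFactors = FALSE
  )
}

group_mean_intakes <- function() {
  # whole-sample mean g/day per group, survey-like magnitudes
  c("Fruit and vegetables" = 441, "Berries" = 40, "Legumes" = 3,
    "Nuts and seeds" = 7, "Potatoes" = 90, "Grains" = 127, "Pork" = 32,
    "Beef" = 29, "Processed meat" = 40, "Poultry" = 40, "Game" = 4,
    "Offal" = 2, "Fish" = 37, "Eggs" = 35, "Liquid dairy" = 446,
    "Solid dairy" = 62, "Vegetable fat" = 20, "Animal fat" = 12,
    "Sweets" = 26, "Juices" = 120, "Coffee and tea" = 600,
    "Alcoholic beverages" = 110, "Non-alcoholic beverages" = 250,
    "Condiments" = 25, "Other" = 30)
}

cluster_group_multipliers <- function(K) {
  groups <- food_group_vocabulary()
  m <- matrix(1, K, length(groups), dimnames = list(NULL, groups))
  if (K == 1L) return(m)
  # archetypes: 1 low-impact plant-leaning, 2 average, 3 "good compromise"
  # (high fruit/veg, fish, legumes, nuts; low red meat), 4 above-average
  # impact, 5 high-impact meat-heavy. Extra clusters (K > 5) stay average.
  set_row <- function(i, ...) {
    v <- c(...)
    m[i, names(v)] <<- v
  }
  if (K >= 1) set_row(1, "Pork" = 0.56, "Beef" = 0.48, "Processed meat" = 0.75,
                      "Poultry" = 0.50, "Fish" = 0.62, "Eggs" = 0.71,
                      "Liquid dairy" = 0.65, "Solid dairy" = 0.92,
                      "Grains" = 1.22, "Fruit and vegetables" = 0.88,
                      "Sweets" = 1.38, "Potatoes" = 1.1)
  if (K >= 2) set_row(2, "Fish" = 0.9, "Nuts and seeds" = 0.85,
                      "Fruit and vegetables" = 0.95)
  if (K >= 3) set_row(3, "Fruit and vegetables" = 1.47, "Legumes" = 1.67,
                      "Nuts and seeds" = 1.86, "Fish" = 1.73, "Berries" = 1.5,
                      "Beef" = 0.66, "Pork" = 0.72, "Processed meat" = 0.65,
                      "Liquid dairy" = 0.90, "Sweets" = 0.81,
                      "Vegetable fat" = 1.3, "Grains" = 1.1)
  if (K >= 4) set_row(4, "Pork" = 1.35, "Beef" = 1.3, "Processed meat" = 1.2,
                      "Poultry" = 1.25, "Liquid dairy" = 1.15, "Eggs" = 1.15)
  if (K >= 5) set_row(5, "Beef" = 2.69, "Pork" = 2.22, "Poultry" = 2.2,
                      "Processed meat" = 1.13, "Eggs" = 1.91,
                      "Liquid dairy" = 1.28, "Solid dairy" = 1.18,
                      "Fish" = 1.32, "Fruit and vegetables" = 1.15,
                      "Grains" = 0.61, "Sweets" = 0.5, "Nuts and seeds" = 1.0)
  m
}

energy_densities <- function() {
  # kJ per gram of food as consumed
  c("Fruit and vegetables" = 1.6, "Berries" = 1.9, "Legumes" = 4.0,
    "Nuts and seeds" = 25.0, "Potatoes" = 3.2, "Grains" = 10.0, "Pork" = 9.0,
    "Beef" = 8.0, "Processed meat" = 11.0, "Poultry" = 7.0, "Game" = 5.0,
    "Offal" = 5.5, "Fish" = 6.5, "Eggs" = 6.0, "Liquid dairy" = 2.3,
    "Solid dairy" = 13.0, "Vegetable fat" = 30.0, "Animal fat" = 30.0,
    "Sweets" = 18.0, "Juices" = 1.8, "Coffee and tea" = 0.1,
    "Alcoholic beverages" = 1.8, "Non-alcoholic beverages" = 0.8,
    "Condiments" = 4.0, "Other" = 3.0)
}

nutrient_names <- function() {
  c("energy_kj", "protein_g", "plant_protein_g", "animal_protein_g",
    "carb_g", "sucrose_g", "fiber_g", "fat_g", "sfa_g", "mufa_g", "pufa_g",
    "trans_fa_g", "cholesterol_mg", "alcohol_g", "starch_g", "lactose_g",
    "omega3_g", "omega6_g", "vitamin_a_ug", "vitamin_b1_mg", "vitamin_b2_mg",
    "niacin_mg", "vitamin_b6_mg", "folate_ug", "vitamin_b12_ug",
    "vitamin_c_mg", "vitamin_d_ug", "vitamin_e_mg", "vitamin_k_ug",
    "calcium_mg", "phosphorus_mg", "magnesium_mg", "iron_mg", "zinc_mg",
    "iodine_ug", "selenium_ug", "potassium_mg", "sodium_mg", "salt_g",
    "water_g", "carotenoids_ug", "copper_mg", "manganese_mg", "chromium_ug",
    "molybdenum_ug", "biotin_ug", "pantothenic_acid_mg")
}

animal_groups <- function() {
  c("Pork", "Beef", "Processed meat", "Poultry", "Game", "Offal", "Fish",
    "Eggs", "Liquid dairy", "Solid dairy", "Animal fat")
}

livestock_groups <- function() {
  c("Pork", "Beef", "Processed meat", "Poultry", "Game", "Offal", "Eggs",
    "Liquid dairy", "Solid dairy", "Animal fat")
}

build_nutrient_composition <- function(foods) {
  nn <- nutrient_names()
  F <- nrow(foods)
  comp <- matrix(0, F, length(nn), dimnames = list(foods$food_id, nn))
  g <- foods$food_group
  animal <- g %in% animal_groups()

  comp[, "energy_kj"] <- energy_densities()[g]
  prot <- c("Fruit and vegetables" = 0.012, "Berries" = 0.008, "Legumes" = 0.08,
            "Nuts and seeds" = 0.2, "Potatoes" = 0.02, "Grains" = 0.1,
            "Pork" = 0.2, "Beef" = 0.22, "Processed meat" = 0.15,
            "Poultry" = 0.22, "Game" = 0.22, "Offal" = 0.18, "Fish" = 0.2,
            "Eggs" = 0.125, "Liquid dairy" = 0.034, "Solid dairy" = 0.2,
            "Vegetable fat" = 0.001, "Animal fat" = 0.005, "Sweets" = 0.05,
            "Juices" = 0.005, "Coffee and tea" = 0.002,
            "Alcoholic beverages" = 0.004, "Non-alcoholic beverages" = 0.001,
            "Condiments" = 0.02, "Other" = 0.02)[g]
  comp[, "plant_protein_g"] <- ifelse(animal, 0, prot)
  comp[, "animal_protein_g"] <- ifelse(animal, prot, 0)
  comp[, "protein_g"] <- prot
  fat <- c("Fruit and vegetables" = 0.003, "Berries" = 0.005, "Legumes" = 0.01,
           "Nuts and seeds" = 0.55, "Potatoes" = 0.001, "Grains" = 0.02,
           "Pork" = 0.15, "Beef" = 0.12, "Processed meat" = 0.22,
           "Poultry" = 0.08, "Game" = 0.03, "Offal" = 0.05, "Fish" = 0.08,
           "Eggs" = 0.1, "Liquid dairy" = 0.015, "Solid dairy" = 0.28,
           "Vegetable fat" = 0.8, "Animal fat" = 0.82, "Sweets" = 0.2,
           "Juices" = 0.001, "Coffee and tea" = 0.001,
           "Alcoholic beverages" = 0, "Non-alcoholic beverages" = 0,
           "Condiments" = 0.05, "Other" = 0.02)[g]
  comp[, "fat_g"] <- fat
  plant_fat <- g %in% c("Vegetable fat", "Nuts and seeds", "Legumes",
                        "Grains", "Fruit and vegetables", "Berries")
  fish <- g == "Fish"
  comp[, "pufa_g"] <- fat * ifelse(plant_fat, 0.5, ifelse(fish, 0.35, 0.1))
  comp[, "sfa_g"] <- fat * ifelse(plant_fat, 0.12, 0.42)
  comp[, "mufa_g"] <- fat * ifelse(plant_fat, 0.35, 0.4)
  comp[, "trans_fa_g"] <- fat * ifelse(animal, 0.03, 0.005)
  comp[, "omega3_g"] <- fat * ifelse(fish, 0.25, ifelse(plant_fat, 0.05, 0.01))
  comp[, "omega6_g"] <- fat * ifelse(plant_fat, 0.4, 0.08)
  carb <- c("Fruit and vegetables" = 0.08, "Berries" = 0.08, "Legumes" = 0.12,
            "Nuts and seeds" = 0.1, "Potatoes" = 0.17, "Grains" = 0.45,
            "Pork" = 0, "Beef" = 0, "Processed meat" = 0.02, "Poultry" = 0,
            "Game" = 0, "Offal" = 0.01, "Fish" = 0, "Eggs" = 0.01,
            "Liquid dairy" = 0.05, "Solid dairy" = 0.03,
            "Vegetable fat" = 0.001, "Animal fat" = 0.001, "Sweets" = 0.6,
            "Juices" = 0.1, "Coffee and tea" = 0.003,
            "Alcoholic beverages" = 0.03, "Non-alcoholic beverages" = 0.05,
            "Condiments" = 0.1, "Other" = 0.05)[g]
  comp[, "carb_g"] <- carb
  comp[, "sucrose_g"] <- carb * ifelse(g %in% c("Sweets", "Juices",
                                                "Non-alcoholic beverages",
                                                "Berries"), 0.6, 0.1)
  comp[, "starch_g"] <- carb * ifelse(g %in% c("Grains", "Potatoes"), 0.8, 0.1)
  comp[, "lactose_g"] <- ifelse(g == "Liquid dairy", 0.045,
                                ifelse(g == "Solid dairy", 0.01, 0))
  comp[, "fiber_g"] <- c("Fruit and vegetables" = 0.025, "Berries" = 0.035,
                         "Legumes" = 0.06, "Nuts and seeds" = 0.07,
                         "Potatoes" = 0.015, "Grains" = 0.08)[g]
  comp[is.na(comp[, "fiber_g"]), "fiber_g"] <- 0.001
  comp[, "alcohol_g"] <- ifelse(g == "Alcoholic beverages", 0.05, 0)
  comp[, "cholesterol_mg"] <- ifelse(animal, 0.8, 0)
  comp[, "water_g"] <- pmax(0, 1 - prot - fat - carb - 0.02)

  # micronutrients: deterministic food-specific profiles (low-discrepancy
  # construction, no RNG) so the food -> nutrient map has nearly full rank
  # and distinct diets remain distinguishable after aggregation
  micro <- setdiff(nutrient_names(), colnames(comp)[colSums(abs(comp)) > 0])
  micro <- setdiff(micro, "energy_kj")
  base <- 0.002 + 0.01 * (as.integer(factor(g, levels = food_group_vocabulary())) %% 7)
  for (j in seq_along(micro)) {
    u <- (seq_len(F) * (j + 2) * 0.6180339887) %% 1   # golden-ratio sequence
    comp[, micro[j]] <- base * (0.2 + 1.6 * u) *
      (1 + 0.5 * (j %% 3)) * ifelse(animal, 1.4, 1.0)
  }

  # marker nutrients: each food group dominates one micronutrient column
  # (as in real composition tables: vitamin C <-> fruit, B12 <-> meat,
  # iodine <-> fish), so group-level intake differences remain identifiable
  # after foods are aggregated into nutrients
  groups_all <- food_group_vocabulary()
  gmean <- group_mean_intakes()
  for (gi in seq_along(groups_all)) {
    marker <- micro[(gi - 1L) %% length(micro) + 1L]
    sel <- g == groups_all[gi]
    comp[sel, marker] <- comp[sel, marker] + 300 / gmean[groups_all[gi]]
  }
  comp
}

impact_factor_ranges <- function() {
  # per-gram characterization-factor ranges by food group; units:
  # gwp kg CO2-eq/g, land m2 annual-crop-eq/g, marine kg N-eq/g,
  # freshwater kg P-eq/g. Animal-source groups carry the high GWP/land
  # ranges; fish carries the dominant freshwater-eutrophication range.
  groups <- food_group_vocabulary()
  lo <- matrix(0, length(groups), 4,
               dimnames = list(groups, c("gwp", "land_use", "marine_eutroph",
                                         "freshwater_eutroph")))
  hi <- lo
  set <- function(gr, gwp, land, mar, fresh) {
    lo[gr, ] <<- c(gwp[1], land[1], mar[1], fresh[1])
    hi[gr, ] <<- c(gwp[2], land[2], mar[2], fresh[2])
  }
  set("Beef",            c(28e-3, 36e-3), c(30e-3, 45e-3), c(25e-6, 35e-6), c(3.0e-6, 4.5e-6))
  set("Pork",            c(6e-3, 9e-3),   c(8e-3, 12e-3),  c(9e-6, 13e-6),  c(1.6e-6, 2.4e-6))
  set("Processed meat",  c(8e-3, 12e-3),  c(9e-3, 14e-3),  c(10e-6, 15e-6), c(1.8e-6, 2.6e-6))
  set("Poultry",         c(5e-3, 7e-3),   c(6e-3, 9e-3),   c(7e-6, 10e-6),  c(1.3e-6, 1.9e-6))
  set("Game",            c(2e-3, 4e-3),   c(1e-3, 3e-3),   c(2e-6, 4e-6),   c(0.3e-6, 0.6e-6))
  set("Offal",           c(6e-3, 10e-3),  c(6e-3, 10e-3),  c(6e-6, 9e-6),   c(1.0e-6, 1.6e-6))
  set("Fish",            c(4e-3, 7e-3),   c(1e-3, 2e-3),   c(14e-6, 20e-6), c(14e-6, 20e-6))
  set("Eggs",            c(3e-3, 5e-3),   c(4e-3, 6e-3),   c(5e-6, 8e-6),   c(0.9e-6, 1.4e-6))
  set("Liquid dairy",    c(1.4e-3, 2.0e-3), c(1.6e-3, 2.4e-3), c(2.2e-6, 3.2e-6), c(0.5e-6, 0.8e-6))
  set("Solid dairy",     c(8e-3, 12e-3),  c(9e-3, 13e-3),  c(11e-6, 16e-6), c(2.2e-6, 3.2e-6))
  set("Animal fat",      c(7e-3, 10e-3),  c(8e-3, 12e-3),  c(8e-6, 12e-6),  c(1.5e-6, 2.2e-6))
  set("Fruit and vegetables", c(0.6e-3, 1.2e-3), c(0.8e-3, 1.6e-3), c(1.0e-6, 2.0e-6), c(0.20e-6, 0.4e-6))
  set("Berries",         c(0.8e-3, 1.4e-3), c(1.0e-3, 2.0e-3), c(1.0e-6, 2.0e-6), c(0.2e-6, 0.4e-6))
  set("Legumes",         c(0.8e-3, 1.6e-3), c(2.0e-3, 4.0e-3), c(2.0e-6, 4.0e-6), c(0.3e-6, 0.6e-6))
  set("Nuts and seeds",  c(2e-3, 4e-3),   c(6e-3, 10e-3),  c(4e-6, 7e-6),   c(0.8e-6, 1.4e-6))
  set("Potatoes",        c(0.4e-3, 0.8e-3), c(0.8e-3, 1.4e-3), c(1.0e-6, 2.0e-6), c(0.2e-6, 0.4e-6))
  set("Grains",          c(1.2e-3, 2.0e-3), c(2.5e-3, 4.5e-3), c(3.0e-6, 5.0e-6), c(0.5e-6, 0.9e-6))
  set("Vegetable fat",   c(3e-3, 6e-3),   c(6e-3, 10e-3),  c(5e-6, 8e-6),   c(0.9e-6, 1.5e-6))
  set("Sweets",          c(2e-3, 4e-3),   c(3e-3, 5e-3),   c(3e-6, 5e-6),   c(0.6e-6, 1.0e-6))
  set("Juices",          c(0.6e-3, 1.2e-3), c(0.8e-3, 1.4e-3), c(1.0e-6, 2.0e-6), c(0.2e-6, 0.4e-6))
  set("Coffee and tea",  c(0.3e-3, 0.7e-3), c(0.4e-3, 0.8e-3), c(0.5e-6, 1.0e-6), c(0.1e-6, 0.2e-6))
  set("Alcoholic beverages", c(0.8e-3, 1.4e-3), c(1.0e-3, 1.8e-3), c(1.0e-6, 2.0e-6), c(0.2e-6, 0.4e-6))
  set("Non-alcoholic beverages", c(0.3e-3, 0.6e-3), c(0.3e-3, 0.6e-3), c(0.4e-6, 0.8e-6), c(0.1e-6, 0.2e-6))
  set("Condiments",      c(1e-3, 2e-3),   c(1e-3, 2e-3),   c(1.5e-6, 2.5e-6), c(0.3e-6, 0.5e-6))
  set("Other",           c(1e-3, 2e-3),   c(1e-3, 2e-3),   c(1.5e-6, 2.5e-6), c(0.3e-6, 0.5e-6))
  list(lo = lo, hi = hi)
}

sociodemographic_model <- function(K) {
  # per-cluster distributions; clusters beyond the five archetypes reuse the
  # average profile
  avg <- list(p_female = 0.56, age_mean = 56, age_sd = 14,
              educ = c(0.31, 0.45, 0.24), income_mean = 5.0,
              mun = c(urban = 0.67, `semi-urban` = 0.18, rural = 0.15),
              smoking = c(0.58, 0.2, 0.05, 0.17), pal = c(0.24, 0.5, 0.2, 0.06),
              bmi_mean = 27.4, bmi_sd = 4.5)
  profiles <- rep(list(avg), K)
  tweak <- function(i, ...) {
    v <- list(...)
    profiles[[i]][names(v)] <<- v
  }
  if (K >= 1) tweak(1, p_female = 0.53, age_mean = 61, income_mean = 4.5,
                    bmi_mean = 26.7, pal = c(0.29, 0.5, 0.16, 0.05))
  if (K >= 3) tweak(3, p_female = 0.66, age_mean = 61.4, income_mean = 5.0,
                    educ = c(0.22, 0.43, 0.35), bmi_mean = 27.0,
                    smoking = c(0.65, 0.2, 0.04, 0.11),
                    pal = c(0.14, 0.5, 0.27, 0.09))
  if (K >= 4) tweak(4, age_mean = 51, income_mean = 5.4, bmi_mean = 28.2)
  if (K >= 5) tweak(5, p_female = 0.35, age_mean = 48.6, income_mean = 5.8,
                    bmi_mean = 28.0, pal = c(0.21, 0.5, 0.21, 0.08))
  profiles
}

#' Generate a synthetic study population
#'
#' Draws cluster labels from the spec's cluster shares, per-person food
#' intakes log-normally within the assigned cluster, nutrient intakes as
#' intake times the food x nutrient composition matrix with multiplicative
#' log-normal noise, and sociodemographic attributes from the per-cluster
#' categorical model. Total energy intake is exactly
#' \code{sum(intake * energy_density)} (no noise), so energy is perfectly
#' consistent with the intake table. Survey weights come from the inverse of
#' a non-response propensity (logistic in age and sex) and are normalised to
#' mean one.
#'
#' @param spec a \code{\link{population_spec}}.
#' @return A list with elements \code{intakes}, \code{nutrients},
#'   \code{persons} (data.frames keyed by \code{person_id}) and \code{truth}
#'   (data.frame \code{person_id}, \code{cluster} — the planted labels).
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  if (nrow(spec$log_mu) != spec$K || length(spec$cluster_proportions) != spec$K)
    stop("cluster count inconsistent between proportions and intake parameters")
  set.seed(spec$seed)
  n <- spec$n_persons
  K <- spec$K
  F <- nrow(spec$foods)
  person_id <- sprintf("p%05d", seq_len(n))

  cluster <- sample.int(K, n, replace = TRUE, prob = spec$cluster_proportions)

  z <- matrix(stats::rnorm(n * F), n, F)
  intake <- exp(spec$log_mu[cluster, , drop = FALSE] +
                  z * spec$log_sigma[cluster, , drop = FALSE])
  colnames(intake) <- spec$foods$food_id

  comp <- spec$nutrient_composition
  nutrients <- intake %*% comp
  energy_exact <- as.vector(intake %*% spec$energy_density)
  if (spec$nutrient_noise_sd > 0) {
    noise <- exp(matrix(stats::rnorm(n * ncol(comp), 0, spec$nutrient_noise_sd),
                        n, ncol(comp)))
    nutrients <- nutrients * noise
  }
  nutrients[, "energy_kj"] <- energy_exact
  # keep the protein identity exact under noise
  nutrients[, "protein_g"] <- nutrients[, "plant_protein_g"] +
    nutrients[, "animal_protein_g"]

  persons <- draw_persons(spec, cluster, person_id)

  list(
    intakes = data.frame(person_id = person_id, intake, check.names = FALSE,
                         stringsAsFactors = FALSE),
    nutrients = data.frame(person_id = person_id, nutrients,
                           check.names = FALSE, stringsAsFactors = FALSE),
    persons = persons,
    truth = data.frame(person_id = person_id, cluster = cluster,
                       stringsAsFactors = FALSE)
  )
}

draw_persons <- function(spec, cluster, person_id) {
  n <- length(cluster)
  prof <- spec$socio
  draw_cat <- function(probs_by_cluster, levels) {
    vapply(cluster, function(k) {
      p <- probs_by_cluster[[k]]
      sample(levels, 1L, prob = p)
    }, levels[1])
  }
  p_female <- vapply(prof, `[[`, numeric(1), "p_female")[cluster]
  sex <- ifelse(stats::runif(n) < p_female, "female", "male")
  age <- pmin(95, pmax(18, stats::rnorm(n,
    vapply(prof, `[[`, numeric(1), "age_mean")[cluster],
    vapply(prof, `[[`, numeric(1), "age_sd")[cluster])))
  education <- draw_cat(lapply(prof, `[[`, "educ"), 1:3)
  income <- pmin(10L, pmax(1L, round(stats::rnorm(n,
    vapply(prof, `[[`, numeric(1), "income_mean")[cluster], 2))))
  municipality <- draw_cat(lapply(prof, `[[`, "mun"),
                           c("urban", "semi-urban", "rural"))
  smoking <- draw_cat(lapply(prof, `[[`, "smoking"), 1:4)
  physical_activity <- draw_cat(lapply(prof, `[[`, "pal"), 1:4)
  bmi <- stats::rnorm(n, vapply(prof, `[[`, numeric(1), "bmi_mean")[cluster],
                      vapply(prof, `[[`, numeric(1), "bmi_sd")[cluster])
  bmi <- pmax(16, bmi)
  waist <- 2.4 * bmi + ifelse(sex == "male", 28, 18) + stats::rnorm(n, 0, 4)

  wm <- spec$weight_model
  respond_p <- stats::plogis(wm$intercept + wm$age * (age - 55) / 20 +
                               wm$female * (sex == "female"))
  w <- 1 / respond_p
  survey_weight <- w / mean(w)

  data.frame(person_id = person_id, sex = sex, age = age,
             education = as.integer(education), income = as.integer(income),
             municipality = municipality, smoking = as.integer(smoking),
             physical_activity = as.integer(physical_activity),
             bmi = bmi, waist = waist, survey_weight = survey_weight,
             stringsAsFactors = FALSE)
}

#' Generate synthetic per-food impact factors
#'
#' Draws a per-gram characterization factor for each food uniformly within
#' its food group's configured range, for the four impact categories (GWP,
#' land use, marine and freshwater eutrophication). By construction the
#' animal-source groups carry higher GWP and land-use ranges than the plant
#' groups and fish carries the dominant freshwater-eutrophication range.
#'
#' @param spec a \code{\link{population_spec}}.
#' @return An impact factor table: \code{food_id}, four per-gram impact
#'   columns, \code{origin_flag = "domestic"}, \code{adapted = FALSE}.
#' @export
generate_impact_factors <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed + 1L)
  lo <- spec$impact_ranges$lo[spec$foods$food_group, , drop = FALSE]
  hi <- spec$impact_ranges$hi[spec$foods$food_group, , drop = FALSE]
  F <- nrow(lo)
  u <- matrix(stats::runif(F * 4), F, 4)
  fac <- lo + u * (hi - lo)
  out <- data.frame(food_id = spec$foods$food_id, fac,
                    origin_flag = "domestic", adapted = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[2:5] <- colnames(spec$impact_ranges$lo)
  out
}

#' Generate synthetic trade (import/export) records
#'
#' Produces annual import and export masses per food. Livestock-derived foods
#' and grains are export-leaning (ratio below one, hence classified domestic
#' under the ratio-greater-than-one rule); the remaining plant-based groups
#' are import-leaning.
#'
#' @param spec a \code{\link{population_spec}}.
#' @param import_leaning character vector of food groups whose foods get
#'   import/export ratio above one; defaults to the non-livestock,
#'   non-grain groups.
#' @return data.frame \code{food_id}, \code{import_t}, \code{export_t}.
#' @export
generate_trade_records <- function(spec, import_leaning = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed + 2L)
  if (is.null(import_leaning))
    import_leaning <- setdiff(food_group_vocabulary(),
                              c(livestock_groups(), "Grains", "Potatoes",
                                "Liquid dairy", "Solid dairy"))
  F <- nrow(spec$foods)
  base <- stats::runif(F, 1e3, 1e5)
  imp_lean <- spec$foods$food_group %in% import_leaning
  ratio <- ifelse(imp_lean, stats::runif(F, 1.5, 8), stats::runif(F, 0.05, 0.8))
  data.frame(food_id = spec$foods$food_id,
             import_t = base * ratio, export_t = base,
             stringsAsFactors = FALSE)
}
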