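#' Modified Baltic Sea Diet Score configuration
#'
#' The score has eight components. Seven are scored 0-3 by sex-specific
#' quartile of the component value (right-closed bins, ties fall to the lower
#' bin): fruits and berries, vegetables, whole-grain cereals, low-fat milk
#' and fish intakes and the PUFA/(SFA + trans) fatty-acid ratio score
#' upwards; red and processed meat scores in reverse (3 for the lowest
#' quartile). The eighth component awards 1 point when alcohol intake is at
#' or below a sex-specific threshold. The total therefore ranges 0-22.
#'
#' @param food_components named list of character vectors: for each
#'   quartile-scored food component, the food groups whose intakes are
#'   summed. Must contain \code{fruits_berries}, \code{vegetables},
#'   \code{whole_grains}, \code{low_fat_milk}, \code{fish},
#'   \code{red_processed_meat}.
#' @param pufa_vars,sfa_vars character vectors of nutrient columns forming
#'   the numerator and denominator of the fatty-acid ratio.
#' @param alcohol_var nutrient column with alcohol intake in g/day.
#' @param alcohol_threshold named vector \code{c(female = , male = )},
#'   g/day of pure ethanol at or below which the point is awarded.
#' @param cutpoints optional externally supplied cut points: a list
#'   \code{component -> list(male = c(q1, q2, q3), female = ...)}; when
#'   absent, sex-specific survey-weighted quartiles of the study population
#'   are used.
#' @return An object of class \code{"bsds_config"}.
#' @export
bsds_config <- function(food_components = list(
                          fruits_berries = c("Fruit and vegetables", "Berries"),
                          vegetables = "Fruit and vegetables",
                          whole_grains = "Grains",
                          low_fat_milk = "Liquid dairy",
                          fish = "Fish",
                          red_processed_meat = c("Beef", "Pork", "Processed meat")),
                        pufa_vars = "pufa_g",
                        sfa_vars = c("sfa_g", "trans_fa_g"),
                        alcohol_var = "alcohol_g",
                        alcohol_threshold = c(female = 10, male = 20),
                        cutpoints = NULL) {
  needed <- c("fruits_berries", "vegetables", "whole_grains", "low_fat_milk",
              "fish", "red_processed_meat")
  if (!all(needed %in% names(food_components)))
    stop("food_components must define: ", paste(needed, collapse = ", "))
  if (any(alcohol_threshold <= 0)) stop("alcohol thresholds must be > 0")
  structure(list(food_components = food_components, pufa_vars = pufa_vars,
                 sfa_vars = sfa_vars, alcohol_var = alcohol_var,
                 alcohol_threshold = alcohol_threshold, cutpoints = cutpoints),
            class = "bsds_config")
}

quartile_points <- function(x, q) {
  # right-closed bins: x <= q1 -> 0, (q1, q2] -> 1, (q2, q3] -> 2, > q3 -> 3
  vapply(x, function(v) sum(v > q), numeric(1))
}

#' Compute the modified Baltic Sea Diet Score per person
#'
#' @param intakes intake table (g/day per food).
#' @param nutrients nutrient table (must contain the configured fatty-acid
#'   and alcohol columns).
#' @param persons person table (for \code{sex} and \code{survey_weight}).
#' @param registry food registry mapping food_id to food_group.
#' @param config a \code{\link{bsds_config}}.
#' @return data.frame with \code{person_id}, one 0-3 column per quartile
#'   component, \code{alcohol} (0/1) and the integer \code{mbsds} total in
#'   \code{[0, 22]}.
#' @export
compute_mbsds <- function(intakes, nutrients, persons, registry,
                          config = bsds_config()) {
  stopifnot(inherits(config, "bsds_config"))
  n <- nrow(intakes)
  ord_p <- match(intakes$person_id, persons$person_id)
  ord_n <- match(intakes$person_id, nutrients$person_id)
  if (anyNA(ord_p) || anyNA(ord_n))
    stop("persons/nutrients missing for some intake rows")
  sex <- persons$sex[ord_p]
  w <- persons$survey_weight[ord_p]

  foods <- setdiff(names(intakes), "person_id")
  fg <- registry$food_group[match(foods, registry$food_id)]

  comp_value <- function(groups_wanted) {
    cols <- foods[fg %in% groups_wanted]
    if (!length(cols)) stop("no foods found for component groups: ",
                            paste(groups_wanted, collapse = ", "))
    rowSums(intakes[, cols, drop = FALSE])
  }
  values <- lapply(config$food_components, comp_value)
  num <- rowSums(nutrients[ord_n, config$pufa_vars, drop = FALSE])
  den <- rowSums(nutrients[ord_n, config$sfa_vars, drop = FALSE])
  values$pufa_ratio <- num / pmax(den, .Machine$double.eps)

  score_component <- function(x, reversed) {
    pts <- numeric(n)
    for (s in unique(sex)) {
      rows <- sex == s
      q <- config$cutpoints[[cur_comp]][[s]] %||%
        wtd_quantile(x[rows], w[rows], c(0.25, 0.5, 0.75))
      if (length(unique(q)) == 1L && stats::var(x[rows]) < .Machine$double.eps)
        stop("component '", cur_comp, "' is constant within sex '", s,
             "'; quartiles undefined - supply external cut points")
      pts[rows] <- quartile_points(x[rows], q)
    }
    if (reversed) 3 - pts else pts
  }

  out <- data.frame(person_id = intakes$person_id, stringsAsFactors = FALSE)
  for (cur_comp in names(values)) {
    out[[cur_comp]] <- score_component(values[[cur_comp]],
                                       reversed = cur_comp == "red_processed_meat")
  }
  alc <- nutrients[[config$alcohol_var]][ord_n]
  thr <- config$alcohol_threshold[sex]
  out$alcohol <- as.numeric(alc <= thr)
  out$mbsds <- rowSums(out[, setdiff(names(out), "person_id")])
  stopifnot(all(out$mbsds >= 0 & out$mbsds <= 22))
  out
}
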