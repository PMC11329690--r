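#' Per-person daily environmental impacts
#'
#' Multiplies the amount of each food consumed (g/person/day) by its per-gram
#' characterization factor and sums over foods, for the four impact
#' categories. GWP is reported in kg CO2-eq/day and land use in m2
#' annual-crop-eq/day; the two eutrophication categories, whose factors are
#' stored in kg N-eq and kg P-eq per gram, are reported in g/day.
#'
#' @param intakes intake table (\code{person_id} plus food columns, g/day).
#' @param factors impact factor table (per gram).
#' @param on_missing_factor \code{"error"} (default) or \code{"drop"}: what to
#'   do when a consumed food has no factor row.
#' @return data.frame \code{person_id}, \code{gwp}, \code{land_use},
#'   \code{marine_eutroph}, \code{freshwater_eutroph}.
#' @export
person_impacts <- function(intakes, factors, on_missing_factor = c("error", "drop")) {
  on_missing_factor <- match.arg(on_missing_factor)
  foods <- setdiff(names(intakes), "person_id")
  missing <- setdiff(foods, factors$food_id)
  if (length(missing)) {
    if (on_missing_factor == "error")
      stop("foods without impact factors: ", paste(missing, collapse = ", "))
    warning("dropping foods without impact factors: ",
            paste(missing, collapse = ", "))
    foods <- setdiff(foods, missing)
  }
  X <- as.matrix(intakes[, foods, drop = FALSE])
  idx <- match(foods, factors$food_id)
  Fm <- as.matrix(factors[idx, c("gwp", "land_use", "marine_eutroph",
                                 "freshwater_eutroph")])
  imp <- X %*% Fm
  # eutrophication in g/day (factors are kg-eq per g)
  imp[, "marine_eutroph"] <- imp[, "marine_eutroph"] * 1000
  imp[, "freshwater_eutroph"] <- imp[, "freshwater_eutroph"] * 1000
  data.frame(person_id = intakes$person_id, imp, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Food-group contribution decomposition of impacts
#'
#' Survey-weighted mean daily contribution of each food group to each impact
#' category, per cluster and for the whole sample (cluster label
#' \code{"ALL"}). Contributions within a cluster and impact sum exactly to
#' that cluster's mean total impact.
#'
#' @param intakes intake table.
#' @param factors impact factor table (per gram).
#' @param groups food registry (or any data.frame with \code{food_id},
#'   \code{food_group}).
#' @param labels cluster label per person (same order as \code{intakes}), or
#'   \code{NULL} for the sample-level decomposition only.
#' @param weights survey weights (default unit).
#' @return data.frame \code{cluster}, \code{food_group}, \code{impact},
#'   \code{contribution} (mean units/day, eutrophication in g/day).
#' @export
group_contributions <- function(intakes, factors, groups, labels = NULL,
                                weights = NULL) {
  foods <- setdiff(names(intakes), "person_id")
  n <- nrow(intakes)
  w <- check_weights(weights, n)
  if (!is.null(labels) && length(labels) != n)
    stop("every person needs a cluster label")
  idx <- match(foods, factors$food_id)
  if (anyNA(idx)) stop("foods without impact factors: ",
                       paste(foods[is.na(idx)], collapse = ", "))
  gidx <- match(foods, groups$food_id)
  if (anyNA(gidx)) stop("foods not in registry: ",
                        paste(foods[is.na(gidx)], collapse = ", "))
  fg <- groups$food_group[gidx]
  X <- as.matrix(intakes[, foods, drop = FALSE])
  impacts <- c("gwp", "land_use", "marine_eutroph", "freshwater_eutroph")
  scale <- c(gwp = 1, land_use = 1, marine_eutroph = 1000,
             freshwater_eutroph = 1000)

  per_group <- function(rows) {
    out <- expand.grid(food_group = sort(unique(fg)), impact = impacts,
                       stringsAsFactors = FALSE)
    out$contribution <- NA_real_
    for (imp in impacts) {
      contrib <- sweep(X[rows, , drop = FALSE], 2, factors[[imp]][idx] * scale[imp], `*`)
      by_group <- rowsum(t(contrib), fg)   # group x person
      m <- as.vector(by_group %*% w[rows]) / sum(w[rows])
      out$contribution[out$impact == imp] <-
        m[match(out$food_group[out$impact == imp], rownames(by_group))]
    }
    out
  }
  res <- cbind(cluster = "ALL", per_group(seq_len(n)))
  if (!is.null(labels)) {
    for (k in sort(unique(labels))) {
      res <- rbind(res, cbind(cluster = as.character(k),
                              per_group(which(labels == k))))
    }
  }
  res
}
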