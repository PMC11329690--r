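#' Country adaptation of impact factors
#'
#' Foods consumed in the target country are classified as imported or
#' domestically produced from trade statistics: a food whose import/export
#' mass ratio exceeds one is treated as imported (and gets the European
#' electricity mix); a ratio of one or below means domestically produced
#' (and gets the domestic mix). The adaptation itself is applied at the
#' characterized-impact level: an additive electricity-mix correction
#' (replace the share of the life-cycle impact attributable to electricity,
#' valued at the source mix, with the same share valued at the target mix)
#' plus a multiplicative feed-origin correction for livestock foods.
#'
#' @name lci-adapt
NULL

#' @describeIn lci-adapt import/export mass ratio of one trade record;
#'   \code{import/export}, \code{+Inf} when only imports exist, and 0 (hence
#'   domestic) when both masses are zero.
#' @param import_t,export_t annual import and export masses (same unit).
#' @export
import_export_ratio <- function(import_t, export_t) {
  if (any(import_t < 0) || any(export_t < 0))
    stop("trade masses must be non-negative")
  r <- ifelse(export_t == 0,
              ifelse(import_t > 0, Inf, 0),
              import_t / export_t)
  r
}

#' @describeIn lci-adapt origin classification from a ratio: strictly greater
#'   than one is \code{"imported"}, otherwise \code{"domestic"} (the boundary
#'   ratio of exactly one is domestic).
#' @param ratio non-negative ratio (may be \code{Inf}).
#' @export
classify_origin <- function(ratio) {
  if (any(is.na(ratio)) || any(ratio < 0)) stop("ratio must be >= 0")
  ifelse(ratio > 1, "imported", "domestic")
}

#' Adaptation rule set
#'
#' @param electricity_intensity data.frame with columns \code{impact},
#'   \code{source}, \code{european}, \code{domestic}: per-impact electricity
#'   intensities (impact units per unit electricity) of the inventory's
#'   source mix and of the two candidate target mixes.
#' @param electricity_share named numeric vector (by \code{food_id}) or a
#'   single number in \code{[0, 1]}: share of each food's life-cycle impact
#'   attributable to electricity use.
#' @param feed_factor named numeric vector (by impact category) of
#'   multiplicative corrections applied to livestock foods when feed is
#'   switched to domestic production; defaults to 1 (no change).
#' @param livestock_foods character vector of food_ids subject to the feed
#'   correction.
#' @return An object of class \code{"adaptation_rules"}.
#' @export
adaptation_rules <- function(electricity_intensity,
                             electricity_share = 0,
                             feed_factor = c(gwp = 1, land_use = 1,
                                             marine_eutroph = 1,
                                             freshwater_eutroph = 1),
                             livestock_foods = character(0)) {
  stopifnot(all(c("impact", "source", "european", "domestic") %in%
                  names(electricity_intensity)))
  if (any(electricity_share < 0 | electricity_share > 1))
    stop("electricity shares must lie in [0, 1]")
  if (any(unlist(electricity_intensity[, c("source", "european", "domestic")]) < 0))
    stop("electricity intensities must be >= 0")
  structure(list(electricity_intensity = electricity_intensity,
                 electricity_share = electricity_share,
                 feed_factor = feed_factor,
                 livestock_foods = livestock_foods),
            class = "adaptation_rules")
}

#' Apply country-adaptation rules to an impact factor table
#'
#' For each food and impact category the adapted factor is
#' \code{base - share * intensity_source + share * intensity_target}, where
#' the target intensity is the European mix for imported foods and the
#' domestic mix for domestically produced foods (origin from
#' \code{\link{classify_origin}} on the trade ratio). Livestock foods are
#' additionally multiplied by the per-impact feed factor. Factors that would
#' become negative are clipped at zero with a warning; the \code{adapted}
#' flag and \code{origin_flag} are set on the returned table.
#'
#' @param base impact factor table (per gram).
#' @param trade trade record table (\code{food_id}, \code{import_t},
#'   \code{export_t}); every food in \code{base} must appear unless
#'   \code{default_origin} is given.
#' @param rules an \code{\link{adaptation_rules}} object.
#' @param default_origin optional \code{"imported"}/\code{"domestic"} used for
#'   foods without a trade record.
#' @return The adapted impact factor table.
#' @export
apply_adaptation <- function(base, trade, rules, default_origin = NULL) {
  stopifnot(inherits(rules, "adaptation_rules"))
  impacts <- c("gwp", "land_use", "marine_eutroph", "freshwater_eutroph")
  missing_trade <- setdiff(base$food_id, trade$food_id)
  if (length(missing_trade) && is.null(default_origin))
    stop("foods without trade record and no default origin: ",
         paste(missing_trade, collapse = ", "))

  idx <- match(base$food_id, trade$food_id)
  origin <- rep(default_origin %||% "domestic", nrow(base))
  has <- !is.na(idx)
  origin[has] <- classify_origin(
    import_export_ratio(trade$import_t[idx[has]], trade$export_t[idx[has]]))

  share <- rules$electricity_share
  if (!is.null(names(share))) {
    share <- share[base$food_id]
    share[is.na(share)] <- 0
  } else {
    share <- rep(share, nrow(base))
  }

  out <- base
  clipped <- FALSE
  for (imp in impacts) {
    row <- rules$electricity_intensity[rules$electricity_intensity$impact == imp, ]
    if (!nrow(row)) next
    target <- ifelse(origin == "imported", row$european[1], row$domestic[1])
    adapted <- base[[imp]] - share * row$source[1] + share * target
    feed <- rules$feed_factor[[imp]] %||% 1
    is_livestock <- base$food_id %in% rules$livestock_foods
    adapted[is_livestock] <- adapted[is_livestock] * feed
    if (any(adapted < 0)) {
      clipped <- TRUE
      adapted[adapted < 0] <- 0
    }
    out[[imp]] <- adapted
  }
  if (clipped)
    warning("some adapted factors were negative and were clipped to 0")
  out$origin_flag <- origin
  out$adapted <- TRUE
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
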