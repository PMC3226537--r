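# Costing: unit prices, price-year indexation and per-child aggregation.
#
# The analysis takes the healthcare-system perspective.  Two cost
# categories exist: direct medical items (consultations, admissions,
# diagnostic tests, medication) accrue to every child, and intervention
# items (nurse visits, mite-impermeable covers, hypoallergenic formula,
# brochures) accrue only to children who received prevention.  All prices
# are indexed to a common target year (default 2009) before valuation.

#' Unit price table
#'
#' @param items data frame with columns `item` (character), `unit_price`
#'   (EUR, >= 0), `price_year` (integer), `category`
#'   (`"direct_medical"` or `"intervention"`).
#' @param index_factors named numeric vector: cumulative inflation factor
#'   from each price year to the target year (all > 0). Years absent from
#'   the map cannot be indexed. The target year itself defaults to
#'   factor 1 if not listed.
#' @param target_year integer, default 2009.
#' @return An object of class `unit_price_table`.
#' @export
#' @examples
#' unit_price_table(
#'   data.frame(item = "gp_visit", unit_price = 28, price_year = 2009,
#'              category = "direct_medical"))
unit_price_table <- function(items,
                             index_factors = NULL,
                             target_year = 2009L) {
  required <- c("item", "unit_price", "price_year", "category")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols)) {
    abort("price table is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  items <- as.data.frame(items)[required]
  if (anyDuplicated(items$item)) {
    abort("duplicate cost item(s): %s",
          paste(unique(items$item[duplicated(items$item)]), collapse = ", "))
  }
  check_nonneg(items$unit_price, "unit_price")
  bad <- !items$category %in% c("direct_medical", "intervention")
  if (any(bad)) {
    abort("unknown category for item(s): %s",
          paste(items$item[bad], collapse = ", "))
  }
  if (is.null(index_factors)) index_factors <- numeric(0)
  if (length(index_factors) && (is.null(names(index_factors)) ||
                                any(!is.finite(index_factors)) ||
                                any(index_factors <= 0))) {
    abort("'index_factors' must be a named numeric vector of positive factors")
  }
  tgt <- as.character(target_year)
  if (!tgt %in% names(index_factors)) {
    index_factors[tgt] <- 1.0
  }
  structure(
    list(items = items,
         index_factors = index_factors,
         target_year = as.integer(target_year)),
    class = "unit_price_table"
  )
}

#' Index a price to the table's target year
#'
#' @param price EUR amount in `price_year` terms.
#' @param price_year the year the price was expressed in.
#' @param table a [unit_price_table()].
#' @return EUR in target-year terms, rounded half-up to cents.
#' @export
index_price <- function(price, price_year, table) {
  stopifnot(inherits(table, "unit_price_table"))
  check_nonneg(price, "price")
  key <- as.character(price_year)
  if (!key %in% names(table$index_factors)) {
    abort("no index factor for price year %s (target year %d)",
          key, table$target_year)
  }
  round_half_up(price * table$index_factors[[key]], 2)
}

# indexed price per item, as a named vector (internal)
indexed_prices <- function(table) {
  vapply(seq_len(nrow(table$items)), function(i) {
    index_price(table$items$unit_price[i], table$items$price_year[i], table)
  }, numeric(1)) |>
    stats::setNames(table$items$item)
}

# names of the ru_* columns of a cohort, stripped of the prefix
resource_items <- function(cohort) {
  sub("^ru_", "", grep("^ru_", names(cohort), value = TRUE))
}

#' Total cost of one child's resource use
#'
#' Sums quantity times target-year indexed unit price over the child's
#' resource-use map. Intervention-category items are counted only when
#' `include_intervention` is `TRUE` (prevention recipients); children in
#' the control or natural-history strata accrue direct medical costs only.
#'
#' @param resource_use named numeric vector of non-negative quantities,
#'   or a single cohort row holding `ru_<item>` columns.
#' @param table a [unit_price_table()].
#' @param include_intervention logical.
#' @return EUR, rounded half-up to cents.
#' @export
#' @examples
#' pt <- unit_price_table(
#'   data.frame(item = "gp_visit", unit_price = 28, price_year = 2009,
#'              category = "direct_medical"))
#' child_cost(c(gp_visit = 2), pt)  # 56
child_cost <- function(resource_use, table, include_intervention = FALSE) {
  stopifnot(inherits(table, "unit_price_table"))
  if (is.data.frame(resource_use)) {
    stopifnot(nrow(resource_use) == 1L)
    cols <- grep("^ru_", names(resource_use), value = TRUE)
    resource_use <- stats::setNames(as.numeric(resource_use[1, cols]),
                                    sub("^ru_", "", cols))
  }
  if (length(resource_use) == 0L) return(0)
  if (is.null(names(resource_use)) || any(names(resource_use) == "")) {
    abort("'resource_use' must be a named vector of quantities")
  }
  check_nonneg(resource_use, "resource_use")
  unknown <- setdiff(names(resource_use), table$items$item)
  if (length(unknown)) {
    abort("unknown cost item(s): %s", paste(unknown, collapse = ", "))
  }
  prices <- indexed_prices(table)
  cats <- stats::setNames(table$items$category, table$items$item)
  keep <- include_intervention | cats[names(resource_use)] == "direct_medical"
  round_half_up(sum(resource_use[keep] * prices[names(resource_use)[keep]]), 2)
}

# Vectorized per-record costs. `include_intervention` is a logical
# scalar or per-record vector; equals child_cost() row by row.
costs_for <- function(cohort, table, include_intervention) {
  n <- nrow(cohort)
  if (n == 0L) return(numeric(0))
  items <- resource_items(cohort)
  if (length(items) == 0L) return(rep(0, n))
  unknown <- setdiff(items, table$items$item)
  if (length(unknown)) {
    abort("unknown cost item(s): %s", paste(unknown, collapse = ", "))
  }
  prices <- indexed_prices(table)[items]
  cats <- stats::setNames(table$items$category, table$items$item)[items]
  q <- as.matrix(cohort[paste0("ru_", items)])
  direct_cols <- cats == "direct_medical"
  direct <- as.vector(q[, direct_cols, drop = FALSE] %*% prices[direct_cols])
  total <- as.vector(q %*% prices)
  round_half_up(ifelse(rep_len(include_intervention, n), total, direct), 2)
}

# per-record costs for a whole cohort; intervention items counted for
# multifaceted/unifaceted children only
cohort_costs <- function(cohort, table) {
  grp <- cohort_groups(cohort)
  costs_for(cohort, table, grp %in% c("multifaceted", "unifaceted"))
}

#' Default (placeholder) unit price table
#'
#' The actual unit prices used in the underlying trial are not published;
#' these are round placeholder values in 2009 EUR so that the pipeline is
#' runnable end to end. They are not estimates of Dutch 2009 tariffs.
#'
#' @return A [unit_price_table()].
#' @export
default_price_table <- function() {
  read_price_table(system.file("extdata", "price_table_default.json",
                               package = "prevcea", mustWork = TRUE))
}

#' Read a unit price table from JSON
#'
#' Schema: `{"target_year": int, "index_factors": {"<year>": factor, ...},
#' "items": [{"item": str, "unit_price": num, "price_year": int,
#' "category": "direct_medical"|"intervention"}, ...]}`.
#'
#' @param path JSON file path.
#' @return A [unit_price_table()].
#' @export
read_price_table <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unit_price_table(
    items = as.data.frame(cfg$items),
    index_factors = unlist(cfg$index_factors),
    target_year = if (is.null(cfg$target_year)) 2009L else cfg$target_year
  )
}
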