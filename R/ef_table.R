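#' Emission-factor table
#'
#' Long-format table of per-item, per-impact-category factors, the pluggable
#' stand-in for commercial inventory databases. Each row gives the impact per
#' kg (or per utility unit) of an item, with an optional lognormal geometric
#' standard deviation describing its uncertainty; `gsd = 1` means no spread.
#'
#' @param item_key Character vector of item keys (feed ingredients, roughages,
#'   utilities, the additive, land-use-change adders).
#' @param category Impact-category keys (see [impact_categories()]).
#' @param value Factor values, impact units per unit of item; must be >= 0.
#' @param gsd Lognormal geometric standard deviations, >= 1; `NA` defaults to 1.
#'
#' @return An object of class `ef_table` (a data frame).
#' @export
ef_table <- function(item_key, category, value, gsd = 1) {
  d <- data.frame(
    item_key = as.character(item_key),
    category = as.character(category),
    value = as.numeric(value),
    gsd = as.numeric(gsd),
    stringsAsFactors = FALSE
  )
  d$gsd[is.na(d$gsd)] <- 1
  dup <- duplicated(d[c("item_key", "category")])
  if (any(dup)) {
    keys <- unique(paste(d$item_key[dup], d$category[dup], sep = "/"))
    stop_validation(sprintf("duplicate (item, category) key(s): %s",
                            paste(keys, collapse = ", ")), fields = keys)
  }
  check_fields(list(
    category = all(d$category %in% category_keys()),
    value = all(is.finite(d$value)) && all(d$value >= 0),
    gsd = all(is.finite(d$gsd)) && all(d$gsd >= 1)
  ), "ef_table")
  class(d) <- c("ef_table", "data.frame")
  d
}

#' Look up an emission factor
#'
#' @param ef An [ef_table()].
#' @param item Item key.
#' @param category Impact-category key.
#' @param default Value returned when the (item, category) cell is absent;
#'   the default `NULL` makes a missing cell an error.
#' @return The factor value.
#' @export
ef_factor <- function(ef, item, category, default = NULL) {
  i <- which(ef$item_key == item & ef$category == category)
  if (length(i) == 0L) {
    if (!is.null(default)) return(default)
    stop_resolution(sprintf("no emission factor for (%s, %s)", item, category),
                    keys = paste(item, category, sep = "/"))
  }
  ef$value[i]
}

ef_gsd <- function(ef, item, category) {
  i <- which(ef$item_key == item & ef$category == category)
  if (length(i) == 0L) 1 else ef$gsd[i]
}

#' Read / write an emission-factor table
#'
#' Comma-delimited text with a one-line header `item_key,category,value,gsd`.
#' An empty or missing `gsd` column defaults to 1 (no spread).
#'
#' @param path File path.
#' @return `read_ef_table` returns an [ef_table()]; `write_ef_table` returns
#'   `path` invisibly.
#' @export
read_ef_table <- function(path) {
  if (!file.exists(path)) {
    stop_validation(sprintf("emission-factor table not found: %s", path))
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_key", "category", "value")
  if (!all(need %in% names(d))) {
    stop_validation(sprintf("EF table header must name %s",
                            paste(need, collapse = ", ")))
  }
  if (!"gsd" %in% names(d)) d$gsd <- 1
  ef_table(d$item_key, d$category, d$value, d$gsd)
}

#' @rdname read_ef_table
#' @param ef An [ef_table()] to serialize.
#' @export
write_ef_table <- function(ef, path) {
  stopifnot(inherits(ef, "ef_table"))
  utils::write.csv(as.data.frame(ef), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
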