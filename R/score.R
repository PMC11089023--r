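#' Construct a points-based risk-score table
#'
#' A score table is an ordered list of items, each mapping a patient feature
#' to integer points, plus a high-risk cutoff on the total. Two item types
#' are supported: `"binary"` (points for `TRUE`/1 and `FALSE`/0) and
#' `"bins"` (a partition of a numeric axis into right-open intervals, one
#' point value per interval).
#'
#' @param items named list of items; each item is a list with `feature`
#'   (column name), `type` (`"binary"` or `"bins"`) and either
#'   `points_true`/`points_false` or `breaks` (ascending interior
#'   breakpoints) with `points` (length `length(breaks) + 1`, ordered by
#'   increasing feature value; intervals are `[b_i, b_{i+1})`).
#' @param cutoff integer high-risk cutoff: total `>= cutoff` is high risk.
#' @return Object of class `score_table`.
#' @seealso [default_score_table()], [total_score()]
#' @export
score_table <- function(items, cutoff) {
  for (nm in names(items)) {
    it <- items[[nm]]
    if (!it$type %in% c("binary", "bins")) abort("unknown item type for ", nm)
    if (it$type == "bins") {
      if (length(it$points) != length(it$breaks) + 1L) {
        abort("bins item ", nm, ": need one point value per interval")
      }
      if (is.unsorted(it$breaks, strictly = TRUE)) {
        abort("bins item ", nm, ": breaks must be strictly increasing")
      }
    }
  }
  tab <- structure(list(items = items, cutoff = as.integer(cutoff)),
                   class = "score_table")
  rng <- enumerate_score_range(tab)
  if (tab$cutoff < rng$min || tab$cutoff > rng$max) {
    abort("cutoff must lie within the achievable total range [",
          rng$min, ", ", rng$max, "]")
  }
  tab
}

#' The shipped progression risk-score table
#'
#' The published point system for locally advanced pancreatic cancer
#' assessed as stable disease after intraoperative radiotherapy:
#' CA19-9 non-response 2 points; rim-enhancement present 1 point;
#' peripancreatic fat infiltration present 1 point; ECV `>= 20%` −2 points,
#' `[16, 20)%` 0 points (reference), `< 16%` 1 point. Totals range −2 to 5;
#' the high-risk cutoff is 2. The printed points are shipped verbatim rather
#' than re-derived: they are not reproducible from the published regression
#' coefficients under any single base increment (see [sullivan_points()] and
#' the methods vignette).
#'
#' @return A `score_table`.
#' @export
default_score_table <- function() {
  score_table(
    items = list(
      ca199_response = list(feature = "ca199_responder", type = "binary",
                            points_true = 0L, points_false = 2L),
      rim_enhancement = list(feature = "rim_enhancement", type = "binary",
                             points_true = 1L, points_false = 0L),
      ecv = list(feature = "ecv_pct", type = "bins",
                 breaks = c(16, 20), points = c(1L, 0L, -2L)),
      fat_infiltration = list(feature = "fat_infiltration", type = "binary",
                              points_true = 1L, points_false = 0L)
    ),
    cutoff = 2L
  )
}

item_points <- function(item, values) {
  if (item$type == "binary") {
    v <- if (is.logical(values)) values else values != 0
    if (anyNA(v)) abort("missing value for scored feature ", item$feature)
    ifelse(v, item$points_true, item$points_false)
  } else {
    if (anyNA(values) || any(!is.finite(values))) {
      abort("missing or non-finite value for scored feature ", item$feature)
    }
    item$points[findInterval(values, item$breaks) + 1L]
  }
}

#' Score patients with a risk table
#'
#' Applies every item of the table to the derived feature columns, returning
#' the per-item points, the integer total and the risk class
#' (`high` iff total `>= cutoff`).
#'
#' @param features data frame with the feature columns the table's items
#'   name (see [derive_features()]); one row per patient.
#' @param table a [score_table()]; default the shipped table.
#' @return `features` with added columns `points_<item>` per item, `total`
#'   and `risk_class` (factor `low`/`high`).
#' @examples
#' pt <- data.frame(ca199_responder = FALSE, rim_enhancement = 1,
#'                  fat_infiltration = 1, ecv_pct = 15.9)
#' total_score(pt)$total  # 5
#' @export
total_score <- function(features, table = default_score_table()) {
  stopifnot(inherits(table, "score_table"))
  out <- features
  total <- integer(nrow(features))
  for (nm in names(table$items)) {
    it <- table$items[[nm]]
    if (!it$feature %in% names(features)) {
      abort("missing scored feature column: ", it$feature)
    }
    pts <- as.integer(item_points(it, features[[it$feature]]))
    out[[paste0("points_", nm)]] <- pts
    total <- total + pts
  }
  out$total <- total
  out$risk_class <- stratify(total, table$cutoff)
  out
}

#' Stratify totals into risk classes
#'
#' @param total integer score totals.
#' @param cutoff high-risk cutoff; `total >= cutoff` is high risk.
#' @return Factor with levels `low`, `high`.
#' @export
stratify <- function(total, cutoff = 2L) {
  factor(ifelse(total >= cutoff, "high", "low"), levels = c("low", "high"))
}

#' Enumerate the achievable totals of a score table
#'
#' Brute-force enumeration over the Cartesian product of every item's
#' category points; returns the minimum, maximum and the full achievable
#' set. Agrees with interval arithmetic (sum of per-item minima/maxima) by
#' construction, which the test suite asserts.
#'
#' @param table a [score_table()].
#' @return List with `min`, `max`, `achievable` (sorted integer vector) and
#'   `n_combinations`.
#' @export
enumerate_score_range <- function(table) {
  stopifnot(inherits(table, "score_table"))
  per_item <- lapply(table$items, function(it) {
    if (it$type == "binary") c(it$points_true, it$points_false) else it$points
  })
  grid <- expand.grid(per_item)
  totals <- rowSums(grid)
  list(min = min(totals), max = max(totals),
       achievable = sort(unique(as.integer(totals))),
       n_combinations = nrow(grid))
}

#' Derive candidate integer points from Cox coefficients (Sullivan's method)
#'
#' The generic construction behind points-based clinical scores: each
#' category of each feature gets
#' \eqn{points = round(\beta (v - v_{ref}) / B)} where \eqn{v} is the
#' category's value (1/0 for binary features, bin midpoints for continuous
#' ones), \eqn{v_{ref}} the reference category's value and \eqn{B} the base
#' increment — the amount of linear predictor worth one point (often the
#' coefficient of a chosen binary feature). Rounding is half away from zero.
#' The unrounded values are returned for audit.
#'
#' @param betas named numeric: one Cox log-hazard coefficient per feature
#'   (per unit of the category value).
#' @param categories named list, one entry per feature: a data frame with
#'   columns `category` (label), `value` (numeric) and `ref` (logical,
#'   exactly one TRUE).
#' @param base_increment positive scalar `B`.
#' @return Data frame with columns `feature`, `category`, `value`, `raw`
#'   (unrounded points) and `points`.
#' @examples
#' sullivan_points(
#'   betas = c(rim = log(2)),
#'   categories = list(rim = data.frame(category = c("absent", "present"),
#'                                      value = c(0, 1),
#'                                      ref = c(TRUE, FALSE))),
#'   base_increment = log(2))  # "present" gets exactly 1 point
#' @export
sullivan_points <- function(betas, categories, base_increment) {
  if (base_increment <= 0) abort("base_increment must be positive")
  if (!all(names(categories) %in% names(betas))) {
    abort("every feature in categories needs a coefficient in betas")
  }
  rows <- lapply(names(categories), function(f) {
    cat <- categories[[f]]
    if (sum(cat$ref) != 1L) abort("feature ", f, " must have exactly one reference category")
    vref <- cat$value[cat$ref]
    raw <- betas[[f]] * (cat$value - vref) / base_increment
    data.frame(feature = f, category = cat$category, value = cat$value,
               raw = raw, points = as.integer(round_half_away(raw)))
  })
  do.call(rbind, rows)
}

#' Serialize / deserialize a score table as JSON
#'
#' @param table a [score_table()].
#' @param path JSON path.
#' @return `write_score_table` returns `path` invisibly; `read_score_table`
#'   the reconstructed `score_table`.
#' @export
write_score_table <- function(table, path) {
  stopifnot(inherits(table, "score_table"))
  jsonlite::write_json(list(items = table$items, cutoff = table$cutoff),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  items <- lapply(raw$items, function(it) {
    if (it$type == "bins") {
      it$breaks <- as.numeric(it$breaks)
      it$points <- as.integer(it$points)
    } else {
      it$points_true <- as.integer(it$points_true)
      it$points_false <- as.integer(it$points_false)
    }
    it
  })
  score_table(items, cutoff = raw$cutoff)
}
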