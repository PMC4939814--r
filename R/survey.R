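#' @importFrom rlang abort warn .data
#' @importFrom stats rbinom rlnorm rpois runif setNames quantile
NULL

# canonical field names of a household record
.mandatory_fields <- c("total_expenditure", "food_expenditure", "oop_health", "size")
.optional_fields <- c("weight", "urban", "used_outpatient", "used_inpatient")

#' Construct a validated household survey dataset
#'
#' A `survey_dataset` is a tibble with one row per surveyed household and
#' canonical columns `total_expenditure`, `food_expenditure`, `oop_health`
#' (all in the same currency units per period), `size` (persons), `weight`
#' (sampling weight, defaults to 1), and optional `urban`,
#' `used_outpatient`, `used_inpatient` binary flags. Validation enforces the
#' invariants the downstream measures rely on: positive total expenditure,
#' non-negative food and OOP, food <= total (so capacity to pay is
#' non-negative), OOP <= total (OOP is a component of total expenditure),
#' integer size >= 1 and positive weights.
#'
#' @param data data frame with the canonical columns (optional ones may be
#'   absent).
#' @param source_label free-text provenance note stored as an attribute.
#' @param validation one of `"strict"` (any violation is an error),
#'   `"drop"` (offending rows are removed and tallied) or `"clamp"`
#'   (negatives raised to 0, food and OOP capped at total, size floored at
#'   1; rows with non-positive total expenditure or non-positive weight are
#'   still dropped since no clamp makes them meaningful).
#' @return a `survey_dataset`: tibble plus attributes `source_label` and
#'   `load_report` (see [validation_report()]).
#' @export
survey_dataset <- function(data, source_label = "unlabelled",
                           validation = c("strict", "drop", "clamp")) {
  validation <- match.arg(validation)
  data <- tibble::as_tibble(data)
  missing <- setdiff(.mandatory_fields, names(data))
  if (length(missing) > 0) {
    abort(paste0("missing mandatory column(s): ", paste(missing, collapse = ", ")),
          class = "finprot_config_error")
  }
  if (nrow(data) == 0) {
    abort("survey contains no households", class = "finprot_input_error")
  }
  if (!"weight" %in% names(data)) data$weight <- 1
  data$weight[is.na(data$weight)] <- 1

  for (f in .mandatory_fields) {
    if (!is.numeric(data[[f]])) {
      abort(paste0("column '", f, "' is not numeric"), class = "finprot_parse_error")
    }
  }

  report <- list(rows_read = nrow(data), policy = validation,
                 dropped = integer(), clamped = integer())

  # rule set: name, violation predicate, clamp action (NULL = must drop)
  rules <- list(
    list(name = "total>0", bad = function(d) !(d$total_expenditure > 0), fix = NULL),
    list(name = "weight>0", bad = function(d) !(d$weight > 0), fix = NULL),
    list(name = "no-missing", bad = function(d) {
      Reduce(`|`, lapply(.mandatory_fields, function(f) is.na(d[[f]])))
    }, fix = NULL),
    list(name = "food>=0", bad = function(d) d$food_expenditure < 0,
         fix = function(d, i) { d$food_expenditure[i] <- 0; d }),
    list(name = "oop>=0", bad = function(d) d$oop_health < 0,
         fix = function(d, i) { d$oop_health[i] <- 0; d }),
    list(name = "size>=1", bad = function(d) d$size < 1,
         fix = function(d, i) { d$size[i] <- 1; d }),
    list(name = "food<=total", bad = function(d) d$food_expenditure > d$total_expenditure,
         fix = function(d, i) { d$food_expenditure[i] <- d$total_expenditure[i]; d }),
    list(name = "oop<=total", bad = function(d) d$oop_health > d$total_expenditure,
         fix = function(d, i) { d$oop_health[i] <- d$total_expenditure[i]; d })
  )

  for (rule in rules) {
    bad <- rule$bad(data)
    bad[is.na(bad)] <- TRUE
    if (!any(bad)) next
    idx <- which(bad)
    if (validation == "strict") {
      abort(paste0("validation rule '", rule$name, "' violated by ",
                   length(idx), " row(s), first at row ", idx[1]),
            class = "finprot_validation_error")
    }
    if (validation == "clamp" && !is.null(rule$fix)) {
      data <- rule$fix(data, idx)
      report$clamped[rule$name] <- length(idx)
    } else {
      data <- data[-idx, , drop = FALSE]
      report$dropped[rule$name] <- length(idx)
    }
  }
  if (nrow(data) == 0) {
    abort("no valid households remain after validation", class = "finprot_input_error")
  }
  data$size <- as.integer(round(data$size))

  structure(data,
            class = c("survey_dataset", class(tibble::tibble())),
            source_label = source_label,
            load_report = report)
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("<survey_dataset> ", nrow(x), " households (", attr(x, "source_label"), ")\n",
      sep = "")
  NextMethod()
}

#' Retrieve the load/validation report of a survey dataset
#'
#' @param dataset a [survey_dataset()].
#' @return list with `rows_read`, `policy`, and named integer tallies
#'   `dropped` and `clamped` per validation rule.
#' @export
validation_report <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  attr(dataset, "load_report")
}

#' Read a household survey from CSV
#'
#' Reads an RFC-4180 CSV with a header row, renames columns to the canonical
#' fields through `column_map`, optionally rescales columns (to harmonize
#' recall periods, e.g. annual to monthly), and validates under the chosen
#' policy.
#'
#' @param path CSV file path.
#' @param column_map named list mapping canonical field names
#'   (`total_expenditure`, `food_expenditure`, `oop_health`, `size`, and
#'   optionally `weight`, `urban`, `used_outpatient`, `used_inpatient`) to
#'   the CSV column names. An entry may also be
#'   `list(column = "oop_year", multiplier = 1/12)` to rescale at load
#'   time. `NULL` (default) assumes the CSV already uses canonical names.
#' @param validation_policy `"strict"`, `"drop"` or `"clamp"`; see
#'   [survey_dataset()].
#' @return a validated [survey_dataset()]; the load report is retrievable
#'   with [validation_report()].
#' @export
read_survey <- function(path, column_map = NULL,
                        validation_policy = c("strict", "drop", "clamp")) {
  validation_policy <- match.arg(validation_policy)
  if (!file.exists(path)) {
    abort(paste0("cannot read survey file: ", path), class = "finprot_input_error")
  }
  raw <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(paste0("failed to parse CSV: ", conditionMessage(e)),
                              class = "finprot_parse_error"))
  if (nrow(raw) == 0) abort("empty survey file", class = "finprot_input_error")

  if (!is.null(column_map)) {
    out <- list()
    for (field in names(column_map)) {
      spec <- column_map[[field]]
      col <- if (is.list(spec)) spec$column else spec
      mult <- if (is.list(spec) && !is.null(spec$multiplier)) spec$multiplier else 1
      if (!col %in% names(raw)) {
        abort(paste0("column '", col, "' (mapped to field '", field,
                     "') not found in ", path),
              class = "finprot_config_error")
      }
      v <- raw[[col]]
      out[[field]] <- if (is.numeric(v)) v * mult else v
    }
    raw <- tibble::as_tibble(out)
  }
  survey_dataset(raw, source_label = path, validation = validation_policy)
}

#' Write a survey dataset to CSV
#'
#' Canonical columns only, same dialect [read_survey()] accepts, so a
#' write/read round trip reproduces the records exactly.
#'
#' @param dataset a [survey_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(dataset, path) {
  stopifnot(inherits(dataset, "survey_dataset"))
  readr::write_csv(tibble::as_tibble(dataset), path, progress = FALSE)
  invisible(path)
}

#' Household capacity to pay
#'
#' Capacity to pay (non-food or "non-discretionary" expenditure) is total
#' household expenditure minus food expenditure; validation guarantees it
#' is non-negative.
#'
#' @param dataset a [survey_dataset()].
#' @return numeric vector, one value per household, in record order.
#' @export
capacity_to_pay <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  dataset$total_expenditure - dataset$food_expenditure
}

#' Per-capita household expenditure
#'
#' Total (or total net of OOP health payments) expenditure divided by raw
#' household size; no adult-equivalence scale is applied.
#'
#' @param dataset a [survey_dataset()].
#' @param net_of_oop subtract OOP health payments from the numerator first?
#' @return numeric vector of per-person expenditures in record order;
#'   non-negative (validation enforces OOP <= total).
#' @export
per_capita_expenditure <- function(dataset, net_of_oop = FALSE) {
  stopifnot(inherits(dataset, "survey_dataset"))
  num <- dataset$total_expenditure - if (net_of_oop) dataset$oop_health else 0
  num / dataset$size
}
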