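#' Calories burned during an activity
#'
#' Standard METS energy expenditure:
#' `kcal = MET x weight_kg x duration_hours`. Linear in both duration and
#' body weight, and additive over any partition of the duration. Manual
#' exercise labels of the form `"manual:<name>"` resolve `<name>` in the
#' MET table.
#'
#' @param label Activity label (vectorized), e.g. `"walking"` or
#'   `"manual:cycling"`.
#' @param duration_minutes Duration in minutes (>= 0, vectorized).
#' @param weight_kg Body weight in kilograms (> 0).
#' @param mets MET table from [met_table()].
#' @return Numeric kcal, same length as `label`.
#' @examples
#' activity_kcal("walking", 60, 70) # 3.5 * 70 * 1 = 245
#' @export
activity_kcal <- function(label, duration_minutes, weight_kg,
                          mets = met_table()) {
  stopifnot_scalar_number(weight_kg, "weight_kg", min = 0, strict = TRUE)
  if (any(duration_minutes < 0)) {
    abort("`duration_minutes` must be >= 0.")
  }
  key <- sub("^manual:", "", label)
  met <- mets$met[match(key, mets$label)]
  if (anyNA(met)) {
    bad <- unique(label[is.na(met)])
    abort(sprintf(
      "Unknown activity label(s) in MET table: %s.",
      paste(bad, collapse = ", ")
    ))
  }
  met * weight_kg * (duration_minutes / 60)
}

#' Calories consumed from a food-log entry
#'
#' `kcal = kcal_per_unit x quantity`, looked up by `food_id` in the food
#' table. A non-missing `label_kcal` (calories read directly off a package
#' label) overrides the table entirely.
#'
#' @param food_id Food identifier (vectorized).
#' @param quantity Units consumed (>= 0, vectorized).
#' @param food_table Tibble from [read_food_table()].
#' @param label_kcal Optional direct calorie entry; `NA` means "use the
#'   table".
#' @return Numeric kcal.
#' @examples
#' ft <- read_food_table()
#' food_kcal("F201", 2, ft) # one apple is 80 kcal/unit
#' @export
food_kcal <- function(food_id, quantity, food_table = read_food_table(),
                      label_kcal = NA_real_) {
  if (any(quantity < 0)) abort("`quantity` must be >= 0.")
  n <- max(length(food_id), length(quantity), length(label_kcal))
  food_id <- rep_len(food_id, n)
  quantity <- rep_len(quantity, n)
  label_kcal <- rep_len(label_kcal, n)
  per_unit <- food_table$kcal_per_unit[match(food_id, food_table$food_id)]
  need_table <- is.na(label_kcal)
  if (any(need_table & is.na(per_unit))) {
    bad <- unique(food_id[need_table & is.na(per_unit)])
    abort(sprintf(
      "Unknown food_id(s): %s.", paste(bad, collapse = ", ")
    ))
  }
  ifelse(need_table, per_unit * quantity, label_kcal)
}
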