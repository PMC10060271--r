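#' Build a plate map
#'
#' A plate map assigns each well a role in the screen: `vehicle` (untreated
#' negative control, the 100% viability anchor), `positive` (maximal-kill
#' control, the 0% anchor), `treated` (a drug at one concentration) or
#' `empty`. Concentrations are stored in molar.
#'
#' @param well_id character vector of plate coordinates (e.g. `"B07"`).
#' @param role one of `"vehicle"`, `"positive"`, `"treated"`, `"empty"` per well.
#' @param drug drug name for treated wells (`NA` otherwise).
#' @param concentration molar concentration for treated wells, `> 0`.
#' @param replicate replicate-group label (defaults to 1).
#' @param plate_format wells per plate used to validate coordinates (96 or 384).
#'
#' @return A `plate_map` tibble with one row per well.
#' @export
#' @examples
#' plate_map(
#'   well_id = c("A01", "A02", "A03"),
#'   role = c("vehicle", "positive", "treated"),
#'   drug = c(NA, NA, "cisplatin"),
#'   concentration = c(NA, NA, 1e-6)
#' )
plate_map <- function(well_id, role, drug = NA_character_,
                      concentration = NA_real_, replicate = 1L,
                      plate_format = 384) {
  pm <- tibble::tibble(
    well_id = as.character(well_id),
    role = as.character(role),
    drug = rep_len(as.character(drug), length(well_id)),
    concentration = rep_len(as.numeric(concentration), length(well_id)),
    replicate = rep_len(as.integer(replicate), length(well_id))
  )
  validate_plate_map(pm, plate_format = plate_format)
}

plate_roles <- c("vehicle", "positive", "treated", "empty")

#' Validate a plate map
#'
#' Checks well-id uniqueness and format validity, role values, and that
#' treated rows carry a drug and a positive molar concentration.
#'
#' @param pm a data frame with columns `well_id`, `role`, `drug`,
#'   `concentration`, `replicate`.
#' @inheritParams plate_map
#' @return The validated `plate_map` tibble (invisibly usable downstream).
#' @export
validate_plate_map <- function(pm, plate_format = 384) {
  req <- c("well_id", "role", "drug", "concentration", "replicate")
  missing_cols <- setdiff(req, names(pm))
  if (length(missing_cols))
    abort_field("plate_map", paste("missing columns:",
                                   paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(pm$well_id))
    abort_field("well_id", paste("duplicate well(s):",
                paste(unique(pm$well_id[duplicated(pm$well_id)]), collapse = ", ")))
  bad_role <- setdiff(unique(pm$role), plate_roles)
  if (length(bad_role))
    abort_field("role", paste("unknown role(s):", paste(bad_role, collapse = ", ")))
  dims <- plate_dims(plate_format)
  ok <- grepl("^[A-P][0-9]{2}$", pm$well_id)
  if (any(!ok))
    abort_field("well_id", paste("not a plate coordinate:",
                                 paste(pm$well_id[!ok], collapse = ", ")))
  row_i <- match(substr(pm$well_id, 1, 1), LETTERS)
  col_i <- as.integer(substr(pm$well_id, 2, 3))
  if (any(row_i > dims[1] | col_i < 1 | col_i > dims[2]))
    abort_field("well_id", sprintf("outside a %d-well plate", plate_format))
  treated <- pm$role == "treated"
  if (any(treated & (is.na(pm$drug) | pm$drug == "")))
    abort_field("drug", "treated wells must name a drug")
  if (any(treated & (!is.finite(pm$concentration) | pm$concentration <= 0)))
    abort_field("concentration", "treated wells need a molar concentration > 0")
  pm <- tibble::as_tibble(pm)
  class(pm) <- c("plate_map", class(pm))
  pm
}

plate_dims <- function(plate_format) {
  switch(as.character(plate_format),
         "96" = c(8L, 12L),
         "384" = c(16L, 24L),
         abort_field("plate_format", "supported formats: 96, 384"))
}

#' Lay out a one-drug titration plate map
#'
#' Convenience constructor for a single-drug dose-response experiment:
#' `n_vehicle` vehicle wells, `n_positive` positive-control wells and one
#' well per concentration, filled row-major from `A01`.
#'
#' @param drug drug name.
#' @param concentrations molar concentrations of the titration.
#' @param n_vehicle,n_positive number of control wells.
#' @param replicates treated replicates per concentration.
#' @inheritParams plate_map
#' @return A `plate_map` tibble.
#' @export
titration_plate_map <- function(drug, concentrations, n_vehicle = 3,
                                n_positive = 3, replicates = 1,
                                plate_format = 384) {
  n_tr <- length(concentrations) * replicates
  n <- n_vehicle + n_positive + n_tr
  dims <- plate_dims(plate_format)
  if (n > dims[1] * dims[2])
    abort_field("plate_map", "more wells requested than the plate holds")
  idx <- seq_len(n) - 1L
  ids <- sprintf("%s%02d", LETTERS[idx %/% dims[2] + 1], idx %% dims[2] + 1)
  plate_map(
    well_id = ids,
    role = c(rep("vehicle", n_vehicle), rep("positive", n_positive),
             rep("treated", n_tr)),
    drug = c(rep(NA, n_vehicle + n_positive), rep(drug, n_tr)),
    concentration = c(rep(NA, n_vehicle + n_positive),
                      rep(concentrations, each = replicates)),
    replicate = c(rep(1L, n_vehicle + n_positive),
                  rep(seq_len(replicates), times = length(concentrations))),
    plate_format = plate_format
  )
}

#' Read / write a plate map CSV
#'
#' Comma-separated, UTF-8, header row, `.` decimal; columns `well_id`,
#' `role`, `drug`, `concentration`, `replicate`.
#'
#' @param path file path.
#' @inheritParams plate_map
#' @return `read_plate_map()` returns a validated `plate_map` tibble.
#' @export
read_plate_map <- function(path, plate_format = 384) {
  if (!file.exists(path))
    stop("plate map file not found: ", path, call. = FALSE)
  pm <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_plate_map(tibble::as_tibble(pm), plate_format = plate_format)
}

#' @rdname read_plate_map
#' @param pm a `plate_map`.
#' @export
write_plate_map <- function(pm, path) {
  utils::write.csv(as.data.frame(pm), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
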