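#' Read individual morphometric measurements
#'
#' The trait table holds one row per measured individual: species, individual
#' identifier, length of the visible ovipositor sheath and of the metatibia,
#' both in micrometres and strictly positive. TSV, header row, UTF-8,
#' decimal points.
#'
#' @param path path to a TSV with exactly the columns `species`,
#'   `individual_id`, `sheath_length`, `metatibia_length`.
#' @return a validated tibble of trait records.
#' @export
read_trait_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    species = readr::col_character(),
    individual_id = readr::col_character(),
    sheath_length = readr::col_double(),
    metatibia_length = readr::col_double()
  ), progress = FALSE)
  validate_trait_records(df)
}

#' Validate trait records
#'
#' @param df data frame of individual measurements; see [read_trait_table()]
#'   for the required columns. Errors carry the offending row numbers —
#'   records are rejected, never repaired.
#' @return the records as a tibble.
#' @export
validate_trait_records <- function(df) {
  required <- c("species", "individual_id", "sheath_length", "metatibia_length")
  check_columns(df, required, "trait table")
  df <- as_tibble(df)
  if (nrow(df) == 0) abort("trait table is empty.")
  for (col in c("species", "individual_id")) {
    bad <- which(is.na(df[[col]]) | !nzchar(df[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("empty %s at row(s) %s.", col, toString(head(bad, 5))))
    }
  }
  for (col in c("sheath_length", "metatibia_length")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
    if (length(bad) > 0) {
      abort(sprintf("%s must be > 0; violated at row(s) %s.",
                    col, toString(head(bad, 5))))
    }
  }
  key <- paste(df$species, df$individual_id, sep = "\r")
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate (species, individual_id) at row(s) %s.",
                  toString(head(which(duplicated(key)), 5))))
  }
  df
}

#' Read host records
#'
#' One row per rearing record: which parasitoid species emerged from which
#' host insect species, with the host's family and order and the family of
#' the plant the host was collected on (`plant_family` may be missing: some
#' records lack plant data and are dropped only for plant-level analyses).
#'
#' @param path path to a TSV with exactly the columns `parasitoid_species`,
#'   `host_species`, `host_family`, `host_order`, `plant_family`.
#' @return a validated tibble of host records.
#' @export
read_host_records <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    parasitoid_species = readr::col_character(),
    host_species = readr::col_character(),
    host_family = readr::col_character(),
    host_order = readr::col_character(),
    plant_family = readr::col_character()
  ), progress = FALSE, na = c("", "NA"))
  validate_host_records(df)
}

#' Validate host records
#'
#' Enforces non-empty parasitoid and host species and a consistent host
#' taxonomy within the table: each host species belongs to exactly one
#' family and each family to exactly one order.
#'
#' @param df data frame of host records; see [read_host_records()].
#' @return the records as a tibble.
#' @export
validate_host_records <- function(df) {
  required <- c("parasitoid_species", "host_species", "host_family",
                "host_order", "plant_family")
  check_columns(df, required, "host table")
  df <- as_tibble(df)
  if (nrow(df) == 0) abort("host table is empty.")
  for (col in c("parasitoid_species", "host_species", "host_family",
                "host_order")) {
    bad <- which(is.na(df[[col]]) | !nzchar(df[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("empty %s at row(s) %s.", col, toString(head(bad, 5))))
    }
  }
  fam_per_sp <- tapply(df$host_family, df$host_species,
                       function(x) length(unique(x)))
  if (any(fam_per_sp > 1)) {
    abort(paste0("host species mapped to more than one family: ",
                 toString(names(fam_per_sp)[fam_per_sp > 1])))
  }
  ord_per_fam <- tapply(df$host_order, df$host_family,
                        function(x) length(unique(x)))
  if (any(ord_per_fam > 1)) {
    abort(paste0("host family mapped to more than one order: ",
                 toString(names(ord_per_fam)[ord_per_fam > 1])))
  }
  df
}

check_columns <- function(df, required, what) {
  if (!is.data.frame(df)) abort(paste0(what, " must be a data frame."))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s lacks required column(s): %s.", what, toString(missing)))
  }
  extra <- setdiff(names(df), required)
  if (length(extra) > 0) {
    abort(sprintf("%s has unknown column(s): %s.", what, toString(extra)))
  }
  df[, required]
}
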