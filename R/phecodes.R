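#' Read a phecode map
#'
#' Reads a phecode-to-ICD map in the CSV dialect used throughout the package:
#' columns `phecode`, `description`, `icd10_codes` (semicolon-joined),
#' `exclude_range_lo`, `exclude_range_hi`, `parent_phecode`, and an optional
#' `sex` column (`both`/`male`/`female`) restricting sex-specific phenotypes.
#'
#' @param path CSV file path.
#' @return Tibble of class `phecode_map`.
#' @export
read_phecode_map <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         phecode = readr::col_character(),
                         parent_phecode = readr::col_character(),
                         .default = readr::col_guess()))
  as_phecode_map(x)
}

as_phecode_map <- function(x) {
  need <- c("phecode", "description", "icd10_codes",
            "exclude_range_lo", "exclude_range_hi", "parent_phecode")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("phecode map is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "phewasmr_config_error")
  }
  x <- as_tibble(x)
  if (!"sex" %in% names(x)) x$sex <- "both"
  x$sex[is.na(x$sex)] <- "both"
  structure(x, class = c("phecode_map", class(x)))
}

# uppercase, dot-insensitive ICD normalization
normalize_icd <- function(codes) gsub(".", "", toupper(codes), fixed = TRUE)

# long lookup table icd -> phecode from the semicolon-joined column
map_icd_lookup <- function(map) {
  tidyr::separate_rows(
    tibble(phecode = map$phecode, icd = map$icd10_codes),
    "icd", sep = ";"
  ) |>
    dplyr::mutate(icd = normalize_icd(trimws(.data$icd))) |>
    dplyr::filter(.data$icd != "")
}

# all ancestors (transitive parents) of each phecode, including itself
phecode_ancestors <- function(map) {
  parent <- setNames(map$parent_phecode, map$phecode)
  vapply(map$phecode, function(ph) {
    chain <- ph
    cur <- ph
    while (!is.na(parent[cur]) && parent[cur] != "" &&
           parent[cur] %in% names(parent) && !(parent[cur] %in% chain)) {
      cur <- parent[[cur]]
      chain <- c(chain, cur)
    }
    paste(chain, collapse = ";")
  }, character(1))
}

#' Map ICD diagnoses to phecodes
#'
#' Converts a long-format diagnosis table to per-participant phecode sets.
#' ICD codes are matched case- and dot-insensitively. A diagnosis mapping to
#' a child phecode also counts as a case of all its ancestors (parent
#' propagation, the phecode-system convention). Unmapped codes are counted
#' and reported via a message, not an error.
#'
#' @param diagnoses Data frame with columns `participant_id`, `icd10`.
#' @param map A `phecode_map`.
#' @return Tibble `participant_id`, `phecode` (distinct pairs).
#' @export
map_to_phecodes <- function(diagnoses, map) {
  stopifnot(all(c("participant_id", "icd10") %in% names(diagnoses)))
  map <- as_phecode_map(map)
  lookup <- map_icd_lookup(map)
  dx <- tibble(participant_id = diagnoses$participant_id,
               icd = normalize_icd(diagnoses$icd10))
  hit <- dplyr::inner_join(dx, lookup, by = "icd",
                           relationship = "many-to-many")
  n_unmapped <- sum(!dx$icd %in% lookup$icd)
  if (n_unmapped > 0) {
    inform(sprintf("map_to_phecodes: %d diagnosis record(s) had no phecode",
                   n_unmapped))
  }
  anc <- phecode_ancestors(map)
  hit |>
    dplyr::mutate(phecode = anc[.data$phecode]) |>
    tidyr::separate_rows("phecode", sep = ";") |>
    dplyr::distinct(.data$participant_id, .data$phecode)
}

#' Build the case/control/excluded partition for one phecode
#'
#' Cases are participants carrying the phecode. Among the rest, anyone
#' carrying any phecode inside the target's exclusion range (a numeric
#' interval of related conditions) is excluded from the control group;
#' everyone else is a control. For sex-specific phecodes, the analyzable
#' cohort is first restricted to that sex. The three sets partition the
#' analyzable cohort.
#'
#' @param phecode Target phecode id.
#' @param phecode_sets Output of [map_to_phecodes()].
#' @param map A `phecode_map`.
#' @param participants Data frame with `participant_id` (and `sex`, required
#'   when the map marks the phecode sex-specific) defining the full cohort.
#' @return A list of class `case_control`: `phecode`, `description`,
#'   `case_ids`, `control_ids`, `excluded_ids`, `n_case`, `n_control`.
#' @export
build_case_control <- function(phecode, phecode_sets, map, participants) {
  map <- as_phecode_map(map)
  row <- map[map$phecode == phecode, ]
  if (nrow(row) == 0) {
    abort(sprintf("phecode %s not in map", phecode),
          class = "phewasmr_config_error")
  }
  ids <- participants$participant_id
  if (row$sex[1] %in% c("male", "female")) {
    if (!"sex" %in% names(participants)) {
      abort("sex-specific phecode requires a sex column in participants",
            class = "phewasmr_config_error")
    }
    ids <- ids[participants$sex == row$sex[1]]
  }
  sets <- phecode_sets[phecode_sets$participant_id %in% ids, ]
  case_ids <- unique(sets$participant_id[sets$phecode == phecode])
  lo <- row$exclude_range_lo[1]
  hi <- row$exclude_range_hi[1]
  in_range <- !is.na(lo) & !is.na(hi) &
    suppressWarnings(as.numeric(sets$phecode)) >= lo &
    suppressWarnings(as.numeric(sets$phecode)) <= hi
  range_ids <- unique(sets$participant_id[in_range %in% TRUE])
  excluded_ids <- setdiff(range_ids, case_ids)
  control_ids <- setdiff(ids, c(case_ids, excluded_ids))
  structure(list(phecode = phecode,
                 description = row$description[1],
                 case_ids = case_ids,
                 control_ids = control_ids,
                 excluded_ids = excluded_ids,
                 n_case = length(case_ids),
                 n_control = length(control_ids)),
            class = "case_control")
}

#' @export
print.case_control <- function(x, ...) {
  cat(sprintf("<case_control> phecode %s (%s): %d cases, %d controls, %d excluded\n",
              x$phecode, x$description, x$n_case, x$n_control,
              length(x$excluded_ids)))
  invisible(x)
}

#' @export
tidy.case_control <- function(x, ...) {
  tibble(phecode = x$phecode, description = x$description,
         n_case = x$n_case, n_control = x$n_control,
         n_excluded = length(x$excluded_ids))
}
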