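#' Read a phenotype table into long (genotype, environment, value) form
#'
#' Multi-environment trial phenotypes are accepted in two layouts. `"wide"`
#' has one row per genotype: the first column is the genotype id and every
#' remaining column is one environment of line means. `"long"` has columns
#' `genotype`, `environment`, `value` and optionally `replicate`; replicate
#' observations are collapsed to line means by the arithmetic mean.
#' Missing cells may be empty or `NA`. Malformed input is rejected, never
#' silently coerced.
#'
#' @param path Path to a CSV file.
#' @param layout `"wide"` or `"long"`.
#' @return A tibble with columns `genotype`, `environment`, `value`
#'   (one row per line mean).
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines("genotype,E1,E2\ng1,10,12\ng2,11,15", f)
#' read_phenotypes(f, layout = "wide")
read_phenotypes <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  if (layout == "wide") {
    if (ncol(raw) < 3) abort("Wide phenotype file needs a genotype column plus >= 2 environments.")
    env_cols <- names(raw)[-1]
    bad <- env_cols[!vapply(raw[env_cols], is.numeric, logical(1))]
    if (length(bad) > 0) {
      abort(paste0("Non-numeric trait column(s): ", paste(bad, collapse = ", ")))
    }
    empty <- env_cols[vapply(raw[env_cols], function(x) all(is.na(x)), logical(1))]
    if (length(empty) > 0) {
      abort(paste0("Environment column(s) with no observed values: ",
                   paste(empty, collapse = ", ")))
    }
    names(raw)[1] <- "genotype"
    long <- tidyr::pivot_longer(raw, -"genotype",
                                names_to = "environment", values_to = "value")
  } else {
    need <- c("genotype", "environment", "value")
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols) > 0) {
      abort(paste0("Long phenotype file is missing column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    if (!is.numeric(raw$value)) abort("`value` column must be numeric.")
    long <- raw %>%
      dplyr::group_by(.data$genotype, .data$environment) %>%
      dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") %>%
      dplyr::mutate(value = ifelse(is.nan(.data$value), NA_real_, .data$value))
  }
  long$genotype <- as.character(long$genotype)
  long$environment <- as.character(long$environment)
  check_phenotypes(long)
}

#' Write a long phenotype tibble as a wide CSV
#'
#' @param pheno Tibble with `genotype`, `environment`, `value`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  pheno <- check_phenotypes(pheno)
  wide <- tidyr::pivot_wider(pheno, id_cols = "genotype",
                             names_from = "environment", values_from = "value")
  readr::write_csv(wide, path, na = "NA")
  invisible(path)
}

#' Read a biallelic marker matrix for inbred lines
#'
#' First column is the genotype id; remaining columns are markers coded
#' `-1` (parent-A homozygote), `0` (heterozygote), `+1` (parent-B
#' homozygote). Files coded `{0, 1, 2}` are accepted with
#' `recode_012 = TRUE` and shifted to the signed coding.
#'
#' @param path CSV path.
#' @param recode_012 Interpret codes as `{0, 1, 2}` and recode.
#' @return Numeric matrix, genotypes in rows (rownames), markers in columns.
#' @export
read_markers <- function(path, recode_012 = FALSE) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  marker_matrix(raw, recode_012 = recode_012)
}

#' Write a marker matrix as CSV
#' @param markers Coded matrix with genotype rownames, or tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path) {
  m <- marker_matrix(markers)
  out <- dplyr::bind_cols(tibble(genotype = rownames(m)), tibble::as_tibble(m))
  readr::write_csv(out, path, na = "NA")
  invisible(path)
}

#' Read daily weather in a NASA-POWER-like layout
#'
#' Expects columns `site`, `date` (ISO-8601), `T2M_MAX`, `T2M_MIN` and
#' optionally `DAY_LENGTH` (hours). Lower-case `tmax`/`tmin` column names
#' are also accepted.
#'
#' @param path CSV path.
#' @return Tibble with `site`, `date` (Date), `tmax`, `tmin` and, when
#'   present, `day_length`.
#' @export
read_weather <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  nm <- names(raw)
  pick <- function(...) {
    cands <- c(...)
    hit <- cands[cands %in% nm]
    if (length(hit) == 0) abort(paste0("Weather file is missing a ", cands[1], " column."))
    hit[1]
  }
  out <- tibble(
    site = as.character(raw[[pick("site", "SITE")]]),
    date = as.Date(raw[[pick("date", "DATE", "YYYYMMDD")]]),
    tmax = as.numeric(raw[[pick("T2M_MAX", "tmax")]]),
    tmin = as.numeric(raw[[pick("T2M_MIN", "tmin")]])
  )
  if ("DAY_LENGTH" %in% nm) out$day_length <- as.numeric(raw$DAY_LENGTH)
  if ("day_length" %in% nm) out$day_length <- as.numeric(raw$day_length)
  bad <- which(out$tmax < out$tmin)
  if (length(bad) > 0) {
    abort(paste0("tmax < tmin on ", length(bad), " day(s), first at row ", bad[1], "."))
  }
  out
}

#' Read site metadata (site, latitude, longitude)
#' @param path CSV path with columns `site`, `latitude`, `longitude`.
#' @return Tibble.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("site", "latitude")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Site file is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(abs(raw$latitude) > 90)) abort("Latitudes must lie in [-90, 90].")
  raw$site <- as.character(raw$site)
  tibble::as_tibble(raw)
}
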