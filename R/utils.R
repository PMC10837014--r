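#' @importFrom rlang abort warn inform .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Validate a long phenotype tibble (genotype, environment, value).
# Returns it with genotype/environment as character, after structural checks.
check_phenotypes <- function(pheno, min_env_per_genotype = 2) {
  if (!is.data.frame(pheno)) {
    abort("`pheno` must be a data frame with columns genotype, environment, value.")
  }
  need <- c("genotype", "environment", "value")
  missing_cols <- setdiff(need, names(pheno))
  if (length(missing_cols) > 0) {
    abort(paste0("`pheno` is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  pheno <- tibble::as_tibble(pheno)
  pheno$genotype <- as.character(pheno$genotype)
  pheno$environment <- as.character(pheno$environment)
  if (!is.numeric(pheno$value)) {
    abort("`pheno$value` must be numeric (line means).")
  }
  dup <- pheno %>%
    dplyr::count(.data$genotype, .data$environment) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "Duplicate (genotype, environment) cells; average replicates first (see read_phenotypes layout = 'long'). First offender: ",
      dup$genotype[1], " / ", dup$environment[1]
    ))
  }
  obs <- dplyr::filter(pheno, !is.na(.data$value))
  if (dplyr::n_distinct(obs$environment) < 2 || dplyr::n_distinct(obs$genotype) < 2) {
    abort("Need at least 2 genotypes and 2 environments with observed values.")
  }
  per_geno <- dplyr::count(obs, .data$genotype)
  thin <- per_geno$genotype[per_geno$n < min_env_per_genotype]
  if (length(thin) > 0) {
    warn(paste0(
      length(thin), " genotype(s) observed in fewer than ", min_env_per_genotype,
      " environments will be unusable for reaction-norm estimation (e.g. ", thin[1], ")."
    ))
  }
  pheno
}

# Long phenotype tibble -> genotype x environment matrix (NA for missing cells).
pheno_matrix <- function(pheno, environments = NULL) {
  pheno <- check_phenotypes(pheno)
  if (!is.null(environments)) {
    bad <- setdiff(environments, unique(pheno$environment))
    if (length(bad) > 0) {
      abort(paste0("Environment(s) not present in `pheno`: ", paste(bad, collapse = ", ")))
    }
    pheno <- dplyr::filter(pheno, .data$environment %in% environments)
  } else {
    environments <- sort(unique(pheno$environment))
  }
  wide <- tidyr::pivot_wider(
    pheno,
    id_cols = "genotype", names_from = "environment", values_from = "value"
  )
  m <- as.matrix(wide[, environments, drop = FALSE])
  rownames(m) <- wide$genotype
  storage.mode(m) <- "double"
  m
}

# Markers: accept a tibble (first column genotype id) or a coded numeric matrix
# with genotype rownames. Returns a numeric matrix, codes in {-1, 0, 1, NA}.
marker_matrix <- function(markers, recode_012 = FALSE) {
  if (is.matrix(markers)) {
    m <- markers
    if (is.null(rownames(m))) abort("Marker matrix needs genotype rownames.")
  } else if (is.data.frame(markers)) {
    ids <- as.character(markers[[1]])
    m <- as.matrix(markers[, -1, drop = FALSE])
    rownames(m) <- ids
  } else {
    abort("`markers` must be a matrix or data frame.")
  }
  storage.mode(m) <- "double"
  if (recode_012) m <- m - 1
  codes <- unique(as.vector(m))
  codes <- codes[!is.na(codes)]
  bad <- setdiff(codes, c(-1, 0, 1))
  if (length(bad) > 0) {
    abort(paste0(
      "Marker codes must be in {-1, 0, 1} (or {0, 1, 2} with recode_012 = TRUE); found: ",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  m
}

# Mean-impute missing marker codes column-wise (deterministic; inbred panels).
impute_markers <- function(m) {
  na_cols <- which(colSums(is.na(m)) > 0)
  for (j in na_cols) {
    mu <- mean(m[, j], na.rm = TRUE)
    if (is.nan(mu)) mu <- 0
    m[which(is.na(m[, j])), j] <- mu
  }
  m
}
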