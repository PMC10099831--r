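#' Read a per-field-of-view cell count table
#'
#' Reads a delimited-text table of DAPI and BONCAT cell counts, one row per
#' microscopy field of view, with the columns `sample_id`, `habitat`,
#' `incubation`, `incubation_time_days`, `replicate`, `field_of_view`,
#' `dapi_count`, `boncat_count`. Counts must be non-negative integers with
#' `boncat_count <= dapi_count` (BONCAT-positive cells are a subset of
#' DAPI-stained cells). Extra columns are kept with a notice.
#'
#' @param path path to a CSV (or whitespace-delimited) file.
#' @return A validated `data.frame` of class `count_table`.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl(",", first)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           strip.white = TRUE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("count file is empty: ", path)
  validate_counts(tab)
}

count_table_columns <- c("sample_id", "habitat", "incubation",
                         "incubation_time_days", "replicate",
                         "field_of_view", "dapi_count", "boncat_count")

#' Validate a count table
#'
#' @param tab a data.frame with the columns described in [read_counts()].
#' @return `tab` classed as `count_table`.
#' @export
validate_counts <- function(tab) {
  missing <- setdiff(count_table_columns, names(tab))
  if (length(missing)) {
    stop("count table missing column(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(tab), count_table_columns)
  if (length(extra)) {
    message("count table: keeping unrecognized column(s): ",
            paste(extra, collapse = ", "))
  }
  for (col in c("dapi_count", "boncat_count")) {
    v <- tab[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) ||
        any(v != floor(v))) {
      stop(col, " must contain non-negative integers")
    }
  }
  if (any(tab$incubation_time_days < 0)) {
    stop("incubation_time_days must be non-negative")
  }
  bad <- which(tab$boncat_count > tab$dapi_count)
  if (length(bad)) {
    stop("boncat_count exceeds dapi_count in row(s): ",
         paste(bad, collapse = ", "))
  }
  class(tab) <- c("count_table", "data.frame")
  tab
}

#' Per-field active fraction
#'
#' The fraction of DAPI-stained cells that are BONCAT-positive, i.e.
#' translationally active, in one field of view. Fields with zero DAPI
#' cells have an undefined fraction and return `NA` (they are excluded
#' from group summaries, with a logged count).
#'
#' @param dapi_count total DAPI-stained cells (non-negative integer(s)).
#' @param boncat_count BONCAT-positive cells, `<= dapi_count`.
#' @return Fraction(s) in [0, 1], `NA` where `dapi_count == 0`.
#' @export
#' @examples
#' fov_active_fraction(100, 50)  # 0.5
fov_active_fraction <- function(dapi_count, boncat_count) {
  if (any(dapi_count < 0) || any(boncat_count < 0)) {
    stop("counts must be non-negative")
  }
  if (any(boncat_count > dapi_count)) {
    stop("boncat_count cannot exceed dapi_count")
  }
  ifelse(dapi_count > 0, boncat_count / dapi_count, NA_real_)
}

#' Grouped active-fraction summaries
#'
#' Computes the mean and sample standard deviation (n - 1 denominator) of
#' per-field active fractions within each group. Fields with zero DAPI
#' cells are excluded (with a message). Groups with fewer than 20 usable
#' fields are flagged `low_n`, reflecting the convention of counting at
#' least 20 random fields of view per incubation.
#'
#' @param tab a `count_table` (see [read_counts()], [validate_counts()]).
#' @param group_by character vector of grouping columns, e.g.
#'   `c("habitat", "incubation")`.
#' @return A data.frame with the group keys plus `mean_active_fraction`,
#'   `sd_active_fraction` (`NA` for single-field groups), `n_fov`, `low_n`.
#' @export
summarize_groups <- function(tab, group_by) {
  stopifnot(inherits(tab, "data.frame"))
  if (nrow(tab) == 0L) stop("empty count table")
  if (length(group_by) == 0L) stop("group_by must name at least one column")
  missing <- setdiff(group_by, names(tab))
  if (length(missing)) {
    stop("grouping column(s) not in table: ", paste(missing, collapse = ", "))
  }
  frac <- fov_active_fraction(tab$dapi_count, tab$boncat_count)
  excluded <- sum(is.na(frac))
  if (excluded > 0) {
    message(excluded, " field(s) with zero DAPI cells excluded from summary")
  }
  keep <- !is.na(frac)
  keys <- tab[keep, group_by, drop = FALSE]
  f <- frac[keep]
  if (!length(f)) stop("no usable fields of view")
  idx <- interaction(keys, drop = TRUE, lex.order = TRUE)
  res <- do.call(rbind, lapply(levels(idx), function(lv) {
    sel <- idx == lv
    row <- unique(keys[sel, , drop = FALSE])[1, , drop = FALSE]
    row$mean_active_fraction <- mean(f[sel])
    row$sd_active_fraction <- if (sum(sel) > 1L) stats::sd(f[sel]) else NA_real_
    row$n_fov <- sum(sel)
    row
  }))
  rownames(res) <- NULL
  res$low_n <- res$n_fov < 20L
  res
}

#' Classical one-way ANOVA on active fractions
#'
#' Tests equality of group means with the classical equal-variance one-way
#' analysis of variance (F statistic on k - 1 and N - k degrees of freedom),
#' the test used for comparing replicate incubations' active fractions.
#' Degenerate inputs are handled explicitly: identical values everywhere
#' give F = 0, p = 1; zero within-group variance with unequal means gives
#' F = Inf, p = 0 with a warning.
#'
#' @param groups a list of numeric vectors (one per group, each length >= 2),
#'   or a data.frame with columns `value` and `group`.
#' @return A list with `F`, `p_value`, `df_between`, `df_within`.
#' @export
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))  # F = 1.5 on (1, 4) df
one_way_anova <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  if (!is.list(groups) || length(groups) < 2L) {
    stop("at least 2 groups required")
  }
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("each group needs at least 2 observations")
  values <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(values))) stop("non-finite observations")
  g <- factor(rep(seq_along(groups), sizes))
  k <- length(groups); N <- length(values)
  within_var <- sum(vapply(groups, function(x) sum((x - mean(x))^2),
                           numeric(1)))
  means <- vapply(groups, mean, numeric(1))
  if (within_var == 0) {
    if (max(means) - min(means) == 0) {
      return(list(F = 0, p_value = 1, df_between = k - 1L,
                  df_within = N - k))
    }
    warning("zero within-group variance with unequal means; p = 0")
    return(list(F = Inf, p_value = 0, df_between = k - 1L,
                df_within = N - k))
  }
  fit <- stats::anova(stats::lm(values ~ g))
  list(F = fit$`F value`[1], p_value = fit$`Pr(>F)`[1],
       df_between = fit$Df[1], df_within = fit$Df[2])
}

#' Simulate a synthetic BONCAT count table
#'
#' Generates per-field DAPI totals from a Poisson law and BONCAT-positive
#' counts from a beta-binomial law with mean `true_fraction`. The
#' overdispersion parameter is the scale of the underlying beta law
#' (shapes `true_fraction / od` and `(1 - true_fraction) / od`); at
#' `overdispersion = 0` the per-field fraction is fixed and the counts are
#' plain binomial. Fully reproducible from `seed`.
#'
#' @param true_fraction the population active fraction in [0, 1].
#' @param n_fov number of fields of view (>= 1).
#' @param mean_cells_per_fov Poisson mean of total cells per field (> 0).
#' @param overdispersion beta-scale overdispersion (>= 0; 0 = binomial).
#' @param seed integer seed; required for reproducibility.
#' @param sample_id,habitat,incubation,incubation_time_days,replicate
#'   metadata stamped on every row.
#' @return A `count_table` data.frame with `n_fov` rows.
#' @export
#' @examples
#' tab <- simulate_counts(0.52, n_fov = 50, mean_cells_per_fov = 100,
#'                        overdispersion = 0.1, seed = 1)
simulate_counts <- function(true_fraction, n_fov, mean_cells_per_fov,
                            overdispersion = 0, seed,
                            sample_id = "synthetic", habitat = "ice",
                            incubation = "ex_situ",
                            incubation_time_days = 1, replicate = "r1") {
  if (true_fraction < 0 || true_fraction > 1) {
    stop("true_fraction must lie in [0, 1]")
  }
  if (n_fov < 1 || n_fov != floor(n_fov)) stop("n_fov must be a positive integer")
  if (mean_cells_per_fov <= 0) stop("mean_cells_per_fov must be positive")
  if (overdispersion < 0) stop("overdispersion must be non-negative")
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  dapi <- stats::rpois(n_fov, mean_cells_per_fov)
  p <- if (overdispersion > 0 && true_fraction > 0 && true_fraction < 1) {
    stats::rbeta(n_fov, true_fraction / overdispersion,
                 (1 - true_fraction) / overdispersion)
  } else {
    rep(true_fraction, n_fov)
  }
  boncat <- stats::rbinom(n_fov, dapi, p)
  validate_counts(data.frame(
    sample_id = sample_id, habitat = habitat, incubation = incubation,
    incubation_time_days = incubation_time_days, replicate = replicate,
    field_of_view = seq_len(n_fov),
    dapi_count = dapi, boncat_count = boncat,
    stringsAsFactors = FALSE))
}
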