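#' Median of a parameter map within a region of interest
#'
#' ROI summaries use the median, which is robust to the heavy-tailed voxel
#' distributions of relaxometry maps. Sentinel (`NA`) voxels — unfit or
#' masked-out — are excluded and their count reported via attribute
#' `n_excluded`.
#'
#' @param map Numeric array (parameter map).
#' @param mask Logical/0-1 array of the same shape.
#' @return Median of in-mask non-sentinel voxels (`NA` if none), with
#'   attributes `n_used` and `n_excluded`.
#' @export
roi_median <- function(map, mask) {
  if (!all(dim(map) == dim(mask)))
    stop("map and mask are not congruent", call. = FALSE)
  v <- map[as.logical(mask)]
  if (length(v) == 0L)
    stop("empty mask", call. = FALSE)
  ok <- is.finite(v)
  out <- if (any(ok)) stats::median(v[ok]) else NA_real_
  structure(out, n_used = sum(ok), n_excluded = sum(!ok))
}

#' Read / validate an uptake table
#'
#' An uptake table is tidy: one row per subject x region x timepoint with
#' ROI-median `r1_median` and `r2star_median` (1/s; `r2star_median` is `NA`
#' for blood, where venous R2* is too heterogeneous to use).
#'
#' @param x A data frame or a path to a CSV file (comment lines starting
#'   with `#` allowed, e.g. a units header).
#' @return The validated table with class `uptake_table`.
#' @export
as_uptake_table <- function(x) {
  if (is.character(x))
    x <- utils::read.csv(x, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("subject", "region", "timepoint", "r1_median", "r2star_median")
  if (!all(need %in% names(x)))
    stop("uptake table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  key <- paste(x$subject, x$region, x$timepoint)
  if (anyDuplicated(key))
    stop("duplicate subject x region x timepoint rows", call. = FALSE)
  if (any(!is.na(x$r2star_median[x$region == "blood"])))
    stop("blood rows must not carry r2star_median", call. = FALSE)
  if (!inherits(x, "uptake_table")) class(x) <- c("uptake_table", class(x))
  x
}

.lookup <- function(tab, subject, region, timepoint, col) {
  i <- tab$subject == subject & tab$region == region &
    tab$timepoint == timepoint
  if (!any(i)) return(NA_real_)
  tab[[col]][which(i)[1]]
}

#' Blood-normalised relaxation-rate changes
#'
#' For each subject with the required rows, computes the change relative to
#' the pre-infusion baseline, `delta_r1 = r1(t) - r1(pre)` and likewise for
#' R2*, and the blood-normalised quantities
#' \deqn{\Delta R_{1,norm} = \Delta R_1 / \Delta R_1^{blood}, \qquad
#'       \Delta R^*_{2,norm} = \Delta R_2^* / \Delta R_1^{blood},}
#' using the same subject's blood delta-R1 at the same timepoint. Under a
#' linear rate-concentration relationship and purely intravascular contrast
#' (true immediately post-infusion), the normalised R1 change approximates
#' the cerebral blood volume fraction, and the normalised R2* change is
#' proportional to it.
#'
#' @param table An uptake table ([as_uptake_table]).
#' @param region Region name (not `"blood"`).
#' @param timepoint Post-infusion timepoint (`"post"`, `"24h"`,
#'   `"1month"`).
#' @return Data frame, one row per subject: `delta_r1`, `delta_r2star`,
#'   `delta_r1_blood`, `delta_r1_norm`, `delta_r2star_norm`. Normalised
#'   values are `NA` when the subject's blood delta-R1 is zero or missing.
#' @export
normalized_change <- function(table, region, timepoint) {
  table <- as_uptake_table(table)
  if (region == "blood")
    stop("normalisation target must be a tissue region", call. = FALSE)
  if (timepoint == "pre")
    stop("'timepoint' must be post-infusion", call. = FALSE)
  subjects <- unique(table$subject)
  out <- lapply(subjects, function(s) {
    r1_pre <- .lookup(table, s, region, "pre", "r1_median")
    r1_t <- .lookup(table, s, region, timepoint, "r1_median")
    r2_pre <- .lookup(table, s, region, "pre", "r2star_median")
    r2_t <- .lookup(table, s, region, timepoint, "r2star_median")
    b_pre <- .lookup(table, s, "blood", "pre", "r1_median")
    b_t <- .lookup(table, s, "blood", timepoint, "r1_median")
    if (is.na(b_pre) || is.na(b_t))
      stop(sprintf("missing blood r1 for subject %s at %s", s, timepoint),
           call. = FALSE)
    d1 <- r1_t - r1_pre
    d2 <- r2_t - r2_pre
    db <- b_t - b_pre
    data.frame(subject = s, region = region, timepoint = timepoint,
               delta_r1 = d1, delta_r2star = d2, delta_r1_blood = db,
               delta_r1_norm = if (!is.na(db) && db != 0) d1 / db else
                 NA_real_,
               delta_r2star_norm = if (!is.na(db) && db != 0) d2 / db else
                 NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Coefficient of variation (%)
#'
#' `100 * sd / mean` using the population (1/n) standard deviation, so the
#' three-value example `c(1, 2, 3)` gives 40.8%.
#'
#' @param x Numeric vector (`NA`s dropped).
#' @return CoV in percent.
#' @export
cov_percent <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  100 * sqrt(mean((x - m)^2)) / m
}

# Paired t-test tolerating the zero-variance edge: identical vectors give
# t = 0, p = 1 (stats::t.test refuses essentially-constant data).
paired_t <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  d <- x[ok] - y[ok]
  if (length(d) < 3L)
    return(list(t = NA_real_, p = NA_real_, n = length(d), mean_diff =
                  if (length(d)) mean(d) else NA_real_))
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, n = length(d), mean_diff = 0))
    return(list(t = sign(mean(d)) * Inf, p = 0, n = length(d),
                mean_diff = mean(d)))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), p = tt$p.value, n = length(d),
       mean_diff = mean(d))
}

#' Cohort-level statistics on an uptake table
#'
#' Reproduces the inference chain applied to ROI-median relaxation rates:
#' \itemize{
#'   \item per region and post-infusion timepoint, a two-sided paired t-test
#'     of the rate against baseline (R1 and R2* separately);
#'   \item paired comparisons between consecutive post-infusion timepoints;
#'   \item per region and timepoint, linear regression of `delta_r2star` on
#'     `delta_r1` across subjects (intercept, slope, R-squared, Pearson r
#'     and its p-value);
#'   \item group summaries of the blood-normalised changes (mean, CoV%);
#'   \item paired between-tissue comparisons of the normalised changes
#'     (all tissue pairs).
#' }
#' No multiple-testing correction is applied; raw p-values are reported
#' against a plain 0.05 threshold. Subjects missing a row for a given test
#' are dropped pairwise (and counted in `n`).
#'
#' @param table An uptake table ([as_uptake_table]).
#' @param timepoints Post-infusion timepoints to analyse.
#' @return A list of data frames: `vs_baseline`, `between_timepoints`,
#'   `regression`, `normalized_summary`, `between_tissues`; class
#'   `cohort_stats`.
#' @export
cohort_stats <- function(table, timepoints = c("post", "24h")) {
  table <- as_uptake_table(table)
  regions <- setdiff(unique(table$region), character(0))
  tissues <- setdiff(regions, "blood")

  get_vec <- function(region, tp, col) {
    subjects <- sort(unique(table$subject))
    vapply(subjects, function(s) .lookup(table, s, region, tp, col), 0)
  }

  vs_baseline <- list(); k <- 0L
  for (rg in regions) for (tp in timepoints) for (col in
      c("r1_median", "r2star_median")) {
    if (rg == "blood" && col == "r2star_median") next
    res <- paired_t(get_vec(rg, tp, col), get_vec(rg, "pre", col))
    k <- k + 1L
    vs_baseline[[k]] <- data.frame(region = rg, timepoint = tp,
      measure = sub("_median", "", col), n = res$n,
      mean_change = res$mean_diff, t = res$t, p = res$p,
      stringsAsFactors = FALSE)
  }
  vs_baseline <- do.call(rbind, vs_baseline)

  between_tp <- list(); k <- 0L
  if (length(timepoints) >= 2L) {
    prs <- utils::combn(timepoints, 2, simplify = FALSE)
    for (rg in regions) for (pr in prs) for (col in
        c("r1_median", "r2star_median")) {
      if (rg == "blood" && col == "r2star_median") next
      res <- paired_t(get_vec(rg, pr[2], col), get_vec(rg, pr[1], col))
      k <- k + 1L
      between_tp[[k]] <- data.frame(region = rg, from = pr[1], to = pr[2],
        measure = sub("_median", "", col), n = res$n,
        mean_change = res$mean_diff, t = res$t, p = res$p,
        stringsAsFactors = FALSE)
    }
  }
  between_tp <- if (k) do.call(rbind, between_tp) else NULL

  regression <- list(); k <- 0L
  norm_all <- list()
  for (rg in tissues) for (tp in timepoints) {
    nc <- normalized_change(table, rg, tp)
    norm_all[[paste(rg, tp)]] <- nc
    ok <- is.finite(nc$delta_r1) & is.finite(nc$delta_r2star)
    if (sum(ok) >= 3L && stats::sd(nc$delta_r1[ok]) > 0 &&
        stats::sd(nc$delta_r2star[ok]) > 0) {
      f <- stats::lm(delta_r2star ~ delta_r1, data = nc[ok, ])
      ct <- stats::cor.test(nc$delta_r1[ok], nc$delta_r2star[ok])
      k <- k + 1L
      regression[[k]] <- data.frame(region = rg, timepoint = tp,
        n = sum(ok), beta0 = unname(stats::coef(f)[1]),
        beta1 = unname(stats::coef(f)[2]),
        r_squared = summary(f)$r.squared,
        pearson_r = unname(ct$estimate), p = ct$p.value,
        stringsAsFactors = FALSE)
    }
  }
  regression <- if (k) do.call(rbind, regression) else NULL

  norm_summary <- do.call(rbind, lapply(names(norm_all), function(nm) {
    nc <- norm_all[[nm]]
    data.frame(region = nc$region[1], timepoint = nc$timepoint[1],
      n = sum(is.finite(nc$delta_r1_norm)),
      mean_delta_r1_norm = mean(nc$delta_r1_norm, na.rm = TRUE),
      cov_delta_r1_norm = cov_percent(nc$delta_r1_norm),
      mean_delta_r2star_norm = mean(nc$delta_r2star_norm, na.rm = TRUE),
      cov_delta_r2star_norm = cov_percent(nc$delta_r2star_norm),
      stringsAsFactors = FALSE)
  }))

  between_tissues <- list(); k <- 0L
  if (length(tissues) >= 2L) {
    prs <- utils::combn(sort(tissues), 2, simplify = FALSE)
    for (pr in prs) for (tp in timepoints) for (col in
        c("delta_r1_norm", "delta_r2star_norm")) {
      a <- norm_all[[paste(pr[1], tp)]]; b <- norm_all[[paste(pr[2], tp)]]
      m <- merge(a[, c("subject", col)], b[, c("subject", col)],
                 by = "subject", suffixes = c("_a", "_b"))
      res <- paired_t(m[[paste0(col, "_a")]], m[[paste0(col, "_b")]])
      k <- k + 1L
      between_tissues[[k]] <- data.frame(region_a = pr[1], region_b = pr[2],
        timepoint = tp, measure = col, n = res$n,
        mean_diff = res$mean_diff, t = res$t, p = res$p,
        stringsAsFactors = FALSE)
    }
  }
  between_tissues <- if (k) do.call(rbind, between_tissues) else NULL

  structure(list(vs_baseline = vs_baseline,
                 between_timepoints = between_tp,
                 regression = regression,
                 normalized_summary = norm_summary,
                 between_tissues = between_tissues),
            class = "cohort_stats")
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat("<cohort_stats>\n\n== Changes vs baseline (paired t) ==\n")
  print(x$vs_baseline, row.names = FALSE, digits = 3)
  if (!is.null(x$between_timepoints)) {
    cat("\n== Between post-infusion timepoints ==\n")
    print(x$between_timepoints, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$regression)) {
    cat("\n== Regression of delta-R2* on delta-R1 ==\n")
    print(x$regression, row.names = FALSE, digits = 3)
  }
  cat("\n== Blood-normalised changes (mean, CoV%) ==\n")
  print(x$normalized_summary, row.names = FALSE, digits = 3)
  if (!is.null(x$between_tissues)) {
    cat("\n== Between-tissue comparisons (normalised changes) ==\n")
    print(x$between_tissues, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
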