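#' Summary statistics per morphometric parameter
#'
#' Mean, standard deviation (n-1 denominator), standard error and
#' coefficient of variability (SD/mean) for every numeric parameter of a
#' measurement table. With a single nucleus the dispersion statistics are
#' recorded as missing.
#'
#' @param records Data frame from [measure_nuclei()] (or any data frame of
#'   numeric parameter columns).
#' @param population Optional population identifier stored on the result.
#' @return Data frame with one row per parameter: `parameter`, `n`, `mean`,
#'   `sd`, `se`, `cv`.
#' @export
summarize_records <- function(records, population = NA_character_) {
  num <- records[vapply(records, is.numeric, logical(1))]
  n <- nrow(num)
  out <- data.frame(
    parameter = names(num),
    n = n,
    mean = vapply(num, mean, numeric(1), na.rm = TRUE),
    sd = if (n > 1) vapply(num, stats::sd, numeric(1), na.rm = TRUE)
         else NA_real_,
    row.names = NULL
  )
  out$se <- out$sd / sqrt(n)
  out$cv <- out$sd / out$mean
  out$population <- population
  out
}

#' Pairwise Wilcoxon rank-sum comparisons between populations
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) tests for every pair of
#' populations, per parameter, with Bonferroni correction. The correction
#' family is all pairwise comparisons within one parameter (so each
#' parameter's p-values are corrected by the number of population pairs);
#' set `family = "global"` to correct over all parameters at once. Exact
#' p-values are used for small untied samples, the normal approximation with
#' midranks otherwise (the default behaviour of [stats::wilcox.test()]).
#'
#' @param records Data frame of measurements including a grouping column.
#' @param group Name of the grouping column.
#' @param parameters Character vector of parameter columns to test
#'   (defaults to all numeric columns).
#' @param family `"per_parameter"` (default) or `"global"` Bonferroni
#'   family.
#' @return Data frame with columns `parameter`, `group1`, `group2`,
#'   `p_raw`, `p_adjusted`.
#' @export
compare_populations <- function(records, group = "population",
                                parameters = NULL,
                                family = c("per_parameter", "global")) {
  family <- match.arg(family)
  if (!group %in% names(records)) stop("no column '", group, "'")
  g <- factor(records[[group]])
  if (nlevels(g) < 2) stop("need at least two populations")
  if (is.null(parameters)) {
    parameters <- names(records)[vapply(records, is.numeric, logical(1))]
  }
  pairs <- utils::combn(levels(g), 2)
  rows <- list()
  for (p in parameters) {
    for (j in seq_len(ncol(pairs))) {
      a <- records[[p]][g == pairs[1, j]]
      b <- records[[p]][g == pairs[2, j]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      pv <- if (length(a) >= 1 && length(b) >= 1 &&
                (length(unique(c(a, b))) > 1)) {
        suppressWarnings(stats::wilcox.test(a, b, exact = NULL)$p.value)
      } else 1
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, group1 = pairs[1, j], group2 = pairs[2, j],
        p_raw = pv
      )
    }
  }
  out <- do.call(rbind, rows)
  m <- if (family == "per_parameter") ncol(pairs)
       else ncol(pairs) * length(parameters)
  out$p_adjusted <- pmin(1, out$p_raw * m)
  out
}
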