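#' Box-and-whisker summary of a sample
#'
#' Median, first and third quartiles (linear-interpolation quantiles,
#' type 7), and whiskers at the most extreme data points inside the
#' 1.5 * IQR fences `[q1 - 1.5 (q3 - q1), q3 + 1.5 (q3 - q1)]`.
#'
#' @param values Numeric vector, n >= 1.
#' @return List with `n`, `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`, `outliers`.
#' @export
box_summary <- function(values) {
  values <- values[is.finite(values)]
  stop_if(length(values) == 0L, "empty sample")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_f <- q[1] - 1.5 * iqr; hi_f <- q[3] + 1.5 * iqr
  inside <- values >= lo_f & values <= hi_f
  list(n = length(values), median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(values[inside]), whisker_high = max(values[inside]),
       outliers = sort(values[!inside]))
}

# asymptotic two-sample KS p-value (Smirnov limiting distribution with the
# standard finite-sample correction of the argument)
ks_p_asymptotic <- function(D, n1, n2) {
  en <- sqrt(n1 * n2 / (n1 + n2))
  lambda <- (en + 0.12 + 0.11 / en) * D
  if (lambda < 1e-3) return(1)
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the maximum absolute difference between the two empirical CDFs;
#' the p-value uses the asymptotic two-sample formula (adequate at the
#' cohort sizes typical of behavioral assays). For very small samples an
#' exact p-value can be requested.
#'
#' @param a,b Numeric samples, each n >= 2.
#' @param exact If `TRUE`, compute the exact small-sample p-value instead of
#'   the asymptotic one.
#' @return List with `D`, `p_value`, `n_a`, `n_b`.
#' @export
ks_two_sample <- function(a, b, exact = FALSE) {
  a <- sort(a[is.finite(a)]); b <- sort(b[is.finite(b)])
  stop_if(length(a) < 2L || length(b) < 2L,
          "both samples need at least 2 values")
  n1 <- length(a); n2 <- length(b)
  pooled <- sort(unique(c(a, b)))
  # ECDFs evaluated on the pooled support
  Fa <- findInterval(pooled, a) / n1
  Fb <- findInterval(pooled, b) / n2
  D <- max(abs(Fa - Fb))
  p <- if (exact)
    suppressWarnings(stats::ks.test(a, b, exact = TRUE)$p.value)
  else ks_p_asymptotic(D, n1, n2)
  list(D = D, p_value = p, n_a = n1, n_b = n2)
}

significance_marker <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.05) "*" else ""
}

#' Compare cohorts metric by metric
#'
#' Builds one group comparison per metric from per-animal metric tables:
#' box-and-whisker summaries per group, the two-sample Kolmogorov-Smirnov
#' statistic between the two groups, and significance markers (`*` for
#' p < 0.05, `***` for p < 0.001). No multiple-testing correction is
#' applied; the number of tests is reported so users can apply their own.
#'
#' @param summaries_by_group Named list (>= 2 groups) of data.frames with
#'   one row per animal and the metrics as columns.
#' @param metrics Character vector of metric column names.
#' @param out_dir Optional directory: writes `report.json`, `report.csv`
#'   and (when `figures = TRUE`) one box-plot PNG per metric.
#' @param figures Whether to write figures (requires `out_dir`).
#' @return List of class `cohort_report`: `comparisons` (one element per
#'   metric), `groups`, `n_tests`. Metrics absent from a group are reported
#'   with `absent_in` set, not silently dropped.
#' @export
compare_cohorts <- function(summaries_by_group, metrics, out_dir = NULL,
                            figures = FALSE) {
  stop_if(length(summaries_by_group) < 2L, "need at least two groups")
  stop_if(is.null(names(summaries_by_group)),
          "summaries_by_group must be a named list")
  groups <- names(summaries_by_group)
  g1 <- groups[1]; g2 <- groups[2]
  comparisons <- lapply(metrics, function(m) {
    absent <- groups[!vapply(summaries_by_group,
                             function(df) m %in% names(df), logical(1))]
    if (length(absent))
      return(list(metric = m, absent_in = absent))
    vals <- lapply(summaries_by_group, function(df)
      df[[m]][is.finite(df[[m]])])
    ks <- if (length(vals[[g1]]) >= 2 && length(vals[[g2]]) >= 2)
      ks_two_sample(vals[[g1]], vals[[g2]])
    else list(D = NA_real_, p_value = NA_real_)
    list(metric = m,
         groups = lapply(vals, box_summary),
         D = ks$D, p_value = ks$p_value,
         marker = significance_marker(ks$p_value))
  })
  names(comparisons) <- metrics
  report <- structure(list(comparisons = comparisons, groups = groups,
                           n_tests = sum(vapply(comparisons, function(x)
                             !is.null(x$D), logical(1)))),
                      class = "cohort_report")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    rows <- do.call(rbind, lapply(comparisons, function(x) {
      if (!is.null(x$absent_in))
        return(data.frame(metric = x$metric, group = NA, n = NA,
                          median = NA, q1 = NA, q3 = NA, D = NA,
                          p_value = NA, marker = "absent"))
      do.call(rbind, lapply(names(x$groups), function(g) {
        s <- x$groups[[g]]
        data.frame(metric = x$metric, group = g, n = s$n,
                   median = s$median, q1 = s$q1, q3 = s$q3,
                   D = x$D, p_value = x$p_value, marker = x$marker)
      }))
    }))
    utils::write.csv(rows, file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    if (figures) {
      for (m in metrics) {
        x <- comparisons[[m]]
        if (!is.null(x$absent_in)) next
        grDevices::png(file.path(out_dir, paste0("box_", m, ".png")),
                       width = 480, height = 480)
        vals <- lapply(summaries_by_group, function(df)
          df[[m]][is.finite(df[[m]])])
        graphics::boxplot(vals, main = paste0(m, " ", x$marker),
                          ylab = m, range = 1.5, col = c("grey80",
                                                         "indianred"))
        grDevices::dev.off()
      }
    }
  }
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort comparison (%s), %d tests, no multiplicity correction\n",
              paste(x$groups, collapse = " vs "), x$n_tests))
  for (cmp in x$comparisons) {
    if (!is.null(cmp$absent_in)) {
      cat(sprintf("  %-24s absent in: %s\n", cmp$metric,
                  paste(cmp$absent_in, collapse = ", ")))
    } else {
      meds <- vapply(cmp$groups, function(s) s$median, numeric(1))
      cat(sprintf("  %-24s %s  D = %.3f, p = %.3g %s\n", cmp$metric,
                  paste(sprintf("%s: %.3g", names(meds), meds),
                        collapse = ", "),
                  cmp$D, cmp$p_value, cmp$marker))
    }
  }
  invisible(x)
}

#' Read a cohort report back from disk
#'
#' @param out_dir Directory written by [compare_cohorts()].
#' @return A `cohort_report` (numeric content identical to what was
#'   written).
#' @export
read_report <- function(out_dir) {
  path <- file.path(out_dir, "report.json")
  stop_if(!file.exists(path), "no report.json in ", out_dir)
  r <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  structure(r, class = "cohort_report")
}
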