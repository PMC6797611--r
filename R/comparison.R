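#' Per-region differences between two processing streams
#'
#' Subtracts, entry by entry, the template-space (e.g. MNI-warped and
#' smoothed) region matrix from the native-space one. The sign
#' convention is native minus template throughout, so a negative
#' difference means the template-space pipeline inflated the measure.
#' Missing entries propagate.
#'
#' @param S_native Native-space [region_matrix].
#' @param S_template Template-space [region_matrix] with identical
#'   region and subject order.
#' @return A [region_matrix] of differences.
#' @export
region_differences <- function(S_native, S_template) {
  stopifnot(inherits(S_native, "region_matrix"), inherits(S_template, "region_matrix"))
  if (!identical(dim(S_native), dim(S_template)) ||
      !identical(attr(S_native, "region_labels"), attr(S_template, "region_labels")) ||
      !identical(attr(S_native, "subject_ids"), attr(S_template, "subject_ids"))) {
    stop("Matrices must share regions and subjects in identical order ",
         "(native: ", nrow(S_native), "x", ncol(S_native),
         ", template: ", nrow(S_template), "x", ncol(S_template), ").",
         call. = FALSE)
  }
  new_region_matrix(unclass(S_native) - unclass(S_template),
                    attr(S_native, "region_labels"),
                    attr(S_native, "region_names"),
                    attr(S_native, "subject_ids"),
                    paste0("diff(", attr(S_native, "statistic"), ")"))
}

#' Per-region one-sample t-test on paired differences
#'
#' For each brain area, tests whether the mean across subjects of the
#' native-minus-template difference is zero: `t = dbar / (s / sqrt(n))`
#' with the sample standard deviation `s`, two-sided p from the t
#' distribution on `n - 1` degrees of freedom. No multiple-testing
#' correction is applied by default (the conventional uncorrected
#' p < alpha map); Bonferroni or Benjamini-Hochberg adjustment is
#' available via `adjust`. Zero-variance regions are degenerate: with
#' a zero mean they get `t = 0, p = 1`; with a non-zero mean the
#' difference is exactly constant across subjects, and the region is
#' flagged (`p = 0`) with a warning rather than hidden.
#'
#' @param D A [region_matrix] of differences (see
#'   [region_differences()]); each region needs >= 2 non-missing
#'   subjects.
#' @param alpha Significance level, default 0.05.
#' @param adjust `"none"` (default), `"bonferroni"` or `"BH"`.
#' @return A tibble of class `region_comparison` with columns `label`,
#'   `name_area`, `n`, `mean_difference`, `t_statistic`, `p_value`,
#'   `significant`, `degenerate`; attributes `alpha`, `adjust`,
#'   `n_subjects`.
#' @export
ttest_per_region <- function(D, alpha = 0.05, adjust = "none") {
  stopifnot(inherits(D, "region_matrix"))
  if (!adjust %in% c("none", "bonferroni", "BH")) {
    stop("`adjust` must be \"none\", \"bonferroni\" or \"BH\".", call. = FALSE)
  }
  X <- unclass(D)
  n <- rowSums(!is.na(X))
  short <- which(n < 2L)
  if (length(short)) {
    stop("Region(s) with fewer than 2 observations: ",
         paste(attr(D, "region_names")[short], collapse = ", "), call. = FALSE)
  }
  dbar <- rowMeans(X, na.rm = TRUE)
  s <- apply(X, 1L, stats::sd, na.rm = TRUE)
  tt <- numeric(nrow(X))
  p <- numeric(nrow(X))
  degenerate <- s == 0 & dbar != 0
  zero <- s == 0 & dbar == 0
  ok <- !degenerate & !zero
  tt[ok] <- dbar[ok] / (s[ok] / sqrt(n[ok]))
  p[ok] <- 2 * stats::pt(abs(tt[ok]), df = n[ok] - 1L, lower.tail = FALSE)
  tt[zero] <- 0
  p[zero] <- 1
  if (any(degenerate)) {
    tt[degenerate] <- sign(dbar[degenerate]) * Inf
    p[degenerate] <- 0
    warning(sum(degenerate), " region(s) with zero variance but non-zero mean ",
            "difference (constant offset across subjects); flagged degenerate.",
            call. = FALSE)
  }
  p_adj <- stats::p.adjust(p, method = if (adjust == "none") "none" else adjust)
  out <- tibble::tibble(
    label = attr(D, "region_labels"),
    name_area = attr(D, "region_names"),
    n = as.integer(n),
    mean_difference = dbar,
    t_statistic = tt,
    p_value = p_adj,
    significant = p_adj < alpha,
    degenerate = degenerate
  )
  attr(out, "alpha") <- alpha
  attr(out, "adjust") <- adjust
  attr(out, "n_subjects") <- ncol(X)
  class(out) <- c("region_comparison", class(out))
  out
}

#' @export
print.region_comparison <- function(x, ...) {
  cat("<region_comparison> ", nrow(x), " regions, ",
      sum(x$significant), " significant at alpha = ", attr(x, "alpha"),
      " (", attr(x, "adjust"), ")\n", sep = "")
  NextMethod()
}

#' One-row summary of a regional comparison
#'
#' @param x A `region_comparison`.
#' @param ... Unused.
#' @method glance region_comparison
#' @export
glance.region_comparison <- function(x, ...) {
  tibble::tibble(
    n_regions = nrow(x),
    n_significant = sum(x$significant),
    frac_significant = mean(x$significant),
    alpha = attr(x, "alpha"),
    adjust = attr(x, "adjust"),
    mean_of_mean_differences = mean(x$mean_difference)
  )
}

#' Write a comparison table as TSV
#'
#' @param x A `region_comparison`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(x, path) {
  stopifnot(inherits(x, "region_comparison"))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "label" & names(df) != "n"
  df[num] <- lapply(df[num], function(col) formatC(col, digits = 12L, format = "g"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste0("# alpha=", attr(x, "alpha"), " adjust=", attr(x, "adjust")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
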