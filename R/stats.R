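#' Kruskal-Wallis omnibus test
#'
#' Rank-based k-group omnibus test on mid-ranks with the standard tie
#' correction (via [stats::kruskal.test()]); the p-value uses the chi-square
#' approximation with `k - 1` degrees of freedom.
#'
#' @param groups list of >= 2 numeric vectors, each nonempty, >= 3 values in
#'   total.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  n <- lengths(groups)
  if (any(n == 0L)) stop("every group must have at least one observation")
  if (sum(n) < 3L) stop("need at least three observations in total")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep.int(seq_along(groups), n))
  if (length(unique(x)) == 1L)
    stop("all values identical: the statistic is undefined")
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

#' Dunn's post hoc test over a declared comparison family
#'
#' For each pair in the family, computes the Dunn z statistic
#' `z = (Rbar_a - Rbar_b) / SE` over the pooled mid-ranking, with the
#' tie-corrected standard error
#' `SE = sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_a + 1/n_b))`,
#' `T = sum(t^3 - t)` over tied-value groups. Unadjusted p-values are
#' two-sided normal; the adjustment multiplies by the family size
#' (Bonferroni over the declared family, capped at 1). Only the declared
#' pairs are tested - the family is an input, never all-pairs by default.
#'
#' @param groups named list of numeric vectors.
#' @param family list of length-2 character (or index) vectors naming the
#'   comparisons.
#' @param adjustment `"bonferroni"` (default) or `"none"`.
#' @return Data frame (group_a, group_b, z, p_unadjusted, p_adjusted).
#' @export
dunn_posthoc <- function(groups, family,
                         adjustment = c("bonferroni", "none")) {
  adjustment <- match.arg(adjustment)
  if (length(family) == 0L) stop("the comparison family is empty")
  if (is.null(names(groups)))
    names(groups) <- as.character(seq_along(groups))
  nms <- names(groups)
  fam <- lapply(family, function(p) {
    if (is.numeric(p)) p <- nms[p]
    if (length(p) != 2L || !all(p %in% nms))
      stop("family pair references unknown groups: ",
           paste(p, collapse = " vs "))
    p
  })
  x <- unlist(groups, use.names = FALSE)
  g <- rep(nms, lengths(groups))
  r <- rank(x)  # mid-ranks
  N <- length(x)
  rbar <- tapply(r, g, mean)
  nn <- tapply(r, g, length)
  ties <- table(x)
  TIE <- sum(ties^3 - ties)
  s2 <- N * (N + 1) / 12 - TIE / (12 * (N - 1))
  m <- length(fam)
  rows <- lapply(fam, function(p) {
    se <- sqrt(s2 * (1 / nn[[p[1]]] + 1 / nn[[p[2]]]))
    z <- (rbar[[p[1]]] - rbar[[p[2]]]) / se
    pu <- 2 * stats::pnorm(-abs(z))
    data.frame(group_a = p[1], group_b = p[2], z = z, p_unadjusted = pu,
               p_adjusted = if (adjustment == "bonferroni")
                 min(1, m * pu) else pu)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median and quartiles
#'
#' Inclusive linear-interpolation quartiles ([stats::quantile()] type 7),
#' the convention used for violin-plot median/quartile guide lines.
#'
#' @param values numeric vector, n >= 1.
#' @return list with `median`, `q1`, `q3`, `n`.
#' @export
summarize_distribution <- function(values) {
  if (length(values) < 1L) stop("need at least one value")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], n = length(values))
}

#' Multi-group comparison of granule measurements
#'
#' For each measure in the cohort table (pooled granule volumes; per-
#' mitochondrion granule densities), runs the Kruskal-Wallis omnibus test
#' and Dunn's post hoc over the declared family, and reports per-group n,
#' median and quartiles.
#'
#' @param table long-format data frame with columns condition, tomogram_id,
#'   unit_id, measure, value.
#' @param family list of condition pairs to compare (e.g. control vs each
#'   disease line); when NULL, every condition is compared against
#'   `control`.
#' @param control control condition name used to build the default family.
#' @param adjustment multiplicity adjustment passed to [dunn_posthoc()].
#' @param on_degenerate `"error"` (default): a measure with identical
#'   values, or missing conditions, raises the undefined-statistic error;
#'   `"mark"`: such a measure yields a `group_comparison_degenerate` marker
#'   carrying the reason, so a multi-measure run can continue (used by the
#'   pipeline, where an undertrained model can legitimately detect nothing).
#' @return A list of `group_comparison` objects (one per measure), itself
#'   classed `group_comparison_set`.
#' @export
run_group_comparisons <- function(table, family = NULL, control = NULL,
                                  adjustment = "bonferroni",
                                  on_degenerate = c("error", "mark")) {
  on_degenerate <- match.arg(on_degenerate)
  need <- c("condition", "measure", "value")
  if (!all(need %in% names(table)))
    stop("table must have columns condition, measure, value")
  if (!all(is.finite(table$value)) || any(table$value < 0))
    stop("values must be finite and >= 0")
  conds <- unique(table$condition)
  if (length(conds) < 2L) stop("need at least two conditions")
  if (is.null(family)) {
    if (is.null(control)) stop("provide either a family or a control name")
    if (!control %in% conds) stop("unknown control condition: ", control)
    family <- lapply(setdiff(conds, control), function(cn) c(control, cn))
  }
  out <- lapply(unique(table$measure), function(ms) {
    sub <- table[table$measure == ms, , drop = FALSE]
    groups <- split(sub$value, sub$condition)
    groups <- groups[order(match(names(groups), conds))]
    if (on_degenerate == "mark") {
      bad <- if (length(groups) < 2L)
        "fewer than two conditions carry this measure"
      else if (length(unique(sub$value)) == 1L)
        "all values identical"
      else NULL
      if (!is.null(bad))
        return(structure(list(measure = ms, reason = bad),
                         class = "group_comparison_degenerate"))
    }
    kw <- kruskal_wallis(groups)
    pw <- dunn_posthoc(groups, family, adjustment)
    summ <- do.call(rbind, lapply(names(groups), function(nm) {
      s <- summarize_distribution(groups[[nm]])
      data.frame(condition = nm, n = s$n, median = s$median,
                 q1 = s$q1, q3 = s$q3)
    }))
    structure(list(measure = ms, H = kw$H, df = kw$df, p_omnibus = kw$p,
                   pairwise = pw, family = family,
                   adjustment = adjustment, group_summary = summ),
              class = "group_comparison")
  })
  names(out) <- unique(table$measure)
  structure(out, class = "group_comparison_set")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Measure: %s\n", x$measure))
  cat(sprintf("  Kruskal-Wallis H = %.4g, df = %d, p = %.4g\n",
              x$H, x$df, x$p_omnibus))
  cat(sprintf("  Dunn's post hoc (%s over %d declared pairs):\n",
              x$adjustment, nrow(x$pairwise)))
  for (i in seq_len(nrow(x$pairwise))) {
    r <- x$pairwise[i, ]
    cat(sprintf("    %s vs %s: z = %.3f, p = %.4g, p_adj = %.4g\n",
                r$group_a, r$group_b, r$z, r$p_unadjusted, r$p_adjusted))
  }
  cat("  Groups:\n")
  for (i in seq_len(nrow(x$group_summary))) {
    s <- x$group_summary[i, ]
    cat(sprintf("    %s: n = %d, median = %.4g [%.4g, %.4g]\n",
                s$condition, s$n, s$median, s$q1, s$q3))
  }
  invisible(x)
}

#' @export
print.group_comparison_degenerate <- function(x, ...) {
  cat(sprintf("Measure: %s\n  not testable: %s\n", x$measure, x$reason))
  invisible(x)
}

#' @export
print.group_comparison_set <- function(x, ...) {
  for (g in x) { print(g); cat("\n") }
  invisible(x)
}

#' Flatten comparison results to one row per test
#'
#' @param results a [run_group_comparisons()] result.
#' @return Data frame with the omnibus row (`test = "kruskal_wallis"`) and
#'   one row per pairwise Dunn test, per measure.
#' @export
comparison_table <- function(results) {
  stopifnot(inherits(results, "group_comparison_set"))
  rows <- lapply(results, function(x) {
    if (inherits(x, "group_comparison_degenerate"))
      return(data.frame(measure = x$measure, test = "degenerate",
                        group_a = NA, group_b = NA, statistic = NA,
                        p = NA, p_adjusted = NA))
    omni <- data.frame(measure = x$measure, test = "kruskal_wallis",
                       group_a = NA, group_b = NA, statistic = x$H,
                       p = x$p_omnibus, p_adjusted = NA)
    pw <- data.frame(measure = x$measure, test = "dunn",
                     group_a = x$pairwise$group_a,
                     group_b = x$pairwise$group_b,
                     statistic = x$pairwise$z, p = x$pairwise$p_unadjusted,
                     p_adjusted = x$pairwise$p_adjusted)
    rbind(omni, pw)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
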