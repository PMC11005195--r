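# Holm-Sidak step-down adjustment: order p ascending, adjust the i-th of m as
# 1 - (1 - p)^(m - i + 1), then enforce monotonicity by running max.
holm_sidak_adjust <- function(p) {
  o <- order(p)
  m <- length(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Dunn's rank-based post hoc z statistics after a Kruskal-Wallis test,
# with the standard tie correction; Bonferroni-adjusted two-sided p values.
dunn_posthoc <- function(values_by_group, control = NULL) {
  groups <- names(values_by_group)
  all_v <- unlist(values_by_group, use.names = FALSE)
  N <- length(all_v)
  rk <- rank(all_v)
  ties <- table(all_v)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  splits <- rep(groups, vapply(values_by_group, length, integer(1)))
  rbar <- tapply(rk, splits, mean)
  n <- tapply(rk, splits, length)
  pairs <- if (is.null(control)) utils::combn(groups, 2, simplify = FALSE)
           else lapply(setdiff(groups, control), function(g) c(control, g))
  rows <- lapply(pairs, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[pr[1]] + 1 / n[pr[2]]))
    z <- (rbar[pr[1]] - rbar[pr[2]]) / se
    data.frame(group1 = pr[1], group2 = pr[2], statistic = unname(z),
               p_value = unname(2 * stats::pnorm(-abs(z))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$p_adjusted <- pmin(out$p_value * nrow(out), 1)
  out
}

# One-sided 2x2 chi-square: signed square root of the X^2 statistic (sign from
# the difference in proportions, group 1 minus group 2) referred to the normal
# tail named by `alternative`.
chisq_2x2_one_sided <- function(tab, alternative) {
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2 x 2 table", call. = FALSE)
  if (any(tab < 0) || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate 2 x 2 table", call. = FALSE)
  x2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  z <- sqrt(x2$statistic) * sign(tab[1, 1] / sum(tab[1, ]) - tab[2, 1] / sum(tab[2, ]))
  p <- if (alternative == "greater") stats::pnorm(z, lower.tail = FALSE)
       else stats::pnorm(z)
  list(statistic = unname(z), p_value = unname(p))
}

#' Group comparison by a declared design
#'
#' One entry point for the statistical tests used on cohort readouts:
#' one-tailed Student's t (paired or unpaired), Mann-Whitney, one-way ANOVA
#' with Dunnett's or Holm-Sidak post hoc comparisons against a control,
#' Kruskal-Wallis with Dunn's post hoc, and a one-sided chi-square on a 2 x 2
#' contingency table. The direction of every one-tailed test must be declared
#' in the design — it is never inferred from the data.
#'
#' @param values_by_group Named list of numeric vectors (or, for
#'   `"chisq_2x2"`, a 2 x 2 count matrix or a named list of two
#'   `c(high, low)` count vectors).
#' @param design List with `test` (one of `"t"`, `"mann_whitney"`,
#'   `"anova_dunnett"`, `"anova_holm_sidak"`, `"kruskal_dunn"`,
#'   `"chisq_2x2"`), `alternative` (`"greater"`, `"less"`, `"two.sided"`;
#'   required for one-tailed designs, interpreted as group 1 vs group 2),
#'   optional `paired` (t only) and `control` (post hoc family).
#' @param outliers Optional outlier rule applied per group before testing
#'   (`"mad"` or `NULL`); exclusions are reported, never silent.
#' @return List of class `comparison_result`: `test_name`, `groups`,
#'   `statistic`, `p_value`, `direction`, `n` (per group, after exclusion),
#'   `excluded_outliers`, and `posthoc` (data.frame) for multi-group designs.
#' @export
compare_groups <- function(values_by_group, design, outliers = NULL) {
  if (is.null(design$test)) stop("`design$test` is required", call. = FALSE)
  test <- match.arg(design$test, c("t", "mann_whitney", "anova_dunnett",
                                   "anova_holm_sidak", "kruskal_dunn",
                                   "chisq_2x2"))
  if (test == "chisq_2x2") {
    tab <- if (is.matrix(values_by_group)) values_by_group
           else do.call(rbind, values_by_group)
    alt <- design$alternative
    if (is.null(alt) || !alt %in% c("greater", "less"))
      stop("chisq_2x2 is one-sided: declare alternative 'greater' or 'less'",
           call. = FALSE)
    res <- chisq_2x2_one_sided(tab, alt)
    return(structure(list(test_name = "one-sided chi-square 2x2",
                          groups = rownames(tab), statistic = res$statistic,
                          p_value = res$p_value, direction = alt,
                          n = rowSums(tab), excluded_outliers = numeric(0),
                          posthoc = NULL),
                     class = "comparison_result"))
  }

  if (!is.list(values_by_group) || is.null(names(values_by_group)))
    stop("`values_by_group` must be a named list", call. = FALSE)
  excluded <- list()
  if (!is.null(outliers)) {
    for (g in names(values_by_group)) {
      r <- remove_outliers(values_by_group[[g]], method = outliers)
      values_by_group[[g]] <- r$kept
      if (length(r$excluded)) excluded[[g]] <- r$excluded
    }
  }
  n <- vapply(values_by_group, length, integer(1))
  if (test %in% c("t", "anova_dunnett", "anova_holm_sidak") && any(n < 2))
    stop(sprintf("parametric test needs n >= 2 in every group (got: %s)",
                 paste(n, collapse = ", ")), call. = FALSE)
  groups <- names(values_by_group)

  if (test %in% c("t", "mann_whitney")) {
    if (length(groups) != 2L) stop("two-group design expected", call. = FALSE)
    alt <- design$alternative
    if (is.null(alt))
      stop("declare `alternative` ('greater', 'less' or 'two.sided') in the design",
           call. = FALSE)
    x <- values_by_group[[1]]; y <- values_by_group[[2]]
    ht <- if (test == "t")
            stats::t.test(x, y, alternative = alt,
                          paired = isTRUE(design$paired), var.equal = TRUE)
          else stats::wilcox.test(x, y, alternative = alt, exact = FALSE)
    return(structure(list(test_name = ht$method, groups = groups,
                          statistic = unname(ht$statistic),
                          p_value = ht$p.value, direction = alt, n = n,
                          excluded_outliers = excluded, posthoc = NULL),
                     class = "comparison_result"))
  }

  # multi-group designs
  df <- data.frame(
    value = unlist(values_by_group, use.names = FALSE),
    group = factor(rep(groups, n), levels = groups))
  control <- if (is.null(design$control)) groups[1] else design$control
  if (!control %in% groups)
    stop(sprintf("control group '%s' not found", control), call. = FALSE)
  df$group <- stats::relevel(df$group, ref = control)
  if (test == "kruskal_dunn") {
    kw <- stats::kruskal.test(value ~ group, data = df)
    ph <- dunn_posthoc(values_by_group, control = control)
    return(structure(list(test_name = "Kruskal-Wallis with Dunn's post hoc",
                          groups = groups, statistic = unname(kw$statistic),
                          p_value = kw$p.value, direction = "two.sided", n = n,
                          excluded_outliers = excluded, posthoc = ph),
                     class = "comparison_result"))
  }
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  if (test == "anova_dunnett") {
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
    sm <- summary(gl)
    ph <- data.frame(comparison = names(sm$test$coefficients),
                     estimate = unname(sm$test$coefficients),
                     statistic = unname(sm$test$tstat),
                     p_adjusted = unname(as.numeric(sm$test$pvalues)),
                     stringsAsFactors = FALSE)
    name <- "one-way ANOVA with Dunnett's post hoc"
  } else {
    others <- setdiff(groups, control)
    raw <- vapply(others, function(g)
      stats::t.test(values_by_group[[g]], values_by_group[[control]],
                    var.equal = TRUE)$p.value, numeric(1))
    ph <- data.frame(comparison = paste(others, "-", control),
                     p_value = unname(raw),
                     p_adjusted = holm_sidak_adjust(unname(raw)),
                     stringsAsFactors = FALSE)
    name <- "one-way ANOVA with Holm-Sidak post hoc"
  }
  structure(list(test_name = name, groups = groups,
                 statistic = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
                 direction = "two.sided", n = n,
                 excluded_outliers = excluded, posthoc = ph),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison> %s\n  groups: %s (n = %s)\n  statistic %.4g, p = %.4g (%s)\n",
              x$test_name, paste(x$groups, collapse = ", "),
              paste(x$n, collapse = "/"), x$statistic, x$p_value, x$direction))
  if (length(x$excluded_outliers))
    cat(sprintf("  excluded outliers: %s\n",
                paste(vapply(names(x$excluded_outliers), function(g)
                  sprintf("%s: %s", g,
                          paste(signif(x$excluded_outliers[[g]], 4), collapse = ",")),
                  character(1)), collapse = "; ")))
  if (!is.null(x$posthoc)) {
    cat("  post hoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Robust outlier exclusion
#'
#' Median absolute deviation rule: values farther than `k` scaled MADs
#' (1.4826 * MAD, the normal-consistent scale) from the median are excluded.
#' A MAD of zero (all values equal) excludes nothing. Exclusions are always
#' reported alongside the kept values.
#'
#' @param values Numeric vector of length >= 4.
#' @param method Only `"mad"` is implemented.
#' @param k Cut-off in scaled MAD units, default 3.
#' @return List with `kept` and `excluded`.
#' @export
remove_outliers <- function(values, method = "mad", k = 3) {
  if (!identical(method, "mad"))
    stop(sprintf("unknown outlier method '%s'", method), call. = FALSE)
  if (length(values) < 4L) stop("need >= 4 values", call. = FALSE)
  s <- stats::mad(values)   # includes the 1.4826 consistency constant
  if (s == 0) return(list(kept = values, excluded = numeric(0)))
  out <- abs(values - stats::median(values)) > k * s
  list(kept = values[!out], excluded = values[out])
}

#' Cross-level summary matrix
#'
#' Joins the molecular readouts (AB-FRET efficiency, donor-acceptor distance,
#' FRET index) with the morphological readouts (axis ratio, body length) per
#' embryo, and reports per-group medians of every column — the table behind
#' efficiency-versus-morphology and dose-response views.
#'
#' @param molecular data.frame with `embryo_id`, `group` and any of
#'   `E_percent`, `R_DA_nm`, `index`.
#' @param morphological Optional data.frame with `embryo_id`, `group`,
#'   `axis_ratio`, `body_length`; if NULL or empty, a molecular-only table is
#'   returned with a warning.
#' @param groups Optional character vector fixing group order.
#' @return List with `per_embryo` (joined data.frame) and `group_medians`.
#' @export
summary_matrix <- function(molecular, morphological = NULL, groups = NULL) {
  stopifnot(is.data.frame(molecular),
            all(c("embryo_id", "group") %in% names(molecular)))
  per <- molecular
  if (is.null(morphological) || nrow(morphological) == 0L) {
    warning("no morphological input: molecular-only summary", call. = FALSE)
  } else {
    unmatched <- setdiff(unique(morphological$group), unique(molecular$group))
    if (length(unmatched))
      stop(sprintf("unmatched group label(s): %s",
                   paste(unmatched, collapse = ", ")), call. = FALSE)
    per <- merge(molecular,
                 morphological[setdiff(names(morphological), "group")],
                 by = "embryo_id", all.x = TRUE, sort = FALSE)
  }
  if (is.null(groups)) groups <- unique(per$group)
  missing <- setdiff(groups, unique(per$group))
  if (length(missing))
    stop(sprintf("missing group(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  per$group <- factor(per$group, levels = groups)
  per <- per[order(per$group, per$embryo_id), , drop = FALSE]
  num <- names(per)[vapply(per, is.numeric, logical(1))]
  med <- do.call(rbind, c(lapply(groups, function(g) {
    sub <- per[per$group == g, num, drop = FALSE]
    cbind(data.frame(group = g, n = nrow(sub)),
          as.data.frame(lapply(sub, stats::median, na.rm = TRUE)))
  }), list(make.row.names = FALSE)))
  list(per_embryo = per, group_medians = med)
}
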