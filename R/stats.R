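#' One-way ANOVA on a tidy table
#'
#' Classical between/within decomposition with the p-value from the F
#' distribution. When the between-group sum of squares is exactly zero
#' (identical group means, e.g. all values equal) the statistic is reported
#' as 0 with p = 1 rather than 0/0.
#'
#' @param data data frame.
#' @param value,group column names (tidy-eval) holding the response and the
#'   grouping factor.
#' @return tibble with one row per term (`group`, `Residuals`): `term`, `df`,
#'   `sumsq`, `meansq`, `statistic`, `p.value`.
#' @export
one_way_anova <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- droplevels(g[keep])
  if (nlevels(g) < 2) abort("one_way_anova needs at least 2 groups")
  if (length(v) - nlevels(g) < 2) {
    abort("one_way_anova needs at least 2 residual degrees of freedom")
  }
  term_name <- as_name(enquo(group))
  df_b <- nlevels(g) - 1
  df_w <- length(v) - nlevels(g)
  # degenerate layout (identical values everywhere): zero between-group
  # variation is F = 0, not 0/0 or a ratio of rounding noise
  if (diff(range(v)) == 0) {
    return(tibble(term = c(term_name, "Residuals"), df = c(df_b, df_w),
                  sumsq = c(0, 0), meansq = c(0, 0),
                  statistic = c(0, NA), p.value = c(1, NA)))
  }
  # near-perfect fits are caught below; anova's warning adds nothing
  tab <- suppressWarnings(anova(lm(v ~ g)))
  out <- tibble(term = c(term_name, "Residuals"),
                df = tab$Df, sumsq = tab$`Sum Sq`, meansq = tab$`Mean Sq`,
                statistic = tab$`F value`, p.value = tab$`Pr(>F)`)
  # equal group means to machine precision: report the F = 0 path
  if (out$sumsq[1] <= 1e-20 * (sum(v^2) + 1)) {
    out$statistic[1] <- 0
    out$p.value[1] <- 1
  }
  out
}

#' Nested ANOVA: lineage tested against the species stratum
#'
#' Tests a 2-level lineage factor over species nested within lineage. The
#' lineage mean square is compared against the among-species-within-lineage
#' mean square, so with `s` species the test has `(1, s - 2)` degrees of
#' freedom regardless of how many individual animals contribute — the design
#' that treats species, not fish, as the unit of replication.
#'
#' Two variants are offered: `"species_means"` (default) collapses the data
#' to species means and runs the lineage contrast on them; `"individuals"`
#' fits the full nested layout on per-animal values and forms the same F from
#' the lineage and species-within-lineage mean squares.
#'
#' @param data data frame.
#' @param value,species,lineage tidy-eval column names.
#' @param level unit of replication, `"species_means"` or `"individuals"`.
#' @return tibble of terms (`lineage`, `species_within_lineage`, and for the
#'   individual-level variant `Residuals`) with `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value`. Only the lineage row carries a test.
#' @export
nested_anova <- function(data, value, species, lineage,
                         level = c("species_means", "individuals")) {
  level <- match.arg(level)
  v <- dplyr::pull(data, {{ value }})
  sp <- factor(dplyr::pull(data, {{ species }}))
  li <- factor(dplyr::pull(data, {{ lineage }}))
  keep <- !is.na(v) & !is.na(sp) & !is.na(li)
  v <- v[keep]; sp <- droplevels(sp[keep]); li <- droplevels(li[keep])
  map <- unique(data.frame(sp = sp, li = li))
  if (any(duplicated(map$sp))) {
    abort("each species must map to exactly one lineage")
  }
  per_lineage <- table(map$li)
  if (any(per_lineage < 2)) {
    abort(paste0("lineage(s) with a single species: ",
                 paste(names(per_lineage)[per_lineage < 2], collapse = ", "),
                 " — no among-species error term"))
  }
  if (level == "species_means") {
    means <- tapply(v, sp, mean)
    dd <- data.frame(m = as.numeric(means), li = map$li[match(names(means), map$sp)])
    tab <- anova(lm(m ~ li, data = dd))
    out <- tibble(term = c("lineage", "species_within_lineage"),
                  df = tab$Df, sumsq = tab$`Sum Sq`, meansq = tab$`Mean Sq`,
                  statistic = tab$`F value`, p.value = tab$`Pr(>F)`)
  } else {
    tab <- anova(lm(v ~ li + sp))
    ms_li <- tab["li", "Mean Sq"]
    ms_sp <- tab["sp", "Mean Sq"]
    Fv <- ms_li / ms_sp
    df1 <- tab["li", "Df"]
    df2 <- tab["sp", "Df"]
    out <- tibble(
      term = c("lineage", "species_within_lineage", "Residuals"),
      df = c(df1, df2, tab["Residuals", "Df"]),
      sumsq = c(tab["li", "Sum Sq"], tab["sp", "Sum Sq"],
                tab["Residuals", "Sum Sq"]),
      meansq = c(ms_li, ms_sp, tab["Residuals", "Mean Sq"]),
      statistic = c(Fv, NA, NA),
      p.value = c(pf(Fv, df1, df2, lower.tail = FALSE), NA, NA))
  }
  out
}

#' Two-way ANOVA with Šidák-adjusted planned comparisons
#'
#' Interaction-inclusive two-way decomposition (Type II sums of squares, so
#' unbalanced designs are handled consistently), followed by planned
#' cell-mean comparisons adjusted by the Šidák formula over the number of
#' comparisons actually requested. The default comparison set contrasts the
#' levels of `factor_b` within each level of `factor_a` — e.g. day vs night
#' activity within each species.
#'
#' @param data data frame.
#' @param value,factor_a,factor_b tidy-eval column names.
#' @param comparisons list of length-2 character vectors, each naming two
#'   cells as `"<a>:<b>"`; `NULL` requests all pairwise `factor_b` contrasts
#'   within each `factor_a` level.
#' @return list with `anova` (term table, Type II) and `comparisons` (tibble:
#'   `cell_1`, `cell_2`, `estimate`, `se`, `statistic`, `df`, `p.value`,
#'   `p.adj`).
#' @export
two_way_anova_sidak <- function(data, value, factor_a, factor_b,
                                comparisons = NULL) {
  v <- dplyr::pull(data, {{ value }})
  a <- factor(dplyr::pull(data, {{ factor_a }}))
  b <- factor(dplyr::pull(data, {{ factor_b }}))
  keep <- !is.na(v) & !is.na(a) & !is.na(b)
  v <- v[keep]; a <- droplevels(a[keep]); b <- droplevels(b[keep])
  cell_tab <- table(a, b)
  if (any(cell_tab == 0)) {
    empty <- which(cell_tab == 0, arr.ind = TRUE)
    cells <- paste(rownames(cell_tab)[empty[, 1]],
                   colnames(cell_tab)[empty[, 2]], sep = ":")
    abort(paste0("empty design cell(s): ", paste(cells, collapse = ", ")))
  }
  dd <- data.frame(v = v, a = a, b = b)
  fit <- lm(v ~ a * b, data = dd)
  tab <- car::Anova(fit, type = 2)
  terms_map <- c(a = as_name(enquo(factor_a)), b = as_name(enquo(factor_b)),
                 `a:b` = paste0(as_name(enquo(factor_a)), ":",
                                as_name(enquo(factor_b))),
                 Residuals = "Residuals")
  anova_tbl <- tibble(term = unname(terms_map[rownames(tab)]),
                      sumsq = tab$`Sum Sq`, df = tab$Df,
                      statistic = tab$`F value`, p.value = tab$`Pr(>F)`)

  # cell-means parameterisation for the planned contrasts
  cm_fit <- lm(v ~ 0 + interaction(a, b, sep = ":"), data = dd)
  cm_names <- sub("^interaction\\(a, b, sep = \":\"\\)", "", names(coef(cm_fit)))
  if (is.null(comparisons)) {
    comparisons <- list()
    for (al in levels(a)) {
      bl <- levels(b)
      if (length(bl) >= 2) {
        prs <- utils::combn(bl, 2, simplify = FALSE)
        comparisons <- c(comparisons,
                         lapply(prs, function(p) paste(al, p, sep = ":")))
      }
    }
  }
  m <- length(comparisons)
  V <- vcov(cm_fit)
  beta <- coef(cm_fit)
  df_res <- fit$df.residual
  comp_tbl <- list_rbind(map(comparisons, function(pair) {
    i <- match(pair[1], cm_names)
    j <- match(pair[2], cm_names)
    if (is.na(i) || is.na(j)) {
      abort(paste0("unknown cell in comparison: ",
                   paste(pair[c(is.na(i), is.na(j))], collapse = ", "),
                   " (cells are '<", as_name(enquo(factor_a)), ">:<",
                   as_name(enquo(factor_b)), ">')"))
    }
    est <- beta[i] - beta[j]
    se <- sqrt(V[i, i] + V[j, j] - 2 * V[i, j])
    tstat <- est / se
    p <- 2 * pt(abs(tstat), df_res, lower.tail = FALSE)
    tibble(cell_1 = pair[1], cell_2 = pair[2], estimate = unname(est),
           se = unname(se), statistic = unname(tstat), df = df_res,
           p.value = unname(p))
  }))
  comp_tbl$p.adj <- sidak_adjust(comp_tbl$p.value, m)
  list(anova = anova_tbl, comparisons = comp_tbl)
}

#' Šidák multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for `m` comparisons; monotone in `p` and never
#' smaller than the raw p-value.
#'
#' @param p raw p-values.
#' @param m number of comparisons (default: `length(p)`).
#' @return adjusted p-values.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  if (m < 1) abort("m must be >= 1")
  pmin(1, 1 - (1 - p)^m)
}

#' Levene's median test (Brown-Forsythe)
#'
#' Tests equality of spread across groups by a one-way ANOVA on absolute
#' deviations from the group medians, which is robust to non-normality.
#'
#' @inheritParams one_way_anova
#' @return term table as [one_way_anova()].
#' @export
levene_median_test <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    abort("levene_median_test needs >= 2 groups with >= 2 observations each")
  }
  med <- tapply(v, g, median)
  dd <- tibble(adev = abs(v - med[as.character(g)]), g = g)
  out <- one_way_anova(dd, adev, g)
  out$term[1] <- as_name(enquo(group))
  out
}

#' One-sample t-test
#'
#' Two-sided test of whether the mean differs from `mu0`; used on per-animal
#' activity change ratios to test rhythmicity against the null of no
#' day/night preference (`mu0 = 0`).
#'
#' @param values numeric vector (`NA` dropped).
#' @param mu0 reference mean.
#' @return one-row tibble: `estimate` (mean), `se`, `statistic` (t), `df`,
#'   `p.value`, `n`.
#' @export
one_sample_ttest <- function(values, mu0 = 0) {
  v <- values[!is.na(values)]
  if (length(v) < 2) abort("one_sample_ttest needs n >= 2")
  if (var(v) == 0) abort("zero variance: t statistic undefined")
  tt <- t.test(v, mu = mu0)
  tibble(estimate = unname(tt$estimate), se = unname(tt$stderr),
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p.value = tt$p.value, n = length(v))
}
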