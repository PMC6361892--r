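#' Univariate test result
#'
#' Light container for the group-comparison and correlation statistics the
#' pipeline reports: the statistic (U, chi-squared, t, rho), a normal
#' approximation z where applicable, the p-value and its mode (exact or
#' asymptotic), tails, and the effect size `r = z / sqrt(N)` used for
#' Mann-Whitney comparisons.
#'
#' @param statistic name of the statistic.
#' @param value its value.
#' @param p p-value.
#' @param z normal-approximation z, if applicable.
#' @param p_mode `"exact"` or `"asymptotic"`.
#' @param tails 1 or 2.
#' @param effect_r effect size r.
#' @param n1,n2 group sizes.
#' @param note free-text annotation.
#' @return An object of class `alpha_test`.
#' @keywords internal
alpha_test <- function(statistic, value, p, z = NA_real_,
                       p_mode = "asymptotic", tails = 2,
                       effect_r = NA_real_, n1 = NA_integer_,
                       n2 = NA_integer_, note = NULL) {
  structure(list(statistic = statistic, value = value, z = z, p = p,
                 p_mode = p_mode, tails = tails, effect_r = effect_r,
                 n1 = n1, n2 = n2, note = note),
            class = "alpha_test")
}

#' @export
print.alpha_test <- function(x, ...) {
  cat(sprintf("%s = %.4g", x$statistic, x$value))
  if (!is.na(x$z)) cat(sprintf(", z = %.3f", x$z))
  cat(sprintf(", %s %d-tailed p = %.4g", x$p_mode, x$tails, x$p))
  if (!is.na(x$effect_r)) cat(sprintf(", r = %.2f", x$effect_r))
  cat("\n")
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Assumption-driven choice between t-test and Mann-Whitney
#'
#' Tests normality per group (Shapiro-Wilk) and homogeneity of variance
#' (Levene's test on a two-group factor). The parametric independent-samples
#' t-test is chosen only when all three p-values exceed `alpha`; otherwise
#' the two-sided Mann-Whitney U-test is used. A constant (zero-variance)
#' group forces Mann-Whitney with a warning, since Shapiro-Wilk is undefined
#' there.
#'
#' @param values_a,values_b numeric vectors, each of length >= 3.
#' @param alpha assumption-test significance level.
#' @return A list: `test` (`"t"` or `"mann_whitney"`), the assumption
#'   p-values (`shapiro_a`, `shapiro_b`, `levene`), and `reason`.
#' @export
choose_test <- function(values_a, values_b, alpha = 0.05) {
  if (length(values_a) < 3L || length(values_b) < 3L) {
    stop("each group needs at least 3 observations")
  }
  if (stats::sd(values_a) == 0 || stats::sd(values_b) == 0) {
    warning("constant group: normality untestable, forcing Mann-Whitney")
    return(list(test = "mann_whitney", shapiro_a = NA_real_,
                shapiro_b = NA_real_, levene = NA_real_,
                reason = "zero-variance group"))
  }
  sa <- stats::shapiro.test(values_a)$p.value
  sb <- stats::shapiro.test(values_b)$p.value
  g <- factor(rep(c("a", "b"), c(length(values_a), length(values_b))))
  lv <- car::leveneTest(c(values_a, values_b), g)[1L, "Pr(>F)"]
  ok <- sa > alpha && sb > alpha && lv > alpha
  list(test = if (ok) "t" else "mann_whitney",
       shapiro_a = sa, shapiro_b = sb, levene = lv,
       reason = if (ok) "assumptions met" else "normality or variance assumption violated")
}

#' Mann-Whitney U-test with z and effect size
#'
#' Reports U for group A (number of (a, b) pairs with a ranked above b),
#' the tie-corrected normal-approximation z without continuity correction,
#' and the effect size `r = z / sqrt(n1 + n2)`. The exact p-value enumerates
#' the full null distribution of U (no ties); with ties, or when
#' `n1 * n2 > exact_threshold` under `p_mode = "auto"`, the asymptotic normal
#' p is used instead. Requesting `"exact"` with ties present falls back to
#' asymptotic with a warning. The exact two-tailed p doubles the smaller tail
#' probability; the U null is symmetric without ties, so this equals summing
#' outcomes as or more extreme in both tails.
#'
#' @param values_a,values_b numeric vectors (non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` (A larger) or
#'   `"less"`.
#' @param p_mode `"auto"`, `"exact"` or `"asymptotic"`.
#' @param exact_threshold largest `n1 * n2` for which `"auto"` enumerates.
#' @return An `alpha_test` with `statistic = "U"`.
#' @export
mann_whitney <- function(values_a, values_b,
                         alternative = c("two.sided", "greater", "less"),
                         p_mode = c("auto", "exact", "asymptotic"),
                         exact_threshold = 400) {
  alternative <- match.arg(alternative)
  p_mode <- match.arg(p_mode)
  if (length(values_a) == 0L || length(values_b) == 0L) {
    stop("both groups must be non-empty")
  }
  n1 <- length(values_a); n2 <- length(values_b); N <- n1 + n2
  pooled <- c(values_a, values_b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  tt <- table(pooled)
  sd_u <- sqrt(n1 * n2 / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1))))
  z <- if (sd_u == 0) 0 else (u - n1 * n2 / 2) / sd_u
  eff <- z / sqrt(N)

  want_exact <- switch(p_mode,
                       exact = TRUE,
                       asymptotic = FALSE,
                       auto = !ties && n1 * n2 <= exact_threshold)
  if (want_exact && ties) {
    warning("ties present: exact Mann-Whitney p unavailable, using asymptotic")
    want_exact <- FALSE
  }
  if (want_exact) {
    p <- switch(alternative,
      greater = stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE),
      less = stats::pwilcox(u, n1, n2),
      two.sided = {
        lo <- min(u, n1 * n2 - u)
        min(1, 2 * stats::pwilcox(lo, n1, n2))
      })
    mode <- "exact"
  } else {
    p <- switch(alternative,
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z),
      two.sided = 2 * stats::pnorm(-abs(z)))
    mode <- "asymptotic"
  }
  alpha_test("U", u, p = p, z = z, p_mode = mode,
             tails = if (alternative == "two.sided") 2 else 1,
             effect_r = eff, n1 = n1, n2 = n2,
             note = if (ties) "tie-corrected variance" else NULL)
}

#' Normal-approximation z and effect size from a printed U
#'
#' Converts a Mann-Whitney U and the two group sizes into the (tie-free)
#' normal-approximation z without continuity correction,
#' `z = (U - n1 n2 / 2) / sqrt(n1 n2 (n1 + n2 + 1) / 12)`, and the effect
#' size `r = z / sqrt(n1 + n2)` — the form in which cohort papers tabulate
#' their group comparisons.
#'
#' @param u Mann-Whitney U statistic (for group A).
#' @param n1,n2 group sizes.
#' @return A list with `z` and `r`.
#' @export
mann_whitney_z <- function(u, n1, n2) {
  sd_u <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  z <- (u - n1 * n2 / 2) / sd_u
  list(z = z, r = z / sqrt(n1 + n2))
}

#' Pearson chi-square for a 2x2 contingency table
#'
#' Pearson's chi-squared on 1 degree of freedom without continuity
#' correction, with the asymptotic two-sided p-value — the convention used
#' for demographic sex-distribution comparisons.
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @return An `alpha_test` with `statistic = "chi_squared"`.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("`table` must be 2x2")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("both margins must be positive")
  }
  # asymptotic p is the convention here; silence the small-expected-count note
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  alpha_test("chi_squared", unname(ct$statistic), p = ct$p.value,
             p_mode = "asymptotic", tails = 2,
             n1 = sum(table[1L, ]), n2 = sum(table[2L, ]))
}

#' Spearman rank correlation
#'
#' Spearman's rho on pairwise-complete observations with average ranks for
#' ties and a two-tailed p-value (exact for small tie-free samples,
#' asymptotic otherwise, following the base-R convention).
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @return An `alpha_test` with `statistic = "rho"`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    stop("rho undefined: one variable has zero rank variance")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  alpha_test("rho", unname(ct$estimate), p = ct$p.value,
             p_mode = if (!ties && length(x) < 1290) "exact" else "asymptotic",
             tails = 2, n1 = length(x))
}

#' Winsorize the maximum value
#'
#' Replaces every occurrence of the maximum by the largest strictly smaller
#' value, bounding the influence of a single extreme subject on rank
#' correlations. An all-equal vector is returned unchanged; `NA`s are
#' ignored and preserved. When the maximum is tied, every occurrence moves to
#' the next distinct value, so repeated application keeps shrinking the range
#' until the vector is constant (the operation is not idempotent in general).
#'
#' @param values numeric vector of length >= 2.
#' @return The winsorized vector.
#' @export
winsorize_max <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  v <- values[!is.na(values)]
  if (length(v) < 2L || length(unique(v)) == 1L) return(values)
  mx <- max(v)
  nxt <- max(v[v < mx])
  values[!is.na(values) & values == mx] <- nxt
  values
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level `q`: with ordered p-values `p(1) <= ... <=
#' p(m)`, rejects all hypotheses up to the largest `i` with
#' `p(i) <= i q / m`. Returns the per-hypothesis rejection flag and the BH
#' adjusted p-values.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q target false discovery rate.
#' @return Data frame with columns `p`, `p_adjusted`, `reject`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  data.frame(p = p_values, p_adjusted = adj, reject = !is.na(adj) & adj <= q)
}

#' Default ADI-R item sets for restricted-and-repetitive-behaviour subtypes
#'
#' A literature-informed default grouping of ADI-R "ever" items into the
#' three conventional RRB subtypes. Item-set membership varies across
#' published factor solutions, so treat this as an editable configuration
#' (any named list of disjoint item-id vectors works), not a normative
#' scoring key.
#'
#' @return Named list of character vectors of item ids.
#' @export
adi_r_subtype_items <- function() {
  list(
    repetitive_motor = c("item_77", "item_78"),   # hand/finger, complex mannerisms
    insistence_on_sameness = c("item_74", "item_75"),  # routines, resistance to change
    circumscribed_interests = c("item_67", "item_68")  # preoccupations, interests
  )
}

#' Restricted-and-repetitive-behaviour subtype scores
#'
#' Sums each subject's raw "ever" item scores over the item set configured
#' for each subtype. A missing item score makes that subject's subtype score
#' missing; other subtypes are still computed.
#'
#' @param item_table data frame, one row per subject, one column per item id
#'   (an `id` column, if present, is carried through).
#' @param item_sets named list of disjoint, non-empty item-id vectors; every
#'   id must be a column of `item_table`.
#' @return Data frame with one column per subtype (plus `id` if supplied).
#' @export
rrb_subtype_scores <- function(item_table, item_sets = adi_r_subtype_items()) {
  if (length(item_sets) == 0L) stop("`item_sets` must be non-empty")
  if (any(lengths(item_sets) == 0L)) stop("empty item set in `item_sets`")
  all_items <- unlist(item_sets)
  if (anyDuplicated(all_items)) stop("item sets must be disjoint")
  unknown <- setdiff(all_items, names(item_table))
  if (length(unknown)) {
    stop("unknown item id(s) in config: ", paste(unknown, collapse = ", "))
  }
  out <- data.frame(row.names = seq_len(nrow(item_table)))
  if ("id" %in% names(item_table)) out$id <- item_table$id
  for (nm in names(item_sets)) {
    cols <- item_table[, item_sets[[nm]], drop = FALSE]
    if (any(cols < 0, na.rm = TRUE)) stop("item scores must be non-negative")
    out[[nm]] <- rowSums(cols)   # NA if any item missing
  }
  out
}

#' Brain-behaviour correlation table
#'
#' Spearman correlations between connectivity summaries and dimensional
#' trait scales within a subject subset, mirroring the layout of a
#' connectivity-by-trait correlation table. FDR correction is applied only
#' to the scales not declared a priori (hypotheses stated in advance are
#' reported uncorrected).
#'
#' @param cohort data frame with one row per subject: a `group` column, the
#'   connectivity summary columns and the trait scale columns.
#' @param group_filter character vector of groups to keep, or `NULL` for all.
#' @param measures named character vector mapping measure display names to
#'   cohort columns; default global and selected-edge dbWPLI.
#' @param scales character vector of trait scale columns.
#' @param fdr_q FDR level for the non-a-priori family, or `NULL` to skip.
#' @param a_priori scales with pre-registered hypotheses, left uncorrected.
#' @return Data frame: `measure`, `scale`, `n`, `rho`, `p`, and (when FDR is
#'   applied) `p_adjusted`, `reject`, `a_priori`.
#' @export
correlation_analysis <- function(cohort, group_filter = NULL,
                                 measures = c(global = "global_dbwpli",
                                              selected = "selected_dbwpli"),
                                 scales, fdr_q = NULL,
                                 a_priori = character(0)) {
  if (!is.null(group_filter)) {
    cohort <- cohort[cohort$group %in% group_filter, , drop = FALSE]
    if (nrow(cohort) == 0L) stop("no subjects left after group filter")
  }
  if (nrow(cohort) < 4L) stop("need at least 4 subjects after filtering")
  missing_cols <- setdiff(c(unname(measures), scales), names(cohort))
  if (length(missing_cols)) {
    stop("cohort table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  rows <- expand.grid(measure = names(measures), scale = scales,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(rows)), function(k) {
    ts <- spearman(cohort[[measures[[rows$measure[k]]]]],
                   cohort[[rows$scale[k]]])
    data.frame(measure = rows$measure[k], scale = rows$scale[k],
               n = ts$n1, rho = ts$value, p = ts$p)
  })
  out <- do.call(rbind, res)
  if (!is.null(fdr_q)) {
    out$a_priori <- out$scale %in% a_priori
    fam <- !out$a_priori
    out$p_adjusted <- NA_real_
    out$reject <- NA
    if (any(fam)) {
      fd <- bh_fdr(out$p[fam], q = fdr_q)
      out$p_adjusted[fam] <- fd$p_adjusted
      out$reject[fam] <- fd$reject
    }
  }
  rownames(out) <- NULL
  out
}
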