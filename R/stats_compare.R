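# Group-comparison statistics used to annotate the survey tables:
# one-way ANOVA across varieties, Kolmogorov-Smirnov normality and
# mean-centered Levene homogeneity checks, pairwise comparisons, and
# compact letter displays ("different letters differ at p < 0.05").

# common validation: named list of >= 2 groups, each >= 2 finite values
check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of at least two groups", call. = FALSE)
  }
  if (is.null(names(groups)) || any(names(groups) == "") ||
      anyDuplicated(names(groups))) {
    stop("groups must be uniquely named", call. = FALSE)
  }
  ok <- vapply(groups, function(g)
    is.numeric(g) && length(g) >= 2 && all(is.finite(g)), logical(1))
  if (!all(ok)) {
    stop("every group needs >= 2 finite numeric values; offending: ",
         paste(names(groups)[!ok], collapse = ", "), call. = FALSE)
  }
  groups
}

groups_to_df <- function(groups) {
  data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups))
  )
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA of a named list of replicate
#' vectors: the ratio of between-group to within-group mean squares and
#' its F-test p-value.
#'
#' @param groups Named list of numeric vectors, each with at least two
#'   finite values.
#' @return A list with `f_stat`, `p_value`, `df` (numerator,
#'   denominator).
#' @export
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
one_way_anova <- function(groups) {
  groups <- check_groups(groups)
  df <- groups_to_df(groups)
  ft <- stats::oneway.test(value ~ group, data = df, var.equal = TRUE)
  list(f_stat = unname(ft$statistic),
       p_value = unname(ft$p.value),
       df = unname(ft$parameter))
}

#' Levene's test for homogeneity of variance (mean-centered)
#'
#' The mean-centered Levene statistic: a one-way ANOVA applied to the
#' absolute deviations of each observation from its group mean.  Small
#' p-values indicate heterogeneous variances.
#'
#' @inheritParams one_way_anova
#' @return A list with `w_stat`, `p_value`, `df`.
#' @export
#' @examples
#' levene_mean(list(a = c(1, 2, 3), b = c(2, 4, 6)))
levene_mean <- function(groups) {
  groups <- check_groups(groups)
  dev <- lapply(groups, function(g) abs(g - mean(g)))
  if (all(unlist(dev) == 0)) {
    stop("all within-group deviations are zero; Levene statistic ",
         "undefined", call. = FALSE)
  }
  # identical spread patterns: no between-group deviation signal at all
  if (stats::var(vapply(dev, mean, numeric(1))) == 0 &&
      all(vapply(dev, stats::var, numeric(1)) == 0)) {
    return(list(w_stat = 0, p_value = 1,
                df = c(length(groups) - 1,
                       sum(lengths(groups)) - length(groups))))
  }
  res <- one_way_anova(dev)
  list(w_stat = res$f_stat, p_value = res$p_value, df = res$df)
}

#' Kolmogorov-Smirnov normality check
#'
#' Sup-distance between the empirical CDF of the sample and a normal
#' CDF with the sample's own mean and standard deviation.  Because the
#' reference parameters are estimated from the same data, the p-value is
#' conservative (biased upward); no small-sample correction is applied.
#'
#' @param values Numeric vector, at least 3 finite values with non-zero
#'   spread.
#' @return A list with `d_stat` and `p_value`.
#' @export
#' @examples
#' ks_normality(c(1, 2, 3, 4, 5))
ks_normality <- function(values) {
  stopifnot(is.numeric(values))
  values <- values[is.finite(values)]
  if (length(values) < 3) {
    stop("need at least 3 finite values", call. = FALSE)
  }
  s <- stats::sd(values)
  if (s == 0) stop("zero standard deviation; normality check undefined",
                   call. = FALSE)
  kt <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean = mean(values), sd = s))
  list(d_stat = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Pairwise group comparisons
#'
#' All pairwise comparisons of group means following a one-way ANOVA:
#' either Tukey's honest significant difference on the pooled mean
#' square (the conventional generator of letter displays, controlling
#' the family-wise error rate) or unadjusted pooled-variance t tests.
#'
#' @inheritParams one_way_anova
#' @param method `"tukey"` or `"t"`.
#' @return A tibble with `group1`, `group2`, `p_value`.
#' @export
#' @examples
#' pairwise_comparisons(list(a = c(1, 2), b = c(5, 6), c = c(1.4, 2.2)))
pairwise_comparisons <- function(groups, method = c("tukey", "t")) {
  method <- match.arg(method)
  groups <- check_groups(groups)
  df <- groups_to_df(groups)
  if (method == "tukey") {
    fit <- stats::aov(value ~ group, data = df)
    tk <- stats::TukeyHSD(fit)$group
    pair <- strsplit(rownames(tk), "-", fixed = TRUE)
    out <- tibble::tibble(
      group1 = vapply(pair, `[`, "", 2),
      group2 = vapply(pair, `[`, "", 1),
      p_value = unname(tk[, "p adj"])
    )
  } else {
    pt <- stats::pairwise.t.test(df$value, df$group,
                                 p.adjust.method = "none",
                                 pool.sd = TRUE)$p.value
    idx <- which(!is.na(pt), arr.ind = TRUE)
    out <- tibble::tibble(
      group1 = colnames(pt)[idx[, 2]],
      group2 = rownames(pt)[idx[, 1]],
      p_value = pt[idx]
    )
  }
  # canonical pair order: by position of each group in the input list
  lv <- names(groups)
  swap <- match(out$group1, lv) > match(out$group2, lv)
  tmp <- out$group1[swap]
  out$group1[swap] <- out$group2[swap]
  out$group2[swap] <- tmp
  out[order(match(out$group1, lv), match(out$group2, lv)), ]
}

#' Compact letter display from a pairwise significance pattern
#'
#' Assigns letters to groups so that two groups share at least one
#' letter exactly when they are *not* significantly different
#' (insert-and-absorb algorithm).  Letters are lettered in the order the
#' groups are supplied, so pass groups sorted by descending mean for the
#' conventional table presentation.
#'
#' @param pairwise A data frame with columns `group1`, `group2`, and
#'   either `significant` (logical) or `p_value` (compared against
#'   `alpha`), covering every pair of `groups`.
#' @param groups Character vector of group names fixing the letter
#'   order.
#' @param alpha Significance level when `pairwise` carries p-values.
#' @return Named character vector of letter strings.
#' @export
#' @examples
#' pw <- data.frame(group1 = c("a", "a", "b"), group2 = c("b", "c", "c"),
#'                  significant = c(FALSE, TRUE, FALSE))
#' compact_letters(pw, c("a", "b", "c"))
compact_letters <- function(pairwise, groups, alpha = 0.05) {
  stopifnot(is.data.frame(pairwise), is.character(groups),
            length(groups) >= 1, !anyDuplicated(groups))
  if (!all(c("group1", "group2") %in% names(pairwise))) {
    stop("pairwise needs columns group1 and group2", call. = FALSE)
  }
  if ("significant" %in% names(pairwise)) {
    sig_flag <- as.logical(pairwise$significant)
  } else if ("p_value" %in% names(pairwise)) {
    stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
    sig_flag <- pairwise$p_value < alpha
  } else {
    stop("pairwise needs a 'significant' or 'p_value' column",
         call. = FALSE)
  }
  # significance lookup, symmetric
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  sig <- stats::setNames(sig_flag, key(pairwise$group1, pairwise$group2))
  all_pairs <- utils::combn(groups, 2)
  if (length(groups) > 1) {
    missing <- !key(all_pairs[1, ], all_pairs[2, ]) %in% names(sig)
    if (any(missing)) {
      stop("pairwise map incomplete; missing pair(s): ",
           paste(all_pairs[1, missing], all_pairs[2, missing],
                 sep = "-", collapse = ", "), call. = FALSE)
    }
  }
  # insert-and-absorb: start with one letter shared by everyone, split
  # on each significant pair, absorb redundant columns
  cols <- list(groups)
  if (length(groups) > 1) {
    for (j in seq_len(ncol(all_pairs))) {
      g1 <- all_pairs[1, j]
      g2 <- all_pairs[2, j]
      if (!sig[[key(g1, g2)]]) next
      new_cols <- list()
      for (col in cols) {
        if (g1 %in% col && g2 %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, g2)),
                        list(setdiff(col, g1)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb: drop any column whose membership is contained in another
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a != b && keep[b] &&
              all(new_cols[[a]] %in% new_cols[[b]]) &&
              (length(new_cols[[a]]) < length(new_cols[[b]]) || a > b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  # order columns by their first member in the supplied group order
  first <- vapply(cols, function(col) min(match(col, groups)), numeric(1))
  cols <- cols[order(first)]
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(cols)) {
    for (g in cols[[i]]) out[[g]] <- paste0(out[[g]], letters_pool[i])
  }
  out
}

#' Full group comparison with letter display
#'
#' Bundles the pipeline's per-row statistics: one-way ANOVA, pairwise
#' comparisons at `alpha`, and the compact letter display with groups
#' lettered by descending mean (ties broken by name).
#'
#' @inheritParams one_way_anova
#' @param alpha Significance level for the pairwise comparisons.
#' @param method Pairwise procedure, `"tukey"` (default) or `"t"`.
#' @return A list of class `group_comparison` with `anova`, `pairwise`,
#'   `letters` (in the original group order), and `summary` (tibble
#'   `group`, `n`, `mean`, `sd`, `letters`).
#' @export
#' @examples
#' group_compare(list(a = c(1, 2), b = c(5, 6), c = c(5.1, 6.2)))
group_compare <- function(groups, alpha = 0.05,
                          method = c("tukey", "t")) {
  method <- match.arg(method)
  groups <- check_groups(groups)
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  av <- one_way_anova(groups)
  pw <- pairwise_comparisons(groups, method = method)
  means <- vapply(groups, mean, numeric(1))
  letter_order <- names(groups)[order(-means, names(groups))]
  letters_by_group <- compact_letters(pw, letter_order, alpha = alpha)
  summary <- tibble::tibble(
    group = names(groups),
    n = lengths(groups),
    mean = unname(means),
    sd = vapply(groups, stats::sd, numeric(1)),
    letters = unname(letters_by_group[names(groups)])
  )
  structure(list(anova = av, pairwise = pw,
                 letters = letters_by_group[names(groups)],
                 alpha = alpha, method = method, summary = summary),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%g, %g) = %.4g, p = %.4g (%s pairwise, alpha = %g)\n",
              x$anova$df[1], x$anova$df[2], x$anova$f_stat,
              x$anova$p_value, x$method, x$alpha))
  print(x$summary)
  invisible(x)
}
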