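#' Standard error of the mean
#'
#' The error-bar unit for every group-level figure: sample standard
#' deviation (n - 1 denominator) divided by the square root of n, computed
#' across chats — the chat is the statistical unit of analysis.
#'
#' @param values Numeric vector of per-chat values.
#' @return The SEM, or `NA` when fewer than 2 finite values are supplied
#'   (a single chat has no dispersion estimate; it is reported missing,
#'   never 0).
#' @examples
#' sem(c(0, 2)) # sd = sqrt(2), sem = 1
#' @export
sem <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) {
    return(NA_real_)
  }
  sd(values) / sqrt(n)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value — the default for comparing per-chat
#' statistic vectors between two chat groups, whose sizes and variances
#' are generally unequal. Student's pooled-variance variant is available
#' via `var_equal = TRUE`.
#'
#' @param a,b Numeric vectors, each with at least 2 finite values.
#' @param var_equal Use the pooled-variance (Student) test instead.
#' @return A list with elements `t`, `df`, `p`.
#' @examples
#' welch_t(c(1, 2, 3, 4), c(3, 4, 5, 6))
#' @export
welch_t <- function(a, b, var_equal = FALSE) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("Each group needs at least 2 finite values for a t-test.")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    # degenerate: no variance anywhere
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  res <- stats::t.test(a, b, var.equal = var_equal)
  list(
    t = unname(res$statistic),
    df = unname(res$parameter),
    p = unname(res$p.value)
  )
}

#' Significance stars for a p-value
#'
#' `***` for p < .001, `**` for p < .01, `*` for p < .05, else `""`.
#'
#' @param p A p-value (vectorized).
#' @return Character vector of star annotations.
#' @export
signif_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    .default = ""
  )
}

#' Compare a per-chat statistic between two chat groups
#'
#' Takes per-chat values labelled by group (e.g. the output of
#' [rule_frequency()] for one code, or [per_chat_lemma_frequency()], or
#' the per-chat means of a [score_corpus()] summary) and produces the
#' machinery behind every comparison figure: group means, SEM error bars,
#' a t-test and a star annotation. If either group has fewer than 2
#' chats the means and SEMs are still reported but `t`, `df`, `p` are
#' missing.
#'
#' @param data A data frame with a group column and a value column.
#' @param value Name of the value column (default `"pct"`).
#' @param group Name of the group column (default `"group"`).
#' @param statistic_name Label for the statistic being compared.
#' @param var_equal Use Student's pooled test instead of Welch (default
#'   `FALSE`).
#' @return An object of class `group_comparison`.
#' @examples
#' df <- tibble::tibble(
#'   group = rep(c("opposition", "control"), each = 4),
#'   pct = c(30, 32, 28, 31, 2, 1, 3, 2)
#' )
#' compare_groups(df, statistic_name = "rule frequency (%)")
#' @export
compare_groups <- function(data, value = "pct", group = "group",
                           statistic_name = value, var_equal = FALSE) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame of per-chat values.")
  }
  if (!all(c(value, group) %in% names(data))) {
    abort(sprintf("`data` must have columns '%s' and '%s'.", group, value))
  }
  labs <- sort(unique(as.character(data[[group]])))
  if (length(labs) != 2) {
    abort(sprintf(
      "compare_groups() needs exactly 2 group labels, found %d (%s).",
      length(labs), paste(labs, collapse = ", ")
    ))
  }
  vals <- purrr::map(labs, function(l) {
    v <- data[[value]][data[[group]] == l]
    v[is.finite(v)]
  })
  names(vals) <- labs
  summary <- tibble(
    group = labs,
    n = unname(purrr::map_int(vals, length)),
    mean = unname(purrr::map_dbl(vals, mean)),
    sem = unname(purrr::map_dbl(vals, sem))
  )
  if (all(summary$n >= 2)) {
    tt <- welch_t(vals[[1]], vals[[2]], var_equal = var_equal)
  } else {
    warn("A group has fewer than 2 chats: t-test not computed.")
    tt <- list(t = NA_real_, df = NA_real_, p = NA_real_)
  }
  structure(
    list(
      statistic_name = statistic_name,
      values = vals,
      summary = summary,
      t = tt$t, df = tt$df, p = tt$p,
      stars = signif_stars(tt$p),
      var_equal = var_equal
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison: %s>\n", x$statistic_name))
  print(x$summary)
  if (!is.na(x$p)) {
    cat(sprintf(
      "%s t = %.3f, df = %.2f, p = %.4g %s\n",
      if (x$var_equal) "Student" else "Welch", x$t, x$df, x$p, x$stars
    ))
  } else {
    cat("t-test: not computed (a group has < 2 chats)\n")
  }
  invisible(x)
}

#' @describeIn compare_groups `tidy()` returns the per-group summary
#'   (group, n, mean, sem) with the test columns repeated.
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @export
tidy.group_comparison <- function(x, ...) {
  dplyr::mutate(
    x$summary,
    statistic_name = x$statistic_name,
    t = x$t, df = x$df, p = x$p, stars = x$stars
  )
}

#' @describeIn compare_groups `glance()` returns one row with the test
#'   result.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(
    statistic_name = x$statistic_name,
    mean_a = x$summary$mean[1], mean_b = x$summary$mean[2],
    sem_a = x$summary$sem[1], sem_b = x$summary$sem[2],
    t = x$t, df = x$df, p = x$p, stars = x$stars
  )
}

#' @describeIn compare_groups `autoplot()` draws the two group means with
#'   SEM error bars and the star annotation.
#' @param object A `group_comparison`.
#' @export
autoplot.group_comparison <- function(object, ...) {
  dat <- object$summary
  y_top <- max(dat$mean + dplyr::coalesce(dat$sem, 0), na.rm = TRUE)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$group), width = 0.6, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c("grey65", "grey20")) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean - .data$sem,
        ymax = .data$mean + .data$sem
      ),
      width = 0.15, na.rm = TRUE
    ) +
    ggplot2::labs(
      x = NULL, y = object$statistic_name,
      caption = "Error bars: SEM across chats"
    ) +
    ggplot2::theme_minimal()
  if (nzchar(object$stars)) {
    p <- p + ggplot2::annotate(
      "text",
      x = 1.5, y = y_top * 1.08, label = object$stars, size = 6
    )
  }
  p
}

#' Holm correction across a family of comparisons
#'
#' The primary analyses report unadjusted p-values (one test per figure
#' panel); when many codes or lemmas are compared at once, a Holm
#' step-down correction can be applied across the family. Off by default
#' everywhere.
#'
#' @param comparisons A list of `group_comparison` objects.
#' @param method Passed to [stats::p.adjust()] (default `"holm"`).
#' @return A tibble: one row per comparison with `p` and adjusted
#'   `p_adj`, stars recomputed from `p_adj`.
#' @export
adjust_comparisons <- function(comparisons, method = "holm") {
  p <- purrr::map_dbl(comparisons, "p")
  p_adj <- p.adjust(p, method = method)
  tibble(
    statistic_name = purrr::map_chr(comparisons, "statistic_name"),
    p = p,
    p_adj = p_adj,
    stars = signif_stars(p_adj)
  )
}
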