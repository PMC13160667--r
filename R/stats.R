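# Group statistics: pooled-variance two-sample t and two-way fixed-effects
# ANOVA, as used for the cohort comparisons. Alpha is fixed at 0.05 and no
# multiple-testing correction is applied.

new_stat_result <- function(test, ...) {
  structure(c(list(test = test, alpha = 0.05), list(...)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  if (x$test == "t_two_sample") {
    cat(sprintf("t(%d) = %.4g, p = %.4g (%d-tailed; two-tailed p = %.4g)\n",
                x$df, x$statistic, x$p, x$tails, x$p_two_tailed))
  } else {
    cat("Two-way ANOVA:\n")
    print(x$table, row.names = FALSE)
  }
  invisible(x)
}

#' Pooled-variance two-sample t test
#'
#' Classic equal-variance two-sample t with `df = n_a + n_b - 2`. Both tail
#' conventions are computed; `tails` selects which is reported as `p` (the
#' one-tailed p is taken in the observed direction of the difference). The
#' degenerate case of two zero-variance samples with equal means is reported
#' as t = 0, p = 1.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param tails 1 or 2.
#' @return a `stat_result` with `statistic`, `df`, `p`, `p_one_tailed`,
#'   `p_two_tailed`.
#' @export
t_two_sample <- function(a, b, tails = 2) {
  if (length(a) < 2 || length(b) < 2) stop_arg("need >= 2 values per group")
  if (!tails %in% c(1, 2)) stop_arg("`tails` must be 1 or 2")
  na <- length(a); nb <- length(b)
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  if (sp2 == 0) {
    tval <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
  } else {
    tval <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  }
  p2 <- 2 * stats::pt(-abs(tval), df)
  p1 <- stats::pt(-abs(tval), df)
  new_stat_result("t_two_sample", statistic = tval, df = df,
                  tails = as.integer(tails),
                  p = if (tails == 2) p2 else p1,
                  p_one_tailed = p1, p_two_tailed = p2)
}

#' Two-way fixed-effects ANOVA
#'
#' Standard `aov` fit of `values ~ A * B` with main-effect and interaction
#' F tests. Every factor needs at least two levels and every cell at least
#' one observation (an empty cell is an error naming the cell). When every
#' cell holds exactly one observation the interaction is untestable: an
#' additive model is fitted and the interaction row is reported as `NA` with
#' `interaction_testable = FALSE`.
#'
#' @param values numeric response.
#' @param factorA,factorB factors (coerced).
#' @return a `stat_result` with a `table` data.frame (`term`, `df1`, `df2`,
#'   `F`, `p`).
#' @export
anova_two_way <- function(values, factorA, factorB) {
  A <- factor(factorA); B <- factor(factorB)
  if (nlevels(A) < 2 || nlevels(B) < 2) {
    stop_arg("both factors need >= 2 levels")
  }
  cells <- table(A, B)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop_arg("empty cell: ", levels(A)[empty[1]], " x ", levels(B)[empty[2]])
  }
  interaction_ok <- any(cells > 1)
  form <- if (interaction_ok) values ~ A * B else values ~ A + B
  fit <- stats::aov(form)
  sm <- summary(fit)[[1]]
  terms <- trimws(rownames(sm))
  df_res <- sm[terms == "Residuals", "Df"]
  pick <- function(term) {
    i <- match(term, terms)
    if (is.na(i)) c(NA_real_, NA_real_, NA_real_)
    else c(sm[i, "Df"], sm[i, "F value"], sm[i, "Pr(>F)"])
  }
  rows <- rbind(A = pick("A"), B = pick("B"), `A:B` = pick("A:B"))
  tab <- data.frame(term = c("A", "B", "A:B"),
                    df1 = rows[, 1], df2 = df_res,
                    F = rows[, 2], p = rows[, 3], row.names = NULL)
  if (!interaction_ok) {
    message("one observation per cell: interaction untestable (additive fit)")
  }
  new_stat_result("anova_two_way", table = tab,
                  interaction_testable = interaction_ok, df_residual = df_res)
}
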