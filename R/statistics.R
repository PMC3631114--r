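#' Paired t test
#'
#' Classical paired t on the differences, two-sided. Used to judge
#' whether a fatigue protocol changed the secant modulus (first vs last
#' cycle over samples). The degenerate case of *identical* series returns
#' t = 0, p = 1; constant non-zero differences (zero variance but
#' non-zero mean) are rejected as degenerate input.
#'
#' @param x,y equal-length numeric vectors (length >= 2).
#' @return List: `statistic`, `df`, `p_value`, `mean_difference`.
#' @examples
#' paired_t_test(c(142, 150, 139), c(134, 141, 133))
#' @export
paired_t_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2,
            is.numeric(x), is.numeric(y))
  d <- x - y
  if (all(d == 0)) {
    return(list(statistic = 0, df = length(d) - 1L, p_value = 1,
                mean_difference = 0))
  }
  if (sd(d) == 0) stop("degenerate input: differences have zero variance")
  tt <- t.test(x, y, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = unname(tt$estimate))
}

# Shared model machinery: full two-factor interaction model with
# sum-to-zero contrasts. Returns the design pieces needed by both the
# ANOVA decomposition and the Tukey post hoc.
two_factor_fit <- function(data, response, factor_a, factor_b) {
  for (nm in c(response, factor_a, factor_b)) {
    if (!nm %in% names(data)) stop("column '", nm, "' not found")
  }
  y <- data[[response]]
  A <- factor(data[[factor_a]])
  B <- factor(data[[factor_b]])
  stopifnot(is.numeric(y), nlevels(A) >= 2, nlevels(B) >= 2)
  tab <- table(A, B)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop("empty cell: ", rownames(tab)[empty[1]], " x ",
         colnames(tab)[empty[2]], "; ANOVA with interaction needs every ",
         "cell occupied")
  }
  if (any(tab < 2)) {
    warning("some cells have fewer than 2 observations; interaction ",
            "mean squares are weakly determined")
  }
  df_model <- data.frame(y = y, A = A, B = B)
  X <- model.matrix(~ A * B, df_model,
                    contrasts.arg = list(A = "contr.sum", B = "contr.sum"))
  fit <- lm.fit(X, y)
  rss_full <- sum(fit$residuals^2)
  df_res <- length(y) - ncol(X)
  list(y = y, A = A, B = B, X = X, assign = attr(X, "assign"),
       rss_full = rss_full, df_res = df_res, tab = tab)
}

#' Two-way ANOVA with interaction (Type III sums of squares)
#'
#' Fixed-effects two-factor ANOVA for possibly unbalanced designs. Each
#' effect's sum of squares is the increase in residual sum of squares
#' when that effect's columns are dropped from the full sum-to-zero
#' interaction model (partial, Type III, decomposition); for balanced
#' designs this coincides with the classical sequential decomposition.
#'
#' @param data data.frame of observations.
#' @param response name of the numeric response column.
#' @param factor_a,factor_b names of the two factor columns (defaults
#'   `"histology"` and `"treatment"`).
#' @return data.frame of class `anova_table` with one row per effect
#'   (`factor_a`, `factor_b`, interaction, residuals): `sum_sq`, `df`,
#'   `mean_sq`, `statistic` (F), `p_value`.
#' @examples
#' d <- data.frame(value = rnorm(40),
#'                 histology = rep(c("AM", "PL"), each = 20),
#'                 treatment = rep(c("F", "C"), 20))
#' two_way_anova(d)
#' @export
two_way_anova <- function(data, response = "value", factor_a = "histology",
                          factor_b = "treatment") {
  m <- two_factor_fit(data, response, factor_a, factor_b)
  rss_term <- function(term) {
    Xr <- m$X[, m$assign != term, drop = FALSE]
    sum(lm.fit(Xr, m$y)$residuals^2) - m$rss_full
  }
  terms <- c(factor_a, factor_b, paste0(factor_a, ":", factor_b))
  ss <- vapply(1:3, rss_term, numeric(1))
  dfs <- vapply(1:3, function(t) sum(m$assign == t), numeric(1))
  ms_res <- m$rss_full / m$df_res
  out <- data.frame(
    term = c(terms, "Residuals"),
    sum_sq = c(ss, m$rss_full),
    df = c(dfs, m$df_res),
    mean_sq = c(ss / dfs, ms_res),
    statistic = c((ss / dfs) / ms_res, NA_real_),
    p_value = c(pf((ss / dfs) / ms_res, dfs, m$df_res, lower.tail = FALSE),
                NA_real_),
    stringsAsFactors = FALSE
  )
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Tukey--Kramer post hoc comparisons among the four cells
#'
#' All pairwise comparisons among the (factor A x factor B) cell means,
#' using the residual mean square of the full interaction model and the
#' studentized range distribution. The Tukey--Kramer harmonic form
#' `SE = sqrt(MSE/2 * (1/n_i + 1/n_j))` handles unequal cell sizes; for
#' equal n it reduces to the classical Tukey HSD. Stars mark adjusted
#' p below 0.05 (`*`), 0.02 (`**`) and 0.01 (`***`).
#'
#' @inheritParams two_way_anova
#' @return data.frame of class `tukey_result`: `group1`, `group2`,
#'   `mean_difference`, `q` (studentized-range statistic), `p_adj`,
#'   `stars`.
#' @export
tukey_posthoc <- function(data, response = "value", factor_a = "histology",
                          factor_b = "treatment") {
  m <- two_factor_fit(data, response, factor_a, factor_b)
  if (m$df_res < 1) stop("no residual degrees of freedom for the post hoc")
  cell <- interaction(m$A, m$B, sep = ":", drop = TRUE)
  means <- tapply(m$y, cell, mean)
  ns <- tapply(m$y, cell, length)
  k <- nlevels(cell)
  mse <- m$rss_full / m$df_res
  pairs <- utils::combn(levels(cell), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    diff <- means[[g1]] - means[[g2]]
    se <- sqrt(mse / 2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    q <- abs(diff) / se
    p <- ptukey(q, nmeans = k, df = m$df_res, lower.tail = FALSE)
    data.frame(group1 = g1, group2 = g2, mean_difference = diff,
               q = q, p_adj = p, stars = significance_stars(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("tukey_result", "data.frame")
  out
}

# Star notation at the 0.05 / 0.02 / 0.01 thresholds.
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (pp < 0.01) "***" else if (pp < 0.02) "**" else if (pp < 0.05) "*" else ""
  }, character(1))
}
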