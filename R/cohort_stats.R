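# Cohort statistics layer: group comparisons, Pearson correlation matrix,
# linear regression with standardized coefficients and variance inflation
# factors.

#' Compare a variable between groups
#'
#' Continuous variables: two groups are compared with a two-tailed unpaired
#' Welch t test; more than two with one-way ANOVA.  Discrete variables:
#' chi-square test on the group-by-level contingency table, switching to the
#' Fisher exact test when any expected cell count is below 5 and the table is
#' 2x2.
#'
#' @param values_by_group named list, one element per group: numeric vectors
#'   for `variable_kind = "continuous"`, character/factor vectors for
#'   `"discrete"`.
#' @param variable_kind `"continuous"` or `"discrete"`.
#' @param variable optional variable name carried into the result.
#' @return An object of class `group_comparison`: per-group summaries, the
#'   test used (`"t-test"`, `"anova"`, `"chi-square"` or `"Fisher"`) and the
#'   p value.
#' @export
compare_groups <- function(values_by_group,
                           variable_kind = c("continuous", "discrete"),
                           variable = "value") {
  variable_kind <- match.arg(variable_kind)
  if (!is.list(values_by_group) || length(values_by_group) < 2L)
    stop_gait("`values_by_group` must be a named list with at least two groups",
              "parameter_error")
  if (any(lengths(values_by_group) == 0L))
    stop_gait("every group must be non-empty", "parameter_error")
  if (is.null(names(values_by_group)))
    names(values_by_group) <- paste0("group", seq_along(values_by_group))

  if (variable_kind == "continuous") {
    groups <- lapply(values_by_group, as.numeric)
    means <- vapply(groups, mean, numeric(1))
    sds <- vapply(groups, function(x) if (length(x) > 1) sd(x) else 0, numeric(1))
    counts <- lengths(groups)
    if (length(groups) == 2L) {
      if (all(sds == 0))
        stop_gait("both groups have zero variance; the t test is degenerate",
                  "degenerate_input_error")
      ht <- t.test(groups[[1]], groups[[2]], var.equal = FALSE,
                   alternative = "two.sided")
      test <- "t-test"
      p <- unname(ht$p.value)
    } else {
      y <- unlist(groups, use.names = FALSE)
      g <- factor(rep(names(groups), counts))
      p <- summary(aov(y ~ g))[[1]][["Pr(>F)"]][1]
      test <- "anova"
    }
    out <- list(variable = variable, kind = "continuous", means = means,
                sds = sds, counts = counts, test = test, p_value = p)
  } else {
    tab <- do.call(rbind, lapply(values_by_group, function(v)
      table(factor(v, levels = sort(unique(unlist(values_by_group)))))))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    use_fisher <- any(expected < 5) && all(dim(tab) == c(2L, 2L))
    if (use_fisher) {
      p <- fisher.test(tab)$p.value
      test <- "Fisher"
    } else {
      p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
      test <- "chi-square"
    }
    out <- list(variable = variable, kind = "discrete", table = tab,
                counts = rowSums(tab), test = test, p_value = p)
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (%s, %s): p = %.4g\n", x$variable, x$kind,
              x$test, x$p_value))
  if (x$kind == "continuous") {
    for (g in names(x$means))
      cat(sprintf("  %s: mean %.3f (SD %.3f), n = %d\n", g, x$means[[g]],
                  x$sds[[g]], x$counts[[g]]))
  } else print(x$table)
  invisible(x)
}

#' Pearson correlation matrix with p values
#'
#' Pairwise-complete Pearson correlations between the numeric columns of
#' `variables`, with two-tailed p values from the t distribution.  The
#' diagonal is `r = 1` with `p = NA`.
#'
#' @param variables data frame (or matrix) of numeric variables; at least 3
#'   complete observations per pair.
#' @return An object of class `correlation_matrix` with components `r`, `p`
#'   and `n` (symmetric matrices).
#' @export
correlation_matrix <- function(variables) {
  x <- as.data.frame(variables)
  if (ncol(x) < 2L)
    stop_gait("at least two variables are required", "parameter_error")
  for (nm in names(x)) {
    if (!is.numeric(x[[nm]]))
      stop_gait(sprintf("variable \"%s\" is not numeric", nm), "parameter_error")
    if (var(x[[nm]], na.rm = TRUE) == 0 || all(is.na(x[[nm]])))
      stop_gait(sprintf("variable \"%s\" is constant; its correlations are undefined", nm),
                "undefined_correlation_error")
  }
  k <- ncol(x)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(names(x), names(x)))
  diag(r) <- 1
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j) next
    ok <- stats::complete.cases(x[[i]], x[[j]])
    m <- sum(ok)
    if (m < 3L)
      stop_gait(sprintf("fewer than 3 complete observations for pair (%s, %s)",
                        names(x)[i], names(x)[j]), "parameter_error")
    rij <- cor(x[[i]][ok], x[[j]][ok])
    tt <- rij * sqrt((m - 2) / (1 - rij^2))
    pij <- if (abs(rij) >= 1) 0 else 2 * stats::pt(abs(tt), df = m - 2, lower.tail = FALSE)
    r[i, j] <- r[j, i] <- rij
    p[i, j] <- p[j, i] <- pij
    n[i, j] <- n[j, i] <- m
  }
  diag(n) <- colSums(!is.na(x))
  structure(list(r = r, p = p, n = n), class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat("<correlation_matrix> Pearson r (pairwise complete)\n")
  print(round(x$r, digits))
  invisible(x)
}

#' Linear regression with standardized coefficients and VIFs
#'
#' Ordinary least squares of `response` on `predictors` (listwise deletion of
#' incomplete rows).  Reported per predictor: the unstandardized coefficient
#' B, the standardized coefficient beta (the slope after z-scoring response
#' and predictor, i.e. `B * sd(x) / sd(y)`), the t statistic, two-tailed p
#' value and the variance inflation factor `VIF_j = 1 / (1 - R2_j)`, where
#' `R2_j` is from regressing predictor j on the remaining predictors.
#'
#' @param data data frame containing the variables.
#' @param response name of the response column.
#' @param predictors character vector of predictor column names.
#' @return An object of class `regression_report`: `coefficients` data frame
#'   (term, B, beta, t, p_value, vif), `intercept`, `r_squared`, `n`.
#' @export
fit_linear_model <- function(data, response, predictors) {
  data <- as.data.frame(data)
  vars <- c(response, predictors)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0)
    stop_gait(paste0("missing variable(s): ", paste(missing_cols, collapse = ", ")),
              "parameter_error")
  d <- data[stats::complete.cases(data[vars]), vars]
  n <- nrow(d)
  if (n <= length(predictors) + 1L)
    stop_gait("need more complete observations than predictors + 1", "parameter_error")
  for (v in predictors)
    if (var(d[[v]]) == 0)
      stop_gait(sprintf("predictor \"%s\" is constant", v), "singular_design_error")

  X <- as.matrix(d[predictors])
  if (qr(cbind(1, X))$rank < ncol(X) + 1L)
    stop_gait("predictors are perfectly collinear; the design is singular",
              "singular_design_error")

  fml <- stats::as.formula(paste(response, "~",
                                 paste(sprintf("`%s`", predictors), collapse = " + ")))
  fit <- lm(fml, data = d)
  sm <- summary(fit)
  cf <- sm$coefficients
  sdx <- apply(X, 2, sd)
  sdy <- sd(d[[response]])
  beta <- unname(cf[-1, 1]) * sdx / sdy

  vif <- vapply(seq_along(predictors), function(j) {
    if (length(predictors) == 1L) return(1)
    r2j <- summary(lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2j)
  }, numeric(1))

  structure(list(
    coefficients = data.frame(
      term = predictors,
      B = unname(cf[-1, 1]),
      beta = unname(beta),
      t = unname(cf[-1, 3]),
      p_value = unname(cf[-1, 4]),
      vif = unname(vif)),
    intercept = unname(cf[1, 1]),
    r_squared = sm$r.squared,
    n = n,
    response = response),
    class = "regression_report")
}

#' @export
print.regression_report <- function(x, digits = 4, ...) {
  cat(sprintf("<regression_report> response: %s (n = %d, R2 = %.3f)\n",
              x$response, x$n, x$r_squared))
  cat(sprintf("  (Constant) B = %.4g\n", x$intercept))
  df <- x$coefficients
  df[-1] <- lapply(df[-1], signif, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}
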