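#' Intergrader agreement: intraclass correlation coefficients
#'
#' Computes the single-measure and average-measure intraclass correlation
#' coefficients from a complete subjects-by-raters matrix via the standard
#' two-way ANOVA mean-square decomposition. The default model is two-way
#' random effects with absolute agreement, i.e. ICC(2,1) and ICC(2,k) — the
#' usual choice when two interchangeable graders each rate every scan. The
#' two-way mixed, consistency form (ICC(3,1)/ICC(3,k)) is available via
#' `model = "consistency"`.
#'
#' @param ratings numeric matrix, one row per subject, one column per rater;
#'   no missing cells.
#' @param model `"agreement"` (default, ICC(2,.)) or `"consistency"`
#'   (ICC(3,.)).
#' @return list with `icc_single`, `icc_average`, `model`, `n`, `k` and the
#'   mean squares `msr`, `msc`, `mse`.
#' @export
#' @examples
#' m <- cbind(c(10, 12, 8, 15, 11), c(11, 14, 9, 15, 13))
#' icc_agreement(m)
icc_agreement <- function(ratings, model = c("agreement", "consistency")) {
  model <- match.arg(model)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) pv_stop("ratings must have no missing cells",
                              "perivasc_input_error")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) {
    pv_stop("need at least 2 subjects and 2 raters", "perivasc_input_error")
  }
  grand <- mean(ratings)
  rowm <- rowMeans(ratings); colm <- colMeans(ratings)
  msr <- k * sum((rowm - grand)^2) / (n - 1)           # between subjects
  msc <- n * sum((colm - grand)^2) / (k - 1)           # between raters
  sse <- sum((ratings - outer(rowm, colm, "+") + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))                     # residual

  if (model == "agreement") {
    den1 <- msr + (k - 1) * mse + k * (msc - mse) / n
    denk <- msr + (msc - mse) / n
  } else {
    den1 <- msr + (k - 1) * mse
    denk <- msr
  }
  if (den1 <= 0 || denk <= 0) {
    pv_warn("zero between-subject variance: ICC undefined, returning 0",
            "perivasc_degenerate_warning")
    icc1 <- 0; icck <- 0
  } else {
    icc1 <- (msr - mse) / den1
    icck <- (msr - mse) / denk
  }
  list(icc_single = icc1, icc_average = icck, model = model,
       n = n, k = k, msr = msr, msc = msc, mse = mse)
}

# Two-sample t-test that degrades gracefully on zero-variance input
# (t.test either errors or returns NaN there, depending on the exact case).
safe_t_test <- function(x, y, paired = FALSE, var.equal = FALSE) {
  degenerate <- function() {
    delta <- if (paired) mean(x - y) else mean(x) - mean(y)
    if (isTRUE(all.equal(delta, 0))) {
      list(statistic = c(t = 0), p.value = 1,
           parameter = c(df = length(x) - 1))
    } else {
      # zero variance but a real separation: report it as certain
      list(statistic = c(t = Inf * sign(delta)), p.value = 0,
           parameter = c(df = length(x) - 1))
    }
  }
  res <- tryCatch(
    t.test(x, y, paired = paired, var.equal = var.equal),
    error = function(e) {
      if (!grepl("essentially constant", conditionMessage(e))) stop(e)
      degenerate()
    })
  if (is.nan(res$p.value)) res <- degenerate()
  res
}

#' Group comparison: one-way ANOVA with Bonferroni post-hoc t-tests
#'
#' Performs the omnibus one-way ANOVA across groups for one metric, followed
#' by all pairwise independent t-tests with Bonferroni correction (adjusted
#' P = raw P times the number of pairwise comparisons, capped at 1). Post-hoc
#' tests use the equal-variance Student form by default; `posthoc = "welch"`
#' drops the equal-variance assumption. A pair where a zero-variance group
#' makes the Student statistic undefined falls back to a defined degenerate
#' result.
#'
#' @param data data frame of per-eye records.
#' @param metric name of the numeric outcome column.
#' @param group name of the grouping column (default `"group"`).
#' @param posthoc `"student"` (default) or `"welch"`.
#' @return list with `anova` (`f`, `df1`, `df2`, `p`), `posthoc` data frame
#'   (one row per pair: `group1`, `group2`, `t`, `p_raw`, `p_bonferroni`),
#'   and `group_stats` (n, mean, sd per group).
#' @export
group_comparison <- function(data, metric, group = "group",
                             posthoc = c("student", "welch")) {
  posthoc <- match.arg(posthoc)
  y <- data[[metric]]; g <- factor(data[[group]])
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(g[keep])
  lv <- levels(g)
  if (length(lv) < 2L) pv_stop("need at least 2 groups",
                               "perivasc_input_error")
  if (any(table(g) < 2L)) pv_stop("each group needs n >= 2",
                                  "perivasc_input_error")
  ow <- oneway.test(y ~ g, var.equal = TRUE)
  pairs <- utils::combn(lv, 2L)
  n_comp <- ncol(pairs)
  ph <- lapply(seq_len(n_comp), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tt <- safe_t_test(y[g == a], y[g == b],
                      var.equal = (posthoc == "student"))
    data.frame(group1 = a, group2 = b,
               t = unname(tt$statistic), p_raw = tt$p.value,
               p_bonferroni = min(1, tt$p.value * n_comp),
               stringsAsFactors = FALSE)
  })
  gs <- do.call(rbind, lapply(lv, function(l) {
    data.frame(group = l, n = sum(g == l), mean = mean(y[g == l]),
               sd = sd(y[g == l]), stringsAsFactors = FALSE)
  }))
  list(anova = list(f = unname(ow$statistic),
                    df1 = unname(ow$parameter[1]),
                    df2 = unname(ow$parameter[2]),
                    p = ow$p.value),
       posthoc = do.call(rbind, ph),
       group_stats = gs)
}

#' Paired comparison of obstructive and contralateral quadrants
#'
#' Classical paired t-test on within-eye differences between the quadrant
#' containing the venous obstruction and its (diagonally opposite) reference
#' quadrant. When every difference is zero the test is reported as t = 0,
#' P = 1 rather than erroring.
#'
#' @param obstructive numeric vector of obstructive-quadrant reflectivities.
#' @param contralateral numeric vector of the paired contralateral values.
#' @return list with `t`, `df`, `p`, `mean_difference`, `n`.
#' @export
paired_quadrant_test <- function(obstructive, contralateral) {
  if (length(obstructive) != length(contralateral) ||
      length(obstructive) < 2L) {
    pv_stop("need paired vectors of equal length n >= 2",
            "perivasc_input_error")
  }
  tt <- safe_t_test(obstructive, contralateral, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       mean_difference = mean(obstructive - contralateral),
       n = length(obstructive))
}

# z-score with sample SD; binary factors/characters/logicals become 0/1 first.
standardize_var <- function(x, name = "variable") {
  if (is.logical(x)) x <- as.numeric(x)
  if (is.character(x) || is.factor(x)) {
    lv <- sort(unique(as.character(x[!is.na(x)])))
    if (length(lv) > 2L) {
      pv_stop(sprintf("'%s' has %d levels; only binary categorical predictors are supported",
                      name, length(lv)), "perivasc_input_error")
    }
    x <- as.numeric(match(as.character(x), lv) - 1L)
  }
  s <- sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) return(rep(NA_real_, length(x)))
  (x - mean(x, na.rm = TRUE)) / s
}

#' Univariate and multivariate standardized-beta regression
#'
#' Fits, for each candidate predictor, a simple linear regression of the
#' z-standardized outcome on the z-standardized predictor (so the univariate
#' standardized beta equals the Pearson correlation), then a multivariate
#' model restricted to predictors whose univariate P value is below
#' `entry_p` (default 0.2, the conventional entry rule for this screen).
#' Binary categorical predictors are coded 0/1 before standardization;
#' missing values are dropped listwise per model and the per-model n is
#' reported.
#'
#' @param data data frame of per-eye records.
#' @param outcome name of the outcome column (default
#'   `"corrected_reflectivity"`).
#' @param predictors character vector of predictor column names.
#' @param entry_p univariate P threshold for entry into the multivariate
#'   model (default 0.2).
#' @return list with `univariate` and `multivariate` data frames (columns
#'   `predictor`, `standardized_beta`, `p_value`, `n`), and `entered`, the
#'   predictors that met the entry rule.
#' @export
regression_suite <- function(data, outcome = "corrected_reflectivity",
                             predictors, entry_p = 0.2) {
  if (!outcome %in% names(data)) {
    pv_stop(sprintf("outcome '%s' not found", outcome),
            "perivasc_input_error")
  }
  missing_pred <- setdiff(predictors, names(data))
  if (length(missing_pred)) {
    pv_stop(paste("predictors not found:",
                  paste(missing_pred, collapse = ", ")),
            "perivasc_input_error")
  }
  uni <- do.call(rbind, lapply(predictors, function(p) {
    d <- data.frame(y = data[[outcome]], x = data[[p]])
    d <- d[stats::complete.cases(d), , drop = FALSE]
    zy <- standardize_var(d$y, outcome)
    zx <- standardize_var(d$x, p)
    if (nrow(d) < 3L || anyNA(zx) || anyNA(zy)) {
      return(data.frame(predictor = p, standardized_beta = NA_real_,
                        p_value = NA_real_, n = nrow(d),
                        stringsAsFactors = FALSE))
    }
    fit <- summary(lm(zy ~ zx))
    data.frame(predictor = p,
               standardized_beta = fit$coefficients["zx", "Estimate"],
               p_value = fit$coefficients["zx", "Pr(>|t|)"],
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  entered <- uni$predictor[!is.na(uni$p_value) & uni$p_value < entry_p]

  multi <- data.frame(predictor = character(), standardized_beta = numeric(),
                      p_value = numeric(), n = integer(),
                      stringsAsFactors = FALSE)
  if (length(entered) > 0L) {
    cols <- c(outcome, entered)
    d <- data[, cols, drop = FALSE]
    d <- d[stats::complete.cases(d), , drop = FALSE]
    if (nrow(d) <= length(entered) + 1L) {
      pv_stop("too few complete cases for the multivariate model",
              "perivasc_input_error")
    }
    z <- data.frame(lapply(seq_along(cols), function(i) {
      standardize_var(d[[cols[i]]], cols[i])
    }))
    names(z) <- c(".y", paste0("x", seq_along(entered)))
    fit <- lm(.y ~ . - 1, data = z)
    if (anyNA(coef(fit))) {
      bad <- entered[is.na(coef(fit))]
      pv_stop(paste("rank-deficient multivariate design; collinear predictors:",
                    paste(bad, collapse = ", ")),
              "perivasc_collinearity_error")
    }
    sm <- summary(fit)$coefficients
    multi <- data.frame(predictor = entered,
                        standardized_beta = unname(sm[, "Estimate"]),
                        p_value = unname(sm[, "Pr(>|t|)"]),
                        n = nrow(d), stringsAsFactors = FALSE)
  }
  list(univariate = uni, multivariate = multi, entered = entered,
       entry_p = entry_p)
}

#' Disease-duration sub-analysis
#'
#' Splits eyes at a disease-duration cut (default 36 months from first
#' visit), compares reflectivity and injection burden between the two strata
#' with independent t-tests, and fits within each stratum a simple
#' standardized regression of reflectivity on injections per year, reporting
#' the standardized beta, R-squared and P value stratum by stratum.
#'
#' @param data data frame with `duration_months` plus outcome and predictor
#'   columns.
#' @param split_months duration cut in months (default 36).
#' @param outcome outcome column (default `"corrected_reflectivity"`).
#' @param predictor predictor column (default `"injections_per_year"`).
#' @return list with `strata` (n and duration summary per stratum),
#'   `comparisons` (between-stratum t-tests on outcome and predictor), and
#'   `regressions` (per-stratum standardized beta, r_squared, p; `NA` with a
#'   warning when a stratum has fewer than 3 complete cases).
#' @export
duration_subanalysis <- function(data, split_months = 36,
                                 outcome = "corrected_reflectivity",
                                 predictor = "injections_per_year") {
  dur <- data$duration_months
  early <- !is.na(dur) & dur < split_months
  late <- !is.na(dur) & dur >= split_months
  if (sum(early) == 0L || sum(late) == 0L) {
    pv_stop(sprintf("empty stratum at split %s months", split_months),
            "perivasc_input_error")
  }
  strata <- data.frame(
    stratum = c(sprintf("<%d months", split_months),
                sprintf(">=%d months", split_months)),
    n = c(sum(early), sum(late)),
    duration_mean = c(mean(dur[early]), mean(dur[late])),
    duration_sd = c(sd(dur[early]), sd(dur[late])),
    stringsAsFactors = FALSE)

  cmp <- do.call(rbind, lapply(c(outcome, predictor), function(v) {
    tt <- safe_t_test(data[[v]][early], data[[v]][late], var.equal = TRUE)
    data.frame(variable = v,
               mean_early = mean(data[[v]][early], na.rm = TRUE),
               mean_late = mean(data[[v]][late], na.rm = TRUE),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))

  reg_one <- function(sel, label) {
    d <- data.frame(y = data[[outcome]][sel], x = data[[predictor]][sel])
    d <- d[stats::complete.cases(d), , drop = FALSE]
    if (nrow(d) < 3L) {
      pv_warn(sprintf("stratum '%s' has n < 3; regression skipped", label),
              "perivasc_small_stratum_warning")
      return(data.frame(stratum = label, standardized_beta = NA_real_,
                        r_squared = NA_real_, p = NA_real_, n = nrow(d),
                        stringsAsFactors = FALSE))
    }
    fit <- summary(lm(standardize_var(d$y) ~ standardize_var(d$x)))
    data.frame(stratum = label,
               standardized_beta = fit$coefficients[2, "Estimate"],
               r_squared = fit$r.squared,
               p = fit$coefficients[2, "Pr(>|t|)"],
               n = nrow(d), stringsAsFactors = FALSE)
  }
  regs <- rbind(reg_one(early, strata$stratum[1]),
                reg_one(late, strata$stratum[2]))
  list(strata = strata, comparisons = cmp, regressions = regs,
       split_months = split_months)
}
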