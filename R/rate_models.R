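# Comprehension-versus-speech-rate models.
#
# Two candidate descriptions of how median slider scores fall with speech
# rate x: a straight line y = b0 + b1 * x, and a three-parameter sigmoid
#   y = b0 / (1 + exp(-b1 * (x - b2)))
# where b0 is the maximum asymptote, b1 the growth rate (negative for a
# declining curve) and b2 the center, the rate at which the main drop in
# comprehension occurs. The models are compared by rate-stratified k-fold
# cross-validation (Pearson r between predicted and observed scores per
# fold) and a Wilcoxon signed-rank test over subjects.

new_rate_fit <- function(model, params, x, y, fitted, converged = TRUE,
                         diagnostics = NULL) {
  structure(list(model = model, params = params, x = x, y = y,
                 fitted.values = fitted, residuals = y - fitted,
                 converged = converged, diagnostics = diagnostics,
                 per_fold = NULL, mean_r = NA_real_, mean_mse = NA_real_),
            class = "rate_fit")
}

#' Fit a linear comprehension-decline model
#'
#' Ordinary least squares for `y = b0 + b1 * x`.
#'
#' @param x speech rates (at least two distinct values).
#' @param y median slider scores.
#' @return an object of class `rate_fit` with `params` `(b0, b1)`; supports
#'   `coef()`, `predict()`, `print()`, `summary()`, `residuals()`, `plot()`.
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stopf("'x' and 'y' must have equal length >= 2")
  if (length(unique(x)) < 2) stopf("'x' is constant; linear fit is rank deficient")
  fit <- stats::lm.fit(cbind(b0 = 1, b1 = x), y)
  params <- stats::setNames(fit$coefficients, c("b0", "b1"))
  new_rate_fit("linear", params, x, y, fitted = fit$fitted.values)
}

sigmoid_fun <- function(x, b0, b1, b2) b0 / (1 + exp(-b1 * (x - b2)))

#' Fit a sigmoidal comprehension-decline model
#'
#' Nonlinear least squares (bounded Levenberg-Marquardt via
#' [minpack.lm::nlsLM()]) for `y = b0 / (1 + exp(-b1 * (x - b2)))`. A
#' declining curve is encoded with `b1 < 0`. Default initialization is
#' `b0 = max(y)`, `b1 = -1`, `b2 = median(x)`; bounds constrain
#' `b0` to `(0, 1.5]` and `b2` to `[min(x), max(x)]`. On non-convergence, up
#' to 10 seeded random restarts are drawn within the bounds before a fit
#' error (carrying the collected diagnostics) is raised.
#'
#' @param x speech rates; at least 4 points spanning at least 3 distinct
#'   values.
#' @param y median slider scores.
#' @param init optional named start values `(b0, b1, b2)`.
#' @param bounds optional list with `lower` and `upper` named vectors.
#' @param restarts number of random restarts on failure.
#' @param seed seed for the restart draws.
#' @return an object of class `rate_fit` with `params` `(b0, b1, b2)`.
#' @export
fit_sigmoid <- function(x, y, init = NULL, bounds = NULL, restarts = 10,
                        seed = 1) {
  if (length(x) != length(y)) stopf("'x' and 'y' must have equal length")
  if (length(x) < 4 || length(unique(x)) < 3)
    stopf("need >= 4 points spanning >= 3 distinct rates")
  lower <- c(b0 = 1e-6, b1 = -50, b2 = min(x))
  upper <- c(b0 = 1.5, b1 = 50, b2 = max(x))
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) lower[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) upper[names(bounds$upper)] <- bounds$upper
  }
  start <- c(b0 = min(max(y), upper["b0"]), b1 = -1, b2 = stats::median(x))
  names(start) <- c("b0", "b1", "b2")
  start <- pmin(pmax(start, lower), upper)
  if (!is.null(init)) start[names(init)] <- init
  df <- data.frame(x = x, y = y)
  try_fit <- function(st) {
    tryCatch(minpack.lm::nlsLM(y ~ b0 / (1 + exp(-b1 * (x - b2))), data = df,
                               start = as.list(st), lower = lower,
                               upper = upper,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200)),
             error = function(e) e)
  }
  fit <- try_fit(start)
  diag <- list()
  if (inherits(fit, "error")) {
    diag$first_error <- conditionMessage(fit)
    starts <- with_seed(seed, replicate(restarts, stats::setNames(
      stats::runif(3, pmax(lower, c(0.01, -10, min(x))),
                   pmin(upper, c(1.5, 10, max(x)))), c("b0", "b1", "b2")),
      simplify = FALSE))
    for (st in starts) {
      fit <- try_fit(st)
      if (!inherits(fit, "error")) break
    }
  }
  if (inherits(fit, "error")) {
    diag$last_error <- conditionMessage(fit)
    stopf("sigmoid fit failed to converge after %d restarts (%s)",
          restarts, diag$last_error)
  }
  params <- stats::coef(fit)[c("b0", "b1", "b2")]
  new_rate_fit("sigmoid", params, x, y,
               fitted = sigmoid_fun(x, params["b0"], params["b1"], params["b2"]),
               diagnostics = diag)
}

#' @export
coef.rate_fit <- function(object, ...) object$params

#' @export
predict.rate_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else
    if (is.list(newdata)) newdata$x else newdata
  p <- object$params
  if (object$model == "linear") p["b0"] + p["b1"] * x
  else sigmoid_fun(x, p["b0"], p["b1"], p["b2"])
}

#' @export
residuals.rate_fit <- function(object, ...) object$residuals

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> %s model, %d trials\n", x$model, length(x$x)))
  print(round(x$params, 4))
  invisible(x)
}

#' @export
summary.rate_fit <- function(object, ...) {
  cat(sprintf("%s comprehension-decline model (%d trials)\n",
              tools::toTitleCase(object$model), length(object$x)))
  print(round(object$params, 4))
  cat(sprintf("residual SD %.4f\n", stats::sd(object$residuals)))
  if (!is.null(object$per_fold)) {
    cat(sprintf("cross-validation: mean r %.3f, mean MSE %.4f over %d folds\n",
                object$mean_r, object$mean_mse, nrow(object$per_fold)))
  }
  invisible(object)
}

#' @export
plot.rate_fit <- function(x, ...) {
  ord <- order(x$x)
  graphics::plot(x$x, x$y, xlab = "speech rate", ylab = "median slider score",
                 pch = 16, col = "grey50", ...)
  xx <- seq(min(x$x), max(x$x), length.out = 200)
  graphics::lines(xx, predict(x, xx), lwd = 2,
                  col = if (x$model == "sigmoid") "firebrick" else "steelblue")
  invisible(x)
}

#' Rate-stratified cross-validation folds
#'
#' Assigns trials to `k` folds so that each fold receives an equal number of
#' trials of each speech rate (remainder dealt round-robin), shuffling within
#' rate by the seed.
#'
#' @param rates per-trial speech-rate labels.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return integer fold assignment (1..k) per trial.
#' @export
stratified_folds <- function(rates, k = 5, seed = 1) {
  tab <- table(rates)
  if (any(tab < k))
    stopf("stratification impossible: rate %s has %d < k = %d trials",
          names(tab)[which.min(tab)], min(tab), k)
  fold <- integer(length(rates))
  with_seed(seed, {
    for (r in names(tab)) {
      idx <- sample(which(as.character(rates) == r))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

cv_one_subject <- function(x, y, k, seed) {
  fold <- stratified_folds(x, k = k, seed = seed)
  per_fold <- lapply(seq_len(k), function(f) {
    tr <- fold != f; te <- fold == f
    lin <- fit_linear(x[tr], y[tr])
    sig <- fit_sigmoid(x[tr], y[tr])
    p_lin <- predict(lin, x[te]); p_sig <- predict(sig, x[te])
    data.frame(fold = f,
               r_linear = suppressWarnings(stats::cor(p_lin, y[te])),
               r_sigmoid = suppressWarnings(stats::cor(p_sig, y[te])),
               mse_linear = mean((p_lin - y[te])^2),
               mse_sigmoid = mean((p_sig - y[te])^2))
  })
  do.call(rbind, per_fold)
}

#' Compare linear and sigmoid models by cross-validation
#'
#' Fits both models within rate-stratified k-fold cross-validation and
#' compares held-out prediction accuracy (Pearson r between predicted and
#' observed median scores, plus MSE). For a single subject, per-fold metrics
#' and their means are returned. For a cohort (a named list of per-subject
#' trial tables), per-subject mean r values are compared with a Wilcoxon
#' signed-rank test (exact distribution for n <= 25, zero differences
#' dropped).
#'
#' @param trials either a data.frame with columns `x` (speech rate) and `y`
#'   (median score), or a list of such data.frames, one per subject.
#' @param k number of folds (default 5).
#' @param seed fold-shuffle seed.
#' @return an object of class `rate_model_comparison`: list with
#'   `per_subject` (data.frame of `r_linear`, `r_sigmoid`, `mse_linear`,
#'   `mse_sigmoid`), `per_fold` (single-subject case), `wilcoxon_stat`,
#'   `p_value`, and `winner` (`"sigmoid"`, `"linear"` or `"tie"`).
#' @export
crossval_compare <- function(trials, k = 5, seed = 1) {
  single <- is.data.frame(trials)
  subjects <- if (single) list(s1 = trials) else trials
  if (is.null(names(subjects)))
    names(subjects) <- sprintf("s%d", seq_along(subjects))
  res <- lapply(seq_along(subjects), function(i) {
    d <- subjects[[i]]
    if (!all(c("x", "y") %in% names(d)))
      stopf("each trial table needs columns 'x' and 'y'")
    cv_one_subject(d$x, d$y, k = k, seed = child_seed(seed, i))
  })
  per_subject <- do.call(rbind, lapply(seq_along(res), function(i) {
    m <- res[[i]]
    data.frame(subject = names(subjects)[i],
               r_linear = mean(m$r_linear, na.rm = TRUE),
               r_sigmoid = mean(m$r_sigmoid, na.rm = TRUE),
               mse_linear = mean(m$mse_linear),
               mse_sigmoid = mean(m$mse_sigmoid),
               stringsAsFactors = FALSE)
  }))
  wstat <- NA_real_; pval <- NA_real_
  if (nrow(per_subject) >= 2) {
    d <- per_subject$r_sigmoid - per_subject$r_linear
    d <- d[d != 0]
    if (length(d) > 0) {
      wt <- stats::wilcox.test(d, exact = length(d) <= 25, correct = TRUE)
      wstat <- unname(wt$statistic); pval <- wt$p.value
    } else pval <- 1
  }
  winner <- {
    dm <- mean(per_subject$r_sigmoid) - mean(per_subject$r_linear)
    if (abs(dm) < .Machine$double.eps) "tie" else
      if (dm > 0) "sigmoid" else "linear"
  }
  structure(list(per_subject = per_subject,
                 per_fold = if (single) res[[1]] else NULL,
                 wilcoxon_stat = wstat, p_value = pval, winner = winner,
                 k = k),
            class = "rate_model_comparison")
}

#' @export
print.rate_model_comparison <- function(x, ...) {
  cat(sprintf("<rate_model_comparison> %d subject(s), %d-fold stratified CV\n",
              nrow(x$per_subject), x$k))
  cat(sprintf("  mean r: linear %.3f, sigmoid %.3f -> winner: %s\n",
              mean(x$per_subject$r_linear), mean(x$per_subject$r_sigmoid),
              x$winner))
  if (!is.na(x$p_value))
    cat(sprintf("  Wilcoxon signed-rank on per-subject r: V = %s, p = %.4g\n",
                format(x$wilcoxon_stat), x$p_value))
  invisible(x)
}

#' Paired t-test with Cohen's d
#'
#' Paired-samples t-test on `a - b`, with the standardized effect size
#' `d = mean(diff) / sd(diff) = t / sqrt(n)`.
#'
#' @param a,b paired numeric vectors of equal length `n >= 2`.
#' @return list with `t_stat`, `df`, `p_value`, `d`, `mean_diff`.
#' @export
paired_cohens_d <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stopf("'a' and 'b' must be paired vectors of length >= 2")
  d <- a - b
  if (stats::sd(d) == 0)
    stopf("zero-variance differences: paired t undefined")
  tt <- stats::t.test(d)
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, d = mean(d) / stats::sd(d), mean_diff = mean(d))
}

#' Two-way fixed-effects ANOVA
#'
#' Crossed two-factor analysis of variance with interaction (e.g. speech
#' rate by pentile on slider or similarity scores), via [stats::aov()].
#'
#' @param values numeric response.
#' @param factor_a,factor_b factors (coerced); every crossed cell must be
#'   non-empty.
#' @param names_ab labels for the two factors in the output.
#' @return data.frame with `effect`, `df`, `F`, `p`.
#' @export
two_way_anova <- function(values, factor_a, factor_b,
                          names_ab = c("factor_a", "factor_b")) {
  fa <- factor(factor_a); fb <- factor(factor_b)
  if (nlevels(fa) < 2 || nlevels(fb) < 2)
    stopf("both factors need at least 2 levels")
  if (any(table(fa, fb) == 0)) stopf("empty design cell(s)")
  if (stats::sd(values) == 0) {
    eff <- c(names_ab, paste(names_ab, collapse = ":"))
    return(data.frame(effect = eff,
                      df = c(nlevels(fa) - 1L, nlevels(fb) - 1L,
                             (nlevels(fa) - 1L) * (nlevels(fb) - 1L)),
                      F = 0, p = 1, stringsAsFactors = FALSE))
  }
  fit <- stats::aov(values ~ fa * fb)
  sm <- summary(fit)[[1]]
  eff <- trimws(rownames(sm))
  keep <- eff != "Residuals"
  map <- c(fa = names_ab[1], fb = names_ab[2],
           `fa:fb` = paste(names_ab, collapse = ":"))
  data.frame(effect = unname(map[eff[keep]]),
             df = sm$Df[keep],
             F = sm$`F value`[keep],
             p = sm$`Pr(>F)`[keep],
             stringsAsFactors = FALSE)
}

#' Long-format analysis table for a session
#'
#' Joins trial records with summary scores into one row per trial, carrying
#' the variables of the comprehension analyses, each rescaled to 0-1 so model
#' coefficients are comparable: `median_slider_score` (already 0-1),
#' `speech_rate_01` (min-max over observed rates), `scale_10_01`
#' (rating / 10), `semantic_01` (min-max over the written-summary scores),
#' `digit_span_01` ((span - 3) / 6) and `digit_in_noise_01` (percent / 100).
#' Trials without a summary carry `NA` semantic scores, not zeros. Raw
#' columns are kept alongside. Mixed-effects model fitting on this table is
#' delegated to the user's preferred package; the companion formula is
#' `median_slider_score ~ speech_rate + (1 | digit_span) + (1 | digit_in_noise)`.
#'
#' @param records list of trial records.
#' @param scores optional data.frame from [score_summaries()].
#' @return data.frame with one row per trial; duplicate trial ids raise an
#'   error.
#' @export
build_trial_table <- function(records, scores = NULL) {
  tab <- do.call(rbind, lapply(records, function(r) data.frame(
    participant_id = r$participant_id, trial_id = r$trial_id,
    speech_rate = r$speech_rate, duration_s = r$duration_s,
    median_slider_score = median_score(r$trace),
    scale_10 = if (is.null(r$scale_10)) NA_integer_ else r$scale_10,
    mc_correct = if (is.null(r$mc_correct)) NA_integer_ else r$mc_correct,
    digit_span = r$digit_span, digit_in_noise = r$digit_in_noise,
    stringsAsFactors = FALSE)))
  if (anyDuplicated(paste(tab$participant_id, tab$trial_id)))
    stopf("duplicate trial keys in 'records'")
  if (!is.null(scores)) {
    keys <- if ("participant_id" %in% names(scores))
      c("participant_id", "trial_id") else "trial_id"
    if (anyDuplicated(scores[keys])) stopf("duplicate trial keys in 'scores'")
    tab <- merge(tab, scores, by = keys, all.x = TRUE, sort = FALSE)
  } else {
    tab$written_summary_score <- NA_real_
    tab$heard_segment_score <- NA_real_
    tab$contextual_score <- NA_real_
  }
  rng <- range(tab$speech_rate)
  tab$speech_rate_01 <- if (diff(rng) == 0) 0 else
    (tab$speech_rate - rng[1]) / diff(rng)
  tab$scale_10_01 <- tab$scale_10 / 10
  ws <- tab$written_summary_score
  if (any(!is.na(ws)) && diff(range(ws, na.rm = TRUE)) > 0) {
    wr <- range(ws, na.rm = TRUE)
    tab$semantic_01 <- (ws - wr[1]) / diff(wr)
  } else tab$semantic_01 <- NA_real_
  tab$digit_span_01 <- (tab$digit_span - 3) / 6
  tab$digit_in_noise_01 <- tab$digit_in_noise / 100
  tab
}
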