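# Nonlinear logistic risk models mapping an integer marker score to a
# predicted entity risk. Three closed forms are supported:
#   shift:    y = 1 / (1 + exp(s * (x - a)))
#   shift2:   y = 1 / (1 + exp(s * (x - a + b)))
#   plateau:  y = 1 / (a + exp(s * (x - b)))
# The published fits write the exponent as exp(x - a ...), i.e. s = +1,
# which *decreases* with the score and contradicts both the rising
# risk-vs-score curves and the score construction ("1 equaling a better
# chance of an event"); the default orientation is therefore s = -1 (risk
# increases with the score), with the verbatim printed form available via
# s = +1. Under either orientation the shift form crosses risk 0.5 at
# x = a. In the shift2 form only a - b is identifiable.

RISK_FORMS <- c("shift", "shift2", "plateau")

#' Construct a risk model
#'
#' @param entity Target entity label.
#' @param form One of `"shift"`, `"shift2"`, `"plateau"` (see Details in
#'   [predict_risk()]).
#' @param a,b Parameters (score units / dimensionless); `b` is unused by the
#'   shift form. The plateau form requires `a > 0`.
#' @param s Orientation, `-1` (risk increases with score, default) or `+1`
#'   (the verbatim printed form).
#' @return Object of class `risk_model`.
#' @export
risk_model <- function(entity, form, a, b = NA_real_, s = -1) {
  form <- match.arg(form, RISK_FORMS)
  if (!s %in% c(-1, 1)) stop("`s` must be -1 or +1", call. = FALSE)
  if (form == "plateau" && (is.na(a) || a <= 0)) {
    stop("the plateau form requires a > 0", call. = FALSE)
  }
  if (form %in% c("shift2", "plateau") && is.na(b)) {
    stop("form '", form, "' requires parameter b", call. = FALSE)
  }
  structure(list(entity = entity, form = form, a = a, b = b, s = s),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  f <- switch(x$form,
    shift = sprintf("1 / (1 + exp(%+d * (x - %.4f)))", x$s, x$a),
    shift2 = sprintf("1 / (1 + exp(%+d * (x - %.4f + %.4f)))", x$s, x$a, x$b),
    plateau = sprintf("1 / (%.4f + exp(%+d * (x - %.4f)))", x$a, x$s, x$b))
  cat("Risk model for ", x$entity, ": y = ", f, "\n", sep = "")
  invisible(x)
}

#' The three published risk models
#'
#' NSOI: shift2 form with a = 15.4536, b = 131.3080 (degenerate as printed —
#' only a - b enters the curve, and exp(x - a + b) is astronomically large
#' for any attainable score, so the literal curve is ~0 for s = +1 and ~1
#' for s = -1; exposed verbatim). MALT lymphoma: shift form with a = 8.5000.
#' IgG4-ROD: plateau form with a = 0.8164, b = 11.831 (its low-score limit
#' 1/a = 1.22 exceeds 1, so reported risks are clamped only when asked for a
#' probability).
#'
#' @param s Orientation for all three models (default `-1`; see [risk_model()]).
#' @return Named list of three `risk_model` objects.
#' @export
#' @examples
#' published_models()[["MALT"]]
published_models <- function(s = -1) {
  list(
    "NSOI" = risk_model("NSOI", "shift2", a = 15.4536, b = 131.3080, s = s),
    "MALT" = risk_model("MALT", "shift", a = 8.5000, s = s),
    "IgG4-ROD" = risk_model("IgG4-ROD", "plateau", a = 0.8164, b = 11.831, s = s))
}

#' Predicted risk at given scores
#'
#' Evaluates the model curve. The shift forms are evaluated through
#' `plogis()` so large exponents cannot overflow; the plateau form
#' saturates at `1/a` (low-score limit for s = -1). With `clamp = TRUE`
#' the value is truncated to `[0, 1]` for reporting as a probability; the
#' raw curve value is available with `clamp = FALSE`.
#'
#' @param model A `risk_model`.
#' @param score Numeric score(s).
#' @param clamp Truncate to `[0, 1]` (default `TRUE`).
#' @return Numeric vector of risks (never `NaN` or infinite for finite
#'   scores).
#' @export
#' @examples
#' predict_risk(published_models()[["MALT"]], 0:12)
predict_risk <- function(model, score, clamp = TRUE) {
  stopifnot(inherits(model, "risk_model"), is.finite(score))
  y <- switch(model$form,
    shift = plogis(-model$s * (score - model$a)),
    shift2 = plogis(-model$s * (score - model$a + model$b)),
    plateau = {
      z <- model$s * (score - model$b)
      # exp() overflow gives Inf -> risk 0; underflow gives the 1/a plateau
      1 / (model$a + exp(z))
    })
  if (clamp) pmin(1, pmax(0, y)) else y
}

#' Risk curve over a score range
#'
#' @param model A `risk_model`.
#' @param scores Scores to evaluate (default 0..15).
#' @return Tibble: `score`, `risk` (clamped), `risk_raw`.
#' @export
risk_curve <- function(model, scores = 0:15) {
  tibble::tibble(score = scores,
                 risk = predict_risk(model, scores, clamp = TRUE),
                 risk_raw = predict_risk(model, scores, clamp = FALSE))
}

# Empirical risk (fraction of target entity) per distinct score value.
empirical_risk <- function(score, is_target) {
  tibble::tibble(score = score, y = as.numeric(is_target)) |>
    dplyr::summarise(risk = mean(.data$y), w = dplyr::n(), .by = "score") |>
    dplyr::arrange(.data$score)
}

#' Fit a risk model to scores and labels
#'
#' Computes the empirical risk (fraction of the target entity) at every
#' distinct score value, then fits the chosen closed form to the
#' (score, risk) pairs by weighted nonlinear least squares
#' (Levenberg-Marquardt). The association between score and label is also
#' tested with a binomial generalized linear model (likelihood-ratio test of
#' the score term against the intercept-only model).
#'
#' For the shift2 form only the offset `a - b` is identifiable; the fit
#' reports it as `a` with `b = 0`.
#'
#' @param data Tibble of per-sample scores and entity labels.
#' @param positive The target entity label.
#' @param form Model form (`"shift"`, `"shift2"`, `"plateau"`).
#' @param score,entity Column names (strings) in `data`.
#' @param s Orientation (default `-1`).
#' @return Object of class `risk_fit`: the fitted `risk_model` plus the GLM
#'   p-value and the empirical-risk table. Methods: [tidy()], [glance()],
#'   `predict()`.
#' @export
fit_risk_model <- function(data, positive, form = "shift", score = "score",
                           entity = "entity", s = -1) {
  form <- match.arg(form, RISK_FORMS)
  x <- data[[score]]
  yl <- data[[entity]]
  if (is.null(x) || is.null(yl)) {
    stop("`data` must contain columns '", score, "' and '", entity, "'",
         call. = FALSE)
  }
  if (!positive %in% yl) stop("no sample labelled '", positive, "'", call. = FALSE)
  if (all(yl == positive)) stop("both classes must be present", call. = FALSE)
  if (length(unique(x)) < 2) {
    stop("need >= 2 distinct score values to fit a curve", call. = FALSE)
  }
  emp <- empirical_risk(x, yl == positive)

  mid <- (mean(x[yl == positive]) + mean(x[yl != positive])) / 2
  fml <- switch(form,
    shift = risk ~ 1 / (1 + exp(s * (score - a))),
    shift2 = risk ~ 1 / (1 + exp(s * (score - a))),  # identifiable offset only
    plateau = risk ~ 1 / (a + exp(s * (score - b))))
  start <- switch(form,
    shift = list(a = mid), shift2 = list(a = mid),
    plateau = list(a = 1, b = mid))
  lower <- switch(form,
    shift = -Inf, shift2 = -Inf, plateau = c(a = 1e-6, b = -Inf))
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = cbind(emp, s = s), start = start,
                      weights = emp$w, lower = lower,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("risk-model fit did not converge (", conditionMessage(e),
           "); last start was a = ", signif(mid, 4), call. = FALSE)
    })
  cf <- coef(fit)
  model <- switch(form,
    shift = risk_model(positive, "shift", a = cf[["a"]], s = s),
    shift2 = risk_model(positive, "shift2", a = cf[["a"]], b = 0, s = s),
    plateau = risk_model(positive, "plateau", a = cf[["a"]], b = cf[["b"]], s = s))

  y01 <- as.integer(yl == positive)
  glm_fit <- suppressWarnings(glm(y01 ~ x, family = binomial()))
  glm_p <- suppressWarnings(
    anova(glm_fit, test = "Chisq")[["Pr(>Chi)"]][2])

  structure(list(model = model, fit = fit, glm_p = glm_p, risk_table = emp,
                 n = length(x), positive = positive, form = form),
            class = "risk_fit")
}

#' @export
print.risk_fit <- function(x, ...) {
  print(x$model)
  cat("fit to ", nrow(x$risk_table), " distinct scores from ", x$n,
      " samples; GLM association p = ", format.pval(x$glm_p, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.risk_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, "Estimate"],
                 std.error = sm[, "Std. Error"])
}

#' @exportS3Method generics::glance
glance.risk_fit <- function(x, ...) {
  tibble::tibble(entity = x$positive, form = x$form, n = x$n,
                 n_scores = nrow(x$risk_table), glm_p = x$glm_p,
                 converged = x$fit$convInfo$isConv %||% TRUE)
}

#' @export
predict.risk_fit <- function(object, score, clamp = TRUE, ...) {
  predict_risk(object$model, score, clamp = clamp)
}

#' Leave-one-out cross-validated risks on a score/label table
#'
#' For each sample the risk model is fitted on the remaining n - 1 samples
#' and evaluated at the held-out sample's score.
#'
#' @inheritParams fit_risk_model
#' @return `data` with an added `risk_loo` column.
#' @export
loocv_risk <- function(data, positive, form = "shift", score = "score",
                       entity = "entity", s = -1) {
  n <- nrow(data)
  if (n < 3) stop("leave-one-out validation needs n >= 3", call. = FALSE)
  risk <- vapply(seq_len(n), function(i) {
    fit <- fit_risk_model(data[-i, ], positive, form = form, score = score,
                          entity = entity, s = s)
    predict_risk(fit$model, data[[score]][i])
  }, numeric(1))
  dplyr::mutate(data, risk_loo = risk)
}

#' Leave-one-out cross-validated risks from a count matrix
#'
#' Scores the cohort with `panel` (scores are per-sample, so they do not
#' change under sample deletion), then applies [loocv_risk()].
#'
#' @param counts Normalized counts tibble.
#' @param labels Labels tibble.
#' @param panel One entity's rules; its `entity` value is the target class
#'   unless `positive` is given.
#' @param form,s Passed to [fit_risk_model()].
#' @param positive Target entity label.
#' @return Tibble: `sample_id`, `entity`, `score`, `risk_loo`.
#' @export
loocv_scores <- function(counts, labels, panel, form = "shift",
                         positive = unique(panel$entity), s = -1) {
  sc <- score_cohort(counts, panel)
  data <- dplyr::inner_join(labels, sc, by = "sample_id")
  loocv_risk(data, positive = positive, form = form, s = s)
}
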