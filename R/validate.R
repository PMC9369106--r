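# ROC/AUC evaluation with stratified percentile-bootstrap confidence
# intervals, and the end-to-end validation-cohort report.

# AUC by the trapezoidal rule over the tie-aware ROC sweep; identical to the
# Mann-Whitney U normalization with half credit for ties.
auc_trapezoid <- function(score, y01) {
  ths <- sort(unique(score), decreasing = TRUE)
  n_pos <- sum(y01 == 1)
  n_neg <- sum(y01 == 0)
  tpr <- c(0, vapply(ths, function(t) sum(score >= t & y01 == 1), numeric(1)) / n_pos)
  fpr <- c(0, vapply(ths, function(t) sum(score >= t & y01 == 0), numeric(1)) / n_neg)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' ROC curve and AUC
#'
#' Sweeps a threshold over the distinct score values (predicting the
#' positive class when `score >= threshold`) and reports sensitivity and
#' specificity at each threshold plus the area under the curve by the
#' trapezoidal rule, which equals the Mann-Whitney U normalization with
#' half credit for ties.
#'
#' @param data Tibble with a score column and a truth column.
#' @param truth,score Column names (strings) in `data`.
#' @param positive Value of `truth` counted as the positive class.
#' @return Object of class `orbital_roc` (list with `curve`, `auc`, `n_pos`,
#'   `n_neg`); methods [tidy()], [glance()], [autoplot()].
#' @export
#' @examples
#' d <- tibble::tibble(score = c(0, 1, 2, 3), entity = c("a", "a", "b", "b"))
#' glance(roc_auc(d, "entity", "score", positive = "b"))
roc_auc <- function(data, truth, score, positive) {
  sc <- data[[score]]
  y01 <- as.integer(data[[truth]] == positive)
  if (length(unique(y01)) < 2) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  ths <- sort(unique(sc), decreasing = TRUE)
  curve <- tibble::tibble(
    threshold = c(Inf, ths),
    sensitivity = vapply(c(Inf, ths), function(t) mean(sc[y01 == 1] >= t), numeric(1)),
    specificity = vapply(c(Inf, ths), function(t) mean(sc[y01 == 0] < t), numeric(1)))
  structure(list(curve = curve, auc = auc_trapezoid(sc, y01),
                 n_pos = sum(y01 == 1), n_neg = sum(y01 == 0),
                 positive = positive, ci = NULL, n_boot = NULL,
                 level = NULL, seed = NULL),
            class = "orbital_roc")
}

#' Bootstrap confidence interval for the AUC
#'
#' Percentile interval over stratified resamples (cases and controls
#' resampled within class, so every replicate keeps both classes).
#' Reproducible for a fixed seed.
#'
#' @inheritParams roc_auc
#' @param n_boot Number of bootstrap iterations (>= 100; the reference
#'   procedure uses 1000).
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return An `orbital_roc` with `ci`, `n_boot`, `level`, `seed` filled in.
#' @export
bootstrap_auc_ci <- function(data, truth, score, positive, n_boot = 1000L,
                             level = 0.95, seed = 1L) {
  if (n_boot < 100) stop("`n_boot` must be >= 100", call. = FALSE)
  roc <- roc_auc(data, truth, score, positive)
  sc <- data[[score]]
  y01 <- as.integer(data[[truth]] == positive)
  pos <- which(y01 == 1)
  neg <- which(y01 == 0)
  aucs <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
      auc_trapezoid(sc[idx], y01[idx])
    }, numeric(1))
  })
  alpha2 <- (1 - level) / 2
  roc$ci <- unname(quantile(aucs, c(alpha2, 1 - alpha2)))
  roc$n_boot <- n_boot
  roc$level <- level
  roc$seed <- seed
  roc
}

#' @export
print.orbital_roc <- function(x, ...) {
  cat("ROC for positive class '", x$positive, "': AUC = ",
      sprintf("%.3f", x$auc), sep = "")
  if (!is.null(x$ci)) {
    cat(sprintf(" (%d%% bootstrap CI %.3f-%.3f, %d iterations)",
                round(100 * x$level), x$ci[1], x$ci[2], x$n_boot))
  }
  cat("\n", x$n_pos, " positives / ", x$n_neg, " negatives\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.orbital_roc <- function(x, ...) x$curve

#' @exportS3Method generics::glance
glance.orbital_roc <- function(x, ...) {
  tibble::tibble(positive = x$positive, auc = x$auc,
                 ci_low = if (is.null(x$ci)) NA_real_ else x$ci[1],
                 ci_high = if (is.null(x$ci)) NA_real_ else x$ci[2],
                 n_pos = x$n_pos, n_neg = x$n_neg,
                 n_boot = x$n_boot %||% NA_integer_)
}

# Binomial GLM likelihood-ratio p for score -> class association.
glm_association_p <- function(score, y01) {
  fit <- suppressWarnings(glm(y01 ~ score, family = binomial()))
  suppressWarnings(anova(fit, test = "Chisq")[["Pr(>Chi)"]][2])
}

#' End-to-end validation-cohort report
#'
#' Scores every sample against all panels, evaluates each panel's
#' one-versus-rest discrimination (ROC with stratified bootstrap CI and a
#' binomial-GLM likelihood-ratio p), attaches model-predicted risks, builds
#' the cross-score synopsis (every sample by all three scores) and flags
#' samples whose off-entity score reaches an alert threshold — by default a
#' lymphoma score of 1 or more in a non-lymphoma sample, the pattern that
#' identified occult progression in the original validation cohort.
#'
#' @param counts Normalized validation counts tibble.
#' @param labels Labels tibble.
#' @param panels Panel table (default [published_panels()]).
#' @param models Named list of `risk_model`s keyed by entity (default
#'   [published_models()]).
#' @param n_boot,level,seed Bootstrap settings (see [bootstrap_auc_ci()]).
#' @param alert_entity Panel whose score triggers the alert.
#' @param alert_threshold Minimum off-entity score that triggers it.
#' @return Object of class `orbital_validation`: list with `summary` (one
#'   row per entity: AUC, CI, GLM p), `synopsis` (sample x score table),
#'   `scores` (long scores with risks), `alerts` and `roc` (named list of
#'   `orbital_roc`).
#' @export
validation_report <- function(counts, labels, panels = published_panels(),
                              models = published_models(), n_boot = 1000L,
                              level = 0.95, seed = 1L,
                              alert_entity = "MALT", alert_threshold = 1) {
  assert_counts(counts)
  assert_labels(labels, counts)
  scores <- score_all(counts, panels) |>
    dplyr::rename(panel_entity = "entity") |>
    dplyr::inner_join(labels, by = "sample_id")
  scores$risk <- vapply(seq_len(nrow(scores)), function(i) {
    m <- models[[scores$panel_entity[i]]]
    if (is.null(m)) NA_real_ else predict_risk(m, scores$score[i])
  }, numeric(1))

  entities <- unique(panels$entity)
  roc <- list()
  rows <- lapply(seq_along(entities), function(k) {
    e <- entities[k]
    d <- scores[scores$panel_entity == e, ]
    r <- bootstrap_auc_ci(d, "entity", "score", positive = e,
                          n_boot = n_boot, level = level, seed = seed + k)
    roc[[e]] <<- r
    p <- glm_association_p(d$score, as.integer(d$entity == e))
    tibble::tibble(entity = e, n_pos = r$n_pos, n_neg = r$n_neg,
                   auc = r$auc, ci_low = r$ci[1], ci_high = r$ci[2],
                   glm_p = p)
  })
  summary <- dplyr::bind_rows(rows)

  synopsis <- scores |>
    dplyr::select("sample_id", "entity", "panel_entity", "score") |>
    tidyr::pivot_wider(names_from = "panel_entity", values_from = "score",
                       names_prefix = "score_")
  alert_col <- paste0("score_", alert_entity)
  alerts <- synopsis[synopsis$entity != alert_entity &
                       synopsis[[alert_col]] >= alert_threshold, , drop = FALSE]

  structure(list(summary = summary, synopsis = synopsis, scores = scores,
                 alerts = alerts, roc = roc, alert_entity = alert_entity,
                 alert_threshold = alert_threshold),
            class = "orbital_validation")
}

#' @export
print.orbital_validation <- function(x, ...) {
  cat("Validation report over", nrow(x$synopsis), "samples\n\n")
  print(as.data.frame(x$summary), row.names = FALSE, digits = 3)
  cat("\n", nrow(x$alerts), " sample(s) with ", x$alert_entity, " score >= ",
      x$alert_threshold, " outside ", x$alert_entity, "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.orbital_validation <- function(x, ...) x$summary
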