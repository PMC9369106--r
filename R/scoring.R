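# The three published binarized marker panels and the score computation:
# each rule is a gene, a direction and a cut-off on the normalized count
# scale; a sample's score is the number of rules that fire. Inequalities at
# the cut-off are strict in both directions (a count exactly at the cut-off
# scores 0); flip with `strict = FALSE` if boundary counts should score.

#' The published diagnostic score panels
#'
#' Twelve rules for NSOI (11 up-regulated markers plus down-regulated
#' RPS27A), twelve all-down rules for MALT lymphoma and fifteen all-up rules
#' for IgG4-ROD, each with its published cut-off. Shipped as a plain-text
#' config (`inst/extdata/marker_panels.csv`).
#'
#' @return Tibble with columns `entity`, `gene`, `direction`, `cutoff`.
#' @export
#' @examples
#' dplyr::count(published_panels(), entity, direction)
published_panels <- function() {
  path <- system.file("extdata", "marker_panels.csv", package = "orbitdx",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    entity = readr::col_character(), gene = readr::col_character(),
    direction = readr::col_character(), cutoff = readr::col_double()))
}

assert_panel <- function(panel) {
  if (!all(c("gene", "direction", "cutoff") %in% names(panel))) {
    stop("a score panel needs columns gene, direction, cutoff", call. = FALSE)
  }
  if (!all(panel$direction %in% c("up", "down"))) {
    stop("panel directions must be 'up' or 'down'", call. = FALSE)
  }
  if (any(panel$cutoff <= 0)) stop("panel cut-offs must be > 0", call. = FALSE)
  if (anyDuplicated(panel$gene)) {
    stop("panel genes must be unique within a panel", call. = FALSE)
  }
  invisible(panel)
}

#' Binarized marker score of one expression profile
#'
#' Each rule is binarized against its cut-off (up rule fires when the count
#' exceeds the cut-off, down rule when it falls below) and the hits are
#' summed; the score ranges from 0 to the number of rules.
#'
#' @param profile Tibble with columns `gene`, `count` (normalized counts),
#'   or a named numeric vector.
#' @param panel One entity's rules (e.g. one entity slice of
#'   [published_panels()]).
#' @param strict Use strict inequalities at the cut-off (default); with
#'   `FALSE`, counts exactly at the cut-off also fire.
#' @return Integer score.
#' @export
#' @examples
#' panel <- dplyr::filter(published_panels(), entity == "MALT")
#' compute_score(setNames(rep(0, 12), panel$gene), panel)
compute_score <- function(profile, panel, strict = TRUE) {
  assert_panel(panel)
  if (is.numeric(profile)) {
    profile <- tibble::tibble(gene = names(profile), count = unname(profile))
  }
  missing <- setdiff(panel$gene, profile$gene)
  if (length(missing) > 0) {
    ent <- if ("entity" %in% names(panel)) unique(panel$entity) else "panel"
    stop("profile is missing gene(s) ", paste(missing, collapse = ", "),
         " required by the ", paste(ent, collapse = "/"), " panel",
         call. = FALSE)
  }
  v <- profile$count[match(panel$gene, profile$gene)]
  hit <- ifelse(panel$direction == "up",
                if (strict) v > panel$cutoff else v >= panel$cutoff,
                if (strict) v < panel$cutoff else v <= panel$cutoff)
  as.integer(sum(hit))
}

#' Score every sample of a cohort against one panel
#'
#' @param counts Normalized counts tibble containing every panel gene.
#' @param panel One entity's rules.
#' @param strict Passed to [compute_score()].
#' @return Tibble: `sample_id`, `score` (order matches the sample columns).
#' @export
score_cohort <- function(counts, panel, strict = TRUE) {
  assert_counts(counts)
  endo <- count_matrix(counts, c("Endogenous", "Housekeeping"))
  smp <- sample_ids(counts)
  scores <- vapply(smp, function(s) {
    compute_score(setNames(endo[, s], rownames(endo)), panel, strict = strict)
  }, integer(1))
  tibble::tibble(sample_id = smp, score = scores)
}

#' Score a cohort against all panels
#'
#' @param counts Normalized counts tibble.
#' @param panels Panel table with an `entity` column (default the published
#'   panels).
#' @param strict Passed to [compute_score()].
#' @return Long tibble: `sample_id`, `entity` (the panel's target entity),
#'   `score`.
#' @export
score_all <- function(counts, panels = published_panels(), strict = TRUE) {
  stopifnot("entity" %in% names(panels))
  rows <- lapply(unique(panels$entity), function(e) {
    sc <- score_cohort(counts, panels[panels$entity == e, ], strict = strict)
    dplyr::mutate(sc, entity = e, .after = "sample_id")
  })
  dplyr::bind_rows(rows)
}
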