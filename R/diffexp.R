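# Group-versus-rest differential expression with a normality-gated
# parametric/non-parametric test and Benjamini-Hochberg adjustment.

# Shapiro-Wilk normality check for one arm; arms that are too small or
# constant cannot support the normality assumption and route to the rank test.
arm_is_normal <- function(x, alpha) {
  if (length(x) < 3 || length(x) > 5000 || sd(x) == 0) return(FALSE)
  shapiro.test(x)$p.value >= alpha
}

#' Two-group test for one gene with a normality gate
#'
#' Applies the Shapiro-Wilk test to each arm; if both arms look normal
#' (p >= `alpha_normality`) a two-sided t test is used (Welch by default),
#' otherwise the Wilcoxon-Mann-Whitney rank-sum test. Direction is the sign
#' of `mean(group) - mean(rest)`. Fully tied input (zero variance in both
#' arms, equal means) is degenerate: p = 1, direction undefined.
#'
#' @param values Numeric per-sample values.
#' @param in_group Logical per sample: `TRUE` for the entity arm.
#' @param alpha_normality Gate level for the Shapiro-Wilk test.
#' @param var_equal Use the pooled-variance t test instead of Welch.
#' @return List with `p_value`, `direction` (`"up"`, `"down"` or `NA`) and
#'   `test` (`"t"`, `"wilcoxon"` or `"degenerate"`).
#' @export
#' @examples
#' test_gene(c(1, 2, 3, 10, 11, 12), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
test_gene <- function(values, in_group, alpha_normality = 0.05,
                      var_equal = FALSE) {
  stopifnot(length(values) == length(in_group))
  x <- values[in_group]
  y <- values[!in_group]
  if (length(x) < 2 || length(y) < 2) {
    stop("need >= 2 samples in both the group and the rest", call. = FALSE)
  }
  delta <- mean(x) - mean(y)
  if (sd(x) == 0 && sd(y) == 0 && delta == 0) {
    return(list(p_value = 1, direction = NA_character_, test = "degenerate"))
  }
  direction <- if (delta > 0) "up" else if (delta < 0) "down" else NA_character_
  if (arm_is_normal(x, alpha_normality) && arm_is_normal(y, alpha_normality)) {
    p <- t.test(x, y, var.equal = var_equal)$p.value
    list(p_value = p, direction = direction, test = "t")
  } else {
    p <- suppressWarnings(wilcox.test(x, y)$p.value)
    list(p_value = p, direction = direction, test = "wilcoxon")
  }
}

#' Entity-versus-rest differential genes
#'
#' For every entity, each expressed Endogenous gene is tested entity versus
#' all other samples with [test_gene()]; p-values are Benjamini-Hochberg
#' adjusted within each entity.
#'
#' @param counts Normalized counts tibble.
#' @param labels Labels tibble; every entity needs >= 2 samples.
#' @param mask Optional [noise_filter()] output restricting the gene set to
#'   [expressed_genes()].
#' @param alpha Significance level on the adjusted p-value.
#' @param alpha_normality,var_equal Passed to [test_gene()].
#' @return Tibble: `gene`, `entity`, `direction`, `p_value`, `adj_p`,
#'   `significant`.
#' @export
differential_genes <- function(counts, labels, mask = NULL, alpha = 0.05,
                               alpha_normality = 0.05, var_equal = FALSE) {
  assert_counts(counts)
  ent <- aligned_entities(counts, labels)
  if (length(unique(ent)) < 2) stop("need >= 2 entities", call. = FALSE)
  sizes <- table(ent)
  if (any(sizes < 2)) {
    stop("every entity needs >= 2 samples; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  endo <- count_matrix(counts, "Endogenous")
  if (!is.null(mask)) {
    keep <- intersect(rownames(endo), expressed_genes(mask))
    endo <- endo[keep, , drop = FALSE]
  }
  res <- lapply(unique(ent), function(g) {
    in_g <- ent == g
    tests <- apply(endo, 1, test_gene, in_group = in_g,
                   alpha_normality = alpha_normality, var_equal = var_equal)
    tibble::tibble(
      gene = rownames(endo),
      entity = g,
      direction = unname(vapply(tests, `[[`, character(1), "direction")),
      p_value = unname(vapply(tests, `[[`, numeric(1), "p_value"))) |>
      dplyr::mutate(adj_p = p.adjust(.data$p_value, method = "BH"),
                    significant = .data$adj_p <= alpha)
  })
  dplyr::bind_rows(res)
}

#' Significant-gene sets per entity
#'
#' @param de Output of [differential_genes()].
#' @return Named list of character vectors (significant genes per entity).
#' @export
significant_sets <- function(de) {
  sig <- de[de$significant, , drop = FALSE]
  split(sig$gene, sig$entity)
}

#' Pairwise overlap of per-entity gene sets
#'
#' Computes every pairwise intersection with counts and both directional
#' percentages (each set's share of the overlap), as in a Venn summary.
#'
#' @param sets Named list of character vectors.
#' @return Tibble: `set1`, `set2`, `size1`, `size2`, `overlap`,
#'   `pct_of_set1`, `pct_of_set2`.
#' @export
#' @examples
#' overlap_sets(list(A = c("x", "y", "z"), B = c("y", "z", "w")))
overlap_sets <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  nm <- names(sets)
  if (length(nm) < 2) {
    return(tibble::tibble(set1 = character(), set2 = character(),
                          size1 = integer(), size2 = integer(),
                          overlap = integer(), pct_of_set1 = numeric(),
                          pct_of_set2 = numeric()))
  }
  pairs <- utils::combn(nm, 2)
  rows <- apply(pairs, 2, function(p) {
    a <- unique(sets[[p[1]]]); b <- unique(sets[[p[2]]])
    ov <- length(intersect(a, b))
    tibble::tibble(set1 = p[1], set2 = p[2],
                   size1 = length(a), size2 = length(b), overlap = ov,
                   pct_of_set1 = if (length(a)) 100 * ov / length(a) else NA_real_,
                   pct_of_set2 = if (length(b)) 100 * ov / length(b) else NA_real_)
  })
  dplyr::bind_rows(rows)
}
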