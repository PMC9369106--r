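# Three-step data processing: technical (negative-control background)
# normalization, biological (reference-gene) normalization, and the
# basal-noise filter that decides which genes count as expressed.

#' Technical (background) normalization against negative controls
#'
#' For each sample the background is `mean + 2 * SD` of that sample's
#' negative-control counts; it is subtracted from every Endogenous and
#' Housekeeping probe, flooring at zero (negative expression is
#' meaningless and the noise filter assumes non-negative counts). Control
#' probes pass through unchanged.
#'
#' @param counts Counts tibble with at least two Negative probes.
#' @return Counts tibble of the same shape.
#' @export
technical_normalize <- function(counts) {
  assert_counts(counts)
  neg <- counts$probe_class == "Negative"
  if (sum(neg) < 2) {
    stop("technical normalization needs >= 2 Negative probes to compute a SD",
         call. = FALSE)
  }
  target <- counts$probe_class %in% c("Endogenous", "Housekeeping")
  out <- counts
  for (s in sample_ids(counts)) {
    nv <- counts[[s]][neg]
    bg <- mean(nv) + 2 * sd(nv)
    out[[s]][target] <- pmax(0, counts[[s]][target] - bg)
  }
  out
}

#' Biological normalization against reference genes
#'
#' Each sample's Endogenous and Housekeeping counts are rescaled so the
#' per-sample geometric mean of the housekeeping probes equals the
#' cohort-wide geometric mean of those per-sample means (the standard
#' reference-gene scaling for nCounter data). Zeros are guarded by a +1
#' pseudocount applied only inside a geometric mean that contains a zero.
#'
#' @param counts Counts tibble with >= 1 Housekeeping probe; every sample
#'   must have at least one positive housekeeping count.
#' @return Counts tibble of the same shape.
#' @export
biological_normalize <- function(counts) {
  assert_counts(counts)
  hk <- counts$probe_class == "Housekeeping"
  if (sum(hk) < 1) stop("no Housekeeping probes present", call. = FALSE)
  smp <- sample_ids(counts)
  g <- vapply(smp, function(s) {
    v <- counts[[s]][hk]
    if (all(v == 0)) {
      stop("sample '", s, "' has all housekeeping counts zero; cannot normalize",
           call. = FALSE)
    }
    geo_mean(v)
  }, numeric(1))
  target_mean <- exp(mean(log(g)))
  factors <- target_mean / g
  scale_cols <- counts$probe_class %in% c("Endogenous", "Housekeeping")
  out <- counts
  for (i in seq_along(smp)) {
    out[[smp[i]]][scale_cols] <- counts[[smp[i]]][scale_cols] * factors[i]
  }
  attr(out, "scale_factors") <- factors
  out
}

#' Full normalization chain
#'
#' Technical normalization followed by biological normalization, in the
#' order the processing pipeline prescribes.
#'
#' @inheritParams technical_normalize
#' @param skip_biological Skip the reference-gene step.
#' @return Normalized counts tibble.
#' @export
normalize_counts <- function(counts, skip_biological = FALSE) {
  out <- technical_normalize(counts)
  if (!skip_biological) out <- biological_normalize(out)
  out
}

#' Basal-noise filter
#'
#' Decides, per gene and group, whether expression rises above background:
#' a one-sided one-sample t-test of the gene's counts in that group against
#' the group's negative-control threshold (per-sample `mean + 2 * SD` of
#' negative controls, averaged over the group's samples). A gene counts as
#' expressed overall if `p <= alpha` in at least one group. Zero-variance
#' groups use the sign limit of the t statistic: p = 0 above the threshold,
#' 0.5 at it, 1 below it.
#'
#' @param counts Counts tibble (normalized or raw).
#' @param labels Labels tibble (`sample_id`, `entity`); each entity needs
#'   >= 2 samples.
#' @param alpha Significance level of the noise test (default 0.05).
#' @return Tibble with columns `gene`, `entity`, `p_value`, `expressed`
#'   (per gene/group) — summarize with [expressed_genes()].
#' @export
noise_filter <- function(counts, labels, alpha = 0.05) {
  assert_counts(counts)
  ent <- aligned_entities(counts, labels)
  sizes <- table(ent)
  if (any(sizes < 2)) {
    stop("noise filter needs >= 2 samples per group; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  neg <- count_matrix(counts, "Negative")
  if (nrow(neg) < 2) stop("need >= 2 Negative probes", call. = FALSE)
  thr_sample <- apply(neg, 2, function(v) mean(v) + 2 * sd(v))
  endo <- count_matrix(counts, "Endogenous")
  groups <- unique(ent)

  one_sided_p <- function(x, mu) {
    if (sd(x) == 0) {
      m <- mean(x)
      return(if (m > mu) 0 else if (m == mu) 0.5 else 1)
    }
    t.test(x, mu = mu, alternative = "greater")$p.value
  }

  res <- lapply(groups, function(g) {
    in_g <- ent == g
    thr <- mean(thr_sample[in_g])
    p <- unname(apply(endo[, in_g, drop = FALSE], 1, one_sided_p, mu = thr))
    tibble::tibble(gene = rownames(endo), entity = g, p_value = p,
                   expressed = p <= alpha)
  })
  dplyr::bind_rows(res)
}

#' Genes passing the noise filter in at least one group
#'
#' @param mask Output of [noise_filter()].
#' @return Character vector of expressed gene symbols.
#' @export
expressed_genes <- function(mask) {
  sort(unique(mask$gene[mask$expressed]))
}
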