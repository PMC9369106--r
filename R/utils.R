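# Internal helpers shared across modules.

PROBE_CLASSES <- c("Endogenous", "Housekeeping", "Negative", "Positive")

# Column names that carry probe metadata in a counts tibble; every other
# column is a sample.
META_COLS <- c("probe_name", "probe_class")

sample_ids <- function(counts) setdiff(names(counts), META_COLS)

assert_counts <- function(counts, call = sys.call(-1)) {
  if (!is.data.frame(counts) || !all(META_COLS %in% names(counts))) {
    stop("`counts` must be a data frame with columns 'probe_name' and 'probe_class'",
         call. = FALSE)
  }
  bad <- setdiff(unique(counts$probe_class), PROBE_CLASSES)
  if (length(bad) > 0) {
    stop("unknown probe_class token(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  dup <- counts$probe_name[duplicated(counts$probe_name)]
  if (length(dup) > 0) {
    stop("duplicate probe name(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  smp <- sample_ids(counts)
  for (s in smp) {
    v <- counts[[s]]
    if (!is.numeric(v)) stop("sample column '", s, "' is not numeric", call. = FALSE)
    if (anyNA(v) || any(v < 0)) {
      stop("sample column '", s, "' contains negative or missing counts", call. = FALSE)
    }
  }
  invisible(counts)
}

# counts tibble -> numeric matrix (probes x samples), rownames = probe names
count_matrix <- function(counts, class = NULL) {
  x <- counts
  if (!is.null(class)) x <- x[x$probe_class %in% class, , drop = FALSE]
  m <- as.matrix(x[, sample_ids(counts), drop = FALSE])
  rownames(m) <- x$probe_name
  m
}

assert_labels <- function(labels, counts = NULL) {
  if (!is.data.frame(labels) || !all(c("sample_id", "entity") %in% names(labels))) {
    stop("`labels` must be a data frame with columns 'sample_id' and 'entity'",
         call. = FALSE)
  }
  if (!is.null(counts)) {
    smp <- sample_ids(counts)
    if (!setequal(labels$sample_id, smp)) {
      stop("label sample_ids do not match the count matrix samples", call. = FALSE)
    }
  }
  invisible(labels)
}

# entity vector aligned with the sample columns of `counts`
aligned_entities <- function(counts, labels) {
  assert_labels(labels, counts)
  labels$entity[match(sample_ids(counts), labels$sample_id)]
}

# Geometric mean; +1 pseudocount applied only when zeros are present, and
# only inside the mean (see biological_normalize()).
geo_mean <- function(x) {
  if (any(x == 0)) exp(mean(log(x + 1))) else exp(mean(log(x)))
}
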