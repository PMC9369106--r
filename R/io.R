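# RCC and CSV input/output. RCC is the nCounter instrument's per-sample
# format: plain text, comma-separated, organised in <Section>...</Section>
# blocks; the Code_Summary block holds CodeClass,Name,Accession,Count rows.

# Fold instrument CodeClass dialects ("Endogenous1s", "Positive1", ...) onto
# the four canonical classes by prefix.
map_code_class <- function(x) {
  out <- rep(NA_character_, length(x))
  for (cls in PROBE_CLASSES) out[startsWith(x, cls)] <- cls
  if (anyNA(out)) {
    stop("unknown CodeClass token(s): ", paste(unique(x[is.na(out)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Read a single-sample RCC file
#'
#' Parses the Code_Summary section into a one-sample counts tibble. CodeClass
#' dialect variants (e.g. `Endogenous1s`) are folded onto the canonical class
#' by prefix. The sample id is taken from the Sample_Attributes `ID` field,
#' falling back to the Lane_Attributes `ID`, then the file name.
#'
#' @param path Path to an RCC file.
#' @return Counts tibble: `probe_name`, `probe_class`, one sample column.
#' @export
read_rcc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  open <- grep("^<[A-Za-z_]+>$", lines)
  close <- grep("^</[A-Za-z_]+>$", lines)
  sections <- list()
  for (i in seq_along(open)) {
    name <- sub("^<([A-Za-z_]+)>$", "\\1", lines[open[i]])
    end <- close[close > open[i]][1]
    if (is.na(end)) stop("unterminated RCC section <", name, ">", call. = FALSE)
    sections[[name]] <- lines[seq(open[i] + 1L, end - 1L)]
  }
  if (is.null(sections$Code_Summary)) {
    stop("not a valid RCC file (missing Code_Summary section): ", path, call. = FALSE)
  }

  attr_field <- function(section, key) {
    if (is.null(section)) return(NA_character_)
    hit <- grep(paste0("^", key, ","), section, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    val <- sub(paste0("^", key, ","), "", hit[1])
    if (nzchar(val)) val else NA_character_
  }
  sid <- attr_field(sections$Sample_Attributes, "ID")
  if (is.na(sid)) sid <- attr_field(sections$Lane_Attributes, "ID")
  if (is.na(sid)) sid <- sub("\\.[Rr][Cc][Cc]$", "", basename(path))

  body <- sections$Code_Summary
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2 || !startsWith(body[1], "CodeClass")) {
    stop("Code_Summary must start with a CodeClass,Name,Accession,Count header",
         call. = FALSE)
  }
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  bad_len <- which(lengths(rows) != 4L)
  if (length(bad_len) > 0) {
    stop("malformed Code_Summary row ", bad_len[1], call. = FALSE)
  }
  rec <- do.call(rbind, rows)
  cnt <- suppressWarnings(as.numeric(rec[, 4]))
  bad <- which(is.na(cnt) | cnt < 0 | cnt != round(cnt))
  if (length(bad) > 0) {
    stop("negative or non-numeric count in Code_Summary row ", bad[1],
         " (probe ", rec[bad[1], 2], ")", call. = FALSE)
  }
  counts <- tibble::tibble(
    probe_name = rec[, 2],
    probe_class = map_code_class(rec[, 1]),
    !!sid := as.numeric(cnt))
  assert_counts(counts)
}

#' Write a single sample as an RCC file
#'
#' RCC semantically holds raw instrument counts, so only integer counts are
#' accepted; normalized (fractional) matrices must go through
#' [write_counts_csv()] instead.
#'
#' @param counts Counts tibble with exactly one sample column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rcc <- function(counts, path) {
  assert_counts(counts)
  smp <- sample_ids(counts)
  if (length(smp) != 1) stop("RCC holds exactly one sample", call. = FALSE)
  v <- counts[[smp]]
  if (any(v != round(v))) {
    stop("RCC holds raw integer counts; write normalized matrices as CSV",
         call. = FALSE)
  }
  lines <- c(
    "<Header>", "FileVersion,1.7", "SoftwareVersion,4.0.0.3", "</Header>",
    "<Sample_Attributes>", paste0("ID,", smp), "Owner,", "Comments,synthetic",
    "Date,", "GeneRLF,", "SystemAPF,", "</Sample_Attributes>",
    "<Lane_Attributes>", "ID,1", "FovCount,555", "FovCounted,555",
    "ScannerID,", "StagePosition,1", "BindingDensity,", "CartridgeID,",
    "</Lane_Attributes>",
    "<Code_Summary>", "CodeClass,Name,Accession,Count",
    paste(counts$probe_class, counts$probe_name, "NA", format(v, scientific = FALSE, trim = TRUE),
          sep = ","),
    "</Code_Summary>", "<Messages>", "</Messages>")
  writeLines(lines, path)
  invisible(path)
}

# Canonical probe order for CSV output: Endogenous first (alphabetical by
# symbol), controls last, keeping diffs stable across writes.
canonical_order <- function(counts) {
  cls <- factor(counts$probe_class, levels = PROBE_CLASSES)
  counts[order(cls, counts$probe_name), , drop = FALSE]
}

#' Read / write the counts CSV dialect
#'
#' The CSV dialect has columns `probe_name`, `probe_class`, then one numeric
#' column per sample. [write_counts_csv()] writes probes in canonical order
#' (Endogenous alphabetical, controls last); on canonical files read and
#' write are exact inverses.
#'
#' @param path File path.
#' @return [read_counts_csv()]: a counts tibble.
#' @export
read_counts_csv <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    probe_name = readr::col_character(),
    probe_class = readr::col_character(),
    .default = readr::col_double()))
  assert_counts(tibble::as_tibble(x))
}

#' @rdname read_counts_csv
#' @param counts Counts tibble.
#' @export
write_counts_csv <- function(counts, path) {
  assert_counts(counts)
  readr::write_csv(canonical_order(counts), path)
  invisible(path)
}

#' Read / write sample labels
#'
#' Two-column CSV: `sample_id`, `entity`.
#'
#' @param path File path.
#' @return [read_labels_csv()]: tibble with `sample_id`, `entity`.
#' @export
read_labels_csv <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(), entity = readr::col_character()))
  assert_labels(tibble::as_tibble(x))
  x
}

#' @rdname read_labels_csv
#' @param labels Labels tibble.
#' @export
write_labels_csv <- function(labels, path) {
  assert_labels(labels)
  readr::write_csv(labels[, c("sample_id", "entity")], path)
  invisible(path)
}
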