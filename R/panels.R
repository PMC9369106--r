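#' Build an nCounter-style probe panel
#'
#' Constructs a probe table with the four nCounter probe classes. Endogenous
#' probes come first: any `required_genes` in the order given, then
#' deterministic filler symbols (`G0002`, `G0003`, ... numbered by overall
#' endogenous position) so panels are reproducible. Housekeeping, negative
#' and positive control probes follow.
#'
#' @param n_endogenous Number of Endogenous probes (>= `length(required_genes)`).
#' @param n_housekeeping,n_negative,n_positive Numbers of Housekeeping,
#'   Negative and Positive control probes.
#' @param required_genes Gene symbols that must be present (placed first).
#' @return A tibble with columns `probe_name`, `probe_class`.
#' @export
#' @examples
#' build_panel(3, 2, 2, 2, required_genes = "AQP1")
build_panel <- function(n_endogenous, n_housekeeping = 0L, n_negative = 0L,
                        n_positive = 0L, required_genes = character()) {
  if (anyDuplicated(required_genes)) {
    stop("`required_genes` contains duplicates", call. = FALSE)
  }
  if (n_endogenous < length(required_genes)) {
    stop("`n_endogenous` is smaller than the number of required genes", call. = FALSE)
  }
  n_fill <- n_endogenous - length(required_genes)
  filler <- if (n_fill > 0) {
    sprintf("G%04d", seq(length(required_genes) + 1L, n_endogenous))
  } else character()
  endo <- c(required_genes, filler)
  hk  <- if (n_housekeeping > 0) sprintf("HK%02d", seq_len(n_housekeeping)) else character()
  neg <- if (n_negative > 0) sprintf("NEG%02d", seq_len(n_negative)) else character()
  pos <- if (n_positive > 0) sprintf("POS%02d", seq_len(n_positive)) else character()
  panel <- tibble::tibble(
    probe_name = c(endo, hk, neg, pos),
    probe_class = c(rep("Endogenous", length(endo)),
                    rep("Housekeeping", length(hk)),
                    rep("Negative", length(neg)),
                    rep("Positive", length(pos)))
  )
  if (anyDuplicated(panel$probe_name)) {
    dup <- unique(panel$probe_name[duplicated(panel$probe_name)])
    stop("panel probe names collide: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  panel
}

#' The screening CodeSet: two pooled discovery panels
#'
#' The discovery design pools a 770-gene tumor-progression panel and a
#' 594-gene immunology panel (1364 endogenous targets) with 30 reference
#' genes. Marker and decision-tree genes are placed first; remaining targets
#' are deterministic filler symbols.
#'
#' @return A tibble with columns `probe_name`, `probe_class` (1364 Endogenous,
#'   30 Housekeeping, 8 Negative, 6 Positive probes).
#' @export
screening_panel <- function() {
  req <- union(published_panels()$gene, c("PLA2G2A", "RBM47", "IRF4"))
  build_panel(770L + 594L, n_housekeeping = 30L, n_negative = 8L,
              n_positive = 6L, required_genes = sort(req))
}

#' The validation CodeSet configuration
#'
#' The custom validation CodeSet targets the marker genes of the three
#' diagnostic score panels plus five stably expressed reference genes
#' (ACTB, B2M, GAPDH, RPL19, RPLP0). Shipped as a plain-text config in
#' `inst/extdata/validation_codeset.csv`.
#'
#' @return A tibble with columns `gene`, `role` (`"target"` or `"reference"`).
#' @export
validation_codeset <- function() {
  path <- system.file("extdata", "validation_codeset.csv", package = "orbitdx",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    gene = readr::col_character(), role = readr::col_character()))
}

#' The validation CodeSet as a probe panel
#'
#' Target genes become Endogenous probes and the five reference genes become
#' Housekeeping probes; standard negative/positive control sets are added.
#'
#' @return A tibble with columns `probe_name`, `probe_class`.
#' @export
validation_panel <- function() {
  cs <- validation_codeset()
  targets <- cs$gene[cs$role == "target"]
  refs <- cs$gene[cs$role == "reference"]
  panel <- build_panel(length(targets), n_negative = 8L, n_positive = 6L,
                       required_genes = targets)
  hk <- tibble::tibble(probe_name = refs, probe_class = "Housekeeping")
  dplyr::bind_rows(panel[panel$probe_class == "Endogenous", ], hk,
                   panel[panel$probe_class != "Endogenous", ])
}
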