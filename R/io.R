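# Plain-text dialects for every pipeline input/output.

#' Write all synthetic study inputs to a directory
#'
#' Writes the tab/comma-separated dialects the pipeline reads back:
#' `cohorts.tsv` (peptide level), `mouse.tsv`, `cell_panel.tsv`,
#' `secretome_pair1.tsv`/`secretome_pair2.tsv`, `edges.tsv` (scored
#' 3-column edge list), `survival.csv`, and `truth.json`.
#'
#' @param study Output of [simulate_study()].
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_inputs <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(study$plasma$peptides, file.path(dir, "cohorts.tsv"))
  readr::write_tsv(study$mouse$series, file.path(dir, "mouse.tsv"))
  readr::write_tsv(study$panel$panel, file.path(dir, "cell_panel.tsv"))
  readr::write_tsv(study$secretome$pairs[[1]],
                   file.path(dir, "secretome_pair1.tsv"))
  readr::write_tsv(study$secretome$pairs[[2]],
                   file.path(dir, "secretome_pair2.tsv"))
  write_edge_tsv(study$graph, file.path(dir, "edges.tsv"))
  readr::write_csv(study$survival$cohort, file.path(dir, "survival.csv"))
  truth <- study$truth
  jsonlite::write_json(
    truth[c("up_proteins", "down_proteins", "mouse_fast_proteins",
            "panel_undetected", "signature_genes", "seed")],
    file.path(dir, "truth.json"), auto_unbox = FALSE)
  invisible(dir)
}

read_input_file <- function(dir, name, reader) {
  path <- file.path(dir, name)
  if (!file.exists(path)) abort(sprintf("missing input file: %s", path))
  reader(path)
}

#' Read study inputs from a directory
#'
#' Counterpart of [write_study_inputs()]; errors name any missing file.
#'
#' @param dir Directory containing the input files.
#' @return A list with `peptides`, `mouse`, `panel`, `secretome` (list of
#'   two tibbles), `graph_edges`, `survival`.
#' @export
read_study_inputs <- function(dir) {
  tsv <- function(p) readr::read_tsv(p, show_col_types = FALSE,
                                     progress = FALSE)
  list(
    peptides = read_input_file(dir, "cohorts.tsv", tsv),
    mouse = read_input_file(dir, "mouse.tsv", tsv),
    panel = read_input_file(dir, "cell_panel.tsv", tsv),
    secretome = list(
      read_input_file(dir, "secretome_pair1.tsv", tsv),
      read_input_file(dir, "secretome_pair2.tsv", tsv)
    ),
    graph_edges = read_input_file(dir, "edges.tsv", read_edge_file),
    survival = read_input_file(dir, "survival.csv", function(p) {
      readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
    })
  )
}
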