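#' Load a packaged table of printed producer classifications
#'
#' The package ships TSV copies of the published class labels: the
#' 72-isolate preliminary assay (37 degC, 24/48 h), the 10-isolate selected
#' panel at 37 degC, and the selected panel under the temperature, NaCl and
#' pH condition grids. These serve as worked-example inputs for
#' [tally_classes()], [cross_tab()] and as the latent ground truth of
#' [default_study_design()].
#'
#' @param table One of `"preliminary"`, `"selected"`, `"temperature"`,
#'   `"nacl"`, `"ph"`.
#' @return A `data.frame` with columns `isolate_id`, `factor`, `level`,
#'   `timepoint_h`, `class` (ordered factor NP < WP < MP < SP).
#' @export
load_printed_classes <- function(table = c("preliminary", "selected",
                                           "temperature", "nacl", "ph")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0("classes_", table, ".tsv"),
                      package = "biofilmq", mustWork = TRUE)
  dat <- utils::read.delim(path, stringsAsFactors = FALSE)
  dat$class <- producer_factor(dat$class)
  dat
}
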