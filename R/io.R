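#' Read / write trajectory CSV
#'
#' The on-disk trajectory format is a plain CSV with columns
#' `time_s,x_mm,y_mm,hand,block_id,condition` (hand in {L, R}), one file per
#' session or per (session, hand).
#'
#' @param path File path.
#' @return `read_trajectory_csv` returns the session data frame;
#'   `write_trajectory_csv` returns `path` invisibly.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "x_mm", "y_mm", "hand", "block_id", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_invalid_parameter(paste0("trajectory CSV is missing column(s): ",
                                  paste(miss, collapse = ", ")))
  df[need]
}

#' @rdname read_trajectory_csv
#' @param session Session data frame ([generate_session()] layout).
#' @export
write_trajectory_csv <- function(session, path) {
  utils::write.csv(session, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-block metrics as TSV
#'
#' @param metrics Data frame from [block_metrics()].
#' @param path Output file.
#' @export
write_metrics_tsv <- function(metrics, path) {
  write_tsv_fixed(metrics, path)
  invisible(path)
}

# Deterministic TSV writer: numbers rendered with a fixed number of
# significant digits so that identical inputs give byte-identical files.
write_tsv_fixed <- function(df, path, digits = 10) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = digits, format = "g")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
}

#' Shipped normative and patient fixtures
#'
#' Loaders for the small JSON fixtures installed with the package: the
#' printed normative summaries (behavioral OI and per-ROI beta values of the
#' n = 12 healthy controls), the two patients' printed condition scores, and
#' the three region-of-interest fixtures. Values that are printed in the
#' source results but are not reconstructible from the rounded summary
#' inputs are carried verbatim in `annotations` fields for reference, never
#' recomputed against.
#'
#' @return `cl_behavioral_fixture()`: list with `norm`
#'   (a [normative_summary()]), `diff_sd` (control SD of the CL − LL
#'   difference), `frequency` (normative mean/SD), and `cases` (per-patient
#'   LL/CL OI means and drawing frequency). `cl_roi_fixtures()`: named list
#'   of per-ROI fixtures, each with `roi`, `mni`, `norm`, `diff_sd`, `cases`.
#' @examples
#' cl_behavioral_fixture()$norm
#' names(cl_roi_fixtures())
#' @export
cl_behavioral_fixture <- function() {
  raw <- read_fixture("behavioral_fixture.json")
  list(norm = do.call(normative_summary, raw$norm),
       diff_sd = raw$diff_sd,
       frequency = raw$frequency,
       cases = raw$cases,
       annotations = raw$annotations)
}

#' @rdname cl_behavioral_fixture
#' @export
cl_roi_fixtures <- function() {
  raw <- read_fixture("roi_fixtures.json")
  lapply(raw, function(f) {
    f$norm <- do.call(normative_summary, f$norm)
    f$mni <- unlist(f$mni)
    f
  })
}

read_fixture <- function(name) {
  path <- system.file("extdata", name, package = "circleslines")
  if (!nzchar(path))
    stop("fixture ", name, " not found in installed package")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read a study configuration
#'
#' Configurations are YAML (or equivalent R lists) naming the seed, the
#' per-case generator settings and output options for [end_to_end()].
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_study_config <- function(path) {
  yaml::read_yaml(path)
}
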