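#' Read a long-format acylcarnitine time-course table
#'
#' Expects a CSV/TSV with header columns `condition, dox_ng_ml, replicate,
#' compartment, species, time_min, conc_nmol_per_g`. Cells equal to `"ND"`
#' (not determined / below limit of quantification) or left empty become
#' below-LOQ flags; species tokens are parsed as `C2`--`C16`. Malformed rows
#' raise descriptive errors with their row number.
#'
#' @param path File path. Tab-separated files are detected from a `.tsv`
#'   extension.
#' @return A validated `fao_timecourse` data frame.
#' @export
read_timecourse <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.csv(path, sep = sep, colClasses = "character",
                  strip.white = TRUE)
  miss <- setdiff(timecourse_cols, names(raw))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  conc_chr <- raw$conc_nmol_per_g
  nd <- toupper(conc_chr) == "ND" | conc_chr == "" | is.na(conc_chr)
  conc <- suppressWarnings(as.numeric(conc_chr))
  bad <- !nd & is.na(conc)
  if (any(bad))
    stop("non-numeric concentration at row ", which(bad)[1] + 1L,
         " of ", path, ": '", conc_chr[which(bad)[1]], "'", call. = FALSE)
  raw$conc_nmol_per_g <- conc
  raw$below_loq <- nd
  raw$dox_ng_ml <- as.numeric(raw$dox_ng_ml)
  as_timecourse(raw)
}

#' Write a time course in the canonical long CSV format
#'
#' Below-LOQ records are written as `ND`, so
#' `read_timecourse(write_timecourse(x))` round-trips.
#'
#' @param dataset An `fao_timecourse`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(dataset, path) {
  out <- as.data.frame(dataset)[, timecourse_cols]
  out$conc_nmol_per_g <- ifelse(dataset$below_loq, "ND",
                                format(dataset$conc_nmol_per_g, digits = 15,
                                       scientific = FALSE, trim = TRUE))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wide-layout time-course sheet
#'
#' Accepts the supplementary-workbook style layout with one column per time
#' point (`t0, t7, ...` or bare `0, 7, ...` headers, `X0, X7, ...` after R's
#' header mangling) next to `condition, dox_ng_ml, replicate, compartment,
#' species`, and converts it to the canonical long format.
#'
#' @param path CSV file path.
#' @return A validated `fao_timecourse` data frame.
#' @export
read_timecourse_wide <- function(path) {
  raw <- read.csv(path, colClasses = "character", strip.white = TRUE,
                  check.names = TRUE)
  idcols <- setdiff(timecourse_cols, c("time_min", "conc_nmol_per_g"))
  miss <- setdiff(idcols, names(raw))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  tcols <- grep("^[Xt]?_?[0-9]+$", setdiff(names(raw), idcols), value = TRUE)
  if (!length(tcols))
    stop("no time-point columns found in ", path, call. = FALSE)
  times <- as.numeric(sub("^[Xt]?_?", "", tcols))
  long <- do.call(rbind, lapply(seq_along(tcols), function(j) {
    data.frame(raw[idcols], time_min = times[j],
               conc_nmol_per_g = raw[[tcols[j]]],
               stringsAsFactors = FALSE)
  }))
  conc_chr <- long$conc_nmol_per_g
  nd <- toupper(conc_chr) == "ND" | conc_chr == "" | is.na(conc_chr)
  long$conc_nmol_per_g <- suppressWarnings(as.numeric(conc_chr))
  long$below_loq <- nd
  long$dox_ng_ml <- as.numeric(long$dox_ng_ml)
  as_timecourse(long)
}

#' Read a qPCR cycle-threshold table
#'
#' Long CSV with columns `sample, group, gene, ct`; Ct values must lie in
#' (0, 45).
#'
#' @param path CSV file path.
#' @return A data frame of class `fao_ct_table`.
#' @export
read_ct_table <- function(path) {
  d <- read.csv(path, strip.white = TRUE)
  miss <- setdiff(c("sample", "group", "gene", "ct"), names(d))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  d$ct <- as.numeric(d$ct)
  if (any(!is.finite(d$ct) | d$ct <= 0 | d$ct >= 45))
    stop("Ct values must lie in (0, 45)", call. = FALSE)
  class(d) <- c("fao_ct_table", "data.frame")
  d
}

#' Read a run-configuration file
#'
#' Human-readable YAML key-value configuration used by the command-line
#' interface; see [fao_cli()] for the recognised keys.
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

write_results_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
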