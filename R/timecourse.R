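timecourse_cols <- c("condition", "dox_ng_ml", "replicate", "compartment",
                     "species", "time_min", "conc_nmol_per_g")

#' Construct and validate an acylcarnitine time-course dataset
#'
#' The canonical long format: one row per measured concentration, columns
#' `condition`, `dox_ng_ml` (doxycycline dose, ng/mL), `replicate`,
#' `compartment` (`"intracellular"`/`"extracellular"`), `species` (`"C2"` ...
#' `"C16"`, odd chains such as `"C3"` allowed for descriptive use),
#' `time_min` and `conc_nmol_per_g` (nmol/g protein). A logical `below_loq`
#' column flags values under the limit of quantification; those records carry
#' `NA` concentrations and are excluded from likelihoods.
#'
#' @param df A data frame with the columns above (`below_loq` optional).
#' @return The validated data frame with class `fao_timecourse`.
#' @export
as_timecourse <- function(df) {
  stopifnot(is.data.frame(df))
  miss <- setdiff(timecourse_cols, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(df$below_loq)) df$below_loq <- FALSE
  df$species <- toupper(as.character(df$species))
  badsp <- !grepl("^C([2-9]|1[0-6])$", df$species)
  if (any(badsp))
    stop("unknown species token(s) at row(s) ",
         paste(utils::head(which(badsp), 5), collapse = ", "), ": ",
         paste(unique(df$species[badsp]), collapse = ", "), call. = FALSE)
  df$time_min <- as.numeric(df$time_min)
  df$conc_nmol_per_g <- as.numeric(df$conc_nmol_per_g)
  neg <- !df$below_loq & !is.na(df$conc_nmol_per_g) & df$conc_nmol_per_g < 0
  if (any(neg))
    stop("negative concentration at row(s) ",
         paste(utils::head(which(neg), 5), collapse = ", "), call. = FALSE)
  key <- paste(df$condition, df$replicate, df$compartment, df$species,
               df$time_min, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (condition, replicate, compartment, species, time) at row ",
         which(duplicated(key))[1], call. = FALSE)
  class(df) <- c("fao_timecourse", "data.frame")
  df
}

#' Restrict a time course to the records entering the likelihood
#'
#' Keeps intracellular records of the observed species of `spec`, drops
#' below-LOQ records (with a warning, no imputation) and refuses non-positive
#' measurements, whose log10 is undefined.
#'
#' @param dataset An [as_timecourse()] data frame.
#' @param spec A [fao_model_spec()].
#' @param condition Optional single condition id to keep.
#' @return A filtered `fao_timecourse`.
#' @export
fit_records <- function(dataset, spec, condition = NULL) {
  d <- dataset
  if (!is.null(condition)) d <- d[d$condition == condition, , drop = FALSE]
  d <- d[d$compartment == "intracellular" &
           d$species %in% species_label(spec$observed), , drop = FALSE]
  if (any(d$below_loq)) {
    warning(sum(d$below_loq),
            " below-LOQ record(s) excluded from the likelihood")
    d <- d[!d$below_loq, , drop = FALSE]
  }
  bad <- is.na(d$conc_nmol_per_g) | d$conc_nmol_per_g <= 0
  if (any(bad)) {
    i <- which(bad)[1]
    stop("non-positive concentration cannot enter the log-likelihood ",
         "(condition ", d$condition[i], ", replicate ", d$replicate[i],
         ", ", d$species[i], ", t=", d$time_min[i], ")", call. = FALSE)
  }
  d
}
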