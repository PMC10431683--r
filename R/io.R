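#' Read a model configuration file
#'
#' YAML key-value file with optional `phys` and `chem` sections overriding
#' individual parameter defaults; all defaults are embedded, so any subset
#' (or no file at all) is valid.
#'
#' @param path YAML file, or `NULL` for all defaults
#' @return list with elements `phys` ([phys_params()]) and `chem`
#'   ([chem_params()])
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) return(list(phys = phys_params(), chem = chem_params()))
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), c("phys", "chem"))
  if (length(bad))
    stop("unknown config sections: ", paste(bad, collapse = ", "),
         call. = FALSE)
  list(phys = do.call(phys_params, as.list(cfg$phys)),
       chem = do.call(chem_params, as.list(cfg$chem)))
}

#' Write the current parameter configuration
#'
#' @param path output YAML path
#' @param phys,chem parameter sets to record
#' @return `path`, invisibly
#' @export
write_config <- function(path, phys = phys_params(), chem = chem_params()) {
  yaml::write_yaml(list(phys = unclass(phys), chem = unclass(chem)), path)
  invisible(path)
}

#' Write a simulation to CSV
#'
#' Long-format concentration table (`time_h`, `compartment`,
#' `concentration`, `units`, `free_or_total`).
#'
#' @param sim a `ceq_sim` object
#' @param path output CSV path
#' @param compartments traces to include
#' @return `path`, invisibly
#' @export
write_concentration_csv <- function(sim, path,
    compartments = c("plasma", "plasma_free", "liver", "kidney", "lung",
                     "lung_if")) {
  utils::write.csv(as_concentration_table(sim, compartments), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read an observed concentration dataset
#'
#' CSV with columns `study_id`, `time_h`, `compartment`, `concentration`
#' and optionally `lloq` (and any extra columns, which are kept).
#'
#' @param path CSV path
#' @return data.frame
#' @export
read_observed_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "time_h", "compartment", "concentration")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("observed CSV lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out
}
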