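#' Read a quadrat-census CSV
#'
#' Reads and validates the long-format census schema: one row per
#' quadrat and census interval, columns `shore`, `quadrat`, `period`,
#' `T_days`, `N_start`, `N_end`, `operc_area`, `basal_area`,
#' `dead_cover` (header required, UTF-8, `.` decimal). Missing columns
#' raise a schema error naming them; non-numeric cells in numeric
#' columns raise row errors with line numbers.
#'
#' @param path Path to the CSV file.
#' @return A validated data.frame in the census schema.
#' @seealso [write_observations()]
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  need <- c("shore", "quadrat", "period", "T_days", "N_start", "N_end",
            "operc_area", "basal_area", "dead_cover")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("schema error: missing column(s) ", paste(miss, collapse = ", "))
  num_cols <- setdiff(need, c("shore", "quadrat", "period"))
  errs <- character(0)
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(v) & !is.na(raw[[cn]]) & nzchar(raw[[cn]]))
    if (length(bad))
      errs <- c(errs, paste0("column '", cn, "': non-numeric value at line ",
                             paste(bad + 1L, collapse = ", ")))
    raw[[cn]] <- v
  }
  if (length(errs)) stop("row error(s):\n  ", paste(errs, collapse = "\n  "))
  check_observations(raw[need])
}

#' Write a quadrat-census CSV
#'
#' Writes observations in the schema read by [read_observations()], with
#' rows ordered deterministically by shore, quadrat, period and numbers
#' serialised at full precision, so a write/read round trip preserves
#' values.
#'
#' @param observations A census-schema data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path) {
  obs <- check_observations(observations)
  ord <- order(obs$shore, obs$quadrat, obs$period)
  obs <- obs[ord, c("shore", "quadrat", "period", "T_days", "N_start",
                    "N_end", "operc_area", "basal_area", "dead_cover")]
  utils::write.csv(format(obs, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Resolve a run configuration from flags and a config file
#'
#' Merges a named list of command-line flag values over a YAML or JSON
#' configuration file: flags override file values; unknown keys are
#' rejected so typos fail loudly.
#'
#' @param flags Named list of flag values (possibly empty).
#' @param file Optional path to a YAML (`.yml`/`.yaml`) or JSON
#'   (`.json`) file of defaults.
#' @param allowed Character vector of permitted keys.
#' @return Named list: file values overridden by flags.
#' @export
resolve_config <- function(flags = list(), file = NULL, allowed) {
  stopifnot(is.list(flags), is.character(allowed))
  cfg <- list()
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file)
    cfg <- if (grepl("\\.ya?ml$", file, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML config requires the 'yaml' package")
      yaml::read_yaml(file)
    } else if (grepl("\\.json$", file, ignore.case = TRUE)) {
      if (!requireNamespace("jsonlite", quietly = TRUE))
        stop("JSON config requires the 'jsonlite' package")
      jsonlite::read_json(file, simplifyVector = TRUE)
    } else stop("config file must be .yaml/.yml or .json: ", file)
    if (is.null(cfg)) cfg <- list()
  }
  unknown <- setdiff(union(names(cfg), names(flags)), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(flags)] <- flags
  cfg
}
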