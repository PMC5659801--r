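# Readers/writers: long CSV is the canonical trajectory interchange format;
# results round-trip through JSON with provenance (seed, config hash).

.TRAJ_COLS <- c("cell_id", "condition", "observable", "time_min", "value_au")

#' Read a single-cell trajectory table
#'
#' Reads and validates a long-format trajectory CSV with columns `cell_id`,
#' `condition`, `observable`, `time_min`, `value_au`. Wide sheets (one
#' column per observable next to `cell_id`, `condition`, `time_min`) are
#' melted to long format automatically.
#'
#' @param path CSV file path.
#' @return Validated long-format data frame.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(.TRAJ_COLS %in% names(tab))) {
    key <- c("cell_id", "condition", "time_min")
    if (all(key %in% names(tab))) {          # wide layout: melt
      obs_cols <- setdiff(names(tab), key)
      long <- do.call(rbind, lapply(obs_cols, function(o)
        data.frame(tab[key], observable = o, value_au = tab[[o]],
                   stringsAsFactors = FALSE)))
      tab <- long[, .TRAJ_COLS]
    } else {
      stop("trajectory table must contain columns: ",
           paste(.TRAJ_COLS, collapse = ", "))
    }
  }
  validate_trajectories(tab[, .TRAJ_COLS])
}

validate_trajectories <- function(tab) {
  bad_cond <- setdiff(unique(tab$condition), c("epo", "bleach", "chx"))
  if (length(bad_cond) > 0)
    stop("unknown condition(s): ", paste(bad_cond, collapse = ", "))
  for (cond in unique(tab$condition)) {
    bad_obs <- setdiff(unique(tab$observable[tab$condition == cond]),
                       observables(cond))
    if (length(bad_obs) > 0)
      stop("unknown observable name(s) for condition ", cond, ": ",
           paste(bad_obs, collapse = ", "))
  }
  if (!is.numeric(tab$time_min) || any(!is.finite(tab$time_min)))
    stop("non-numeric or non-finite time values")
  if (any(tab$time_min < 0)) stop("times must be nonnegative")
  if (!is.numeric(tab$value_au) || any(!is.finite(tab$value_au)))
    stop("non-numeric or non-finite measurement values (rows ",
         paste(utils::head(which(!is.finite(suppressWarnings(
           as.numeric(tab$value_au)))), 5), collapse = ", "), ")")
  key <- paste(tab$cell_id, tab$observable, tab$time_min)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    stop("duplicate (cell, observable, time) key at row ", dup, ": ",
         key[dup])
  }
  rownames(tab) <- NULL
  tab
}

#' @rdname read_trajectories
#' @param tab Long-format trajectory table (validated before writing).
#' @param path Output CSV path.
#' @export
write_trajectories <- function(tab, path) {
  tab <- validate_trajectories(tab[, .TRAJ_COLS])
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read analysis results with provenance
#'
#' Serializes fit, profile or analysis results to JSON together with a
#' schema version, the RNG seed, a configuration hash and a timestamp.
#' `read_results()` validates the provenance block (a missing seed is an
#' error) and returns the payload.
#'
#' @param obj Serializable result (lists / vectors / data frames).
#' @param path Output JSON path.
#' @param seed The RNG seed the result was produced with.
#' @param config Optional configuration object hashed into the provenance.
#' @return `write_results()` the path, invisibly; `read_results()` a list
#'   with elements `payload` and `provenance`.
#' @export
write_results <- function(obj, path, seed, config = NULL) {
  if (missing(seed) || is.null(seed)) stop("a seed is required for provenance")
  out <- list(
    provenance = list(schema_version = "1.0", package = "epoRtraffic",
                      seed = as.integer(seed),
                      config_hash = config_hash(config),
                      timestamp = format(Sys.time(), tz = "UTC",
                                         "%Y-%m-%dT%H:%M:%SZ")),
    payload = obj)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(out$provenance) || is.null(out$provenance$seed))
    stop("invalid results file: missing provenance seed")
  out
}

# Deterministic 32-bit rolling hash of a configuration object (no external
# digest dependency; ASCII serialization keeps it platform-stable).
config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  raw <- as.integer(serialize(config, NULL, ascii = TRUE))
  h <- 5381
  for (b in raw) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
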