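#' Load an experiment configuration from YAML
#'
#' Unknown keys are rejected by name; missing keys fall back to the
#' documented \code{\link{experimentConfig}} defaults; typed invariants are
#' validated on construction. An empty file yields the full default
#' configuration.
#'
#' @param path Path to a YAML file.
#' @return An \code{\link{experimentConfig}}.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(experimentConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(experimentConfig, vals)
}

#' Write an experiment configuration to YAML
#'
#' Round-trips through \code{\link{loadConfig}}.
#'
#' @param config An \code{\link{experimentConfig}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
saveConfig <- function(config, path) {
  vals <- unclass(config)
  vals$seeds <- as.integer(vals$seeds)
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Serialize result records
#'
#' Writes a records table to CSV or JSON at full precision; reading the
#' file back yields the same fields. Non-response rows keep an explicit
#' missing response angle.
#'
#' @param records A non-empty data frame.
#' @param path Output path.
#' @param format "csv" or "json".
#' @return \code{path}, invisibly.
#' @export
writeResults <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("records must be a non-empty data frame")
  if (format == "csv") {
    utils::write.csv(records, path, row.names = FALSE)
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read back serialized result records
#'
#' @param path File written by \code{\link{writeResults}}.
#' @param format "csv" or "json".
#' @return A data frame.
#' @export
readResults <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") utils::read.csv(path)
  else as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Snapshot network weights to JSON
#'
#' Full-precision JSON serialization of all learned weights, keyed by
#' projection name, plus the critic state.
#'
#' @param network A \code{pbwm_network}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
saveWeights <- function(network, path) {
  keys <- c("Wgo_in", "Wnogo_in", "Wgo_out", "Wnogo_out",
            "Wocc_go_in", "Wocc_nogo_in", "Wocc_go_out", "Wocc_nogo_out",
            "Wrep_in", "Wrep_pfc")
  snap <- lapply(network[keys], function(w) {
    if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
    else list(dim = length(w), data = as.numeric(w))
  })
  snap$v <- network$v
  jsonlite::write_json(snap, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore network weights from a JSON snapshot
#'
#' @param network A \code{pbwm_network} with matching architecture.
#' @param path Snapshot written by \code{\link{saveWeights}}.
#' @return The network with restored weights.
#' @export
loadWeights <- function(network, path) {
  snap <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in setdiff(names(snap), "v")) {
    w <- snap[[key]]
    cur <- network[[key]]
    if (is.matrix(cur)) {
      stopifnot(all(dim(cur) == w$dim))
      network[[key]] <- matrix(w$data, w$dim[1], w$dim[2])
    } else {
      stopifnot(length(cur) == w$dim)
      network[[key]] <- as.numeric(w$data)
    }
  }
  network$v <- snap$v
  network
}
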