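#' Write a trajectory to CSV with a JSON sidecar
#'
#' Writes columns `t,X,Y,Z` at full double precision (17 significant
#' digits, so a round trip is exact to 1e-12 absolute) and a `<path>.json` sidecar
#' recording the full configuration that produced the run, including the
#' divergence flag. Diverged trajectories are written up to the last finite
#' row.
#'
#' @param traj A `stress_trajectory` (or any trajectory tibble with a `t`
#'   column).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(lapply(traj, function(x) formatC(x, digits = 17,
                                                       format = "g")))
  names(df) <- names(traj)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(config = attr(traj, "config"),
                  orders = attr(traj, "orders"),
                  diverged = is_diverged(traj),
                  n_rows = nrow(traj))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a trajectory CSV
#'
#' Validates the header (`t` plus state columns), numeric content and
#' uniform time spacing; parse failures report the offending line. The JSON
#' sidecar, when present, restores the configuration and divergence flag.
#'
#' @param path CSV path written by [write_trajectory()].
#' @param required_cols Columns that must be present.
#' @return A trajectory tibble (class `stress_trajectory` when the state
#'   columns are `X`, `Y`, `Z`).
#' @export
read_trajectory <- function(path, required_cols = c("t", "X", "Y", "Z")) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "stressdyn_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required_cols, names(df))
  if (length(missing_cols)) {
    abort(sprintf("malformed trajectory file %s: missing column(s) %s",
                  path, paste(missing_cols, collapse = ", ")),
          class = "stressdyn_io_error")
  }
  for (cn in required_cols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cn]]))))
    if (length(bad)) {
      abort(sprintf("non-numeric value in column '%s' at line %d of %s",
                    cn, bad[1] + 1, path),
            class = "stressdyn_io_error")
    }
    df[[cn]] <- as.numeric(df[[cn]])
  }
  dt <- diff(df$t)
  if (length(dt) && max(abs(dt - dt[1])) > 1e-9 * max(1, abs(dt[1]))) {
    bad <- which(abs(dt - dt[1]) > 1e-9 * max(1, abs(dt[1])))[1]
    abort(sprintf("non-uniform time grid at line %d of %s", bad + 2, path),
          class = "stressdyn_io_error")
  }
  sidecar_path <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  }
  out <- tibble::as_tibble(df)
  cls <- if (all(c("X", "Y", "Z") %in% names(df))) "stress_trajectory"
  structure(out,
            class = c(cls, "fode_trajectory", class(tibble())),
            config = sidecar$config,
            orders = unlist(sidecar$orders),
            diverged = isTRUE(sidecar$diverged))
}
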