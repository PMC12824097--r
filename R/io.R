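# FNV-1a hash of a canonicalized R object (deparsed after sorting
# names recursively); dependency-free stand-in for a digest
.canonicalize <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x))) x <- x[order(names(x))]
    x <- lapply(x, .canonicalize)
  }
  x
}
.config_hash <- function(x) {
  s <- paste(deparse(.canonicalize(x)), collapse = "")
  bytes <- utf8ToInt(s)
  h <- Reduce(function(a, b) (a * 31 + b) %% 2147483647, bytes, 0)
  sprintf("%08x", as.integer(h))
}

#' Export result tables with run metadata
#'
#' Writes a data frame as CSV (with a `#`-prefixed metadata header:
#' package version, seed, canonical config hash) or as JSON with a
#' metadata block. Re-exporting identical inputs is byte-identical.
#'
#' @param tables a data frame, or named list of data frames (written
#'   as `<out_path>/<name>.<format>`).
#' @param out_path output file (single table) or directory.
#' @param format `"csv"` or `"json"`.
#' @param seed seed recorded in the metadata.
#' @param config configuration list hashed into the metadata.
#' @return Invisibly, the written file path(s).
#' @export
export_results <- function(tables, out_path, format = c("csv", "json"),
                           seed = NULL, config = list()) {
  format <- match.arg(format)
  meta <- list(package = "fluctens",
               version = as.character(utils::packageVersion("fluctens")),
               seed = seed,
               config_hash = .config_hash(config))
  write_one <- function(tab, path) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    if (format == "csv") {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(sprintf("# %s: %s", names(meta),
                         vapply(meta, function(v)
                           if (is.null(v)) "NA" else as.character(v), "")),
                 con)
      utils::write.csv(tab, con, row.names = FALSE)
    } else {
      jsonlite::write_json(list(metadata = meta, data = tab), path,
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    path
  }
  if (is.data.frame(tables)) {
    out <- write_one(tables, out_path)
  } else {
    out <- vapply(names(tables), function(nm) {
      write_one(tables[[nm]], file.path(out_path, paste0(nm, ".", format)))
    }, "")
  }
  invisible(out)
}

#' Read a result CSV written by [export_results()]
#'
#' @param path file path.
#' @return The data frame (metadata lines are skipped).
#' @export
read_results <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write / read a fluctuation movie as plain text
#'
#' Movies are serialized as a CSV of frame-major pixel values plus a
#' JSON sidecar (`<path>.json`) carrying units, pixel size, frame
#' interval, seed and the truth-tension field. Plain-text (rather than
#' TIFF) keeps the round trip dependency-free and diffable.
#'
#' @param movie a [fluctuation_movie()].
#' @param path CSV path.
#' @return `write_movie` invisibly returns `path`; `read_movie`
#'   returns the reconstructed [fluctuation_movie()].
#' @export
write_movie <- function(movie, path) {
  d <- dim(movie$values)
  mat <- matrix(movie$values, nrow = d[1])   # frames x (H*W), column-major
  utils::write.csv(mat, path, row.names = FALSE)
  meta <- list(units = movie$units, dim = d, pixel_size = movie$pixel_size,
               frame_interval = movie$frame_interval, seed = movie$seed,
               truth_tension = movie$truth_tension)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mat <- as.matrix(utils::read.csv(path))
  vals <- array(mat, meta$dim)
  tt <- if (!is.null(meta$truth_tension))
    matrix(unlist(meta$truth_tension), meta$dim[2], meta$dim[3]) else NULL
  fluctuation_movie(vals, units = meta$units, pixel_size = meta$pixel_size,
                    frame_interval = meta$frame_interval,
                    seed = meta$seed, truth_tension = tt)
}

#' Write / read a 1-D curve (scattering profile or correlation curve)
#'
#' Two-column CSV with a one-line header.
#'
#' @param curve a [scattering_profile()] or [correlation_curve()].
#' @param path CSV path.
#' @return `write_curve` invisibly returns `path`; `read_curve`
#'   reconstructs the object (`type` chooses the class).
#' @export
write_curve <- function(curve, path) {
  if (inherits(curve, "scattering_profile")) {
    df <- data.frame(s = curve$s, intensity = curve$intensity)
    if (!is.null(curve$sigma_I)) df$sigma_I <- curve$sigma_I
  } else if (inherits(curve, "correlation_curve")) {
    df <- data.frame(tau = curve$tau, g = curve$g)
  } else stop("write_curve: unsupported object")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @param type `"scattering"` or `"correlation"`.
#' @export
read_curve <- function(path, type = c("scattering", "correlation")) {
  type <- match.arg(type)
  df <- utils::read.csv(path)
  if (type == "scattering")
    scattering_profile(df$s, df$intensity, sigma_I = df$sigma_I)
  else correlation_curve(df$tau, df$g)
}
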