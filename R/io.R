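## ASCII / CSV / JSON input-output.

.parseHeaderKeys <- function(lines) {
  hdr <- grep("^\\s*#", lines, value = TRUE)
  keys <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*[:=]\\s*(.+?)\\s*$", h))[[1]]
    if (length(m) == 3) keys[[m[2]]] <- m[3]
  }
  keys
}

#' Read a scattering curve from an ASCII file
#'
#' Accepts plain two- or three-column ASCII (q, I and optionally sigma),
#' whitespace or comma delimited, with \code{#}-prefixed comment lines.
#' Units default to \eqn{\mathrm{\AA}^{-1}} and \eqn{mm^{-1}}; a header
#' comment of the form \code{# units_q: nm^-1} or \code{# units_I: cm^-1}
#' declares otherwise and triggers conversion. Header keys
#' \code{concentration}, \code{solvent} and \code{label} populate the curve
#' metadata.
#'
#' @param path file path.
#' @return A [ScatterCurve-class].
#' @export
readScatterCurve <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keys <- .parseHeaderKeys(lines)
  data <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(data)) stop("no data rows in ", path)
  fields <- strsplit(trimws(gsub(",", " ", data)), "\\s+")
  ncols <- unique(lengths(fields))
  if (length(ncols) != 1L || !ncols %in% 2:3)
    stop("expected 2 or 3 numeric columns")
  vals <- suppressWarnings(vapply(fields, function(f) as.numeric(f[seq_len(ncols)]),
                                  numeric(ncols)))
  if (any(!is.finite(vals))) stop("non-numeric data rows in ", path)
  vals <- t(vals)
  if (nrow(vals) < 10L) stop("fewer than 10 data points")
  q <- vals[, 1]; I <- vals[, 2]
  sigma <- if (ncols == 3) vals[, 3] else NULL
  uq <- tolower(keys$units_q %||% "a^-1")
  if (grepl("nm", uq)) q <- q * 0.1
  ui <- tolower(keys$units_I %||% "mm^-1")
  if (grepl("cm", ui)) { I <- I * 0.1; if (!is.null(sigma)) sigma <- sigma * 0.1 }
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  meta <- list()
  if (!is.null(keys$concentration))
    meta$concentration <- as.numeric(keys$concentration)
  if (!is.null(keys$solvent)) meta$solvent <- keys$solvent
  if (!is.null(keys$label)) meta$label <- keys$label
  ScatterCurve(q, I, sigma = sigma, meta = meta)
}

#' Write a scattering curve to an ASCII file
#'
#' Counterpart of [readScatterCurve()]: full-precision columns with unit and
#' metadata header comments; round-trips losslessly.
#'
#' @param curve a [ScatterCurve-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeScatterCurve <- function(curve, path) {
  stopifnot(is(curve, "ScatterCurve"))
  hdr <- c("# units_q: A^-1", "# units_I: mm^-1")
  for (k in intersect(names(curve@meta), c("concentration", "solvent", "label")))
    hdr <- c(hdr, sprintf("# %s: %s", k, curve@meta[[k]]))
  cols <- cbind(curve@q, curve@intensity)
  if (length(curve@sigma)) cols <- cbind(cols, curve@sigma)
  body <- apply(cols, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write a DLS trace (two-column ASCII)
#'
#' Lag time (s) and \eqn{g_2} columns with the optical setup in header
#' comments (\code{wavelength}, \code{angle}, \code{refractiveIndex},
#' \code{temperature}, \code{viscosity}).
#'
#' @param path file path.
#' @return [readDlsTrace()]: a [DLSTrace-class]; [writeDlsTrace()]:
#'   \code{path}, invisibly.
#' @export
readDlsTrace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keys <- .parseHeaderKeys(lines)
  data <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(trimws(gsub(",", " ", data)), "\\s+")
  vals <- t(vapply(fields, function(f) as.numeric(f[1:2]), numeric(2)))
  if (any(!is.finite(vals))) stop("non-numeric data rows in ", path)
  num <- function(k, d) if (is.null(keys[[k]])) d else as.numeric(keys[[k]])
  DLSTrace(vals[, 1], vals[, 2],
           wavelength = num("wavelength", 532), angle = num("angle", 90),
           refractiveIndex = num("refractiveIndex", 1.33),
           temperature = num("temperature", 298.15),
           viscosity = num("viscosity", 0.89))
}

#' @rdname readDlsTrace
#' @param trace a [DLSTrace-class].
#' @export
writeDlsTrace <- function(trace, path) {
  stopifnot(is(trace, "DLSTrace"))
  s <- trace@setup
  hdr <- sprintf("# %s: %s", names(s), unlist(s))
  body <- paste(formatC(trace@tau, format = "g", digits = 17),
                formatC(trace@g2, format = "g", digits = 17))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write a deposition table (CSV)
#'
#' Columns \code{location}, \code{mass_ug}, \code{cutoff_um}; the flow rate
#' travels in a \code{# flowRate: <L/min>} comment.
#'
#' @param path file path.
#' @return [readDepositionTable()]: a [DepositionTable-class];
#'   [writeDepositionTable()]: \code{path}, invisibly.
#' @export
readDepositionTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  keys <- .parseHeaderKeys(readLines(path, warn = FALSE))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("location", "mass_ug", "cutoff_um")
  if (!all(need %in% names(df)))
    stop("deposition CSV must have columns: ", paste(need, collapse = ", "))
  DepositionTable(df$location, df$mass_ug, df$cutoff_um,
                  flowRate = as.numeric(keys$flowRate %||% 15))
}

#' @rdname readDepositionTable
#' @param table a [DepositionTable-class].
#' @export
writeDepositionTable <- function(table, path) {
  stopifnot(is(table, "DepositionTable"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# flowRate: %g", table@flowRate), con)
  utils::write.csv(data.frame(location = table@location,
                              mass_ug = table@mass,
                              cutoff_um = table@cutoff),
                   con, row.names = FALSE)
  invisible(path)
}

#' Serialize a ground-truth record to / from JSON
#'
#' @param gt a ground-truth record as attached by the synthetic generators.
#' @param path file path.
#' @return [readGroundTruth()] returns the record; the writer returns
#'   \code{path} invisibly.
#' @export
writeGroundTruth <- function(gt, path) {
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "groundTruth")
}

## recursively convert stage results (S4 / lists) to plain lists for JSON
.asReportList <- function(x) {
  if (isVirtualClass(class(x)) || is.null(x)) return(NULL)
  if (is(x, "ScatterCurve"))
    return(list(type = "ScatterCurve", n = length(x@q),
                qRange = range(x@q), meta = x@meta))
  if (isS4(x)) {
    out <- lapply(stats::setNames(slotNames(class(x)), slotNames(class(x))),
                  function(nm) .asReportList(slot(x, nm)))
    out$type <- class(x)[1]
    return(out)
  }
  if (inherits(x, "groundTruth")) return(unclass(x))
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, .asReportList))
  x
}

#' Write a machine-readable analysis report
#'
#' Writes a JSON report (all stage results, seeds, configuration echo,
#' software version and a config hash) plus per-stage CSV summary tables
#' where a tabular form exists.
#'
#' @param results named list of stage results (fit objects, decomposition
#'   results, aerodynamic results, summary data.frames, ...).
#' @param dir output directory (created if needed).
#' @param config configuration echoed into the report.
#' @param seed seed echoed into the report.
#' @return paths of the files written, invisibly.
#' @export
writeReport <- function(results, dir, config = NULL, seed = NULL) {
  if (!length(results)) stop("empty results")
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  payload <- list(
    software = "nanoscatter",
    version = as.character(utils::packageVersion("nanoscatter")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    configHash = .configHash(config),
    config = config,
    results = .asReportList(results))
  jsonPath <- file.path(dir, "report.json")
  jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, force = TRUE)
  written <- jsonPath
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(x, p, row.names = FALSE)
      written <- c(written, p)
    }
  }
  invisible(written)
}

#' Reload a JSON report
#'
#' @param path path to a \code{report.json} written by [writeReport()].
#' @return the report as a list.
#' @export
readReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

.configHash <- function(config) {
  if (is.null(config)) return(NA_character_)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}
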