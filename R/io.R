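# Delimited-text and binary matrix I/O plus TSV writers for metric maps
# and group results. Text numbers carry 17 significant digits so
# round-trips and determinism checks are meaningful.

#' Write a numeric matrix
#'
#' Text format: one header row with column ids, then tab-separated rows
#' with 17 significant digits. Binary format: a serialized R object
#' (exact round-trip).
#'
#' @param matrix numeric matrix.
#' @param path output file.
#' @param format \code{"text"} or \code{"binary"}.
#' @return the path, invisibly.
#' @export
writeMatrix <- function(matrix, path, format = c("text", "binary")) {
  format <- match.arg(format)
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("'matrix' must be a numeric matrix")
  if (format == "binary") {
    saveRDS(matrix, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(sprintf("c%d", seq_len(ncol(matrix))), collapse = "\t"), con)
    apply(matrix, 1, function(r)
      writeLines(paste(.fmt17(r), collapse = "\t"), con))
  }
  invisible(path)
}

#' Read a numeric matrix written by \code{writeMatrix}
#'
#' @param path input file.
#' @param format \code{"text"} or \code{"binary"}.
#' @return numeric matrix.
#' @export
readMatrix <- function(path, format = c("text", "binary")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "binary") {
    m <- readRDS(path)
    if (!is.matrix(m) || !is.numeric(m)) stop("file does not contain a numeric matrix")
    return(m)
  }
  lines <- readLines(path)
  if (length(lines) < 2L) stop("parse error at line 1: need a header and at least one row")
  nf <- count.fields(path, sep = "\t")
  bad <- which(nf != nf[1])
  if (length(bad))
    stop(sprintf("parse error at line %d: expected %d fields, found %d",
                 bad[1], nf[1], nf[bad[1]]))
  vals <- lapply(seq_along(lines)[-1], function(i) {
    v <- suppressWarnings(as.numeric(strsplit(lines[i], "\t", fixed = TRUE)[[1]]))
    if (anyNA(v)) stop(sprintf("parse error at line %d: non-numeric field", i))
    v
  })
  do.call(rbind, vals)
}

#' Write sensor geometry as TSV
#'
#' Columns: channel, type, x, y, z, ox, oy, oz, ax, ay, az (positions,
#' pickup orientations and gradiometer axes in meters / unit vectors).
#' @param sensorArray a \code{SensorArray}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSensorArray <- function(sensorArray, path) {
  stopifnot(is(sensorArray, "SensorArray"))
  df <- cbind(sensorArray@positions, sensorArray@orientations, sensorArray@axes)
  lines <- c(paste(c("channel", "type", "x", "y", "z", "ox", "oy", "oz",
                     "ax", "ay", "az"), collapse = "\t"),
             vapply(seq_len(nChannels(sensorArray)), function(i)
               paste(c(i, sensorArray@types[i], .fmt17(df[i, ])), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write source geometry as TSV
#'
#' Columns: source, x, y, z, ox, oy, oz, depth (meters / unit vectors).
#' @param sourceSpace a \code{SourceSpace}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSourceSpace <- function(sourceSpace, path) {
  stopifnot(is(sourceSpace, "SourceSpace"))
  df <- cbind(sourceSpace@positions, sourceSpace@orientations, sourceSpace@depth)
  lines <- c(paste(c("source", "x", "y", "z", "ox", "oy", "oz", "depth"),
                   collapse = "\t"),
             vapply(seq_len(nSources(sourceSpace)), function(i)
               paste(c(i, .fmt17(df[i, ])), collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write metric maps as TSV
#'
#' Columns: source_id, x, y, z, depth, mode, method, dle_cm, sd_sqrtcm,
#' oa_norm.
#'
#' @param maps a \code{MetricMaps} or a list of them (rows concatenated).
#' @param sourceSpace the template \code{SourceSpace} (coordinates).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeMetricMaps <- function(maps, sourceSpace, path) {
  stopifnot(is(sourceSpace, "SourceSpace"))
  if (is(maps, "MetricMaps")) maps <- list(maps)
  header <- paste(c("source_id", "x", "y", "z", "depth", "mode", "method",
                    "dle_cm", "sd_sqrtcm", "oa_norm"), collapse = "\t")
  lines <- header
  for (m in maps) {
    n <- length(m@dle)
    if (n != nSources(sourceSpace)) stop("map does not match the source space")
    lines <- c(lines, vapply(seq_len(n), function(i)
      paste(c(i, .fmt17(sourceSpace@positions[i, ]),
              .fmt17(sourceSpace@depth[i]), m@mode, m@method,
              .fmt17(c(m@dle[i], m@sd[i], m@oa[i]))), collapse = "\t"),
      character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a group result as TSV
#'
#' Columns: vertex_id, x, y, z, metric, mode, contrast, mean_diff, sd, t, p.
#'
#' @param groupResult a \code{GroupResult}.
#' @param sourceSpace the template \code{SourceSpace}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeGroupResult <- function(groupResult, sourceSpace, path) {
  stopifnot(is(groupResult, "GroupResult"), is(sourceSpace, "SourceSpace"))
  ct <- groupResult@contrast
  lines <- c(paste(c("vertex_id", "x", "y", "z", "metric", "mode", "contrast",
                     "mean_diff", "sd", "t", "p"), collapse = "\t"),
             vapply(seq_along(groupResult@meanMap), function(i)
               paste(c(i, .fmt17(sourceSpace@positions[i, ]), ct[3], ct[4],
                       paste0(ct[1], "-", ct[2]),
                       .fmt17(c(groupResult@meanMap[i], groupResult@sdMap[i],
                                groupResult@tMap[i], groupResult@pMap[i]))),
                     collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}
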