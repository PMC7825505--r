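#' Point-cloud, trajectory and IMU file I/O
#'
#' Readers and writers for every on-disk artifact the pipeline produces, so
#' each stage can be checkpointed and inspected. Only ASCII dialects are
#' supported: PCD and PLY point clouds, and plain CSV for trajectories and
#' IMU logs. Binary files are rejected with a clear message -- at desk scale,
#' inspectability beats speed.
#'
#' A point cloud is a plain `data.frame` with columns `x`, `y`, `z` (metres,
#' right-handed z-up frame) and optionally `intensity`, `ring` (beam index
#' 0-15), `time_offset` (seconds since sweep start) and `label` (integer
#' ground-truth or cluster label).
#'
#' @name io_formats
NULL

POINT_FIELDS <- c("x", "y", "z", "intensity", "ring", "time_offset", "label")

validate_point_cloud <- function(points) {
  if (!is.data.frame(points)) stop("point cloud must be a data.frame")
  miss <- setdiff(c("x", "y", "z"), names(points))
  if (length(miss)) stop("point cloud lacks required column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(points$x) & is.finite(points$y) & is.finite(points$z)))
    stop("point coordinates must be finite")
  if ("ring" %in% names(points) && length(points$ring) &&
      (min(points$ring) < 0 || max(points$ring) > 15))
    stop("ring index must lie in [0, 15]")
  if ("time_offset" %in% names(points) && length(points$time_offset) &&
      min(points$time_offset) < 0)
    stop("time_offset must be non-negative")
  invisible(points)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pcd", "ply")) ext else stop("cannot guess point-cloud format from extension: ", path)
}

#' Read a point cloud from an ASCII PCD or PLY file
#'
#' @param path file path.
#' @param format `"pcd"`, `"ply"` or `"auto"` (from the file extension).
#' @return `data.frame` with columns `x`, `y`, `z` and any of
#'   `intensity`, `ring`, `time_offset`, `label` present in the file;
#'   unknown fields are dropped.
#' @export
read_point_cloud <- function(path, format = c("auto", "pcd", "ply")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") format <- guess_format(path)
  if (format == "pcd") read_pcd(path) else read_ply(path)
}

read_pcd <- function(path) {
  lines <- readLines(path, n = 64, warn = FALSE)
  hdr <- list()
  data_line <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    tok <- strsplit(ln, "\\s+")[[1]]
    key <- toupper(tok[1])
    hdr[[key]] <- tok[-1]
    if (key == "DATA") { data_line <- i; break }
  }
  if (is.na(data_line)) stop("malformed PCD header in ", path, ": no DATA line found")
  if (tolower(hdr$DATA[1]) != "ascii")
    stop("only ASCII PCD is supported (line ", data_line, ": DATA ", hdr$DATA[1], ")")
  if (is.null(hdr$FIELDS)) stop("malformed PCD header in ", path, ": missing FIELDS line")
  fields <- hdr$FIELDS
  if (!all(c("x", "y", "z") %in% fields))
    stop("PCD schema error in ", path, ": FIELDS must include x, y, z")
  if (is.null(hdr$POINTS)) stop("malformed PCD header in ", path, ": missing POINTS line")
  n <- as.integer(hdr$POINTS[1])
  dt <- data.table::fread(path, skip = data_line, header = FALSE, sep = " ",
                          col.names = fields, showProgress = FALSE)
  if (nrow(dt) != n)
    stop("PCD format error in ", path, ": header declares POINTS ", n,
         " but file contains ", nrow(dt), " data rows")
  out <- as.data.frame(dt)[, intersect(fields, POINT_FIELDS), drop = FALSE]
  if ("ring" %in% names(out)) out$ring <- as.integer(out$ring)
  if ("label" %in% names(out)) out$label <- as.integer(out$label)
  validate_point_cloud(out)
}

read_ply <- function(path) {
  lines <- readLines(path, n = 128, warn = FALSE)
  if (length(lines) == 0 || trimws(lines[1]) != "ply")
    stop("malformed PLY header in ", path, ": first line must be 'ply'")
  props <- character()
  n <- NA_integer_
  end <- NA_integer_
  in_vertex <- FALSE
  for (i in seq(2, length(lines))) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) == 0) next
    if (tok[1] == "format") {
      if (tok[2] != "ascii")
        stop("only ASCII PLY is supported (line ", i, ": format ", tok[2], ")")
    } else if (tok[1] == "element") {
      if (tok[2] == "vertex") { n <- as.integer(tok[3]); in_vertex <- TRUE }
      else {
        if (as.integer(tok[3]) > 0)
          stop("unsupported PLY element '", tok[2], "' with non-zero count (line ", i, ")")
        in_vertex <- FALSE
      }
    } else if (tok[1] == "property" && in_vertex) {
      props <- c(props, tok[length(tok)])
    } else if (tok[1] == "end_header") { end <- i; break }
  }
  if (is.na(end)) stop("malformed PLY header in ", path, ": no end_header")
  if (is.na(n)) stop("malformed PLY header in ", path, ": no vertex element")
  if (!all(c("x", "y", "z") %in% props))
    stop("PLY schema error in ", path, ": vertex needs x, y, z properties")
  dt <- data.table::fread(path, skip = end, header = FALSE, sep = " ",
                          col.names = props, showProgress = FALSE)
  if (nrow(dt) != n)
    stop("PLY format error in ", path, ": header declares ", n,
         " vertices but file contains ", nrow(dt), " data rows")
  out <- as.data.frame(dt)[, intersect(props, POINT_FIELDS), drop = FALSE]
  if ("ring" %in% names(out)) out$ring <- as.integer(out$ring)
  if ("label" %in% names(out)) out$label <- as.integer(out$label)
  validate_point_cloud(out)
}

#' Write a point cloud to an ASCII PCD or PLY file
#'
#' Coordinates are written with enough digits that a write/read round trip
#' preserves them to well below 1e-6 m.
#'
#' @param points point-cloud `data.frame` (see [read_point_cloud()]).
#' @param path output path.
#' @param format `"pcd"`, `"ply"` or `"auto"`.
#' @export
write_point_cloud <- function(points, path, format = c("auto", "pcd", "ply")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  validate_point_cloud(points)
  if (nrow(points) == 0) stop("refusing to write an empty point cloud")
  cols <- intersect(POINT_FIELDS, names(points))
  df <- points[, cols, drop = FALSE]
  num <- vapply(df, function(col) {
    if (is.integer(col)) format(col) else sprintf("%.9g", col)
  }, character(nrow(df)))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(df))
  body <- do.call(paste, c(split(num, col(num)), sep = " "))
  if (format == "pcd") {
    type <- ifelse(vapply(df, is.integer, logical(1)), "I", "F")
    hdr <- c("# .PCD v0.7 - Point Cloud Data file format",
             "VERSION 0.7",
             paste("FIELDS", paste(cols, collapse = " ")),
             paste("SIZE", paste(rep(4, length(cols)), collapse = " ")),
             paste("TYPE", paste(type, collapse = " ")),
             paste("COUNT", paste(rep(1, length(cols)), collapse = " ")),
             paste("WIDTH", nrow(df)),
             "HEIGHT 1",
             "VIEWPOINT 0 0 0 1 0 0 0",
             paste("POINTS", nrow(df)),
             "DATA ascii")
  } else {
    type <- ifelse(vapply(df, is.integer, logical(1)), "int", "double")
    hdr <- c("ply", "format ascii 1.0",
             paste("element vertex", nrow(df)),
             paste("property", type, cols),
             "end_header")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read / write trajectories
#'
#' Trajectories are CSV files with columns
#' `timestamp, tx, ty, tz, qx, qy, qz, qw` (seconds, metres, unit quaternion
#' scalar-last) -- the layout common in SLAM evaluation tooling. Timestamps
#' must be strictly increasing. Quaternions that deviate from unit norm by
#' more than 1e-6 are normalized with a warning; NaN entries are a parse
#' error.
#'
#' @param path CSV file path.
#' @return `data.frame` of class `trajectory`.
#' @export
read_trajectory <- function(path) {
  df <- as.data.frame(data.table::fread(path, showProgress = FALSE))
  need <- c("timestamp", "tx", "ty", "tz", "qx", "qy", "qz", "qw")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trajectory CSV lacks column(s): ", paste(miss, collapse = ", "))
  df <- df[, need]
  if (any(!is.finite(as.matrix(df)))) stop("trajectory parse error: non-finite values in ", path)
  if (nrow(df) > 1 && any(diff(df$timestamp) <= 0))
    stop("trajectory timestamps must be strictly increasing in ", path)
  qn <- sqrt(df$qx^2 + df$qy^2 + df$qz^2 + df$qw^2)
  if (any(abs(qn - 1) > 1e-6)) {
    warning("normalizing ", sum(abs(qn - 1) > 1e-6), " non-unit quaternion(s) in ", path)
  }
  df$qx <- df$qx / qn; df$qy <- df$qy / qn; df$qz <- df$qz / qn; df$qw <- df$qw / qn
  class(df) <- c("trajectory", "data.frame")
  df
}

#' @rdname read_trajectory
#' @param traj trajectory `data.frame` (columns as above).
#' @export
write_trajectory <- function(traj, path) {
  need <- c("timestamp", "tx", "ty", "tz", "qx", "qy", "qz", "qw")
  miss <- setdiff(need, names(traj))
  if (length(miss)) stop("trajectory lacks column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(traj)[, need]
  lines <- c(paste(need, collapse = ","),
             do.call(sprintf, c(list("%.17g,%.17g,%.17g,%.17g,%.17g,%.17g,%.17g,%.17g"),
                                lapply(df, identity))))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write IMU logs
#'
#' IMU logs are CSV files with columns
#' `timestamp, wx, wy, wz, ax, ay, az`: angular velocity (rad/s) and specific
#' force (m/s^2) in the body frame.
#'
#' @param path CSV file path.
#' @export
read_imu <- function(path) {
  df <- as.data.frame(data.table::fread(path, showProgress = FALSE))
  need <- c("timestamp", "wx", "wy", "wz", "ax", "ay", "az")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("IMU CSV lacks column(s): ", paste(miss, collapse = ", "))
  df <- df[, need]
  if (any(!is.finite(as.matrix(df)))) stop("IMU parse error: non-finite values in ", path)
  if (nrow(df) > 1 && any(diff(df$timestamp) <= 0))
    stop("IMU timestamps must be strictly increasing in ", path)
  df
}

#' @rdname read_imu
#' @param imu IMU `data.frame` (columns as above).
#' @export
write_imu <- function(imu, path) {
  need <- c("timestamp", "wx", "wy", "wz", "ax", "ay", "az")
  miss <- setdiff(need, names(imu))
  if (length(miss)) stop("IMU data lacks column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(imu)[, need]
  lines <- c(paste(need, collapse = ","),
             do.call(sprintf, c(list("%.17g,%.17g,%.17g,%.17g,%.17g,%.17g,%.17g"),
                                lapply(df, identity))))
  writeLines(lines, path)
  invisible(path)
}
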