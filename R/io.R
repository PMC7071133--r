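# On-disk formats: trial bundles as a directory (metadata.json,
# skeleton.csv, clouds.csv, ground_truth.json), depth frames as plain
# 16-bit ASCII PGM (P2), point clouds as ASCII PLY, lower-edge series as
# CSV. All formats are plain text and tool-inspectable.

#' Write a trial bundle to a directory
#'
#' @param bundle a `trial_bundle`.
#' @param path target directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_trial_bundle <- function(bundle, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- bundle$metadata
  meta$spec <- bundle$spec[c("obstacle_type", "height", "depth")]
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(bundle$skeleton, file.path(path, "skeleton.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$clouds, file.path(path, "clouds.csv"),
                   row.names = FALSE)
  jsonlite::write_json(bundle$ground_truth, file.path(path, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trial bundle from a directory
#'
#' Validates the layout written by [write_trial_bundle()]: metadata.json
#' must exist; skeleton and cloud rows are re-sorted by time with a warning
#' if they arrive out of order.
#'
#' @param path bundle directory.
#' @return a `trial_bundle` (without the synthetic-only `params` field when
#'   absent on disk).
#' @export
read_trial_bundle <- function(path) {
  meta_file <- file.path(path, "metadata.json")
  if (!file.exists(meta_file))
    stop("not a trial bundle: missing metadata.json in ", path)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  spec <- obstacle_spec(meta$spec$obstacle_type, meta$spec$height,
                        meta$spec$depth)
  meta$spec <- NULL
  skeleton <- utils::read.csv(file.path(path, "skeleton.csv"))
  clouds <- utils::read.csv(file.path(path, "clouds.csv"))
  need_sk <- c("frame", "time", "point", "x", "y", "z")
  if (!all(need_sk %in% names(skeleton)))
    stop("skeleton.csv lacks column(s): ",
         paste(setdiff(need_sk, names(skeleton)), collapse = ", "))
  if (is.unsorted(skeleton$time)) {
    warning("skeleton rows out of time order; re-sorting")
    skeleton <- skeleton[order(skeleton$time, skeleton$point), ]
  }
  if (is.unsorted(clouds$time)) {
    warning("cloud rows out of time order; re-sorting")
    clouds <- clouds[order(clouds$time), ]
  }
  times <- sort(unique(skeleton$time))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("timestamps are not strictly increasing")
  gt_file <- file.path(path, "ground_truth.json")
  gt <- if (file.exists(gt_file))
    jsonlite::read_json(gt_file, simplifyVector = TRUE) else NULL
  structure(list(metadata = meta, spec = spec, times = times,
                 skeleton = skeleton, clouds = clouds, ground_truth = gt),
            class = "trial_bundle")
}

#' Write a depth frame as 16-bit ASCII PGM (P2)
#'
#' @param depth integer matrix (mm), values 0..65535.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(depth, path) {
  stopifnot(all(depth >= 0), all(depth <= 65535))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(depth), nrow(depth)), "65535"), con)
  # one image row per line
  writeLines(apply(depth, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read a 16-bit ASCII PGM (P2) depth frame
#'
#' @param path PGM file.
#' @return integer matrix (rows x cols).
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  if (trimws(lines[1]) != "P2") stop("not an ASCII PGM (P2) file: ", path)
  dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  vals <- as.integer(unlist(strsplit(trimws(lines[-(1:3)]), "\\s+")))
  matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
}

#' Write points as ASCII PLY
#'
#' @param points matrix/data.frame with columns x, y, z (metres).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ply <- function(points, path) {
  pts <- as.matrix(as.data.frame(points)[, c("x", "y", "z")])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(pts)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  utils::write.table(format(pts, trim = TRUE, digits = 9), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ASCII PLY point cloud
#'
#' @param path PLY file.
#' @return matrix with columns x, y, z.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || trimws(lines[1]) != "ply")
    stop("corrupt PLY file (missing magic): ", path)
  if (!grepl("ascii", lines[2]))
    stop("only ASCII PLY is supported: ", path)
  head_end <- which(trimws(lines) == "end_header")
  if (!length(head_end)) stop("corrupt PLY file (no end_header): ", path)
  nv_line <- grep("^element vertex", lines[seq_len(head_end)], value = TRUE)
  nv <- as.integer(sub("element vertex\\s+", "", nv_line[1]))
  body <- lines[(head_end + 1):(head_end + nv)]
  vals <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"),
                                function(v) as.numeric(v[1:3])))
  if (anyNA(vals)) stop("corrupt PLY vertex data in: ", path)
  colnames(vals) <- c("x", "y", "z")
  vals
}

#' Write a lower-edge series as CSV
#'
#' Layout: frame, time, foot, x, z; missing frames appear with NA x/z so
#' they are never silently dropped.
#'
#' @param series a [lower_edge_series()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_edge_csv <- function(series, path) {
  rows <- lapply(seq_along(series$edges), function(f) {
    e <- series$edges[[f]]
    if (is.null(e))
      data.frame(frame = f, time = series$times[f], foot = series$foot,
                 x = NA_real_, z = NA_real_)
    else
      data.frame(frame = f, time = series$times[f], foot = series$foot,
                 x = e$x, z = e$z)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a lower-edge series from CSV
#'
#' A column mapping adapts external layouts: give `columns` as a named
#' vector mapping the canonical names (frame, time, foot, x, z) to the
#' file's column names.
#'
#' @param path CSV file.
#' @param columns named character vector of column mappings.
#' @return named list of [lower_edge_series()], one per foot label found.
#' @export
read_edge_csv <- function(path,
                          columns = c(frame = "frame", time = "time",
                                      foot = "foot", x = "x", z = "z")) {
  raw <- utils::read.csv(path)
  missing_cols <- setdiff(unname(columns), names(raw))
  if (length(missing_cols))
    stop("edge CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  dat <- data.frame(frame = raw[[columns["frame"]]],
                    time = raw[[columns["time"]]],
                    foot = raw[[columns["foot"]]],
                    x = raw[[columns["x"]]], z = raw[[columns["z"]]])
  out <- list()
  for (ft in unique(dat$foot)) {
    sub <- dat[dat$foot == ft, ]
    frames <- sort(unique(sub$frame))
    times <- vapply(frames, function(f) sub$time[sub$frame == f][1], numeric(1))
    edges <- lapply(frames, function(f) {
      e <- sub[sub$frame == f & !is.na(sub$x), c("x", "z")]
      if (!nrow(e)) return(NULL)
      e <- e[order(e$x), ]
      rownames(e) <- NULL
      e
    })
    out[[ft]] <- lower_edge_series(edges, times, ft)
  }
  out
}
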