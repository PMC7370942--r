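# Readers and writers: PLY point clouds (ascii + binary little-endian with
# per-vertex uchar RGB), CSV coordinate tables, PNG frames, YAML/JSON
# configuration.

PLY_FLOAT <- c("float", "float32")
PLY_UCHAR <- c("uchar", "uint8")

#' Write a colored point cloud as PLY
#'
#' @param cloud a [colored_point_cloud()].
#' @param path output file.
#' @param format `"binary"` (binary_little_endian) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path, format = c("binary", "ascii")) {
  stopifnot(inherits(cloud, "colored_point_cloud"))
  format <- match.arg(format)
  n <- nrow(cloud$positions)
  hdr <- c("ply",
           if (format == "binary") "format binary_little_endian 1.0"
           else "format ascii 1.0",
           "comment produced by capreg",
           paste("element vertex", n),
           "property float x", "property float y", "property float z",
           "property uchar red", "property uchar green",
           "property uchar blue",
           "end_header")
  if (format == "ascii") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    tab <- cbind(format(cloud$positions, trim = TRUE, digits = 9),
                 cloud$colors)
    writeLines(apply(tab, 1, paste, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    fl <- writeBin(as.numeric(t(cloud$positions)), raw(), size = 4,
                   endian = "little")
    fm <- matrix(fl, nrow = 12L)                 # 12 bytes xyz per vertex
    cm <- matrix(as.raw(t(cloud$colors)), nrow = 3L)
    writeBin(as.vector(rbind(fm, cm)), con)
  }
  invisible(path)
}

#' Read a colored point cloud from PLY
#'
#' Supports ascii and binary_little_endian PLY with float32 vertex
#' coordinates and uchar red/green/blue per-vertex colors, in any property
#' order (unknown float/uchar properties are skipped).
#'
#' @param path PLY file.
#' @return A [colored_point_cloud()].
#' @export
read_point_cloud <- function(path) {
  if (!file.exists(path))
    stop_capreg("file_not_found", paste("no such file:", path))
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character(0)
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln))
      stop_capreg("parse_error", "PLY header has no end_header line")
    lines <- c(lines, ln)
    if (identical(trimws(ln), "end_header")) break
    if (length(lines) > 200L)
      stop_capreg("parse_error", "PLY header too long (no end_header)")
  }
  if (!identical(trimws(lines[1]), "ply"))
    stop_capreg("parse_error",
                paste0("not a PLY file; first line: '", lines[1], "'"))
  fmt_line <- grep("^\\s*format\\s", lines, value = TRUE)
  if (!length(fmt_line))
    stop_capreg("parse_error", "PLY header missing format line")
  fmt <- strsplit(trimws(fmt_line[1]), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop_capreg("parse_error",
                paste0("unsupported PLY format line: '", fmt_line[1], "'"))

  elt <- grep("^\\s*element\\s", lines)
  vline <- grep("^\\s*element\\s+vertex\\s", lines)
  if (!length(vline))
    stop_capreg("parse_error", "PLY header has no vertex element")
  n <- as.integer(strsplit(trimws(lines[vline[1]]), "\\s+")[[1]][3])
  if (is.na(n) || n < 0)
    stop_capreg("parse_error",
                paste0("bad vertex count line: '", lines[vline[1]], "'"))
  # vertex properties: lines between the vertex element and the next element
  stop_at <- c(elt[elt > vline[1]], grep("end_header", lines))[1]
  pl <- lines[(vline[1] + 1):(stop_at - 1)]
  pl <- pl[grepl("^\\s*property\\s", pl)]
  props <- do.call(rbind, lapply(pl, function(x) {
    f <- strsplit(trimws(x), "\\s+")[[1]]
    if (length(f) != 3L)
      stop_capreg("parse_error", paste0("bad property line: '", x, "'"))
    data.frame(type = f[2], name = f[3], stringsAsFactors = FALSE)
  }))
  need <- c("x", "y", "z", "red", "green", "blue")
  if (!all(c("x", "y", "z") %in% props$name))
    stop_capreg("parse_error", "PLY vertex element lacks x/y/z properties")
  if (!all(c("red", "green", "blue") %in% props$name))
    stop_capreg("missing_color",
                "PLY vertex element lacks red/green/blue properties")

  if (fmt == "ascii") {
    vals <- scan(con, what = numeric(), n = n * nrow(props), quiet = TRUE)
    if (length(vals) < n * nrow(props))
      stop_capreg("parse_error", "PLY ascii body shorter than declared")
    m <- matrix(vals, ncol = nrow(props), byrow = TRUE)
    colnames(m) <- props$name
    return(colored_point_cloud(m[, c("x", "y", "z"), drop = FALSE],
                               m[, c("red", "green", "blue"), drop = FALSE]))
  }

  sizes <- ifelse(props$type %in% PLY_FLOAT, 4L,
                  ifelse(props$type %in% PLY_UCHAR, 1L, NA_integer_))
  if (anyNA(sizes))
    stop_capreg("parse_error",
                paste0("unsupported property type(s): ",
                       paste(unique(props$type[is.na(sizes)]), collapse = ", ")))
  stride <- sum(sizes)
  body <- readBin(con, raw(), n = n * stride)
  if (length(body) < n * stride)
    stop_capreg("parse_error", "PLY binary body shorter than declared")
  bm <- matrix(body, nrow = stride)
  offs <- cumsum(c(0L, sizes))[seq_len(nrow(props))]
  getcol <- function(name) {
    i <- match(name, props$name)
    if (sizes[i] == 4L)
      readBin(as.vector(bm[offs[i] + 1:4, , drop = FALSE]), "numeric",
              size = 4L, n = n, endian = "little")
    else as.integer(bm[offs[i] + 1L, ])
  }
  pos <- cbind(getcol("x"), getcol("y"), getcol("z"))
  cols <- cbind(getcol("red"), getcol("green"), getcol("blue"))
  colored_point_cloud(pos, cols)
}

#' Read/write labeled fiducial CSV (label,x,y,z)
#'
#' @param path CSV file.
#' @return [fiducial_set()] for the reader; `path` invisibly for the writer.
#' @export
read_fiducials_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, c("x", "y", "z")])
  rownames(m) <- tab$label
  fiducial_set(m)
}

#' @rdname read_fiducials_csv
#' @param fiducials a [fiducial_set()].
#' @export
write_fiducials_csv <- function(fiducials, path) {
  tab <- data.frame(label = rownames(fiducials),
                    x = fiducials[, 1], y = fiducials[, 2],
                    z = fiducials[, 3], row.names = NULL)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a model-cap table
#'
#' CSV schema `kind,id,x,y,z` with `kind` in fiducial / source / detector /
#' channel; fiducial rows carry the nine labels, all other kinds are
#' treated as probe positions to interpolate.
#'
#' @param path CSV file.
#' @return [register_model_cap()] object for the reader.
#' @export
read_model_cap_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  fid <- tab[tab$kind == "fiducial", ]
  pr <- tab[tab$kind != "fiducial", ]
  fm <- as.matrix(fid[, c("x", "y", "z")])
  rownames(fm) <- fid$id
  pm <- as.matrix(pr[, c("x", "y", "z")])
  rownames(pm) <- pr$id
  register_model_cap(fiducial_set(fm), pm)
}

#' @rdname read_model_cap_csv
#' @param model a `model_cap`; probes are written with kind `"channel"`.
#' @export
write_model_cap_csv <- function(model, path) {
  stopifnot(inherits(model, "model_cap"))
  tab <- rbind(
    data.frame(kind = "fiducial", id = rownames(model$fiducials),
               x = model$fiducials[, 1], y = model$fiducials[, 2],
               z = model$fiducials[, 3], row.names = NULL),
    data.frame(kind = "channel", id = rownames(model$probes),
               x = model$probes[, 1], y = model$probes[, 2],
               z = model$probes[, 3], row.names = NULL))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write per-channel position CSV (channel,x,y,z)
#'
#' The shared schema for video-derived output and digitizer exports.
#'
#' @param path CSV file.
#' @param method,session_id stored in the returned measurement.
#' @return [session_measurement()] for the reader.
#' @export
read_channels_csv <- function(path, method = "video",
                              session_id = basename(path)) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, c("x", "y", "z")])
  rownames(m) <- tab$channel
  session_measurement(m, method = method, session_id = session_id)
}

#' @rdname read_channels_csv
#' @param measurement a [session_measurement()].
#' @export
write_channels_csv <- function(measurement, path) {
  stopifnot(inherits(measurement, "session_measurement"))
  p <- measurement$channel_positions
  tab <- data.frame(channel = rownames(p), x = p[, 1], y = p[, 2],
                    z = p[, 3], row.names = NULL)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a frame as PNG
#'
#' @param path PNG file.
#' @param frame_index,timestamp_s metadata for the returned frame.
#' @return [capreg_frame()] for the reader.
#' @export
read_frame_png <- function(path, frame_index = 1L, timestamp_s = 0) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3L))
  capreg_frame(a[, , 1:3, drop = FALSE] * 255, frame_index, timestamp_s)
}

#' @rdname read_frame_png
#' @param frame a [capreg_frame()].
#' @export
write_frame_png <- function(frame, path) {
  stopifnot(inherits(frame, "capreg_frame"))
  png::writePNG(frame$pixels / 255, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run; values can come from a
#' YAML or JSON file via [read_pipeline_config()], with the same defaults.
#'
#' @param ply_path path to the subject point cloud (PLY); may be `NA` when
#'   a cloud object is passed to [run_pipeline()] directly.
#' @param model_cap_path path to the model-cap CSV.
#' @param reference_mni_path path to the reference MNI fiducial CSV
#'   (default: the table shipped with the package).
#' @param sticker_hue,hue_tol sticker hue and tolerance (fractions of the
#'   hue circle); `link_radius_mm`, `min_cluster_size` cluster parameters;
#'   `reject_threshold` frame-rejection blackened fraction.
#' @param seed integer seed (logged and used for any sampling).
#' @param output_dir where intermediate artifacts go (`NA` = don't write).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(ply_path = NA_character_,
                            model_cap_path = NA_character_,
                            reference_mni_path =
                              system.file("extdata",
                                          "reference_mni_fiducials.csv",
                                          package = "capreg"),
                            sticker_hue = 1 / 3, hue_tol = 0.15,
                            link_radius_mm = 10, min_cluster_size = 5L,
                            reject_threshold = 0.98, seed = 0L,
                            output_dir = NA_character_) {
  if (hue_tol <= 0 || hue_tol >= 0.5)
    stop_capreg("invalid_parameter", "`hue_tol` must lie in (0, 0.5)")
  if (sticker_hue < 0 || sticker_hue >= 1)
    stop_capreg("invalid_parameter", "`sticker_hue` must lie in [0, 1)")
  if (link_radius_mm <= 0)
    stop_capreg("invalid_parameter", "`link_radius_mm` must be > 0")
  if (min_cluster_size < 1)
    stop_capreg("invalid_parameter", "`min_cluster_size` must be >= 1")
  if (reject_threshold <= 0 || reject_threshold > 1)
    stop_capreg("invalid_parameter", "`reject_threshold` must lie in (0, 1]")
  structure(list(ply_path = ply_path, model_cap_path = model_cap_path,
                 reference_mni_path = reference_mni_path,
                 sticker_hue = sticker_hue, hue_tol = hue_tol,
                 link_radius_mm = link_radius_mm,
                 min_cluster_size = as.integer(min_cluster_size),
                 reject_threshold = reject_threshold,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML (`.yml`/`.yaml`) or JSON configuration file; keys match
#'   the arguments of [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop_capreg("file_not_found", paste("no such config file:", path))
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, vals[intersect(names(vals),
                                          names(formals(pipeline_config)))])
}

# short stable hash of a config for log lines (FNV-1a over its deparse)
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = ""))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}
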