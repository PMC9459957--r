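# Readers and writers for the on-disk formats: flat TXT point clouds,
# raw profile CSV, calibration JSON and scan-archive folders. Angles in
# files are degrees, lengths centimeters; every writer emits a
# format-version header comment.

LABEL_CODES <- c(stem = 0L, leaf = 1L, pot = 2L, other = 3L)

label_to_code <- function(lab) {
  code <- LABEL_CODES[lab]
  code[is.na(code)] <- LABEL_CODES["other"]
  unname(code)
}

code_to_label <- function(code) {
  names(LABEL_CODES)[match(code, LABEL_CODES)]
}

#' Write / read a point cloud as flat TXT
#'
#' Whitespace-delimited numeric columns `x y z [intensity] [label]` (label
#' encoded 0 = stem, 1 = leaf, 2 = pot, 3 = other), `#` comment header,
#' six decimal places (round trips are lossless at 1e-6). Optional columns
#' absent from the file stay absent from the cloud.
#'
#' @param cloud a [point_cloud()].
#' @param path file path.
#' @return `write_cloud_txt()`: the path, invisibly. `read_cloud_txt()`: a
#'   [point_cloud()].
#' @export
write_cloud_txt <- function(cloud, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cols <- c("x y z",
            if (!is.null(cloud$intensity)) "intensity",
            if (!is.null(cloud$label)) "label")
  writeLines(c("# phenoscan cloud v1; lengths cm",
               paste("# columns:", paste(cols, collapse = " "))), con)
  m <- cloud$points
  if (!is.null(cloud$intensity)) m <- cbind(m, cloud$intensity)
  txt <- apply(m, 1, function(r) paste(sprintf("%.6f", r), collapse = " "))
  if (!is.null(cloud$label))
    txt <- paste(txt, label_to_code(cloud$label))
  writeLines(txt, con)
  invisible(path)
}

#' @rdname write_cloud_txt
#' @export
read_cloud_txt <- function(path) {
  lines <- readLines(path)
  # the writer records the column layout; honour it when present
  col_hdr <- grep("^\\s*#\\s*columns:", lines, value = TRUE)
  hdr_names <- if (length(col_hdr))
    strsplit(trimws(sub("^\\s*#\\s*columns:", "", col_hdr[1])), "\\s+")[[1]]
  body_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(body_idx) == 0)
    return(point_cloud(matrix(numeric(0), ncol = 3)))
  toks <- strsplit(trimws(lines[body_idx]), "\\s+")
  ncols <- unique(lengths(toks))
  if (length(ncols) != 1) {
    bad <- body_idx[which(lengths(toks) != lengths(toks)[1])[1]]
    stop(sprintf("inconsistent column count at line %d of %s", bad, path))
  }
  if (ncols < 3)
    stop(sprintf("expected at least 3 columns (x y z) in %s, got %d",
                 path, ncols))
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals)) {
    bad_row <- which(vapply(toks, function(t)
      anyNA(suppressWarnings(as.numeric(t))), TRUE))[1]
    stop(sprintf("non-numeric value at line %d of %s", body_idx[bad_row],
                 path))
  }
  m <- matrix(vals, ncol = ncols, byrow = TRUE)
  cols <- if (!is.null(hdr_names) && length(hdr_names) == ncols) hdr_names
          else c("x", "y", "z", if (ncols >= 4) "intensity",
                 if (ncols >= 5) "label")
  colnames(m) <- cols
  point_cloud(m[, c("x", "y", "z"), drop = FALSE],
              intensity = if ("intensity" %in% cols) m[, "intensity"],
              label = if ("label" %in% cols)
                code_to_label(as.integer(m[, "label"])))
}

#' Write / read raw profiles as CSV
#'
#' One row per valid return, columns `disc_angle_deg, beam_angle_deg,
#' distance_cm, intensity` (header line mandatory; `#` comments allowed).
#'
#' @param profiles a [profile()] or list of profiles.
#' @param path file path.
#' @return `write_profiles_csv()`: the path, invisibly.
#'   `read_profiles_csv()`: a list of [profile()] objects, one per distinct
#'   disc angle, in file order.
#' @export
write_profiles_csv <- function(profiles, path) {
  if (inherits(profiles, "lidar_profile")) profiles <- list(profiles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# phenoscan raw profiles v1; angles deg, lengths cm", con)
  writeLines("disc_angle_deg,beam_angle_deg,distance_cm,intensity", con)
  for (p in profiles) {
    if (nrow(p) == 0) next
    intens <- if (!is.null(p$intensity)) p$intensity else rep(1, nrow(p))
    writeLines(sprintf("%.4f,%.6f,%.6f,%.6f", attr(p, "disc_angle_deg"),
                       p$beam_angle_deg, p$distance_cm, intens), con)
  }
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", comment.char = "#")
  need <- c("disc_angle_deg", "beam_angle_deg", "distance_cm")
  if (!all(need %in% names(df)))
    stop("profile CSV needs columns ", paste(need, collapse = ", "))
  angs <- unique(df$disc_angle_deg)
  lapply(angs, function(a) {
    sub <- df[df$disc_angle_deg == a, ]
    sub <- sub[order(sub$beam_angle_deg), ]
    profile(sub$beam_angle_deg, sub$distance_cm,
            intensity = if ("intensity" %in% names(sub)) sub$intensity,
            disc_angle_deg = a)
  })
}

#' Write / read platform calibration JSON
#'
#' Fields `d_cm`, `h_cm`, `tilt_deg`, `created`, `target_fit_rms_cm`.
#'
#' @param calib a [platform_calibration()].
#' @param path file path.
#' @return `write_calibration_json()`: the path, invisibly.
#'   `read_calibration_json()`: a [platform_calibration()].
#' @export
write_calibration_json <- function(calib, path) {
  stopifnot(inherits(calib, "platform_calibration"))
  jsonlite::write_json(
    list(format = "phenoscan calibration v1",
         d_cm = calib$d_cm, h_cm = calib$h_cm, tilt_deg = calib$tilt_deg,
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         target_fit_rms_cm = if (is.finite(calib$target_fit_rms_cm))
           calib$target_fit_rms_cm),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path)
  need <- c("d_cm", "h_cm", "tilt_deg")
  if (!all(need %in% names(j)))
    stop("calibration JSON needs fields ", paste(need, collapse = ", "))
  platform_calibration(j$d_cm, j$h_cm, j$tilt_deg,
                       target_fit_rms_cm =
                         if (!is.null(j$target_fit_rms_cm))
                           as.numeric(j$target_fit_rms_cm) else NA_real_)
}

#' Open a scan-archive folder
#'
#' Discovers the files of one scanned plant in a database folder laid out as
#' `<campaign>/<plant>_<day>/`: a raw point cloud, a processed point cloud
#' (with stem/leaf labels), optional calibration and metadata JSON; images
#' are tolerated and ignored. File roles are recognised by name (`raw`,
#' `proc`/`processed`/`label`) and, failing that, by column count.
#'
#' @param folder path to the plant folder.
#' @return A list of class `scan_archive` with elements `raw`, `processed`
#'   (point clouds or `NULL`), `calibration`, `metadata` and `folder`.
#' @export
open_osf_scan <- function(folder) {
  if (!dir.exists(folder)) stop("no such folder: ", folder)
  files <- list.files(folder, full.names = TRUE)
  txts <- files[grepl("\\.(txt|xyz|csv)$", files, ignore.case = TRUE)]
  jsons <- files[grepl("\\.json$", files, ignore.case = TRUE)]
  if (length(txts) == 0)
    stop("unrecognized layout in ", folder,
         ": expected a raw and/or processed point cloud (.txt), optional ",
         "calibration/metadata .json and images; found: ",
         if (length(files)) paste(basename(files), collapse = ", ")
         else "nothing")
  is_raw <- grepl("raw", basename(txts), ignore.case = TRUE)
  is_proc <- grepl("proc|label", basename(txts), ignore.case = TRUE)
  raw_path <- txts[is_raw][1]
  proc_path <- txts[is_proc][1]
  if (is.na(raw_path) && is.na(proc_path)) {
    # fall back on column count: 5 columns means labels (processed)
    ncols <- vapply(txts, function(f) {
      l <- readLines(f, n = 20)
      l <- l[!grepl("^\\s*#", l) & nzchar(trimws(l))]
      if (length(l) == 0) 0L else length(strsplit(trimws(l[1]), "\\s+")[[1]])
    }, 1L)
    proc_path <- txts[ncols >= 5][1]
    raw_path <- setdiff(txts, proc_path)[1]
  }
  meta_path <- jsons[grepl("meta", basename(jsons), ignore.case = TRUE)][1]
  calib_path <- jsons[grepl("calib", basename(jsons), ignore.case = TRUE)][1]
  meta <- if (!is.na(meta_path)) jsonlite::read_json(meta_path) else {
    nm <- strsplit(basename(normalizePath(folder, mustWork = FALSE)), "_")[[1]]
    list(plant = nm[1], day = if (length(nm) > 1) nm[2] else NA)
  }
  structure(list(
    raw = if (!is.na(raw_path)) read_cloud_txt(raw_path),
    processed = if (!is.na(proc_path)) read_cloud_txt(proc_path),
    calibration = if (!is.na(calib_path)) read_calibration_json(calib_path),
    metadata = meta,
    folder = folder), class = "scan_archive")
}
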