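#' Marker trajectory set
#'
#' Labelled skin-marker positions over capture frames, in mm, lab frame
#' (right-handed, Z-up). Missing samples are carried as a validity mask,
#' never as silent zeros.
#'
#' @param labels character vector of marker names (unique).
#' @param positions numeric array frames x markers x 3 (mm).
#' @param rate capture frequency in Hz (> 0).
#' @param valid_mask logical frames x markers matrix; default: TRUE where
#'   all three coordinates are finite.
#' @return Object of class \code{marker_trajectory_set}.
#' @export
marker_trajectory_set <- function(labels, positions, rate,
                                  valid_mask = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate marker labels", call. = FALSE)
  positions <- as.array(positions)
  if (length(dim(positions)) != 3L || dim(positions)[3] != 3L ||
      dim(positions)[2] != length(labels)) {
    stop("positions must be a frames x markers x 3 array", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) ||
      rate <= 0) {
    stop("rate must be a positive scalar (Hz)", call. = FALSE)
  }
  if (is.null(valid_mask)) {
    valid_mask <- apply(is.finite(positions), c(1, 2), all)
    dim(valid_mask) <- dim(positions)[1:2]
  }
  valid_mask <- matrix(as.logical(valid_mask), dim(positions)[1],
                       dim(positions)[2])
  if (any(!is.finite(positions[rep(valid_mask, 3)]))) {
    stop("positions must be finite wherever valid_mask is TRUE",
         call. = FALSE)
  }
  structure(list(labels = labels, positions = positions, rate = rate,
                 valid_mask = valid_mask),
            class = "marker_trajectory_set")
}

#' @export
print.marker_trajectory_set <- function(x, ...) {
  cat(sprintf("Marker trajectories: %d markers x %d frames @ %g Hz (%d gaps)\n",
              length(x$labels), dim(x$positions)[1], x$rate,
              sum(!x$valid_mask)))
  invisible(x)
}

n_frames <- function(m) dim(m$positions)[1]

# Per-frame matrix of marker positions (markers x 3), NA where invalid.
frame_points <- function(m, i) {
  p <- m$positions[i, , , drop = TRUE]
  p <- matrix(p, length(m$labels), 3)
  p[!m$valid_mask[i, ], ] <- NA_real_
  rownames(p) <- m$labels
  p
}

#' Read marker trajectories
#'
#' Two dialects are supported. \code{"tsv"} is the house dialect: a
#' tab-separated table whose header row is
#' \code{Frame Time <label>_X <label>_Y <label>_Z ...}, positions in mm;
#' empty cells or NaN mark gaps. \code{"trc"} is the standard TRC motion
#' capture interchange format; its declared units ("m" or "mm") are
#' honoured and positions are always returned in mm. No gap filling is
#' performed at read time.
#'
#' @param path file path.
#' @param dialect \code{"tsv"} or \code{"trc"}.
#' @return A \code{\link{marker_trajectory_set}}.
#' @export
read_markers <- function(path, dialect = c("tsv", "trc")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(dialect, tsv = read_markers_tsv(path), trc = read_markers_trc(path))
}

read_markers_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "numeric",
                          na.strings = c("", "NA", "NaN"))
  nm <- names(df)
  if (length(nm) < 5L || nm[1] != "Frame" || nm[2] != "Time") {
    stop("TSV dialect requires header 'Frame\tTime\t<label>_X ...'",
         call. = FALSE)
  }
  tcol <- df$Time
  if (any(diff(tcol) <= 0)) {
    stop("non-monotone time column", call. = FALSE)
  }
  coord <- nm[-(1:2)]
  if (anyDuplicated(coord)) stop("duplicate labels", call. = FALSE)
  ok <- grepl("_[XYZ]$", coord)
  if (!all(ok)) stop("marker columns must end in _X/_Y/_Z", call. = FALSE)
  labels <- unique(sub("_[XYZ]$", "", coord))
  nfr <- nrow(df)
  pos <- array(NA_real_, c(nfr, length(labels), 3))
  for (j in seq_along(labels)) {
    for (k in 1:3) {
      cn <- paste0(labels[j], "_", c("X", "Y", "Z")[k])
      if (!cn %in% coord) stop("missing column ", cn, call. = FALSE)
      pos[, j, k] <- df[[cn]]
    }
  }
  rate <- 1 / stats::median(diff(tcol))
  marker_trajectory_set(labels, pos, rate)
}

read_markers_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5L) stop("not a TRC file (too short)", call. = FALSE)
  hdrk <- strsplit(lines[2], "\t")[[1]]
  hdrv <- strsplit(lines[3], "\t")[[1]]
  meta <- stats::setNames(as.list(hdrv), hdrk)
  rate <- as.numeric(meta[["DataRate"]])
  units <- meta[["Units"]]
  if (is.null(units) || !units %in% c("mm", "m")) {
    stop("TRC Units must be 'mm' or 'm'", call. = FALSE)
  }
  scale <- if (identical(units, "m")) 1000 else 1
  labrow <- strsplit(lines[4], "\t")[[1]]
  labels <- labrow[labrow != "" & !labrow %in% c("Frame#", "Time")]
  if (anyDuplicated(labels)) stop("duplicate labels in TRC", call. = FALSE)
  body <- lines[-(1:5)]
  body <- body[nzchar(trimws(body))]
  rows <- lapply(strsplit(body, "\t"), function(x) {
    suppressWarnings(as.numeric(x))
  })
  ncol_exp <- 2 + 3 * length(labels)
  m <- t(vapply(rows, function(r) {
    length(r) <- ncol_exp
    r
  }, numeric(ncol_exp)))
  if (any(diff(m[, 2]) <= 0)) stop("non-monotone time column", call. = FALSE)
  pos <- array(NA_real_, c(nrow(m), length(labels), 3))
  for (j in seq_along(labels)) {
    pos[, j, ] <- m[, 2 + (3 * (j - 1) + 1):(3 * j), drop = FALSE] * scale
  }
  marker_trajectory_set(labels, pos, rate)
}

#' Write marker trajectories
#'
#' Writes the house TSV dialect or a TRC file (see
#' \code{\link{read_markers}}). TRC output always declares mm.
#'
#' @param markers a \code{\link{marker_trajectory_set}}.
#' @param path output path.
#' @param dialect \code{"tsv"} or \code{"trc"}.
#' @export
write_markers <- function(markers, path, dialect = c("tsv", "trc")) {
  dialect <- match.arg(dialect)
  nfr <- n_frames(markers)
  tcol <- (seq_len(nfr) - 1) / markers$rate
  pos <- markers$positions
  pos[rep(!markers$valid_mask, 3)] <- NA_real_
  if (dialect == "tsv") {
    cols <- list(Frame = seq_len(nfr), Time = tcol)
    for (j in seq_along(markers$labels)) {
      for (k in 1:3) {
        cols[[paste0(markers$labels[j], "_", c("X", "Y", "Z")[k])]] <-
          pos[, j, k]
      }
    }
    df <- as.data.frame(cols, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE, na = "")
  } else {
    nm <- length(markers$labels)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      paste("PathFileType", "4", "(X/Y/Z)", basename(path), sep = "\t"),
      paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
            "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames",
            sep = "\t"),
      paste(markers$rate, markers$rate, nfr, nm, "mm", markers$rate, 1, nfr,
            sep = "\t"),
      paste(c("Frame#", "Time",
              as.vector(rbind(markers$labels, "", ""))), collapse = "\t"),
      paste(c("", "", paste0(rep(c("X", "Y", "Z"), nm),
                             rep(seq_len(nm), each = 3))), collapse = "\t")
    ), con)
    for (i in seq_len(nfr)) {
      v <- as.vector(t(matrix(pos[i, , ], nm, 3)))
      writeLines(paste(c(i, format(tcol[i], digits = 15),
                         ifelse(is.na(v), "", format(v, digits = 15))),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Bone surface model with landmarks and cortical regions of interest
#'
#' A triangle mesh in the imaging frame (mm) together with named bone
#' landmarks (the point set transformed into the lab frame each frame),
#' named surface (skin) landmarks at the neutral position, and named
#' vertex-index subsets marking cortical regions of interest such as the
#' lateral cortex of the ischial tuberosity.
#'
#' @param vertices V x 3 numeric matrix (mm).
#' @param faces F x 3 integer matrix of 1-based vertex indices.
#' @param bone_landmarks named list or N x 3 matrix with rownames.
#' @param surface_landmarks named list or N x 3 matrix with rownames.
#' @param rois named list of integer vectors (1-based vertex indices).
#' @return Object of class \code{bone_model}.
#' @export
bone_model <- function(vertices, faces, bone_landmarks = NULL,
                       surface_landmarks = NULL, rois = list()) {
  vertices <- as_points3(vertices, "vertices")
  faces <- as.matrix(faces)
  if (ncol(faces) != 3L) stop("faces must be F x 3", call. = FALSE)
  storage.mode(faces) <- "integer"
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  bone_landmarks <- as_landmarks(bone_landmarks)
  surface_landmarks <- as_landmarks(surface_landmarks)
  if (length(intersect(rownames(bone_landmarks),
                       rownames(surface_landmarks)))) {
    stop("bone and surface landmark names must be disjoint", call. = FALSE)
  }
  if (!is.list(rois)) stop("rois must be a named list", call. = FALSE)
  for (nm in names(rois)) {
    idx <- as.integer(rois[[nm]])
    if (length(idx) == 0L) stop("ROI '", nm, "' is empty", call. = FALSE)
    if (min(idx) < 1L || max(idx) > nrow(vertices)) {
      stop("ROI '", nm, "' has out-of-range vertex indices", call. = FALSE)
    }
    rois[[nm]] <- idx
  }
  structure(list(vertices = vertices, faces = faces,
                 bone_landmarks = bone_landmarks,
                 surface_landmarks = surface_landmarks, rois = rois),
            class = "bone_model")
}

as_landmarks <- function(x) {
  if (is.null(x)) {
    return(matrix(numeric(0), 0, 3, dimnames = list(character(0), NULL)))
  }
  if (is.list(x) && !is.data.frame(x)) {
    x <- do.call(rbind, lapply(x, as.numeric))
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L || is.null(rownames(x)) || anyDuplicated(rownames(x))) {
    stop("landmarks must be uniquely named 3-vectors", call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

#' @export
print.bone_model <- function(x, ...) {
  cat(sprintf(
    "Bone model: %d vertices, %d faces, %d bone / %d surface landmarks, %d ROIs\n",
    nrow(x$vertices), nrow(x$faces), nrow(x$bone_landmarks),
    nrow(x$surface_landmarks), length(x$rois)))
  invisible(x)
}

#' Read a bone model from mesh + landmark + ROI files
#'
#' The mesh may be ASCII STL or ASCII PLY (mm). The landmark file is JSON
#' with objects \code{bone} and \code{surface}, each mapping landmark
#' names to [x, y, z] mm triples. The ROI file is JSON mapping ROI names
#' to arrays of 1-based vertex indices.
#'
#' @param mesh_path STL or PLY path (format chosen by extension, or
#'   autodetected).
#' @param landmarks_path optional landmark JSON path.
#' @param roi_path optional ROI JSON path.
#' @return A validated \code{\link{bone_model}}.
#' @export
read_bone_model <- function(mesh_path, landmarks_path = NULL,
                            roi_path = NULL) {
  mesh <- read_mesh(mesh_path)
  bl <- sl <- NULL
  if (!is.null(landmarks_path)) {
    lm <- jsonlite::read_json(landmarks_path, simplifyVector = TRUE)
    if (!is.null(lm$bone)) bl <- lm_matrix(lm$bone)
    if (!is.null(lm$surface)) sl <- lm_matrix(lm$surface)
  }
  rois <- list()
  if (!is.null(roi_path)) {
    rois <- jsonlite::read_json(roi_path, simplifyVector = TRUE)
    rois <- lapply(rois, as.integer)
  }
  bone_model(mesh$vertices, mesh$faces, bl, sl, rois)
}

lm_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  m <- do.call(rbind, lapply(x, as.numeric))
  rownames(m) <- names(x)
  m
}

#' Write landmark / ROI JSON files
#'
#' Companion writers for the JSON schemas consumed by
#' \code{\link{read_bone_model}}.
#'
#' @param bone,surface named landmark matrices (rows = names).
#' @param rois named list of 1-based vertex index vectors.
#' @param path output path.
#' @export
write_landmarks <- function(bone, surface, path) {
  obj <- list(
    bone = stats::setNames(lapply(seq_len(nrow(bone)),
                                  function(i) unname(bone[i, ])),
                           rownames(bone)),
    surface = stats::setNames(lapply(seq_len(nrow(surface)),
                                     function(i) unname(surface[i, ])),
                              rownames(surface)))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
write_rois <- function(rois, path) {
  jsonlite::write_json(rois, path, digits = NA)
  invisible(path)
}

# --- mesh I/O (ASCII STL / ASCII PLY) -------------------------------------

read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1, warn = FALSE)
  if (grepl("^ply", first)) read_ply(path) else read_stl(path)
}

read_stl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^\\s*solid", lines[1])) {
    stop("only ASCII STL is supported", call. = FALSE)
  }
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) %% 3 != 0) stop("malformed STL: vertex count not a multiple of 3",
                                 call. = FALSE)
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x) {
    as.numeric(x[2:4])
  }))
  # weld duplicate corners so faces share vertices
  key <- apply(round(v, 9), 1, paste, collapse = ",")
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  vertices <- v[uk, , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  list(vertices = vertices, faces = faces)
}

write_stl <- function(vertices, faces, path, name = "mesh") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  for (i in seq_len(nrow(faces))) {
    tri <- vertices[faces[i, ], , drop = FALSE]
    nrm <- cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    nn <- sqrt(sum(nrm^2))
    if (nn > 0) nrm <- nrm / nn
    writeLines(c(
      sprintf("  facet normal %.9g %.9g %.9g", nrm[1], nrm[2], nrm[3]),
      "    outer loop",
      sprintf("      vertex %.12g %.12g %.12g", tri[, 1], tri[, 2], tri[, 3]),
      "    endloop",
      "  endfacet"), con)
  }
  writeLines(paste("endsolid", name), con)
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("malformed PLY: no end_header", call. = FALSE)
  hdr <- lines[1:end]
  if (!any(grepl("^format ascii", hdr))) {
    stop("only ASCII PLY is supported", call. = FALSE)
  }
  nv <- as.integer(sub("element vertex\\s+", "",
                       grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face\\s+", "",
                       grep("^element face", hdr, value = TRUE)))
  body <- lines[(end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vert <- do.call(rbind, lapply(strsplit(trimws(body[1:nv]), "\\s+"),
                                function(x) as.numeric(x[1:3])))
  faces <- do.call(rbind, lapply(strsplit(trimws(body[nv + (1:nf)]), "\\s+"),
                                 function(x) {
    x <- as.integer(x)
    if (x[1] != 3L) stop("only triangle faces are supported", call. = FALSE)
    x[2:4] + 1L
  }))
  list(vertices = vert, faces = faces)
}

write_ply <- function(vertices, faces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(vertices)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.12g %.12g %.12g",
                     vertices[, 1], vertices[, 2], vertices[, 3]), con)
  writeLines(paste(3, faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L), con)
  invisible(path)
}

#' Write a bone model's mesh to STL or PLY
#'
#' @param model a \code{\link{bone_model}}.
#' @param path output path ending in .stl or .ply.
#' @export
write_mesh <- function(model, path) {
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    write_ply(model$vertices, model$faces, path)
  } else {
    write_stl(model$vertices, model$faces, path)
  }
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# --- GRF and curve CSV ----------------------------------------------------

#' Ground-reaction-force record
#'
#' @param force numeric vector (vertical component, N) or F x 3 matrix.
#' @param rate sampling rate in Hz.
#' @return Object of class \code{grf_record} with elements \code{force}
#'   (matrix, last column = vertical) and \code{rate}.
#' @export
grf_record <- function(force, rate) {
  if (is.null(dim(force))) force <- matrix(as.numeric(force), ncol = 1)
  force <- as.matrix(force)
  if (any(!is.finite(force))) stop("GRF values must be finite", call. = FALSE)
  if (!is.numeric(rate) || rate <= 0) stop("rate must be > 0", call. = FALSE)
  structure(list(force = force, rate = rate), class = "grf_record")
}

vertical_force <- function(grf) grf$force[, ncol(grf$force)]

#' Read / write ground reaction forces (CSV)
#'
#' CSV with a header row; a \code{time} column in seconds and one or three
#' force columns in N (the last force column is treated as vertical). The
#' sampling rate is recovered from the time column.
#'
#' @param path CSV path.
#' @return \code{read_grf}: a \code{\link{grf_record}}.
#' @export
read_grf <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) {
    stop("empty or missing GRF file: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path)
  if (nrow(df) == 0L) stop("GRF file has no data rows", call. = FALSE)
  if (!"time" %in% names(df)) stop("GRF CSV must have a 'time' column",
                                   call. = FALSE)
  fcols <- setdiff(names(df), "time")
  if (!length(fcols)) stop("GRF CSV has no force columns", call. = FALSE)
  fm <- as.matrix(df[fcols])
  if (!is.numeric(fm) || any(!is.finite(fm))) {
    stop("non-numeric cell in GRF file", call. = FALSE)
  }
  rate <- 1 / stats::median(diff(df$time))
  grf_record(fm, rate)
}

#' @rdname read_grf
#' @param grf a \code{\link{grf_record}}.
#' @export
write_grf <- function(grf, path) {
  df <- data.frame(time = (seq_len(nrow(grf$force)) - 1) / grf$rate)
  fn <- if (ncol(grf$force) == 3) c("fx", "fy", "fz") else "fz"
  df[fn] <- grf$force
  utils::write.csv(format(df, digits = 15), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read / write a gait-normalized curve (CSV)
#'
#' Two-column CSV \code{percent,value_mm}: values at equally spaced
#' percentages of the gait cycle.
#'
#' @param curve numeric vector of node values (mm), or a
#'   \code{normalized_curve}.
#' @param path CSV path.
#' @export
write_curve <- function(curve, path) {
  if (inherits(curve, "normalized_curve")) curve <- curve$values
  pct <- seq(0, 100, length.out = length(curve))
  df <- data.frame(percent = pct, value_mm = as.numeric(curve))
  utils::write.csv(format(df, digits = 17), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @return \code{read_curve}: a numeric vector with attribute
#'   \code{percent}.
#' @export
read_curve <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) {
    stop("empty or missing curve file: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path)
  if (!all(c("percent", "value_mm") %in% names(df))) {
    stop("curve CSV must have columns percent,value_mm", call. = FALSE)
  }
  structure(as.numeric(df$value_mm), percent = as.numeric(df$percent))
}

#' Read / write a subjects-by-nodes curve matrix (CSV)
#'
#' Rows are subjects, columns the gait-cycle nodes (default 101). Used as
#' input to the SPM/SnPM comparisons.
#'
#' @param m numeric matrix, subjects x nodes.
#' @param path CSV path.
#' @export
write_curve_matrix <- function(m, path) {
  colnames(m) <- paste0("p", seq(0, 100, length.out = ncol(m)))
  utils::write.csv(format(as.data.frame(m), digits = 17), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_matrix
#' @export
read_curve_matrix <- function(path) {
  as.matrix(utils::read.csv(path))
}
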