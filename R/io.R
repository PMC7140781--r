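x_attr <- function(node, name, required = TRUE) {
  v <- xml2::xml_attr(node, name)
  if (required && (is.na(v) || !nzchar(v))) {
    abort(sprintf("missing mandatory attribute `%s` on <%s>.",
                  name, xml2::xml_name(node)),
          class = "skelgaze_schema_error")
  }
  v
}

#' Read an experiment description file
#'
#' Parses the XML experiment dialect (elements
#' `experiment/source/interval/mapping` with an optional per-source
#' skeleton payload; the DTDs ship under `inst/extdata/`). Skeleton
#' payloads reference sidecar files relative to the XML location: a
#' keyframe CSV for 2D skeletons, a motion text file for 3D sequences.
#'
#' @param path Path to the experiment XML file.
#' @return A list with `sources` (tibble, one row per media source, see
#'   [media_source()]) and `skeletons` (named list of `skel_skeleton2d` /
#'   `skel_motion3d`, keyed by source name).
#' @export
read_experiment_xml <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "experiment") {
    abort("root element must be <experiment>.", class = "skelgaze_schema_error")
  }
  base <- dirname(path)
  sources <- list()
  skeletons <- list()
  for (node in xml2::xml_find_all(doc, "./source")) {
    name <- x_attr(node, "name")
    duration <- as.numeric(x_attr(node, "duration"))
    fmt <- xml2::xml_attr(node, "format")
    if (is.na(fmt)) fmt <- "none"
    ivs <- xml2::xml_find_all(node, "./interval")
    intervals <- NULL
    if (length(ivs)) {
      intervals <- tibble(
        start_ms = as.numeric(vapply(ivs, x_attr, "", "start")),
        end_ms = as.numeric(vapply(ivs, x_attr, "", "end"))
      )
    }
    map_node <- xml2::xml_find_first(node, "./mapping")
    reference <- if (inherits(map_node, "xml_missing")) NA_character_ else
      x_attr(map_node, "reference")
    sources[[name]] <- media_source(name, duration, intervals, reference, fmt)
    if (fmt == "skeleton2d") {
      sk <- xml2::xml_find_first(node, "./skeleton2d")
      if (inherits(sk, "xml_missing")) {
        abort(sprintf("source `%s` declares format skeleton2d but has no <skeleton2d>.", name),
              class = "skelgaze_schema_error")
      }
      fps <- as.numeric(x_attr(sk, "fps"))
      kf_file <- x_attr(sk, "keyframes")
      jn <- xml2::xml_find_all(sk, "./joint")
      joints <- tibble(
        name = vapply(jn, x_attr, "", "name"),
        parent = vapply(jn, function(n) {
          p <- xml2::xml_attr(n, "parent")
          if (is.na(p) || !nzchar(p)) NA_character_ else p
        }, "")
      )
      bn <- xml2::xml_find_all(sk, "./bone")
      bones <- tibble(
        joint_a = vapply(bn, x_attr, "", "a"),
        joint_b = vapply(bn, x_attr, "", "b"),
        width_px = as.numeric(vapply(bn, x_attr, "", "width")),
        depth_level = as.integer(as.numeric(vapply(bn, x_attr, "", "depth")))
      )
      keyframes <- read_keyframes_csv(file.path(base, kf_file))
      skeletons[[name]] <- skeleton2d(joints, bones, keyframes, fps)
    } else if (fmt == "motion3d") {
      mo <- xml2::xml_find_first(node, "./motion3d")
      if (inherits(mo, "xml_missing")) {
        abort(sprintf("source `%s` declares format motion3d but has no <motion3d>.", name),
              class = "skelgaze_schema_error")
      }
      skeletons[[name]] <- read_motion_text(file.path(base, x_attr(mo, "file")))
    }
  }
  sources <- dplyr::bind_rows(sources)
  validate_sources(sources)
  list(sources = sources, skeletons = skeletons)
}

#' Write an experiment description file
#'
#' Inverse of [read_experiment_xml()]; skeleton sidecar files are written
#' next to the XML (named `<source>_keyframes.csv` / `<source>_motion.txt`).
#'
#' @param sources Media-source tibble ([media_source()] rows).
#' @param skeletons Named list of skeleton payloads keyed by source name.
#' @param path Output XML path.
#' @return `path`, invisibly.
#' @export
write_experiment_xml <- function(sources, skeletons = list(), path) {
  validate_sources(sources)
  base <- dirname(path)
  doc <- xml2::xml_new_root("experiment")
  for (k in seq_len(nrow(sources))) {
    row <- sources[k, ]
    node <- xml2::xml_add_child(doc, "source", name = row$name,
                                duration = format(row$duration_ms, scientific = FALSE, digits = 15),
                                format = row$format)
    iv <- row$intervals[[1]]
    implicit <- nrow(iv) == 1 && iv$start_ms[1] == 0 && iv$end_ms[1] == row$duration_ms
    if (!implicit) {
      for (r in seq_len(nrow(iv))) {
        xml2::xml_add_child(node, "interval",
                            start = format(iv$start_ms[r], scientific = FALSE, digits = 15),
                            end = format(iv$end_ms[r], scientific = FALSE, digits = 15))
      }
    }
    if (!is.na(row$reference)) {
      xml2::xml_add_child(node, "mapping", reference = row$reference)
    }
    sk <- skeletons[[row$name]]
    if (row$format == "skeleton2d") {
      if (is.null(sk)) abort(sprintf("no skeleton payload for source `%s`.", row$name),
                             class = "skelgaze_schema_error")
      kf_file <- paste0(row$name, "_keyframes.csv")
      sk_node <- xml2::xml_add_child(node, "skeleton2d",
                                     fps = format(sk$fps), keyframes = kf_file)
      for (r in seq_len(nrow(sk$joints))) {
        xml2::xml_add_child(sk_node, "joint", name = sk$joints$name[r],
                            parent = ifelse(is.na(sk$joints$parent[r]), "",
                                            sk$joints$parent[r]))
      }
      for (r in seq_len(nrow(sk$bones))) {
        xml2::xml_add_child(sk_node, "bone",
                            a = sk$bones$joint_a[r], b = sk$bones$joint_b[r],
                            width = format(sk$bones$width_px[r]),
                            depth = format(sk$bones$depth_level[r]))
      }
      write_keyframes_csv(sk$keyframes, file.path(base, kf_file))
    } else if (row$format == "motion3d") {
      if (is.null(sk)) abort(sprintf("no motion payload for source `%s`.", row$name),
                             class = "skelgaze_schema_error")
      mo_file <- paste0(row$name, "_motion.txt")
      xml2::xml_add_child(node, "motion3d", file = mo_file)
      write_motion_text(sk, file.path(base, mo_file))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read per-viewer gaze captures
#'
#' Parses the viewer XML dialect (`viewer/capture/sample`). Joint labels
#' are normalized through the nomenclature table; unknown labels are kept
#' verbatim with a warning, empty labels mean gaze off the character.
#'
#' @param path Path to a viewer XML file.
#' @param quiet Suppress unknown-joint warnings.
#' @return A tibble with one row per sample: `viewer`, `media`,
#'   `order_index`, `t`, `x`, `y`, `joint`.
#' @export
read_viewer_xml <- function(path, quiet = FALSE) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "viewer") {
    abort("root element must be <viewer>.", class = "skelgaze_schema_error")
  }
  viewer_id <- x_attr(doc, "id")
  out <- list()
  for (cap in xml2::xml_find_all(doc, "./capture")) {
    media <- x_attr(cap, "media")
    ord <- as.integer(as.numeric(x_attr(cap, "order")))
    if (is.na(ord) || ord < 1L) {
      abort("capture order index must be >= 1.",
            class = "skelgaze_validation_error")
    }
    sm <- xml2::xml_find_all(cap, "./sample")
    df <- tibble(
      viewer = viewer_id, media = media, order_index = ord,
      t = as.numeric(vapply(sm, x_attr, "", "t")),
      x = as.numeric(vapply(sm, x_attr, "", "x")),
      y = as.numeric(vapply(sm, x_attr, "", "y")),
      joint = vapply(sm, function(n) {
        j <- xml2::xml_attr(n, "joint")
        if (is.na(j)) "" else j
      }, "")
    )
    n_decl <- xml2::xml_attr(cap, "n")
    if (!is.na(n_decl) && as.integer(n_decl) != nrow(df)) {
      abort(sprintf("capture (%s, %s) declares %s samples but contains %d.",
                    viewer_id, media, n_decl, nrow(df)),
            class = "skelgaze_validation_error")
    }
    validate_samples(df[, c("t", "x", "y", "joint")])
    df$joint <- normalize_joint_labels(df$joint, quiet = quiet)
    out[[length(out) + 1L]] <- df
  }
  dplyr::bind_rows(out)
}

#' Write per-viewer gaze captures
#'
#' @param captures Tibble as returned by [read_viewer_xml()] (single
#'   viewer).
#' @param path Output XML path.
#' @return `path`, invisibly.
#' @export
write_viewer_xml <- function(captures, path) {
  captures <- as_tibble(captures)
  ids <- unique(captures$viewer)
  if (length(ids) != 1L) {
    abort("write_viewer_xml writes one viewer per file.",
          class = "skelgaze_validation_error")
  }
  doc <- xml2::xml_new_root("viewer", id = ids)
  groups <- dplyr::group_split(captures, media, order_index)
  for (g in groups) {
    cap <- xml2::xml_add_child(doc, "capture", media = g$media[1],
                               order = format(g$order_index[1]),
                               n = format(nrow(g)))
    for (r in seq_len(nrow(g))) {
      xml2::xml_add_child(cap, "sample",
                          t = format(g$t[r], scientific = FALSE),
                          x = format(g$x[r], scientific = FALSE, digits = 15),
                          y = format(g$y[r], scientific = FALSE, digits = 15),
                          joint = g$joint[r])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read / write a 2D keyframe table
#'
#' Plain CSV with columns `frame`, `joint`, `x`, `y` holding the manually
#' annotated joint positions at keyframed video frames.
#'
#' @param path CSV path.
#' @return Tibble of keyframes.
#' @export
read_keyframes_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          frame = readr::col_integer(),
                          joint = readr::col_character(),
                          x = readr::col_double(),
                          y = readr::col_double()))
  as_tibble(df)
}

#' @rdname read_keyframes_csv
#' @param keyframes Tibble with columns `frame`, `joint`, `x`, `y`.
#' @export
write_keyframes_csv <- function(keyframes, path) {
  readr::write_csv(keyframes[, c("frame", "joint", "x", "y")], path)
  invisible(path)
}

#' Read / write 3D motion text
#'
#' BVH-style plain-text motion format: a header naming the frame rate and
#' the joint order, then one line per frame with the root translation
#' followed by four quaternion components (`w x y z`) per joint.
#'
#' @param path Motion text path.
#' @return A `skel_motion3d`.
#' @export
read_motion_text <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  hdr_fps <- grep("^fps ", lines, value = TRUE)
  hdr_joints <- grep("^joints ", lines, value = TRUE)
  if (!length(hdr_fps) || !length(hdr_joints)) {
    abort("motion text needs `fps` and `joints` header lines.",
          class = "skelgaze_schema_error")
  }
  fps <- as.numeric(sub("^fps ", "", hdr_fps[1]))
  joint_names <- strsplit(sub("^joints ", "", hdr_joints[1]), "\\s+")[[1]]
  data_lines <- lines[!grepl("^(fps|joints) ", lines)]
  vals <- lapply(data_lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  n <- length(joint_names)
  width <- 3 + 4 * n
  if (any(vapply(vals, length, 1L) != width)) {
    abort("motion text frame lines have the wrong number of values.",
          class = "skelgaze_schema_error")
  }
  m <- do.call(rbind, vals)
  root <- m[, 1:3, drop = FALSE]
  rot <- array(NA_real_, dim = c(nrow(m), n, 4))
  for (j in seq_len(n)) {
    rot[, j, ] <- m[, 3 + (j - 1) * 4 + 1:4, drop = FALSE]
  }
  motion3d(joint_names, rot, root, fps)
}

#' @rdname read_motion_text
#' @param motion A `skel_motion3d`.
#' @export
write_motion_text <- function(motion, path) {
  stopifnot(inherits(motion, "skel_motion3d"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("fps", format(motion$fps)),
               paste("joints", paste(motion$joint_names, collapse = " "))), con)
  for (f in seq_len(motion$n_frames)) {
    row <- c(motion$root[f, ], as.vector(t(motion$rotations[f, , ])))
    writeLines(paste(format(row, digits = 17, trim = TRUE), collapse = " "), con)
  }
  invisible(path)
}

#' Read / write a mesh as OBJ plus a JSON weight sidecar
#'
#' Only `v` and `f` records of the OBJ format are used (triangular faces).
#' Skinning weights travel in a JSON sidecar mapping each vertex to its
#' joint weights.
#'
#' @param obj_path OBJ file path.
#' @param weights_path JSON sidecar path (defaults to the OBJ path with a
#'   `.weights.json` extension).
#' @return A `skel_mesh`.
#' @export
read_mesh_obj <- function(obj_path, weights_path = NULL) {
  weights_path <- weights_path %||% sub("\\.obj$", ".weights.json", obj_path)
  lines <- readLines(obj_path)
  v_lines <- grep("^v ", lines, value = TRUE)
  f_lines <- grep("^f ", lines, value = TRUE)
  vertices <- do.call(rbind, lapply(v_lines, function(l)
    as.numeric(strsplit(trimws(sub("^v ", "", l)), "\\s+")[[1]][1:3])))
  faces <- do.call(rbind, lapply(f_lines, function(l) {
    toks <- strsplit(trimws(sub("^f ", "", l)), "\\s+")[[1]]
    as.integer(sub("/.*$", "", toks))[1:3]
  }))
  wj <- jsonlite::read_json(weights_path, simplifyVector = TRUE)
  weights <- as_tibble(wj)
  weights$vertex <- as.integer(weights$vertex)
  skinned_mesh(vertices, faces, weights)
}

#' @rdname read_mesh_obj
#' @param mesh A `skel_mesh`.
#' @export
write_mesh_obj <- function(mesh, obj_path, weights_path = NULL) {
  stopifnot(inherits(mesh, "skel_mesh"))
  weights_path <- weights_path %||% sub("\\.obj$", ".weights.json", obj_path)
  v <- apply(mesh$vertices, 1, function(r)
    paste("v", paste(format(r, digits = 17, trim = TRUE), collapse = " ")))
  f <- apply(mesh$faces, 1, function(r) paste("f", paste(r, collapse = " ")))
  writeLines(c(v, f), obj_path)
  jsonlite::write_json(mesh$weights, weights_path, digits = NA)
  invisible(obj_path)
}

#' Export result tables to CSV
#'
#' Writes one UTF-8 CSV per named table (header row, deterministic column
#' order as given) so observed features can feed external statistical
#' analysis.
#'
#' @param tables Named list of data frames.
#' @param dir Output directory (created if absent).
#' @return Character vector of written file paths, invisibly.
#' @export
export_stats_csv <- function(tables, dir) {
  if (!length(tables) || is.null(names(tables)) || any(!nzchar(names(tables)))) {
    abort("`tables` must be a non-empty named list.",
          class = "skelgaze_validation_error")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(as_tibble(tables[[nm]]), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
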