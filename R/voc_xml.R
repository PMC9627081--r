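# LabelImg PASCAL-VOC XML dialect:
#   <annotation><filename/><size><width/><height/><depth/></size>
#     <object><name/><bndbox><xmin/><ymin/><xmax/><ymax/></bndbox></object>*
#   </annotation>
# VOC coordinates are 1-based inclusive; the internal representation is
# 0-based half-open, so reading maps (xmin, ymin, xmax, ymax) to
# (xmin - 1, ymin - 1, xmax, ymax) and writing inverts that.

voc_field <- function(node, xpath, path, as_num = FALSE) {
  hit <- xml2::xml_find_first(node, xpath)
  if (inherits(hit, "xml_missing")) {
    stop("read_voc_xml: '", path, "': missing element <", xpath, ">",
         call. = FALSE)
  }
  txt <- xml2::xml_text(hit)
  if (!as_num) return(txt)
  val <- suppressWarnings(as.numeric(txt))
  if (is.na(val)) {
    stop("read_voc_xml: '", path, "': non-numeric <", xpath, "> value '",
         txt, "'", call. = FALSE)
  }
  val
}

#' Read one LabelImg PASCAL-VOC annotation file
#'
#' Parses a single per-frame XML annotation. Coordinates are converted from
#' the 1-based inclusive VOC convention to the internal 0-based half-open
#' one. A file with no `<object>` elements yields an empty annotation, not
#' an error.
#'
#' @param path Path to the XML file.
#' @return List with `frame_id` (the `<filename>` without extension, falling
#'   back to the file name), `width`/`height` (NA when no `<size>` element),
#'   and `annotations`, a data frame of ground-truth instances.
#' @export
read_voc_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("read_voc_xml: '", path, "': malformed XML (", conditionMessage(e),
         ")", call. = FALSE)
  })
  fname <- xml2::xml_find_first(doc, "./filename")
  frame_id <- if (inherits(fname, "xml_missing")) {
    sub("\\.xml$", "", basename(path))
  } else {
    sub("\\.[A-Za-z0-9]+$", "", xml2::xml_text(fname))
  }
  size <- xml2::xml_find_first(doc, "./size")
  width <- height <- NA_real_
  if (!inherits(size, "xml_missing")) {
    width <- voc_field(size, "./width", path, as_num = TRUE)
    height <- voc_field(size, "./height", path, as_num = TRUE)
  }
  objs <- xml2::xml_find_all(doc, "./object")
  if (length(objs) == 0L) {
    ann <- data.frame(frame_id = character(0), species = character(0),
                      xmin = numeric(0), ymin = numeric(0),
                      xmax = numeric(0), ymax = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    rows <- lapply(objs, function(obj) {
      bb <- xml2::xml_find_first(obj, "./bndbox")
      if (inherits(bb, "xml_missing")) {
        stop("read_voc_xml: '", path, "': <object> without <bndbox>",
             call. = FALSE)
      }
      data.frame(
        frame_id = frame_id,
        species = voc_field(obj, "./name", path),
        xmin = voc_field(bb, "./xmin", path, as_num = TRUE) - 1,
        ymin = voc_field(bb, "./ymin", path, as_num = TRUE) - 1,
        xmax = voc_field(bb, "./xmax", path, as_num = TRUE),
        ymax = voc_field(bb, "./ymax", path, as_num = TRUE),
        stringsAsFactors = FALSE
      )
    })
    ann <- do.call(rbind, rows)
    bad <- which(ann$xmax <= ann$xmin | ann$ymax <= ann$ymin)
    if (length(bad) > 0L) {
      stop("read_voc_xml: '", path, "': degenerate <bndbox> in object ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (!is.na(width)) {
      out <- ann$xmin < 0 | ann$ymin < 0 | ann$xmax > width |
        ann$ymax > height
      if (any(out)) {
        stop("read_voc_xml: '", path, "': box outside image in object ",
             paste(which(out), collapse = ", "), call. = FALSE)
      }
    }
  }
  list(frame_id = frame_id, width = width, height = height,
       annotations = ann)
}

#' Write one LabelImg PASCAL-VOC annotation file
#'
#' Mirror of [read_voc_xml()]: internal 0-based half-open coordinates are
#' written back as 1-based inclusive VOC integers.
#'
#' @param annotations Data frame of instances for one frame (may be empty).
#' @param path Output path.
#' @param frame_id Frame identifier; written as `<filename>` with a `.jpg`
#'   extension.
#' @param width,height Image size in pixels (optional but recommended).
#' @return `path`, invisibly.
#' @export
write_voc_xml <- function(annotations, path, frame_id,
                          width = NA, height = NA) {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "images")
  xml2::xml_add_child(doc, "filename", paste0(frame_id, ".jpg"))
  if (!is.na(width) && !is.na(height)) {
    size <- xml2::xml_add_child(doc, "size")
    xml2::xml_add_child(size, "width", format(width))
    xml2::xml_add_child(size, "height", format(height))
    xml2::xml_add_child(size, "depth", "3")
  }
  if (nrow(annotations) > 0L) {
    validate_boxes(annotations, "write_voc_xml")
    for (i in seq_len(nrow(annotations))) {
      obj <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(obj, "name", annotations$species[i])
      xml2::xml_add_child(obj, "pose", "Unspecified")
      xml2::xml_add_child(obj, "truncated", "0")
      xml2::xml_add_child(obj, "difficult", "0")
      bb <- xml2::xml_add_child(obj, "bndbox")
      xml2::xml_add_child(bb, "xmin", format(annotations$xmin[i] + 1))
      xml2::xml_add_child(bb, "ymin", format(annotations$ymin[i] + 1))
      xml2::xml_add_child(bb, "xmax", format(annotations$xmax[i]))
      xml2::xml_add_child(bb, "ymax", format(annotations$ymax[i]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a directory of VOC annotation files
#'
#' @param dir Directory containing `*.xml` files, one per frame.
#' @return List with `annotations` (row-bound ground-truth table across all
#'   frames, with `gt_id`s assigned) and `frames` (data frame of
#'   `frame_id`, `width`, `height`, including frames with no instances).
#' @export
read_voc_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  if (length(files) == 0L) {
    stop("read_voc_dir: no .xml files under '", dir, "'", call. = FALSE)
  }
  parsed <- lapply(files, read_voc_xml)
  frames <- data.frame(
    frame_id = vapply(parsed, `[[`, "", "frame_id"),
    width = vapply(parsed, `[[`, 0, "width"),
    height = vapply(parsed, `[[`, 0, "height"),
    stringsAsFactors = FALSE
  )
  ann <- do.call(rbind, lapply(parsed, `[[`, "annotations"))
  list(annotations = as_annotations(ann), frames = frames)
}

#' Write annotations as one VOC XML file per frame
#'
#' @param annotations Ground-truth table (see [as_annotations()]).
#' @param dir Output directory (created if needed).
#' @param frames Optional data frame `frame_id`, `width`, `height`; frames
#'   listed here but absent from `annotations` are written as empty
#'   annotation files.
#' @return Character vector of written paths, invisibly.
#' @export
write_voc_dir <- function(annotations, dir, frames = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(frames)) {
    frames <- data.frame(frame_id = unique(annotations$frame_id),
                         width = NA, height = NA, stringsAsFactors = FALSE)
  }
  paths <- character(nrow(frames))
  for (i in seq_len(nrow(frames))) {
    fid <- frames$frame_id[i]
    paths[i] <- file.path(dir, paste0(fid, ".xml"))
    write_voc_xml(annotations[annotations$frame_id == fid, , drop = FALSE],
                  paths[i], fid,
                  width = frames$width[i], height = frames$height[i])
  }
  invisible(paths)
}
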