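# Ground-truth emitters. All pixel-space annotations share the render
# module's coordinate convention: origin top-left, pixel (r, c) covers
# [ (c-1) s, c s ) x [ (r-1) s, r s ) µm relative to the frame origin,
# camera centered on the colony centroid unless an explicit center is given.

#' Annotate a frame
#'
#' Maps every agent's outline to pixel coordinates, clips it to the image
#' rectangle and derives the tight bounding box. Agents wholly outside the
#' field of view are omitted.
#'
#' @param world a `colony_world`.
#' @param config a [render_config()] (image size + calibration).
#' @param center optional camera center (x, y) in µm.
#' @param frame_index frame number stored in the annotation.
#' @return A `frame_annotation`: list with `frame_index`, `image_size`,
#'   `center`, `calibration` and `cells` (list of per-cell records with
#'   `cell_id`, `parent_id`, `polygon` (n x 2 px), `bbox`
#'   `(x_min, y_min, x_max, y_max)` px).
#' @export
annotate <- function(world, config = render_config(), center = NULL,
                     frame_index = 0L) {
  if (is.null(center)) center <- default_center(world)
  org <- frame_origin(center, config)
  h <- config$image_size[1L]; w <- config$image_size[2L]
  s <- config$calibration
  clip_rect <- cbind(c(0, w, w, 0), c(0, 0, h, h))  # CCW in pixel coords
  cells <- list()
  for (i in seq_len(nrow(world$agents))) {
    ag <- world$agents[i, ]
    poly <- as.matrix(agent_outline(ag, config$n_vertices))
    px <- cbind((poly[, 1L] - org["x0"]) / s, (poly[, 2L] - org["y0"]) / s)
    if (signed_area(px) < 0) px <- px[rev(seq_len(nrow(px))), , drop = FALSE]
    clipped <- sutherland_hodgman(px, clip_rect)
    if (nrow(clipped) < 3L || abs(signed_area(clipped)) < 1e-9) next
    dimnames(clipped) <- NULL
    bbox <- c(x_min = min(clipped[, 1L]), y_min = min(clipped[, 2L]),
              x_max = max(clipped[, 1L]), y_max = max(clipped[, 2L]))
    cells[[length(cells) + 1L]] <-
      list(cell_id = ag$id, parent_id = ag$parent_id,
           polygon = clipped, bbox = bbox)
  }
  structure(list(frame_index = as.integer(frame_index),
                 image_size = config$image_size, center = center,
                 calibration = s, cells = cells),
            class = "frame_annotation")
}

#' Write YOLO detection labels
#'
#' One line per cell: `"0 cx cy w h"` with box center and size normalized to
#' `[0, 1]` by the image dimensions (class index 0 = cell).
#'
#' @param annotation a [annotate()] result.
#' @param path output `.txt` path.
#' @return `path`, invisibly.
#' @export
write_yolo <- function(annotation, path) {
  h <- annotation$image_size[1L]; w <- annotation$image_size[2L]
  lines <- vapply(annotation$cells, function(cl) {
    b <- cl$bbox
    cx <- (b[["x_min"]] + b[["x_max"]]) / 2 / w
    cy <- (b[["y_min"]] + b[["y_max"]]) / 2 / h
    bw <- (b[["x_max"]] - b[["x_min"]]) / w
    bh <- (b[["y_max"]] - b[["y_min"]]) / h
    sprintf("0 %.6f %.6f %.6f %.6f", cx, cy, bw, bh)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write COCO instance-segmentation annotations
#'
#' Standard COCO JSON with polygon `segmentation` (flattened
#' `[x1, y1, x2, y2, ...]` pixel lists), `bbox` as `[x, y, w, h]`, shoelace
#' `area`, globally unique annotation ids and a single category `"cell"`.
#'
#' @param annotations list of [annotate()] results.
#' @param image_paths character vector of image file names, parallel to
#'   `annotations`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_coco <- function(annotations, image_paths, path) {
  stopifnot(length(annotations) == length(image_paths))
  images <- lapply(seq_along(annotations), function(i) {
    a <- annotations[[i]]
    list(id = i, file_name = image_paths[[i]],
         height = a$image_size[1L], width = a$image_size[2L])
  })
  anns <- list()
  aid <- 0L
  for (i in seq_along(annotations)) {
    for (cl in annotations[[i]]$cells) {
      aid <- aid + 1L
      seg <- as.vector(t(cl$polygon))
      b <- cl$bbox
      anns[[aid]] <- list(
        id = aid, image_id = i, category_id = 1L,
        segmentation = list(seg),
        bbox = c(b[["x_min"]], b[["y_min"]],
                 b[["x_max"]] - b[["x_min"]], b[["y_max"]] - b[["y_min"]]),
        area = polygon_area(cl$polygon),
        iscrowd = 0L)
    }
  }
  doc <- list(images = images, annotations = anns,
              categories = list(list(id = 1L, name = "cell")))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a COCO annotation file
#'
#' Inverse of [write_coco()]; used for round-trip checks and downstream
#' consumption.
#'
#' @param path `.json` path written by [write_coco()].
#' @return The parsed document: list with `images`, `annotations`,
#'   `categories`; each annotation's `segmentation` is restored to an
#'   n x 2 polygon matrix under `polygon`.
#' @export
read_coco <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  doc$annotations <- lapply(doc$annotations, function(a) {
    seg <- unlist(a$segmentation[[1L]])
    a$polygon <- matrix(seg, ncol = 2L, byrow = TRUE)
    a
  })
  doc
}

#' Write a 16-bit instance label mask
#'
#' Background 0; pixels of the i-th annotated cell carry label i (per-frame
#' labels 1..n in cell-id order). A pixel claimed by several polygons is
#' assigned to the cell with the smaller id (deterministic tie-break).
#' Pixels are labelled by their centers.
#'
#' @param annotation a [annotate()] result with fewer than 65536 cells.
#' @param path output `.tif` path (16-bit).
#' @return The label matrix, invisibly.
#' @export
write_masks <- function(annotation, path) {
  n <- length(annotation$cells)
  if (n >= 65536L) stop("too many cells for a 16-bit mask", call. = FALSE)
  h <- annotation$image_size[1L]; w <- annotation$image_size[2L]
  lab <- matrix(0L, h, w)
  ord <- order(vapply(annotation$cells, `[[`, numeric(1), "cell_id"))
  # paint in descending label order so smaller labels overwrite on overlap
  for (k in rev(seq_len(n))) {
    cl <- annotation$cells[[ord[k]]]
    poly <- cl$polygon
    b <- cl$bbox
    c0 <- max(1L, floor(b[["x_min"]]) + 1L); c1 <- min(w, ceiling(b[["x_max"]]))
    r0 <- max(1L, floor(b[["y_min"]]) + 1L); r1 <- min(h, ceiling(b[["y_max"]]))
    if (c0 > c1 || r0 > r1) next
    cols <- c0:c1; rows <- r0:r1
    gx <- rep(cols - 0.5, each = length(rows))
    gy <- rep(rows - 0.5, times = length(cols))
    inside <- points_in_polygon(gx, gy, poly)
    m <- matrix(inside, nrow = length(rows))
    lab[rows, cols][m] <- k
  }
  if (!is.null(path)) {
    tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L)
  }
  invisible(lab)
}

#' Write TrackMate-style lineage XML
#'
#' Minimal TrackMate dialect: one spot per cell per emitted frame (position
#' in µm, radius = equivalent-area circle radius), edges linking each cell's
#' consecutive-frame spots and a mother's last spot to each daughter's first
#' spot, grouped into one track per lineage (founder subtree).
#'
#' @param trajectory list of `colony_world` snapshots (one per frame).
#' @param path output `.xml` path.
#' @return `path`, invisibly.
#' @export
write_trackmate <- function(trajectory, path) {
  frames <- seq_along(trajectory) - 1L
  # collect spots: one per (frame, cell)
  spots <- list()
  sid <- 0L
  spot_id <- list()  # spot_id[[frame]][cell id as character]
  for (f in seq_along(trajectory)) {
    ag <- trajectory[[f]]$agents
    ids <- character(0)
    m <- integer(0)
    for (i in seq_len(nrow(ag))) {
      sid <- sid + 1L
      area <- polygon_area(shape_outline(ag$kind[i], ag$length[i],
                                         ag$width[i], ag$bend[i]))
      spots[[sid]] <- list(id = sid, frame = frames[f], cell = ag$id[i],
                           x = ag$x[i], y = ag$y[i],
                           radius = sqrt(area / pi))
      m[as.character(ag$id[i])] <- sid
    }
    spot_id[[f]] <- m
  }
  # edges: same cell frame f -> f+1; mother's last spot -> daughter's first
  edges <- list()
  parent_of <- integer(0)
  for (w in trajectory) {
    pp <- w$agents$parent_id
    names(pp) <- as.character(w$agents$id)
    parent_of[names(pp)] <- pp
  }
  last_spot <- integer(0)  # most recent spot id per cell id
  for (f in seq_along(trajectory)) {
    cur <- spot_id[[f]]
    for (cid in names(cur)) {
      if (!is.null(last_spot[cid]) && !is.na(last_spot[cid])) {
        edges[[length(edges) + 1L]] <- c(last_spot[[cid]], cur[[cid]])
      } else {
        par <- parent_of[cid]
        if (length(par) && !is.na(par) &&
            !is.na(last_spot[as.character(par)][1L])) {
          edges[[length(edges) + 1L]] <- c(last_spot[[as.character(par)]],
                                           cur[[cid]])
        }
      }
    }
    # update last seen spots after linking (a mother's final spot must stay
    # addressable for daughters appearing in the next frame)
    for (cid in names(cur)) last_spot[cid] <- cur[[cid]]
  }
  doc <- xml2::xml_new_root("TrackMate", version = "7.0.0")
  model <- xml2::xml_add_child(doc, "Model", spatialunits = "micron",
                               timeunits = "frame")
  allspots <- xml2::xml_add_child(model, "AllSpots",
                                  nspots = as.character(length(spots)))
  for (f in seq_along(trajectory)) {
    sif <- xml2::xml_add_child(allspots, "SpotsInFrame",
                               frame = as.character(frames[f]))
    for (s in spots) {
      if (s$frame != frames[f]) next
      xml2::xml_add_child(sif, "Spot",
        ID = as.character(s$id), name = sprintf("ID%d", s$id),
        FRAME = as.character(s$frame),
        POSITION_X = sprintf("%.6f", s$x),
        POSITION_Y = sprintf("%.6f", s$y),
        POSITION_Z = "0",
        RADIUS = sprintf("%.6f", s$radius),
        QUALITY = "1")
    }
  }
  alltracks <- xml2::xml_add_child(model, "AllTracks")
  # group edges into lineage tracks: union by connected spots
  if (length(edges)) {
    # map spot -> root founder of its cell lineage
    root_of_cell <- function(cid) {
      cur <- cid
      repeat {
        p <- parent_of[as.character(cur)]
        if (!length(p) || is.na(p)) return(cur)
        cur <- p
      }
    }
    spot_cell <- vapply(spots, `[[`, numeric(1), "cell")
    by_track <- split(seq_along(edges), vapply(edges, function(e)
      root_of_cell(spot_cell[e[1L]]), numeric(1)))
    tid <- 0L
    for (tr in by_track) {
      tid <- tid + 1L
      tnode <- xml2::xml_add_child(alltracks, "Track",
                                   TRACK_ID = as.character(tid),
                                   name = sprintf("Track_%d", tid))
      for (ei in tr) {
        xml2::xml_add_child(tnode, "Edge",
                            SPOT_SOURCE_ID = as.character(edges[[ei]][1L]),
                            SPOT_TARGET_ID = as.character(edges[[ei]][2L]))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Dataset specification
#'
#' Parameters of a batch ground-truth dataset: independent colonies are
#' simulated and snapshotted at per-image target densities spanning
#' `cell_count_range`.
#'
#' @param n_images number of frames to generate (>= 1).
#' @param image_size frame side length in px (square frames).
#' @param calibration µm/pixel.
#' @param cell_count_range `(min, max)` cells per frame.
#' @param seed integer base seed; image i uses `seed + i`.
#' @param emitters subset of `c("yolo", "coco", "masks")`.
#' @return A `dataset_spec` list.
#' @export
dataset_spec <- function(n_images = 128L, image_size = 512L,
                         calibration = 0.09, cell_count_range = c(0L, 512L),
                         seed = 1L, emitters = c("yolo", "coco", "masks")) {
  if (n_images < 1) stop("n_images must be >= 1", call. = FALSE)
  if (cell_count_range[2L] < cell_count_range[1L] || cell_count_range[1L] < 0)
    stop("need cell_count_range max >= min >= 0", call. = FALSE)
  bad <- setdiff(emitters, c("yolo", "coco", "masks"))
  if (length(bad)) stop("unknown emitters: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 calibration = calibration,
                 cell_count_range = as.integer(cell_count_range),
                 seed = as.integer(seed), emitters = emitters),
            class = "dataset_spec")
}

# per-image target counts: log-uniform over [max(1, min), max] (density
# spread helps detector training); when the range starts at 0 a small share
# of frames is left empty
sample_target_counts <- function(spec) {
  with_seed(derive_seed(spec$seed, -1L), {
    lo <- max(1L, spec$cell_count_range[1L])
    hi <- max(lo, spec$cell_count_range[2L])
    u <- stats::runif(spec$n_images)
    tgt <- round(exp(log(lo) + u * (log(hi) - log(lo))))
    if (spec$cell_count_range[1L] == 0L) {
      empty <- stats::runif(spec$n_images) < 1 / 32
      tgt[empty] <- 0L
    }
    as.integer(pmin(tgt, hi))
  })
}

#' Generate a ground-truth dataset
#'
#' Runs one independent colony simulation per image (seeded `spec$seed + i`),
#' snapshots it once its population reaches the image's target count, renders
#' the phase-contrast frame and writes every requested annotation format plus
#' a JSON manifest (per-image seed, target and achieved cell count). Fully
#' deterministic for a fixed spec.
#'
#' @param spec a [dataset_spec()].
#' @param model a [homeostasis_model()] shared by all colonies.
#' @param render a [render_config()]; its image size and calibration are
#'   overridden by the spec.
#' @param dir output directory (created if missing).
#' @param sim_config a [simulation_config()] template for the per-image
#'   simulations (seed and duration are managed per image).
#' @param max_steps per-image step budget; images whose target count is not
#'   reached within it are recorded as errors in the manifest.
#' @return The manifest, invisibly (list with resolved spec and per-image
#'   records).
#' @export
generate_ground_truth_dataset <- function(spec, model = homeostasis_model(),
                                          render = render_config(),
                                          dir = "dataset",
                                          sim_config = NULL,
                                          max_steps = 3000L) {
  stopifnot(inherits(spec, "dataset_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  render$image_size <- c(spec$image_size, spec$image_size)
  render$calibration <- spec$calibration
  targets <- sample_target_counts(spec)
  annotations <- list()
  image_files <- character(0)
  records <- vector("list", spec$n_images)
  for (i in seq_len(spec$n_images)) {
    img_seed <- spec$seed + i
    cfg <- if (is.null(sim_config)) {
      simulation_config(seed = img_seed, model = model, duration = 0)
    } else {
      sim_config$seed <- as.integer(img_seed)
      sim_config
    }
    target <- targets[i]
    if (target == 0L) {
      world <- structure(list(time = 0, agents = empty_agents(),
                              next_id = 1L, seed = img_seed),
                         class = "colony_world")
      reached <- TRUE
    } else {
      world <- init_world(cfg)
      res <- step_until_count(world, cfg, target, max_steps)
      reached <- res$reached
      world <- res$world
      # never exceed the spec's maximum: fall back to the pre-threshold state
      if (nrow(world$agents) > spec$cell_count_range[2L])
        world <- res$previous
    }
    fname <- sprintf("frame_%06d.tif", i)
    img <- render_phase_contrast(world, render, seed = derive_seed(img_seed, 7L))
    write_frame(img, file.path(dir, fname))
    ann <- annotate(world, render, frame_index = i)
    annotations[[i]] <- ann
    image_files[i] <- fname
    if ("yolo" %in% spec$emitters)
      write_yolo(ann, file.path(dir, sprintf("frame_%06d.txt", i)))
    if ("masks" %in% spec$emitters)
      write_masks(ann, file.path(dir, sprintf("mask_%06d.tif", i)))
    records[[i]] <- list(image = fname, seed = img_seed,
                         target_count = target,
                         cell_count = length(ann$cells),
                         time_h = world$time,
                         error = if (reached) NULL else
                           "target count not reached within step budget")
  }
  if ("coco" %in% spec$emitters)
    write_coco(annotations, image_files, file.path(dir, "annotations.json"))
  manifest <- list(
    spec = unclass(spec),
    model = unclass(model),
    note = "independent colony per image; image i seeded spec$seed + i",
    images = records)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
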