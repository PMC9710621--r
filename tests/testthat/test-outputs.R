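# ground-truth emitters: annotations, YOLO, COCO, masks, TrackMate, meshes

make_world <- function(agents) {
  structure(list(time = 0, agents = agents, next_id = max(agents$id) + 1L,
                 seed = 1L), class = "colony_world")
}

test_that("annotation maps cells to pixels consistently with the calibration", {
  w <- grow_colony(15, seed = 9)
  rc <- render_config(image_size = c(256L, 256L))
  ann <- annotate(w, rc)
  expect_length(ann$cells, nrow(w$agents))
  for (cl in ann$cells) {
    i <- match(cl$cell_id, w$agents$id)
    um_area <- polygon_area(agent_outline(w$agents[i, ]))
    px_area <- polygon_area(cl$polygon)
    expect_lt(abs(px_area / (um_area / rc$calibration^2) - 1), 0.02)
    # polygon inside its bbox, bbox tight within a vertex
    expect_true(all(cl$polygon[, 1] >= cl$bbox[["x_min"]] - 1e-9))
    expect_true(all(cl$polygon[, 1] <= cl$bbox[["x_max"]] + 1e-9))
    expect_equal(min(cl$polygon[, 2]), cl$bbox[["y_min"]])
    expect_equal(max(cl$polygon[, 2]), cl$bbox[["y_max"]])
  }
  # empty world -> empty annotation
  we <- make_world(cell_agent(1L))
  we$agents <- empty_agents()
  expect_length(annotate(we, rc)$cells, 0L)
  # one centered cell -> box centered within a pixel
  wc <- make_world(cell_agent(1L, x = 0, y = 0))
  annc <- annotate(wc, rc, center = c(0, 0))
  b <- annc$cells[[1]]$bbox
  expect_lt(abs((b[["x_min"]] + b[["x_max"]]) / 2 - 128), 1)
  expect_lt(abs((b[["y_min"]] + b[["y_max"]]) / 2 - 128), 1)
})

test_that("YOLO lines are normalized boxes, one per cell", {
  w <- grow_colony(12, seed = 10)
  rc <- render_config(image_size = c(256L, 256L))
  ann <- annotate(w, rc)
  path <- withr::local_tempfile(fileext = ".txt")
  write_yolo(ann, path)
  lines <- readLines(path)
  expect_length(lines, length(ann$cells))
  vals <- do.call(rbind, lapply(strsplit(lines, " "), as.numeric))
  expect_true(all(vals[, 1] == 0))
  expect_true(all(vals[, 2:5] >= 0 & vals[, 2:5] <= 1))
  # empty frame -> empty file
  we <- make_world(cell_agent(1L)); we$agents <- empty_agents()
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_yolo(annotate(we, rc), path2)
  expect_length(readLines(path2), 0L)
})

test_that("COCO files round-trip losslessly and report consistent areas", {
  w1 <- grow_colony(8, seed = 13)
  w2 <- grow_colony(14, seed = 14)
  rc <- render_config(image_size = c(256L, 256L))
  anns <- list(annotate(w1, rc, frame_index = 1L),
               annotate(w2, rc, frame_index = 2L))
  path <- withr::local_tempfile(fileext = ".json")
  write_coco(anns, c("a.tif", "b.tif"), path)
  doc <- read_coco(path)
  expect_length(doc$images, 2L)
  expect_length(doc$annotations,
                length(anns[[1]]$cells) + length(anns[[2]]$cells))
  flat <- c(anns[[1]]$cells, anns[[2]]$cells)
  for (k in seq_along(doc$annotations)) {
    a <- doc$annotations[[k]]
    expect_equal(a$polygon, flat[[k]]$polygon, tolerance = 1e-12)
    expect_lt(abs(a$area / polygon_area(a$polygon) - 1), 0.02)
    expect_equal(a$category_id, 1L)
  }
})

test_that("label masks agree with the other emitters", {
  for (seed in c(15, 16)) {
    w <- grow_colony(10 + seed, seed = seed)
    rc <- render_config(image_size = c(256L, 256L))
    ann <- annotate(w, rc)
    path <- withr::local_tempfile(fileext = ".tif")
    lab <- write_masks(ann, path)
    labels <- setdiff(unique(as.vector(lab)), 0L)
    expect_setequal(labels, seq_along(ann$cells))
    # round trip through the 16-bit TIFF
    back <- tiff::readTIFF(path, as.is = TRUE)
    expect_identical(back, unclass(lab))
    # per-cell mask area within 2% of the polygon (COCO) area
    for (k in seq_along(ann$cells)) {
      px_area <- polygon_area(ann$cells[[k]]$polygon)
      if (px_area > 200)  # skip tiny clipped slivers where 1 px matters
        expect_lt(abs(sum(lab == k) / px_area - 1), 0.02)
    }
  }
})

test_that("TrackMate XML mirrors the lineage forest", {
  # non-dividing cell over 5 frames: 5 spots, 4 edges
  cfg <- simulation_config(seed = 1, dt = 0.1, duration = 0.4, emit_every = 1L,
                           model = homeostasis_model("timer",
                                                     trigger_mean = 99,
                                                     trigger_cv = 0,
                                                     rate_mean = 0.1,
                                                     rate_cv = 0))
  tr <- run_simulation(cfg)
  path <- withr::local_tempfile(fileext = ".xml")
  write_trackmate(tr, path)
  x <- xml2::read_xml(path)
  expect_length(xml2::xml_find_all(x, ".//Spot"), 5L)
  expect_length(xml2::xml_find_all(x, ".//Edge"), 4L)
  # a division: mother's last spot has out-degree 2
  cfg2 <- simulation_config(seed = 1, dt = 0.1, duration = 0.5,
                            emit_every = 1L,
                            model = homeostasis_model("timer",
                                                      trigger_mean = 0.35,
                                                      trigger_cv = 0,
                                                      rate_mean = log(2),
                                                      rate_cv = 0))
  tr2 <- run_simulation(cfg2)
  path2 <- withr::local_tempfile(fileext = ".xml")
  write_trackmate(tr2, path2)
  x2 <- xml2::read_xml(path2)
  nspots <- sum(vapply(tr2, function(w) nrow(w$agents), integer(1)))
  expect_length(xml2::xml_find_all(x2, ".//Spot"), nspots)
  deg <- table(xml2::xml_attr(xml2::xml_find_all(x2, ".//Edge"),
                              "SPOT_SOURCE_ID"))
  expect_equal(max(deg), 2)
  expect_equal(sum(deg == 2), 1)  # exactly one division in this run
})

test_that("exported meshes are watertight with closed-form volumes", {
  cocc <- cell_agent(1L, kind = "coccoid", length = 1, width = 1)
  rod <- cell_agent(2L, kind = "rod", length = 2, width = 1)
  sphere_vol <- pi / 6
  capsule_vol <- pi * 0.25 * 1 + pi / 6
  m_c <- agent_mesh(cocc, 16L)
  m_r <- agent_mesh(rod, 16L)
  expect_lt(abs(mesh_volume(m_c) / sphere_vol - 1), 0.01)
  expect_lt(abs(mesh_volume(m_r) / capsule_vol - 1), 0.01)
  for (m in list(m_c, m_r)) expect_true(mesh_is_watertight(m))
  bent <- cell_agent(3L, kind = "bent_rod", length = 2, width = 0.8, bend = 1)
  expect_true(mesh_is_watertight(agent_mesh(bent, 16L)))
  ell <- cell_agent(4L, kind = "ellipsoid", length = 3, width = 1)
  expect_lt(abs(mesh_volume(agent_mesh(ell, 16L)) /
                  (4 / 3 * pi * 1.5 * 0.5 * 0.5) - 1), 0.01)
  # volume error decreases with angular resolution
  errs <- vapply(c(8L, 16L, 32L), function(res)
    abs(mesh_volume(agent_mesh(cocc, res)) - sphere_vol), numeric(1))
  expect_true(all(diff(errs) < 0))
  # binary STL has the exact expected byte size
  path <- withr::local_tempfile(fileext = ".stl")
  export_mesh(rod, path)
  expect_equal(file.info(path)$size, 84 + 50 * nrow(m_r$faces))
})

test_that("the dataset generator writes a consistent, deterministic dataset", {
  spec <- dataset_spec(n_images = 3L, image_size = 192L, calibration = 0.09,
                       cell_count_range = c(0L, 48L), seed = 77L)
  d1 <- withr::local_tempdir()
  man <- generate_ground_truth_dataset(spec, dir = d1)
  expect_length(man$images, 3L)
  counts <- vapply(man$images, function(r) r$cell_count, numeric(1))
  expect_true(all(counts >= 0 & counts <= 48))
  frames <- list.files(d1, pattern = "^frame_\\d+\\.tif$")
  expect_length(frames, 3L)
  img <- tiff::readTIFF(file.path(d1, frames[1]))
  expect_equal(dim(img), c(192L, 192L))
  # cross-emitter consistency per frame
  coco <- read_coco(file.path(d1, "annotations.json"))
  for (i in 1:3) {
    ny <- length(readLines(file.path(d1, sprintf("frame_%06d.txt", i))))
    nc <- sum(vapply(coco$annotations, function(a) a$image_id, numeric(1)) == i)
    lab <- tiff::readTIFF(file.path(d1, sprintf("mask_%06d.tif", i)),
                          as.is = TRUE)
    expect_equal(ny, counts[i])
    expect_equal(nc, counts[i])
    expect_equal(length(setdiff(unique(as.vector(lab)), 0L)), counts[i])
  }
  # bit-identical regeneration
  d2 <- withr::local_tempdir()
  generate_ground_truth_dataset(spec, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})
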