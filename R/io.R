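#' Write a silhouette set to disk
#'
#' Masks as 8-bit PNG (0/255), the rig as JSON, one file per view.
#'
#' @param sil a `silhouette_set`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_silhouettes <- function(sil, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(sil$masks)) {
    png::writePNG(sil$masks[[i]] * 1,
                  file.path(dir, paste0(sil$views[[i]]$label, ".png")))
  }
  rig <- sil$rig
  jsonlite::write_json(unclass(rig), file.path(dir, "rig.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a silhouette set written by [write_silhouettes()]
#'
#' @param dir directory containing view PNGs and `rig.json`.
#' @return a `silhouette_set`.
#' @export
read_silhouettes <- function(dir) {
  rig_raw <- jsonlite::read_json(file.path(dir, "rig.json"),
                                 simplifyVector = TRUE)
  rig <- camera_rig(side_azimuths = rig_raw$side_azimuths,
                    has_top_view = rig_raw$has_top_view,
                    image_size = rig_raw$image_size,
                    projection = rig_raw$projection,
                    camera_distance = rig_raw$camera_distance,
                    world_extent = rig_raw$world_extent)
  views <- calibrated_views(rig)
  masks <- lapply(views, function(v) {
    m <- png::readPNG(file.path(dir, paste0(v$label, ".png")))
    if (length(dim(m)) == 3) m <- m[, , 1]
    m > 0.5
  })
  structure(list(masks = masks, views = views, rig = rig),
            class = "silhouette_set")
}

#' Write plant ground truth as CSV
#'
#' @param model a `plant_model`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(model, path) {
  utils::write.csv(model$ground_truth, path, row.names = FALSE)
  invisible(path)
}

#' Write a skeleton graph as node and edge CSV tables
#'
#' @param skel a `skeleton_graph`.
#' @param node_path,edge_path output CSV paths.
#' @return `node_path`, invisibly.
#' @export
write_skeleton <- function(skel, node_path, edge_path) {
  nd <- skel$nodes
  nd$node_id <- seq_len(nrow(nd))
  utils::write.csv(nd[, c("node_id", "x", "y", "z", "radius_mm")],
                   node_path, row.names = FALSE)
  utils::write.csv(skel$edges, edge_path, row.names = FALSE)
  invisible(node_path)
}

#' Write per-leaf angles and phyllotaxic series as CSV
#'
#' @param record a `phyllotaxy_record`.
#' @param angles_path,series_path output CSV paths.
#' @param plant_id,timepoint identifiers stored with every row.
#' @return `angles_path`, invisibly.
#' @export
write_angles <- function(record, angles_path, series_path,
                         plant_id = "plant", timepoint = 1) {
  a <- record$angles
  a <- cbind(plant_id = plant_id, timepoint = timepoint, a)
  utils::write.csv(a, angles_path, row.names = FALSE)
  if (!is.null(record$series)) {
    s <- record$series
    utils::write.csv(data.frame(plant_id = plant_id, timepoint = timepoint,
                                angle_index = seq_along(s$phyllo),
                                phyllo_deg = s$phyllo, Phi_deg = s$Phi,
                                kept = s$kept),
                     series_path, row.names = FALSE)
  }
  invisible(angles_path)
}
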