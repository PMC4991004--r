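#' Serialize a contour tree / branch decomposition to JSON
#'
#' Schema: `nodes` (id, vertex_index, value, kind), `arcs` (upper, lower
#' node ids), and for decompositions `branches` (id, parent, children,
#' depth, value span, voxel count).
#'
#' @param x a `contour_tree` or `branch_decomposition`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(x, path) {
  if (inherits(x, "contour_tree")) {
    obj <- list(nodes = x$nodes, arcs = x$arcs[, c("upper", "lower")])
  } else if (inherits(x, "branch_decomposition")) {
    br <- x$branches
    kids <- branch_children(x)
    val <- x$nodes$value
    obj <- list(
      nodes = x$nodes,
      branches = lapply(seq_len(nrow(br)), function(i) {
        b <- list(id = br$id[i],
                  children = I(kids[[as.character(br$id[i])]]),
                  depth = br$depth[i],
                  value_span = c(val[br$bottom_node[i]], val[br$top_node[i]]),
                  persistence = br$persistence[i],
                  n_voxels = br$n_voxels[i])
        if (!is.na(br$parent[i])) b$parent <- br$parent[i]
        b
      }))
  } else stop("expected a `contour_tree` or `branch_decomposition`")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Run the full illumination pipeline and write its artifacts
#'
#' Executes build -> simplify -> segment -> annotate -> illuminate -> render
#' on a volume and writes: the branch decomposition (`<prefix>_tree.json`),
#' the attribute table (`<prefix>_attrs.csv`), the lighting table
#' (`<prefix>_lighting.json`), the segmentation (`<prefix>_seg.raw/.hdr`),
#' the rendered image (`<prefix>.ppm`), and the full configuration
#' (`<prefix>_config.json`) for provenance. Identical configurations produce
#' byte-identical outputs.
#'
#' @param volume a [scalar_field] or a path readable by [read_volume()].
#' @param out_prefix path prefix for all artifacts.
#' @param mode,connectivity,measure,threshold,w,V,L0,gamma0,Q,K parameters
#'   passed to [topo_illumination()].
#' @param tf optional transfer function (JSON path or `transfer_function`).
#' @param render_width,render_height image size.
#' @param opacity default opacity when `tf` is missing.
#' @return (invisibly) a list with the fit and the artifact paths.
#' @export
run_pipeline <- function(volume, out_prefix,
                         mode = "saliency", connectivity = 6,
                         measure = "persistence", threshold = 0,
                         w = 0.71, V = 50, L0 = 10, gamma0 = 0.8,
                         Q = 1, K = 300, tf = NULL,
                         render_width = NULL, render_height = NULL,
                         opacity = 0.15) {
  field <- if (is.character(volume)) read_volume(volume) else volume
  stopifnot_field(field)
  fit <- topo_illumination(field, mode = mode, connectivity = connectivity,
                           measure = measure, threshold = threshold,
                           w = w, V = V, L0 = L0, gamma0 = gamma0, Q = Q, K = K)
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- list(tree = paste0(out_prefix, "_tree.json"),
                attrs = paste0(out_prefix, "_attrs.csv"),
                lighting = paste0(out_prefix, "_lighting.json"),
                seg = paste0(out_prefix, "_seg.raw"),
                image = paste0(out_prefix, ".ppm"),
                config = paste0(out_prefix, "_config.json"))
  write_tree_json(fit$branches, paths$tree)
  write_attributes_csv(fit$attributes, paths$attrs)
  write_lighting_json(fit$lighting, paths$lighting)
  write_segmentation(fit$segmentation, paths$seg)
  if (is.character(tf)) tf <- read_transfer_json(tf)
  ids <- sort(unique(as.vector(fit$segmentation$labels)))
  if (is.null(tf)) tf <- transfer_function(ids, opacity = opacity)
  ext <- (field$dims - 1) * field$spacing
  cfg <- render_config(
    width = if (is.null(render_width)) 4 * field$dims[1] else render_width,
    height = if (is.null(render_height)) 4 * field$dims[2] else render_height,
    position = c(ext[1] / 2, ext[2] / 2, -2 * max(ext) - 1),
    look_at = ext / 2)
  img <- raycast_image(field, fit$segmentation, fit$lighting, tf, cfg)
  write_image(img, paths$image)
  jsonlite::write_json(c(fit$config, list(mode = mode)), paths$config,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(fit = fit, image = img, paths = paths))
}
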