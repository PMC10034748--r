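# Plain-text serialization: volumes and acquisition datasets (JSON/CSV
# containers), block schemes and trained models (JSON). Text formats keep the
# artifacts portable and diffable; no binary containers are required.

#' Write / read a complex volume as JSON
#'
#' Stores shape, voxel size, and flat real/imaginary vectors (column-major).
#'
#' @param x complex 3D array
#' @param path output file
#' @export
write_volume <- function(x, path) {
  obj <- list(shape = dim(x), voxel_size = attr(x, "voxel_size") %||% 1,
              re = as.vector(Re(x)), im = as.vector(Im(x)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  image_volume(array(complex(real = obj$re, imaginary = obj$im), obj$shape),
               voxel_size = obj$voxel_size)
}

#' Write / read a simulated acquisition dataset
#'
#' Directory container with `meta.json` (grid shape, voxel size, seed,
#' ordering), `coords.csv`, `dcf.csv`, `kspace.csv` (re/im column pair per
#' channel) and `maps.csv`.
#'
#' @param dir output directory (created)
#' @param kspace `kspace`
#' @param traj `radial_traj`
#' @param dcf `radial_dcf`
#' @param maps `coil_maps`
#' @param voxel_size,seed metadata recorded in `meta.json`
#' @export
write_dataset <- function(dir, kspace, traj, dcf, maps, voxel_size = 1, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  shape <- dim(maps)[1:3]
  jsonlite::write_json(
    list(shape = shape, n_channels = kspace$n_channels,
         n_spokes = traj$n_spokes, n_readout = traj$n_readout,
         grid_n = traj$grid_n, ordering_mode = traj$ordering_mode,
         weighted = kspace$weighted, voxel_size = voxel_size, seed = seed),
    file.path(dir, "meta.json"), digits = NA, auto_unbox = TRUE)
  utils::write.csv(data.frame(kx = traj$coords[, 1], ky = traj$coords[, 2],
                              kz = traj$coords[, 3]),
                   file.path(dir, "coords.csv"), row.names = FALSE)
  utils::write.csv(data.frame(weight = dcf$weights, scale = dcf$scale),
                   file.path(dir, "dcf.csv"), row.names = FALSE)
  ks <- as.data.frame(do.call(cbind, lapply(seq_len(kspace$n_channels), function(c_i)
    cbind(Re(kspace$samples[c_i, ]), Im(kspace$samples[c_i, ])))))
  names(ks) <- as.vector(t(outer(seq_len(kspace$n_channels),
                                 c("re", "im"),
                                 function(i, p) paste0(p, "_ch", i))))
  utils::write.csv(ks, file.path(dir, "kspace.csv"), row.names = FALSE)
  mp <- as.data.frame(do.call(cbind, lapply(seq_len(dim(maps)[4]), function(c_i)
    cbind(as.vector(Re(maps[, , , c_i])), as.vector(Im(maps[, , , c_i]))))))
  names(mp) <- as.vector(t(outer(seq_len(dim(maps)[4]), c("re", "im"),
                                 function(i, p) paste0(p, "_ch", i))))
  utils::write.csv(mp, file.path(dir, "maps.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  co <- utils::read.csv(file.path(dir, "coords.csv"))
  dc <- utils::read.csv(file.path(dir, "dcf.csv"))
  ks <- utils::read.csv(file.path(dir, "kspace.csv"))
  mp <- utils::read.csv(file.path(dir, "maps.csv"))
  n_ch <- meta$n_channels
  traj <- structure(list(coords = as.matrix(co), n_spokes = meta$n_spokes,
                         n_readout = meta$n_readout, grid_n = meta$grid_n,
                         ordering = seq_len(meta$n_spokes),
                         ordering_mode = meta$ordering_mode,
                         spoke_of_sample = rep(seq_len(meta$n_spokes),
                                               each = meta$n_readout)),
                    class = "radial_traj")
  samples <- t(vapply(seq_len(n_ch), function(c_i)
    complex(real = ks[[2 * c_i - 1]], imaginary = ks[[2 * c_i]]),
    complex(nrow(ks))))
  maps <- array(0i, c(meta$shape, n_ch))
  for (c_i in seq_len(n_ch))
    maps[, , , c_i] <- array(complex(real = mp[[2 * c_i - 1]],
                                     imaginary = mp[[2 * c_i]]), meta$shape)
  class(maps) <- c("coil_maps", class(maps))
  list(kspace = kspace_data(samples, weighted = isTRUE(meta$weighted)),
       traj = traj,
       dcf = structure(list(weights = dc$weight, scale = dc$scale[1]),
                       class = "radial_dcf"),
       maps = maps, meta = meta)
}

#' Serialize a block scheme to JSON (and back)
#'
#' @param scheme a `block_scheme`
#' @param path optional file; when NULL the JSON string is returned
#' @export
block_scheme_to_json <- function(scheme, path = NULL) {
  obj <- list(volume_shape = scheme$volume_shape, splits = scheme$splits,
              halo = scheme$halo, n_blocks = scheme$n_blocks,
              n_internal_faces = scheme$n_internal_faces,
              blocks = lapply(scheme$blocks, function(b)
                list(index = b$index, core = as.vector(b$core),
                     ext = as.vector(b$ext))))
  if (is.null(path)) jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  else { jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE); invisible(path) }
}

#' @rdname block_scheme_to_json
#' @param json JSON string or file path
#' @export
block_scheme_from_json <- function(json) {
  obj <- if (file.exists(json)) jsonlite::read_json(json, simplifyVector = TRUE)
  else jsonlite::fromJSON(json)
  plan_blocks(obj$volume_shape, obj$splits, obj$halo)
}

#' Save / load a trained unrolled model as JSON
#'
#' Stores the full configuration (channels, blocks, unrolls, scheme, seeds)
#' and the flattened parameter vector for exact reload.
#'
#' @param model an `unrolled_model`
#' @param path file path
#' @export
save_model <- function(model, path) {
  obj <- list(n_unrolls = model$n_unrolls,
              cfg = unclass(model$cfg),
              dc_enabled = model$dc_enabled,
              shared_weights = model$shared_weights,
              volume_shape = model$scheme$volume_shape,
              splits = model$scheme$splits, halo = model$scheme$halo,
              params = model_params(model))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(reg_config, obj$cfg[c("channels", "kernel", "n_res_blocks",
                                       "leaky_slope", "init_seed")])
  model <- unrolled_model(obj$n_unrolls, obj$volume_shape, splits = obj$splits,
                          cfg = cfg, dc_enabled = obj$dc_enabled,
                          shared_weights = obj$shared_weights,
                          halo = obj$halo)
  model_set_params(model, obj$params)
}
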