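#' Read a binary 3D volume
#'
#' Supports multi-page TIFF (one page per z-slice; within a page rows are y
#' and columns are x, so a file with 3 pages of 4 columns x 5 rows yields
#' dims `(4, 5, 3)`) and headerless raw uint8 volumes (x fastest, then y,
#' then z; `dims` required). Values must be 0/1 after reading unless a
#' `threshold` is given, in which case values strictly greater than the
#' threshold become solid (1).
#'
#' @param path input file; `.tif`/`.tiff` is treated as TIFF, anything else
#'   as raw uint8.
#' @param dims required for raw input: `(nx, ny, nz)`.
#' @param threshold optional binarization threshold on the raw values.
#' @param voxel_edge physical voxel edge to attach to the image.
#' @return a [pore_image()].
#' @export
read_volume <- function(path, dims = NULL, threshold = NULL, voxel_edge = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    nz <- length(pages)
    ny <- nrow(pages[[1L]])
    nx <- ncol(pages[[1L]])
    vals <- array(0, c(nx, ny, nz))
    for (z in seq_len(nz)) vals[, , z] <- t(pages[[z]])
  } else {
    if (is.null(dims))
      stop("raw volumes need explicit dims = c(nx, ny, nz)")
    dims <- as.integer(dims)
    expected <- prod(dims)
    if (file.size(path) != expected)
      stop("raw volume size mismatch: file has ", file.size(path),
           " bytes, dims imply ", expected)
    con <- file(path, "rb")
    on.exit(close(con))
    vals <- array(as.integer(readBin(con, "raw", n = expected)), dims)
  }
  if (!is.null(threshold)) vals <- (vals > threshold) * 1L
  pore_image(vals, voxel_edge = voxel_edge)
}

#' Write a binary 3D volume
#'
#' Inverse of [read_volume()]: multi-page 8-bit TIFF (z pages) or raw uint8.
#' Round-trips bit-exactly with [read_volume()].
#'
#' @param image a [pore_image()].
#' @param path output file; extension selects the format as in
#'   [read_volume()].
#' @return `path`, invisibly.
#' @export
write_volume <- function(image, path) {
  stopifnot(inherits(image, "pore_image"))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- lapply(seq_len(image$dims[3L]), function(z)
      t(matrix(image$values[, , z], image$dims[1L], image$dims[2L])) * 1.0)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(image$values), con)
  }
  invisible(path)
}

# fixed 12-significant-digit formatting so identical runs give byte-identical
# CSV output
.fmt12 <- function(x) {
  if (is.numeric(x) && !is.integer(x)) formatC(x, digits = 12, format = "g")
  else x
}

.write_csv12 <- function(df, path) {
  df[] <- lapply(df, .fmt12)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a voxel graph as an edge list and coordinate table
#'
#' Writes `<prefix>-edges.csv.gz` (columns `i, j`, 1-based node ids) and
#' `<prefix>-nodes.csv.gz` (columns `node, x, y, z`, 0-based voxel indices).
#'
#' @param graph a [build_voxel_graph()] result.
#' @param prefix output path prefix.
#' @return the two file paths, invisibly.
#' @export
write_graph <- function(graph, prefix) {
  stopifnot(inherits(graph, "voxel_graph"))
  ep <- paste0(prefix, "-edges.csv.gz")
  np <- paste0(prefix, "-nodes.csv.gz")
  con <- gzfile(ep)
  utils::write.csv(data.frame(i = graph$edges[, 1L], j = graph$edges[, 2L]),
                   con, row.names = FALSE, quote = FALSE)
  con <- gzfile(np)
  utils::write.csv(data.frame(node = seq_len(graph$n), graph$coords),
                   con, row.names = FALSE, quote = FALSE)
  invisible(c(edges = ep, nodes = np))
}

#' Write learned conductances as an edge-list CSV
#'
#' Columns `ball_i, ball_j, theta`.
#'
#' @param net a [build_ball_network()] result.
#' @param theta per-edge conductances (default: the stored ones).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_theta_csv <- function(net, path, theta = net$edges$theta) {
  .write_csv12(data.frame(ball_i = net$edges$i, ball_j = net$edges$j,
                          theta = theta), path)
}

#' Read a ball set from a CSV of x, y, z, r
#'
#' @param path CSV with columns `x, y, z, r` (voxel units).
#' @return a [ball_set()].
#' @export
read_balls_csv <- function(path) {
  df <- utils::read.csv(path)
  ball_set(as.matrix(df[, c("x", "y", "z")]), df$r)
}

#' @rdname read_balls_csv
#' @param balls a [ball_set()] to write.
#' @export
write_balls_csv <- function(balls, path) {
  stopifnot(inherits(balls, "ball_set"))
  .write_csv12(balls[, c("x", "y", "z", "r")], path)
}

#' Write the compound totals of a coupled run as CSV
#'
#' Columns `time` (seconds) and the five pool totals, at 12 significant
#' digits.
#'
#' @param record a [run_coupled()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_totals_csv <- function(record, path) {
  stopifnot(inherits(record, "decomposition_record"))
  .write_csv12(data.frame(time = record$times, record$totals), path)
}

#' Write a run manifest
#'
#' Every command-line run records exactly one manifest: the configuration
#' snapshot, seeds, package version, input checksums and the simulated time
#' span, as YAML.
#'
#' @param path output YAML path.
#' @param config named list: the configuration snapshot.
#' @param seeds named list or vector of seeds used.
#' @param inputs character vector of input file paths (md5-summed).
#' @param sim_start,sim_end simulated time span covered (seconds).
#' @return the manifest list, invisibly.
#' @export
run_manifest <- function(path, config = list(), seeds = list(),
                         inputs = character(), sim_start = NA,
                         sim_end = NA) {
  man <- list(
    package = "poresim",
    version = as.character(utils::packageVersion("poresim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    seeds = as.list(seeds),
    input_md5 = as.list(tools::md5sum(inputs)),
    sim_start = sim_start,
    sim_end = sim_end
  )
  yaml::write_yaml(man, path)
  invisible(man)
}

#' Run a full decomposition scenario from a YAML configuration
#'
#' Ties the modules together: builds (or loads) the geometry, constructs the
#' voxel graph, places the initial compounds, and runs the coupled
#' simulation. See `system.file("extdata", "example-scenario.yaml",
#' package = "poresim")` for the schema; all time steps are in seconds,
#' masses in ug C, rates in day^-1 and `D` in voxel^2 day^-1.
#'
#' @param cfg configuration list (as from [yaml::read_yaml()]) or a path to
#'   a YAML file.
#' @return a list with `record` ([run_coupled()] output), `graph`, `image`
#'   and the effective `cfg`.
#' @export
run_scenario <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  geo <- cfg$geometry
  image <- if (!is.null(geo$image)) {
    read_volume(geo$image, dims = geo$dims, threshold = geo$threshold)
  } else if (identical(geo$kind, "ball_packing")) {
    generate_ball_packing(dims = unlist(geo$dims),
                          n_balls = geo$n_balls %||% 20L,
                          radius_range = unlist(geo$radius_range %||% c(4, 8)),
                          porosity_target = geo$porosity,
                          seed = geo$seed)$image
  } else if (identical(geo$kind, "chain")) {
    chain_image(geo$length)
  } else if (identical(geo$kind, "slab")) {
    slab_image(unlist(geo$dims), thickness = geo$thickness %||% 2L)
  } else if (identical(geo$kind, "full_cube")) {
    full_pore_image(unlist(geo$dims))
  } else stop("unknown geometry specification")
  graph <- build_voxel_graph(image)

  init <- cfg$initial %||% list()
  dom <- init$dom %||% list()
  mb <- init$mb %||% list()
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  state0 <- initialize_scenario(
    graph,
    dom_total = num(dom$total) %||% 0,
    dom_placement = dom$placement %||% "first_layers",
    axis = dom$axis %||% "z",
    n_layers = dom$n_layers %||% 2L,
    n_spots = mb$n_spots %||% 0L,
    mb_total = num(mb$total),
    cells = num(mb$cells), mass_per_cell = num(mb$mass_per_cell),
    som_total = num(init$som_total) %||% 0,
    fom_total = num(init$fom_total) %||% 0,
    seed = mb$seed %||% cfg$seed
  )
  bio <- do.call(bio_params,
                 (cfg$bio %||% list())[intersect(names(cfg$bio),
                                                 names(formals(bio_params)))])
  dif <- cfg$diffusion %||% list()
  trf <- cfg$transformation %||% list()
  record <- run_coupled(
    state0, graph, bio,
    D = dif$D %||% 100950,
    dt_diffusion = dif$dt %||% 30,
    dt_transformation = trf$dt %||% 30,
    duration = cfg$duration %||% 0,
    cadence = cfg$cadence %||% 3600,
    scheme = dif$scheme %||% "implicit",
    mode = trf$mode %||% "asynchronous",
    record_layers = cfg$record_layers
  )
  list(record = record, graph = graph, image = image, cfg = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
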