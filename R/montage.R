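#' Default 16-channel sensorimotor montage
#'
#' Sixteen 10-20 locations covering the sensorimotor cortex: a 5 x 3 grid
#' of fronto-central, central and centro-parietal electrodes plus one
#' configurable extra channel (default `"Fz"`).
#'
#' @param extra label of the 16th channel.
#' @return character vector of 16 channel labels.
#' @export
default_montage <- function(extra = "Fz") {
  c("FC3", "FC1", "FCz", "FC2", "FC4",
    "C3",  "C1",  "Cz",  "C2",  "C4",
    "CP3", "CP1", "CPz", "CP2", "CP4",
    extra)
}

#' Default Laplacian neighbor map
#'
#' Orthogonal nearest neighbors on the 5 x 3 sensorimotor grid (e.g.
#' `Cz` is surrounded by `FCz`, `CPz`, `C1` and `C2`). Channels outside
#' the grid (the configurable extra) get an empty neighbor list and pass
#' through the spatial filter unchanged. The map is a named list of
#' character vectors and can be edited or loaded from JSON with
#' [read_laplacian()].
#'
#' @param channels montage labels; defaults to [default_montage()].
#' @return named list mapping each channel to its neighbor labels.
#' @export
default_laplacian <- function(channels = default_montage()) {
  grid <- matrix(c("FC3", "FC1", "FCz", "FC2", "FC4",
                   "C3",  "C1",  "Cz",  "C2",  "C4",
                   "CP3", "CP1", "CPz", "CP2", "CP4"),
                 nrow = 3, byrow = TRUE)
  nb <- list()
  for (r in 1:3) for (c in 1:5) {
    n <- character()
    if (r > 1) n <- c(n, grid[r - 1, c])
    if (r < 3) n <- c(n, grid[r + 1, c])
    if (c > 1) n <- c(n, grid[r, c - 1])
    if (c < 5) n <- c(n, grid[r, c + 1])
    nb[[grid[r, c]]] <- n
  }
  out <- lapply(channels, function(ch) {
    v <- nb[[ch]]
    if (is.null(v)) character() else intersect(v, channels)
  })
  names(out) <- channels
  out
}

#' Read / write a Laplacian neighbor map as JSON
#'
#' @param path file path.
#' @return `read_laplacian()` returns a named list of neighbor vectors.
#' @export
read_laplacian <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(m, as.character)
}

#' @rdname read_laplacian
#' @param map neighbor map (named list).
#' @export
write_laplacian <- function(map, path) {
  jsonlite::write_json(map, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Topographic/spectral region specification
#'
#' The two topographic regions conventionally used to summarize
#' sensorimotor discriminancy: `lateral` (FC3, FC4, C3, C4, CP3, CP4) and
#' `medial` (FCz, Cz, CPz), crossed with the `mu` (8-14 Hz) or `beta`
#' (22-32 Hz) band. A band labeled `f` covers `[f - 1, f + 1)` Hz, so the
#' beta region comprises the 2 Hz bins 22, 24, ..., 32 (6 bins) and mu the
#' bins 8, 10, 12, 14 (4 bins).
#'
#' @param name `"medial"` or `"lateral"`.
#' @param band `"mu"` or `"beta"`.
#' @return object of class `region_spec` with `channels` and `bins`.
#' @export
region_spec <- function(name = c("medial", "lateral"), band = c("beta", "mu")) {
  name <- match.arg(name)
  band <- match.arg(band)
  channels <- switch(name,
    medial  = c("FCz", "Cz", "CPz"),
    lateral = c("FC3", "FC4", "C3", "C4", "CP3", "CP4"))
  bins <- switch(band, mu = seq(8, 14, by = 2), beta = seq(22, 32, by = 2))
  structure(list(name = name, band = band, channels = channels, bins = bins),
            class = "region_spec")
}
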