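#' Read a pharmacophore from JSON
#'
#' Reads the interchange JSON format used by pharmacophore search tools: an
#' object with a `points` array of `{name, x, y, z, radius}` entries. Class
#' names must be spelled exactly as in [FEATURE_CLASSES]. A missing radius
#' defaults to 1 Angstrom.
#'
#' @param path Path to a JSON file.
#' @return A [pharmacophore()].
#' @export
read_pharmacophore <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  pts <- obj$points
  if (is.null(pts)) stop("JSON has no 'points' array")
  points <- lapply(pts, function(p) {
    if (is.null(p$name)) stop("point without class name")
    if (is.null(p$x) || is.null(p$y) || is.null(p$z)) {
      stop("point without full coordinates")
    }
    radius <- if (is.null(p$radius)) 1.0 else as.numeric(p$radius)
    latent <- if (is.null(p$latent)) NULL else as.numeric(unlist(p$latent))
    pharm_point(p$name, c(p$x, p$y, p$z), radius = radius, latent = latent)
  })
  name <- if (is.null(obj$name)) basename(path) else obj$name
  pharmacophore(points, name = name)
}

#' Write a pharmacophore to JSON
#'
#' Inverse of [read_pharmacophore()]; the write-read round trip preserves
#' classes, coordinates and radii. Latent vectors, when present, are
#' carried in a `latent` field per point.
#'
#' @param ph A [pharmacophore()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pharmacophore <- function(ph, path) {
  stopifnot(inherits(ph, "pharmacophore"))
  pts <- lapply(ph$points, function(p) {
    out <- list(name = p$cls,
                x = p$position[1], y = p$position[2], z = p$position[3],
                radius = p$radius, enabled = TRUE)
    if (!is.null(p$latent)) out$latent <- p$latent
    out
  })
  obj <- list(name = ph$name, points = pts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
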