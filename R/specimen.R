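# Point-cloud specimen generators and SMLM localization import.

#' Construct a point cloud from coordinates
#'
#' Low-level constructor for custom specimens: takes an n x 3 matrix of
#' (x, y, z) emitter coordinates in micrometres (specimen-centred), optional
#' strictly positive brightness weights (default 1) and an optional
#' bounding box (defaults to the coordinate extent).
#'
#' @param positions n x 3 numeric matrix (x, y, z) in um, or NULL for an
#'   empty cloud.
#' @param weights per-emitter brightness weights.
#' @param bounds 2 x 3 bounding box (rows min, max).
#' @return a [PointCloud-class]
#' @export
newPointCloud <- function(positions, weights = NULL, bounds = NULL) {
  if (is.null(positions) || length(positions) == 0L)
    positions <- matrix(numeric(0), 0, 3)
  positions <- as.matrix(positions)
  colnames(positions) <- c("x", "y", "z")
  if (is.null(weights)) weights <- rep(1, nrow(positions))
  if (is.null(bounds)) {
    if (nrow(positions) == 0L) {
      bounds <- matrix(0, 2, 3)
    } else {
      bounds <- rbind(apply(positions, 2, min), apply(positions, 2, max))
    }
  }
  dimnames(bounds) <- list(c("min", "max"), c("x", "y", "z"))
  new("PointCloud", positions = positions, weights = weights, bounds = bounds)
}

#' Generate a sphere-bounded uniform point cloud
#'
#' Draws \code{nPoints} emitters uniformly inside a sphere of the given
#' radius centred at the specimen origin, by rejection sampling from the
#' enclosing cube. The mean distance from the centre of a uniform-in-ball
#' sample converges to \code{3*radius/4}.
#'
#' @param nPoints number of emitters (>= 0).
#' @param radius sphere radius in micrometres (default 5, matching the
#'   simulated spherical specimens).
#' @param seed integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @return a [PointCloud-class]
#' @examples
#' cl <- generateSphereCloud(1000, radius = 5, seed = 7)
#' max(sqrt(rowSums(positions(cl)^2)))  # <= 5
#' @export
generateSphereCloud <- function(nPoints, radius = 5, seed = 1L) {
  nPoints <- checkCount(nPoints, "nPoints")
  if (!is.numeric(radius) || radius <= 0) stop("radius must be positive")
  bounds <- rbind(min = rep(-radius, 3), max = rep(radius, 3))
  if (nPoints == 0L) return(newPointCloud(NULL, bounds = bounds))
  pos <- withSeed(seed, {
    out <- matrix(NA_real_, nPoints, 3)
    got <- 0L
    while (got < nPoints) {
      m <- ceiling((nPoints - got) * 2)
      cand <- matrix(stats::runif(3 * m, -radius, radius), m, 3)
      keep <- rowSums(cand^2) <= radius^2
      cand <- cand[keep, , drop = FALSE]
      take <- min(nrow(cand), nPoints - got)
      if (take > 0) {
        out[(got + 1L):(got + take), ] <- cand[seq_len(take), , drop = FALSE]
        got <- got + take
      }
    }
    out
  })
  newPointCloud(pos, bounds = bounds)
}

#' Generate a chromatin-like confined random-walk point cloud
#'
#' Emulates a dense, filamentous, laterally bounded chromatin structure as a
#' confined 3D random walk with fixed step length: emitters sit at every walk
#' vertex, consecutive emitters are exactly \code{step} apart, and the walk
#' is confined to \code{|x|,|y| <= boxSide/2} and \code{|z| <= zExtent}.
#' Steps that would leave the box are redrawn (rejection), which preserves
#' both the confinement and the exact step length.
#'
#' @param nPoints number of emitters (>= 1).
#' @param boxSide lateral bounding square side in micrometres (default 16).
#' @param step walk step length in micrometres (default 0.05).
#' @param seed integer seed.
#' @param zExtent axial half-extent of the confinement in micrometres
#'   (default 2).
#' @return a [PointCloud-class]
#' @export
generateChromatinCloud <- function(nPoints, boxSide = 16, step = 0.05,
                                   seed = 1L, zExtent = 2) {
  nPoints <- checkCount(nPoints, "nPoints")
  if (nPoints < 1L) stop("nPoints must be at least 1")
  if (boxSide <= 0 || step <= 0) stop("boxSide and step must be positive")
  if (step > boxSide)
    stop("infeasible confinement: step exceeds boxSide")
  half <- boxSide / 2
  pos <- withSeed(seed, {
    out <- matrix(0, nPoints, 3)
    cur <- c(0, 0, 0)
    for (i in seq_len(nPoints)[-1]) {
      repeat {
        v <- stats::rnorm(3)
        v <- v / sqrt(sum(v^2)) * step
        cand <- cur + v
        if (abs(cand[1]) <= half && abs(cand[2]) <= half &&
            abs(cand[3]) <= zExtent) break
      }
      cur <- cand
      out[i, ] <- cur
    }
    out
  })
  bounds <- rbind(min = c(-half, -half, -zExtent),
                  max = c(half, half, zExtent))
  newPointCloud(pos, bounds = bounds)
}

#' Read an SMLM-style localization table
#'
#' Reads a comma-separated localization table with a header naming \code{x},
#' \code{y} and \code{z} columns (case-insensitive; extra columns ignored),
#' converts coordinates to micrometres and re-centres them on the specimen
#' origin (the midpoint of the bounding box).
#'
#' @param path CSV file path.
#' @param unit unit of the stored coordinates, \code{"nm"} or \code{"um"}.
#' @return a [PointCloud-class]
#' @export
readSmlmCsv <- function(path, unit = c("nm", "um")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  names(df) <- tolower(trimws(names(df)))
  need <- c("x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("empty data section in ", path, "; returning an empty cloud")
    return(newPointCloud(NULL))
  }
  for (col in need) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) | is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at data line %d",
        col, bad[1]))
    df[[col]] <- v
  }
  pos <- as.matrix(df[, need])
  if (unit == "nm") pos <- pos / 1000
  ctr <- (apply(pos, 2, min) + apply(pos, 2, max)) / 2
  pos <- sweep(pos, 2, ctr)
  newPointCloud(pos)
}

#' Write a point cloud as an SMLM-style CSV
#'
#' Inverse of [readSmlmCsv()]: writes \code{x,y,z} columns in the requested
#' unit. Round-tripping preserves coordinates to well below 1e-9 um.
#'
#' @param cloud a [PointCloud-class]
#' @param path output CSV path.
#' @param unit output unit, \code{"nm"} or \code{"um"}.
#' @return the path, invisibly
#' @export
writeSmlmCsv <- function(cloud, path, unit = c("nm", "um")) {
  unit <- match.arg(unit)
  stopifnot(is(cloud, "PointCloud"))
  pos <- positions(cloud)
  if (unit == "nm") pos <- pos * 1000
  df <- as.data.frame(pos)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
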