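# Electrode montages: construction, .sfp I/O, sphere fitting, synthetic nets.

#' Electrode montage
#'
#' A montage holds channel labels and 3D sensor positions (head frame,
#' millimetres), optionally together with the best-fitting sphere computed by
#' [fit_sphere()].
#'
#' @param labels character vector of unique channel names.
#' @param positions numeric matrix, channels x 3, positions in mm.
#' @param fitted_sphere optional list with elements `center` (length-3, mm)
#'   and `radius` (mm) as produced by [fit_sphere()].
#' @return an object of class `electrode_montage`.
#' @export
electrode_montage <- function(labels, positions, fitted_sphere = NULL) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (length(labels) != nrow(positions))
    stop_fmt("%d labels but %d positions", length(labels), nrow(positions))
  if (anyDuplicated(labels))
    stop_fmt("duplicate channel label: %s", labels[duplicated(labels)][1])
  if (!all(is.finite(positions)))
    stop_fmt("non-finite electrode coordinates")
  if (ncol(positions) != 3L)
    stop_fmt("positions must be channels x 3")
  rownames(positions) <- labels
  structure(list(labels = as.character(labels), positions = positions,
                 fitted_sphere = fitted_sphere),
            class = "electrode_montage")
}

#' @export
print.electrode_montage <- function(x, ...) {
  cat(sprintf("<electrode_montage> %d channels", length(x$labels)))
  if (!is.null(x$fitted_sphere))
    cat(sprintf(", fitted sphere r = %.1f mm", x$fitted_sphere$radius))
  cat("\n")
  invisible(x)
}

#' Read / write electrode positions in .sfp format
#'
#' One line per channel: `label x y z` (mm, whitespace separated). Fiducial
#' rows whose label starts with `Fid` are skipped on reading.
#'
#' @param path file path.
#' @return [read_montage()] returns an `electrode_montage`.
#' @export
read_montage <- function(path) {
  tab <- tryCatch(
    read.table(path, header = FALSE, col.names = c("label", "x", "y", "z"),
               colClasses = c("character", "numeric", "numeric", "numeric")),
    warning = function(w) stop_fmt("malformed .sfp file '%s': %s", path, conditionMessage(w)),
    error = function(e) stop_fmt("malformed .sfp file '%s': %s", path, conditionMessage(e)))
  keep <- !grepl("^Fid", tab$label)
  tab <- tab[keep, , drop = FALSE]
  if (anyDuplicated(tab$label))
    stop_fmt("duplicate channel label in '%s': %s", path,
             tab$label[duplicated(tab$label)][1])
  electrode_montage(tab$label, as.matrix(tab[, c("x", "y", "z")]))
}

#' @rdname read_montage
#' @param montage an `electrode_montage`.
#' @export
write_montage <- function(montage, path) {
  stopifnot(inherits(montage, "electrode_montage"))
  df <- data.frame(label = montage$labels,
                   x = montage$positions[, 1],
                   y = montage$positions[, 2],
                   z = montage$positions[, 3])
  # full double precision so a round trip is bit-identical
  lines <- sprintf("%s %.17g %.17g %.17g", df$label, df$x, df$y, df$z)
  writeLines(lines, path)
  invisible(path)
}

#' Generate a quasi-uniform synthetic sensor net
#'
#' Places `n_channels` points quasi-uniformly (Fibonacci lattice) on the upper
#' portion of a sphere of the given radius, leaving out the cheek/neck region
#' (the cap covers ~2.7 pi steradians). Stands in for a high-density geodesic
#' net whose face/neck sensors are excluded from analysis.
#'
#' @param n_channels number of electrodes (>= 16).
#' @param radius sphere radius in mm.
#' @param seed integer seed (the lattice is deterministic; the seed fixes the
#'   azimuthal phase so distinct seeds give distinct but equivalent nets).
#' @return an `electrode_montage` with labels `E1...En`.
#' @export
generate_montage <- function(n_channels = 204, radius = 90, seed = 1) {
  if (n_channels < 16L) stop_fmt("n_channels must be >= 16, got %d", n_channels)
  # cap: area 2.7*pi sr  =>  z/r in [cos(theta_max), 1], 1 - cos = 1.35
  zmin <- 1 - 1.35
  i <- seq_len(n_channels)
  z <- 1 - (i - 0.5) / n_channels * (1 - zmin)         # uniform in area
  golden <- pi * (3 - sqrt(5))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  phase <- runif(1, 0, 2 * pi)
  phi <- phase + golden * i
  rho <- sqrt(pmax(0, 1 - z^2))
  pos <- radius * cbind(rho * cos(phi), rho * sin(phi), z)
  electrode_montage(paste0("E", i), pos)
}

#' Fit the best sphere to a montage and project electrodes onto it
#'
#' Least-squares sphere fit (algebraic form, exact for noiseless data)
#' followed by radial projection of every electrode onto the fitted surface.
#'
#' @param montage an `electrode_montage`.
#' @return the montage with `fitted_sphere` set and `positions` projected.
#' @export
fit_sphere <- function(montage) {
  stopifnot(inherits(montage, "electrode_montage"))
  P <- montage$positions
  if (nrow(P) < 4L) stop_fmt("sphere fit needs >= 4 electrodes")
  # |x|^2 = 2 c.x + (R^2 - |c|^2): linear in (c, k)
  A <- cbind(2 * P, 1)
  if (qr(A)$rank < 4L) stop_fmt("electrodes are coplanar; cannot fit a sphere")
  b <- rowSums(P^2)
  sol <- qr.solve(A, b)
  center <- sol[1:3]
  radius <- sqrt(sol[4] + sum(center^2))
  rel <- sweep(P, 2L, center, "-")
  d <- sqrt(rowSums(rel^2))
  proj <- sweep(rel, 1L, radius / d, "*")
  proj <- sweep(proj, 2L, center, "+")
  rownames(proj) <- montage$labels
  montage$positions <- proj
  montage$fitted_sphere <- list(center = unname(center), radius = unname(radius))
  montage
}
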