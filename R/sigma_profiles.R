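# sigma-profiles as discrete histograms: a uniform sigma grid (e/A^2) with a
# non-negative area weight per grid point. "Area under the curve" is summation
# of per-point weights, exact for gridded data.

#' Construct a sigma-profile
#'
#' A sigma-profile is the histogram of a molecule's COSMO screening-charge
#' density over its surface: for each value of sigma (e/A^2) on a uniform
#' grid, the surface area (A^2) carrying that polarity. The ordinate stored
#' here is always an *area weight* per grid point, so downstream integration
#' is plain summation.
#'
#' @param sigma Numeric vector of screening-charge densities (e/A^2),
#'   strictly increasing on a uniform grid (relative tolerance 1e-9).
#' @param p Numeric vector of non-negative area weights (A^2), same length
#'   as `sigma`.
#' @param name Constituent identifier.
#' @return An object of class `sigma_profile` with fields `name`, `sigma`,
#'   `p` and `grid_spacing` (NA for a single-point profile).
#' @seealso [read_sigma_profile()], [integrate_descriptors()], [total_area()]
#' @export
sigma_profile <- function(sigma, p, name = "profile") {
  if (!is.numeric(sigma) || !is.numeric(p))
    stop("sigma and p must be numeric")
  if (length(sigma) != length(p))
    stop("sigma and p must have the same length")
  if (length(sigma) == 0L)
    stop("empty profile")
  if (any(!is.finite(sigma)))
    stop("non-finite sigma value at row ", which(!is.finite(sigma))[1L])
  if (any(!is.finite(p)))
    stop("non-finite ordinate at row ", which(!is.finite(p))[1L])
  if (any(p < 0))
    stop("negative ordinate at row ", which(p < 0)[1L])
  spacing <- NA_real_
  if (length(sigma) > 1L) {
    d <- diff(sigma)
    if (any(d <= 0))
      stop("sigma grid not strictly increasing at row ", which(d <= 0)[1L] + 1L)
    spacing <- mean(d)
    bad <- which(abs(d - spacing) / spacing > 1e-9)
    if (length(bad))
      stop("sigma grid not uniform at row ", bad[1L] + 1L)
  }
  structure(
    list(name = as.character(name), sigma = as.numeric(sigma),
         p = as.numeric(p), grid_spacing = spacing),
    class = "sigma_profile"
  )
}

#' @export
print.sigma_profile <- function(x, ...) {
  cat(sprintf("sigma-profile '%s': %d points, sigma in [%g, %g] e/A^2, total area %.4g A^2\n",
              x$name, length(x$sigma), min(x$sigma), max(x$sigma), total_area(x)))
  invisible(x)
}

#' Read a sigma-profile from a two-column text file
#'
#' The file holds one grid point per line: sigma (e/A^2) then the ordinate,
#' separated by whitespace or commas; lines starting with `#` are comments.
#' COSMO exports differ in whether the ordinate is already an area per grid
#' point or an area *density* p(sigma); the convention must be declared and
#' is never guessed. Under `"density"` each ordinate is multiplied by the
#' grid spacing so that stored values are always areas.
#'
#' @param path File to read.
#' @param area_convention `"area"` (ordinate is area per grid point) or
#'   `"density"` (ordinate is area density; requires >= 2 grid points).
#' @param name Constituent identifier; defaults to the file name without
#'   extension.
#' @param sort Sort rows by sigma before validation. Default `FALSE`: an
#'   out-of-order grid is then a hard error naming the offending row.
#' @return A [sigma_profile()].
#' @export
read_sigma_profile <- function(path,
                               area_convention = c("area", "density"),
                               name = NULL, sort = FALSE) {
  area_convention <- match.arg(area_convention)
  if (!file.exists(path))
    stop("no such file: ", path)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (!length(rows))
    stop("no data rows in ", path)
  sigma <- numeric(length(rows))
  p <- numeric(length(rows))
  for (i in seq_along(rows)) {
    fields <- strsplit(trimws(lines[rows[i]]), "[,[:space:]]+")[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2L || any(is.na(vals[1:2])))
      stop("cannot parse two numeric columns at ", path, " row ", rows[i])
    sigma[i] <- vals[1L]
    p[i] <- vals[2L]
  }
  if (any(p < 0))
    stop("negative ordinate at ", path, " row ", rows[which(p < 0)[1L]])
  if (sort) {
    o <- order(sigma)
    sigma <- sigma[o]
    p <- p[o]
  }
  prof <- tryCatch(
    sigma_profile(sigma, p, name = name),
    error = function(e) stop("invalid profile in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (area_convention == "density") {
    if (is.na(prof$grid_spacing))
      stop("density convention needs >= 2 grid points to infer spacing: ", path)
    prof$p <- prof$p * prof$grid_spacing
  }
  prof
}

#' Write a sigma-profile to a two-column text file
#'
#' Inverse of [read_sigma_profile()] under the `"area"` convention; full
#' double precision (17 significant digits) so a round trip is bitwise exact.
#'
#' @param profile A [sigma_profile()].
#' @param path Output file.
#' @export
write_sigma_profile <- function(profile, path) {
  stopifnot(inherits(profile, "sigma_profile"))
  lines <- c(sprintf("# sigma-profile: %s", profile$name),
             "# sigma_e_per_A2  area_A2",
             sprintf("%.17g %.17g", profile$sigma, profile$p))
  writeLines(lines, path)
  invisible(path)
}

#' Total surface area of a sigma-profile
#'
#' Sum of the per-point area weights; the conserved quantity that
#' [integrate_descriptors()] redistributes over the ten regions.
#'
#' @param profile A [sigma_profile()].
#' @return Total area (A^2).
#' @export
total_area <- function(profile) {
  stopifnot(inherits(profile, "sigma_profile"))
  sum(profile$p)
}

#' Region boundaries of the ten S-descriptors
#'
#' Eleven edges from -0.025 to +0.025 e/A^2 in steps of 0.005, delimiting
#' the ten descriptor regions.
#'
#' @return Numeric vector of length 11.
#' @export
descriptor_region_edges <- function() {
  seq(-0.025, 0.025, by = 0.005)
}

#' Construct a descriptor vector
#'
#' @param S Ten non-negative region areas S1..S10 (A^2).
#' @param truncated_mass Profile area found outside \[-0.025, +0.025\] e/A^2.
#' @param name Identifier carried over from the source profile or mixture.
#' @return Object of class `descriptor_vector` with fields `S` (named
#'   S1..S10), `region_edges`, `truncated_mass`, `name`.
#' @export
descriptor_vector <- function(S, truncated_mass = 0, name = "") {
  S <- as.numeric(S)
  if (length(S) != 10L)
    stop("a descriptor vector has exactly 10 values, got ", length(S))
  if (any(!is.finite(S)) || any(S < -1e-12))
    stop("descriptor values must be finite and non-negative")
  S[S < 0] <- 0
  names(S) <- paste0("S", 1:10)
  structure(
    list(S = S, region_edges = descriptor_region_edges(),
         truncated_mass = as.numeric(truncated_mass), name = as.character(name)),
    class = "descriptor_vector"
  )
}

#' @export
print.descriptor_vector <- function(x, ...) {
  cat(sprintf("S-descriptors '%s' (A^2):\n", x$name))
  print(round(x$S, 4))
  if (x$truncated_mass > 0)
    cat(sprintf("  truncated mass outside +/-0.025 e/A^2: %.4g A^2\n",
                x$truncated_mass))
  invisible(x)
}

#' Integrate a sigma-profile into the ten S-descriptors
#'
#' The sigma axis is divided into 10 contiguous regions of width
#' 0.005 e/A^2 covering -0.025 to +0.025 e/A^2, and the area in each region
#' is summed into S1..S10. A grid point lying exactly (within `edge_tol`) on
#' an interior boundary is split evenly between the two neighbouring
#' regions; points exactly at -0.025 or +0.025 belong wholly to regions 1
#' and 10. Mass strictly outside the range is accumulated in
#' `truncated_mass` with a warning and is never folded into the edge
#' regions, since silently reassigning tail mass would bias the descriptors.
#'
#' @param profile A [sigma_profile()].
#' @param edge_tol Absolute tolerance for "exactly on a boundary".
#' @return A [descriptor_vector()]; `sum(S) + truncated_mass` equals
#'   [total_area()] of the input to 1e-9 relative.
#' @export
integrate_descriptors <- function(profile, edge_tol = 1e-12) {
  stopifnot(inherits(profile, "sigma_profile"))
  edges <- descriptor_region_edges()
  S <- numeric(10L)
  truncated <- 0
  sig <- profile$sigma
  w <- profile$p
  for (i in seq_along(sig)) {
    s <- sig[i]
    a <- w[i]
    if (a == 0) next
    if (abs(s - edges[1L]) <= edge_tol) {
      S[1L] <- S[1L] + a
    } else if (abs(s - edges[11L]) <= edge_tol) {
      S[10L] <- S[10L] + a
    } else if (s < edges[1L] || s > edges[11L]) {
      truncated <- truncated + a
    } else {
      hit <- which(abs(s - edges[2:10]) <= edge_tol)
      if (length(hit)) {
        # interior boundary: evenly split between the two adjoining regions
        j <- hit[1L]
        S[j] <- S[j] + a / 2
        S[j + 1L] <- S[j + 1L] + a / 2
      } else {
        S[findInterval(s, edges)] <- S[findInterval(s, edges)] + a
      }
    }
  }
  if (truncated > 0)
    warning(sprintf("profile '%s': %.6g A^2 of area outside [-0.025, 0.025] e/A^2 excluded from descriptors",
                    profile$name, truncated))
  descriptor_vector(S, truncated_mass = truncated, name = profile$name)
}

#' Write a table of descriptor vectors to CSV
#'
#' @param descriptors List of [descriptor_vector()] objects.
#' @param path Output CSV with columns name, S1..S10, truncated_mass.
#' @export
write_descriptor_table <- function(descriptors, path) {
  df <- descriptor_table(descriptors)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Collect descriptor vectors into a data frame
#'
#' @param descriptors List of [descriptor_vector()] objects.
#' @return Data frame with columns name, S1..S10, truncated_mass.
#' @export
descriptor_table <- function(descriptors) {
  stopifnot(length(descriptors) > 0)
  rows <- lapply(descriptors, function(d) {
    stopifnot(inherits(d, "descriptor_vector"))
    c(list(name = d$name), as.list(d$S), list(truncated_mass = d$truncated_mass))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
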