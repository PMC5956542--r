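#' @include AllClasses.R
NULL

#' Domain specification constructor
#'
#' @param width,height full-medium extent (cm).
#' @param roiX,roiY region-of-interest intervals (cm).
#' @param dx,dy export grid spacing (cm).
#' @return a \linkS4class{DomainSpec}.
#' @examples
#' d <- domainSpec()
#' diff(d@roiX) / d@dx  # 200 lateral cells
#' @export
domainSpec <- function(width = 5, height = 5, roiX = c(0, 2.5),
                       roiY = c(0, 5), dx = 0.0125, dy = 0.0125) {
  new("DomainSpec", width = width, height = height, roiX = roiX, roiY = roiY,
      dx = dx, dy = dy)
}

#' Material constructors
#'
#' \code{liverMaterial} is the background liver-mimicking solid
#' (rho = 1200 kg/m^3, nu = 0.499, E = 6 kPa, shear speed about 1.29 m/s);
#' \code{bloodMaterial} the nearly stress-free blood-mimicking crack filler
#' (rho = 1060 kg/m^3, nu = 0.499, E = 0.005 Pa).
#'
#' @param density kg/m^3.
#' @param poisson Poisson's ratio.
#' @param young Young's modulus (Pa).
#' @return a \linkS4class{MaterialSpec}.
#' @export
materialSpec <- function(density, poisson, young) {
  new("MaterialSpec", density = density, poisson = poisson, young = young)
}

#' @rdname materialSpec
#' @export
liverMaterial <- function() materialSpec(1200, 0.499, 6000)

#' @rdname materialSpec
#' @export
bloodMaterial <- function() materialSpec(1060, 0.499, 0.005)

#' Derived elastic quantities
#'
#' @param material a \linkS4class{MaterialSpec}.
#' @return \code{shearModulus}: \eqn{\mu = E/(2(1+\nu))} in Pa;
#'   \code{shearSpeed}: \eqn{\sqrt{\mu/\rho}} in m/s.
#' @export
shearModulus <- function(material) {
  stopifnot(is(material, "MaterialSpec"))
  material@young / (2 * (1 + material@poisson))
}

#' @rdname shearModulus
#' @export
shearSpeed <- function(material) {
  sqrt(shearModulus(material) / material@density)
}

#' Crack geometry constructor
#'
#' Presets for the three study geometries:
#' \describe{
#'   \item{straight}{3.2 cm deep, 1.6 mm thick, inclined 15 degrees from the
#'     vertical, top edges at x = 1.354 and 1.519 cm.}
#'   \item{slim}{0.5 cm deep, 0.5 mm thick, same tilt and right edge as the
#'     straight crack, top edges at x = 1.467 and 1.519 cm.}
#'   \item{curved}{bounded by two arcs of radius 4.5 cm whose centres sit at
#'     the top-surface level at x = -3.146 and -2.981 cm; 1.8 cm tall, top
#'     edges at x = 1.354 and 1.519 cm.}
#'   \item{none}{homogeneous control (no crack).}
#' }
#'
#' @param shape one of \code{"straight"}, \code{"curved"}, \code{"slim"},
#'   \code{"none"}.
#' @return a \linkS4class{CrackSpec}.
#' @examples
#' rightEdgeX(crackSpec("straight"), 0)      # 1.519
#' rightEdgeX(crackSpec("curved"), 1.709)    # about 1.182
#' @export
crackSpec <- function(shape = c("straight", "curved", "slim", "none")) {
  shape <- match.arg(shape)
  tilt <- 15
  switch(shape,
    straight = new("CrackSpec", shape = shape, topLeftX = 1.354,
                   topRightX = 1.519, depth = 3.2,
                   thickness = 0.165 * cos(tilt * pi / 180), tilt = tilt,
                   radius = NA_real_, centerX = c(NA_real_, NA_real_)),
    slim = new("CrackSpec", shape = shape, topLeftX = 1.467,
               topRightX = 1.519, depth = 0.5,
               thickness = 0.052 * cos(tilt * pi / 180), tilt = tilt,
               radius = NA_real_, centerX = c(NA_real_, NA_real_)),
    curved = new("CrackSpec", shape = shape, topLeftX = 1.354,
                 topRightX = 1.519, depth = 1.8, thickness = 0.16,
                 tilt = NA_real_, radius = 4.5,
                 centerX = c(-3.146, -2.981)),
    none = new("CrackSpec", shape = shape, topLeftX = NA_real_,
               topRightX = NA_real_, depth = NA_real_, thickness = NA_real_,
               tilt = NA_real_, radius = NA_real_,
               centerX = c(NA_real_, NA_real_)))
}

.checkDepths <- function(crack, depth) {
  if (crack@shape == "none")
    stop("the homogeneous control has no crack edges")
  if (any(depth < -1e-12) || any(depth > crack@depth + 1e-12))
    stop("depth outside [0, ", crack@depth, "] cm")
}

#' Analytic crack edge positions
#'
#' Transverse (x) position of the crack's right (near-end, facing the push
#' rod artefact side) or left edge at a given depth. For the tilted
#' straight/slim cracks the edge recedes linearly,
#' \eqn{x(d) = x_{top} - d \tan(15^\circ)}; for the curved crack it follows
#' the bounding arc, \eqn{x(d) = x_c + \sqrt{r^2 - d^2}}.
#'
#' @param crack a \linkS4class{CrackSpec}.
#' @param depth depth(s) below the top surface (cm), within
#'   \code{[0, crack@depth]}.
#' @return edge position(s) in cm.
#' @examples
#' rightEdgeX(crackSpec("straight"), 2.917)  # about 0.738
#' leftEdgeX(crackSpec("slim"), 0)           # 1.467
#' @export
rightEdgeX <- function(crack, depth) {
  stopifnot(is(crack, "CrackSpec"))
  .checkDepths(crack, depth)
  if (crack@shape == "curved")
    crack@centerX[2] + sqrt(crack@radius^2 - depth^2)
  else
    crack@topRightX - depth * tan(crack@tilt * pi / 180)
}

#' @rdname rightEdgeX
#' @export
leftEdgeX <- function(crack, depth) {
  stopifnot(is(crack, "CrackSpec"))
  .checkDepths(crack, depth)
  if (crack@shape == "curved")
    crack@centerX[1] + sqrt(crack@radius^2 - depth^2)
  else
    crack@topLeftX - depth * tan(crack@tilt * pi / 180)
}

#' Horizontal thickness of a crack
#'
#' Horizontal gap between the two edges. For the straight and slim cracks
#' this is the constant top gap \code{topRightX - topLeftX} (the
#' perpendicular thickness times \code{1/cos(tilt)}). For the curved crack
#' the horizontal gap is also depth-independent (the two arcs are laterally
#' shifted copies), and that constant gap is returned.
#'
#' @param crack a \linkS4class{CrackSpec}.
#' @return gap in cm.
#' @examples
#' horizontalThickness(crackSpec("straight"))  # 0.165
#' @export
horizontalThickness <- function(crack) {
  stopifnot(is(crack, "CrackSpec"))
  if (crack@shape == "none") stop("no crack in the homogeneous control")
  if (crack@shape == "curved") diff(crack@centerX)
  else crack@topRightX - crack@topLeftX
}

#' Ground-truth edge table
#'
#' Analytic right-edge positions at the requested depths, the reference
#' ("given") column of the quantitative detection report.
#'
#' @param crack a \linkS4class{CrackSpec}.
#' @param depths depths (cm) within the crack extent.
#' @return data.frame with columns \code{depth}, \code{given_x} (cm),
#'   monotone in depth.
#' @export
groundTruthTable <- function(crack, depths) {
  if (length(depths) == 0)
    return(data.frame(depth = numeric(0), given_x = numeric(0)))
  depths <- sort(depths)
  data.frame(depth = depths, given_x = rightEdgeX(crack, depths))
}

#' Default report depths
#'
#' The depth rows at which detection reports are evaluated by default for
#' each geometry (the rows of the reference comparison table).
#'
#' @param shape crack shape.
#' @return numeric vector of depths (cm).
#' @export
defaultReportDepths <- function(shape) {
  switch(shape,
    straight = c(0.208, 0.291, 0.416, 0.917, 1.291, 1.709, 2.083, 2.500,
                 2.917),
    curved = c(0.208, 0.291, 0.416, 0.917, 1.291, 1.709),
    slim = c(0.208, 0.291, 0.416),
    stop("no default depths for shape '", shape, "'"))
}

#' Rasterize the phantom onto material maps
#'
#' Builds cell-centred density and shear-modulus grids over the full domain
#' at the given resolution, assigning the filler material to every cell
#' whose centre lies between the crack's left and right edge curves down to
#' the crack depth, and the background elsewhere.
#'
#' @param domain a \linkS4class{DomainSpec}.
#' @param crack a \linkS4class{CrackSpec} (\code{"none"} for the homogeneous
#'   control).
#' @param bg,filler background and crack \linkS4class{MaterialSpec}s.
#' @param resolution grid spacing (cm); must resolve the crack with at least
#'   three cells across its perpendicular thickness.
#' @return a \linkS4class{MaterialField}.
#' @examples
#' mf <- buildMaterialField(domainSpec(), crackSpec("none"))
#' range(mf@mu)  # uniform, about 2001.3 Pa
#' @export
buildMaterialField <- function(domain, crack, bg = liverMaterial(),
                               filler = bloodMaterial(),
                               resolution = domain@dx) {
  stopifnot(is(domain, "DomainSpec"), is(crack, "CrackSpec"))
  if (crack@shape != "none" && resolution > crack@thickness / 3 + 1e-12)
    stop("resolution too coarse for the crack: need <= ",
         signif(crack@thickness / 3, 3), " cm")
  x <- seq(resolution / 2, domain@width, by = resolution)
  y <- seq(resolution / 2, domain@height, by = resolution)
  nx <- length(x); ny <- length(y)
  dens <- matrix(bg@density, nx, ny)
  mu <- matrix(shearModulus(bg), nx, ny)
  mask <- matrix(FALSE, nx, ny)
  if (crack@shape != "none") {
    yin <- which(y <= crack@depth)
    xl <- leftEdgeX(crack, y[yin])
    xr <- rightEdgeX(crack, y[yin])
    for (k in seq_along(yin)) {
      j <- yin[k]
      inside <- x >= xl[k] & x <= xr[k]
      mask[inside, j] <- TRUE
    }
    dens[mask] <- filler@density
    mu[mask] <- shearModulus(filler)
  }
  new("MaterialField", x = x, y = y, density = dens, mu = mu, mask = mask,
      resolution = resolution, crack = crack)
}

#' Crack mask accessor
#'
#' @param field a \linkS4class{MaterialField}.
#' @return logical matrix marking filler cells.
#' @export
crackMask <- function(field) {
  stopifnot(is(field, "MaterialField"))
  field@mask
}
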