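# Ternary energy-flow construction: channel fractions and the fixed
# equilateral reference triangle.

.DEFAULT_ASSIGNMENT <- c(bacterial = "left", fungal = "right", plant = "apex")

#' The fixed energy-flow reference triangle
#'
#' Equilateral triangle with base from (0,0) to (100,0) and apex at
#' (50, 86.6): 100 sin(60 degrees) reported at the one-decimal convention
#' used for these plots, so that emitted coordinates match the published
#' frame exactly. Side midpoints and the centroid complete the seven-point
#' reference frame.
#'
#' @param apexY apex height; the default 86.6 is the one-decimal rounding
#'   of 100 sin(60).
#' @return an [EnergyTriangle-class].
#' @examples
#' referenceTriangle()
#' @export
referenceTriangle <- function(apexY = round(100 * sin(pi / 3), 1)) {
  v <- rbind(left = c(0, 0), right = c(100, 0), apex = c(50, apexY))
  colnames(v) <- c("x", "y")
  mid <- rbind(base = (v["left", ] + v["right", ]) / 2,
               leftSide = (v["left", ] + v["apex", ]) / 2,
               rightSide = (v["right", ] + v["apex", ]) / 2)
  new("EnergyTriangle", vertices = v, midpoints = mid,
      centroid = colMeans(v))
}

#' Seven-point reference frame of the triangle
#'
#' @param triangle an [EnergyTriangle-class].
#' @return data.frame of the 3 vertices, 3 side midpoints and centroid.
#' @export
referenceFrame <- function(triangle = referenceTriangle()) {
  pts <- rbind(triangle@vertices, triangle@midpoints,
               centroid = triangle@centroid)
  data.frame(point = rownames(pts), x = pts[, 1], y = pts[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Energy-channel fractions from metabolic footprints
#'
#' Divides the bacterivore, fungivore and plant-parasite footprints by
#' their three-channel sum, giving the relative weight of the bacterial,
#' fungal and plant energy channels. The omnivore-predator footprint is
#' excluded by default (the channel construction names only the three
#' basal channels); \code{opPolicy = "proportional"} folds OPMF into the
#' channels in proportion to the three fractions, which leaves the simplex
#' point unchanged but matters if the returned absolute fluxes are used.
#' A sample whose three-channel sum is zero gets NA fractions.
#'
#' @param footprints data.frame from [groupFootprints()].
#' @param opPolicy \code{"exclude"} (default) or \code{"proportional"}.
#' @return data.frame with \code{sample_id}, \code{f_bact},
#'   \code{f_fung}, \code{f_plant}.
#' @export
channelFractions <- function(footprints, opPolicy = c("exclude", "proportional")) {
  opPolicy <- match.arg(opPolicy)
  tot <- footprints$BFMF + footprints$FFMF + footprints$PPMF
  f <- function(v) ifelse(tot > 0, v / tot, NA_real_)
  data.frame(sample_id = footprints$sample_id,
             f_bact = f(footprints$BFMF), f_fung = f(footprints$FFMF),
             f_plant = f(footprints$PPMF),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Map channel fractions into the reference triangle
#'
#' Barycentric interpolation of the three vertices:
#' xy = f_bact * V_bacterial + f_fung * V_fungal + f_plant * V_plant.
#' The default channel-to-vertex assignment puts the bacterial channel at
#' the lower-left corner, the fungal channel at the lower-right corner
#' and the plant channel at the apex; it is a documented configuration,
#' not a fixed convention.
#'
#' @param fractions data.frame from [channelFractions()] (or any frame
#'   with \code{f_bact}, \code{f_fung}, \code{f_plant}).
#' @param triangle an [EnergyTriangle-class].
#' @param assignment named character vector mapping channels
#'   (\code{bacterial}, \code{fungal}, \code{plant}) to vertices
#'   (\code{left}, \code{right}, \code{apex}).
#' @return \code{fractions} with added \code{x}, \code{y} columns.
#' @export
ternaryToCartesian <- function(fractions, triangle = referenceTriangle(),
                               assignment = .DEFAULT_ASSIGNMENT) {
  stopifnot(setequal(names(assignment), c("bacterial", "fungal", "plant")),
            setequal(assignment, c("left", "right", "apex")))
  V <- triangle@vertices
  f <- as.matrix(fractions[, c("f_bact", "f_fung", "f_plant")])
  B <- rbind(V[assignment[["bacterial"]], ],
             V[assignment[["fungal"]], ],
             V[assignment[["plant"]], ])
  xy <- f %*% B
  fractions$x <- xy[, 1]
  fractions$y <- xy[, 2]
  fractions
}

#' Recover channel fractions from triangle coordinates
#'
#' Inverts the barycentric map by solving the 2x2 linear system; the
#' round-trip through [ternaryToCartesian()] is exact to numerical
#' precision within the printed frame.
#'
#' @param xy matrix or data.frame with \code{x}, \code{y} columns.
#' @inheritParams ternaryToCartesian
#' @return matrix with columns \code{f_bact}, \code{f_fung},
#'   \code{f_plant}.
#' @export
cartesianToTernary <- function(xy, triangle = referenceTriangle(),
                               assignment = .DEFAULT_ASSIGNMENT) {
  V <- triangle@vertices
  vb <- V[assignment[["bacterial"]], ]
  vf <- V[assignment[["fungal"]], ]
  vp <- V[assignment[["plant"]], ]
  A <- cbind(vb - vp, vf - vp)  # 2x2
  xy <- as.matrix(as.data.frame(xy)[, c("x", "y")])
  rhs <- t(xy) - vp
  sol <- solve(A, rhs)          # 2 x n
  out <- cbind(f_bact = sol[1, ], f_fung = sol[2, ],
               f_plant = 1 - sol[1, ] - sol[2, ])
  out
}
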