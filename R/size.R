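#' Metric size estimate from pixel measurements
#'
#' Converts a pixel-space bounding box plus triangulated distance into a
#' metric wingspan and height, `PW = D * pW * SIA / (f * y0)` (and likewise
#' `PH`), together with the isosceles-triangle area size measure
#' `Oapprox = PW * PH / 2`.
#'
#' @param pW,pH bounding-box width and height in pixels (`>= 0`).
#' @param D triangulated distance(s) in m (`> 0`).
#' @param intr a [camera_intrinsics()].
#' @return a data.frame with columns `PW`, `PH` (m) and `Oapprox` (m^2).
#' @examples
#' size_from_pixels(14, 6, 100, camera_intrinsics())
#' @export
size_from_pixels <- function(pW, pH, D, intr) {
  if (any(D <= 0)) stop("D must be positive")
  if (any(pW < 0) || any(pH < 0)) stop("pixel sizes must be non-negative")
  s <- intr$sia / (intr$f * intr$y0)
  PW <- D * pW * s
  PH <- D * pH * s
  data.frame(PW = PW, PH = PH, Oapprox = triangle_area(PW, PH))
}

#' Isosceles-triangle area size measure
#'
#' The one-number size measure: the area of the isosceles triangle whose
#' base is the wingspan and whose height is the body height,
#' `Oapprox = PW * PH / 2`.
#'
#' @param PW wingspan(s) in m (`>= 0`).
#' @param PH height(s) in m (`>= 0`).
#' @return area(s) in m^2.
#' @examples
#' triangle_area(1.1, 0.4)   # 0.22, the small/medium boundary
#' triangle_area(1.45, 0.66) # 0.4785, prints as 0.48
#' @export
triangle_area <- function(PW, PH) {
  if (any(PW < 0) || any(PH < 0)) stop("dimensions must be non-negative")
  PW * PH / 2
}

#' Class boundaries from reference species dimensions
#'
#' The small/medium and medium/large boundaries are the triangle areas of
#' two boundary species: by default the common buzzard (wingspan 1.1 m,
#' height 0.4 m, area 0.22 m^2) and the red kite (1.45 m, 0.66 m, area
#' 0.4785 m^2, conventionally printed as 0.48). The boundary areas are kept
#' at full precision by default.
#'
#' @param ref_small_to_medium numeric pair `(wingspan m, height m)` of the
#'   species marking the small/medium boundary.
#' @param ref_medium_to_large numeric pair for the medium/large boundary.
#' @param rounded if TRUE, round the boundary areas to 2 decimals (the
#'   conventional printed values 0.22 and 0.48).
#' @return an object of class `class_boundaries`: `list(Ob1, Ob2)` in m^2,
#'   `0 < Ob1 < Ob2`.
#' @examples
#' boundaries_from_species()
#' @export
boundaries_from_species <- function(ref_small_to_medium = c(1.1, 0.4),
                                    ref_medium_to_large = c(1.45, 0.66),
                                    rounded = FALSE) {
  if (any(ref_small_to_medium <= 0) || any(ref_medium_to_large <= 0)) {
    stop("species dimensions must be positive")
  }
  Ob1 <- triangle_area(ref_small_to_medium[1], ref_small_to_medium[2])
  Ob2 <- triangle_area(ref_medium_to_large[1], ref_medium_to_large[2])
  if (rounded) {
    Ob1 <- round_half_away(Ob1, 2)
    Ob2 <- round_half_away(Ob2, 2)
  }
  if (Ob1 >= Ob2) stop("degenerate boundaries: Ob1 must be < Ob2")
  structure(list(Ob1 = Ob1, Ob2 = Ob2), class = "class_boundaries")
}

#' @export
print.class_boundaries <- function(x, ...) {
  cat(sprintf("class_boundaries: Ob1 = %g m^2, Ob2 = %g m^2\n", x$Ob1, x$Ob2))
  invisible(x)
}

#' Classify a size measure into small/medium/large
#'
#' Partition of `[0, Inf)`: `small` on `[0, Ob1)`, `medium` on `[Ob1, Ob2)`,
#' `large` on `[Ob2, Inf)` -- objects exactly at a boundary fall into the
#' larger class, erring on the safe side for a hazard-monitoring
#' application.
#'
#' @param Oapprox triangle-area size measure(s) in m^2 (`>= 0`).
#' @param bounds a [boundaries_from_species()] object (default: the
#'   reference species boundaries).
#' @return a factor with ordered levels `small < medium < large`.
#' @examples
#' classify_size(c(0.035, 0.437, 1.156))
#' classify_size(c(0.22, 0.48)) # boundary values: medium, large
#' @export
classify_size <- function(Oapprox, bounds = boundaries_from_species()) {
  if (any(Oapprox < 0)) stop("Oapprox must be non-negative")
  factor(ifelse(Oapprox < bounds$Ob1, "small",
                ifelse(Oapprox < bounds$Ob2, "medium", "large")),
         levels = c("small", "medium", "large"), ordered = TRUE)
}
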