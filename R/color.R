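# Colour-space conversions and the CIEDE2000 colour difference.
#
# The pipeline works in CIE 1976 L*a*b* throughout: images are decoded from a
# display (power-law) encoding to linear RGB, mapped to CIE XYZ with the
# standard sRGB/D65 primary matrix, and converted to Lab against the D65
# white point. All per-image colour statistics are computed in Lab, never in
# gamma-encoded RGB.

#' D65 reference white
#'
#' Tristimulus values of the D65 white point with Y normalised to 1 (row sums
#' of the standard sRGB-to-XYZ matrix).
#'
#' @return named numeric vector `c(X, Y, Z)`.
#' @export
d65_white <- function() .D65

# standard linear sRGB (D65) -> XYZ matrix, IEC 61966-2-1
.RGB2XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE,
  dimnames = list(c("X", "Y", "Z"), c("R", "G", "B")))

# white as the exact row sums, so (1,1,1) maps onto it identically
.D65 <- c(X = sum(.RGB2XYZ[1, ]), Y = sum(.RGB2XYZ[2, ]),
          Z = sum(.RGB2XYZ[3, ]))

#' Decode display-encoded RGB to normalised linear RGB
#'
#' Inverts the power-law presentation transform (default exponent 0.42, the
#' plain-power stand-in for the sRGB curve used when rendering stimuli). The
#' piecewise sRGB electro-optical transfer function is available as an
#' alternative.
#'
#' @param x numeric vector/matrix/array of channel values; 8-bit integers in
#'   `[0, 255]` when `encoding = "8bit"`, reals in `[0, 1]` when
#'   `encoding = "unit"`.
#' @param power encoding exponent in `(0, 1]`; decoding raises to `1/power`.
#' @param encoding `"8bit"` or `"unit"`.
#' @param piecewise if `TRUE`, use the piecewise sRGB EOTF instead of the
#'   plain power law (`power` is then ignored).
#' @return object shaped like `x` with linear values in `[0, 1]`.
#' @export
decode_to_linear <- function(x, power = 0.42, encoding = c("8bit", "unit"),
                             piecewise = FALSE) {
  encoding <- match.arg(encoding)
  .check_scalar(power, "power", positive = TRUE)
  if (power > 1) stop("'power' must lie in (0, 1]", call. = FALSE)
  hi <- if (encoding == "8bit") 255 else 1
  v <- unclass(x)
  if (any(!is.finite(v)) || any(v < 0) || any(v > hi))
    stop(sprintf("channel values outside [0, %s]", hi), call. = FALSE)
  u <- v / hi
  out <- if (piecewise) {
    ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
  } else {
    u^(1 / power)
  }
  attributes(out) <- attributes(x)
  out
}

#' Encode linear RGB for presentation
#'
#' Forward power-law transform to 8-bit display values:
#' `round(255 * (x / max_brightness)^power)`. Values above `max_brightness`
#' are clipped with a warning.
#'
#' @param x numeric linear values, nominally in `[0, max_brightness]`.
#' @param max_brightness linear value mapped to 255.
#' @param power encoding exponent in `(0, 1]`.
#' @param piecewise if `TRUE`, use the piecewise sRGB OETF.
#' @return integer object shaped like `x`, values in `0:255`.
#' @export
to_presentation_rgb <- function(x, max_brightness = 1, power = 0.42,
                                piecewise = FALSE) {
  .check_scalar(max_brightness, "max_brightness", positive = TRUE)
  .check_scalar(power, "power", positive = TRUE)
  v <- unclass(x)
  if (any(!is.finite(v)) || any(v < 0))
    stop("linear values must be finite and >= 0", call. = FALSE)
  if (any(v > max_brightness)) {
    warning("linear values above max_brightness clipped", call. = FALSE)
    v <- pmin(v, max_brightness)
  }
  u <- v / max_brightness
  enc <- if (piecewise) {
    ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)
  } else {
    u^power
  }
  out <- as.integer(round(255 * enc))
  attributes(out) <- attributes(x)
  out
}

#' Linear RGB to CIE XYZ
#'
#' Applies the standard sRGB (D65) primary matrix; `(1, 1, 1)` maps to the
#' D65 white point with Y = 1.
#'
#' @param rgb linear RGB: length-3 vector, n x 3 matrix, or h x w x 3 array,
#'   channels in `[0, 1]`.
#' @return XYZ in the same shape.
#' @export
linear_rgb_to_xyz <- function(rgb) {
  d <- dim(rgb)
  m <- if (!is.null(d) && length(d) == 3L) .flatten_lab(rgb) else .as_color_matrix(rgb, "rgb")
  if (any(m < -1e-9) || any(m > 1 + 1e-9))
    stop("linear RGB channels must lie in [0, 1]", call. = FALSE)
  out <- m %*% t(.RGB2XYZ)
  .reshape_like(out, rgb, c("X", "Y", "Z"))
}

#' CIE XYZ to linear RGB
#'
#' Inverse of [linear_rgb_to_xyz()]; out-of-gamut colours yield channels
#' outside `[0, 1]` (not clipped).
#'
#' @param xyz XYZ colours (vector, matrix or array).
#' @return linear RGB in the same shape.
#' @export
xyz_to_linear_rgb <- function(xyz) {
  d <- dim(xyz)
  m <- if (!is.null(d) && length(d) == 3L) .flatten_lab(xyz) else .as_color_matrix(xyz, "xyz")
  out <- m %*% t(solve(.RGB2XYZ))
  .reshape_like(out, xyz, c("R", "G", "B"))
}

# f(t) of the CIE Lab definition and its inverse
.lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}
.lab_f_inv <- function(ft) {
  d <- 6 / 29
  ifelse(ft > d, ft^3, 3 * d^2 * (ft - 4 / 29))
}

.reshape_like <- function(out, template, names3) {
  d <- dim(template)
  if (is.null(d)) {
    out <- drop(out)
    if (length(out) == 3L) names(out) <- names3
  } else {
    dim(out) <- d
    dimnames(out) <- if (length(d) == 2L) list(NULL, names3) else NULL
  }
  out
}

#' CIE XYZ to CIE 1976 L*a*b*
#'
#' Standard cube-root/linear-segment conversion against a reference white;
#' the white itself maps to `(100, 0, 0)`.
#'
#' @param xyz XYZ colours (length-3 vector, n x 3 matrix, h x w x 3 array).
#' @param white reference white, strictly positive tristimulus values.
#' @return Lab in the same shape.
#' @export
xyz_to_lab <- function(xyz, white = d65_white()) {
  if (any(white <= 0)) stop("reference white must be strictly positive", call. = FALSE)
  d <- dim(xyz)
  m <- if (!is.null(d) && length(d) == 3L) .flatten_lab(xyz) else .as_color_matrix(xyz, "xyz")
  fx <- .lab_f(m[, 1] / white[[1]])
  fy <- .lab_f(m[, 2] / white[[2]])
  fz <- .lab_f(m[, 3] / white[[3]])
  out <- cbind(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
  .reshape_like(out, xyz, c("L", "a", "b"))
}

#' CIE 1976 L*a*b* to CIE XYZ
#'
#' Exact inverse of [xyz_to_lab()] on its domain.
#'
#' @inheritParams xyz_to_lab
#' @param lab Lab colours (vector, matrix or array).
#' @return XYZ in the same shape.
#' @export
lab_to_xyz <- function(lab, white = d65_white()) {
  if (any(white <= 0)) stop("reference white must be strictly positive", call. = FALSE)
  d <- dim(lab)
  m <- if (!is.null(d) && length(d) == 3L) .flatten_lab(lab) else .as_color_matrix(lab, "lab")
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  out <- cbind(.lab_f_inv(fx) * white[[1]],
               .lab_f_inv(fy) * white[[2]],
               .lab_f_inv(fz) * white[[3]])
  .reshape_like(out, lab, c("X", "Y", "Z"))
}

#' Display RGB to CIELab
#'
#' Convenience composition: decode to linear, map to XYZ, convert to Lab.
#'
#' @inheritParams decode_to_linear
#' @param white reference white passed to [xyz_to_lab()].
#' @return Lab colours shaped like the input.
#' @export
rgb_to_lab <- function(x, power = 0.42, encoding = c("8bit", "unit"),
                       piecewise = FALSE, white = d65_white()) {
  xyz_to_lab(linear_rgb_to_xyz(decode_to_linear(x, power, encoding, piecewise)),
             white = white)
}

#' CIELab to display RGB
#'
#' Inverse convenience path used to render synthetic scenes; linear values
#' are clipped to `[0, 1]` before encoding (out-of-gamut colours saturate).
#'
#' @param lab Lab colours.
#' @param power encoding exponent.
#' @param white reference white.
#' @return integer 8-bit RGB shaped like the input.
#' @export
lab_to_rgb <- function(lab, power = 0.42, white = d65_white()) {
  lin <- xyz_to_linear_rgb(lab_to_xyz(lab, white = white))
  lin <- pmin(pmax(unclass(lin), 0), 1)
  attributes(lin) <- attributes(lab)
  to_presentation_rgb(lin, max_brightness = 1, power = power)
}

#' CIEDE2000 colour difference
#'
#' Full CIE 2000 formula, including the chroma-dependent G correction,
#' hue-angle branch rules (angles from `atan2`, mapped to `[0, 360)`), the
#' weighting functions `S_L`, `S_C`, `S_H` and the rotation term `R_T`.
#' Symmetric in its arguments and zero iff the colours coincide.
#'
#' @param lab1,lab2 Lab colours: length-3 vectors or n x 3 matrices
#'   (recycled row-wise to a common length).
#' @param kL,kC,kH parametric weighting factors, strictly positive
#'   (default 1).
#' @return numeric vector of non-negative colour differences.
#' @export
delta_e_ciede2000 <- function(lab1, lab2, kL = 1, kC = 1, kH = 1) {
  if (kL <= 0 || kC <= 0 || kH <= 0)
    stop("kL, kC, kH must be strictly positive", call. = FALSE)
  m1 <- .as_color_matrix(lab1, "lab1")
  m2 <- .as_color_matrix(lab2, "lab2")
  n <- max(nrow(m1), nrow(m2))
  if (nrow(m1) < n) m1 <- m1[rep_len(seq_len(nrow(m1)), n), , drop = FALSE]
  if (nrow(m2) < n) m2 <- m2[rep_len(seq_len(nrow(m2)), n), , drop = FALSE]
  if (any(!is.finite(m1)) || any(!is.finite(m2)))
    stop("Lab inputs must be finite", call. = FALSE)

  L1 <- m1[, 1]; a1 <- m1[, 2]; b1 <- m1[, 3]
  L2 <- m2[, 1]; a2 <- m2[, 2]; b2 <- m2[, 3]
  C1 <- sqrt(a1^2 + b1^2)
  C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1
  a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2)
  C2p <- sqrt(a2p^2 + b2^2)

  hdeg <- function(b, ap) {
    h <- atan2(b, ap) * 180 / pi
    h <- ifelse(h < 0, h + 360, h)
    ifelse(b == 0 & ap == 0, 0, h)
  }
  h1p <- hdeg(b1, a1p)
  h2p <- hdeg(b2, a2p)

  dLp <- L2 - L1
  dCp <- C2p - C1p
  zeroC <- C1p * C2p == 0
  dh <- h2p - h1p
  dh <- ifelse(dh > 180, dh - 360, ifelse(dh < -180, dh + 360, dh))
  dh <- ifelse(zeroC, 0, dh)
  dHp <- 2 * sqrt(C1p * C2p) * sin(dh / 2 * pi / 180)

  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hsum <- h1p + h2p
  habs <- abs(h1p - h2p)
  hbp <- ifelse(zeroC, hsum,
         ifelse(habs <= 180, hsum / 2,
         ifelse(hsum < 360, (hsum + 360) / 2, (hsum - 360) / 2)))

  Tt <- 1 - 0.17 * cos((hbp - 30) * pi / 180) +
            0.24 * cos((2 * hbp) * pi / 180) +
            0.32 * cos((3 * hbp + 6) * pi / 180) -
            0.20 * cos((4 * hbp - 63) * pi / 180)
  dtheta <- 30 * exp(-(((hbp - 275) / 25)^2))
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * Tt
  RT <- -sin(2 * dtheta * pi / 180) * RC

  sqrt((dLp / (kL * SL))^2 + (dCp / (kC * SC))^2 + (dHp / (kH * SH))^2 +
       RT * (dCp / (kC * SC)) * (dHp / (kH * SH)))
}
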