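# geometry fixtures built in code

circle_section <- function(R, n = 360, z = 0, label = NA_character_) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cross_section(R * cos(th), R * sin(th), z = z, label = label)
}

ellipse_section <- function(a, b, n = 720, z = 0, label = NA_character_) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cross_section(a * cos(th), b * sin(th), z = z, label = label)
}

# independent perimeter oracle: numeric quadrature of the arc-length integrand
ellipse_perimeter_quadrature <- function(a, b) {
  4 * stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                       0, pi / 2, rel.tol = 1e-12)$value
}

# 24-point square ring (collinear runs along each side, corners excluded)
square_section <- function(half = 0.05) {
  s <- seq(-half, half, length.out = 7)
  x <- c(s, rep(half, 5), rev(s), rep(-half, 5))
  y <- c(rep(-half, 7), s[2:6], rep(half, 7), rev(s[2:6]))
  cross_section(x, y)
}

ref_fabric <- function(subject, class, position) {
  fb <- reference_fabrics()
  as_fabric_spec(fb[fb$subject == subject & fb$class == class &
                    fb$position == position, ])
}

# frustum-style leg: circular sections at given girths
frustum_leg <- function(girths = c(B = 0.22, B1 = 0.26, C = 0.34, D = 0.335),
                        heights = c(B = 0, B1 = 0.08, C = 0.22, D = 0.32),
                        n = 180, tissue = NULL) {
  secs <- lapply(names(girths), function(p)
    circle_section(girths[[p]] / (2 * pi), n = n, z = heights[[p]], label = p))
  leg_model(secs, rigidity = if (is.null(tissue)) "rigid" else "soft",
            tissue = tissue)
}
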