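# Shared fixture builders: all test inputs are generated in code.

# Half-ellipse endocardial contour: annuli at (-r, 0) and (r, 0), apex at
# (0, L); odd n places the exact apex on the contour.
half_ellipse <- function(r = 22, L = 90, n = 101, view = "4CH", phase = "ED") {
  th <- seq(0, pi, length.out = n)
  lax_contour(cbind(-r * cos(th), L * sin(th)), view, phase)
}

# Rigid transform (rotation by `angle` about origin, then translation).
transform_points <- function(p, angle = 0, shift = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(p %*% t(R), 2, shift, `+`)
}

transform_set <- function(set, angle = 0, shift = c(0, 0)) {
  set$contours <- lapply(set$contours, function(ct) {
    ct$points <- transform_points(ct$points, angle, shift)
    ct
  })
  set
}

# Contour set whose ES contours are the ED contours scaled by k about the
# annular midpoint (a pure similarity motion).
scaled_set <- function(k, r = 22, L = 90, n = 101) {
  contours <- list()
  for (v in c("2CH", "3CH", "4CH")) {
    ed <- half_ellipse(r, L, n, view = v, phase = "ED")
    contours[[paste(v, "ED")]] <- ed
    contours[[paste(v, "ES")]] <- lax_contour(k * ed$points, v, "ES")
  }
  contour_set(contours, subject_id = "scaled", paired = TRUE)
}

table2_means <- function() {
  ind_reference()$mean_pct
}
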