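#' Constrain a predicted y to [0, 1]
#'
#' PLS-DA predicted y values are unbounded; values above 1 are replaced by
#' 1 and below 0 by 0 before the ternary normalization.
#'
#' @param y_hat numeric vector.
#' @return clipped vector.
#' @export
constrain <- function(y_hat) pmin(1, pmax(0, y_hat))

#' Map three one-vs-rest predictions to ternary coordinates
#'
#' Each of the three predicted y's (cholestatic, hepatocellular, recovered)
#' is clipped to `[0, 1]` and the triple divided by its sum, giving the
#' relative shares that position a sample on the phenotype simplex. The
#' all-zero triple has no defined direction; it maps to the centroid
#' `(1/3, 1/3, 1/3)` and is flagged `indeterminate` so downstream plots
#' never silently drop samples.
#'
#' @param y_c,y_h,y_r predicted y for the cholestatic-, hepatocellular- and
#'   recovered-vs-rest models (vectorized).
#' @return data frame: `c`, `h`, `r` (each in `[0, 1]`, summing to 1),
#'   `indeterminate` (logical).
#' @export
to_ternary <- function(y_c, y_h, y_r) {
  cc <- constrain(y_c); hh <- constrain(y_h); rr <- constrain(y_r)
  s <- cc + hh + rr
  ind <- s == 0
  s[ind] <- 1
  out <- data.frame(c = cc / s, h = hh / s, r = rr / s,
                    indeterminate = ind)
  out$c[ind] <- out$h[ind] <- out$r[ind] <- 1 / 3
  out
}

# simplex vertices (side length 1): cholestatic bottom-left, hepatocellular
# bottom-right, recovered apex
TERNARY_VERTICES <- matrix(c(0, 0,
                             1, 0,
                             0.5, sqrt(3) / 2),
                           ncol = 2, byrow = TRUE,
                           dimnames = list(c("c", "h", "r"), c("x", "y")))

#' Barycentric embedding of ternary coordinates
#'
#' Vertices: cholestatic at (0,0), hepatocellular at (1,0), recovered at
#' the apex (0.5, sqrt(3)/2), matching the layout in which recovered
#' patients cluster in the upper corner, cholestatic bottom-left and
#' hepatocellular bottom-right.
#'
#' @param coord data frame with columns `c`, `h`, `r` (from
#'   [to_ternary()]).
#' @return data frame with Cartesian `x`, `y`.
#' @export
embed_ternary <- function(coord) {
  m <- as.matrix(coord[, c("c", "h", "r")])
  xy <- m %*% TERNARY_VERTICES
  data.frame(x = xy[, "x"], y = xy[, "y"])
}

#' Distance to the recovered vertex
#'
#' Euclidean distance between the embedded point and the recovered apex
#' (0% cholestatic, 0% hepatocellular): an intuitive measure of how far a
#' sample's metabolome is from the recovered status. Dimensionless in
#' `[0, 1]` for the unit side length.
#'
#' @inheritParams embed_ternary
#' @return numeric vector of distances.
#' @export
recovery_distance <- function(coord) {
  xy <- embed_ternary(coord)
  apex <- TERNARY_VERTICES["r", ]
  sqrt((xy$x - apex[["x"]])^2 + (xy$y - apex[["y"]])^2)
}

#' Per-patient longitudinal trajectories on the simplex
#'
#' Orders each patient's samples by timepoint and attaches embedded
#' coordinates and recovery distances. Patients with a single sample yield
#' single-point trajectories; duplicated (patient, timepoint) pairs are an
#' error.
#'
#' @param coords data frame with `patient_id`, `timepoint`, `c`, `h`, `r`
#'   and optionally `sample_id` and a clinical `label`.
#' @return data frame of class `ternary_trajectory`, sorted by patient and
#'   timepoint, with `x`, `y` and `recovery_distance` columns appended.
#' @export
build_trajectories <- function(coords) {
  need <- c("patient_id", "timepoint", "c", "h", "r")
  if (!all(need %in% names(coords)))
    stopf("coords needs columns: %s", paste(need, collapse = ", "))
  dup <- duplicated(coords[, c("patient_id", "timepoint")])
  if (any(dup))
    stopf("duplicate (patient, timepoint): %s",
          paste(unique(paste(coords$patient_id[dup], coords$timepoint[dup],
                             sep = "/")), collapse = ", "))
  coords <- coords[order(coords$patient_id, coords$timepoint), , drop = FALSE]
  xy <- embed_ternary(coords)
  coords$x <- xy$x; coords$y <- xy$y
  coords$recovery_distance <- recovery_distance(coords)
  rownames(coords) <- NULL
  class(coords) <- c("ternary_trajectory", "data.frame")
  coords
}

#' Plot samples and trajectories on the ternary simplex
#'
#' ggplot2 rendering of the phenotype simplex with class-coloured points
#' (green cholestatic, orange hepatocellular, grey mixed, blue recovered)
#' and per-patient connected trajectories. Requires ggplot2.
#'
#' @param traj a `ternary_trajectory` (or any data frame with `x`, `y` and
#'   optionally `label` and `patient_id`).
#' @param connect draw per-patient paths.
#' @return a ggplot object.
#' @export
plot_ternary <- function(traj, connect = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("plot_ternary needs the ggplot2 package")
  tri <- data.frame(x = TERNARY_VERTICES[c(1, 2, 3, 1), "x"],
                    y = TERNARY_VERTICES[c(1, 2, 3, 1), "y"])
  cols <- c(cholestatic = "#2ca02c", hepatocellular = "#ff7f0e",
            mixed = "#7f7f7f", recovered = "#1f77b4",
            unknown = "black", unclassifiable = "black")
  p <- ggplot2::ggplot(traj, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = tri, ggplot2::aes(x = .data$x, y = .data$y),
                       inherit.aes = FALSE, colour = "grey30") +
    ggplot2::coord_fixed() + ggplot2::theme_void()
  if (connect && "patient_id" %in% names(traj))
    p <- p + ggplot2::geom_path(ggplot2::aes(group = .data$patient_id),
                                colour = "grey60")
  if ("label" %in% names(traj))
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$label)) +
      ggplot2::scale_colour_manual(values = cols, name = "clinical label")
  else p <- p + ggplot2::geom_point()
  ann <- data.frame(x = TERNARY_VERTICES[, "x"],
                    y = TERNARY_VERTICES[, "y"] +
                      c(-0.04, -0.04, 0.04),
                    lab = c("cholestatic", "hepatocellular", "recovered"))
  p + ggplot2::geom_text(data = ann,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      label = .data$lab),
                         inherit.aes = FALSE, size = 3)
}
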