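#' Area-of-interest set
#'
#' Named simple polygons in normalized display coordinates ([0,1] x [0,1],
#' origin top-left) with unique priority ranks resolving overlaps: lower
#' rank wins. The canonical four regions are Road, Cockpit,
#' ExternalEnvironment and CockpitTotal; CockpitTotal is computed but
#' excluded from statistics by default.
#'
#' @param aois data frame / tibble with columns `name`, `priority`
#'   (unique integers, 1 = highest), `vertices` (list column of n x 2
#'   matrices).
#' @return Tibble of class `aoi_set`, sorted by priority.
#' @export
aoi_set <- function(aois) {
  aois <- tibble::as_tibble(aois)
  assert_that(all(c("name", "priority", "vertices") %in% names(aois)),
              "aoi_set needs name, priority, vertices")
  assert_that(!anyDuplicated(aois$priority), "priority ranks must be unique")
  for (v in aois$vertices)
    assert_that(is.matrix(v) && ncol(v) == 2 && nrow(v) >= 3,
                "each AoI polygon needs an n x 2 vertex matrix, n >= 3")
  out <- aois[order(aois$priority), ]
  class(out) <- c("aoi_set", class(out))
  out
}

#' Default AoI geometry
#'
#' A schematic driving field of view: Road as the central band, Cockpit as
#' the instrumented region at the bottom centre, CockpitTotal as the whole
#' bottom strip, and ExternalEnvironment as a U-shaped region covering the
#' top and sides. Priorities: Cockpit > Road > ExternalEnvironment >
#' CockpitTotal.
#'
#' @return An [aoi_set()].
#' @export
default_aois <- function() {
  rect <- function(x0, y0, x1, y1)
    rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
  ext <- rbind(c(0, 0), c(1, 0), c(1, 0.75), c(0.85, 0.75), c(0.85, 0.25),
               c(0.15, 0.25), c(0.15, 0.75), c(0, 0.75))
  aoi_set(tibble::tibble(
    name = c("Cockpit", "Road", "ExternalEnvironment", "CockpitTotal"),
    priority = 1:4,
    vertices = list(rect(0.40, 0.78, 0.60, 0.95),
                    rect(0.15, 0.25, 0.85, 0.75),
                    ext,
                    rect(0.10, 0.75, 0.90, 1.00))
  ))
}

# Ray-casting point-in-polygon with boundary points counted as inside
# (deterministic boundary semantics are required by the AoI priority tie
# rule, which no installed polygon package guarantees).
point_in_polygon <- function(px, py, vertices) {
  n <- nrow(vertices)
  xs <- vertices[, 1]; ys <- vertices[, 2]
  inside <- logical(length(px))
  for (p in seq_along(px)) {
    x <- px[p]; y <- py[p]
    hit <- FALSE
    on_edge <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
      # boundary test: collinear and within the segment bbox
      cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
      if (abs(cross) < 1e-12 &&
          x >= min(xi, xj) - 1e-12 && x <= max(xi, xj) + 1e-12 &&
          y >= min(yi, yj) - 1e-12 && y <= max(yi, yj) + 1e-12) {
        on_edge <- TRUE
        break
      }
      if ((yi > y) != (yj > y) &&
          x < (xj - xi) * (y - yi) / (yj - yi) + xi) hit <- !hit
      j <- i
    }
    inside[p] <- on_edge || hit
  }
  inside
}

#' Assign fixations to areas of interest
#'
#' Point-in-polygon membership of each fixation centroid; overlapping
#' membership is resolved by priority rank, centroids outside every polygon
#' get `NA`.
#'
#' @param fixations tibble with centroid columns `x`, `y` (from
#'   [classify_fixations()]).
#' @param aois an [aoi_set()].
#' @return `fixations` with an added `aoi` character column.
#' @export
assign_aoi <- function(fixations, aois) {
  aoi <- rep(NA_character_, nrow(fixations))
  for (k in rev(seq_len(nrow(aois)))) {   # lowest priority first; higher wins
    hit <- point_in_polygon(fixations$x, fixations$y, aois$vertices[[k]])
    aoi[hit] <- aois$name[k]
  }
  fixations$aoi <- aoi
  fixations
}
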