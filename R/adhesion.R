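#' Rebuild the spring-link network of the adherent monolayer
#'
#' Links exist exactly between pairs of unreleased cells within
#' `adhesion_radius` patch units of each other. Cells that have cleaved their
#' surface ligand (released) carry no links; a reverted cell re-acquires
#' links at the next rebuild.
#'
#' @param world A `scratch_world`.
#' @return Two-column integer matrix of cell indices (one row per unordered
#'   pair), possibly with zero rows.
#' @export
rebuild_links <- function(world) {
  stopifnot(inherits(world, "scratch_world"))
  idx <- which(!world$cells$released)
  if (length(idx) < 2) return(matrix(integer(0), ncol = 2,
                                     dimnames = list(NULL, c("i", "j"))))
  x <- world$cells$x[idx]
  y <- world$cells$y[idx]
  r2 <- world$params$adhesion_radius^2
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  pair <- which(upper.tri(d2) & d2 <= r2, arr.ind = TRUE)
  cbind(i = idx[pair[, 1]], j = idx[pair[, 2]])
}

#' Apply Hooke-like spring adjustments along adhesion links
#'
#' Each link pulls (or pushes) its two endpoints along the connecting line
#' with displacement `spring_constant * (distance - rest_length)` apiece,
#' equal and opposite, patterned after a spring layout. A cell's total spring
#' displacement is capped at its per-tick step length, so adhesion confines
#' rather than teleports. Cells exactly at rest length experience no
#' adjustment.
#'
#' @param world A `scratch_world`.
#' @param links Link matrix from [rebuild_links()].
#' @return Updated world (positions).
#' @export
apply_springs <- function(world, links) {
  if (is.null(links) || nrow(links) == 0) return(world)
  cl <- world$cells
  p <- world$params
  i <- links[, 1]; j <- links[, 2]
  ddx <- cl$x[j] - cl$x[i]
  ddy <- cl$y[j] - cl$y[i]
  d <- sqrt(ddx^2 + ddy^2)
  nz <- d > 1e-12
  f <- numeric(length(d))
  f[nz] <- p$spring_constant * (d[nz] - p$rest_length) / d[nz]
  fx <- f * ddx
  fy <- f * ddy

  n <- .n_cells(world)
  acc_x <- numeric(n); acc_y <- numeric(n)
  sx <- rowsum(c(fx, -fx), group = c(i, j))
  sy <- rowsum(c(fy, -fy), group = c(i, j))
  who <- as.integer(rownames(sx))
  acc_x[who] <- sx[, 1]
  acc_y[who] <- sy[, 1]

  mag <- sqrt(acc_x^2 + acc_y^2)
  cap <- .step_len(world, cl$mu)
  over <- mag > cap & mag > 0
  if (any(over)) {
    scale <- cap[over] / mag[over]
    acc_x[over] <- acc_x[over] * scale
    acc_y[over] <- acc_y[over] * scale
  }

  cl$x <- .clamp_x(world, cl$x + acc_x)
  cl$y <- .clamp_y(world, cl$y + acc_y)
  world$cells <- cl
  world
}
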