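#' Edges of the 3-D Delaunay tessellation
#'
#' Incremental Bowyer-Watson tessellation of a 3-D point set, returning
#' the unique point-pair edges of the tetrahedralisation. Used as the
#' neighbour filter of tessellation-based contact schemes: only atom
#' pairs sharing a tessellation edge are eligible as contacts.
#'
#' Near-degenerate circumsphere tests (point sets close to coplanar)
#' are resolved conservatively by treating points within numerical
#' tolerance of a circumsphere as inside it, which can only add edges
#' locally; downstream distance and separation filters still apply.
#'
#' @param xyz n x 3 numeric matrix of coordinates.
#' @return Two-column integer matrix of edges (i < j, 1-based rows of
#'   `xyz`). Fewer than 2 points give a 0-row matrix; exactly 2 or 3
#'   points give all pairs.
#' @export
delaunay_edges <- function(xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, all(is.finite(xyz)))
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(), 0, 2))
  if (n <= 4) {
    e <- t(utils::combn(n, 2))
    storage.mode(e) <- "integer"
    return(e)
  }

  # bounding super-tetrahedron, generous margin
  ctr <- colMeans(xyz)
  span <- max(apply(xyz, 2, function(v) diff(range(v))), 1) * 50
  sv <- rbind(ctr + c(0, 0, 3) * span,
              ctr + c(-2, -2, -1) * span,
              ctr + c(2, -2, -1) * span,
              ctr + c(0, 2.5, -1) * span)
  pts <- rbind(sv, xyz)            # points 1..4 are super vertices
  tets <- list(1:4)
  circ <- list(.circumsphere(pts[1:4, ]))

  for (p in 5:(n + 4L)) {
    bad <- logical(length(tets))
    for (t in seq_along(tets)) {
      cc <- circ[[t]]
      bad[t] <- sum((pts[p, ] - cc$c)^2) <= cc$r2 * (1 + 1e-9) + 1e-9
    }
    if (!any(bad)) {
      # numerical fallback: point escaped every circumsphere; attach to
      # the tetrahedron with nearest circumcenter
      d2 <- vapply(circ, function(cc) sum((pts[p, ] - cc$c)^2) - cc$r2,
                   0)
      bad[which.min(d2)] <- TRUE
    }
    # boundary faces of the cavity: faces appearing exactly once
    faces <- do.call(rbind, lapply(tets[bad], function(v)
      rbind(sort(v[-1]), sort(v[-2]), sort(v[-3]), sort(v[-4]))))
    key <- paste(faces[, 1], faces[, 2], faces[, 3])
    once <- names(which(table(key) == 1))
    tets <- tets[!bad]
    circ <- circ[!bad]
    for (fk in once) {
      f <- faces[match(fk, key), ]
      newt <- c(f, p)
      cc <- .circumsphere(pts[newt, ])
      if (is.null(cc)) next                 # degenerate sliver, drop
      tets[[length(tets) + 1L]] <- newt
      circ[[length(circ) + 1L]] <- cc
    }
  }

  edges <- matrix(integer(), 0, 2)
  for (v in tets) {
    if (any(v <= 4L)) next                  # touches the super-tetrahedron
    w <- sort(v) - 4L
    edges <- rbind(edges, t(utils::combn(w, 2)))
  }
  edges <- unique(edges)
  storage.mode(edges) <- "integer"
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

# circumsphere of a tetrahedron: center c with |c - v_i|^2 equal for all
# vertices; NULL when the four points are (numerically) coplanar
.circumsphere <- function(v) {
  a <- 2 * (v[2:4, , drop = FALSE] -
              matrix(v[1, ], 3, 3, byrow = TRUE))
  b <- rowSums(v[2:4, , drop = FALSE]^2) - sum(v[1, ]^2)
  det_a <- det(a)
  scale <- max(abs(a))
  if (!is.finite(det_a) || abs(det_a) < 1e-10 * scale^3) return(NULL)
  cen <- solve(a, b)
  list(c = cen, r2 = sum((cen - v[1, ])^2))
}
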