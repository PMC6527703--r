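# Fixture meshes built in code: a hand-wound unit cube, a square pyramid
# with equilateral faces, and a flat 3x3 grid patch.

unit_cube <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(c(1, 4, 3), c(1, 3, 2),   # bottom
             c(5, 6, 7), c(5, 7, 8),   # top
             c(1, 2, 6), c(1, 6, 5),   # front
             c(3, 4, 8), c(3, 8, 7),   # back
             c(1, 5, 8), c(1, 8, 4),   # left
             c(2, 3, 7), c(2, 7, 6))   # right
  triangulated_surface(v, f, name = "unit_cube")
}

# open square pyramid whose four faces are equilateral (60 deg apex angles);
# apex is the only interior vertex
equilateral_pyramid <- function() {
  base <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  apex <- c(0.5, 0.5, sqrt(0.5))
  triangulated_surface(rbind(base, apex),
                       rbind(c(1, 2, 5), c(2, 3, 5), c(3, 4, 5), c(4, 1, 5)),
                       name = "pyramid")
}

# flat 3x3 grid in the z = 0 plane; vertex 5 (the centre) is interior
flat_grid <- function() {
  g <- expand.grid(x = 0:2, y = 0:2)
  v <- cbind(as.matrix(g), 0)
  idx <- function(x, y) x + 1L + 3L * y
  f <- do.call(rbind, lapply(0:1, function(cy) do.call(rbind, lapply(0:1,
    function(cx) rbind(c(idx(cx, cy), idx(cx + 1, cy), idx(cx + 1, cy + 1)),
                       c(idx(cx, cy), idx(cx + 1, cy + 1), idx(cx, cy + 1)))))))
  triangulated_surface(v, f, name = "flat_grid")
}

# single triangle in the z = 0 plane with area 1/2
single_triangle <- function() {
  triangulated_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       matrix(c(1, 2, 3), 1), name = "tri")
}
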