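# Shared fixtures, built in code. The cache avoids re-meshing/re-assembling
# the same phantom across tests within a file.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

canonical_simplex <- function() {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           rbind(1:4), watertight = TRUE)
}

small_jaw <- function() cached("jaw_r1", make_jaw_phantom(phantom_spec("jaw", resolution = 1)))

small_jaw_stage <- function() cached("jaw_r1_stage", as_stage_spec(small_jaw(), "stage 1"))

# 5-tet decomposition of the unit cube (independent of the package's
# 6-tet Freudenthal subdivision); used as a volume oracle.
cube5 <- function() {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                 c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  tets <- rbind(c(1, 2, 4, 5), c(2, 3, 4, 7), c(2, 6, 7, 5),
                c(4, 7, 8, 5), c(2, 7, 4, 5))
  tet_mesh(nodes, tets)
}

random_rotation <- function() {
  # QR of a random matrix, sign-fixed to a proper rotation
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
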