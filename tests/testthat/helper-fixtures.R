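# shared fixtures built in code

cube_cloud <- function(label = "cube") {
  m <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  dimnames(m) <- NULL
  pointcloud(m, label = label)
}

# regular tetrahedron, edge 1
tetra_cloud <- function() {
  pointcloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                   c(0.5, sqrt(3) / 6, sqrt(2 / 3))), label = "tetra")
}

# rotation about z then x
rot3 <- function(th, ph) {
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Rx <- rbind(c(1, 0, 0), c(0, cos(ph), -sin(ph)), c(0, sin(ph), cos(ph)))
  Rz %*% Rx
}

sphere_surface_cloud <- function(n, seed) {
  withr::with_seed(seed, {
    z <- matrix(rnorm(3 * n), ncol = 3)
    pointcloud(z / sqrt(rowSums(z^2)), label = "sphere")
  })
}

group_ds <- function(tab, g) tab[tab$group == g, ]

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

mammal_primate_pool <- function(tab) tab[tab$group != "bird", ]
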