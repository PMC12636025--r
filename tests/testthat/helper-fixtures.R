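# shared fixtures built in code

# random proper rotation matrix
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Cartesian Hessian of a network of harmonic springs at their natural
# lengths: exact zero modes for rigid translations and rotations
spring_hessian <- function(coords, masses, k = 300) {
  n <- nrow(coords)
  h <- matrix(0, 3 * n, 3 * n)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      u <- coords[b, ] - coords[a, ]
      u <- u / sqrt(sum(u^2))
      blk <- k * outer(u, u)
      ia <- (3 * a - 2):(3 * a); ib <- (3 * b - 2):(3 * b)
      h[ia, ia] <- h[ia, ia] + blk
      h[ib, ib] <- h[ib, ib] + blk
      h[ia, ib] <- h[ia, ib] - blk
      h[ib, ia] <- h[ib, ia] - blk
    }
  }
  hessian_block(h, masses)
}

# the four catalytic steps of the urethanase demo landscape
demo_steps <- function() {
  list(
    mechanism_step("conformational", 4.5, 2.6,
                   ts_label = "TSconf", product_label = "ES_active"),
    mechanism_step("acylation", 21.2, -16.7,
                   reference = "global_reference",
                   ts_label = "TS1(A)", product_label = "EA"),
    mechanism_step("hydrolysis", 18.2, -11.1,
                   ts_label = "TS(H)", product_label = "PC(H)"),
    mechanism_step("decarboxylation", 12.1, 9.1,
                   ts_label = "TS(D)", product_label = "PC(D)")
  )
}

# trajectory with a protein-like site, a ligand and programmable waters:
# water_positions is a list (one element per frame) of named lists
# resid -> c(x, y, z)
site_water_trajectory <- function(water_positions) {
  n_frames <- length(water_positions)
  resids <- sort(unique(unlist(lapply(water_positions, names))))
  n_wat <- length(resids)
  n_atoms <- 2L + n_wat
  coords <- array(0, c(n_frames, n_atoms, 3))
  far <- c(50, 50, 50)
  for (f in seq_len(n_frames)) {
    coords[f, 1L, ] <- c(0, 0, 0)
    coords[f, 2L, ] <- c(1, 0, 0)
    for (w in seq_len(n_wat)) {
      pos <- water_positions[[f]][[resids[w]]]
      coords[f, 2L + w, ] <- if (is.null(pos)) far else pos
    }
  }
  atoms <- data.frame(
    name = c("OG", "C1", rep("O", n_wat)),
    element = c("O", "C", rep("O", n_wat)),
    resid = c(1L, 2L, as.integer(resids)),
    resname = c("SER", "LIG", rep("HOH", n_wat))
  )
  md_trajectory(coords, atoms = atoms)
}
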