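# Shared fixtures: everything is generated in code at test time.

# render a single shape on a generous frame and measure it
render_measure <- function(spec, frame = c(128, 128), pixel_size = 0.5) {
  out <- generate_particle_image(list(spec), frame, pixel_size, seed = 1L)
  rec <- shape_descriptors(segment_particles(out$image))
  list(rec = rec, truth = out$truth)
}

# tie-corrected Kruskal-Wallis H computed from first principles (the
# independent oracle: ranks assigned by hand via order/averaging, never
# via kruskal.test)
brute_force_H <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  # midranks
  o <- order(values)
  rk <- numeric(N)
  i <- 1L
  while (i <= N) {
    j <- i
    while (j < N && values[o[j + 1L]] == values[o[i]]) j <- j + 1L
    rk[o[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  rs <- tapply(rk, groups, sum)
  ni <- tabulate(groups)
  h <- 12 / (N * (N + 1)) * sum(rs^2 / ni) - 3 * (N + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# shoelace polygon area (oracle used for solidity checks)
shoelace <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

star_vertices <- function(center, n, R, r, phase = 0) {
  k <- 2 * n
  ang <- phase + seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  rad <- rep(c(R, r), n)
  cbind(center[1] + rad * cos(ang), center[2] + rad * sin(ang))
}
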