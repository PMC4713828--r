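# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately share no code with the package internals.

# symmetric (edge-inclusive) reflection of index i into 1..n
reflect_idx <- function(i, n) {
  ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
}

# Niblack threshold by explicit per-pixel window loops (population sd)
oracle_niblack <- function(m, radius, k) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ri <- reflect_idx((i - radius):(i + radius), nr)
      ci <- reflect_idx((j - radius):(j + radius), nc)
      w <- m[ri, ci]
      mu <- mean(w)
      sd_pop <- sqrt(mean((w - mu)^2))
      out[i, j] <- mu + k * sd_pop
    }
  }
  out
}

# Exact two-sided signed-rank p by full enumeration of all 2^n sign patterns
oracle_wilcoxon_p <- function(baseline, followup) {
  d <- baseline - followup
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 12)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  s_tot <- sum(r)
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(signs, 1, function(s) {
    wp <- sum(r[s])
    min(wp, s_tot - wp)
  })
  mean(w_all <= w_obs)
}

# flat four-boundary set for a given image width
flat_boundaries <- function(width, ilm = 20, rpe_inner = 60, rpe_outer = 70,
                            csj = 170, fovea_x = NULL, scan_id = "fixture") {
  boundary_set(
    list(ILM = rep(ilm, width), RPE_inner = rep(rpe_inner, width),
         RPE_outer = rep(rpe_outer, width), CSJ = rep(csj, width)),
    scan_id = scan_id, fovea_x = fovea_x
  )
}

# uniform-intensity 8-bit scan
flat_bscan <- function(nr, nc, value = 128, lateral = 10, axial = 5,
                       scan_id = "fixture") {
  bscan(matrix(value, nr, nc), 8L, lateral, axial, scan_id = scan_id)
}

# write a boundary-JSON file from 0-based polylines, return its path
write_boundary_json <- function(boundaries, path = tempfile(fileext = ".json"),
                                scan_id = "json_fixture", fovea_x = NULL,
                                lateral = 10, axial = 5) {
  obj <- list(scan_id = scan_id, lateral_scale_um_per_px = lateral,
              axial_scale_um_per_px = axial, fovea_x = fovea_x,
              boundaries = boundaries)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  path
}
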