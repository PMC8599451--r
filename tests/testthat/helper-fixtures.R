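# Shared fixtures and independent oracles, all built in code at test time.

# solid disk section on a white background (uniform hue/sat/brightness)
disk_section <- function(s, r_px, pixel_size, hue = 100, sat = 180,
                         bright = 80, hole_r = 0, center = NULL) {
  x <- matrix(rep(1:s, each = s), s, s)
  y <- matrix(rep(1:s, s), s, s)
  ctr <- center %||% c((s + 1) / 2, (s + 1) / 2)
  d2 <- (x - ctr[2])^2 + (y - ctr[1])^2
  inside <- d2 <= r_px^2
  if (hole_r > 0) inside[d2 <= hole_r^2] <- FALSE
  rgb <- array(255, c(s, s, 3))
  n <- sum(inside)
  cols <- t(grDevices::col2rgb(grDevices::hsv(hue / 255, sat / 255, bright / 255)))
  for (k in 1:3) {
    ch <- rgb[, , k]; ch[inside] <- cols[k]; rgb[, , k] <- ch
  }
  section_image(rgb, pixel_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sinusoidal stripe pattern whose axis is at theta_deg (fiber direction)
stripe_image <- function(theta_deg, s = 256, period = 8, amp = 80) {
  th <- theta_deg * pi / 180
  x <- matrix(rep(1:s, each = s), s, s)
  y <- matrix(rep(1:s, s), s, s)
  100 + amp * sin(2 * pi * (x * cos(th) + y * sin(th)) / period)
}

# --- exhaustive 256-candidate threshold oracles (independent of R/) -----

hist256_oracle <- function(img) {
  v <- pmin(pmax(round(as.vector(img)), 0), 255)
  tabulate(v + 1L, nbins = 256L)
}

bf_isodata <- function(h) {
  g <- 0:255
  for (t in 0:255) {
    lo <- g <= t
    n0 <- sum(h[lo]); n1 <- sum(h[!lo])
    if (n0 == 0 || n1 == 0) next
    m0 <- sum(g[lo] * h[lo]) / n0
    m1 <- sum(g[!lo] * h[!lo]) / n1
    if (t >= (m0 + m1) / 2) return(t)
  }
  NA_integer_
}

bf_yen <- function(h) {
  p <- h / sum(h)
  best <- -Inf; bt <- NA_integer_
  for (t in 1:255) {
    p1 <- sum(p[1:t]); s1 <- sum(p[1:t]^2); s2 <- sum(p[(t + 1):256]^2)
    if (s1 > 0 && s2 > 0 && p1 > 0 && p1 < 1) {
      crit <- -log(s1 * s2) + 2 * log(p1 * (1 - p1))
      if (crit > best) { best <- crit; bt <- t - 1L }
    }
  }
  bt
}

bf_triangle <- function(h) {
  nz <- which(h > 0L)
  bmin <- nz[1] - 1L; bmax <- nz[length(nz)] - 1L
  peak <- which.max(h) - 1L
  flipped <- (peak - bmin) > (bmax - peak)
  hh <- if (flipped) rev(h) else h
  p2 <- if (flipped) 255L - peak else peak
  e2 <- if (flipped) 255L - bmin else bmax
  hp <- hh[p2 + 1L]
  best <- -Inf; bt <- NA_integer_
  for (b in (p2 + 1L):e2) {
    line_h <- hp * (1 - (b - p2) / (e2 - p2))
    dev <- line_h - hh[b + 1L]
    if (dev > best) { best <- dev; bt <- b }
  }
  if (flipped) 255L - bt else bt
}

# moment preservation solved by numeric root finding over the below-
# threshold fraction q (independent of the closed-form quadratic)
bf_moments_numeric <- function(h) {
  p <- h / sum(h); g <- 0:255
  m1 <- sum(g * p); m2 <- sum(g^2 * p); m3 <- sum(g^3 * p)
  E <- function(q) {
    za <- m1 - sqrt((1 - q) / q * (m2 - m1^2))
    zb <- m1 + sqrt(q / (1 - q) * (m2 - m1^2))
    q * za^3 + (1 - q) * zb^3 - m3
  }
  p0 <- stats::uniroot(E, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  which(cumsum(p) >= p0 - 1e-12)[1] - 1L
}

# --- block-structured expression fixture (study conditions) -------------

expr_block_fixture <- function(seed) {
  expr_sim_spec(
    n_genes = 1000, baseline_meanlog = 5, dispersion = 0.02,
    maturation_gene_sets = list(sarcomere = 1:30),
    effect_log2fc = list(sarcomere = c(mus = 2, acomys = 0.3)),
    species_genes = 101:160, species_log2fc = 4, seed = seed)
}

expr_planted_genes <- function(ge) rownames(ge$matrix)[c(1:30, 101:160)]

# match detected peaks against truth within a tolerance (samples)
match_peaks <- function(detected, truth, tol) {
  tp <- sum(vapply(truth, function(i) any(abs(detected - i) <= tol), logical(1)))
  list(sensitivity = tp / length(truth),
       precision = sum(vapply(detected, function(i)
         any(abs(truth - i) <= tol), logical(1))) / max(length(detected), 1))
}
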