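# Shared fixtures and independent oracles for the test suite.

# A small slide that still carries both regions and 2-3 glomeruli:
# 1.6 x 1.2 mm at 2 um/px, cortex-heavy so capsules fit comfortably.
tiny_spec <- function(seed = 1L, ...) {
  args <- list(width_px = 800L, height_px = 600L, mpp = 2,
               cortex_fraction = 0.65, target_gd = 2.23,
               area_mean = 20000, area_sd = 2500, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(slide_spec, args)
}

# Flat synthetic slide built directly from region colors (no
# generator): a uniform field of one tissue class with optional
# hand-placed tuft ellipses. Used to probe detector thresholds with
# exactly known pixel support.
palette_rgb <- function(what, k = 1) exp(-k * switch(what,
  background = c(0.025, 0.030, 0.028),
  cortex     = c(0.095, 0.320, 0.220),
  medulla    = c(0.070, 0.233, 0.165),   # base + mean stripe
  tuft       = c(0.600, 0.800, 0.360)))

flat_slide <- function(H = 200L, W = 200L, what = "cortex", mpp = 2) {
  px <- array(0, c(H, W, 3))
  col <- palette_rgb(what)
  for (ch in 1:3) px[, , ch] <- col[ch]
  slide_image(px, mpp = mpp)
}

# paint an axis-aligned tuft ellipse (semi-axes in um) onto a slide
paint_tuft <- function(image, cx_um, cy_um, a_um, b_um) {
  d <- dim(image$pixels); mpp <- image$mpp
  xs <- (seq_len(d[2]) - 1) * mpp; ys <- (seq_len(d[1]) - 1) * mpp
  X <- matrix(xs, d[1], d[2], byrow = TRUE); Y <- matrix(ys, d[1], d[2])
  m <- ((X - cx_um) / a_um)^2 + ((Y - cy_um) / b_um)^2 <= 1
  col <- palette_rgb("tuft")
  for (ch in 1:3) {
    pl <- image$pixels[, , ch]; pl[m] <- col[ch]; image$pixels[, , ch] <- pl
  }
  image
}

all_cortex_mask <- function(image) {
  region_mask(matrix(1L, dim(image$pixels)[1], dim(image$pixels)[2]),
              mpp = image$mpp)
}

# BFS connected-component oracle (slow, obviously correct)
bfs_label <- function(m, conn = 8) {
  H <- nrow(m); W <- ncol(m); lab <- matrix(0L, H, W); k <- 0L
  offs <- if (conn == 8) {
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, , drop = FALSE]
  } else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  for (i in seq_len(H)) for (j in seq_len(W)) if (m[i, j] && lab[i, j] == 0L) {
    k <- k + 1L; queue <- list(c(i, j)); lab[i, j] <- k
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (o in seq_len(nrow(offs))) {
        r <- p[1] + offs[o, 1]; cc <- p[2] + offs[o, 2]
        if (r >= 1 && r <= H && cc >= 1 && cc <= W && m[r, cc] && lab[r, cc] == 0L) {
          lab[r, cc] <- k; queue <- c(queue, list(c(r, cc)))
        }
      }
    }
  }
  lab
}

# exhaustive maximum one-to-one matching size (oracle for match counts
# on small instances): recursion over references
max_matching_size <- function(elig) {
  if (!nrow(elig) || !ncol(elig)) return(0L)
  best <- 0L
  recurse <- function(j, used) {
    if (j > ncol(elig)) { best <<- max(best, sum(used)); return(invisible()) }
    # prune: even matching everything left cannot beat best
    if (sum(used) + (ncol(elig) - j + 1) <= best) return(invisible())
    recurse(j + 1L, used)                      # leave reference j unmatched
    for (i in which(elig[, j] & !used)) {
      used[i] <- TRUE; recurse(j + 1L, used); used[i] <- FALSE
    }
  }
  recurse(1L, logical(nrow(elig)))
  best
}

# closed-form mean/sd of a truncated normal (recovery-test reference)
truncnorm_moments <- function(mean, sd, lo, hi) {
  mean <- unname(mean); sd <- unname(sd); lo <- unname(lo); hi <- unname(hi)
  a <- (lo - mean) / sd; b <- (hi - mean) / sd
  z <- pnorm(b) - pnorm(a)
  m1 <- mean + sd * (dnorm(a) - dnorm(b)) / z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z - ((dnorm(a) - dnorm(b)) / z)^2)
  c(mean = m1, sd = sqrt(v))
}
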