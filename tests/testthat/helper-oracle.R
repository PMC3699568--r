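# Brute-force co-occurrence enumerator: the independent oracle against which
# the vectorized implementation is checked. Double loop over every pixel,
# same direction convention (x = column, y = row increasing downward).
brute_glcm <- function(px, d, direction, symmetric = TRUE, n_levels = 8L) {
  px <- unclass(px)
  step <- switch(as.character(direction),
    "0"   = c(0L, d),    # (drow, dcol)
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d),
    stop("bad direction")
  )
  counts <- matrix(0L, n_levels, n_levels)
  nr <- nrow(px); nc <- ncol(px)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      r2 <- r + step[1L]; c2 <- cc + step[2L]
      if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
        i <- px[r, cc] + 1L; j <- px[r2, c2] + 1L
        counts[i, j] <- counts[i, j] + 1L
        if (symmetric) counts[j, i] <- counts[j, i] + 1L
      }
    }
  }
  counts
}

rotate90 <- function(m) t(m)[, nrow(m):1, drop = FALSE] # counter-clockwise

random_image <- function(nr, nc, n_levels) {
  gray_image(matrix(sample(0:(n_levels - 1L), nr * nc, replace = TRUE),
                    nr, nc))
}
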