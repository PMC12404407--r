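# shared fixtures and independent oracle helpers, built in code

erf_ref <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# brute-force point-to-polyline distance (independent of the package path)
brute_polyline_dist <- function(p, polyline) {
  best <- Inf
  for (i in seq_len(nrow(polyline) - 1L)) {
    a <- polyline[i, ]; b <- polyline[i + 1L, ]
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    best <- min(best, sqrt(sum((p - (a + t * ab))^2)))
  }
  best
}

# direct weighted normal-equation slope over an index window (oracle)
wls_slope_oracle <- function(z, u, w) {
  X <- cbind(1, z)
  A <- t(X) %*% (w * X)
  b <- t(X) %*% (w * u)
  solve(A, b)[2]
}

small_bilayer_phantom <- function() {
  # 500 um of 16 kPa over 1000 um of 48 kPa at dz = 5 um
  soft <- material_spec("soft", 16, 25)
  stiff <- material_spec("stiff", 48, 30)
  labels <- array(0L, dim = c(4, 4, 300))
  labels[, , 101:300] <- 1L
  phantom_model(labels, list(`0` = soft, `1` = stiff), c(15, 15, 5))
}

tiny_idc_masks <- function() {
  dense <- matrix(FALSE, 100, 100)
  dense[31:70, 31:70] <- TRUE          # 40 x 40 block
  idc <- matrix(FALSE, 100, 100)
  idc[41:60, 41:60] <- TRUE            # nested 20 x 20 block
  list(dense = dense, idc = idc)
}
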