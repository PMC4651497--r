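# Independent oracles used by the tests. These deliberately use different
# algorithms from the package code paths they check.

# Brute-force connected components: voxel-at-a-time stack flood fill over an
# explicit neighbour scan. Returns a list of integer matrices (voxel indices).
oracle_components <- function(bin, connectivity = 26L) {
  dims <- dim(bin)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  ord <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[switch(as.character(connectivity),
                      "6" = ord == 1, "18" = ord >= 1 & ord <= 2,
                      "26" = ord >= 1), ]
  seen <- array(FALSE, dims)
  comps <- list()
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    if (!bin[i, j, k] || seen[i, j, k]) next
    stack <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    comp <- NULL
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      comp <- rbind(comp, v)
      for (o in seq_len(nrow(offs))) {
        w <- v + c(offs$dx[o], offs$dy[o], offs$dz[o])
        if (any(w < 1) || any(w > dims)) next
        if (bin[w[1], w[2], w[3]] && !seen[w[1], w[2], w[3]]) {
          seen[w[1], w[2], w[3]] <- TRUE
          stack[[length(stack) + 1]] <- w
        }
      }
    }
    comps[[length(comps) + 1]] <- comp
  }
  comps
}

# Exact one-sided Wilcoxon signed-rank p by explicit enumeration of all 2^N
# sign assignments (N small, no ties assumed).
oracle_wilcoxon_p_greater <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  sums <- as.vector(signs %*% r)
  mean(sums >= W)
}

# Build a minimal stat-map object around a given one-tailed p array, for
# cluster-extraction tests that need full control over the map.
fake_statmap <- function(p_arr, t_arr = NULL, spacing = c(1, 1, 1)) {
  dims <- dim(p_arr)
  if (is.null(t_arr)) t_arr <- stats::qt(p_arr, df = 10)
  structure(list(t = sq_volume(t_arr, spacing),
                 p = sq_volume(p_arr, spacing),
                 valid = sq_volume(array(!is.na(p_arr), dims), spacing,
                                   type = "mask"),
                 n_controls = 11L, df = 10L),
            class = "sq_statmap")
}

full_mask <- function(dims, spacing = c(1, 1, 1)) {
  sq_volume(array(TRUE, dims), spacing, type = "mask")
}
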