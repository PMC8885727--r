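# shared helpers: small configs, point-set builders, brute-force oracles

test_cfg <- function(...) pipelineConfig(stimFrame = 40L, ...)

rel_err <- function(x, ref) max(abs(x - ref) / pmax(abs(ref), .Machine$double.eps))

# n x 3 Gaussian cluster
gauss_cluster <- function(n, centre, sigma) {
  sweep(matrix(rnorm(n * 3, 0, sigma), n, 3), 2, centre, "+")
}

# brute-force two-sided permutation p for the Spearman correlation:
# recursive enumeration over all orderings, independent of the package path
oracle_spearman_p <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  r_obs <- abs(cor(rx, ry))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  rs <- vapply(perms(ry), function(p) abs(cor(rx, p)), 0)
  mean(rs >= r_obs - 1e-12)
}

# brute-force KS D: sweep every pooled breakpoint
oracle_ks_D <- function(x, y) {
  breaks <- sort(unique(c(x, y)))
  max(vapply(breaks, function(b) abs(mean(x <= b) - mean(y <= b)), 0))
}

# match segmented colour-1 clusters to generating synapses by centroid
match_to_truth <- function(structureSet, trueCentres, maxDist = 1000) {
  cen <- as.matrix(structureSet@synapses[, c("cx", "cy", "cz")])
  vapply(seq_len(nrow(cen)), function(i) {
    d <- sqrt(colSums((t(trueCentres) - cen[i, ])^2))
    if (min(d) <= maxDist) which.min(d) else NA_integer_
  }, 1L)
}
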