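# Shared builders for test fixtures; everything is generated in code.

# A small count cube with explicit counts/person-years. Schemes need at
# least two bins, so a single-column cube borrows the first label of a
# two-bin scheme (the smoothing code never consults the scheme).
toy_cube <- function(y, n, ids = NULL, breaks = NULL) {
  y <- as.matrix(y); n <- as.matrix(n)
  J <- ncol(y)
  if (is.null(breaks)) breaks <- seq(0, by = 10, length.out = max(J, 2))
  scheme <- parse_age_scheme(breaks)
  if (is.null(ids)) ids <- paste0("R", seq_len(nrow(y)))
  dimnames(y) <- dimnames(n) <- list(ids, scheme$labels[seq_len(J)])
  storage.mode(y) <- "integer"
  structure(list(y = y, n = n, region_ids = ids, scheme = scheme),
            class = "count_cube")
}

# A neighborhood dictionary from an explicit named list.
toy_nb <- function(neighbors, rule = "queen") {
  structure(list(neighbors = lapply(neighbors, sort), rule = rule),
            class = "nb_dict")
}

# Random rectilinear tessellation of the unit square by recursive
# guillotine cuts. Produces T-junctions (a vertex of one cell lying in the
# interior of another cell's edge), which stresses the contiguity code
# beyond plain grids.
random_tessellation <- function(n_cells, seed) {
  withr::with_seed(seed, {
    rects <- list(c(0, 0, 1, 1))               # x0, y0, x1, y1
    while (length(rects) < n_cells) {
      k <- sample.int(length(rects), 1,
                      prob = vapply(rects, function(r) (r[3] - r[1]) * (r[4] - r[2]),
                                    numeric(1)))
      r <- rects[[k]]
      if (stats::runif(1) < 0.5) {             # vertical cut
        cut <- stats::runif(1, r[1] + 0.2 * (r[3] - r[1]),
                            r[3] - 0.2 * (r[3] - r[1]))
        rects[[k]] <- c(r[1], r[2], cut, r[4])
        rects[[length(rects) + 1]] <- c(cut, r[2], r[3], r[4])
      } else {                                 # horizontal cut
        cut <- stats::runif(1, r[2] + 0.2 * (r[4] - r[2]),
                            r[4] - 0.2 * (r[4] - r[2]))
        rects[[k]] <- c(r[1], r[2], r[3], cut)
        rects[[length(rects) + 1]] <- c(r[1], cut, r[3], r[4])
      }
    }
    polys <- lapply(rects, function(r)
      list(cbind(c(r[1], r[3], r[3], r[1]), c(r[2], r[2], r[4], r[4]))))
    stats::setNames(polys, paste0("cell", seq_along(polys)))
  })
}

# Independent gamma-quantile oracle: invert the gamma CDF by bisection.
# The bracket tolerance is relative to the bracket's upper end so that the
# tiny lower quantiles of small-shape gammas are resolved too.
bisect_gamma_quantile <- function(p, shape, rate, rel_tol = 1e-13) {
  lo <- 0
  hi <- shape / rate + 1
  while (stats::pgamma(hi, shape, rate) < p) hi <- hi * 2
  while (hi - lo > rel_tol * hi) {
    mid <- (lo + hi) / 2
    if (stats::pgamma(mid, shape, rate) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
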