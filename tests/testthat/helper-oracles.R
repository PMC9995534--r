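# Independent oracles used to validate the package implementations.
# Deliberately naive: literal transcriptions of the rules, with graph
# components from igraph rather than the package's own labeling code.

half_offsets <- function(connectivity) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[m > 0, , drop = FALSE]
  m <- m[m > 0]
  offs <- switch(as.character(connectivity),
                 "6" = offs[m == 1, , drop = FALSE],
                 "18" = offs[m <= 2, , drop = FALSE],
                 offs)
  keep <- offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
    (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0)
  offs[keep, , drop = FALSE]
}

lattice_edges <- function(d, connectivity) {
  idx <- array(seq_len(prod(d)), d)
  offs <- half_offsets(connectivity)
  pairs <- lapply(seq_len(nrow(offs)), function(r) {
    dx <- offs[r, 1]; dy <- offs[r, 2]; dz <- offs[r, 3]
    xs <- max(1, 1 - dx):min(d[1], d[1] - dx)
    ys <- max(1, 1 - dy):min(d[2], d[2] - dy)
    zs <- max(1, 1 - dz):min(d[3], d[3] - dz)
    a <- idx[xs, ys, zs]
    b <- idx[xs + dx, ys + dy, zs + dz]
    cbind(as.vector(a), as.vector(b))
  })
  do.call(rbind, pairs)
}

# flood-fill reference labeling via igraph components
oracle_label_components <- function(active, connectivity = 26, edges = NULL) {
  d <- dim(active)
  if (is.null(edges)) edges <- lattice_edges(d, connectivity)
  keep <- active[edges[, 1]] & active[edges[, 2]]
  g <- igraph::make_empty_graph(prod(d), directed = FALSE)
  g <- igraph::add_edges(g, t(edges[keep, , drop = FALSE]))
  memb <- igraph::components(g)$membership
  lab <- array(0L, d)
  lab[active] <- match(memb[active], unique(memb[active]))
  lab
}

# literal threshold-sum TFCE (positive part only)
oracle_tfce_pos <- function(stat, mask = NULL, H = 2, E = 0.5, dh,
                            connectivity = 26, edges = NULL) {
  d <- dim(stat)
  if (is.null(mask)) mask <- array(TRUE, d)
  if (is.null(edges)) edges <- lattice_edges(d, connectivity)
  out <- array(0, d)
  vmax <- max(stat[mask], 0)
  nst <- floor(vmax / dh + 1e-12)
  for (k in seq_len(nst)) {
    h <- k * dh
    act <- mask & stat >= h
    if (!any(act)) next
    lab <- oracle_label_components(act, connectivity, edges)
    sizes <- tabulate(lab[act])
    out[act] <- out[act] + sizes[lab[act]]^E * h^H * dh
  }
  out
}

# literal transcription of the plateau rule: last-50 mean and SD, first
# index whose next n_consec values stay inside the 2-SD band
oracle_plateau <- function(x, n_last = 50, n_consec = 9, k_sd = 2) {
  n <- length(x)
  tailv <- x[(n - n_last + 1):n]
  p <- mean(tailv)
  s <- sd(tailv)
  step <- NA_integer_
  for (k in seq_len(n - n_consec + 1)) {
    w <- x[k:(k + n_consec - 1)]
    if (all(abs(w - p) <= k_sd * s)) {
      step <- k
      break
    }
  }
  list(plateau = p, step = step)
}

# small helper: a cohort-free stack of pure-noise maps
make_noise_stack <- function(n, d, sd = 1) {
  mask <- array(TRUE, d)
  cohort_stack(matrix(rnorm(n * prod(d), 0, sd), n, prod(d)), mask)
}
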