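# Independent oracles used to pin the numerical conventions.

# Dense diffusion-map oracle: builds the row-stochastic Markov matrix
# explicitly and diagonalizes it with the general (nonsymmetric) solver --
# a different code path from the symmetric-conjugate implementation.
oracle_diffusion <- function(a, alpha = 0.5, n_components = 3) {
  a <- unclass(as.matrix(a))
  q <- rowSums(a)
  w <- a / outer(q^alpha, q^alpha)
  m <- w / rowSums(w)
  e <- eigen(m)
  ord <- order(Re(e$values), decreasing = TRUE)
  vals <- Re(e$values)[ord]
  vecs <- Re(e$vectors)[, ord, drop = FALSE]
  vecs <- vecs / vecs[, 1]
  keep <- 1 + seq_len(n_components)
  comps <- vecs[, keep, drop = FALSE] *
    rep(vals[keep] / (1 - vals[keep]), each = nrow(m))
  list(eigenvalues = vals[keep], components = comps)
}

# Definitional step-up Benjamini-Hochberg: q_(i) = min(1, min_{j>=i} n p_(j)/j)
oracle_bh <- function(p) {
  n <- length(p)
  sp <- sort(p)
  qs <- vapply(seq_len(n),
               function(i) min(1, min(n * sp[i:n] / (i:n))),
               numeric(1))
  qs[match(p, sp)]
}

# random symmetric nonnegative affinity with unit diagonal and connected graph
random_affinity <- function(n) {
  m <- matrix(runif(n * n, 0.05, 1), n)
  a <- (m + t(m)) / 2
  diag(a) <- 1
  a
}

# small noise-free planted study used by several recovery tests
tiny_planted_study <- function(n_voxels = 200, n_parcels = 60, k = 2,
                               snr = Inf, seed = 1) {
  dom <- make_voxel_domain(n_voxels, nuclei = 4, voxel_size = 2, seed = seed)
  par <- make_parcel_set(n_parcels, 7, seed = seed)
  cort <- plant_cortical_connectivity(par, k = k,
                                      weights = 3 / seq_len(k),
                                      noise_sd = 0, seed = seed)
  axes <- diag(3)[seq_len(k), , drop = FALSE]
  pulv <- plant_pulvinar_connectivity(dom, par, cort$cortical_gradients,
                                      axes, snr = snr, seed = seed)
  list(domain = dom, parcels = par, cortical = cort, pulvinar = pulv)
}

# embed a voxel-by-parcel connectome directly (cosine affinity route)
embed_connectome <- function(w, n_components = 4, alpha = 0.5) {
  diffusion_embedding(cosine_affinity(as.matrix(w)), alpha = alpha,
                      n_components = n_components)
}

# match recovered gradients to planted axes by maximum |r|
match_axes <- function(components, axes) {
  cm <- abs(cor(components, axes))
  idx <- apply(cm, 2, which.max)
  data.frame(axis = seq_len(ncol(axes)), gradient = idx,
             abs_r = cm[cbind(idx, seq_len(ncol(axes)))])
}
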