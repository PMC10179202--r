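# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the default run stays fast.

# smooth soft-edged sphere, centred on the projection/FFT centre convention
make_sphere_volume <- function(size = 64, radius = size * 0.28,
                               edge = 1.5) {
  ax <- seq_len(size) - 1 - size / 2
  r <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
  new_volume(1 / (1 + exp((r - radius) / edge)), voxel_size = 1)
}

# tiny heterogeneous stack for plumbing tests
make_tiny_stack <- function(K = 2, per_class = 12, size = 32, snr = 1,
                            seed = 42) {
  vols <- lapply(seq_len(K) - 1L, function(c)
    make_phantom_volume(c, size, num_blobs = 8, separation = 1, seed = seed))
  cfg <- simulation_config(num_classes = K, images_per_class = per_class,
                           snr = snr, seed = seed)
  build_heterogeneous_stack(vols, cfg)
}

# exhaustive permutation matrix (rows = all orderings of 1..n)
all_perms <- function(n) {
  if (n == 1) return(matrix(1))
  do.call(rbind, lapply(seq_len(n), function(i) {
    p <- all_perms(n - 1)
    cbind(i, ifelse(p >= i, p + 1, p))
  }))
}

# brute-force matched accuracy by enumerating cluster-to-class assignments
accuracy_by_enumeration <- function(pred, truth) {
  pl <- sort(unique(pred)); tl <- sort(unique(truth))
  K <- max(length(pl), length(tl))
  tab <- matrix(0, K, K)
  for (a in seq_along(pl)) for (b in seq_along(tl))
    tab[a, b] <- sum(pred == pl[a] & truth == tl[b])
  pm <- all_perms(K)
  max(apply(pm, 1, function(p) sum(tab[cbind(seq_len(K), p)]))) / length(truth)
}
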