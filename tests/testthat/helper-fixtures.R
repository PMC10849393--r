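# small shared fixtures; everything is generated in code
tiny_geometry <- function(n_axons = 6, n_branches = 2) {
  build_geometry(n_axons = n_axons, synapses_per_axon = 10,
                 n_branches = n_branches)
}

quiet_params <- function(...) spine_params(noise_sd = 0, ...)

# brute-force pairwise kernel sum, the independent O(n^2) oracle for the
# bilinear model
brute_overlap <- function(kernel, pre, post) {
  tot <- 0
  for (tp in post$times) {
    for (tq in pre$times) {
      tot <- tot + eval_kernel(kernel, (tp - tq) * 1000)
    }
  }
  tot
}

# a smooth bump kernel used for planted-recovery and oracle tests
bump_kernel <- function() {
  grid <- seq(-50, 50, by = 1)
  make_kernel(grid, interior = exp(-(grid - 7)^2 / 50))
}
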