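# Shared fixtures, built in code at test time.

# small scene used by several files; memoised per session
small_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_field(scene_config(image_size = c(160, 160),
                                            n_cells = 4,
                                            mitolysosomes_per_cell = 3,
                                            rng_seed = 101))
    cache
  }
})

# background-corrected channels + mito mask for a field
corrected_channels <- function(field, seg = seg_config()) {
  list(green = subtract_background(field$green, seg),
       red = subtract_background(field$red, seg))
}

# disc mask centred in an n x n frame
disc_mask <- function(n, radius, centre = c((n + 1) / 2, (n + 1) / 2)) {
  rr <- matrix(rep(seq_len(n), n), n, n)
  cc <- t(rr)
  (rr - centre[1])^2 + (cc - centre[2])^2 <= radius^2
}

# MITAB-dialect row for one interaction
mitab_row <- function(a, b) {
  sprintf(paste0("entrez gene/locuslink:%s\tentrez gene/locuslink:%s\t",
                 "biogrid:1|entrez gene/locuslink:%s\t",
                 "biogrid:2|entrez gene/locuslink:%s\t-\t-"), a, b, a, b)
}
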