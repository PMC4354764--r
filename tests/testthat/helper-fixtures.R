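# small programmatic fixtures shared across test files

# a series whose subtraction image has a bright block on a dim background
block_series <- function(size = 12, block_rows = 4:8, block_cols = 4:8,
                         bg_post = 20, block_post = 220, pre = 10,
                         speck = NULL, n_phases = 9) {
  arr <- array(pre, dim = c(n_phases, size, size))
  for (t in 2:n_phases) {
    arr[t, , ] <- bg_post
    arr[t, block_rows, block_cols] <- block_post
    if (!is.null(speck)) arr[t, speck[1], speck[2]] <- block_post
  }
  dce_series(arr)
}

full_roi <- function(size = 12) mask_image(matrix(TRUE, size, size), "roi")

# series where every pixel shares one curve
uniform_series <- function(values, size = 8) {
  arr <- array(rep(values, size * size), dim = c(length(values), size, size))
  dce_series(arr)
}
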