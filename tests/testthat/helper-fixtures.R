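# Shared fixture builders; everything is generated in code at test time.

meta_popc <- function(id = "S1", compound = "CONTROL", rep = 1L,
                      probe = "DI8ANEPPS", ...) {
  sample_meta(id, "POPC", compound, rep, probe = probe, ...)
}

# flat spectrum on the acquisition grid
const_spectrum <- function(value, id = "S1", is_blank = FALSE) {
  grid <- seq(400, 625, by = 1)
  spectrum(grid, rep(value, length(grid)),
           sample_meta(id, "POPC", is_blank = is_blank))
}

# independent direct-summation oracle for the reconvolved curve: treats each
# IRF channel as a point mass at its center and integrates the decay law
# over every lag bin by Simpson quadrature -- no FFT, no closed forms shared
# with the implementation
oracle_reconvolution <- function(alphas, taus, irf, width, n_channels,
                                 background = 0, nsub = 21L) {
  kern <- irf / sum(irf)
  model_f <- function(t) {
    out <- numeric(length(t))
    pos <- t >= 0
    for (i in seq_along(alphas)) {
      out[pos] <- out[pos] + alphas[i] * exp(-t[pos] / taus[i])
    }
    out
  }
  # Simpson bin average of the decay law over each lag window; the quadrature
  # domain is clipped to t >= 0 so the causality kink never sits inside a
  # Simpson panel
  lagavg <- vapply(seq_len(n_channels), function(k) {
    a <- (k - 1) * width - width / 2
    b <- a + width
    lo <- max(a, 0)
    if (b <= 0) return(0)
    x <- seq(lo, b, length.out = nsub)
    y <- model_f(x)
    wts <- c(1, rep(c(4, 2), length.out = nsub - 2), 1)
    h <- (b - lo) / (nsub - 1)
    (h / 3) * sum(wts * y) / width
  }, 0)
  out <- numeric(n_channels)
  for (j in seq_len(n_channels)) {
    i <- seq_len(j)
    out[j] <- sum(kern[i] * lagavg[j - i + 1])
  }
  out + background
}

# deterministic small manifest CSV written by hand
write_toy_manifest <- function(dir, rows) {
  path <- file.path(dir, "manifest.csv")
  writeLines(c("sample_id,kind,lipid_system,compound,replicate,probe,compound_conc_uM,blank_id,is_blank,file",
               rows), path)
  path
}
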