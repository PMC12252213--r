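# shared fixture builders (everything is generated in code; no binary data)

# tiny deterministic raster: values 1..(nr*nc) filled by row from the north
toy_raster <- function(nr = 4, nc = 5, cellsize = 1, xll = 0, yll = 0,
                       name = "toy", values = NULL) {
  v <- if (is.null(values)) matrix(seq_len(nr * nc), nr, nc, byrow = TRUE)
       else values
  new_raster(v, grid_spec(nc, nr, xll, yll, cellsize), name)
}

# two-layer aligned stack with known values
toy_stack <- function(nr = 4, nc = 5) {
  assemble_stack(list(
    toy_raster(nr, nc, name = "a"),
    toy_raster(nr, nc, name = "b",
               values = matrix(rev(seq_len(nr * nc)), nr, nc, byrow = TRUE))))
}

# small presence/background problem with a single informative variable:
# presence x drawn from the upper range of background x
toy_pb <- function(n_pres = 40, n_bg = 300, seed = 7, informative = TRUE) {
  withr::with_seed(seed, {
    bg <- tibble::tibble(x = runif(n_bg, 0, 10), z = runif(n_bg, 0, 5))
    pres <- tibble::tibble(
      x = if (informative) runif(n_pres, 6, 10) else runif(n_pres, 0, 10),
      z = runif(n_pres, 0, 5))
    list(pres = pres, bg = bg)
  })
}

# default-condition synthetic dataset, shared by several tests via memoisation
default_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 101) {
    key <- as.character(seed)
    if (!is.null(cache[[key]])) return(cache[[key]])
    cfg <- generator_config(seed = seed)
    st <- gen_env_stack(cfg)
    suit <- true_suitability(st, cfg)
    occ <- sample_presences(suit, cfg$n_presences, seed = seed + 1)
    pres <- extract_at_points(occ, st)
    pres <- pres[!pres$nodata, , drop = FALSE]
    bg <- sample_background(st, 10000, seed = seed + 2)
    cache[[key]] <- list(cfg = cfg, stack = st, suit = suit, occ = occ,
                         pres = pres, bg = bg)
    cache[[key]]
  }
})
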