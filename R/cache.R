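# Package-local memo cache for grid-sized constants (polar coordinates,
# Zernike basis rasters, propagation transfer functions). Entries are keyed
# by the full parameter set; large-grid entries (> 1024 px) are not cached
# to bound memory.

.sadhm_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder, cache_if = TRUE) {
  if (!cache_if) return(builder())
  val <- .sadhm_cache[[key]]
  if (is.null(val)) {
    val <- builder()
    .sadhm_cache[[key]] <- val
  }
  val
}

#' Clear sadhm's internal memo cache
#'
#' Drops cached polar grids, basis rasters and propagation kernels (they are
#' rebuilt on demand).
#'
#' @return invisibly, the number of entries dropped.
#' @export
clear_sadhm_cache <- function() {
  n <- length(ls(.sadhm_cache))
  rm(list = ls(.sadhm_cache), envir = .sadhm_cache)
  invisible(n)
}
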