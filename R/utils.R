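# Internal helpers: deterministic per-component RNG streams and provenance.

#' Derive a reproducible sub-seed for a named component
#'
#' One root seed drives every generator in the package; each component
#' (sequence, mutations, annotation tracks, ...) draws from its own stream
#' whose seed is a stable hash of the component name mixed with the root
#' seed. Streams therefore do not cross-contaminate when one component's
#' consumption changes.
#'
#' @param seed integer root seed.
#' @param component character scalar naming the stream.
#' @return An integer in [1, 2^31 - 2], usable with [set.seed()].
#' @examples
#' componentSeed(1L, "mutations")
#' @export
componentSeed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(component))
  m <- 2147483629                       # prime < 2^31
  h <- 5381
  for (b in utf8ToInt(component)) h <- (h * 33 + b) %% m
  as.integer((h + (abs(as.numeric(seed)) %% m) * 48271) %% m + 1)
}

# Evaluate expr under a local RNG state seeded from (seed, component);
# the caller's RNG state is restored afterwards.
withStream <- function(seed, component, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(componentSeed(seed, component))
  expr
}

# FNV-1a hash of a character scalar, as 8 hex digits (provenance headers).
fnv1a <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(x)) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

# Provenance header lines written at the top of every output file.
provenanceHeader <- function(seed = NA, extra = character()) {
  c(sprintf("# hotspotErosion %s", as.character(packageVersion("hotspotErosion"))),
    sprintf("# seed=%s", as.character(seed)),
    if (length(extra)) paste0("# ", extra))
}

writeTsvWithHeader <- function(df, path, seed = NA, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenanceHeader(seed, extra), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
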